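# Catalytic-loop location and RD / non-RD / ACF classification of
# kinase domains, summarised per subfamily clade.

#' Locate the catalytic loop across an alignment
#'
#' The catalytic loop is anchored on a reference row known to carry the
#' conserved His-Arg-Asp (HRD) tripeptide: the alignment columns of the
#' reference's H, R and D are projected onto every row and the residues
#' at those columns are read off. This replaces de-novo motif discovery,
#' which is unnecessary when the target motif is known a priori.
#'
#' @param aln An `"aa_alignment"`.
#' @param reference_id Row id whose ungapped sequence contains a literal
#'   `"HRD"` run (the first run is used).
#' @return Data frame with one row per alignment row: `protein_id`,
#'   `H_col`, `R_col`, `D_col` (alignment column indices) and
#'   `h_residue`, `r_residue`, `d_residue` (residue or `"-"`).
#' @export
locate_catalytic_loop <- function(aln, reference_id) {
  stopifnot(inherits(aln, "aa_alignment"))
  if (!reference_id %in% names(aln))
    stop("reference id ", reference_id, " not in alignment")
  ref <- str_chars(aln[[reference_id]])
  nong <- which(ref != "-")
  ungapped <- paste(ref[nong], collapse = "")
  pos <- regexpr("HRD", ungapped, fixed = TRUE)[1]
  if (pos < 0)
    stop("reference ", reference_id,
         " lacks an HRD run; choose another anchor sequence")
  cols <- nong[pos:(pos + 2L)]
  m <- aln_matrix(aln)
  data.frame(protein_id = rownames(m),
             H_col = cols[1], R_col = cols[2], D_col = cols[3],
             h_residue = m[, cols[1]],
             r_residue = m[, cols[2]],
             d_residue = m[, cols[3]],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Classify catalytic loops as RD, non-RD or ACF
#'
#' A kinase is `RD` when the catalytic aspartate is present and the
#' preceding position holds the conserved arginine; `nonRD` when the
#' aspartate is present but the arginine is replaced (the substituting
#' residue is recorded; a gap at the arginine position also counts as
#' absence of R and is flagged in `r_gap`); and `ACF` (alternative
#' catalytic function) when the catalytic aspartate itself is absent.
#'
#' @param loops Result of [locate_catalytic_loop()].
#' @return Data frame `protein_id`, `motif_class` (`RD`/`nonRD`/`ACF`),
#'   `r_residue`, `r_gap`.
#' @export
classify_rd_motif <- function(loops) {
  d_ok <- loops$d_residue == "D"
  r <- loops$r_residue
  cls <- ifelse(!d_ok, "ACF", ifelse(r == "R", "RD", "nonRD"))
  data.frame(protein_id = loops$protein_id,
             motif_class = cls,
             r_residue = r,
             r_gap = d_ok & r == "-",
             stringsAsFactors = FALSE)
}

#' Summarise motif classes per subfamily group
#'
#' @param calls Result of [classify_rd_motif()].
#' @param assignment Named vector tip -> group (e.g. from
#'   [assign_subfamily_groups()]); ids absent from it are grouped as
#'   `"unassigned"`.
#' @return Data frame per group x class: `group`, `motif_class`, `n`,
#'   `fraction` (within group) and `residues`, the spectrum observed at
#'   the arginine position (e.g. `"C:5,G:2"`).
#' @export
summarize_motifs <- function(calls, assignment) {
  grp <- unname(assignment[calls$protein_id])
  grp[is.na(grp)] <- "unassigned"
  out <- list()
  for (g in sort(unique(grp))) {
    sub <- calls[grp == g, , drop = FALSE]
    for (cl in c("RD", "nonRD", "ACF")) {
      s2 <- sub[sub$motif_class == cl, , drop = FALSE]
      spec <- ""
      if (nrow(s2)) {
        tb <- sort(table(s2$r_residue), decreasing = TRUE)
        spec <- paste(sprintf("%s:%d", names(tb), as.integer(tb)), collapse = ",")
      }
      out[[length(out) + 1L]] <- data.frame(
        group = g, motif_class = cl, n = nrow(s2),
        fraction = if (nrow(sub)) nrow(s2) / nrow(sub) else 0,
        residues = spec, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
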