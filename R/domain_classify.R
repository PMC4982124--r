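# Retrieval of kinases, TM kinases and LRR-RLKs from a domain-annotation
# table, and extraction of (possibly merged) kinase-domain units.

#' Load a proteome with its gene models and domain annotations
#'
#' Reads a proteome FASTA, an optional GFF3 of gene models (gene/mRNA/CDS
#' features whose mRNA rows carry a `primary=true|false` attribute) and a
#' tab-separated domain table (`protein_id`, `accession`, `start`, `end`;
#' 1-based inclusive protein coordinates). Domain rows are validated
#' against the protein lengths and malformed rows are reported with their
#' line number.
#'
#' @param proteome_fasta Path to the proteome FASTA.
#' @param gff_file Optional path to the GFF3; when `NULL`, every protein
#'   is treated as the primary transcript of its own gene.
#' @param domain_tsv Path to the domain table.
#' @param species Species identifier attached to every record.
#' @return A list with `proteins` (data frame: `protein_id`, `gene_id`,
#'   `species`, `is_primary`, `sequence`), `domains` (data frame:
#'   `protein_id`, `accession`, `start`, `end`) and `loci` (data frame of
#'   gene coordinates, or `NULL` without a GFF3).
#' @export
load_annotated_proteome <- function(proteome_fasta, gff_file = NULL, domain_tsv,
                                    species = "unknown") {
  seqs <- read_fasta(proteome_fasta)
  if (anyDuplicated(names(seqs)))
    stop("duplicate protein ids in ", proteome_fasta)

  if (!is.null(gff_file)) {
    g <- as.data.frame(rtracklayer::import(gff_file))
    mrna <- g[g$type == "mRNA", , drop = FALSE]
    gene <- g[g$type == "gene", , drop = FALSE]
    parent <- vapply(mrna$Parent, function(p) as.character(p)[1], character(1))
    proteins <- data.frame(
      protein_id = mrna$ID,
      gene_id = parent,
      species = species,
      is_primary = tolower(ifelse(is.na(mrna$primary), "true", mrna$primary)) == "true",
      stringsAsFactors = FALSE)
    missing <- setdiff(proteins$protein_id, names(seqs))
    if (length(missing))
      stop("mRNA ids absent from proteome FASTA: ", paste(head(missing, 5), collapse = ", "))
    proteins$sequence <- unname(seqs[proteins$protein_id])
    loci <- data.frame(gene_id = gene$ID,
                       chromosome = as.character(gene$seqnames),
                       start = gene$start, end = gene$end,
                       strand = as.character(gene$strand),
                       stringsAsFactors = FALSE)
  } else {
    proteins <- data.frame(protein_id = names(seqs), gene_id = names(seqs),
                           species = species, is_primary = TRUE,
                           sequence = unname(seqs), stringsAsFactors = FALSE)
    loci <- NULL
  }

  domains <- read_tsv(domain_tsv)
  req <- c("protein_id", "accession", "start", "end")
  if (!all(req %in% names(domains)))
    stop("domain table must have columns: ", paste(req, collapse = ", "))
  domains <- domains[, req, drop = FALSE]
  if (nrow(domains)) {
    unknown <- !domains$protein_id %in% names(seqs)
    if (any(unknown))
      stop("domain table row(s) ", paste(head(which(unknown) + 1L, 5), collapse = ", "),
           ": protein id not in proteome FASTA")
    plen <- nchar(seqs)[domains$protein_id]
    bad <- which(domains$start < 1L | domains$start > domains$end |
                   domains$end > plen)
    if (length(bad))
      stop("domain table row(s) ", paste(head(bad + 1L, 5), collapse = ", "),
           ": coordinates outside protein length")
  }
  list(proteins = proteins, domains = domains, loci = loci)
}

#' Keep one primary transcript per gene
#'
#' Alternative splice variants are excluded from all analyses: for every
#' gene the primary-flagged transcript is retained. A gene with no
#' primary flag keeps its longest transcript, with a warning.
#'
#' @param proteins Protein data frame as from [load_annotated_proteome()].
#' @return The filtered protein data frame, one row per `gene_id`.
#' @export
filter_primary_transcripts <- function(proteins) {
  if (!nrow(proteins)) return(proteins)
  keep <- unlist(lapply(split(seq_len(nrow(proteins)), proteins$gene_id), function(ix) {
    prim <- ix[proteins$is_primary[ix]]
    if (length(prim) >= 1L) return(prim[1L])
    warning("gene ", proteins$gene_id[ix[1]],
            " has no primary transcript; keeping the longest", call. = FALSE)
    ix[which.max(nchar(proteins$sequence[ix]))]
  }))
  out <- proteins[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify proteins into the kinase / TM-kinase / LRR-RLK funnel
#'
#' Assigns each protein the deepest tier of the nested classification:
#' `kinase` (any kinase-domain hit), `TM-kinase` (kinase plus at least one
#' transmembrane helix; receptor-like cytoplasmic kinases fail here) and
#' `LRR-RLK` (kinase, TM and at least one leucine-rich-repeat domain).
#' Proteins without a kinase hit are tier `none` regardless of other
#' domains.
#'
#' @param proteins Protein data frame (usually primary transcripts only).
#' @param domains Domain annotation data frame.
#' @param lrr_accessions,kinase_accessions,tm_accession Accession sets
#'   defining the three diagnostic domain classes; the defaults are the
#'   Pfam kinase pair PF00069/PF07714, the 11 Pfam LRR accessions, and
#'   the reserved `TMHELIX` accession.
#' @return Data frame `protein_id`, `tier` (factor with levels
#'   `none < kinase < TM-kinase < LRR-RLK`).
#' @export
classify_proteins <- function(proteins, domains,
                              lrr_accessions = LRR_ACCESSIONS,
                              kinase_accessions = KINASE_ACCESSIONS,
                              tm_accession = TM_ACCESSION) {
  stopifnot(length(lrr_accessions) > 0, length(kinase_accessions) > 0,
            length(tm_accession) > 0)
  has <- function(acc) proteins$protein_id %in%
    unique(domains$protein_id[domains$accession %in% acc])
  kin <- has(kinase_accessions)
  tm <- has(tm_accession)
  lrr <- has(lrr_accessions)
  tier <- rep("none", nrow(proteins))
  tier[kin] <- "kinase"
  tier[kin & tm] <- "TM-kinase"
  tier[kin & tm & lrr] <- "LRR-RLK"
  data.frame(protein_id = proteins$protein_id,
             tier = factor(tier, levels = c("none", "kinase", "TM-kinase", "LRR-RLK")),
             stringsAsFactors = FALSE)
}

#' Count the classification funnel
#'
#' @param classified Result of [classify_proteins()].
#' @return Named vector of cumulative tier counts (`kinase` includes
#'   TM-kinases and LRR-RLKs, etc.), mirroring the nested tiers of a
#'   domain-architecture survey table.
#' @export
classification_funnel <- function(classified) {
  t <- classified$tier
  c(proteins = length(t),
    kinase = sum(t %in% c("kinase", "TM-kinase", "LRR-RLK")),
    tm_kinase = sum(t %in% c("TM-kinase", "LRR-RLK")),
    lrr_rlk = sum(t == "LRR-RLK"))
}

#' Extract kinase-domain units, merging truncated hits
#'
#' Some proteins carry more than one raw kinase-domain hit, either
#' because a single catalytic domain was annotated as two truncated
#' fragments or because the protein genuinely has tandem kinase domains.
#' Overlapping hits are unioned. Two consecutive hits are merged into one
#' unit iff the gap between them is at most `merge_gap_max` and the
#' merged span does not exceed `merged_len_max` (a typical protein-kinase
#' domain is ~250-300 aa; the default cap keeps a merged unit below 1.5x
#' that); otherwise they are kept as separate units.
#'
#' @param proteins Protein data frame.
#' @param domains Domain annotation data frame.
#' @param kinase_accessions Accessions counting as kinase-domain hits.
#' @param merge_gap_max Maximum inter-hit gap (aa) for merging.
#' @param merged_len_max Maximum merged span (aa).
#' @return Data frame of kinase-domain units: `protein_id`, `unit_index`,
#'   `start`, `end`, `sequence`, `merged_from`.
#' @export
extract_kinase_domains <- function(proteins, domains,
                                   kinase_accessions = KINASE_ACCESSIONS,
                                   merge_gap_max = 100L, merged_len_max = 450L) {
  hits <- domains[domains$accession %in% kinase_accessions, , drop = FALSE]
  hits <- hits[hits$protein_id %in% proteins$protein_id, , drop = FALSE]
  if (!nrow(hits))
    return(data.frame(protein_id = character(), unit_index = integer(),
                      start = integer(), end = integer(), sequence = character(),
                      merged_from = integer(), stringsAsFactors = FALSE))
  seqs <- setNames(proteins$sequence, proteins$protein_id)
  out <- list()
  for (pid in unique(hits$protein_id)) {
    h <- hits[hits$protein_id == pid, , drop = FALSE]
    h <- h[order(h$start, h$end), , drop = FALSE]
    # union overlapping raw hits first
    iv <- list(c(h$start[1], h$end[1], 1L))
    if (nrow(h) > 1L) for (i in 2:nrow(h)) {
      last <- iv[[length(iv)]]
      if (h$start[i] <= last[2]) { # overlap: take the union
        iv[[length(iv)]] <- c(last[1], max(last[2], h$end[i]), last[3] + 1L)
      } else iv[[length(iv) + 1L]] <- c(h$start[i], h$end[i], 1L)
    }
    # merge truncated fragments under the gap/span rule
    units <- list(iv[[1]])
    if (length(iv) > 1L) for (i in 2:length(iv)) {
      last <- units[[length(units)]]
      gap <- iv[[i]][1] - last[2] - 1L
      span <- iv[[i]][2] - last[1] + 1L
      if (gap <= merge_gap_max && span <= merged_len_max) {
        units[[length(units)]] <- c(last[1], iv[[i]][2], last[3] + iv[[i]][3])
      } else units[[length(units) + 1L]] <- iv[[i]]
    }
    for (u in seq_along(units)) {
      v <- units[[u]]
      out[[length(out) + 1L]] <- data.frame(
        protein_id = pid, unit_index = u, start = v[1], end = v[2],
        sequence = substr(seqs[[pid]], v[1], v[2]), merged_from = v[3],
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
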