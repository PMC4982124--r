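# Kinase-domain multiple alignment and the pre-phylogeny filters:
# short-sequence removal, gap-column trimming, redundancy reduction.

#' Construct an alignment object
#'
#' An alignment is a named character vector of equal-length gapped
#' amino-acid strings with class `"aa_alignment"`.
#'
#' @param rows Named character vector of gapped sequences.
#' @return An `"aa_alignment"` object.
#' @export
as_alignment <- function(rows) {
  stopifnot(is.character(rows), length(rows) >= 1L, !is.null(names(rows)))
  if (length(unique(nchar(rows))) != 1L)
    stop("alignment rows must all have equal length")
  if (any(grepl("^-*$", rows))) stop("alignment contains an all-gap row")
  structure(rows, class = "aa_alignment")
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat(sprintf("Amino-acid alignment: %d rows x %d columns\n",
              length(x), nchar(x[[1]])))
  invisible(x)
}

# Character matrix view of an alignment (rows = sequences).
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(unclass(aln), "", fixed = TRUE))
  rownames(m) <- names(aln)
  m
}

# Residue-frequency profile (20 x L); gap mass is simply absent, so
# gap-rich columns score low against everything.
profile_of <- function(mat) {
  L <- ncol(mat)
  p <- matrix(0, nrow = length(AA_ALPHABET), ncol = L,
              dimnames = list(AA_ALPHABET, NULL))
  n <- nrow(mat)
  for (a in AA_ALPHABET) p[a, ] <- colSums(mat == a) / n
  p
}

# Fractional common k-mer distance used for the guide tree.
kmer_distance_matrix <- function(seqs, k = 3L) {
  kmers <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(table(character()))
    table(substring(s, 1:(n - k + 1L), k:n))
  })
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ti <- kmers[[i]]; tj <- kmers[[j]]
    shared <- sum(pmin(ti[names(tj)[names(tj) %in% names(ti)]],
                       tj[names(tj) %in% names(ti)]))
    denom <- max(1L, min(sum(ti), sum(tj)))
    d[i, j] <- d[j, i] <- 1 - shared / denom
  }
  d
}

#' Progressive multiple alignment of amino-acid sequences
#'
#' Builds a guide tree from fractional common k-mer distances
#' (average-linkage clustering) and merges sequences and profiles along
#' it by global dynamic programming with affine gap costs over
#' profile-profile substitution scores. A gap run of length L costs
#' `gap_open + L * gap_extend`. Deterministic for a fixed input order.
#'
#' @param sequences Named character vector of ungapped amino-acid
#'   sequences (a single sequence is returned unchanged as a one-row
#'   alignment).
#' @param gap_open,gap_extend Affine gap scores (negative).
#' @param substitution_matrix Residue substitution score matrix; default
#'   BLOSUM62.
#' @return An `"aa_alignment"`; attribute `"score"` carries the final
#'   profile-merge DP score.
#' @export
progressive_align <- function(sequences, gap_open = -10, gap_extend = -1,
                              substitution_matrix = NULL) {
  if (length(sequences) < 1L) stop("no sequences to align")
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq", seq_along(sequences))
  if (length(sequences) == 1L) return(as_alignment(sequences))
  S <- substitution_matrix %||% blosum62()
  S <- S[AA_ALPHABET, AA_ALPHABET]

  merge_two <- function(rows1, rows2) {
    m1 <- do.call(rbind, strsplit(rows1, "", fixed = TRUE))
    m2 <- do.call(rbind, strsplit(rows2, "", fixed = TRUE))
    C <- crossprod(profile_of(m1), S %*% profile_of(m2))
    res <- affine_align_path(C, gap_open, gap_extend)
    apply_path <- function(rows, mat, path) {
      out <- matrix("-", nrow = nrow(mat), ncol = length(path))
      nz <- path != 0L
      out[, nz] <- mat[, path[nz], drop = FALSE]
      setNames(apply(out, 1L, paste, collapse = ""), names(rows))
    }
    out <- c(apply_path(rows1, m1, res$path1), apply_path(rows2, m2, res$path2))
    attr(out, "score") <- res$score
    out
  }

  d <- kmer_distance_matrix(sequences)
  hc <- hclust(as.dist(d), method = "average")
  nodes <- vector("list", nrow(hc$merge))
  leaf <- function(i) setNames(sequences[i], names(sequences)[i])
  score <- NA_real_
  for (s in seq_len(nrow(hc$merge))) {
    a <- hc$merge[s, 1]; b <- hc$merge[s, 2]
    ra <- if (a < 0) leaf(-a) else nodes[[a]]
    rb <- if (b < 0) leaf(-b) else nodes[[b]]
    nodes[[s]] <- merge_two(ra, rb)
    score <- attr(nodes[[s]], "score")
  }
  final <- nodes[[nrow(hc$merge)]]
  final <- final[names(sequences)] # restore input row order
  structure(as_alignment(final), score = score)
}

#' Remove short sequences
#'
#' Sequences shorter than `min_len` residues (strictly) are removed
#' before alignment-based analyses.
#'
#' @param sequences Named character vector.
#' @param min_len Minimum length in amino acids.
#' @return The retained sequences; removed ids in attribute `"removed"`.
#' @export
filter_short <- function(sequences, min_len = 100L) {
  drop <- nchar(sequences) < min_len
  out <- sequences[!drop]
  if (any(drop))
    message("filter_short: removed ", sum(drop), " sequence(s): ",
            paste(names(sequences)[drop], collapse = ", "))
  attr(out, "removed") <- names(sequences)[drop]
  out
}

#' Remove gap-rich alignment columns
#'
#' Columns whose gap fraction exceeds `max_gap_fraction` are removed;
#' row order is preserved and the provenance of kept columns is
#' returned.
#'
#' @param aln An `"aa_alignment"`.
#' @param max_gap_fraction Columns with gap fraction strictly above this
#'   are removed.
#' @return Trimmed `"aa_alignment"`; attribute `"kept_columns"` maps new
#'   columns to original indices, attribute `"report"` tabulates every
#'   column's gap fraction and fate.
#' @export
trim_gap_columns <- function(aln, max_gap_fraction = 0.9) {
  stopifnot(inherits(aln, "aa_alignment"))
  m <- aln_matrix(aln)
  gf <- colMeans(m == "-")
  keep <- which(gf <= max_gap_fraction)
  if (!length(keep))
    stop("degenerate alignment: every column exceeds the gap-fraction threshold")
  out <- apply(m[, keep, drop = FALSE], 1L, paste, collapse = "")
  structure(as_alignment(setNames(out, names(aln))),
            kept_columns = keep,
            report = data.frame(column = seq_along(gf), gap_fraction = gf,
                                kept = seq_along(gf) %in% keep))
}

#' Percent identity between two sequences
#'
#' Global pairwise alignment (BLOSUM62, affine gaps), identity computed
#' over alignment columns excluding terminal gap runs.
#'
#' @param a,b Amino-acid strings.
#' @return Percent identity in `[0, 100]`.
#' @export
pairwise_identity <- function(a, b) {
  pa <- Biostrings::pairwiseAlignment(Biostrings::AAString(a), Biostrings::AAString(b),
                                      substitutionMatrix = blosum62(),
                                      gapOpening = 10, gapExtension = 1,
                                      type = "global")
  identity_from_aligned(as.character(Biostrings::alignedPattern(pa)),
                        as.character(Biostrings::alignedSubject(pa)))
}

identity_from_aligned <- function(sa, sb) {
  ca <- str_chars(sa); cb <- str_chars(sb)
  nga <- which(ca != "-"); ngb <- which(cb != "-")
  lo <- max(min(nga), min(ngb)); hi <- min(max(nga), max(ngb))
  if (hi < lo) return(0)
  w <- lo:hi
  100 * sum(ca[w] == cb[w] & ca[w] != "-") / length(w)
}

#' Reduce sequence-set redundancy by pairwise identity
#'
#' Two-sided redundancy filter: while any pair exceeds
#' `max_similarity` percent identity, the longer member is kept (ties
#' keep the lexicographically smaller id); afterwards, any sequence whose
#' maximum identity to all kept others falls below `min_similarity` is
#' removed as unrelated. Identity is computed over global pairwise
#' alignment columns excluding terminal gaps.
#'
#' @param sequences Named character vector (at least one sequence).
#' @param max_similarity,min_similarity Percent thresholds.
#' @return Retained sequences; removed ids with reasons in attribute
#'   `"removed"`.
#' @export
decrease_redundancy <- function(sequences, max_similarity = 99, min_similarity = 30) {
  stopifnot(length(sequences) >= 1L)
  n <- length(sequences)
  if (n == 1L) return(sequences)
  ids <- names(sequences)
  idm <- matrix(100, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(sequences[(i + 1L):n]),
      Biostrings::AAString(sequences[[i]]),
      substitutionMatrix = blosum62(), gapOpening = 10, gapExtension = 1,
      type = "global")
    ap <- as.character(Biostrings::alignedPattern(pa))
    as_ <- as.character(Biostrings::alignedSubject(pa))
    for (j in seq_along(ap))
      idm[i, i + j] <- idm[i + j, i] <- identity_from_aligned(ap[j], as_[j])
  }
  keep <- ids
  removed <- character()
  repeat {
    sub <- idm[keep, keep, drop = FALSE]
    diag(sub) <- 0
    mx <- max(sub)
    if (mx <= max_similarity) break
    w <- which(sub == mx, arr.ind = TRUE)[1L, ]
    pair <- sort(keep[w])
    la <- nchar(sequences[[pair[1]]]); lb <- nchar(sequences[[pair[2]]])
    # keep the longer; on a tie keep the lexicographically smaller id
    drop_id <- if (la > lb) pair[2] else if (lb > la) pair[1] else pair[2]
    keep <- setdiff(keep, drop_id)
    removed <- c(removed, setNames("redundant", drop_id))
  }
  if (length(keep) > 1L) {
    sub <- idm[keep, keep, drop = FALSE]
    diag(sub) <- NA
    far <- keep[apply(sub, 1L, max, na.rm = TRUE) < min_similarity]
    if (length(far)) {
      keep <- setdiff(keep, far)
      removed <- c(removed, setNames(rep("unrelated", length(far)), far))
    }
  }
  out <- sequences[keep]
  attr(out, "removed") <- removed
  out
}

#' Write an alignment to aligned FASTA
#' @param aln An `"aa_alignment"`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_alignment <- function(aln, path) write_fasta(unclass(aln), path)

#' Read an aligned FASTA file as an alignment
#' @param path Path to aligned FASTA.
#' @return An `"aa_alignment"`.
#' @export
read_alignment <- function(path) as_alignment(read_fasta(path))
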