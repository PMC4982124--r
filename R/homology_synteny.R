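# Cross-species homology: all-vs-all local-alignment similarity search,
# bidirectional best hits with clade confirmation, and syntenic-block
# identification by exact k-mer anchor chaining.

#' All-vs-all local-alignment similarity search
#'
#' Scores every query against every subject with Smith-Waterman local
#' alignment (BLOSUM62, affine gaps by default) and ranks subjects per
#' query by score, breaking ties by percent identity and then by
#' subject id. An optional shared k-mer prefilter restricts the
#' alignment to the most promising subjects; non-candidates keep rank
#' positions after all aligned subjects.
#'
#' @param queries,subjects Named character vectors of protein sequences.
#' @param substitution_matrix Substitution matrix (default BLOSUM62).
#' @param gap_opening,gap_extension Positive gap costs, as in
#'   [Biostrings::pairwiseAlignment()].
#' @param prefilter_k,prefilter_top When `prefilter_top` is finite, only
#'   the `prefilter_top` subjects sharing most `prefilter_k`-mers with
#'   the query are aligned.
#' @return Data frame `query_id`, `subject_id`, `score`, `identity`,
#'   `rank` (dense per query).
#' @export
pairwise_similarity_search <- function(queries, subjects,
                                       substitution_matrix = NULL,
                                       gap_opening = 10, gap_extension = 1,
                                       prefilter_k = 4L, prefilter_top = Inf) {
  stopifnot(length(queries) > 0, length(subjects) > 0)
  S <- substitution_matrix %||% blosum62()
  subj_set <- Biostrings::AAStringSet(subjects)
  kmers <- NULL
  if (is.finite(prefilter_top))
    kmers <- lapply(subjects, function(s)
      unique(substring(s, 1:max(1L, nchar(s) - prefilter_k + 1L),
                       prefilter_k:max(prefilter_k, nchar(s)))))
  out <- list()
  for (q in names(queries)) {
    cand <- names(subjects)
    if (is.finite(prefilter_top) && length(subjects) > prefilter_top) {
      qk <- unique(substring(queries[[q]],
                             1:max(1L, nchar(queries[[q]]) - prefilter_k + 1L),
                             prefilter_k:max(prefilter_k, nchar(queries[[q]]))))
      shared <- vapply(kmers, function(k) sum(k %in% qk), numeric(1))
      cand <- names(sort(shared, decreasing = TRUE))[seq_len(prefilter_top)]
    }
    pa <- Biostrings::pairwiseAlignment(
      subj_set[cand], Biostrings::AAString(queries[[q]]),
      substitutionMatrix = S, gapOpening = gap_opening,
      gapExtension = gap_extension, type = "local")
    sc <- Biostrings::score(pa)
    idy <- Biostrings::pid(pa)
    df <- data.frame(query_id = q, subject_id = cand, score = sc,
                     identity = idy, stringsAsFactors = FALSE)
    df <- df[order(-df$score, -df$identity, df$subject_id), , drop = FALSE]
    df$rank <- seq_len(nrow(df))
    out[[q]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Ortholog pairs by bidirectional best hits
#'
#' A pair `(a, b)` is emitted iff `b` is the rank-1 hit of `a` in the
#' A-to-B search and `a` is the rank-1 hit of `b` in the B-to-A search.
#'
#' @param hits_ab,hits_ba Hit tables from
#'   [pairwise_similarity_search()], one per direction.
#' @return Data frame `gene_a`, `gene_b`, `bbh` (always `TRUE`),
#'   `score_ab`, `score_ba`.
#' @export
bidirectional_best_hits <- function(hits_ab, hits_ba) {
  top_ab <- hits_ab[hits_ab$rank == 1L, , drop = FALSE]
  top_ba <- hits_ba[hits_ba$rank == 1L, , drop = FALSE]
  back <- setNames(top_ba$subject_id, top_ba$query_id)
  mutual <- !is.na(back[top_ab$subject_id]) &
    back[top_ab$subject_id] == top_ab$query_id
  res <- data.frame(gene_a = top_ab$query_id[mutual],
                    gene_b = top_ab$subject_id[mutual],
                    bbh = TRUE,
                    score_ab = top_ab$score[mutual],
                    stringsAsFactors = FALSE)
  res$score_ba <- top_ba$score[match(res$gene_b, top_ba$query_id)]
  res <- res[order(res$gene_a), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Confirm ortholog pairs by shared clade membership
#'
#' A pair is clade-confirmed when both members co-occur in at least one
#' well-supported clade of the joint two-species tree. Unconfirmed pairs
#' are retained but flagged; pairs with a member missing from the tree
#' are flagged untestable (`NA`).
#'
#' @param pairs Result of [bidirectional_best_hits()].
#' @param clades Result of [find_well_supported_clades()] on the joint
#'   tree.
#' @param id_map Optional named vector translating tree tip ids to the
#'   pair id namespace.
#' @return `pairs` with a logical `clade_confirmed` column.
#' @export
confirm_orthologs_by_clade <- function(pairs, clades, id_map = NULL) {
  tipsets <- lapply(clades, function(cl) {
    t <- cl$tips
    if (!is.null(id_map)) t <- unname(id_map[t][!is.na(id_map[t])])
    t
  })
  all_tips <- unique(unlist(tipsets))
  confirmed <- logical(nrow(pairs))
  testable <- pairs$gene_a %in% all_tips & pairs$gene_b %in% all_tips
  for (i in seq_len(nrow(pairs))) {
    confirmed[i] <- any(vapply(tipsets, function(t)
      pairs$gene_a[i] %in% t && pairs$gene_b[i] %in% t, logical(1)))
  }
  pairs$clade_confirmed <- ifelse(testable | confirmed, confirmed, NA)
  pairs
}

# 2-bit rolling encoding of all k-mers of an ACGT string; exact for
# k <= 26 (values stay below 2^52). Returns NA at windows with non-ACGT.
encode_kmers <- function(seq, k) {
  codes <- c(A = 0, C = 1, G = 2, T = 3)[str_chars(seq)]
  n <- length(codes)
  if (n < k) return(numeric(0))
  v <- stats::filter(codes, 4^((k - 1):0), sides = 1)
  as.numeric(v[k:n]) # value at i = k-mer starting at i - k + 1 ... shifted below
}

#' Find exact shared anchors between two nucleotide sequences
#'
#' Reports maximal exact shared k-mer runs between the two sequences, on
#' both strands. Only k-mers unique within each sequence are used as
#' seeds (repetitive seeds are uninformative for collinearity);
#' overlapping or abutting seed matches on one diagonal are merged into
#' maximal runs.
#'
#' @param seq_a,seq_b Nucleotide strings (ACGT).
#' @param k Seed length in bp (>= 8).
#' @return Data frame `pos_a`, `pos_b` (1-based starts on the forward
#'   strands), `length`, `orientation` (`same`/`inverted`).
#' @export
find_anchors <- function(seq_a, seq_b, k = 21L) {
  if (k < 8L) stop("k must be >= 8")
  na <- nchar(seq_a); nb <- nchar(seq_b)
  empty <- data.frame(pos_a = numeric(0), pos_b = numeric(0),
                      length = numeric(0), orientation = character(0),
                      stringsAsFactors = FALSE)
  if (na < k || nb < k) return(empty)
  ka <- encode_kmers(seq_a, k)
  uniq <- function(v) { d <- duplicated(v) | duplicated(v, fromLast = TRUE); !d & !is.na(v) }
  ua <- uniq(ka)
  match_dir <- function(kb, flip) {
    ub <- uniq(kb)
    ia <- which(ua)
    mb <- match(ka[ia], kb)
    ok <- !is.na(mb) & ub[pmin(mb, length(ub))]
    ia <- ia[ok]; jb <- mb[ok]
    if (!length(ia)) return(NULL)
    # merge seeds on one diagonal into maximal runs
    ord <- order(jb - ia, ia)
    ia <- ia[ord]; jb <- jb[ord]
    newrun <- c(TRUE, diff(ia) != 1L | diff(jb) != 1L)
    run <- cumsum(newrun)
    starts_a <- tapply(ia, run, min); starts_b <- tapply(jb, run, min)
    lens <- tapply(ia, run, function(x) max(x) - min(x) + k)
    if (flip) {
      # coordinates were on revcomp(B): convert run to forward-strand B
      b_start <- nb - (starts_b + lens - 1) + 1
      data.frame(pos_a = as.numeric(starts_a), pos_b = as.numeric(b_start),
                 length = as.numeric(lens), orientation = "inverted",
                 stringsAsFactors = FALSE)
    } else {
      data.frame(pos_a = as.numeric(starts_a), pos_b = as.numeric(starts_b),
                 length = as.numeric(lens), orientation = "same",
                 stringsAsFactors = FALSE)
    }
  }
  fwd <- match_dir(encode_kmers(seq_b, k), flip = FALSE)
  rev <- match_dir(encode_kmers(revcomp(seq_b), k), flip = TRUE)
  res <- rbind(fwd, rev)
  if (is.null(res)) return(empty)
  res <- res[order(res$pos_a, res$pos_b), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Chain collinear anchors into syntenic blocks
#'
#' Same-orientation anchors are chained greedily along sequence A when
#' the gaps on both sequences are at most `max_anchor_gap` and the
#' anchors are collinear (B coordinates increasing for `same`
#' orientation, decreasing for `inverted`). Chains spanning less than
#' `min_block_length` bp on sequence A are discarded.
#'
#' @param anchors Result of [find_anchors()].
#' @param max_anchor_gap Maximum inter-anchor gap in bp on either
#'   sequence.
#' @param min_block_length Minimum block span in bp (default 1,000, the
#'   usual floor for a reportable syntenic block).
#' @return Data frame `start_a`, `end_a`, `start_b`, `end_b`,
#'   `orientation`, `length`, `n_anchors`.
#' @export
chain_synteny_blocks <- function(anchors, max_anchor_gap = 5000,
                                 min_block_length = 1000) {
  empty <- data.frame(start_a = numeric(0), end_a = numeric(0),
                      start_b = numeric(0), end_b = numeric(0),
                      orientation = character(0), length = numeric(0),
                      n_anchors = integer(0), stringsAsFactors = FALSE)
  if (!nrow(anchors)) return(empty)
  blocks <- list()
  for (ori in unique(anchors$orientation)) {
    a <- anchors[anchors$orientation == ori, , drop = FALSE]
    a <- a[order(a$pos_a, a$pos_b), , drop = FALSE]
    ea <- a$pos_a + a$length - 1
    eb <- a$pos_b + a$length - 1
    cur <- NULL
    flush <- function(c_) {
      len <- c_$end_a - c_$start_a + 1
      if (len >= min_block_length)
        blocks[[length(blocks) + 1L]] <<- data.frame(
          start_a = c_$start_a, end_a = c_$end_a,
          start_b = c_$start_b, end_b = c_$end_b,
          orientation = ori, length = len, n_anchors = c_$n,
          stringsAsFactors = FALSE)
    }
    for (i in seq_len(nrow(a))) {
      if (is.null(cur)) {
        cur <- list(start_a = a$pos_a[i], end_a = ea[i],
                    start_b = a$pos_b[i], end_b = eb[i], n = 1L)
        next
      }
      gap_a <- a$pos_a[i] - cur$end_a - 1
      if (ori == "same") {
        gap_b <- a$pos_b[i] - cur$end_b - 1
        collinear <- a$pos_b[i] > cur$end_b
      } else {
        gap_b <- cur$start_b - eb[i] - 1
        collinear <- eb[i] < cur$start_b
      }
      if (gap_a <= max_anchor_gap && gap_b <= max_anchor_gap &&
          gap_a >= -a$length[i] && collinear) {
        cur$end_a <- max(cur$end_a, ea[i])
        if (ori == "same") cur$end_b <- max(cur$end_b, eb[i])
        else cur$start_b <- min(cur$start_b, a$pos_b[i])
        cur$n <- cur$n + 1L
      } else {
        flush(cur)
        cur <- list(start_a = a$pos_a[i], end_a = ea[i],
                    start_b = a$pos_b[i], end_b = eb[i], n = 1L)
      }
    }
    if (!is.null(cur)) flush(cur)
  }
  if (!length(blocks)) return(empty)
  res <- do.call(rbind, blocks)
  res <- res[order(res$start_a), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Genome-vs-genome synteny scan
#'
#' Runs [find_anchors()] and [chain_synteny_blocks()] for every pair of
#' chromosomes of the two genomes.
#'
#' @param genome_a,genome_b Named character vectors of chromosome
#'   sequences.
#' @param k Anchor seed length.
#' @param max_anchor_gap,min_block_length Chaining parameters.
#' @return Data frame of blocks with `chrom_a`/`chrom_b` columns.
#' @export
synteny_scan <- function(genome_a, genome_b, k = 21L,
                         max_anchor_gap = 5000, min_block_length = 1000) {
  out <- list()
  for (ca in names(genome_a)) for (cb in names(genome_b)) {
    bl <- chain_synteny_blocks(find_anchors(genome_a[[ca]], genome_b[[cb]], k = k),
                               max_anchor_gap = max_anchor_gap,
                               min_block_length = min_block_length)
    if (nrow(bl)) {
      bl$chrom_a <- ca; bl$chrom_b <- cb
      out[[length(out) + 1L]] <- bl
    }
  }
  if (!length(out))
    return(data.frame(start_a = numeric(0), end_a = numeric(0),
                      start_b = numeric(0), end_b = numeric(0),
                      orientation = character(0), length = numeric(0),
                      n_anchors = integer(0), chrom_a = character(0),
                      chrom_b = character(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("chrom_a", "start_a", "end_a", "chrom_b", "start_b", "end_b",
          "orientation", "length", "n_anchors")]
}
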