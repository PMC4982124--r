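# Chromosomal arrangement of family genes: 200 kb clusters, tandem
# duplicated paralogs (cluster + clade concordance), and a text
# chromosome map.

#' Detect gene clusters within a genomic window
#'
#' Per chromosome, genes are sorted by start and chained by single
#' linkage: consecutive genes whose gap (next start minus previous end)
#' is at most `window` fall in one cluster. Clusters need at least two
#' members; singletons are reported in an attribute. With
#' `measure = "start"` the start-to-start distance is used instead of
#' the gap.
#'
#' @param loci Data frame `gene_id`, `chromosome`, `start`, `end` (and
#'   optionally `strand`).
#' @param window Chaining window in bp (default 200 kb).
#' @param measure `"gap"` (default, length-robust) or `"start"`.
#' @return Data frame, one row per cluster: `cluster_id`, `chromosome`,
#'   `n_members`, `start`, `end`, and list column `members` (gene ids in
#'   coordinate order). Attribute `"singletons"` lists unclustered genes.
#' @export
detect_clusters <- function(loci, window = 200000, measure = c("gap", "start")) {
  measure <- match.arg(measure)
  if (anyDuplicated(loci$gene_id))
    stop("duplicate gene_id in loci: ",
         paste(unique(loci$gene_id[duplicated(loci$gene_id)]), collapse = ", "))
  stopifnot(all(loci$start <= loci$end))
  out <- list(); singles <- character()
  cid <- 0L
  for (chr in sort(unique(loci$chromosome))) {
    l <- loci[loci$chromosome == chr, , drop = FALSE]
    l <- l[order(l$start, l$end), , drop = FALSE]
    if (nrow(l) == 1L) { singles <- c(singles, l$gene_id); next }
    dist <- if (measure == "gap") l$start[-1] - l$end[-nrow(l)]
            else l$start[-1] - l$start[-nrow(l)]
    grp <- cumsum(c(1L, as.integer(dist > window)))
    for (g in unique(grp)) {
      mem <- l[grp == g, , drop = FALSE]
      if (nrow(mem) < 2L) { singles <- c(singles, mem$gene_id); next }
      cid <- cid + 1L
      out[[cid]] <- data.frame(
        cluster_id = sprintf("C%03d", cid), chromosome = chr,
        n_members = nrow(mem), start = min(mem$start), end = max(mem$end),
        stringsAsFactors = FALSE)
      out[[cid]]$members <- list(mem$gene_id)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(cluster_id = character(), chromosome = character(),
               n_members = integer(), start = numeric(), end = numeric(),
               members = I(list()), stringsAsFactors = FALSE)
  attr(res, "singletons") <- singles
  res
}

#' Identify tandem duplicated paralogs
#'
#' Tandem paralogs are genes that both (a) share a well-supported clade
#' in the phylogeny and (b) co-occur in one genomic cluster. For every
#' clade x cluster combination, members present in both (at least two)
#' form a tandem paralog set. A gene belongs to at most one set: larger
#' clades win, ties go to the higher support.
#'
#' @param clusters Result of [detect_clusters()].
#' @param clades Result of [find_well_supported_clades()] (tip ids must
#'   be translatable to gene ids).
#' @param id_map Optional named vector translating clade tip ids to gene
#'   ids (e.g. protein -> gene).
#' @return Data frame, one row per tandem set: `set_id`, `cluster_id`,
#'   `chromosome`, `n_members`, `clade_support`, list column `members`.
#' @export
identify_tandem_paralogs <- function(clusters, clades, id_map = NULL) {
  translate <- function(tips) {
    if (is.null(id_map)) tips else unname(id_map[tips][!is.na(id_map[tips])])
  }
  ord <- order(-vapply(clades, function(cl) length(cl$tips), integer(1)),
               -vapply(clades, function(cl) cl$support, numeric(1)))
  used <- character()
  out <- list()
  sid <- 0L
  for (cl in clades[ord]) {
    genes <- translate(cl$tips)
    for (i in seq_len(nrow(clusters))) {
      mem <- intersect(setdiff(clusters$members[[i]], used), genes)
      if (length(mem) >= 2L) {
        sid <- sid + 1L
        row <- data.frame(set_id = sprintf("T%03d", sid),
                          cluster_id = clusters$cluster_id[i],
                          chromosome = clusters$chromosome[i],
                          n_members = length(mem),
                          clade_support = cl$support,
                          stringsAsFactors = FALSE)
        row$members <- list(mem)
        out[[sid]] <- row
        used <- c(used, mem)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(set_id = character(), cluster_id = character(),
               chromosome = character(), n_members = integer(),
               clade_support = numeric(), members = I(list()),
               stringsAsFactors = FALSE)
}

#' Cluster composition statistics
#'
#' @param clusters Result of [detect_clusters()].
#' @param tandem_sets Result of [identify_tandem_paralogs()].
#' @param family_genes Character vector of all family gene ids under
#'   study.
#' @return One-row data frame: total genes, genes in clusters (count and
#'   percent), number of clusters, and the fraction of clusters
#'   containing tandem paralogs.
#' @export
cluster_composition_stats <- function(clusters, tandem_sets, family_genes) {
  in_clusters <- unique(unlist(clusters$members))
  tandem_clusters <- unique(tandem_sets$cluster_id)
  data.frame(
    n_genes = length(family_genes),
    n_in_clusters = sum(family_genes %in% in_clusters),
    pct_in_clusters = if (length(family_genes))
      100 * sum(family_genes %in% in_clusters) / length(family_genes) else 0,
    n_clusters = nrow(clusters),
    n_clusters_with_tandem = length(tandem_clusters),
    frac_clusters_tandem = if (nrow(clusters))
      length(tandem_clusters) / nrow(clusters) else 0)
}

#' Render a text chromosome map
#'
#' One track per chromosome listing genes in coordinate order, with the
#' cluster (if any) each gene belongs to. The layout is deterministic
#' and machine-parseable; [parse_chromosome_map()] inverts it.
#'
#' @param loci Gene locus data frame.
#' @param clusters Optional [detect_clusters()] result.
#' @param chrom_lengths Optional named vector of chromosome lengths;
#'   loci beyond a length are an error.
#' @return Character vector of map lines.
#' @export
render_chromosome_map <- function(loci, clusters = NULL, chrom_lengths = NULL) {
  if (!nrow(loci)) return(character())
  if (!is.null(chrom_lengths)) {
    over <- loci$end > chrom_lengths[loci$chromosome]
    if (any(!is.na(over) & over))
      stop("locus beyond chromosome length: ",
           paste(loci$gene_id[which(over)], collapse = ", "))
  }
  cluster_of <- character()
  if (!is.null(clusters) && nrow(clusters))
    for (i in seq_len(nrow(clusters)))
      cluster_of[clusters$members[[i]]] <- clusters$cluster_id[i]
  lines <- character()
  for (chr in sort(unique(loci$chromosome))) {
    l <- loci[loci$chromosome == chr, , drop = FALSE]
    l <- l[order(l$start), , drop = FALSE]
    len <- if (!is.null(chrom_lengths)) chrom_lengths[[chr]] else max(l$end)
    lines <- c(lines, sprintf("## %s length=%.0f genes=%d", chr, len, nrow(l)))
    cl <- cluster_of[l$gene_id]
    cl[is.na(cl)] <- "."
    lines <- c(lines, sprintf("%s\t%s\t%.0f\t%.0f\t%s\t%s", chr, l$gene_id,
                              l$start, l$end, l$strand, cl))
  }
  lines
}

#' Parse a text chromosome map back into loci
#'
#' @param lines Character vector produced by [render_chromosome_map()].
#' @return Data frame `gene_id`, `chromosome`, `start`, `end`, `strand`,
#'   `cluster`.
#' @export
parse_chromosome_map <- function(lines) {
  body <- lines[!startsWith(lines, "##")]
  if (!length(body))
    return(data.frame(gene_id = character(), chromosome = character(),
                      start = numeric(), end = numeric(), strand = character(),
                      cluster = character(), stringsAsFactors = FALSE))
  f <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
  data.frame(gene_id = f[, 2], chromosome = f[, 1],
             start = as.numeric(f[, 3]), end = as.numeric(f[, 4]),
             strand = f[, 5], cluster = f[, 6], stringsAsFactors = FALSE)
}
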