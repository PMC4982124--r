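# End-to-end orchestration: classify -> align/filter -> phylogeny ->
# motifs -> chromosomal arrangement -> orthologs/synteny, with a
# survey-style run report (classification funnel + per-group counts).

#' Pipeline parameters
#'
#' All stage tunables with their standard defaults: kinase-domain merge
#' rule (gap <= 100 aa, merged span <= 450 aa), short-sequence floor
#' (100 aa), redundancy thresholds (99% / 30%), clade support threshold
#' (0.70), clustering window (200 kb) and minimum syntenic block
#' (1,000 bp).
#'
#' @param min_kd_len Minimum kinase-domain length (aa).
#' @param merge_gap_max,merged_len_max Kinase-domain merge rule (aa).
#' @param max_gap_fraction Gap-column trimming threshold.
#' @param max_similarity,min_similarity Redundancy thresholds (%).
#' @param support_threshold Clade support threshold.
#' @param n_bootstrap Bootstrap replicates.
#' @param cluster_window Gene clustering window (bp).
#' @param anchor_k Synteny anchor seed length (bp).
#' @param max_anchor_gap,min_block_length Synteny chaining parameters (bp).
#' @param run_synteny Whether to run the genome-vs-genome synteny scan.
#' @param seed Seed for the bootstrap resampling.
#' @return A list of class `"pipeline_params"`.
#' @export
pipeline_params <- function(min_kd_len = 100L, merge_gap_max = 100L,
                            merged_len_max = 450L, max_gap_fraction = 0.9,
                            max_similarity = 99, min_similarity = 30,
                            support_threshold = 0.70, n_bootstrap = 100L,
                            cluster_window = 200000, anchor_k = 21L,
                            max_anchor_gap = 5000, min_block_length = 1000,
                            run_synteny = TRUE, seed = 1L) {
  p <- as.list(environment())
  stopifnot(p$support_threshold >= 0, p$support_threshold <= 1,
            p$max_gap_fraction >= 0, p$max_gap_fraction <= 1,
            p$n_bootstrap >= 1, p$cluster_window >= 0,
            p$min_block_length >= 1)
  structure(p, class = "pipeline_params")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
}

load_dataset_paths <- function(paths) {
  sp <- lapply(names(paths$species), function(s) {
    p <- paths$species[[s]]
    for (f in c("proteome", "gff", "domains"))
      if (is.null(p[[f]]) || !file.exists(p[[f]]))
        stop("missing ", f, " file for species ", s)
    b <- load_annotated_proteome(p$proteome, p$gff, p$domains, species = s)
    b$species_id <- s
    if (!is.null(p$genome) && file.exists(p$genome))
      b$genome <- read_fasta(p$genome)
    b
  })
  names(sp) <- names(paths$species)
  ref <- list(
    proteins = read_fasta(paths$reference$proteome),
    domains = read_tsv(paths$reference$domains),
    labels = read_tsv(paths$reference$labels))
  structure(list(species = sp, reference = ref), class = "rlk_dataset")
}

# Kinase-domain unit sequences of the reference bundle (exemplars and
# outgroup), named by protein id.
reference_kd_sequences <- function(reference, params) {
  prot <- data.frame(protein_id = names(reference$proteins),
                     gene_id = names(reference$proteins),
                     species = "reference", is_primary = TRUE,
                     sequence = unname(reference$proteins),
                     stringsAsFactors = FALSE)
  kd <- extract_kinase_domains(prot, reference$domains,
                               merge_gap_max = params$merge_gap_max,
                               merged_len_max = params$merged_len_max)
  setNames(kd$sequence, kd$protein_id)
}

#' Run the full LRR-RLK identification and annotation pipeline
#'
#' Executes, per species: domain classification (kinase / TM-kinase /
#' LRR-RLK), kinase-domain extraction and merging, the alignment filter
#' chain (short-sequence removal, redundancy reduction, progressive
#' alignment, gap-column trimming), bootstrap NJ phylogeny with the
#' labelled reference, subfamily group assignment, catalytic-loop
#' classification, and 200 kb cluster / tandem-paralog detection; then,
#' across species: BBH ortholog identification confirmed on a joint
#' two-species tree, and (optionally) a genome-vs-genome synteny scan.
#' Stages run in order; a failure names the stage.
#'
#' @param dataset An `"rlk_dataset"` from [simulate_rlk_dataset()], or a
#'   list of file paths (`species = list(<id> = list(proteome, gff,
#'   domains, genome))`, `reference = list(proteome, domains, labels)`).
#' @param params A [pipeline_params()].
#' @param out_dir Optional run directory for TSV/Newick/JSON outputs.
#' @return A `"run_report"`: per-species funnel counts, group counts,
#'   motif-class counts, cluster/tandem counts, ortholog and synteny
#'   counts, provenance, and a `details` element with the full stage
#'   outputs.
#' @export
run_pipeline <- function(dataset, params = pipeline_params(), out_dir = NULL) {
  if (!inherits(dataset, "rlk_dataset"))
    dataset <- run_stage("classify", load_dataset_paths(dataset))
  ref_kds <- run_stage("classify", reference_kd_sequences(dataset$reference, params))
  ref_labels <- as_label_vector(dataset$reference$labels)

  per_species <- list()
  details <- list(species = list())
  kd_pools <- list()
  for (sp in names(dataset$species)) {
    b <- dataset$species[[sp]]

    prim <- run_stage("classify", filter_primary_transcripts(b$proteins))
    classified <- run_stage("classify", classify_proteins(prim, b$domains))
    funnel <- classification_funnel(classified)
    lrr_ids <- classified$protein_id[classified$tier == "LRR-RLK"]
    lrr_prot <- prim[prim$protein_id %in% lrr_ids, , drop = FALSE]

    kds <- run_stage("extract_kd", extract_kinase_domains(
      lrr_prot, b$domains, merge_gap_max = params$merge_gap_max,
      merged_len_max = params$merged_len_max))
    kd_seqs <- setNames(kds$sequence, ifelse(
      ave(kds$unit_index, kds$protein_id, FUN = length) > 1L,
      paste0(kds$protein_id, "|kd", kds$unit_index), kds$protein_id))

    aln_in <- run_stage("align", {
      kept <- filter_short(c(kd_seqs, ref_kds), min_len = params$min_kd_len)
      decrease_redundancy(kept, max_similarity = params$max_similarity,
                          min_similarity = params$min_similarity)
    })
    aln <- run_stage("align", trim_gap_columns(
      progressive_align(aln_in), max_gap_fraction = params$max_gap_fraction))

    tree <- run_stage("phylo", bootstrap_support(
      aln, n_replicates = params$n_bootstrap, seed = params$seed))
    assignment <- run_stage("phylo", split_group_xii(
      tree, assign_subfamily_groups(tree, ref_labels,
                                    support_threshold = params$support_threshold),
      ref_labels, support_threshold = params$support_threshold))
    query_tips <- setdiff(names(assignment), names(ref_labels))
    group_counts <- table(factor(assignment[query_tips],
                                 levels = c(GROUP_LABELS, "unassigned")))

    calls <- run_stage("motifs", {
      anchor <- NULL
      for (cand in intersect(names(ref_labels), names(aln))) {
        if (grepl("HRD", gsub("-", "", aln[[cand]]), fixed = TRUE)) { anchor <- cand; break }
      }
      if (is.null(anchor)) stop("no reference row with an intact HRD loop")
      classify_rd_motif(locate_catalytic_loop(aln, anchor))
    })
    query_calls <- calls[calls$protein_id %in% query_tips, , drop = FALSE]
    motif_counts <- table(factor(query_calls$motif_class,
                                 levels = c("RD", "nonRD", "ACF")))
    motif_summary <- summarize_motifs(query_calls, assignment)

    tip_gene <- setNames(lrr_prot$gene_id[match(sub("\\|kd\\d+$", "", query_tips),
                                                lrr_prot$protein_id)], query_tips)
    arr <- run_stage("arrange", {
      loci <- b$loci[b$loci$gene_id %in% unname(tip_gene), , drop = FALSE]
      clusters <- detect_clusters(loci, window = params$cluster_window)
      clades <- find_well_supported_clades(tree, params$support_threshold)
      tandem <- identify_tandem_paralogs(clusters, clades, id_map = tip_gene)
      list(loci = loci, clusters = clusters, clades = clades, tandem = tandem,
           stats = cluster_composition_stats(clusters, tandem, unique(unname(tip_gene))),
           map = render_chromosome_map(loci, clusters))
    })

    kd_pools[[sp]] <- kd_seqs
    per_species[[sp]] <- list(
      funnel = c(funnel, kd_units = nrow(kds)),
      group_counts = as.list(group_counts),
      motif_counts = as.list(motif_counts),
      clusters = list(n_clusters = nrow(arr$clusters),
                      n_genes_in_clusters = arr$stats$n_in_clusters,
                      pct_in_clusters = arr$stats$pct_in_clusters,
                      n_tandem_sets = nrow(arr$tandem),
                      n_tandem_genes = sum(arr$tandem$n_members)))
    details$species[[sp]] <- list(
      classified = classified, kds = kds, alignment = aln, tree = tree,
      assignment = assignment, motif_calls = calls,
      motif_summary = motif_summary, arrange = arr,
      lrr_proteins = lrr_prot, tip_gene = tip_gene)
  }

  # ---- cross-species orthology ---------------------------------------
  sp_ids <- names(dataset$species)
  orth <- NULL; joint <- NULL
  if (length(sp_ids) >= 2L) {
    a <- sp_ids[1]; b <- sp_ids[2]
    prot_of <- function(sp) {
      lp <- details$species[[sp]]$lrr_proteins
      setNames(lp$sequence, lp$protein_id)
    }
    orth <- run_stage("orthologs", {
      pa <- prot_of(a); pb <- prot_of(b)
      if (length(pa) && length(pb)) {
        cap <- min(25L, max(length(pa), length(pb)))
        hits_ab <- pairwise_similarity_search(pa, pb, prefilter_top = cap)
        hits_ba <- pairwise_similarity_search(pb, pa, prefilter_top = cap)
        bidirectional_best_hits(hits_ab, hits_ba)
      } else data.frame(gene_a = character(), gene_b = character(), bbh = logical(),
                        score_ab = numeric(), score_ba = numeric())
    })
    joint <- run_stage("orthologs", {
      # no redundancy reduction here: at low divergence true orthologs can
      # exceed the identity cap, and both members must stay on the joint
      # tree for clade confirmation
      kept <- filter_short(c(kd_pools[[a]], kd_pools[[b]], ref_kds),
                           params$min_kd_len)
      aln2 <- trim_gap_columns(progressive_align(kept),
                               max_gap_fraction = params$max_gap_fraction)
      bootstrap_support(aln2, n_replicates = params$n_bootstrap,
                        seed = params$seed)
    })
    orth <- run_stage("orthologs", confirm_orthologs_by_clade(
      orth, find_well_supported_clades(joint, params$support_threshold)))
  }

  synteny <- NULL
  if (isTRUE(params$run_synteny) && length(sp_ids) >= 2L &&
      !is.null(dataset$species[[sp_ids[1]]]$genome) &&
      !is.null(dataset$species[[sp_ids[2]]]$genome)) {
    synteny <- run_stage("synteny", synteny_scan(
      dataset$species[[sp_ids[1]]]$genome, dataset$species[[sp_ids[2]]]$genome,
      k = params$anchor_k, max_anchor_gap = params$max_anchor_gap,
      min_block_length = params$min_block_length))
  }

  report <- list(
    species = per_species,
    orthologs = list(
      n_bbh = if (is.null(orth)) 0L else nrow(orth),
      n_clade_confirmed = if (is.null(orth)) 0L else sum(orth$clade_confirmed %in% TRUE)),
    synteny = list(
      n_blocks = if (is.null(synteny)) 0L else nrow(synteny),
      total_block_length = if (is.null(synteny)) 0 else sum(synteny$length)),
    provenance = list(seed = params$seed,
                      params = unclass(params)[order(names(params))],
                      package = "familyscope",
                      version = as.character(utils::packageVersion("familyscope"))))
  report$details <- c(details, list(ortholog_pairs = orth, joint_tree = joint,
                                    synteny_blocks = synteny))
  class(report) <- "run_report"
  if (!is.null(out_dir)) write_run_report(report, out_dir)
  report
}

#' Serialize a run report (without bulky details) to JSON text
#'
#' Deterministic for identical inputs and seed: rerunning the pipeline
#' with the same configuration yields byte-identical text.
#'
#' @param report A `"run_report"`.
#' @return A JSON character scalar.
#' @export
report_json <- function(report) {
  x <- unclass(report)
  x$details <- NULL
  as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE))
}

#' Write run outputs to a directory
#'
#' Emits the summary report JSON, rendered summary tables, per-species
#' assignment and motif TSVs, cluster and tandem TSVs, Newick trees,
#' ortholog and synteny TSVs, and the text chromosome maps.
#'
#' @param report A `"run_report"`.
#' @param out_dir Output directory.
#' @return Invisibly, `out_dir`.
#' @export
write_run_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(report_json(report), file.path(out_dir, "run_report.json"))
  tabs <- render_tables(report)
  writeLines(tabs$text, file.path(out_dir, "summary_tables.txt"))
  for (sp in names(report$details$species)) {
    d <- report$details$species[[sp]]
    write_tsv(data.frame(tip = names(d$assignment), group = unname(d$assignment)),
              file.path(out_dir, paste0(sp, "_groups.tsv")))
    write_tsv(d$motif_calls, file.path(out_dir, paste0(sp, "_motifs.tsv")))
    cl <- d$arrange$clusters
    if (nrow(cl)) {
      cl$members <- vapply(cl$members, paste, character(1), collapse = ";")
      write_tsv(cl, file.path(out_dir, paste0(sp, "_clusters.tsv")))
    }
    td <- d$arrange$tandem
    if (nrow(td)) {
      td$members <- vapply(td$members, paste, character(1), collapse = ";")
      write_tsv(td, file.path(out_dir, paste0(sp, "_tandem.tsv")))
    }
    ape::write.tree(d$tree, file.path(out_dir, paste0(sp, "_tree.nwk")))
    writeLines(d$arrange$map, file.path(out_dir, paste0(sp, "_chromosome_map.txt")))
  }
  if (!is.null(report$details$ortholog_pairs))
    write_tsv(report$details$ortholog_pairs, file.path(out_dir, "ortholog_pairs.tsv"))
  if (!is.null(report$details$joint_tree))
    ape::write.tree(report$details$joint_tree, file.path(out_dir, "joint_tree.nwk"))
  if (!is.null(report$details$synteny_blocks))
    write_tsv(report$details$synteny_blocks, file.path(out_dir, "synteny_blocks.tsv"))
  invisible(out_dir)
}

#' Render the survey tables of a run report
#'
#' Produces the domain-classification funnel table (one column per
#' species, kinase-domain unit totals in parentheses on the LRR-RLK row)
#' and the per-subfamily-group count matrix whose column totals equal
#' the LRR-RLK counts of the funnel.
#'
#' @param report A `"run_report"`.
#' @return List with data frames `funnel` and `groups`, and `text`, an
#'   aligned plain-text rendering.
#' @export
render_tables <- function(report) {
  sps <- names(report$species)
  funnel <- data.frame(tier = c("Predicted proteins", "Kinases", "TM kinases",
                                "TM kinases with LRR (KD)"))
  for (sp in sps) {
    f <- report$species[[sp]]$funnel
    funnel[[sp]] <- c(as.character(f[["proteins"]]), as.character(f[["kinase"]]),
                      as.character(f[["tm_kinase"]]),
                      sprintf("%d (%d)", f[["lrr_rlk"]], f[["kd_units"]]))
  }
  glabs <- c(GROUP_LABELS, "unassigned")
  groups <- data.frame(group = c(paste("LRR", glabs), "Total"))
  for (sp in sps) {
    gc <- unlist(report$species[[sp]]$group_counts)[glabs]
    gc[is.na(gc)] <- 0L
    stopifnot(sum(gc) == report$species[[sp]]$funnel[["lrr_rlk"]])
    groups[[sp]] <- c(as.integer(gc), sum(gc))
  }
  fmt <- function(df, title) {
    widths <- pmax(nchar(names(df)), apply(df, 2, function(x) max(nchar(x), 0)))
    line <- function(vals) paste(mapply(formatC, vals, width = widths,
                                        MoreArgs = list(flag = "-")), collapse = "  ")
    c(title, line(names(df)), apply(df, 1, line), "")
  }
  list(funnel = funnel, groups = groups,
       text = c(fmt(funnel, "Protein classification by diagnostic domains"),
                fmt(groups, "Receptors per subfamily group")))
}

#' @export
print.run_report <- function(x, ...) {
  cat("LRR-RLK pipeline run report\n")
  writeLines(render_tables(x)$text)
  cat(sprintf("BBH ortholog pairs: %d (%d clade-confirmed)\n",
              x$orthologs$n_bbh, x$orthologs$n_clade_confirmed))
  cat(sprintf("Syntenic blocks: %d (total %.0f bp)\n",
              x$synteny$n_blocks, x$synteny$total_block_length))
  invisible(x)
}
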