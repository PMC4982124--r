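test_that("same configuration and seed reproduce byte-identical bundles", {
  cfg <- small_cfg(seed = 7)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_dataset(simulate_rlk_dataset(cfg), d1)
  write_dataset(simulate_rlk_dataset(cfg), d2)
  files <- sort(list.files(d1))
  expect_identical(files, sort(list.files(d2)))
  expect_identical(unname(tools::md5sum(file.path(d1, files))),
                   unname(tools::md5sum(file.path(d2, files))))
})

test_that("an empty configuration yields empty bundles without error", {
  cfg <- small_cfg(n_families = 0L, n_decoy_kinase = 0L, n_decoy_tm_kinase = 0L,
                   n_synteny_segments = 0L)
  ds <- simulate_rlk_dataset(cfg)
  expect_equal(nrow(ds$truth$genes), 0L)
  expect_equal(nrow(ds$species$spA$proteins), 0L)
  expect_equal(nrow(ds$species$spA$loci), 0L)
  d <- withr::local_tempdir()
  expect_no_error(write_dataset(ds, d))
})

test_that("truth-table gene counts match an independent re-parse of the GFF3", {
  cfg <- small_cfg(n_families = 10L, members_per_family_range = c(2L, 2L),
                   ortholog_fraction = 1, n_decoy_kinase = 0L,
                   n_decoy_tm_kinase = 0L, n_synteny_segments = 0L,
                   n_chromosomes = 4L, chromosome_length = 1.6e6, seed = 5)
  ds <- simulate_rlk_dataset(cfg)
  d <- withr::local_tempdir()
  write_dataset(ds, d)
  for (sp in c("spA", "spB")) {
    tg <- ds$truth$genes[ds$truth$genes$species == sp, ]
    expect_equal(nrow(tg), 20L) # 10 families x 2 members, all shared
    g <- as.data.frame(rtracklayer::import(file.path(d, paste0(sp, ".gff3"))))
    expect_equal(sum(g$type == "gene"), 20L)
    mrna <- g[g$type == "mRNA", ]
    expect_equal(sum(tolower(mrna$primary) == "true"),
                 unname(ds$truth$n_primary_transcripts[sp]))
    expect_setequal(g$ID[g$type == "gene"], tg$gene_id)
  }
})

test_that("emitted proteins are exact translations of their CDS in the genome", {
  ds <- small_dataset()
  d <- withr::local_tempdir()
  write_dataset(ds, d)
  for (sp in c("spA", "spB")) {
    g <- as.data.frame(rtracklayer::import(file.path(d, paste0(sp, ".gff3"))))
    cds <- g[g$type == "CDS", ]
    genome <- read_fasta(file.path(d, paste0(sp, "_genome.fa")))
    prot <- read_fasta(file.path(d, paste0(sp, "_proteins.fa")))
    expect_gt(nrow(cds), 0)
    for (i in seq_len(nrow(cds))) {
      s <- substr(genome[[as.character(cds$seqnames[i])]], cds$start[i], cds$end[i])
      if (as.character(cds$strand[i]) == "-") s <- familyscope:::revcomp(s)
      p <- sub("\\*$", "", as.character(
        Biostrings::translate(Biostrings::DNAString(s), no.init.codon = TRUE)))
      pid <- sub("\\.cds$", "", cds$ID[i])
      expect_identical(p, unname(prot[pid]))
    }
  }
})

test_that("domain annotations fall inside protein lengths and include the funnel elements", {
  ds <- small_dataset()
  for (sp in c("spA", "spB")) {
    b <- ds$species[[sp]]
    plen <- setNames(nchar(b$proteins$sequence), b$proteins$protein_id)
    expect_true(all(b$domains$start >= 1))
    expect_true(all(b$domains$end <= plen[b$domains$protein_id]))
    # every planted receptor has, in order, LRR < TM < kinase annotations
    tg <- ds$truth$genes
    for (gid in tg$gene_id[tg$species == sp & tg$tier == "LRR-RLK"]) {
      d <- b$domains[b$domains$protein_id == paste0(gid, ".1"), ]
      lrr <- d[d$accession %in% familyscope:::LRR_ACCESSIONS, ]
      tm <- d[d$accession == "TMHELIX", ]
      kin <- d[d$accession %in% c("PF00069", "PF07714"), ]
      expect_gte(nrow(lrr), 1)
      expect_equal(nrow(tm), 1)
      expect_gte(nrow(kin), 1)
      expect_lt(max(lrr$end), min(tm$start))
      expect_lt(max(tm$end), min(kin$start))
    }
  }
})

test_that("planted tandem arrays satisfy the 200 kb rule by construction", {
  ds <- small_dataset()
  expect_gt(length(ds$truth$tandem_arrays), 0)
  for (arr in ds$truth$tandem_arrays) {
    loci <- ds$species[[arr$species]]$loci
    l <- loci[match(arr$gene_ids, loci$gene_id), ]
    expect_true(all(l$chromosome == arr$chromosome))
    l <- l[order(l$start), ]
    gaps <- l$start[-1] - l$end[-nrow(l)]
    expect_true(all(gaps < 200000))
  }
})

test_that("catalytic-loop motifs are planted as requested", {
  template <- plant_kinase_motif(raa(50) |> paste0("HRD", raa(50)), "RD")
  loop <- attr(template, "loop_pos")
  expect_identical(as.vector(substr(template, loop, loop + 2)), "HRD")

  non_rd <- plant_kinase_motif(template, "nonRD", "C")
  expect_identical(as.vector(substr(non_rd, loop, loop + 2)), "HCD")

  acf <- plant_kinase_motif(template, "ACF")
  expect_identical(as.vector(substr(acf, loop, loop + 2)), "HRA")

  expect_error(plant_kinase_motif(template, "nonRD", "R"), "contradiction")
  expect_error(plant_kinase_motif(gsub("HRD", "AAA", template), "RD"), "HRD")
})

test_that("sequence mutation respects rate, mask, seed and bounds", {
  s <- rnt(10000)
  expect_identical(mutate_sequence(s, 0), s)
  expect_error(mutate_sequence(s, -0.1), "rate")
  expect_error(mutate_sequence(s, 0.6), "rate")

  m1 <- mutate_sequence(s, 0.1, seed = 99)
  m2 <- mutate_sequence(s, 0.1, seed = 99)
  expect_identical(m1, m2)
  # oracle: direct Hamming count
  frac <- mean(strsplit(s, "")[[1]] != strsplit(m1, "")[[1]])
  expect_lt(abs(frac - 0.1), 0.01)

  mask <- 1:500
  m3 <- mutate_sequence(s, 0.5, seed = 1, mask = mask)
  expect_identical(substr(m3, 1, 500), substr(s, 1, 500))
})

test_that("infeasible gene placement raises a capacity error", {
  cfg <- small_cfg(n_families = 10L, n_chromosomes = 1L,
                   chromosome_length = 3e5)
  expect_error(simulate_rlk_dataset(cfg), "capacity")
})

test_that("generator configuration is validated", {
  expect_error(generator_config(mutation_rate = 0.7), "mutation_rate")
  expect_error(generator_config(motif_class_probs = c(RD = 0.5, nonRD = 0.4, ACF = 0.2)),
               "sum to 1")
  expect_error(generator_config(members_per_family_range = c(3, 2)),
               "members_per_family_range")
})
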