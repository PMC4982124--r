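make_proteins <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(protein_id = r[[1]], gene_id = r[[2]], species = "t",
               is_primary = r[[3]], sequence = r[[4]], stringsAsFactors = FALSE)))
}

test_that("loader validates the domain table against the proteome", {
  d <- withr::local_tempdir()
  fa <- file.path(d, "p.fa")
  write_fasta(c(p1 = raa(120), p2 = raa(80)), fa)

  tsv <- file.path(d, "d.tsv")
  writeLines("protein_id\taccession\tstart\tend", tsv)
  inp <- load_annotated_proteome(fa, NULL, tsv)
  expect_equal(nrow(inp$domains), 0L)
  expect_equal(nrow(inp$proteins), 2L)

  writeLines(c("protein_id\taccession\tstart\tend", "p2\tPF00069\t10\t150"), tsv)
  expect_error(load_annotated_proteome(fa, NULL, tsv), "row.*2")

  writeLines(c("protein_id\taccession\tstart\tend", "nope\tPF00069\t1\t10"), tsv)
  expect_error(load_annotated_proteome(fa, NULL, tsv), "not in proteome")
})

test_that("loaded record counts match the generator truth table", {
  ds <- small_dataset()
  d <- withr::local_tempdir()
  write_dataset(ds, d)
  p <- dataset_paths(d)
  inp <- load_annotated_proteome(p$species$spA$proteome, p$species$spA$gff,
                                 p$species$spA$domains, species = "spA")
  b <- ds$species$spA
  expect_equal(nrow(inp$proteins), nrow(b$proteins))
  expect_equal(sum(inp$proteins$is_primary),
               unname(ds$truth$n_primary_transcripts["spA"]))
  expect_setequal(inp$loci$gene_id, b$loci$gene_id)
  expect_equal(nrow(inp$domains), nrow(b$domains))
})

test_that("primary-transcript filtering keeps exactly one record per gene", {
  pr <- make_proteins(list("g1.1", "g1", TRUE, raa(50)),
                      list("g1.2", "g1", FALSE, raa(40)),
                      list("g1.3", "g1", FALSE, raa(45)),
                      list("g2.1", "g2", TRUE, raa(50)))
  out <- filter_primary_transcripts(pr)
  expect_equal(nrow(out), 2L)
  expect_setequal(out$protein_id, c("g1.1", "g2.1"))

  # all primary: identity
  expect_identical(filter_primary_transcripts(pr[pr$is_primary, ]),
                   `rownames<-`(pr[pr$is_primary, ], NULL))

  # no primary flag: the longest wins, with a warning
  pr2 <- make_proteins(list("g3.1", "g3", FALSE, raa(30)),
                       list("g3.2", "g3", FALSE, raa(60)))
  expect_warning(out2 <- filter_primary_transcripts(pr2), "no primary")
  expect_identical(out2$protein_id, "g3.2")

  # many genes, several transcripts each: one record per gene id
  big <- do.call(rbind, lapply(1:50, function(i) make_proteins(
    list(sprintf("g%d.1", i), sprintf("g%d", i), TRUE, raa(40)),
    list(sprintf("g%d.2", i), sprintf("g%d", i), FALSE, raa(40)),
    list(sprintf("g%d.3", i), sprintf("g%d", i), FALSE, raa(40)))))
  out3 <- filter_primary_transcripts(big)
  expect_equal(nrow(out3), length(unique(big$gene_id)))
})

test_that("tier classification follows the nested LRR/TM/kinase rule", {
  pr <- make_proteins(list("a", "a", TRUE, raa(400)),
                      list("b", "b", TRUE, raa(400)),
                      list("c", "c", TRUE, raa(400)),
                      list("d", "d", TRUE, raa(400)))
  dom <- data.frame(
    protein_id = c("a", "a", "a", "b", "b", "c", "c", "d"),
    accession = c("PF00069", "TMHELIX", "PF13855",
                  "PF07714", "TMHELIX",
                  "PF13855", "TMHELIX",
                  "PF00069"),
    start = c(100, 50, 10, 100, 50, 10, 50, 100),
    end = c(380, 72, 33, 380, 72, 33, 72, 380))
  cls <- classify_proteins(pr, dom)
  tiers <- setNames(as.character(cls$tier), cls$protein_id)
  expect_identical(tiers[["a"]], "LRR-RLK")
  expect_identical(tiers[["b"]], "TM-kinase")
  expect_identical(tiers[["c"]], "none") # kinase is the root requirement
  expect_identical(tiers[["d"]], "kinase")
})

test_that("funnel counts are monotone and exact on noise-free synthetic data", {
  ds <- small_dataset()
  for (sp in c("spA", "spB")) {
    b <- ds$species[[sp]]
    prim <- filter_primary_transcripts(b$proteins)
    cls <- classify_proteins(prim, b$domains)
    f <- classification_funnel(cls)
    expect_true(f[["lrr_rlk"]] <= f[["tm_kinase"]])
    expect_true(f[["tm_kinase"]] <= f[["kinase"]])
    expect_true(f[["kinase"]] <= f[["proteins"]])
    tg <- ds$truth$genes[ds$truth$genes$species == sp, ]
    # planted membership recovered exactly: precision = recall = 1
    expect_setequal(cls$protein_id[cls$tier == "LRR-RLK"],
                    paste0(tg$gene_id[tg$tier == "LRR-RLK"], ".1"))
    expect_equal(f[["tm_kinase"]] - f[["lrr_rlk"]], sum(tg$tier == "TM-kinase"))
    expect_equal(f[["kinase"]] - f[["tm_kinase"]], sum(tg$tier == "kinase"))
  }
})

test_that("kinase-domain units merge truncated hits under the gap/span rule", {
  pr <- make_proteins(list("p1", "p1", TRUE, raa(900)),
                      list("p2", "p2", TRUE, raa(900)),
                      list("p3", "p3", TRUE, raa(900)),
                      list("p4", "p4", TRUE, raa(900)),
                      list("p5", "p5", TRUE, raa(900)))
  dom <- data.frame(
    protein_id = c("p1", "p2", "p2", "p3", "p3", "p4", "p4", "p5", "p5"),
    accession = "PF00069",
    start = c(10, 10, 161, 10, 600, 10, 350, 10, 100),
    end = c(300, 150, 300, 300, 890, 300, 500, 200, 280))
  kd <- extract_kinase_domains(pr, dom)

  one <- kd[kd$protein_id == "p1", ]
  expect_equal(nrow(one), 1L)
  expect_equal(one$merged_from, 1L)

  # gap 10 aa, merged span 291 aa: merged into one unit
  mrg <- kd[kd$protein_id == "p2", ]
  expect_equal(nrow(mrg), 1L)
  expect_equal(c(mrg$start, mrg$end, mrg$merged_from), c(10, 300, 2))
  expect_identical(mrg$sequence, substr(pr$sequence[pr$protein_id == "p2"], 10, 300))

  # gap 299 aa: a genuine tandem-kinase protein, two units
  two <- kd[kd$protein_id == "p3", ]
  expect_equal(nrow(two), 2L)
  expect_equal(two$unit_index, 1:2)

  # gap 49 aa but merged span 491 > 450: kept separate
  sep <- kd[kd$protein_id == "p4", ]
  expect_equal(nrow(sep), 2L)

  # overlapping raw hits: union taken
  ovl <- kd[kd$protein_id == "p5", ]
  expect_equal(nrow(ovl), 1L)
  expect_equal(c(ovl$start, ovl$end), c(10, 280))

  # unit count >= protein count, equality iff nothing unmergeable
  expect_gte(nrow(kd), length(unique(kd$protein_id)))
})
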