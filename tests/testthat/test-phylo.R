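test_that("Poisson-corrected distances follow the closed form", {
  a <- paste(rep("A", 200), collapse = "")
  half <- paste0(paste(rep("A", 100), collapse = ""), paste(rep("C", 100), collapse = ""))
  aln <- as_alignment(c(x = a, y = a, z = half))
  D <- compute_distances(aln)
  expect_equal(D["x", "y"], 0)
  expect_equal(D["x", "z"], log(2)) # p = 0.5

  # 40 mismatches in 200 shared columns: d = -ln(0.8)
  m40 <- paste0(paste(rep("C", 40), collapse = ""), paste(rep("A", 160), collapse = ""))
  D2 <- compute_distances(as_alignment(c(x = a, y = m40, z = a)))
  expect_equal(D2["x", "y"], -log(1 - 40 / 200))

  # disjoint gap patterns: no shared columns is an error naming the pair
  bad <- as_alignment(c(p = "AC--", q = "--AC", r = "ACAC"))
  expect_error(compute_distances(bad), "zero shared non-gap columns")

  # saturated pair capped
  opp <- chartr("A", "C", a)
  expect_warning(D3 <- compute_distances(as_alignment(c(x = a, y = opp, z = a)), d_max = 7),
                 "capped")
  expect_equal(D3["x", "y"], 7)
})

test_that("three-taxon NJ solves the three-point formulas", {
  dm <- matrix(c(0, 3, 4,
                 3, 0, 5,
                 4, 5, 0), 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- build_nj_tree(dm)
  expect_setequal(tr$tip.label, c("a", "b", "c"))
  el <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(el[["a"]], (3 + 4 - 5) / 2)
  expect_equal(el[["b"]], (3 + 5 - 4) / 2)
  expect_equal(el[["c"]], (4 + 5 - 3) / 2)
  expect_error(build_nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("NJ recovers the quartet topology chosen by the four-point condition", {
  set.seed(21)
  for (rep in 1:20) {
    tr <- ape::rtree(4, br = function(n) runif(n, 0.1, 1))
    dm <- ape::cophenetic.phylo(tr)
    ids <- rownames(dm)
    # oracle: of the three pairings, the additive topology minimizes the sum
    sums <- c(dm[ids[1], ids[2]] + dm[ids[3], ids[4]],
              dm[ids[1], ids[3]] + dm[ids[2], ids[4]],
              dm[ids[1], ids[4]] + dm[ids[2], ids[3]])
    split_oracle <- list(c(ids[1], ids[2]), c(ids[1], ids[3]),
                         c(ids[1], ids[4]))[[which.min(sums)]]
    nj <- build_nj_tree(dm)
    expect_true(ape::is.monophyletic(nj, split_oracle))
  }
})

test_that("NJ exactly recovers random additive trees, matching the reference implementation", {
  set.seed(77)
  for (rep in 1:20) {
    n <- sample(5:12, 1)
    tr <- ape::rtree(n, br = function(k) runif(k, 0.05, 1))
    dm <- ape::cophenetic.phylo(tr)
    mine <- build_nj_tree(dm)
    expect_equal(ape::dist.topo(ape::unroot(tr), mine), 0,
                 ignore_attr = TRUE)
    # independent cross-check: agrees with ape's NJ topology
    expect_equal(ape::dist.topo(ape::nj(dm), mine), 0, ignore_attr = TRUE)
  }
})

test_that("bootstrap supports behave at the forced extremes", {
  set.seed(9)
  fam1 <- raa(120); fam2 <- raa(120)
  seqs <- setNames(c(vapply(1:4, function(i) familyscope:::mutate_protein(fam1, 0.05), character(1)),
                     vapply(1:4, function(i) familyscope:::mutate_protein(fam2, 0.05), character(1))),
                   c(paste0("a", 1:4), paste0("b", 1:4)))
  aln <- progressive_align(seqs)
  tree <- bootstrap_support(aln, n_replicates = 30, seed = 2)
  # the edge separating the two planted families has full support
  clades <- find_well_supported_clades(tree, support_threshold = 0.95)
  tipsets <- lapply(clades, `[[`, "tips")
  expect_true(any(vapply(tipsets, function(t) setequal(t, paste0("a", 1:4)), logical(1)) |
                  vapply(tipsets, function(t) setequal(t, paste0("b", 1:4)), logical(1))))

  one <- bootstrap_support(aln, n_replicates = 1, seed = 5)
  sup <- familyscope:::node_supports(one)
  expect_true(all(sup[!is.na(sup)] %in% c(0, 1)))
  expect_error(bootstrap_support(aln, n_replicates = 0), "n_replicates")
})

test_that("bootstrap supports are invariant to tip-order permutation", {
  set.seed(14)
  base <- raa(100)
  seqs <- setNames(vapply(1:6, function(i) familyscope:::mutate_protein(base, 0.15),
                          character(1)), paste0("s", 1:6))
  t1 <- bootstrap_support(progressive_align(seqs), n_replicates = 20, seed = 8)
  perm <- seqs[c(4, 2, 6, 1, 5, 3)]
  t2 <- bootstrap_support(progressive_align(perm), n_replicates = 20, seed = 8)
  k1 <- familyscope:::bipartition_keys(t1)
  k2 <- familyscope:::bipartition_keys(t2)
  s1 <- setNames(familyscope:::node_supports(t1)[as.integer(names(k1)) - 6], k1)
  s2 <- setNames(familyscope:::node_supports(t2)[as.integer(names(k2)) - 6], k2)
  shared <- intersect(names(s1), names(s2))
  expect_gt(length(shared), 0)
  expect_equal(s1[shared], s2[shared])
})

test_that("well-supported clade enumeration matches an exhaustive edge scan", {
  txt <- "(((a:1,b:1)0.9:1,(c:1,d:1)0.5:1)0.8:1,(e:1,(f:1,g:1)1.0:1)0.6:1,h:1);"
  tree <- ape::read.tree(text = txt)
  cl <- find_well_supported_clades(tree, support_threshold = 0.70)
  got <- lapply(cl, `[[`, "tips")
  # oracle: scan every internal node by hand
  sup <- as.numeric(tree$node.label)
  expect_setequal(vapply(got, function(t) paste(sort(t), collapse = ","), character(1)),
                  c("a,b", "a,b,c,d", "f,g"))
  # nested clade links to its smallest enclosing reported clade
  ab <- which(vapply(got, function(t) setequal(t, c("a", "b")), logical(1)))
  expect_equal(sort(got[[cl[[ab]]$parent]]), c("a", "b", "c", "d"))

  all_hi <- ape::read.tree(text = "((a:1,b:1)1:1,(c:1,d:1)1:1,e:1);")
  expect_length(find_well_supported_clades(all_hi, 0.7), 2L)
  all_lo <- ape::read.tree(text = "((a:1,b:1)0.5:1,(c:1,d:1)0.5:1,e:1);")
  expect_length(find_well_supported_clades(all_lo, 0.7), 0L)
})

test_that("subfamily assignment propagates labels only through supported homogeneous clades", {
  txt <- "((q1:1,r1:1)0.9:1,(q2:1,r2:1)0.6:1,(q3:1,(r3:1,r4:1)0.95:0.5)0.9:1,og:3);"
  tree <- ape::read.tree(text = txt)
  labs <- c(r1 = "III", r2 = "V", r3 = "X", r4 = "XI", og = "outgroup")
  asg <- assign_subfamily_groups(tree, labs, support_threshold = 0.70, root = FALSE)
  expect_identical(unname(asg["q1"]), "III")       # supported, homogeneous
  expect_identical(unname(asg["q2"]), "unassigned") # support 0.6 below cut
  expect_identical(unname(asg["q3"]), "unassigned") # mixed references: never guessed
  # references keep their prior labels
  expect_identical(unname(asg[c("r1", "r2", "r3", "r4")]), c("III", "V", "X", "XI"))
  expect_error(assign_subfamily_groups(tree, c(zz = "I")), "no labelled reference")
})

test_that("group XII splits into XIIa/XIIb by exemplar clades", {
  txt <- "((q1:1,(ra1:1,ra2:1)0.9:1)0.9:1,(q2:1,(rb1:1,rb2:1)0.9:1)0.9:1,og:3);"
  tree <- ape::read.tree(text = txt)
  labs <- c(ra1 = "XIIa", ra2 = "XIIa", rb1 = "XIIb", rb2 = "XIIb", og = "outgroup")
  asg <- c(q1 = "XII", q2 = "XII", ra1 = "XIIa", ra2 = "XIIa",
           rb1 = "XIIb", rb2 = "XIIb", og = "outgroup")
  out <- split_group_xii(tree, asg, labs)
  expect_identical(unname(out["q1"]), "XIIa")
  expect_identical(unname(out["q2"]), "XIIb") # the two-exemplar clade role
  labs_no_b <- labs[labs != "XIIb"]
  expect_warning(out2 <- split_group_xii(tree, asg, labs_no_b), "XIIb")
  expect_identical(unname(out2[c("q1", "q2")]), c("XIIa", "XIIa"))
})

test_that("assignment recovers every planted group on noise-free synthetic data", {
  ds <- small_dataset()
  prim <- filter_primary_transcripts(ds$species$spA$proteins)
  cls <- classify_proteins(prim, ds$species$spA$domains)
  kds <- extract_kinase_domains(prim[prim$protein_id %in%
                                       cls$protein_id[cls$tier == "LRR-RLK"], ],
                                ds$species$spA$domains)
  ref_kds <- familyscope:::reference_kd_sequences(ds$reference, pipeline_params())
  aln <- progressive_align(c(setNames(kds$sequence, kds$protein_id), ref_kds))
  tree <- bootstrap_support(aln, n_replicates = 30, seed = 1)
  asg <- assign_subfamily_groups(tree, ds$reference$labels)
  tg <- ds$truth$genes
  qt <- setdiff(names(asg), ds$reference$labels$protein_id)
  expect_identical(unname(asg[qt]),
                   tg$group[match(sub("\\.1$", "", qt), tg$gene_id)])
})
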