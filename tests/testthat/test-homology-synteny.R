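test_that("local alignment scores match an independent Smith-Waterman oracle", {
  S <- matrix(-1, 20, 20, dimnames = list(familyscope:::AA_ALPHABET,
                                          familyscope:::AA_ALPHABET))
  diag(S) <- 2
  set.seed(4)
  for (i in 1:6) {
    q <- raa(6); s <- raa(6)
    hits <- pairwise_similarity_search(setNames(q, "q"), setNames(s, "s"),
                                       substitution_matrix = S,
                                       gap_opening = 0, gap_extension = 2)
    expect_equal(hits$score, sw_local_score(q, s, match = 2, mismatch = -1, gap = -2))
  }
})

test_that("a query identical to a subject ranks it first with the self score", {
  set.seed(6)
  subj <- setNames(c(raa(80), raa(80), raa(80)), c("s1", "s2", "s3"))
  q <- setNames(subj[["s2"]], "q")
  hits <- pairwise_similarity_search(q, subj)
  top <- hits[hits$rank == 1L, ]
  expect_identical(top$subject_id, "s2")
  expect_equal(top$identity, 100)
  expect_true(all(hits$score[hits$rank > 1] <= top$score))
})

test_that("bidirectional best hits require mutual rank-1", {
  ab <- data.frame(query_id = c("a1", "a1", "a2", "a2"),
                   subject_id = c("b1", "b2", "b2", "b1"),
                   score = c(10, 5, 9, 3), identity = 90, rank = c(1, 2, 1, 2))
  ba <- data.frame(query_id = c("b1", "b1", "b2", "b2"),
                   subject_id = c("a1", "a2", "a1", "a2"),
                   score = c(10, 4, 8, 7), identity = 90, rank = c(1, 2, 1, 2))
  pairs <- bidirectional_best_hits(ab, ba)
  # a1<->b1 mutual; a2->b2 but b2->a1: no pair
  expect_equal(nrow(pairs), 1L)
  expect_identical(c(pairs$gene_a, pairs$gene_b), c("a1", "b1"))

  # symmetry: swapping the two species gives the same pair set
  rev <- bidirectional_best_hits(ba, ab)
  expect_setequal(paste(pairs$gene_a, pairs$gene_b),
                  paste(rev$gene_b, rev$gene_a))
})

test_that("clade confirmation flags co-clustered, split, and untestable pairs", {
  pairs <- data.frame(gene_a = c("a1", "a2", "a3"), gene_b = c("b1", "b2", "b3"),
                      bbh = TRUE, score_ab = 1, score_ba = 1)
  clades <- list(list(tips = c("a1", "b1", "x"), support = 0.9, node = 1, parent = NA),
                 list(tips = c("a2", "x"), support = 0.8, node = 2, parent = NA),
                 list(tips = c("b2", "y"), support = 0.8, node = 3, parent = NA))
  out <- confirm_orthologs_by_clade(pairs, clades)
  expect_identical(out$clade_confirmed, c(TRUE, FALSE, NA))
})

test_that("planted ortholog pairs are mutual best hits against paralog decoys", {
  cfg <- small_cfg(n_families = 5L, members_per_family_range = c(3L, 3L),
                   ortholog_fraction = 2 / 3, n_synteny_segments = 0L,
                   n_chromosomes = 4L, chromosome_length = 1.6e6, seed = 27)
  ds <- simulate_rlk_dataset(cfg)
  prot <- function(sp) {
    tg <- ds$truth$genes
    ids <- paste0(tg$gene_id[tg$species == sp & tg$tier == "LRR-RLK"], ".1")
    b <- ds$species[[sp]]$proteins
    setNames(b$sequence[match(ids, b$protein_id)], ids)
  }
  pa <- prot("spA"); pb <- prot("spB")
  pairs <- bidirectional_best_hits(pairwise_similarity_search(pa, pb),
                                   pairwise_similarity_search(pb, pa))
  got <- paste(sub("\\.1$", "", pairs$gene_a), sub("\\.1$", "", pairs$gene_b))
  want <- paste(ds$truth$ortholog_pairs$gene_a, ds$truth$ortholog_pairs$gene_b)
  expect_setequal(got, want) # precision = recall = 1 at zero mutation
})

test_that("anchors cover identical sequences and respect strand", {
  set.seed(44)
  s <- rnt(5000)
  a <- find_anchors(s, s)
  expect_equal(nrow(a), 1L)
  expect_equal(c(a$pos_a, a$pos_b, a$length), c(1, 1, 5000))
  expect_identical(a$orientation, "same")

  rc <- familyscope:::revcomp(s)
  inv <- find_anchors(s, rc)
  expect_equal(nrow(inv), 1L)
  expect_identical(inv$orientation, "inverted")
  expect_equal(c(inv$pos_a, inv$pos_b, inv$length), c(1, 1, 5000))

  expect_equal(nrow(find_anchors(rnt(2000), rnt(2000))), 0L)
  expect_error(find_anchors(s, s, k = 4), "k must be")
})

test_that("anchors tile a mutated planted segment", {
  set.seed(55)
  seg <- rnt(2000)
  chr_a <- paste0(rnt(10000), seg, rnt(10000))
  chr_b <- paste0(rnt(8000), mutate_sequence(seg, 0.01, seed = 5), rnt(12000))
  a <- find_anchors(chr_a, chr_b)
  in_seg <- a[a$pos_a >= 10001 & a$pos_a + a$length - 1 <= 12000, ]
  covered <- sum(in_seg$length)
  expect_gte(covered / 2000, 0.8)
})

test_that("block chaining follows the interval-arithmetic oracle and the length floor", {
  one <- data.frame(pos_a = 100, pos_b = 500, length = 1200, orientation = "same")
  bl <- chain_synteny_blocks(one)
  expect_equal(nrow(bl), 1L)
  expect_equal(c(bl$start_a, bl$end_a, bl$length), c(100, 1299, 1200))

  short <- data.frame(pos_a = 100, pos_b = 500, length = 800, orientation = "same")
  expect_equal(nrow(chain_synteny_blocks(short)), 0L)

  # two collinear anchors 3 kb apart merge into one block spanning both
  two <- data.frame(pos_a = c(100, 3700), pos_b = c(500, 4100),
                    length = c(600, 600), orientation = "same")
  m <- chain_synteny_blocks(two)
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start_a, m$end_a, m$n_anchors), c(100, 4299, 2))

  # 50 kb apart: two candidate chains, both below the 1,000 bp floor
  far <- data.frame(pos_a = c(100, 50700), pos_b = c(500, 51100),
                    length = c(600, 600), orientation = "same")
  expect_equal(nrow(chain_synteny_blocks(far)), 0L)
  # raising the floor above a chain's span drops it
  expect_equal(nrow(chain_synteny_blocks(two, min_block_length = 5000)), 0L)
  # every reported block honours the floor
  set.seed(66)
  anc <- data.frame(pos_a = sort(sample.int(1e5, 30)),
                    pos_b = sort(sample.int(1e5, 30)),
                    length = sample(50:400, 30, replace = TRUE),
                    orientation = "same")
  bl2 <- chain_synteny_blocks(anc)
  if (nrow(bl2)) expect_true(all(bl2$length >= 1000))
})

test_that("the genome scan recovers planted syntenic segments", {
  ds <- small_dataset()
  sb <- synteny_scan(ds$species$spA$genome, ds$species$spB$genome)
  pb <- ds$truth$planted_blocks
  expect_gt(nrow(pb), 0)
  for (i in seq_len(nrow(pb))) {
    hit <- sb[sb$chrom_a == pb$chrom_a[i] & sb$chrom_b == pb$chrom_b[i] &
                sb$start_a <= pb$end_a[i] & sb$end_a >= pb$start_a[i], ]
    expect_gt(nrow(hit), 0)
  }
})
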