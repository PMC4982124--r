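# Synthetic two-species LRR-RLK genome simulator with planted ground truth.
#
# The generator emits, per species, a genome FASTA, a GFF3 with
# gene/mRNA/CDS features (mRNAs carry a primary=true|false attribute), a
# proteome FASTA and an InterProScan-style domain table, plus a labelled
# reference proteome (the Arabidopsis role) and a truth table covering
# every downstream stage: family membership, subfamily group, catalytic
# loop class, tandem arrays, ortholog pairs and planted syntenic segments.

# One sense codon per amino acid keeps reverse translation trivial;
# codon usage realism is deliberately out of scope.
CODON_OF_AA <- c(
  A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT", G = "GGT",
  H = "CAT", I = "ATT", K = "AAA", L = "CTT", M = "ATG", N = "AAT",
  P = "CCT", Q = "CAA", R = "CGT", S = "TCT", T = "ACT", V = "GTT",
  W = "TGG", Y = "TAT"
)
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Configuration for the synthetic dataset generator
#'
#' Collects and validates every tunable of [simulate_rlk_dataset()]. The
#' defaults describe a small but fully featured pair of related genomes:
#' one gene family per subfamily group (I-XVI with XII split into XIIa and
#' XIIb), a minority of families arranged as tandem arrays, most members
#' shared between the two species as one-to-one orthologs, and catalytic
#' loop classes drawn with the non-RD class in the majority, as observed
#' in LRR-XII receptor kinases.
#'
#' @param n_families Number of planted LRR-RLK gene families.
#' @param members_per_family_range Integer vector `c(min, max)`; the
#'   member count of each family is drawn uniformly from this range.
#' @param n_chromosomes Chromosomes per species.
#' @param chromosome_length Chromosome length in bp. Must be large enough
#'   to hold all planted genes; otherwise generation stops with a
#'   capacity error.
#' @param tandem_array_fraction Fraction of families laid out as tandem
#'   arrays (members adjacent on one chromosome, neighbour gaps well
#'   under the 200 kb clustering window).
#' @param ortholog_fraction Fraction of each family's members present in
#'   both species as a planted one-to-one ortholog pair; the remaining
#'   members are species-specific paralog decoys.
#' @param motif_class_probs Named probabilities over `RD`, `nonRD`, `ACF`
#'   for the catalytic-loop class of each family; must sum to 1.
#' @param nonRD_residue_weights Named probabilities over the residues
#'   `C`, `G`, `S`, `Y`, `W` substituting the arginine in non-RD loops.
#' @param mutation_rate Per-site nucleotide substitution rate applied on
#'   the branch from each member ancestor to its copy in each species;
#'   in `[0, 0.5]`.
#' @param seed Integer seed; the same configuration and seed reproduce
#'   byte-identical output files.
#' @param paralog_divergence Per-site substitution rate on the branch
#'   from the family ancestor to each member ancestor; keeps paralogs
#'   more distant than orthologs so reciprocal-best-hit recovery is
#'   well-posed.
#' @param alt_transcript_fraction Fraction of genes that also emit an
#'   alternative (non-primary) transcript, so the splice-variant
#'   exclusion filter has work to do.
#' @param split_kd_fraction Fraction of families whose kinase domain is
#'   annotated as two truncated hits separated by a small gap, so the
#'   KD merge rule is exercised.
#' @param n_decoy_kinase,n_decoy_tm_kinase Per species, numbers of
#'   planted kinase-only and TM-kinase-only decoy genes (no LRRs).
#' @param n_synteny_segments,synteny_segment_length Number and length
#'   (bp) of intergenic segments copied between the two genomes as
#'   planted syntenic blocks.
#' @param n_outgroup Number of divergent outgroup kinase sequences in
#'   the reference bundle, used to root trees.
#' @param family_divergence Per-residue divergence of each family's
#'   kinase domain from the shared kinase-domain scaffold; all planted
#'   kinase domains are homologous, as real ones are, so they remain
#'   alignable across families.
#' @param outgroup_divergence Per-residue divergence of the outgroup
#'   kinase family from the scaffold; larger than `family_divergence`
#'   so the outgroup attaches outside the ingroup radiation.
#' @return An object of class `"generator_config"`.
#' @export
generator_config <- function(n_families = 17L,
                             members_per_family_range = c(2L, 3L),
                             n_chromosomes = 5L,
                             chromosome_length = 2.5e6,
                             tandem_array_fraction = 0.3,
                             ortholog_fraction = 0.7,
                             motif_class_probs = c(RD = 0.25, nonRD = 0.65, ACF = 0.10),
                             nonRD_residue_weights = c(C = 0.55, G = 0.40, S = 0.02, Y = 0.02, W = 0.01),
                             mutation_rate = 0,
                             seed = 1L,
                             paralog_divergence = 0.08,
                             alt_transcript_fraction = 0.3,
                             split_kd_fraction = 0.2,
                             n_decoy_kinase = 5L,
                             n_decoy_tm_kinase = 5L,
                             n_synteny_segments = 4L,
                             synteny_segment_length = 2000L,
                             n_outgroup = 3L,
                             family_divergence = 0.30,
                             outgroup_divergence = 0.45) {
  cfg <- list(
    n_families = as.integer(n_families),
    members_per_family_range = as.integer(members_per_family_range),
    n_chromosomes = as.integer(n_chromosomes),
    chromosome_length = as.numeric(chromosome_length),
    tandem_array_fraction = tandem_array_fraction,
    ortholog_fraction = ortholog_fraction,
    motif_class_probs = motif_class_probs,
    nonRD_residue_weights = nonRD_residue_weights,
    mutation_rate = mutation_rate,
    seed = as.integer(seed),
    paralog_divergence = paralog_divergence,
    alt_transcript_fraction = alt_transcript_fraction,
    split_kd_fraction = split_kd_fraction,
    n_decoy_kinase = as.integer(n_decoy_kinase),
    n_decoy_tm_kinase = as.integer(n_decoy_tm_kinase),
    n_synteny_segments = as.integer(n_synteny_segments),
    synteny_segment_length = as.integer(synteny_segment_length),
    n_outgroup = as.integer(n_outgroup),
    family_divergence = family_divergence,
    outgroup_divergence = outgroup_divergence
  )
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  stopifnot(cfg$n_families >= 0L, cfg$n_chromosomes >= 1L)
  if (length(cfg$members_per_family_range) != 2L ||
      cfg$members_per_family_range[1] < 1L ||
      cfg$members_per_family_range[1] > cfg$members_per_family_range[2])
    stop("members_per_family_range must be c(min, max) with 1 <= min <= max")
  for (f in c("tandem_array_fraction", "ortholog_fraction",
              "alt_transcript_fraction", "split_kd_fraction")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || v < 0 || v > 1) stop(f, " must be in [0, 1]")
  }
  if (cfg$mutation_rate < 0 || cfg$mutation_rate > 0.5)
    stop("mutation_rate must be in [0, 0.5]")
  if (cfg$paralog_divergence < 0 || cfg$paralog_divergence > 0.5)
    stop("paralog_divergence must be in [0, 0.5]")
  if (cfg$family_divergence < 0 || cfg$family_divergence > 0.9 ||
      cfg$outgroup_divergence < 0 || cfg$outgroup_divergence > 0.9)
    stop("family_divergence and outgroup_divergence must be in [0, 0.9]")
  p <- cfg$motif_class_probs
  if (!setequal(names(p), c("RD", "nonRD", "ACF")) || abs(sum(p) - 1) > 1e-9)
    stop("motif_class_probs must be named RD/nonRD/ACF and sum to 1")
  w <- cfg$nonRD_residue_weights
  if (is.null(names(w)) || any(!names(w) %in% c("C", "G", "S", "Y", "W")) ||
      abs(sum(w) - 1) > 1e-9)
    stop("nonRD_residue_weights must be named over C/G/S/Y/W and sum to 1")
  invisible(cfg)
}

#' Plant a catalytic-loop motif into a kinase-domain template
#'
#' Rewrites the catalytic loop of an amino-acid kinase-domain template at
#' its H-R-D site: `RD` leaves the conserved His-Arg-Asp tripeptide in
#' place, `nonRD` substitutes the arginine with the requested residue,
#' and `ACF` (alternative catalytic function) replaces the catalytic
#' aspartate with alanine, producing a degenerate loop.
#'
#' @param kd_template Amino-acid string containing a literal `"HRD"` run
#'   (the designated catalytic-loop site).
#' @param motif_class One of `"RD"`, `"nonRD"`, `"ACF"`.
#' @param residue Single residue replacing the arginine for `nonRD`;
#'   requesting `"R"` contradicts the non-RD class and is an error.
#' @return The rewritten amino-acid string, with the 1-based position of
#'   the loop histidine in attribute `"loop_pos"`.
#' @export
plant_kinase_motif <- function(kd_template, motif_class = c("RD", "nonRD", "ACF"),
                               residue = NULL) {
  motif_class <- match.arg(motif_class)
  pos <- regexpr("HRD", kd_template, fixed = TRUE)[1]
  if (pos < 0) stop("kd_template contains no HRD catalytic-loop site")
  chars <- str_chars(kd_template)
  if (motif_class == "nonRD") {
    if (is.null(residue)) stop("nonRD planting requires a substituting residue")
    residue <- toupper(residue)
    if (identical(residue, "R"))
      stop("contradiction: residue R requested for a non-RD motif")
    chars[pos + 1L] <- residue
  } else if (motif_class == "ACF") {
    chars[pos + 2L] <- "A"
  }
  structure(chars_str(chars), loop_pos = as.integer(pos))
}

#' Mutate a nucleotide sequence at a fixed substitution rate
#'
#' Applies independent per-site substitutions (uniform over the three
#' alternative bases). Positions listed in `mask` are protected; the
#' generator uses this to shield planted motif codons and domain-boundary
#' codons from noise.
#'
#' @param seq Nucleotide string (ACGT).
#' @param rate Substitution probability per site, in `[0, 0.5]`.
#' @param seed Optional integer seed; when given, the caller's RNG stream
#'   is left untouched.
#' @param mask Optional integer vector of 1-based protected positions.
#' @return Mutated nucleotide string.
#' @export
mutate_sequence <- function(seq, rate, seed = NULL, mask = NULL) {
  if (!is.numeric(rate) || rate < 0 || rate > 0.5)
    stop("rate must be in [0, 0.5]")
  if (rate == 0) return(seq)
  with_seed(seed, {
    chars <- str_chars(seq)
    hit <- runif(length(chars)) < rate
    if (!is.null(mask)) hit[mask] <- FALSE
    idx <- which(hit)
    if (length(idx)) {
      # draw one of the three non-identical bases per hit site
      for (i in idx) chars[i] <- sample(setdiff(DNA_BASES, chars[i]), 1L)
    }
    chars_str(chars)
  })
}

reverse_translate <- function(protein, add_stop = TRUE) {
  codons <- CODON_OF_AA[str_chars(protein)]
  if (anyNA(codons)) stop("protein contains residues outside the 20-letter alphabet")
  paste0(paste(codons, collapse = ""), if (add_stop) "TAA" else "")
}

# Replace internal stop codons introduced by mutation with the ancestor codon.
sanitize_cds <- function(cds, ancestor_cds) {
  n <- nchar(cds)
  starts <- seq(1L, n - 3L, by = 3L) # exclude terminal stop codon
  codons <- substring(cds, starts, starts + 2L)
  bad <- which(codons %in% STOP_CODONS)
  if (length(bad)) {
    chars <- str_chars(cds)
    anc <- str_chars(ancestor_cds)
    for (b in bad) {
      ix <- (starts[b]):(starts[b] + 2L)
      chars[ix] <- anc[ix]
    }
    cds <- chars_str(chars)
  }
  cds
}

rand_aa <- function(n) chars_str(sample(AA_ALPHABET, n, replace = TRUE))

# Amino-acid level point substitutions, protecting masked positions.
mutate_protein <- function(seq, rate, mask = integer()) {
  chars <- str_chars(seq)
  hit <- runif(length(chars)) < rate
  hit[mask] <- FALSE
  idx <- which(hit)
  for (i in idx) chars[i] <- sample(setdiff(AA_ALPHABET, chars[i]), 1L)
  chars_str(chars)
}

# A fresh kinase-domain scaffold with the HRD loop planted at loop_at as
# its first occurrence.
kd_scaffold <- function(kd_len = 280L, loop_at = 131L) {
  chars <- str_chars(rand_aa(kd_len))
  chars[loop_at:(loop_at + 2L)] <- c("H", "R", "D")
  scrub_preloop_hrd(chars_str(chars), loop_at)
}

# Remove any HRD occurrence before the designated loop so the loop is
# always the first (anchor-locatable) occurrence.
scrub_preloop_hrd <- function(kd, loop_at) {
  repeat {
    first <- regexpr("HRD", kd, fixed = TRUE)[1]
    if (first < 0 || first >= loop_at) return(kd)
    chars <- str_chars(kd)
    chars[first + 1L] <- "K"
    kd <- chars_str(chars)
  }
}

# Architecture of one planted gene; returns sequence, domain rows and
# protein-coordinate landmarks. `tier` picks which elements are present.
build_architecture <- function(tier = c("LRR-RLK", "TM-kinase", "kinase"),
                               motif_class = "RD", residue = NULL,
                               split_kd = FALSE, lrr_accession = "PF13855",
                               kinase_accession = "PF00069",
                               kd_base = NULL, kd_divergence = 0) {
  tier <- match.arg(tier)
  loop_at <- 131L # position of the H within the KD
  if (is.null(kd_base)) kd_base <- kd_scaffold()
  kd <- kd_base
  if (kd_divergence > 0)
    kd <- mutate_protein(kd, kd_divergence, mask = loop_at:(loop_at + 2L))
  kd <- scrub_preloop_hrd(kd, loop_at)
  kd <- plant_kinase_motif(kd, motif_class, residue)

  pieces <- list(nterm = rand_aa(20L))
  dom <- list()
  if (tier == "LRR-RLK") {
    for (r in 1:3) pieces[[paste0("lrr", r)]] <- rand_aa(24L)
    pieces$linker <- rand_aa(8L)
  }
  if (tier %in% c("LRR-RLK", "TM-kinase")) {
    pieces$tm <- chars_str(sample(c("A", "I", "L", "V", "F", "M", "W"), 23L, replace = TRUE))
    pieces$juxta <- rand_aa(15L)
  }
  pieces$kd <- as.character(kd)
  pieces$tail <- rand_aa(15L)

  seq <- paste(unlist(pieces), collapse = "")
  off <- 0L
  coords <- list()
  for (nm in names(pieces)) {
    len <- nchar(pieces[[nm]])
    coords[[nm]] <- c(off + 1L, off + len)
    off <- off + len
  }
  rows <- list()
  if (tier == "LRR-RLK") {
    for (r in 1:3) {
      cc <- coords[[paste0("lrr", r)]]
      rows[[length(rows) + 1L]] <- data.frame(accession = lrr_accession,
                                              start = cc[1], end = cc[2])
    }
  }
  if (tier %in% c("LRR-RLK", "TM-kinase")) {
    cc <- coords$tm
    rows[[length(rows) + 1L]] <- data.frame(accession = TM_ACCESSION,
                                            start = cc[1], end = cc[2])
  }
  kc <- coords$kd
  if (split_kd) {
    # two truncated kinase hits, 10 aa apart: merged downstream into one unit
    rows[[length(rows) + 1L]] <- data.frame(accession = kinase_accession,
                                            start = kc[1], end = kc[1] + 139L)
    rows[[length(rows) + 1L]] <- data.frame(accession = kinase_accession,
                                            start = kc[1] + 150L, end = kc[2])
  } else {
    rows[[length(rows) + 1L]] <- data.frame(accession = kinase_accession,
                                            start = kc[1], end = kc[2])
  }
  list(
    sequence = seq,
    domains = do.call(rbind, rows),
    kd_start = kc[1], kd_end = kc[2],
    loop_pos = kc[1] + loop_at - 1L # protein coordinate of the loop H
  )
}

#' Generate a synthetic two-species LRR-RLK dataset with planted truth
#'
#' Builds two related species genomes plus a labelled reference proteome.
#' Each planted LRR-RLK family descends from a random ancestor protein
#' (N-terminal region, three LRR repeats, one TM helix, a kinase domain
#' with a planted catalytic loop, C-terminal tail). Member ancestors
#' diverge from the family ancestor at `paralog_divergence`; each species
#' copy diverges from its member ancestor at `mutation_rate`. Motif
#' codons and domain-boundary codons are shielded from mutation, and
#' mutations creating internal stop codons are reverted, so proteins stay
#' exact translations of their single-exon CDS.
#'
#' @param config A [generator_config()].
#' @param out_dir Optional directory; when given the bundles are also
#'   written to disk (see [write_dataset()]).
#' @return An object of class `"rlk_dataset"`: per-species bundles
#'   (`genome`, `proteins`, `domains`, `loci`, `transcripts`), a
#'   `reference` bundle (proteome, domains, labels), and `truth`, the
#'   machine-readable truth table.
#' @export
simulate_rlk_dataset <- function(config = generator_config(), out_dir = NULL) {
  validate_generator_config(config)
  ds <- with_seed(config$seed, generate_dataset_impl(config))
  ds$config <- config
  class(ds) <- "rlk_dataset"
  if (!is.null(out_dir)) write_dataset(ds, out_dir)
  ds
}

generate_dataset_impl <- function(cfg) {
  species <- c("spA", "spB")
  nf <- cfg$n_families

  # ---- family plans -------------------------------------------------
  fam_group <- if (nf > 0) GROUP_LABELS[(seq_len(nf) - 1L) %% length(GROUP_LABELS) + 1L] else character()
  fam_class <- character(nf); fam_residue <- rep(NA_character_, nf)
  tandem_fams <- if (nf > 0) sort(sample(nf, round(cfg$tandem_array_fraction * nf))) else integer()
  split_fams <- if (nf > 0) sort(sample(nf, round(cfg$split_kd_fraction * nf))) else integer()

  scaffold <- kd_scaffold() # shared ancestral kinase domain

  genes <- list()      # per-gene truth rows
  prot_seqs <- list(spA = list(), spB = list())
  dom_rows <- list(spA = list(), spB = list())
  units <- list(spA = list(), spB = list()) # placement units
  ortholog_pairs <- list()
  ref_seqs <- list(); ref_doms <- list(); ref_labels <- list()

  for (f in seq_len(nf)) {
    cls <- sample(names(cfg$motif_class_probs), 1L, prob = cfg$motif_class_probs)
    res <- if (cls == "nonRD")
      sample(names(cfg$nonRD_residue_weights), 1L, prob = cfg$nonRD_residue_weights)
    else NA_character_
    fam_class[f] <- cls; fam_residue[f] <- res
    arch <- build_architecture(
      "LRR-RLK", motif_class = cls, residue = res,
      split_kd = f %in% split_fams,
      lrr_accession = LRR_ACCESSIONS[(f - 1L) %% length(LRR_ACCESSIONS) + 1L],
      kinase_accession = KINASE_ACCESSIONS[(f - 1L) %% 2L + 1L],
      kd_base = scaffold, kd_divergence = cfg$family_divergence
    )
    anc_cds <- reverse_translate(arch$sequence)
    # protect motif codons, domain-boundary codons and the stop codon
    prot_aa <- c(arch$loop_pos:(arch$loop_pos + 2L),
                 arch$domains$start, arch$domains$end)
    mask <- unique(c(unlist(lapply(prot_aa, function(p) (3L * (p - 1L) + 1L):(3L * p))),
                     (nchar(anc_cds) - 2L):nchar(anc_cds)))

    mm <- cfg$members_per_family_range
    nm <- mm[1] + sample.int(mm[2] - mm[1] + 1L, 1L) - 1L
    n_shared <- round(cfg$ortholog_fraction * nm)
    for (m in seq_len(nm)) {
      mem_cds <- sanitize_cds(
        mutate_sequence(anc_cds, cfg$paralog_divergence, mask = mask), anc_cds)
      in_sp <- if (m <= n_shared) species else species[(m %% 2L) + 1L]
      ids <- setNames(sprintf("%s_F%02dM%d", in_sp, f, m), in_sp)
      for (sp in in_sp) {
        cds <- sanitize_cds(
          mutate_sequence(mem_cds, cfg$mutation_rate, mask = mask), mem_cds)
        prot <- substr(as.character(Biostrings::translate(
          Biostrings::DNAString(cds), no.init.codon = TRUE)), 1L,
          (nchar(cds) / 3L) - 1L)
        gid <- ids[[sp]]
        prot_seqs[[sp]][[paste0(gid, ".1")]] <- as.character(prot)
        d <- arch$domains
        d$protein_id <- paste0(gid, ".1")
        dom_rows[[sp]][[gid]] <- d
        genes[[length(genes) + 1L]] <- data.frame(
          gene_id = gid, species = sp, family = f, group = fam_group[f],
          motif_class = cls, nonrd_residue = res, tier = "LRR-RLK",
          tandem_family = f %in% tandem_fams,
          kd_start = arch$kd_start, kd_end = arch$kd_end,
          loop_pos = arch$loop_pos, cds = cds,
          stringsAsFactors = FALSE)
      }
      if (length(in_sp) == 2L)
        ortholog_pairs[[length(ortholog_pairs) + 1L]] <-
          data.frame(gene_a = ids[["spA"]], gene_b = ids[["spB"]])
    }
    # reference exemplar(s): the family ancestor, labelled with its group
    rid <- sprintf("REF_F%02d", f)
    ref_seqs[[rid]] <- arch$sequence
    rd <- arch$domains; rd$protein_id <- rid
    ref_doms[[rid]] <- rd
    ref_labels[[rid]] <- fam_group[f]
    if (fam_group[f] == "XIIb") { # second exemplar, the At1g35710/At4g08850 role
      rid2 <- sprintf("REF_F%02db", f)
      ex2 <- sanitize_cds(mutate_sequence(anc_cds, 0.03, mask = mask), anc_cds)
      p2 <- substr(as.character(Biostrings::translate(Biostrings::DNAString(ex2),
                                                      no.init.codon = TRUE)),
                   1L, (nchar(ex2) / 3L) - 1L)
      ref_seqs[[rid2]] <- p2
      rd2 <- arch$domains; rd2$protein_id <- rid2
      ref_doms[[rid2]] <- rd2
      ref_labels[[rid2]] <- "XIIb"
    }
  }

  genes_df <- if (length(genes)) do.call(rbind, genes) else
    data.frame(gene_id = character(), species = character(), family = integer(),
               group = character(), motif_class = character(),
               nonrd_residue = character(), tier = character(),
               tandem_family = logical(), kd_start = integer(),
               kd_end = integer(), loop_pos = integer(), cds = character(),
               stringsAsFactors = FALSE)

  # ---- decoys -------------------------------------------------------
  decoys <- list()
  for (sp in species) {
    for (tier in c("kinase", "TM-kinase")) {
      nd <- if (tier == "kinase") cfg$n_decoy_kinase else cfg$n_decoy_tm_kinase
      tag <- if (tier == "kinase") "DK" else "DT"
      for (i in seq_len(nd)) {
        arch <- build_architecture(tier, motif_class = "RD")
        cds <- reverse_translate(arch$sequence)
        gid <- sprintf("%s_%s%02d", sp, tag, i)
        prot_seqs[[sp]][[paste0(gid, ".1")]] <- arch$sequence
        d <- arch$domains; d$protein_id <- paste0(gid, ".1")
        dom_rows[[sp]][[gid]] <- d
        decoys[[length(decoys) + 1L]] <- data.frame(
          gene_id = gid, species = sp, tier = tier, cds = cds,
          stringsAsFactors = FALSE)
      }
    }
  }
  decoys_df <- if (length(decoys)) do.call(rbind, decoys) else
    data.frame(gene_id = character(), species = character(),
               tier = character(), cds = character(), stringsAsFactors = FALSE)

  # ---- shared intergenic segments (planted synteny) -----------------
  seg_seqs <- replicate(cfg$n_synteny_segments,
                        chars_str(sample(DNA_BASES, cfg$synteny_segment_length,
                                         replace = TRUE)))

  # ---- placement ----------------------------------------------------
  placed <- list()
  blocks <- list()
  seg_pos <- list(spA = list(), spB = list())
  for (sp in species) {
    u <- list()
    sp_genes <- genes_df[genes_df$species == sp, , drop = FALSE]
    for (f in unique(sp_genes$family)) {
      fg <- sp_genes[sp_genes$family == f, , drop = FALSE]
      if (f %in% tandem_fams && nrow(fg) >= 2L) {
        u[[length(u) + 1L]] <- list(kind = "tandem", ids = fg$gene_id, cds = fg$cds)
      } else {
        for (i in seq_len(nrow(fg)))
          u[[length(u) + 1L]] <- list(kind = "gene", ids = fg$gene_id[i], cds = fg$cds[i])
      }
    }
    sp_dec <- decoys_df[decoys_df$species == sp, , drop = FALSE]
    for (i in seq_len(nrow(sp_dec)))
      u[[length(u) + 1L]] <- list(kind = "gene", ids = sp_dec$gene_id[i], cds = sp_dec$cds[i])
    for (s in seq_len(cfg$n_synteny_segments))
      u[[length(u) + 1L]] <- list(kind = "segment", ids = sprintf("SEG%02d", s),
                                  cds = if (sp == "spA") seg_seqs[s] else
                                    mutate_sequence(seg_seqs[s], cfg$mutation_rate))
    if (length(u)) u <- u[sample(length(u))]

    chrom <- 1L; cursor <- 50001
    margin <- 50000
    rows <- list()
    for (unit in u) {
      lens <- nchar(unit$cds)
      gaps <- if (length(lens) > 1L) sample(20000:80000, length(lens) - 1L, replace = TRUE) else integer()
      needed <- sum(lens) + sum(gaps)
      while (cursor + needed > cfg$chromosome_length - margin) {
        chrom <- chrom + 1L
        cursor <- 50001
        if (chrom > cfg$n_chromosomes)
          stop("capacity error: planted genes cannot be placed without overlap; ",
               "increase chromosome_length or n_chromosomes")
      }
      at <- cursor
      for (i in seq_along(unit$ids)) {
        strand <- if (unit$kind == "segment") "+" else sample(c("+", "-"), 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          id = unit$ids[i], kind = unit$kind, chromosome = sprintf("chr%d", chrom),
          start = at, end = at + nchar(unit$cds[i]) - 1, strand = strand,
          seq = unit$cds[i], unit = length(placed[[sp]] %||% list()) + length(rows),
          stringsAsFactors = FALSE)
        if (unit$kind == "segment")
          seg_pos[[sp]][[unit$ids[i]]] <- c(chrom = sprintf("chr%d", chrom),
                                            start = at, end = at + nchar(unit$cds[i]) - 1)
        at <- at + nchar(unit$cds[i]) + if (i < length(unit$ids)) gaps[i] else 0L
      }
      cursor <- at + sample(205000:260000, 1L)
    }
    placed[[sp]] <- if (length(rows)) do.call(rbind, rows) else
      data.frame(id = character(), kind = character(), chromosome = character(),
                 start = numeric(), end = numeric(), strand = character(),
                 seq = character(), stringsAsFactors = FALSE)
  }
  for (s in seq_len(cfg$n_synteny_segments)) {
    a <- seg_pos$spA[[sprintf("SEG%02d", s)]]
    b <- seg_pos$spB[[sprintf("SEG%02d", s)]]
    blocks[[length(blocks) + 1L]] <- data.frame(
      chrom_a = a[["chrom"]], start_a = as.numeric(a[["start"]]), end_a = as.numeric(a[["end"]]),
      chrom_b = b[["chrom"]], start_b = as.numeric(b[["start"]]), end_b = as.numeric(b[["end"]]),
      stringsAsFactors = FALSE)
  }

  # ---- genomes ------------------------------------------------------
  genomes <- list()
  for (sp in species) {
    chroms <- list()
    for (c_i in seq_len(cfg$n_chromosomes)) {
      bg <- sample(DNA_BASES, cfg$chromosome_length, replace = TRUE)
      pl <- placed[[sp]]
      pl <- pl[pl$chromosome == sprintf("chr%d", c_i), , drop = FALSE]
      for (i in seq_len(nrow(pl))) {
        s <- if (pl$strand[i] == "-") revcomp(pl$seq[i]) else pl$seq[i]
        bg[pl$start[i]:pl$end[i]] <- str_chars(s)
      }
      chroms[[sprintf("chr%d", c_i)]] <- chars_str(bg)
    }
    genomes[[sp]] <- unlist(chroms)
  }

  # ---- per-species bundles -----------------------------------------
  bundles <- list()
  truth_tx_count <- c(spA = 0L, spB = 0L)
  for (sp in species) {
    pl <- placed[[sp]]
    gpl <- pl[pl$kind != "segment", , drop = FALSE]
    prot <- unlist(prot_seqs[[sp]]) %||% setNames(character(), character())
    doms <- if (length(dom_rows[[sp]])) do.call(rbind, dom_rows[[sp]]) else
      data.frame(protein_id = character(), accession = character(),
                 start = integer(), end = integer(), stringsAsFactors = FALSE)
    rownames(doms) <- NULL
    doms <- doms[, c("protein_id", "accession", "start", "end")]

    # alternative transcripts: truncated by 21 codons, flagged non-primary
    tx <- data.frame(protein_id = sprintf("%s.1", gpl$id), gene_id = gpl$id,
                     primary = rep(TRUE, nrow(gpl)), trunc = rep(0L, nrow(gpl)),
                     stringsAsFactors = FALSE)
    n_alt <- round(cfg$alt_transcript_fraction * nrow(gpl))
    if (n_alt > 0L) {
      alt_ix <- sort(sample(nrow(gpl), n_alt))
      alt_rows <- list(); alt_prot <- character(); alt_dom <- list()
      for (i in alt_ix) {
        gid <- gpl$id[i]
        p1 <- prot[[paste0(gid, ".1")]]
        if (nchar(p1) <= 40L) next
        pid <- paste0(gid, ".2")
        p2 <- substr(p1, 1L, nchar(p1) - 20L)
        alt_prot[[pid]] <- p2
        d <- doms[doms$protein_id == paste0(gid, ".1"), , drop = FALSE]
        d$protein_id <- pid
        d <- d[d$start <= nchar(p2), , drop = FALSE]
        d$end <- pmin(d$end, nchar(p2))
        alt_dom[[pid]] <- d
        alt_rows[[length(alt_rows) + 1L]] <- data.frame(
          protein_id = pid, gene_id = gid, primary = FALSE, trunc = 20L,
          stringsAsFactors = FALSE)
      }
      if (length(alt_rows)) {
        tx <- rbind(tx, do.call(rbind, alt_rows))
        prot <- c(prot, unlist(alt_prot))
        doms <- rbind(doms, do.call(rbind, alt_dom))
      }
    }
    tx <- tx[order(tx$protein_id), , drop = FALSE]
    prot <- prot[order(names(prot))]
    doms <- doms[order(doms$protein_id, doms$start), , drop = FALSE]
    rownames(doms) <- NULL
    truth_tx_count[sp] <- sum(tx$primary)

    loci <- data.frame(gene_id = gpl$id, chromosome = gpl$chromosome,
                       start = gpl$start, end = gpl$end, strand = gpl$strand,
                       stringsAsFactors = FALSE)
    loci <- loci[order(loci$chromosome, loci$start), , drop = FALSE]
    rownames(loci) <- NULL

    proteins <- data.frame(
      protein_id = names(prot),
      gene_id = tx$gene_id[match(names(prot), tx$protein_id)],
      species = rep(sp, length(prot)),
      is_primary = tx$primary[match(names(prot), tx$protein_id)],
      sequence = unname(prot),
      stringsAsFactors = FALSE)

    bundles[[sp]] <- list(species_id = sp, genome = genomes[[sp]],
                          proteins = proteins, domains = doms, loci = loci,
                          transcripts = tx)
  }

  # ---- reference bundle (labelled exemplars + outgroup) -------------
  if (cfg$n_outgroup > 0L) {
    # one divergent kinase family, so the outgroup is monophyletic
    og_arch <- build_architecture("kinase", motif_class = "RD",
                                  kd_base = scaffold,
                                  kd_divergence = cfg$outgroup_divergence)
    og_cds <- reverse_translate(og_arch$sequence)
    for (i in seq_len(cfg$n_outgroup)) {
      cds <- sanitize_cds(mutate_sequence(og_cds, 0.05), og_cds)
      prot <- substr(as.character(Biostrings::translate(
        Biostrings::DNAString(cds), no.init.codon = TRUE)), 1L,
        (nchar(cds) / 3L) - 1L)
      rid <- sprintf("OUTG%d", i)
      ref_seqs[[rid]] <- prot
      rd <- og_arch$domains; rd$protein_id <- rid
      ref_doms[[rid]] <- rd
      ref_labels[[rid]] <- "outgroup"
    }
  }
  ref_dom_df <- if (length(ref_doms)) {
    x <- do.call(rbind, ref_doms); rownames(x) <- NULL
    x[, c("protein_id", "accession", "start", "end")]
  } else data.frame(protein_id = character(), accession = character(),
                    start = integer(), end = integer(), stringsAsFactors = FALSE)
  reference <- list(
    proteins = unlist(ref_seqs) %||% setNames(character(), character()),
    domains = ref_dom_df,
    labels = data.frame(protein_id = names(ref_labels) %||% character(),
                        group = unlist(ref_labels) %||% character(),
                        stringsAsFactors = FALSE))

  # ---- truth table --------------------------------------------------
  tandem_arrays <- list()
  for (sp in species) {
    loci <- bundles[[sp]]$loci
    fams <- genes_df[genes_df$species == sp & genes_df$tandem_family, , drop = FALSE]
    for (f in unique(fams$family)) {
      ids <- fams$gene_id[fams$family == f]
      if (length(ids) < 2L) next
      ord <- loci[match(ids, loci$gene_id), , drop = FALSE]
      ord <- ord[order(ord$start), , drop = FALSE]
      tandem_arrays[[length(tandem_arrays) + 1L]] <-
        list(species = sp, chromosome = ord$chromosome[1], gene_ids = ord$gene_id)
    }
  }
  gcols <- c("gene_id", "species", "family", "group", "motif_class",
             "nonrd_residue", "tier", "tandem_family", "kd_start", "kd_end",
             "loop_pos")
  truth_genes <- rbind(
    genes_df[, gcols, drop = FALSE],
    if (nrow(decoys_df)) data.frame(
      gene_id = decoys_df$gene_id, species = decoys_df$species,
      family = NA_integer_, group = NA_character_, motif_class = NA_character_,
      nonrd_residue = NA_character_, tier = decoys_df$tier,
      tandem_family = FALSE, kd_start = NA_integer_, kd_end = NA_integer_,
      loop_pos = NA_integer_, stringsAsFactors = FALSE))
  for (sp in species) {
    loci <- bundles[[sp]]$loci
    ix <- truth_genes$species == sp
    m <- match(truth_genes$gene_id[ix], loci$gene_id)
    truth_genes$chromosome[ix] <- loci$chromosome[m]
    truth_genes$start[ix] <- loci$start[m]
    truth_genes$end[ix] <- loci$end[m]
    truth_genes$strand[ix] <- loci$strand[m]
  }
  rownames(truth_genes) <- NULL
  truth <- structure(list(
    genes = truth_genes,
    ortholog_pairs = if (length(ortholog_pairs)) do.call(rbind, ortholog_pairs) else
      data.frame(gene_a = character(), gene_b = character(), stringsAsFactors = FALSE),
    tandem_arrays = tandem_arrays,
    planted_blocks = if (length(blocks)) do.call(rbind, blocks) else
      data.frame(chrom_a = character(), start_a = numeric(), end_a = numeric(),
                 chrom_b = character(), start_b = numeric(), end_b = numeric(),
                 stringsAsFactors = FALSE),
    n_primary_transcripts = truth_tx_count
  ), class = "rlk_truth")

  list(species = bundles, reference = reference, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a synthetic dataset to disk
#'
#' Emits, per species, `<sp>_genome.fa`, `<sp>.gff3`, `<sp>_proteins.fa`
#' and `<sp>_domains.tsv`, plus the reference bundle
#' (`reference_proteins.fa`, `reference_domains.tsv`,
#' `reference_labels.tsv`) and the truth table (`truth.json`). Output is
#' byte-deterministic for a fixed configuration and seed.
#'
#' @param dataset An `"rlk_dataset"` from [simulate_rlk_dataset()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of written paths.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "rlk_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (sp in names(dataset$species)) {
    b <- dataset$species[[sp]]
    paths <- c(paths,
      write_fasta(b$genome, file.path(dir, paste0(sp, "_genome.fa"))),
      write_gff3(b, file.path(dir, paste0(sp, ".gff3"))),
      write_fasta(setNames(b$proteins$sequence, b$proteins$protein_id),
                  file.path(dir, paste0(sp, "_proteins.fa"))),
      write_tsv(b$domains, file.path(dir, paste0(sp, "_domains.tsv"))))
  }
  paths <- c(paths,
    write_fasta(dataset$reference$proteins, file.path(dir, "reference_proteins.fa")),
    write_tsv(dataset$reference$domains, file.path(dir, "reference_domains.tsv")),
    write_tsv(dataset$reference$labels, file.path(dir, "reference_labels.tsv")))
  tj <- file.path(dir, "truth.json")
  writeLines(jsonlite::toJSON(unclass(dataset$truth), auto_unbox = TRUE,
                              digits = NA, pretty = TRUE), tj)
  invisible(c(paths, tj))
}

# GFF3 writer: gene/mRNA/CDS features, 1-based inclusive coordinates,
# mRNA rows carry primary=true|false. Hand-formatted so output bytes are
# stable across runs.
write_gff3 <- function(bundle, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  loci <- bundle$loci[order(bundle$loci$chromosome, bundle$loci$start), , drop = FALSE]
  tx <- bundle$transcripts
  for (i in seq_len(nrow(loci))) {
    g <- loci[i, ]
    writeLines(sprintf("%s\tfamilyscope\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       g$chromosome, g$start, g$end, g$strand, g$gene_id), con)
    gtx <- tx[tx$gene_id == g$gene_id, , drop = FALSE]
    gtx <- gtx[order(gtx$protein_id), , drop = FALSE]
    for (j in seq_len(nrow(gtx))) {
      t <- gtx[j, ]
      # alternative transcripts drop trailing codons: shorten the CDS 3' end
      cut <- 3L * (t$trunc + if (t$trunc > 0L) 1L else 0L)
      if (g$strand == "+") { cs <- g$start; ce <- g$end - cut }
      else { cs <- g$start + cut; ce <- g$end }
      writeLines(sprintf("%s\tfamilyscope\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s;primary=%s",
                         g$chromosome, cs, ce, g$strand, t$protein_id, g$gene_id,
                         if (t$primary) "true" else "false"), con)
      writeLines(sprintf("%s\tfamilyscope\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds;Parent=%s",
                         g$chromosome, cs, ce, g$strand, t$protein_id, t$protein_id), con)
    }
  }
  invisible(path)
}

#' @export
print.rlk_dataset <- function(x, ...) {
  cat("Synthetic LRR-RLK dataset\n")
  for (sp in names(x$species)) {
    b <- x$species[[sp]]
    cat(sprintf("  %s: %d chromosomes, %d genes, %d proteins (%d primary)\n",
                sp, length(b$genome), nrow(b$loci), nrow(b$proteins),
                sum(b$proteins$is_primary)))
  }
  cat(sprintf("  reference: %d labelled sequences\n", nrow(x$reference$labels)))
  cat(sprintf("  truth: %d genes, %d ortholog pairs, %d tandem arrays, %d planted blocks\n",
              nrow(x$truth$genes), nrow(x$truth$ortholog_pairs),
              length(x$truth$tandem_arrays), nrow(x$truth$planted_blocks)))
  invisible(x)
}
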