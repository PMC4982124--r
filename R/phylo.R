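# Distance-based phylogeny of kinase domains: Poisson-corrected
# distances, neighbor-joining, nonparametric bootstrap support, and
# clade-based subfamily group assignment against labelled references.
# Trees are ape "phylo" objects; supports live in node labels.

#' Poisson-corrected distances from an alignment
#'
#' For each pair of rows, `p` is the proportion of differing sites among
#' shared non-gap columns and the distance is the Poisson correction
#' `d = -ln(1 - p)`. Saturated pairs (`p >= 1`) are capped at `d_max`
#' with a warning.
#'
#' @param aln An `"aa_alignment"` with at least 3 rows.
#' @param d_max Cap for saturated distances.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
compute_distances <- function(aln, d_max = 10) {
  stopifnot(inherits(aln, "aa_alignment"))
  m <- aln_matrix(aln)
  if (nrow(m) < 2L) stop("need at least 2 aligned sequences")
  enc <- matrix(match(m, AA_ALPHABET), nrow = nrow(m)) # gaps/X -> NA
  n <- nrow(m)
  ids <- rownames(m)
  # shared non-gap columns and matches per pair, via crossproducts
  N <- matrix(as.numeric(!is.na(enc)), nrow = n)
  shared <- tcrossprod(N)
  matches <- matrix(0, n, n)
  for (k in seq_along(AA_ALPHABET)) {
    A <- matrix(as.numeric(!is.na(enc) & enc == k), nrow = n)
    matches <- matches + tcrossprod(A)
  }
  diag(shared) <- diag(shared) + (diag(shared) == 0) # self-pairs are fine
  bad <- which(shared == 0, arr.ind = TRUE)
  if (nrow(bad))
    stop("zero shared non-gap columns for pair ",
         ids[bad[1, 1]], " / ", ids[bad[1, 2]])
  p <- (shared - matches) / shared
  sat <- p >= 1
  D <- -log(pmax(1 - p, .Machine$double.xmin))
  D[sat] <- d_max
  D <- pmin(D, d_max)
  diag(D) <- 0
  D <- (D + t(D)) / 2
  dimnames(D) <- list(ids, ids)
  if (any(sat)) warning("saturated pair(s) capped at d_max = ", d_max, call. = FALSE)
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining agglomeration. Ties in the Q criterion are
#' broken by the lexicographically smallest id pair (internal nodes are
#' identified by their smallest descendant tip). Negative branch lengths
#' are clamped to zero with the deficit moved to the sister edge.
#'
#' @param dm Symmetric distance matrix (zero diagonal, >= 3 taxa) with
#'   ids as dimnames.
#' @return An unrooted `"phylo"` tree.
#' @export
build_nj_tree <- function(dm) {
  if (!isTRUE(all.equal(dm, t(dm), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  ids <- rownames(dm)
  n <- length(ids)
  if (n < 3L) stop("need at least 3 taxa")
  nwk <- setNames(ids, ids)      # partial newick per active node
  key <- setNames(ids, ids)      # lexicographic id of each active node
  D <- dm
  while (nrow(D) > 3L) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    ka <- key[rownames(D)[cand[, 1]]]; kb <- key[rownames(D)[cand[, 2]]]
    lo <- pmin(ka, kb); hi <- pmax(ka, kb)
    pick <- order(lo, hi)[1L]
    i <- cand[pick, 1]; j <- cand[pick, 2]
    a <- rownames(D)[i]; b <- rownames(D)[j]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- max(li + lj, 0); lj <- 0 }
    u <- paste0("u", m) # internal working id, never printed
    newd <- (D[i, ] + D[j, ] - D[i, j]) / 2
    D <- rbind(cbind(D, newd), c(newd, 0))
    rownames(D)[m + 1L] <- colnames(D)[m + 1L] <- u
    D <- D[-c(i, j), -c(i, j), drop = FALSE]
    nwk[u] <- sprintf("(%s:%.10g,%s:%.10g)", nwk[a], li, nwk[b], lj)
    key[u] <- min(key[a], key[b])
  }
  abc <- rownames(D)
  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  ord <- order(key[abc])
  lens <- pmax(c(la, lb, lc), 0)[ord]
  tree <- ape::read.tree(text = sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                                        nwk[abc[ord[1]]], lens[1],
                                        nwk[abc[ord[2]]], lens[2],
                                        nwk[abc[ord[3]]], lens[3]))
  tree
}

# Canonical bipartition keys of a tree: for each non-root internal node,
# the side of the split not containing the alphabetically first tip,
# sorted and collapsed. Tip-order invariant.
bipartition_keys <- function(tree) {
  pp <- ape::prop.part(tree)
  labels <- attr(pp, "labels")
  ref <- min(labels)
  nt <- length(labels)
  keys <- character(0)
  nodes <- integer(0)
  for (i in seq_along(pp)) {
    node <- nt + i
    tipset <- labels[pp[[i]]]
    if (length(tipset) == nt) next # root: not a bipartition
    side <- if (ref %in% tipset) setdiff(labels, tipset) else tipset
    keys <- c(keys, paste(sort(side), collapse = "|"))
    nodes <- c(nodes, node)
  }
  setNames(keys, nodes)
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Builds the NJ tree from the full alignment, then resamples alignment
#' columns with replacement `n_replicates` times, rebuilds the tree for
#' each replicate, and reports for every internal edge the fraction of
#' replicates containing the same bipartition. Supports are stored in
#' the tree's node labels, in `[0, 1]`.
#'
#' @param aln An `"aa_alignment"`.
#' @param n_replicates Number of bootstrap replicates (>= 1).
#' @param seed Optional seed; results are deterministic given it.
#' @param d_max Distance cap, as in [compute_distances()].
#' @return A `"phylo"` tree with node labels carrying supports.
#' @export
bootstrap_support <- function(aln, n_replicates = 100L, seed = NULL, d_max = 10) {
  if (!is.numeric(n_replicates) || n_replicates < 1L)
    stop("n_replicates must be >= 1")
  tree0 <- build_nj_tree(compute_distances(aln, d_max = d_max))
  keys0 <- bipartition_keys(tree0)
  m <- aln_matrix(aln)
  # resample by original column order so supports are invariant to row order
  counts <- setNames(numeric(length(keys0)), keys0)
  used <- 0L
  with_seed(seed, {
    for (b in seq_len(n_replicates)) {
      idx <- sample.int(ncol(m), ncol(m), replace = TRUE)
      rep_aln <- as_alignment(setNames(
        apply(m[, idx, drop = FALSE], 1L, paste, collapse = ""), rownames(m)))
      kb <- tryCatch(bipartition_keys(build_nj_tree(
        suppressWarnings(compute_distances(rep_aln, d_max = d_max)))),
        error = function(e) NULL)
      if (is.null(kb)) next
      used <- used + 1L
      hit <- keys0 %in% kb
      counts[keys0[hit]] <- counts[keys0[hit]] + 1
    }
  })
  if (used == 0L) stop("no usable bootstrap replicates")
  sup <- counts / used
  nt <- length(tree0$tip.label)
  nlab <- rep("", tree0$Nnode)
  for (k in seq_along(keys0)) {
    node <- as.integer(names(keys0)[k])
    nlab[node - nt] <- sprintf("%.6g", sup[[keys0[k]]])
  }
  tree0$node.label <- nlab
  attr(tree0, "n_replicates") <- used
  tree0
}

node_supports <- function(tree) {
  if (is.null(tree$node.label)) return(rep(NA_real_, tree$Nnode))
  suppressWarnings(as.numeric(tree$node.label))
}

# Descendant tip labels per internal node (named by node number).
node_clades <- function(tree) {
  pp <- ape::prop.part(tree)
  labels <- attr(pp, "labels")
  nt <- length(labels)
  setNames(lapply(pp, function(ix) labels[ix]), nt + seq_along(pp))
}

#' Enumerate well-supported clades
#'
#' Lists every clade whose defining edge has support strictly above the
#' threshold. Nested clades are reported with a link to their smallest
#' enclosing reported clade.
#'
#' @param tree A `"phylo"` tree with supports in node labels (use
#'   [bootstrap_support()] or a Newick file with support node labels).
#' @param support_threshold Support threshold (default 0.70).
#' @return List of clades, each `list(tips, support, node, parent)`;
#'   `parent` indexes the enclosing clade in the returned list (NA at the
#'   top level). Ordered by decreasing clade size.
#' @export
find_well_supported_clades <- function(tree, support_threshold = 0.70) {
  sup <- node_supports(tree)
  clades <- node_clades(tree)
  nt <- length(tree$tip.label)
  keep <- which(!is.na(sup) & sup > support_threshold)
  if (!length(keep)) return(list())
  out <- lapply(keep, function(i) list(
    tips = clades[[as.character(nt + i)]],
    support = sup[i], node = nt + i, parent = NA_integer_))
  sizes <- vapply(out, function(x) length(x$tips), integer(1))
  ord <- order(-sizes)
  out <- out[ord]
  for (i in seq_along(out)) {
    for (j in seq_along(out)) {
      if (i == j) next
      if (length(out[[j]]$tips) > length(out[[i]]$tips) &&
          all(out[[i]]$tips %in% out[[j]]$tips)) {
        # smallest enclosing clade wins
        if (is.na(out[[i]]$parent) ||
            length(out[[j]]$tips) < length(out[[out[[i]]$parent]]$tips))
          out[[i]]$parent <- j
      }
    }
  }
  out
}

#' Root a tree on outgroup tips
#'
#' @param tree A `"phylo"` tree.
#' @param outgroup_ids Tip ids of the outgroup; ids absent from the tree
#'   are ignored.
#' @return A rooted `"phylo"`; supports in node labels follow their
#'   edges.
#' @export
root_with_outgroup <- function(tree, outgroup_ids) {
  og <- intersect(outgroup_ids, tree$tip.label)
  if (!length(og)) stop("no outgroup tips present in the tree")
  if (!is.null(tree$node.label)) tree$node.label[tree$node.label == ""] <- NA
  if (!ape::is.monophyletic(tree, og)) og <- og[1L] # fall back to one tip
  ape::root(tree, outgroup = og, resolve.root = TRUE, edgelabel = TRUE)
}

as_label_vector <- function(reference_labels) {
  if (is.data.frame(reference_labels))
    return(setNames(reference_labels$group, reference_labels$protein_id))
  if (!is.null(names(reference_labels))) return(reference_labels)
  stop("reference_labels must be a named vector or a protein_id/group data frame")
}

#' Assign subfamily groups by co-clustering with labelled references
#'
#' Each unlabelled tip receives the label of the smallest well-supported
#' clade containing it (support strictly above the threshold on the
#' clade's defining edge) whose reference tips are label-homogeneous.
#' Tips contained in no such clade stay `unassigned` — including tips
#' falling between two differently labelled reference clades, which are
#' never guessed. Reference tips always keep their prior labels.
#'
#' @param tree A `"phylo"` with supports in node labels.
#' @param reference_labels Named vector or `protein_id`/`group` data
#'   frame of reference tip labels; the label `"outgroup"` marks rooting
#'   tips and is never propagated.
#' @param support_threshold Support threshold (default 0.70, the usual
#'   confidence cut for clade reliability).
#' @param root Root on outgroup-labelled tips first, when present.
#' @return Named character vector: tip id -> group label (references keep
#'   theirs; queries get a group or `"unassigned"`).
#' @export
assign_subfamily_groups <- function(tree, reference_labels,
                                    support_threshold = 0.70, root = TRUE) {
  labels <- as_label_vector(reference_labels)
  refs <- intersect(names(labels), tree$tip.label)
  if (!length(refs)) stop("tree contains no labelled reference tips")
  og <- refs[labels[refs] == "outgroup"]
  if (root && length(og)) tree <- root_with_outgroup(tree, og)
  sup <- node_supports(tree)
  clades <- node_clades(tree)
  nt <- length(tree$tip.label)
  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root_node <- nt + 1L

  assign_one <- function(tip_ix) {
    node <- parent[tip_ix]
    while (node != 0L) {
      s <- if (node == root_node) NA_real_ else sup[node - nt]
      if (!is.na(s) && s > support_threshold) {
        tips <- clades[[as.character(node)]]
        rin <- intersect(tips, refs)
        if (length(rin)) {
          labs <- unique(labels[rin])
          if (length(labs) == 1L && labs != "outgroup") return(labs)
          return("unassigned") # mixed references: never guess
        }
      }
      if (node == root_node) break
      node <- parent[node]
    }
    "unassigned"
  }

  out <- setNames(rep(NA_character_, nt), tree$tip.label)
  for (i in seq_len(nt)) {
    id <- tree$tip.label[i]
    out[id] <- if (id %in% refs) unname(labels[id]) else assign_one(i)
  }
  out
}

#' Split group XII assignments into XIIa and XIIb
#'
#' Tips assigned to the undivided group XII are relabelled `XIIa` or
#' `XIIb` by the same clade-homogeneity rule, restricted to the XIIa/XIIb
#' reference exemplars. Without any XIIb reference, every XII tip is
#' labelled XIIa with a warning.
#'
#' @param tree A `"phylo"` with supports.
#' @param assignment Result of [assign_subfamily_groups()].
#' @param reference_labels Reference labels including XIIa/XIIb
#'   exemplars.
#' @param support_threshold Support threshold.
#' @return Updated assignment vector.
#' @export
split_group_xii <- function(tree, assignment, reference_labels,
                            support_threshold = 0.70) {
  labels <- as_label_vector(reference_labels)
  xii_tips <- names(assignment)[assignment == "XII"]
  if (!length(xii_tips)) return(assignment)
  sub_labels <- labels[labels %in% c("XIIa", "XIIb", "outgroup")]
  if (!any(sub_labels == "XIIb")) {
    warning("no XIIb reference present; labelling all XII tips XIIa", call. = FALSE)
    assignment[xii_tips] <- "XIIa"
    return(assignment)
  }
  sub <- assign_subfamily_groups(tree, sub_labels,
                                 support_threshold = support_threshold)
  hit <- sub[xii_tips] %in% c("XIIa", "XIIb")
  assignment[xii_tips[hit]] <- sub[xii_tips[hit]]
  assignment
}
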