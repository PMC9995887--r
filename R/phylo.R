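## Neighbor-joining phylogeny, bootstrap supports and monophyly tests.
##
## Tree inference here is deliberately desk-scale: NJ on p-distances (or
## their Poisson transform) with a standard column-resampling bootstrap,
## standing in for maximum-likelihood inference on a curated alignment. The
## clade-recovery claims tested downstream (three label-monophyletic clades,
## high between-clade support) are robust to this substitution and the
## reports label the method as NJ.

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration via [ape::nj()]. Negative branch lengths (an NJ
#' artifact) are clamped to zero and flagged via the
#' `"negative_branch_clamped"` attribute.
#'
#' @param d Symmetric numeric matrix with zero diagonal and labels.
#' @return An unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) stopf("distance matrix must be square")
  if (nrow(d) < 3L) stopf("need >= 3 labels for a tree")
  if (any(abs(d - t(d)) > 1e-8)) stopf("distance matrix is not symmetric")
  if (any(!is.finite(d)) || any(d < 0)) stopf("distances must be finite and >= 0")
  if (is.null(rownames(d))) stopf("distance matrix needs labels")
  tr <- ape::nj(d)
  clamped <- any(tr$edge.length < 0)
  tr$edge.length[tr$edge.length < 0] <- 0
  attr(tr, "negative_branch_clamped") <- clamped
  tr
}

## Tip-label sets for each internal node of a phylo (stored rooting).
node_tip_sets <- function(tree) {
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  lapply(pp, function(idx) labs[idx])
}

## Does any internal edge of the (unrooted) tree separate exactly `leaves`
## from the rest?
split_exists <- function(tree, leaves) {
  all_tips <- tree$tip.label
  k <- length(leaves)
  if (k == 0L || k == length(all_tips)) return(FALSE)
  if (k == 1L || k == length(all_tips) - 1L) return(TRUE)  # trivial leaf split
  target <- sort(leaves)
  comp <- sort(setdiff(all_tips, leaves))
  for (tips in node_tip_sets(tree)) {
    st <- sort(tips)
    if (identical(st, target) || identical(st, comp)) return(TRUE)
  }
  FALSE
}

#' Count label-monophyletic clades on a tree
#'
#' A clade (set of equally-labeled leaves) is monophyletic iff some
#' bipartition of the unrooted tree separates exactly its leaves from all
#' others. Invariant to leaf order and rooting.
#'
#' @param tree `ape::phylo`.
#' @param labels Named character vector mapping every leaf to a clade label.
#' @return List with `count` (number of monophyletic clades) and `by_clade`
#'   (named logical vector).
#' @export
clade_monophyly <- function(tree, labels) {
  missing_ <- setdiff(tree$tip.label, names(labels))
  if (length(missing_))
    stopf("unlabeled leaf/leaves: %s", paste(missing_, collapse = ", "))
  clades <- unique(unname(labels[tree$tip.label]))
  by_clade <- vapply(clades, function(cl) {
    leaves <- tree$tip.label[labels[tree$tip.label] == cl]
    split_exists(tree, leaves)
  }, TRUE)
  names(by_clade) <- clades
  list(count = sum(by_clade), by_clade = by_clade)
}

## Deterministic per-replicate seed derived from (seed, replicate index).
replicate_seed <- function(seed, rep) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(rep)
}

#' Bootstrap supports for an NJ tree from an alignment
#'
#' Builds the NJ tree from the full alignment, then resamples alignment
#' columns with replacement `n_reps` times (one RNG stream keyed by
#' `(seed, replicate index)`), rebuilds the NJ tree per replicate, and
#' records for each internal bipartition of the base tree the percentage of
#' replicates containing it ([ape::prop.clades()], unrooted).
#'
#' @param aln Named character vector of equal-length aligned sequences.
#' @param n_reps Number of replicates (>= 1).
#' @param seed Integer seed; same seed means identical supports.
#' @param model Distance model, "p" or "poisson".
#' @return The base `phylo` with `node.label` holding supports in `[0, 100]`
#'   and a `support` attribute (numeric vector, one per internal node; the
#'   root entry of the stored rooting is NA).
#' @export
bootstrap_support <- function(aln, n_reps, seed = 1L, model = "p") {
  if (!is_count(n_reps) || n_reps < 1) stopf("n_reps must be >= 1")
  L <- unique(nchar(aln))
  if (length(L) != 1L) stopf("ragged alignment")
  base <- nj_tree(dist_from_alignment(aln, model))
  chars <- do.call(rbind, strsplit(unname(aln), "", fixed = TRUE))
  rownames(chars) <- names(aln)
  rep_trees <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cols <- with_seed(replicate_seed(seed, r),
                      sample.int(L, L, replace = TRUE))
    rep_aln <- apply(chars[, cols, drop = FALSE], 1L, paste, collapse = "")
    rep_trees[[r]] <- nj_tree(dist_from_alignment(rep_aln, model))
  }
  counts <- ape::prop.clades(base, rep_trees, rooted = FALSE)
  support <- 100 * counts / n_reps
  base$node.label <- ifelse(is.na(support), "", format(support, trim = TRUE))
  attr(base, "support") <- support
  base
}

#' Support of the bipartition separating a leaf set
#'
#' @param tree Tree from [bootstrap_support()].
#' @param leaves Leaf labels of the putative clade.
#' @return Support percentage, or NA when no internal edge of the tree
#'   isolates that leaf set.
#' @export
clade_support <- function(tree, leaves) {
  support <- attr(tree, "support")
  if (is.null(support)) stopf("tree carries no bootstrap supports")
  sets <- node_tip_sets(tree)
  target <- sort(leaves)
  comp <- sort(setdiff(tree$tip.label, leaves))
  for (k in seq_along(sets)) {
    st <- sort(sets[[k]])
    if (identical(st, target) || identical(st, comp)) {
      if (!is.na(support[k])) return(support[k])
    }
  }
  NA_real_
}

## Tips on the far side of the edge (v -> nb) seen from v, in the stored
## (rooted) representation of the phylo.
far_side_tips <- function(tree, v, nb, parent_side) {
  ntip <- length(tree$tip.label)
  if (!parent_side) {
    if (nb <= ntip) return(tree$tip.label[nb])
    sets <- node_tip_sets(tree)
    return(sets[[nb - ntip]])
  }
  sets <- node_tip_sets(tree)
  below_v <- if (v <= ntip) tree$tip.label[v] else sets[[v - ntip]]
  setdiff(tree$tip.label, below_v)
}

#' Assign a query protein to a clade by tree placement
#'
#' Builds an NJ tree over the references plus the query and inspects the two
#' subtrees adjacent to the query's attachment node: if the label-pure ones
#' among them agree on a single clade, that clade is returned, otherwise
#' "unresolved".
#'
#' @param query `ProteinRecord`.
#' @param refs Reference panel (list of `ProteinRecord`s with `true_clade`),
#'   at least two per represented clade.
#' @return One of "alpha", "beta", "pla2like", "unresolved".
#' @export
tree_placement_clade <- function(query, refs) {
  ref_clades <- vapply(refs, function(r) r$true_clade %||% "none", "")
  if (any(table(ref_clades) < 2L))
    stopf("reference panel needs >= 2 members per clade")
  qid <- "query__"
  q2 <- query; q2$id <- qid
  d <- distance_matrix(c(refs, list(q2)))
  tr <- nj_tree(d)
  labels <- stats::setNames(ref_clades, vapply(refs, `[[`, "", "id"))
  ntip <- length(tr$tip.label)
  t_idx <- match(qid, tr$tip.label)
  v <- tr$edge[tr$edge[, 2L] == t_idx, 1L]
  ## neighbors of v other than the query tip
  sub_labels <- character()
  kids <- tr$edge[tr$edge[, 1L] == v, 2L]
  kids <- kids[kids != t_idx]
  for (nb in kids) {
    tips <- far_side_tips(tr, v, nb, parent_side = FALSE)
    labs <- unique(unname(labels[setdiff(tips, qid)]))
    if (length(labs) == 1L) sub_labels <- c(sub_labels, labs)
  }
  parent <- tr$edge[tr$edge[, 2L] == v, 1L]
  if (length(parent) == 1L) {
    tips <- far_side_tips(tr, v, parent, parent_side = TRUE)
    labs <- unique(unname(labels[setdiff(tips, qid)]))
    if (length(labs) == 1L) sub_labels <- c(sub_labels, labs)
  }
  u <- unique(sub_labels)
  if (length(u) == 1L) u else "unresolved"
}
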