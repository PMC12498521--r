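#' Upsample the minority class
#'
#' Taxa of the minority class are drawn with replacement until the classes
#' contain equally many sequences; duplicates are recorded as replicate
#' counts (equivalent to physically duplicated design-matrix rows).
#'
#' @param h An `esl_hypothesis`.
#' @param seed Integer seed making the draw reproducible.
#' @return A balanced `esl_hypothesis`.
#' @export
balance_up <- function(h, seed = 42L) {
  stopifnot(inherits(h, "esl_hypothesis"))
  pos <- names(h$labels)[h$labels == 1]
  neg <- names(h$labels)[h$labels == -1]
  if (length(pos) == length(neg)) return(h)
  minority <- if (length(pos) < length(neg)) pos else neg
  deficit <- abs(length(pos) - length(neg))
  reps <- h$replicates
  extra <- withr::with_seed(seed,
                            sample(minority, deficit, replace = TRUE))
  for (t in extra) reps[t] <- reps[t] + 1L
  new_hypothesis(h$labels, h$focal_name, h$weights, reps)
}

#' Downsample the majority class
#'
#' A uniform sample without replacement of the majority class, of minority
#' size, is retained; the other majority taxa are dropped from the
#' hypothesis (and hence from the training rows).
#'
#' @inheritParams balance_up
#' @return A balanced `esl_hypothesis` over a subset of the taxa.
#' @export
balance_down <- function(h, seed = 42L) {
  stopifnot(inherits(h, "esl_hypothesis"))
  pos <- names(h$labels)[h$labels == 1]
  neg <- names(h$labels)[h$labels == -1]
  if (length(pos) == length(neg)) return(h)
  majority <- if (length(pos) > length(neg)) pos else neg
  m <- min(length(pos), length(neg))
  keep_maj <- withr::with_seed(seed, sample(majority, m, replace = FALSE))
  keep <- names(h$labels)[names(h$labels) %in%
                            c(setdiff(names(h$labels), majority), keep_maj)]
  new_hypothesis(h$labels[keep], h$focal_name, h$weights[keep],
                 h$replicates[keep])
}

#' Weight classes inversely to their size
#'
#' Each taxon in class c receives weight n_total / (2 n_c), so both classes
#' contribute equal total weight (n_total / 2) to the loss and the weights
#' sum to the number of taxa. No resampling is involved.
#'
#' @param h An `esl_hypothesis`.
#' @return The hypothesis with rebalanced weights.
#' @export
balance_weighted <- function(h) {
  stopifnot(inherits(h, "esl_hypothesis"))
  n <- length(h$labels)
  npos <- sum(h$labels == 1)
  nneg <- n - npos
  w <- ifelse(h$labels == 1, n / (2 * npos), n / (2 * nneg))
  new_hypothesis(h$labels, h$focal_name,
                 stats::setNames(w, names(h$labels)), h$replicates)
}

# patristic distance from every leaf to `node`; unit branch lengths when the
# tree has none (or incomplete ones)
.leaf_node_distance <- function(tree, node) {
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    tree$edge.length <- rep(1, nrow(tree$edge))
  }
  dn <- ape::dist.nodes(tree)
  stats::setNames(dn[seq_len(ape::Ntip(tree)), node], tree$tip.label)
}

# order taxa for removal: most distant from the focal node first,
# ties broken by reverse alphabetical name
.removal_order <- function(taxa, dist_to_focal) {
  taxa[order(-dist_to_focal[taxa], -rank(taxa), method = "radix")]
}

#' Phylogeny-aware class balancing
#'
#' Builds a balanced hypothesis directly from the tree. All leaves of the
#' focal clade get +1. Starting from the focal node, the walk moves to
#' successive ancestors, adding all leaves of each newly encountered sister
#' subtree to the -1 class, and stops as soon as the -1 class is at least as
#' large as the focal clade (or the root is passed). If the classes are then
#' unequal, taxa are removed from the larger class one at a time, starting
#' with the taxon most distant from the focal clade (patristic distance to
#' the focal node; unit branch lengths when the tree has none; ties broken
#' by reverse alphabetical name), until the classes match. Taxa never
#' visited receive no label and are excluded from training. Removing taxa
#' from the focal clade itself distorts the hypothesis, so that case
#' triggers a prominent warning.
#'
#' @param tree A rooted `phylo` with the focal clade labeled.
#' @param clade_label Label of the focal internal node.
#' @return A balanced `esl_hypothesis` with equal class sizes.
#' @export
balance_phylo <- function(tree, clade_label) {
  if (!inherits(tree, "phylo")) {
    stop("phylo balancing requires --tree (a rooted phylogeny)",
         call. = FALSE)
  }
  node <- .labeled_node(tree, clade_label)
  if (is.na(node)) {
    stop("clade label '", clade_label, "' not found in tree", call. = FALSE)
  }
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  pos <- .clade_tips(tree, node)
  if (length(pos) == ntip) {
    stop("focal clade '", clade_label, "' contains all leaves; ",
         "no taxa left for the -1 class", call. = FALSE)
  }
  neg <- character(0)
  cur <- node
  while (cur != root && length(neg) < length(pos)) {
    parent <- tree$edge[tree$edge[, 2] == cur, 1]
    sibs <- tree$edge[tree$edge[, 1] == parent, 2]
    sibs <- sibs[sibs != cur]
    for (s in sibs) neg <- c(neg, .clade_tips(tree, s))
    cur <- parent
  }
  d <- .leaf_node_distance(tree, node)
  if (length(neg) > length(pos)) {
    drop <- .removal_order(neg, d)[seq_len(length(neg) - length(pos))]
    neg <- setdiff(neg, drop)
  } else if (length(pos) > length(neg)) {
    warning("phylo balancing removed ", length(pos) - length(neg),
            " taxa from the focal clade '", clade_label,
            "'; this can distort the hypothesis being tested -- consider ",
            "weighted balancing instead", call. = FALSE)
    drop <- .removal_order(pos, d)[seq_len(length(pos) - length(neg))]
    pos <- setdiff(pos, drop)
  }
  sel <- tree$tip.label[tree$tip.label %in% c(pos, neg)]
  labels <- stats::setNames(ifelse(sel %in% pos, 1, -1), sel)
  new_hypothesis(labels, focal_name = clade_label)
}
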