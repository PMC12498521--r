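#' Construct an evolutionary hypothesis (response vector)
#'
#' A hypothesis assigns every analyzed taxon to the focal class (+1, e.g.
#' membership of a clade or presence of a trait) or the contrast class (-1).
#' Per-taxon weights scale each taxon's contribution to the logistic loss;
#' replicate counts realize upsampling as integer row multiplicities.
#'
#' @param labels Named numeric vector of +1/-1 (names are taxa).
#' @param focal_name Name of the clade or trait being modeled.
#' @param weights Named positive weights (default 1 per taxon).
#' @param replicates Named integer counts >= 1 (default 1 per taxon).
#' @return An `esl_hypothesis` object.
#' @export
new_hypothesis <- function(labels, focal_name = "hypothesis",
                           weights = NULL, replicates = NULL) {
  taxa <- names(labels)
  if (is.null(taxa) || any(!nzchar(taxa))) {
    stop("labels must be a named vector of taxa", call. = FALSE)
  }
  if (anyDuplicated(taxa)) {
    stop("duplicate taxon '", taxa[anyDuplicated(taxa)], "' in hypothesis",
         call. = FALSE)
  }
  if (!all(labels %in% c(-1, 1))) {
    stop("invalid class designation: labels must be +1 or -1", call. = FALSE)
  }
  if (!any(labels == 1) || !any(labels == -1)) {
    stop("one class empty: hypothesis needs taxa in both +1 and -1",
         call. = FALSE)
  }
  if (is.null(weights)) weights <- stats::setNames(rep(1, length(taxa)), taxa)
  if (is.null(replicates)) {
    replicates <- stats::setNames(rep(1L, length(taxa)), taxa)
  }
  stopifnot(all(is.finite(weights)), all(weights > 0),
            all(replicates >= 1L))
  structure(list(labels = labels, focal_name = focal_name,
                 weights = weights[taxa], replicates = replicates[taxa]),
            class = "esl_hypothesis")
}

#' @export
print.esl_hypothesis <- function(x, ...) {
  np <- sum(x$replicates[x$labels == 1])
  nn <- sum(x$replicates[x$labels == -1])
  cat("Hypothesis '", x$focal_name, "': ", np, " taxa (+1) vs ", nn,
      " taxa (-1)\n", sep = "")
  invisible(x)
}

#' Read a two-column class file
#'
#' Parses a tab-separated file with the taxon name in column 1 and the class
#' designation (+1 or -1) in column 2. The hypothesis name is the file
#' basename without extension.
#'
#' @param path Path to the class file.
#' @return An `esl_hypothesis`.
#' @export
read_class_file <- function(path) {
  if (!file.exists(path)) stop("class file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  labels <- numeric(0)
  for (k in keep) {
    fields <- strsplit(lines[k], "\t", fixed = TRUE)[[1]]
    fields <- trimws(fields)
    if (length(fields) != 2L || !nzchar(fields[1])) {
      stop("malformed class file line ", k, ": '", lines[k], "'",
           call. = FALSE)
    }
    cls <- switch(fields[2],
                  "+1" = 1, "1" = 1, "-1" = -1, "−1" = -1,
                  stop("invalid class designation '", fields[2],
                       "' at line ", k, " (must be +1 or -1)", call. = FALSE))
    if (fields[1] %in% names(labels)) {
      stop("duplicate taxon ", fields[1], " at line ", k, call. = FALSE)
    }
    labels[fields[1]] <- cls
  }
  new_hypothesis(labels, focal_name = sub("\\.[^.]*$", "", basename(path)))
}

#' Read a rooted phylogeny in Newick format
#'
#' @param path Path to a Newick file. The tree must be rooted; internal node
#'   labels, when present, name candidate focal clades.
#' @return An `ape::phylo` object.
#' @export
read_phylogeny <- function(path) {
  if (!file.exists(path)) stop("tree file not found: ", path, call. = FALSE)
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick tree in ", path,
                          call. = FALSE)
  if (!ape::is.rooted(tree)) {
    stop("tree in ", path, " is unrooted; clade hypotheses require a ",
         "rooted tree (rerooting is not done silently)", call. = FALSE)
  }
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate leaf names in tree", call. = FALSE)
  }
  labs <- tree$node.label
  labs <- labs[!is.na(labs) & nzchar(labs)]
  if (anyDuplicated(labs)) {
    stop("duplicate internal node labels in tree", call. = FALSE)
  }
  tree
}

# internal node numbers in preorder (root first), using cladewise edge order
.preorder_nodes <- function(tree) {
  tr <- stats::reorder(tree, "cladewise")
  unique(c(ape::Ntip(tr) + 1L, tr$edge[, 2]))
}

# node number of the internal node carrying `label`, or NA
.labeled_node <- function(tree, label) {
  if (is.null(tree$node.label)) return(NA_integer_)
  hit <- which(!is.na(tree$node.label) & tree$node.label == label)
  if (!length(hit)) return(NA_integer_)
  ape::Ntip(tree) + hit[1]
}

# leaf labels under an internal node
.clade_tips <- function(tree, node) {
  if (node <= ape::Ntip(tree)) return(tree$tip.label[node])
  ape::extract.clade(tree, node)$tip.label
}

#' Turn a labeled clade into a two-class hypothesis
#'
#' All leaves in the subtree rooted at the labeled internal node are assigned
#' +1; all remaining leaves are assigned -1.
#'
#' @param tree A rooted `phylo` with internal node labels.
#' @param clade_label Label of the focal internal node.
#' @return An `esl_hypothesis` named after the clade.
#' @export
clade_to_hypothesis <- function(tree, clade_label) {
  node <- .labeled_node(tree, clade_label)
  if (is.na(node)) {
    avail <- tree$node.label[!is.na(tree$node.label) & nzchar(tree$node.label)]
    stop("clade label '", clade_label, "' not found in tree; available: ",
         if (length(avail)) paste(avail, collapse = ", ") else "(none)",
         call. = FALSE)
  }
  inside <- .clade_tips(tree, node)
  labels <- stats::setNames(ifelse(tree$tip.label %in% inside, 1, -1),
                            tree$tip.label)
  new_hypothesis(labels, focal_name = clade_label)
}

#' Label all internal nodes deterministically
#'
#' Keeps existing labels; unlabeled internal nodes receive
#' `node_<preorder index>` where the index is the node's position in a
#' preorder (cladewise) traversal of the whole tree, so labels are stable
#' across runs.
#'
#' @param tree A rooted `phylo`.
#' @return The tree with every internal node labeled.
#' @export
label_internal_nodes <- function(tree) {
  ntip <- ape::Ntip(tree)
  pre <- .preorder_nodes(tree)
  if (is.null(tree$node.label)) {
    tree$node.label <- rep(NA_character_, tree$Nnode)
  }
  for (nd in pre[pre > ntip]) {
    k <- nd - ntip
    if (is.na(tree$node.label[k]) || !nzchar(tree$node.label[k])) {
      tree$node.label[k] <- paste0("node_", match(nd, pre))
    }
  }
  tree
}

#' Enumerate candidate focal clades of a tree
#'
#' Every internal node except the root is a candidate (the root's hypothesis
#' would have an empty -1 class). Candidates whose leaf count falls outside
#' `[lower, upper]` are excluded. Unlabeled nodes are auto-labeled as in
#' [label_internal_nodes()]; labels are returned in preorder.
#'
#' @param tree A rooted `phylo`.
#' @param lower,upper Minimum and maximum number of clade members.
#' @return Character vector of clade labels (possibly empty).
#' @export
generate_clade_list <- function(tree, lower = 1L, upper = Inf) {
  stopifnot(lower >= 1L, lower <= upper)
  tree <- label_internal_nodes(tree)
  ntip <- ape::Ntip(tree)
  pre <- .preorder_nodes(tree)
  internal <- pre[pre > ntip]
  internal <- internal[internal != ntip + 1L]   # drop root
  labs <- character(0)
  for (nd in internal) {
    sz <- length(.clade_tips(tree, nd))
    if (sz >= lower && sz <= upper) {
      labs <- c(labs, tree$node.label[nd - ntip])
    }
  }
  labs
}

#' Read a clade-list file (one focal clade label per line)
#'
#' @param path Path to the list file.
#' @return Character vector of clade labels, in file order.
#' @export
read_clade_list <- function(path) {
  if (!file.exists(path)) stop("clade list file not found: ", path,
                               call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("clade list file ", path, " is empty",
                           call. = FALSE)
  lines
}
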