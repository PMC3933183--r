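# canonical key for one split side (the side not containing the reference
# taxon, which is the lexicographically smallest label)
canonical_split <- function(side, taxa) {
  ref <- sort(taxa)[1]
  if (ref %in% side) side <- setdiff(taxa, side)
  paste(sort(side), collapse = "|")
}

#' Non-trivial bipartitions of a tree
#'
#' One canonical taxon-set key per internal edge; sides are canonicalized to
#' the side not containing a fixed reference taxon (the alphabetically first
#' label). A fully resolved unrooted binary tree on n taxa yields exactly
#' n - 3 bipartitions; trees on fewer than 4 taxa yield none.
#'
#' @param tree an `ape::phylo`.
#' @return character vector of split keys (member labels joined by `|`).
#' @export
bipartitions <- function(tree) {
  taxa <- tree$tip.label
  n <- length(taxa)
  if (n < 4L) return(character(0))
  tree <- ape::unroot(tree)
  pp <- ape::prop.part(tree)
  keys <- character(0)
  for (clade in pp) {
    side <- taxa[clade]
    if (length(side) < 2L || length(side) > n - 2L) next
    keys <- c(keys, canonical_split(side, taxa))
  }
  unique(keys)
}

#' Bipartition counts over a set of trees
#'
#' @param trees list of `ape::phylo` trees on identical taxon sets.
#' @return object of class `bipartition_table`: data.frame with `split`,
#'   `count`, `frequency`; attributes `n_trees`, `taxa`.
#' @export
bipartition_table <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  taxa <- sort(trees[[1]]$tip.label)
  for (tr in trees)
    if (!setequal(tr$tip.label, taxa)) stopf("trees have mismatched taxon sets")
  counts <- table(unlist(lapply(trees, bipartitions)))
  out <- data.frame(split = names(counts), count = as.integer(counts),
                    frequency = as.integer(counts) / length(trees),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$split), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, n_trees = length(trees), taxa = taxa,
            class = c("bipartition_table", "data.frame"))
}

# pairwise compatibility of split sides (sets not containing the reference)
splits_compatible <- function(a, b, taxa) {
  ov <- length(intersect(a, b))
  ov == 0L || ov == length(a) || ov == length(b)
}

#' Majority-rule consensus of a tree set
#'
#' Retains bipartitions occurring in strictly more than `cutoff` of the
#' trees (so a split in exactly half of them is excluded); at cutoff >= 0.5
#' the retained splits are pairwise compatible by pigeonhole, which is
#' asserted. Internal node labels of the returned tree carry the support
#' percentages.
#'
#' @param trees list of `ape::phylo` trees on identical taxon sets.
#' @param cutoff retention threshold in `[0.5, 1]` (default 0.5).
#' @param digits decimal places for support percentages (default 0).
#' @return an `ape::phylo` consensus tree with supports in `node.label`.
#' @export
majority_rule_consensus <- function(trees, cutoff = 0.5, digits = 0) {
  if (cutoff < 0.5 || cutoff > 1) stopf("cutoff must be in [0.5, 1]")
  tab <- bipartition_table(trees)
  taxa <- attr(tab, "taxa")
  keep <- tab[tab$frequency > cutoff, , drop = FALSE]
  sides <- lapply(strsplit(keep$split, "|", fixed = TRUE), identity)
  if (length(sides) > 1L) {
    for (i in seq_along(sides)[-1]) for (j in seq_len(i - 1L))
      if (!splits_compatible(sides[[i]], sides[[j]], taxa))
        stopf("retained splits are incompatible; cutoff too low")
  }
  support <- round(100 * keep$frequency, digits)
  # nest compatible clades (all exclude the reference taxon) into newick
  build <- function(members, idx) {
    inside <- idx[vapply(idx, function(i) all(sides[[i]] %in% members), logical(1))]
    maximal <- inside[vapply(inside, function(i) {
      !any(vapply(setdiff(inside, i), function(j)
        all(sides[[i]] %in% sides[[j]]) && length(sides[[j]]) > length(sides[[i]]),
        logical(1)))
    }, logical(1))]
    used <- unique(unlist(sides[maximal]))
    parts <- c(vapply(maximal, function(i)
      paste0(build(sides[[i]], setdiff(inside, i)), format(support[i])),
      character(1)),
      setdiff(members, used))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  nwk <- paste0(build(taxa, seq_along(sides)), ";")
  ape::read.tree(text = nwk)
}

#' Bipartition-resolution summary
#'
#' Counts internal bipartitions supported at or above a threshold out of the
#' `n_taxa - 3` possible in a fully resolved unrooted tree, and the mean
#' support over internal nodes.
#'
#' @param x a tree with numeric support values in `node.label` (e.g. from
#'   [majority_rule_consensus()]), or a data.frame with a `support` column.
#' @param threshold support threshold in percent (default 70).
#' @param n_taxa taxon count (taken from the tree when `x` is a tree).
#' @return list with `n_resolved`, `n_possible`, `mean_support`.
#' @export
support_summary <- function(x, threshold = 70, n_taxa = NULL) {
  if (inherits(x, "phylo")) {
    n_taxa <- length(x$tip.label)
    supports <- suppressWarnings(as.numeric(x$node.label))
    supports <- supports[!is.na(supports)]
  } else {
    if (is.null(n_taxa)) stopf("n_taxa required with a support table")
    supports <- x$support
  }
  list(n_resolved = sum(supports >= threshold),
       n_possible = n_taxa - 3L,
       mean_support = if (length(supports)) mean(supports) else NA_real_)
}

#' Root a tree on the edge defined by an outgroup
#'
#' The outgroup must form one side of an existing bipartition (or be a single
#' taxon); the root is placed on that edge and the topology is otherwise
#' unchanged.
#'
#' @param tree an `ape::phylo`.
#' @param outgroup character vector of outgroup taxa.
#' @return a rooted `ape::phylo`.
#' @export
root_at_split <- function(tree, outgroup) {
  miss <- setdiff(outgroup, tree$tip.label)
  if (length(miss)) stopf("unknown outgroup taxon '%s'", miss[1])
  if (length(outgroup) > 1L) {
    key <- canonical_split(outgroup, tree$tip.label)
    if (!(key %in% bipartitions(tree)))
      stopf("outgroup is not monophyletic in the tree")
  }
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}
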