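#' Parse and write Newick trees
#'
#' Thin wrappers around ape's Newick reader/writer that validate input and
#' keep a consistent error surface with the rest of the package.
#'
#' @param text a Newick string.
#' @return [parse_newick()] returns an `ape::phylo` tree; [write_newick()]
#'   returns a Newick string.
#' @export
parse_newick <- function(text) {
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close) stopf("unbalanced parentheses in Newick string")
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree)) stopf("could not parse Newick string")
  if (anyDuplicated(tree$tip.label)) stopf("duplicate leaf labels")
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    stopf("negative branch length")
  tree
}

#' @rdname parse_newick
#' @param tree an `ape::phylo` tree.
#' @export
write_newick <- function(tree) {
  ape::write.tree(tree)
}
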