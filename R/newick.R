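#' Read and write Newick trees
#'
#' Thin wrappers around [ape::read.tree()] / [ape::write.tree()] that add the
#' validation this pipeline needs: the Newick string must parse, and tip
#' labels must be unique (they identify clonal isolates).
#'
#' @param path path to a Newick file.
#' @return a rooted `phylo` object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  tree <- tryCatch(
    ape::read.tree(path),
    error = function(e) abort(sprintf("cannot parse Newick in %s: %s", path, conditionMessage(e)))
  )
  if (is.null(tree)) abort(sprintf("cannot parse Newick in %s", path))
  validate_tree(tree)
}

validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) abort("expected a `phylo` tree")
  if (anyDuplicated(tree$tip.label)) {
    abort(sprintf(
      "duplicate tip label(s): %s",
      paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", ")
    ))
  }
  tree
}

#' @rdname read_newick
#' @param tree a `phylo` object.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(validate_tree(tree), file = path)
  invisible(path)
}
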