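# Rooting.

#' Midpoint rooting
#'
#' Places the root at the midpoint of the longest tip-to-tip path — the
#' choice when no outgroup exists.
#'
#' @param tree Unrooted (or rooted) `phylo` with branch lengths.
#' @return Rooted `phylo`.
#' @export
midpoint_root <- function(tree) {
  stopifnot(!is.null(tree$edge.length))
  if (length(tree$tip.label) == 2L) {
    h <- sum(tree$edge.length) / 2
    return(ape::read.tree(text = sprintf("(%s:%.15g,%s:%.15g);",
                                         tree$tip.label[1L], h,
                                         tree$tip.label[2L], h)))
  }
  phangorn::midpoint(ape::unroot(tree))
}

#' Outgroup rooting
#'
#' Roots the tree on the branch separating a monophyletic outgroup from the
#' ingroup.
#'
#' @param tree `phylo`.
#' @param outgroup Character vector of outgroup tip labels.
#' @return Rooted `phylo`.
#' @export
outgroup_root <- function(tree, outgroup) {
  missing <- setdiff(outgroup, tree$tip.label)
  if (length(missing)) {
    stop("outgroup tip(s) not in tree: ", paste(missing, collapse = ", "))
  }
  utree <- ape::unroot(tree)
  if (length(outgroup) > 1L &&
      !sets_monophyletic(utree, list(outgroup))) {
    # name the outgroup members whose smallest covering clade drags in
    # non-outgroup tips
    sets <- node_tipsets(utree)
    cover <- sets[[which.min(vapply(sets, function(s) {
      if (all(outgroup %in% s)) length(s) else Inf
    }, numeric(1)))]]
    conflict <- setdiff(cover, outgroup)
    stop("outgroup is not monophyletic; conflicting tip(s): ",
         paste(conflict, collapse = ", "))
  }
  ape::root(utree, outgroup = outgroup, resolve.root = TRUE)
}
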