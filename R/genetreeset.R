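## Ordered collection of gene trees with per-tree metadata.

#' Construct a gene-tree set
#'
#' An ordered collection of `phylo` objects over possibly unequal taxon
#' subsets, carrying a per-tree id and the mean internal-edge support computed
#' by [mean_support()].
#'
#' @param trees List of `phylo` (or `multiPhylo`).
#' @param ids Optional character vector of unique tree ids; defaults to
#'   `"g1", "g2", ...`.
#' @return An object of class `gene_tree_set`: a list with elements `trees`
#'   (list of `phylo`) and `meta` (data.frame with columns `id`, `n_tips`,
#'   `mean_support`).
#' @export
gene_tree_set <- function(trees, ids = NULL) {
  trees <- as_tree_list(trees)
  if (!length(trees)) stop("empty tree set")
  if (is.null(ids)) ids <- paste0("g", seq_along(trees))
  ids <- as.character(ids)
  if (length(ids) != length(trees)) stop("ids and trees lengths differ")
  if (anyDuplicated(ids)) stop("duplicate tree ids")
  for (tr in trees) {
    validate_tree(tr)
    if (length(tr$tip.label) < 3L) stop("gene trees must have >= 3 leaves")
  }
  meta <- data.frame(
    id = ids,
    n_tips = vapply(trees, function(t) length(t$tip.label), 0L),
    mean_support = vapply(trees, mean_support, 0.0),
    stringsAsFactors = FALSE)
  structure(list(trees = trees, meta = meta), class = "gene_tree_set")
}

#' Coerce tree collections to a plain list of phylo
#' @param x A `gene_tree_set`, `multiPhylo`, list of `phylo`, or single `phylo`.
#' @return A list of `phylo` objects.
#' @export
as_tree_list <- function(x) {
  if (inherits(x, "gene_tree_set")) return(x$trees)
  if (inherits(x, "phylo")) return(list(x))
  if (inherits(x, "multiPhylo")) return(unclass(x))
  if (is.list(x)) return(x)
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
       " as a tree list")
}

#' @export
length.gene_tree_set <- function(x) length(x$trees)

#' @export
`[.gene_tree_set` <- function(x, i) {
  gene_tree_set(x$trees[i], ids = x$meta$id[i])
}

#' @export
print.gene_tree_set <- function(x, ...) {
  cat(sprintf("gene_tree_set: %d trees, %d-%d tips, mean support %s\n",
              length(x$trees), min(x$meta$n_tips), max(x$meta$n_tips),
              format(mean(x$meta$mean_support, na.rm = TRUE), digits = 4)))
  invisible(x)
}
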