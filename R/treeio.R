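## Tree data model and topology primitives.
##
## Trees are ape "phylo" objects throughout: tips 1..n, internal nodes
## n+1..n+Nnode, support values stored as internal node labels (the label of a
## node annotates the edge above it, as in standard Newick usage).

#' Parse a Newick string into a phylo object
#'
#' Thin validating wrapper around [ape::read.tree()]. Internal node labels are
#' kept verbatim; numeric labels are interpreted downstream as support values.
#'
#' @param text A single Newick statement terminated by ";".
#' @return An object of class `phylo`.
#' @examples
#' tr <- parse_newick("((A:1.0,B:1.0)90:0.5,C:1.5);")
#' mean_support(tr)
#' @export
parse_newick <- function(text) {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text)))
    stop("empty or invalid Newick input")
  text <- trimws(text)
  .check_parens(text)
  if (!grepl(";\\s*$", text))
    stop("Newick statement must be terminated by ';'")
  tr <- ape::read.tree(text = text)
  if (is.null(tr)) stop("failed to parse Newick string")
  validate_tree(tr)
  tr
}

.check_parens <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    else if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop(sprintf("unbalanced parentheses: unmatched ')' at character %d", i))
    }
  }
  if (depth > 0L)
    stop(sprintf("unbalanced parentheses: %d '(' left open at end of input (length %d)",
                 depth, length(chars)))
  invisible(TRUE)
}

#' Validate a phylo object
#'
#' Checks the invariants the rest of the package relies on: unique non-empty
#' leaf names, non-negative branch lengths, a connected acyclic edge matrix.
#'
#' @param tree A `phylo` object.
#' @return The tree, invisibly. Errors on violation.
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  tips <- tree$tip.label
  if (any(!nzchar(tips))) stop("empty leaf name")
  if (anyDuplicated(tips))
    stop("duplicate leaf name: ", tips[duplicated(tips)][1L])
  if (!is.null(tree$edge.length)) {
    if (anyNA(tree$edge.length)) stop("missing (NA) branch lengths present")
    if (any(tree$edge.length < 0)) stop("negative branch length")
  }
  nch <- tabulate(tree$edge[, 2L], nbins = max(tree$edge))
  if (any(nch > 1L)) stop("node with more than one parent: tree is not a tree")
  invisible(tree)
}

#' Write a phylo object as a deterministic Newick string
#'
#' Children under every node are ordered by their smallest descendant leaf
#' name, so topologically identical trees always serialize identically
#' (reproducible diffs). Supports are written as internal node labels.
#'
#' @param tree A `phylo` object.
#' @param digits Significant digits for branch lengths.
#' @return A Newick string terminated by ";".
#' @export
write_newick <- function(tree, digits = 15) {
  validate_tree(tree)
  n <- length(tree$tip.label)
  nnode <- tree$Nnode
  nmax <- n + nnode
  kids <- vector("list", nmax)
  blen <- rep(NA_real_, nmax)
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1L]; ch <- tree$edge[k, 2L]
    kids[[p]] <- c(kids[[p]], ch)
    if (!is.null(tree$edge.length)) blen[ch] <- tree$edge.length[k]
  }
  root <- setdiff(tree$edge[, 1L], tree$edge[, 2L])[1L]
  ## smallest descendant leaf name per node, for deterministic rotation
  minlab <- character(nmax)
  minlab[seq_len(n)] <- tree$tip.label
  ## postorder guarantees a node's children are labeled before the node
  for (v in unique(ape::reorder.phylo(tree, "postorder")$edge[, 1L]))
    minlab[v] <- min(minlab[kids[[v]]])
  fmt_len <- function(v) {
    if (is.na(v)) "" else paste0(":", format(v, digits = digits, scientific = FALSE))
  }
  rec <- function(v) {
    if (v <= n) return(paste0(tree$tip.label[v], fmt_len(blen[v])))
    ch <- kids[[v]][order(minlab[kids[[v]]], method = "radix")]
    lab <- if (!is.null(tree$node.label)) tree$node.label[v - n] else ""
    if (is.na(lab)) lab <- ""
    paste0("(", paste(vapply(ch, rec, ""), collapse = ","), ")", lab, fmt_len(blen[v]))
  }
  paste0(rec(root), ";")
}

## ---- bipartitions ---------------------------------------------------------

#' Construct a canonical bipartition
#'
#' A bipartition (split) is the pair of leaf sets separated by removing an
#' internal edge. The canonical form is order-independent: `side_a` is the
#' side containing the lexicographically smallest taxon, both sides sorted.
#'
#' @param side_a,side_b Disjoint non-empty character vectors of taxon names.
#' @return An object of class `bipartition` with elements `side_a`, `side_b`.
#' @export
bipartition <- function(side_a, side_b) {
  side_a <- sort(unique(as.character(side_a)), method = "radix")
  side_b <- sort(unique(as.character(side_b)), method = "radix")
  if (!length(side_a) || !length(side_b)) stop("bipartition sides must be non-empty")
  if (length(intersect(side_a, side_b))) stop("bipartition sides must be disjoint")
  if (side_b[1L] < side_a[1L]) { tmp <- side_a; side_a <- side_b; side_b <- tmp }
  structure(list(side_a = side_a, side_b = side_b), class = "bipartition")
}

#' @export
format.bipartition <- function(x, ...) {
  paste0(paste(x$side_a, collapse = ","), "|", paste(x$side_b, collapse = ","))
}

#' @export
print.bipartition <- function(x, ...) {
  cat("bipartition:", format(x), "\n")
  invisible(x)
}

#' Test whether a bipartition is non-trivial
#' @param x A `bipartition`.
#' @return `TRUE` iff both sides have at least two taxa.
#' @export
is_nontrivial <- function(x) length(x$side_a) >= 2L && length(x$side_b) >= 2L

## Integer tip sets below every node (over the tree's own tip indices).
.tip_sets <- function(tree) {
  n <- length(tree$tip.label)
  sets <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) sets[[i]] <- i
  eo <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(eo)))
    sets[[eo[k, 1L]]] <- c(sets[[eo[k, 1L]]], sets[[eo[k, 2L]]])
  sets
}

## Canonical split keys for fast set algebra. `universe` is the sorted taxon
## vector defining index space; key = comma-joined sorted indices of the side
## containing universe[1]. Trees are treated as unrooted: the root split
## duplicates are removed by unique().
.split_keys <- function(tree, universe = sort(tree$tip.label, method = "radix")) {
  n_u <- length(universe)
  idx <- match(tree$tip.label, universe)
  sets <- .tip_sets(tree)
  n <- length(tree$tip.label)
  keys <- character(0L)
  for (v in (n + 1L):(n + tree$Nnode)) {
    side <- sort(idx[sets[[v]]])
    if (length(side) < 2L || length(side) > n_u - 2L) next
    if (!1L %in% side) side <- setdiff(seq_len(n_u), side)
    keys <- c(keys, paste(side, collapse = ","))
  }
  unique(keys)
}

.key_to_bipartition <- function(key, universe) {
  a <- as.integer(strsplit(key, ",", fixed = TRUE)[[1L]])
  bipartition(universe[a], universe[-a])
}

#' Non-trivial bipartitions of a tree
#'
#' One bipartition per internal edge of the unrooted version of the tree;
#' splits with a side of fewer than two taxa are excluded. A fully resolved
#' unrooted tree on n leaves yields exactly n - 3 bipartitions.
#'
#' @param tree A `phylo` object.
#' @return A list of `bipartition` objects (possibly empty).
#' @export
bipartitions <- function(tree) {
  validate_tree(tree)
  if (length(tree$tip.label) < 4L) return(list())
  universe <- sort(tree$tip.label, method = "radix")
  lapply(.split_keys(tree, universe), .key_to_bipartition, universe = universe)
}

#' Robinson-Foulds distance between two trees
#'
#' The size of the symmetric difference of the trees' non-trivial bipartition
#' sets (trees compared unrooted), plus the normalized version
#' raw / (|B1| + |B2|), defined as 0 when both sets are empty.
#'
#' @param t1,t2 `phylo` objects with identical leaf sets.
#' @return A list with components `raw` (integer) and `normalized` (in [0,1]).
#' @export
rf_distance <- function(t1, t2) {
  u1 <- sort(t1$tip.label, method = "radix")
  u2 <- sort(t2$tip.label, method = "radix")
  if (length(u1) != length(u2) || any(u1 != u2))
    stop("trees have different leaf sets; use restrict() to reduce both to ",
         "their shared taxa first")
  k1 <- .split_keys(t1, u1)
  k2 <- .split_keys(t2, u1)
  raw <- length(setdiff(k1, k2)) + length(setdiff(k2, k1))
  denom <- length(k1) + length(k2)
  list(raw = as.integer(raw),
       normalized = if (denom == 0L) 0 else raw / denom)
}

## ---- restriction ----------------------------------------------------------

#' Restrict a tree to a taxon subset
#'
#' Returns the induced subtree on `taxa`. Degree-2 nodes arising from pruning
#' are suppressed with branch lengths summed; when two supported edges merge,
#' the retained edge keeps the larger of the two numeric supports
#' (conservative merging).
#'
#' @param tree A `phylo` object.
#' @param taxa Character vector, a subset of the leaf set with >= 2 names.
#' @return The restricted `phylo`.
#' @export
restrict <- function(tree, taxa) {
  taxa <- unique(as.character(taxa))
  if (!all(taxa %in% tree$tip.label))
    stop("taxa not in tree: ", paste(setdiff(taxa, tree$tip.label), collapse = ", "))
  if (length(taxa) < 2L) stop("need at least 2 taxa to restrict to")
  if (length(taxa) == length(tree$tip.label)) return(tree)
  pruned <- ape::drop.tip(tree, setdiff(tree$tip.label, taxa),
                          collapse.singles = FALSE)
  .collapse_singles_max_support(pruned)
}

## Suppress degree-2 internal nodes; lengths sum, supports merge by max.
.collapse_singles_max_support <- function(tree) {
  n <- length(tree$tip.label)
  edge <- tree$edge
  len <- if (is.null(tree$edge.length)) rep(NA_real_, nrow(edge)) else tree$edge.length
  lab <- rep(NA_character_, max(edge))
  if (!is.null(tree$node.label))
    lab[(n + 1L):(n + tree$Nnode)] <- tree$node.label
  repeat {
    nkids <- tabulate(edge[, 1L], nbins = max(edge))
    root <- setdiff(edge[, 1L], edge[, 2L])[1L]
    singles <- which(nkids == 1L)
    singles <- singles[singles > n]
    if (!length(singles)) break
    v <- singles[1L]
    e2 <- which(edge[, 1L] == v)            # v -> c
    child <- edge[e2, 2L]
    if (v == root) {
      edge <- edge[-e2, , drop = FALSE]; len <- len[-e2]
    } else {
      e1 <- which(edge[, 2L] == v)          # p -> v
      edge[e1, 2L] <- child
      len[e1] <- sum(len[c(e1, e2)])
      if (child > n) {
        s <- suppressWarnings(as.numeric(c(lab[v], lab[child])))
        if (any(!is.na(s))) lab[child] <- format(max(s, na.rm = TRUE))
      }
      edge <- edge[-e2, , drop = FALSE]; len <- len[-e2]
    }
  }
  ## renumber to ape convention via parent arrays
  keep <- sort(unique(as.integer(edge)))
  id_of <- integer(max(keep)); id_of[keep] <- seq_along(keep)
  np <- length(keep)
  parent <- rep(0L, np); plen <- rep(NA_real_, np); labs <- rep(NA_character_, np)
  for (k in seq_len(nrow(edge))) {
    parent[id_of[edge[k, 2L]]] <- id_of[edge[k, 1L]]
    plen[id_of[edge[k, 2L]]] <- len[k]
  }
  labs[id_of[keep]] <- lab[keep]
  tips_old <- keep[keep <= n]
  .make_phylo(parent, plen, tip_ids = id_of[tips_old],
              tip_labels = tree$tip.label[tips_old], node_labels = labs)
}

## Build a valid phylo from parent pointers.
##  parent: integer vector over node ids 1..N (0 = root);
##  blen:   length-to-parent per node (NA allowed);
##  tip_ids / tip_labels: which ids are tips and their names;
##  node_labels: optional labels per id (internal ids only are used).
.make_phylo <- function(parent, blen, tip_ids, tip_labels, node_labels = NULL) {
  np <- length(parent)
  ntip <- length(tip_ids)
  is_tip <- logical(np); is_tip[tip_ids] <- TRUE
  kids <- split(seq_len(np)[parent != 0L], parent[parent != 0L])
  root <- which(parent == 0L)
  newid <- integer(np)
  newid[tip_ids] <- seq_len(ntip)
  cnt <- ntip
  stack <- root
  while (length(stack)) {                    # preorder numbering of internals
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (!is_tip[v]) {
      cnt <- cnt + 1L
      newid[v] <- cnt
      stack <- c(stack, rev(kids[[as.character(v)]]))
    }
  }
  nnode <- cnt - ntip
  ch <- which(parent != 0L)
  edge <- cbind(newid[parent[ch]], newid[ch])
  o <- order(edge[, 1L], edge[, 2L])
  edge <- edge[o, , drop = FALSE]
  el <- blen[ch][o]
  tr <- list(edge = edge, Nnode = nnode, tip.label = tip_labels)
  if (!all(is.na(el))) tr$edge.length <- el
  if (!is.null(node_labels)) {
    nl <- rep(NA_character_, nnode)
    for (v in seq_len(np)) if (!is_tip[v]) nl[newid[v] - ntip] <- node_labels[v]
    if (any(!is.na(nl))) { nl[is.na(nl)] <- ""; tr$node.label <- nl }
  }
  class(tr) <- "phylo"
  attr(tr, "order") <- NULL
  tr
}

## ---- support --------------------------------------------------------------

#' Mean support over labeled internal edges
#'
#' Arithmetic mean of the numeric internal node labels, excluding the root
#' node (whose label annotates no edge). Edges without a numeric label are not
#' counted. Returns `NA` when no internal edge carries a numeric support.
#'
#' @param tree A `phylo` object.
#' @return A single numeric, or `NA_real_` if undefined.
#' @export
mean_support <- function(tree) {
  if (is.null(tree$node.label)) return(NA_real_)
  n <- length(tree$tip.label)
  internal_children <- unique(tree$edge[, 2L][tree$edge[, 2L] > n])
  s <- suppressWarnings(as.numeric(tree$node.label[internal_children - n]))
  s <- s[!is.na(s)]
  if (!length(s)) NA_real_ else mean(s)
}

## ---- greedy consensus -----------------------------------------------------

#' Greedy consensus tree
#'
#' Ranks the bipartitions observed across the input trees by frequency and
#' adds them in decreasing order while mutually compatible (ties broken by the
#' canonical string of the split's smaller side, for determinism). Used in
#' this package as a simple species-tree estimator for parameter-recovery
#' checks; it is not a substitute for likelihood or coalescent inference.
#'
#' @param trees A `gene_tree_set`, `multiPhylo`, or list of `phylo` sharing
#'   one leaf set.
#' @return A `phylo`; node labels give the percentage of input trees
#'   displaying each retained split.
#' @export
greedy_consensus <- function(trees) {
  trees <- as_tree_list(trees)
  if (!length(trees)) stop("empty tree set")
  universe <- sort(trees[[1L]]$tip.label, method = "radix")
  for (tr in trees)
    if (length(tr$tip.label) != length(universe) ||
        !setequal(tr$tip.label, universe))
      stop("all trees must share one leaf set")
  keys <- unlist(lapply(trees, .split_keys, universe = universe))
  if (!length(keys)) return(ape::read.tree(text = paste0(
    "(", paste(universe, collapse = ","), ");")))
  freq <- table(keys)
  nuni <- length(universe)
  sides <- lapply(names(freq), function(k)
    as.integer(strsplit(k, ",", fixed = TRUE)[[1L]]))
  tie_key <- vapply(sides, function(a) {
    b <- setdiff(seq_len(nuni), a)
    small <- if (length(a) < length(b)) a else if (length(b) < length(a)) b else a
    paste(universe[small], collapse = ",")
  }, "")
  ord <- order(-as.integer(freq), tie_key, method = "radix")
  accepted <- list(); acc_freq <- integer(0)
  for (i in ord) {
    a <- sides[[i]]
    ok <- all(vapply(accepted, function(b) .sides_compatible(a, b, nuni), TRUE))
    if (ok) { accepted[[length(accepted) + 1L]] <- a
              acc_freq <- c(acc_freq, as.integer(freq[i])) }
  }
  .tree_from_splits(accepted, universe,
                    labels = sprintf("%d", round(100 * acc_freq / length(trees))))
}

## splits given as index vectors of the side containing taxon 1
.sides_compatible <- function(a, b, n) {
  ac <- setdiff(seq_len(n), a); bc <- setdiff(seq_len(n), b)
  !length(intersect(a, b)) || !length(intersect(a, bc)) ||
    !length(intersect(ac, b)) || !length(intersect(ac, bc))
}

## Build a tree displaying a compatible split family; clades are the sides not
## containing taxon 1 (rooting on taxon 1's pendant edge).
.tree_from_splits <- function(sides, universe, labels = NULL) {
  n <- length(universe)
  clades <- lapply(sides, function(a) setdiff(seq_len(n), a))
  ord <- order(-lengths(clades))
  clades <- clades[ord]
  labels <- if (!is.null(labels)) labels[ord]
  build <- function(members, avail) {
    ## avail: indices into clades of candidates strictly inside `members`
    inside <- avail[vapply(avail, function(i)
      length(clades[[i]]) < length(members) && all(clades[[i]] %in% members),
      TRUE)]
    parts <- character(0)
    used <- integer(0)
    for (i in inside) {
      if (length(intersect(clades[[i]], used))) next  # covered by a maximal clade
      lab <- if (is.null(labels)) "" else labels[i]
      parts <- c(parts, paste0("(", build(clades[[i]], inside), ")", lab))
      used <- c(used, clades[[i]])
    }
    singles <- setdiff(members, used)
    parts <- c(parts, universe[singles])
    paste(sort(parts, method = "radix"), collapse = ",")
  }
  txt <- paste0("(", build(seq_len(n), seq_along(clades)), ");")
  ape::read.tree(text = txt)
}

## ---- file IO --------------------------------------------------------------

#' Read one or more Newick trees from a file
#'
#' One tree per line; gzip-compressed files are accepted. In strict mode a
#' tree containing duplicate taxa is an error.
#'
#' @param path File path (optionally `.gz`).
#' @param strict Reject duplicate taxa within a tree (default TRUE).
#' @return A list of `phylo` objects.
#' @export
read_newick_file <- function(path, strict = TRUE) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("no trees in file: ", path)
  trees <- lapply(lines, function(x) {
    tr <- ape::read.tree(text = x)
    if (is.null(tr)) stop("failed to parse tree in ", path)
    if (strict) validate_tree(tr)
    tr
  })
  trees
}

#' Write trees to a Newick file, one per line
#'
#' @param trees A `phylo`, list of `phylo`, `multiPhylo` or `gene_tree_set`.
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_newick_file <- function(trees, path) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- as_tree_list(trees)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(vapply(trees, write_newick, ""), con)
  invisible(path)
}
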