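## Gene-tree / reference-tree agreement: support filtering, per-node
## concordance-conflict accounting (PhyParts-style), ILS node support, and
## tree-distance distribution comparison.

#' Filter gene trees by mean support
#'
#' Keeps trees whose mean internal-edge support is strictly greater than
#' `threshold` (trees "with average support values more than" the cutoff).
#' Trees with no numeric support labels have undefined mean support and are
#' dropped; the attached report counts them separately.
#'
#' @param trees A [gene_tree_set()] (or coercible collection).
#' @param threshold Support cutoff (strict inequality). Default 60.
#' @return A `gene_tree_set` with attribute `report`: a list with
#'   `n_input`, `n_kept`, `n_dropped_low_support`, `n_dropped_no_support`.
#' @export
filter_by_mean_support <- function(trees, threshold = 60) {
  if (!inherits(trees, "gene_tree_set")) trees <- gene_tree_set(trees)
  ms <- trees$meta$mean_support
  keep <- !is.na(ms) & ms > threshold
  report <- list(n_input = length(ms),
                 n_kept = sum(keep),
                 n_dropped_low_support = sum(!is.na(ms) & ms <= threshold),
                 n_dropped_no_support = sum(is.na(ms)))
  if (!any(keep)) stop("no gene trees pass the support filter")
  out <- trees[keep]
  attr(out, "report") <- report
  out
}

## ---- node classification --------------------------------------------------

## Per-tree split cache over a common taxon universe U (sorted names).
## Returns list(taxa = integer indices of the tree's tips in U,
##              sides = list of integer vectors: for each non-trivial split of
##                      the tree, the side containing the tree's smallest
##                      universe index, sorted).
.gene_split_cache <- function(tree, universe) {
  idx <- match(tree$tip.label, universe)
  if (anyNA(idx))
    stop("gene tree contains taxa absent from the reference: ",
         tree$tip.label[which(is.na(idx))[1L]])
  taxa <- sort(idx)
  n <- length(tree$tip.label)
  sets <- .tip_sets(tree)
  sides <- list()
  seen <- character(0)
  anchor <- taxa[1L]
  for (v in (n + 1L):(n + tree$Nnode)) {
    side <- sort(idx[sets[[v]]])
    if (length(side) < 2L || length(side) > n - 2L) next
    if (!anchor %in% side) side <- setdiff(taxa, side)
    key <- paste(side, collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    sides[[length(sides) + 1L]] <- side
  }
  list(taxa = taxa, sides = sides, keys = seen)
}

## Classify one reference split (integer sides over U) against one cached
## gene tree. Returns list(status, conflict = side vector or NULL).
.classify_cached <- function(ref_a, ref_b, cache) {
  a <- intersect(ref_a, cache$taxa)
  b <- intersect(ref_b, cache$taxa)
  if (length(a) < 2L || length(b) < 2L)
    return(list(status = "uninformative", conflict = NULL))
  anchor <- cache$taxa[1L]
  ra <- if (anchor %in% a) a else b      # restricted split, canonical side
  key <- paste(sort(ra), collapse = ",")
  if (key %in% cache$keys)
    return(list(status = "concordant", conflict = NULL))
  ## conflict: some gene split with all four side intersections non-empty
  best <- NULL; best_key <- NULL
  for (i in seq_along(cache$sides)) {
    g <- cache$sides[[i]]
    gc <- setdiff(cache$taxa, g)
    if (length(intersect(g, a)) && length(intersect(g, b)) &&
        length(intersect(gc, a)) && length(intersect(gc, b))) {
      k <- cache$keys[i]
      if (is.null(best_key) || k < best_key) { best <- g; best_key <- k }
    }
  }
  if (is.null(best)) return(list(status = "uninformative", conflict = NULL))
  list(status = "conflict", conflict = best)
}

#' Classify a gene tree against one reference bipartition
#'
#' Restricts the reference split to the gene tree's taxa. If either restricted
#' side has fewer than two taxa the tree is uninformative for that split; if
#' the restricted split is displayed by the gene tree it is concordant; if
#' some gene-tree split is incompatible with it (all four pairwise side
#' intersections non-empty) it is a conflict, reported with the
#' lowest-canonical-order incompatible split; otherwise (unresolved) it is
#' uninformative.
#'
#' @param reference_split A [bipartition()].
#' @param gene_tree A `phylo`.
#' @return A list with `status` (one of `"concordant"`, `"conflict"`,
#'   `"uninformative"`) and `conflict` (a `bipartition` or `NULL`).
#' @export
classify_tree_at_node <- function(reference_split, gene_tree) {
  if (!inherits(reference_split, "bipartition")) stop("need a bipartition")
  universe <- sort(union(c(reference_split$side_a, reference_split$side_b),
                         gene_tree$tip.label), method = "radix")
  cache <- .gene_split_cache(gene_tree, universe)
  res <- .classify_cached(match(reference_split$side_a, universe),
                          match(reference_split$side_b, universe), cache)
  if (!is.null(res$conflict)) {
    shared <- cache$taxa
    res$conflict <- bipartition(universe[res$conflict],
                                universe[setdiff(shared, res$conflict)])
  }
  res
}

#' Per-node concordance accounting of gene trees against a reference tree
#'
#' For every non-trivial bipartition of the reference tree, counts how many
#' gene trees are concordant with it, in conflict (split by the identity of
#' the single most frequent conflicting split versus all others), or
#' uninformative. This is the accounting behind pie-chart concordance
#' displays: at every node the four counts sum to the number of gene trees.
#'
#' @param reference A `phylo` reference (species) tree.
#' @param trees A [gene_tree_set()] or coercible collection; gene trees may
#'   cover taxon subsets of the reference.
#' @return A data.frame with one row per reference split: `node` (reference
#'   internal node number), `split`, the four counts `n_concordant`,
#'   `n_conflict_top`, `n_conflict_other`, `n_uninformative`, the matching
#'   fractions (`f_*`), and `top_conflict` (split string or NA).
#' @export
node_concordance <- function(reference, trees) {
  tlist <- as_tree_list(trees)
  if (!length(tlist)) stop("empty gene-tree set")
  validate_tree(reference)
  universe <- sort(reference$tip.label, method = "radix")
  nuni <- length(universe)
  ref_keys <- .split_keys(reference, universe)
  if (!length(ref_keys)) stop("reference tree has no non-trivial bipartitions")
  ref_sides <- lapply(ref_keys, function(k)
    as.integer(strsplit(k, ",", fixed = TRUE)[[1L]]))
  ## map splits back to reference internal nodes for reporting
  node_of_key <- .ref_node_of_split(reference, universe)
  caches <- lapply(tlist, .gene_split_cache, universe = universe)
  ntrees <- length(tlist)
  rows <- vector("list", length(ref_sides))
  for (j in seq_along(ref_sides)) {
    a <- ref_sides[[j]]; b <- setdiff(seq_len(nuni), a)
    n_conc <- 0L; n_unin <- 0L
    conflict_tab <- new.env(parent = emptyenv())
    for (cc in caches) {
      res <- .classify_cached(a, b, cc)
      if (res$status == "concordant") n_conc <- n_conc + 1L
      else if (res$status == "uninformative") n_unin <- n_unin + 1L
      else {
        ## key the tally by the conflicting split over the tree's shared taxa
        k <- format(bipartition(universe[res$conflict],
                                universe[setdiff(cc$taxa, res$conflict)]))
        cur <- if (is.null(conflict_tab[[k]])) 0L else conflict_tab[[k]]
        conflict_tab[[k]] <- cur + 1L
      }
    }
    ck <- ls(conflict_tab)
    n_conf <- if (length(ck)) sum(vapply(ck, function(k) conflict_tab[[k]], 0L)) else 0L
    if (length(ck)) {
      cnts <- vapply(ck, function(k) conflict_tab[[k]], 0L)
      top_i <- order(-cnts, ck, method = "radix")[1L]   # ties: lowest split string
      n_top <- unname(cnts[top_i]); top_str <- ck[top_i]
    } else { top_str <- NA_character_; n_top <- 0L }
    rows[[j]] <- data.frame(
      node = node_of_key[[ref_keys[j]]],
      split = format(.key_to_bipartition(ref_keys[j], universe)),
      n_concordant = n_conc,
      n_conflict_top = n_top,
      n_conflict_other = n_conf - n_top,
      n_uninformative = n_unin,
      f_concordant = n_conc / ntrees,
      f_conflict_top = n_top / ntrees,
      f_conflict_other = (n_conf - n_top) / ntrees,
      f_uninformative = n_unin / ntrees,
      top_conflict = top_str,
      stringsAsFactors = FALSE, row.names = NULL)
  }
  out <- do.call(rbind, rows)
  attr(out, "n_trees") <- ntrees
  out
}

## reference internal node whose tipward side realises each split key
.ref_node_of_split <- function(tree, universe) {
  n <- length(tree$tip.label)
  idx <- match(tree$tip.label, universe)
  sets <- .tip_sets(tree)
  out <- list()
  for (v in (n + 1L):(n + tree$Nnode)) {
    side <- sort(idx[sets[[v]]])
    if (length(side) < 2L || length(side) > length(universe) - 2L) next
    if (!1L %in% side) side <- setdiff(seq_len(length(universe)), side)
    k <- paste(side, collapse = ",")
    if (is.null(out[[k]])) out[[k]] <- v
  }
  out
}

#' ILS support for each node of an organelle (plastid) tree
#'
#' The fraction of MSC-simulated gene trees concordant with each plastid-tree
#' node. The headline fraction uses the informative-only denominator
#' (concordant / (total - uninformative)), so gene trees lacking the relevant
#' taxa do not dilute the signal; the all-trees fraction is also reported. A
#' node supported by (almost) no simulated trees cannot be explained by
#' incomplete lineage sorting alone.
#'
#' @param plastid_tree A `phylo` reference (e.g. plastome phylogeny).
#' @param simulated A [gene_tree_set()] of MSC-simulated gene trees.
#' @param not_ils_threshold Fractions at or below this are flagged as not
#'   explicable by ILS (default 0.01).
#' @return The [node_concordance()] table plus columns `ils_fraction`
#'   (informative denominator), `ils_fraction_all` (all-trees denominator)
#'   and logical `not_ils_explicable`.
#' @export
ils_node_support <- function(plastid_tree, simulated, not_ils_threshold = 0.01) {
  tab <- node_concordance(plastid_tree, simulated)
  n_inf <- attr(tab, "n_trees") - tab$n_uninformative
  tab$ils_fraction <- ifelse(n_inf > 0, tab$n_concordant / n_inf, NA_real_)
  tab$ils_fraction_all <- tab$n_concordant / attr(tab, "n_trees")
  tab$not_ils_explicable <- !is.na(tab$ils_fraction) &
    tab$ils_fraction <= not_ils_threshold
  tab
}

## ---- distance distributions ----------------------------------------------

#' Normalized RF distances from each gene tree to a reference
#'
#' For every gene tree, the reference is restricted to the taxa shared with
#' that tree and the normalized Robinson-Foulds distance is computed. Trees
#' sharing fewer than four taxa with the reference carry no unrooted topology
#' information and are skipped (counted in the result).
#'
#' @param trees A [gene_tree_set()] or coercible collection.
#' @param reference A `phylo`.
#' @param label Label for the distribution (plots, reports).
#' @return An object of class `distance_distribution`: list with `label`,
#'   `distances` (numeric in [0,1]), `ids`, `n_skipped`.
#' @export
distance_distribution <- function(trees, reference, label = "empirical") {
  tlist <- as_tree_list(trees)
  ids <- if (inherits(trees, "gene_tree_set")) trees$meta$id
         else paste0("g", seq_along(tlist))
  ref_universe <- sort(reference$tip.label, method = "radix")
  ref_keys_full <- .split_keys(reference, ref_universe)
  dist <- numeric(0); kept <- character(0); skipped <- 0L
  for (i in seq_along(tlist)) {
    tr <- tlist[[i]]
    shared <- intersect(tr$tip.label, reference$tip.label)
    if (length(shared) < 4L) { skipped <- skipped + 1L; next }
    if (length(shared) == length(ref_universe) &&
        length(tr$tip.label) == length(ref_universe)) {
      k2 <- .split_keys(tr, ref_universe)
      raw <- length(setdiff(ref_keys_full, k2)) + length(setdiff(k2, ref_keys_full))
      denom <- length(ref_keys_full) + length(k2)
      d <- if (denom == 0L) 0 else raw / denom
    } else {
      r1 <- restrict(reference, shared)
      r2 <- if (length(shared) == length(tr$tip.label)) tr else restrict(tr, shared)
      d <- rf_distance(r1, r2)$normalized
    }
    dist <- c(dist, d); kept <- c(kept, ids[i])
  }
  structure(list(label = label, distances = dist, ids = kept,
                 n_skipped = skipped),
            class = "distance_distribution")
}

#' @export
print.distance_distribution <- function(x, ...) {
  cat(sprintf("distance_distribution '%s': n = %d, mean = %.4f (%d skipped)\n",
              x$label, length(x$distances), mean(x$distances), x$n_skipped))
  invisible(x)
}

#' Compare two tree-distance distributions
#'
#' Two-sample Kolmogorov-Smirnov test on the raw distance samples (standard
#' two-sample ECDF definition; ties allowed) plus a histogram overlap
#' coefficient on shared bins over [0, 1].
#'
#' @param empirical,simulated `distance_distribution` objects (or bare
#'   numeric vectors of normalized distances).
#' @param bin_width Histogram bin width for the overlap coefficient
#'   (default 0.05, matching the visual granularity of normalized-RF
#'   histograms).
#' @return List with `ks_statistic`, `ks_p_value`, `overlap_coefficient`.
#' @export
compare_distributions <- function(empirical, simulated, bin_width = 0.05) {
  x <- if (inherits(empirical, "distance_distribution")) empirical$distances else empirical
  y <- if (inherits(simulated, "distance_distribution")) simulated$distances else simulated
  if (!length(x) || !length(y)) stop("empty distance sample")
  ks <- suppressWarnings(stats::ks.test(x, y))
  breaks <- seq(0, 1, by = bin_width)
  if (breaks[length(breaks)] < 1) breaks <- c(breaks, 1)
  h1 <- graphics::hist(x, breaks = breaks, plot = FALSE)$counts / length(x)
  h2 <- graphics::hist(y, breaks = breaks, plot = FALSE)$counts / length(y)
  list(ks_statistic = unname(ks$statistic),
       ks_p_value = unname(ks$p.value),
       overlap_coefficient = sum(pmin(h1, h2)))
}

#' Write a node-concordance table as tab-separated values
#' @param tab Table from [node_concordance()] or [ils_node_support()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_concordance_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
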