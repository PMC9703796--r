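## Multispecies-coalescent (MSC) gene-tree simulation on a species tree,
## with optional hybridization edges and an organelle-tree sampler.
##
## Branch lengths are coalescent units throughout: time scaled so that k
## lineages coalesce at rate k(k-1)/2 per unit. Randomness comes from R's
## Mersenne-Twister stream, seeded explicitly per simulated tree; per-gene
## substream seeds are derived by fixed integer arithmetic from the run seed,
## so any single replicate is reproducible in isolation.

#' Validate a species tree for coalescent simulation
#'
#' The tree must be rooted, binary, ultrametric (tips contemporaneous within
#' tolerance) and carry finite non-negative branch lengths in coalescent
#' units. Species trees in the ASTRAL convention lack terminal branch
#' lengths; these are rejected unless `terminal_fill` supplies a length for
#' every terminal branch, because a silent default would bias the amount of
#' incomplete lineage sorting simulated on the tips.
#'
#' With `terminal_fill`, every terminal branch (all must be missing) is
#' assigned the length that makes the tips contemporaneous, placing them
#' `terminal_fill` coalescent units below the most recent internal node.
#'
#' @param tree A `phylo`, or Newick string.
#' @param terminal_fill Optional positive number controlling how missing
#'   terminal branch lengths are filled (see above).
#' @return The validated (possibly filled) `phylo`.
#' @export
validate_species_tree <- function(tree, terminal_fill = NULL) {
  if (is.character(tree)) tree <- parse_newick(tree)
  if (!inherits(tree, "phylo")) stop("species tree must be a phylo object")
  n <- length(tree$tip.label)
  if (is.null(tree$edge.length))
    stop("species tree has no branch lengths; coalescent units are required")
  if (anyNA(tree$edge.length)) {
    term <- tree$edge[, 2L] <= n
    if (is.null(terminal_fill) || anyNA(tree$edge.length[!term]) ||
        !all(is.na(tree$edge.length[term])))
      stop("species tree has missing branch lengths; supply terminal_fill ",
           "to assign lengths to terminal branches (ASTRAL-style input)")
    if (terminal_fill <= 0) stop("terminal_fill must be > 0")
    el <- tree$edge.length
    el[term] <- 0
    tmp <- tree; tmp$edge.length <- el
    depth <- ape::node.depth.edgelength(tmp)
    parent_depth <- depth[tree$edge[term, 2L]]   # tip depth = parent depth here
    target <- max(parent_depth) + terminal_fill
    tree$edge.length[term] <- target - parent_depth
  }
  if (any(tree$edge.length < 0)) stop("negative branch length in species tree")
  if (!ape::is.binary.phylo(tree) || !ape::is.rooted(tree))
    stop("species tree must be rooted and binary")
  tree
}

## node times measured backwards from the present (tips at 0)
.sp_prep <- function(tree, tol = 1e-8) {
  n <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)   # distance from root
  tmax <- max(depth[seq_len(n)])
  tv <- tmax - depth
  if (any(abs(tv[seq_len(n)]) > tol * max(tmax, 1)))
    stop("species tree must be ultrametric (contemporaneous tips)")
  tv[seq_len(n)] <- 0
  parent <- integer(n + tree$Nnode)
  for (k in seq_len(nrow(tree$edge))) parent[tree$edge[k, 2L]] <- tree$edge[k, 1L]
  kids <- vector("list", n + tree$Nnode)
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1L]
    kids[[p]] <- c(kids[[p]], tree$edge[k, 2L])
  }
  nanc <- integer(n + tree$Nnode)        # ancestor count, for tie-breaking
  for (k in seq_len(nrow(tree$edge)))    # edges are preorder-ish; iterate twice
    nanc[tree$edge[k, 2L]] <- NA_integer_
  root <- n + 1L
  nanc[root] <- 0L
  repeat {
    done <- TRUE
    for (k in seq_len(nrow(tree$edge))) {
      p <- tree$edge[k, 1L]; ch <- tree$edge[k, 2L]
      if (is.na(nanc[ch]) && !is.na(nanc[p])) { nanc[ch] <- nanc[p] + 1L; done <- FALSE }
    }
    if (done) break
  }
  list(ntip = n, nnode = tree$Nnode, time = tv, parent = parent,
       children = kids, root = root, nanc = nanc, labels = tree$tip.label)
}

#' Define a hybridization event on a species tree
#'
#' At `time` (coalescent units before present), every gene lineage then
#' present on the recipient edge independently switches to the donor edge
#' with probability `gamma` (the inheritance probability). Edges are named by
#' the node at their tipward end: a tip label, an internal node label, or a
#' node number.
#'
#' @param recipient,donor Edge identifiers (see above).
#' @param time Event time in coalescent units, strictly inside both edges'
#'   time spans.
#' @param gamma Inheritance probability in [0, 1].
#' @return An object of class `hyb_event`.
#' @export
hybridization_event <- function(recipient, donor, time, gamma) {
  if (!is.numeric(gamma) || gamma < 0 || gamma > 1) stop("gamma must be in [0, 1]")
  if (!is.numeric(time) || time < 0) stop("event time must be non-negative")
  structure(list(recipient = recipient, donor = donor,
                 time = as.numeric(time), gamma = as.numeric(gamma)),
            class = "hyb_event")
}

.resolve_edge <- function(tree, x) {
  n <- length(tree$tip.label)
  if (is.numeric(x)) {
    x <- as.integer(x)
    if (x < 1L || x > n + tree$Nnode) stop("node id out of range: ", x)
    return(x)
  }
  i <- match(x, tree$tip.label)
  if (!is.na(i)) return(i)
  if (!is.null(tree$node.label)) {
    j <- match(x, tree$node.label)
    if (!is.na(j)) return(n + j)
  }
  stop("cannot resolve edge identifier: ", x)
}

.resolve_events <- function(tree, sp, events, scale = 1) {
  if (is.null(events) || !length(events)) return(NULL)
  if (inherits(events, "hyb_event")) events <- list(events)
  out <- lapply(events, function(ev) {
    r <- .resolve_edge(tree, ev$recipient)
    d <- .resolve_edge(tree, ev$donor)
    te <- ev$time * scale
    for (v in c(r, d)) {
      if (v == sp$root) stop("cannot place event on the root stem")
      lo <- sp$time[v]; hi <- sp$time[sp$parent[v]]
      if (te <= lo || te >= hi)
        stop(sprintf("event time %g not strictly inside edge above node %d (%g, %g)",
                     te, v, lo, hi))
    }
    list(recipient = r, donor = d, time = te, gamma = ev$gamma)
  })
  key <- vapply(out, function(e) sprintf("%d@%.12g", e$recipient, e$time), "")
  if (anyDuplicated(key))
    stop("overlapping hybridization events on the same edge at the same time")
  out[order(vapply(out, `[[`, 0.0, "time"))]
}

## One MSC genealogy. `sp` from .sp_prep (times already scaled if needed).
.sim_msc_core <- function(sp, events, samples_per_species) {
  m <- samples_per_species
  ntip_g <- sp$ntip * m
  max_nodes <- 2L * ntip_g - 1L
  parent_g <- integer(max_nodes)
  time_g <- numeric(max_nodes)
  nxt <- ntip_g
  pools <- vector("list", sp$ntip + sp$nnode)
  for (i in seq_len(sp$ntip))
    pools[[i]] <- seq.int((i - 1L) * m + 1L, i * m)
  ## event schedule: species-node joins (root included) + hybridization moves
  ev_time <- sp$time[(sp$ntip + 1L):(sp$ntip + sp$nnode)]
  sched <- data.frame(time = ev_time, type = "join",
                      node = (sp$ntip + 1L):(sp$ntip + sp$nnode))
  hyb_idx <- seq_along(events)
  if (length(events)) {
    sched <- rbind(sched, data.frame(
      time = vapply(events, `[[`, 0.0, "time"), type = "hyb", node = hyb_idx))
  }
  ## at equal times, children must join before their ancestors
  depth_rank <- ifelse(sched$type == "join", sp$nanc[sched$node], 0L)
  sched <- sched[order(sched$time, -depth_rank, sched$node), , drop = FALSE]

  coalesce <- function(pool, t0, t1) {
    k <- length(pool)
    while (k >= 2L) {
      t0 <- t0 + stats::rexp(1L, rate = k * (k - 1L) / 2)
      if (t0 > t1) break
      pr <- sample.int(k, 2L)
      nxt <<- nxt + 1L
      parent_g[pool[pr]] <<- nxt
      time_g[nxt] <<- t0
      pool <- c(pool[-pr], nxt)
      k <- k - 1L
    }
    pool
  }

  tcur <- 0
  active <- seq_len(sp$ntip)           # pools that may hold lineages
  for (r in seq_len(nrow(sched))) {
    te <- sched$time[r]
    if (te > tcur) {
      for (p in active)
        if (length(pools[[p]]) >= 2L) pools[[p]] <- coalesce(pools[[p]], tcur, te)
      tcur <- te
    }
    if (sched$type[r] == "join") {
      v <- sched$node[r]
      ch <- sp$children[[v]]
      pools[[v]] <- c(pools[[ch[1L]]], pools[[ch[2L]]])
      pools[[ch[1L]]] <- integer(0); pools[[ch[2L]]] <- integer(0)
      active <- c(setdiff(active, ch), v)
    } else {
      e <- events[[sched$node[r]]]
      if (e$gamma > 0 && length(pools[[e$recipient]])) {
        mv <- stats::runif(length(pools[[e$recipient]])) < e$gamma
        if (any(mv)) {
          pools[[e$donor]] <- c(pools[[e$donor]], pools[[e$recipient]][mv])
          pools[[e$recipient]] <- pools[[e$recipient]][!mv]
          active <- unique(c(active, e$donor))
        }
      }
    }
  }
  ## all lineages are now in the root pool; finish on the unbounded root stem
  pool <- pools[[sp$root]]
  if (length(pool) != ntip_g - (nxt - ntip_g))
    stop("internal error: lineages stranded below the root")
  pool <- coalesce(pool, tcur, Inf)

  tips <- if (m == 1L) sp$labels else
    paste0(rep(sp$labels, each = m), "_", rep(seq_len(m), sp$ntip))
  .make_phylo(parent_g[seq_len(nxt)], {
    bl <- numeric(nxt)
    for (v in seq_len(nxt))
      bl[v] <- if (parent_g[v] == 0L) NA_real_ else time_g[parent_g[v]] - time_g[v]
    bl
  }, tip_ids = seq_len(ntip_g), tip_labels = tips)
}

#' Simulate one gene tree under the multispecies coalescent
#'
#' Within each species-tree branch, lineage pairs coalesce at rate 1 per pair
#' (rate k(k-1)/2 for k lineages); uncoalesced lineages enter the parent
#' branch; above the root, coalescence continues on an unbounded stem until a
#' single lineage remains. With hybridization events, lineages on the
#' recipient edge at the event time jump to the donor edge with probability
#' gamma; `gamma = 0` reduces exactly to the pure MSC (no random numbers are
#' drawn for the event).
#'
#' @param species_tree `phylo` (or Newick) with branch lengths in coalescent
#'   units; rooted, binary, ultrametric.
#' @param seed Integer seed; identical seed gives an identical tree.
#' @param events Optional list of [hybridization_event()] objects.
#' @param samples_per_species Gene copies sampled per species (default 1,
#'   tips then keep the species labels; with more, tips are `label_1`, ...).
#' @param terminal_fill See [validate_species_tree()].
#' @return A `phylo` gene tree with branch lengths in coalescent units.
#' @examples
#' sp <- parse_newick("((A:1,B:1):1,C:2);")
#' g <- simulate_gene_tree(sp, seed = 1)
#' @export
simulate_gene_tree <- function(species_tree, seed, events = NULL,
                               samples_per_species = 1L, terminal_fill = NULL) {
  tree <- validate_species_tree(species_tree, terminal_fill)
  sp <- .sp_prep(tree)
  ev <- .resolve_events(tree, sp, events)
  if (!is.null(seed)) set.seed(as.integer(seed))
  .sim_msc_core(sp, ev, as.integer(samples_per_species))
}

#' @rdname simulate_gene_tree
#' @export
simulate_gene_tree_network <- function(species_tree, events, seed,
                                       samples_per_species = 1L,
                                       terminal_fill = NULL) {
  simulate_gene_tree(species_tree, seed = seed, events = events,
                     samples_per_species = samples_per_species,
                     terminal_fill = terminal_fill)
}

#' Derive the per-gene substream seed
#'
#' Fixed integer arithmetic on (seed, gene index); all values stay below
#' 2^31 so results are identical across platforms.
#'
#' @param seed Run seed (integer).
#' @param k Gene index (1-based).
#' @return An integer seed.
#' @export
derive_seed <- function(seed, k) {
  as.integer(((as.double(seed) %% 94906265) * 22695477 +
                as.double(k) * 1103515245) %% 2147483647)
}

#' Simulate a set of gene trees under the MSC
#'
#' `n_genes` independent replicates of [simulate_gene_tree()]; replicate k
#' uses the substream seed `derive_seed(seed, k)`, so it can be reproduced in
#' isolation.
#'
#' @inheritParams simulate_gene_tree
#' @param n_genes Number of gene trees (>= 1).
#' @return A [gene_tree_set()] with ids `sim1..simN`.
#' @export
simulate_gene_trees <- function(species_tree, n_genes, seed, events = NULL,
                                samples_per_species = 1L, terminal_fill = NULL) {
  n_genes <- as.integer(n_genes)
  if (n_genes < 1L) stop("n_genes must be >= 1")
  tree <- validate_species_tree(species_tree, terminal_fill)
  sp <- .sp_prep(tree)
  ev <- .resolve_events(tree, sp, events)
  m <- as.integer(samples_per_species)
  trees <- vector("list", n_genes)
  for (k in seq_len(n_genes)) {
    set.seed(derive_seed(seed, k))
    trees[[k]] <- .sim_msc_core(sp, ev, m)
  }
  gene_tree_set(trees, ids = paste0("sim", seq_len(n_genes)))
}

#' Sample an organelle (plastid/mitochondrial) gene tree
#'
#' A single genealogy simulated after multiplying all species-tree branch
#' lengths (and event times) by `scale`, reflecting the smaller effective
#' population size of a haploid, uniparentally inherited genome (default 4 =
#' diploid biparental / haploid uniparental). At hybridization events the
#' organelle lineage follows the donor with probability gamma, which models
#' chloroplast capture.
#'
#' @inheritParams simulate_gene_tree
#' @param scale Positive branch-length multiplier (default 4).
#' @return A `phylo` organelle tree.
#' @export
sample_organelle_tree <- function(species_tree, events = NULL, scale = 4,
                                  seed = NULL, terminal_fill = NULL) {
  if (!is.numeric(scale) || scale <= 0) stop("scale must be > 0")
  tree <- validate_species_tree(species_tree, terminal_fill)
  tree$edge.length <- tree$edge.length * scale
  sp <- .sp_prep(tree)
  ev <- .resolve_events(tree, sp, events, scale = scale)
  if (!is.null(seed)) set.seed(as.integer(seed))
  .sim_msc_core(sp, ev, 1L)
}

#' Canonical topology key of a tree
#'
#' A string identifying the tree's topology: sorted clade index sets for
#' rooted comparison, or sorted non-trivial split keys for unrooted. Two
#' trees on the same taxa get equal keys iff they have the same topology.
#'
#' @param tree A `phylo`.
#' @param rooted Compare as rooted (clades) or unrooted (splits)?
#' @return A single string.
#' @export
topology_key <- function(tree, rooted = TRUE) {
  universe <- sort(tree$tip.label, method = "radix")
  if (!rooted) return(paste(sort(.split_keys(tree, universe)), collapse = ";"))
  idx <- match(tree$tip.label, universe)
  sets <- .tip_sets(tree)
  n <- length(tree$tip.label)
  keys <- vapply((n + 1L):(n + tree$Nnode), function(v)
    paste(sort(idx[sets[[v]]]), collapse = ","), "")
  paste(sort(unique(keys)), collapse = ";")
}

#' Read a hybridization-event table
#'
#' Tab-separated sidecar file with columns `recipient`, `donor`, `time`,
#' `gamma` (header required), matching the Newick species tree it accompanies.
#'
#' @param path File path.
#' @return List of [hybridization_event()] objects.
#' @export
read_events_file <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("recipient", "donor", "time", "gamma")
  if (!all(need %in% names(df)))
    stop("event table must have columns: ", paste(need, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i)
    hybridization_event(df$recipient[i], df$donor[i], df$time[i], df$gamma[i]))
}
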