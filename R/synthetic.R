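## Synthetic study fixtures: Yule species trees, MSC/hybridization gene-tree
## sets, Jukes-Cantor alignments, and VCF-like site records with an exact
## truth ledger, so every downstream filter outcome is computable in advance.

#' Fixture configuration
#'
#' Bundles every knob of the synthetic-data generator. Rates are per
#' coalescent-unit time; the substitution scale is substitutions per site per
#' coalescent unit. Depth and quality parameters control the planted variant
#' records: passing cells draw depth `4 + Poisson(depth_mean - 4)` and site
#' quality `Uniform(20, qual_max)`; planted violations draw strictly below
#' the respective cutoffs.
#'
#' @param n_taxa Number of species (>= 3).
#' @param rate Speciation rate of the Yule species tree.
#' @param n_genes Number of gene trees / alignments.
#' @param events Optional list of [hybridization_event()].
#' @param aln_length Alignment length per gene (bp).
#' @param subst_rate Substitutions per site per coalescent unit.
#' @param depth_mean Mean read depth of passing cells (> 4).
#' @param qual_max Upper bound of passing site qualities.
#' @param p_low_depth Per-cell probability of a planted low-depth violation.
#' @param p_low_qual Per-site probability of a planted low-quality site.
#' @param p_het Per-cell probability of a planted heterozygous call.
#' @param organelle_scale Branch-length multiplier for the organelle tree.
#' @param seed Integer master seed.
#' @return A list of class `fixture_config`.
#' @export
fixture_config <- function(n_taxa = 8L, rate = 1, n_genes = 50L,
                           events = NULL, aln_length = 1000L,
                           subst_rate = 0.05, depth_mean = 20,
                           qual_max = 60, p_low_depth = 0.05,
                           p_low_qual = 0.05, p_het = 0.05, seed = 1L,
                           organelle_scale = 4) {
  if (n_taxa < 3L) stop("n_taxa must be >= 3")
  stopifnot(rate > 0, n_genes >= 1L, aln_length >= 1L, subst_rate >= 0,
            depth_mean > 4, p_low_depth >= 0, p_low_qual >= 0, p_het >= 0,
            organelle_scale > 0)
  structure(list(n_taxa = as.integer(n_taxa), rate = rate,
                 n_genes = as.integer(n_genes), events = events,
                 aln_length = as.integer(aln_length),
                 subst_rate = subst_rate, depth_mean = depth_mean,
                 qual_max = qual_max, p_low_depth = p_low_depth,
                 p_low_qual = p_low_qual, p_het = p_het,
                 organelle_scale = organelle_scale,
                 seed = as.integer(seed)),
            class = "fixture_config")
}

#' Generate a Yule species tree in coalescent units
#'
#' Pure-birth process: with k lineages the next speciation waits
#' Exp(k * rate), and a uniformly chosen lineage splits. After the n-th tip
#' appears the process runs one further waiting time to give the tips
#' positive pendant branches. The tree is ultrametric; `depth` optionally
#' rescales the root depth to a target number of coalescent units.
#'
#' @param n_taxa Number of tips (>= 3).
#' @param rate Speciation rate (> 0).
#' @param seed Integer seed.
#' @param depth Optional target root-to-tip depth after rescaling.
#' @return A rooted binary ultrametric `phylo` with tips `t01, t02, ...`.
#' @export
generate_species_tree <- function(n_taxa, rate = 1, seed = 1L, depth = NULL) {
  if (rate <= 0) stop("speciation rate must be > 0")
  if (n_taxa < 3L) stop("n_taxa must be >= 3")
  set.seed(as.integer(seed))
  ## lineage bookkeeping: parent pointer and birth time per node
  parent <- c(0L, 1L, 1L)          # root splits immediately into two lineages
  birth <- c(0, 0, 0)
  active <- c(2L, 3L)
  tcur <- 0
  while (length(active) < n_taxa) {
    k <- length(active)
    tcur <- tcur + stats::rexp(1L, rate = k * rate)
    u <- active[sample.int(k, 1L)]
    id1 <- length(parent) + 1L; id2 <- id1 + 1L
    parent <- c(parent, u, u)
    birth <- c(birth, tcur, tcur)
    active <- c(setdiff(active, u), id1, id2)
  }
  tend <- tcur + stats::rexp(1L, rate = n_taxa * rate)
  ## a lineage ends where its children are born; surviving tips end at tend
  end_time <- rep(tend, length(parent))
  kids_of <- split(seq_along(parent)[-1L], parent[-1L])
  for (v in seq_along(parent))
    if (!v %in% active) end_time[v] <- birth[kids_of[[as.character(v)]][1L]]
  blen <- end_time - birth
  if (!is.null(depth)) blen <- blen * depth / tend
  ## remap: tips (active, in id order) first, then internals
  tips <- sort(active)
  ids <- c(tips, setdiff(seq_along(parent), tips))
  newid <- integer(length(parent)); newid[ids] <- seq_along(ids)
  tr <- .make_phylo(parent = {
    p <- integer(length(parent))
    p[newid] <- ifelse(parent == 0L, 0L, newid[pmax(parent, 1L)])
    p
  }, blen = { b <- numeric(length(parent)); b[newid] <- blen; b },
  tip_ids = seq_along(tips),
  tip_labels = sprintf("t%02d", seq_along(tips)))
  tr
}

#' Evolve sequences along a gene tree under Jukes-Cantor
#'
#' Site-independent JC69 evolution with a uniform root sequence; the expected
#' number of substitutions per site on a branch is its length times `rate`.
#' Backed by [phangorn::simSeq()].
#'
#' @param gene_tree A `phylo` with branch lengths.
#' @param length Alignment length (sites).
#' @param rate Substitutions per site per branch-length unit.
#' @param seed Integer seed.
#' @return A character matrix (taxa x sites) over A,C,G,T (uppercase).
#' @export
evolve_sequences <- function(gene_tree, length, rate = 1, seed = 1L) {
  if (is.null(gene_tree$edge.length) || anyNA(gene_tree$edge.length))
    stop("gene tree must have branch lengths")
  set.seed(as.integer(seed))
  if (rate == 0) {
    root <- sample(c("a", "c", "g", "t"), length, replace = TRUE)
    m <- matrix(rep(root, each = ape::Ntip(gene_tree)),
                nrow = ape::Ntip(gene_tree),
                dimnames = list(gene_tree$tip.label, NULL))
  } else {
    dat <- phangorn::simSeq(gene_tree, l = length, rate = rate)
    m <- as.character(dat)
  }
  m <- toupper(m)
  m[, , drop = FALSE]
}

#' Generate VCF-like site records with an exact truth ledger
#'
#' One record per column of the truth alignment. Violations are planted
#' independently: low-depth cells (depth drawn in 0..3), low-quality sites
#' (site QUAL drawn below 20) and heterozygous cells (second allele differs
#' from the truth base). The ledger records, per sample-site, the first
#' filter rule that must mask it, with fixed precedence depth > quality >
#' heterozygosity, so downstream masking counts are exactly predictable.
#'
#' @param truth Character matrix (samples x sites) over A,C,G,T.
#' @param config A [fixture_config()]; fields `depth_mean`, `qual_max`,
#'   `p_low_depth`, `p_low_qual`, `p_het`, `seed` are used.
#' @return List with `records` ([site_records()]), `ledger` (character
#'   matrix of "ok"/"depth"/"quality"/"het"), and `truth`.
#' @export
generate_site_records <- function(truth, config = fixture_config()) {
  if (any(!truth %in% c("A", "C", "G", "T")))
    stop("truth alignment must contain only A,C,G,T")
  set.seed(derive_seed(config$seed, 777L))
  nsamp <- nrow(truth); ns <- ncol(truth)
  bases <- c("A", "C", "G", "T")
  low_qual <- stats::runif(ns) < config$p_low_qual
  qual <- ifelse(low_qual, stats::runif(ns, 0, 19.99),
                 stats::runif(ns, 20, config$qual_max))
  low_depth <- matrix(stats::runif(nsamp * ns) < config$p_low_depth, nsamp)
  depth <- matrix(0L, nsamp, ns)
  depth[low_depth] <- sample(0:3, sum(low_depth), replace = TRUE)
  depth[!low_depth] <- 4L + stats::rpois(sum(!low_depth),
                                         config$depth_mean - 4)
  het <- matrix(stats::runif(nsamp * ns) < config$p_het, nsamp)
  a1 <- truth
  a2 <- truth
  if (any(het)) {
    idx <- which(het)
    a2[idx] <- vapply(truth[idx], function(b)
      sample(setdiff(bases, b), 1L), "")
  }
  ledger <- matrix("ok", nsamp, ns)
  ledger[het] <- "het"
  ledger[matrix(rep(low_qual, each = nsamp), nsamp)] <- "quality"
  ledger[low_depth] <- "depth"
  ref <- vapply(seq_len(ns), function(j) {
    tb <- table(truth[, j])
    sort(names(tb)[tb == max(tb)], method = "radix")[1L]
  }, "")
  samples <- rownames(truth)
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(nsamp))
  rec <- site_records(chrom = rep("chr1", ns), pos = seq_len(ns), ref = ref,
                      qual = qual, a1 = a1, a2 = a2, depth = depth,
                      samples = samples)
  dimnames(ledger) <- list(samples, NULL)
  list(records = rec, ledger = ledger, truth = truth)
}

#' Generate a complete study fixture on disk
#'
#' Writes the ground-truth species tree, the MSC (optionally hybridizing)
#' gene-tree set, per-gene JC69 alignments, one organelle tree, a VCF of
#' planted site records (from the first gene's alignment), and a manifest
#' with per-file MD5 checksums and the derived seeds. Rerunning with the same
#' config reproduces identical checksums.
#'
#' @param config A [fixture_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list of all file paths plus the in-memory objects
#'   (`species_tree`, `gene_trees`, `organelle_tree`, `alignments`,
#'   `site_data`).
#' @export
generate_study_fixture <- function(config = fixture_config(), dir) {
  if (missing(dir)) stop("output directory required")
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok || file.access(dir, 2L) != 0L)
    stop("destination not writable: ", dir)
  for (d in c("trees", "alignments", "variants"))
    dir.create(file.path(dir, d), showWarnings = FALSE)

  sp <- generate_species_tree(config$n_taxa, config$rate,
                              seed = derive_seed(config$seed, 1L))
  gts <- simulate_gene_trees(sp, n_genes = config$n_genes,
                             seed = derive_seed(config$seed, 2L),
                             events = config$events)
  org <- sample_organelle_tree(sp, events = config$events,
                               scale = config$organelle_scale,
                               seed = derive_seed(config$seed, 3L))
  alns <- lapply(seq_len(config$n_genes), function(k)
    evolve_sequences(gts$trees[[k]], config$aln_length, config$subst_rate,
                     seed = derive_seed(config$seed, 1000L + k)))
  names(alns) <- gts$meta$id
  site_data <- generate_site_records(alns[[1L]], config)

  paths <- list(
    species_tree = file.path(dir, "trees", "species.nwk"),
    gene_trees = file.path(dir, "trees", "gene_trees.nwk"),
    organelle_tree = file.path(dir, "trees", "organelle.nwk"),
    variants = file.path(dir, "variants", "sites.vcf"),
    manifest = file.path(dir, "manifest.tsv"))
  write_newick_file(sp, paths$species_tree)
  write_newick_file(gts, paths$gene_trees)
  write_newick_file(org, paths$organelle_tree)
  aln_paths <- character(0)
  for (k in seq_along(alns)) {
    p <- file.path(dir, "alignments", sprintf("gene_%03d.fasta", k))
    write_fasta_alignment(alns[[k]], p)
    aln_paths <- c(aln_paths, p)
  }
  write_vcf_records(site_data$records, paths$variants)
  files <- c(unlist(paths[names(paths) != "manifest"]), aln_paths)
  manifest <- data.frame(
    file = sub(paste0("^", dir, "/?"), "", files),
    md5 = unname(tools::md5sum(files)),
    seed = config$seed, stringsAsFactors = FALSE)
  utils::write.table(manifest, paths$manifest, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(paths, list(alignment_files = aln_paths, species_tree_obj = sp,
                          gene_trees_obj = gts, organelle_tree_obj = org,
                          alignments = alns, site_data = site_data)))
}

#' Neighbor-joining tree from a JC69 alignment (test utility)
#'
#' Distance-based gene-tree estimator used only to confirm that synthetic
#' alignments carry recoverable phylogenetic signal; it is not part of the
#' analysis pipeline.
#'
#' @param aln Character matrix (taxa x sites).
#' @return A `phylo`.
#' @export
nj_tree <- function(aln) {
  d <- ape::dist.dna(ape::as.DNAbin(tolower(aln)), model = "JC69",
                     pairwise.deletion = TRUE)
  if (any(!is.finite(d))) d[!is.finite(d)] <- max(d[is.finite(d)]) * 2
  ape::nj(d)
}
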