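ref5 <- function() parse_newick("(((A,B),(C,D)),E);")

test_that("support filter is strictly greater-than and drops unlabeled trees", {
  mk <- function(s) parse_newick(sprintf("(((A,B)%s,C),(D,E));", s))
  gts <- gene_tree_set(list(mk("59"), mk("60"), mk("61"),
                            parse_newick("(((A,B),C),(D,E));")))
  out <- filter_by_mean_support(gts, 60)
  expect_equal(length(out), 1L)
  expect_equal(out$meta$mean_support, 61)
  rep <- attr(out, "report")
  expect_equal(rep$n_dropped_low_support, 2L)
  expect_equal(rep$n_dropped_no_support, 1L)
  # all pass when every tree is fully supported
  gts2 <- gene_tree_set(list(mk("100"), mk("100")))
  expect_equal(length(filter_by_mean_support(gts2, 60)), 2L)
})

test_that("node classification handles concordance, conflict and missing taxa", {
  bp <- bipartition(c("A", "B"), c("C", "D", "E"))
  expect_equal(classify_tree_at_node(bp, ref5())$status, "concordant")
  # side collapses to one taxon -> uninformative
  expect_equal(classify_tree_at_node(bp, parse_newick("((A,C),(D,E));"))$status,
               "uninformative")
  res <- classify_tree_at_node(bp, parse_newick("((A,C),(B,(D,E)));"))
  expect_equal(res$status, "conflict")
  expect_true(is_nontrivial(res$conflict))
})

test_that("classification agrees with a brute-force compatibility oracle", {
  bp <- bipartition(c("A", "B"), c("C", "D", "E"))
  for (i in 1:60) {
    gt <- rand_tree(5, seed = 4000 + i)
    gt$tip.label <- c("A", "B", "C", "D", "E")[match(gt$tip.label,
                                                     sort(gt$tip.label))]
    got <- classify_tree_at_node(bp, gt)$status
    # oracle: enumerate the gene tree's splits with ape and test directly
    keys <- oracle_split_keys(gt)
    universe <- sort(gt$tip.label)
    sides <- lapply(keys, function(k) {
      idx <- as.integer(strsplit(k, ",", fixed = TRUE)[[1L]])
      universe[idx]
    })
    conc <- any(vapply(sides, function(s)
      setequal(s, c("A", "B")) || setequal(s, c("C", "D", "E")), TRUE))
    confl <- any(vapply(sides, function(s)
      !oracle_compatible(s, setdiff(universe, s), c("A", "B"),
                         c("C", "D", "E")), TRUE))
    expected <- if (conc) "concordant" else if (confl) "conflict" else "uninformative"
    expect_equal(got, expected)
  }
})

test_that("node_concordance tallies counts and identifies the top conflict", {
  ref <- ref5()
  gts <- gene_tree_set(rep(list(ref), 10))
  tab <- node_concordance(ref, gts)
  expect_equal(tab$n_concordant, rep(10L, nrow(tab)))
  expect_equal(tab$n_conflict_top + tab$n_conflict_other +
                 tab$n_uninformative, rep(0L, nrow(tab)))

  alt <- parse_newick("(((A,C),(B,D)),E);")
  gts2 <- gene_tree_set(c(rep(list(ref), 6), rep(list(alt), 4)))
  tab2 <- node_concordance(ref, gts2)
  ab <- tab2[tab2$split == "A,B|C,D,E", ]
  expect_equal(ab$n_concordant, 6L)
  expect_equal(ab$n_conflict_top, 4L)
  expect_equal(ab$n_conflict_other, 0L)
  expect_equal(ab$top_conflict, "A,C|B,D,E")
  expect_error(node_concordance(ref, list()), "empty")
})

test_that("node_concordance matches a per-tree oracle on a mixed fixture", {
  ref <- ref5()
  set.seed(99)
  trees <- lapply(1:20, function(i) {
    n <- sample(4:5, 1)
    gt <- rand_tree(5, seed = 7000 + i)
    gt$tip.label <- c("A", "B", "C", "D", "E")[match(gt$tip.label,
                                                     sort(gt$tip.label))]
    if (n == 4) restrict(gt, sample(gt$tip.label, 4)) else gt
  })
  gts <- gene_tree_set(trees)
  tab <- node_concordance(ref, gts)
  for (j in seq_len(nrow(tab))) {
    sides <- strsplit(tab$split[j], "|", fixed = TRUE)[[1L]]
    bp <- bipartition(strsplit(sides[1], ",")[[1L]],
                      strsplit(sides[2], ",")[[1L]])
    states <- vapply(trees, function(t) classify_tree_at_node(bp, t)$status, "")
    expect_equal(tab$n_concordant[j], sum(states == "concordant"))
    expect_equal(tab$n_conflict_top[j] + tab$n_conflict_other[j],
                 sum(states == "conflict"))
    expect_equal(tab$n_uninformative[j], sum(states == "uninformative"))
  }
})

test_that("node_concordance is invariant to gene-tree order and rerooting", {
  ref <- ref5()
  set.seed(5)
  trees <- lapply(1:12, function(i) {
    gt <- rand_tree(5, seed = 8100 + i)
    gt$tip.label <- c("A", "B", "C", "D", "E")[match(gt$tip.label,
                                                     sort(gt$tip.label))]
    gt
  })
  tab1 <- node_concordance(ref, gene_tree_set(trees))
  tab2 <- node_concordance(ref, gene_tree_set(rev(trees)))
  expect_equal(tab1[order(tab1$split), -1], tab2[order(tab2$split), -1])
  rerooted <- lapply(trees, function(t) ape::root(t, outgroup = "E",
                                                  resolve.root = TRUE))
  tab3 <- node_concordance(ref, gene_tree_set(rerooted))
  expect_equal(tab1[order(tab1$split), -1], tab3[order(tab3$split), -1])
})

test_that("ils_node_support reports both denominators and flags zero nodes", {
  spl <- parse_newick("(((A:10,B:10):10,(C:10,D:10):10):10,E:30);")
  sims <- simulate_gene_trees(spl, 200, seed = 4)
  it <- ils_node_support(spl, sims)
  expect_true(all(it$ils_fraction >= 0.99))
  expect_false(any(it$not_ils_explicable))
  # minor-topology fraction ~ (1/3) e^(-t): ingroup triplet with a distant
  # outgroup so deeper coalescence is negligible
  t <- 0.8
  sp <- parse_newick(sprintf(
    "(((A:1,B:1):%g,C:%g):10,D:%g);", t, 1 + t, 11 + t))
  plastid <- parse_newick(sprintf(
    "(((A:1,C:1):%g,B:%g):10,D:%g);", t, 1 + t, 11 + t))
  n <- 3000
  sims2 <- simulate_gene_trees(sp, n, seed = 10)
  it2 <- ils_node_support(plastid, sims2)
  ac <- it2[it2$split == "A,C|B,D", ]
  p <- (1 / 3) * exp(-t)
  expect_lt(abs(ac$ils_fraction - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("distance_distribution composes per-tree RF and skips tiny overlaps", {
  ref <- ref5()
  gts <- gene_tree_set(rep(list(ref), 4))
  dd <- distance_distribution(gts, ref)
  expect_equal(dd$distances, rep(0, 4))
  alt <- parse_newick("(((A,C),(B,D)),E);")
  dd2 <- distance_distribution(gene_tree_set(list(alt, alt)), ref)
  expect_equal(dd2$distances, rep(1, 2))
  # mixed fixture equals per-tree oracle calls
  trees <- lapply(1:10, function(i) {
    gt <- rand_tree(5, seed = 8200 + i)
    gt$tip.label <- c("A", "B", "C", "D", "E")[match(gt$tip.label,
                                                     sort(gt$tip.label))]
    gt
  })
  dd3 <- distance_distribution(gene_tree_set(trees), ref)
  expect_equal(dd3$distances, vapply(trees, function(t)
    rf_distance(t, ref)$normalized, 0))
  # a tree sharing 3 taxa is skipped
  small <- parse_newick("((A,B),E);")
  dd4 <- distance_distribution(gene_tree_set(c(trees, list(small))), ref)
  expect_equal(dd4$n_skipped, 1L)
  expect_length(dd4$distances, 10L)
})

test_that("compare_distributions: KS and overlap behave at the extremes", {
  same <- compare_distributions(c(0.1, 0.4, 0.7), c(0.1, 0.4, 0.7))
  expect_equal(same$ks_statistic, 0)
  expect_equal(same$overlap_coefficient, 1)
  disjoint <- compare_distributions(rep(0, 10), rep(1, 10))
  expect_equal(disjoint$ks_statistic, 1)
  expect_equal(disjoint$overlap_coefficient, 0)
  shifted <- compare_distributions(c(0.1, 0.2, 0.3), c(0.2, 0.3, 0.4))
  # brute-force ECDF sweep oracle
  xs <- sort(unique(c(0.1, 0.2, 0.3, 0.4)))
  d_oracle <- max(vapply(xs, function(v)
    abs(mean(c(0.1, 0.2, 0.3) <= v) - mean(c(0.2, 0.3, 0.4) <= v)), 0))
  expect_equal(shifted$ks_statistic, d_oracle)
  expect_error(compare_distributions(numeric(0), c(0.1)), "empty")
})
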