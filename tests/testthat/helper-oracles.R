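# Independent oracles and fixture builders used across the suite.

# Random binary tree with deterministic labels t1..tn.
rand_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n)
  tr$tip.label <- paste0("t", seq_len(n))[match(tr$tip.label, sort(tr$tip.label))]
  tr
}

# Independent split enumeration via ape::prop.part (different code path from
# coaldisc's own bipartition extraction): canonical keys over sorted labels.
oracle_split_keys <- function(tree) {
  universe <- sort(tree$tip.label, method = "radix")
  n <- length(universe)
  pp <- ape::prop.part(ape::unroot(tree))
  labs <- attr(pp, "labels")
  keys <- vapply(pp, function(idx) {
    side <- sort(match(labs[idx], universe))
    if (length(side) < 2L || length(side) > n - 2L) return(NA_character_)
    if (!1L %in% side) side <- setdiff(seq_len(n), side)
    paste(side, collapse = ",")
  }, "")
  unique(keys[!is.na(keys)])
}

# Brute-force RF: symmetric difference of independently enumerated split sets.
oracle_rf <- function(t1, t2) {
  k1 <- oracle_split_keys(t1); k2 <- oracle_split_keys(t2)
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

# Brute-force split compatibility on name sets.
oracle_compatible <- function(a1, b1, a2, b2) {
  !length(intersect(a1, a2)) || !length(intersect(a1, b2)) ||
    !length(intersect(b1, a2)) || !length(intersect(b1, b2))
}

# Concordance probability of the 4-taxon caterpillar (((A,B):x,C):y,D) under
# the MSC, by conditioning on where the coalescences happen (quadrature for
# the three-lineage stage).
caterpillar_concordance <- function(x, y) {
  p_case1 <- (1 - exp(-x)) * ((1 - exp(-y)) + exp(-y) / 3)
  integrand <- function(s)
    3 * exp(-3 * s) * (1 / 3) * ((1 - exp(-(y - s))) + exp(-(y - s)) / 3)
  p2 <- stats::integrate(integrand, 0, y)$value + exp(-3 * y) / 18
  p_case1 + exp(-x) * p2
}

# 12-taxon ultrametric species tree, all internal branches >= 6 coalescent
# units, containing the subclade ((t05,t06),t09) so that a t05 -> t09
# chloroplast capture perturbs exactly one plastid split.
capture_fixture_tree <- function() {
  n3 <- "(((t01:6,t02:6):6,t03:12):6,t04:18)"            # depth 18
  w <- "((t05:6,t06:6):6,t09:12)"                         # depth 12
  n4 <- paste0("(", w, ":6,(t07:6,t08:6):12)")            # depth 18
  n5 <- paste0("(", n3, ":6,", n4, ":6)")                 # depth 24
  y <- "((t10:6,t11:6):6,t12:12)"                         # depth 12
  parse_newick(paste0("(", n5, ":6,", y, ":18);"))        # depth 30
}

capture_fixture_event <- function(gamma = 1) {
  hybridization_event(recipient = "t05", donor = "t09", time = 3,
                      gamma = gamma)
}
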