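---
title: "Dissecting gene-tree discordance with coaldisc: models, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting gene-tree discordance with coaldisc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coaldisc)
```

## The problem

Phylogenomic datasets routinely show two kinds of conflict. First, individual
nuclear gene trees disagree with the species tree and with each other.
Second, the phylogeny of a uniparentally inherited organellar genome (the
plastome, in plants) can contradict the nuclear species tree — cyto-nuclear
discordance. Both patterns can arise from incomplete lineage sorting (ILS),
a neutral consequence of ancestral polymorphism, or from hybridization and
introgression (including chloroplast capture, where an organelle genome
crosses a species boundary). Telling these apart matters because they imply
different evolutionary histories.

`coaldisc` implements the simulation-based test used in plant phylogenomics
for this purpose: simulate many gene trees under the multispecies coalescent
(MSC) on the species tree — the ILS-only null — and ask whether the observed
conflicts are compatible with that null, node by node and in aggregate. The
package also implements the alignment-side bookkeeping such studies need:
genome-skimming SNP matrices with depth/quality/heterozygosity masking,
missing-data column thresholds, invariant-site removal, and supermatrix
concatenation.

## The multispecies coalescent simulator

The species tree is a rooted, binary, ultrametric `phylo` whose branch
lengths are **coalescent units**: time rescaled so that k gene lineages
coalesce at rate k(k−1)/2 per unit. Within each species-tree branch, lineage
pairs coalesce with exponential waiting times; lineages that fail to
coalesce enter the parent branch, and coalescence above the root continues
on an unbounded stem — forced by the model, since every pair of lineages
must eventually find a common ancestor.

```{r msc}
sp <- parse_newick("((A:1,B:1):1,C:2);")
g <- simulate_gene_tree(sp, seed = 1)
write_newick(g)
```

On this three-taxon tree, the probability that a gene tree matches the
species tree is 1 − (2/3)e^(−t) with t the internal branch length — the
package's simulations reproduce this closed form, which is the main
correctness anchor of the simulator (see the test suite).

Two design points deserve explanation:

* **Terminal branch lengths are mandatory.** Species trees estimated with
  summary-coalescent methods (the ASTRAL convention) carry internal branch
  lengths in coalescent units but no terminal lengths. How those are filled
  changes the amount of ILS simulated on the tips, so `coaldisc` refuses to
  guess: `validate_species_tree(tree, terminal_fill =)` must be used
  explicitly, and it fills terminal branches so that tips are
  contemporaneous, `terminal_fill` units below the most recent internal
  node.
* **Reproducibility.** All randomness comes from R's Mersenne-Twister
  stream. A run seed expands into per-gene substream seeds by fixed integer
  arithmetic (`derive_seed`), so replicate k of a 10,000-tree run can be
  regenerated in isolation — useful when a single odd genealogy needs
  inspection.

### Hybridization and the organelle sampler

A `hybridization_event(recipient, donor, time, gamma)` adds one reticulation
to the species tree: every gene lineage present on the recipient edge at the
event time independently jumps to the donor edge with probability gamma (the
inheritance probability). `gamma = 0` reduces exactly to the pure MSC — the
code draws no random numbers for the event, so the two simulators produce
identical streams, which the tests exploit as an exact reduction check.

`sample_organelle_tree()` draws a single genealogy after multiplying all
branch lengths by `scale` (default 4). The default reflects the effective
population size of a haploid, uniparentally inherited genome relative to a
diploid biparental nuclear genome; it is a documented, overridable modeling
choice, not an estimate. Because the organelle behaves as one locus, a
hybridization event with high gamma produces chloroplast capture: the
organelle tree shows the recipient inside the donor clade while nuclear gene
trees do not.

## Concordance accounting

`node_concordance(reference, trees)` classifies every gene tree at every
non-trivial reference bipartition, in the style of bipartition-based
conflict analysis tools:

1. restrict the reference split to the gene tree's taxa; if either side
   drops below two taxa the tree is **uninformative** at that node;
2. if the restricted split is displayed by the gene tree, it is
   **concordant**;
3. otherwise, if some gene-tree split is incompatible with it (all four
   pairwise side intersections non-empty), it **conflicts**, and the single
   most frequent conflicting split is tracked separately from the rest;
4. otherwise (unresolved overlap) it is uninformative.

At every node the four counts sum to the number of gene trees — an invariant
the tests verify on a thousand random collections. Ties for the top conflict
break by the lexicographically smallest split string, so output is
deterministic.

`ils_node_support(plastid_tree, simulated)` applies the same machinery with
MSC-simulated gene trees against an organelle reference. The headline
fraction divides concordant trees by *informative* trees: gene trees missing
the relevant taxa carry no signal about a node, and counting them in the
denominator would dilute every fraction toward zero. Because the choice of
denominator is a genuine judgment call, the all-trees variant
(`ils_fraction_all`) is emitted alongside. A node whose fraction falls at or
below `not_ils_threshold` (default 0.01) is flagged `not_ils_explicable` —
if essentially no ILS-only genealogy reproduces a plastid clade, ILS cannot
explain it, and hybridization becomes the parsimonious reading.

```{r ils, eval = FALSE}
sp <- generate_species_tree(12, rate = 1, seed = 1)
plastid <- sample_organelle_tree(sp, seed = 2)
sims <- simulate_gene_trees(sp, n_genes = 10000, seed = 3)
ils_node_support(plastid, sims)
```

## Distance distributions

`distance_distribution()` computes the normalized Robinson–Foulds distance
of each gene tree to a reference (restricting to shared taxa; trees sharing
fewer than four taxa are skipped and counted). Gene trees are used fully
resolved as given: the upstream filtering acts on whole trees via
`filter_by_mean_support()` — strictly greater than the cutoff, so a mean
support of exactly 60 is dropped at the conventional threshold of 60 — and
not by collapsing weak edges inside trees.

`compare_distributions()` quantifies what is usually judged by eye when an
empirical distance histogram is plotted over a simulated one: a two-sample
Kolmogorov–Smirnov statistic on the raw samples (standard ECDF definition;
ties are expected since normalized RF is discrete) and a histogram overlap
coefficient on bins of width 0.05, matching the visual granularity of such
plots. When empirical gene trees really are MSC draws from the reference,
the KS p-value exceeds 0.01 in ≥95% of repetitions — the package's
self-consistency control.

## SNP matrices from genome skimming

The variant-side module reproduces the post-hoc filters applied to
genome-skimming SNP data after read mapping and genotype calling (which are
out of scope — they belong to the upstream callers):

* `filter_sites()` masks a sample's call when read depth < 4, site quality
  < 20, or the genotype is heterozygous. The boundaries pass: the rules
  delete strictly "less than", so depth 4 and quality 20 survive. The
  heterozygosity rule masks per sample by default; whether published
  pipelines dropped whole sites instead is usually unstated, so a
  `drop_site` policy is available. Likewise "site quality" is read as the
  site-level QUAL, with a genotype-quality switch.
* `apply_missing_threshold()` keeps columns whose missing fraction
  (N and gap both count) is ≤ the threshold — inclusive, because a
  threshold of "40% missing data" names a tolerated level. Note the
  asymmetry with the support filter, which is strict; both boundaries
  follow the conventional wording of the respective rules and are
  documented at the function level.
* `remove_invariant_sites()` requires at least two distinct states among
  A,C,G,T; missing symbols, gaps and IUPAC ambiguities are not states.
* `concatenate_alignments()` pads absent taxa with N and records 1-based
  inclusive partitions; `split_by_partition()` inverts it exactly.
* `mask_uncovered()` keeps reference regions covered by at least one
  sample. Intervals are 0-based half-open (the BED convention) at the API
  boundary and converted internally, which keeps off-by-one errors at the
  I/O layer where they can be tested.
* `consensus_sequence()` takes the most common base per site, with IUPAC
  ambiguity codes on ties — information-preserving and deterministic,
  rather than an arbitrary pick.

## The synthetic-data generator

Published analyses of this kind start from sequencing data that cannot be
regenerated at desk scale, so `coaldisc` ships a generator that emulates the
*statistical structure* of every input instead:

* `generate_species_tree()` — Yule trees in coalescent units (ultrametric,
  rescalable depth);
* `simulate_gene_trees()` — the MSC itself, with optional hybridization;
* `evolve_sequences()` — Jukes–Cantor alignments along gene trees. JC69 is
  deliberate: its closed-form distance lets tests verify the sequences
  against theory; richer substitution models would add parameters without
  adding testability.
* `generate_site_records()` — VCF-like records with *planted* violations:
  low-depth cells, low-quality sites, heterozygous calls. A truth ledger
  records, per sample-site, the first rule that must mask it (precedence
  depth → quality → heterozygosity, so a cell failing several rules is
  attributed once). Downstream masking counts are therefore exactly
  predictable, and the tests require exact agreement, not statistical
  agreement.
* `generate_study_fixture()` — writes the whole bundle (trees, alignments,
  VCF, manifest with MD5 checksums and seeds) so the command-line pipeline
  can run end to end; reruns are byte-identical.

What the generator does *not* emulate: sequencing reads and mapping
artifacts, indels, rate heterogeneity across sites, linkage between sites,
and population-level sampling within species. Passing tests therefore
demonstrate that the *analysis logic* is correct under its stated model,
not that the model captures every property of real skimming data.

A neighbor-joining utility (`nj_tree`) exists purely so tests can confirm
the fixtures carry recoverable signal; it is not part of the analysis
pipeline.

## Numerical and design choices

* Trees are compared **unrooted** everywhere (bipartitions, RF), since
  rooted figures are routinely compared with unrooted conflict tools;
  rooted clade keys are used only for topology frequency spectra where the
  MSC's rooted predictions are the target.
* Newick output sorts children by smallest descendant leaf name, so
  serialization is deterministic and diffs are meaningful.
* `restrict()` suppresses degree-2 nodes by summing branch lengths and
  keeping the **maximum** of the merged supports — conservative in the
  sense that a retained edge never reports less support than its best
  evidence.
* `greedy_consensus()` breaks frequency ties by the canonical string of the
  split's smaller side. It exists as a deterministic species-tree estimator
  for parameter-recovery tests (1,000 MSC trees on internal branches ≥ 2
  coalescent units recover the true topology essentially always); it is not
  a substitute for likelihood or quartet-based inference.
* Ultrametricity is checked to a relative tolerance of 1e-8; simulated gene
  trees on an ultrametric species tree are themselves ultrametric to 1e-9,
  which the tests assert.

## Problem sizes used in validation

The statistical checks run at sizes chosen to give tight Monte-Carlo error
while staying desk-sized: 10,000 simulated gene trees for the closed-form
and planted-capture checks (Monte-Carlo SE below 0.005 on a probability),
100 repetitions of 200-vs-2,000-tree distance comparisons for the KS
self-consistency rate, 20,000 replicates per tree for cross-validation
against an independent coalescent simulator (total-variation distance
< 0.02), and 100 seeds for the consensus-recovery rate. The acceptance
script reports the same quantities at the same or moderately reduced sizes.

## Known limitations

* The hybridization model is a pulse at an instant (lineages jump once);
  continuous migration is out of scope.
* One allele per species is the default sampling design; multiple samples
  per species are supported by the simulator but not by the concordance
  accounting's assumptions about taxon identity.
* gamma is a simulation parameter, not something the package estimates.
* The SNP module implements post-hoc filters only; read mapping and
  genotype calling quality are upstream concerns it cannot correct.
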