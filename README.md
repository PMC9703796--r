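# coaldisc

Multispecies-coalescent simulation and gene-tree discordance analysis for
plant phylogenomics.

When nuclear gene trees conflict with each other, or a plastome phylogeny
contradicts the nuclear species tree, the question is *why*: incomplete
lineage sorting (ILS) — the neutral noise of the multispecies coalescent
(MSC) — or hybridization and chloroplast capture? `coaldisc` is an R package
for researchers who want to answer that question with simulations rather
than intuition. It provides:

* an MSC gene-tree simulator on a species tree with branch lengths in
  coalescent units, extended with hybridization edges (inheritance
  probability γ) and an organelle-tree sampler for cyto-nuclear scenarios;
* PhyParts-style node-wise accounting of gene trees against a reference
  tree (concordant / top conflict / other conflict / uninformative), and an
  ILS node-support test: the fraction of MSC-simulated gene trees
  concordant with each node of a plastid tree;
* Robinson–Foulds distance-distribution comparison (two-sample KS statistic
  and histogram overlap) between empirical and simulated gene trees;
* the genome-skimming SNP matrix toolkit: per-site masking (depth < 4,
  quality < 20, heterozygous — boundaries pass), VCF→FASTA conversion,
  most-common-base consensus with IUPAC ties, missing-data column
  thresholds, invariant-site removal, gene-length filters, coverage
  masking, and supermatrix concatenation with partition bookkeeping;
* a synthetic-data generator (Yule species trees, MSC gene trees, JC69
  alignments, VCF-like records with a planted truth ledger) so the entire
  pipeline runs and validates with no external data.

## The model in brief

Branch lengths of the species tree are coalescent units: k lineages
coalesce at rate k(k−1)/2 per unit. On a three-taxon species tree with
internal branch t, the probability that a gene tree matches the species
tree is

    P(concordant) = 1 − (2/3) e^(−t)

and each minor topology has probability (1/3)e^(−t). These closed forms,
their four-taxon extension, and an independent coalescent simulator
(msprime) anchor the correctness of the simulator in the test suite. At a
hybridization event, each lineage on the recipient edge follows the donor
edge with probability γ; γ = 0 is exactly the pure MSC. The organelle
sampler multiplies branch lengths by 4 by default (haploid, uniparental
inheritance) and lets the plastid lineage follow γ — chloroplast capture.

## Worked example

Simulate 1,000 MSC gene trees on a five-taxon species tree, tally per-node
concordance, and test whether a plastid tree produced by a chloroplast
capture (γ = 1, A → C) can be explained by ILS:

```r
library(coaldisc)

sp <- parse_newick("(((A:2,B:2):2,(C:2,D:2):2):2,E:6);")
sims <- simulate_gene_trees(sp, n_genes = 1000, seed = 42)

node_concordance(sp, sims)[, c(2:5, 11)]
#>       split n_concordant n_conflict_top n_conflict_other top_conflict
#> 1 A,B|C,D,E          911             42               47    A,C,D|B,E
#> 2 A,B,E|C,D          903             42               55    A,B,C|D,E

distance_distribution(sims, sp)
#> distance_distribution 'empirical': n = 1000, mean = 0.0930 (0 skipped)

plastid <- sample_organelle_tree(
  sp, events = list(hybridization_event("A", "C", time = 1, gamma = 1)),
  seed = 3)
ils_node_support(plastid, sims)[, c("split", "ils_fraction", "not_ils_explicable")]
#>       split ils_fraction not_ils_explicable
#> 1 A,C,D|B,E        0.043              FALSE
#> 2 A,C|B,D,E        0.006               TRUE
```

Reading the output: with 2-coalescent-unit internal branches, about 91% of
gene trees are concordant at each species-tree node, and the most frequent
conflicting split is tracked separately from the long tail. The plastid
tree shows A captured into the C clade. The {A,C} node is supported by only
0.6% of ILS-only simulations — flagged as not explicable by ILS — while the
broader {A,C,D} grouping still arises in 4.3% of simulations, so ILS alone
cannot be ruled out for it. This is exactly the per-node logic used to
attribute cyto-nuclear discordance to hybridization rather than ILS.

The SNP side works on VCF-like records:

```r
rec <- read_vcf_records("variants/sites.vcf")
aln <- sites_to_alignment(rec)                 # depth/quality/het masking
aln <- apply_missing_threshold(aln, 0.5)       # drop columns > 50% missing
aln <- remove_invariant_sites(aln)
write_fasta_alignment(aln, "matrix_0.5MS.fasta")
```

A command-line wrapper (`inst/cli/coaldisc`) exposes the stages as
subcommands (`fixture`, `sim-genetrees`, `organelle-tree`, `concord`,
`ils-test`, `distdist`, `snp-filter`, `matrix-filter`, `concat`,
`gene-filter`) over a plain key=value config with deterministic seeding.

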