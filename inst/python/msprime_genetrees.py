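"""Independent MSC gene-tree sampler used only for cross-validation.

Reads an ultrametric, rooted, binary species tree in Newick (branch lengths
in coalescent units) and simulates gene trees with msprime, one population
per species-tree branch (size 1, ploidy 1, so time = coalescent units).
Prints one Newick gene tree per line, tips labelled with the species names.
"""
import argparse
import sys

import dendropy
import msprime


def build_demography(path):
    tree = dendropy.Tree.get(path=path, schema="newick")
    tree.calc_node_ages(ultrametricity_precision=1e-6)
    dem = msprime.Demography()
    names = {}
    counter = [0]

    def pop_name(node):
        if node.is_leaf():
            return node.taxon.label.replace(" ", "_")
        counter[0] += 1
        return f"anc{counter[0]}"

    for node in tree.postorder_node_iter():
        names[node] = pop_name(node)
        dem.add_population(name=names[node], initial_size=1)
    splits = []
    for node in tree.postorder_node_iter():
        if not node.is_leaf():
            splits.append((node.age, [names[c] for c in node.child_nodes()],
                           names[node]))
    for time, derived, ancestral in sorted(splits, key=lambda x: x[0]):
        dem.add_population_split(time=time, derived=derived,
                                 ancestral=ancestral)
    dem.sort_events()
    tips = [lf.taxon.label.replace(" ", "_") for lf in tree.leaf_node_iter()]
    return dem, tips


def main():
    ap = argparse.ArgumentParser()
    ap.add_argument("--tree", required=True)
    ap.add_argument("--reps", type=int, required=True)
    ap.add_argument("--seed", type=int, required=True)
    args = ap.parse_args()

    dem, tips = build_demography(args.tree)
    reps = msprime.sim_ancestry(
        samples={t: 1 for t in tips}, demography=dem, ploidy=1,
        random_seed=args.seed, num_replicates=args.reps)
    for ts in reps:
        t = ts.first()
        labels = {u: ts.population(ts.node(u).population).metadata["name"]
                  for u in ts.samples()}
        sys.stdout.write(t.as_newick(node_labels=labels) + "\n")


if __name__ == "__main__":
    main()
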