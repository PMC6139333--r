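"""Independent coalescent simulation of a matched three-species
isolation-with-migration model, used as an external cross-check of the
package's structured-coalescent simulator.

Conventions matched to the R package: diploid sizes N with pairwise
coalescence rate 1/(2N) (implemented here as haploid populations of size 2N),
times in generations, migration entry (i, j) = backward rate at which a
lineage in i moves to j = forward fraction of i replaced by migrants from j,
Jukes-Cantor finite-sites mutation on a discrete genome.

Usage: python msprime_im.py REPS SEED OUT_CSV
Writes one row per replicate: within-species segregating sites, pairwise
difference sums, and the cross-species difference sum for species pair (a, b).
"""
import sys

import msprime
import numpy as np

# matched model point (kept in sync with the R acceptance test)
N = {"a": 2e7, "b": 3e7, "c": 1e7}
N_PAIR = 8e6
N_ROOT = 5e6
T0 = 1.2e7
T1 = 2.4e7
MU = 1.1e-10
L = 384
SAMPLES = {"a": 10, "b": 8, "c": 7}
# directed 2Nm into the recipient: M2NM[(src, dst)]
M2NM = {("a", "b"): 1.0, ("b", "a"): 0.5, ("a", "c"): 0.3,
        ("c", "a"): 0.2, ("b", "c"): 0.4, ("c", "b"): 0.6}


def demography():
    dem = msprime.Demography()
    for p, n in N.items():
        dem.add_population(name=p, initial_size=2 * n)
    dem.add_population(name="anc_ac", initial_size=2 * N_PAIR)
    dem.add_population(name="root", initial_size=2 * N_ROOT)
    # backward lineage rate i -> j equals forward fraction of i replaced by
    # migrants from j: 2Nm[(j, i)] / (2 N_i)
    for (src, dst), m2nm in M2NM.items():
        dem.set_migration_rate(source=dst, dest=src, rate=m2nm / (2 * N[dst]))
    dem.add_population_split(time=T0, derived=["a", "c"], ancestral="anc_ac")
    dem.add_population_split(time=T1, derived=["anc_ac", "b"],
                             ancestral="root")
    dem.sort_events()
    return dem


def pair_sums(counts_by_group, n_by_group, g1, g2):
    """within-group difference sums and cross sums from per-site allele
    counts (lists of dicts allele -> count)"""
    within = {g1: 0.0, g2: 0.0}
    seg = {g1: 0, g2: 0}
    cross = 0.0
    for site in counts_by_group:
        for g in (g1, g2):
            c = site[g]
            n = n_by_group[g]
            homo = sum(v * (v - 1) / 2 for v in c.values())
            within[g] += n * (n - 1) / 2 - homo
            if len([v for v in c.values() if v > 0]) > 1:
                seg[g] += 1
        cp = sum(site[g1].get(a, 0) * site[g2].get(a, 0)
                 for a in set(site[g1]) | set(site[g2]))
        cross += n_by_group[g1] * n_by_group[g2] - cp
    return seg, within, cross


def main(reps, seed, out):
    dem = demography()
    rows = []
    sample_sets = {}
    start = 0
    for g, n in SAMPLES.items():
        sample_sets[g] = list(range(start, start + n))
        start += n
    rng = np.random.default_rng(seed)
    for ts in msprime.sim_ancestry(
            samples=[msprime.SampleSet(n, population=p, ploidy=1)
                     for p, n in SAMPLES.items()],
            demography=dem, sequence_length=L, ploidy=1,
            num_replicates=reps, random_seed=seed):
        mts = msprime.sim_mutations(ts, rate=MU, model=msprime.JC69(),
                                    random_seed=int(rng.integers(1, 2**31)))
        counts = []
        for var in mts.variants():
            alleles = np.array(var.alleles, dtype=object)
            states = alleles[var.genotypes]
            site = {}
            for g, idx in sample_sets.items():
                vals, cnt = np.unique(states[idx], return_counts=True)
                site[g] = dict(zip(vals.tolist(), cnt.tolist()))
            counts.append(site)
        seg, within, cross = pair_sums(counts, SAMPLES, "a", "b")
        rows.append((seg["a"], seg["b"], within["a"], within["b"], cross))
    with open(out, "w") as fh:
        fh.write("S_a,S_b,within_a,within_b,cross_ab\n")
        for r in rows:
            fh.write(",".join(str(x) for x in r) + "\n")


if __name__ == "__main__":
    main(int(sys.argv[1]), int(sys.argv[2]), sys.argv[3])
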