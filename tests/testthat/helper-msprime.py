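"""Independent structured-coalescent oracle for the cross-validation test.

Two-deme isolation-with-migration model matched to the package's scaling
contract: haploid populations of size 1 make one msprime generation equal
one internal time unit (pair-coalescence rate 1), per-lineage migration
rate m = M/2, split at 2*tau, infinite-sites mutation at rate theta/2 per
unit time. Writes one TSV row (S, pi, piA, piB, dxy) per replicate.
"""
import sys

import msprime

n_rep = int(sys.argv[1])
seed = int(sys.argv[2])
out = sys.argv[3]

THETA = 2.0     # both demes, reference scale
M = 4.0         # 4Nm per direction -> per-lineage rate 2
TAU = 0.3       # 4Ne units -> internal split time 0.6
N_PER_DEME = 10

dem = msprime.Demography()
dem.add_population(name="A", initial_size=1.0)
dem.add_population(name="B", initial_size=1.0)
dem.add_population(name="AB", initial_size=1.0)
dem.set_migration_rate("A", "B", M / 2.0)
dem.set_migration_rate("B", "A", M / 2.0)
dem.add_population_split(time=2.0 * TAU, derived=["A", "B"], ancestral="AB")

with open(out, "w") as fh:
    fh.write("S\tpi\tpiA\tpiB\tdxy\n")
    reps = msprime.sim_ancestry(
        samples={"A": N_PER_DEME, "B": N_PER_DEME},
        demography=dem, ploidy=1, sequence_length=1,
        discrete_genome=False, num_replicates=n_rep, random_seed=seed)
    for i, ts in enumerate(reps):
        mts = msprime.sim_mutations(
            ts, rate=THETA / 2.0, discrete_genome=False,
            random_seed=seed + 1 + i)
        a = mts.samples(population=0)
        b = mts.samples(population=1)
        S = mts.segregating_sites(span_normalise=False)
        pi = mts.diversity(span_normalise=False)
        piA = mts.diversity(sample_sets=a, span_normalise=False)
        piB = mts.diversity(sample_sets=b, span_normalise=False)
        dxy = mts.divergence(sample_sets=[a, b], span_normalise=False)
        fh.write(f"{S}\t{pi}\t{piA}\t{piB}\t{dxy}\n")
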