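# esudelim

Delimitation and validation of evolutionarily significant units (ESUs)
from phased multilocus sequence data.

Species restricted to naturally fragmented habitats — mountaintop "sky
island" amphibians are the motivating system — often consist of lineages
with highly restricted gene flow that deserve separate conservation
management, yet are too recently diverged for strict reciprocal-monophyly
criteria. `esudelim` implements a two-step, gene-flow-aware delimitation:

1. **Discovery** — spatially explicit Bayesian clustering (coloured
   Voronoi tessellation, uncorrelated allele-frequencies model, collapsed
   Dirichlet-multinomial likelihood) proposes biogeographical units (BUs)
   and a posterior over their number *K*, plus a Mantel permutation test
   of isolation by distance on GENPOFAD multilocus distances.
2. **Validation and estimation** — ABC model choice over an eight-model
   catalogue of migration/collapse hypotheses (all-connected through
   panmixia) decides which BUs are distinct ESUs; an
   isolation-with-migration model combining the configured lineage
   topology with the best model's gene-flow routes then co-estimates
   `theta = 4 Ne mu` per deme, split times `tau` (4 Ne units, converted
   to years), and migration rates `M = 4 Ne m`, by rejection ABC with
   weighted posteriors, optional regression adjustment, and a PCA
   goodness-of-fit check.

Both steps are driven by a built-in structured-coalescent simulator
(island + isolation-with-migration, infinite sites, Rcpp core) whose
scaling contract `E[pi] = theta`, `E[S] = theta a1(n)`,
`E[dxy] = theta (1 + 2 tau)` is pinned by the test suite and
cross-validated against msprime. A synthetic-data generator produces
study-shaped fixtures (3 demes, 13 sites, 88 individuals, one mtDNA +
two nuclear loci) with a known truth sidecar.

## Worked example

```r
library(esudelim)

# a study-shaped synthetic dataset with known truth (K = 3)
d <- generate_study_like_dataset(study_template(rng_seed = 1))

report <- run_pipeline(d$alignments, d$sample_table,
                       config = list(
                         cluster = cluster_config(n_iter = 2e4, thinning = 20,
                                                  rng_seed = 5),
                         n_sims_choice = 2000, n_sims_est = 20000,
                         rng_seed = 5))
report
```

On this fixture the report prints (output of the run above):

```
=== ESU delimitation report ===
Discovered units: modal K = 3 (PP = 0.97)
IBD Mantel: r^2 = 0.674, p = 0.0001
Best model: 3 (PP = 0.920)
Validated ESUs: BU1, BU2, BU3
  theta_BU1    mean 3.865  95% HPD [0.21483, 8.5238]
  theta_BU2    mean 3.2541  95% HPD [0.28922, 8.1196]
  theta_BU3    mean 2.4471  95% HPD [0.23517, 6.7802]
  tau1         mean 0.17603  95% HPD [0.0066719, 0.38166]
  tau2         mean 0.34173  95% HPD [0.12022, 0.49999]
  M_BU1.BU2    mean 25.778  95% HPD [1.471, 47.311]
  M_BU2.BU1    mean 25.431  95% HPD [4.1544, 49.703]
  M_BU2.BU3    mean 25.468  95% HPD [0.26534, 46.893]
  M_BU3.BU2    mean 26.98  95% HPD [3.0006, 49.983]
  split times: tau1 ~ 7.59e+04 years, tau2 ~ 1.47e+05 years
mtDNA exclusivity: shared haplotypes present
```

Reading it: the tessellation posterior concentrates on three units that
coincide exactly with the three simulated mountain demes (adjusted Rand
index 1 against the truth sidecar). The Mantel test is significant here
because in this fixture's geography the most divergent demes are also
the farthest apart — on real sky-island data the same test is the check
that structure is *not* a mere distance cline. Model choice picks the
stepping-stone hypothesis in which the two non-sister units are mutually
isolated (the truth's route structure); since the best model collapses
nothing, all three BUs are validated as ESUs. The ABC posterior brackets
the simulated truth (reference-scale theta 3.4/1.2/1.6; tau1 = 0.15,
tau2 = 0.39 in 4 Ne units) with deliberately honest credible intervals —
with three loci, small-deme theta and sub-migrant gene-flow rates are
only weakly identified, and the intervals say so.

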