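# kinbayes

Bayesian kinase inference from dynamic phosphoproteomics.

When cells are stimulated with a hormone — the motivating system is the
vasopressin analog dDAVP acting on renal inner-medullary collecting-duct
(IMCD) cells — hundreds of phosphorylation sites change abundance within
minutes. A multiplexed (TMT) time-course experiment measures, for every
phosphosite, log2(treated/vehicle) ratios at 1, 2, 5 and 15 minutes in
replicate. `kinbayes` turns such ratio tables into a ranked list of the
protein kinases most likely responsible for each group of co-regulated
sites.

## The method

**1. Regulation filter.** A site is called regulated when, at one or more
time points, both criteria hold at that time point:

* one-sample t-test of the replicate log2 ratios against 0 gives *p* < 0.05,
  and
* the mean log2 ratio falls outside the empirical 95% confidence range
  [−*h*, +*h*], where *h* = 2 × the largest per-time-point standard
  deviation of the mean ratios across all sites, rounded to two decimals.

With reference SDs of 0.104, 0.104, 0.128, 0.148 this gives *h* = 0.30, and
the nominal false-discovery product is 0.05 × 0.05 = 0.0025 (see the
vignette for why the realised null rate is higher).

**2. Motif / time-course clustering.** Each regulated site carries a 13-mer
sequence window (positions −6…+6, phosphoacceptor at 0, `J` padding at
protein termini). Sites are partitioned with strict precedence — proline at
+1 (Group I, proline-directed kinases), else R/K/H at −3 (Group II,
basophilic kinases), else S/T/Y at −3/−2 (Group III), else Group IV — and
then subclustered by the direction of the 15-minute response, the time to
half-maximal response, and the shape class of the time course, yielding leaf
clusters such as `II.A.1.b`.

**3. Sequential Bayesian ranking.** For each cluster, a probability vector
over a kinase registry starts uniform and is updated by Bayes' Rule seven
times, once per evidence layer: three expression datasets (transcript + two
protein), phosphoacceptor S/T/Y preference, subcellular colocalization,
curated activity direction, and substrate-motif matching by
information-content dot products. Evidence scores *x* become likelihoods via
the complement of the minimum Bayes factor,

    cMBF = 1 − exp(−z*² / 2),   z* = x / pivot,

floored at 0.5 so that missing evidence can never eliminate a kinase; the
activity layer uses the discrete values 0.9 (direction match), 0.1
(mismatch), 0.7 (regulated, direction unknown), 0.5 (no data). Results are
reported as probability ratios (posterior / uniform prior). Kinases missing
from a dataset are imputed from their nearest kinome-tree neighbor.

A seeded synthetic-data generator (`simulate_experiment()`) produces
complete inputs — ratio tables with the reference noise structure, planted
motif-bearing regulated sites with defined temporal shapes, and evidence
tables consistent with the planted kinases — so the entire pipeline is
testable without any download.

## Worked example

```r
library(kinbayes)

sim     <- simulate_experiment(sim_config(seed = 1))
report  <- filter_regulated(sim$sites)
print(report)
#> Regulation filter report
#>   sites tested: 500
#>   per-time SDs: 1min=0.129, 2min=0.130, 5min=0.151, 15min=0.182
#>   confidence range: [-0.36, 0.36] (multiplier 2)
#>   estimated FDR (product rule): 0.0025
#>   regulated sites: 39 (7.80%)

clusters <- cluster_sites(sim$sites, report$regulated_ids)
ranking  <- rank_kinases(sim$sites, clusters, sim$bundle)
print(ranking)
#> Kinase ranking over 5 cluster(s)
#>   I.B (n=7, increased): KIN01 (5.9), KIN04 (2.5), KIN03 (1.5), KIN02 (1.5), KIN11 (1.5)
#>   II.A.1.b (n=6, increased): KIN02 (4.7), KIN03 (4.2), KIN04 (1.6), KIN01 (1.6), KIN18 (1.3)
#>   II.B.2 (n=4, increased): KIN03 (4.8), KIN02 (3.9), KIN04 (1.5), KIN01 (1.5), KIN18 (1.5)
#>   III.A (n=10, increased): KIN04 (4.9), KIN01 (2.9), KIN03 (1.7), KIN02 (1.7), KIN09 (1.3)
#>   IV.B (n=9, decreased): KIN05 (3.9), KIN09 (2.9), KIN06 (2.7), KIN18 (2.5), KIN10 (1.9)
```

The per-time SDs are estimated from all 500 simulated sites (the planted
regulated sites inflate them above the configured 0.104–0.148, widening the
confidence range to ±0.36). Each cluster line shows the member count, the
majority direction at 15 min, and the top five kinases with their
probability ratios — the planted kinase (`KIN01`…`KIN05`) ranks first in
its intended cluster. `compile_top_kinases(ranking, k = 5)` then unions the
per-cluster top lists, and `export_network()` writes a SIF edge file plus an
attribute table for network viewers.

The same stages are available from a shell via the thin wrapper
`inst/cli/kinbayes.R` (subcommands `simulate`, `filter`, `cluster`, `rank`,
`export-network`, `run-all`), and `run_all()` writes every stage output
plus a JSON manifest (seed, thresholds, pivots, input checksums) for
bit-reproducible reruns.

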