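# refstab

Reference-gene stability analysis for RT-qPCR.

## The problem

Relative quantification by RT-qPCR normalizes a target gene against one or
more *reference* ("housekeeping") genes assumed to be stably expressed.
That assumption is routinely wrong — GAPDH, ACTB and 18S all vary between
tissues, treatments and cell lines — so a candidate panel has to be
screened for stability first. `refstab` implements the standard screening
workflow for quantification-cycle (Cp/Cq) data in one tested R package:

- **geNorm** — a gene's stability measure *M* is the average, over all
  partner genes *k*, of the standard deviation of `log2(Q_j / Q_k)` across
  samples. The least stable gene (highest *M*) is excluded stepwise until
  two remain; `M > 1.5` flags an unreliable gene. The pairwise variation
  `V_n/n+1 = SD(log2(NF_n / NF_{n+1}))` of normalization factors (NF =
  geometric mean of the *n* most stable genes' quantities) decides how many
  reference genes are needed (`V < 0.15`: no benefit from another gene).
- **NormFinder** — a model-based analysis of `y = log2 Q`: per-sample
  centering removes loading shifts, then each gene gets an intragroup
  variance `sigma2_ig` (small-panel-corrected) and a shrunken intergroup
  deviation `d_ig`; `stability_i = mean_g(|d_ig| + sqrt(sigma2_ig / n_g))`,
  lower is better. The optimal two-gene combination exploits cancellation
  of opposite-sign group deviations.
- **BestKeeper** — works on raw Cp: per-gene descriptives with the
  `SD > 1.00` unreliability rule, the BestKeeper index (per-sample
  geometric mean Cp of retained genes, capped at 10 analyzed genes), and
  Pearson correlation *r* of each gene with the index (higher = better).
- **Consensus** — per-method competition ranks (ties share the lowest rank:
  1, 1, 3) aggregated by the geometric mean of each gene's rank tuple;
  lowest geometric mean wins.

A seeded synthetic-data module generates grouped Cp matrices (baseline +
group offset + shared per-sample loading shift + gene noise + technical
replicate jitter) with known ground truth, so the whole pipeline can be
validated end to end. Cp-to-quantity conversion (`Q = E^-dCp`) and
standard-curve efficiency estimation (`E = 10^(-1/slope)`) are included.

## Worked example

```r
library(refstab)
sim <- simulate_cp(preset_truth("paper-like", seed = 11))  # 12 genes, 4 cell lines x 6 samples x 3 wells
res <- run_pipeline(sim$cp, out_dir = "demo_out")
res$consensus
```

prints (elided):

```
collapsed technical replicates: 24 biological samples
geNorm most stable pair: 18S + PUM1
NormFinder best two-gene combination: GAPDH + HPRT-1
pre-excluding 2 gene(s) most unstable under geNorm+NormFinder for BestKeeper: PBGD, TBP
consensus top gene: HPRT-1

Consensus ranking (geometric mean of genorm + normfinder + bestkeeper ranks)
   gene genorm normfinder bestkeeper geomean final_rank
 HPRT-1      3          1          2   1.817          1
   PUM1      1          2          4   2.000          2
   ACTB      5          3          1   2.466          3
   ...
final ordering: HPRT-1 > PUM1 > ACTB > 18S > B2M > ALAS1 > GUSB > PPIA > GAPDH > RPL-29 > TBP > PBGD
```

Read it as: each gene's three columns are its competition rank under
geNorm (ascending *M*), NormFinder (ascending stability) and BestKeeper
(descending *r*); `geomean` is the geometric mean of the three ranks and
orders the final column. The two genes the 10-gene BestKeeper cap forced
out (here PBGD, TBP) are ranked after all scored genes, ordered by their
geNorm *M*. In this preset all genes share the same noise SD except 18S
(slightly tighter) and PBGD (much noisier), so top ranks among the
similar genes shuffle from seed to seed while PBGD reliably lands last.
`res$genorm$v_series` shows `V_2/3 > 0.15` here, i.e. this noisy world
wants a third reference gene; on the `"clean"` preset the designed stable
gene wins outright.

The bundled published 12-gene osteosarcoma cell-line panel shows the
consensus module reproducing a real study's ranking from per-method
scores alone:

```r
consensus_from_scores(load_panel_scores())
#> final ordering: PUM1 > PPIA > 18S > ACTB > HPRT-1 > GAPDH > B2M > ALAS1 > PBGD > TBP > RPL-29 > GUSB
```

## Command line

```sh
exec/refstab simulate --preset grouped-bias --seed 11 --out sim/
exec/refstab run --cp sim/cp.tsv --layout long --groups sim/groups.tsv --out report/
```

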