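---
title: "Choosing stable RT-qPCR reference genes with refstab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Choosing stable RT-qPCR reference genes with refstab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refstab)
```

## The data model and its assumptions

All three stability algorithms start from the same implicit decomposition
of a quantification-cycle measurement for gene $g$ in sample $s$:

$$\mathrm{Cp}_{gs} = \mu_g + \delta_{g,\mathrm{group}(s)} + \ell_s + \varepsilon_{gs},$$

a per-gene baseline, an optional group-specific expression offset, a
*loading shift* $\ell_s$ shared by every gene of the sample (RNA input, RT
efficiency), and residual noise, with technical-replicate jitter on top.
Noise is taken additive and normal on the Cp scale — equivalently
log-normal on quantities — which is the standard qPCR error model and the
model NormFinder assumes. The synthetic generator (below) simulates exactly
this decomposition, which is both its strength (ground truth is exact) and
its limitation (real data violate it).

Cp values convert to relative quantities as $Q_{gs} = E_g^{-\Delta
\mathrm{Cp}_{gs}}$. Two conventions are fixed here and worth stating:

* **Calibrator**: $\Delta\mathrm{Cp}$ is taken against each gene's minimum
  Cp across samples, so $Q \in (0, 1]$ with per-gene maximum exactly 1.
  Every downstream statistic uses only ratios or log-differences of $Q$
  between samples, so the calibrator choice is immaterial to the results;
  the per-gene minimum is the common convention and keeps quantities
  bounded.
* **Log base 2** throughout. geNorm's original description works in
  log2; NormFinder is base-agnostic up to a global scale that cancels in
  ranking. Using one base keeps geNorm $M$ and NormFinder stabilities on
  comparable "cycles at perfect doubling" scales.

Technical replicates are averaged *on the Cp scale* before the quantity
transform; the arithmetic mean of Cp equals the geometric mean of
quantities, which is the usual qPCR practice. Missing Cp values are a hard
error by default; an explicit option drops affected samples whole (never
genes), because all three algorithms need complete matrices.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| amplification efficiency $E$ | 2 | fold/cycle | perfect doubling; per-gene values in $(1, 2.2]$ accepted from standard curves |
| geNorm reliability threshold on $M$ | 1.5 | log2 units | conventional cut above which a gene is flagged unusable |
| geNorm $V_{n/n+1}$ threshold | 0.15 | log2 units | conventional cut below which adding the $(n{+}1)$-th gene is unnecessary |
| BestKeeper SD rule | 1.00 | cycles | genes more dispersed than one cycle are flagged unreliable |
| BestKeeper gene cap | 10 | genes | compatibility with the classic tool; configurable because this implementation has no intrinsic cap |

Efficiency estimation fits $\mathrm{Cp} \sim \log_{10}(\text{dilution})$ by
ordinary least squares and reports $E = 10^{-1/\text{slope}}$ and $r^2$,
leaving the usual $r^2 > 0.99$ gate to the caller. At least three distinct
dilution points are required; a series narrower than two decades and a
positive slope are surfaced as diagnostics rather than silent results.

## Algorithmic choices where the field's descriptions are open

**geNorm stepwise ties.** If two genes tie for the worst $M$ during
exclusion, the one appearing later in input order is removed. Ties have
measure zero on real data; determinism matters for reproducible reports.
Each gene's reported $M$ is the value at its exclusion step (the stepwise
trajectory); the full-panel $M$ is retained alongside. Ranks follow the
trajectory with the final pair sharing rank 1 and the next gene taking
rank 3 (competition ranking) — the only convention consistent with
published rank tables where two genes tie at rank 1 and the next carries
rank 3.

**NormFinder constants.** The intragroup variance uses two-way residuals
$r_{ij} = y_{ij} - \bar y_{i\cdot} - \bar y_{\cdot j} + \bar y$, whose raw
mean squares $u_i$ satisfy $E[u_i] = (1 - 2/k)\sigma_i^2 + \sum_j
\sigma_j^2 / k^2$ for a $k$-gene panel; inverting gives the closed-form
correction $\hat\sigma_i^2 = (u_i - \sum u / (k(k-1)))\,k/(k-2)$ (hence the
$k \ge 3$ requirement; negative moment estimates are clamped to 0). The
intergroup deviation $\hat d_{ig}$ is the gene's centered group mean minus
its across-group average, shrunk by $\gamma^2 / (\gamma^2 +
\hat\sigma^2_{ig}/n_g)$ with $\gamma^2 = \sum \hat d^2 / ((k-1)(m-1))$ —
the empirical variance of the raw deviations with degrees of freedom
reflecting the double centering. Group sizes may be unequal; $n_g$ enters
the shrinkage and standard-error terms per group. The test suite arbitrates
these constants against an independent oracle that obtains the residuals
from `lm(y ~ gene + sample)` and solves the unbiasedness system exactly;
agreement is required to $10^{-9}$.

**NormFinder pair stability.** A pair's intergroup deviation is the mean of
the two genes' shrunken $d$ values (opposite signs cancel — the rationale
for combinations) and its sampling term is the standard error of that mean,
$\sqrt{(\sigma_a^2 + \sigma_b^2)/(4 n_g)}$, keeping pair scores directly
comparable to single-gene scores.

**Grouped vs ungrouped penalties are on different scales.** The ungrouped
analysis folds any between-group offset *quadratically* into a pooled SD,
while the grouped stability is *linear* in $|d|$; a gene with a 2-cycle
offset in one of four groups therefore gets a numerically *smaller*
grouped stability than ungrouped one, even though only the grouped
analysis identifies the offset as systematic. Comparisons between the two
estimators are consequently made relative to the panel (the offset gene's
stability over the median of the unaffected genes), and the acceptance
property asserts per-seed detection (the offset gene is the grouped panel
maximum) plus a population-level penalization excess, not a per-seed
absolute-value comparison.

**BestKeeper.** The analysis runs on raw Cp, matching the classic tool and
explaining why its ranking can diverge from geNorm/NormFinder (a gene that
tracks the shared loading shift tightly correlates best with the index even
if that shift is large). SD uses the $n-1$ denominator. The SD > 1 rule is
a flag, not a removal: flagged genes leave the index but their $r$ is still
reported; only *pre-excluded* genes (the gene-cap workflow) have no $r$. If
fewer than two analyzed genes pass the SD rule — possible whenever the
loading shift alone exceeds a cycle — the index falls back to all analyzed
genes and the result carries the diagnostic `index_fallback_all_genes`;
a hard failure here would leave valid datasets unanalyzable. $p$-values
for $r$ (two-sided, $t$ transform, $n-2$ df) are reported but never used
for ranking.

**Consensus.** Competition ranks per method; geometric mean of the rank
tuple, reported to 3 decimals with the unrounded value used for sorting;
ties broken by arithmetic mean rank, then input order. Genes without a
BestKeeper $r$ rank after all scored genes, ordered by ascending geNorm
$M$ — the policy that reproduces published tables where pre-excluded genes
occupy the last positions. One tempting invariant is *false* and
deliberately not asserted: appending a duplicate of an existing method can
legitimately change the final ordering (with ranks $m_1 = (1, 2, 3)$ and
$m_2 = (3, 1, 2)$ over three genes, adding a second copy of $m_1$ swaps
the top two), because the $k$-th root re-weights disagreements. What does
hold, and is tested: method order never matters, and appending a fully
tied method changes nothing.

## What the synthetic generator does and does not establish

`preset_truth()` ships three 12-gene, four-cell-line worlds run in
triplicate wells:

* `"clean"` — one designed stable gene (noise SD 0.05 cycles, no offsets)
  among 11 genes at 0.5; loading SD 0.8. Used for end-to-end recovery: the
  consensus pipeline must rank the designed gene first in at least 95% of
  200 seeds.
* `"grouped-bias"` — moderate uniform noise (0.2) plus a single 2-cycle
  offset for one gene in one group; detectable only by a group-aware
  method. Used for the NormFinder detection property.
* `"paper-like"` — baselines spanning ~15.7 (18S) to ~30.7 (PBGD) cycles
  with the ribosomal gene lowest, emulating the Cp profile of a published
  osteosarcoma cell-line panel; per-gene noise reflecting that panel's
  reported extremes.

Noise SDs, the loading SD of 0.8 cycles and six biological samples per
group are fixed design choices representing a realistic cell-line
experiment, chosen once; they are not tuned to test outcomes. A green
recovery test establishes that the pipeline identifies designed stability
*under the generator's own error model* — additive normal Cp noise,
exchangeable samples, no amplification-curve artifacts, no inter-plate
effects, no outliers. It does not establish performance under model
misspecification, and the published-panel checks cover only the consensus
arithmetic (the study's raw Cp data are not public, so per-method numeric
parity with its geNorm/NormFinder/BestKeeper scores is not claimed
anywhere in the package).

## Numerical notes and degenerate inputs

* Cp values must be finite and in (0, 45) cycles; duplicate gene or sample
  identifiers, incomplete group maps and duplicate (sample, gene,
  replicate) triples are classed format/validation errors naming the
  offender.
* Efficiencies outside $(1, 2.2]$ are rejected (a fold-change per cycle of
  1 or below is meaningless; above 2.2 indicates a broken standard curve).
* Variance clamping: any negative corrected variance becomes 0 before a
  square root.
* $\gamma^2 = 0$ (no intergroup signal at all) sets all shrunken $d$ to 0.
* Zero-variance genes get `NA` correlation with a diagnostic instead of an
  error; a constant gene is still a valid (indeed perfect) candidate for
  the other methods.
* Report TSVs are written at full precision and are byte-identical across
  reruns of the same configuration; only the JSON manifest carries a
  timestamp. Display rounding is 3 decimals.

## Known limitations

* No parsing of thermal-cycler vendor exports, melting curves or gel
  images; input is plain delimited text.
* BestKeeper's regression-vs-index slope/intercept outputs are not
  implemented (only SD, CV, $r$, $p$ and the index are used here).
* No confidence intervals on stability values; no aggregation schemes
  beyond the geometric mean of ranks.
* The NormFinder implementation targets the standard published model; it
  does not emulate quirks of any particular GUI/macro distribution of the
  tool.
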