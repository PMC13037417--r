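---
title: "Methods: from small-RNA counts to validated qPCR biomarkers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from small-RNA counts to validated qPCR biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirvalid)
```

mirvalid implements the statistical spine of a two-platform miRNA biomarker
study: discovery by small-RNA sequencing, selection of endogenous reference
miRNAs from the sequencing data itself, and confirmation by RT-qPCR with
ΔΔCT quantification. This vignette records the models, the defaults and why
they are what they are, and the places where the design was genuinely open.

## The synthetic cohort

Every stage is exercised against a generator with known truth
(`sim_config()`, `simulate_counts()`, `simulate_ct()`), emulating an
archival FFPE cohort: by default 18 tumor and 6 control samples over 300
miRNAs.

Counts are negative binomial with variance $\mu + \alpha\mu^2$; per-miRNA
dispersions scatter log-normally around the global `dispersion`
(default 0.05, a typical biological CV of ~22 % for bulk tissue).
Dispersion below $10^{-8}$ degenerates to Poisson. Library sizes are drawn
log-uniformly (default 200 k–1 M reads — miRNA-mapped depth, not raw
throughput) and expected counts are the per-group relative abundances
scaled by depth. Base abundances are log-normal (log-sd 1.5), reproducing
the strong skew of small-RNA libraries.

A fraction `frac_de` (default 0.15) of miRNAs carries a planted log2 fold
change drawn uniformly from `lfc_range` (default 1–4, sign-balanced), and
`n_stable` miRNAs are planted as normalizer-like: zero fold change and
near-Poisson noise. Two stratification choices matter and are deliberate:

* planted DE miRNAs come from the sub-75th-percentile abundance stratum
  with balanced signs, so the library composition is essentially the same
  in both groups. Without this, a large fold change on a dominant miRNA
  shifts every other miRNA's relative abundance between groups, which
  floors the CV of *all* candidates and would make the CV screen test a
  compositional artifact instead of the method;
* planted stable miRNAs come from the above-median stratum, where real
  endogenous controls live and where counting noise does not mask their
  low biological variance.

The qPCR layer maps relative abundance to cycles as
$CT = \texttt{ct\_offset} - \log_2(\text{abundance}) + N(0,
\texttt{ct\_noise\_sd})$, with abundance the miRNA's expected share of the
library — qPCR input mass is fixed, so CT is depth-independent. The default
offset 12 puts typical shares ($10^{-2}$–$10^{-6}$) at CT 18–32;
`ct_noise_sd` = 0.25 cycles covers combined RT and plate noise for a good
LNA assay; CTs beyond `ct_limit` = 35 are flagged undetermined and excluded
from group means rather than imputed (the simplest defensible treatment of
a censored CT). One technical replicate per assay is generated; replicates,
when present in real data, are averaged per (sample, assay) before ΔCT.

What the generator does **not** emulate: isomiR structure, UMI/adapter
artifacts, FFPE fragmentation chemistry, batch effects, and amplification
efficiencies below 100 %. Passing recovery tests therefore demonstrate the
statistics are implemented correctly and are well calibrated under NB
noise — not that any particular wet-lab panel will validate.

## Differential expression

`de_test()` is intentionally a transparent simplification of the NB
machinery in the mainstream DE packages (which remain the right tool for
real discovery cohorts): median-of-ratios size factors, log2 fold change of
normalized group means with pseudocount 0.5 (avoids infinities on zero
rows), pooled method-of-moments dispersion floored at $10^{-8}$, and a
delta-method standard error on the log scale. Two numerical choices:

* the Wald statistic is referred to a **t distribution with
  $n_1+n_2-2$ df**, not the normal. With moment-estimated dispersion at
  6 + 6 samples the normal reference is anticonservative; the t reference
  gives an observed type-I rate of 0.050 on a 2 500-miRNA null cohort
  (this is re-measured by the test suite and the acceptance script);
* the permutation option uses the same statistic against its group-label
  permutation distribution with the add-one estimate
  $(b+1)/(B+1)$, so p-values are never zero.

Calls use the discovery thresholds |log₂FC| ≥ 1 and BH-FDR < 0.01. At
moderate counts the estimator's counting-noise sd is non-negligible
(≈ 0.25 log2 units at ~35 mean counts), so recovery of a planted effect is
assessed on the estimate distribution, not on a per-miRNA worst case.

`rank_candidates()` orders called miRNAs for panel design by the mean of
the |log₂FC| rank (descending) and the FDR rank (ascending), optionally
tie-broken by a pathway-annotation count and finally by ID, so panel
composition is deterministic.

## Normalizer selection

`select_normalizers()` composes four stages, with per-stage survivor counts
kept for audit:

1. **FDR filter** — keep miRNAs with FDR strictly above 0.05;
2. **fold-change proximity** — rank by |log₂FC| ascending. "Fold change
   closest to 1" is the operative criterion: ranking raw fold change
   ascending would favor the most down-regulated miRNA, which contradicts
   the goal of change-neutral references, so proximity on the ratio scale
   wins. Ties break by FDR descending (less evidence of change first),
   then ID. This stage is a pass-through ranking — no cut is applied here,
   the retention happens at the CV stage, configurably;
3. **CV screen** — coefficient of variation of CPM across *all* samples
   (both groups pooled, n−1 sd); the ⌈m/2⌉ lowest-CV candidates are
   retained (rounding up is the inclusive default);
4. **exclusion list** — a user-supplied file of cancer-implicated miRNAs,
   matched case-insensitively. No literature mining is attempted: which
   miRNAs are "cancer-implicated" is a curation judgment, not a
   computation.

The top-*n* survivors by CV (default 3, the customary trio for qPCR
normalization) are proposed, then checked with GeNorm.

## GeNorm

`genorm()` implements the classic stability measure from scratch:
$V_{jk} = \mathrm{sd}_s\!\left[\log_2(q_{js}/q_{ks})\right]$ (n−1 sd, log
base 2) and $M_j = \mathrm{mean}_{k \ne j} V_{jk}$. M is invariant to
per-sample scaling, so CPM, relative quantities or $2^{-CT}$ are equally
valid inputs (`ct_to_expression()` converts, with an efficiency hook that
defaults to perfect doubling since assay efficiencies are rarely known).
The ranking removes the highest-M gene iteratively, recomputing after each
removal; exact ties break by ID. The pairwise-variation curve
$V(n, n{+}1)$ is the sd of $\log_2(NF_n/NF_{n+1})$ with $NF_n$ the
per-sample geometric mean of the top-n genes; the recommended panel size is
the smallest n with $V < 0.15$, the threshold proposed with the original
algorithm, applied strictly (a V of exactly 0.15 does not qualify). With
fewer than three genes the curve is empty and two references are
recommended with a warning. The implementation is verified against
brute-force enumeration oracles on all small matrices.

## ΔΔCT quantification

`delta_ct()` aggregates references by the arithmetic mean of their CT
values — equivalent to the geometric mean of their linear quantities, the
standard for multi-reference normalization. Samples with no determined
reference are dropped by name. `ddct_quantify()` then computes
$\Delta\Delta CT$, $FC = 2^{-\Delta\Delta CT}$, and fold regulation
($FC$ if $FC \ge 1$, else $-1/FC$ — magnitudes are always ≥ 1, FC = 1 maps
to +1, so −1 is never produced and the FR↔FC round trip is the identity on
the produced values).

Two open choices are surfaced rather than buried. Vendor analysis portals
do not document their significance test; we default to a **Welch t-test on
per-sample ΔCT**, the standard for a two-group unequal-variance design,
with a label-permutation alternative (`test = "permutation"`). And the test
is run on ΔCT (cycle scale) rather than $2^{-\Delta CT}$: the cycle scale
is closer to normal and variance-stable; both options exist because either
convention appears in practice. Volcano classes use |FR| ≥ 2 and p < 0.05.

## Concordance and enrichment

`summarize_validation()` counts validated (non-ns) assays;
`overlap_sets()` partitions two signed call sets into concordant,
discordant and unique miRNAs — the cross-tissue comparison;
`direction_concordance()` reports, over miRNAs significant on both
platforms, the fraction whose sequencing and qPCR directions agree.
"Validated" at the cross-platform level means significant on both platforms
with the same direction; the single-platform panel summaries do not impose
the sequencing condition.

`ora_test()` is the exact upper-tail hypergeometric test
$P(X \ge k)$ with fold enrichment $(k/n)/(K/N)$ and BH adjustment across
sets. Gene symbols are upper-cased before matching (symbol-case drift
across species annotations); query or set genes outside the universe are
dropped and reported; set-size bounds default to 2–2000. The default
universe — the union of all set genes — is a fallback that warns, because
it is not a genome-wide background; supply one. Target prediction itself is
out of scope: target tables are inputs (`simulate_targets()` emits
plausible score-distributed ones for testing), and the score ≥ 60 cutoff is
the customary confidence bound of the prediction database ecosystem.

## Reproducibility and problem sizes

A single global seed drives everything. The generator's count stream uses
the seed directly; the CT stream uses seed + 1000003 and the target tables
seed + 2000003, so adding a stage never perturbs earlier draws.
`run_pipeline()` writes all stage tables plus a manifest of every threshold
actually applied; inputs on disk are never modified.

The shipped test and acceptance suites size their simulations for tight
statistical power at interactive runtimes: 2 500 null miRNAs for type-I
calibration (Monte-Carlo sd 0.0044 at α = 0.05), 20 seeds × 200 miRNAs for
effect recovery, 20 seeds × 120 miRNAs for normalizer recovery, and 5-seed
end-to-end runs. These sizes are the package's own choices and can be
scaled up freely.

## Known limitations

* The DE test has no dispersion shrinkage or empirical Bayes moderation;
  at very small n it is noisier than the mainstream packages it simplifies.
* Multi-factor designs, batch correction and isomiR resolution are out of
  scope.
* GeNorm assumes the candidate references are not co-regulated; M cannot
  detect a set of genes that varies together.
* Amplification efficiency is assumed 100 % unless supplied; strongly
  divergent assay efficiencies bias ΔΔCT fold changes.
* The enrichment stage inherits every bias of the supplied target
  predictions and gene-set database; it tests over-representation, not
  pathway activity.
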