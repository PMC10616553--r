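---
title: "phosflow methods: from reporter ions to kinase networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{phosflow methods: from reporter ions to kinase networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosflow)
```

phosflow reconstructs kinase signaling changes from isobaric-label (TMT)
phosphoproteomics of perturbed cell lines. The canonical application it is
built around is a drug-response screen: several cell lines, each treated
with an inhibitor or vehicle in replicate, each line quantified in its own
TMT10 plex (4 treated + 4 vehicle + 2 pooled-reference channels), with the
goal of deciding which kinases gained or lost activity and which
substrate-level changes those activity changes explain. This vignette is
the package's own account of the models and the choices behind them; the
README shows the surface-level workflow.

## Quantification model (`compute_log_ratios`, `collapse_features`)

Reporter-ion intensities are only comparable within a plex, so every PSM's
channel intensities are converted to log2 ratios against the *geometric
mean of the reference channels of that same PSM*:
`log2(I_channel) - mean(log2(I_ref))`. Because the reference channels are a
pool of all samples, these ratios are comparable across plexes. Rows
without a usable (positive, non-missing) reference intensity carry no
ratio information and are dropped with a logged count.

Rollup is median-based and two-staged: PSMs -> peptide (median of PSM
ratios, per sample), peptide -> protein or phosphosite (median of peptide
ratios). Medians make the rollup idempotent — duplicating every PSM changes
nothing — and robust to residual outliers.

### Recursive Dixon outlier removal

Before the PSM -> peptide median, peptides observed by more than two PSMs
are screened per sample with Dixon's Q test (r10 statistic): the most
extreme value is removed while `Q = gap/range` exceeds the two-sided
alpha = 0.05 critical value for the current n (0.970, 0.829, 0.710, ... for
n = 3, 4, 5, ...), recursing until no rejection or n < 3. The critical
values are tabulated for n up to 30; beyond that the package trims values
further than 3 MADs from the median, which is the robust-screening
equivalent at sample sizes where Dixon tables stop.

Two properties of this test matter for interpretation and are quantified
by `dixon_removal_rates()` on generator output:

* **False-rejection floor.** A level-0.05 test rejects ~5% of clean
  peptide-sample groups by construction. At 4 PSMs per peptide that is
  ~1.2–1.4% of clean PSM values removed. This is a property of the test's
  level, not of the implementation; it cannot be pushed below ~1% without
  changing alpha.
* **Masking.** The r10 statistic tests a *single* extreme value. Two gross
  outliers in one group hide each other: a same-side pair leaves no gap, an
  opposite-side pair doubles the range. At an outlier rate of 5% per cell
  and 4 PSMs per peptide, ~13% of planted outliers share a group, which
  caps overall recall near 87% even at negligible noise. Recall restricted
  to singleton-outlier groups is the meaningful implementation check
  (~99% at high shift/noise ratio); a 4-log2 outlier needs a shift/noise
  ratio of roughly 16 or more to clear `Q_crit(4) = 0.829` reliably.

## Normalization (`align_and_scale`)

Per sample, a two-component Gaussian mixture is fitted to the log2 ratios
by EM and the *global mode of the fitted density* is subtracted, so that
the most likely log-ratio is zero — the natural "no change" anchor when an
unknown minority of features genuinely moved. Numerical choices:

* EM initialization at the 25th/90th percentiles; convergence at a relative
  log-likelihood change below 1e-8; at most 500 iterations; non-convergence
  falls back to median centering (recorded per sample in the normalization
  report).
* **Variance floor.** Mixture likelihoods are unbounded as a component
  variance shrinks onto one observation; with a fixed tiny floor a spike
  component can own the density mode and produce multi-unit shifts. The
  floor is therefore proportional to the data spread,
  `max(1e-3, 0.05 * sd(x))`: narrow enough never to disturb a genuine
  component, wide enough that a spike's density cannot dominate the bulk.
* **Mode location.** The fitted density can be bimodal, and a single
  golden-section search can converge to the minor mode. The mode is located
  on a dense grid over `[min(mu) - 4 max(sigma), max(mu) + 4 max(sigma)]`
  and then refined by golden-section search within the bracketing grid
  cell.

Scaling is an *equalization*, not a standardization: each sample's SD is
computed on values inside both the 5th–95th percentile of its log-ratios
and the 5th–95th percentile of the feature reference intensities (trimming
removes leverage from ratio outliers and from ill-quantified low-intensity
features), and each sample is divided by its trimmed SD relative to the
geometric mean of all samples' trimmed SDs. This equalizes spread across
samples and plexes while leaving the overall fold-change scale intact; a
clean unit-variance sample gets a factor near 1. One consequence worth
knowing: when a large fraction of features truly changes in some samples,
their trimmed SD is genuinely larger and their fold changes are compressed
accordingly — one more reason the downstream threshold is a modest 0.58
(see below) and the synthetic defaults keep perturbed sites a minority.

Sample-level QC uses classical metric MDS (`stats::cmdscale`) on Euclidean
distances over complete-case features.

## Differential statistics (`fit_moderated_t` and friends)

Each cell line is analyzed separately (its plex is a complete 4 + 4
design; there is no cross-plex random effect to model in a one-plex-per-
line layout). Per feature, `b = mean(treated) - mean(vehicle)` with pooled
residual variance `s2` on `d` degrees of freedom, then empirical-Bayes
moderation

`s2_post = (d0 s0^2 + d s2) / (d0 + d)`,
`t = b / (s_post sqrt(1/n_t + 1/n_v))`, `df = d0 + d`.

The prior `(d0, s0^2)` is estimated by moment matching of `log(s2)` to the
scaled-F model via `limma::fitFDist` — the standard estimator; the test
suite cross-checks the full statistic against an independent limma
`lmFit`/`eBayes` run. `d0 = 0` recovers the ordinary pooled t-test and
`d0 = Inf` a known-variance z-like test, both exposed for verification.

Phosphosites are adjusted for protein abundance by subtraction
(`b_site - b_protein`), with standard errors added in quadrature and
degrees of freedom combined by Satterthwaite; sites without protein-level
quantification are removed and counted. Significance requires both
`adj_p < 0.05` (Benjamini–Hochberg) and `|b| > 0.58` — the log2 equivalent
of a ±50% fold change (`round(log2(1.5), 2)`), a deliberately modest bar
because MS2-level TMT quantification compresses ratios. Site-level results
are additionally filtered to localization probability >= 0.75 *before*
testing, and BH is recomputed on the survivors so the multiplicity
correction matches the tested family. Non-significant features carry
direction 0: they contribute nothing downstream.

## Causal network inference (`match_causal_relations`, `test_protein_activities`)

The prior knowledge is a set of signed, site-specific relations: *source
(de)phosphorylates target at site s*, with the site annotated activatory,
inhibitory, or unknown for the target's function. An edge explains an
observed change when three conditions hold:

1. the changed site matches the prior site exactly (residue + position; no
   positional tolerance window);
2. the source's activity direction `a` is evidenced — by its own changed
   sites that are annotated activatory/inhibitory (`a = effect * direction`),
   or, only in the absence of site evidence, by its total-protein abundance
   direction; contradictory evidence excludes the source entirely;
3. the target direction obeys the consistency condition
   `d = sign(relation) * a`.

The evidence-priority and conflict rules are the package's choice where
the general method leaves them open: site-specific evidence speaks to
activity more directly than abundance, and a contradicted activity is no
evidence at all.

Protein activities are tested by label randomization: the observed
statistic for protein k and hypothesis `a` is the number of measured prior
target sites with `d = sign * a`; the null redistributes the direction
labels over *all measured sites* (B = 10,000 draws by default), preserving
the global up/down/unchanged counts. The sampling frame is the full
measured universe rather than per-protein target sets because the labels
being permuted — "which sites moved, and which way" — are a property of
the dataset. `p = (#{null >= obs} + 1)/(B + 1)`; activation and
inactivation are tested separately, BH-adjusted together, and each protein
reports its smaller adjusted p (ties resolved toward the larger supporting
target set), called at adjusted p < 0.1.

The change-detection FDR is swept (0.1, 0.01, 0.001, 0.0001 by default)
and the activity test repeated per cutoff. Call counts are *not* monotone
in the cutoff, and stricter cutoffs frequently yield more calls: removing
marginal, direction-noisy sites sharpens both the observed consistency
counts and the permutation null. The sweep output includes the
signed-log10-adjusted-p heatmap matrix per protein per cutoff.

### Calibration diagnostics

The permutation p-value is discrete and, with the +1 correction, slightly
super-uniform by construction, so a two-sided KS test against U(0,1)
rejects a perfectly calibrated implementation once enough p-values are
pooled. The test suite therefore checks calibration the standard way for
discrete tests: the randomized (tie-broken) p-value
`(n_gt + U (n_eq + 1))/(B + 1)` must be uniform, and the reported p-values
must show no deviation in the anti-conservative direction (one-sided KS).
Both null-tie counts are exposed in the `activity_calls` output, and the
uncollapsed two-row-per-protein table (`collapse = FALSE`) exists because
the per-protein minimum is a selected statistic that is not uniform under
the null. The BH false-discovery property is checked with a binomial bound
over 20 null sub-runs (the per-run false-discovery indicator is
Bernoulli(~0.05), so its 20-run mean is itself noisy).

## Directional PTM signature enrichment (`score_enrichment`)

Signatures are site sets with optional member directions (`u`/`d`: the
direction a site moves when the signature's kinase or perturbation is
active). Members annotated `d` have their statistic sign flipped before
ranking, so "down site going down" counts as positive evidence. All
measured sites are ranked by the (flipped) statistic, descending, ties
broken deterministically by site id; walking the list, the running sum
gains `|stat|^w / sum(|stat|^w over members)` at members and loses
`1/(N - N_members)` at non-members; the ES is the extremum of largest
absolute value, with ties (to within 1e-12 accumulated rounding) resolved
to the positive side. The default weight `w = 0.75` follows the
site-signature enrichment convention; `w = 0` gives the unweighted
KS-like statistic, invariant under monotone transformation of the
statistics. A set matching every measured site has no misses and its
running sum is the cumulative member weight, making ES = 1 — the
degenerate case is defined, just uninformative. The ranking statistic
default is the moderated t of protein-adjusted sites (a signed,
variance-stabilized quantity); signed -log10 adjusted p is a reasonable
alternative.

The null permutes site labels (B >= 1000), not samples, because the
enrichment stage consumes only the per-site statistic vector. For sets
without directional annotations this is computed, equivalently and much
faster, by placing the matched members at uniformly random ranks;
directional sets are rescored from scratch since flipping re-ranks the
list. `NES = ES / mean(|null ES| of the same sign)` and the p-value
compares |ES| within the same-sign null half, BH across signatures.

## What the synthetic generator emulates — and what it does not

`generate_prior_network`, `simulate_perturbation` and
`generate_reporter_tables` produce data with the statistical structure the
pipeline assumes, with known ground truth:

* the default study layout: 3 cell lines x (4 treated + 4 vehicle + 2
  reference) in 3 TMT10 plexes, 24 samples, with the third line marked
  insensitive (its treated channels carry no effect) — emulating a
  drug-insensitive control line;
* a prior of 20 kinases x 10 target sites (defaults), of which 5 kinases
  are inhibited (`a = -1`) at `delta = 1` log2 unit; perturbed sites are
  deliberately a minority (~25%) of the site matrix so the per-sample
  density mode stays identifiable — mirroring real screens, where most of
  the phosphoproteome does not respond to a targeted inhibitor;
* log-normal baseline abundances (log2 mean 20, sd 2: a realistic
  reporter-ion dynamic range), a per-PSM ionization offset (sd 0.5) shared
  across channels, and iid per-cell log2 noise (default sd 0.3; ~0.2 is a
  typical well-behaved TMT dataset, and several calibration fixtures use
  it);
* reference channels built as the within-plex geometric mean of the clean
  sample channels plus channel noise — the pooled-aliquot construction; the
  pool is computed before outlier injection because gross outliers are
  acquisition artifacts of individual channels, not of the pool;
* gross outliers as additive ±4 log2 shifts on single sample-channel
  cells (rate 2% by default), missingness as blanked sample-channel cells
  (2%), never on reference channels, so every row keeps its ratio anchor;
* localization probabilities from the 90%-in-[0.9, 1], 10%-in-[0.3, 0.75)
  mixture, exercising the 0.75 filter.

Not emulated: co-isolation interference and ratio compression at the
spectrum level, isotope impurity leakage between channels,
retention-time or batch structure, intensity-dependent missingness, shared
peptides between proteins, and multiply-phosphorylated peptides. Passing
tests on this generator therefore demonstrate correctness of the
statistical machinery under its stated model, not robustness to every MS
artifact; the normalization and threshold choices inherit their
justification from the field's practice, not from the simulation.

## Problem sizes and runtimes

The test-suite fixtures are sized for exhaustive or well-powered checks at
interactive cost: oracle equivalence runs 300 random <= 4-node causal
instances, all 2^N member subsets at N <= 8 for the enrichment score, and
1000 random BH vectors; calibration pools 50 seeded replicates of the
activity and enrichment permutation tests (B = 1000) and a 2000-site null
generator run; recovery runs the full pipeline on the default design with
240 sites and B = 10,000 permutations. The acceptance script recomputes
the same headline quantities from scratch in well under a minute.

## Known limitations

* Dixon screening at alpha = 0.05 removes ~1.3% of clean PSM values, and
  multi-outlier masking caps overall recall (see above); both numbers are
  reported by `dixon_removal_rates()` rather than hidden.
* Joint scale equalization compresses fold changes in samples where a
  large fraction of features truly changes.
* The two-component EM needs on the order of 30+ features per sample;
  small matrices fall back to median centering.
* Site matching is exact on residue + position; isoform or off-by-one site
  annotations in a real prior will not match.
* Multi-hop causal explanations are represented implicitly as unions of
  consistent single edges; no path enumeration is attempted.
* The moderated-t approximation replaces a mixed-effects model; with one
  plex per cell line and no technical replicates the fixed-effects
  contrast is the same estimand, but datasets with repeated runs per
  sample would need the fuller model.
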