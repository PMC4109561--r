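---
title: "Up-state analysis of MEA recordings: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Up-state analysis of MEA recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meaburst)
```

## The scientific problem

Cultured neocortical networks on multi-electrode arrays (MEAs) alternate
between silent *down-states* and synchronized population *up-states* (network
bursts) in which most recorded units fire together. In control ("WT")
cultures up-states are short — mean duration about 0.75 s, onset-to-onset
inter-burst intervals (IBI) around 19 s, array-aggregate firing near 68 Hz —
and up-states longer than 15 s occur with probability of order 1e-5. Cultures
expressing an epilepsy-linked nicotinic-receptor subunit ("Mutant" mode here)
keep the short bursting mode but additionally produce rare, very long
(tens of seconds) up-states — the in-vitro correlate of seizures — with a
probability roughly two orders of magnitude higher, and a conspicuous absence
of intermediate durations (a support gap between about 4 and 16 s).

`meaburst` implements the full analysis chain for such recordings — spike
cleaning and sorting, up-state detection, per-unit burst metrics,
excitatory/inhibitory and network-state classification, duration
distributions, nonparametric comparisons, and dose-response fits — together
with a seeded synthetic-recording generator that reproduces the statistical
structure the analysis assumes. Raw electrophysiology for this preparation is
not publicly deposited, so the generator is the package's test bed: every
pipeline stage is validated by parameter recovery against the generator's
ground truth.

## The synthetic recording generator

### Up-state schedule

Onset-to-onset intervals are exponential with mean `ibi_mean` (19 s WT, 24 s
Mutant), clamped so that consecutive bursts are separated by at least
`min_down` = 0.2 s of silence. Burst durations follow the two-component
mixture

\[
BD \sim (1-p_{long})\,\mathrm{TruncExp}(\mu_s;\,(0, g_1]) +
        p_{long}\,\mathrm{U}(\ell_1, \ell_2),
\]

a truncated exponential for the short mode and a uniform for the long mode —
the simplest families matching the reported means and ranges. The truncation
scale is solved so the *truncated* mean equals `bd_short_mean` (0.75 s WT).
The gap `(g_1, \ell_1)` is a hard support gap: WT uses gap (4, 10) s with long
range (10, 32) s, Mutant gap (4, 16) s with long range (16, 32) s, so no
Mutant burst can last between 4 and 16 s. `p_long` is 1e-5 (WT) and 1e-3
(Mutant); with the WT long mode spanning 10–32 s, the WT probability of an
up-state above 15 s is \(10^{-5}\times 17/22 \approx 7.7\times10^{-6}\), and
the Mutant/WT ratio of `P(BD > 15 s)` is about 130.

The Mutant short-mode mean is 1.8 s: mutant networks burst longer in every
state (a representative mutant record spends 2320 s in up-states over 1058
bursts, about 2.2 s per burst, against 0.42 s per burst for its control
litter-mate), and 1.8 s is the largest round value a truncated exponential on
(0, 4] can reach (its mean is bounded by 2).

### Spike trains

Each up-state engages inhibitory units always, and each excitatory unit with
a probability that grows with the network state — at generation time the
state proxy is the burst-duration quartile within the schedule, and the
engagement probabilities interpolate (0.6, 0.75, 0.9, 1.0) from the shortest
to the longest quartile; only the 0.6 and 1.0 endpoints are empirically
anchored. *Engaged* means *participates*: an engaged unit emits at least one
spike (its Poisson count is conditioned on being positive). Engaged units
fire inhomogeneous Poisson trains under an envelope with instantaneous rise
and exponential decay, decay constant 30% of the burst duration, so the spike
mass thins toward the burst end. A sequential scan enforces the 2.5 ms
refractory period. Down-states are silent.

The overall intensity is calibrated by root finding: the expected realized
spike count — envelope mass corrected for dead time
(\(\lambda \to \lambda/(1+\lambda\tau_r)\)) and for the at-least-one-spike
conditioning (\(m \to m/(1-e^{-m})\)) — is matched to
`target_array_rate × duration`. Because drugs scale the *target*, normalized
dose-response ratios are unbiased by the refractory nonlinearity. WT targets
68 Hz; the Mutant preset targets 145 Hz, which is the same *within-burst*
per-unit intensity as WT once the roughly fourfold longer bursts at a 24 s
IBI are accounted for — the action-potential drive is genotype-independent,
the time spent bursting is not. If a drug-scaled target falls below the
participation floor (one spike per engaged unit per burst) the generator
warns and uses the minimal intensity; if the target exceeds the refractory
ceiling it stops with an error.

Two realism constants break the symmetry between unit classes: inhibitory
units fire 2.5× faster than excitatory units (the usual interneuron
convention) and per-unit rates carry lognormal heterogeneity with
`sdlog = 0.25`. These produce the bimodal Fano-factor / spike-number /
intra-burst-rate pattern across units on which the unsupervised
excitatory/inhibitory classification relies.

### Waveforms and contamination

Each unit has a fixed biphasic template on 48 samples (1.2 ms at 40 kHz);
units sharing an electrode differ in amplitude and width. Spikes are the
template plus Gaussian noise (SD 0.05 against a unit peak), and templates do
not depend on the up-state a spike falls in — waveforms inside a seizure-like
event match those outside it, as in the real preparation. A contamination
fraction (default 5%) of spikes are over- or under-sized copies of the unit's
own template (scale U(1.6, 2.2) or U(0.25, 0.55), equally likely), emulating
spike overlaps and partial captures. This choice is deliberate: a single
distant "artifact template" would form its own tight cluster that K-means
happily isolates and the outlier cut then never removes; scatter along the
template ray is what a distance threshold can and should catch.

### Drugs

A drug is a Hill inhibition of firing,
\(s(C) = 1/(1+(C/IC_{50})^h)\), applied to the target rate, plus a
multiplicative suppression of `p_long`. Carbamazepine uses IC50 49 uM in WT
and 10 uM in Mutant mode (hill 1) and extinguishes the long mode on a
threshold-linear ramp — scale \(\max(0, 2s-1)\), i.e. full long mode at zero
concentration, none at or beyond the IC50. The ramp rather than the plain
Hill factor is needed because the observed effect is absolute: at 30 uM (3×
the Mutant IC50) no seizure-like event survives at all, while a proportional
scaling would still leave a measurable rate of them. Gabazine, penicillin-G
and midazolam mildly depress firing (IC50 defaults 5 uM, 2 mM, 20 nM) and
set the long mode to zero, matching their observed suppression of long
bursts.

## The analysis pipeline

### Cleaning and sorting

`clean_refractory()` removes spikes closer than 2.5 ms to the last kept spike
(sequential scan: idempotent, order-preserving, never removes the first
spike). `sort_waveforms()` reproduces the offline sorting stage per
electrode: PCA of the snippets, K-means into the expected unit count, and
removal of spikes farther than 1.4 from their cluster centroid. Three
numerical choices deserve explanation:

* **Component retention.** A fixed 3 components would, on electrodes whose
  structure lives in fewer directions, retain noise-only components whose
  spread equals the noise itself and make genuine spikes look like outliers.
  Components are instead kept while their eigenvalue exceeds twice the median
  eigenvalue (the median tracks the flat noise floor), capped at 3.
* **The 1.4 threshold's scale.** With a per-cluster covariance the distance
  of a genuine member is chi-distributed (d degrees of freedom) and a 1.4
  cutoff would discard over half of a perfectly good Gaussian cluster in 3
  PCs — irreconcilable with the contract that total exclusion stays below
  10%. Distances are therefore measured with each retained component
  standardized to its **global** (all-spike) SD: between-cluster spread is
  part of the scale, members of separated clusters sit well inside 1.4, and
  scale-outliers stick far out. Clustering itself runs on the eigen-scaled
  scores (normalizing per component would inflate noise directions and
  distort the cluster geometry).
* **Calibrated MANOVA.** A MANOVA p-value computed on K-means labels is
  meaningless as-is: any K-means split of a single Gaussian separates the
  means, and PCA picks the directions in which the sample happens to spread.
  The reported p-value is therefore Monte-Carlo calibrated: the observed
  Pillai trace is ranked against Pillai traces from the identical
  PCA + K-means pipeline applied to multivariate-normal null waveforms with
  the observed covariance (199 seeded replicates). Sorted units are accepted
  at p < 0.01; a duplicated single unit is honestly flagged.

If the distance cut would remove more than 10% of an electrode's spikes the
electrode is flagged for manual review and left untouched rather than
silently over-deleted. `exclude_irregular_electrodes()` drops electrodes
below 0.05 Hz or silent in more than half of the 10-minute segments — the
original criterion is unstated, so the rule is exposed as parameters and
logged per electrode.

### Up-state detection

`detect_upstates()` slides a window (default 10 ms, stepped at 1 ms) over the
pooled spike train with hysteresis thresholds: an up-state opens at the first
window reaching `high_thr` (default a quarter of the unit count per window)
and closes only after the count stays below `low_thr` (default 2
spikes/window) for `min_interburst` (default 100 ms) — the two-threshold
design is what keeps a 30 s seizure-like event in one piece while still
resolving bursts 200 ms apart. Boundaries are snapped to the first and last
spike inside the interval, so the burst duration is the spike span, matching
the per-burst durations that timestamp-based software reports; the
window-edge alternative is not used (the step would otherwise quantize all
durations). The detector is verified, on short recordings, against an
exhaustive 1 ms-step state-machine oracle. `auto_tune_thresholds()` grid
searches window, thresholds and minimum interburst length to maximize the
temporal Jaccard agreement with a smoothed population-rate mask, for
recordings where the defaults do not fit; it is deterministic.

Per-unit annotations within a detected up-state follow the conventional
sparse-burst rules: one spike counts as SN 1 with BD 2 ms; two spikes as SN 2
with BD equal to their ISI; three or more spikes as BD = last − first spike.
A unit's burst is all of its spikes inside the network up-state; a standalone
ISI-based per-unit burst finder is intentionally not implemented. Units that
keep firing through the down-states (typically 1–2 per network) are discarded
by `discard_tonic_units()` (default: down-state rate above 0.1 Hz, a
parameter because the original rule is qualitative).

### Metrics and classification

`segment_stats()` computes, per unit and time segment, mean burst duration
and spike number, spike rate, intra-burst spike rate (total SN / total
per-unit BD), mean onset-to-onset IBI over engaged bursts, and the Fano
factor of 100 ms spike counts (window choice documented, parameterized; the
source method names no window). Units with no burst in a segment are flagged
missing, never zeroed. IBIs are onset-to-onset — consistent with IBIs of
8–10 s reported alongside sub-second durations, which offset-to-onset gaps
would contradict only marginally but onset-to-onset matches exactly.

`classify_units()` standardizes the (FF, BD, SN, IBSR) features — the
four statistics that are bimodal across units — reduces them by PCA to 90%
variance, K-means with K = 2 (20 seeded restarts, best inertia, ties to the
lowest seed), removes outliers at the 1.4 distance, and labels the larger
cluster excitatory (neocortical proportions; no other labelling rule is
available without spike shapes, which are deliberately not used). The
alternative reading of the source's "FF-based data reducing PCA" — PCA on FF
across segments only — was considered and set aside: it discards the three
other bimodal features that make the split robust. FF bimodality is reported
as the bimodality coefficient (informational; no dip-test implementation is
available in the package's dependency set).

`classify_states()` builds one feature vector per up-state — the pooled
spike-number time histogram (0.1 s bins, first 10 bins), the total pooled
SN, the number of engaged neurons, and BD — standardizes, reduces by PCA,
and K-means with K = 4 (K fixed by the analysis tradition, not selected),
relabelling states by ascending mean pooled SN. `engagement_fraction()` then
measures, e.g., that about 60% of excitatory units participate in state-1
up-states while inhibitory units participate in all of them.

### Distributions and statistics

`bd_histogram()` bins durations into left-closed 0.25 s bins (edges at
integer multiples; a duration exactly on an edge goes up — the convention is
ours to fix, and the long-up-state probability is computed on raw durations
precisely so that no edge choice can move it). Four normalizations are
maintained with their conservation identities: counts, time per bin, fraction
of events, fraction of record time. `pool_bd_histograms()`,
`p_long_upstate()` and `cumulative_bd()` cover cohort pooling and the pre/post
drug comparisons.

The nonparametric battery uses base R where base R is the reference:
Mann-Whitney and Wilcoxon signed-rank via `wilcox.test` (exact for small
untied samples, tie-corrected normal approximation otherwise). Kruskal-Wallis
gains an exact enumeration (all assignments of the pooled observations to the
group sizes) for total n ≤ 10, since base R offers only the chi-square
approximation; note that at those sizes the chi-square approximation is
coarse (absolute p differences up to ~0.1 against the exact null — a known
property of the approximation, which is why the exact path exists at all).
Dunn's post hoc z-comparisons on pooled midranks with Bonferroni correction
are implemented in-package (no suitable dependency is installed) and checked
in the test suite against a label-permutation oracle; the partition of groups
into mutually indistinguishable sets is the connected components of the
"not significantly different" graph. Histogram-level Wilcoxon comparisons
first align supports by zero-padding empty bins (`align_histograms()`), the
distributional heuristic used in this analysis tradition.

### Pharmacology

`dose_response_curve()` normalizes array-aggregate rates by the
zero-concentration control; `fit_ic50()` fits the two-parameter Hill curve
(top 1, bottom 0) by deterministic multi-start least squares — a
four-parameter logistic would be under-determined at 3–6 concentrations. The
fit requires the series to bracket half-inhibition and is scale-equivariant
in the concentration unit. `compare_pre_post()` assembles the wash-in
workflow: cumulative BD curves, long-event counts above configurable
thresholds, and a Kruskal-Wallis p-value.

## Problem sizes, seeds, and reproducibility

A single master seed governs every stochastic stage; per-stage and per-unit
streams are derived deterministically from it, so the same configuration is
bit-reproducible, and `run_pipeline()` writes byte-identical outputs for
identical configs. The bundled test suite and `scripts/acceptance.R` size
their cohorts for desk-scale runs — e.g. 27 half-hour WT experiments for the
pooled duration statistics, one 2 h recording for the state/engagement
analysis, 1 h Mutant chunks accumulated until 20 long-mode events for the
maximum-duration estimate, and 10-minute recordings per concentration for
dose-response fits — sizes at which every recovered quantity sits several
standard errors inside its target band.

## What passing tests do and do not show

The generator reproduces the *statistical* structure of the preparation:
alternating silence and population bursts, genotype-specific duration
mixtures with a support gap, state-dependent excitatory engagement,
always-engaged inhibitory units, refractoriness, stable waveforms,
Hill-scaled pharmacology. It deliberately omits electrode geometry and
spatial correlations, synaptic dynamics within bursts (the envelope is a
phenomenological rate profile), culture-to-culture heterogeneity beyond
per-unit lognormal rates, drifting electrodes, and true waveform variability
(bursty amplitude adaptation, electrode crosstalk). Parameter recovery on
synthetic data therefore validates the *pipeline* — detection, sorting,
classification, estimation are internally consistent and unbiased at realistic
signal strengths — but does not by itself certify performance on real
recordings whose violations of these assumptions are unknown.

## Known limitations

* The up-state detector assumes pooled-population silence between bursts;
  recordings with strong tonic background would need `discard_tonic_units()`
  first (which itself needs a provisional detection) or auto-tuned thresholds.
* The exact Kruskal-Wallis enumeration is combinatorial; it is capped at
  total n = 10 by default.
* The calibrated MANOVA is Monte-Carlo: its p-values have resolution 1/(R+1)
  (0.005 at the default 199 replicates) and a seeded but simulation-dependent
  value.
* Unit classification requires at least 10 units with complete statistics and
  two genuinely distinct firing phenotypes; it refuses degenerate inputs
  rather than guessing.
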