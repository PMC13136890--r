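---
title: "Detecting RNA modifications from nanopore error and signal profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting RNA modifications from nanopore error and signal profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poremod)
```

## The detection problem

Direct RNA nanopore sequencing threads native RNA 3′→5′ through a protein
pore while a motor protein ratchets it along; the ionic current through the
pore reports on the few nucleotides in the sensing region. A chemical
modification — on the base (m1Ψ, 5moU, m5C), the ribose (2′OMe, 2′MOE, 2′F,
LNA) or the backbone (phosphorothioate) — changes that current, and the
change surfaces in two distinct places:

1. **Basecall errors.** When the perturbation exceeds what the basecaller's
   model can absorb, the position (and, through the k-mer context, its
   neighbours) accumulates mismatches, deletions and insertions.
2. **The raw signal.** Dwell time, current mean and current SD shift even
   when the basecaller still emits the correct base — notably for backbone
   chemistries that barely raise the error rate.

`poremod` scores both, per reference position, against a canonical control
sample sequenced under the same conditions. The intended regime is the one
where ground truth exists: synthetic standards with site-specific
modifications at known positions, or fully substituted transcripts.

## Total variation percentage

For a pileup row with base-call counts $a, c, g, u$, deletion calls $d$ and
insertion events $i$ at a position with reference base $r$:

$$\mathrm{TV} = 100 \cdot \frac{\text{mismatches} + d + i}{a + c + g + u + d + i},$$

where mismatches are all base calls other than $r$. Conventions that the
formula does not pin down, fixed here:

* Calls are normalized to the RNA alphabet on ingestion (T→U).
* An insertion of any length is **one** event, anchored at the reference
  position it follows; at most one per read per position.
* Depth (`a+c+g+u+del`) excludes insertion calls, which have no reference
  position of their own, but the TV denominator includes them.
* A zero denominator makes the position *undefined* (`NA`), not 0%:
  coverage gaps must not deflate averages or enter metrics.

The per-type breakdown divides the same numerator into mismatch-by-base,
deletion and insertion components over the same denominator, so components
sum to the total exactly; the suite enforces this to 10⁻⁹.

The optional BAM adapter (`pileup_from_alignments()`) reproduces these
counts from coordinate-sorted alignments via Rsamtools, dropping unmapped
and secondary records and reads under a mapping-quality floor (default Q20).

## Energy distance over 3-nt windows

Per read and reference position, signal-to-reference aligners (Remora,
Uncalled4 — upstream of this package; their tabular output is the input
here) provide dwell time, current mean and current SD. For a window centered
at position $p$, each read covering $p-1, p, p+1$ contributes the
9-dimensional vector of the three features at the three positions. With
feature sets $X$ (modified, $n$ vectors) and $Y$ (control, $m$ vectors):

$$E_{n,m}(X,Y) = \frac{2}{nm}\sum_{i,j}\lVert x_i - y_j\rVert
 - \frac{1}{n^2}\sum_{i,j}\lVert x_i - x_j\rVert
 - \frac{1}{m^2}\sum_{i,j}\lVert y_i - y_j\rVert.$$

$E$ is symmetric, scales linearly with the data, is non-negative in
expectation and zero in the population exactly when the two distributions
coincide. The raw statistic is used as a score, not converted to a p-value:
profiles are compared across positions, where a common null scale cancels.

**Preprocessing.** Dwell times are log-transformed (natural log; any fixed
base is a uniform channel rescaling). Each channel is then robustly scaled
per position as $(x - \mathrm{median})/(1.4826\,\mathrm{MAD})$, with the
median and MAD pooled over *both* samples at that position. Pooling is
deliberate: scaling each sample to its own center would subtract exactly
the between-sample location shifts the statistic is meant to detect. A
zero-MAD channel falls back to centering only, with a warning.

**Numerical choices.**

* All three $E$ terms are sliced from one pairwise distance matrix over the
  concatenated samples, so identical multisets cancel to exactly zero and
  the statistic matches a brute-force double-loop oracle to 10⁻¹⁰.
* `min_vectors` (default 10 per sample per window): below this the position
  is undefined rather than noisily estimated.
* `max_vectors` (default 1000): the computation is quadratic in read count
  and real datasets reach 10⁶ reads, so larger windows are uniformly
  subsampled under a dedicated seed (`subsample_seed`), leaving the caller's
  RNG untouched.
* Edge positions have no 3-nt window and are undefined; a read missing any
  window position (e.g. through a deletion) is excluded from that window
  only, never imputed.
* Reads are kept only if they cover at least 90% of the reference
  (`coverage_filter`, boundary inclusive — a read at exactly the threshold
  is retained).

## Detection metrics and quantification

Positive labels are the exact modified positions; neighbours count as
negatives. AUROC uses the mid-rank Mann–Whitney form (invariant under
monotone score transforms and identical to trapezoidal integration of the
ROC sweep); AUPRC is step-wise average precision, with tied scores handled
as one threshold group and no interpolation, avoiding the over-estimation of
interpolated PR curves. Thresholded confusion matrices use inclusive ≥
comparison. Because the k-mer sensing region smears both statistics over
neighbouring positions, false positives are post-hoc *attributed* when
within a window (default 7 nt, centered — distance to the nearest true site
≤ 7) of a true site; this is reporting, not label smoothing.

Modification-aware basecaller pileups (a 10-column bedMethyl-like dialect)
are summarized with the canonical-call denominator:
$\mathrm{percent\_modified} = 100\, n_\mathrm{mod}/(n_\mathrm{mod} +
n_\mathrm{canonical})$. Reads miscalled, deleted or filtered
($n_\mathrm{other}$) never enter the ratio — the single most consequential
quantification convention, since at high-error sites the reported
percentage describes only the correctly basecalled minority. Cumulative
sums of the percentage along the transcript give a transcript-level
summary: rising for modified samples, near-flat for controls.

## What the synthetic generator emulates

`simulate_dataset()` produces paired canonical/modified bundles (pileups,
signal matrices, mod-call pileups, truth) with the phenomenology the
analysis assumes, each aspect switchable through `sim_config()`:

* **Deletion-dominant error elevation** at modified sites
  (`modified_error`, default mismatch/deletion/insertion =
  0.05/0.15/0.01) over a low background (0.02/0.01/0.005, total ≈ 3.5%),
  decaying linearly to baseline over `neighbor_halfwidth` (default 2) nt —
  the field reports elevated errors at proximal bases without a functional
  form, so linear decay is the simplest declared choice.
* **Signal effects at sites**: additive current-mean shift
  (`mod_mean_shift`, default 0.3 = 3× the per-event noise SD of 0.1) and
  multiplicative current-SD inflation (default 1.5).
* **Offset dwell perturbation**: the dwell shift is applied at
  `site + dwell_offset` (default 10 nt, clipped at the reference end), not
  at the site — 3′→5′ translocation places the modification near the motor
  protein while a position ~10 nt away sits in the pore. Default shift
  0.3 on log dwell (≈ 0.6 σ of the log-normal dwell, σ = 0.5): visible in
  medians at realistic depth, deliberately not dramatic.
* **3′-anchored coverage decay**: every read includes the 3′ terminus; a
  `five_prime_dropout` fraction (default 0.5) is truncated at the 5′ side
  with geometric truncation depth (mean 15 nt). No internal gaps other than
  deletions.
* **Sub-stoichiometric modified calls**: on correctly basecalled reads
  only, modified positions are called modified with `mod_call_rate`
  (default 0.8) and unmodified ones with `false_mod_rate` (default 0.01).
  Rows cover exactly the positions of the modification's canonical base
  (`canonical_base`, default A) — a modification-aware model only emits
  calls where its target base is expected — and generated references carry
  that base at every modified site, mirroring the shared-base design of
  site-specific standards.

Defaults place nine modified positions in three alternating clusters
(33/35/37, 70/72/74, 107/109/111) on a 120-nt reference with 200 reads per
sample. The current SD is drawn as a scaled |Normal| rather than a Gamma;
only its inflation ratio matters downstream.

**What it does not emulate** — and hence what passing tests do not show
about real data: raw squiggle synthesis and basecaller behaviour (errors
are drawn from declared rates, not from a pore model), k-mer
sequence-context dependence of current levels and error rates, correlated
errors along a read, alignment artefacts, and stoichiometry mixtures other
than the binomial call model. Recovery rates on this generator demonstrate
that the statistics and plumbing are correct, not field performance.

## Test design and problem sizes

Determinism is contract: one seed fixes every byte of a simulated bundle,
and generation restores the caller's RNG state. The suite checks, among
others:

* exact hand-enumerated total-variation fixtures and the breakdown sum rule;
* energy distance against an independent double-loop oracle (200 random
  9-dimensional instances, n, m ≤ 100), plus symmetry, scale equivariance
  and exact zero on identical multisets;
* AUROC (rank form) against the ROC-sweep trapezoid on random score/label
  sets, and AUPRC closed forms;
* null calibration: with all effects zero (10 seeds, 200/200 reads), the
  modified-vs-control energy profile is compared against a disjoint
  control-split profile by Kolmogorov–Smirnov at α = 0.01, using equal
  read subsets on both sides because the null scale of $E_{n,m}$ depends on
  n and m — unequal sizes would separate the profiles for reasons unrelated
  to calibration; site AUROC must sit near chance.
* recovery: at generator defaults (10 seeds), total-variation AUROC ≥ 0.9
  and energy-distance AUROC ≥ 0.85; the dwell-only experiment (single site,
  600 reads per sample — the depth scale of the emulated modified samples,
  needed because the offset dwell signal is subtle) must place the profile
  argmax at site + offset ± 1.

`scripts/acceptance.R` re-runs these study conditions end to end from a
single command-line seed and writes the resulting quantities as JSON.

## Known limitations

Beyond the generator's scope listed above: the pipeline is two-sample only
(no k-sample generalization), has no permutation p-values (scores are
compared across positions), no per-read classification, and treats the
attribution window geometry (centered, ≤ 7 nt) as a convention — the
directional alternative is equally defensible. Datasets whose two samples
were scaled or normalized differently upstream violate the pooled-scaling
assumption and should be re-extracted together.
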