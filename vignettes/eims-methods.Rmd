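---
title: "Methods: judging predicted EI mass spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: judging predicted EI mass spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eims)
```

## The problem

Electron ionization (EI) at 70 eV is the standard hard-ionization mode of
GC–MS: it fragments molecules reproducibly, and unknowns are identified by
matching their fragment spectra against curated libraries. Methods that
predict EI spectra *in silico* — from molecular-dynamics fragmentation
simulations or learned models — must be judged with exactly the match
factors practitioners use for identification, and their failure modes
(missing fragments, inflated molecular ions) interact with those match
factors in instructive ways. This package implements that judging
machinery: spectrum I/O, the two standard match factors, a simplified
consensus-spectrum assembler, molecular flexibility descriptors, and the
batch statistics used to compare predictions across compound classes.

## Spectra and binning

A spectrum here is a unit-mass peak list: strictly increasing positive
integer m/z with non-negative intensities. Raw m/z values are binned by
round-half-up (`floor(x + 0.5)`), the deterministic convention of
unit-mass EI libraries; intensities falling into one bin are summed, so
binning conserves total intensity exactly. Base-peak normalization to 999
follows library convention but is presentation-only: both match factors
are provably invariant to rescaling either spectrum, so the package never
normalizes implicitly before scoring (avoiding double-normalization bugs).

Two text formats are supported. The JCAMP-DX subset is the one peak-table
dialect spectrum exporters emit: labelled `##KEY=value` lines, an AFFN
`##PEAK TABLE=(XY..XY)` block, `##END=`; compressed ASDF ordinate forms
are out of scope. Unknown labels are preserved in order, making
`parse_jcamp(write_jcamp(s))` lossless. NIST MSP records (`Name:`,
`Num Peaks:`, mz/intensity pairs) cover library exchange. Declared peak
counts are enforced: a mismatch is an integrity error, not a warning,
because truncated peak tables silently corrupt match factors.

## Match factors

Both scores are reported as integers on the 0–1000 scale (round half up),
the convention of library search software. Spectra are aligned on the
sorted union of their m/z sets — peaks match only at identical nominal
mass; there is no tolerance window at unit-mass resolution — with zeros
where a peak is absent.

The cosine score is the normalized dot product of the aligned intensity
vectors. The weighted dot product computes the same cosine on weights

$$W = I^{\,m} \cdot (m/z)^{\,n}, \qquad m = 0.6,\; n = 3$$

applied to raw intensities per spectrum (zero where the peak is absent).
The defaults are the long-standing GC–MS library-search choices: the
intensity exponent compresses the dominance of the base peak, and the
cubic mass weight emphasizes high-m/z fragments, which are fewer, more
structure-specific, and harder to predict. With $m = 1, n = 0$ the
weighted score reduces exactly to the cosine — a property the test suite
checks on random pairs. Because binning forbids m/z 0, the mass weight can
never annihilate a real peak.

The practical consequence, reproduced as a property test: when the
high-mass quarter of a spectrum's peaks is deleted, the weighted dot
product drops much further than the cosine. A prediction can agree well on
the low-mass fragment envelope (decent cosine) while being nearly useless
for identification (weighted dot in the 100s).

## Spectrum assembly from trajectory events

Fragmentation-trajectory simulations produce, per trajectory, a final set
of one to three fragments with vertical ionization potentials (IPs). The
assembler converts an ensemble of such events into a consensus spectrum in
two steps:

1. **Charge assignment.** Per event, the charge goes to the fragment with
   the lowest IP — Stevenson's rule — with ties split equally. This is the
   deterministic default. A `boltzmann` option softens the rule to
   $w_i \propto \exp(-(IP_i - IP_{\min})/kT)$ with an electronic
   temperature $kT$ in eV (default 0.1 eV, a plausible electronic energy
   scale; the original statistical weighting is not specified precisely
   enough to copy). As $kT \to 0$ the Boltzmann weights converge to the
   lowest-IP rule, a limit the tests verify on random events.
2. **Counting.** Intensity at mass M is the sum of charge weights of
   fragments with nominal mass M over all events; neutral fragments
   contribute nothing (EI detects cations only), and equal-mass ions from
   different formulas accumulate into one peak. Pre-normalization total
   intensity therefore equals the event count, and assembly is a pure
   function: identical ensembles give byte-identical spectra.

Each trajectory contributes its final charged species only, via its event
record; sequential fragmentation within a trajectory is represented by
whatever final fragment set the event table records. Simulation
bookkeeping — trajectory count (`ntraj`, default 25 per atom), impact
excess energy per atom (`ieeatm`, 0.6 eV), initial temperature (`tinit`,
500 K) — is carried as labels; no dynamics or energy deposition is
computed here, since generating fragments is the prediction method's job,
not the evaluator's.

## Flexibility descriptors

Conformational flexibility is a candidate explanation for prediction
accuracy differences, so two descriptors are computed from the
hydrogen-suppressed heavy-atom graph.

**Rotatable bond number (RBN)** counts single bonds that are not in a
ring, not amide bonds (single C–N where the carbon bears a double-bonded
oxygen), and not terminal (both endpoints of degree ≥ 2 — rotating a
terminal bond generates no new conformer). Ring perception uses bridge
detection: a bond is in a ring iff it lies on some cycle, which suffices
at this scope without SSSR subtleties.

**Kier flexibility index (PHI).** With $A$ heavy atoms, $P_1$ bonds,
$P_2$ two-bond paths ($P_2 = \sum_v \deg(v)(\deg(v)-1)/2$) and
$\alpha = \sum_i (r_i / r_{C_{sp3}} - 1)$ a covalent-radius correction:

$$^1\kappa_\alpha = \frac{(A+\alpha)(A+\alpha-1)^2}{(P_1+\alpha)^2},\quad
  ^2\kappa_\alpha = \frac{(A+\alpha-1)(A+\alpha-2)^2}{(P_2+\alpha)^2},\quad
  \Phi = \frac{^1\kappa_\alpha \cdot {}^2\kappa_\alpha}{A}.$$

The alpha table covers the CHNO+F scope of the intended applications
(C sp3 0.00, C sp2 −0.13, C sp −0.22, N sp3 −0.04, N sp2 −0.20,
N sp −0.29, O sp3 −0.04, O sp2 −0.20, F −0.07). Aromatic carbons take the
sp2 value; aromatic heteroatoms without an exocyclic double bond (furan O,
pyrrole N) take their sp3 value — this convention reproduces the reference
values for furan (0.55), 2-nonene (7.52) and 1,8-nonadiene (7.05) that the
tests assert. For a linear all-sp3 chain the formula collapses to
$\Phi = A - 1$ exactly, a closed form the tests check for A = 3…12. PHI is
undefined below three atoms ($P_2 = 0$).

Known limitation: descriptor software differs on bridged polycyclics —
this implementation's standard formula gives adamantane $\Phi = 1.00$,
while some commercial packages print ≈1.17; adamantane PHI is therefore
not asserted anywhere. Its RBN of 0 is unambiguous. Two further published
values (2-propynyloxy benzene PHI, 2,4-dimethyl-oxetane RBN) are mutually
inconsistent across their sources and are likewise not test targets.

## Synthetic data: what it emulates and what it does not

The generator exists so every stage is testable without proprietary
libraries or quantum-chemistry runs. `gen_reference()` draws distinct
nominal masses from [26, max_mz] with the molecular ion always present and
assigns intensities by geometric decay (ratio 0.75) over a randomly
permuted rank — the simplest model yielding base-peak-dominated,
fragment-rich, EI-like spectra. It is statistical, not physical: no
isotope patterns, no fragmentation chemistry, no mass-intensity
correlation structure beyond the molecular ion.

`perturb_spectrum()` layers the documented error modes of in silico
prediction onto a reference: random peak loss (`p_drop = 0.5` by default,
reflecting predictions that produce a handful of fragments where
experiments show dozens), extra loss probability for top-quartile m/z
peaks (`high_mass_bias = 0.3`, the mechanism behind weighted-dot collapse),
molecular-ion inflation (`mol_ion_boost = 3`; the boosted molecular ion is
then never dropped), spurious hydrogen-loss peaks at [M−1]…[M−4]
(`h_loss_intensity = 150` on the 999 scale), and log-normal intensity
jitter (σ = 0.4). Defaults were fixed once from the qualitative error
descriptions and typical EI intensity scales, with max_mz = 130 matching
the ~129 Da average of small CHNO molecules; they are study conditions,
not tuning knobs. A draw that deletes every peak is retried on a fresh
substream (documented retry, error after 100).

Passing tests on this synthetic model therefore demonstrate that the
*evaluation machinery* behaves correctly — scores rank error severity,
statistics recover planted differences — not that any prediction method
achieves particular accuracy on real spectra.

All generators take explicit seeds, derive sub-seeds arithmetically, and
save/restore the global RNG state, so nothing in the package perturbs or
depends on the caller's random state.

## Batch statistics

`summarize_scores()` reports n, mean, median, sample SD (n−1; absent for a
single record) and the three conventional threshold fractions — strictly
greater than 700 (plausible match), strictly greater than 850
(identification grade), strictly below 500 (discarded) — separately per
score.

`compare_classes()` runs Welch two-sample t-tests, two-sided, of each
eligible compound class against a reference class. Welch is the robust
default when group variances differ and no specific test is mandated;
two-sided because directionality is not known in advance. Classes need at
least 50 records to enter (smaller groups make the comparison unreliable;
the threshold is an argument). The reference defaults to the lowest-mean
eligible class so each row reads as "how much better than the weakest
class". No multiple-testing correction is applied by default — raw
p-values are the convention in the source analyses — but
`p_adjust = TRUE` adds Benjamini–Hochberg values. The test suite verifies
the machinery by simulation: power ≥ 0.95 against a 130-point shift at
SD 200 with 75 per group, and type-I error within 0.05 ± 0.02 under the
null (200 seeded replicates each).

`correlate_flexibility()` uses Spearman rank correlation (descriptor
distributions are skewed and scores are bounded; ranks are the safe
choice), returning NA for constant descriptors. `sweep_summarize()` is a
thin per-parameter-value aggregation for ntraj/ieeatm/tinit-style sweeps.

## Numerical choices and problem sizes

Scores clamp the pre-rounding cosine at 1 before scaling (floating-point
guard for identical spectra) and round half up to integers. JCAMP/MSP
writers format numbers without scientific notation at up to 15 significant
digits, so write→parse→write is byte-stable. The test suite exercises 500
random pairs for score properties, 100 seeded trials for the
high-mass-sensitivity property, 200 replicates for each statistical
simulation, and 100 random spectra per format for round-trips — sizes at
which the checked properties are already stable and the whole suite runs
in well under a minute.
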