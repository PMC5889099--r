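---
title: "Nucleosome-phased DNA methylation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nucleosome-phased DNA methylation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methphase)
```

# The problem

Whole-genome bisulfite sequencing (WGBS) reads methylation state one
cytosine at a time: unmethylated cytosines are converted to uracil and read
as T, methylated cytosines stay C, so each position yields a pair of counts
— informative reads, and unconverted ("methylated") reads. Two signals in
such data carry information about chromatin organisation rather than about
individual regulatory elements:

* Around CTCF-binding sites that are occupied in essentially all cell
  types, CG methylation dips into a wide "V" and oscillates with a period
  near 175 bp — one nucleosome plus one linker. Methylation peaks fall on
  linker DNA and valleys on nucleosome-occupied DNA, and the amplitude of
  this oscillation grows as lymphocytes differentiate. `methphase` measures
  that amplitude as a single scalar, the *nucleosome influence*.
* Outside the CG context, methylation (mCH) is a faint signal sitting on
  top of bisulfite conversion error. Where it genuinely occurs it is
  concentrated in CA trinucleotide contexts (CAC above all), and it is
  excluded from lamina-associated domains (LADs).

The package implements the full path from a per-cytosine call table to
these summaries, and ships a synthetic-data generator that emulates the
statistical structure of the signals so every step can be validated by
parameter recovery.

# Record-level model and filters

A cytosine record is `(chrom, pos, strand, context, n_meth, n_total,
exclude_flag)`; `context` is the trinucleotide on the cytosine's own strand.
Records are retained when `6 <= n_total <= 250`: the lower bound is the
minimum evidence for a per-site level, the upper bound removes mapping
pile-ups. Genotype-level exclusions (heterozygous or uncertain positions)
are upstream concerns represented by `exclude_flag`; the package starts at
the call table.

Conversion efficiency is estimated from spike-in controls of known state:
the unmethylated control (phage lambda in the original design) gives the
under-conversion rate $e$ (reads wrongly retained as C), the methylated
control (phage T7) the over-conversion rate (reads wrongly converted). A
sample passes QC when its conversion rate $1-e$ is at least 0.997. Both
rates enter the observation model

$$p_{\mathrm{obs}} = p\,(1 - \mathrm{over}) + (1 - p)\,e,$$

which attenuates any true signal of amplitude $\Delta p$ by the factor
$(1 - \mathrm{over} - e) \approx 0.95$ at the defaults. Recovery tests
against generated truth compare on the observed scale for this reason: the
attenuation is a property of bisulfite chemistry, not an estimator bias.

# Calling mCH against the conversion-error background

Every unmethylated cytosine shows unconverted reads at rate $e$, so
apparent mCH must beat a Binomial($n$, $e$) background. A non-CG cytosine
is called methylated iff

$$n_{\mathrm{meth}} \ge 2 \quad\text{and}\quad
  n_{\mathrm{meth}} > n\,e + 2\sqrt{n\,e(1-e)},$$

i.e. at least two unconverted reads and more than two standard deviations
above the background mean. We interpret the "two SD" rule on the count
scale of the per-site binomial; a count-scale and a fraction-scale
formulation give identical decisions, since both sides of the inequality
scale by $1/n$. An exact-binomial variant (`exact = TRUE` in `call_mch()`;
tail probability below $1 - \Phi(2)$) is provided as a stricter mode. $e$
is always taken from the same sample's unmethylated control, never pooled
across samples, so that a sample's own conversion chemistry sets its
background.

The genome-wide mCH fraction is calls over eligible sites (non-CG records
passing the coverage filter). Context composition is summarised from the
11-mer around each called cytosine (position 6), reverse-complemented for
minus-strand calls; per-position information content is $2 - H$ bits with
$H$ the Shannon entropy of the column.

LAD depletion is tested one-sided: under the null, calls fall into LADs
like any eligible site, so the in-LAD call count is
Binomial($n_{\mathrm{calls}}$, fraction of eligible sites in LADs) and the
p-value is the lower tail. A label-shuffling permutation p (equivalently, a
hypergeometric draw, since shuffling fixes both margins) is available as a
finite-population cross-check; the two agree when calls are a small
fraction of eligible sites.

# Spike detection

Exon-localised non-conversion spikes are found by sliding a window of ten
consecutive eligible non-CG cytosines (both strands interleaved by
position, gaps ignored) and flagging windows whose mean per-site level
strictly exceeds 20%. Overlapping or touching qualifying windows merge into
one region spanning the first to last member cytosine; regions are
reported as 0-based half-open intervals with their cytosine count and mean
level, and annotated against exons by any-base overlap. The strict
threshold carries a $10^{-9}$ guard so a window at exactly 20% never
qualifies regardless of floating-point summation order. The merging rule —
one region per maximal run of covered cytosines — reflects how the
original observations were reported as single per-exon events; windows are
not restricted to one strand, and may span arbitrary genomic gaps between
consecutive eligible cytosines (per-region gap structure is recoverable
from the interval and the record table).

# Anchored profiles

`aggregate_profile()` measures offsets from the motif centre, defined as
the floor midpoint of the motif interval (the zero point is otherwise
arbitrary). Minus-strand anchors are mirrored so binding orientation is
preserved, and in strand-resolved mode record strands are swapped
accordingly (motif strand vs opposite strand); opposite-strand values are
stored positive — plotting them negated is a display convention. The
default profile value is read-pooled ($\sum n_{\mathrm{meth}} / \sum
n_{\mathrm{total}}$ per offset); an unweighted per-site mean is available
because aggregation order is a genuine free choice. Offsets with no
informative read stay missing rather than zero-filled; the wavelet step
interpolates them explicitly.

# Wavelet decomposition and the nucleosome-influence metric

The anchored profile mixes a wide V-shaped trend, the ~175 bp oscillation,
a known 8–10 bp fine-scale periodicity, and sampling noise. A
multi-resolution analysis with the Daubechies extremal-phase filter of
length 16 separates these additively. Two implementation choices matter:

* **Maximal-overlap (undecimated) transform.** The decimated DWT is not
  translation-invariant, so extrema located on its detail signal would
  move by up to a filter length when the anchor shifts. The MODWT keeps
  one coefficient per input sample and commutes with translation, which
  the test suite verifies directly.
* **Reflection boundaries.** The profile is extended by its mirror image
  before the circular transform and cropped afterwards, avoiding
  wrap-around artifacts at the window edges.

Detail levels 6–8 (pass-bands of roughly 64–512 bp at 1 bp sampling)
define "nucleosome scale", bracketing the 175 bp repeat while excluding
both the fine-scale periodicity and the trend; the smooth at level 8
carries the V. The decomposition is exact: input = trend + selected
details + residual to $10^{-9}$, and a pure 175 bp sine places over 99% of
its variance in the selected band.

Peaks and valleys are located on the detail signal — the first local
maximum and minimum on each side of the anchor, scanning outward within
1 kb. The amplitude is then read from the *untransformed* profile as the
difference of means over the 10 bp surrounding peak and valley; the short
window averages out the 8–10 bp periodicity while shrinking a 175 bp sine
by under 1%. Missing gaps are linearly interpolated first, with profiles
rejected when any gap exceeds 50 bp (a profile that sparse cannot support
1 bp-scale extrema localisation).

Sidedness is a genuine design opening: we analyse both sides and report
the mean. This has a second virtue: the V-trend contributes $\pm$ (trend
slope $\times$ peak–valley distance) to the two single-side amplitudes
with opposite signs, so the mean of sides cancels the trend contamination
to first order. The period estimate is the mean spacing of successive
detail peaks per side, averaged, and flagged low-confidence when the sides
disagree by more than 20%. *Nucleosome influence* is the mean-of-sides
amplitude with the sign convention linker minus nucleosome (positive when
linkers are more methylated); it uses the methylation signal alone, with
no nucleosome-position input. Absolute influence values on real data have
no published scale to validate against, so tests validate parameter
recovery on synthetic data instead.

# Differential methylation and phase enrichment

Positions present and genotype-clean in both samples are tested on the
2x2 table {meth, unmeth} x {sample 1, sample 2}: Fisher's exact test
(two-sided by probability ordering, the mainstream convention) when any
*expected* cell count is below ten, else Pearson's chi-square with one
degree of freedom and no continuity correction; zero-margin tables return
p = 1, flagged degenerate. Adjustment is Benjamini–Hochberg (the cited
"false discovery rate method"); the significance threshold defaults to
q < 0.05 and is configurable, since no fixed threshold is canonical.

Significant changes are placed into phase bands derived from the
oscillation metrics: band centres extend the located peak (linker) and
valley (nucleosome) periodically at the estimated period $P$, each offset
joins the band of its nearest centre when within $P/4$, and each side of
the anchor uses its own extrema (the oscillation phase runs continuously
through the anchor, so upstream extrema are *not* mirror images of
downstream ones). The bands are disjoint and parameter-free given $P$. The
gain/loss x linker/nucleosome table is tested two-sided with Fisher's
test; the odds ratio uses a Haldane +0.5 correction when a cell is zero.

# The synthetic-data generator

`sim_config()` defines the study conditions; `simulate_annotations()` and
`simulate_sample()` realise them deterministically given the seed.

**Reference sequence.** Bases are i.i.d. uniform except that CG
dinucleotides are removed and re-planted at geometric spacing (mean 30 bp),
giving a controlled density of CG cytosine pairs (~100k CGs on the default
3 Mb genome, enough for ~25 informative CG sites per profile offset across
500 anchors). Both cytosines of a planted CG share one methylation
probability, emulating symmetric maintenance methylation.

**CG landscape.** Flat at `baseline_cg_meth` = 0.7, except within 2 kb of
an occupied CTCF motif where the probability follows

$$p(x) = b - d\,\max\!\left(0, 1 - \tfrac{|x|}{w}\right)
       + A \sin\!\left(\tfrac{2\pi (x - \phi)}{P}\right)$$

with trend depth $d = 0.3$ over half-width $w = 1000$ bp (the V recovers
the genome-wide level within 1–2 kb), period $P = 175$ bp, and phase
$\phi = P/2$ so a methylation valley (nucleosome) sits adjacent to the
motif-proximal dip. The oscillation half-amplitude default $A = 0.05$ is a
free parameter — no absolute amplitude is published — chosen as a clearly
resolvable but far-from-saturating oscillation (peak-to-valley 0.1 on a
0.7 baseline). Constitutive and cell-type-specific (occupied) sites carry
the full signal; "unoccupied" negative-control sites stay at baseline.

**Diffuse mCH.** A fraction `mch_rate_in` = 0.10 of non-CG cytosines
outside LADs (0 inside: complete exclusion) is truly methylated at level
0.25, site selection stratified by trinucleotide context: per-context
counts are drawn from a multinomial over `mch_context_weights` and sites
sampled uniformly within each context, so the realised composition matches
the weights up to multinomial error. Together (~7% of eligible sites
called, mean mCH level ~3%) these define a naive-T-like sample in which
genuine diffuse mCH clearly dominates the conversion-error background.

The weight defaults require a word. The observed quantities of interest —
CA > 90%, CAC ≈ 72% *among called sites* — are compositions of the called
set, which mixes true mCH with conversion-error background calls. At the
default coverage and $e = 0.0025$ the caller's false-call rate is ~0.27%
of eligible sites, i.e. ~3.6% of all calls, and those calls carry the
genomic context distribution (CA ≈ 1/3, CAC severely depleted once most
true-CAC sites are methylated). Setting the true-methylome weights
directly to the observed targets would therefore undershoot after
dilution. The defaults ($w_{CAC} = 0.746$, CA total 0.955) are the
closed-form inversion of that mixing at the default conditions, placing
the *expected called* composition at 72.0% CAC / 93.1% CA. Note also that
the uniform-composition reference genome under-represents CA contexts
relative to a real genome, so emulating a CA-dominated composition
methylates most available CAC sites; the emulated feature is the
composition of calls, not per-context saturation.

**Errors and coverage.** `n_total ~ Poisson(30)` per cytosine and
`n_meth ~ Binomial(n_total, p_obs)` with the observation model above.
Over-conversion defaults to 0.05. Under-conversion defaults to 0.0025
(conversion rate 0.9975): the 0.997 figure associated with this QC is the
*exclusion threshold*, and a sample generated exactly at the threshold
would pass or fail by a coin flip; the default emulates a retained sample,
comfortably but not unrealistically above the bar.

**Annotations, spikes, controls.** LADs cover 1/3 of the genome in a few
large blocks (broken-stick lengths, exact total). Exons are 150 bp;
`spike_exons` renders all non-CG cytosines of chosen exons at a fixed
non-conversion level, giving runs of 10+ elevated cytosines for the spike
detector to recover. Spike-in controls are separate tables
(`methylated_control`, `unmethylated_control`) generated at $p = 1$ and
$p = 0$ with the same coverage and error model, mirroring the
spiked-phage design.

**What the generator does not emulate.** Read-level artifacts (mapping
bias, incomplete trimming), realistic base composition and CpG islands,
genotype error, hydroxymethylation, any chromatin structure beyond the
stated profile shape, and between-sample biological covariance. Passing
recovery tests therefore demonstrates correctness of the estimators under
the stated statistical model, not robustness to every artifact of real
libraries.

# Problem sizes and determinism

The default configuration (3 Mb genome, 500 constitutive + 50 specific +
50 unoccupied anchors, ~1.5 M cytosines, 20k control cytosines per phage)
runs the full simulate-and-analyse path in well under a minute on one
core; the test suite uses this scale for end-to-end recovery and smaller
genomes (130 kb–1.3 Mb) for unit and property tests. All randomness
derives from the config seed (annotations at `seed`, sample at
`seed + 1`), so identical configs reproduce outputs byte for byte.

# Known limitations

* The amplitude estimator reads the observed scale; reporting on the true
  methylation scale would require dividing by $(1 - \mathrm{over} - e)$,
  which is deliberately left to the caller since both rates are sample
  estimates.
* Single-side amplitudes carry first-order trend contamination (cancelled
  in the mean of sides); profiles with strongly asymmetric trends would
  need explicit detrending.
* The period estimator needs at least two detail peaks per side within the
  search window; profiles shorter than ~2.5 periods per side return
  not-found rather than an extrapolated guess.
* `dm_scan()` tests positions independently; regional (DMR) aggregation
  and covariate adjustment are out of scope.
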