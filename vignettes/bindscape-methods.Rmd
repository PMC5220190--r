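---
title: "bindscape: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{bindscape: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: the models and
their assumptions, the tunable constants and where their defaults come from,
what the synthetic generators emulate (and deliberately do not), and the
numerical and design choices that were genuinely open.  It states no
empirical result that the test suite does not itself compute.

# The analysis in one paragraph

A transcription factor's ChIP-Seq peaks ("binding regions") are filtered by
peak height, classified by where they fall relative to genes, and profiled
position-by-position upstream of transcription starts.  The promoter profile
is modelled as a flat non-specific baseline plus two Gaussian binding modes
(proximal and distal).  A nine-state chromatin segmentation stratifies the
profile and splits target genes into state-exclusive lists, which are
compared by GO-term membership.  Finally, a position weight matrix scans the
binding-region fragments for the factor's specific site, asking whether the
sequence signal concentrates in a particular chromatin state.  Every
significance statement uses either a Monte-Carlo track permutation test or an
exact 2x2 test.

# Coordinates and conventions

All internal coordinates are 1-based closed intervals on
`GenomicRanges::GRanges`, the R/Bioconductor convention.  GFF3 (1-based
closed) and BED (0-based half-open) are converted only in the readers and
writers, so no other code ever adjusts an offset.  (An earlier design sketch
used 0-based half-open internals; on a GRanges stack that would mean fighting
the whole ecosystem, so the single-point-of-conversion rationale was kept and
the convention flipped.)

Two offset conventions coexist deliberately, mirroring field usage:

* **Profiles** use 0 = TSS; the default window `[-1500, 100]` holds 1601
  positions.
* **Upstream interval names** use the promoter "+1" convention with no
  offset 0: the seven 500-bp bins are `[-3500; -3000]` ... `[-500; +1]`, and
  the 5'UTR dataset is `[+1; AUG]`.  Internally bin `k` covers offsets
  `-(3500 - 500(k-1)) .. -(3500 - 500k) - 1`; "+1" is the TSS base itself.

"Overlap" always means at least one shared base.  Regions truncated by a
chromosome end are kept if non-empty.  Upstream arithmetic is strand-aware:
for a minus-strand transcript, "-3500" lies at `tss + 3500`.

# Key constants

| constant | default | meaning |
|---|---|---|
| `min_height` | 7 | peak-height cutoff defining binding regions |
| profile window | `[-1500, 100]` | TSS-relative profiling range (bp) |
| linkage window | `[-3500; +1]` | region-to-gene assignment range |
| upstream bins | 7 x 500 bp | permutation-test interval datasets |
| PWM threshold | 0.91 | min-max normalised score cutoff |
| GO robust term | >3%, FDR<0.05 | fraction of list + BH-adjusted enrichment |
| site-density tests | 0.05/8, 0.01/8 | Bonferroni over the eight intervals |
| `n_perm` | 10000 | Monte-Carlo permutations (pipeline default) |

The peak-height filter is stated ambiguously in the source material ("height
at least seven" vs "limited by seven"); it is implemented as `height >=
threshold` with the threshold exposed.

# The permutation test

`permute_track()` re-places every interval uniformly at random on its own
chromosome, preserving lengths, independently of the others.  The literature
this analysis follows cites its permutation scheme without details, so the
simplest defensible null was chosen and isolated behind one function; both
the query and the reference role can be permuted (`permute =` argument,
default query).  GC- or annotation-matched nulls are out of scope.

The statistic is the *fraction of overlap*: shared bases divided by the
permuted track's total (unreduced) length.  `p_empirical = (r + 1) /
(n_perm + 1)` counts the fixed upper (enrichment) tail, `r = #{null >=
observed}`.  This choice makes `p_empirical` exactly uniform under the null
(the property the calibration tests verify) and never zero; the direction
(`enriched` / `depleted` / `neutral` by comparison with the null mean) is
reported separately, and depletion strength is read from `direction` plus
`p_normal`, or as `1 - p_empirical + 1/(n_perm + 1)`.  A direction-adaptive
tail would concentrate on `[0, 0.5]` under the null and was rejected for
that reason.

Finite permutation counts floor the empirical p-value at `1/(n_perm + 1)`;
magnitudes such as 1e-135 can only come from the normal approximation
`p_normal` (tail of the z-score against the permutation moments), which is
reported alongside and agrees with `p_empirical` in order of magnitude away
from the floor.  Two caveats the tests document: the overlap statistic is
integer-valued, so fixtures whose intervals nest exactly (equal widths on a
regular grid) pile probability onto a few atoms and make the conservative
`(r+1)/(n+1)` super-uniform rather than uniform; and `p_normal` is only an
approximation in the far tail.

# The bimodal profile model

The occurrence profile value at offset `x` is the fraction of *genes* (not
transcripts; a position hits a gene if any of its transcripts hits) whose
position `TSS + x` overlaps the track.  The model is

`f(x) = C + A_p * phi(x; m_p, s_p) + A_d * phi(x; m_d, s_d)`

with `phi` the normal *density* (units 1/bp, so the amplitudes `A` carry
units of bp x fraction — worth stating because "Norm" is often written
without units).  `C` is the flat contribution of non-specific binding.

The source analysis fitted its curve "empirically"; this package supplies a
reproducible estimator: multi-start L-BFGS-B least squares (3x3 grid of mean
pairs, two sigma patterns, parameter scaling, a polishing pass), box
constraints `C, A >= 0`, means within the window and `<= 0` by default,
`sigma` in `[5, 5000]`, followed by relabelling so `m_dist < m_prox`, and a
**nested model comparison**: the distal component is kept only if it at
least halves the residual sum of squares relative to the single-Gaussian
fit (`min_improvement = 0.5`).  The nested test resolves two degeneracies a
free 7-parameter fit exhibits: a very wide Gaussian is indistinguishable
from the baseline `C` over a finite window, and a second Gaussian co-located
with the first merely refines its shape (the empirical profile peak is a
Gaussian convolved with the peak-length distribution, so it has heavier
shoulders than a pure Gaussian).  Measured on the package's own generator,
the second component improves RSS by under ~25% when the truth is unimodal
and by over ~95% when a distal mode is really present, so 0.5 separates the
regimes decisively.  The cost is deliberate: genuinely weak distal modes
(RSS gain below 50%) are shrunk to `A_dist = 0`.

Parameter identifiability also depends on the window.  `[-1500, 100]`
truncates a distal mode at `-900` with `sigma = 400` at ~1.5 sigma, leaving
`C`, `A_dist` and `sigma_dist` poorly separated; recovery experiments
therefore fit over `[-2500, 100]`, wide enough to contain the distal mode
plus a baseline plateau.

# Chromatin-state stratification

The per-state profiles are profiles of the track's intersection fragments
with each state's domains, plus a "rest" group defined as the reduced track
minus the profiled states' domains.  Because the groups partition the
track's bases, the per-state profiles sum position-wise to the total profile
*exactly* — the suite asserts equality at 1e-12, not approximately.

Gene lists by state follow the exclusivity rule: a gene (linked to regions
through its `[-3500; +1]` window) enters the "states 1 or 2" list if any of
its regions touches a state-1/2 domain and none touches state 4, and vice
versa; genes qualifying for both lists are dropped from both.  Gene flagging
uses >= 1 bp of region-domain overlap (the source text is ambiguous between
whole-region and fragment-level attribution; the >= 1 bp reading is the
declared interpretation).

# PWM scanning

The position frequency matrix for the EIN3-family site (TEIL motif,
consensus `AYGWAYCT`) ships as a *synthetic reconstruction*: the original
aligned-site counts are in literature not redistributable here, so 20
pseudo-sites split degenerate columns evenly (`teil_pfm()`), and users can
supply real counts via `read_pfm()`.  Weights default to log-odds with
background-proportional pseudocounts,

`w(b, j) = ln[(n(b,j) + p*q_b) / ((N + p) * q_b)]`,

uniform background `q = 0.25`, pseudocount `p = 1`; the weight function is a
plug-in (`weight_fun`) because the exact weighting scheme of the original
model is described elsewhere and was not reproduced.  Scores are min-max
normalised to `[0, 1]` column-wise, and the 0.91 threshold is interpreted on
this normalised scale (a declared assumption).  Scanning slides a width-8
window at step 1, scans both strands by default (the motif is
non-palindromic), counts a position once if either orientation passes, and
excludes windows containing ambiguous bases from both numerator and
denominator.  Densities are hits per scorable position; the pipeline also
reports them normalised by the genome-average density.  A generic
density-versus-threshold calibration curve (`density_threshold_curve()`)
reproduces the procedure used to pick a cutoff against a control set.

# GO comparison

Enrichment against the background universe uses the EASE score — the
one-sided Fisher exact p-value after removing one gene from the
term-positive, in-list cell — which penalises terms supported by very few
genes.  Robust terms per list need > 3% of the list and BH FDR < 0.05; the
union of robust terms is then compared between the two lists with a
two-sided Fisher test, BH-adjusted at FDR < 0.05.  Only direct annotations
are used; there is no GO-graph propagation, and the background universe is
user-supplied (default: all annotated genes) because a web service's
internal background cannot be reproduced exactly.

# The synthetic world

The generators produce a compact plant-like genome: lognormal gene lengths
(mean 2 kb) and intergenic gaps (mean 3 kb), ~1 gene per 5 kb, 80% of
transcripts with a 5'UTR (lognormal, mean 150 bp), GC 0.36, random strands.
The state map emulates the canonical layout — state 1 as a narrow TSS band,
state 2 proximal promoter, state 3 genic, state 4 as distal upstream bands
for 70% of genes, states 5-9 tiling the residual genome — and is a true
partition, which is what makes profile additivity exact.  Peaks mix three
components: uniform genome-wide background (the realisation of `C` —
non-specific binding is genome-wide, not window-limited), and proximal /
distal Gaussian offsets at `-150 +/- 100` and `-900 +/- 400` with weights
0.30 / 0.45 / 0.25.  Peak lengths are lognormal with >95% of mass below
500 bp; heights are geometric, calibrated so `P(height >= 7)` equals a
configured retention (default 0.85).  Motif planting writes consensus-drawn
octamers at Poisson positions per state domain; GO tables draw per-term
membership Bernoulli at configured fractions per gene subset.  Every
generator is a pure function of `(seed, parameters)` and records its truth.

What the synthetic world does *not* emulate — and hence what a green test
does not establish: read-level noise and mapping artifacts (no reads are
simulated), realistic sequence composition beyond i.i.d. GC content,
correlated peak shapes or summit structure, GO-term correlation structure,
and — importantly for the profile model — the generator embeds promoters in
a packed genome, so with realistic 3-kb spacing a gene's upstream window
overlaps its neighbours' promoter peaks.  That contamination is *real*
structure, not an artifact, and it biases naive parameter recovery; the
recovery experiments therefore isolate promoters with 9-kb mean spacing,
trading realism for a controlled test of the estimator.  Conversely,
pipeline-level runs use the realistic spacing and accept that the fitted
distal parameters describe the observable profile, not the planted
generator values.

# Degenerate inputs and tie-breaks

* Empty query track: `overlap_fraction()` raises (the statistic is
  undefined), `occurrence_profile()` returns zeros for an empty *track* but
  raises on an empty *transcript set*.
* Empty 2x2 margins: `fisher_exact()` returns p = 1 with a warning;
  `ease_score(a = 0)` returns 1 by construction.
* `observed == null_mean`: direction is `neutral`; the empirical p still
  counts the upper tail.
* Transcripts with `tss == aug` have no 5'UTR and contribute nothing to the
  eighth upstream dataset.
* Sequences shorter than the motif contribute zero scorable positions;
  0-position scans carry `density = NA` and are excluded from comparisons
  with a note.
* `fit_bimodal` relabels components after optimisation so `m_dist < m_prox`;
  exact ties keep the optimiser's labelling.

# Known limitations

* The permutation null ignores interval spacing and chromatin accessibility;
  enrichment against it conflates "non-random" with "non-uniform".
* `p_normal` extrapolates a normal tail far beyond the permutation support.
* The nested-fit rule cannot detect distal modes that improve RSS by less
  than 50%.
* The EASE/BH pipeline treats terms independently; correlated terms share
  genes and the FDR is nominal, not exact.
* The reconstructed PFM carries consensus information only; scores between
  0 and 1 are coarser than a matrix estimated from real aligned sites.
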