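---
title: "Multi-scale copy-number tracks: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale copy-number tracks: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Clinical assessment of copy-number variation (CNV) from sequencing read
depth needs the same data at several genomic scales at once: a whole-genome
view to read chromosome- and arm-level aneuploidy, an intermediate view for
sub-chromosomal gains and losses, and an exon/bait-level view for focal
events in single genes. It also needs contextual evidence — segmented calls,
structural-variant breakpoints, B-allele frequencies, per-assay blacklists,
per-disease whitelists — displayed alongside the estimates, because
read-depth CNV calling from targeted assays remains false-positive prone.

cnscope implements the data model and the computational core for that
workflow: tab-separated track tables catalogued by one index table, binned
at four display resolutions (1 Mb, 50 kb, 5 kb, bait), a robust
reference-based copy-number estimator, a sample-versus-sample ratio mode,
contextual filters, a synthetic cohort simulator, and a deterministic static
renderer of the classic three-panel view. Interactive browsing is a
non-goal: the `view_spec()` object replaces clicks with a declarative
selection, which keeps the whole artifact headless and byte-for-byte
testable.

## The estimation model

Let $x_i$ be the read count of sample $x$ in bin $i$ after aggregation.
Estimation proceeds **aggregate → scale → GC-correct → estimate**:

1. **Library scaling.** $x$ is scaled by
   $s = \operatorname{median}_i\, m_i / x_i$ over bins where both the
   reference level $m_i$ and $x_i$ are positive. A median of ratios (rather
   than a ratio of totals) keeps large CNVs from dragging the scale.

2. **GC correction.** Bins are grouped into GC strata of width 2%; the
   median count per stratum, smoothed by a running median across strata
   (window 5), gives the bias factor $f(\mathrm{gc})$; corrected counts are
   $x_i \cdot \tilde{m}/f(\mathrm{gc}_i)$ with $\tilde m$ the global median.
   This stratified running-median estimator is a deliberate design choice:
   it is assumption-light, monotone-bias-proof, and isolated behind one
   operation so a local-regression alternative can be swapped in. GC
   correction as implemented is scale-equivariant, so steps 1 and 2 commute;
   the pipeline applies a second (near-unit) scaling pass after correction
   so the sample's level is calibrated to the reference on the corrected
   scale. Factors are estimated per resolution independently, because
   bait-level GC differs from 1 Mb-bin GC and each display scale must be
   self-consistent.

3. **Reference model.** Given a cohort of samples on the same grid, each is
   first normalised to the per-bin cross-sample median in one pass; then
   per bin the reference location is the **median** and the reference SD is
   $1.4826 \times \mathrm{MAD}$ (the Gaussian consistency constant). Robust
   estimators mean tumour samples can sit in the reference set without
   biasing it — the 20-normals-plus-5-tumours test asserts that the
   contaminated reference matches the normals-only reference within 2% at
   ≥99% of bins.

4. **Copy number.** $\mathrm{cn}_i = p \cdot x_i / m_i$ with baseline
   ploidy $p = 2$ (per-chromosome override available, e.g. for sex
   chromosomes), and $\mathrm{sd}_i = p \cdot \hat\sigma_i / m_i$. The
   reported error bar carries **only the sample-side contribution**: it
   ignores the uncertainty of the reference itself and therefore
   *underestimates* the SD of the CN estimate. With enough reference
   samples it is a good lower bound; the acceptance suite checks the
   one-sided property directly (mean reported sd ≤ empirical SD over 50
   replicates). Error bars default to ±1 sd, configurable at the renderer.

5. **Low-coverage floor.** Bins whose reference median falls below
   $\max(10, 1\%\ \text{of the chromosome's median})$ are flagged
   `low_ref` and get missing CN rather than an exploding ratio. Both
   constants are arguments.

**Ratio mode.** With two samples, one becomes the denominator:
$r_i = a_i / b_i$, missing where $b_i$ sits below a floor (0.25 copies for
CN tracks; 10 counts for count tracks, whose denominator is first rescaled
to the numerator). Because any counts-based data scales the same way, the
same operation serves RNA-seq abundance ratios. A reference of $n = 1$
leaves the reference SD undefined (NA) but CN computable, which is exactly
what the two-sample workflows need.

## Binning and re-binning

All aggregation is **linear in overlap width**: an interval's count is
apportioned to bins proportionally to the overlapping width, so totals are
conserved for intervals inside the grid, and every operation is checkable
against a per-base accumulation oracle (the test suite does exactly that,
at 1e-9). Re-binning a value track takes the overlap-weighted mean; the
re-binned sd follows the variance-of-weighted-mean convention
$\mathrm{sd}^2 = \sum w_i\,\mathrm{sd}_i^2 / (\sum w_i)^2$, treating fine
bins as independent estimates (the original system does not state its
rule; this is ours). Bins with zero coverage get an explicit NA gap —
never 0, never interpolated: a clinical display must not invent coverage.
Caller output arrives as SEG (log2 ratios, converted by
$\mathrm{CN} = 2\cdot 2^{\log_2 r}$, 1-based coordinates shifted to the
internal 0-based half-open convention), bedGraph or plain ratio tables.

## Coordinates and formats

Coordinates are 0-based half-open everywhere internally (BED convention);
1-based only at I/O boundaries that demand it (SEG, GTF). Chromosome names
are canonicalised by stripping a leading `chr`, re-added on output by
flag. Track files carry the fixed column set `chrom start end N sd gc
label` with `.` for missing; writers emit LF, 6-significant-digit floats
and integer coordinates, so the same table always produces identical
bytes and `read(write(T)) == T` holds for every kind. The index table
(`sample_id kind resolution path name group`) is the catalogue; more than
one `sample_id` switches multi-sample mode on automatically, and the
`group` column is the non-interactive stand-in for run-time reference-set
selection. URL sources are limited to what base R connections provide
(this build runs offline; no download cache).

## What the simulator emulates — and what it does not

`simulate_cohort()` draws per-bin counts as
$\mathrm{Poisson}\!\left(d \cdot \tfrac{\mathrm{CN_{eff}}}{2} \cdot
e^{\beta(\mathrm{gc}-0.5)}\right)$ with
$\mathrm{CN_{eff}} = 2(1-f) + \mathrm{CN}\cdot f$ for a planted segment of
copy number CN at cellular fraction $f$; $d$ is the mean depth with a 10%
log-normal per-sample wobble, and the GC field is a smooth sinusoid along
each chromosome plus small jitter, clipped to [0.2, 0.8]. Poisson (not
negative-binomial) noise is the default — the simplest model that
exercises every estimator — with an overdispersion knob for FFPE-like
noise. The four presets fix the regimes the tool is used in, with
documented seeds (101–104):

* `germline_exon_del`: targeted panel, 500× per bait, 20 references, one
  clonal single-exon heterozygous deletion;
* `hyperdiploid`: 50 kb genome-wide bins, gains on chromosomes 3, 5, 7, 9,
  11, 15, 19 and 21 plus monosomy 13 and a focal TP53-locus deletion at
  90% cellular fraction (12 references; depth 100/bin — a stated world,
  not a tuned one);
* `ctdna_focal_amp`: targeted panel at 60% tumour fraction with 20- and
  15-copy focal amplifications and a focal TP53 deletion (15 references,
  800×);
* `lowpass_wgs`: ~2× genome coverage (667 × 150 bp reads per 50 kb bin,
  10 references) with one whole-chromosome gain and a focal 8-copy
  amplification on 17q.

Presets use a 24-chromosome hg19-like layout (the hyperdiploid pattern
structurally needs one); the 3×10 Mb toy genome serves the per-base
oracles and fast CI runs. What the simulator does **not** model: mappability
and homology artefacts, bait-to-bait efficiency variation beyond GC,
fragment-length effects, correlated (wavy) noise, and subclonal structure
beyond a single fraction per segment. A green recovery test therefore
establishes correctness of the estimator chain under the stated noise
model — not performance on real FFPE libraries.

## Rendering

The figure is composed as a scene of drawing primitives in pixel
coordinates, then serialised. The SVG writer formats every number with
fixed precision, so identical inputs give byte-identical files (asserted
in the tests); PNG/PDF go through grDevices from the same scene. Values
above the display ceiling (default 6 copies) are drawn as red overflow
triangles at the panel top — the cue to rescale and reveal focal
amplifications — and the triangle count equals the number of over-ceiling
bins in the feature report. Overflow comparison is strict (`>`); a value
exactly at the ceiling displays at the ceiling. Breakpoints draw as
vertical ticks, with an arc for intra-chromosomal pairs inside the panel
and partner-chromosome labels otherwise. Blacklist masking flags bins but
never deletes values (curators must still be able to inspect them);
whitelists filter displayed annotations only, never CN data — our reading
of display filtering as clutter control, not data censoring.

## Numerical choices and degenerate inputs

* MAD consistency constant 1.4826 throughout.
* Median of an even count is the midpoint average (standard); the
  reference oracle in the tests re-implements it by explicit sorting.
* GC strata with fewer than 3 populated levels skip the running-median
  smoothing; bins without GC pass through uncorrected and are reported.
* `bait_grid` merges overlapping and bookended targets; empty layouts,
  intervals past chromosome ends, `start >= end` and non-numeric values
  are errors that name the offender and line.
* Alt/patch contigs are dropped with a logged warning; rows on unknown
  chromosomes are dropped with a counted warning.
* All randomness is seeded through one `with_seed()` wrapper that restores
  the caller's RNG state.

## Known limitations

No segmentation or statistical CNV calling (segments and breakpoints are
consumed as input); no tumour purity/ploidy fitting; no VCF-encoded CNV
ingestion or database-backed index sources; no live client-server
browsing — the HTML export is a static page. The assembly is
unconstrained: fixtures default to an hg19-like layout, but nothing
depends on it.
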