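---
title: "Isolate fingerprinting by interspacer sizing: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isolate fingerprinting by interspacer sizing: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isrtyper)
```

This vignette records the scientific model behind `isrtyper` and the design
decisions that were genuinely open: what the synthetic-data generator
emulates (and does not), the numerical choices in sizing and grouping, and
what a passing test suite does and does not establish about real data.

## The measurement being modelled

A fluorescently end-labelled PCR amplicon spanning the 16S–23S rRNA
interspacer is electrophoresed on a capillary sequencer together with a
23-fragment internal size standard (50–1000 bp) carrying a different dye.
The instrument reports fluorescence per scan for each dye channel.
Migration time is a monotone but nonlinear function of fragment length, so
absolute scan positions mean nothing until they are calibrated against the
co-electrophoresed ladder — which is why every trace carries its own
standard. An isolate's fingerprint is the set of sized amplicons: the
tallest ("major") peak plus any "minor" peaks, which arise from multiple
rRNA operons with different spacer lengths.

## The synthetic-data generator

The generator's parameters are the packaged phylotype panel: 43 phylotypes
with isolate counts in a 192-isolate pilot arm and a 576-isolate main arm
(742 assignable isolates in total), modal major/minor amplicon sizes with
their observed ranges, modal 0–3 acid and H₂O₂ scores, per-phylotype
double-strong counts, and a Gram-morphotype annotation. Defaults are the
study conditions; none of them are tuning knobs.

**Size wobble.** Each peak size is drawn as the phylotype's modal value
with probability $1 - 0.3\,w$ (default wobble scale $w = 1$), otherwise
uniformly over the rest of the stated integer range; $w = 0$ collapses all
sizes to their modes. A plain uniform draw over the range was considered
and rejected: for a two-value range such as 293–294 bp it makes the sample
mode a coin flip, so the generator could not reproduce its own panel's
modal sizes — the central observable of the whole method. The 0.7/0.3
split mirrors the phenotype dispersion model below. Ranges are printed
only where spread was observed; phylotypes without a printed range never
wobble.

**Linked wobble.** For *Gardnerella vaginalis*-like organisms the major
and minor peaks shift together. The panel's marginal minor mode (441 bp)
and the fixed interval reported for individual isolates (15 bp below the
major) are mutually inconsistent — marginal modes of a wobbling pair need
not differ by the per-isolate interval — so the generator treats the
per-isolate interval as authoritative: one major is drawn from the
438–466 bp range and each minor is placed at the fixed interval from it
(`link_interval_bp`, 15 for *G. vaginalis*, −206 for the
*Gemella haemolysans* pair whose two isolates sit 3 bp apart with the
minor above the major).

**Phenotype dispersion.** Only modal scores are known per phylotype, so
each isolate scores the mode with probability 0.7 and otherwise one
adjacent score (equal split, clipped to 0–3); tie-set modes such as "0–1"
first pick one of the two uniformly. This is a stand-in: the real joint
distribution of scores within a phylotype is unknowable from modes alone,
so per-phylotype double-strong counts emerge stochastically and are
checked against the generator's own truth, not against the panel's printed
counts.

**Artifacts.** `inject_artifacts()` marks trace failures and builds
"enrichments" — nominally single isolates containing two strains — by
unioning the full peak set of a second, different phylotype into a
record's minors (its own major stays tallest). One panel phylotype
(*St. piscifermentans*) prints no ISR sizes at all; its single isolate is
generated as a trace failure rather than inventing sizes for it.
`append_unassigned_isolates()` adds isolates whose fingerprints (majors in
the 600–720 bp window, which the panel does not occupy) belong to groups
that are never sequenced, emulating the unidentifiable fraction of a real
collection.

**What is not modelled:** dye-spectral pull-up, stutter/+A artifacts,
size-dependent peak broadening or height decay, plate effects, and any
coupling between phenotype and fingerprint beyond the shared phylotype.
Passing tests therefore demonstrate that the *analysis* is correct under a
clean forward model, not that the defaults would survive a dirty
instrument run.

## Trace synthesis and sizing: numerical choices

- **Mobility curve** `scan = 500 + 40·size^0.9`: strictly monotone and
  mildly nonlinear, so naive linear interpolation between the two
  flanking ladder fragments is measurably wrong and monotone-cubic
  calibration is genuinely exercised. The 50–1000 bp window maps to about
  1.8k–20.6k scans, the scale of a 1.5 h capillary run.
- **Peak shape**: Gaussian, σ = 6 scans; major apex 10 000 a.u., minors
  at 0.35 of the major, ladder peaks 6 000 a.u., additive Gaussian noise
  with s.d. 25 a.u. (clamped at zero). With these defaults the apex
  quantization error on the integer scan grid (~0.5 scan ≈ 0.025 bp at
  300 bp) vanishes under integer rounding, which is what makes the
  noise-free round trip exact.
- **Peak calling**: local maxima above 500 a.u., thinned tallest-first to
  a 12-scan minimum separation; a plateau counts once, at its left edge.
  The implementation is checked against an independent brute-force scan.
- **Calibration**: all 23 ladder fragments are required; with more peaks
  than fragments the tallest 23 are kept, with fewer the trace fails
  closed (mirroring real failed electropherograms). The interpolant is a
  Hyman-filtered monotone cubic spline, exact at every knot; no
  extrapolation — sample peaks outside the knot range are dropped with a
  warning.
- **Rounding**: half away from zero, to integer bp; all reference sizes
  are integers. Percentages throughout use the same rule, which is what
  printed summary tables conventionally use (742/768 → 97%, 22/768 →
  2.9%).
- **Minor threshold**: minors must reach 10% of the major's height. The
  true instrument-software cutoff behind the reference fingerprints is
  unstated; 0.10 is declared, not inferred, and is a visible parameter of
  `size_and_classify()`.

## Grouping: the matching relation

Two fingerprints match when majors agree within ±1 bp and the minor sets
correspond one-to-one within ±2 bp (cardinality must agree; a lenient
subset mode exists but is off by default, because a fingerprint is the
full pattern of peaks present). With `interval_mode` on (the default), a
pair also matches when the single shift that superimposes the majors is at
most 4 bp and then superimposes every minor within ±2 bp — the
linked-wobble case. The shift is deliberately *fixed* to the major
difference rather than searched with extra slack on the major: granting
tolerance twice let phylotypes 6 bp apart (*L.* sp. N6 at 290/[488] vs
*L. coleohominis* at 284/[488–9]) chain into one group, which the
reference grouping keeps apart.

Groups are the single-linkage closure, because the underlying notion is
"shares the peak pattern", not distance to a centroid. The documented risk
is chaining at large tolerances; the group count is provably non-increasing
in the tolerances, and the suite checks this property. Processing order is
canonicalized (ascending isolate id), making the partition and group labels
invariant to input permutation. Consensus fingerprints take per-position
modes with ties broken toward the smaller size.

Even at the defaults some true phylotypes are genuinely unresolvable by
ISR alone: *L.* sp. N6 (289–290/[487–491]) and *L. reuteri* (289/[491])
overlap outright, and wobbled isolates of the two draw identical
signatures. This mirrors the method's real resolution limit and is why
discordance detection exists downstream.

## Propagation and its conservative rules

One representative per group (the lexicographically first member; the
budget is configurable upward, since how many representatives per group a
real study sequences is a design choice) plus every double-strong isolate
is "sequenced": the generator reveals the true label with a percent
identity drawn from 97–100 for described species and 85–96 for novel
groups — only the 97% novelty threshold is load-bearing downstream. The
group's majority sequenced label propagates to unsequenced members. Two
conservative rules are declared rather than inherited: a majority *tie*
yields unidentified (a real analyst would resolve it by eye; an automatic
rule must not guess), and groups whose sequenced members disagree are
flagged discordant wholesale. Coverage bookkeeping therefore partitions
isolates into sequenced / propagated / failed-trace / no-representative /
tied, and the identity `n_seq + n_prop + n_failed + n_no_rep + n_tie =
n_total` is asserted inside `coverage_stats()`.

## Phenotype scoring

`categorize_phenotype()` is total on the 16-cell score grid and is tested
against an exhaustively hand-written truth table. The double-strong set
{2/3, 3/2, 3/3} is the field's categorization, taken as given; note
it excludes 2/2, so double-strong ⊂ double-positive strictly. Gram
morphotype is carried as annotation only and gates nothing. Modal scores
in summaries render adjacent ties as "a–b"; wider ties (possible only in
small groups) render the full set.

## Problem sizes and determinism

The packaged workflows run the 768-isolate study scenario end to end
(census 742 + 4 failed + 22 never-sequenced, 3 mixtures); trace-level
simulations in the tests use the full per-phylotype census counts (108
*L. crispatus*, 68 *G. vaginalis*) and a 1000-fragment sizing-error sweep,
chosen so the whole suite completes in a few minutes on a laptop. All
randomness flows from one integer seed through fixed per-stage offsets;
equal seeds give bitwise-identical records, traces, tables and manifests,
and the pipeline writes the seed into its run manifest.

## Known limitations

- Fingerprint groups are not guaranteed pure even at default tolerances
  (see the N6/*L. reuteri* overlap); strain-level claims need the
  sequenced subset.
- The phenotype dispersion model is a stand-in; joint phenotype counts of
  a real collection cannot be regenerated from modal scores.
- The forward model's noise is additive and white; real capillary traces
  are not, so the 99%-within-1-bp sizing property should be read as a
  statement about the model, not the instrument.
- Percent identities are simulated reveals, not alignments; there is no
  sequence handling anywhere in the package.
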