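---
title: "Summit-based MeDIP-Seq analysis: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Summit-based MeDIP-Seq analysis: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medipscape)
```

## The summit-count model

MeDIP-Seq measures where the methylated fraction of a genome is, not how
methylated any single CpG is. After peak calling, the information we keep
per peak is its summit: one base, optionally with a score. Every statistic
in this package is therefore a point-process statistic:

- **Region density** for bar-plot comparisons:
  $d_C = n_C / A_C$, where $n_C$ counts summits inside the *merged union*
  of the intervals of class $C$ and $A_C$ is that union's area in bp.
  Merging first keeps numerator and denominator on the same measure — a
  summit under two overlapping transcript exons counts once, matching the
  once-counted area beneath it.
- **Profile density** for line plots: per offset bin $b$ of width $w$
  around a set of anchors, $p_b = m_b / N$, where $m_b$ counts
  (summit, anchor) pairs whose strand-oriented offset falls in
  $[bw, (b+1)w)$ and $N$ is the number of anchors. Here multiplicity is
  deliberate: a summit near two TSSs genuinely contributes to both genes'
  profiles, and $N$ in the denominator is the count of anchors, not of
  covered anchors — anchors near a chromosome edge keep truncated windows,
  a mild edge bias we accept to keep the stated normalization exact.

The same two-mode distinction is exposed in the query API
(`count_points_in(..., mode = "unique" | "per_region")`) and tested against
exhaustive scans.

Three-bin splice-event densities (200 bp upstream, body, 200 bp
downstream) pool bins *per event instance* — counts with multiplicity,
areas summed per event — because events are anchors in the profile sense:
two overlapping retained introns are two observations of retention, not
one stretch of genome. Upstream bins truncated by the chromosome start
keep their clipped area.

## Coordinates and orientation

Everything internal is 0-based half-open, the native convention of BED,
genePred/refFlat, cpgIslandExt, rmsk and bedGraph; the GRanges conversion
helpers are the only place ±1 arithmetic happens. Orientation rules:

- TSS: the first transcribed base — `txStart` on `+`, `txEnd − 1` on `−`.
  Using the transcribed base (rather than the half-open bound itself) makes
  profiles exactly invariant under strand flip plus coordinate mirror,
  which the test suite asserts bin-for-bin.
- Promoters: `[TSS − L, TSS)` on `+`, `[txEnd, txEnd + L)` on `−`, clipped
  at position 0; both the 5 kb window and a proximal 2 kb window are always
  derived, since promoter-scale claims differ between the two.
- Terminal exons resolve in transcript orientation (the genomically last
  exon of a `−` transcript is its first), and a terminal exon is *coding*
  iff it intersects `[cdsStart, cdsEnd)` under half-open overlap — an exon
  ending exactly at `cdsStart` is non-coding.

## Key parameters

| parameter | default | role |
|---|---|---|
| `promoter_bp` | 5000 bp | distal promoter window upstream of TSS |
| `proximal_bp` | 2000 bp | proximal promoter window |
| TSS profile | flank 5000 bp, bin 100 bp | metagene resolution |
| junction profile | flank 200 bp, bin 10 bp | exon-boundary resolution |
| `smooth_k` | 5 bins | centered moving average |
| precedence | exon > promoter\_5kb > intron > repeats | exclusive classification |
| CGI criteria | len > 200 bp, GC > 0.5, obs/exp > 0.6 | strict inequalities |
| size bins | 100 bp steps, 200 → ≥1000 | island size classes |
| expression strata | mean ± 1 sample SD of log2 mean intensity | high/low genes |
| `match_bp` | 100 bp | saturation proximity match |

"Sliding window" profiles are implemented as contiguous non-overlapping
bins followed by the moving average: pairing overlapping windows *and* a
moving average would smooth twice. The moving average shrinks its window
symmetrically at the edges (the first of five-point smoothing averages
bins 1–3), so output length equals input length and no invented zeros pull
the profile ends down. Classification precedence puts exon first because
exonic methylation is the contrast of interest and a summit in an exon
that is also another gene's promoter should count as exonic; the order is
an explicit argument everywhere it matters.

Island genomic location uses largest base-pair overlap among exon,
promoter, intron, with ties broken exon > promoter > intron and
non-overlapping islands sent to `others`. Only the category list is
standard; majority overlap is the least surprising rule for islands that
straddle classes.

## The synthetic-data generator

`simulation_config()` defines the study conditions; `simulate_dataset()`
realizes them deterministically from the seed. The genome is a toy: two
chromosomes (6 + 3 Mb), 250 non-overlapping transcripts with 2–8 exons
(log-normal exon/intron lengths), 10% non-coding, and a 25% chance each
that the first/last exon is entirely UTR; 300 CpG islands placed in
promoter/exon/intron/intergenic space; 600 repeat elements in intergenic
space. Placed elements never overlap each other (free-space carving), so
every class has unambiguous ground truth.

Summits follow a two-stage mixture: draw a class with probability
proportional to `weight × area` over a disjoint partition of the genome,
then a uniform position within the class. Expected densities are
closed-form, `n · w_c / Σ_k w_k A_k`, which is what makes parameter
recovery testable with binomial tolerances. Default weights plant the
biology the analyses are designed to detect: exon 5 : promoter 2 :
intron 1, retained-intron bodies at 3 (carved out of the intron class —
the weight order defines the partition, earlier names win overlaps),
AT-rich repeat classes low, satellite high. Because retained introns sit
inside the measured intron class, the *bulk* exon:intron density ratio
under the defaults is ≈3.8, not 5; the 5:1 recovery check therefore runs
with a uniform intron weight, which is the condition it states.

Planted structure and its recovery:

- **TSS dip**: summits within 500 bp of an expressed gene's TSS are kept
  with probability 0.2 (flat thinning). Flat rather than graded keeps the
  expected profile piecewise-constant and the argmin test assumption-free.
- **Island status**: islands drawn unmethylated are excluded from the
  placement universe entirely; methylated islands with no summit after
  placement receive one (relocating an intergenic summit, so the total
  count is preserved). `classify_islands()` must — and does — recover the
  planted status exactly.
- **Expression**: planted high genes *are* the dip-carrying expressed
  genes; separation 2 SD with 0.3 SD replicate noise puts the expected
  stratification sensitivity above 99%.
- **Ct table**: constructed so `enrichment()` returns each planted E
  exactly; this is a construction identity, and is labelled as such in the
  tests.

What the generator does **not** emulate: read-level coverage and fragment
size, CpG-density-dependent MeDIP efficiency, overlapping isoforms,
chromosome-scale domains, and any correlation between repeat class and
genic context (repeats are intergenic only). Passing tests therefore
demonstrate that the *estimators* recover planted structure, not that real
rat liver data would show these effect sizes.

## Numerical choices and degenerate inputs

- Zero-area regions are an error in density calls (no silent 0/0); an
  empty gene list yields a valid empty feature set.
- Fractions are undefined for an empty summit set and raise.
- Zero expression variance yields empty strata, not an error — the
  stratification is well defined, it just selects nobody.
- Concordance with zero variance in either binned vector raises
  (correlation undefined) rather than returning NA.
- Saturation at fraction 1 returns exactly 1 by construction; empty
  subsamples are skipped with a warning.
- The replicate-concordance fixture uses a deliberately peaked intensity
  field: for two independent draws from a shared per-bin mean $\mu_b$,
  expected Pearson r is $\mathrm{var}(\mu)/(\mathrm{var}(\mu)+\bar\mu)$;
  the default weights give ≈0.35 at 1 kb bins, so a meaningful
  high-concordance check needs contrast ≫ noise, and the fixture's weights
  put the expectation near 0.9.

## Problem sizes

Tests run the generator at 2,000–50,000 summits on the 9 Mb toy genome;
oracle-equivalence checks use 100 random fixtures of 1,000 intervals ×
5,000 points; parameter-recovery checks use 100,000 (density ratio) and
50,000 (intron retention) summits, sizes at which the binomial sampling
error is several times smaller than the asserted tolerance bands. These
are the package's chosen reference conditions for a laptop-scale run; all
of them are arguments, not constants.

## Known limitations

- Introns are per-transcript; overlapping isoforms double-represent
  shared intronic bp in profile anchor sets (areas, being merged, are
  safe). Gene-level isoform collapsing is out of scope.
- Promoter windows are fixed-width upstream boxes; no CAGE/TSS-cluster
  refinement.
- Saturation operates on summit events with proximity matching, a
  surrogate for re-calling peaks on reduced read sets; its absolute
  recovery values are not comparable to read-level saturation analyses.
- The CGI validator recomputes GC and CpG obs/exp from a provided
  sequence string but does not fetch genome sequence; de novo island
  detection is out of scope.
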