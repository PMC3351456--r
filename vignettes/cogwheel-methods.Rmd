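---
title: "Methods: set partitioning, the Edwards cogwheel geometry, and dose-response summaries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: set partitioning, the Edwards cogwheel geometry, and dose-response summaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cogwheel)
```

## The problem

Comparative experiments in pharmacology and proteomics routinely produce
more lists than a classical three-circle Venn diagram can hold. The motivating
design is a log dose-response study: one non-stimulated (reference) condition
plus five logarithmically increasing agonist doses, each yielding a list of
phosphoproteins (or enriched GO term groups, or signaling pathways). Six sets
generate $2^6 - 1 = 63$ disjoint intersection regions, and the scientific
questions — which members are unique to a single dose, which are shared
between doses but absent at baseline, how two cellular contexts compare dose
by dose — are all questions about those regions.

`cogwheel` answers them in three layers: exact set partitioning, a validated
planar geometry for display, and dose-response summaries.

## Partitioning

Every member of the union of the $n$ input sets (where $2 \le n \le 6$)
is assigned a membership mask: bit $i-1$ is set iff the member occurs in set
$i$, with set 1 (the first spreadsheet column) as the least significant bit.
The region index is the integer value of the mask, a bijection onto
$1..2^n-1$; the convention is fixed here because the column order of the
export should follow the numerical set order, and a bitmask does that
deterministically. All $2^n - 1$ regions are always materialized, empty ones
as empty lists, so a six-set partition always has exactly 63 keys.

Labels are compared as exact strings after trimming; comparison is
case-sensitive by default (gene symbols are case-meaningful) with an
ignore-case option. Duplicates within a column are collapsed at load and
counted. No fuzzy matching or identifier mapping is attempted.

### The five-colour classification

Relative to a reference set (by default the first column, the non-stimulated
condition), each region receives exactly one code:

| code  | meaning |
|-------|-----------------------------------------------------------|
| GREEN | common to all doses and the reference set (all bits set)  |
| BLUE  | unique to the reference set only                          |
| RED   | unique to one dose, absent from the reference ("dose-unique") |
| GREY  | in two or more doses, absent from the reference           |
| BLACK | in the reference plus some but not all doses              |

One boundary case is genuinely open: a region containing the reference plus
exactly *one* dose is neither "unique" nor "common to multiple doses" under a
literal reading of the scheme. We assign it to BLACK, because such members
are present in the non-stimulated state and not unique to anything — BLACK is
the "also at baseline" bucket. Under this rule the codes tile the signature
space; for $n=6$, reference 1, the census over the 63 signatures is
BLUE 1, RED 5, GREY 26, BLACK 30, GREEN 1 (enumerable by
`classify_region(1:63, 1, 6)`).

## The Edwards cogwheel geometry

A valid Venn diagram for up to six sets can be built by projecting
hemispheres and a tennis-ball-seam curve from a sphere to the plane; on
paper the later curves look like cogwheels with doubling numbers of teeth.
The planar membership predicates used here are:

* set 1: left half of the frame ($x < c_x$),
* set 2: upper half ($y < c_y$; screen convention, $y$ grows downward),
* set 3: the disc $\rho < r$ about the frame centre,
* sets $k \in \{4,5,6\}$: the cogwheel region
  $\rho < r\,(1 + a_k \cos(m_k \theta + \varphi_k))$
  with teeth $m = (2, 4, 8)$ and nested amplitudes
  $a = (0.50, 0.30, 0.17)$.

### Why the phases are zero

The topological requirement is that each new curve crosses the circle once
inside every arc cut by all previous curves, alternating in/out. The zeros of
$\cos(2\theta)$, $\cos(4\theta)$ and $\cos(8\theta)$ are nested dyadic angle
sets that interleave with each other and with the half-plane axes, which is
exactly that requirement — so the default phases are $(0, 0, 0)$, all crests
aligned on the $+x$ axis. Offsetting $\varphi_4$ by $\pi/2$ (an apparently
harmless symmetrization) drops the crossings of the first cogwheel onto the
half-plane axes and destroys the diagram: four of the sixteen four-set
regions vanish. That configuration is kept in the test suite as the
deliberate failure case.

No claim about the geometry is taken on trust. `validate_layout()`
grid-samples the membership signature over the frame (default $10^6$
samples) and reports every realized $n$-bit pattern; a layout is accepted
iff all $2^n$ patterns (including "outside every set") occur. The shipped
defaults pass for every $n$ with a minimum region support of roughly
$9\times10^2$ samples at $n=6$; validation is re-run, not assumed, whenever
the CLI receives geometry overrides. Amplitudes must be strictly decreasing
in $(0,1)$ and teeth must double ($m_5 = 2 m_4$, $m_6 = 2 m_5$); these are
constructor invariants.

Region label anchors are the centroid of the largest 4-connected sample
component of each region (grid default $600\times600$); if a crescent's
centroid falls outside the region the anchor snaps to the nearest region
sample. Every returned anchor is verified to reproduce its region's
signature. Exact visual equivalence to any particular published rendering is
a non-goal; topological validity is the property that is enforced.

Rendering emits SVG 1.1: one closed path per set (half-plane rectangles
clipped to the frame, the circle, cogwheel outlines sampled at $\ge 720$
points), 35% fill opacity, one text element per populated region (counts,
region index, or member text, per display mode), and a `<title>` tooltip per
populated region carrying the full membership — the roll-over analog. Text
mode truncates beyond 12 labels with an ellipsis; the tooltip always has the
full list. Output is byte-deterministic. PNG export rasterizes the layout
directly (per-pixel membership, alpha-composited fills) at
`dpi/96` canvas scaling.

## Dose-response summaries

`dose_unique_profile()` reports, for each dose, the size of its RED region;
each dose's share of the total dose-unique pool as an integer percent
(rounded half-up, since published values are integer percents; raw fractions
are retained in the returned object); and the *stimulated-unique fraction*:
total RED members divided by the number of members found at one or more
doses **but not** in the reference set. That denominator — RED plus GREY
mass — is one reading of "stimulated members excluding those common to the
non-stimulated sample"; because the alternative (counting members that also
occur at baseline, i.e. adding BLACK and GREEN mass) is defensible, the
denominator is isolated behind the `denominator` argument
(`"stimulated_only"` default, `"all_stimulated"` toggle).

`cross_context_compare()` takes two collections with identical condition
name sequences (e.g. control-state and oxidative-stress-state cells) and
reports per condition the two set sizes and their exact string intersection.

## The synthetic generator

`partition_plan()` fixes a per-signature member count; `generate_collection()`
synthesizes fresh sequential labels (`P<seed>_000001`, …) and places each in
exactly the sets named by its signature, returning both the collection and
the exact expected partition. Generation is deterministic given the seed and
label-disjoint across seeds. The generator emulates the *combinatorial*
structure of real list collections — overlap patterns, set sizes, a known
ground truth — and nothing else: no identifier semantics, no
mass-spectrometric noise, no peptide-level evidence. Passing tests therefore
certify the set algebra, IO, geometry and summaries, not any property of
upstream enrichment or identification pipelines.

`dose_response_plan()` builds six-set plans shaped like the dose-response
applications. The RED counts follow the per-dose shares of the chosen
context, and the GREY total is sized so the stimulated-unique fraction comes
out at the context's published value; BLUE/BLACK/GREEN mass (0.4, 0.8 and
0.1 of `scale`, spread uniformly where applicable) is filler that enters
neither percentage. Preset contexts encode the published values: control
phosphoproteins 15/15/21/22/27% with 36% stimulated-unique; oxidative-stress
(CMP) phosphoproteins 7/11/24/27/31% with 38%; GO-term and pathway variants
with the published anchors (control GO 24% at 10 nM; CMP GO 54% at 100 µM
and 4% at 10 nM; control pathways 11% at 10 nM; CMP pathways 0% at 10 nM).
Where a context's remaining shares were never published (e.g. the CMP GO
mid-dose split), they are fixed once at plausible values summing to 100 —
they are scaffolding for the anchored values and are asserted nowhere. The
default `scale = 100` makes every share an exact integer count.

## Numerical and format choices

* **Percent rounding** is half-up (`floor(x + 0.5)`), not banker's rounding,
  matching how integer percentages are conventionally reported.
* **XLSX support** is a minimal, self-contained OOXML layer: cells are
  written as inline strings (numeric-looking identifiers survive verbatim),
  the zip container uses zero timestamps and deterministic deflate streams,
  and reading touches only the first worksheet of a workbook, by workbook
  order. The writer's output is cross-checked against an independent xlsx
  reader in the test suite.
* **Grid resolutions**: 1000×1000 for validation (≈10⁶ samples, comfortably
  resolving the thinnest default regions), 600×600 for anchors; both are
  arguments, and the CLI re-validates any overridden geometry before
  drawing.
* **Degenerate inputs**: empty columns are dropped before counting sets; an
  empty set is allowed inside a valid collection (its bit simply never
  occurs); set counts outside 2–6 are hard errors; an all-empty dose panel
  is an error in profiling.

## Known limitations

* Exactly one reference set; nested or multiple references are out of scope.
* Areas are not proportional to region sizes (by design — an area-
  proportional six-set diagram is not generally realizable).
* Label matching is exact string comparison; synonym or accession mapping
  must happen upstream.
* More than six sets are rejected rather than approximated.
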