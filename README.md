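# cogwheel

Edwards "cogwheel" Venn analysis of two to six named sets.

Comparative list experiments — a log dose-response phosphoproteomics panel,
parallel GO-term or pathway enrichment runs, any study producing up to six
lists of identifiers — need more than the classical three-circle Venn
diagram. `cogwheel` partitions 2–6 named sets of string labels into **all**
`2^n − 1` disjoint intersection regions (63 for six sets), classifies every
region against a reference (non-stimulated) set with a five-colour scheme,
draws a *validated* Edwards cogwheel Venn diagram as SVG (optionally PNG),
exports per-region membership spreadsheets, and computes the dose-response
summaries that make six-condition comparisons readable: dose-unique counts
and proportions, and dose-by-dose cross-context overlap.

## The model in brief

Each member of the union gets an *n*-bit membership mask (bit *i−1* set iff
the member is in set *i*; set 1 = first spreadsheet column = least
significant bit). The mask value is the region index, a bijection onto
`1..2^n−1`. Against a reference set, regions are coloured:

- **GREEN** — common to all doses and the reference (all bits set)
- **BLUE** — unique to the reference only
- **RED** — unique to a single dose, absent from the reference ("dose-unique")
- **GREY** — shared between doses, absent from the reference
- **BLACK** — in the reference plus some but not all doses

For display, sets are realized as two half-planes, a circle, and up to three
cogwheel curves `ρ < r(1 + a_k cos(m_k θ + φ_k))` with doubling teeth
`m = (2, 4, 8)`. The geometry is never assumed correct: `validate_layout()`
grid-samples it and a layout ships only if every one of the `2^n` membership
patterns is realized. See `vignette("cogwheel-methods")`.

## Worked example

```r
library(cogwheel)

cl <- set_collection(list(
  NS   = c("GIT1", "PAK1", "CALM1"),       # non-stimulated reference
  D10  = c("GIT1", "PAK1", "MAP2", "RTN4"),
  D100 = c("PAK1", "GAB2")
))
p <- compute_partition(cl)
p
#> <venn_partition> n = 3 sets, 7 regions (5 non-empty), union size 6
write_summary(p)
#>   region_index   signature size category
#> 1            1          NS    1     BLUE
#> 2            2         D10    2      RED
#> 3            3      NS∩D10    1    BLACK
#> 4            4        D100    1      RED
#> 5            5     NS∩D100    0    BLACK
#> 6            6    D10∩D100    0     GREY
#> 7            7 NS∩D10∩D100    1    GREEN
```

Reading: region 2 holds the two labels found only at the low dose (MAP2,
RTN4 — RED, dose-unique), region 3 the label shared by reference and low
dose (GIT1 — BLACK), region 7 the label common to everything (PAK1 — GREEN).
All 7 = 2³−1 regions are listed, empty ones included.

The synthetic generator plants a known partition; the dose-response presets
reproduce the published study conditions by construction:

```r
fx <- generate_collection(dose_response_plan("control", seed = 1))
dose_unique_profile(compute_partition(fx$collection))
#> <dose_profile> reference: NS
#>   10nM         unique   15  (15% of dose-unique pool)
#>   100nM        unique   15  (15% of dose-unique pool)
#>   1uM          unique   21  (21% of dose-unique pool)
#>   10uM         unique   22  (22% of dose-unique pool)
#>   100uM        unique   27  (27% of dose-unique pool)
#>   dose-unique members: 100 of 278 stimulated (36%, denominator: stimulated_only)
```

Drawing (diagram with counts in every populated region, tooltips with full
membership):

```r
ly <- edwards_layout(6, validate = TRUE)
render_svg(ly, compute_partition(fx$collection), mode = "counts",
           path = "venn.svg")
```

## Command line

A thin Rscript front end is installed at `cli/cogwheel` under the package
library (`system.file("cli", "cogwheel", package = "cogwheel")`):

```sh
cogwheel partition --input sets.xlsx [--no-header] [--ignore-case] [--include-empty] --out DIR
cogwheel draw      --input sets.csv --display {counts,index,text} [--png DPI] [--geometry CFG] --out DIR
cogwheel profile   --input sets.csv [--reference NAME] [--denominator {stimulated,all}] [--compare OTHER] --out DIR
cogwheel fixture   --plan {control,cmp,control_go,cmp_go,control_pathway,cmp_pathway,random} --scale N --seed S --out DIR
```

Input files are CSV/TSV/XLSX with one column per set, first row = set names
(XLSX: first worksheet only). stdout carries only the paths written;
diagnostics go to stderr. Exit codes: 0 success, 2 input format error,
3 unsupported set count, 4 geometry validation failure, 5 mismatched
condition names.

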