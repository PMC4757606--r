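# triweb

Quantitative bi- and tripartite interaction-network diagrams for R —
layout, deterministic rendering, and interchange formats for the kind of
layered food-web figures used in agro-ecology and biological-control
research (pest–predator diet webs, host–parasitoid–hyperparasitoid webs,
pollination networks).

## The problem

A quantitative food web displays three things at once on up to three
trophic levels:

* **taxon abundances** — each taxon on a level is a horizontal bar whose
  width is `abundance × scale` (pixels per abundance unit); a
  resource-only level whose abundances are unknown can instead be shown
  as a row of uniform circles;
* **interaction strengths** — each link between taxa on *adjacent*
  levels becomes either a trapezoid band (both ends proportional to
  strength) or a triangle whose base width `strength × link_scale`
  sits on the **consumer** side and whose apex points at the resource
  taxon (the natural shape for prey-detection frequencies, which do not
  quantify prey individuals);
* **direction** — per level interface, `bottom_up` places the consumer
  (triangle base / band origin) on the lower level, `top_down` on the
  upper one, so a middle level of predators can consume both downward
  (extraguild prey) and upward (intraguild prey).

Link attachments along a bar are packed contiguously and centred; when
the nominal widths exceed the bar (diet fractions can sum past 100 %)
they are compressed by the common factor `bar_width / total` so they
exactly tile the bar. In the fully quantitative one-to-one case — every
consumed individual maps to exactly one consumer individual, so each
taxon's abundance equals its summed link strengths and both levels share
one scale — that rule reproduces exact tiling with no compression,
which is the defining property of such webs. An optional offset scale
bar per level draws a stated number of abundance units for visual
reference.

Everything is deterministic: the same web always yields the same
geometry and byte-identical PNG (via libpng), BMP (24-bit uncompressed,
written by the package) and SVG output, so figures are reproducible and
diffable. No network *analysis* is provided — the companion export to
the [`cheddar`](https://cran.r-project.org/package=cheddar) community
format (nodes / trophic links / properties) exists precisely so analysis
can happen there.

## Worked example

`make_fig2_like()` generates a two-level parasitoid–hyperparasitoid web
with synthetic counts that satisfy the one-to-one property:

```r
library(triweb)

web <- make_fig2_like(1)
web
#> <food_web> 2 levels, 6 taxa, 8 links, canvas 700x420 px
#>   validation: 0 error(s), 0 warning(s)

glance(web)
#> # A tibble: 1 × 7
#>   n_levels n_taxa n_links total_strength connectance n_violations valid
#>      <int>  <int>   <int>          <dbl>       <dbl>        <int> <lgl>
#> 1        2      6       8             54           1            0 TRUE
```

`n_links = 8` counts the realised primary→hyperparasitoid links and
`total_strength = 54` the hyperparasitised individuals; since every
individual is counted once on each level, the level abundances sum to
54 on both sides, which is why the link bands tile every bar exactly.

```r
web    <- assign_auto_colours(web)   # hue-wheel colours for taxa, links
layout <- compute_layout(web)        # pure geometry, y-up coordinates
layout
#> <web_layout> canvas 700x420 px: 6 bars, 0 circles, 8 link polygons, 2 scale bars

writeBin(render(layout, render_options("png")), "parasitoid-web.png")
autoplot(layout)                     # ggplot2 preview of the same geometry
export_cheddar(web, dir = "parasitoid-web-community")
```

The two scale bars are each 40 px wide: 10 individuals at the shared
scale of 4 px per individual. From the shell the same pipeline is:

```sh
Rscript inst/cli/triweb demo --fixture fig2 --out web.png --seed 1
Rscript inst/cli/triweb validate --species species.csv --interactions interactions.csv
Rscript inst/cli/triweb export-cheddar --fixture fig1 --out community/
```

Input tables are semicolon-delimited with `.` decimals: species as
`level;taxon;abundance;colour` (colour an optional `R,G,B` triple) and
interactions as `lower_taxon;upper_taxon;strength`. Whole webs persist
as a versioned JSON project (`save_project()` / `load_project()`) that
round-trips field-for-field.

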