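---
title: "Laying out quantitative layered interaction webs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Laying out quantitative layered interaction webs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triweb)
```

## The model

A web is a layered graph with at most three trophic levels. Level 0 is
the bottom band of the canvas; higher levels stack upward, each a
`bar_height`-tall band, with the leftover vertical space inside the
margins split evenly between the (at most two) level interfaces. Links
may only join taxa on adjacent levels: level-skipping and within-level
interactions are validation errors, because a layered drawing has no
place to put them without ambiguity.

Three display rules carry all the quantitative content:

* **Bars.** A taxon's bar width is `abundance × scale`, with `scale` a
  per-level constant in pixels per abundance unit. Bars run left to
  right in taxon input order, separated by `taxon_spacing` pixels, and
  each level's row is centred on the canvas width. (Centring was an
  open choice — left-alignment and justified distribution are equally
  defensible; centring keeps sparse levels visually balanced over dense
  ones and is what we ship.)
* **Circles.** A level that only ever serves as a resource may be drawn
  as uniform circles (radius `circle_radius`) when abundances are
  unknown; the validator rejects circle mode on any level that acts as
  a consumer side of a gap, since a circle has no width to carry
  quantitative attachments.
* **Link shapes.** A `bar`-shaped link is a four-vertex trapezoid whose
  two horizontal edges are the anchor intervals on the two bars. A
  `triangle` link puts its base (width `strength × link_scale`) on the
  consumer's bar and a single apex on the resource taxon — at the
  resource bar's facing edge centre, or at the circle centre for
  circle-mode levels. The apex rule is our convention; published
  figures of this style show apexes near taxon centres but no source
  states the exact target, and the centre is the only choice that is
  invariant under the resource's own anchor layout.

**Direction** is modelled per interface (gap), not per level: with
three levels there are only two interfaces, and each needs exactly one
direction. `bottom_up` places the consumer on the lower level of the
gap, `top_down` on the upper one. This single switch resolves both the
triangle-base side and the consumer/resource roles in the cheddar
export. It also lets a middle level consume in both gaps — the classic
tripartite arrangement with extraguild prey below a predator level and
intraguild prey above it.

## Anchor packing

All links attached to one side of one bar are ordered by the horizontal
centre of their opposite endpoint (ties broken by link input order) —
a one-pass crossing-reduction heuristic, not an optimiser; global
crossing minimisation is NP-hard and out of scope. Their nominal widths
`strength × link_scale` are then packed contiguously:

* if the total fits inside the bar, the block is centred;
* if it overflows (diet fractions can legitimately sum past 100 %),
  every attachment is compressed by the common factor
  `bar_width / total` so the block exactly tiles the bar.

Consequently the attached width on any bar is
`min(bar_width, Σ strength × link_scale)` — an identity the test suite
asserts to 1e-9 px over random webs — and each attachment's width is
non-decreasing in its own strength. Clipping instead of compressing was
the alternative; compression was chosen because it preserves the
*relative* strengths within the bar, which is what a proportional-diet
figure communicates. In the fully quantitative one-to-one limit (each
taxon's abundance equals its summed incident strengths and `link_scale`
equals the level scale) the compression factor is exactly 1 and the
bands tile every bar with zero gap; this limit is a constructed
invariant of `make_fig2_like()` and an acceptance check.

Degenerate inputs are drawn, not refused: zero-strength links are
dropped from the geometry with a validation warning; zero-abundance
taxa render as zero-width bars (warning), and their attachments
compress to zero width at the bar's position; an all-zero strength set
collapses to zero-width anchors at the bar centre.

## Parameters that matter

| parameter | units | default | why |
|---|---|---|---|
| `scale` (per level) | px / abundance unit | 1 | chosen per figure; the scale-bar value is stated in abundance units so readers can invert it |
| `link_scale` (per gap) | px / strength unit | 1 | equal to the level scale in one-to-one webs; free otherwise |
| `bar_height` | px | 30 | band thickness; purely visual |
| `taxon_spacing` | px | 18 | separation within a level row |
| `margin` | px | 40 | also hosts the scale bar (offset 6 px above its level, height `bar_height / 2`) |
| `circle_radius` | px | 16 | circle-mode marker size |
| `canvas` | px | 900 × 650 | must be large enough that every vertex stays inside; the random-web generator picks scales so each row fills ≤ 90 % of the usable width |

## Colour

The colour model is 24-bit RGB — 256³ = 16,777,216 representable
colours, serialised as `#RRGGBB`. Automatic assignment walks the HSV
hue wheel within each level: the *n* uncoloured taxa get hues `k/n`
turns (input order) at saturation 0.75 and value 0.9, quantised with
`floor(255 · channel)`. Spacing hues per level maximises adjacent
contrast where it matters (bars sitting side by side) and guarantees
pairwise-distinct colours for up to 64 uncoloured taxa per level. Links
inherit their consumer-side endpoint's colour, so a consumer's diet
fans out in its own colour when read against the flow direction.
User-set colours are never overwritten. The assignment is a pure
function of the web; the `seed` argument is accepted for interface
stability only.

## Rendering and determinism

Geometry is computed in y-up real-valued pixel coordinates;
rasterisation flips to image rows and rounds. A pixel is filled iff its
centre lies inside the shape, with half-open `[x0, x1)` intervals so
adjacent shapes tile without double-painting. This makes
integer-coordinate rectangles pixel-exact — a 10 × 10 bar is exactly
100 pixels — which is why antialiasing defaults off; switching it on
renders at double resolution and box-downsamples, trading exactness
for smoother edges in presentation output. The scanline rasteriser is
written in the package because the drawing contract here is
byte-reproducibility: PNG bytes come from `png::writePNG` on the pixel
array, BMP is written directly as uncompressed 24-bit, and SVG is
emitted with a fixed number format — none carries timestamps or
environment-dependent metadata, so re-renders are byte-identical.
Known limitation: the raster formats carry no text (there is no font
rasteriser in the package); taxon and level labels appear in the SVG
output and as label anchors in the geometry, and `autoplot()` draws
them via ggplot2.

## Interchange formats

The import dialects are semicolon-delimited with a fixed header as
format signature and `.` as the only decimal separator; a decimal comma
fails loudly with a hint rather than being locale-guessed, since a
silently mis-parsed abundance is worse than an error. Writers are exact
inverses of readers (numbers are serialised with enough digits to
re-read bit-identically). Projects persist as one versioned JSON
document (`fwd_project_version`), with doubles written at 17
significant digits — the precision at which IEEE-754 values round-trip
exactly. The cheddar export emits the three-document community layout
(nodes with the level label as `category`, abundance as `M`, colour as
hex; trophic links with consumer/resource resolved from each gap's
direction; properties with `title` and `M.units`), which is the form
cheddar's `LoadCommunity()` consumes.

## What the generators emulate — and what they do not

`make_fig1_like()` reproduces the *structure* of a tripartite
carabid-diet study: 5 extraguild prey groups (circles, below), 2
carabid size classes (bars, middle, scale bar worth 20 beetles), 10
intraguild prey taxa (circles, above), triangle links based on the
carabid bars in both gaps (`top_down` below, `bottom_up` above).
`make_fig2_like()` reproduces a quantitative
parasitoid–hyperparasitoid web: two bar levels sharing one scale,
`top_down` trapezoid bands, scale bars worth 10 individuals, and
integer counts constructed so every taxon's abundance equals its summed
link strengths. All abundances and strengths are synthetic draws
(detection proportions uniform on [0.02, 0.98]; counts Poisson with
mean 6; carabid totals uniform on [40, 120]) because the original
studies' tables live outside any source available here; only the
published structure — taxon names and counts, shapes, directions,
scale-bar values — is copied. Passing tests therefore demonstrate the
geometry and format contracts, not agreement with any published
dataset's numbers.

`make_random_web()` draws bar-mode webs only (abundances always
present, `round(connectance × n_lower × n_upper)` links per gap,
uniform strengths). Circle mode is exercised through the structured
fixtures; keeping the random generator bar-only keeps the independent
brute-force oracle's domain crisply specified.

## Verification sizes

The brute-force layout oracle re-derives every coordinate with explicit
loops and is compared vertex-for-vertex at 1e-9 px over 200 random webs
of up to 4 taxa per level; round-trip identities run over 500 random
webs; tiling and rendering determinism run over the structured fixtures
and all three output formats. These sizes make the full suite complete
in about a minute on one core while covering every shape × direction ×
level-count combination many times over.
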