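# Pure geometry. Everything here works in y-up coordinates with level 0 at
# the bottom of the canvas; the renderer flips to image conventions.
# Positions are real-valued pixels; rasterisation rounds, geometry does not.

#' Place abundance-scaled bars along a level
#'
#' Bar `k` gets width `abundance[k] * scale`; bars run left to right in
#' input order, separated by exactly `spacing` pixels, the first starting
#' at `origin_x`. Zero abundances give zero-width bars that still consume
#' their separating space.
#'
#' @param abundances ordered non-negative abundances.
#' @param scale pixels per abundance unit (> 0).
#' @param spacing pixels between consecutive bars (>= 0).
#' @param origin_x left edge of the first bar.
#' @return tibble with columns `start`, `width` (one row per bar).
#' @export
layout_level_bars <- function(abundances, scale, spacing, origin_x = 0) {
  stopifnot(scale > 0, spacing >= 0)
  if (any(abundances < 0)) abort("abundances must be non-negative")
  widths <- abundances * scale
  starts <- origin_x + cumsum(c(0, utils::head(widths, -1) + spacing))
  tibble(start = starts, width = widths)
}

#' Place uniform circles along a level
#'
#' `n` equal circles with centres on the level mid-line `y_mid`,
#' consecutive centres `2 * radius + spacing` apart, the first centre at
#' `origin_x + radius`.
#'
#' @param n number of circles.
#' @param radius circle radius in pixels (> 0).
#' @param spacing pixels between circle edges (>= 0).
#' @param origin_x left edge of the first circle.
#' @param y_mid level mid-line y-coordinate.
#' @return tibble with columns `cx`, `cy`, `r`.
#' @export
layout_level_circles <- function(n, radius, spacing, origin_x = 0, y_mid = 0) {
  stopifnot(radius > 0, spacing >= 0, n >= 0)
  if (n == 0) return(tibble(cx = double(), cy = double(), r = double()))
  cx <- origin_x + radius + (seq_len(n) - 1) * (2 * radius + spacing)
  tibble(cx = cx, cy = y_mid, r = radius)
}

#' Allocate link attachment intervals along a bar
#'
#' Each attachment has nominal width `strength * link_scale`. If the
#' nominal widths fit inside the bar they are packed contiguously and
#' centred; if they overflow, all are compressed by the common factor
#' `bar_width / total` so they exactly tile the bar. Order is preserved
#' and attachments never overlap, so the total attached width is
#' `min(bar_width, sum(strength) * link_scale)`.
#'
#' @param bar_start,bar_width the bar's x-interval (`bar_width >= 0`).
#' @param strengths ordered non-negative link strengths.
#' @param link_scale pixels per strength unit (> 0).
#' @return tibble with columns `start`, `width`, one row per strength.
#' @export
allocate_anchors <- function(bar_start, bar_width, strengths, link_scale) {
  if (bar_width < 0) abort("bar width must be non-negative")
  if (any(strengths < 0)) abort("strengths must be non-negative")
  stopifnot(link_scale > 0)
  widths <- strengths * link_scale
  total <- sum(widths)
  if (total <= bar_width) {
    start0 <- bar_start + (bar_width - total) / 2
  } else {
    widths <- widths * (bar_width / total)
    start0 <- bar_start
  }
  starts <- start0 + cumsum(c(0, utils::head(widths, -1)))
  tibble(start = starts, width = widths)
}

#' Trapezoid band polygon for a bar-shaped link
#'
#' Joins the lower anchor interval at `y_lower` to the upper anchor
#' interval at `y_upper` with a 4-vertex polygon whose two horizontal
#' edges have exactly the anchor widths.
#'
#' @param lower_start,lower_width lower anchor interval.
#' @param upper_start,upper_width upper anchor interval.
#' @param y_lower,y_upper the two level y-coordinates (must differ).
#' @return tibble of 4 vertices (`x`, `y`) in cyclic order.
#' @export
link_polygon_bar <- function(lower_start, lower_width,
                             upper_start, upper_width,
                             y_lower, y_upper) {
  stopifnot(y_lower != y_upper)
  tibble(
    x = c(lower_start, lower_start + lower_width,
          upper_start + upper_width, upper_start),
    y = c(y_lower, y_lower, y_upper, y_upper)
  )
}

#' Triangle polygon for a triangle-shaped link
#'
#' The base interval sits on the consumer side at `y_base`; the apex is a
#' single vertex at `(apex_x, y_apex)` on the opposite (resource) level.
#'
#' @param base_start,base_width base anchor interval.
#' @param y_base consumer-side y-coordinate.
#' @param apex_x,y_apex apex position on the resource level.
#' @return tibble of 3 vertices (`x`, `y`).
#' @export
link_polygon_triangle <- function(base_start, base_width, y_base,
                                  apex_x, y_apex) {
  stopifnot(y_base != y_apex)
  tibble(
    x = c(base_start, base_start + base_width, apex_x),
    y = c(y_base, y_base, y_apex)
  )
}

#' Width of a scale (reference) bar
#'
#' An offset reference bar whose width represents `value_units` abundance
#' units at the level's scale, e.g. the hatched bar representing 20
#' carabid beetles.
#'
#' @param value_units reference value in abundance units (> 0).
#' @param scale pixels per abundance unit (> 0).
#' @return width in pixels.
#' @export
layout_scale_bar <- function(value_units, scale) {
  stopifnot(value_units > 0, scale > 0)
  value_units * scale
}

# Vertical bands: each level is a bar_height-tall band; the leftover
# height inside the margins is split evenly between the gaps.
level_bands <- function(web) {
  s <- web$settings
  n <- nrow(web$levels)
  gap_h <- if (n > 1) {
    (s$canvas_height - 2 * s$margin - n * s$bar_height) / (n - 1)
  } else {
    0
  }
  y_bottom <- s$margin + (web$levels$index) * (s$bar_height + gap_h)
  tibble(
    index = web$levels$index,
    y_bottom = y_bottom,
    y_top = y_bottom + s$bar_height,
    y_mid = y_bottom + s$bar_height / 2
  )
}

# Facing y-coordinate of a level towards a gap: bar levels attach links at
# the band edge nearest the gap; circle levels attach at the mid-line
# (triangle apexes target circle centres).
facing_y <- function(band, mode, side) {
  if (identical(mode, "circles")) return(band$y_mid)
  if (side == "lower") band$y_top else band$y_bottom
}

#' Compute the full layout geometry of a web
#'
#' Orchestrates the geometric primitives: stacks the levels bottom-up,
#' centres each level's row of bars or circles horizontally, allocates
#' link anchor intervals along every bar (ordered by the horizontal
#' centre of the link's opposite endpoint, ties broken by link input
#' order, to reduce crossings), and builds one trapezoid or triangle
#' polygon per positive-strength link according to the gap's shape and
#' direction. Zero-strength links are dropped. The result is
#' renderer-agnostic geometry; the same input always yields the same
#' output.
#'
#' @param web a valid [food_web()].
#' @return an object of class `web_layout`: a list of tibbles `bars`
#'   (`taxon`, `level`, `x`, `y`, `width`, `height`, `colour`), `circles`
#'   (`taxon`, `level`, `cx`, `cy`, `r`, `colour`), `links` (`link`,
#'   `lower`, `upper`, `gap`, `shape`, `colour`, and a `poly` list-column
#'   of vertex tibbles), `scale_bars` (`level`, `x`, `y`, `width`,
#'   `height`), `labels` (`kind`, `ref`, `x`, `y`, `text`), plus the
#'   canvas width/height.
#' @export
compute_layout <- function(web) {
  stop_if_invalid(web)
  s <- web$settings
  bands <- level_bands(web)

  bars <- list()
  circles <- list()
  labels <- list()
  # per-taxon horizontal extent and centre, needed for anchors and apexes
  extent <- tibble(
    id = character(), level = integer(),
    start = double(), width = double(), centre = double()
  )

  for (k in seq_len(nrow(web$levels))) {
    lv <- web$levels[k, ]
    band <- bands[bands$index == lv$index, ]
    tx <- web$taxa[web$taxa$level == lv$index, ]
    if (identical(lv$display_mode, "circles")) {
      n <- nrow(tx)
      row_w <- n * 2 * s$circle_radius + max(n - 1, 0) * s$taxon_spacing
      origin <- (s$canvas_width - row_w) / 2
      cc <- layout_level_circles(n, s$circle_radius, s$taxon_spacing,
                                 origin_x = origin, y_mid = band$y_mid)
      if (n) {
        circles[[length(circles) + 1L]] <- tibble(
          taxon = tx$id, level = lv$index,
          cx = cc$cx, cy = cc$cy, r = cc$r, colour = tx$colour
        )
        extent <- bind_rows(extent, tibble(
          id = tx$id, level = lv$index,
          start = cc$cx - cc$r, width = 2 * cc$r, centre = cc$cx
        ))
        label_y <- if (lv$index == 0) band$y_bottom - 4 else band$y_top + 4
        labels[[length(labels) + 1L]] <- tibble(
          kind = "taxon", ref = tx$id, x = cc$cx, y = label_y, text = tx$name
        )
      }
    } else {
      widths <- tx$abundance * lv$scale
      row_w <- sum(widths) + max(nrow(tx) - 1, 0) * s$taxon_spacing
      origin <- (s$canvas_width - row_w) / 2
      iv <- layout_level_bars(tx$abundance, lv$scale, s$taxon_spacing,
                              origin_x = origin)
      if (nrow(tx)) {
        bars[[length(bars) + 1L]] <- tibble(
          taxon = tx$id, level = lv$index,
          x = iv$start, y = band$y_bottom,
          width = iv$width, height = s$bar_height, colour = tx$colour
        )
        extent <- bind_rows(extent, tibble(
          id = tx$id, level = lv$index,
          start = iv$start, width = iv$width, centre = iv$start + iv$width / 2
        ))
        label_y <- if (lv$index == 0) band$y_bottom - 4 else band$y_top + 4
        labels[[length(labels) + 1L]] <- tibble(
          kind = "taxon", ref = tx$id, x = iv$start + iv$width / 2,
          y = label_y, text = tx$name
        )
      }
    }
    labels[[length(labels) + 1L]] <- tibble(
      kind = "level", ref = as.character(lv$index),
      x = 4, y = band$y_mid, text = lv$label
    )
  }

  ext_start <- stats::setNames(extent$start, extent$id)
  ext_width <- stats::setNames(extent$width, extent$id)
  ext_centre <- stats::setNames(extent$centre, extent$id)
  level_of <- stats::setNames(web$taxa$level, web$taxa$id)

  lk <- web$links
  lk$input <- seq_len(nrow(lk))
  lk <- lk[!is.na(lk$strength) & lk$strength > 0, , drop = FALSE]

  # anchor allocation: for one taxon on one side of one gap, order its
  # incident links by the opposite endpoint's centre (ties: input order)
  # and pack them along the taxon's extent
  anchors_for <- function(ids, own, opp, gap) {
    sub <- lk[lk$gap == gap$lower_level & lk[[own]] != "" , , drop = FALSE]
    out <- vector("list", length(ids))
    names(out) <- ids
    for (id in ids) {
      inc <- sub[sub[[own]] == id, , drop = FALSE]
      if (!nrow(inc)) { out[[id]] <- inc["input"]; next }
      ord <- order(ext_centre[inc[[opp]]], inc$input)
      inc <- inc[ord, , drop = FALSE]
      iv <- allocate_anchors(ext_start[[id]], ext_width[[id]],
                             inc$strength, gap$link_scale)
      out[[id]] <- tibble(input = inc$input, start = iv$start, width = iv$width)
    }
    out
  }

  links_out <- list()
  if (nrow(lk)) {
    lk$gap <- level_of[lk$lower]
    for (k in seq_len(nrow(web$gaps))) {
      gap <- web$gaps[k, ]
      gl <- lk[lk$gap == gap$lower_level, , drop = FALSE]
      if (!nrow(gl)) next
      lo_band <- bands[bands$index == gap$lower_level, ]
      up_band <- bands[bands$index == gap$lower_level + 1L, ]
      lo_mode <- web$levels$display_mode[web$levels$index == gap$lower_level]
      up_mode <- web$levels$display_mode[web$levels$index == gap$lower_level + 1L]
      y_lo <- facing_y(lo_band, lo_mode, "lower")
      y_up <- facing_y(up_band, up_mode, "upper")

      if (identical(gap$shape, "bar")) {
        lo_anchor <- anchors_for(unique(gl$lower), "lower", "upper", gap)
        up_anchor <- anchors_for(unique(gl$upper), "upper", "lower", gap)
        polys <- map(seq_len(nrow(gl)), function(j) {
          l <- gl[j, ]
          a_lo <- lo_anchor[[l$lower]]
          a_up <- up_anchor[[l$upper]]
          a_lo <- a_lo[a_lo$input == l$input, ]
          a_up <- a_up[a_up$input == l$input, ]
          link_polygon_bar(a_lo$start, a_lo$width, a_up$start, a_up$width,
                           y_lo, y_up)
        })
      } else {
        base_is_lower <- gap$direction == "bottom_up"
        own <- if (base_is_lower) "lower" else "upper"
        opp <- if (base_is_lower) "upper" else "lower"
        y_base <- if (base_is_lower) y_lo else y_up
        y_apex <- if (base_is_lower) y_up else y_lo
        base_anchor <- anchors_for(unique(gl[[own]]), own, opp, gap)
        polys <- map(seq_len(nrow(gl)), function(j) {
          l <- gl[j, ]
          a <- base_anchor[[l[[own]]]]
          a <- a[a$input == l$input, ]
          link_polygon_triangle(a$start, a$width, y_base,
                                ext_centre[[l[[opp]]]], y_apex)
        })
      }
      gap_idx <- gap$lower_level
      gap_shape <- gap$shape
      links_out[[length(links_out) + 1L]] <- tibble(
        link = gl$input, lower = gl$lower, upper = gl$upper,
        gap = gap_idx, shape = gap_shape, colour = gl$colour,
        poly = polys
      )
    }
  }

  scale_bars <- list()
  for (k in seq_len(nrow(web$levels))) {
    lv <- web$levels[k, ]
    if (is.na(lv$scale_bar)) next
    band <- bands[bands$index == lv$index, ]
    scale_bars[[length(scale_bars) + 1L]] <- tibble(
      level = lv$index,
      x = s$margin,
      y = band$y_top + 6,
      width = layout_scale_bar(lv$scale_bar, lv$scale),
      height = s$bar_height / 2,
      value = lv$scale_bar
    )
  }

  empty_links <- tibble(
    link = integer(), lower = character(), upper = character(),
    gap = integer(), shape = character(), colour = character(),
    poly = list()
  )
  out <- list(
    bars = if (length(bars)) bind_rows(bars) else
      tibble(taxon = character(), level = integer(), x = double(),
             y = double(), width = double(), height = double(),
             colour = character()),
    circles = if (length(circles)) bind_rows(circles) else
      tibble(taxon = character(), level = integer(), cx = double(),
             cy = double(), r = double(), colour = character()),
    links = if (length(links_out)) bind_rows(links_out) else empty_links,
    scale_bars = if (length(scale_bars)) bind_rows(scale_bars) else
      tibble(level = integer(), x = double(), y = double(),
             width = double(), height = double(), value = double()),
    labels = bind_rows(labels),
    canvas_width = s$canvas_width,
    canvas_height = s$canvas_height
  )
  structure(out, class = "web_layout")
}

#' @export
print.web_layout <- function(x, ...) {
  cat(sprintf(
    "<web_layout> canvas %gx%g px: %d bars, %d circles, %d link polygons, %d scale bars\n",
    x$canvas_width, x$canvas_height,
    nrow(x$bars), nrow(x$circles), nrow(x$links), nrow(x$scale_bars)
  ))
  invisible(x)
}

#' Serialise layout geometry as JSON
#'
#' A renderer-agnostic dump: one typed record per shape (bar, circle,
#' link polygon, scale bar, label) plus the canvas size, for downstream
#' renderers outside R.
#'
#' @param layout a [compute_layout()] result.
#' @return a JSON string.
#' @export
layout_to_json <- function(layout) {
  stopifnot(inherits(layout, "web_layout"))
  links <- layout$links
  link_records <- map(seq_len(nrow(links)), function(k) {
    list(
      type = "link", shape = links$shape[k],
      lower = links$lower[k], upper = links$upper[k],
      colour = links$colour[k],
      x = links$poly[[k]]$x, y = links$poly[[k]]$y
    )
  })
  doc <- list(
    canvas = list(width = layout$canvas_width, height = layout$canvas_height),
    bars = layout$bars,
    circles = layout$circles,
    links = link_records,
    scale_bars = layout$scale_bars,
    labels = layout$labels
  )
  jsonlite::toJSON(doc, dataframe = "rows", auto_unbox = TRUE,
                   digits = I(17), pretty = TRUE)
}
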