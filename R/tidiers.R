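#' Tidy a food web
#'
#' One row per taxon, joined with its level's display settings.
#'
#' @param x a [food_web()].
#' @param ... unused.
#' @return a tibble with columns `id`, `name`, `level`, `level_label`,
#'   `display_mode`, `abundance`, `colour`, `degree` (number of incident
#'   links) and `total_strength` (summed strength of incident links).
#' @method tidy food_web
#' @export
tidy.food_web <- function(x, ...) {
  lk <- x$links
  incident <- function(id) lk$lower == id | lk$upper == id
  x$taxa |>
    left_join(
      x$levels |>
        dplyr::select("index", level_label = "label", "display_mode"),
      by = c(level = "index")
    ) |>
    mutate(
      degree = map_dbl(.data$id, function(i) sum(incident(i))),
      total_strength = map_dbl(.data$id, function(i) {
        sum(lk$strength[incident(i)])
      })
    )
}

#' One-row summary of a food web
#'
#' @param x a [food_web()].
#' @param ... unused.
#' @return a tibble with `n_levels`, `n_taxa`, `n_links`,
#'   `total_strength`, `connectance` (realised fraction of possible
#'   adjacent-level links), `n_violations` and `valid`.
#' @method glance food_web
#' @export
glance.food_web <- function(x, ...) {
  per_level <- table(factor(x$taxa$level, levels = x$levels$index))
  possible <- if (nrow(x$levels) > 1) {
    sum(utils::head(per_level, -1) * utils::tail(per_level, -1))
  } else {
    0
  }
  v <- validate_web(x)
  tibble(
    n_levels = nrow(x$levels),
    n_taxa = nrow(x$taxa),
    n_links = nrow(x$links),
    total_strength = sum(x$links$strength),
    connectance = if (possible > 0) nrow(x$links) / possible else NA_real_,
    n_violations = sum(v$severity == "error"),
    valid = !any(v$severity == "error")
  )
}

#' Tidy layout geometry
#'
#' Unnests every emitted shape into one long vertex table, convenient
#' for plotting or external processing.
#'
#' @param x a `web_layout` from [compute_layout()].
#' @param ... unused.
#' @return a tibble with columns `shape` (`"bar"`, `"circle"`, `"link"`,
#'   `"scale_bar"`), `ref`, `colour`, `part`, `x`, `y`.
#' @method tidy web_layout
#' @export
tidy.web_layout <- function(x, ...) {
  rect_vertices <- function(x0, y0, w, h) {
    tibble(x = c(x0, x0 + w, x0 + w, x0), y = c(y0, y0, y0 + h, y0 + h))
  }
  rows <- list()
  b <- x$bars
  for (k in seq_len(nrow(b))) {
    rows[[length(rows) + 1L]] <- mutate(
      rect_vertices(b$x[k], b$y[k], b$width[k], b$height[k]),
      shape = "bar", ref = b$taxon[k], colour = b$colour[k], part = k
    )
  }
  ci <- x$circles
  for (k in seq_len(nrow(ci))) {
    rows[[length(rows) + 1L]] <- tibble(
      x = ci$cx[k], y = ci$cy[k],
      shape = "circle", ref = ci$taxon[k], colour = ci$colour[k], part = k
    )
  }
  lk <- x$links
  for (k in seq_len(nrow(lk))) {
    rows[[length(rows) + 1L]] <- mutate(
      lk$poly[[k]],
      shape = "link", ref = sprintf("%s->%s", lk$lower[k], lk$upper[k]),
      colour = lk$colour[k], part = k
    )
  }
  sb <- x$scale_bars
  for (k in seq_len(nrow(sb))) {
    rows[[length(rows) + 1L]] <- mutate(
      rect_vertices(sb$x[k], sb$y[k], sb$width[k], sb$height[k]),
      shape = "scale_bar", ref = as.character(sb$level[k]),
      colour = NA_character_, part = k
    )
  }
  out <- bind_rows(rows)
  if (!nrow(out)) {
    return(tibble(shape = character(), ref = character(),
                  colour = character(), part = integer(),
                  x = double(), y = double()))
  }
  dplyr::select(out, "shape", "ref", "colour", "part", "x", "y")
}

circle_poly <- function(cx, cy, r, n = 72) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  tibble(x = cx + r * cos(th), y = cy + r * sin(th))
}

#' Plot layout geometry with ggplot2
#'
#' A presentation-quality preview of the computed geometry: link bands
#' and triangles behind abundance bars and circles, scale bars hatched
#' by outline, taxon and level labels at their anchors.
#'
#' @param object a `web_layout` from [compute_layout()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot web_layout
#' @export
autoplot.web_layout <- function(object, ...) {
  lk <- object$links
  link_df <- bind_rows(map(seq_len(nrow(lk)), function(k) {
    mutate(lk$poly[[k]], part = paste0("link", k), colour = lk$colour[k])
  }))
  bars <- object$bars
  bar_df <- bind_rows(map(seq_len(nrow(bars)), function(k) {
    tibble(
      x = bars$x[k] + c(0, 1, 1, 0) * bars$width[k],
      y = bars$y[k] + c(0, 0, 1, 1) * bars$height[k],
      part = paste0("bar", k), colour = bars$colour[k]
    )
  }))
  ci <- object$circles
  circle_df <- bind_rows(map(seq_len(nrow(ci)), function(k) {
    mutate(circle_poly(ci$cx[k], ci$cy[k], ci$r[k]),
           part = paste0("circle", k), colour = ci$colour[k])
  }))
  sb <- object$scale_bars
  sb_df <- bind_rows(map(seq_len(nrow(sb)), function(k) {
    tibble(
      x = sb$x[k] + c(0, 1, 1, 0) * sb$width[k],
      y = sb$y[k] + c(0, 0, 1, 1) * sb$height[k],
      part = paste0("sb", k)
    )
  }))
  lb <- object$labels

  p <- ggplot2::ggplot()
  if (nrow(link_df)) {
    p <- p + ggplot2::geom_polygon(
      data = link_df,
      ggplot2::aes(.data$x, .data$y, group = .data$part, fill = .data$colour),
      alpha = 0.85
    )
  }
  if (nrow(bar_df)) {
    p <- p + ggplot2::geom_polygon(
      data = bar_df,
      ggplot2::aes(.data$x, .data$y, group = .data$part, fill = .data$colour)
    )
  }
  if (nrow(circle_df)) {
    p <- p + ggplot2::geom_polygon(
      data = circle_df,
      ggplot2::aes(.data$x, .data$y, group = .data$part, fill = .data$colour)
    )
  }
  if (nrow(sb_df)) {
    p <- p + ggplot2::geom_polygon(
      data = sb_df,
      ggplot2::aes(.data$x, .data$y, group = .data$part),
      fill = "white", colour = "black", linewidth = 0.4
    )
  }
  if (nrow(lb)) {
    p <- p + ggplot2::geom_text(
      data = lb,
      ggplot2::aes(.data$x, .data$y, label = .data$text),
      size = 3, vjust = ifelse(lb$kind == "level", 0.5,
                               ifelse(lb$y < object$canvas_height / 2, 1, 0)),
      hjust = ifelse(lb$kind == "level", 0, 0.5)
    )
  }
  p +
    ggplot2::scale_fill_identity() +
    ggplot2::coord_fixed(
      xlim = c(0, object$canvas_width),
      ylim = c(0, object$canvas_height), expand = FALSE
    ) +
    ggplot2::theme_void()
}

#' @rdname autoplot.web_layout
#' @param seed passed to [assign_auto_colours()].
#' @method autoplot food_web
#' @export
autoplot.food_web <- function(object, seed = 1L, ...) {
  autoplot(compute_layout(assign_auto_colours(object, seed)))
}

#' @export
plot.food_web <- function(x, ...) print(autoplot(x, ...))

#' @export
plot.web_layout <- function(x, ...) print(autoplot(x, ...))
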