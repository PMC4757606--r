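# Brute-force reference layout, written independently of the package
# internals: plain base-R loops that enumerate every position from the
# layout rules. Used to cross-check compute_layout vertex-for-vertex on
# small webs.

oracle_layout <- function(web) {
  s <- web$settings
  n <- nrow(web$levels)
  W <- s$canvas_width; H <- s$canvas_height
  bh <- s$bar_height; m <- s$margin; sp <- s$taxon_spacing; cr <- s$circle_radius

  gap_h <- if (n > 1) (H - 2 * m - n * bh) / (n - 1) else 0

  y_bot <- numeric(n); y_top <- numeric(n); y_mid <- numeric(n)
  for (i in 0:(n - 1)) {
    y_bot[i + 1] <- m + i * (bh + gap_h)
    y_top[i + 1] <- y_bot[i + 1] + bh
    y_mid[i + 1] <- y_bot[i + 1] + bh / 2
  }

  bars <- NULL; circles <- NULL
  left <- c(); wid <- c(); centre <- c()   # per taxon id
  for (i in 0:(n - 1)) {
    lvl <- web$levels[web$levels$index == i, ]
    ids <- web$taxa$id[web$taxa$level == i]
    if (lvl$display_mode == "circles") {
      total <- length(ids) * 2 * cr + (length(ids) - 1) * sp
      x <- (W - total) / 2
      for (k in seq_along(ids)) {
        cx <- x + cr
        circles <- rbind(circles, data.frame(
          taxon = ids[k], cx = cx, cy = y_mid[i + 1], r = cr,
          stringsAsFactors = FALSE
        ))
        left[ids[k]] <- cx - cr; wid[ids[k]] <- 2 * cr; centre[ids[k]] <- cx
        x <- x + 2 * cr + sp
      }
    } else {
      ab <- web$taxa$abundance[web$taxa$level == i]
      widths <- ab * lvl$scale
      total <- sum(widths) + (length(ids) - 1) * sp
      x <- (W - total) / 2
      for (k in seq_along(ids)) {
        bars <- rbind(bars, data.frame(
          taxon = ids[k], x = x, y = y_bot[i + 1],
          width = widths[k], height = bh, stringsAsFactors = FALSE
        ))
        left[ids[k]] <- x; wid[ids[k]] <- widths[k]
        centre[ids[k]] <- x + widths[k] / 2
        x <- x + widths[k] + sp
      }
    }
  }

  tx_level <- structure(web$taxa$level, names = web$taxa$id)
  links <- web$links
  links$input <- seq_len(nrow(links))
  links <- links[!is.na(links$strength) & links$strength > 0, , drop = FALSE]

  # anchor intervals for the links incident on taxon `id` on gap `g`
  # (side = "lower"/"upper" column of the links to match on)
  anchor_tbl <- function(id, g, side) {
    opp <- if (side == "lower") "upper" else "lower"
    inc <- links[tx_level[links$lower] == g & links[[side]] == id, , drop = FALSE]
    if (!nrow(inc)) return(NULL)
    key <- order(centre[inc[[opp]]], inc$input)
    inc <- inc[key, , drop = FALSE]
    ls <- web$gaps$link_scale[web$gaps$lower_level == g]
    nominal <- inc$strength * ls
    if (sum(nominal) <= wid[id]) {
      x <- left[id] + (wid[id] - sum(nominal)) / 2
    } else {
      nominal <- nominal * wid[id] / sum(nominal)
      x <- left[id]
    }
    out <- data.frame(input = inc$input, start = NA_real_, width = nominal)
    for (k in seq_len(nrow(out))) {
      out$start[k] <- x
      x <- x + nominal[k]
    }
    out
  }

  facing <- function(level_idx, side) {
    mode <- web$levels$display_mode[web$levels$index == level_idx]
    if (mode == "circles") return(y_mid[level_idx + 1])
    if (side == "lower") y_top[level_idx + 1] else y_bot[level_idx + 1]
  }

  polys <- list()
  for (j in seq_len(nrow(links))) {
    l <- links[j, ]
    g <- tx_level[[l$lower]]
    gap <- web$gaps[web$gaps$lower_level == g, ]
    y_lo <- facing(g, "lower")
    y_up <- facing(g + 1, "upper")
    if (gap$shape == "bar") {
      a_lo <- anchor_tbl(l$lower, g, "lower")
      a_lo <- a_lo[a_lo$input == l$input, ]
      a_up <- anchor_tbl(l$upper, g, "upper")
      a_up <- a_up[a_up$input == l$input, ]
      poly <- data.frame(
        x = c(a_lo$start, a_lo$start + a_lo$width,
              a_up$start + a_up$width, a_up$start),
        y = c(y_lo, y_lo, y_up, y_up)
      )
    } else {
      if (gap$direction == "bottom_up") {
        base_id <- l$lower; base_side <- "lower"
        y_base <- y_lo; apex_id <- l$upper; y_apex <- y_up
      } else {
        base_id <- l$upper; base_side <- "upper"
        y_base <- y_up; apex_id <- l$lower; y_apex <- y_lo
      }
      a <- anchor_tbl(base_id, g, base_side)
      a <- a[a$input == l$input, ]
      poly <- data.frame(
        x = c(a$start, a$start + a$width, centre[[apex_id]]),
        y = c(y_base, y_base, y_apex)
      )
    }
    polys[[as.character(l$input)]] <- poly
  }

  scale_bars <- NULL
  for (i in 0:(n - 1)) {
    lvl <- web$levels[web$levels$index == i, ]
    if (is.na(lvl$scale_bar)) next
    scale_bars <- rbind(scale_bars, data.frame(
      level = i, x = m, y = y_top[i + 1] + 6,
      width = lvl$scale_bar * lvl$scale, height = bh / 2
    ))
  }

  list(bars = bars, circles = circles, links = polys, scale_bars = scale_bars)
}

# vertex-for-vertex comparison of compute_layout against the oracle;
# returns the largest absolute coordinate deviation
layout_deviation <- function(web) {
  got <- compute_layout(web)
  ref <- oracle_layout(web)
  dev <- 0
  note <- function(a, b) max(dev, max(abs(a - b), 0))

  if (!is.null(ref$bars)) {
    stopifnot(nrow(got$bars) == nrow(ref$bars),
              all(got$bars$taxon == ref$bars$taxon))
    for (col in c("x", "y", "width", "height")) {
      dev <- note(got$bars[[col]], ref$bars[[col]])
    }
  } else {
    stopifnot(nrow(got$bars) == 0)
  }
  if (!is.null(ref$circles)) {
    stopifnot(nrow(got$circles) == nrow(ref$circles),
              all(got$circles$taxon == ref$circles$taxon))
    for (col in c("cx", "cy", "r")) {
      dev <- note(got$circles[[col]], ref$circles[[col]])
    }
  } else {
    stopifnot(nrow(got$circles) == 0)
  }
  stopifnot(nrow(got$links) == length(ref$links))
  for (k in seq_len(nrow(got$links))) {
    ref_poly <- ref$links[[as.character(got$links$link[k])]]
    got_poly <- got$links$poly[[k]]
    stopifnot(nrow(got_poly) == nrow(ref_poly))
    dev <- note(got_poly$x, ref_poly$x)
    dev <- note(got_poly$y, ref_poly$y)
  }
  if (!is.null(ref$scale_bars)) {
    stopifnot(nrow(got$scale_bars) == nrow(ref$scale_bars))
    for (col in c("x", "y", "width", "height")) {
      dev <- note(got$scale_bars[[col]], ref$scale_bars[[col]])
    }
  } else {
    stopifnot(nrow(got$scale_bars) == 0)
  }
  dev
}
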