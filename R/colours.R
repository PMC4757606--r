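# Colour helpers: 24-bit RGB triples serialised as "#RRGGBB" strings.

#' Convert an RGB triple to a hex colour string
#'
#' @param r,g,b integer channels in 0--255; `r` may also be a length-3
#'   vector holding all three channels.
#' @return `#RRGGBB` string (upper case).
#' @export
rgb_to_hex <- function(r, g = NULL, b = NULL) {
  if (is.null(g)) {
    stopifnot(length(r) == 3)
    b <- r[[3]]; g <- r[[2]]; r <- r[[1]]
  }
  ch <- as.integer(c(r, g, b))
  if (any(is.na(ch)) || any(ch < 0L) || any(ch > 255L)) {
    abort("each RGB channel must be an integer in 0..255")
  }
  sprintf("#%02X%02X%02X", ch[1], ch[2], ch[3])
}

#' Convert a hex colour string to an RGB triple
#'
#' @param hex `#RRGGBB` string.
#' @return integer vector of length 3 (red, green, blue in 0--255).
#' @export
hex_to_rgb <- function(hex) {
  if (length(hex) != 1 || !is_hex_colour(hex)) {
    abort(sprintf("'%s' is not a #RRGGBB colour", paste(hex, collapse = ",")))
  }
  as.integer(strtoi(substring(hex, c(2, 4, 6), c(3, 5, 7)), base = 16L))
}

# HSV -> 24-bit RGB with floor quantisation: channel = floor(255 * value).
# hue in turns [0, 1), saturation and value in [0, 1].
hsv_to_rgb255 <- function(hue, saturation, value) {
  h6 <- (hue %% 1) * 6
  i <- floor(h6)
  f <- h6 - i
  p <- value * (1 - saturation)
  q <- value * (1 - saturation * f)
  t <- value * (1 - saturation * (1 - f))
  rgb01 <- switch(as.character(i %% 6),
    "0" = c(value, t, p),
    "1" = c(q, value, p),
    "2" = c(p, value, t),
    "3" = c(p, q, value),
    "4" = c(t, p, value),
    "5" = c(value, p, t)
  )
  pmin(as.integer(floor(255 * rgb01)), 255L)
}

# Evenly spaced hue-wheel palette: n hues at k/n turns, fixed S and V.
auto_palette <- function(n, saturation = 0.75, value = 0.9) {
  if (n == 0) return(character())
  map_chr(seq_len(n) - 1L, function(k) {
    rgb_to_hex(hsv_to_rgb255(k / n, saturation, value))
  })
}

#' Fill in missing taxon and link colours
#'
#' Every taxon without a colour receives one from a hue wheel: the `n`
#' uncoloured taxa of a level get hues `k/n` turns (k in input order) at
#' saturation 0.75 and value 0.9, converted to 24-bit RGB. Hues are
#' maximally spaced within each level, so up to 64 uncoloured taxa per
#' level are guaranteed pairwise-distinct colours. Links without a
#' colour inherit the colour of their consumer-side endpoint: the lower
#' taxon in a `bottom_up` gap, the upper taxon in a `top_down` gap.
#' User-supplied colours are never overwritten.
#'
#' @param web a valid [food_web()].
#' @param seed integer; accepted for interface stability. The assignment
#'   is a deterministic function of the web alone, so the seed does not
#'   change the result.
#' @return the web with every `colour` field filled.
#' @export
assign_auto_colours <- function(web, seed = 1L) {
  stop_if_invalid(web)
  tx <- web$taxa
  for (lvl in web$levels$index) {
    sel <- which(tx$level == lvl & !is_hex_colour(tx$colour))
    tx$colour[sel] <- auto_palette(length(sel))
  }
  lk <- web$links
  if (nrow(lk)) {
    level_of <- stats::setNames(tx$level, tx$id)
    colour_of <- stats::setNames(tx$colour, tx$id)
    for (k in which(!is_hex_colour(lk$colour))) {
      gap <- web$gaps[web$gaps$lower_level == level_of[[lk$lower[k]]], ]
      donor <- if (gap$direction == "bottom_up") lk$lower[k] else lk$upper[k]
      lk$colour[k] <- colour_of[[donor]]
    }
  }
  web$taxa <- tx
  web$links <- lk
  web
}

#' Is every taxon and link coloured?
#'
#' @param web a [food_web()].
#' @return `TRUE` if no `colour` field is missing.
#' @export
is_fully_coloured <- function(web) {
  all(is_hex_colour(web$taxa$colour)) && all(is_hex_colour(web$links$colour))
}
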