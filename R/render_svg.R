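# SVG 1.1 output: one shape element per geometry item, plus text
# elements for the label anchors. Numbers are formatted with a fixed
# locale-independent rule so the byte stream is deterministic.

svg_num <- function(x) {
  s <- sprintf("%.4f", x)
  s <- sub("0+$", "", s)
  sub("\\.$", "", s)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

render_svg <- function(layout, options) {
  w <- layout$canvas_width
  h <- layout$canvas_height
  flip <- function(y) h - y
  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(
      '<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="%s" height="%s" viewBox="0 0 %s %s">',
      svg_num(w), svg_num(h), svg_num(w), svg_num(h)
    ),
    "<defs>",
    '<pattern id="hatch" width="4" height="4" patternTransform="rotate(45)" patternUnits="userSpaceOnUse"><rect width="4" height="4" fill="#FFFFFF"/><rect width="1" height="4" fill="#000000"/></pattern>',
    "</defs>",
    sprintf('<rect x="0" y="0" width="%s" height="%s" fill="%s"/>',
            svg_num(w), svg_num(h), options$background)
  )

  lk <- layout$links
  for (k in seq_len(nrow(lk))) {
    p <- lk$poly[[k]]
    pts <- paste(sprintf("%s,%s", svg_num(p$x), svg_num(flip(p$y))),
                 collapse = " ")
    out <- c(out, sprintf('<polygon points="%s" fill="%s" fill-opacity="0.85"/>',
                          pts, lk$colour[k]))
  }
  b <- layout$bars
  for (k in seq_len(nrow(b))) {
    out <- c(out, sprintf(
      '<rect x="%s" y="%s" width="%s" height="%s" fill="%s"/>',
      svg_num(b$x[k]), svg_num(flip(b$y[k] + b$height[k])),
      svg_num(b$width[k]), svg_num(b$height[k]), b$colour[k]
    ))
  }
  ci <- layout$circles
  for (k in seq_len(nrow(ci))) {
    out <- c(out, sprintf(
      '<circle cx="%s" cy="%s" r="%s" fill="%s"/>',
      svg_num(ci$cx[k]), svg_num(flip(ci$cy[k])), svg_num(ci$r[k]),
      ci$colour[k]
    ))
  }
  sb <- layout$scale_bars
  for (k in seq_len(nrow(sb))) {
    out <- c(out, sprintf(
      '<rect x="%s" y="%s" width="%s" height="%s" fill="url(#hatch)" stroke="#000000" stroke-width="1"/>',
      svg_num(sb$x[k]), svg_num(flip(sb$y[k] + sb$height[k])),
      svg_num(sb$width[k]), svg_num(sb$height[k])
    ))
  }
  lb <- layout$labels
  for (k in seq_len(nrow(lb))) {
    anchor <- if (lb$kind[k] == "level") "start" else "middle"
    out <- c(out, sprintf(
      '<text x="%s" y="%s" font-size="%s" font-family="sans-serif" text-anchor="%s">%s</text>',
      svg_num(lb$x[k]), svg_num(flip(lb$y[k])), svg_num(options$font_size),
      anchor, xml_escape(lb$text[k])
    ))
  }
  paste0(paste(c(out, "</svg>"), collapse = "\n"), "\n")
}
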