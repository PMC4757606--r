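# Rasterisation. The geometry arrives in y-up coordinates; the raster is
# row-major with row 1 at the top, so y flips here. A pixel in image row
# r, column c has its centre at (c - 0.5, H - r + 0.5) in geometry
# coordinates. With antialiasing off a pixel is filled iff its centre
# lies inside the shape, which makes integer-coordinate rectangles
# pixel-exact: a w x h bar covers exactly w*h pixel centres.
#
# Shapes are painted by computing linear index vectors into h x w
# channel matrices; all assignments happen in render_raster's own frame
# so the matrices are modified in place.

# columns whose centres fall inside [x0, x1) ... half-open so adjacent
# shapes tile without gaps or double-painting
cols_in <- function(x0, x1, width) {
  lo <- max(1L, as.integer(ceiling(x0 + 0.5)))
  hi <- min(width, as.integer(floor(x1 + 0.5)))
  if (hi < lo) integer() else lo:hi
}

rows_in <- function(y0, y1, height) {
  # geometry interval [y0, y1) -> image rows; row r centre at H - r + 0.5
  lo <- max(1L, as.integer(ceiling(height - y1 + 0.5)))
  hi <- min(height, as.integer(floor(height - y0 + 0.5)))
  if (hi < lo) integer() else lo:hi
}

lin_idx <- function(rows, cols, height) {
  if (!length(rows) || !length(cols)) return(integer())
  as.vector(outer(rows, (cols - 1L) * height, `+`))
}

rect_indices <- function(x, y, w, h, W, H) {
  lin_idx(rows_in(y, y + h, H), cols_in(x, x + w, W), H)
}

circle_indices <- function(cx, cy, r, W, H) {
  rows <- rows_in(cy - r, cy + r, H)
  idx <- vector("list", length(rows))
  for (k in seq_along(rows)) {
    py <- H - rows[k] + 0.5
    half <- sqrt(max(r^2 - (py - cy)^2, 0))
    idx[[k]] <- lin_idx(rows[k], cols_in(cx - half, cx + half, W), H)
  }
  unlist(idx)
}

# even-odd scanline fill; open polygons are closed implicitly
polygon_indices <- function(xs, ys, W, H) {
  x1 <- xs; y1 <- ys
  x2 <- c(xs[-1], xs[1]); y2 <- c(ys[-1], ys[1])
  rows <- rows_in(min(ys), max(ys), H)
  idx <- vector("list", length(rows))
  for (k in seq_along(rows)) {
    py <- H - rows[k] + 0.5
    crossing <- (y1 <= py & y2 > py) | (y2 <= py & y1 > py)
    if (!any(crossing)) next
    t <- (py - y1[crossing]) / (y2[crossing] - y1[crossing])
    px <- sort(x1[crossing] + t * (x2[crossing] - x1[crossing]))
    spans <- vector("list", length(px) %/% 2)
    for (j in seq_along(spans)) {
      spans[[j]] <- cols_in(px[2 * j - 1], px[2 * j], W)
    }
    idx[[k]] <- lin_idx(rows[k], unlist(spans), H)
  }
  unlist(idx)
}

# scale bar decoration: 1-px black outline plus 45-degree hatch stripes
# with a 4-px period (cosmetic)
scale_bar_dark_indices <- function(x, y, w, h, W, H) {
  rows <- rows_in(y, y + h, H)
  cols <- cols_in(x, x + w, W)
  idx <- vector("list", length(rows))
  for (k in seq_along(rows)) {
    py <- H - rows[k] + 0.5
    px <- cols - 0.5
    on_border <- (py - y < 1) | (y + h - py < 1) |
      (px - x < 1) | (x + w - px < 1)
    on_hatch <- ((floor(px) + floor(py)) %% 4) < 1
    idx[[k]] <- lin_idx(rows[k], cols[on_border | on_hatch], H)
  }
  unlist(idx)
}

render_raster <- function(layout, options) {
  ss <- if (isTRUE(options$antialias)) 2L else 1L
  W <- as.integer(round(layout$canvas_width)) * ss
  H <- as.integer(round(layout$canvas_height)) * ss
  bg <- hex_to_rgb(options$background) / 255
  red <- matrix(bg[1], H, W)
  green <- matrix(bg[2], H, W)
  blue <- matrix(bg[3], H, W)
  put <- function(idx, hex) {
    rgb <- hex_to_rgb(hex) / 255
    red[idx] <<- rgb[1]
    green[idx] <<- rgb[2]
    blue[idx] <<- rgb[3]
  }

  lk <- layout$links
  for (k in seq_len(nrow(lk))) {
    p <- lk$poly[[k]]
    put(polygon_indices(p$x * ss, p$y * ss, W, H), lk$colour[k])
  }
  b <- layout$bars
  for (k in seq_len(nrow(b))) {
    put(rect_indices(b$x[k] * ss, b$y[k] * ss, b$width[k] * ss,
                     b$height[k] * ss, W, H), b$colour[k])
  }
  ci <- layout$circles
  for (k in seq_len(nrow(ci))) {
    put(circle_indices(ci$cx[k] * ss, ci$cy[k] * ss, ci$r[k] * ss, W, H),
        ci$colour[k])
  }
  sb <- layout$scale_bars
  for (k in seq_len(nrow(sb))) {
    put(rect_indices(sb$x[k] * ss, sb$y[k] * ss, sb$width[k] * ss,
                     sb$height[k] * ss, W, H), "#FFFFFF")
    put(scale_bar_dark_indices(sb$x[k] * ss, sb$y[k] * ss, sb$width[k] * ss,
                               sb$height[k] * ss, W, H), "#000000")
  }

  raster <- array(c(red, green, blue), dim = c(H, W, 3))
  if (ss > 1L) raster <- downsample2(raster)
  raster
}

downsample2 <- function(raster) {
  d <- dim(raster)
  h <- d[1] %/% 2L; w <- d[2] %/% 2L
  out <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) {
    m <- raster[, , ch]
    out[, , ch] <- (m[seq(1, 2 * h, 2), seq(1, 2 * w, 2)] +
                    m[seq(2, 2 * h, 2), seq(1, 2 * w, 2)] +
                    m[seq(1, 2 * h, 2), seq(2, 2 * w, 2)] +
                    m[seq(2, 2 * h, 2), seq(2, 2 * w, 2)]) / 4
  }
  out
}

# 24-bit uncompressed BMP (BITMAPINFOHEADER, bottom-up rows, BGR order,
# rows padded to 4-byte boundaries); no metadata, so output is a pure
# function of the pixels
encode_bmp <- function(raster) {
  d <- dim(raster)
  h <- d[1]; w <- d[2]
  row_bytes <- w * 3L
  pad <- (4L - row_bytes %% 4L) %% 4L
  img_size <- (row_bytes + pad) * h
  file_size <- 54L + img_size

  px <- round(raster * 255)
  # interleave channels as BGR within each row, rows bottom-up
  bgr <- array(0L, dim = c(3L, w, h))
  for (row in seq_len(h)) {
    bgr[1, , h - row + 1L] <- px[row, , 3]
    bgr[2, , h - row + 1L] <- px[row, , 2]
    bgr[3, , h - row + 1L] <- px[row, , 1]
  }
  if (pad == 0L) {
    body <- as.raw(as.vector(bgr))
  } else {
    rows_raw <- matrix(as.raw(0), nrow = row_bytes + pad, ncol = h)
    rows_raw[seq_len(row_bytes), ] <- as.raw(as.vector(bgr))
    body <- as.vector(rows_raw)
  }

  u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")
  header <- c(
    charToRaw("BM"), u32(file_size), u32(0), u32(54),
    u32(40), u32(w), u32(h), u16(1), u16(24), u32(0), u32(img_size),
    u32(2835), u32(2835), u32(0), u32(0)
  )
  c(header, body)
}
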