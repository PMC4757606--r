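#' Rendering options
#'
#' @param format one of `"png"`, `"bmp"`, `"svg"`.
#' @param background background colour as `#RRGGBB`.
#' @param antialias logical; when `TRUE` the raster formats are rendered
#'   at double resolution and box-downsampled. Off by default so shapes
#'   are pixel-exact.
#' @param font_size label font size in points (SVG output only; the
#'   raster formats carry no text).
#' @return a list of class `render_options`.
#' @export
render_options <- function(format = "png", background = "#FFFFFF",
                           antialias = FALSE, font_size = 11) {
  check_format(format)
  structure(
    list(format = format, background = toupper(background),
         antialias = isTRUE(antialias), font_size = font_size),
    class = "render_options"
  )
}

SUPPORTED_FORMATS <- c("png", "bmp", "svg")

check_format <- function(format) {
  if (!is.character(format) || length(format) != 1 ||
      !format %in% SUPPORTED_FORMATS) {
    abort(sprintf(
      "unsupported format '%s'; supported formats are %s",
      paste(format, collapse = ","), paste(SUPPORTED_FORMATS, collapse = ", ")
    ))
  }
  invisible(format)
}

#' Render layout geometry to image bytes
#'
#' Serialises a [compute_layout()] result to PNG, BMP (24-bit
#' uncompressed) or SVG 1.1. Output is deterministic: the bytes are a
#' pure function of the geometry and options, with no timestamps or
#' environment-dependent metadata, so repeated renders are
#' byte-identical. Link polygons are painted first, then bars and
#' circles, then scale bars. The image dimensions equal the web's
#' canvas.
#'
#' @param geometry a `web_layout` from [compute_layout()]; every shape
#'   must carry a colour (build the layout from an
#'   [assign_auto_colours()]ed web).
#' @param options a [render_options()].
#' @return raw vector of file bytes.
#' @export
render <- function(geometry, options = render_options()) {
  stopifnot(inherits(geometry, "web_layout"))
  if (!inherits(options, "render_options")) {
    abort("options must be created with render_options()")
  }
  missing_col <- c(
    geometry$bars$colour[!is_hex_colour(geometry$bars$colour)],
    geometry$circles$colour[!is_hex_colour(geometry$circles$colour)],
    geometry$links$colour[!is_hex_colour(geometry$links$colour)]
  )
  if (length(missing_col)) {
    abort("geometry has uncoloured shapes; run assign_auto_colours() on the web first")
  }
  switch(options$format,
    png = png::writePNG(render_raster(geometry, options)),
    bmp = encode_bmp(render_raster(geometry, options)),
    svg = charToRaw(render_svg(geometry, options))
  )
}

#' Render a web straight to image bytes
#'
#' Convenience wrapper: auto-colours any missing colours, computes the
#' layout and renders it.
#'
#' @param web a valid [food_web()].
#' @param options a [render_options()].
#' @param seed passed to [assign_auto_colours()].
#' @return raw vector of file bytes.
#' @export
render_web <- function(web, options = render_options(), seed = 1L) {
  web <- assign_auto_colours(web, seed)
  render(compute_layout(web), options)
}

#' Write a rendered web to a file
#'
#' @param web a valid [food_web()].
#' @param path output file path.
#' @param format image format; defaults to the lower-cased file
#'   extension of `path`.
#' @param ... passed to [render_options()].
#' @param seed passed to [assign_auto_colours()].
#' @return `path`, invisibly.
#' @export
write_web_image <- function(web, path,
                            format = tolower(tools::file_ext(path)),
                            ..., seed = 1L) {
  bytes <- render_web(web, render_options(format = format, ...), seed = seed)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(bytes, con)
  invisible(path)
}
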