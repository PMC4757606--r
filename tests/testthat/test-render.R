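test_that("an empty canvas renders to an all-background image of exact size", {
  lay <- bare_layout(100, 50)
  bytes <- render(lay, render_options("png", background = "#FFFFFF"))
  img <- png::readPNG(bytes)
  expect_identical(dim(img)[1:2], c(50L, 100L))
  expect_true(all(img == 1))
})

test_that("a 10x10 bar at integer coordinates covers exactly 100 pixels", {
  bar <- tibble::tibble(
    taxon = "t", level = 0L, x = 20, y = 15, width = 10, height = 10,
    colour = "#FF0000"
  )
  lay <- bare_layout(100, 50, bars = bar)
  for (fmt in c("png", "bmp")) {
    bytes <- render(lay, render_options(fmt, antialias = FALSE))
    img <- if (fmt == "png") png::readPNG(bytes) else decode_bmp(bytes)
    expect_identical(count_colour_pixels(img, "#FF0000"), 100L)
    expect_identical(count_colour_pixels(img, "#FFFFFF"),
                     100L * 50L - 100L)
  }
})

test_that("pixel content is identical between PNG and BMP", {
  web <- assign_auto_colours(make_fig2_like(1))
  lay <- compute_layout(web)
  png_img <- png::readPNG(render(lay, render_options("png")))
  bmp_img <- decode_bmp(render(lay, render_options("bmp")))
  expect_identical(dim(png_img)[1:2], dim(bmp_img)[1:2])
  expect_equal(png_img, bmp_img, tolerance = 1e-9)
})

test_that("rendering is byte-identical across repeated runs", {
  for (name in c("fig1", "fig2")) {
    web <- assign_auto_colours(demo_web(name, seed = 2))
    lay <- compute_layout(web)
    for (fmt in c("png", "bmp", "svg")) {
      expect_identical(render(lay, render_options(fmt)),
                       render(lay, render_options(fmt)))
    }
  }
})

test_that("SVG output carries one shape element per geometry item", {
  web <- assign_auto_colours(make_fig1_like(1))
  lay <- compute_layout(web)
  svg <- rawToChar(render(lay, render_options("svg")))
  count <- function(re) sum(gregexpr(re, svg)[[1]] > 0)
  expect_identical(count("<polygon "), nrow(lay$links))
  # one background rect + one per bar + one per scale bar, plus the two
  # fixed tiles of the hatch pattern definition
  expect_identical(count("<rect "),
                   3L + nrow(lay$bars) + nrow(lay$scale_bars))
  expect_identical(count("<circle "), nrow(lay$circles))
  expect_identical(count("<text "), nrow(lay$labels))
})

test_that("unsupported formats are refused with the supported list", {
  expect_error(render_options("gif"), "png, bmp, svg")
  expect_error(render_options("pdf"), "unsupported format")
})

test_that("uncoloured geometry is refused", {
  web <- make_fig2_like(1)  # no colours assigned
  lay <- compute_layout(web)
  expect_error(render(lay, render_options("png")), "assign_auto_colours")
})

test_that("antialiased output stays deterministic and close to exact", {
  bar <- tibble::tibble(
    taxon = "t", level = 0L, x = 20.5, y = 15, width = 9, height = 10,
    colour = "#0000FF"
  )
  lay <- bare_layout(60, 40, bars = bar)
  a1 <- render(lay, render_options("png", antialias = TRUE))
  a2 <- render(lay, render_options("png", antialias = TRUE))
  expect_identical(a1, a2)
  img <- png::readPNG(a1)
  # total blue mass equals the bar area whether or not edges are soft
  blue_mass <- sum(1 - img[, , 1])
  expect_equal(blue_mass, 90, tolerance = 0.5)
})

test_that("write_web_image infers the format from the extension", {
  path <- withr::local_tempfile(fileext = ".svg")
  write_web_image(make_fig2_like(1), path)
  expect_match(readChar(path, 100), "<?xml", fixed = TRUE)
})
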