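test_that("bars are placed in order with exact spacing and scaling", {
  got <- layout_level_bars(c(20, 10), scale = 2, spacing = 8, origin_x = 0)
  expect_equal(got$start, c(0, 48), tolerance = 0)
  expect_equal(got$width, c(40, 20), tolerance = 0)

  one <- layout_level_bars(5, scale = 1, spacing = 0, origin_x = 3)
  expect_equal(one$start, 3)
  expect_equal(one$width, 5)

  zero <- layout_level_bars(c(0, 10), scale = 1, spacing = 4, origin_x = 0)
  expect_equal(zero$width[1], 0)
  expect_equal(zero$start[2], 4)  # spacing only after a zero-width bar

  expect_error(layout_level_bars(c(-1, 2), 1, 0), "non-negative")
})

test_that("circle rows have uniform centre gaps of 2r + spacing", {
  got <- layout_level_circles(2, radius = 10, spacing = 5, origin_x = 0)
  expect_equal(got$cx, c(10, 35), tolerance = 0)

  expect_identical(nrow(layout_level_circles(0, 10, 5)), 0L)

  fifteen <- layout_level_circles(15, radius = 16, spacing = 18)
  expect_equal(unique(diff(fifteen$cx)), 2 * 16 + 18, tolerance = 1e-12)
})

test_that("anchors compress to tile overfull bars and centre in underfull ones", {
  over <- allocate_anchors(0, 30, strengths = c(0.6, 0.4), link_scale = 50)
  expect_equal(over$start, c(0, 18), tolerance = 1e-12)
  expect_equal(over$width, c(18, 12), tolerance = 1e-12)
  expect_equal(sum(over$width), 30, tolerance = 1e-12)

  under <- allocate_anchors(0, 30, strengths = c(0.2, 0.1), link_scale = 50)
  expect_equal(under$start, c(7.5, 17.5), tolerance = 1e-12)
  expect_equal(under$width, c(10, 5), tolerance = 1e-12)

  zero <- allocate_anchors(0, 30, strengths = c(0, 0), link_scale = 50)
  expect_equal(zero$start, c(15, 15))
  expect_equal(zero$width, c(0, 0))

  expect_error(allocate_anchors(0, -1, 1, 1), "non-negative")
})

test_that("trapezoid polygons have the stated cyclic vertex order", {
  got <- link_polygon_bar(0, 10, 50, 20, y_lower = 100, y_upper = 0)
  expect_equal(got$x, c(0, 10, 70, 50), tolerance = 0)
  expect_equal(got$y, c(100, 100, 0, 0), tolerance = 0)

  rect <- link_polygon_bar(5, 10, 5, 10, y_lower = 0, y_upper = 40)
  expect_equal(rect$x, c(5, 15, 15, 5))

  degen <- link_polygon_bar(0, 10, 7, 0, y_lower = 0, y_upper = 40)
  expect_identical(nrow(degen), 4L)
  expect_equal(degen$x[3], degen$x[4])
})

test_that("triangle polygons put the base on the consumer side", {
  got <- link_polygon_triangle(0, 10, y_base = 100, apex_x = 60, y_apex = 0)
  expect_equal(got$x, c(0, 10, 60), tolerance = 0)
  expect_equal(got$y, c(100, 100, 0), tolerance = 0)

  seg <- link_polygon_triangle(5, 0, y_base = 0, apex_x = 5, y_apex = 10)
  expect_identical(nrow(seg), 3L)
})

test_that("scale bars are value times scale wide", {
  expect_equal(layout_scale_bar(20, 2), 40)
  expect_equal(layout_scale_bar(10, 2), 20)
  expect_equal(layout_scale_bar(1, 1), 1)
  expect_error(layout_scale_bar(0, 1))
})

test_that("compute_layout emits one shape per taxon and link", {
  web <- food_web(
    taxa = data.frame(name = c("a", "x"), level = 0:1, abundance = c(4, 2)),
    links = data.frame(lower = "a", upper = "x", strength = 1)
  )
  got <- compute_layout(assign_auto_colours(web))
  expect_identical(nrow(got$bars), 2L)
  expect_identical(nrow(got$links), 1L)
  expect_identical(nrow(got$links$poly[[1]]), 4L)

  expect_error(compute_layout(four_level_web()), "validation")
})

test_that("bar-shaped polygons have two horizontal edges at the level y's", {
  web <- assign_auto_colours(make_fig2_like(4))
  got <- compute_layout(web)
  y_lo_top <- unique(got$bars$y[got$bars$level == 0]) + unique(got$bars$height)
  y_up_bot <- unique(got$bars$y[got$bars$level == 1])
  for (p in got$links$poly) {
    expect_identical(nrow(p), 4L)
    expect_setequal(p$y, c(y_lo_top, y_up_bot))
    expect_equal(sum(p$y == y_lo_top), 2L)
  }
})

test_that("triangle apexes in the carabid fixture sit on prey circle centres", {
  web <- assign_auto_colours(make_fig1_like(1))
  got <- compute_layout(web)
  lower_gap <- got$links[got$links$gap == 0L, ]
  prey <- got$circles[got$circles$level == 0L, ]
  for (k in seq_len(nrow(lower_gap))) {
    p <- lower_gap$poly[[k]]
    expect_identical(nrow(p), 3L)
    apex <- p[3, ]
    centre <- prey[prey$taxon == lower_gap$lower[k], ]
    expect_equal(apex$x, centre$cx, tolerance = 1e-12)
    expect_equal(apex$y, centre$cy, tolerance = 1e-12)
  }
  # bases sit on the carabid bars (consumer side) in both gaps
  carabids <- got$bars[got$bars$level == 1L, ]
  base_y <- purrr::map_dbl(got$links$poly, ~ .x$y[1])
  expect_true(all(base_y[got$links$gap == 0L] ==
                    unique(carabids$y)))
  expect_true(all(base_y[got$links$gap == 1L] ==
                    unique(carabids$y + carabids$height)))
})

test_that("zero-strength links are dropped from the geometry", {
  web <- two_level_web(strengths = c(0, 0.2))
  got <- compute_layout(assign_auto_colours(web))
  expect_identical(nrow(got$links), 1L)
  expect_identical(got$links$link, 2L)
})

test_that("shared-scale one-to-one webs tile every bar exactly", {
  for (seed in c(1, 23, 456)) {
    web <- make_fig2_like(seed)
    got <- compute_layout(assign_auto_colours(web))
    for (i in seq_len(nrow(got$bars))) {
      bar <- got$bars[i, ]
      side_y <- if (bar$level == 0) bar$y + bar$height else bar$y
      covered <- 0
      for (p in got$links$poly) {
        on_bar <- abs(p$y - side_y) < 1e-9
        if (sum(on_bar) == 2) {
          xs <- sort(p$x[on_bar])
          if (xs[1] >= bar$x - 1e-9 && xs[2] <= bar$x + bar$width + 1e-9) {
            covered <- covered + (xs[2] - xs[1])
          }
        }
      }
      expect_equal(covered, bar$width, tolerance = 1e-9)
    }
  }
})

test_that("permuting link input order leaves the polygon set unchanged", {
  web <- assign_auto_colours(three_level_web())
  base <- compute_layout(web)
  perm <- web
  idx <- c(3, 1, 2)
  perm$links <- perm$links[idx, ]
  got <- compute_layout(perm)
  key <- function(l) paste(l$lower, l$upper)
  m <- match(key(base$links), key(got$links))
  for (k in seq_along(m)) {
    expect_equal(got$links$poly[[m[k]]], base$links$poly[[k]], tolerance = 0)
  }
})

test_that("geometry serialises to a JSON shape dump", {
  web <- assign_auto_colours(make_fig2_like(1))
  lay <- compute_layout(web)
  js <- jsonlite::fromJSON(layout_to_json(lay), simplifyVector = FALSE)
  expect_identical(length(js$bars), nrow(lay$bars))
  expect_identical(length(js$links), nrow(lay$links))
  expect_identical(length(js$links[[1]]$x), nrow(lay$links$poly[[1]]))
  expect_equal(js$canvas$width, 700)
})
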