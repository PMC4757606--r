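# Property-style checks over randomly generated webs (fixed seeds).

anchor_cover <- function(layout, bar) {
  side_edges <- c(bar$y, bar$y + bar$height)
  total <- 0
  for (p in layout$links$poly) {
    for (edge in side_edges) {
      on_bar <- abs(p$y - edge) < 1e-9
      if (sum(on_bar) == 2) {
        xs <- sort(p$x[on_bar])
        if (xs[1] >= bar$x - 1e-6 && xs[2] <= bar$x + bar$width + 1e-6) {
          total <- total + (xs[2] - xs[1])
        }
      }
    }
  }
  total
}

test_that("anchor widths conserve min(bar width, total nominal width)", {
  for (seed in 1:20) {
    web <- random_case_web(seed)
    if (!nrow(web$links)) next
    web <- assign_auto_colours(web)
    lay <- compute_layout(web)
    level_of <- stats::setNames(web$taxa$level, web$taxa$id)
    for (i in seq_len(nrow(lay$bars))) {
      bar <- lay$bars[i, ]
      for (g in web$gaps$lower_level) {
        gap <- web$gaps[web$gaps$lower_level == g, ]
        side <- if (bar$level == g) "lower" else
          if (bar$level == g + 1L) "upper" else next
        if (gap$shape == "triangle") {
          base_side <- if (gap$direction == "bottom_up") "lower" else "upper"
          if (side != base_side) next
        }
        inc <- web$links[[side]] == bar$taxon &
          level_of[web$links$lower] == g
        nominal <- sum(web$links$strength[inc]) * gap$link_scale
        if (!any(inc)) next
        got <- 0
        y_edge <- if (side == "lower") bar$y + bar$height else bar$y
        for (p in lay$links$poly[lay$links$link %in% which(inc)]) {
          on_bar <- abs(p$y - y_edge) < 1e-9
          if (sum(on_bar) == 2) got <- got + abs(diff(p$x[on_bar]))
        }
        expect_equal(got, min(bar$width, nominal), tolerance = 1e-9)
      }
    }
  }
})

test_that("increasing one link's strength never shrinks its anchor", {
  base <- two_level_web(strengths = c(0.4, 0.3))
  width_of_first <- function(web) {
    lay <- compute_layout(assign_auto_colours(web))
    p <- lay$links$poly[[which(lay$links$link == 1L)]]
    abs(diff(p$x[abs(p$y - min(p$y)) < 1e-9][1:2]))
  }
  widths <- purrr::map_dbl(seq(0.05, 3, by = 0.15), function(s) {
    web <- base
    web$links$strength[1] <- s
    width_of_first(web)
  })
  expect_true(all(diff(widths) >= -1e-12))
})

test_that("every emitted vertex lies inside the canvas", {
  for (seed in 1:20) {
    web <- assign_auto_colours(random_case_web(seed))
    lay <- compute_layout(web)
    verts <- tidy(lay)
    expect_true(all(verts$x >= -1e-9 & verts$x <= lay$canvas_width + 1e-9))
    expect_true(all(verts$y >= -1e-9 & verts$y <= lay$canvas_height + 1e-9))
  }
  # the demo fixtures, scale bars and labels included
  for (name in c("fig1", "fig2")) {
    lay <- compute_layout(assign_auto_colours(demo_web(name, 1)))
    verts <- tidy(lay)
    expect_true(all(verts$x >= 0 & verts$x <= lay$canvas_width))
    expect_true(all(verts$y >= 0 & verts$y <= lay$canvas_height))
    expect_true(all(lay$labels$x >= 0 & lay$labels$x <= lay$canvas_width))
    expect_true(all(lay$labels$y >= 0 & lay$labels$y <= lay$canvas_height))
  }
})

test_that("left-to-right bar order follows taxon input order on every level", {
  for (seed in 1:10) {
    web <- random_case_web(seed)
    lay <- compute_layout(assign_auto_colours(web))
    for (lvl in unique(lay$bars$level)) {
      bars <- lay$bars[lay$bars$level == lvl, ]
      expect_identical(bars$taxon, web$taxa$id[web$taxa$level == lvl])
      expect_true(all(diff(bars$x) > 0))
    }
  }
})

test_that("compute_layout is deterministic", {
  web <- assign_auto_colours(random_case_web(11))
  expect_identical(compute_layout(web), compute_layout(web))
})

test_that("small webs match the brute-force layout vertex-for-vertex", {
  for (seed in 1:25) {
    web <- assign_auto_colours(random_case_web(seed))
    expect_lt(layout_deviation(web), 1e-9)
  }
  # and the structured fixtures, circles and triangles included
  expect_lt(layout_deviation(assign_auto_colours(make_fig1_like(3))), 1e-9)
  expect_lt(layout_deviation(assign_auto_colours(make_fig2_like(3))), 1e-9)
})

test_that("tidy and glance summarise webs consistently", {
  web <- three_level_web()
  td <- tidy(web)
  expect_identical(nrow(td), nrow(web$taxa))
  expect_identical(
    td$degree[td$id == "carabids"], 3
  )
  gl <- glance(web)
  expect_identical(gl$n_links, 3L)
  expect_true(gl$valid)
  expect_equal(gl$connectance, 3 / (2 * 1 + 1 * 1))

  expect_s3_class(autoplot(web), "ggplot")
})
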