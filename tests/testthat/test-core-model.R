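test_that("a minimal web and the demo-sized webs validate clean", {
  one_level <- food_web(
    taxa = data.frame(name = c("a", "b"), level = 0, abundance = c(1, 2))
  )
  expect_identical(nrow(validate_web(one_level)), 0L)
  expect_true(is_valid_web(one_level))
  expect_identical(nrow(validate_web(two_level_web())), 0L)
  expect_identical(nrow(validate_web(three_level_web())), 0L)
})

test_that("webs with more than three levels are rejected", {
  v <- validate_web(four_level_web())
  expect_true("too_many_levels" %in% v$code)
  expect_true(all(v$severity[v$code == "too_many_levels"] == "error"))
  expect_false(is_valid_web(four_level_web()))
})

test_that("links must join adjacent levels and existing taxa", {
  web <- three_level_web()
  web$links <- rbind(
    web$links,
    tibble::tibble(lower = "aphids", upper = "spiders", strength = 0.1,
                   colour = NA_character_)
  )
  v <- validate_web(web)
  expect_true("non_adjacent_link" %in% v$code)
  expect_match(v$message[v$code == "non_adjacent_link"], "aphids->spiders")

  web2 <- two_level_web()
  web2$links$upper[1] <- "ghost"
  expect_true("dangling_link" %in% validate_web(web2)$code)

  # within-level links are non-adjacent too
  web3 <- two_level_web()
  web3$links$upper[1] <- "aphids"
  expect_true("non_adjacent_link" %in% validate_web(web3)$code)
})

test_that("taxon-level invariants are reported with stable codes", {
  web <- two_level_web()
  web$taxa$id[2] <- "aphids"
  expect_true("duplicate_taxon_id" %in% validate_web(web)$code)

  web <- two_level_web()
  web$taxa$abundance[1] <- -5
  expect_true("negative_abundance" %in% validate_web(web)$code)

  web <- two_level_web()
  web$taxa$abundance[1] <- NA_real_
  expect_true("missing_abundance" %in% validate_web(web)$code)

  web <- two_level_web()
  web$taxa$colour[1] <- "#GGGGGG"
  expect_true("bad_colour" %in% validate_web(web)$code)

  web <- two_level_web()
  web$taxa$level[3] <- 7L
  expect_true("bad_level_index" %in% validate_web(web)$code)
})

test_that("zero-strength links and zero-width bars warn but do not invalidate", {
  web <- two_level_web(strengths = c(0, 0.2))
  v <- validate_web(web)
  expect_identical(v$severity[v$code == "zero_strength_link"], "warning")
  expect_true(is_valid_web(web))

  web$taxa$abundance[2] <- 0
  v <- validate_web(web)
  expect_identical(v$severity[v$code == "zero_abundance"], "warning")
  expect_true(is_valid_web(web))
})

test_that("circle mode is only allowed for resource-only levels", {
  # top_down makes the upper level the consumer; circles there must fail
  web <- two_level_web(direction = "top_down")
  web$levels$display_mode[2] <- "circles"
  web$taxa$abundance[2:3] <- NA_real_
  expect_true("circle_level_is_consumer" %in% validate_web(web)$code)

  # bottom_up: upper level is the resource, circles fine
  web2 <- two_level_web(direction = "bottom_up", shape = "triangle")
  web2$levels$display_mode[2] <- "circles"
  web2$taxa$abundance[2:3] <- NA_real_
  expect_identical(nrow(validate_web(web2)), 0L)
})

test_that("validate_web is idempotent and side-effect free", {
  web <- four_level_web()
  web$links <- tibble::tibble(lower = "a", upper = "ghost", strength = -1,
                              colour = NA_character_)
  before <- unserialize(serialize(web, NULL))
  v1 <- validate_web(web)
  v2 <- validate_web(web)
  expect_identical(v1, v2)
  expect_identical(web, before)
})

test_that("the colour model is 24-bit RGB", {
  expect_equal(colour_space_size(), 256^3)
  expect_identical(colour_space_size(), 16777216L)
  expect_gte(colour_space_size(), 16e6)
  expect_error(rgb_to_hex(256, 0, 0), "0..255")
  expect_error(rgb_to_hex(-1, 0, 0), "0..255")
  expect_identical(hex_to_rgb(rgb_to_hex(12, 200, 255)), c(12L, 200L, 255L))
})
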