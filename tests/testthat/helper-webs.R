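# Small web builders shared across tests.

two_level_web <- function(strengths = c(0.35, 0.2),
                          direction = "bottom_up",
                          shape = "bar", ...) {
  food_web(
    taxa = data.frame(
      name = c("aphids", "small carabids", "large carabids"),
      level = c(0, 1, 1),
      abundance = c(60, 25, 30)
    ),
    links = data.frame(
      lower = "aphids",
      upper = c("small carabids", "large carabids"),
      strength = strengths
    ),
    gaps = data.frame(lower_level = 0, shape = shape,
                      direction = direction, link_scale = 40),
    ...
  )
}

three_level_web <- function() {
  food_web(
    taxa = data.frame(
      name = c("aphids", "thrips", "carabids", "spiders"),
      level = c(0, 0, 1, 2),
      abundance = c(40, 30, 20, 10)
    ),
    links = data.frame(
      lower = c("aphids", "thrips", "carabids"),
      upper = c("carabids", "carabids", "spiders"),
      strength = c(0.5, 0.25, 0.4)
    ),
    gaps = data.frame(lower_level = 0:1,
                      shape = c("bar", "triangle"),
                      direction = c("top_down", "bottom_up"),
                      link_scale = c(30, 30))
  )
}

four_level_web <- function() {
  web <- food_web(
    taxa = data.frame(name = c("a", "b", "c"), level = 0:2,
                      abundance = c(1, 1, 1))
  )
  web$levels <- rbind(
    web$levels,
    tibble::tibble(index = 3L, label = "level 3", display_mode = "bars",
                   scale = 1, scale_bar = NA_real_)
  )
  web$taxa <- rbind(
    web$taxa,
    tibble::tibble(id = "d", name = "d", level = 3L, abundance = 1,
                   colour = NA_character_)
  )
  web
}

expect_web_equal <- function(got, want) {
  expect_identical(class(got), "food_web")
  expect_equal(got$levels, want$levels, tolerance = 0)
  expect_equal(got$gaps, want$gaps, tolerance = 0)
  expect_equal(got$taxa, want$taxa, tolerance = 0)
  expect_equal(got$links, want$links, tolerance = 0)
  expect_equal(got$settings, want$settings, tolerance = 0)
}

# random web spanning the generator's parameter space, for round-trip and
# property loops
random_case_web <- function(seed) {
  set.seed(seed)
  n_levels <- sample(1:3, 1)
  make_random_web(
    n_levels = n_levels,
    taxa_per_level = sample(1:4, n_levels, replace = TRUE),
    connectance = stats::runif(1, 0.3, 1),
    shapes = sample(c("bar", "triangle"), max(n_levels - 1, 1), replace = TRUE),
    directions = sample(c("bottom_up", "top_down"), max(n_levels - 1, 1),
                        replace = TRUE),
    seed = seed
  )
}

# minimal geometry container for direct renderer tests
bare_layout <- function(width, height,
                        bars = NULL, links = NULL) {
  empty_poly <- tibble::tibble(
    link = integer(), lower = character(), upper = character(),
    gap = integer(), shape = character(), colour = character(),
    poly = list()
  )
  structure(
    list(
      bars = bars %||% tibble::tibble(
        taxon = character(), level = integer(), x = double(), y = double(),
        width = double(), height = double(), colour = character()
      ),
      circles = tibble::tibble(
        taxon = character(), level = integer(), cx = double(),
        cy = double(), r = double(), colour = character()
      ),
      links = links %||% empty_poly,
      scale_bars = tibble::tibble(
        level = integer(), x = double(), y = double(), width = double(),
        height = double(), value = double()
      ),
      labels = tibble::tibble(
        kind = character(), ref = character(), x = double(), y = double(),
        text = character()
      ),
      canvas_width = width, canvas_height = height
    ),
    class = "web_layout"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# tiny 24-bit BMP decoder, enough to verify the writer
decode_bmp <- function(bytes) {
  u32 <- function(off) sum(as.integer(bytes[off + 1:4]) * 256^(0:3))
  stopifnot(rawToChar(bytes[1:2]) == "BM")
  offset <- u32(10)
  w <- u32(18); h <- u32(22)
  depth <- sum(as.integer(bytes[29:30]) * 256^(0:1))
  stopifnot(depth == 24)
  row_bytes <- w * 3
  pad <- (4 - row_bytes %% 4) %% 4
  arr <- array(0, dim = c(h, w, 3))
  pos <- offset
  for (row in h:1) {
    chunk <- as.integer(bytes[pos + seq_len(row_bytes)])
    m <- matrix(chunk, nrow = 3)
    arr[row, , 1] <- m[3, ] / 255
    arr[row, , 2] <- m[2, ] / 255
    arr[row, , 3] <- m[1, ] / 255
    pos <- pos + row_bytes + pad
  }
  arr
}

count_colour_pixels <- function(raster, hex) {
  rgb <- triweb::hex_to_rgb(hex) / 255
  sum(abs(raster[, , 1] - rgb[1]) < 1e-9 &
        abs(raster[, , 2] - rgb[2]) < 1e-9 &
        abs(raster[, , 3] - rgb[3]) < 1e-9)
}
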