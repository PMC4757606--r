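# Deterministic web generators. Two of them copy the published structure
# of well-known example webs -- a tripartite carabid diet web and a
# primary/hyperparasitoid web -- with synthetic abundances and strengths
# (the original studies' numbers live in external tables and are not
# reproduced here); the third draws random webs for property tests.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

#' Generate a random valid web
#'
#' Draws a bar-mode web with the requested shape: per gap, exactly
#' `round(connectance * n_lower * n_upper)` links are realised between
#' uniformly sampled taxon pairs, with strengths uniform on
#' `strength_range`. Abundances are uniform on `abundance_range`. Each
#' level's pixel scale is chosen so its bar row fills at most 90% of the
#' canvas width inside the margins, so all geometry stays on canvas.
#' Output is a pure function of the arguments (the seed included).
#'
#' @param n_levels number of levels, 1--3.
#' @param taxa_per_level integer vector (recycled to `n_levels`).
#' @param connectance fraction of possible adjacent-level links
#'   realised, in (0, 1].
#' @param strength_range,abundance_range uniform sampling intervals.
#' @param shapes,directions per-gap link shape and direction (recycled).
#' @param seed integer seed.
#' @param ... passed to [food_web()].
#' @return a [food_web()] that passes [validate_web()].
#' @export
make_random_web <- function(n_levels = 2,
                            taxa_per_level = 3,
                            connectance = 1,
                            strength_range = c(0.1, 1),
                            abundance_range = c(5, 50),
                            shapes = "bar",
                            directions = "bottom_up",
                            seed = 1L,
                            ...) {
  stopifnot(n_levels >= 1, n_levels <= 3,
            connectance > 0, connectance <= 1)
  taxa_per_level <- rep_len(taxa_per_level, n_levels)
  stopifnot(all(taxa_per_level >= 1))
  with_seed(seed, {
    taxa <- bind_rows(map(seq_len(n_levels) - 1L, function(lvl) {
      n <- taxa_per_level[lvl + 1L]
      tibble(
        id = sprintf("t%d_%d", lvl, seq_len(n)),
        name = sprintf("taxon %d.%d", lvl, seq_len(n)),
        level = lvl,
        abundance = stats::runif(n, abundance_range[1], abundance_range[2])
      )
    }))
    links <- NULL
    if (n_levels > 1) {
      links <- bind_rows(map(seq_len(n_levels - 1L) - 1L, function(g) {
        lo <- taxa$id[taxa$level == g]
        up <- taxa$id[taxa$level == g + 1L]
        pairs <- expand.grid(lower = lo, upper = up,
                             stringsAsFactors = FALSE)
        n_links <- round(connectance * nrow(pairs))
        pick <- sort(sample.int(nrow(pairs), n_links))
        tibble(
          lower = pairs$lower[pick], upper = pairs$upper[pick],
          strength = stats::runif(n_links, strength_range[1], strength_range[2])
        )
      }))
      if (!nrow(links)) links <- NULL
    }
    web <- food_web(taxa = taxa, links = links, ...)
    s <- web$settings
    usable <- 0.9 * (s$canvas_width - 2 * s$margin)
    web$levels$scale <- vapply(web$levels$index, function(lvl) {
      ab <- taxa$abundance[taxa$level == lvl]
      row_sp <- (length(ab) - 1) * s$taxon_spacing
      max_total <- usable - row_sp
      max_total / (sum(ab) * 1.1)
    }, numeric(1))
    if (n_levels > 1) {
      web$gaps$shape <- rep_len(shapes, n_levels - 1L)
      web$gaps$direction <- rep_len(directions, n_levels - 1L)
      # keep nominal anchor totals near bar widths without forcing overflow
      web$gaps$link_scale <- vapply(seq_len(n_levels - 1L), function(g) {
        min(web$levels$scale[g], web$levels$scale[g + 1L]) * 0.8
      }, numeric(1))
    }
    web
  })
}

#' Tripartite carabid diet web (demo fixture)
#'
#' A three-level web shaped like a classic molecular-diet study:
#' two carabid consumer size classes in the middle (abundance-scaled
#' bars, scale bar worth 20 beetles), five extraguild prey groups below
#' and ten intraguild prey taxa above, both displayed as circles since
#' prey abundances are unknown. Links are triangles whose base width
#' encodes the proportion of carabids testing positive for that prey:
#' the lower gap runs top-down (carabid bars carry the bases, prey
#' circles the apexes) and the upper gap bottom-up (again base-on-
#' carabid). Detection proportions are synthetic, uniform on [0, 1].
#'
#' @param seed integer seed for the synthetic proportions.
#' @return a valid [food_web()].
#' @export
make_fig1_like <- function(seed = 1L) {
  extraguild <- c("aphids", "thrips", "collembolans", "earthworms", "dipterans")
  carabids <- c("small carabids", "large carabids")
  intraguild <- c(
    "Pachygnatha spp.", "Lycosidae", "Linyphiidae", "other spiders",
    "Pterostichus spp.", "Poecilus spp.", "Harpalus spp.", "Bembidion spp.",
    "Coccinella septempunctata", "lacewings"
  )
  with_seed(seed, {
    carabid_n <- round(stats::runif(2, 40, 120))
    taxa <- bind_rows(
      tibble(id = extraguild, name = extraguild, level = 0L,
             abundance = NA_real_),
      tibble(id = carabids, name = carabids, level = 1L,
             abundance = carabid_n),
      tibble(id = intraguild, name = intraguild, level = 2L,
             abundance = NA_real_)
    )
    links <- bind_rows(
      tibble(
        lower = rep(extraguild, times = length(carabids)),
        upper = rep(carabids, each = length(extraguild)),
        strength = round(stats::runif(10, 0.02, 0.98), 2)
      ),
      tibble(
        lower = rep(carabids, each = length(intraguild)),
        upper = rep(intraguild, times = length(carabids)),
        strength = round(stats::runif(20, 0.02, 0.98), 2)
      )
    )
    food_web(
      taxa = taxa, links = links,
      levels = tibble(
        index = 0:2,
        label = c("extraguild prey", "carabids", "intraguild prey"),
        display_mode = c("circles", "bars", "circles"),
        scale = c(1, 2, 1),
        scale_bar = c(NA, 20, NA)
      ),
      gaps = tibble(
        lower_level = 0:1,
        shape = "triangle",
        direction = c("top_down", "bottom_up"),
        link_scale = c(60, 60)
      ),
      canvas = c(900, 650),
      title = "carabid diet web"
    )
  })
}

#' Quantitative parasitoid--hyperparasitoid web (demo fixture)
#'
#' A two-level fully quantitative web: primary parasitoids below, two
#' hyperparasitoid taxa above, links drawn as trapezoid bands top-down
#' (the hyperparasitoids are the consumers). Every hyperparasitised
#' primary corresponds to exactly one hyperparasitoid individual, so
#' each taxon's abundance equals the summed strength of its incident
#' links, both levels share one pixel scale, and the link bands tile
#' every bar exactly. Counts are synthetic integers; both levels carry
#' a scale bar worth 10 individuals.
#'
#' @param seed integer seed for the synthetic counts.
#' @return a valid [food_web()].
#' @export
make_fig2_like <- function(seed = 1L) {
  primaries <- c("Aphidius rhopalosiphi", "Aphidius ervi",
                 "Ephedrus plagiator", "Praon volucre")
  hypers <- c("Dendrocerus carpenteri", "Phaenoglyphis villosa")
  with_seed(seed, {
    counts <- matrix(
      stats::rpois(length(primaries) * length(hypers), lambda = 6),
      nrow = length(primaries),
      dimnames = list(primaries, hypers)
    )
    # every taxon must keep a positive abundance
    counts[rowSums(counts) == 0, 1] <- 1L
    for (j in which(colSums(counts) == 0)) counts[1, j] <- 1L
    links <- tibble(
      lower = rep(primaries, times = length(hypers)),
      upper = rep(hypers, each = length(primaries)),
      strength = as.vector(counts)
    )
    links <- links[links$strength > 0, , drop = FALSE]
    taxa <- bind_rows(
      tibble(id = primaries, name = primaries, level = 0L,
             abundance = rowSums(counts)),
      tibble(id = hypers, name = hypers, level = 1L,
             abundance = colSums(counts))
    )
    shared_scale <- 4
    food_web(
      taxa = taxa, links = links,
      levels = tibble(
        index = 0:1,
        label = c("primary parasitoids", "hyperparasitoids"),
        display_mode = "bars",
        scale = shared_scale,
        scale_bar = 10
      ),
      gaps = tibble(
        lower_level = 0L, shape = "bar", direction = "top_down",
        link_scale = shared_scale
      ),
      canvas = c(700, 420),
      title = "parasitoid web"
    )
  })
}

#' Look up a demo fixture by name
#'
#' @param name `"fig1"`, `"fig2"` or `"random"`.
#' @param seed integer seed.
#' @return a valid [food_web()].
#' @export
demo_web <- function(name, seed = 1L) {
  switch(name,
    fig1 = make_fig1_like(seed),
    fig2 = make_fig2_like(seed),
    random = make_random_web(
      n_levels = 3, taxa_per_level = c(4, 3, 2),
      connectance = 0.75, seed = seed
    ),
    abort(sprintf("unknown fixture '%s'; available: fig1, fig2, random", name))
  )
}
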