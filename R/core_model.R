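#' Construct a food web
#'
#' A `food_web` bundles the taxa, the weighted links between adjacent
#' trophic levels, the per-level and per-gap display settings and the
#' canvas dimensions into one validated-on-demand container. Up to three
#' levels are supported; links may only join taxa on adjacent levels.
#'
#' `taxa` needs at least `name` and `level` columns. `level` is 0-based
#' with 0 the bottom level. `abundance` may be `NA` only for taxa on a
#' level displayed in circle mode. `colour` is an optional `#RRGGBB`
#' string (or `NA` to be filled later by [assign_auto_colours()]).
#'
#' `links` needs `lower`, `upper` (taxon ids, on levels `i` and `i + 1`)
#' and `strength` (non-negative). Which end is the consumer follows from
#' the enclosing gap's `direction`: `"bottom_up"` puts the consumer on
#' the lower level (links point up towards the resource), `"top_down"`
#' on the upper level.
#'
#' @param taxa data frame with columns `name`, `level`, and optionally
#'   `id` (defaults to `name`), `abundance`, `colour`.
#' @param links data frame with columns `lower`, `upper`, `strength`,
#'   and optionally `colour`; `NULL` for a web without links.
#' @param levels optional data frame overriding per-level display
#'   settings: columns among `index`, `label`, `display_mode`
#'   (`"bars"` or `"circles"`), `scale` (pixels per abundance unit),
#'   `scale_bar` (reference value in abundance units, `NA` for none).
#' @param gaps optional data frame overriding per-gap settings: columns
#'   among `lower_level`, `shape` (`"bar"` or `"triangle"`),
#'   `direction` (`"bottom_up"` or `"top_down"`), `link_scale`
#'   (pixels per strength unit).
#' @param canvas numeric length-2, canvas width and height in pixels.
#' @param margin,bar_height,taxon_spacing layout constants in pixels.
#' @param circle_radius radius in pixels used for circle-mode levels.
#' @param title project title, used by the cheddar export.
#' @return an object of class `food_web`.
#' @examples
#' web <- food_web(
#'   taxa = data.frame(
#'     name = c("aphids", "parasitoid"), level = c(0, 1),
#'     abundance = c(50, 20)
#'   ),
#'   links = data.frame(lower = "aphids", upper = "parasitoid", strength = 20)
#' )
#' validate_web(web)
#' @export
food_web <- function(taxa,
                     links = NULL,
                     levels = NULL,
                     gaps = NULL,
                     canvas = c(900, 650),
                     margin = 40,
                     bar_height = 30,
                     taxon_spacing = 18,
                     circle_radius = 16,
                     title = "food web") {
  taxa <- normalise_taxa(taxa)
  links <- normalise_links(links)
  n_levels <- if (nrow(taxa)) max(taxa$level) + 1L else 1L
  levels <- normalise_levels(levels, n_levels)
  gaps <- normalise_gaps(gaps, n_levels)

  structure(
    list(
      levels = levels,
      gaps = gaps,
      taxa = taxa,
      links = links,
      settings = list(
        canvas_width = as.numeric(canvas[[1]]),
        canvas_height = as.numeric(canvas[[2]]),
        margin = as.numeric(margin),
        bar_height = as.numeric(bar_height),
        taxon_spacing = as.numeric(taxon_spacing),
        circle_radius = as.numeric(circle_radius),
        title = as.character(title)
      )
    ),
    class = "food_web"
  )
}

normalise_taxa <- function(taxa) {
  taxa <- as_tibble(as.data.frame(taxa))
  if (!nrow(taxa)) {
    return(tibble(
      id = character(), name = character(), level = integer(),
      abundance = double(), colour = character()
    ))
  }
  stopifnot(all(c("name", "level") %in% names(taxa)))
  if (!"id" %in% names(taxa)) taxa$id <- taxa$name
  if (!"abundance" %in% names(taxa)) taxa$abundance <- NA_real_
  if (!"colour" %in% names(taxa)) taxa$colour <- NA_character_
  tibble(
    id = as.character(taxa$id),
    name = as.character(taxa$name),
    level = as.integer(taxa$level),
    abundance = as.numeric(taxa$abundance),
    colour = toupper(as.character(taxa$colour))
  )
}

normalise_links <- function(links) {
  if (is.null(links) || !NROW(links)) {
    return(tibble(
      lower = character(), upper = character(),
      strength = double(), colour = character()
    ))
  }
  links <- as_tibble(as.data.frame(links))
  stopifnot(all(c("lower", "upper", "strength") %in% names(links)))
  if (!"colour" %in% names(links)) links$colour <- NA_character_
  tibble(
    lower = as.character(links$lower),
    upper = as.character(links$upper),
    strength = as.numeric(links$strength),
    colour = toupper(as.character(links$colour))
  )
}

normalise_levels <- function(levels, n_levels) {
  defaults <- tibble(
    index = seq_len(n_levels) - 1L,
    label = paste("level", seq_len(n_levels) - 1L),
    display_mode = "bars",
    scale = 1,
    scale_bar = NA_real_
  )
  if (is.null(levels)) return(defaults)
  levels <- as_tibble(as.data.frame(levels))
  if (!"index" %in% names(levels)) levels$index <- seq_len(nrow(levels)) - 1L
  for (col in setdiff(names(defaults), names(levels))) {
    levels[[col]] <- defaults[[col]][match(levels$index, defaults$index)]
  }
  out <- defaults
  hit <- match(levels$index, out$index)
  for (col in c("label", "display_mode", "scale", "scale_bar")) {
    out[[col]][hit[!is.na(hit)]] <- levels[[col]][!is.na(hit)]
  }
  out$index <- as.integer(out$index)
  out$scale <- as.numeric(out$scale)
  out$scale_bar <- as.numeric(out$scale_bar)
  out
}

normalise_gaps <- function(gaps, n_levels) {
  n_gaps <- max(n_levels - 1L, 0L)
  defaults <- tibble(
    lower_level = seq_len(n_gaps) - 1L,
    shape = "bar",
    direction = "bottom_up",
    link_scale = 1
  )
  if (is.null(gaps) || n_gaps == 0L) return(defaults)
  gaps <- as_tibble(as.data.frame(gaps))
  if (!"lower_level" %in% names(gaps)) {
    gaps$lower_level <- seq_len(nrow(gaps)) - 1L
  }
  out <- defaults
  hit <- match(gaps$lower_level, out$lower_level)
  for (col in intersect(c("shape", "direction", "link_scale"), names(gaps))) {
    out[[col]][hit[!is.na(hit)]] <- gaps[[col]][!is.na(hit)]
  }
  out$lower_level <- as.integer(out$lower_level)
  out$link_scale <- as.numeric(out$link_scale)
  out
}

#' @export
print.food_web <- function(x, ...) {
  cat(sprintf(
    "<food_web> %d level%s, %d taxa, %d links, canvas %gx%g px\n",
    nrow(x$levels), if (nrow(x$levels) == 1) "" else "s",
    nrow(x$taxa), nrow(x$links),
    x$settings$canvas_width, x$settings$canvas_height
  ))
  v <- validate_web(x)
  err <- sum(v$severity == "error")
  wrn <- sum(v$severity == "warning")
  cat(sprintf("  validation: %d error(s), %d warning(s)\n", err, wrn))
  invisible(x)
}

# Which level acts as the consumer side of a gap. The direction names the
# end the links visually start from (wide/base end): bottom_up draws the
# base on the lower level, i.e. the lower level is the consumer.
consumer_level <- function(gap) {
  if (gap$direction == "bottom_up") gap$lower_level else gap$lower_level + 1L
}

is_hex_colour <- function(x) {
  !is.na(x) & grepl("^#[0-9A-Fa-f]{6}$", x)
}

#' Validate a food web
#'
#' Checks every structural invariant of the model and returns the
#' violations as a tibble rather than throwing: a malformed candidate web
#' (dangling link endpoints, four levels, negative strengths, ...) is
#' data, not an exception. An empty result, or one containing only
#' warnings, means the web is drawable.
#'
#' Violation codes include `too_many_levels`, `bad_level_index`,
#' `duplicate_taxon_id`, `negative_abundance`, `missing_abundance`,
#' `bad_colour`, `dangling_link`, `non_adjacent_link`,
#' `negative_strength`, `bad_scale`, `bad_link_scale`, `bad_display_mode`,
#' `bad_shape`, `bad_direction`, `circle_level_is_consumer` and the
#' warning codes `zero_strength_link` and `zero_abundance`.
#'
#' @param web a [food_web()].
#' @return tibble with columns `code`, `severity` (`"error"` or
#'   `"warning"`), `subject` and `message`; zero rows for a fully clean
#'   web.
#' @export
validate_web <- function(web) {
  stopifnot(inherits(web, "food_web"))
  out <- list()
  bad <- function(code, subject, message, severity = "error") {
    out[[length(out) + 1L]] <<- tibble(
      code = code, severity = severity,
      subject = as.character(subject), message = message
    )
  }

  n_levels <- nrow(web$levels)
  if (n_levels > 3) {
    bad(
      "too_many_levels", "levels",
      sprintf("web has %d levels; at most 3 trophic levels are supported", n_levels)
    )
  }
  if (n_levels < 1) bad("no_levels", "levels", "web has no levels")

  tx <- web$taxa
  dup <- unique(tx$id[duplicated(tx$id)])
  for (id in dup) {
    bad("duplicate_taxon_id", id, sprintf("taxon id '%s' is not unique", id))
  }
  for (k in seq_len(nrow(tx))) {
    t <- tx[k, ]
    if (is.na(t$level) || t$level < 0 || t$level >= n_levels) {
      bad(
        "bad_level_index", t$id,
        sprintf("taxon '%s' has level %s outside 0..%d", t$id, t$level, n_levels - 1L)
      )
      next
    }
    mode <- web$levels$display_mode[web$levels$index == t$level]
    if (is.na(t$abundance)) {
      if (!identical(mode, "circles")) {
        bad(
          "missing_abundance", t$id,
          sprintf("taxon '%s' has no abundance but its level is in bar mode", t$id)
        )
      }
    } else if (t$abundance < 0) {
      bad(
        "negative_abundance", t$id,
        sprintf("taxon '%s' has negative abundance %g", t$id, t$abundance)
      )
    } else if (t$abundance == 0 && identical(mode, "bars")) {
      bad(
        "zero_abundance", t$id,
        sprintf("taxon '%s' has abundance 0 and will render as a zero-width bar", t$id),
        severity = "warning"
      )
    }
    if (!is.na(t$colour) && !is_hex_colour(t$colour)) {
      bad(
        "bad_colour", t$id,
        sprintf("taxon '%s' colour '%s' is not a #RRGGBB triple", t$id, t$colour)
      )
    }
  }

  lv <- web$levels
  for (k in seq_len(nrow(lv))) {
    if (!lv$display_mode[k] %in% c("bars", "circles")) {
      bad(
        "bad_display_mode", lv$index[k],
        sprintf("level %d display_mode '%s' is not 'bars' or 'circles'", lv$index[k], lv$display_mode[k])
      )
    }
    if (is.na(lv$scale[k]) || lv$scale[k] <= 0) {
      bad(
        "bad_scale", lv$index[k],
        sprintf("level %d scale must be a positive number of pixels per unit", lv$index[k])
      )
    }
    if (!is.na(lv$scale_bar[k]) && lv$scale_bar[k] <= 0) {
      bad(
        "bad_scale", lv$index[k],
        sprintf("level %d scale_bar value must be positive", lv$index[k])
      )
    }
  }

  gp <- web$gaps
  if (nrow(gp) > 2) {
    bad("too_many_gaps", "gaps", "at most 2 level interfaces can exist")
  }
  for (k in seq_len(nrow(gp))) {
    g <- gp[k, ]
    if (!g$shape %in% c("bar", "triangle")) {
      bad(
        "bad_shape", g$lower_level,
        sprintf("gap %d shape '%s' is not 'bar' or 'triangle'", g$lower_level, g$shape)
      )
    }
    if (!g$direction %in% c("bottom_up", "top_down")) {
      bad(
        "bad_direction", g$lower_level,
        sprintf("gap %d direction '%s' is not 'bottom_up' or 'top_down'", g$lower_level, g$direction)
      )
    }
    if (is.na(g$link_scale) || g$link_scale <= 0) {
      bad(
        "bad_link_scale", g$lower_level,
        sprintf("gap %d link_scale must be positive", g$lower_level)
      )
    }
  }

  lk <- web$links
  level_of <- stats::setNames(tx$level, tx$id)
  for (k in seq_len(nrow(lk))) {
    l <- lk[k, ]
    subj <- sprintf("%s->%s", l$lower, l$upper)
    missing_end <- FALSE
    for (end in c(l$lower, l$upper)) {
      if (!end %in% tx$id) {
        bad(
          "dangling_link", subj,
          sprintf("link %s references unknown taxon '%s'", subj, end)
        )
        missing_end <- TRUE
      }
    }
    if (!missing_end) {
      dl <- level_of[[l$lower]]
      du <- level_of[[l$upper]]
      if (!isTRUE(du - dl == 1L)) {
        bad(
          "non_adjacent_link", subj,
          sprintf(
            "link %s joins levels %s and %s; links must join level i to level i+1",
            subj, dl, du
          )
        )
      }
    }
    if (is.na(l$strength) || l$strength < 0) {
      bad(
        "negative_strength", subj,
        sprintf("link %s strength must be a non-negative number", subj)
      )
    } else if (l$strength == 0) {
      bad(
        "zero_strength_link", subj,
        sprintf("link %s has strength 0 and is dropped from the layout", subj),
        severity = "warning"
      )
    }
    if (!is.na(l$colour) && !is_hex_colour(l$colour)) {
      bad(
        "bad_colour", subj,
        sprintf("link %s colour '%s' is not a #RRGGBB triple", subj, l$colour)
      )
    }
  }

  # circle mode only for resource-only levels: a circle-mode level must not
  # be the consumer side of any adjacent gap that carries links
  if (nrow(gp) && nrow(lk)) {
    for (k in seq_len(nrow(gp))) {
      g <- gp[k, ]
      cl <- consumer_level(g)
      mode <- lv$display_mode[lv$index == cl]
      if (identical(mode, "circles")) {
        in_gap <- !is.na(level_of[lk$lower]) & level_of[lk$lower] == g$lower_level
        if (any(in_gap, na.rm = TRUE)) {
          bad(
            "circle_level_is_consumer", cl,
            sprintf(
              "level %d is displayed as circles but is the consumer side of gap %d; circle view is only for resource-only levels",
              cl, g$lower_level
            )
          )
        }
      }
    }
  }

  if (!length(out)) {
    return(tibble(
      code = character(), severity = character(),
      subject = character(), message = character()
    ))
  }
  bind_rows(out)
}

#' Is a web free of validation errors?
#'
#' Warnings (zero-strength links, zero-width bars) do not make a web
#' invalid.
#'
#' @param web a [food_web()].
#' @return `TRUE` if [validate_web()] reports no `error`-severity rows.
#' @export
is_valid_web <- function(web) {
  !any(validate_web(web)$severity == "error")
}

stop_if_invalid <- function(web) {
  v <- validate_web(web)
  if (any(v$severity == "error")) {
    abort(c(
      "web fails validation; see validate_web() for the full report",
      stats::setNames(
        sprintf("%s: %s", v$code[v$severity == "error"], v$message[v$severity == "error"]),
        rep("x", sum(v$severity == "error"))
      )
    ))
  }
  invisible(v)
}

#' Number of representable colours
#'
#' The colour model is 24-bit RGB: three channels of 256 values each,
#' i.e. 16,777,216 distinct colours.
#'
#' @return integer, `256^3`.
#' @export
colour_space_size <- function() {
  channel <- 256L
  channel * channel * channel
}
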