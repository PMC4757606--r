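# Project persistence: one versioned JSON document bundling data and
# display settings, so a web can be re-opened and tweaked later.
# Doubles are written with 17 significant digits, which round-trips
# IEEE-754 values exactly.

PROJECT_VERSION <- "1"

#' Save a food web project
#'
#' Serialises the full web -- taxa, links, level and gap settings,
#' canvas -- as a versioned JSON document. [load_project()] restores it
#' field-for-field.
#'
#' @param web a valid [food_web()].
#' @param path optional file path; if `NULL` the JSON text is returned
#'   only.
#' @return the JSON document as a string, invisibly if written.
#' @export
save_project <- function(web, path = NULL) {
  stop_if_invalid(web)
  doc <- list(
    fwd_project_version = PROJECT_VERSION,
    settings = web$settings,
    levels = web$levels,
    gaps = web$gaps,
    taxa = web$taxa,
    links = web$links
  )
  txt <- as.character(jsonlite::toJSON(
    doc, dataframe = "columns", auto_unbox = TRUE, digits = I(17),
    na = "null", pretty = TRUE
  ))
  emit_text(txt, path)
}

project_field <- function(doc, name, path) {
  if (is.null(doc[[name]])) {
    abort(sprintf("invalid project document: missing field '%s'", path))
  }
  doc[[name]]
}

as_chr_na <- function(x) {
  out <- as.character(unlist(lapply(x, function(v) if (is.null(v)) NA_character_ else v)))
  if (!length(x)) character() else out
}

as_dbl_na <- function(x) {
  if (!length(x)) return(double())
  as.numeric(unlist(lapply(x, function(v) if (is.null(v)) NA_real_ else v)))
}

#' Load a food web project
#'
#' @param file path to, or text of, a document written by
#'   [save_project()].
#' @return the restored [food_web()].
#' @export
load_project <- function(file) {
  txt <- paste(read_text_lines(file), collapse = "\n")
  doc <- tryCatch(
    jsonlite::fromJSON(txt, simplifyDataFrame = FALSE, simplifyVector = FALSE),
    error = function(e) abort(paste0("invalid project document: ", conditionMessage(e)))
  )
  version <- doc$fwd_project_version
  if (is.null(version)) {
    abort("invalid project document: missing field 'fwd_project_version'")
  }
  if (!identical(as.character(version), PROJECT_VERSION)) {
    abort(sprintf(
      "unsupported project version '%s'; this build reads version %s",
      version, PROJECT_VERSION
    ))
  }
  s <- project_field(doc, "settings", "settings")
  for (f in c("canvas_width", "canvas_height", "margin", "bar_height",
              "taxon_spacing", "circle_radius", "title")) {
    project_field(s, f, paste0("settings.", f))
  }
  lv <- project_field(doc, "levels", "levels")
  gp <- project_field(doc, "gaps", "gaps")
  tx <- project_field(doc, "taxa", "taxa")
  lk <- project_field(doc, "links", "links")
  for (f in c("id", "name", "level")) project_field(tx, f, paste0("taxa.", f))

  web <- food_web(
    taxa = tibble(
      id = as_chr_na(tx$id), name = as_chr_na(tx$name),
      level = as.integer(as_dbl_na(tx$level)),
      abundance = as_dbl_na(tx$abundance),
      colour = as_chr_na(tx$colour)
    ),
    links = if (length(lk$lower)) {
      tibble(
        lower = as_chr_na(lk$lower), upper = as_chr_na(lk$upper),
        strength = as_dbl_na(lk$strength), colour = as_chr_na(lk$colour)
      )
    } else {
      NULL
    },
    canvas = c(s$canvas_width, s$canvas_height),
    margin = s$margin, bar_height = s$bar_height,
    taxon_spacing = s$taxon_spacing, circle_radius = s$circle_radius,
    title = s$title
  )
  # settings tables are authoritative, not re-derived
  web$levels <- tibble(
    index = as.integer(as_dbl_na(lv$index)),
    label = as_chr_na(lv$label),
    display_mode = as_chr_na(lv$display_mode),
    scale = as_dbl_na(lv$scale),
    scale_bar = as_dbl_na(lv$scale_bar)
  )
  web$gaps <- tibble(
    lower_level = as.integer(as_dbl_na(gp$lower_level)),
    shape = as_chr_na(gp$shape),
    direction = as_chr_na(gp$direction),
    link_scale = as_dbl_na(gp$link_scale)
  )
  web
}
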