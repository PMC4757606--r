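# Semicolon-delimited import/export dialects. The grammar is deliberately
# strict: ';' field separator, '.' decimal separator, fixed header as a
# format signature. Decimal commas inside fields fail loudly with a hint
# rather than being locale-sniffed.

SPECIES_HEADER <- c("level", "taxon", "abundance", "colour")
INTERACTIONS_HEADER <- c("lower_taxon", "upper_taxon", "strength")

read_text_lines <- function(file) {
  if (length(file) == 1 && !grepl("\n", file) && file.exists(file)) {
    txt <- readChar(file, file.size(file), useBytes = TRUE)
    Encoding(txt) <- "UTF-8"
  } else {
    txt <- paste(file, collapse = "\n")
  }
  txt <- sub("^\ufeff", "", txt)  # accept a UTF-8 BOM
  txt <- gsub("\r\n", "\n", txt, fixed = TRUE)
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  lines[!(seq_along(lines) > 1 & lines == "" &
            seq_along(lines) == length(lines))]
}

NUM_RE <- "^[+-]?([0-9]+(\\.[0-9]*)?|\\.[0-9]+)([eE][+-]?[0-9]+)?$"

parse_real <- function(cell, row, field) {
  if (grepl(",", cell, fixed = TRUE)) {
    abort(sprintf(
      "row %d: '%s' value '%s' contains a comma; decimals must use '.' (the ';' delimiter does not imply comma decimals)",
      row, field, cell
    ))
  }
  if (!grepl(NUM_RE, cell)) {
    abort(sprintf("row %d: '%s' value '%s' is not a number", row, field, cell))
  }
  as.numeric(cell)
}

check_header <- function(got, want, what) {
  if (!identical(got, want)) {
    abort(sprintf(
      "not a %s file: expected header '%s' but found '%s'",
      what, paste(want, collapse = ";"), paste(got, collapse = ";")
    ))
  }
}

#' Read a species table
#'
#' Parses the semicolon-delimited species dialect with header
#' `level;taxon;abundance;colour`. Empty `abundance` and `colour` cells
#' become `NA`; colour cells are `R,G,B` triples (channels 0--255) and
#' are canonicalised to `#RRGGBB`. Surrounding whitespace is trimmed.
#' Format errors (wrong header, wrong field count, unparseable numbers)
#' name the 1-based row.
#'
#' @param file path to a file, or a string/character vector holding the
#'   file content.
#' @return tibble with columns `level` (integer), `taxon` (character),
#'   `abundance` (double, `NA` if absent), `colour` (`#RRGGBB` or `NA`),
#'   in file order.
#' @export
read_species_csv <- function(file) {
  lines <- read_text_lines(file)
  if (!length(lines)) abort("empty file: expected header 'level;taxon;abundance;colour'")
  header <- trimws(strsplit(lines[[1]], ";", fixed = TRUE)[[1]])
  check_header(header, SPECIES_HEADER, "species")
  body <- lines[-1]
  body <- body[body != ""]
  if (!length(body)) {
    return(tibble(level = integer(), taxon = character(),
                  abundance = double(), colour = character()))
  }
  rows <- strsplit(body, ";", fixed = TRUE)
  recs <- imap(rows, function(r, i) {
    rowno <- i + 1L
    if (length(r) > 4) {
      abort(sprintf("row %d: expected 4 fields, found %d", rowno, length(r)))
    }
    length(r) <- 4L
    r[is.na(r)] <- ""
    r <- trimws(r)
    level <- parse_real(r[[1]], rowno, "level")
    if (level != floor(level) || level < 0 || level > 2) {
      abort(sprintf("row %d: level '%s' must be an integer in 0..2", rowno, r[[1]]))
    }
    abundance <- if (r[[3]] == "") NA_real_ else parse_real(r[[3]], rowno, "abundance")
    if (!is.na(abundance) && abundance < 0) {
      abort(sprintf("row %d: negative abundance %s", rowno, r[[3]]))
    }
    colour <- if (r[[4]] == "") NA_character_ else parse_rgb_cell(r[[4]], rowno)
    tibble(level = as.integer(level), taxon = r[[2]],
           abundance = abundance, colour = colour)
  })
  bind_rows(recs)
}

parse_rgb_cell <- function(cell, rowno) {
  parts <- trimws(strsplit(cell, ",", fixed = TRUE)[[1]])
  if (length(parts) != 3 || !all(grepl("^[0-9]+$", parts))) {
    abort(sprintf("row %d: colour '%s' is not an 'R,G,B' triple", rowno, cell))
  }
  ch <- as.integer(parts)
  if (any(ch > 255)) {
    abort(sprintf("row %d: colour channel out of range in '%s' (0..255)", rowno, cell))
  }
  rgb_to_hex(ch)
}

#' Read an interactions table
#'
#' Parses the semicolon-delimited interactions dialect with header
#' `lower_taxon;upper_taxon;strength`. Strengths must be non-negative
#' reals with '.' decimals.
#'
#' @inheritParams read_species_csv
#' @return tibble with columns `lower_taxon`, `upper_taxon`, `strength`,
#'   in file order.
#' @export
read_interactions_csv <- function(file) {
  lines <- read_text_lines(file)
  if (!length(lines)) abort("empty file: expected header 'lower_taxon;upper_taxon;strength'")
  header <- trimws(strsplit(lines[[1]], ";", fixed = TRUE)[[1]])
  check_header(header, INTERACTIONS_HEADER, "interactions")
  body <- lines[-1]
  body <- body[body != ""]
  if (!length(body)) {
    return(tibble(lower_taxon = character(), upper_taxon = character(),
                  strength = double()))
  }
  rows <- strsplit(body, ";", fixed = TRUE)
  recs <- imap(rows, function(r, i) {
    rowno <- i + 1L
    if (length(r) != 3) {
      abort(sprintf("row %d: expected 3 fields, found %d", rowno, length(r)))
    }
    r <- trimws(r)
    strength <- parse_real(r[[3]], rowno, "strength")
    if (strength < 0) {
      abort(sprintf("row %d: negative strength %s", rowno, r[[3]]))
    }
    tibble(lower_taxon = r[[1]], upper_taxon = r[[2]], strength = strength)
  })
  bind_rows(recs)
}

fmt_real <- function(x) {
  # shortest representation that re-reads exactly; always '.' decimals
  vapply(x, function(v) {
    if (is.na(v)) return("")
    s <- format(v, scientific = FALSE, trim = TRUE, digits = 15)
    if (as.numeric(s) != v) s <- sprintf("%.17g", v)
    s
  }, character(1), USE.NAMES = FALSE)
}

#' Write a species table
#'
#' Inverse of [read_species_csv()]: re-reading the output reproduces the
#' records exactly. Semicolon delimiter, '.' decimals, no trailing
#' delimiter; colours serialised as `R,G,B`.
#'
#' @param records tibble as returned by [read_species_csv()].
#' @param path optional file path; if `NULL` the text is returned only.
#' @return the file content as a single string, invisibly if written.
#' @export
write_species_csv <- function(records, path = NULL) {
  colour_cell <- vapply(records$colour, function(h) {
    if (is.na(h)) "" else paste(hex_to_rgb(h), collapse = ",")
  }, character(1), USE.NAMES = FALSE)
  lines <- c(
    paste(SPECIES_HEADER, collapse = ";"),
    sprintf("%d;%s;%s;%s", records$level, records$taxon,
            fmt_real(records$abundance), colour_cell)
  )
  emit_text(lines, path)
}

#' Write an interactions table
#'
#' Inverse of [read_interactions_csv()] (round-trip identity).
#'
#' @param records tibble as returned by [read_interactions_csv()].
#' @inheritParams write_species_csv
#' @return the file content as a single string, invisibly if written.
#' @export
write_interactions_csv <- function(records, path = NULL) {
  lines <- c(
    paste(INTERACTIONS_HEADER, collapse = ";"),
    sprintf("%s;%s;%s", records$lower_taxon, records$upper_taxon,
            fmt_real(records$strength))
  )
  emit_text(lines, path)
}

emit_text <- function(lines, path) {
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeBin(charToRaw(txt), con)
    return(invisible(txt))
  }
  txt
}

#' Assemble a food web from species and interaction records
#'
#' Taxon ids are the taxon names (which must therefore be unique across
#' the web). Levels whose taxa all lack abundances default to circle
#' display mode.
#'
#' @param species tibble from [read_species_csv()].
#' @param interactions tibble from [read_interactions_csv()], or `NULL`.
#' @param ... further arguments passed to [food_web()] (`levels`,
#'   `gaps`, `canvas`, ...).
#' @return a [food_web()].
#' @export
as_food_web <- function(species, interactions = NULL, ...) {
  taxa <- tibble(
    id = species$taxon, name = species$taxon,
    level = species$level, abundance = species$abundance,
    colour = species$colour
  )
  links <- if (!is.null(interactions) && nrow(interactions)) {
    tibble(lower = interactions$lower_taxon,
           upper = interactions$upper_taxon,
           strength = interactions$strength)
  } else {
    NULL
  }
  args <- list(...)
  if (is.null(args$levels) && nrow(taxa)) {
    # resource-only convention: a level with no abundances at all is
    # displayed as circles
    lv <- sort(unique(taxa$level))
    mode <- vapply(lv, function(l) {
      if (all(is.na(taxa$abundance[taxa$level == l]))) "circles" else "bars"
    }, character(1))
    args$levels <- tibble(index = lv, display_mode = mode)
  }
  do.call(food_web, c(list(taxa = taxa, links = links), args))
}
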