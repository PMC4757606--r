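# Export to the cheddar community format: three comma-delimited
# documents (nodes, trophic links, properties) that cheddar's
# LoadCommunity() reads from a directory.

csv_quote <- function(x) {
  needs <- grepl("[,\"\n]", x)
  x[needs] <- paste0('"', gsub('"', '""', x[needs]), '"')
  x
}

#' Export a web as a cheddar community
#'
#' Produces the three documents of the cheddar community layout:
#' `nodes.csv` (columns `node`, `category` = the level label, `M` =
#' abundance with empty cells where absent, `colour` as `#RRGGBB`),
#' `trophic.links.csv` (columns `resource`, `consumer`), and
#' `properties.csv` (`title`, `M.units`). Consumer/resource roles follow
#' each gap's direction: `bottom_up` makes the lower taxon the consumer
#' and the upper taxon the resource, `top_down` the reverse. Only links
#' with positive strength are exported. Node names containing commas,
#' quotes or newlines are quoted.
#'
#' @param web a valid, fully coloured [food_web()] (run
#'   [assign_auto_colours()] first).
#' @param dir optional directory; when given, the three files are
#'   written there as `nodes.csv`, `trophic.links.csv`,
#'   `properties.csv`.
#' @param m_units value for the `M.units` property.
#' @return named list of three strings: `nodes`, `trophic.links`,
#'   `properties`; invisibly if written to `dir`.
#' @export
export_cheddar <- function(web, dir = NULL, m_units = "individuals") {
  stop_if_invalid(web)
  if (!is_fully_coloured(web)) {
    abort("web is not fully coloured; run assign_auto_colours() before exporting")
  }
  tx <- web$taxa
  label_of <- stats::setNames(web$levels$label, web$levels$index)
  nodes <- paste0(
    paste(c("node", "category", "M", "colour"), collapse = ","), "\n",
    paste(sprintf(
      "%s,%s,%s,%s",
      csv_quote(tx$name),
      csv_quote(label_of[as.character(tx$level)]),
      fmt_real(tx$abundance),
      tx$colour
    ), collapse = "\n"),
    if (nrow(tx)) "\n" else ""
  )

  lk <- web$links[!is.na(web$links$strength) & web$links$strength > 0, ,
                  drop = FALSE]
  name_of <- stats::setNames(tx$name, tx$id)
  level_of <- stats::setNames(tx$level, tx$id)
  rows <- character(nrow(lk))
  for (k in seq_len(nrow(lk))) {
    gap <- web$gaps[web$gaps$lower_level == level_of[[lk$lower[k]]], ]
    if (gap$direction == "bottom_up") {
      consumer <- lk$lower[k]; resource <- lk$upper[k]
    } else {
      consumer <- lk$upper[k]; resource <- lk$lower[k]
    }
    rows[k] <- sprintf("%s,%s", csv_quote(name_of[[resource]]),
                       csv_quote(name_of[[consumer]]))
  }
  trophic <- paste0(
    "resource,consumer\n",
    paste(rows, collapse = "\n"),
    if (length(rows)) "\n" else ""
  )

  properties <- paste0(
    "title,M.units\n",
    sprintf("%s,%s\n", csv_quote(web$settings$title), csv_quote(m_units))
  )

  out <- list(nodes = nodes, trophic.links = trophic, properties = properties)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    emit_text(sub("\n$", "", nodes), file.path(dir, "nodes.csv"))
    emit_text(sub("\n$", "", trophic), file.path(dir, "trophic.links.csv"))
    emit_text(sub("\n$", "", properties), file.path(dir, "properties.csv"))
    return(invisible(out))
  }
  out
}
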