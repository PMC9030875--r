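#' Representative plankton cell sizes and suspension densities
#'
#' Returns the built-in table of phytoplankton and bacterioplankton taxa with
#' representative cell radii and cell suspension densities across marine
#' habitats (oligotrophic, mesotrophic and eutrophic water columns, plus
#' within-colony densities for colonial phytoplankton). Densities are stored
#' in cells m^-3, the canonical unit throughout the package; conversions to
#' cells mm^-3 happen only inside computations. The same taxon can appear
#' more than once per habitat where independent literature estimates differ;
#' rows are distinguished by `citation`.
#'
#' @return A tibble with columns `habitat` (one of `"oligotrophic"`,
#'   `"mesotrophic"`, `"eutrophic"`, `"colony"`), `taxon`, `metabolism`
#'   (`"phototroph"` or `"heterotroph"`), `cells_per_m3`, `cell_radius_um`
#'   and `citation`.
#'
#' @examples
#' plankton_taxa()
#' dplyr::filter(plankton_taxa(), habitat == "colony")
#' @export
plankton_taxa <- function() {
  out <- tibble::tribble(
    ~habitat,       ~taxon,              ~metabolism,   ~cells_per_m3, ~cell_radius_um, ~citation,
    "oligotrophic", "Bacterioplankton",  "heterotroph", 4.7e10,        0.5,             "B9",
    "oligotrophic", "Bacterioplankton",  "heterotroph", 2.0e11,        0.5,             "B10",
    "oligotrophic", "Diatoms",           "phototroph",  5.6e7,         10.0,            "B11",
    "oligotrophic", "Dinoflagellates",   "phototroph",  6.5e6,         10.0,            "B11",
    "oligotrophic", "PicoEukaryotes",    "phototroph",  6.7e8,         2.0,             "B12",
    "oligotrophic", "PicoEukaryotes",    "phototroph",  2.0e9,         2.0,             "B10",
    "oligotrophic", "Prochlorococcus",   "phototroph",  4.7e10,        0.3,             "B12",
    "oligotrophic", "Prochlorococcus",   "phototroph",  3.8e10,        0.3,             "B10",
    "oligotrophic", "Silicoflagellates", "phototroph",  1.3e7,         10.0,            "B11",
    "oligotrophic", "Synechococcus",     "phototroph",  3.0e9,         1.0,             "B12",
    "oligotrophic", "Synechococcus",     "phototroph",  2.0e9,         1.0,             "B10",
    "mesotrophic",  "Bacterioplankton",  "heterotroph", 3.3e11,        0.5,             "B10",
    "mesotrophic",  "PicoEukaryotes",    "phototroph",  3.0e9,         2.0,             "B10",
    "mesotrophic",  "Prochlorococcus",   "phototroph",  3.1e10,        0.3,             "B10",
    "mesotrophic",  "Synechococcus",     "phototroph",  6.0e9,         1.0,             "B10",
    "eutrophic",    "Bacterioplankton",  "heterotroph", 4.6e11,        0.5,             "B10",
    "eutrophic",    "Bacterioplankton",  "heterotroph", 4.6e13,        0.5,             "B13",
    "eutrophic",    "Chlorophytes",      "phototroph",  8.2e10,        2.5,             "B14",
    "eutrophic",    "Chroococcales",     "phototroph",  8.2e10,        1.0,             "B14",
    "eutrophic",    "Cyanobium",         "phototroph",  4.0e12,        1.0,             "B14",
    "eutrophic",    "PicoEukaryotes",    "phototroph",  3.0e9,         2.0,             "B10",
    "eutrophic",    "PicoEukaryotes",    "phototroph",  1.5e13,        2.0,             "B13",
    "eutrophic",    "Synechococcus",     "phototroph",  4.5e9,         1.0,             "B10",
    "colony",       "Cyanobium",         "phototroph",  1.0e13,        1.0,             "B14",
    "colony",       "Phaeocystis",       "phototroph",  2.4e13,        2.2,             "B8"
  )
  validate_community(out)
}

community_cols <- c("habitat", "taxon", "metabolism", "cells_per_m3", "cell_radius_um")

#' Validate a community table
#'
#' Checks that a data frame follows the community schema: the required
#' columns are present, habitat and metabolism values come from the
#' controlled vocabularies, and radii and densities are strictly positive.
#' Called internally by every function that consumes a community; exported
#' so user-assembled tables can be checked eagerly.
#'
#' @param community A data frame with columns `habitat`, `taxon`,
#'   `metabolism`, `cells_per_m3`, `cell_radius_um` and optionally
#'   `citation`. A `metabolism` of `"Phyto"`/`"Hetero"` (the shorthand used
#'   in field tables) is normalised to `"phototroph"`/`"heterotroph"`.
#' @return The validated community as a tibble (invisibly unchanged apart
#'   from metabolism normalisation and a `citation` column added if absent).
#' @export
validate_community <- function(community) {
  if (!is.data.frame(community)) {
    abort("`community` must be a data frame.")
  }
  missing <- setdiff(community_cols, names(community))
  if (length(missing) > 0) {
    abort(paste0("community table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  out <- tibble::as_tibble(community)
  if (!"citation" %in% names(out)) out$citation <- NA_character_
  out <- dplyr::mutate(
    out,
    metabolism = dplyr::case_match(
      tolower(.data$metabolism),
      c("phyto", "phototroph") ~ "phototroph",
      c("hetero", "heterotroph") ~ "heterotroph",
      .default = tolower(.data$metabolism)
    ),
    habitat = tolower(.data$habitat)
  )
  if (nrow(out) == 0) return(out[, c(community_cols, "citation")])

  bad_hab <- which(!out$habitat %in% habitat_levels)
  if (length(bad_hab) > 0) {
    abort(paste0("invalid habitat in row(s) ", paste(bad_hab, collapse = ", "),
                 "; expected one of: ", paste(habitat_levels, collapse = ", ")))
  }
  bad_met <- which(!out$metabolism %in% metabolism_levels)
  if (length(bad_met) > 0) {
    abort(paste0("invalid metabolism in row(s) ", paste(bad_met, collapse = ", ")))
  }
  bad_rad <- which(!is.finite(out$cell_radius_um) | out$cell_radius_um <= 0)
  if (length(bad_rad) > 0) {
    abort(paste0("cell_radius_um must be > 0; offending row(s): ",
                 paste(bad_rad, collapse = ", ")))
  }
  bad_den <- which(!is.finite(out$cells_per_m3) | out$cells_per_m3 <= 0)
  if (length(bad_den) > 0) {
    abort(paste0("cells_per_m3 must be > 0; offending row(s): ",
                 paste(bad_den, collapse = ", ")))
  }
  out[, c(community_cols, "citation")]
}

#' Read a community table from CSV
#'
#' Reads a CSV with header columns `habitat,taxon,metabolism,cells_per_m3,
#' cell_radius_um` (and optionally `citation`) into a validated community
#' tibble. Units are taken as written in the header names: densities in
#' cells m^-3, radii in micrometres. Scientific notation is accepted.
#'
#' @param path Path to a CSV file.
#' @return A community tibble (see [plankton_taxa()] for the schema).
#' @seealso [write_community()] for the inverse operation.
#' @export
read_community <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("community file not found: ", path))
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_community(raw)
}

#' Write a community table to CSV
#'
#' @param community A community tibble (validated on the way out).
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_community <- function(community, path) {
  out <- validate_community(community)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
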