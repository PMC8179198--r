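# CSV ingestion and result writing.
#
# File dialect (one row per measured height): species, individual,
# organ_type (stem|leaf), conduit_type (vessel|tracheid|hydroid),
# distance_from_tip_cm, mean_conduit_diameter_um. Distances are stored in the
# file in centimetres (field convention) and converted to micrometres at this
# boundary; all internal math is in um / um^2.

DIALECT_COLUMNS <- c("species", "individual", "organ_type", "conduit_type",
                     "distance_from_tip_cm", "mean_conduit_diameter_um")

#' Read tip-to-base conduit profiles from a trait-table CSV
#'
#' Validates the dialect strictly (missing columns, non-numeric or
#' non-positive measurements, and duplicate (individual, distance) rows are
#' reported with their row numbers), groups rows by individual, converts
#' cm → µm and diameter → lumen area, assigns `h_0` by conduit type and sets
#' `h_M` to the basal-most measured distance. Individuals with fewer than 3
#' points are dropped with a warning.
#'
#' @param path CSV file path.
#' @param h0_lookup Named conductive-unit lengths (µm) by conduit type.
#' @return A `"conduit_profiles"` tibble ([as_conduit_profiles()]).
#' @export
read_profiles <- function(path, h0_lookup = h0_defaults()) {
  if (!file.exists(path)) abort_input(sprintf("File not found: %s", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing_cols <- setdiff(DIALECT_COLUMNS, names(raw))
  if (length(missing_cols) > 0) {
    abort_input(paste0("Missing required column(s): ",
                       paste(missing_cols, collapse = ", "), "."))
  }

  parse_positive <- function(col, name) {
    x <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(x) | x <= 0)
    if (length(bad) > 0) {
      abort_input(sprintf(
        "Column `%s` must be a positive number; bad data row(s): %s.",
        name, paste(utils::head(bad, 10), collapse = ", ")
      ))
    }
    x
  }
  dist_cm <- parse_positive("distance_from_tip_cm", "distance_from_tip_cm")
  diam_um <- parse_positive("mean_conduit_diameter_um", "mean_conduit_diameter_um")

  bad_type <- which(!raw$conduit_type %in% names(h0_lookup))
  if (length(bad_type) > 0) {
    abort_input(sprintf("Unknown conduit_type in data row(s): %s.",
                        paste(utils::head(bad_type, 10), collapse = ", ")))
  }
  dup <- which(duplicated(data.frame(raw$individual, dist_cm)))
  if (length(dup) > 0) {
    abort_input(sprintf("Duplicate (individual, distance) data row(s): %s.",
                        paste(utils::head(dup, 10), collapse = ", ")))
  }

  as_conduit_profiles(
    tibble(
      plant_id = raw$individual,
      species = raw$species,
      organ = raw$organ_type,
      conduit_type = raw$conduit_type,
      height_um = dist_cm * 1e4,
      diameter_um = diam_um
    ),
    h0_lookup = h0_lookup
  )
}

#' Write result tables with a run manifest
#'
#' Writes each table as CSV (numeric columns at 6 significant digits,
#' deterministic column order as given) plus a `manifest.json` recording the
#' package version, R version, seed and any configuration passed — enough to
#' re-run the analysis. Re-running with the same inputs produces byte
#' identical files.
#'
#' @param tables Named list of data frames.
#' @param out_dir Output directory (created if needed).
#' @param config Optional named list recorded in the manifest.
#' @param seed Optional seed recorded in the manifest.
#' @return Character vector of written file paths, invisibly.
#' @export
write_results <- function(tables, out_dir, config = list(), seed = NULL) {
  if (!is.list(tables) || is.null(names(tables)) || any(names(tables) == "")) {
    abort_input("`tables` must be a named list of data frames.")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) abort_input(sprintf("Cannot create `%s`.", out_dir))

  paths <- vapply(names(tables), function(nm) {
    tab <- as.data.frame(tables[[nm]])
    num <- vapply(tab, is.double, logical(1))
    tab[num] <- lapply(tab[num], signif, digits = 6)
    p <- file.path(out_dir, paste0(nm, ".csv"))
    readr::write_csv(tab, p)
    p
  }, character(1))

  manifest <- list(
    package = "widenedpipe",
    package_version = as.character(utils::packageVersion("widenedpipe")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed,
    config = config,
    files = basename(unname(paths))
  )
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(c(unname(paths), mpath))
}
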