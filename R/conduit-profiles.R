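#' Build a conduit-profile table from per-measurement records
#'
#' Converts a flat table of conduit-diameter measurements (one row per sampled
#' height) into the package's per-plant container: a tibble of class
#' `"conduit_profiles"` with one row per plant and a `data` list-column of
#' ordered tip-to-base measurements. Diameters are converted to lumen areas
#' (\eqn{\sigma = \pi D^2/4}) at this boundary; all downstream model math is
#' in area space.
#'
#' @param df A data frame with columns `plant_id`, `species`, `organ`
#'   (`"stem"` or `"leaf"`), `conduit_type` (`"vessel"`, `"tracheid"` or
#'   `"hydroid"`), `height_um` (distance from the stem tip, µm) and
#'   `diameter_um` (mean conduit diameter, µm).
#' @param h0_lookup Named vector of conductive-unit lengths (µm) by conduit
#'   type; defaults to [h0_defaults()].
#' @param min_points Plants with fewer measured heights are dropped with a
#'   warning (default 3).
#' @return A `"conduit_profiles"` tibble with columns `plant_id`, `species`,
#'   `organ`, `conduit_type`, `h_0`, `h_M`, `n_points`, `data` (list of
#'   tibbles with `height_um`, `diameter_um`, `area_um2`). `h_M` is the
#'   basal-most measured height; `h_0` comes from the conduit-type lookup.
#' @export
as_conduit_profiles <- function(df, h0_lookup = h0_defaults(), min_points = 3L) {
  required <- c("plant_id", "species", "organ", "conduit_type",
                "height_um", "diameter_um")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort_input(paste0("Missing required columns: ",
                       paste(missing_cols, collapse = ", "), "."))
  }
  if (any(!df$conduit_type %in% names(h0_lookup))) {
    bad <- unique(setdiff(df$conduit_type, names(h0_lookup)))
    abort_input(paste0("Unknown conduit type(s): ", paste(bad, collapse = ", "), "."))
  }
  check_numeric_vec(df$height_um, "height_um", positive = TRUE)
  check_numeric_vec(df$diameter_um, "diameter_um", positive = TRUE)

  dup <- duplicated(df[c("plant_id", "height_um")])
  if (any(dup)) {
    abort_input(paste0("Duplicate (plant_id, height) rows: ",
                       paste(which(dup), collapse = ", "), "."))
  }

  out <- df |>
    dplyr::mutate(area_um2 = pi * .data$diameter_um^2 / 4) |>
    dplyr::arrange(.data$plant_id, .data$height_um) |>
    dplyr::group_by(.data$plant_id, .data$species, .data$organ, .data$conduit_type) |>
    tidyr::nest(data = c("height_um", "diameter_um", "area_um2")) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      h_0 = unname(h0_lookup[.data$conduit_type]),
      h_M = purrr::map_dbl(.data$data, ~ max(.x$height_um)),
      n_points = purrr::map_int(.data$data, nrow)
    ) |>
    dplyr::select("plant_id", "species", "organ", "conduit_type",
                  "h_0", "h_M", "n_points", "data")

  too_few <- out$n_points < min_points
  if (any(too_few)) {
    warn(sprintf("Dropping %d plant(s) with fewer than %d measured heights: %s",
                 sum(too_few), min_points,
                 paste(out$plant_id[too_few], collapse = ", ")))
    out <- out[!too_few, ]
  }
  class(out) <- c("conduit_profiles", class(out))
  out
}

#' Flatten a conduit-profile table back to per-measurement rows
#'
#' Inverse of [as_conduit_profiles()] (up to column order).
#'
#' @param profiles A `"conduit_profiles"` tibble.
#' @return A tibble with one row per measurement.
#' @export
unnest_profiles <- function(profiles) {
  stopifnot(inherits(profiles, "conduit_profiles"))
  profiles |>
    as_tibble() |>
    dplyr::select("plant_id", "species", "organ", "conduit_type", "data") |>
    tidyr::unnest("data")
}

#' @export
print.conduit_profiles <- function(x, ...) {
  cat(sprintf("<conduit_profiles: %d plants, %d measurements>\n",
              nrow(x), sum(x$n_points)))
  NextMethod()
}
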