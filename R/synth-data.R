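# Synthetic cohort generator emulating field-sampled tip-to-base
# conduit-diameter profiles, so the whole pipeline is testable without the
# original trait dataset. The generator reproduces the field protocol (dense
# sampling near the shoot apex, roughly doubling spacing below) and the noise
# structure of 25-conduit diameter means.

#' Specify a synthetic cohort
#'
#' Defaults describe the study conditions the pipeline was designed for:
#' 103 plants spanning about 1–110 m in height, predominantly vessel-bearing
#' with a minority of tracheid plants and a rare hydroid-bearing moss, basal
#' lumen area growing as \eqn{\sigma_M = c\,h_M^{1/2}} (so conductance stays
#' height-invariant up to logarithms and tip diameters are shared across
#' plants), and conduit-diameter measurements that are means of 25 conduits
#' with 20% anatomical variation per conduit.
#'
#' @param n_plants Number of plants (default 103).
#' @param height_range Min/max plant height in metres (default `c(1, 110)`);
#'   heights are drawn log-uniformly.
#' @param conduit_type_mix Named proportions over vessel/tracheid/hydroid
#'   (must sum to 1).
#' @param true_model Generating profile: `"wpm"`, `"sqrt_west"`,
#'   `"linear_savage"` or `"uniform"`.
#' @param sigma_M_c Named per-conduit-type coefficient c (µm^(2-gamma)) of
#'   the amplitude law \eqn{\sigma_M = c\,h_M^{\gamma}} (h_M in µm).
#'   Narrower coefficients for tracheids and hydroids place them at higher
#'   resistance / lower widening cost, as observed.
#' @param sigma_M_gamma Exponent \eqn{\gamma} of the amplitude law
#'   (default 0.5).
#' @param noise_cv Coefficient of variation of individual conduit diameters
#'   about the model curve (default 0.2); measurement noise is lognormal
#'   multiplicative, applied per conduit *before* the 25-conduit averaging.
#' @param n_conduits_per_section Conduits measured per sampled height
#'   (default 25).
#' @param leaf_fraction Fraction of plants whose profile is measured along
#'   leaves rather than stems (metadata only; default 0.1).
#' @param seed Integer seed making the cohort fully reproducible.
#' @return A list of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_plants = 103L,
                        height_range = c(1, 110),
                        conduit_type_mix = c(vessel = 0.85, tracheid = 0.14,
                                             hydroid = 0.01),
                        true_model = "wpm",
                        sigma_M_c = c(vessel = 1.5, tracheid = 0.5,
                                      hydroid = 0.15),
                        sigma_M_gamma = 0.5,
                        noise_cv = 0.2,
                        n_conduits_per_section = 25L,
                        leaf_fraction = 0.1,
                        seed = 1L) {
  n_plants <- as.integer(n_plants)
  check_number(n_plants, "n_plants", positive = TRUE)
  check_numeric_vec(height_range, "height_range", positive = TRUE)
  if (length(height_range) != 2L || height_range[1] > height_range[2]) {
    abort_input("`height_range` must be c(min, max) in metres with min <= max.")
  }
  if (!setequal(names(conduit_type_mix), CONDUIT_TYPES) ||
      abs(sum(conduit_type_mix) - 1) > 1e-8 || any(conduit_type_mix < 0)) {
    abort_input("`conduit_type_mix` must be non-negative proportions over vessel/tracheid/hydroid summing to 1.")
  }
  true_model <- match_model(true_model,
                            c("wpm", "sqrt_west", "linear_savage", "uniform"))
  if (!setequal(names(sigma_M_c), CONDUIT_TYPES) || any(sigma_M_c <= 0)) {
    abort_input("`sigma_M_c` must be positive and named over vessel/tracheid/hydroid.")
  }
  check_number(sigma_M_gamma, "sigma_M_gamma")
  check_number(noise_cv, "noise_cv")
  if (noise_cv < 0) abort_input("`noise_cv` must be non-negative.")
  n_conduits_per_section <- as.integer(n_conduits_per_section)
  check_number(n_conduits_per_section, "n_conduits_per_section", positive = TRUE)
  check_number(leaf_fraction, "leaf_fraction")
  if (leaf_fraction < 0 || leaf_fraction > 1) {
    abort_input("`leaf_fraction` must be in [0, 1].")
  }
  structure(
    list(n_plants = n_plants, height_range = height_range,
         conduit_type_mix = conduit_type_mix[CONDUIT_TYPES],
         true_model = true_model, sigma_M_c = sigma_M_c[CONDUIT_TYPES],
         sigma_M_gamma = sigma_M_gamma, noise_cv = noise_cv,
         n_conduits_per_section = n_conduits_per_section,
         leaf_fraction = leaf_fraction, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Field sampling heights
#'
#' The sampling-height protocol: every centimetre for the first 10 cm from
#' the stem apex, then at 20, 30, 60, 120, 240, 480, 960 cm and doubling
#' thereafter, plus the base of the plant. Heights exceeding the plant are
#' dropped; the base height `h_M` is always included.
#'
#' @param h_M Plant height (µm), positive.
#' @return Strictly increasing heights (µm), ending at `h_M`.
#' @export
#' @examples
#' sampling_heights(1e6) / 1e4 # a 1 m plant, in cm
sampling_heights <- function(h_M) {
  check_number(h_M, "h_M", positive = TRUE)
  ladder_cm <- c(1:10, 20, 30, 60)
  step <- 120
  while (step * 1e4 <= h_M) {
    ladder_cm <- c(ladder_cm, step)
    step <- step * 2
  }
  heights <- ladder_cm * 1e4
  heights <- heights[heights <= h_M]
  sort(unique(c(heights, h_M)))
}

true_area_profile <- function(h, h_M, amplitude, model) {
  amplitude * model_curve(h / h_M, model)
}

#' Generate a synthetic cohort
#'
#' Draws each plant's height log-uniformly from the spec's range, assigns a
#' conduit type, computes the true lumen-area profile of the generating model
#' at the field sampling heights, converts to diameter, and simulates the
#' measured mean conduit diameter at each height as the mean of
#' `n_conduits_per_section` lognormal draws with coefficient of variation
#' `noise_cv` around the true diameter. Fully reproducible from the spec's
#' seed (the caller's RNG state is untouched).
#'
#' @param spec A [cohort_spec()].
#' @return A list with `profiles` (a `"conduit_profiles"` tibble) and
#'   `truth` (tibble: `plant_id`, `conduit_type`, `true_model`,
#'   `true_amplitude` in µm², `h_M` in µm).
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_plants = 5, seed = 42))
#' cohort$profiles
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(spec$seed, {
    n <- spec$n_plants
    h_M <- exp(runif(n, log(spec$height_range[1]), log(spec$height_range[2]))) * 1e6
    type <- sample(CONDUIT_TYPES, n, replace = TRUE,
                   prob = spec$conduit_type_mix)
    organ <- ifelse(runif(n) < spec$leaf_fraction, "leaf", "stem")
    amplitude <- unname(spec$sigma_M_c[type]) * h_M^spec$sigma_M_gamma
    sdlog <- sqrt(log(1 + spec$noise_cv^2))

    rows <- purrr::pmap(
      list(seq_len(n), h_M, type, organ, amplitude),
      function(i, hM, ty, org, amp) {
        h <- sampling_heights(hM)
        sigma_true <- true_area_profile(h, hM, amp, spec$true_model)
        d_true <- 2 * sqrt(sigma_true / pi)
        d_meas <- vapply(d_true, function(d) {
          if (spec$noise_cv == 0) return(d)
          mean(rlnorm(spec$n_conduits_per_section,
                      meanlog = log(d) - sdlog^2 / 2, sdlog = sdlog))
        }, numeric(1))
        tibble(
          plant_id = sprintf("synth_%03d", i),
          species = sprintf("Synthetica species_%03d", i),
          organ = org, conduit_type = ty,
          height_um = h, diameter_um = d_meas
        )
      }
    )
    profiles <- as_conduit_profiles(purrr::list_rbind(rows))
    truth <- tibble(
      plant_id = sprintf("synth_%03d", seq_len(n)),
      conduit_type = type,
      true_model = spec$true_model,
      true_amplitude = amplitude,
      h_M = h_M
    )
    list(profiles = profiles, truth = truth)
  })
}

#' Write a synthetic cohort in the trait-table CSV dialect
#'
#' Generates a cohort and writes it in the same comma-separated dialect that
#' [read_profiles()] consumes (`species`, `individual`, `organ_type`,
#' `conduit_type`, `distance_from_tip_cm`, `mean_conduit_diameter_um`),
#' emulating the published per-plant trait table. Optionally writes the truth
#' table alongside.
#'
#' @param spec A [cohort_spec()].
#' @param path Output CSV path.
#' @param truth_path Optional path for the truth table CSV.
#' @return `path`, invisibly; the generated cohort is attached as attribute
#'   `"cohort"`.
#' @export
emulate_trait_dataset <- function(spec, path, truth_path = NULL) {
  cohort <- generate_cohort(spec)
  flat <- unnest_profiles(cohort$profiles) |>
    dplyr::transmute(
      species = .data$species,
      individual = .data$plant_id,
      organ_type = .data$organ,
      conduit_type = .data$conduit_type,
      distance_from_tip_cm = .data$height_um / 1e4,
      mean_conduit_diameter_um = .data$diameter_um
    )
  readr::write_csv(flat, path)
  if (!is.null(truth_path)) readr::write_csv(cohort$truth, truth_path)
  invisible(structure(path, cohort = cohort))
}
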