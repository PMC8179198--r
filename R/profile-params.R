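#' Conduit profile parameters
#'
#' Bundles the geometric parameters describing one plant's conduit profile:
#' the basal lumen cross-sectional area \eqn{\sigma_M} at height \eqn{h_M}
#' (plant height, measured as distance from the stem tip), the conductive-unit
#' length \eqn{h_0} serving as lower hydraulic cutoff, and — for power-law and
#' uniform competitor profiles — the amplitude \eqn{A}.
#'
#' All lengths are in micrometres and areas in square micrometres; unit
#' conversion happens at the I/O boundary ([read_profiles()]), never here.
#'
#' @param sigma_M Basal conduit lumen area \eqn{\sigma_M} (µm²), strictly
#'   positive.
#' @param h_M Plant height / maximum distance from the stem tip (µm).
#' @param h_0 Conductive-unit length, the lower cutoff (µm); must satisfy
#'   `0 < h_0 < h_M`. Degenerate `h_0 == h_M` is rejected rather than treated
#'   as a limit.
#' @param amplitude_A Amplitude of the power-law (or uniform) competitor
#'   profile (µm²); optional, required only by the power-law/uniform branches.
#'
#' @return A list of class `"profile_params"`.
#' @export
#' @examples
#' profile_params(sigma_M = 800, h_M = 1e7, h_0 = 400)
profile_params <- function(sigma_M, h_M, h_0, amplitude_A = NULL) {
  check_number(sigma_M, "sigma_M", positive = TRUE)
  check_number(h_M, "h_M", positive = TRUE)
  check_number(h_0, "h_0", positive = TRUE)
  if (h_0 >= h_M) {
    abort_domain(sprintf("`h_0` (%g) must be strictly less than `h_M` (%g).", h_0, h_M))
  }
  if (!is.null(amplitude_A)) check_number(amplitude_A, "amplitude_A", positive = TRUE)
  structure(
    list(sigma_M = sigma_M, h_M = h_M, h_0 = h_0, amplitude_A = amplitude_A),
    class = "profile_params"
  )
}

#' @export
print.profile_params <- function(x, ...) {
  cat("<profile_params>\n")
  cat(sprintf("  sigma_M: %g um^2   h_M: %g um   h_0: %g um (eps = %.3g)\n",
              x$sigma_M, x$h_M, x$h_0, x$h_0 / x$h_M))
  if (!is.null(x$amplitude_A)) cat(sprintf("  amplitude_A: %g um^2\n", x$amplitude_A))
  invisible(x)
}

need_amplitude <- function(params) {
  if (is.null(params$amplitude_A)) {
    abort_input("This profile needs `amplitude_A` in `profile_params()`.")
  }
  params$amplitude_A
}
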