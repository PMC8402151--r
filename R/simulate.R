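#' Simulate a DEP well-plate spectrum
#'
#' Generates one light-intensity spectrum under the linear measurement
#' model `intensity_i = scale * Re[K(omega_i)] + offset + e_i`, with
#' `e_i ~ N(0, noise_sd)` independent per well. `scale` and `offset`
#' absorb the (instrument-specific) mapping from band-intensity change
#' to DEP response.
#'
#' @param params a [shell_params()] object (the ground-truth cell).
#' @param medium a [dep_medium()] object.
#' @param frequencies frequency grid, Hz (default [default_frequencies()]).
#' @param scale multiplicative intensity gain, a.u.; must be non-zero.
#' @param offset additive intensity baseline, a.u.
#' @param noise_sd Gaussian well-noise standard deviation, a.u., >= 0.
#' @param seed integer seed for reproducible noise; `NULL` uses (and
#'   advances) the current RNG state.
#' @param label label passed to [dep_spectrum()].
#' @return A [dep_spectrum()] object.
#' @export
#' @examples
#' p <- as_si_params(6.40, 8571, 14.5, 0.26)
#' s <- simulate_spectrum(p, dep_medium(), noise_sd = 0.05, seed = 1)
simulate_spectrum <- function(params, medium,
                              frequencies = default_frequencies(),
                              scale = 1, offset = 0, noise_sd = 0,
                              seed = NULL, label = "") {
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop("noise_sd must be >= 0", call. = FALSE)
  }
  if (!is.numeric(scale) || scale == 0) stop("scale must be non-zero", call. = FALSE)
  clean <- scale * re_cm_spectrum(params, medium, frequencies) + offset
  noise <- if (noise_sd > 0) {
    with_seed(seed, stats::rnorm(length(frequencies), 0, noise_sd))
  } else {
    0
  }
  dep_spectrum(frequencies, clean + noise, label = label)
}
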