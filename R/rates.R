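#' Nonadiabatic hole-transfer rate parameters
#'
#' Bundles the constants of the vibronic (Jortner) rate expression used for
#' every hop in a hole-transport network: a classical outer-sphere
#' reorganization energy, one quantized high-frequency mode with a Huang--Rhys
#' electron--vibration coupling, and an exponential distance decay of the
#' electronic coupling.
#'
#' The inner-sphere reorganization energy is not stored independently: it is
#' the derived product \code{huang_rhys * hbar_omega}.
#'
#' @param lambda_outer Outer-sphere reorganization energy (eV).
#' @param hbar_omega Energy quantum of the high-frequency vibrational mode (eV).
#' @param huang_rhys Dimensionless Huang--Rhys factor \eqn{D = \lambda_{in}/\hbar\omega}.
#' @param beta Tunneling decay constant of the electronic coupling (1/Angstrom).
#' @param V0 Electronic coupling at zero donor--acceptor separation (eV).
#' @param temperature Absolute temperature (K).
#' @param n_max Truncation order of the vibronic sum (integer >= 1).
#'
#' @return An object of class \code{"hb_rate_params"}.
#'
#' @details Defaults are the values typical of biological electron transfer
#' used throughout the package: \code{lambda_outer = 0.9} eV,
#' \code{hbar_omega = 0.15} eV, \code{huang_rhys = 0.5} (so
#' \eqn{\lambda_{in}} = 0.075 eV), \code{beta = 0.6} per Angstrom,
#' \code{V0 = 0.01} eV, 300 K, and \code{n_max = 100} (ample for the
#' factorially decaying vibronic series).
#'
#' @examples
#' p <- rate_params()
#' lambda_inner(p)   # 0.075 eV
#' @export
rate_params <- function(lambda_outer = 0.9, hbar_omega = 0.15,
                        huang_rhys = 0.5, beta = 0.6, V0 = 0.01,
                        temperature = 300, n_max = 100L) {
  stopifnot(
    "lambda_outer must be > 0" = is.numeric(lambda_outer) && lambda_outer > 0,
    "hbar_omega must be > 0" = is.numeric(hbar_omega) && hbar_omega > 0,
    "huang_rhys must be >= 0" = is.numeric(huang_rhys) && huang_rhys >= 0,
    "beta must be > 0" = is.numeric(beta) && beta > 0,
    "V0 must be > 0" = is.numeric(V0) && V0 > 0,
    "temperature must be > 0" = is.numeric(temperature) && temperature > 0,
    "n_max must be >= 1" = is.numeric(n_max) && n_max >= 1
  )
  structure(
    list(lambda_outer = lambda_outer, hbar_omega = hbar_omega,
         huang_rhys = huang_rhys, beta = beta, V0 = V0,
         temperature = temperature, n_max = as.integer(n_max)),
    class = "hb_rate_params"
  )
}

#' @rdname rate_params
#' @param params An \code{hb_rate_params} object.
#' @export
lambda_inner <- function(params) params$huang_rhys * params$hbar_omega

#' @export
print.hb_rate_params <- function(x, ...) {
  cat("Hole-transfer rate parameters\n")
  cat(sprintf("  lambda_outer: %g eV   lambda_inner: %g eV (D = %g, hbar*omega = %g eV)\n",
              x$lambda_outer, lambda_inner(x), x$huang_rhys, x$hbar_omega))
  cat(sprintf("  V0: %g eV   beta: %g 1/A   T: %g K   n_max: %d\n",
              x$V0, x$beta, x$temperature, x$n_max))
  invisible(x)
}

#' Squared electronic coupling at a given edge-to-edge distance
#'
#' The mean-squared electronic coupling decays exponentially with the
#' closest heavy-atom donor--acceptor distance,
#' \eqn{\langle V^2 \rangle = (V_0 e^{-\beta R})^2}.
#'
#' @param distance Edge-to-edge distance (Angstrom), non-negative. Vectorized.
#' @param params An \code{hb_rate_params} object.
#' @return Squared coupling in eV^2.
#' @examples
#' coupling_squared(0, rate_params())   # V0^2 = 1e-4 eV^2
#' @export
coupling_squared <- function(distance, params) {
  stopifnot("distance must be non-negative" = all(distance >= 0))
  (params$V0 * exp(-params$beta * distance))^2
}

#' Vibronic (Jortner) nonadiabatic hole-transfer rate
#'
#' Evaluates the nonadiabatic transfer rate coupling a classical outer-sphere
#' mode and a single quantized high-frequency mode:
#' \deqn{k = \frac{2\pi}{\hbar}\langle V^2\rangle
#'   \sqrt{\frac{1}{4\pi\lambda k_B T}}
#'   \sum_{n=0}^{N} \frac{e^{-D} D^n}{n!}
#'   \exp\!\left[-\frac{(\Delta G + \lambda + n\hbar\omega)^2}
#'                     {4\lambda k_B T}\right]}
#' with \eqn{\lambda} the outer-sphere reorganization energy and the sum over
#' vibronic channels weighted by the Poisson (Huang--Rhys) factor.
#'
#' @param delta_G Standard reaction free energy of the hop (eV); negative is
#'   exergonic. Vectorized.
#' @param distance Edge-to-edge distance (Angstrom).
#' @param params An \code{hb_rate_params} object.
#' @return Rate in 1/s, strictly positive.
#' @seealso [marcus_rate()] for the single-mode classical limit (D = 0).
#' @examples
#' jortner_rate(-0.8, 5, rate_params())
#' @export
jortner_rate <- function(delta_G, distance, params) {
  stopifnot("delta_G must be finite" = all(is.finite(delta_G)))
  vsq <- coupling_squared(distance, params)
  lam <- params$lambda_outer
  kT <- .kB_eV_per_K * params$temperature
  n <- 0:params$n_max
  # dpois gives exp(-D) D^n / n! stably, including the D = 0 point mass at n = 0
  w <- stats::dpois(n, params$huang_rhys)
  fc <- vapply(delta_G, function(dg) {
    sum(w * exp(-(dg + lam + n * params$hbar_omega)^2 / (4 * lam * kT)))
  }, numeric(1))
  (2 * pi / .hbar_eV_s) * vsq * sqrt(1 / (4 * pi * lam * kT)) * fc
}

#' Classical Marcus rate (single-Gaussian limit)
#'
#' The closed-form nonadiabatic rate with a single classical mode of
#' reorganization energy \code{lambda_outer}; it is the exact
#' \eqn{D \to 0} limit of [jortner_rate()] and serves as its analytic oracle.
#'
#' @inheritParams jortner_rate
#' @return Rate in 1/s. Maximal over \code{delta_G} at
#'   \code{delta_G = -lambda_outer} (activationless point).
#' @export
marcus_rate <- function(delta_G, distance, params) {
  stopifnot("delta_G must be finite" = all(is.finite(delta_G)))
  vsq <- coupling_squared(distance, params)
  lam <- params$lambda_outer
  kT <- .kB_eV_per_K * params$temperature
  (2 * pi / .hbar_eV_s) * vsq * sqrt(1 / (4 * pi * lam * kT)) *
    exp(-(delta_G + lam)^2 / (4 * lam * kT))
}
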