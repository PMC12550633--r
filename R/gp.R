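#' Squared-exponential (RBF) kernel
#'
#' \eqn{k(x, x^*) = \sigma_f^2 \exp(-\|x - x^*\|^2 / 2\ell^2)}. Inputs are
#' expected in the optimizer's scaled coordinates (each design coordinate
#' min--max scaled to [0, 1] by its bounds), so a single length scale is
#' meaningful across potentials (V) and distances (Angstrom).
#'
#' @param X,Y Numeric matrices, one row per point, same number of columns
#'   (vectors are treated as single rows).
#' @param sigma_f_sq Kernel variance \eqn{\sigma_f^2 > 0}.
#' @param length_scale Length scale \eqn{\ell > 0} (scaled units).
#' @return \code{nrow(X) x nrow(Y)} covariance matrix.
#' @export
rbf_kernel <- function(X, Y, sigma_f_sq, length_scale) {
  stopifnot(sigma_f_sq > 0, length_scale > 0)
  X <- rbind(X); Y <- rbind(Y)
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
  d2[d2 < 0] <- 0   # clip round-off
  sigma_f_sq * exp(-d2 / (2 * length_scale^2))
}

#' Fit a Gaussian-process surrogate
#'
#' Zero-mean GP regression with the RBF kernel on observed
#' (design, objective) pairs. Observation noise defaults to zero
#' (deterministic simulator observations), so the posterior interpolates the
#' data exactly; a small jitter keeps the Gram factorization stable.
#'
#' @param X Matrix of observed designs (rows), in scaled [0, 1] coordinates.
#' @param y Observed objective values (e.g. bifurcation yields).
#' @param sigma_f_sq Kernel variance; default \code{var(y)} plus a floor.
#' @param length_scale RBF length scale in scaled units; default 0.2.
#' @param sigma_n_sq Observation noise variance; default 0.
#' @param jitter Diagonal jitter added to the Gram matrix.
#' @return Object of class \code{"hb_gp"}.
#' @export
gp_fit <- function(X, y, sigma_f_sq = NULL, length_scale = 0.2,
                   sigma_n_sq = 0, jitter = 1e-10) {
  X <- rbind(X)
  stopifnot("|X| must equal |y|" = nrow(X) == length(y),
            sigma_n_sq >= 0)
  if (is.null(sigma_f_sq)) sigma_f_sq <- max(stats::var(y), 1e-6)
  K <- rbf_kernel(X, X, sigma_f_sq, length_scale) +
    diag(sigma_n_sq + jitter, nrow(X))
  L <- tryCatch(chol(K), error = function(e)
    stop("Gram matrix not positive definite even after jitter: ",
         conditionMessage(e)))
  alpha <- backsolve(L, forwardsolve(t(L), y))
  structure(list(X = X, y = y, sigma_f_sq = sigma_f_sq,
                 length_scale = length_scale, sigma_n_sq = sigma_n_sq,
                 jitter = jitter, L = L, alpha = alpha),
            class = "hb_gp")
}

#' GP posterior mean and variance
#'
#' \eqn{\mu(x^*) = k^T (K + \sigma_n^2 I)^{-1} y}, and
#' \eqn{\sigma^2(x^*) = k(x^*, x^*) - k^T (K + \sigma_n^2 I)^{-1} k},
#' clipped at zero against round-off. Far from all observations the mean
#' reverts to the prior mean 0 and the variance to \eqn{\sigma_f^2}.
#'
#' @param model An [gp_fit()] object.
#' @param X_star Query points, one row each (scaled coordinates).
#' @return List with vectors \code{mean} and \code{variance}.
#' @export
gp_posterior <- function(model, X_star) {
  X_star <- rbind(X_star)
  ks <- rbf_kernel(model$X, X_star, model$sigma_f_sq, model$length_scale)
  mu <- unname(drop(crossprod(ks, model$alpha)))
  # diag of ks^T K^-1 ks via one triangular solve against the Cholesky factor
  w <- forwardsolve(t(model$L), ks)
  var <- model$sigma_f_sq - colSums(w^2)
  var[var < 0] <- 0
  list(mean = mu, variance = unname(var))
}

#' Upper-confidence-bound acquisition
#'
#' \eqn{\alpha(x) = \mu(x) + \kappa \sigma(x)}: large \code{kappa} favours
#' exploration of uncertain regions, small \code{kappa} exploitation of high
#' predicted means.
#'
#' @param mean,std Posterior mean and standard deviation (std >= 0).
#' @param kappa Exploration--exploitation trade-off, >= 0.
#' @return Acquisition value(s).
#' @export
ucb <- function(mean, std, kappa) {
  stopifnot(all(std >= 0), kappa >= 0)
  mean + kappa * std
}

#' Propose the next design by maximizing the UCB acquisition
#'
#' Approximate \eqn{\arg\max_x \alpha(x)} over the unit box (scaled
#' coordinates): score a seeded batch of uniform candidates, then refine the
#' best by cyclic coordinate-wise golden-section search. Deterministic for a
#' fixed seed.
#'
#' @param model An [gp_fit()] object.
#' @param d Dimension of the design space.
#' @param kappa UCB trade-off.
#' @param seed Integer RNG seed for the candidate batch.
#' @param n_candidates Size of the uniform candidate batch.
#' @param refine_iters Passes of coordinate-wise refinement.
#' @return Numeric vector of length \code{d} in [0, 1]^d.
#' @export
propose_next <- function(model, d, kappa = 2, seed = 1,
                         n_candidates = 2048, refine_iters = 2) {
  acq <- function(xm) {
    post <- gp_posterior(model, xm)
    ucb(post$mean, sqrt(post$variance), kappa)
  }
  cand <- matrix(local_runif(n_candidates * d, seed = seed),
                 ncol = d)
  best <- cand[which.max(acq(cand)), ]
  phi <- (sqrt(5) - 1) / 2
  for (pass in seq_len(refine_iters)) {
    for (j in seq_len(d)) {
      lo <- 0; hi <- 1
      f1 <- function(v) { x <- best; x[j] <- v; acq(rbind(x)) }
      a <- hi - phi * (hi - lo); b <- lo + phi * (hi - lo)
      fa <- f1(a); fb <- f1(b)
      for (it in 1:40) {
        if (fa < fb) { lo <- a; a <- b; fa <- fb
                       b <- lo + phi * (hi - lo); fb <- f1(b)
        } else { hi <- b; b <- a; fb <- fa
                 a <- hi - phi * (hi - lo); fa <- f1(a) }
      }
      v <- (lo + hi) / 2
      if (f1(v) > acq(rbind(best))) best[j] <- v
    }
  }
  best
}

# Seeded uniform draws that do not disturb the caller's RNG stream.
local_runif <- function(n, seed, min = 0, max = 1) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  stats::runif(n, min, max)
}
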