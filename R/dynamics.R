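#' Build the microstate transition-rate matrix
#'
#' Assembles the generator \eqn{K} of the master equation
#' \eqn{dP/dt = K P}: for every allowed single-hole hop \eqn{a \to b},
#' entry \eqn{K_{ba}} is the vibronic rate [jortner_rate()] evaluated at
#' \eqn{\Delta G = E(b) - E(a)} and the hop edge's distance; each diagonal
#' entry is minus the sum of the rates leaving its column's state, so every
#' column sums to zero and \eqn{e^{Kt}} conserves probability.
#'
#' Terminal hole acceptors are treated as traps: hops out of a cofactor with
#' role \code{"terminus"} are excluded (\code{absorbing_termini = TRUE}).
#' The termini stand for chemically distinct capture cofactors outside the
#' hopping manifold, and the observable is the probability that holes have
#' \emph{arrived} there; with re-emission allowed, the two-termini state is
#' not the network's free-energy minimum once the repulsion at the vacated
#' dimer switches off, and the arrival curves would not rise monotonically
#' to saturation. Set \code{absorbing_termini = FALSE} for a fully
#' reversible (detailed-balance) network.
#'
#' @param space An [enumerate_states()] state space.
#' @param absorbing_termini Exclude hops leaving terminus-role sites?
#' @return Dense numeric matrix (class \code{"hb_rate_matrix"}), square over
#'   the state-space ordering, units 1/s.
#' @export
build_rate_matrix <- function(space, absorbing_termini = TRUE) {
  ls <- space$landscape
  n <- nrow(space$states)
  energies <- apply(space$states, 1, state_energy, ls = ls)
  K <- matrix(0, n, n)
  tr <- allowed_transitions(space)
  if (absorbing_termini && nrow(tr)) {
    term <- ls$cofactors$id[ls$cofactors$role == "terminus"]
    tr <- tr[!(tr$donor %in% term), , drop = FALSE]
  }
  if (nrow(tr)) {
    dG <- energies[tr$to_state] - energies[tr$from_state]
    rates <- jortner_rate(dG, tr$distance, ls$rate_params)
    for (r in seq_len(nrow(tr)))
      K[tr$to_state[r], tr$from_state[r]] <-
        K[tr$to_state[r], tr$from_state[r]] + rates[r]
  }
  diag(K) <- -colSums(K)
  structure(K, class = c("hb_rate_matrix", "matrix", "array"),
            energies = energies)
}

#' Propagate the master equation
#'
#' Solves \eqn{P(t) = e^{Kt} P(0)} at each requested time, either by the
#' matrix exponential (default; scaling-and-squaring via \pkg{Matrix}) or by
#' stiff ODE integration (\code{deSolve::lsoda} with the exact analytic
#' Jacobian \eqn{K}). The two back ends agree to high accuracy and serve as
#' mutual cross-checks; the ODE route is useful for very large state spaces
#' where repeated exponentials are costly.
#'
#' @param K Rate matrix from [build_rate_matrix()] (any square generator
#'   with zero column sums works).
#' @param P0 Initial probability vector (non-negative, sums to 1).
#' @param times Numeric vector of times (s), non-negative.
#' @param method \code{"expm"} or \code{"ode"}.
#' @return Object of class \code{"hb_trajectory"}: list with \code{times}
#'   and \code{probabilities} (matrix, one row per time, one column per
#'   state).
#' @export
propagate <- function(K, P0, times, method = c("expm", "ode")) {
  method <- match.arg(method)
  n <- nrow(K)
  if (length(P0) != n) stop("P0 length does not match the rate matrix")
  if (any(P0 < 0) || abs(sum(P0) - 1) > 1e-9)
    stop("P0 must be a probability vector (non-negative, summing to 1)")
  if (any(times < 0)) stop("times must be non-negative")
  ord <- order(times)
  ts <- times[ord]
  P <- matrix(NA_real_, length(ts), n)
  if (method == "expm") {
    for (i in seq_along(ts)) {
      P[i, ] <- if (ts[i] == 0) P0
                else as.numeric(stochastic_expm(unclass(K), ts[i]) %*% P0)
    }
  } else {
    deriv <- function(t, y, parms) list(as.numeric(parms %*% y))
    jac <- function(t, y, parms) parms
    t_ode <- ts
    pad <- !any(t_ode == 0)
    if (pad) t_ode <- c(0, t_ode)
    sol <- deSolve::lsoda(y = P0, times = t_ode, func = deriv,
                          parms = unclass(K), jacfunc = jac,
                          jactype = "fullusr",
                          rtol = 1e-10, atol = 1e-12)
    vals <- sol[, -1, drop = FALSE]
    if (pad) vals <- vals[-1, , drop = FALSE]
    P[] <- vals
  }
  P[ord, ] <- P
  structure(list(times = times, probabilities = P),
            class = "hb_trajectory")
}

#' @export
print.hb_trajectory <- function(x, ...) {
  cat(sprintf("Master-equation trajectory: %d times in [%g, %g] s over %d states\n",
              length(x$times), min(x$times), max(x$times),
              ncol(x$probabilities)))
  invisible(x)
}

# e^{Kt} for a generator K (zero column sums, non-negative off-diagonals),
# preserving column-stochasticity exactly. The exponential is taken at a
# scaled time with ||K t / 2^s||_1 <= 1 (where Pade approximation is very
# accurate), then squared s times; after each step the columns are clipped
# at zero and renormalized to sum 1, the projection onto the stochastic
# matrices that the exact result is known to lie in. Without this, round-off
# in repeated squaring at ||Kt|| ~ 1e10 leaks probability at the 1e-6 level.
stochastic_expm <- function(K, t) {
  nrm <- max(colSums(abs(K))) * t
  s <- max(0L, ceiling(log2(max(nrm, 1))))
  M <- as.matrix(Matrix::expm(Matrix::Matrix(K * (t / 2^s))))
  fix <- function(m) {
    m[m < 0] <- 0
    sweep(m, 2, colSums(m), "/")
  }
  M <- fix(M)
  for (i in seq_len(s)) M <- fix(M %*% M)
  M
}

#' Default logarithmic reporting grid
#'
#' @param t_min,t_max Grid end points (s).
#' @param n Number of points, logarithmically spaced.
#' @return Numeric vector of times.
#' @export
default_time_grid <- function(t_min = 1e-9, t_max = 1, n = 60) {
  10^seq(log10(t_min), log10(t_max), length.out = n)
}

# Initial condition (both bifurcation sites occupied) and the bifurcation
# target (one hole on each pathway terminus), identified by role.
bifurcation_states <- function(space) {
  co <- space$landscape$cofactors
  bif <- co$id[co$role == "bifurcation_site"]
  term <- co$id[co$role == "terminus"]
  if (length(term) != 2 || !all(c("hot", "cold") %in% co$pathway[co$role == "terminus"]))
    stop("landscape must declare exactly one hot and one cold terminus")
  list(initial = state_index(space, bif),
       target = state_index(space, term),
       hot_terminus = co$id[co$role == "terminus" & co$pathway == "hot"],
       cold_terminus = co$id[co$role == "terminus" & co$pathway == "cold"])
}

#' Bifurcation quantum yield
#'
#' The probability, at \code{t_final} after hole injection, of the microstate
#' with exactly one hole on each pathway terminus, starting from the doubly
#' occupied bifurcation pair. A yield near 1 means the two holes partition
#' 1:1 onto the hot and cold pathways; holes that exit down the same pathway
#' or stall en route count against it.
#'
#' @param ls An [landscape()] with one hot and one cold terminus.
#' @param t_final Evaluation time (s); default 1 s, long enough for the
#'   canonical design to run to completion.
#' @param method Propagation back end, see [propagate()].
#' @return Yield as a fraction in [0, 1].
#' @examples
#' \donttest{quantum_yield(canonical_landscape())}
#' @export
quantum_yield <- function(ls, t_final = 1, method = "expm") {
  space <- enumerate_states(ls, 2)
  marks <- bifurcation_states(space)
  if (t_final == 0) return(0)
  K <- build_rate_matrix(space)
  P0 <- numeric(nrow(space$states)); P0[marks$initial] <- 1
  traj <- propagate(K, P0, t_final, method = method)
  traj$probabilities[1, marks$target]
}

#' Terminus arrival curves
#'
#' Marginal occupancy probability of the hot and cold termini versus time,
#' starting from the doubly occupied bifurcation pair. Termini have no
#' downhill exits in the canonical design, so these curves rise
#' monotonically toward 1.
#'
#' @param ls An [landscape()].
#' @param times Times (s); defaults to 60 points logarithmic in
#'   [1e-9, 1] s.
#' @param method Propagation back end.
#' @return Object of class \code{"hb_arrival"}: data.frame with columns
#'   \code{time}, \code{hot}, \code{cold}; the landscape is attached as an
#'   attribute so [completion_time()] can refine crossings.
#' @export
arrival_curves <- function(ls, times = default_time_grid(),
                           method = "expm") {
  space <- enumerate_states(ls, 2)
  marks <- bifurcation_states(space)
  K <- build_rate_matrix(space)
  P0 <- numeric(nrow(space$states)); P0[marks$initial] <- 1
  traj <- propagate(K, P0, times, method = method)
  occ <- function(id) {
    col <- which(colnames(space$states) == id)
    as.numeric(traj$probabilities %*% space$states[, col])
  }
  out <- data.frame(time = times,
                    hot = occ(marks$hot_terminus),
                    cold = occ(marks$cold_terminus))
  class(out) <- c("hb_arrival", "data.frame")
  attr(out, "landscape") <- ls
  out
}

#' Threshold-crossing (completion) time of a terminus
#'
#' First time the terminus occupancy probability exceeds \code{threshold},
#' located by bisection in log-time between the last grid point below and
#' the first above the threshold (the occupancy is recomputed exactly at
#' each probe, so the result does not depend on the reporting grid).
#'
#' @param curves An [arrival_curves()] object.
#' @param terminus \code{"hot"} or \code{"cold"}.
#' @param threshold Fraction in (0, 1); 0.5 by default (the convention used
#'   for "completion" here, since saturation times are grid-dependent).
#' @param tol Relative bisection tolerance on the time.
#' @return Crossing time in s, or \code{NA} with a warning if the curve
#'   never reaches the threshold on the simulated horizon.
#' @export
completion_time <- function(curves, terminus = c("hot", "cold"),
                            threshold = 0.5, tol = 1e-3) {
  terminus <- match.arg(terminus)
  stopifnot(threshold > 0, threshold < 1)
  ls <- attr(curves, "landscape")
  p <- curves[[terminus]]
  above <- which(p >= threshold)
  if (!length(above)) {
    warning("terminus occupancy never reaches ", threshold,
            " within the simulated horizon")
    return(NA_real_)
  }
  hi_i <- above[1]
  if (hi_i == 1) return(curves$time[1])
  lo <- curves$time[hi_i - 1]; hi <- curves$time[hi_i]
  space <- enumerate_states(ls, 2)
  marks <- bifurcation_states(space)
  K <- build_rate_matrix(space)
  P0 <- numeric(nrow(space$states)); P0[marks$initial] <- 1
  col <- which(colnames(space$states) ==
                 if (terminus == "hot") marks$hot_terminus else marks$cold_terminus)
  occ_at <- function(t) {
    traj <- propagate(K, P0, t)
    sum(traj$probabilities[1, space$states[, col] == 1L])
  }
  while (hi / lo > 1 + tol) {
    mid <- sqrt(lo * hi)
    if (occ_at(mid) >= threshold) hi <- mid else lo <- mid
  }
  sqrt(lo * hi)
}

#' Export a trajectory or arrival curves as CSV
#'
#' @param x An \code{hb_trajectory} or \code{hb_arrival} object.
#' @param path Output CSV path. Columns: time in seconds, then one
#'   probability column per state (trajectory, named by occupied sites) or
#'   per terminus.
#' @param space For trajectories, the state space used to build them
#'   (supplies column labels); optional.
#' @return \code{path}, invisibly.
#' @export
write_curves_csv <- function(x, path, space = NULL) {
  if (inherits(x, "hb_arrival")) {
    df <- data.frame(time_s = x$time, hot = x$hot, cold = x$cold)
  } else if (inherits(x, "hb_trajectory")) {
    df <- as.data.frame(x$probabilities)
    names(df) <- if (!is.null(space)) {
      apply(space$states, 1, function(s)
        paste(colnames(space$states)[s == 1L], collapse = "+"))
    } else paste0("state", seq_len(ncol(df)))
    df <- cbind(time_s = x$times, df)
  } else stop("x must be an hb_trajectory or hb_arrival object")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
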