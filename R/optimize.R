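#' Tunable design coordinates of a landscape
#'
#' A design vector names the landscape fields the optimizer may move:
#' \code{"pot:<id>"} for a cofactor's potential (V) and
#' \code{"dist:<from>-<to>"} for an edge distance (Angstrom), each with a
#' closed bounds interval. [apply_design()] writes a design vector back into
#' a landscape; all validation re-runs, so an out-of-schema design fails
#' loudly.
#'
#' @param ls A [landscape()].
#' @param x Named numeric vector of design coordinates (physical units).
#' @return A validated \code{hb_landscape} with the coordinates applied.
#' @examples
#' ls <- apply_design(canonical_landscape(), c("pot:WH1" = 1.85, "dist:W2-WL1" = 9))
#' @export
apply_design <- function(ls, x) {
  for (nm in names(x)) {
    parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop("malformed coordinate name \"", nm, "\"")
    if (parts[1] == "pot") {
      i <- match(parts[2], ls$cofactors$id)
      if (is.na(i)) stop("unknown cofactor in coordinate \"", nm, "\"")
      ls$cofactors$potential[i] <- x[[nm]]
    } else if (parts[1] == "dist") {
      ends <- strsplit(parts[2], "-", fixed = TRUE)[[1]]
      if (length(ends) != 2) stop("malformed edge coordinate \"", nm, "\"")
      i <- which((ls$edges$from == ends[1] & ls$edges$to == ends[2]) |
                   (ls$edges$from == ends[2] & ls$edges$to == ends[1]))
      if (!length(i)) stop("unknown edge in coordinate \"", nm, "\"")
      ls$edges$distance[i] <- x[[nm]]
    } else stop("coordinate prefix must be pot: or dist: in \"", nm, "\"")
  }
  validate_landscape(ls)
}

scale_to_unit <- function(x, bounds) {
  vapply(seq_along(x), function(j) {
    b <- bounds[[j]]
    if (b[2] > b[1]) (x[j] - b[1]) / (b[2] - b[1]) else 0.5
  }, numeric(1))
}

unscale_from_unit <- function(u, bounds) {
  out <- vapply(seq_along(u), function(j) {
    b <- bounds[[j]]
    b[1] + u[j] * (b[2] - b[1])
  }, numeric(1))
  names(out) <- names(bounds)
  out
}

#' Bayesian optimization of the bifurcation yield
#'
#' Searches the given design coordinates (potentials, distances) for a
#' landscape maximizing the bifurcation quantum yield at \code{t_final},
#' using a Gaussian-process surrogate with RBF kernel and the
#' upper-confidence-bound acquisition. Initial designs are drawn uniformly
#' within the bounds; each iteration fits the GP to all observations,
#' proposes the UCB argmax ([propose_next()]), and evaluates the true yield
#' there.
#'
#' Coordinates are min--max scaled to [0, 1] by their bounds inside the GP,
#' so the single length scale applies across volts and angstroms.
#'
#' @param base A [landscape()] template.
#' @param tunables Named list of length-2 numeric bounds; names as in
#'   [apply_design()] (\code{"pot:<id>"}, \code{"dist:<from>-<to>"}).
#' @param n_init Number of uniform random initial designs.
#' @param n_iter Number of GP-guided iterations after initialization.
#' @param kappa UCB exploration weight.
#' @param seed Integer seed controlling all randomness; fixed seed gives an
#'   identical search trajectory.
#' @param t_final Objective evaluation time (s).
#' @param length_scale GP length scale in scaled units.
#' @return List of class \code{"hb_bayesopt"}: \code{best_x} (named design
#'   vector, physical units), \code{best_y} (its yield),
#'   \code{best_landscape}, and \code{history} (data.frame with one row per
#'   evaluation: the coordinates, \code{yield}, and the running
#'   \code{incumbent}).
#' @export
optimize_landscape <- function(base, tunables, n_init = 8, n_iter = 20,
                               kappa = 2, seed = 1, t_final = 1,
                               length_scale = 0.2) {
  stopifnot(length(tunables) > 0)
  bad <- vapply(tunables, function(b)
    length(b) != 2 || !all(is.finite(b)) || b[1] > b[2], logical(1))
  if (any(bad)) stop("malformed bounds for ", names(tunables)[bad][1])
  d <- length(tunables)
  objective <- function(u) {
    x <- unscale_from_unit(u, tunables)
    quantum_yield(apply_design(base, x), t_final = t_final)
  }
  U <- matrix(local_runif(n_init * d, seed = seed), ncol = d)
  y <- apply(U, 1, objective)
  for (it in seq_len(n_iter)) {
    model <- gp_fit(U, y, length_scale = length_scale)
    u_next <- propose_next(model, d, kappa = kappa, seed = seed + it)
    U <- rbind(U, u_next)
    y <- c(y, objective(u_next))
  }
  X_phys <- do.call(rbind, lapply(seq_len(nrow(U)), function(i)
    unscale_from_unit(U[i, ], tunables)))
  colnames(X_phys) <- names(tunables)
  hist <- as.data.frame(X_phys)
  hist$yield <- y
  hist$incumbent <- cummax(y)
  i_best <- which.max(y)
  best_x <- unscale_from_unit(U[i_best, ], tunables)
  structure(list(best_x = best_x, best_y = y[i_best],
                 best_landscape = apply_design(base, best_x),
                 history = hist),
            class = "hb_bayesopt")
}

#' @export
print.hb_bayesopt <- function(x, ...) {
  cat(sprintf("Bayesian yield optimization: %d evaluations, best yield %.4f\n",
              nrow(x$history), x$best_y))
  cat("Best design:\n")
  print(round(x$best_x, 4))
  invisible(x)
}
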