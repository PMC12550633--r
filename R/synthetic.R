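#' Random landscape on a template topology
#'
#' Draws relay and terminus potentials and all edge distances uniformly
#' within the given bounds, keeping the template's topology, roles,
#' bifurcation-site potentials and interaction terms fixed. This is the
#' sampling scheme behind the optimizer's initial designs and behind the
#' package's property tests: every generated landscape passes full
#' validation.
#'
#' @param template A [landscape()] supplying topology and fixed fields.
#' @param potential_bounds Length-2 vector, V; bounds for relay/terminus
#'   potentials.
#' @param distance_bounds Length-2 vector, Angstrom; bounds for edge
#'   distances.
#' @param seed Integer seed; fixed seed reproduces the landscape.
#' @return A validated \code{hb_landscape}.
#' @export
random_landscape <- function(template, potential_bounds = c(1.0, 2.0),
                             distance_bounds = c(5, 12), seed = 1) {
  if (potential_bounds[1] > potential_bounds[2])
    stop("potential_bounds are inverted")
  if (distance_bounds[1] > distance_bounds[2])
    stop("distance_bounds are inverted")
  ls <- template
  free <- ls$cofactors$role != "bifurcation_site"
  n_p <- sum(free); n_d <- nrow(ls$edges)
  u <- local_runif(n_p + n_d, seed = seed)
  ls$cofactors$potential[free] <-
    potential_bounds[1] + u[seq_len(n_p)] * diff(potential_bounds)
  ls$edges$distance <-
    distance_bounds[1] + u[n_p + seq_len(n_d)] * diff(distance_bounds)
  validate_landscape(ls)
}

#' Perturbed copy of the canonical bifurcation landscape
#'
#' Adds independent uniform perturbations (on \code{[-scale, +scale]}) to
#' every potential and every edge distance of [canonical_landscape()]. Used as a
#' parameter-recovery harness: small perturbations stay inside the
#' high-yield basin the optimizer is expected to find.
#'
#' @param noise_scale_potential Half-width of the potential perturbation (V).
#' @param noise_scale_distance Half-width of the distance perturbation
#'   (Angstrom).
#' @param seed Integer seed.
#' @return A validated \code{hb_landscape}; with both scales zero, exactly
#'   the canonical fixture.
#' @export
perturbed_canonical <- function(noise_scale_potential = 0.02,
                           noise_scale_distance = 0.2, seed = 1) {
  ls <- canonical_landscape()
  n_p <- nrow(ls$cofactors); n_d <- nrow(ls$edges)
  u <- local_runif(n_p + n_d, seed = seed, min = -1, max = 1)
  ls$cofactors$potential <- ls$cofactors$potential +
    noise_scale_potential * u[seq_len(n_p)]
  ls$edges$distance <- pmax(ls$edges$distance +
                              noise_scale_distance * u[n_p + seq_len(n_d)],
                            0.1)
  validate_landscape(ls)
}
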