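# Shared fixtures built in code.

# two relay sites joined by one edge; no interactions
toy_two_site <- function(potential_a = 1.5, potential_b = 1.5,
                         distance = 5) {
  landscape(
    cofactors = data.frame(
      id = c("A", "B"),
      role = c("relay", "relay"),
      pathway = c("hot", "cold"),
      potential = c(potential_a, potential_b)),
    edges = data.frame(from = "A", to = "B", distance = distance)
  )
}

# a synthetic Trp residue: nine indole ring heavy atoms on a planar outline
# (two fused rings approximated by their standard 2-D template), plus any
# extra atoms (e.g. hydrogens) supplied by the caller. `transform` is applied
# to all coordinates (rows).
synthetic_trp <- function(extra = NULL,
                          transform = function(m) m) {
  # idealized planar indole template (x, y in Angstrom, z = 0)
  ring2d <- rbind(
    CG  = c(0.00, 0.00), CD1 = c(1.10, 0.80), NE1 = c(2.20, 0.00),
    CD2 = c(0.35, -1.35), CE2 = c(1.75, -1.35), CE3 = c(-0.35, -2.55),
    CZ2 = c(2.45, -2.55), CZ3 = c(0.35, -3.75), CH2 = c(1.75, -3.75))
  m <- cbind(ring2d, z = 0)
  nm <- rownames(ring2d)
  if (!is.null(extra)) {
    m <- rbind(m, as.matrix(extra[, c("x", "y", "z")]))
    nm <- c(nm, extra$name)
  }
  m <- transform(m)
  data.frame(name = nm, x = m[, 1], y = m[, 2], z = m[, 3])
}

rotate_x <- function(deg) {
  th <- deg * pi / 180
  R <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
  function(m) m %*% t(R)
}

rigid_motion <- function(deg_z = 25, shift = c(3, -2, 7)) {
  th <- deg_z * pi / 180
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  function(m) sweep(m %*% t(R), 2, -shift)
}

apply_to_pair <- function(pair, f) {
  tweak <- function(at) {
    m <- f(as.matrix(at[, c("x", "y", "z")]))
    at$x <- m[, 1]; at$y <- m[, 2]; at$z <- m[, 3]
    at
  }
  trp_pair(tweak(pair$atoms_a), tweak(pair$atoms_b))
}
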