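#' Enumerate hole-occupancy microstates
#'
#' A microstate assigns 0 or 1 hole to each cofactor (site exclusion: at most
#' one hole per site). The state space at a fixed total hole count is the set
#' of all \eqn{\binom{n_{sites}}{n_{holes}}} occupancy vectors, ordered
#' lexicographically so that indexing is deterministic.
#'
#' @param ls An [landscape()] object.
#' @param n_holes Total number of holes, between 0 and the number of sites.
#' @return An object of class \code{"hb_state_space"}: a list with
#'   \code{states} (matrix, one row per microstate, columns in the
#'   landscape's cofactor order), \code{landscape}, and \code{n_holes}.
#' @examples
#' sp <- enumerate_states(canonical_landscape(), 2)
#' nrow(sp$states)   # choose(8, 2) = 28
#' @export
enumerate_states <- function(ls, n_holes) {
  n <- nrow(ls$cofactors)
  if (n_holes < 0 || n_holes > n)
    stop("n_holes must lie in [0, ", n, "]")
  combos <- if (n_holes == 0) matrix(integer(0), ncol = 0, nrow = 1)
            else t(utils::combn(n, n_holes))
  states <- matrix(0L, nrow = nrow(combos), ncol = n,
                   dimnames = list(NULL, ls$cofactors$id))
  for (i in seq_len(nrow(combos))) states[i, combos[i, ]] <- 1L
  # lexicographic order on the occupancy vectors
  ord <- do.call(order, as.data.frame(states))
  structure(list(states = states[ord, , drop = FALSE],
                 landscape = ls, n_holes = as.integer(n_holes)),
            class = "hb_state_space")
}

#' @export
print.hb_state_space <- function(x, ...) {
  cat(sprintf("Microstate space: %d holes on %d sites -> %d states\n",
              x$n_holes, ncol(x$states), nrow(x$states)))
  invisible(x)
}

#' Locate a microstate by occupancy
#'
#' @param space An \code{hb_state_space}.
#' @param occupied Character vector of occupied cofactor ids.
#' @return Row index of the matching microstate.
#' @export
state_index <- function(space, occupied) {
  target <- as.integer(colnames(space$states) %in% occupied)
  if (sum(target) != space$n_holes)
    stop("occupancy names ", sum(target), " sites but the space holds ",
         space$n_holes, " holes")
  idx <- which(apply(space$states, 1, function(s) all(s == target)))
  if (!length(idx)) stop("state not found")
  idx
}

#' Free energy of a microstate
#'
#' The hole free energy of an occupancy vector: each hole contributes the
#' unit charge times its site potential (V, hence eV), and every interaction
#' pair with both members occupied adds its repulsion energy. Holes therefore
#' relax from high- to low-potential sites, and doubly occupying a repulsive
#' pair stores the pair energy.
#'
#' @param state 0/1 occupancy vector in the landscape's cofactor order.
#' @param ls The [landscape()].
#' @return Energy in eV.
#' @examples
#' ls <- canonical_landscape()
#' sp <- enumerate_states(ls, 2)
#' state_energy(sp$states[state_index(sp, c("W1", "W2")), ], ls)  # 3.8 eV
#' @export
state_energy <- function(state, ls) {
  e <- sum(state * ls$cofactors$potential)
  it <- ls$interactions
  if (nrow(it)) {
    ia <- match(it$site_a, ls$cofactors$id)
    ib <- match(it$site_b, ls$cofactors$id)
    e <- e + sum(it$epsilon * state[ia] * state[ib])
  }
  e
}

#' Single-hole transitions allowed by the hop graph
#'
#' Two microstates are connected iff they differ by moving exactly one hole
#' across exactly one declared edge (the destination site must be empty:
#' site exclusion). Both directions are listed, each carrying its edge.
#'
#' @param space An \code{hb_state_space}.
#' @return data.frame with columns \code{from_state}, \code{to_state} (row
#'   indices into \code{space$states}), \code{donor}, \code{acceptor}
#'   (cofactor ids) and \code{distance} (Angstrom).
#' @export
allowed_transitions <- function(space) {
  ls <- space$landscape
  st <- space$states
  ids <- colnames(st)
  # index lookup: key each occupancy pattern
  key <- apply(st, 1, paste, collapse = "")
  lookup <- stats::setNames(seq_along(key), key)
  out <- vector("list", 2L * nrow(ls$edges) * nrow(st))
  n_out <- 0L
  for (i in seq_len(nrow(st))) {
    s <- st[i, ]
    for (e in seq_len(nrow(ls$edges))) {
      a <- ls$edges$from[e]; b <- ls$edges$to[e]
      ia <- match(a, ids); ib <- match(b, ids)
      for (dir in 1:2) {
        don <- if (dir == 1) ia else ib
        acc <- if (dir == 1) ib else ia
        if (s[don] == 1L && s[acc] == 0L) {
          s2 <- s; s2[don] <- 0L; s2[acc] <- 1L
          j <- lookup[[paste(s2, collapse = "")]]
          n_out <- n_out + 1L
          out[[n_out]] <- data.frame(
            from_state = i, to_state = j,
            donor = ids[don], acceptor = ids[acc],
            distance = ls$edges$distance[e])
        }
      }
    }
  }
  if (n_out == 0L)
    return(data.frame(from_state = integer(), to_state = integer(),
                      donor = character(), acceptor = character(),
                      distance = numeric()))
  do.call(rbind, out[seq_len(n_out)])
}
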