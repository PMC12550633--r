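#' Coordinates of a tryptophan pair
#'
#' Holds labeled 3D coordinates (Angstrom) for two Trp residues, hydrogens
#' included, for the contact-geometry statistics that characterize a
#' bifurcating dimer: closest H--H distance, indole inter-plane angle, and
#' projected ring overlap area.
#'
#' @param atoms_a,atoms_b data.frames with columns \code{name} (PDB atom
#'   name, e.g. \code{"CG"}, \code{"HE1"}) and \code{x}, \code{y}, \code{z}.
#' @return Object of class \code{"hb_trp_pair"}.
#' @export
trp_pair <- function(atoms_a, atoms_b) {
  chk <- function(df, which) {
    if (!all(c("name", "x", "y", "z") %in% names(df)))
      stop("atoms_", which, " must have columns name, x, y, z")
    df
  }
  structure(list(atoms_a = chk(atoms_a, "a"), atoms_b = chk(atoms_b, "b")),
            class = "hb_trp_pair")
}

# the nine indole ring heavy atoms, standard PDB names
.indole_ring_atoms <- c("CG", "CD1", "CD2", "NE1", "CE2", "CE3",
                        "CZ2", "CZ3", "CH2")

ring_coords <- function(atoms) {
  m <- as.matrix(atoms[atoms$name %in% .indole_ring_atoms,
                       c("x", "y", "z")])
  if (nrow(m) < 3)
    stop("residue supplies only ", nrow(m),
         " indole ring atoms; need the ring to define a plane")
  m
}

is_hydrogen <- function(name) grepl("^[0-9]*H", name)

#' Read a Trp pair from a PDB file
#'
#' Extracts two residues (all atoms, hydrogens included) from a PDB file via
#' \pkg{bio3d}.
#'
#' @param path PDB file path.
#' @param resno_a,resno_b Residue numbers of the two tryptophans.
#' @param chain_a,chain_b Chain identifiers; \code{NULL} matches any chain.
#' @return An [trp_pair()] object.
#' @export
read_trp_pair_pdb <- function(path, resno_a, resno_b,
                              chain_a = NULL, chain_b = NULL) {
  pdb <- bio3d::read.pdb(path)
  grab <- function(resno, chain) {
    sel <- pdb$atom$resno == resno
    if (!is.null(chain)) sel <- sel & pdb$atom$chain == chain
    at <- pdb$atom[sel, ]
    if (!nrow(at)) stop("no atoms for residue ", resno,
                        if (!is.null(chain)) paste0(" chain ", chain))
    data.frame(name = at$elety, x = at$x, y = at$y, z = at$z)
  }
  trp_pair(grab(resno_a, chain_a), grab(resno_b, chain_b))
}

#' Closest hydrogen--hydrogen contact distance
#'
#' Minimum pairwise distance between the hydrogen atoms of the two residues.
#'
#' @param pair An [trp_pair()].
#' @return Distance in Angstrom.
#' @export
closest_hh_distance <- function(pair) {
  ha <- as.matrix(pair$atoms_a[is_hydrogen(pair$atoms_a$name),
                               c("x", "y", "z")])
  hb <- as.matrix(pair$atoms_b[is_hydrogen(pair$atoms_b$name),
                               c("x", "y", "z")])
  if (!nrow(ha) || !nrow(hb))
    stop("both residues must contain at least one hydrogen atom")
  d2 <- outer(rowSums(ha^2), rowSums(hb^2), "+") - 2 * tcrossprod(ha, hb)
  sqrt(max(min(d2), 0))
}

# least-squares plane: centroid + unit normal (smallest singular vector)
fit_plane <- function(m) {
  ctr <- colMeans(m)
  sv <- svd(sweep(m, 2, ctr))
  if (sv$d[2] < 1e-8 * sv$d[1])
    stop("ring atoms are degenerate (collinear); no plane is defined")
  list(centroid = ctr, normal = sv$v[, 3],
       basis = sv$v[, 1:2, drop = FALSE])
}

#' Angle between the indole ring planes
#'
#' Angle between the least-squares planes of the two nine-atom indole
#' rings, folded to [0, 90] degrees (plane orientation has no sign).
#'
#' @param pair An [trp_pair()].
#' @return Angle in degrees.
#' @export
interplane_angle <- function(pair) {
  na <- fit_plane(ring_coords(pair$atoms_a))$normal
  nb <- fit_plane(ring_coords(pair$atoms_b))$normal
  cosang <- abs(sum(na * nb)) / sqrt(sum(na^2) * sum(nb^2))
  acos(min(cosang, 1)) * 180 / pi
}

# Sutherland-Hodgman clipping of a convex subject polygon by a convex clip
# polygon (both counter-clockwise, rows = vertices, 2 columns).
clip_convex <- function(subject, clip) {
  out <- subject
  nc <- nrow(clip)
  for (i in seq_len(nc)) {
    if (nrow(out) == 0) break
    a <- clip[i, ]; b <- clip[if (i == nc) 1 else i + 1, ]
    inside <- function(p) (b[1] - a[1]) * (p[2] - a[2]) -
      (b[2] - a[2]) * (p[1] - a[1]) >= 0
    inter <- function(p, q) {
      # intersection of segment pq with the infinite line ab
      dc <- a - b; dp <- p - q
      n1 <- a[1] * b[2] - a[2] * b[1]
      n2 <- p[1] * q[2] - p[2] * q[1]
      den <- dc[1] * dp[2] - dc[2] * dp[1]
      c(n1 * dp[1] - n2 * dc[1], n1 * dp[2] - n2 * dc[2]) / den
    }
    inp <- out
    out <- matrix(numeric(0), ncol = 2)
    np <- nrow(inp)
    for (j in seq_len(np)) {
      p <- inp[j, ]; q <- inp[if (j == np) 1 else j + 1, ]
      if (inside(q)) {
        if (!inside(p)) out <- rbind(out, inter(p, q))
        out <- rbind(out, q)
      } else if (inside(p)) {
        out <- rbind(out, inter(p, q))
      }
    }
  }
  out
}

shoelace_area <- function(poly) {
  n <- nrow(poly)
  if (is.null(n) || n < 3) return(0)
  i2 <- c(2:n, 1)
  abs(sum(poly[, 1] * poly[i2, 2] - poly[i2, 1] * poly[, 2])) / 2
}

# counter-clockwise convex hull of 2-D points
ccw_hull <- function(pts) {
  h <- grDevices::chull(pts[, 1], pts[, 2])   # chull returns clockwise
  pts[rev(h), , drop = FALSE]
}

#' Projected overlap area of the two indole rings
#'
#' Projects both rings' heavy atoms onto the least-squares plane of the
#' first ring (the convention adopted here; the projection plane is the only
#' free choice in the statistic), takes the convex hull of each projected
#' nine-atom outline, and returns the area of the polygon intersection
#' (Sutherland--Hodgman clipping; both outlines are convex).
#'
#' @param pair An [trp_pair()].
#' @return Overlap area in square Angstrom (0 for disjoint projections).
#' @export
ring_overlap_area <- function(pair) {
  ra <- ring_coords(pair$atoms_a)
  rb <- ring_coords(pair$atoms_b)
  pl <- fit_plane(ra)
  proj <- function(m) sweep(m, 2, pl$centroid) %*% pl$basis
  pa <- ccw_hull(proj(ra))
  pb <- ccw_hull(proj(rb))
  shoelace_area(clip_convex(pa, pb))
}

#' Geometry statistics for one or more Trp pairs
#'
#' Convenience wrapper computing all three contact statistics, optionally
#' over multiple PDB models (frames).
#'
#' @param pairs A single [trp_pair()] or a list of them.
#' @return data.frame with columns \code{frame}, \code{closest_hh_A},
#'   \code{interplane_deg}, \code{overlap_A2}.
#' @export
trp_geometry_table <- function(pairs) {
  if (inherits(pairs, "hb_trp_pair")) pairs <- list(pairs)
  do.call(rbind, lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    data.frame(frame = i,
               closest_hh_A = closest_hh_distance(p),
               interplane_deg = interplane_angle(p),
               overlap_A2 = ring_overlap_area(p))
  }))
}
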