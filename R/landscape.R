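#' Construct a hole-hopping landscape
#'
#' A landscape is the abstract weighted graph on which hole transport is
#' simulated: redox cofactors with site potentials, undirected hop edges with
#' edge-to-edge distances, and pairwise repulsion terms that raise the energy
#' of microstates in which both members of a pair are occupied (the mechanism
#' that energizes the "hot" hole at a bifurcating dimer).
#'
#' Site potentials are stored in volts against the network's own reference
#' (conventionally the cold-pathway terminus); a hole's free energy on a site
#' is the unit charge times the site potential, so holes hop downhill in
#' potential. No conversion to an absolute electrode scale is attempted.
#'
#' @param cofactors data.frame with columns \code{id} (unique short labels),
#'   \code{role} (one of \code{"bifurcation_site"}, \code{"relay"},
#'   \code{"terminus"}), \code{pathway} (one of \code{"hot"}, \code{"cold"},
#'   \code{"bifurcation"}) and \code{potential} (V).
#' @param edges data.frame with columns \code{from}, \code{to} (cofactor ids)
#'   and \code{distance} (closest heavy-atom edge-to-edge distance, Angstrom).
#'   Edges are undirected; at most one per unordered pair.
#' @param interactions data.frame with columns \code{site_a}, \code{site_b}
#'   (cofactor ids) and \code{epsilon} (repulsion energy in eV added when both
#'   sites hold a hole). May have zero rows.
#' @param temperature Absolute temperature (K).
#' @param rate_params An [rate_params()] object; its temperature is kept in
#'   sync with \code{temperature}.
#'
#' @return A validated object of class \code{"hb_landscape"}.
#' @seealso [canonical_landscape()] for the canonical two-pathway fixture,
#'   [load_landscape()] / [save_landscape()] for YAML config I/O.
#' @export
landscape <- function(cofactors, edges,
                      interactions = data.frame(site_a = character(),
                                                site_b = character(),
                                                epsilon = numeric()),
                      temperature = 300,
                      rate_params = hbnet::rate_params()) {
  force(rate_params)
  rate_params$temperature <- temperature
  ls <- structure(
    list(cofactors = as.data.frame(cofactors),
         edges = as.data.frame(edges),
         interactions = as.data.frame(interactions),
         temperature = temperature,
         rate_params = rate_params),
    class = "hb_landscape"
  )
  validate_landscape(ls)
}

#' Validate a landscape
#'
#' Checks referential integrity (all edge and interaction endpoints name
#' existing cofactors), uniqueness of ids, positivity of distances,
#' non-negativity of repulsion energies, uniqueness of undirected edges, and
#' connectivity of the hop graph. Called by every constructor and loader.
#'
#' @param ls An \code{hb_landscape} object.
#' @return \code{ls}, invisibly usable, after passing all checks.
#' @export
validate_landscape <- function(ls) {
  co <- ls$cofactors
  req <- c("id", "role", "pathway", "potential")
  if (!all(req %in% names(co)))
    stop("cofactors must have columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(co$id))
    stop("duplicate cofactor id: ",
         paste(unique(co$id[duplicated(co$id)]), collapse = ", "))
  bad_role <- setdiff(co$role, c("bifurcation_site", "relay", "terminus"))
  if (length(bad_role)) stop("unknown cofactor role: ", bad_role[1])
  bad_path <- setdiff(co$pathway, c("hot", "cold", "bifurcation"))
  if (length(bad_path)) stop("unknown pathway: ", bad_path[1])
  if (!all(is.finite(co$potential)))
    stop("non-finite potential for cofactor: ",
         co$id[!is.finite(co$potential)][1])

  ed <- ls$edges
  if (!all(c("from", "to", "distance") %in% names(ed)))
    stop("edges must have columns: from, to, distance")
  unknown <- setdiff(c(ed$from, ed$to), co$id)
  if (length(unknown))
    stop("edge references unknown cofactor id \"", unknown[1], "\"")
  if (any(!is.finite(ed$distance) | ed$distance <= 0)) {
    i <- which(!is.finite(ed$distance) | ed$distance <= 0)[1]
    stop("non-positive distance on edge ", ed$from[i], "-", ed$to[i])
  }
  key <- apply(cbind(pmin(ed$from, ed$to), pmax(ed$from, ed$to)), 1,
               paste, collapse = "|")
  if (anyDuplicated(key))
    stop("duplicate edge between ", sub("\\|", " and ", key[duplicated(key)][1]))
  if (any(ed$from == ed$to)) stop("self-edge on ", ed$from[ed$from == ed$to][1])

  it <- ls$interactions
  if (nrow(it)) {
    unknown <- setdiff(c(it$site_a, it$site_b), co$id)
    if (length(unknown))
      stop("interaction references unknown cofactor id \"", unknown[1], "\"")
    if (any(it$epsilon < 0)) stop("interaction epsilon must be >= 0")
  }

  if (!is.numeric(ls$temperature) || ls$temperature <= 0)
    stop("temperature must be a positive number of kelvin")
  if (!inherits(ls$rate_params, "hb_rate_params"))
    stop("rate_params must be an hb_rate_params object")

  # Connectivity: an interacting pair (e.g. the bifurcating dimer) is one
  # physical unit, so interaction terms count as adjacency here even though
  # holes only hop along declared edges.
  if (nrow(co) > 1) {
    adj <- lapply(seq_len(nrow(co)), function(i) {
      id <- co$id[i]
      c(ed$to[ed$from == id], ed$from[ed$to == id],
        it$site_b[it$site_a == id], it$site_a[it$site_b == id])
    })
    names(adj) <- co$id
    seen <- co$id[1]
    frontier <- seen
    while (length(frontier)) {
      nxt <- setdiff(unique(unlist(adj[frontier])), seen)
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    if (length(seen) < nrow(co))
      stop("hop graph is disconnected; unreachable: ",
           paste(setdiff(co$id, seen), collapse = ", "))
  }
  ls
}

#' @export
print.hb_landscape <- function(x, ...) {
  cat(sprintf("Hole-hopping landscape: %d cofactors, %d edges, %d interaction term(s), T = %g K\n",
              nrow(x$cofactors), nrow(x$edges), nrow(x$interactions),
              x$temperature))
  print(x$cofactors, row.names = FALSE)
  invisible(x)
}

#' Canonical optimized two-pathway bifurcation landscape
#'
#' The reference eight-cofactor design with near-unit bifurcation yield: a
#' tryptophan dimer (W1, W2, intrinsic potential 1.1 V each) carrying a
#' 1.6 eV hole--hole repulsion, a hot pathway W1--WH1 (1.9 V)--WH2 (1.75 V)--
#' hot terminus (1.6 V) and a cold pathway W2--WL1 (1.1 V)--WL2 (1.05 V)--
#' cold terminus (1.0 V, the reference potential). All edges are 5 Angstrom
#' except the deliberately long 10 Angstrom W2--WL1 edge that delays the cold
#' hole until the hot hole has departed.
#'
#' With both dimer sites occupied the repulsion makes the first hole's
#' effective potential 1.1 + 1.6 = 2.7 V; after it leaves, the remaining
#' hole relaxes to the intrinsic 1.1 V. Encoding the repulsion as an explicit
#' pairwise term (rather than baking 2.7 V into a site) reproduces both
#' regimes automatically.
#'
#' @param temperature Absolute temperature (K); 300 K by default.
#' @param rate_params Rate parameters; defaults to [rate_params()].
#' @return An \code{hb_landscape}.
#' @examples
#' canonical_landscape()
#' @export
canonical_landscape <- function(temperature = 300, rate_params = hbnet::rate_params()) {
  cof <- data.frame(
    id = c("W1", "W2", "WH1", "WH2", "Thot", "WL1", "WL2", "Tcold"),
    role = c("bifurcation_site", "bifurcation_site",
             "relay", "relay", "terminus", "relay", "relay", "terminus"),
    pathway = c("bifurcation", "bifurcation",
                "hot", "hot", "hot", "cold", "cold", "cold"),
    potential = c(1.1, 1.1, 1.9, 1.75, 1.6, 1.1, 1.05, 1.0)
  )
  edg <- data.frame(
    from = c("W1", "WH1", "WH2", "W2", "WL1", "WL2"),
    to = c("WH1", "WH2", "Thot", "WL1", "WL2", "Tcold"),
    distance = c(5, 5, 5, 10, 5, 5)
  )
  inter <- data.frame(site_a = "W1", site_b = "W2", epsilon = 1.6)
  landscape(cof, edg, inter, temperature = temperature,
            rate_params = rate_params)
}

#' Effective site potential under a given occupancy
#'
#' The potential a hole on \code{id} experiences, including repulsion from
#' holes currently occupying its interaction partners. With both dimer sites
#' of [canonical_landscape()] occupied this returns 2.7 V for W1.
#'
#' @param ls An \code{hb_landscape}.
#' @param id Cofactor id.
#' @param occupancy Named 0/1 vector, or a plain 0/1 vector in the
#'   landscape's cofactor order.
#' @return Effective potential in V.
#' @export
effective_potential <- function(ls, id, occupancy) {
  if (is.null(names(occupancy))) names(occupancy) <- ls$cofactors$id
  v <- ls$cofactors$potential[match(id, ls$cofactors$id)]
  it <- ls$interactions
  for (k in seq_len(nrow(it))) {
    partner <- if (it$site_a[k] == id) it$site_b[k]
               else if (it$site_b[k] == id) it$site_a[k]
               else next
    v <- v + it$epsilon[k] * occupancy[[partner]]
  }
  v
}

## ---- config I/O -----------------------------------------------------------
## Schema: explicit unit suffixes on every dimensional key.

#' Load a landscape from a YAML config
#'
#' The config carries explicit unit suffixes: \code{potential_V},
#' \code{distance_A}, \code{epsilon_eV}, \code{temperature_K}, and the rate
#' parameter block \code{lambda_outer_eV}, \code{hbar_omega_eV},
#' \code{huang_rhys}, \code{beta_invA}, \code{V0_eV}, \code{n_max}.
#' See \code{system.file("extdata", "canonical_landscape.yaml", package = "hbnet")}
#' for a complete document.
#'
#' @param path Path to a YAML file (or a YAML string).
#' @return A validated \code{hb_landscape}.
#' @export
load_landscape <- function(path) {
  doc <- if (file.exists(path)) yaml::read_yaml(path)
         else yaml::yaml.load(path)
  need <- function(x, field, where) {
    if (is.null(x[[field]]))
      stop("missing field \"", field, "\" in ", where)
    x[[field]]
  }
  cof <- do.call(rbind, lapply(need(doc, "cofactors", "config"), function(c0) {
    data.frame(id = need(c0, "id", "cofactor"),
               role = need(c0, "role", paste0("cofactor ", c0$id)),
               pathway = need(c0, "pathway", paste0("cofactor ", c0$id)),
               potential = need(c0, "potential_V", paste0("cofactor ", c0$id)))
  }))
  edg <- do.call(rbind, lapply(need(doc, "edges", "config"), function(e0) {
    data.frame(from = need(e0, "from", "edge"),
               to = need(e0, "to", "edge"),
               distance = need(e0, "distance_A",
                               paste0("edge ", e0$from, "-", e0$to)))
  }))
  inter <- if (length(doc$interactions)) {
    do.call(rbind, lapply(doc$interactions, function(i0) {
      data.frame(site_a = need(i0, "site_a", "interaction"),
                 site_b = need(i0, "site_b", "interaction"),
                 epsilon = need(i0, "epsilon_eV", "interaction"))
    }))
  } else data.frame(site_a = character(), site_b = character(),
                    epsilon = numeric())
  temp <- need(doc, "temperature_K", "config")
  rp <- need(doc, "rate_params", "config")
  params <- rate_params(
    lambda_outer = need(rp, "lambda_outer_eV", "rate_params"),
    hbar_omega = need(rp, "hbar_omega_eV", "rate_params"),
    huang_rhys = need(rp, "huang_rhys", "rate_params"),
    beta = need(rp, "beta_invA", "rate_params"),
    V0 = need(rp, "V0_eV", "rate_params"),
    temperature = temp,
    n_max = need(rp, "n_max", "rate_params")
  )
  landscape(cof, edg, inter, temperature = temp, rate_params = params)
}

#' Save a landscape to a YAML config
#'
#' Inverse of [load_landscape()]: the written document reloads to an
#' identical landscape.
#'
#' @param ls An \code{hb_landscape}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
save_landscape <- function(ls, path) {
  doc <- list(
    temperature_K = ls$temperature,
    cofactors = lapply(seq_len(nrow(ls$cofactors)), function(i) {
      with(ls$cofactors[i, ], list(id = id, role = role, pathway = pathway,
                                   potential_V = potential))
    }),
    edges = lapply(seq_len(nrow(ls$edges)), function(i) {
      with(ls$edges[i, ], list(from = from, to = to, distance_A = distance))
    }),
    interactions = lapply(seq_len(nrow(ls$interactions)), function(i) {
      with(ls$interactions[i, ], list(site_a = site_a, site_b = site_b,
                                      epsilon_eV = epsilon))
    }),
    rate_params = with(ls$rate_params, list(
      lambda_outer_eV = lambda_outer, hbar_omega_eV = hbar_omega,
      huang_rhys = huang_rhys, beta_invA = beta, V0_eV = V0,
      n_max = n_max))
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}
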