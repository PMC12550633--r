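#' Run a full bifurcation simulation and write its outputs
#'
#' Loads (or takes) a landscape, propagates the two-hole master equation on
#' the default log-time grid, and writes: \code{trajectory.csv} (per-state
#' probabilities), \code{arrival_curves.csv} (terminus occupancies), an
#' arrival-curve figure \code{arrival_curves.pdf}, and \code{summary.json}
#' (state-space size, yield at the final time, 50\% completion times).
#'
#' @param config A landscape, or a path to a YAML landscape config.
#' @param outdir Output directory (created if needed).
#' @param times Reporting times (s).
#' @param plot Write the arrival-curve figure?
#' @return The summary list, invisibly.
#' @export
run_simulation <- function(config, outdir, times = default_time_grid(),
                           plot = TRUE) {
  ls <- if (inherits(config, "hb_landscape")) config else load_landscape(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  space <- enumerate_states(ls, 2)
  marks <- bifurcation_states(space)
  K <- build_rate_matrix(space)
  P0 <- numeric(nrow(space$states)); P0[marks$initial] <- 1
  traj <- propagate(K, P0, times)
  curves <- arrival_curves(ls, times)
  write_curves_csv(traj, file.path(outdir, "trajectory.csv"), space = space)
  write_curves_csv(curves, file.path(outdir, "arrival_curves.csv"))
  if (plot) {
    grDevices::pdf(file.path(outdir, "arrival_curves.pdf"), width = 6,
                   height = 4.5)
    on.exit(grDevices::dev.off())
    plot_arrival_curves(curves)
  }
  summary <- list(
    n_states = nrow(space$states),
    yield_at_t_final = traj$probabilities[length(times), marks$target],
    t_final_s = max(times),
    completion_time_hot_s = completion_time(curves, "hot"),
    completion_time_cold_s = completion_time(curves, "cold"),
    spectral_range_s_inv = range(abs(diag(unclass(K))))
  )
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(summary)
}

#' Plot terminus arrival curves
#'
#' Hot and cold terminus occupancy probability versus log time, with dashed
#' markers at the 50\% completion times.
#'
#' @param curves An [arrival_curves()] object.
#' @return The curves, invisibly.
#' @export
plot_arrival_curves <- function(curves) {
  graphics::plot(curves$time, curves$hot, type = "l", log = "x",
                 col = "darkorange", lwd = 2, ylim = c(0, 1),
                 xlab = "time (s)", ylab = "terminus occupancy probability",
                 main = "Hole arrival at the pathway termini")
  graphics::lines(curves$time, curves$cold, col = "steelblue", lwd = 2)
  for (term in c("hot", "cold")) {
    tc <- suppressWarnings(completion_time(curves, term))
    if (is.finite(tc))
      graphics::abline(v = tc, lty = 2,
                       col = if (term == "hot") "darkorange" else "steelblue")
  }
  graphics::legend("topleft", c("hot terminus", "cold terminus"),
                   col = c("darkorange", "steelblue"), lwd = 2, bty = "n")
  invisible(curves)
}

#' Run a Bayesian yield optimization and write its outputs
#'
#' Drives [optimize_landscape()] and writes \code{history.csv} (one row per
#' evaluation with the running incumbent), \code{best_landscape.yaml}, and
#' \code{summary.json}.
#'
#' @param config A landscape or a YAML config path (the search template).
#' @param tunables Named bounds list, as in [optimize_landscape()].
#' @param outdir Output directory.
#' @param ... Passed to [optimize_landscape()] (\code{n_init}, \code{n_iter},
#'   \code{kappa}, \code{seed}, ...).
#' @return The \code{hb_bayesopt} result, invisibly.
#' @export
run_optimization <- function(config, tunables, outdir, ...) {
  ls <- if (inherits(config, "hb_landscape")) config else load_landscape(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  res <- optimize_landscape(ls, tunables, ...)
  utils::write.csv(res$history, file.path(outdir, "history.csv"),
                   row.names = FALSE)
  save_landscape(res$best_landscape, file.path(outdir, "best_landscape.yaml"))
  jsonlite::write_json(
    list(best_yield = res$best_y, best_design = as.list(res$best_x),
         n_evaluations = nrow(res$history)),
    file.path(outdir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(res)
}

#' Write the packaged fixtures to a directory
#'
#' Copies out the canonical landscape config (\code{canonical_landscape.yaml})
#' and the Trp-dimer snapshot repulsion table
#' (\code{trp_repulsion_snapshots.csv}) so they can be edited as starting
#' points for new designs.
#'
#' @param dir Target directory.
#' @return Character vector of the written paths, invisibly.
#' @export
write_fixtures <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "canonical_landscape.yaml")
  save_landscape(canonical_landscape(), p1)
  p2 <- file.path(dir, "trp_repulsion_snapshots.csv")
  file.copy(system.file("extdata", "trp_repulsion_snapshots.csv",
                        package = "hbnet"), p2, overwrite = TRUE)
  invisible(c(p1, p2))
}
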