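#' Hole--hole interaction energy from HOMO-energy shifts
#'
#' The electrostatic repulsion between two nearby radical cations is
#' estimated as the shift of one residue's HOMO energy when its partner is
#' switched from neutral to the radical-cation state:
#' \code{e_homo_charged - e_homo_neutral}. Both energies must come from the
#' same geometry.
#'
#' @param e_homo_charged HOMO energy (eV) with the partner oxidized.
#' @param e_homo_neutral HOMO energy (eV) with the partner neutral.
#' @return Interaction energy in eV.
#' @examples
#' interaction_energy(-5.0, -6.6)   # 1.6 eV
#' @export
interaction_energy <- function(e_homo_charged, e_homo_neutral) {
  e_homo_charged - e_homo_neutral
}

#' Mean repulsion energy over conformational snapshots
#'
#' @param snapshots data.frame with columns \code{label} and
#'   \code{e_interaction} (eV), e.g. from [read_snapshot_table()].
#' @return Arithmetic mean in eV.
#' @export
mean_interaction <- function(snapshots) {
  if (!nrow(snapshots)) stop("snapshot table is empty")
  if (any(!is.finite(snapshots$e_interaction)))
    stop("non-finite interaction energy in snapshot table")
  mean(snapshots$e_interaction)
}

#' Read a snapshot repulsion-energy table
#'
#' Two-column CSV: a snapshot label (e.g. an MD time tag in ps) and the
#' hole--hole repulsion energy in eV. The package ships the reference table
#' of 11 MD-extracted Trp-dimer conformations as
#' \code{system.file("extdata", "trp_repulsion_snapshots.csv",
#' package = "hbnet")}; their mean, 1.63 eV, sets the canonical landscape's
#' repulsion term (rounded to 1.6 eV).
#'
#' @param path CSV path; defaults to the packaged table.
#' @return data.frame with columns \code{label}, \code{e_interaction}.
#' @export
read_snapshot_table <- function(path = system.file("extdata",
                                                   "trp_repulsion_snapshots.csv",
                                                   package = "hbnet")) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c("character", "character"))
  if (!nrow(raw)) stop("snapshot table is empty: ", path)
  if (ncol(raw) < 2) stop("snapshot table needs two columns (label, energy)")
  vals <- suppressWarnings(as.numeric(raw[[2]]))
  if (any(is.na(vals))) {
    bad <- which(is.na(vals))[1]
    stop("malformed energy value on data line ", bad, " of ", path,
         ": \"", raw[[2]][bad], "\"")
  }
  data.frame(label = raw[[1]], e_interaction = vals)
}

#' Write a snapshot repulsion-energy table
#'
#' @param snapshots data.frame as returned by [read_snapshot_table()].
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_snapshot_table <- function(snapshots, path) {
  utils::write.csv(
    data.frame(label = snapshots$label,
               e_interaction_eV = snapshots$e_interaction),
    path, row.names = FALSE)
  invisible(path)
}
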