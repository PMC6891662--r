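# Docking pose post-processing: best-conformer selection, binding-energy /
# inhibition-constant conversion, ligand ranking.

# gas constant in kcal mol^-1 K^-1
.R_KCAL <- 1.98720e-3

#' Select the best (lowest-energy) pose for one ligand
#'
#' Docking engines report several conformers per ligand; the pose with the
#' lowest (most favourable) binding energy is retained. Ties break toward
#' the lowest conformer id.
#'
#' @param poses Data frame of poses for a single ligand with columns
#'   `conformer` and `binding_energy_kcal_mol`.
#' @return The selected row.
#' @export
select_best_pose <- function(poses) {
  if (!is.data.frame(poses) || nrow(poses) == 0)
    stop("at least one pose is required")
  if (is.null(poses$binding_energy_kcal_mol))
    stop("poses need a binding_energy_kcal_mol column")
  if (!is.null(poses$ligand) && length(unique(poses$ligand)) > 1)
    stop("select_best_pose expects poses for a single ligand")
  ord <- order(poses$binding_energy_kcal_mol, poses$conformer)
  poses[ord[1], , drop = FALSE]
}

#' Inhibition constant from binding energy
#'
#' The Boltzmann relation `Ki = exp(dG / (R * T))` with
#' `R = 1.98720e-3 kcal mol^-1 K^-1`, the standard conversion used by
#' docking engines. More negative binding energies give smaller (tighter)
#' inhibition constants; the map is strictly increasing in `dg`.
#'
#' @param dg Binding energy in kcal/mol (negative = favourable); finite.
#' @param temperature Absolute temperature in K (default 298.15).
#' @return Inhibition constant in molar units. Multiply by `1e6` for uM.
#' @examples
#' ki_from_energy(-8.69) * 1e6   # ~0.43 uM
#' @export
ki_from_energy <- function(dg, temperature = 298.15) {
  if (any(!is.finite(dg))) stop("binding energy must be finite")
  if (temperature <= 0) stop("temperature must be positive")
  exp(dg / (.R_KCAL * temperature))
}

#' Binding energy from inhibition constant
#'
#' Inverse of [ki_from_energy()]: `dG = R * T * log(Ki)`.
#'
#' @param ki Inhibition constant in molar units, `> 0`.
#' @param temperature Absolute temperature in K.
#' @return Binding energy in kcal/mol.
#' @export
energy_from_ki <- function(ki, temperature = 298.15) {
  if (any(!is.finite(ki) | ki <= 0)) stop("ki must be positive and finite")
  if (temperature <= 0) stop("temperature must be positive")
  .R_KCAL * temperature * log(ki)
}

#' Rank ligands by best-pose binding energy
#'
#' For each ligand, selects the lowest-energy conformer, converts its
#' binding energy to an inhibition constant, and ranks ligands by ascending
#' energy (equivalently ascending Ki, since the conversion is monotone).
#' Exact duplicate `(ligand, conformer)` rows are merged with a warning.
#'
#' @param poses Data frame with `ligand`, `conformer`,
#'   `binding_energy_kcal_mol` columns (see [read_assay_table()] schema
#'   `"poses"` or [generate_docking_table()]).
#' @param temperature Absolute temperature in K.
#' @return Data frame `ligand, conformer, best_energy, ki_M, ki_uM, rank`
#'   sorted by rank.
#' @export
rank_ligands <- function(poses, temperature = 298.15) {
  if (!is.data.frame(poses) || nrow(poses) == 0)
    stop("at least one pose is required")
  needed <- c("ligand", "conformer", "binding_energy_kcal_mol")
  if (!all(needed %in% names(poses)))
    stop("poses need columns: ", paste(needed, collapse = ", "))
  dup <- duplicated(poses[, c("ligand", "conformer")])
  if (any(dup)) {
    warning("merged ", sum(dup), " duplicate (ligand, conformer) row(s)")
    poses <- poses[!dup, ]
  }
  best <- do.call(rbind, lapply(split(poses, poses$ligand), select_best_pose))
  out <- data.frame(ligand = best$ligand, conformer = best$conformer,
                    best_energy = best$binding_energy_kcal_mol)
  out$ki_M <- ki_from_energy(out$best_energy, temperature)
  out$ki_uM <- out$ki_M * 1e6
  out <- out[order(out$best_energy, out$ligand), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
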