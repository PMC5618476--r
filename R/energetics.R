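# Coulomb constant in kcal mol^-1 Angstrom e^-2, the value used by the AMBER
# family of force fields.
.coulomb_k <- 332.0636

#' Assemble an MM-GBSA energy-component ledger
#'
#' End-state binding free energies are bookkept as
#' `G_bind = E_MM + G_sol - T*S` with `E_MM = E_int + E_ele + E_vdw` and
#' `G_sol = G_polar + G_nonpolar`. Under the single-trajectory protocol
#' (complex, receptor and ligand conformations all taken from the complex
#' trajectory) the internal term cancels, so `e_int` defaults to 0. The
#' entropy term is carried as `minus_t_ds` (i.e. -T*dS, kcal/mol), supplied
#' by the caller — typically a normal-mode average computed elsewhere.
#' Derived sums are recomputed from the components, so the ledger identities
#' hold exactly by construction.
#'
#' @param e_ele,e_vdw,g_polar,g_nonpolar component means, kcal/mol.
#' @param e_int internal (bond/angle/torsion) term, kcal/mol; default 0.
#' @param minus_t_ds entropy term -T*dS, kcal/mol; default `NA` (no free
#'   energy reported).
#' @return object of class `"energy_components"`: the inputs plus derived
#'   `e_mm`, `g_sol`, `e_bind` and `g_bind`.
#' @export
energy_components <- function(e_ele, e_vdw, g_polar, g_nonpolar,
                              e_int = 0, minus_t_ds = NA_real_) {
  vals <- c(e_ele, e_vdw, g_polar, g_nonpolar, e_int)
  if (any(!is.finite(vals))) stop("non-finite energy component")
  e_mm <- e_int + e_ele + e_vdw
  g_sol <- g_polar + g_nonpolar
  e_bind <- e_mm + g_sol
  structure(list(
    e_int = e_int, e_ele = e_ele, e_vdw = e_vdw,
    g_polar = g_polar, g_nonpolar = g_nonpolar,
    minus_t_ds = minus_t_ds,
    e_mm = e_mm, g_sol = g_sol, e_bind = e_bind,
    g_bind = e_bind + minus_t_ds
  ), class = "energy_components")
}

#' @export
print.energy_components <- function(x, ...) {
  cat(sprintf(paste0("MM-GBSA components (kcal/mol):\n",
                     "  e_ele %8.2f  e_vdw %8.2f  g_polar %8.2f  g_nonpolar %8.2f\n",
                     "  e_bind %7.2f  -T*dS %7.2f  g_bind %7.2f\n"),
              x$e_ele, x$e_vdw, x$g_polar, x$g_nonpolar,
              x$e_bind, x$minus_t_ds, x$g_bind))
  invisible(x)
}

#' Aggregate per-frame MM-GBSA components into a binding free energy
#'
#' Averages each component arithmetically over the supplied snapshots (the
#' "mean over the last stretch of the production trajectory" convention),
#' then applies the ledger identities. The entropy term enters once, as a
#' single pre-averaged scalar.
#'
#' @param per_frame data frame with columns `e_ele`, `e_vdw`, `g_polar`,
#'   `g_nonpolar` and optionally `e_int` (assumed 0 when absent), one row
#'   per snapshot.
#' @param minus_t_ds scalar -T*dS, kcal/mol.
#' @return an [energy_components()] of the frame means.
#' @export
aggregate_binding <- function(per_frame, minus_t_ds = NA_real_) {
  per_frame <- as.data.frame(per_frame)
  need <- c("e_ele", "e_vdw", "g_polar", "g_nonpolar")
  missing <- setdiff(need, names(per_frame))
  if (length(missing)) stop("missing component column(s): ",
                            paste(missing, collapse = ", "))
  if (nrow(per_frame) < 1L) stop("no frame records to aggregate")
  cols <- c(need, intersect("e_int", names(per_frame)))
  m <- as.matrix(per_frame[cols])
  if (any(!is.finite(m))) stop("non-finite component value in frame table")
  mu <- colMeans(m)
  energy_components(
    e_ele = mu[["e_ele"]], e_vdw = mu[["e_vdw"]],
    g_polar = mu[["g_polar"]], g_nonpolar = mu[["g_nonpolar"]],
    e_int = if ("e_int" %in% cols) mu[["e_int"]] else 0,
    minus_t_ds = minus_t_ds
  )
}

#' Nonpolar solvation from a surface-area change
#'
#' The linear SASA model `G_np = gamma * SASA + beta` with the widely used
#' surface-tension coefficient gamma = 0.0072 kcal mol^-1 Angstrom^-2 and
#' offset beta = 0, evaluated by a 1.4 Angstrom water probe.
#'
#' @param gamma surface tension, kcal mol^-1 Angstrom^-2.
#' @param beta offset, kcal/mol.
#' @param probe_radius solvent probe radius, Angstrom.
#' @return object of class `"nonpolar_model"`.
#' @export
nonpolar_model <- function(gamma = 0.0072, beta = 0, probe_radius = 1.4) {
  stopifnot(gamma >= 0, probe_radius > 0)
  structure(list(gamma = gamma, beta = beta, probe_radius = probe_radius),
            class = "nonpolar_model")
}

#' @rdname nonpolar_model
#' @param delta_sasa surface-area change, Angstrom^2.
#' @param model a [nonpolar_model()].
#' @return `nonpolar_solvation`: energy in kcal/mol.
#' @export
nonpolar_solvation <- function(delta_sasa, model = nonpolar_model()) {
  if (any(!is.finite(delta_sasa))) stop("non-finite SASA input")
  model$gamma * delta_sasa + model$beta
}

#' Pairwise nonbonded interaction energy between two atom groups
#'
#' Electrostatics as a plain Coulomb sum (k = 332.0636 kcal mol^-1 Angstrom
#' e^-2) and van der Waals as a 12-6 Lennard-Jones sum in the r_min
#' convention, `eps_ij [ (rmin_ij/r)^12 - 2 (rmin_ij/r)^6 ]`, with geometric-
#' mean epsilon and summed rmin/2 combination rules and no cutoff — the
#' functional form of the AMBER force-field family, used here for toy
#' systems whose parameters are supplied explicitly.
#'
#' @param frame n_atoms x 3 coordinates (Angstrom).
#' @param group_a,group_b disjoint [select()] results or index vectors.
#' @param charges per-atom partial charges (e), full-topology length.
#' @param lj_eps per-atom LJ well depths (kcal/mol).
#' @param lj_rmin_half per-atom rmin/2 (Angstrom).
#' @return list with `e_ele` and `e_vdw` (kcal/mol).
#' @export
pair_energy <- function(frame, group_a, group_b, charges, lj_eps, lj_rmin_half) {
  n <- nrow(frame)
  ia <- .sel_indices(group_a, n)
  ib <- .sel_indices(group_b, n)
  if (length(intersect(ia, ib))) stop("groups must be disjoint")
  for (p in list(charges, lj_eps, lj_rmin_half)) {
    if (length(p) != n) stop("parameter vectors must cover all ", n, " atoms")
  }
  bad <- which(!is.finite(charges) | !is.finite(lj_eps) | !is.finite(lj_rmin_half))
  if (length(bad)) stop("missing nonbonded parameter for atom ", bad[1L])
  d2 <- .cross_dist2(frame[ia, , drop = FALSE], frame[ib, , drop = FALSE])
  if (any(d2 < 1e-12)) stop("zero interatomic distance between the groups")
  r <- sqrt(d2)
  qq <- outer(charges[ia], charges[ib])
  e_ele <- sum(.coulomb_k * qq / r)
  eps <- sqrt(outer(lj_eps[ia], lj_eps[ib]))
  rmin <- outer(lj_rmin_half[ia], lj_rmin_half[ib], `+`)
  s6 <- (rmin / r)^6
  e_vdw <- sum(eps * (s6^2 - 2 * s6))
  list(e_ele = e_ele, e_vdw = e_vdw)
}

#' Per-residue decomposition of the ligand binding energy
#'
#' Splits the protein-ligand interaction into residue contributions: for
#' each residue, the frame-averaged pairwise electrostatic and van der Waals
#' energies against the ligand ([pair_energy()]); the polar solvation part
#' per residue is consumed from an external table when supplied (generalized
#' Born decompositions are produced upstream, not computed here); the
#' nonpolar part is `gamma * delta_sasa` per residue when per-residue SASA
#' changes are supplied. The entropy term is never decomposed. By
#' construction the residue-summed ele/vdw terms equal the undecomposed
#' whole-protein totals.
#'
#' @param traj a [trajectory()].
#' @param ligand ligand [select()] result or indices.
#' @param charges,lj_eps,lj_rmin_half per-atom nonbonded parameters.
#' @param g_polar_table optional data frame `residue_id`, `g_polar`.
#' @param delta_sasa_table optional data frame `residue_id`, `delta_sasa`
#'   (Angstrom^2).
#' @param model a [nonpolar_model()] (used with `delta_sasa_table`).
#' @return data frame `residue_id`, `e_ele`, `e_vdw`, `g_polar`,
#'   `g_nonpolar`, `total` (kcal/mol; `total` is the sum of the four terms).
#' @export
per_residue_decomposition <- function(traj, ligand, charges, lj_eps,
                                      lj_rmin_half, g_polar_table = NULL,
                                      delta_sasa_table = NULL,
                                      model = nonpolar_model()) {
  top <- traj$topology
  lig <- .sel_indices(ligand, top$n_atoms)
  lig_res <- unique(top$atoms$residue_id[lig])
  res_ids <- setdiff(sort(unique(top$atoms$residue_id)), lig_res)
  if (length(res_ids) == 0L) stop("no protein residues outside the ligand")
  nf <- n_frames(traj)
  acc_ele <- acc_vdw <- setNames(numeric(length(res_ids)), res_ids)
  by_res <- lapply(res_ids, function(r) which(top$atoms$residue_id == r))
  for (k in seq_len(nf)) {
    x <- frame_coords(traj, k)
    for (j in seq_along(res_ids)) {
      pe <- pair_energy(x, by_res[[j]], lig, charges, lj_eps, lj_rmin_half)
      acc_ele[j] <- acc_ele[j] + pe$e_ele
      acc_vdw[j] <- acc_vdw[j] + pe$e_vdw
    }
  }
  out <- data.frame(residue_id = res_ids,
                    e_ele = unname(acc_ele) / nf,
                    e_vdw = unname(acc_vdw) / nf,
                    g_polar = 0, g_nonpolar = 0)
  if (!is.null(g_polar_table)) {
    g_polar_table <- as.data.frame(g_polar_table)
    miss <- setdiff(g_polar_table$residue_id, res_ids)
    if (length(miss)) stop("polar table names residue(s) absent from the ",
                           "trajectory: ", paste(miss, collapse = ", "))
    m <- match(out$residue_id, g_polar_table$residue_id)
    out$g_polar <- ifelse(is.na(m), 0, g_polar_table$g_polar[m])
  }
  if (!is.null(delta_sasa_table)) {
    delta_sasa_table <- as.data.frame(delta_sasa_table)
    miss <- setdiff(delta_sasa_table$residue_id, res_ids)
    if (length(miss)) stop("SASA table names residue(s) absent from the ",
                           "trajectory: ", paste(miss, collapse = ", "))
    m <- match(out$residue_id, delta_sasa_table$residue_id)
    ds <- ifelse(is.na(m), 0, delta_sasa_table$delta_sasa[m])
    out$g_nonpolar <- nonpolar_solvation(ds, model)
  }
  out$total <- out$e_ele + out$e_vdw + out$g_polar + out$g_nonpolar
  out
}

#' Read / write per-frame energy-component tables
#'
#' Delimited text with header `frame e_ele e_vdw g_polar g_nonpolar`
#' (whitespace- or tab-separated; `#` comment lines ignored).
#'
#' @param path file path.
#' @return `read_energy_table`: data frame of the per-frame components.
#' @export
read_energy_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, comment.char = "#")
  need <- c("e_ele", "e_vdw", "g_polar", "g_nonpolar")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("energy table lacks column(s): ",
                            paste(missing, collapse = ", "))
  df
}

#' @rdname read_energy_table
#' @param df per-frame component data frame.
#' @export
write_energy_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a binding free-energy summary table
#'
#' One row per system: the component means, the enthalpy-like sum
#' `e_bind`, the entropy term and the resulting `g_bind` — the layout of a
#' standard MM-GBSA results table.
#'
#' @param systems named list of [energy_components()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_energy_summary <- function(systems, path) {
  rows <- vapply(names(systems), function(nm) {
    x <- systems[[nm]]
    sprintf("%s\t%.2f\t%.2f\t%.2f\t%.2f\t%.2f\t%.2f\t%.2f",
            nm, x$e_ele, x$e_vdw, x$g_polar, x$g_nonpolar,
            x$e_bind, x$minus_t_ds, x$g_bind)
  }, character(1L))
  writeLines(c("system\te_ele\te_vdw\tg_polar\tg_nonpolar\te_bind\tminus_t_ds\tg_bind",
               rows), path)
  invisible(path)
}
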