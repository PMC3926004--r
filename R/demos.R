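#' Reference crystal constants
#'
#' The C222(1) villin-headpiece crystal form used throughout the examples:
#' cell 19.677 x 39.90 x 75.09 A, 8 chains per cell, and the 35-residue HP35
#' double-norleucine-mutant sequence shipped with the package.
#'
#' @return `villin_cell()`: a [unit_cell()]; `hp35_sequence()`: character
#'   scalar (one-letter codes, `X` = norleucine).
#' @export
villin_cell <- function() unit_cell(19.677, 39.90, 75.09)

#' @rdname villin_cell
#' @export
hp35_sequence <- function() {
  read_fasta_seq(system.file("extdata", "hp35_2f4k.fasta",
                             package = "bfaudit", mustWork = TRUE))
}

# standard atom-name selections within one toy residue
res_atoms <- function(tpl, resno, names) {
  which(tpl$atoms$resno == resno & tpl$atoms$elety %in% names)
}

#' Shipped demonstration configurations
#'
#' Small, fully reproducible pipeline configurations exercising the pipeline
#' end to end in minutes on one CPU:
#'
#' * `demo_bimodal_config()` — "bimodal-demo": one C222(1) cell (8 sites) of a
#'   5-residue toy chain (280 atoms/cell), 1.5 A data, 200 snapshots.
#'   Residues 1-3 are position-restrained; residue 4 carries a coherent
#'   two-site side-chain jump (|d| = 1.8 A, minority population p = 0.3),
#'   residue 5 a chi1 rotamer flip (0/110 degrees, 70/30) plus harmonic
#'   backbone motion.  Mobile atoms governed by multimodal models: 5 of 14
#'   (36%).  The refinement model is the starting conformation (the dominant
#'   site), mirroring a molecular-replacement solution from the experimental
#'   structure; this is the regime in which single-site Gaussian B-factors
#'   underestimate multimodal heterogeneity.
#' * `demo_dw_config()` — unimodal Gaussian crystal for Debye-Waller
#'   recovery: P1 cell, 35 atoms, sigma = 0.2 A/axis on every atom, 1000
#'   snapshots, 1.0 A data; refined isotropic B should approach
#'   `8 pi^2 sigma^2 = 3.158` A^2.
#' * `demo_resolution_config()` — mixed harmonic/bimodal P1 crystal at 1.0 A
#'   used for the resolution-dependence check (truncate to 2.0 A).
#' * `demo_static_config()` — 3x3x3 C222(1) supercell of a 2-residue chain
#'   (216 sites) for the static-vs-dynamic disorder audit.
#'
#' @param seed integer seed controlling all sampling.
#' @param n_snapshots number of snapshots (defaults chosen per demo).
#' @return a [pipeline_config()].
#' @export
demo_bimodal_config <- function(seed = 1, n_snapshots = 200) {
  tpl <- build_template(n_res = 5, cell = villin_cell(), sg = "C2221",
                        mobile_fraction = 0.4)
  models <- list(
    motion_harmonic_iso(res_atoms(tpl, 4, c("N", "CA", "C", "O")), 0.15),
    motion_bimodal(res_atoms(tpl, 4, c("CB", "CG", "CD")),
                   d = c(1.8, 0, 0), p = 0.3, sigma_local = 0.1),
    motion_harmonic_iso(res_atoms(tpl, 5, c("N", "CA", "C", "O", "CB")), 0.45),
    motion_rotamer(res_atoms(tpl, 5, c("CG", "CD")),
                   axis = c(res_atoms(tpl, 5, "CA"), res_atoms(tpl, 5, "CB")),
                   angles = c(0, 110), weights = c(0.7, 0.3),
                   sigma_local = 0.08))
  spec <- ensemble_spec(tpl, models, n_snapshots = n_snapshots,
                        factors = c(1, 1, 1), mode = "iid_per_site",
                        seed = seed)
  pipeline_config(spec, d_min = 1.5, modes = c("iso", "aniso"),
                  model_source = "template", compare_range = c(10, 60))
}

#' @rdname demo_bimodal_config
#' @param sigma harmonic displacement s.d. (A/axis) for the Debye-Waller demo.
#' @export
demo_dw_config <- function(seed = 1, n_snapshots = 1000, sigma = 0.2) {
  tpl <- build_template(n_res = 5, cell = unit_cell(12, 12, 12), sg = "P1",
                        mobile_fraction = 1)
  models <- list(motion_harmonic_iso(seq_len(n_atoms(tpl)), sigma))
  spec <- ensemble_spec(tpl, models, n_snapshots = n_snapshots,
                        factors = c(1, 1, 1), mode = "iid_per_site",
                        seed = seed)
  pipeline_config(spec, d_min = 1.0, modes = "iso", compare_range = NULL,
                  model_source = "template")
}

#' @rdname demo_bimodal_config
#' @export
demo_resolution_config <- function(seed = 1, n_snapshots = 300) {
  tpl <- build_template(n_res = 4, cell = unit_cell(14, 15, 16), sg = "P1",
                        mobile_fraction = 0.5)
  models <- list(
    motion_harmonic_iso(res_atoms(tpl, 3, c("N", "CA", "C", "O", "CB")), 0.35),
    motion_bimodal(res_atoms(tpl, 3, c("CG", "CD")),
                   d = c(1.5, 0, 0), p = 0.3, sigma_local = 0.1),
    motion_harmonic_iso(res_atoms(tpl, 4, c("N", "CA", "C", "O", "CB")), 0.2),
    motion_bimodal(res_atoms(tpl, 4, c("CG", "CD")),
                   d = c(0, 2.4, 1.5), p = 0.3, sigma_local = 0.1))
  spec <- ensemble_spec(tpl, models, n_snapshots = n_snapshots,
                        factors = c(1, 1, 1), mode = "iid_per_site",
                        seed = seed)
  pipeline_config(spec, d_min = 1.0, modes = "iso", compare_range = NULL,
                  model_source = "template", restrain_b = TRUE, w_b = 5)
}

#' @rdname demo_bimodal_config
#' @param factors supercell factors for the static-disorder audit.
#' @export
demo_static_config <- function(seed = 1, n_snapshots = 30,
                               factors = c(3, 3, 3)) {
  tpl <- build_template(n_res = 2, cell = unit_cell(14, 18, 22), sg = "C2221",
                        mobile_fraction = 0.5)
  models <- list(
    motion_harmonic_iso(res_atoms(tpl, 2, c("N", "CA", "C", "O")), 0.35),
    motion_bimodal(res_atoms(tpl, 2, c("CB", "CG", "CD")),
                   d = c(1.5, 0, 0), p = 0.3, sigma_local = 0.1))
  spec <- ensemble_spec(tpl, models, n_snapshots = n_snapshots,
                        factors = factors, mode = "iid_per_site", seed = seed)
  pipeline_config(spec, d_min = 1.8, modes = "iso", compare_range = NULL,
                  model_source = "template")
}

#' Crystal composition bookkeeping
#'
#' Assembles the full supercell for a stated composition (chain atom count,
#' chains per cell, supercell factors) by actually building it, and returns
#' the resulting counts together with the Matthews statistics of the cell.
#'
#' @param cell a [unit_cell()] (default [villin_cell()]).
#' @param sg space group (default C222(1), Z = 8).
#' @param n_res residues per chain.
#' @param atoms_per_chain total atoms per chain (template padded to match).
#' @param factors supercell factors.
#' @param n_snapshots snapshot count the monomer pool is taken over.
#' @param sequence one-letter sequence for the molecular weight (default
#'   [hp35_sequence()]).
#' @return list with `n_atoms_supercell`, `n_monomers_per_snapshot`,
#'   `n_monomers_pooled`, `mw`, `v_m`, `solvent_fraction`, `supercell_dims`.
#' @export
crystal_bookkeeping <- function(cell = villin_cell(), sg = "C2221",
                                n_res = 35, atoms_per_chain = 373,
                                factors = c(3, 3, 3), n_snapshots = 5000,
                                sequence = hp35_sequence()) {
  tpl <- build_template(n_res = n_res, cell = cell, sg = sg,
                        n_atoms = atoms_per_chain)
  super <- build_supercell(tpl, factors)
  monomers <- map_to_reference(super, as_matrix = TRUE)
  mw <- peptide_mw(sequence)
  mt <- compute_matthews(cell, Z = tpl$sg$n_ops, MW = mw)
  n_mono <- unname(dim(monomers)[3])
  list(n_atoms_supercell = n_atoms(super),
       n_monomers_per_snapshot = n_mono,
       n_monomers_pooled = n_mono * n_snapshots,
       mw = mw, v_m = mt$v_m, solvent_fraction = mt$solvent_fraction,
       supercell_dims = c(super$cell$a, super$cell$b, super$cell$c))
}
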