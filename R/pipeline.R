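#' Pipeline configuration
#'
#' Bundles the ensemble spec, structure-factor settings, refinement settings
#' and comparison range for an end-to-end run.
#'
#' @param spec an [ensemble_spec()].
#' @param d_min,d_max resolution range (Angstrom) of the generated data.
#' @param b_offset overall B added to every atom before structure-factor
#'   calculation and removed from the averaged amplitudes afterwards (A^2);
#'   keeps the sharpest form-factor terms well-behaved, default 15.
#' @param sf_method `"direct"` (exact summation) or `"grid"` (density FFT).
#' @param grid_spacing grid spacing for `sf_method = "grid"`.
#' @param modes refinement modes to run, subset of `c("iso", "aniso")`.
#' @param model_source starting model positions: `"average"` (ensemble
#'   average structure) or `"template"`.
#' @param free_fraction,w_b,restrain_b,max_cycles see [refine_config()].
#' @param compare_range actual-B window for the regression summary
#'   (default `c(10, 60)` A^2).
#' @param outdir optional output directory for stage artifacts.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(spec, d_min = 1.5, d_max = Inf, b_offset = 15,
                            sf_method = c("direct", "grid"),
                            grid_spacing = 0.45,
                            modes = c("iso", "aniso"),
                            model_source = c("average", "template"),
                            free_fraction = 0.05, w_b = 0.1,
                            restrain_b = FALSE, max_cycles = 25,
                            compare_range = c(10, 60), outdir = NULL) {
  sf_method <- match.arg(sf_method)
  model_source <- match.arg(model_source)
  stopifnot(inherits(spec, "ensemble_spec"), d_min > 0, d_max > d_min)
  structure(list(spec = spec, d_min = d_min, d_max = d_max,
                 b_offset = b_offset, sf_method = sf_method,
                 grid_spacing = grid_spacing, modes = modes,
                 model_source = model_source,
                 free_fraction = free_fraction, w_b = w_b,
                 restrain_b = restrain_b, max_cycles = max_cycles,
                 compare_range = compare_range, outdir = outdir),
            class = "pipeline_config")
}

# supercell indices whose reduction covers the full symmetry orbit of the
# target unique set (proper rotations only; Friedel mates are implicit)
orbit_indices <- function(unique_hkl, sg, factors) {
  seen <- character(0)
  pieces <- list()
  for (op in sg$ops) {
    hop <- unique_hkl %*% op$R
    key <- paste(hop[, 1], hop[, 2], hop[, 3])
    new <- !(key %in% seen)
    seen <- c(seen, key[new])
    pieces[[length(pieces) + 1L]] <- hop[new, , drop = FALSE]
  }
  hkl <- do.call(rbind, pieces)
  sweep(hkl, 2, factors, "*")
}

#' Ensemble-averaged observed amplitudes
#'
#' Runs the data-generation half of the pipeline: per-snapshot structure
#' factors of the P1 supercell (every atom at occupancy 1 and B =
#' `b_offset`), complex vector averaging over snapshots, reduction to the
#' template's space group and removal of the B offset.
#'
#' @param ensemble a `crystal_ensemble`.
#' @param config a [pipeline_config()].
#' @return a merged [reflection_set()] of "observed" amplitudes.
#' @export
ensemble_observed_sf <- function(ensemble, config) {
  tpl <- ensemble$spec$template
  target_sg <- tpl$sg
  unique_rs <- generate_hkl(tpl$cell, target_sg, d_max = config$d_max,
                            d_min = config$d_min)
  factors <- ensemble$spec$factors
  super_hkl <- orbit_indices(rs_hkl(unique_rs), target_sg, factors)
  skel <- ensemble$skeleton
  skel$atoms$b <- config$b_offset
  skel$atoms$occ <- 1
  nt <- dim(ensemble$coords)[3]
  acc <- complex(nrow(super_hkl))
  for (t in seq_len(nt)) {
    snap <- set_coords_frac(skel, ensemble$coords[, , t])
    if (config$sf_method == "grid") {
      rs_t <- calc_sf_grid(snap, super_hkl, config$grid_spacing,
                           d_min = config$d_min)
    } else {
      rs_t <- calc_sf_direct(snap, super_hkl)
    }
    acc <- acc + rs_t$F
  }
  avg <- reflection_set(super_hkl, skel$cell, space_group("P1"),
                        F = acc / nt)
  red <- reduce_supercell(avg, factors, target_sg, base_cell = tpl$cell)
  shift_overall_b(red, -config$b_offset)
}

#' Run the full pipeline
#'
#' generate -> per-snapshot structure factors (+B offset) -> vector average ->
#' reduce to the target group -> remove offset -> assign free set -> refine
#' (isotropic and/or anisotropic B) -> compare refined against actual
#' B-factors.  Fully reproducible from the config's seed.
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_report`: `observed` (reflection set),
#'   `actual` (fluctuation table), `refined` (per-mode
#'   `refinement_result`s), `comparison` (per-mode `b_comparison`s over the
#'   configured range plus `_all` variants over all atoms), `report` (flat
#'   named list of the headline numbers, percentages for R factors).
#' @export
run_pipeline <- function(config) {
  spec <- config$spec
  ens <- sample_ensemble(spec)
  observed <- ensemble_observed_sf(ens, config)
  observed <- assign_free_set(observed, config$free_fraction,
                              seed = spec$seed + 1L)
  actual <- ensemble_fluctuations(ens)
  model <- if (config$model_source == "average")
    average_structure(ens) else spec$template
  model$atoms$b <- config$b_offset
  model$atoms[c("u11", "u22", "u33", "u12", "u13", "u23")] <- NULL
  model$sg <- spec$template$sg

  refined <- list(); comparison <- list()
  report <- list(
    n_atoms_chain = n_atoms(spec$template),
    n_sites = spec$template$sg$n_ops * prod(spec$factors),
    n_snapshots = spec$n_snapshots,
    n_reflections = nrow(observed),
    n_free = sum(observed$free),
    mean_amplitude = mean(Mod(observed$F)))
  for (mode in config$modes) {
    cfg <- refine_config(mode = mode, restrain_b = config$restrain_b,
                         w_b = config$w_b, max_cycles = config$max_cycles,
                         free_fraction = config$free_fraction)
    res <- refine(model, observed, cfg)
    refined[[mode]] <- res
    cmp <- compare_bfactors(actual, res$structure, range = config$compare_range)
    cmp_all <- compare_bfactors(actual, res$structure)
    comparison[[mode]] <- cmp
    comparison[[paste0(mode, "_all")]] <- cmp_all
    report[[paste0("r_", mode)]] <- 100 * res$r
    report[[paste0("r_free_", mode)]] <- 100 * res$r_free
    report[[paste0("rms_b_", mode)]] <- cmp_all$summary$rms_b
    report[[paste0("delta_max_", mode)]] <- cmp_all$summary$delta_max
    report[[paste0("slope_", mode)]] <- cmp$summary$slope
    report[[paste0("r2_", mode)]] <- cmp$summary$r2
    report[[paste0("frac_under_", mode)]] <- cmp$summary$frac_under
  }
  out <- structure(list(observed = observed, actual = actual,
                        ensemble = ens, model = model,
                        refined = refined, comparison = comparison,
                        report = report, config = config),
                   class = "pipeline_report")
  if (!is.null(config$outdir)) write_pipeline_artifacts(out, config$outdir)
  out
}

write_pipeline_artifacts <- function(pr, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_hkl(pr$observed, file.path(outdir, "observed.hkl"))
  write_fluctuations(pr$actual, file.path(outdir, "actual_fluctuations.tsv"))
  write_pdb(pr$model, file.path(outdir, "model_start.pdb"))
  for (mode in names(pr$refined)) {
    write_pdb(pr$refined[[mode]]$structure,
              file.path(outdir, sprintf("refined_%s.pdb", mode)))
    utils::write.table(pr$refined[[mode]]$trace,
                       file.path(outdir, sprintf("refine_%s_trace.tsv", mode)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_b_comparison(pr$comparison[[mode]],
                       tsv = file.path(outdir,
                                       sprintf("b_comparison_%s.tsv", mode)))
  }
  jsonlite::write_json(pr$report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  r <- x$report
  cat(sprintf("pipeline: %d reflections, %d snapshots x %d sites\n",
              r$n_reflections, r$n_snapshots, r$n_sites))
  for (mode in names(x$refined))
    cat(sprintf("  %s: R = %.2f%% R_free = %.2f%% rms_b = %.2f delta_max = %.2f slope = %.3f\n",
                mode, r[[paste0("r_", mode)]], r[[paste0("r_free_", mode)]],
                r[[paste0("rms_b_", mode)]], r[[paste0("delta_max_", mode)]],
                r[[paste0("slope_", mode)]]))
  invisible(x)
}

#' Static vs dynamic disorder audit
#'
#' Runs the pipeline twice on the same specification: once with the configured
#' number of snapshots (time + ensemble averaging) and once with a single
#' snapshot whose lattice sites carry purely static disorder, then compares
#' the two refined B profiles.  Requires `iid_per_site` mode (static disorder
#' is undefined when all sites share one conformer) and more than one site.
#'
#' @param config a [pipeline_config()]; `modes` is reduced to `"iso"` unless
#'   set otherwise.
#' @return list with `dynamic` and `static` pipeline reports plus `gap`:
#'   RMS and RMS-relative difference between the refined B profiles and their
#'   correlation.
#' @export
audit_static_vs_dynamic <- function(config) {
  spec <- config$spec
  if (spec$mode != "iid_per_site")
    stop("static-disorder audit requires iid_per_site mode")
  n_sites <- spec$template$sg$n_ops * prod(spec$factors)
  if (n_sites < 2 || (n_sites == 1 && spec$n_snapshots == 1))
    stop("static disorder undefined for a single site")
  dynamic <- run_pipeline(config)
  cfg_static <- config
  cfg_static$spec$n_snapshots <- 1L
  static <- run_pipeline(cfg_static)
  mode <- config$modes[1]
  bd <- dynamic$refined[[mode]]$structure$atoms$b
  bs <- static$refined[[mode]]$structure$atoms$b
  gap <- list(rms = sqrt(mean((bd - bs)^2)),
              rms_rel = sqrt(mean(((bd - bs) / pmax((bd + bs) / 2, 1))^2)),
              cor = stats::cor(bd, bs))
  list(dynamic = dynamic, static = static, gap = gap)
}
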