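#' Serialize and parse pipeline configurations
#'
#' A pipeline run is fully described by a YAML file with three blocks:
#' `template` (arguments to [build_template()]), `ensemble` (motion models,
#' snapshot count, supercell factors, mode, seed) and `pipeline`
#' (resolution range, B offset, refinement settings, comparison range).
#' `read_pipeline_config()` rebuilds an identical [pipeline_config()];
#' a write/read round trip reproduces the pipeline behaviour exactly.
#'
#' Motion models are serialized by kind and parameters, e.g.
#' `{kind: bimodal_jump, selection: [22, 23], d: [2, 0, 0], p: 0.5,
#'   sigma_local: 0.1}`.
#'
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @return `read_pipeline_config()` returns a [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  spec <- config$spec
  tpl_args <- attr(spec$template, "build_args")
  if (is.null(tpl_args))
    stop("template does not carry its build arguments; build it with build_template()")
  lst <- list(
    template = tpl_args,
    ensemble = list(
      models = lapply(spec$models, motion_to_list),
      n_snapshots = spec$n_snapshots,
      factors = spec$factors,
      mode = spec$mode,
      seed = spec$seed,
      restrained_sigma = spec$restrained_sigma),
    pipeline = list(
      d_min = config$d_min,
      d_max = if (is.finite(config$d_max)) config$d_max else "inf",
      b_offset = config$b_offset, sf_method = config$sf_method,
      grid_spacing = config$grid_spacing, modes = as.list(config$modes),
      model_source = config$model_source,
      free_fraction = config$free_fraction, w_b = config$w_b,
      restrain_b = config$restrain_b, max_cycles = config$max_cycles,
      compare_range = config$compare_range))
  yaml::write_yaml(lst, path)
  invisible(path)
}

motion_to_list <- function(m) {
  out <- unclass(m)
  if (!is.null(out$cov)) out$cov <- as.vector(out$cov)
  out
}

motion_from_list <- function(l) {
  sel <- unlist(l$selection)
  switch(l$kind,
    harmonic_iso = motion_harmonic_iso(sel, unlist(l$sigma)),
    harmonic_aniso = motion_harmonic_aniso(sel, matrix(unlist(l$cov), 3, 3)),
    bimodal_jump = motion_bimodal(sel, unlist(l$d), l$p, l$sigma_local),
    rotamer_flip = motion_rotamer(sel, unlist(l$axis), unlist(l$angles),
                                  unlist(l$weights), l$sigma_local),
    libration = motion_libration(sel, unlist(l$axis), l$sigma_deg),
    stop("unknown motion kind in config: ", l$kind))
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  lst <- yaml::read_yaml(path)
  ta <- lst$template
  cellv <- unlist(ta$cell)
  tpl <- build_template(kind = ta$kind, n_res = ta$n_res,
                        cell = unit_cell(cellv[1], cellv[2], cellv[3]),
                        sg = ta$sg, mobile_fraction = ta$mobile_fraction,
                        n_atoms = ta$n_atoms, pdb = ta$pdb,
                        b_init = ta$b_init %||% 15)
  en <- lst$ensemble
  spec <- ensemble_spec(tpl,
                        models = lapply(en$models, motion_from_list),
                        n_snapshots = en$n_snapshots,
                        factors = unlist(en$factors), mode = en$mode,
                        seed = en$seed,
                        restrained_sigma = en$restrained_sigma)
  pl <- lst$pipeline
  pipeline_config(spec,
                  d_min = pl$d_min,
                  d_max = if (identical(pl$d_max, "inf")) Inf else pl$d_max,
                  b_offset = pl$b_offset, sf_method = pl$sf_method,
                  grid_spacing = pl$grid_spacing, modes = unlist(pl$modes),
                  model_source = pl$model_source,
                  free_fraction = pl$free_fraction, w_b = pl$w_b,
                  restrain_b = pl$restrain_b, max_cycles = pl$max_cycles,
                  compare_range = unlist(pl$compare_range))
}
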