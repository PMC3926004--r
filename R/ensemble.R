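#' Ensemble specification
#'
#' Bundles everything the generator needs: the template chain, the motion
#' models, snapshot and supercell counts, the site-independence mode and the
#' random seed.  Atoms not covered by any model stay immobile, except that
#' restrained atoms (per the template's `mobile` flag) receive small harmonic
#' jitter of `restrained_sigma` per axis, emulating a position-restrained
#' crystal segment (default 0.058 A/axis, i.e. RMSF ~ 0.1 A).
#'
#' @param template an [xtal_structure()] chain from [build_template()].
#' @param models list of [motion_models].
#' @param n_snapshots number of snapshots to draw.
#' @param factors supercell factors `c(nx, ny, nz)`.
#' @param mode `"iid_per_site"` (each lattice site samples independently) or
#'   `"shared"` (all sites identical within a snapshot).
#' @param seed integer random seed; all sampling derives from it.
#' @param restrained_sigma jitter s.d. (A/axis) for restrained atoms.
#' @return object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(template, models = list(), n_snapshots = 100,
                          factors = c(1, 1, 1),
                          mode = c("iid_per_site", "shared"),
                          seed = 1, restrained_sigma = 0.058) {
  mode <- match.arg(mode)
  stopifnot(inherits(template, "xtal_structure"), n_snapshots >= 1)
  if (inherits(models, "motion_model")) models <- list(models)
  covered <- motion_coverage(models, n_atoms(template), template$atoms$mobile)
  structure(list(template = template, models = models,
                 n_snapshots = as.integer(n_snapshots),
                 factors = as.integer(factors), mode = mode,
                 seed = as.integer(seed),
                 restrained_sigma = restrained_sigma,
                 covered = covered),
            class = "ensemble_spec")
}

# deterministic substream seed for (snapshot t, site s); order-independent
stream_seed <- function(seed, t, s) {
  h <- (abs(seed) * 2654435761 + t * 97561 + s * 51503 + 12582917) %% 2147483647
  as.integer(h)
}

# displacements for one conformer given the spec (consumes the current RNG)
draw_conformer_delta <- function(spec, x0) {
  A <- nrow(x0)
  delta <- matrix(0, A, 3)
  restrained <- !spec$template$atoms$mobile
  if (any(restrained) && spec$restrained_sigma > 0)
    delta[restrained, ] <- stats::rnorm(3 * sum(restrained),
                                        sd = spec$restrained_sigma)
  for (m in spec$models)
    delta[m$selection, ] <- delta[m$selection, , drop = FALSE] +
      sample_motion(m, x0)
  delta
}

#' Sample a crystal ensemble
#'
#' Draws `n_snapshots` supercell snapshots.  Each lattice site (cell copy x
#' symmetry operator) receives a conformer: in `iid_per_site` mode the
#' conformers are independent draws from the motion models; in `shared` mode
#' all sites within a snapshot carry the same conformer.  Displacements are
#' sampled in the Cartesian reference frame, then rotated/translated to the
#' site.  Ground-truth per-atom first and second displacement moments are
#' accumulated over all sampled conformers.
#'
#' Identical spec and seed give bit-identical coordinates; sites use
#' counter-derived substreams so the result does not depend on evaluation
#' order.
#'
#' @param spec an [ensemble_spec()].
#' @return object of class `crystal_ensemble` with fields `spec`, `skeleton`
#'   (the supercell [xtal_structure()] carrying site bookkeeping), `coords`
#'   (array `atoms x 3 x n_snapshots` of fractional supercell coordinates) and
#'   `moments` (per-atom empirical mean/covariance of the sampled
#'   displacements, reference frame, Angstrom).
#' @export
sample_ensemble <- function(spec) {
  tpl <- spec$template
  cell <- tpl$cell
  sg <- tpl$sg
  factors <- spec$factors
  A <- n_atoms(tpl)
  x0_frac <- coords_frac(tpl)
  x0 <- frac_to_cart(cell, x0_frac)

  n_ops <- sg$n_ops
  n_cells <- prod(factors)
  n_sites <- n_ops * n_cells
  cells <- expand.grid(ix = 0:(factors[1] - 1), iy = 0:(factors[2] - 1),
                       iz = 0:(factors[3] - 1))
  # per-site fractional transform: y = (R f + t + shift) / factors
  site_R <- lapply(seq_len(n_sites), function(s) {
    oi <- (s - 1) %% n_ops + 1
    sg$ops[[oi]]$R
  })
  site_t <- lapply(seq_len(n_sites), function(s) {
    oi <- (s - 1) %% n_ops + 1
    ci <- (s - 1) %/% n_ops + 1
    sg$ops[[oi]]$t + as.numeric(cells[ci, ])
  })

  coords <- array(NA_real_, c(A * n_sites, 3, spec$n_snapshots))
  sum1 <- matrix(0, A, 3)
  sum2 <- matrix(0, A, 6)  # u11,u22,u33,u12,u13,u23 accumulators (raw moments)
  n_conf <- 0L
  inv_fac <- diag(1 / factors)

  for (t in seq_len(spec$n_snapshots)) {
    if (spec$mode == "shared") {
      set.seed(stream_seed(spec$seed, t, 0L))
      delta_shared <- draw_conformer_delta(spec, x0)
    }
    for (s in seq_len(n_sites)) {
      if (spec$mode == "iid_per_site") {
        set.seed(stream_seed(spec$seed, t, s))
        delta <- draw_conformer_delta(spec, x0)
      } else delta <- delta_shared
      conf_frac <- cart_to_frac(cell, x0 + delta)
      y <- conf_frac %*% t(site_R[[s]])
      y <- sweep(y, 2, site_t[[s]], "+") %*% inv_fac
      rows <- ((s - 1) * A + 1):(s * A)
      coords[rows, , t] <- y
      if (spec$mode == "iid_per_site" || s == 1L) {
        sum1 <- sum1 + delta
        sum2 <- sum2 + cbind(delta^2,
                             delta[, 1] * delta[, 2],
                             delta[, 1] * delta[, 3],
                             delta[, 2] * delta[, 3])
        n_conf <- n_conf + 1L
      }
    }
  }

  skeleton <- build_supercell(tpl, factors)
  mean_d <- sum1 / n_conf
  raw2 <- sum2 / n_conf
  cov6 <- raw2 - cbind(mean_d^2,
                       mean_d[, 1] * mean_d[, 2],
                       mean_d[, 1] * mean_d[, 3],
                       mean_d[, 2] * mean_d[, 3])
  structure(list(spec = spec, skeleton = skeleton, coords = coords,
                 moments = list(n = n_conf, mean = mean_d, cov = cov6)),
            class = "crystal_ensemble")
}

#' @export
print.crystal_ensemble <- function(x, ...) {
  cat(sprintf("crystal_ensemble: %d snapshots, %d sites x %d atoms, mode %s\n",
              dim(x$coords)[3], x$spec$template$sg$n_ops * prod(x$spec$factors),
              n_atoms(x$spec$template), x$spec$mode))
  invisible(x)
}

#' Single-snapshot (static disorder) ensemble
#'
#' Shortcut for [sample_ensemble()] with one snapshot: in `iid_per_site` mode
#' the one supercell carries purely static site-to-site disorder.
#'
#' @param spec an [ensemble_spec()]; its `n_snapshots` is overridden to 1.
#' @return a `crystal_ensemble` with one snapshot.
#' @export
snapshot_single <- function(spec) {
  spec$n_snapshots <- 1L
  sample_ensemble(spec)
}

#' Extract one snapshot as a structure
#'
#' @param ensemble a `crystal_ensemble`.
#' @param i snapshot index.
#' @return the supercell [xtal_structure()] with that snapshot's coordinates.
#' @export
ensemble_snapshot <- function(ensemble, i) {
  s <- ensemble$skeleton
  set_coords_frac(s, ensemble$coords[, , i])
}

#' Map all ensemble monomers to the reference frame
#'
#' Inverts each site's generating operator and lattice translation for every
#' snapshot (no fitting), returning fractional reference-frame coordinates.
#'
#' @param ensemble a `crystal_ensemble`.
#' @return array `atoms x 3 x (sites * snapshots)`, reference-frame fractional
#'   coordinates (monomer index runs sites-major within each snapshot).
#' @export
ensemble_monomers <- function(ensemble) {
  spec <- ensemble$spec
  tpl <- spec$template
  sg <- tpl$sg
  factors <- spec$factors
  A <- n_atoms(tpl)
  n_ops <- sg$n_ops
  n_cells <- prod(factors)
  n_sites <- n_ops * n_cells
  nt <- dim(ensemble$coords)[3]
  cells <- expand.grid(ix = 0:(factors[1] - 1), iy = 0:(factors[2] - 1),
                       iz = 0:(factors[3] - 1))
  out <- array(NA_real_, c(A, 3, n_sites * nt))
  fac <- diag(as.numeric(factors))
  k <- 0L
  for (t in seq_len(nt)) {
    for (s in seq_len(n_sites)) {
      oi <- (s - 1) %% n_ops + 1
      ci <- (s - 1) %/% n_ops + 1
      rows <- ((s - 1) * A + 1):(s * A)
      y <- ensemble$coords[rows, , t] %*% fac
      y <- sweep(y, 2, sg$ops[[oi]]$t + as.numeric(cells[ci, ]), "-")
      k <- k + 1L
      out[, , k] <- y %*% t(solve(sg$ops[[oi]]$R))
    }
  }
  out
}
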