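#' Motion models
#'
#' Parametric displacement distributions attached to atom selections of the
#' template chain.  Supported kinds:
#'
#' * `motion_harmonic_iso(selection, sigma)` — independent Gaussian jitter with
#'   standard deviation `sigma` Angstrom per Cartesian axis (scalar or one
#'   value per selected atom).
#' * `motion_harmonic_aniso(selection, cov)` — zero-mean Gaussian with a 3x3
#'   positional covariance (A^2) shared by the selected atoms.
#' * `motion_bimodal(selection, d, p, sigma_local)` — two-site jump: with
#'   probability `p` the whole selection is displaced coherently by the vector
#'   `d` (A); local Gaussian jitter `sigma_local` is superimposed.  Per-atom
#'   positional variance along `d` is `p (1-p) |d|^2 + sigma_local^2`.
#' * `motion_rotamer(selection, axis, angles, weights, sigma_local)` — rigid
#'   rotation of the selection about the axis through two template atoms
#'   (indices `axis = c(i, j)`), by an angle drawn from `angles` (degrees,
#'   offsets relative to the template geometry which defines 0) with the given
#'   `weights`; local jitter superimposed.  Emulates correlated side-chain
#'   rotamer flips.
#' * `motion_libration(selection, axis, sigma_deg)` — as above with a
#'   zero-mean Gaussian angle (s.d. `sigma_deg` degrees).
#'
#' @param selection integer indices of template atoms the model governs.
#' @param sigma,cov,d,p,sigma_local,axis,angles,weights,sigma_deg parameters
#'   as described above.
#' @return an object of class `motion_model`.
#' @name motion_models
NULL

new_motion <- function(kind, selection, pars) {
  stopifnot(length(selection) >= 1, all(selection >= 1))
  structure(c(list(kind = kind, selection = as.integer(selection)), pars),
            class = "motion_model")
}

#' @rdname motion_models
#' @export
motion_harmonic_iso <- function(selection, sigma) {
  stopifnot(all(sigma >= 0))
  new_motion("harmonic_iso", selection, list(sigma = sigma))
}

#' @rdname motion_models
#' @export
motion_harmonic_aniso <- function(selection, cov) {
  stopifnot(is.matrix(cov), all(dim(cov) == 3))
  if (max(abs(cov - t(cov))) > 1e-12) stop("covariance must be symmetric")
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-12) stop("covariance must be positive semidefinite")
  new_motion("harmonic_aniso", selection, list(cov = cov))
}

#' @rdname motion_models
#' @export
motion_bimodal <- function(selection, d, p = 0.5, sigma_local = 0.1) {
  stopifnot(length(d) == 3, p >= 0, p <= 1, sigma_local >= 0)
  new_motion("bimodal_jump", selection,
             list(d = as.numeric(d), p = p, sigma_local = sigma_local))
}

#' @rdname motion_models
#' @export
motion_rotamer <- function(selection, axis, angles, weights = NULL,
                           sigma_local = 0.05) {
  stopifnot(length(axis) == 2, length(angles) >= 1, sigma_local >= 0)
  if (is.null(weights)) weights <- rep(1, length(angles))
  stopifnot(length(weights) == length(angles), all(weights >= 0))
  weights <- weights / sum(weights)
  new_motion("rotamer_flip", selection,
             list(axis = as.integer(axis), angles = as.numeric(angles),
                  weights = weights, sigma_local = sigma_local))
}

#' @rdname motion_models
#' @export
motion_libration <- function(selection, axis, sigma_deg) {
  stopifnot(length(axis) == 2, sigma_deg >= 0)
  new_motion("libration", selection,
             list(axis = as.integer(axis), sigma_deg = sigma_deg))
}

#' @export
print.motion_model <- function(x, ...) {
  cat(sprintf("motion_model <%s> on %d atoms\n", x$kind, length(x$selection)))
  invisible(x)
}

# Rodrigues rotation about unit axis u by angle theta (radians)
rotation_about_axis <- function(u, theta) {
  u <- u / sqrt(sum(u^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# Draw Cartesian displacements (n_sel x 3, Angstrom) for one conformer.
# `x0` = template Cartesian coordinates (all atoms); models see their selection.
sample_motion <- function(model, x0) {
  sel <- model$selection
  n <- length(sel)
  switch(model$kind,
    harmonic_iso = matrix(stats::rnorm(3 * n, sd = model$sigma), n, 3),
    harmonic_aniso = {
      L <- chol_psd(model$cov)
      matrix(stats::rnorm(3 * n), n, 3) %*% t(L)
    },
    bimodal_jump = {
      jump <- stats::runif(1) < model$p
      delta <- matrix(stats::rnorm(3 * n, sd = model$sigma_local), n, 3)
      if (jump) delta <- sweep(delta, 2, model$d, "+")
      delta
    },
    rotamer_flip = {
      k <- sample.int(length(model$angles), 1, prob = model$weights)
      theta <- model$angles[k] * pi / 180
      delta_rot(model, x0, theta) +
        matrix(stats::rnorm(3 * n, sd = model$sigma_local), n, 3)
    },
    libration = {
      theta <- stats::rnorm(1, sd = model$sigma_deg) * pi / 180
      delta_rot(model, x0, theta)
    },
    stop("unknown motion kind: ", model$kind))
}

delta_rot <- function(model, x0, theta) {
  p1 <- x0[model$axis[1], ]
  p2 <- x0[model$axis[2], ]
  R <- rotation_about_axis(p2 - p1, theta)
  pts <- x0[model$selection, , drop = FALSE]
  rotated <- sweep(sweep(pts, 2, p1, "-") %*% t(R), 2, p1, "+")
  rotated - pts
}

chol_psd <- function(cov) {
  ed <- eigen(cov, symmetric = TRUE)
  v <- pmax(ed$values, 0)
  ed$vectors %*% diag(sqrt(v)) %*% t(ed$vectors)
}

# number of random draws consumed per conformer (for documentation/testing of
# stream independence); not used by the sampler itself.
motion_coverage <- function(models, n_atoms, mobile) {
  covered <- integer(0)
  for (m in models) {
    if (any(m$selection %in% covered))
      stop("motion model selections overlap")
    if (any(m$selection > n_atoms)) stop("selection outside atom range")
    covered <- c(covered, m$selection)
  }
  covered
}
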