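#' Refinement configuration
#'
#' @param mode `"iso"` (one B per atom) or `"aniso"` (6 U components per atom).
#' @param restrain_b apply a B-similarity restraint over bonded atom pairs.
#' @param w_b restraint weight (objective units per A^4).
#' @param max_cycles maximum refinement cycles (default 25).
#' @param tol convergence tolerance on the change in work-set R per cycle.
#' @param free_fraction fraction of reflections reserved for R_free.
#' @param seed seed for free-set selection (used by [assign_free_set()]).
#' @param b_bounds bounds on isotropic B / diagonal U-equivalent (A^2).
#' @param bond_cutoff distance cutoff (A) defining bonded pairs for the
#'   B-similarity restraint.
#' @return list of class `refine_config`.
#' @export
refine_config <- function(mode = c("iso", "aniso"), restrain_b = FALSE,
                          w_b = 0.1, max_cycles = 25, tol = 1e-5,
                          free_fraction = 0.05, seed = 42,
                          b_bounds = c(0.01, 999), bond_cutoff = 1.8) {
  mode <- match.arg(mode)
  stopifnot(free_fraction > 0, free_fraction < 0.5,
            b_bounds[1] < b_bounds[2], max_cycles >= 1)
  structure(list(mode = mode, restrain_b = restrain_b, w_b = w_b,
                 max_cycles = max_cycles, tol = tol,
                 free_fraction = free_fraction, seed = seed,
                 b_bounds = b_bounds, bond_cutoff = bond_cutoff),
            class = "refine_config")
}

#' Assign a cross-validation (free) reflection set
#'
#' Flags `round(fraction * N)` reflections, sampled uniformly without
#' replacement; reproducible for a given seed.
#'
#' @param rs a [reflection_set()].
#' @param fraction free fraction (default 0.05).
#' @param seed integer seed.
#' @return `rs` with its `free` column set.
#' @export
assign_free_set <- function(rs, fraction = 0.05, seed = 42) {
  stopifnot(fraction > 0, fraction < 0.5)
  n <- nrow(rs)
  nfree <- round(fraction * n)
  if (nfree < 1) stop("too few reflections for the requested free fraction")
  set.seed(seed)
  rs$free <- FALSE
  rs$free[sample.int(n, nfree)] <- TRUE
  rs
}

#' R factors
#'
#' `R = sum | |Fo| - k |Fc| | / sum |Fo|` over the work set, `R_free` over the
#' flagged set using the work-set scale.  Returned as fractions (0.10 = 10%).
#'
#' @param fo,fc observed and calculated amplitudes (numeric or complex).
#' @param free logical free-set flags (default: none free).
#' @param refit_scale least-squares refit of the overall scale k on the work
#'   set (default TRUE); otherwise k = 1.
#' @return list with `r`, `r_free` (NA when no flagged reflections), `k`.
#' @export
compute_r_factors <- function(fo, fc, free = NULL, refit_scale = TRUE) {
  fo <- Mod(fo); fc <- Mod(fc)
  stopifnot(length(fo) == length(fc))
  if (is.null(free)) free <- rep(FALSE, length(fo))
  work <- !free
  if (!any(work)) stop("empty work set")
  k <- if (refit_scale) sum(fo[work] * fc[work]) / sum(fc[work]^2) else 1
  r <- sum(abs(fo[work] - k * fc[work])) / sum(fo[work])
  r_free <- if (any(free))
    sum(abs(fo[free] - k * fc[free])) / sum(fo[free]) else NA_real_
  list(r = r, r_free = r_free, k = k)
}

# bonded pairs (i, j) within cutoff, Cartesian, within the asu chain
bonded_pairs <- function(structure, cutoff = 1.8) {
  cart <- frac_to_cart(structure$cell, coords_frac(structure))
  n <- nrow(cart)
  if (n < 2) return(matrix(integer(0), 0, 2))
  d2 <- as.matrix(stats::dist(cart))^2
  pairs <- which(upper.tri(d2) & d2 <= cutoff^2, arr.ind = TRUE)
  pairs
}

#' Refine displacement parameters against observed amplitudes
#'
#' Least-squares fit of an overall scale and per-atom isotropic B (or
#' anisotropic U) to observed amplitudes, with atomic positions held fixed:
#' minimizes `sum_work (|Fo| - k |Fc|)^2` (plus, optionally, a B-similarity
#' restraint `w_b * sum_bonded (B_i - B_j)^2`) by bounded quasi-Newton
#' (L-BFGS-B) with analytic gradients; the scale `k` is profiled out
#' analytically at every evaluation.  Runs in cycles and stops when the
#' work-set R changes by less than `tol` or `max_cycles` is reached.
#'
#' The model is the asymmetric unit in the reflection set's space group;
#' symmetry mates are summed internally.  In anisotropic mode U tensors are
#' projected back to positive semidefinite (eigenvalues clamped at 1e-4 A^2)
#' after optimization; projections are counted in the result.
#'
#' @param model an [xtal_structure()] (asymmetric unit, positions fixed).
#' @param observed a [reflection_set()] with amplitudes (complex or numeric
#'   `F`) and free flags set (see [assign_free_set()]).
#' @param config a [refine_config()].
#' @return object of class `refinement_result`: `structure` (B/U updated),
#'   `k`, `r`, `r_free` (fractions), `trace` (per-cycle data frame),
#'   `converged`, `restraint_residual`, `n_psd_projected`, `mode`.
#' @export
refine <- function(model, observed, config = refine_config()) {
  stopifnot(inherits(model, "xtal_structure"),
            inherits(observed, "reflection_set"))
  fo <- Mod(observed$F)
  if (any(fo < 0) || all(fo == 0)) stop("invalid observed amplitudes")
  free <- observed$free
  work <- !free
  hkl <- rs_hkl(observed)
  cell <- model$cell
  sg <- rs_sg(observed)
  a <- model$atoms
  A <- nrow(a)
  s2 <- inv_d2(cell, hkl) / 4
  coords <- coords_frac(model)
  ffm <- form_factor_matrix(a$element, s2)
  occ <- a$occ

  # per-op phase matrices (positions fixed -> computed once)
  ops <- sg$ops
  Pops <- lapply(ops, function(op) {
    hop <- hkl %*% op$R
    ph <- as.vector(hkl %*% op$t)
    E <- exp(2i * pi * (coords %*% t(hop)))             # A x R
    E * matrix(exp(2i * pi * ph), A, nrow(hkl), byrow = TRUE)
  })
  iso <- config$mode == "iso"
  if (iso) {
    M0 <- Reduce(`+`, Pops) * (occ * ffm)
  } else {
    Wops <- lapply(ops, function(op) {
      Sop <- scattering_vectors(cell, hkl %*% op$R)
      rbind(Sop[, 1]^2, Sop[, 2]^2, Sop[, 3]^2,
            2 * Sop[, 1] * Sop[, 2], 2 * Sop[, 1] * Sop[, 3],
            2 * Sop[, 2] * Sop[, 3])                    # 6 x R
    })
    CF <- occ * ffm
  }

  pairs <- if (config$restrain_b) bonded_pairs(model, config$bond_cutoff)
           else matrix(integer(0), 0, 2)

  fc_of <- function(par) {
    if (iso) {
      D <- exp(-outer(par, s2))
      colSums(D * M0)
    } else {
      U6 <- matrix(par, A, 6)
      acc <- 0
      for (oi in seq_along(ops))
        acc <- acc + colSums(CF * exp(-2 * pi^2 * (U6 %*% Wops[[oi]])) *
                               Pops[[oi]])
      acc
    }
  }
  beq_of <- function(par) {
    if (iso) par
    else (8 * pi^2 / 3) * rowSums(matrix(par, A, 6)[, 1:3, drop = FALSE])
  }
  restraint <- function(par) {
    if (!nrow(pairs)) return(list(v = 0, g = numeric(length(par))))
    beq <- beq_of(par)
    dd <- beq[pairs[, 1]] - beq[pairs[, 2]]
    g_b <- numeric(A)
    acc <- tapply(c(2 * config$w_b * dd, -2 * config$w_b * dd),
                  c(pairs[, 1], pairs[, 2]), sum)
    g_b[as.integer(names(acc))] <- acc
    g <- if (iso) g_b
         else as.vector(matrix(g_b, A, 6) *
                          rep(c(rep(8 * pi^2 / 3, 3), 0, 0, 0), each = A))
    list(v = config$w_b * sum(dd^2), g = g)
  }

  obj_env <- new.env()
  objective <- function(par) {
    Fc <- fc_of(par)
    fcm <- Mod(Fc)
    k <- sum(fo[work] * fcm[work]) / sum(fcm[work]^2)
    resid <- fo - k * fcm
    rst <- restraint(par)
    obj_env$Fc <- Fc; obj_env$k <- k
    sum(resid[work]^2) + rst$v
  }
  gradient <- function(par) {
    Fc <- obj_env$Fc; k <- obj_env$k
    fcm <- Mod(Fc)
    u <- Conj(Fc) / pmax(fcm, 1e-300)
    wvec <- numeric(length(fo))
    wvec[work] <- -2 * (fo[work] - k * fcm[work]) * k
    rst <- restraint(par)
    if (iso) {
      D <- exp(-outer(par, s2))
      cvec <- wvec * u * (-s2)
      g <- Re((D * M0) %*% cvec)
      as.vector(g) + rst$g
    } else {
      U6 <- matrix(par, A, 6)
      g <- matrix(0, A, 6)
      cu <- wvec * u
      for (oi in seq_along(ops)) {
        G <- CF * exp(-2 * pi^2 * (U6 %*% Wops[[oi]])) * Pops[[oi]]
        g <- g + Re((G * matrix(cu, A, length(cu), byrow = TRUE)) %*%
                      t(Wops[[oi]])) * (-2 * pi^2)
      }
      as.vector(g) + rst$g
    }
  }

  b0 <- pmin(pmax(a$b, config$b_bounds[1]), config$b_bounds[2])
  if (!iso && !has_aniso(model)) {
    # stage the anisotropic fit from a converged isotropic one: starting all
    # six components from a flat overall B can trap the quasi-Newton search
    # in a poor basin, while the iso optimum is reliably close
    iso_cfg <- config
    iso_cfg$mode <- "iso"
    b0 <- refine(model, observed, iso_cfg)$structure$atoms$b
  }
  pscale <- if (iso) 1 else 1 / (8 * pi^2)
  if (iso) {
    par <- b0
    lower <- rep(config$b_bounds[1], A)
    upper <- rep(config$b_bounds[2], A)
  } else {
    u_from_b <- b0 / (8 * pi^2)
    par <- if (has_aniso(model)) as.vector(u_matrix_rows(a))
           else c(u_from_b, u_from_b, u_from_b, numeric(3 * A))
    umax <- config$b_bounds[2] / (8 * pi^2)
    umin <- config$b_bounds[1] / (8 * pi^2)
    lower <- c(rep(umin, 3 * A), rep(-umax, 3 * A))
    upper <- rep(umax, 6 * A)
  }

  trace <- data.frame(cycle = integer(0), r = numeric(0), r_free = numeric(0))
  r_prev <- Inf
  converged <- FALSE
  for (cyc in seq_len(config$max_cycles)) {
    fit <- stats::optim(par, objective, gradient, method = "L-BFGS-B",
                        lower = lower, upper = upper,
                        control = list(maxit = 40, factr = 10,
                                       parscale = rep(pscale, length(par))))
    par <- fit$par
    objective(par)  # refresh Fc/k
    rf <- compute_r_factors(fo, Mod(obj_env$Fc), free)
    trace <- rbind(trace, data.frame(cycle = cyc, r = rf$r,
                                     r_free = rf$r_free))
    if (abs(r_prev - rf$r) < config$tol) { converged <- TRUE; break }
    r_prev <- rf$r
  }

  n_proj <- 0L
  out <- model
  if (iso) {
    out$atoms$b <- par
  } else {
    U6 <- matrix(par, A, 6)
    for (i in seq_len(A)) {
      U <- u6_to_mat(U6[i, ])
      ed <- eigen(U, symmetric = TRUE)
      if (min(ed$values) < 1e-4) {
        n_proj <- n_proj + 1L
        U <- ed$vectors %*% diag(pmax(ed$values, 1e-4)) %*% t(ed$vectors)
        U6[i, ] <- mat_to_u6(U)
      }
    }
    ucols <- c("u11", "u22", "u33", "u12", "u13", "u23")
    for (j in 1:6) out$atoms[[ucols[j]]] <- U6[, j]
    out$atoms$b <- (8 * pi^2 / 3) * rowSums(U6[, 1:3, drop = FALSE])
    par <- as.vector(U6)
  }
  objective(par)
  rf <- compute_r_factors(fo, Mod(obj_env$Fc), free)
  structure(list(structure = out, k = rf$k, r = rf$r, r_free = rf$r_free,
                 trace = trace, converged = converged,
                 restraint_residual = restraint(par)$v,
                 n_psd_projected = n_proj, mode = config$mode),
            class = "refinement_result")
}

#' @export
print.refinement_result <- function(x, ...) {
  cat(sprintf("refinement (%s): R = %.2f%%, R_free = %.2f%%, %d cycles%s\n",
              x$mode, 100 * x$r, 100 * x$r_free, nrow(x$trace),
              if (x$converged) " (converged)" else ""))
  invisible(x)
}
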