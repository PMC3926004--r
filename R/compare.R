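#' Compare actual and refined B-factors
#'
#' Joins the ground-truth fluctuation table with a refined structure atom by
#' atom and summarizes the discrepancy: per-atom differences, RMS deviation,
#' the single largest difference (delta_max), and an ordinary least-squares
#' regression of refined on actual B.  An optional `range` restricts all
#' summary statistics to atoms whose actual B lies inside `[range[1],
#' range[2]]` (the regime where agreement would normally be expected).
#'
#' @param actual a `fluctuation_table` (see [compute_fluctuations()]).
#' @param refined an [xtal_structure()] with refined `b` (and optionally U).
#' @param range optional `c(lo, hi)` window on actual B (A^2).
#' @return object of class `b_comparison`: `per_atom` data frame and `summary`
#'   list with `rms_b`, `delta_max`, `slope`, `intercept`, `r2`, `n_atoms`,
#'   `frac_under` (fraction of atoms with refined < actual).
#' @export
compare_bfactors <- function(actual, refined, range = NULL) {
  act <- as.data.frame(actual)
  ref <- refined$atoms
  if (nrow(act) != nrow(ref) ||
      any(act$resno != ref$resno) || any(act$elety != ref$elety))
    stop("atom id mismatch between actual and refined tables")
  per <- data.frame(resno = act$resno, resid = act$resid, elety = act$elety,
                    actual_b = act$b_iso, refined_b = ref$b,
                    diff = ref$b - act$b_iso)
  ucols <- c("u11", "u22", "u33", "u12", "u13", "u23")
  if (all(ucols %in% names(ref)) && !anyNA(ref$u11)) {
    for (u in ucols) {
      per[[paste0("actual_", u)]] <- act[[u]]
      per[[paste0("refined_", u)]] <- ref[[u]]
    }
  }
  sel <- if (is.null(range)) rep(TRUE, nrow(per))
         else per$actual_b >= range[1] & per$actual_b <= range[2]
  sub <- per[sel, ]
  if (!nrow(sub)) stop("no atoms inside the requested actual-B range")
  rms_b <- sqrt(mean(sub$diff^2))
  delta_max <- max(abs(sub$diff))
  if (stats::var(sub$actual_b) < 1e-6) {
    slope <- intercept <- r2 <- NA_real_
  } else {
    fit <- stats::lm(refined_b ~ actual_b, data = sub)
    slope <- unname(stats::coef(fit)[2])
    intercept <- unname(stats::coef(fit)[1])
    tss <- sum((sub$refined_b - mean(sub$refined_b))^2)
    r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else NA_real_
  }
  structure(list(per_atom = per,
                 summary = list(rms_b = rms_b, delta_max = delta_max,
                                slope = slope, intercept = intercept,
                                r2 = r2, n_atoms = nrow(sub),
                                frac_under = mean(sub$refined_b < sub$actual_b),
                                range = range)),
            class = "b_comparison")
}

#' @export
print.b_comparison <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("B comparison over %d atoms%s: RMS = %.2f A^2, ",
                     "delta_max = %.2f A^2, slope = %.3f, R^2 = %.3f, ",
                     "refined < actual for %.0f%%\n"),
              s$n_atoms,
              if (is.null(s$range)) "" else
                sprintf(" (actual B in [%g, %g])", s$range[1], s$range[2]),
              s$rms_b, s$delta_max, s$slope, s$r2, 100 * s$frac_under))
  invisible(x)
}

#' Export a B comparison
#'
#' Writes the per-atom table as TSV and the summary as JSON.
#'
#' @param cmp a `b_comparison`.
#' @param tsv,json output paths (either may be NULL).
#' @export
write_b_comparison <- function(cmp, tsv = NULL, json = NULL) {
  if (!is.null(tsv))
    utils::write.table(cmp$per_atom, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(cmp$summary, json, auto_unbox = TRUE, digits = NA,
                         null = "null")
  invisible(cmp)
}

# expand an asu reflection set to the full P1 list (all ops + Friedel mates),
# returning h,k,l and complex F ready for Fourier synthesis
expand_to_p1_reflections <- function(hkl, Fv, sg) {
  seen <- new.env(hash = TRUE)
  out_h <- list(); out_F <- list(); n <- 0L
  add <- function(hm, Fm) {
    key <- paste(hm[, 1], hm[, 2], hm[, 3])
    new <- !vapply(key, function(k) exists(k, envir = seen), logical(1))
    if (any(new)) {
      for (k in key[new]) assign(k, TRUE, envir = seen)
      n <<- n + 1L
      out_h[[n]] <<- hm[new, , drop = FALSE]
      out_F[[n]] <<- Fm[new]
    }
  }
  for (op in sg$ops) {
    hop <- hkl %*% op$R
    Fop <- Fv * exp(-2i * pi * as.vector(hkl %*% op$t))
    add(hop, Fop)
    add(-hop, Conj(Fop))
  }
  list(hkl = do.call(rbind, out_h), F = do.call(c, out_F))
}

#' Fourier synthesis of a difference map
#'
#' Computes model structure factors at the observed indices, fits the overall
#' scale on all reflections, and synthesizes the `Fo - Fc` map with
#' coefficients `(|Fo| - k |Fc|) exp(i phi_calc)` expanded to P1.  The map has
#' zero mean by construction (no F(000) term).
#'
#' @param observed a [reflection_set()] with amplitudes.
#' @param model an [xtal_structure()] providing phases (asu + space group).
#' @param grid_spacing map grid spacing in Angstrom.
#' @return object of class `density_map`: list with `grid` (3-d array),
#'   `cell`, `n` (grid dims), `sigma` (map standard deviation) and `k`.
#' @export
difference_map <- function(observed, model, grid_spacing = 0.45) {
  fo <- Mod(observed$F)
  fc_rs <- calc_sf_direct(model, observed)
  fcm <- Mod(fc_rs$F)
  k <- sum(fo * fcm) / sum(fcm^2)
  coef <- (fo - k * fcm) * fc_rs$F / pmax(fcm, 1e-300)
  synth_map(rs_hkl(observed), coef, rs_sg(observed), model$cell, grid_spacing,
            k = k)
}

synth_map <- function(hkl, coef, sg, cell, grid_spacing, k = 1) {
  full <- expand_to_p1_reflections(hkl, coef, sg)
  n1 <- stats::nextn(ceiling(cell$a / grid_spacing), c(2, 3, 5))
  n2 <- stats::nextn(ceiling(cell$b / grid_spacing), c(2, 3, 5))
  n3 <- stats::nextn(ceiling(cell$c / grid_spacing), c(2, 3, 5))
  Fgrid <- array(0 + 0i, c(n1, n2, n3))
  i1 <- full$hkl[, 1] %% n1 + 1
  i2 <- full$hkl[, 2] %% n2 + 1
  i3 <- full$hkl[, 3] %% n3 + 1
  Fgrid[cbind(i1, i2, i3)] <- full$F
  rho <- Re(stats::fft(Fgrid)) / cell$volume
  structure(list(grid = rho, cell = cell, n = c(n1, n2, n3),
                 sigma = stats::sd(as.vector(rho)), k = k),
            class = "density_map")
}

#' Model density map
#'
#' Fourier synthesis of `Fc exp(i phi_c)` for a structure on a grid (useful as
#' the reference in real-space correlations).
#'
#' @param model an [xtal_structure()].
#' @param hkl a [reflection_set()] defining the resolution content.
#' @param grid_spacing grid spacing in Angstrom.
#' @return a `density_map`.
#' @export
model_map <- function(model, hkl, grid_spacing = 0.45) {
  fc <- calc_sf_direct(model, hkl)
  synth_map(rs_hkl(fc), fc$F, rs_sg(fc), model$cell, grid_spacing)
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("density_map %d x %d x %d, sigma = %.4g e/A^3\n",
              x$n[1], x$n[2], x$n[3], x$sigma))
  invisible(x)
}

#' Per-residue real-space correlation
#'
#' Pearson correlation of two maps over the grid points lying within `radius`
#' of any atom of each residue (minimum-image distances, asu atoms expanded by
#' the model's symmetry operators).
#'
#' @param map1,map2 `density_map`s on identical grids.
#' @param model [xtal_structure()] whose residues define the masks.
#' @param radius mask radius in Angstrom (default 2).
#' @return data frame with `resno`, `rscc`, `n_points`.
#' @export
real_space_cc <- function(map1, map2, model, radius = 2) {
  if (!all(map1$n == map2$n)) stop("maps are on different grids")
  cell <- map1$cell
  n <- map1$n
  # all symmetry copies of the atoms, fractional
  frac <- do.call(rbind, lapply(seq_len(model$sg$n_ops), function(i)
    coords_frac(apply_symmetry(model, i))))
  resno <- rep(model$atoms$resno, model$sg$n_ops)
  res_ids <- unique(model$atoms$resno)
  out <- data.frame(resno = res_ids, rscc = NA_real_, n_points = NA_integer_)
  step <- c(cell$a, cell$b, cell$c) / n
  rad_idx <- ceiling(radius / step)
  for (ri in seq_along(res_ids)) {
    rows <- which(resno == res_ids[ri])
    mask <- array(FALSE, n)
    for (j in rows) {
      ctr <- frac[j, ] * n
      i1 <- (floor(ctr[1] - rad_idx[1]):ceiling(ctr[1] + rad_idx[1]))
      i2 <- (floor(ctr[2] - rad_idx[2]):ceiling(ctr[2] + rad_idx[2]))
      i3 <- (floor(ctr[3] - rad_idx[3]):ceiling(ctr[3] + rad_idx[3]))
      dx <- (i1 - ctr[1]) * step[1]
      dy <- (i2 - ctr[2]) * step[2]
      dz <- (i3 - ctr[3]) * step[3]
      inside <- outer(outer(dx^2, dy^2, "+"), dz^2, "+") <= radius^2
      w1 <- i1 %% n[1] + 1; w2 <- i2 %% n[2] + 1; w3 <- i3 %% n[3] + 1
      sub <- mask[w1, w2, w3]
      mask[w1, w2, w3] <- sub | inside
    }
    if (!any(mask)) stop("empty mask for residue ", res_ids[ri])
    out$rscc[ri] <- stats::cor(map1$grid[mask], map2$grid[mask])
    out$n_points[ri] <- sum(mask)
  }
  out
}

#' Write a density map in CCP4/MRC format
#'
#' Minimal mode-2 (float32) writer covering the full unit cell.
#'
#' @param map a `density_map`.
#' @param path output file.
#' @export
write_ccp4_map <- function(map, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  n <- map$n
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(n)               # NC NR NS
  wi(2)               # MODE float32
  wi(c(0, 0, 0))      # start
  wi(n)               # intervals
  wf(c(map$cell$a, map$cell$b, map$cell$c,
       map$cell$alpha, map$cell$beta, map$cell$gamma))
  wi(c(1, 2, 3))      # axis order
  g <- as.vector(map$grid)
  wf(c(min(g), max(g), mean(g)))
  wi(1)               # space group (map stored as P1 cell)
  wi(0)               # NSYMBT
  wi(rep(0, 25))      # extra
  wf(c(0, 0, 0))      # origin
  writeChar("MAP ", con, 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(g))
  wi(0)               # NLABL
  writeBin(raw(800), con)
  wf(g)
  invisible(path)
}
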