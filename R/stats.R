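#' Per-atom fluctuation statistics of pooled monomers
#'
#' Computes, for every atom over all pooled monomers, the mean Cartesian
#' position, the root-mean-square fluctuation `RMSF = sqrt(<|r - <r>|^2>)`,
#' the isotropic Debye-Waller B-factor under the standard convention
#' `B = (8 pi^2 / 3) <|dr|^2>`, and the anisotropic displacement tensor
#' `U = <dr dr^T>` in the Cartesian frame (A^2).  No fitting is performed:
#' monomers must already be expressed in the reference frame
#' (see [map_to_reference()] / [ensemble_monomers()]).
#'
#' @param monomers either an array `atoms x 3 x n` of fractional
#'   reference-frame coordinates, or a list of [xtal_structure()] monomers.
#' @param cell [unit_cell()] used to convert to Cartesian (taken from the
#'   first structure when `monomers` is a list).
#' @param atoms optional atom table for labels.
#' @return a `fluctuation_table` data frame with columns `resno, resid, elety,
#'   element, mean_x, mean_y, mean_z, rmsf, b_iso, u11..u23`; attribute
#'   `n_monomers`.
#' @export
compute_fluctuations <- function(monomers, cell = NULL, atoms = NULL) {
  pm <- pool_monomers(monomers, cell, atoms)
  if (dim(pm$arr)[3] < 2) stop("need at least 2 pooled monomers")
  A <- dim(pm$arr)[1]; M <- dim(pm$arr)[3]
  # Cartesian coordinates: flatten monomers, one matmul
  flat <- matrix(aperm(pm$arr, c(1, 3, 2)), A * M, 3)
  cart <- flat %*% t(pm$cell$orth)
  dim(cart) <- c(A, M, 3)
  mean_pos <- apply(cart, c(1, 3), mean)
  dev <- sweep(cart, c(1, 3), mean_pos, "-")
  u11 <- rowMeans(dev[, , 1]^2); u22 <- rowMeans(dev[, , 2]^2)
  u33 <- rowMeans(dev[, , 3]^2)
  u12 <- rowMeans(dev[, , 1] * dev[, , 2])
  u13 <- rowMeans(dev[, , 1] * dev[, , 3])
  u23 <- rowMeans(dev[, , 2] * dev[, , 3])
  msf <- u11 + u22 + u33
  out <- data.frame(pm$labels,
                    mean_x = mean_pos[, 1], mean_y = mean_pos[, 2],
                    mean_z = mean_pos[, 3],
                    rmsf = sqrt(msf), b_iso = (8 * pi^2 / 3) * msf,
                    u11 = u11, u22 = u22, u33 = u33,
                    u12 = u12, u13 = u13, u23 = u23)
  attr(out, "n_monomers") <- M
  attr(out, "cell") <- pm$cell
  class(out) <- c("fluctuation_table", "data.frame")
  out
}

pool_monomers <- function(monomers, cell = NULL, atoms = NULL) {
  if (is.list(monomers) && inherits(monomers[[1]], "xtal_structure")) {
    cell <- monomers[[1]]$cell
    atoms <- monomers[[1]]$atoms
    arr <- array(unlist(lapply(monomers, coords_frac)),
                 dim = c(n_atoms(monomers[[1]]), 3, length(monomers)))
  } else {
    arr <- monomers
    stopifnot(length(dim(arr)) == 3, dim(arr)[2] == 3)
    if (is.null(cell)) stop("cell required when monomers is an array")
  }
  labels <- if (!is.null(atoms))
    atoms[, c("resno", "resid", "elety", "element")]
  else data.frame(resno = NA_integer_, resid = NA_character_,
                  elety = NA_character_, element = NA_character_,
                  stringsAsFactors = FALSE)[rep(1, dim(arr)[1]), ]
  list(arr = arr, cell = cell, labels = labels)
}

#' Ensemble fluctuation table
#'
#' Convenience wrapper: maps every monomer of a sampled ensemble back to the
#' reference frame and calls [compute_fluctuations()].
#'
#' @param ensemble a `crystal_ensemble`.
#' @return a `fluctuation_table`.
#' @export
ensemble_fluctuations <- function(ensemble) {
  compute_fluctuations(ensemble_monomers(ensemble),
                       cell = ensemble$spec$template$cell,
                       atoms = ensemble$spec$template$atoms)
}

#' Per-snapshot no-fit RMSD series
#'
#' RMSD of each monomer against the reference chain, computed in Cartesian
#' Angstrom on the selected atoms with no rotational/translational fitting,
#' then averaged over the monomers of each snapshot.
#'
#' @param ensemble a `crystal_ensemble`.
#' @param reference reference [xtal_structure()] (default: the template).
#' @param selection integer atom indices (default: all atoms).
#' @return data frame with columns `snapshot`, `rmsd_mean`, `rmsd_sd`.
#' @export
compute_rmsd_series <- function(ensemble, reference = NULL, selection = NULL) {
  tpl <- ensemble$spec$template
  if (is.null(reference)) reference <- tpl
  if (is.null(selection)) selection <- seq_len(n_atoms(tpl))
  if (length(selection) == 0) stop("empty selection")
  ref_cart <- frac_to_cart(reference$cell, coords_frac(reference))[selection, , drop = FALSE]
  mono <- ensemble_monomers(ensemble)
  n_sites <- dim(mono)[3] / dim(ensemble$coords)[3]
  nt <- dim(ensemble$coords)[3]
  out <- data.frame(snapshot = seq_len(nt), rmsd_mean = NA_real_,
                    rmsd_sd = NA_real_)
  for (t in seq_len(nt)) {
    idx <- ((t - 1) * n_sites + 1):(t * n_sites)
    r <- vapply(idx, function(m) {
      cart <- frac_to_cart(tpl$cell, mono[selection, , m])
      sqrt(mean(rowSums((cart - ref_cart)^2)))
    }, numeric(1))
    out$rmsd_mean[t] <- mean(r)
    out$rmsd_sd[t] <- stats::sd(r)
  }
  out
}

#' Ensemble-average structure
#'
#' Coordinate-wise mean over pooled monomers, with B-factors populated from
#' the fluctuation table.  The average of a multimodal ensemble can be
#' nonphysical (e.g. the midpoint of a two-site atom, a collapsed ring); the
#' structure is flagged `possibly_nonphysical` when any atom's RMSF exceeds
#' 0.5 A.
#'
#' @param monomers as in [compute_fluctuations()] (array or list), or a
#'   `crystal_ensemble`.
#' @param cell,atoms see [compute_fluctuations()].
#' @return an [xtal_structure()] with attribute `possibly_nonphysical`.
#' @export
average_structure <- function(monomers, cell = NULL, atoms = NULL) {
  if (inherits(monomers, "crystal_ensemble")) {
    ens <- monomers
    cell <- ens$spec$template$cell
    atoms <- ens$spec$template$atoms
    monomers <- ensemble_monomers(ens)
    sg <- ens$spec$template$sg
  } else sg <- space_group("P1")
  fl <- compute_fluctuations(monomers, cell, atoms)
  frac <- cart_to_frac(cell, as.matrix(fl[, c("mean_x", "mean_y", "mean_z")]))
  if (is.null(atoms)) stop("atom table required")
  at <- atoms
  at$x <- frac[, 1]; at$y <- frac[, 2]; at$z <- frac[, 3]
  at$b <- fl$b_iso
  for (u in c("u11", "u22", "u33", "u12", "u13", "u23")) at[[u]] <- fl[[u]]
  out <- xtal_structure(cell, sg, at)
  attr(out, "possibly_nonphysical") <- any(fl$rmsf > 0.5)
  out
}

# dihedral angle (degrees, in [0, 360)) for points p1..p4, rows of cart coords
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1])
  b2n <- sqrt(sum(b2^2))
  ang <- atan2(sum(m1 * n2) / b2n, sum(n1 * n2)) * 180 / pi
  ang %% 360
}

#' Side-chain dihedral free-energy profile
#'
#' Computes chi1 (and chi2 where defined) for one residue across all pooled
#' monomers, bins them in 10-degree bins and converts the probabilities to a
#' statistical free energy `F = -ln P` in units of RT, shifted so the global
#' minimum is 0.  Empty bins are reported as `NA` (undefined), not zero.
#'
#' @param monomers array/list of monomers or a `crystal_ensemble`.
#' @param residue residue number.
#' @param cell,atoms see [compute_fluctuations()].
#' @param bin_width bin width in degrees (default 10).
#' @return object of class `dihedral_distribution`: list with `residue`,
#'   `breaks`, `P` and `F` (matrix chi1 x chi2, or vectors when chi2 is
#'   undefined), and the raw `chi1`/`chi2` samples.
#' @export
chi_profile <- function(monomers, residue, cell = NULL, atoms = NULL,
                        bin_width = 10) {
  if (inherits(monomers, "crystal_ensemble")) {
    ens <- monomers
    cell <- ens$spec$template$cell
    atoms <- ens$spec$template$atoms
    monomers <- ensemble_monomers(ens)
  }
  pm <- pool_monomers(monomers, cell, atoms)
  stopifnot(!is.null(atoms))
  rows <- which(atoms$resno == residue)
  if (!length(rows)) stop("residue not found: ", residue)
  resname <- atoms$resid[rows[1]]
  defs <- .chi_atoms[[resname]]
  if (is.null(defs)) stop("no chi definition for residue type ", resname)
  idx_of <- function(names) {
    i <- rows[match(names, atoms$elety[rows])]
    if (anyNA(i)) NULL else i
  }
  i1 <- idx_of(defs$chi1)
  if (is.null(i1)) stop("chi1 atoms missing for residue ", residue)
  i2 <- if (!is.null(defs$chi2)) idx_of(defs$chi2) else NULL
  M <- dim(pm$arr)[3]
  chi1 <- numeric(M); chi2 <- if (!is.null(i2)) numeric(M) else NULL
  for (m in seq_len(M)) {
    cart <- frac_to_cart(pm$cell, pm$arr[, , m])
    chi1[m] <- dihedral_angle(cart[i1[1], ], cart[i1[2], ], cart[i1[3], ],
                              cart[i1[4], ])
    if (!is.null(i2))
      chi2[m] <- dihedral_angle(cart[i2[1], ], cart[i2[2], ], cart[i2[3], ],
                                cart[i2[4], ])
  }
  breaks <- seq(0, 360, by = bin_width)
  if (is.null(chi2)) {
    counts <- table(cut(chi1, breaks, include.lowest = TRUE, right = FALSE))
    P <- as.numeric(counts) / M
  } else {
    c1 <- cut(chi1, breaks, include.lowest = TRUE, right = FALSE)
    c2 <- cut(chi2, breaks, include.lowest = TRUE, right = FALSE)
    P <- as.matrix(table(c1, c2)) / M
  }
  F <- -log(P)
  F[!is.finite(F)] <- NA
  F <- F - min(F, na.rm = TRUE)
  structure(list(residue = residue, resid = resname, breaks = breaks,
                 P = P, F = F, chi1 = chi1, chi2 = chi2),
            class = "dihedral_distribution")
}

#' @export
print.dihedral_distribution <- function(x, ...) {
  cat(sprintf("chi profile for residue %d (%s): %s\n", x$residue, x$resid,
              if (is.null(x$chi2)) "chi1 only" else "chi1 x chi2"))
  invisible(x)
}

#' Export a fluctuation table as TSV
#'
#' @param fl a `fluctuation_table`.
#' @param path output file.
#' @export
write_fluctuations <- function(fl, path) {
  utils::write.table(as.data.frame(fl), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
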