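#' Reflection set container
#'
#' A data frame of Miller indices with resolution, complex structure factors
#' (or amplitudes), free-set flags and multiplicities, tied to a cell and
#' space group (stored as attributes).
#'
#' @param hkl n x 3 integer matrix.
#' @param cell a [unit_cell()].
#' @param sg a [space_group()].
#' @param F optional complex structure factors.
#' @return object of class `reflection_set` (a data frame).
#' @export
reflection_set <- function(hkl, cell, sg, F = NULL) {
  hkl <- as_coord_matrix(hkl)
  rs <- data.frame(h = as.integer(hkl[, 1]), k = as.integer(hkl[, 2]),
                   l = as.integer(hkl[, 3]),
                   d = d_spacing(cell, hkl))
  if (!is.null(F)) rs$F <- F
  rs$free <- FALSE
  attr(rs, "cell") <- cell
  attr(rs, "sg") <- sg
  class(rs) <- c("reflection_set", "data.frame")
  rs
}

rs_hkl <- function(rs) cbind(rs$h, rs$k, rs$l)
rs_cell <- function(rs) attr(rs, "cell")
rs_sg <- function(rs) attr(rs, "sg")

#' Generate symmetry-unique Miller indices
#'
#' Enumerates the Friedel-merged, symmetry-unique reflections of the space
#' group's Laue class within a resolution range, with systematic absences and
#' the origin excluded.  For the orthorhombic Laue class mmm the asymmetric
#' unit is `h, k, l >= 0` (each orbit has exactly one such representative);
#' for P1 a standard reciprocal hemisphere is used.
#'
#' @param cell a [unit_cell()].
#' @param sg a [space_group()] or name.
#' @param d_max low-resolution limit in Angstrom (default `Inf`: include all
#'   low-resolution reflections).
#' @param d_min high-resolution limit in Angstrom.
#' @return a [reflection_set()] (indices, no F).
#' @examples
#' nrow(generate_hkl(unit_cell(10, 10, 10), "P1", d_min = 5))  # 16
#' @export
generate_hkl <- function(cell, sg, d_max = Inf, d_min = 1.0) {
  if (is.character(sg)) sg <- space_group(sg)
  stopifnot(d_min > 0, d_max > d_min)
  eps <- 1e-9
  hmax <- floor(cell$a / d_min + eps)
  kmax <- floor(cell$b / d_min + eps)
  lmax <- floor(cell$c / d_min + eps)
  if (sg$name == "P1") {
    g <- expand.grid(h = 0:hmax, k = -kmax:kmax, l = -lmax:lmax)
    hemi <- g$h > 0 | (g$h == 0 & g$k > 0) |
      (g$h == 0 & g$k == 0 & g$l > 0)
    g <- g[hemi, ]
  } else {
    g <- expand.grid(h = 0:hmax, k = 0:kmax, l = 0:lmax)
    g <- g[g$h + g$k + g$l > 0, ]
  }
  hkl <- as.matrix(g)
  d <- d_spacing(cell, hkl)
  keep <- d >= d_min * (1 - eps) & d <= d_max * (1 + eps)
  keep <- keep & !is_absent(sg, hkl)
  hkl <- hkl[keep, , drop = FALSE]
  ord <- order(-d[keep], hkl[, 1], hkl[, 2], hkl[, 3])
  reflection_set(hkl[ord, , drop = FALSE], cell, sg)
}

# Core direct-summation engine.
# coords: A x 3 fractional; elements: length A; b: length A isotropic B (A^2)
# or NULL; u6: A x 6 Cartesian aniso U or NULL (takes precedence); occ: length
# A; hkl: R x 3; ops: list of symmetry operators to sum over.
sf_direct_engine <- function(coords, elements, b, u6, occ, hkl, cell,
                             ops = list(list(R = diag(3L), t = c(0, 0, 0))),
                             chunk = 262144L) {
  A <- nrow(coords)
  R <- nrow(hkl)
  s2 <- inv_d2(cell, hkl) / 4
  Fout <- complex(R)
  ffm <- form_factor_matrix(elements, s2)      # A x R
  occ <- if (is.null(occ)) rep(1, A) else occ
  chunk_rows <- max(1L, floor(chunk / A))
  for (start in seq(1L, R, by = chunk_rows)) {
    idx <- start:min(start + chunk_rows - 1L, R)
    hsub <- hkl[idx, , drop = FALSE]
    acc <- complex(length(idx))
    for (op in ops) {
      hop <- hsub %*% op$R                      # reciprocal action
      phase_t <- as.vector(hsub %*% op$t)       # h . t
      P <- coords %*% t(hop)                    # A x r (fractional dot)
      E <- exp(2i * pi * P)
      if (!is.null(u6)) {
        Sop <- scattering_vectors(cell, hop)    # r x 3 Cartesian
        W <- rbind(Sop[, 1]^2, Sop[, 2]^2, Sop[, 3]^2,
                   2 * Sop[, 1] * Sop[, 2], 2 * Sop[, 1] * Sop[, 3],
                   2 * Sop[, 2] * Sop[, 3])     # 6 x r
        DW <- exp(-2 * pi^2 * (u6 %*% W))       # A x r
      } else if (!is.null(b)) {
        DW <- exp(-outer(b, s2[idx]))
      } else DW <- 1
      contrib <- colSums((occ * ffm[, idx, drop = FALSE]) * DW * E)
      acc <- acc + contrib * exp(2i * pi * phase_t)
    }
    Fout[idx] <- acc
  }
  Fout
}

#' Structure factors by direct summation
#'
#' Exact sum `F(h) = sum_j occ_j f_j(s) DW_j exp(2 pi i h . x_j)` over all
#' atoms, including symmetry mates when the structure is an asymmetric unit in
#' a non-P1 group.  The Debye-Waller factor is `exp(-B s^2)` with
#' `s = sin(theta)/lambda = 1/(2d)` for isotropic atoms and
#' `exp(-2 pi^2 S^T U S)` (Cartesian `S`, `|S| = 1/d`) when anisotropic U
#' tensors are present.
#'
#' @param structure an [xtal_structure()].
#' @param hkl a [reflection_set()] or n x 3 index matrix.
#' @param use_aniso use `u11..u23` columns if present (default TRUE).
#' @return a [reflection_set()] with complex `F`.
#' @export
calc_sf_direct <- function(structure, hkl, use_aniso = TRUE) {
  rs <- if (inherits(hkl, "reflection_set")) hkl
        else reflection_set(hkl, structure$cell, structure$sg)
  idx <- rs_hkl(rs)
  a <- structure$atoms
  miss <- setdiff(unique(a$element), names(.it92))
  if (length(miss)) stop("no form factor for element(s): ",
                         paste(miss, collapse = ","))
  u6 <- if (use_aniso && has_aniso(structure)) u_matrix_rows(a) else NULL
  Fv <- sf_direct_engine(coords_frac(structure), a$element, a$b, u6, a$occ,
                         idx, structure$cell, ops = structure$sg$ops)
  out <- reflection_set(idx, structure$cell, structure$sg, F = Fv)
  out$free <- rs$free
  out
}

#' Structure factors via a real-space density grid
#'
#' Atoms are splatted onto a real-space electron-density grid as sums of
#' Gaussians (form-factor terms and isotropic B combined analytically in real
#' space), the grid is Fourier transformed and sampled at the requested
#' indices.  Requires an orthorhombic cell, a P1 structure (expand first) and
#' strictly positive B (the zero-width constant form-factor term is broadened
#' only by B; see [shift_overall_b()]).
#'
#' Accuracy is limited by grid aliasing of the sharpest form-factor Gaussian
#' terms (nitrogen in particular): at 0.3 A spacing and B >= 8 A^2 the
#' agreement with [calc_sf_direct()] is better than 0.5% in amplitude at
#' 1.0 A resolution; spacings near the Nyquist limit can alias several
#' percent.  Larger overall B (the +15 A^2 offset of the pipeline) suppresses
#' the aliasing.
#'
#' @param structure P1 [xtal_structure()].
#' @param hkl a [reflection_set()] or index matrix.
#' @param grid_spacing target grid spacing in Angstrom (default 0.45).
#' @param d_min high-resolution limit the grid must support
#'   (`grid_spacing <= d_min / 2`).
#' @param trunc_tail per-atom truncation: Gaussian tails are cut where the
#'   remaining mass is below this fraction of f(0) (default 1e-6).
#' @return a [reflection_set()] with complex `F`.
#' @export
calc_sf_grid <- function(structure, hkl, grid_spacing = 0.45, d_min = 1.0,
                         trunc_tail = 1e-6) {
  if (grid_spacing > d_min / 2 + 1e-12)
    stop("grid too coarse for d_min: need grid_spacing <= d_min/2")
  cell <- structure$cell
  if (any(abs(c(cell$alpha, cell$beta, cell$gamma) - 90) > 1e-9))
    stop("grid route requires an orthorhombic cell")
  if (structure$sg$name != "P1")
    structure <- expand_to_p1(structure)
  a <- structure$atoms
  if (any(a$b <= 0))
    stop("grid route requires positive B for every atom (apply shift_overall_b)")
  n1 <- stats::nextn(ceiling(cell$a / grid_spacing), c(2, 3, 5))
  n2 <- stats::nextn(ceiling(cell$b / grid_spacing), c(2, 3, 5))
  n3 <- stats::nextn(ceiling(cell$c / grid_spacing), c(2, 3, 5))
  rho <- array(0, c(n1, n2, n3))
  step <- c(cell$a / n1, cell$b / n2, cell$c / n3)
  xyz <- wrap_frac(coords_frac(structure))
  lncut <- -log(trunc_tail)
  for (j in seq_len(nrow(a))) {
    ff <- .it92[[a$element[j]]]
    av <- c(ff$a, ff$c)
    bv <- c(ff$b, 0) + a$b[j]
    beta <- bv / 4
    alpha <- pi^2 / beta
    # truncation radius from the widest Gaussian term
    rc <- sqrt(lncut / min(alpha))
    ctr <- xyz[j, ] * c(n1, n2, n3)
    lo <- floor(ctr - rc / step)
    hi <- ceiling(ctr + rc / step)
    i1 <- lo[1]:hi[1]; i2 <- lo[2]:hi[2]; i3 <- lo[3]:hi[3]
    dx <- (i1 - ctr[1]) * step[1]
    dy <- (i2 - ctr[2]) * step[2]
    dz <- (i3 - ctr[3]) * step[3]
    r2 <- outer(outer(dx^2, dy^2, "+"), dz^2, "+")
    dens <- array(0, dim(r2))
    for (g in seq_along(av))
      dens <- dens + (a$occ[j] * av[g] * (alpha[g] / pi)^1.5) *
        exp(-alpha[g] * r2)
    w1 <- i1 %% n1 + 1; w2 <- i2 %% n2 + 1; w3 <- i3 %% n3 + 1
    rho[w1, w2, w3] <- rho[w1, w2, w3] + dens
  }
  Fgrid <- stats::fft(rho, inverse = TRUE) * (cell$volume / (n1 * n2 * n3))
  rs <- if (inherits(hkl, "reflection_set")) hkl
        else reflection_set(hkl, cell, structure$sg)
  idx <- rs_hkl(rs)
  i1 <- idx[, 1] %% n1 + 1; i2 <- idx[, 2] %% n2 + 1; i3 <- idx[, 3] %% n3 + 1
  Fv <- Fgrid[cbind(i1, i2, i3)]
  out <- reflection_set(idx, cell, rs_sg(rs) %||% structure$sg, F = Fv)
  out$free <- rs$free
  out
}

#' Apply or remove an overall B offset
#'
#' In reflection space, amplitudes are scaled by `exp(-dB s^2)`; in structure
#' space, `dB` is added to every atom's isotropic B (the result must stay
#' non-negative).  A `+dB` followed by `-dB` is an exact inverse pair.
#'
#' @param x a [reflection_set()] with `F`, or an [xtal_structure()].
#' @param dB B-factor shift in A^2.
#' @return same type as `x`.
#' @export
shift_overall_b <- function(x, dB) {
  if (inherits(x, "reflection_set")) {
    s2 <- inv_d2(rs_cell(x), rs_hkl(x)) / 4
    x$F <- x$F * exp(-dB * s2)
    x
  } else if (inherits(x, "xtal_structure")) {
    nb <- x$atoms$b + dB
    if (any(nb < 0)) stop("shift would make B negative")
    x$atoms$b <- nb
    if (has_aniso(x)) {
      for (u in c("u11", "u22", "u33"))
        x$atoms[[u]] <- x$atoms[[u]] + dB / (8 * pi^2)
    }
    x
  } else stop("unsupported type")
}

#' Vector (complex) average of structure-factor sets
#'
#' `<F> = (1/N) sum_k F_k` per reflection; all inputs must carry identical
#' index lists.  The number of averaged sets is recorded in attribute
#' `n_averaged`.
#'
#' @param sets list of [reflection_set()]s with complex `F`.
#' @return a [reflection_set()] with the averaged `F`.
#' @export
average_sf <- function(sets) {
  stopifnot(length(sets) >= 1)
  ref <- rs_hkl(sets[[1]])
  acc <- sets[[1]]$F
  for (k in seq_along(sets)[-1]) {
    if (!identical(dim(rs_hkl(sets[[k]])), dim(ref)) ||
        any(rs_hkl(sets[[k]]) != ref))
      stop("reflection index lists differ between sets")
    acc <- acc + sets[[k]]$F
  }
  out <- sets[[1]]
  out$F <- acc / length(sets)
  attr(out, "n_averaged") <- length(sets)
  out
}

# Canonical asymmetric-unit representative of indices under the target group's
# Laue symmetry (+ Friedel): the lexicographically largest orbit member.  For
# the orthorhombic Laue class this is the unique all-non-negative
# representative; for P1 it is the hemisphere with the first non-zero index
# positive (matching generate_hkl).  Returns the representative indices, the
# phase bookkeeping (h.t in cycles) and a Friedel-conjugation flag per input.
asu_map <- function(hkl, sg) {
  n <- nrow(hkl)
  best <- matrix(-Inf, n, 3)
  shift <- rep(0, n)       # member index . op translation, in cycles
  needs_conj <- rep(FALSE, n)
  opid <- rep(NA_integer_, n)
  for (oi in seq_along(sg$ops)) {
    op <- sg$ops[[oi]]
    for (fr in c(FALSE, TRUE)) {
      cand <- hkl %*% op$R
      if (fr) cand <- -cand
      lex_better <- cand[, 1] > best[, 1] |
        (cand[, 1] == best[, 1] & cand[, 2] > best[, 2]) |
        (cand[, 1] == best[, 1] & cand[, 2] == best[, 2] &
           cand[, 3] > best[, 3])
      if (any(lex_better)) {
        best[lex_better, ] <- cand[lex_better, , drop = FALSE]
        shift[lex_better] <- (hkl[lex_better, , drop = FALSE] %*% op$t)
        needs_conj[lex_better] <- fr
        opid[lex_better] <- oi
      }
    }
  }
  list(hkl = best, t_dot = shift, conj = needs_conj, op = opid)
}

#' Reduce P1 supercell reflections to the unit cell and target group
#'
#' Keeps supercell reflections whose indices are all divisible by the
#' supercell factors (the Bragg positions of the underlying unit cell),
#' re-indexes them to unit-cell indices, divides F by the number of cells so
#' amplitudes are on the single-cell scale, merges symmetry-equivalent
#' reflections of the target group (amplitude averaging, with a
#' phase-consistency statistic after aligning phase shifts), removes
#' systematic absences and returns the target asymmetric unit.
#'
#' @param rs P1 supercell [reflection_set()] with complex `F`.
#' @param factors supercell factors `c(nx, ny, nz)`.
#' @param target_sg target [space_group()] (or name).
#' @param base_cell unit cell of the reduced data (default: supercell cell
#'   divided by `factors`).
#' @param phase_tol merge warning threshold on the circular spread of aligned
#'   phases (radians) for reflections with significant amplitude.
#' @return merged [reflection_set()] in the target group; attribute
#'   `merge_stats` records the worst phase spread.
#' @export
reduce_supercell <- function(rs, factors, target_sg, base_cell = NULL,
                             phase_tol = 0.5) {
  if (is.character(target_sg)) target_sg <- space_group(target_sg)
  factors <- as.integer(factors)
  cellS <- rs_cell(rs)
  if (is.null(base_cell))
    base_cell <- unit_cell(cellS$a / factors[1], cellS$b / factors[2],
                           cellS$c / factors[3],
                           cellS$alpha, cellS$beta, cellS$gamma)
  hklS <- rs_hkl(rs)
  on_lattice <- hklS[, 1] %% factors[1] == 0 &
    hklS[, 2] %% factors[2] == 0 & hklS[, 3] %% factors[3] == 0
  hkl <- sweep(hklS[on_lattice, , drop = FALSE], 2, factors, "/")
  Fv <- rs$F[on_lattice] / prod(factors)
  keep <- !is_absent(target_sg, hkl)
  hkl <- hkl[keep, , drop = FALSE]
  Fv <- Fv[keep]
  am <- asu_map(hkl, target_sg)
  # align each member's F onto the representative's phase convention:
  # F(rep) = F(member after inverse op) * exp(+2 pi i rep . t); with Friedel
  # conjugation applied first.  Derived from F(R^T h) = F(h) exp(-2 pi i h.t).
  Fal <- Fv
  Fal[am$conj] <- Conj(Fal[am$conj])
  Fal <- Fal * exp(2i * pi * am$t_dot * ifelse(am$conj, 1, -1))
  key <- paste(am$hkl[, 1], am$hkl[, 2], am$hkl[, 3])
  grp <- factor(key, levels = unique(key))
  amp <- tapply(Mod(Fal), grp, mean)
  vec <- tapply(Fal, grp, function(z) mean(z))
  unitv <- tapply(Fal / pmax(Mod(Fal), 1e-300), grp, mean)
  spread <- sqrt(pmax(0, -2 * log(pmin(Mod(unitv), 1))))  # circular s.d.
  reps <- am$hkl[!duplicated(key), , drop = FALSE]
  Fmerged <- amp * vec / pmax(Mod(vec), 1e-300)
  out <- reflection_set(reps, base_cell, target_sg, F = as.complex(Fmerged))
  out$mult <- as.integer(table(grp))
  sig <- amp > 0.02 * max(amp)
  worst <- if (any(sig)) max(spread[sig]) else 0
  if (worst > phase_tol)
    warning(sprintf("phase inconsistency among merged equivalents: %.3f rad",
                    worst))
  attr(out, "merge_stats") <- list(max_phase_spread = worst)
  out
}

#' Truncate a reflection set to lower resolution
#'
#' Keeps reflections with `d >= d_min`, preserving the cell/space-group
#' attributes and all columns.
#'
#' @param rs a [reflection_set()].
#' @param d_min new high-resolution limit (Angstrom).
#' @return truncated [reflection_set()].
#' @export
truncate_resolution <- function(rs, d_min) {
  keep <- rs$d >= d_min * (1 - 1e-9)
  out <- rs[keep, , drop = FALSE]
  attr(out, "cell") <- rs_cell(rs)
  attr(out, "sg") <- rs_sg(rs)
  class(out) <- class(rs)
  out
}

#' Write / read reflections as plain-text HKL
#'
#' Whitespace-separated columns `H K L F PHI FREE` (amplitude in electrons,
#' phase in degrees, free flag 0/1) with `#` header lines carrying the cell
#' and space group.
#'
#' @param rs a [reflection_set()] with `F`.
#' @param path file path.
#' @export
write_hkl <- function(rs, path) {
  cell <- rs_cell(rs)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# CELL %.6g %.6g %.6g %.6g %.6g %.6g",
                       cell$a, cell$b, cell$c, cell$alpha, cell$beta,
                       cell$gamma),
               sprintf("# SPACEGROUP %s", rs_sg(rs)$name),
               "# H K L F PHI FREE"), con)
  phi <- if (is.complex(rs$F)) Arg(rs$F) * 180 / pi else 0
  amp <- Mod(rs$F)
  writeLines(sprintf("%d %d %d %.8g %.6f %d", rs$h, rs$k, rs$l, amp, phi,
                     as.integer(rs$free)), con)
  invisible(path)
}

#' @rdname write_hkl
#' @export
read_hkl <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  cellv <- as.numeric(strsplit(trimws(sub("# CELL", "", hdr[grepl("CELL", hdr)])),
                               "\\s+")[[1]])
  sgname <- trimws(sub("# SPACEGROUP", "", hdr[grepl("SPACEGROUP", hdr)]))
  dat <- utils::read.table(text = lines[!grepl("^#", lines)])
  names(dat) <- c("h", "k", "l", "amp", "phi", "free")
  cell <- unit_cell(cellv[1], cellv[2], cellv[3], cellv[4], cellv[5], cellv[6])
  rs <- reflection_set(as.matrix(dat[, 1:3]), cell, space_group(sgname),
                       F = complex(modulus = dat$amp,
                                   argument = dat$phi * pi / 180))
  rs$free <- dat$free == 1
  rs
}
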