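#' Crystal structure container
#'
#' A single conformer: a unit cell, a space group and an ordered atom table.
#' Coordinates are fractional throughout the package; Cartesian values appear
#' only at I/O boundaries and inside displacement sampling.
#'
#' The atom table has columns `eleno` (serial), `resno`, `resid` (residue
#' name), `elety` (atom name), `element`, `x`, `y`, `z` (fractional), `occ`,
#' `b` (isotropic B, A^2), optionally `u11,u22,u33,u12,u13,u23` (Cartesian
#' anisotropic U, A^2) and a logical `mobile` flag.
#'
#' @param cell a [unit_cell()].
#' @param sg a [space_group()] (or name accepted by it).
#' @param atoms atom data frame as described above.
#' @param z number of chains per unit cell represented by `atoms` when the
#'   structure holds full cell contents; for a single asymmetric-unit chain
#'   use `z = sg$n_ops`.
#' @return object of class `xtal_structure`.
#' @export
xtal_structure <- function(cell, sg, atoms, z = NULL) {
  if (is.character(sg)) sg <- space_group(sg)
  stopifnot(inherits(cell, "unit_cell"), inherits(sg, "space_group"),
            is.data.frame(atoms))
  need <- c("resno", "resid", "elety", "element", "x", "y", "z", "occ", "b")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table lacks columns: ", paste(miss, collapse = ", "))
  if (any(atoms$b < 0)) stop("negative isotropic B")
  if (is.null(atoms$eleno)) atoms$eleno <- seq_len(nrow(atoms))
  if (is.null(atoms$mobile)) atoms$mobile <- TRUE
  if (is.null(z)) z <- sg$n_ops
  structure(list(cell = cell, sg = sg, atoms = atoms, z = z),
            class = "xtal_structure")
}

#' @export
print.xtal_structure <- function(x, ...) {
  cat(sprintf("xtal_structure: %d atoms, %s, Z = %d\n",
              nrow(x$atoms), x$sg$name, x$z))
  print(x$cell)
  invisible(x)
}

n_atoms <- function(s) nrow(s$atoms)

coords_frac <- function(s) {
  m <- as.matrix(s$atoms[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
}

set_coords_frac <- function(s, xyz) {
  s$atoms[, c("x", "y", "z")] <- xyz
  s
}

has_aniso <- function(s) all(c("u11", "u22", "u33", "u12", "u13", "u23") %in%
                               names(s$atoms)) && !anyNA(s$atoms$u11)

u_matrix_rows <- function(atoms) {
  as.matrix(atoms[, c("u11", "u22", "u33", "u12", "u13", "u23")])
}

#' Apply a symmetry operator to a structure
#'
#' Transforms all fractional coordinates by operator `op_index` of the
#' structure's space group and wraps them into `[0, 1)`.  Anisotropic U
#' tensors, stored in the Cartesian frame, are rotated as `R U R^T` (for the
#' orthorhombic groups supported here the Cartesian and fractional rotations
#' coincide up to the orthogonalization, which is handled explicitly).
#'
#' @param structure an [xtal_structure()].
#' @param op_index operator index in `structure$sg$ops`.
#' @param wrap wrap the transformed coordinates into `[0,1)` (default TRUE).
#' @return transformed copy with identical atom ordering.
#' @export
apply_symmetry <- function(structure, op_index, wrap = TRUE) {
  if (op_index < 1 || op_index > structure$sg$n_ops)
    stop("invalid symmetry operator index: ", op_index)
  op <- structure$sg$ops[[op_index]]
  xyz <- coords_frac(structure)
  new <- xyz %*% t(op$R) + matrix(op$t, nrow(xyz), 3, byrow = TRUE)
  if (wrap) new <- wrap_frac(new)
  out <- set_coords_frac(structure, new)
  if (has_aniso(structure)) {
    Rc <- cart_rotation(structure$cell, op$R)
    out$atoms[, c("u11", "u22", "u33", "u12", "u13", "u23")] <-
      rotate_u_rows(u_matrix_rows(structure$atoms), Rc)
  }
  out
}

# Cartesian rotation corresponding to a fractional-space rotation
cart_rotation <- function(cell, R) cell$orth %*% R %*% cell$frac

rotate_u_rows <- function(u6, Rc) {
  out <- u6
  for (i in seq_len(nrow(u6))) {
    U <- u6_to_mat(u6[i, ])
    U2 <- Rc %*% U %*% t(Rc)
    out[i, ] <- mat_to_u6(U2)
  }
  out
}

u6_to_mat <- function(u) matrix(c(u[1], u[4], u[5],
                                  u[4], u[2], u[6],
                                  u[5], u[6], u[3]), 3, 3)

mat_to_u6 <- function(U) c(U[1, 1], U[2, 2], U[3, 3], U[1, 2], U[1, 3], U[2, 3])

#' Expand an asymmetric unit to the full P1 cell
#'
#' Applies every operator of the space group to the given single-chain
#' structure and concatenates the copies (operator-index order), returning a
#' P1 structure with `Z = n_ops` chains.  The per-chain generating operator is
#' recorded in the `copy_op` attribute column so mapping back never has to be
#' inferred.
#'
#' @param structure asymmetric-unit [xtal_structure()].
#' @return P1 [xtal_structure()] with all symmetry copies.
#' @export
expand_to_p1 <- function(structure) {
  copies <- lapply(seq_len(structure$sg$n_ops),
                   function(i) apply_symmetry(structure, i)$atoms)
  for (i in seq_along(copies)) {
    copies[[i]]$copy_op <- i
    copies[[i]]$copy_cell <- 1L
  }
  atoms <- do.call(rbind, copies)
  atoms$eleno <- seq_len(nrow(atoms))
  out <- xtal_structure(structure$cell, space_group("P1"), atoms,
                        z = structure$sg$n_ops)
  attr(out, "base_sg") <- structure$sg
  out
}

#' Build a P1 supercell
#'
#' Replicates the structure's cell contents at all lattice translations of an
#' `nx x ny x nz` block.  If the input is not P1 it is first expanded with
#' [expand_to_p1()].  Copies are ordered cell-index major (x fastest), operator
#' index minor, so monomer-to-operator assignment is fixed by construction.
#'
#' @param structure an [xtal_structure()].
#' @param factors integer vector `c(nx, ny, nz)`, each >= 1.
#' @return P1 [xtal_structure()] with multiplied cell lengths and atom count.
#' @export
build_supercell <- function(structure, factors) {
  factors <- as.integer(factors)
  stopifnot(length(factors) == 3, all(factors >= 1))
  if (structure$sg$name != "P1") structure <- expand_to_p1(structure)
  atoms0 <- structure$atoms
  if (is.null(atoms0$copy_op)) { atoms0$copy_op <- 1L; atoms0$copy_cell <- 1L }
  xyz <- as.matrix(atoms0[, c("x", "y", "z")])
  cells <- expand.grid(ix = 0:(factors[1] - 1), iy = 0:(factors[2] - 1),
                       iz = 0:(factors[3] - 1))
  pieces <- vector("list", nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    sh <- as.numeric(cells[ci, ])
    at <- atoms0
    at[, c("x", "y", "z")] <- sweep(xyz, 2, sh, "+") %*%
      diag(1 / factors)
    at$copy_cell <- ci
    pieces[[ci]] <- at
  }
  atoms <- do.call(rbind, pieces)
  atoms$eleno <- seq_len(nrow(atoms))
  bigcell <- unit_cell(structure$cell$a * factors[1],
                       structure$cell$b * factors[2],
                       structure$cell$c * factors[3],
                       structure$cell$alpha, structure$cell$beta,
                       structure$cell$gamma)
  out <- xtal_structure(bigcell, space_group("P1"), atoms,
                        z = structure$z * prod(factors))
  attr(out, "factors") <- factors
  attr(out, "base_cell") <- structure$cell
  attr(out, "base_sg") <- attr(structure, "base_sg")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Map supercell monomers back to the reference frame
#'
#' Inverts, for every monomer, its generating lattice translation and symmetry
#' operator (recorded at construction time), returning the list of monomer
#' coordinate sets expressed in the reference (asymmetric-unit) frame.  No
#' least-squares fitting is performed at any point.
#'
#' @param crystal_snapshot P1 supercell [xtal_structure()] built by
#'   [build_supercell()] / [expand_to_p1()] from a reference chain.
#' @param sg space group used for the expansion (defaults to C2221 when the
#'   snapshot carries 8 copies per cell, P1 otherwise); needed to invert the
#'   operators.
#' @param as_matrix if TRUE return a 3-d array `atoms x 3 x monomers` of
#'   fractional reference-frame coordinates instead of a list of structures
#'   (fast path used internally).
#' @return list of per-monomer [xtal_structure()]s (or an array).
#' @export
map_to_reference <- function(crystal_snapshot, sg = NULL, as_matrix = FALSE) {
  atoms <- crystal_snapshot$atoms
  if (is.null(atoms$copy_op))
    stop("snapshot does not record its copy/operator assignment")
  factors <- attr(crystal_snapshot, "factors") %||% c(1L, 1L, 1L)
  base_cell <- attr(crystal_snapshot, "base_cell") %||% crystal_snapshot$cell
  if (is.null(sg)) {
    sg <- attr(crystal_snapshot, "base_sg")
    if (is.null(sg)) {
      nop <- max(atoms$copy_op)
      sg <- if (nop == 8) space_group("C2221") else space_group("P1")
    }
  }
  key <- paste(atoms$copy_cell, atoms$copy_op)
  idx <- split(seq_len(nrow(atoms)), factor(key, levels = unique(key)))
  n_per <- lengths(idx)
  if (length(unique(n_per)) != 1)
    stop("atom count not divisible into equal monomers")
  cells <- expand.grid(ix = 0:(factors[1] - 1), iy = 0:(factors[2] - 1),
                       iz = 0:(factors[3] - 1))
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  mono <- vector("list", length(idx))
  for (m in seq_along(idx)) {
    rows <- idx[[m]]
    ci <- atoms$copy_cell[rows[1]]
    oi <- atoms$copy_op[rows[1]]
    frac_super <- xyz[rows, , drop = FALSE]
    # undo supercell scaling + lattice shift
    frac_cell <- frac_super %*% diag(as.numeric(factors))
    frac_cell <- sweep(frac_cell, 2, as.numeric(cells[ci, ]), "-")
    op <- sg$ops[[oi]]
    # invert (R|t): x0 = R^-1 (x - t); R integer orthogonal -> inverse = t(R)
    Rinv <- solve(op$R)
    frac_ref <- sweep(frac_cell, 2, op$t, "-") %*% t(Rinv)
    # wrapping during expansion shifts coordinates by integer lattice vectors;
    # undo it (valid while reference-frame coordinates stay inside [0,1))
    mono[[m]] <- wrap_frac(frac_ref)
  }
  if (as_matrix) {
    arr <- array(unlist(mono), dim = c(n_per[1], 3, length(mono)))
    return(arr)
  }
  lapply(seq_along(mono), function(m) {
    at <- atoms[idx[[m]], , drop = FALSE]
    at[, c("x", "y", "z")] <- mono[[m]]
    at$eleno <- seq_len(nrow(at))
    xtal_structure(base_cell, sg, at, z = sg$n_ops)
  })
}

#' Matthews coefficient and solvent fraction
#'
#' `V_M = V / (Z * MW)`; the solvent fraction uses the standard convention of
#' 1.23 A^3 per Dalton of protein, clamped to `[0, 1]`.
#'
#' @param cell a [unit_cell()].
#' @param Z number of protein chains in the cell.
#' @param MW chain molecular weight in Dalton.
#' @return list with `v_m` (A^3/Da) and `solvent_fraction`.
#' @examples
#' compute_matthews(unit_cell(10, 10, 100), Z = 1, MW = 5000)
#' @export
compute_matthews <- function(cell, Z, MW) {
  stopifnot(Z >= 1)
  if (MW <= 0) stop("molecular weight must be positive")
  v_m <- cell$volume / (Z * MW)
  solv <- 1 - 1.23 / v_m
  list(v_m = v_m, solvent_fraction = min(max(solv, 0), 1))
}

# average atomic masses (Da)
.element_mass <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06)

# residue formulas (residue = amino acid - H2O), counts of C,H,N,O,S
.residue_formula <- list(
  G = c(2, 3, 1, 1, 0),  A = c(3, 5, 1, 1, 0),  S = c(3, 5, 1, 2, 0),
  P = c(5, 7, 1, 1, 0),  V = c(5, 9, 1, 1, 0),  T = c(4, 7, 1, 2, 0),
  C = c(3, 5, 1, 1, 1),  L = c(6, 11, 1, 1, 0), I = c(6, 11, 1, 1, 0),
  N = c(4, 6, 2, 2, 0),  D = c(4, 5, 1, 3, 0),  Q = c(5, 8, 2, 2, 0),
  K = c(6, 12, 2, 1, 0), E = c(5, 7, 1, 3, 0),  M = c(5, 9, 1, 1, 1),
  H = c(6, 7, 3, 1, 0),  F = c(9, 9, 1, 1, 0),  R = c(6, 12, 4, 1, 0),
  Y = c(9, 9, 1, 2, 0),  W = c(11, 10, 2, 1, 0),
  X = c(6, 11, 1, 1, 0)  # norleucine: linear C4 side chain, isomer of Leu
)

#' Peptide molecular weight from sequence
#'
#' Average-mass molecular weight computed from per-residue atomic composition
#' (C, H, N, O, S counts) plus one water for the termini.  One-letter codes;
#' `X` denotes norleucine.
#'
#' @param sequence character scalar of one-letter residue codes, or a vector
#'   of single letters.
#' @return molecular weight in Dalton.
#' @examples
#' peptide_mw("GG")  # diglycine, 132.12
#' @export
peptide_mw <- function(sequence) {
  if (length(sequence) == 1) sequence <- strsplit(sequence, "")[[1]]
  sequence <- toupper(sequence)
  bad <- setdiff(sequence, names(.residue_formula))
  if (length(bad)) stop("unknown residue code(s): ", paste(bad, collapse = ","))
  counts <- Reduce(`+`, .residue_formula[sequence])
  counts[2] <- counts[2] + 2  # terminal H2O
  counts[4] <- counts[4] + 1
  sum(counts * .element_mass[c("C", "H", "N", "O", "S")])
}

#' Read a one-letter protein sequence from FASTA
#'
#' @param path FASTA file; only the first record is read.
#' @return character scalar sequence.
#' @export
read_fasta_seq <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^[;>]", lines)]
  paste(gsub("\\s", "", lines), collapse = "")
}
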