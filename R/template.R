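#' Build a template chain
#'
#' Constructs the single-chain reference structure the ensemble generator
#' perturbs.  Two kinds are supported:
#'
#' * `"toy_helix_bundle"`: an idealized alpha-helical chain (2.3 A radius,
#'   1.5 A rise, 100 degrees per residue) of `n_res` residues placed in the
#'   asymmetric unit.  Each residue carries backbone N, CA, C, O and a short
#'   side chain CB-CG-CD so that chi1/chi2 dihedrals are defined.  When
#'   `n_atoms` exceeds `7 * n_res`, extra carbon pseudo-atoms are appended to
#'   the side chains cyclically, which lets the template match a stated total
#'   composition (e.g. a united-atom chain of 373 atoms).
#' * `"from_pdb"`: reads the first model of a PDB file.
#'
#' A restrained/mobile split is declared on the chain: the N-terminal segment
#' covering `1 - mobile_fraction` of the atoms (by residue blocks) is flagged
#' restrained, the C-terminal remainder mobile.
#'
#' @param kind `"toy_helix_bundle"` or `"from_pdb"`.
#' @param n_res residue count for the toy chain.
#' @param cell [unit_cell()] the chain lives in (default: the C222(1) cell
#'   19.677 x 39.90 x 75.09 A used throughout the examples).
#' @param sg space group name or object (default `"C2221"`).
#' @param mobile_fraction fraction of atoms free to move (default 0.4).
#' @param n_atoms optional total atom count for the toy chain (>= `7 * n_res`).
#' @param pdb path to a PDB file for `kind = "from_pdb"`.
#' @param b_init initial isotropic B assigned to every atom (A^2).
#' @return an [xtal_structure()] with a logical `mobile` column.
#' @examples
#' tpl <- build_template(n_res = 5)
#' table(tpl$atoms$mobile)
#' @export
build_template <- function(kind = c("toy_helix_bundle", "from_pdb"),
                           n_res = 35, cell = NULL, sg = "C2221",
                           mobile_fraction = 0.4, n_atoms = NULL,
                           pdb = NULL, b_init = 15) {
  kind <- match.arg(kind)
  if (is.null(cell)) cell <- unit_cell(19.677, 39.90, 75.09)
  if (is.character(sg)) sg <- space_group(sg)
  if (kind == "from_pdb") {
    if (is.null(pdb) || !file.exists(pdb)) stop("unreadable PDB file")
    s <- read_pdb(pdb)
    s$cell <- cell; s$sg <- sg
    s$atoms$mobile <- mobile_split(s$atoms$resno, mobile_fraction)
    s$atoms$b <- b_init
    attr(s, "build_args") <- list(kind = kind, n_res = NULL,
                                  cell = c(cell$a, cell$b, cell$c),
                                  sg = sg$name,
                                  mobile_fraction = mobile_fraction,
                                  n_atoms = NULL, pdb = pdb, b_init = b_init)
    return(s)
  }
  stopifnot(n_res >= 1)
  per_res <- 7L
  if (!is.null(n_atoms) && n_atoms < per_res * n_res)
    stop("n_atoms smaller than the base composition of ", per_res * n_res)

  rise <- 1.5; radius <- 2.3; turn <- 100 * pi / 180
  helix_pt <- function(t) {
    th <- t * turn
    c(radius * cos(th), radius * sin(th), t * rise)
  }
  atoms <- list()
  for (r in seq_len(n_res)) {
    ca <- helix_pt(r)
    nn <- helix_pt(r - 0.36)
    cc <- helix_pt(r + 0.36)
    th <- r * turn
    radial <- c(cos(th), sin(th), 0)
    perp <- c(-sin(th), cos(th), 0)
    oo <- cc + 1.23 * (0.8 * radial + 0.6 * c(0, 0, 1))
    cb <- ca + 1.53 * (0.94 * radial + 0.34 * c(0, 0, 1))
    cg <- cb + 1.53 * (0.55 * radial + 0.63 * perp + 0.55 * c(0, 0, 1))
    cd <- cg + 1.53 * (0.60 * radial - 0.64 * perp + 0.48 * c(0, 0, 1))
    xyz <- rbind(nn, ca, cc, oo, cb, cg, cd)
    atoms[[r]] <- data.frame(
      resno = r, resid = "TOY",
      elety = c("N", "CA", "C", "O", "CB", "CG", "CD"),
      element = c("N", "C", "C", "O", "C", "C", "C"),
      cx = xyz[, 1], cy = xyz[, 2], cz = xyz[, 3],
      stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, atoms)
  if (!is.null(n_atoms) && n_atoms > nrow(atoms)) {
    extra <- n_atoms - nrow(atoms)
    res_cycle <- rep(seq_len(n_res), length.out = extra)
    host <- atoms[atoms$elety == "CD", ][res_cycle, ]
    ang <- seq_len(extra)
    pad <- data.frame(
      resno = host$resno, resid = "TOY",
      elety = sprintf("E%02d", ave(ang, res_cycle, FUN = seq_along)),
      element = "C",
      cx = host$cx + 1.1 * cos(ang), cy = host$cy + 1.1 * sin(ang),
      cz = host$cz + 0.9 * cos(ang / 2),
      stringsAsFactors = FALSE)
    atoms <- rbind(atoms, pad)
    atoms <- atoms[order(atoms$resno), ]
  }
  # centre the chain inside the asymmetric unit (around x/4, y/4, z centred),
  # then nudge it so every fractional coordinate stays inside [0, 1)
  cart <- as.matrix(atoms[, c("cx", "cy", "cz")])
  rownames(cart) <- NULL
  target <- c(cell$a * 0.25, cell$b * 0.25, cell$c * 0.5)
  cart <- sweep(cart, 2, target - colMeans(cart), "+")
  frac <- cart_to_frac(cell, cart)
  for (j in 1:3) {
    lo <- min(frac[, j]); hi <- max(frac[, j])
    if (hi - lo > 0.9)
      stop("chain does not fit inside the unit cell along axis ", j)
    if (lo < 0.02) frac[, j] <- frac[, j] + (0.02 - lo)
    else if (hi > 0.98) frac[, j] <- frac[, j] - (hi - 0.98)
  }
  out <- data.frame(
    eleno = seq_len(nrow(atoms)),
    resno = atoms$resno, resid = atoms$resid, elety = atoms$elety,
    element = atoms$element,
    x = frac[, 1], y = frac[, 2], z = frac[, 3],
    occ = 1, b = b_init,
    mobile = mobile_split(atoms$resno, mobile_fraction),
    stringsAsFactors = FALSE)
  s <- xtal_structure(cell, sg, out)
  attr(s, "build_args") <- list(kind = kind, n_res = n_res,
                                cell = c(cell$a, cell$b, cell$c),
                                sg = sg$name,
                                mobile_fraction = mobile_fraction,
                                n_atoms = n_atoms, pdb = NULL, b_init = b_init)
  s
}

# N-terminal residues restrained until the restrained atom fraction reaches
# (1 - mobile_fraction); returns logical mobile flag per atom
mobile_split <- function(resno, mobile_fraction) {
  stopifnot(mobile_fraction >= 0, mobile_fraction <= 1)
  n <- length(resno)
  if (mobile_fraction == 0) return(rep(FALSE, n))
  if (mobile_fraction == 1) return(rep(TRUE, n))
  counts <- cumsum(table(factor(resno, levels = unique(resno))))
  cut_res <- which(counts >= (1 - mobile_fraction) * n)[1]
  resno > unique(resno)[cut_res]
}

# chi dihedral atom-name tables: chi1 = N-CA-CB-CG-type, chi2 follows on.
# Standard side-chain definitions; NLE (norleucine) is the linear chain, TOY
# is the package's synthetic residue.
.chi_atoms <- list(
  TOY = list(chi1 = c("N", "CA", "CB", "CG"), chi2 = c("CA", "CB", "CG", "CD")),
  ARG = list(chi1 = c("N", "CA", "CB", "CG"), chi2 = c("CA", "CB", "CG", "CD")),
  ASN = list(chi1 = c("N", "CA", "CB", "CG"), chi2 = c("CA", "CB", "CG", "OD1")),
  ASP = list(chi1 = c("N", "CA", "CB", "CG"), chi2 = c("CA", "CB", "CG", "OD1")),
  CYS = list(chi1 = c("N", "CA", "CB", "SG"), chi2 = NULL),
  GLN = list(chi1 = c("N", "CA", "CB", "CG"), chi2 = c("CA", "CB", "CG", "CD")),
  GLU = list(chi1 = c("N", "CA", "CB", "CG"), chi2 = c("CA", "CB", "CG", "CD")),
  HIS = list(chi1 = c("N", "CA", "CB", "CG"), chi2 = c("CA", "CB", "CG", "ND1")),
  ILE = list(chi1 = c("N", "CA", "CB", "CG1"), chi2 = c("CA", "CB", "CG1", "CD1")),
  LEU = list(chi1 = c("N", "CA", "CB", "CG"), chi2 = c("CA", "CB", "CG", "CD1")),
  LYS = list(chi1 = c("N", "CA", "CB", "CG"), chi2 = c("CA", "CB", "CG", "CD")),
  MET = list(chi1 = c("N", "CA", "CB", "CG"), chi2 = c("CA", "CB", "CG", "SD")),
  NLE = list(chi1 = c("N", "CA", "CB", "CG"), chi2 = c("CA", "CB", "CG", "CD")),
  PHE = list(chi1 = c("N", "CA", "CB", "CG"), chi2 = c("CA", "CB", "CG", "CD1")),
  PRO = list(chi1 = c("N", "CA", "CB", "CG"), chi2 = c("CA", "CB", "CG", "CD")),
  SER = list(chi1 = c("N", "CA", "CB", "OG"), chi2 = NULL),
  THR = list(chi1 = c("N", "CA", "CB", "OG1"), chi2 = NULL),
  TRP = list(chi1 = c("N", "CA", "CB", "CG"), chi2 = c("CA", "CB", "CG", "CD1")),
  TYR = list(chi1 = c("N", "CA", "CB", "CG"), chi2 = c("CA", "CB", "CG", "CD1")),
  VAL = list(chi1 = c("N", "CA", "CB", "CG1"), chi2 = NULL)
)
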