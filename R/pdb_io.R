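#' Read a PDB file
#'
#' Minimal fixed-width reader for ATOM/HETATM, ANISOU, CRYST1 and MODEL
#' records.  ANISOU values follow the PDB convention (U * 1e4, crystallographic
#' frame; for orthorhombic cells this equals the Cartesian tensor).  Returns an
#' [xtal_structure()] (or a list of them for multi-model files) with
#' coordinates converted to fractional.
#'
#' @param path PDB file path.
#' @param multi return a list of structures for multi-MODEL files.
#' @return [xtal_structure()] or list thereof.
#' @export
read_pdb <- function(path, multi = FALSE) {
  lines <- readLines(path)
  cr <- grep("^CRYST1", lines, value = TRUE)
  if (length(cr)) {
    cell <- unit_cell(as.numeric(substr(cr[1], 7, 15)),
                      as.numeric(substr(cr[1], 16, 24)),
                      as.numeric(substr(cr[1], 25, 33)),
                      as.numeric(substr(cr[1], 34, 40)),
                      as.numeric(substr(cr[1], 41, 47)),
                      as.numeric(substr(cr[1], 48, 54)))
    sgname <- trimws(substr(cr[1], 56, 66))
    sg <- tryCatch(space_group(sgname), error = function(e) space_group("P1"))
  } else {
    cell <- unit_cell(100, 100, 100)
    sg <- space_group("P1")
  }
  model_breaks <- grep("^ENDMDL", lines)
  if (!multi || length(model_breaks) == 0) {
    s <- parse_pdb_atoms(lines, cell, sg)
    return(s)
  }
  starts <- c(1, model_breaks + 1)
  out <- list()
  for (i in seq_along(model_breaks)) {
    chunk <- lines[starts[i]:model_breaks[i]]
    out[[i]] <- parse_pdb_atoms(chunk, cell, sg)
  }
  out
}

parse_pdb_atoms <- function(lines, cell, sg) {
  at <- grep("^(ATOM  |HETATM)", lines, value = TRUE)
  if (!length(at)) stop("no ATOM/HETATM records found")
  num <- function(a, b, x) as.numeric(substr(x, a, b))
  chr <- function(a, b, x) trimws(substr(x, a, b))
  xyz_cart <- cbind(num(31, 38, at), num(39, 46, at), num(47, 54, at))
  element <- chr(77, 78, at)
  guess <- substr(gsub("^[0-9 ]*", "", chr(13, 16, at)), 1, 1)
  element <- ifelse(element == "", guess, element)
  atoms <- data.frame(
    eleno = num(7, 11, at),
    resno = num(23, 26, at),
    resid = chr(18, 20, at),
    elety = chr(13, 16, at),
    element = toupper(element),
    occ = num(55, 60, at),
    b = num(61, 66, at),
    stringsAsFactors = FALSE)
  frac <- cart_to_frac(cell, xyz_cart)
  atoms$x <- frac[, 1]; atoms$y <- frac[, 2]; atoms$z <- frac[, 3]
  an <- grep("^ANISOU", lines, value = TRUE)
  if (length(an)) {
    aser <- num(7, 11, an)
    u <- cbind(num(29, 35, an), num(36, 42, an), num(43, 49, an),
               num(50, 56, an), num(57, 63, an), num(64, 70, an)) / 1e4
    m <- match(atoms$eleno, aser)
    ucols <- c("u11", "u22", "u33", "u12", "u13", "u23")
    for (j in 1:6) atoms[[ucols[j]]] <- u[m, j]
  }
  xtal_structure(cell, sg, atoms)
}

#' Write a structure (or list of snapshots) as PDB
#'
#' Emits CRYST1, ATOM (and ANISOU when anisotropic U is present) records;
#' multiple structures are written as MODEL/ENDMDL blocks.
#'
#' @param structure an [xtal_structure()] or list of them.
#' @param path output file.
#' @export
write_pdb <- function(structure, path) {
  if (inherits(structure, "xtal_structure")) structure <- list(structure)
  s1 <- structure[[1]]
  sgfield <- if (s1$sg$name == "C2221") "C 2 2 21" else "P 1"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s%4d",
                     s1$cell$a, s1$cell$b, s1$cell$c,
                     s1$cell$alpha, s1$cell$beta, s1$cell$gamma,
                     sgfield, s1$z), con)
  multi <- length(structure) > 1
  for (mi in seq_along(structure)) {
    s <- structure[[mi]]
    if (multi) writeLines(sprintf("MODEL     %4d", mi), con)
    xyz <- frac_to_cart(s$cell, coords_frac(s))
    a <- s$atoms
    ser <- seq_len(nrow(a)) %% 100000
    lines <- sprintf("ATOM  %5d %-4s%-4s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                     ser, formatC(substr(a$elety, 1, 4), width = 4),
                     substr(a$resid, 1, 3), a$resno %% 10000,
                     xyz[, 1], xyz[, 2], xyz[, 3],
                     pmin(a$occ, 999), pmin(a$b, 999.99), substr(a$element, 1, 2))
    if (has_aniso(s)) {
      u <- round(u_matrix_rows(a) * 1e4)
      anis <- sprintf("ANISOU%5d %-4s%-4s A%4d  %7d%7d%7d%7d%7d%7d      %2s",
                      ser, formatC(substr(a$elety, 1, 4), width = 4),
                      substr(a$resid, 1, 3), a$resno %% 10000,
                      u[, 1], u[, 2], u[, 3], u[, 4], u[, 5], u[, 6],
                      substr(a$element, 1, 2))
      lines <- as.vector(rbind(lines, anis))
    }
    writeLines(lines, con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
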