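#' Space groups
#'
#' Minimal space-group support for the two groups the pipeline needs: `P1` and
#' `C2221` (C-centred orthorhombic with a 2(1) screw along c).  Operators are
#' stored explicitly as integer 3x3 rotations plus fractional translations,
#' taken from the standard crystallographic tables; the C centring is expanded
#' into the operator list so that `C2221` carries 8 operators.
#'
#' @param name `"P1"` or `"C2221"` (also accepts `"C 2 2 21"`).
#' @return an object of class `space_group` with fields `name`, `ops` (list of
#'   `list(R = 3x3 integer matrix, t = length-3 fractional translation)`),
#'   `n_ops`, and `centring`.
#' @examples
#' sg <- space_group("C2221")
#' sg$n_ops  # 8
#' @export
space_group <- function(name) {
  key <- toupper(gsub("[ _()]", "", name))
  if (key %in% c("P1")) {
    ops <- list(list(R = diag(3L), t = c(0, 0, 0)))
    cen <- list(c(0, 0, 0))
  } else if (key %in% c("C2221", "C2221:1")) {
    I3 <- diag(3L)
    rot2z <- diag(c(-1L, -1L, 1L))   # 2(1) screw along c: -x, -y, z+1/2
    rot2y <- diag(c(-1L, 1L, -1L))   # -x, y, -z+1/2
    rot2x <- diag(c(1L, -1L, -1L))   # x, -y, -z
    base <- list(
      list(R = I3,    t = c(0, 0, 0)),
      list(R = rot2z, t = c(0, 0, 0.5)),
      list(R = rot2y, t = c(0, 0, 0.5)),
      list(R = rot2x, t = c(0, 0, 0))
    )
    cen <- list(c(0, 0, 0), c(0.5, 0.5, 0))
    ops <- list()
    for (cv in cen) for (op in base)
      ops[[length(ops) + 1L]] <- list(R = op$R, t = (op$t + cv) %% 1)
  } else {
    stop("unsupported space group: ", name)
  }
  structure(list(name = if (key == "P1") "P1" else "C2221",
                 ops = ops, n_ops = length(ops), centring = cen),
            class = "space_group")
}

#' @export
print.space_group <- function(x, ...) {
  cat(sprintf("Space group %s (%d operators)\n", x$name, x$n_ops))
  invisible(x)
}

#' Systematic absences
#'
#' Predicate for reflections forced to zero by centring or screw axes.  For
#' `C2221` this rejects `h + k` odd (C centring) and `(0,0,l)` with `l` odd
#' (the 2(1) screw along c).
#'
#' @param sg a [space_group()].
#' @param hkl n x 3 integer matrix of Miller indices.
#' @return logical vector, `TRUE` where the reflection is systematically absent.
#' @export
is_absent <- function(sg, hkl) {
  hkl <- as_coord_matrix(hkl)
  if (sg$name == "P1") return(rep(FALSE, nrow(hkl)))
  cen <- (hkl[, 1] + hkl[, 2]) %% 2 != 0
  screw <- hkl[, 1] == 0 & hkl[, 2] == 0 & hkl[, 3] %% 2 != 0
  cen | screw
}

# Compose two operators (R1|t1) o (R2|t2) = (R1 R2 | R1 t2 + t1), translation mod 1
compose_ops <- function(op1, op2) {
  list(R = op1$R %*% op2$R, t = (as.vector(op1$R %*% op2$t) + op1$t) %% 1)
}

# Check that the stored operator list is closed under composition modulo
# lattice translations; returns TRUE or stops.
check_group_closure <- function(sg, tol = 1e-10) {
  same <- function(a, b) {
    all(a$R == b$R) && all(abs((a$t - b$t) %% 1 %% 1) < tol |
                           abs((a$t - b$t) %% 1 %% 1 - 1) < tol)
  }
  for (i in seq_len(sg$n_ops)) for (j in seq_len(sg$n_ops)) {
    comp <- compose_ops(sg$ops[[i]], sg$ops[[j]])
    if (!any(vapply(sg$ops, same, logical(1), a = comp)))
      stop("operator set not closed under composition")
  }
  TRUE
}

# Reciprocal-space action: index row-vector h maps to h' = t(R) %*% h under the
# operator; the structure-factor phase shift is exp(-2*pi*i h . t).
recip_op_indices <- function(op, hkl) {
  as_coord_matrix(hkl) %*% op$R
}
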