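# Atomic scattering factors, International Tables Vol. C 4-Gaussian
# parameterization: f(s) = sum_i a_i exp(-b_i s^2) + c, with s = sin(theta)/lambda
# in A^-1.  f(0) equals the electron count to within the tabulation error.
.it92 <- list(
  H = list(a = c(0.493002, 0.322912, 0.140191, 0.040810),
           b = c(10.5109, 26.1257, 3.14236, 57.7997), c = 0.003038),
  C = list(a = c(2.31000, 1.02000, 1.58860, 0.865000),
           b = c(20.8439, 10.2075, 0.568700, 51.6512), c = 0.215600),
  N = list(a = c(12.2126, 3.13220, 2.01250, 1.16630),
           b = c(0.005700, 9.89330, 28.9975, 0.582600), c = -11.5290),
  O = list(a = c(3.04850, 2.28680, 1.54630, 0.867000),
           b = c(13.2771, 5.70110, 0.323900, 32.9089), c = 0.250800),
  P = list(a = c(6.43450, 4.17910, 1.78000, 1.49080),
           b = c(1.90670, 27.1570, 0.526000, 68.1645), c = 1.11490),
  S = list(a = c(6.90530, 5.20340, 1.43790, 1.58630),
           b = c(1.46790, 22.2151, 0.253600, 56.1720), c = 0.866900)
)

.electron_count <- c(H = 1, C = 6, N = 7, O = 8, P = 15, S = 16)

#' Atomic form factor
#'
#' Evaluate the 4-Gaussian scattering factor of an element at given values of
#' `s = sin(theta)/lambda = 1/(2 d)`.
#'
#' @param element element symbol (H, C, N, O, P, S).
#' @param s2 numeric vector of `s^2` values (A^-2).
#' @return numeric vector `f(s)` in electrons.
#' @examples
#' form_factor("C", 0)  # ~6 electrons
#' @export
form_factor <- function(element, s2) {
  ff <- .it92[[toupper(element)]]
  if (is.null(ff)) stop("no form factor tabulated for element: ", element)
  out <- rep(ff$c, length(s2))
  for (i in 1:4) out <- out + ff$a[i] * exp(-ff$b[i] * s2)
  out
}

#' @rdname form_factor
#' @export
electron_count <- function(element) {
  z <- .electron_count[toupper(element)]
  if (anyNA(z)) stop("unknown element: ", paste(element[is.na(z)], collapse = ","))
  unname(z)
}

# matrix of form factors: rows = elements of `elements`, cols = s2 values
form_factor_matrix <- function(elements, s2) {
  uel <- unique(elements)
  fs <- matrix(0, length(uel), length(s2))
  for (i in seq_along(uel)) fs[i, ] <- form_factor(uel[i], s2)
  fs[match(elements, uel), , drop = FALSE]
}
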