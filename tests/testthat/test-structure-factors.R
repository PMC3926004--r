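test_that("form factors reproduce electron counts and decrease with angle", {
  for (el in c("H", "C", "N", "O", "S", "P"))
    expect_equal(form_factor(el, 0), electron_count(el), tolerance = 0.05)
  s2 <- seq(0, 0.36, length.out = 50)  # s in [0, 0.6]
  for (el in c("C", "N", "O"))
    expect_true(all(diff(form_factor(el, s2)) <= 0))
  expect_error(form_factor("ZZ", 0), "form factor")
})

test_that("unique reflection enumeration matches brute-force counting", {
  # cubic P1, infinity-5 A: 16 Friedel-unique reflections
  expect_equal(nrow(generate_hkl(unit_cell(10, 10, 10), "P1", d_min = 5)), 16)
  # C2221 centring rule
  sg <- space_group("C2221")
  expect_true(is_absent(sg, matrix(c(1, 2, 3), 1)))
  expect_false(is_absent(sg, matrix(c(2, 2, 3), 1)))
  expect_true(is_absent(sg, matrix(c(0, 0, 3), 1)))
  expect_false(is_absent(sg, matrix(c(0, 0, 4), 1)))
  # brute-force full-sphere oracle: count orbits under mmm + Friedel
  cell <- unit_cell(9, 11, 13)
  rs <- generate_hkl(cell, sg, d_min = 2.0)
  grid <- expand.grid(h = -5:5, k = -6:6, l = -7:7)
  grid <- grid[!(grid$h == 0 & grid$k == 0 & grid$l == 0), ]
  d <- d_spacing(cell, as.matrix(grid))
  grid <- grid[d >= 2.0 - 1e-9, ]
  grid <- grid[!is_absent(sg, as.matrix(grid)), ]
  canon <- apply(as.matrix(grid), 1, function(h)
    paste(abs(h), collapse = " "))
  expect_equal(nrow(rs), length(unique(canon)))
  # all representatives are in the mmm asymmetric unit and within range
  expect_true(all(rs$h >= 0 & rs$k >= 0 & rs$l >= 0))
  expect_true(all(rs$d >= 2.0 - 1e-9))
})

test_that("direct summation matches closed forms", {
  cl <- unit_cell(10, 12, 14)
  s <- make_structure(c(0, 0, 0), b = 0, cell = cl)
  rs <- generate_hkl(cl, "P1", d_min = 2)
  f <- calc_sf_direct(s, rs)
  expect_equal(Mod(f$F), form_factor("C", 1 / (4 * f$d^2)), tolerance = 1e-12)
  expect_equal(Arg(f$F), rep(0, nrow(f)), tolerance = 1e-12)
  # atom at (1/2,0,0): F(100) has phase pi
  s$atoms$x <- 0.5
  f1 <- calc_sf_direct(s, matrix(c(1, 0, 0), 1))
  expect_equal(Arg(f1$F), pi, tolerance = 1e-12)
  # pair at +-x: F(h00) = 2 f cos(2 pi h x)
  s2 <- make_structure(rbind(c(0.13, 0, 0), c(-0.13, 0, 0)), b = 0, cell = cl)
  f2 <- calc_sf_direct(s2, matrix(c(2, 0, 0), 1))
  expect_equal(Re(f2$F), 2 * form_factor("C", (2 / 10)^2 / 4) *
                 cos(2 * pi * 2 * 0.13), tolerance = 1e-12)
  expect_error(calc_sf_direct(make_structure(c(0, 0, 0), elements = "FE"),
                              matrix(1:3, 1)), "form factor")
})

test_that("Friedel mates are complex conjugates", {
  set.seed(1)
  s <- make_structure(matrix(runif(15), 5), elements = c("C", "N", "O", "C", "S"),
                      b = 8)
  hkl <- matrix(c(2, 3, 4, 1, -2, 5), 2, byrow = TRUE)
  fa <- calc_sf_direct(s, hkl)
  fb <- calc_sf_direct(s, -hkl)
  expect_equal(fa$F, Conj(fb$F), tolerance = 1e-12)
})

test_that("amplitudes are invariant under the reciprocal group action", {
  tpl <- build_template(n_res = 3, cell = unit_cell(15, 20, 25))
  p1 <- expand_to_p1(tpl)
  sg <- space_group("C2221")
  hkl <- matrix(c(2, 4, 3, 1, 3, 5, 0, 2, 6), 3, byrow = TRUE)
  base <- Mod(calc_sf_direct(p1, hkl)$F)
  for (i in 2:8) {
    hop <- hkl %*% sg$ops[[i]]$R
    expect_equal(Mod(calc_sf_direct(p1, hop)$F), base, tolerance = 1e-8)
  }
})

test_that("grid-based structure factors agree with the direct-sum oracle", {
  set.seed(7)
  cl <- unit_cell(15, 16, 17)
  n <- 10
  at <- data.frame(resno = 1:n, resid = "TOY", elety = "C",
                   element = sample(c("C", "N", "O", "S"), n, TRUE),
                   x = runif(n), y = runif(n), z = runif(n), occ = 1,
                   b = runif(n, 10, 30))
  s <- xtal_structure(cl, "P1", at)
  rs <- generate_hkl(cl, "P1", d_min = 1.0)
  fd <- calc_sf_direct(s, rs)
  # relative error floored at 1% of the RMS amplitude so accidental near-zero
  # reflections do not dominate the ratio
  floorv <- 0.01 * sqrt(mean(Mod(fd$F)^2))
  rel_err <- function(fg) max(abs(Mod(fg$F) - Mod(fd$F)) /
                                pmax(Mod(fd$F), floorv))
  fg <- calc_sf_grid(s, rs, grid_spacing = 0.3, d_min = 1.0)
  expect_lt(rel_err(fg), 0.005)
  # F(000) = electron count of the cell
  f000 <- calc_sf_grid(s, matrix(0, 1, 3), grid_spacing = 0.5, d_min = 1.0)
  expect_equal(Re(f000$F), cell_electrons(s), tolerance = 0.001 * cell_electrons(s))
  # halving the spacing reduces the worst-case deviation (0.5 -> 0.25: the
  # coarse grid aliases the sharpest form-factor terms)
  err_coarse <- rel_err(calc_sf_grid(s, rs, grid_spacing = 0.5, d_min = 1.0))
  err_fine <- rel_err(calc_sf_grid(s, rs, grid_spacing = 0.25, d_min = 1.0))
  expect_lt(err_fine, err_coarse)
  # preconditions
  expect_error(calc_sf_grid(s, rs, grid_spacing = 0.6, d_min = 1.0), "grid")
  s0 <- s; s0$atoms$b <- 0
  expect_error(calc_sf_grid(s0, rs, 0.4, 1.0), "positive B")
})

test_that("overall B shifts scale amplitudes as exp(-dB s^2) and invert", {
  cl <- unit_cell(10, 10, 10)
  s <- make_structure(c(0.2, 0.3, 0.4), b = 5, cell = cl)
  rs <- calc_sf_direct(s, generate_hkl(cl, "P1", d_min = 1.0))
  expect_equal(shift_overall_b(rs, 0)$F, rs$F)
  rt <- shift_overall_b(shift_overall_b(rs, 15), -15)
  expect_equal(rt$F, rs$F, tolerance = 1e-10)
  # dB = 15, d = 1 A: factor exp(-15/4)
  one <- rs[which.min(abs(rs$d - 1))[1], ]
  sh <- shift_overall_b(rs, 15)
  ratio <- Mod(sh$F[which.min(abs(rs$d - 1))[1]]) / Mod(one$F)
  expect_equal(ratio, exp(-15 / (4 * one$d^2)), tolerance = 1e-10)
  # structure-space: adds to B, refuses negative results
  s15 <- shift_overall_b(s, 15)
  expect_equal(s15$atoms$b, 20)
  expect_error(shift_overall_b(s, -6), "negative")
})

test_that("vector averaging is the complex mean", {
  cl <- unit_cell(10, 10, 10)
  s <- make_structure(c(0.2, 0.3, 0.4), b = 5, cell = cl)
  rs <- calc_sf_direct(s, generate_hkl(cl, "P1", d_min = 1.5))
  avg <- average_sf(list(rs, rs, rs))
  expect_equal(avg$F, rs$F)
  neg <- rs; neg$F <- -rs$F
  expect_equal(Mod(average_sf(list(rs, neg))$F), rep(0, nrow(rs)))
  bad <- rs[-1, ]
  attr(bad, "cell") <- attr(rs, "cell"); attr(bad, "sg") <- attr(rs, "sg")
  expect_error(average_sf(list(rs, bad)), "differ")
  # Debye-Waller equivalence: averaging over Gaussian displacements equals a
  # static atom with B = 8 pi^2 sigma^2
  set.seed(31)
  sigma <- 0.25
  hkl <- generate_hkl(cl, "P1", d_min = 1.2)
  sets <- lapply(1:800, function(i) {
    si <- s
    si$atoms[, c("x", "y", "z")] <- si$atoms[, c("x", "y", "z")] +
      rnorm(3, sd = sigma / 10)  # fractional: sigma/cell edge
    calc_sf_direct(si, hkl)
  })
  got <- Mod(average_sf(sets)$F)
  want <- Mod(calc_sf_direct(s, hkl)$F) * exp(-8 * pi^2 * sigma^2 / (4 * hkl$d^2))
  expect_equal(mean(got / want), 1, tolerance = 0.05)
})

test_that("supercell reduction re-indexes, rescales and merges correctly", {
  tpl <- build_template(n_res = 2, cell = unit_cell(12, 14, 16), sg = "C2221")
  p1 <- expand_to_p1(tpl)
  super <- build_supercell(tpl, c(3, 3, 3))
  rsS <- generate_hkl(super$cell, "P1", d_min = 2.0)
  fS <- calc_sf_direct(super, rsS)
  # lattice-sum extinction for indices not divisible by 3
  off <- fS[(fS$h %% 3 != 0) | (fS$k %% 3 != 0) | (fS$l %% 3 != 0), ]
  expect_lt(max(Mod(off$F)), 1e-6 * cell_electrons(tpl) * 27)
  red <- reduce_supercell(fS, c(3, 3, 3), "C2221", base_cell = tpl$cell)
  expect_lt(attr(red, "merge_stats")$max_phase_spread, 1e-6)
  fd <- calc_sf_direct(tpl, red)
  expect_equal(red$F, fd$F, tolerance = 1e-8)
  expect_true(all(!is_absent(space_group("C2221"), cbind(red$h, red$k, red$l))))
})

test_that("HKL text files round-trip and resolution truncation filters", {
  cl <- unit_cell(10, 12, 14)
  s <- make_structure(matrix(runif(9), 3), b = 10, cell = cl)
  rs <- calc_sf_direct(s, generate_hkl(cl, "P1", d_min = 1.5))
  rs <- assign_free_set(rs, 0.1, seed = 3)
  path <- tempfile(fileext = ".hkl")
  write_hkl(rs, path)
  back <- read_hkl(path)
  expect_equal(Mod(back$F), Mod(rs$F), tolerance = 1e-6)
  expect_equal(Arg(back$F), Arg(rs$F), tolerance = 1e-5)
  expect_equal(back$free, rs$free)
  expect_equal(attr(back, "cell")$a, 10)
  tr <- truncate_resolution(rs, 2.0)
  expect_true(all(tr$d >= 2.0 - 1e-9))
  expect_s3_class(tr, "reflection_set")
  expect_equal(attr(tr, "cell")$a, 10)
})
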