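test_that("unit cell transforms invert each other and volume is correct", {
  for (cl in list(unit_cell(19.677, 39.90, 75.09),
                  unit_cell(10, 12, 14, 83, 97, 105))) {
    expect_equal(cl$frac %*% cl$orth, diag(3), tolerance = 1e-10)
    xyz <- matrix(runif(30), 10)
    expect_equal(cart_to_frac(cl, frac_to_cart(cl, xyz)), xyz,
                 tolerance = 1e-10)
  }
  expect_equal(unit_cell(10, 12, 14)$volume, 1680)
  expect_error(unit_cell(-1, 2, 3))
  expect_error(unit_cell(1, 2, 3, alpha = 190))
})

test_that("C2221 operators form a closed group with identity and inverses", {
  sg <- space_group("C2221")
  expect_equal(sg$n_ops, 8)
  expect_true(bfaudit:::check_group_closure(sg))
  expect_true(any(vapply(sg$ops, function(o)
    all(o$R == diag(3)) && all(o$t == 0), logical(1))))
  s <- make_structure(c(0.13, 0.27, 0.41), cell = unit_cell(10, 12, 14),
                      sg = "C2221")
  for (i in seq_len(8)) {
    si <- apply_symmetry(s, i)
    # applying the inverse operator restores the original coordinates
    Rinv <- solve(sg$ops[[i]]$R)
    back <- bfaudit:::wrap_frac(
      (as.matrix(si$atoms[, c("x", "y", "z")]) -
         matrix(sg$ops[[i]]$t, 1)) %*% t(Rinv))
    expect_equal(as.vector(back), c(0.13, 0.27, 0.41), tolerance = 1e-12)
  }
})

test_that("two-fold screw along c transforms and wraps as tabulated", {
  s <- make_structure(c(0.1, 0.2, 0.3), sg = "C2221")
  s2 <- apply_symmetry(s, 2)
  expect_equal(unlist(s2$atoms[, c("x", "y", "z")]), c(x = 0.9, y = 0.8, z = 0.8))
  expect_identical(apply_symmetry(s, 1)$atoms$x, s$atoms$x)
  expect_error(apply_symmetry(s, 9), "invalid")
})

test_that("anisotropic U rotates with the operator", {
  s <- make_structure(c(0.1, 0.2, 0.3), sg = "C2221")
  s$atoms[c("u11", "u22", "u33", "u12", "u13", "u23")] <-
    as.list(c(0.02, 0.05, 0.08, 0.01, 0.005, -0.01))
  s2 <- apply_symmetry(s, 2)  # rotation diag(-1,-1,1): off-diagonals u13,u23 flip
  expect_equal(s2$atoms$u11, 0.02)
  expect_equal(s2$atoms$u12, 0.01)
  expect_equal(s2$atoms$u13, -0.005)
  expect_equal(s2$atoms$u23, 0.01)
})

test_that("supercell construction multiplies volume, counts and cell edges", {
  tpl <- build_template(n_res = 2, cell = unit_cell(12, 14, 16), sg = "C2221")
  p1 <- expand_to_p1(tpl)
  expect_equal(n_atoms(p1), 8 * n_atoms(tpl))
  sc <- build_supercell(tpl, c(3, 3, 3))
  expect_equal(n_atoms(sc), 27 * 8 * n_atoms(tpl))
  expect_equal(sc$cell$volume, 27 * tpl$cell$volume)
  sc1 <- build_supercell(p1, c(1, 1, 1))
  expect_equal(n_atoms(sc1), n_atoms(p1))
  expect_equal(bfaudit:::coords_frac(sc1), bfaudit:::coords_frac(p1))
})

test_that("the stated crystal composition assembles to the printed counts", {
  tpl <- build_template(n_res = 35, cell = villin_cell(), sg = "C2221",
                        n_atoms = 373)
  expect_equal(n_atoms(tpl), 373)
  sc <- build_supercell(tpl, c(3, 3, 3))
  expect_equal(n_atoms(sc), 80568)
  expect_equal(round(c(sc$cell$a, sc$cell$b, sc$cell$c), 2),
               c(59.03, 119.70, 225.27))
})

test_that("map_to_reference inverts the expansion without fitting", {
  tpl <- build_template(n_res = 2, cell = unit_cell(12, 14, 16), sg = "C2221")
  sc <- build_supercell(tpl, c(2, 1, 2))
  monos <- map_to_reference(sc)
  expect_length(monos, 8 * 4)
  for (m in monos[c(1, 9, 17, 32)])
    expect_equal(bfaudit:::coords_frac(m), bfaudit:::coords_frac(tpl),
                 tolerance = 1e-10)
  # perturbing the reference before expansion survives the round trip exactly
  tpl2 <- tpl
  shift <- cart_to_frac(tpl$cell, matrix(c(0.1, 0, 0), 1))
  tpl2$atoms$x <- tpl2$atoms$x + shift[1]
  sc2 <- build_supercell(tpl2, c(2, 1, 2))
  m2 <- map_to_reference(sc2)
  expect_equal(bfaudit:::coords_frac(m2[[5]]),
               bfaudit:::coords_frac(tpl2), tolerance = 1e-10)
  # atom-count mismatch is rejected
  bad <- sc
  bad$atoms <- bad$atoms[-1, ]
  expect_error(map_to_reference(bad), "monomer")
})

test_that("Matthews coefficient and solvent fraction follow the convention", {
  expect_equal(compute_matthews(unit_cell(10, 10, 100), 1, 5000)$v_m, 2.0)
  m <- compute_matthews(unit_cell(10, 10, 100), 1, 10000 / 1.23)
  expect_equal(m$solvent_fraction, 0)
  expect_error(compute_matthews(unit_cell(10, 10, 10), 1, -5))
})

test_that("peptide molecular weight from residue composition", {
  expect_equal(peptide_mw("GG"), 2 * 57.052 + 18.015, tolerance = 1e-3)
  # norleucine is treated as the leucine isomer
  expect_equal(peptide_mw("X"), peptide_mw("L"))
  expect_error(peptide_mw("ZB"))
})

test_that("PDB round trip preserves coordinates, B, cell and ANISOU", {
  tpl <- build_template(n_res = 2, cell = unit_cell(12, 14, 16), sg = "C2221")
  tpl$atoms$b <- seq(5, by = 1, length.out = n_atoms(tpl))
  tpl$atoms[c("u11", "u22", "u33", "u12", "u13", "u23")] <-
    data.frame(u11 = 0.02, u22 = 0.03, u33 = 0.04,
               u12 = 0.001, u13 = -0.002, u23 = 0.003)
  path <- tempfile(fileext = ".pdb")
  write_pdb(tpl, path)
  s <- read_pdb(path)
  expect_equal(s$cell$a, 12)
  expect_equal(s$sg$name, "C2221")
  expect_equal(bfaudit:::coords_frac(s), bfaudit:::coords_frac(tpl),
               tolerance = 1e-3)
  expect_equal(s$atoms$b, tpl$atoms$b, tolerance = 1e-2)
  expect_equal(s$atoms$u11, tpl$atoms$u11, tolerance = 1e-4)
  expect_equal(s$atoms$u13, tpl$atoms$u13, tolerance = 1e-4)
  expect_equal(s$atoms$element, tpl$atoms$element)
  # multi-model files come back as a list of snapshots
  write_pdb(list(tpl, tpl), path)
  lst <- read_pdb(path, multi = TRUE)
  expect_length(lst, 2)
})
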