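test_that("toy template declares the restrained/mobile split by segment", {
  tpl <- build_template(n_res = 35)
  expect_equal(n_atoms(tpl), 245)
  expect_setequal(unique(tpl$atoms$resno[!tpl$atoms$mobile]), 1:21)
  expect_setequal(unique(tpl$atoms$resno[tpl$atoms$mobile]), 22:35)
  # degenerate splits
  expect_true(all(!build_template(n_res = 5, mobile_fraction = 0)$atoms$mobile))
  expect_true(all(build_template(n_res = 5, mobile_fraction = 1)$atoms$mobile))
  # padding to a stated composition appends carbon pseudo-atoms
  tpl373 <- build_template(n_res = 35, n_atoms = 373)
  expect_equal(n_atoms(tpl373), 373)
  expect_error(build_template(n_res = 35, n_atoms = 100), "n_atoms")
})

test_that("from_pdb reads heavy atoms of a minimal one-residue file", {
  path <- tempfile(fileext = ".pdb")
  writeLines(c(
    "CRYST1   10.000   12.000   14.000  90.00  90.00  90.00 P 1           1",
    "ATOM      1  N   ALA A   1       1.000   2.000   3.000  1.00 10.00           N",
    "ATOM      2  CA  ALA A   1       2.200   2.500   3.100  1.00 10.00           C",
    "ATOM      3  C   ALA A   1       3.100   2.000   4.000  1.00 10.00           C",
    "ATOM      4  O   ALA A   1       3.000   1.000   4.700  1.00 10.00           O",
    "ATOM      5  CB  ALA A   1       2.500   4.000   3.000  1.00 10.00           C",
    "END"), path)
  s <- build_template(kind = "from_pdb", pdb = path)
  expect_equal(n_atoms(s), 5)
  expect_equal(s$atoms$elety, c("N", "CA", "C", "O", "CB"))
  expect_error(build_template(kind = "from_pdb", pdb = "no/such.pdb"),
               "unreadable")
})

test_that("zero-variance spec reproduces the template in every snapshot", {
  tpl <- build_template(n_res = 2, cell = unit_cell(12, 14, 16), sg = "C2221",
                        mobile_fraction = 0)
  spec <- ensemble_spec(tpl, list(), n_snapshots = 5, seed = 3,
                        restrained_sigma = 0)
  ens <- sample_ensemble(spec)
  # snapshots are stored without wrapping; compare modulo lattice translations
  ref <- wrap_frac(bfaudit:::coords_frac(build_supercell(tpl, c(1, 1, 1))))
  for (t in 1:5)
    expect_equal(wrap_frac(ens$coords[, , t]), ref, tolerance = 1e-12,
                 ignore_attr = TRUE)
})

test_that("sampling is reproducible by seed and differs across seeds", {
  cfg <- demo_bimodal_config(seed = 7, n_snapshots = 3)
  e1 <- sample_ensemble(cfg$spec)
  e2 <- sample_ensemble(cfg$spec)
  expect_identical(e1$coords, e2$coords)
  cfg2 <- demo_bimodal_config(seed = 8, n_snapshots = 3)
  expect_false(identical(e1$coords, sample_ensemble(cfg2$spec)$coords))
})

test_that("empirical moments match the analytic motion-model moments", {
  tpl <- build_template(n_res = 1, cell = unit_cell(20, 20, 20), sg = "P1",
                        mobile_fraction = 1)
  n <- 10000
  # harmonic: per-axis variance sigma^2
  spec <- ensemble_spec(tpl, list(motion_harmonic_iso(1:7, 0.2)),
                        n_snapshots = n, seed = 11)
  ens <- sample_ensemble(spec)
  v <- ens$moments$cov[, 1:3]
  se <- 0.04 * sqrt(2 / n)
  expect_true(all(abs(v - 0.04) < 3 * se + 1e-4))
  expect_true(all(abs(ens$moments$cov[, 4:6]) < 4 * se))
  # bimodal: variance along d is p(1-p)|d|^2 + sigma_local^2
  spec2 <- ensemble_spec(tpl, list(motion_bimodal(1:7, d = c(2, 0, 0),
                                                  p = 0.5,
                                                  sigma_local = 0.1)),
                         n_snapshots = n, seed = 12)
  ens2 <- sample_ensemble(spec2)
  vx <- ens2$moments$cov[, 1]
  expect_true(all(abs(vx - 1.01) < 3 * 1.01 * sqrt(2 / n) + 3 * 0.02))
  expect_true(all(abs(ens2$moments$cov[, 2] - 0.01) < 0.004))
  # mean displacement along the jump is p * d
  expect_true(all(abs(ens2$moments$mean[, 1] - 1.0) < 0.05))
})

test_that("anisotropic harmonic model reproduces its covariance", {
  tpl <- build_template(n_res = 1, cell = unit_cell(20, 20, 20), sg = "P1",
                        mobile_fraction = 1)
  cov <- matrix(c(0.09, 0.02, 0, 0.02, 0.04, 0.01, 0, 0.01, 0.06), 3, 3)
  spec <- ensemble_spec(tpl, list(motion_harmonic_aniso(1:7, cov)),
                        n_snapshots = 8000, seed = 13)
  ens <- sample_ensemble(spec)
  got <- ens$moments$cov
  expect_equal(colMeans(got),
               c(0.09, 0.04, 0.06, 0.02, 0, 0.01),
               tolerance = 0.01, ignore_attr = TRUE)
})

test_that("rotamer flips rotate the subtree rigidly about the dihedral axis", {
  tpl <- build_template(n_res = 2, cell = unit_cell(15, 15, 15), sg = "P1",
                        mobile_fraction = 1)
  sel <- res_sel(tpl, 2, c("CG", "CD"))
  axis <- c(res_sel(tpl, 2, "CA"), res_sel(tpl, 2, "CB"))
  spec <- ensemble_spec(tpl, list(motion_rotamer(sel, axis, angles = c(0, 120),
                                                 weights = c(0.5, 0.5),
                                                 sigma_local = 0)),
                        n_snapshots = 200, seed = 4, restrained_sigma = 0)
  ens <- sample_ensemble(spec)
  cart0 <- frac_to_cart(tpl$cell, bfaudit:::coords_frac(tpl))
  d0 <- dist(cart0[c(axis, sel), ])
  for (t in c(1, 50, 200)) {
    cart <- frac_to_cart(tpl$cell, ens$coords[, , t])
    expect_equal(as.vector(dist(cart[c(axis, sel), ])), as.vector(d0),
                 tolerance = 1e-9)
  }
  # exactly two distinct CG positions across the ensemble
  xg <- round(ens$coords[sel[1], 1, ], 9)
  expect_equal(length(unique(xg)), 2)
})

test_that("restrained atoms keep RMSF near the configured jitter", {
  tpl <- build_template(n_res = 2, cell = unit_cell(14, 15, 16), sg = "P1",
                        mobile_fraction = 0.5)
  spec <- ensemble_spec(tpl, list(), n_snapshots = 2000, seed = 5)
  fl <- ensemble_fluctuations(sample_ensemble(spec))
  restrained <- !tpl$atoms$mobile
  expect_true(all(fl$rmsf[restrained] > 0))
  target <- 0.058 * sqrt(3)
  expect_true(all(fl$rmsf[restrained] < 2 * target))
  expect_equal(mean(fl$rmsf[restrained]), target, tolerance = 0.1)
  # uncovered mobile atoms are immobile
  expect_true(all(fl$rmsf[tpl$atoms$mobile] == 0))
})

test_that("overlapping selections are rejected", {
  tpl <- build_template(n_res = 2, cell = unit_cell(14, 15, 16), sg = "P1",
                        mobile_fraction = 1)
  expect_error(ensemble_spec(tpl, list(motion_harmonic_iso(1:5, 0.1),
                                       motion_harmonic_iso(4:8, 0.1))),
               "overlap")
})

test_that("single-snapshot iid supercell carries static disorder per site", {
  tpl <- build_template(n_res = 1, cell = unit_cell(12, 14, 16), sg = "C2221",
                        mobile_fraction = 1)
  models <- list(motion_harmonic_iso(1:7, 0.3))
  spec <- ensemble_spec(tpl, models, n_snapshots = 10, factors = c(3, 3, 3),
                        mode = "iid_per_site", seed = 6)
  one <- snapshot_single(spec)
  expect_equal(dim(one$coords)[3], 1)
  mono <- ensemble_monomers(one)
  expect_equal(dim(mono)[3], 216)
  # all 216 conformers distinct
  expect_equal(length(unique(round(mono[1, 1, ], 9))), 216)
  # across-site variance matches the model within sampling error
  fl <- compute_fluctuations(mono, tpl$cell, tpl$atoms)
  expect_equal(mean(fl$rmsf^2), 3 * 0.09,
               tolerance = 3 * sqrt(2 / 216) + 0.02)
  # shared mode: one supercell of identical copies
  spec_sh <- ensemble_spec(tpl, models, n_snapshots = 10, factors = c(1, 1, 1),
                           mode = "shared", seed = 6)
  one_sh <- snapshot_single(spec_sh)
  mono_sh <- ensemble_monomers(one_sh)
  for (m in 2:8)
    expect_equal(mono_sh[, , m], mono_sh[, , 1], tolerance = 1e-12)
})
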