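make_fl <- function(tpl, b) {
  arr <- array(rep(bfaudit:::coords_frac(tpl), 2), c(n_atoms(tpl), 3, 2))
  fl <- compute_fluctuations(arr, tpl$cell, tpl$atoms)
  fl$b_iso <- b
  fl
}

test_that("B comparison summary statistics follow their closed forms", {
  tpl <- build_template(n_res = 1, cell = unit_cell(10, 10, 10), sg = "P1")
  tpl$atoms <- tpl$atoms[1:3, ]
  fl <- make_fl(tpl, c(10, 20, 30))
  refined <- tpl
  refined$atoms$b <- c(8, 16, 24)
  cmp <- compare_bfactors(fl, refined)
  expect_equal(cmp$summary$rms_b, sqrt(56 / 3), tolerance = 1e-10)
  expect_equal(cmp$summary$delta_max, 6)
  expect_equal(cmp$summary$slope, 0.8, tolerance = 1e-10)
  expect_equal(cmp$summary$frac_under, 1)
  ident <- compare_bfactors(fl, {
    r <- tpl; r$atoms$b <- c(10, 20, 30); r
  })
  expect_equal(ident$summary$rms_b, 0)
  expect_equal(ident$summary$slope, 1)
  expect_equal(ident$summary$r2, 1)
  # range restriction never increases delta_max
  cmp_r <- compare_bfactors(fl, refined, range = c(10, 25))
  expect_lte(cmp_r$summary$delta_max, cmp$summary$delta_max)
  expect_equal(cmp_r$summary$n_atoms, 2)
  # degenerate actual variance: regression undefined, not NaN
  flc <- make_fl(tpl, c(10, 10, 10))
  cmp_c <- compare_bfactors(flc, refined)
  expect_true(is.na(cmp_c$summary$slope))
  expect_true(is.na(cmp_c$summary$r2))
  # id mismatch
  bad <- refined; bad$atoms$elety <- rev(bad$atoms$elety)
  expect_error(compare_bfactors(fl, bad), "mismatch")
})

test_that("null difference maps vanish and Parseval holds", {
  tpl <- build_template(n_res = 3, cell = unit_cell(13, 14, 15), sg = "C2221",
                        mobile_fraction = 0.5)
  tpl$atoms$b <- 12
  rs <- generate_hkl(tpl$cell, tpl$sg, d_min = 1.2)
  obs <- calc_sf_direct(tpl, rs)
  dm0 <- difference_map(obs, tpl, grid_spacing = 0.4)
  expect_lt(max(abs(dm0$grid)),
            1e-6 * cell_electrons(tpl) / tpl$cell$volume)
  expect_equal(mean(dm0$grid), 0, tolerance = 1e-12)
  # delete an atom: map variance obeys Parseval; strongest peak marks the atom
  model <- tpl
  model$atoms <- model$atoms[-5, , drop = FALSE]
  dm <- difference_map(obs, model, grid_spacing = 0.25)
  fc <- calc_sf_direct(model, obs)
  coef <- (Mod(obs$F) - dm$k * Mod(fc$F)) * fc$F / pmax(Mod(fc$F), 1e-300)
  full <- bfaudit:::expand_to_p1_reflections(cbind(obs$h, obs$k, obs$l), coef,
                                             attr(obs, "sg"))
  expect_equal(stats::var(as.vector(dm$grid)) * (1 - 1 / length(dm$grid)),
               sum(Mod(full$F)^2) / tpl$cell$volume^2, tolerance = 0.01)
  w <- which(dm$grid == max(dm$grid), arr.ind = TRUE)[1, , drop = FALSE]
  peak <- frac_to_cart(tpl$cell, matrix((w - 1) / dm$n, 1))
  dmin <- min(vapply(1:8, function(i) {
    si <- apply_symmetry(tpl, i)
    at <- frac_to_cart(tpl$cell, as.matrix(si$atoms[5, c("x", "y", "z")]))
    sqrt(sum((peak - at)^2))
  }, numeric(1)))
  expect_lt(dmin, 0.5)
})

test_that("two-site heterogeneity leaves paired difference density", {
  cl <- unit_cell(12, 12, 12)
  base <- make_structure(rbind(c(0.3, 0.3, 0.3), c(0.62, 0.45, 0.5)),
                         b = 8, cell = cl)
  alt <- base
  alt$atoms$x[2] <- alt$atoms$x[2] + 1.8 / cl$a  # second site, 1.8 A away
  hkl <- generate_hkl(cl, "P1", d_min = 1.0)
  obs <- calc_sf_direct(base, hkl)
  obs$F <- 0.5 * (obs$F + calc_sf_direct(alt, hkl)$F)
  dm <- difference_map(obs, base, grid_spacing = 0.3)
  # positive density at the unmodelled site, negative at the over-weighted one
  site2 <- round(c(alt$atoms$x[2], alt$atoms$y[2], alt$atoms$z[2]) * dm$n) + 1
  site1 <- round(c(base$atoms$x[2], base$atoms$y[2], base$atoms$z[2]) * dm$n) + 1
  expect_gt(dm$grid[site2[1], site2[2], site2[3]], 2 * dm$sigma)
  expect_lt(dm$grid[site1[1], site1[2], site1[3]], 0)
})

test_that("real-space correlation separates rigid from heterogeneous residues", {
  tpl <- build_template(n_res = 2, cell = unit_cell(13, 14, 15), sg = "P1",
                        mobile_fraction = 0.5)
  tpl$atoms$b <- 10
  hkl <- generate_hkl(tpl$cell, "P1", d_min = 1.2)
  mm <- model_map(tpl, hkl, grid_spacing = 0.4)
  self <- real_space_cc(mm, mm, tpl)
  expect_equal(self$rscc, rep(1, 2))
  neg <- mm; neg$grid <- -mm$grid
  expect_equal(real_space_cc(mm, neg, tpl)$rscc, rep(-1, 2))
  # observed with a displaced residue-2 side chain: residue 2 correlates worse
  alt <- tpl
  sel <- res_sel(tpl, 2, c("CB", "CG", "CD"))
  alt$atoms$x[sel] <- alt$atoms$x[sel] + 1.6 / tpl$cell$a
  obs <- calc_sf_direct(tpl, hkl)
  obs$F <- 0.5 * (obs$F + calc_sf_direct(alt, hkl)$F)
  om <- bfaudit:::synth_map(cbind(obs$h, obs$k, obs$l), obs$F,
                            attr(obs, "sg"), tpl$cell, 0.4)
  cc <- real_space_cc(om, mm, tpl)
  expect_gt(cc$rscc[1], cc$rscc[2])
  expect_gt(cc$rscc[1], 0.95)
})

test_that("CCP4 map writer emits a well-formed header", {
  tpl <- build_template(n_res = 1, cell = unit_cell(10, 11, 12), sg = "P1")
  mm <- model_map(tpl, generate_hkl(tpl$cell, "P1", d_min = 2), 0.5)
  path <- tempfile(fileext = ".map")
  write_ccp4_map(mm, path)
  con <- file(path, "rb")
  hdr <- readBin(con, "integer", 4, size = 4, endian = "little")
  close(con)
  expect_equal(hdr[1:3], mm$n)
  expect_equal(hdr[4], 2)
  expect_equal(file.size(path), 1024 + 4 * prod(mm$n))
})
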