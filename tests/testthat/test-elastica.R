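test_that("assembled quadratic form reproduces direct quadrature of the density", {
  geom <- quick_geom(D = 5, grid_spacing = 0.2)
  qf <- assemble_quadratic_form(geom)
  nn <- length(qf$x)
  withr::with_seed(42, {
    for (i in 1:5) {
      n <- rnorm(nn, sd = 0.05)
      H <- 1.55 + rnorm(nn, sd = 0.05)
      e_form <- rafttrap:::qf_energy(qf, n, H)
      e_quad <- elastic_energy(geom, n, H)
      expect_lt(abs(e_form - e_quad), 1e-10 * max(1, abs(e_quad)))
    }
  })
})

test_that("uniform far-field state carries zero excess energy", {
  geom <- quick_geom(D = 6, domain = study_lod(), background = study_lod())
  qf <- assemble_quadratic_form(geom)
  nn <- length(qf$x)
  Hff <- 1.8 * (1 - 0.1 / 30)
  expect_lt(abs(elastic_energy(geom, rep(0, nn), rep(Hff, nn))), 1e-12)
})

test_that("identical phases deform nothing and cost nothing at any gap", {
  for (D in c(0, 2, 10)) {
    geom <- quick_geom(D = D, domain = study_lod(), background = study_lod())
    res <- minimize_energy(geom)
    expect_lt(abs(res$W_per_length), 1e-8)
    expect_lt(max(abs(res$state$n)), 1e-8)
  }
})

test_that("dense and banded solves of the stationarity system agree to 1e-6", {
  # <= 400-node grids
  for (D in c(2, 6)) {
    geom <- quick_geom(D = D, grid_spacing = 0.2)
    expect_lte(length(assemble_quadratic_form(geom)$x), 400L)
    e_band <- minimize_energy(geom)$W_per_length
    e_dense <- minimize_energy(geom, dense = TRUE)$W_per_length
    expect_lt(abs(e_band - e_dense), 1e-6 * abs(e_dense))
  }
})

test_that("a stiff tilt modulus locks the director to the surface normal", {
  # tilt as the energy sees it, at interval midpoints
  mid_tilt <- function(res) {
    st <- res$state
    nm <- (st$n[-1] + st$n[-nrow(st)]) / 2
    Hp <- diff(st$H_nm) / diff(st$x_nm)
    max(abs(nm - Hp))
  }
  mk <- function(B, J0, h0, Kt) {
    phase_params(B = B, Kt = Kt, Ka = 30, J0 = J0, h0 = h0, K_stretch = 30)
  }
  sol <- function(Kt) {
    minimize_energy(pair_geometry(mk(20, -0.26, 1.8, Kt),
                                  mk(10, -0.25, 1.3, Kt),
                                  D = 5, grid_spacing = 0.02))
  }
  soft <- sol(10)
  stiff <- sol(1000)
  expect_lt(mid_tilt(stiff), 0.05 * mid_tilt(soft))
})

test_that("minimized state has the mirror symmetry of the geometry", {
  res <- minimize_energy(quick_geom(4))
  st <- res$state
  n_rev <- rev(st$n)
  H_rev <- rev(st$H_nm)
  expect_lt(max(abs(st$n + n_rev)), 1e-8)        # n odd
  expect_lt(max(abs(st$H_nm - H_rev)), 1e-8)     # H even
  expect_gte(res$W_per_length, 0)
})

test_that("energy is stable under grid halving to below 1%", {
  for (ds in c(0.2, 0.1)) {
    e1 <- minimize_energy(quick_geom(5, grid_spacing = ds))$W_per_length
    e2 <- minimize_energy(quick_geom(5, grid_spacing = ds / 2))$W_per_length
    expect_lt(abs(e1 - e2), 0.01 * abs(e2))
  }
})

test_that("wide-gap energy factorizes into two independent boundaries", {
  lam <- single_boundary_energy(study_lod(), study_ldd(), grid_spacing = 0.05)
  expect_gt(lam, 0)
  for (D in c(25, 30)) {
    W <- minimize_energy(quick_geom(D, grid_spacing = 0.05))$W_per_length
    expect_lt(abs(W - 2 * lam), 1e-3)
  }
  expect_lt(abs(single_boundary_energy(study_lod(), study_lod())), 1e-8)
})

test_that("line tension grows strictly with hydrophobic mismatch", {
  lam <- vapply(c(1.7, 1.5, 1.3, 1.1), function(hd) {
    bg <- phase_params(B = 10, Kt = 10, Ka = 30, J0 = -0.2, h0 = hd)
    single_boundary_energy(study_lod(J0 = -0.2), bg, grid_spacing = 0.1)
  }, numeric(1))
  expect_true(all(diff(lam) > 0))
})

test_that("interaction decays exponentially with a nanometre-scale length", {
  geom <- quick_geom(0)
  Ds <- seq(8, 16, by = 1)
  E <- vapply(Ds, function(D) {
    g <- geom; g$D <- D
    minimize_energy(g)$W_per_length
  }, numeric(1))
  plateau <- minimize_energy({g <- geom; g$D <- 30; g})$W_per_length
  dE <- abs(E - plateau)
  fit <- lm(log(dE) ~ Ds)
  ell <- -1 / coef(fit)[[2]]
  # of the order of sqrt(B/Kt) ~ 1-1.4 nm for the study moduli
  expect_gt(ell, 0.5)
  expect_lt(ell, 3)
})

test_that("parameter and geometry validation rejects bad inputs", {
  expect_error(phase_params(B = -1, Kt = 10, Ka = 30, J0 = 0, h0 = 1.5),
               class = "rafttrap_parameter_error")
  expect_error(phase_params(B = 10, Kt = 10, Ka = 30, J0 = NA, h0 = 1.5),
               class = "rafttrap_parameter_error")
  expect_error(pair_geometry(study_lod(), study_ldd(), D = -1),
               class = "rafttrap_parameter_error")
  expect_error(pair_geometry(study_lod(), study_ldd(), D = 5,
                             half_window = 3),
               class = "rafttrap_geometry_error")
  expect_error(elastic_energy(quick_geom(5), n = 1:3, H = 1:3),
               class = "rafttrap_parameter_error")
})

test_that("tension and modulus unit equivalences hold", {
  expect_equal(kbt_per_nm2_to_mN_per_m(30), 120)
  expect_equal(kbt_per_nm2_to_mN_per_m(0.1), 0.4)
  expect_equal(kbt_per_nm_to_pN(1), 4)
})
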