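test_that("ratio strings parse and normalize", {
  expect_equal(parse_ratio("2:1:2:1"), c(2, 1, 2, 1) / 6)
  expect_equal(sum(as_quaternary("3.5:28.5:39.5:28.5")), 1)
  expect_error(parse_ratio("2:-1:1"), class = "rafttrap_parameter_error")
  expect_error(as_quaternary("1:1:1"), class = "rafttrap_parameter_error")
})

test_that("the photolipid pools with its packing analogue", {
  expect_equal(unname(effective_ternary("2:1:2:1", "trans")),
               c(2, 2, 2) / 6)
  expect_equal(unname(effective_ternary("2:1:2:1", "cis")),
               c(3, 1, 2) / 6)
  # no photolipid: ternary is just the first three fractions
  expect_equal(unname(effective_ternary(c(30, 30, 40, 0), "trans")),
               c(0.3, 0.3, 0.4))
  expect_error(effective_ternary("2:1:2:1", "both"),
               class = "rafttrap_parameter_error")
})

test_that("phase compositions unfold to the published quaternaries", {
  # trans liquid-ordered phase
  q <- quaternary_phase_composition(c(3.5, 57, 39.5), "2:1:2:1", "trans")
  expect_equal(unname(q), c(3.5, 28.5, 39.5, 28.5) / 100, tolerance = 1e-9)
  # cis liquid-disordered phase, within 0.5 mol% of the printed values
  q <- quaternary_phase_composition(c(67, 8, 25), "2:1:2:1", "cis")
  expect_lt(max(abs(q - c(45, 8, 25, 22) / 100)), 0.005)
  expect_equal(sum(q), 1)
  # zero photolipid passes through
  q <- quaternary_phase_composition(c(30, 30, 40), c(1, 1, 1, 0), "trans")
  expect_equal(unname(q), c(0.3, 0.3, 0.4, 0))
})

test_that("pool splitting conserves mass and the overall pool ratio", {
  withr::with_seed(7, {
    for (i in 1:20) {
      overall <- as_quaternary(runif(4, 0.05, 1))
      tern <- as_ternary(runif(3, 0.05, 1))
      for (ps in c("trans", "cis")) {
        q <- quaternary_phase_composition(tern, overall, ps)
        expect_equal(sum(q), 1, tolerance = 1e-12)
        pool_sp <- if (ps == "trans") "DPPC" else "DPhPC"
        ratio_overall <- overall[["PhoDAG"]] /
          (overall[[pool_sp]] + overall[["PhoDAG"]])
        ratio_phase <- q[["PhoDAG"]] / (q[[pool_sp]] + q[["PhoDAG"]])
        expect_equal(ratio_phase, ratio_overall, tolerance = 1e-12)
        # round trip back to the ternary
        expect_equal(unname(effective_ternary(q, ps)), unname(tern),
                     tolerance = 1e-12)
      }
    }
  })
})

test_that("weighted curvatures reproduce the tabulated cis values", {
  expect_equal(mean_spontaneous_curvature(c(5, 39, 54, 2), "cis"),
               -0.2025, tolerance = 1e-12)
  expect_equal(round(mean_spontaneous_curvature(c(5, 39, 54, 2), "cis"), 2),
               -0.20)
  expect_equal(mean_spontaneous_curvature(c(45, 8, 25, 22), "cis"),
               -0.3969, tolerance = 1e-12)
  expect_equal(round(mean_spontaneous_curvature(c(45, 8, 25, 22), "cis"), 1),
               -0.4)
  # pure cholesterol recovers the component value
  expect_equal(mean_spontaneous_curvature(c(0, 0, 1, 0), "cis"), -0.37)
})

test_that("weighted curvature is linear and bounded by component values", {
  tab <- curvature_table()
  withr::with_seed(11, {
    for (i in 1:20) {
      a <- as_quaternary(runif(4))
      b <- as_quaternary(runif(4))
      w <- runif(1)
      mix <- as_quaternary(w * a + (1 - w) * b)
      ja <- mean_spontaneous_curvature(a, "trans")
      jb <- mean_spontaneous_curvature(b, "trans")
      expect_equal(mean_spontaneous_curvature(mix, "trans"),
                   w * ja + (1 - w) * jb, tolerance = 1e-12)
      expect_gte(ja, min(tab$J0_nm1))
      expect_lte(ja, max(tab$J0_nm1))
    }
  })
})

test_that("tie-line fixture recovers the published phase table", {
  pc <- dplyr::bind_rows(phase_curvatures("trans"), phase_curvatures("cis"))
  expect_equal(nrow(pc), 4L)
  # published values hold to 0.01/nm (the fixture's exact pool split differs
  # from the 0.5 mol%-rounded printed compositions by up to ~0.003/nm)
  expect_lt(abs(pc$J0_nm1[pc$photostate == "cis" & pc$phase == "LDD"] -
                  (-0.4)), 0.01)
  expect_lt(abs(pc$J0_nm1[pc$photostate == "cis" & pc$phase == "LOD"] -
                  (-0.2)), 0.01)
  # trans weighted averages (the tabulated trans J0 values are not the
  # weighted averages of the printed compositions; see the vignette)
  expect_lt(abs(pc$J0_nm1[pc$photostate == "trans" & pc$phase == "LOD"] -
                  (-0.19)), 0.01)
  expect_lt(abs(pc$J0_nm1[pc$photostate == "trans" & pc$phase == "LDD"] -
                  (-0.225)), 0.01)
  expect_true(all(abs(rowSums(pc[, c("DPhPC", "DPPC", "Chol", "PhoDAG")]) -
                        1) < 1e-9))
})
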