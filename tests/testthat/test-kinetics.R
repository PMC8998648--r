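test_that("Derjaguin boundary length follows the closed form", {
  expect_equal(derjaguin_length(R0 = 8, l_c = 1), 8)
  expect_equal(derjaguin_length(R0 = 450, l_c = 1), 60)
  expect_equal(derjaguin_length(R0 = 0), 0)
  expect_equal(derjaguin_length(R0 = c(2, 8)), 2 * sqrt(2 * c(2, 8)))
  expect_error(derjaguin_length(R0 = -1), class = "rafttrap_parameter_error")
  expect_error(derjaguin_length(R0 = 1, l_c = 0),
               class = "rafttrap_parameter_error")
})

test_that("total barrier is specific barrier times boundary length", {
  expect_equal(interaction_barrier(0.03, 8), 0.24)
  expect_equal(interaction_barrier(0, 123), 0)
  expect_equal(interaction_barrier(0.06, 8), 0.48)
  expect_error(interaction_barrier(-0.1, 8),
               class = "rafttrap_parameter_error")
})

test_that("Boltzmann merger probability behaves and clips correctly", {
  expect_equal(merger_probability(0, A = 1), 1)
  expect_equal(merger_probability(0, A = 5), 1)  # clipped
  expect_equal(merger_probability(0.24, A = exp(-0.33)), exp(-0.57))
  p1 <- merger_probability(c(0.2, 0.4, 0.8), A = 0.7)
  expect_true(all(diff(p1) < 0))
  expect_error(merger_probability(0.1, A = 0),
               class = "rafttrap_parameter_error")
  expect_error(merger_probability(-1), class = "rafttrap_parameter_error")
})

test_that("binomial estimates reproduce the tabulated percentages", {
  est <- estimate_p(c(30, 9, 53, 21), c(19, 10, 42, 86))
  expect_equal(est$p_hat, c(30, 9, 53, 21) / c(49, 19, 95, 107))
  expect_equal(est$p_pct, c(61, 47, 56, 20))
  # normal 95% band reproduces every printed uncertainty
  expect_equal(est$p_err_pct, c(14, 22, 10, 8))
  # two-standard-error convention agrees for the extreme conditions
  expect_equal(rafttrap:::percent_round(est$p_err_2se[c(1, 4)]), c(14, 8))
  expect_equal(est$p_err_2se, 2 * est$se)
})

test_that("degenerate tallies are handled per contract", {
  zero <- estimate_p(0, 10)
  expect_equal(zero$p_hat, 0)
  expect_equal(zero$p_err, 0)
  expect_error(estimate_p(0, 0), class = "rafttrap_estimation_error")
  expect_error(estimate_p(-1, 5), class = "rafttrap_parameter_error")
})

test_that("ln A fit matches an independent least-squares oracle", {
  obs <- tibble::tibble(p_hat = c(0.61, 0.47, 0.56, 0.20),
                        E_i = c(0.24, 0.47, 0.16, 1.26))
  fit <- fit_ln_A(obs)
  # oracle: intercept-only regression of ln p + E_i
  oracle <- unname(coef(lm(I(log(p_hat) + E_i) ~ 1, data = obs))[1])
  expect_equal(fit$ln_A, oracle, tolerance = 1e-12)
  expect_equal(fit$ln_A, -0.3271, tolerance = 1e-3)
  # per-condition residual barriers match the tabulated k_BT (ln A - ln p)
  expect_equal(tidy(fit)$kBT_lnA_minus_lnp,
               c(0.16, 0.43, 0.25, 1.27), tolerance = 0.02)
  g <- glance(fit)
  expect_equal(g$A, exp(fit$ln_A))
  expect_equal(g$nobs, 4L)
})

test_that("single-condition fit inverts the model exactly", {
  one <- tibble::tibble(p_hat = exp(-0.4), E_i = 0.4)
  expect_equal(fit_ln_A(one)$ln_A, 0, tolerance = 1e-12)
  expect_error(fit_ln_A(tibble::tibble(p_hat = c(0.5, 0), E_i = c(1, 2))),
               class = "rafttrap_estimation_error")
})

test_that("merger kinetics chain is monotone decreasing in domain radius", {
  R0 <- c(4, 8, 50, 450)
  p <- merger_probability(
    interaction_barrier(0.03, derjaguin_length(R0)), A = 0.72)
  expect_true(all(diff(p) < 0))
})

test_that("merging rate is the plain quotient", {
  expect_equal(merging_rate(30, 200), 0.15)
  expect_equal(merging_rate(21, 60), 0.35)
  expect_equal(merging_rate(0, 50), 0)
  expect_error(merging_rate(3, 0), class = "rafttrap_parameter_error")
})

test_that("packaged collision tallies match the study and pipe into estimates", {
  counts <- collision_counts()
  expect_equal(nrow(counts), 4L)
  expect_equal(sum(counts$n_merged), 30 + 9 + 53 + 21)
  est <- add_merger_estimates(counts)
  expect_true(all(c("p_hat", "p_err", "p_pct") %in% names(est)))
  expect_equal(sort(est$p_pct), sort(c(61, 47, 56, 20)))
})
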