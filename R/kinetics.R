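#' Effective interacting boundary length (Derjaguin approximation)
#'
#' For two circular domains of radius `R0` whose rim deformations decay over
#' the length `l_c`, the Derjaguin approximation reduces the interaction of
#' the curved boundaries to that of straight boundaries over an effective
#' length \eqn{l_R = 2\sqrt{2 l_c R_0}}.
#'
#' @param R0 domain radius, nm (vectorized).
#' @param l_c characteristic decay length of the deformation, nm.
#' @return Effective boundary length, nm.
#' @examples
#' derjaguin_length(R0 = 8)    # 8 nm
#' derjaguin_length(R0 = 450)  # 60 nm, micrometre-sized domain
#' @export
derjaguin_length <- function(R0, l_c = 1) {
  if (any(!is.finite(R0)) || any(R0 < 0)) {
    abort("`R0` must be non-negative.", class = "rafttrap_parameter_error")
  }
  if (any(!is.finite(l_c)) || any(l_c <= 0)) {
    abort("`l_c` must be positive.", class = "rafttrap_parameter_error")
  }
  2 * sqrt(2 * l_c * R0)
}

#' Total fusion-opposing interaction barrier
#'
#' Multiplies the barrier height per unit boundary length by the effective
#' interacting boundary length.
#'
#' @param E_B barrier height, \eqn{k_BT/\mathrm{nm}} (vectorized).
#' @param l_R effective boundary length, nm; the study uses 8 nm for domains
#'   of all sizes (see [derjaguin_length()] for the size-dependent form).
#' @return Barrier \eqn{E_i}, \eqn{k_BT}.
#' @examples
#' interaction_barrier(0.03)  # 0.24 kBT
#' @export
interaction_barrier <- function(E_B, l_R = 8) {
  if (any(E_B < 0) || any(l_R < 0)) {
    abort("`E_B` and `l_R` must be non-negative.",
          class = "rafttrap_parameter_error")
  }
  E_B * l_R
}

#' Merger probability from the interaction barrier
#'
#' Boltzmann kinetics for the per-collision merger probability,
#' \eqn{\ln p = -E_i/k_BT + \ln A}, clipped to \eqn{[0, 1]}. The prefactor
#' `A` absorbs the frequency of merger attempts and is obtained by fitting
#' ([fit_ln_A()]), never assumed.
#'
#' @param E_i interaction barrier, \eqn{k_BT} (vectorized).
#' @param A dimensionless attempt prefactor, > 0.
#' @return Merger probability in \eqn{[0, 1]}.
#' @export
merger_probability <- function(E_i, A = 1) {
  if (any(E_i < 0)) {
    abort("`E_i` must be non-negative.", class = "rafttrap_parameter_error")
  }
  if (any(!is.finite(A)) || any(A <= 0)) {
    abort("`A` must be positive.", class = "rafttrap_parameter_error")
  }
  pmin(1, A * exp(-E_i))
}

#' Estimate merger probability from collision tallies
#'
#' Binomial point estimate \eqn{\hat p = m/(m+b)} with a normal-approximation
#' uncertainty. The headline uncertainty `p_err` uses `conf_z` standard
#' errors (default 1.96, the normal 95% band, which reproduces the study's
#' printed values); `p_err_2se` reports the plain two-standard-error band.
#'
#' @param n_merged,n_bounced event counts (vectorized).
#' @param conf_z multiple of the binomial standard error used for `p_err`.
#' @return A tibble with columns `n_merged`, `n_bounced`, `n_events`,
#'   `p_hat`, `se`, `p_err`, `p_err_2se`, and display-rounded integer
#'   percentages `p_pct`, `p_err_pct`.
#' @examples
#' estimate_p(30, 19)  # 61 +/- 14 %
#' estimate_p(21, 86)  # 20 +/- 8 %
#' @export
estimate_p <- function(n_merged, n_bounced, conf_z = stats::qnorm(0.975)) {
  if (any(n_merged < 0) || any(n_bounced < 0)) {
    abort("counts must be non-negative.", class = "rafttrap_parameter_error")
  }
  N <- n_merged + n_bounced
  if (any(N < 1)) {
    abort("at least one event is required to estimate p.",
          class = "rafttrap_estimation_error")
  }
  p <- n_merged / N
  se <- sqrt(p * (1 - p) / N)
  tibble(n_merged = n_merged, n_bounced = n_bounced, n_events = N,
         p_hat = p, se = se, p_err = conf_z * se, p_err_2se = 2 * se,
         p_pct = percent_round(p), p_err_pct = percent_round(conf_z * se))
}

#' Add merger-probability estimates to a collision table
#'
#' Data-frame-first wrapper around [estimate_p()].
#'
#' @param data a data frame of collision tallies.
#' @param merged,bounced columns holding the counts (tidy evaluation).
#' @param conf_z see [estimate_p()].
#' @return `data` with the estimate columns appended.
#' @examples
#' collision_counts() |> add_merger_estimates()
#' @export
add_merger_estimates <- function(data, merged = n_merged,
                                 bounced = n_bounced,
                                 conf_z = stats::qnorm(0.975)) {
  m <- dplyr::pull(data, {{ merged }})
  b <- dplyr::pull(data, {{ bounced }})
  est <- estimate_p(m, b, conf_z = conf_z)
  dplyr::bind_cols(data, est[setdiff(names(est),
                                     c("n_merged", "n_bounced"))])
}

# round half-up to integer percent
percent_round <- function(x) floor(100 * x + 0.5)

#' Fit the attempt prefactor ln A across conditions
#'
#' Least-squares estimate of a single \eqn{\ln A} shared by all conditions in
#' the kinetic model \eqn{\ln p = -E_i + \ln A} (energies in \eqn{k_BT}):
#' \eqn{\ln A} minimizes \eqn{\sum_j (\ln \hat p_j + E_{i,j} - \ln A)^2},
#' i.e. it is the mean of \eqn{\ln \hat p_j + E_{i,j}}. The per-condition
#' residual barrier \eqn{k_BT(\ln A - \ln \hat p_j)} is returned for
#' comparison with the modeled \eqn{E_{i,j}}.
#'
#' @param data a data frame with one row per condition.
#' @param p_hat,E_i columns holding the observed merger probability and the
#'   modeled barrier in \eqn{k_BT} (tidy evaluation).
#' @return An object of class `merger_fit` with elements `ln_A`, `A` and a
#'   per-condition tibble; see [tidy.merger_fit()] and [glance.merger_fit()].
#' @examples
#' obs <- tibble::tibble(p_hat = c(0.61, 0.47, 0.56, 0.20),
#'                       E_i = c(0.24, 0.47, 0.16, 1.26))
#' fit <- fit_ln_A(obs)
#' glance(fit)
#' @export
fit_ln_A <- function(data, p_hat = p_hat, E_i = E_i) {
  p <- dplyr::pull(data, {{ p_hat }})
  Ei <- dplyr::pull(data, {{ E_i }})
  if (length(p) < 1 || length(p) != length(Ei)) {
    abort("`p_hat` and `E_i` must be aligned and non-empty.",
          class = "rafttrap_parameter_error")
  }
  if (any(p <= 0) || any(p > 1)) {
    abort("all `p_hat` must lie in (0, 1]; log of zero is undefined.",
          class = "rafttrap_estimation_error")
  }
  ln_A <- mean(log(p) + Ei)
  cond <- tibble(p_hat = p, E_i = Ei,
                 kBT_lnA_minus_lnp = ln_A - log(p),
                 residual = log(p) + Ei - ln_A)
  structure(list(ln_A = ln_A, A = exp(ln_A), conditions = cond),
            class = "merger_fit")
}

#' @export
print.merger_fit <- function(x, ...) {
  cat(sprintf("<merger_fit> ln A = %.4f (A = %.3f), %d condition(s)\n",
              x$ln_A, x$A, nrow(x$conditions)))
  invisible(x)
}

#' Per-condition results of a merger-kinetics fit
#' @param x a [fit_ln_A()] object.
#' @param ... unused.
#' @return Tibble with the observed probabilities, modeled barriers,
#'   per-condition \eqn{k_BT(\ln A - \ln \hat p)} and fit residuals.
#' @method tidy merger_fit
#' @export
tidy.merger_fit <- function(x, ...) x$conditions

#' One-row summary of a merger-kinetics fit
#' @inheritParams tidy.merger_fit
#' @return Tibble with `ln_A`, `A`, `nobs` and the residual sum of squares.
#' @method glance merger_fit
#' @export
glance.merger_fit <- function(x, ...) {
  tibble(ln_A = x$ln_A, A = x$A, nobs = nrow(x$conditions),
         rss = sum(x$conditions$residual^2))
}

#' Merger rate as a plain quotient
#'
#' @param n_merged number of merger events.
#' @param observation_time_s total observation time, s.
#' @return Events per second.
#' @export
merging_rate <- function(n_merged, observation_time_s) {
  if (any(observation_time_s <= 0, na.rm = TRUE)) {
    abort("`observation_time_s` must be positive.",
          class = "rafttrap_parameter_error")
  }
  n_merged / observation_time_s
}

#' Collision tallies of the photolipid study
#'
#' Merged/bounced event counts for large liquid-ordered (LOD) and
#' liquid-disordered (LDD) domains with the photolipid in its trans or cis
#' conformation, with the tabulated observation times.
#'
#' @return A tibble with columns `condition`, `photostate`, `phase`,
#'   `n_merged`, `n_bounced`, `observation_time_s`.
#' @examples
#' collision_counts() |> add_merger_estimates()
#' @export
collision_counts <- function() {
  path <- system.file("extdata", "collision_counts.csv",
                      package = "rafttrap", mustWork = TRUE)
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_tibble(out)
}
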