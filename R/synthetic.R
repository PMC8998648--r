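#' Simulate a Bernoulli merge/bounce collision stream
#'
#' Each domain collision independently ends in a merger with probability
#' `p_true` or a bounce otherwise — the statistical model under which merger
#' probabilities are estimated from tallies. Reproducible for a fixed seed.
#'
#' @param p_true per-collision merger probability in \eqn{[0, 1]}.
#' @param n_events number of collisions (\eqn{\ge 1}).
#' @param seed integer RNG seed.
#' @return A tibble of class `collision_series` with columns `event` and
#'   `outcome` (`"merge"`/`"bounce"`), and attributes `p_true` and `seed`.
#' @examples
#' simulate_collisions(0.61, 49, seed = 7) |> tally_collisions()
#' @export
simulate_collisions <- function(p_true, n_events, seed) {
  if (!is.numeric(p_true) || length(p_true) != 1L ||
      is.na(p_true) || p_true < 0 || p_true > 1) {
    abort("`p_true` must be a probability in [0, 1].",
          class = "rafttrap_parameter_error")
  }
  if (n_events < 1) {
    abort("`n_events` must be at least 1.",
          class = "rafttrap_parameter_error")
  }
  merged <- withr::with_seed(as.integer(seed),
                             rbinom(n_events, 1L, p_true) == 1L)
  out <- tibble(event = seq_len(n_events),
                outcome = ifelse(merged, "merge", "bounce"))
  attr(out, "p_true") <- p_true
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("collision_series", class(out))
  out
}

#' Tally a collision series
#'
#' @param series a [simulate_collisions()] result (or any data frame with an
#'   `outcome` column of `"merge"`/`"bounce"`).
#' @return One-row tibble with `n_merged` and `n_bounced`.
#' @export
tally_collisions <- function(series) {
  tibble(n_merged = sum(series$outcome == "merge"),
         n_bounced = sum(series$outcome == "bounce"))
}

#' Simulate a coalescing domain population
#'
#' Well-mixed (mass-action) pairwise coalescence: collisions arrive as a
#' Poisson process with total rate `collision_rate` \eqn{\times n(n-1)/2} for
#' `n` surviving domains, and each collision merges with probability `p_true`
#' (reducing the count by one) or bounces. Spatial diffusion is not modeled;
#' the generator reproduces the per-collision statistics of a shrinking
#' domain population, not its spatial dynamics.
#'
#' @param n0 initial number of domains (\eqn{\ge 2}).
#' @param collision_rate collisions per domain pair per second, > 0.
#' @param p_true per-collision merger probability.
#' @param t_max simulated time horizon, s.
#' @param seed integer RNG seed.
#' @return A tibble of class `population_trajectory` with columns `time_s`,
#'   `n_domains` and `event` (`"start"`, `"merge"`, `"bounce"`); attributes
#'   record all generator parameters.
#' @examples
#' simulate_population(20, 0.01, 0.5, t_max = 100, seed = 3)
#' @export
simulate_population <- function(n0, collision_rate, p_true, t_max, seed) {
  if (n0 < 2) {
    abort("`n0` must be at least 2.", class = "rafttrap_parameter_error")
  }
  if (collision_rate <= 0 || t_max <= 0) {
    abort("`collision_rate` and `t_max` must be positive.",
          class = "rafttrap_parameter_error")
  }
  if (p_true < 0 || p_true > 1) {
    abort("`p_true` must be a probability in [0, 1].",
          class = "rafttrap_parameter_error")
  }
  sim <- withr::with_seed(as.integer(seed), {
    t <- 0
    n <- as.integer(n0)
    times <- 0; counts <- n; events <- "start"
    while (n > 1L) {
      rate <- collision_rate * n * (n - 1) / 2
      t <- t + rexp(1L, rate)
      if (t > t_max) break
      merged <- runif(1L) < p_true
      if (merged) n <- n - 1L
      times <- c(times, t)
      counts <- c(counts, n)
      events <- c(events, if (merged) "merge" else "bounce")
    }
    tibble(time_s = times, n_domains = counts, event = events)
  })
  attr(sim, "params") <- list(n0 = n0, collision_rate = collision_rate,
                              p_true = p_true, t_max = t_max,
                              seed = as.integer(seed))
  class(sim) <- c("population_trajectory", class(sim))
  sim
}

#' @method autoplot population_trajectory
#' @export
autoplot.population_trajectory <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$time_s, y = .data$n_domains)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time (s)", y = "surviving domains")
}

#' Write a simulated series with its parameter sidecar
#'
#' Writes the table as CSV and all generator parameters (including the seed)
#' as a JSON sidecar next to it, so any output can be regenerated.
#'
#' @param x a [simulate_collisions()] or [simulate_population()] result.
#' @param path CSV path; the sidecar gets the extension `.json`.
#' @return `path`, invisibly.
#' @export
write_series <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  meta <- attr(x, "params") %||%
    list(p_true = attr(x, "p_true"), seed = attr(x, "seed"))
  jsonlite::write_json(meta, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
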