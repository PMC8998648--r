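#' Run the full domain-coalescence analysis
#'
#' Executes every stage on one configuration: interaction energy profiles and
#' barriers for the four photostate/phase-pair conditions, Derjaguin boundary
#' length and total interaction barriers, merger-probability estimates from
#' the collision tallies, the shared attempt-prefactor fit, phase
#' compositions with weighted spontaneous curvatures, and the
#' curvature-frustration verdict. Deterministic given the configuration.
#'
#' @param config a `run_config`, see [default_run_config()] and
#'   [read_run_config()].
#' @param counts collision tallies with columns `photostate`, `phase`,
#'   `n_merged`, `n_bounced`, `observation_time_s`; defaults to the packaged
#'   study tallies [collision_counts()].
#' @param refine refine the barrier position (passed to [energy_profile()]).
#' @return An object of class `domain_report`: a list with the resolved
#'   `config`, `profiles` (long tibble), `summary` (one row per condition:
#'   barriers, kinetics, estimates, curvatures), `ln_A_fit` and
#'   `frustration`.
#' @examples
#' \donttest{
#' cfg <- default_run_config()
#' cfg$grid_spacing <- 0.1  # coarser grid for a quick look
#' report <- run_pipeline(cfg)
#' report$summary
#' }
#' @export
run_pipeline <- function(config = default_run_config(),
                         counts = collision_counts(), refine = TRUE) {
  validate_run_config(config)
  conditions <- tidyr::expand_grid(photostate = c("trans", "cis"),
                                   pair = c("LOD", "LDD"))
  l_R <- if (config$l_R_policy == "fixed") {
    config$l_R
  } else {
    derjaguin_length(config$R0, config$l_c)
  }

  runs <- purrr::pmap(conditions, function(photostate, pair) {
    geom <- study_pair(photostate, pair, D = max(config$D_grid),
                       config = config)
    prof <- energy_profile(geom, D_values = config$D_grid, refine = refine)
    bar <- find_barrier(prof, per_domain = TRUE)
    list(profile = dplyr::mutate(as_tibble(prof),
                                 photostate = photostate, pair = pair,
                                 .before = 1),
         barrier = dplyr::mutate(bar, photostate = photostate, pair = pair,
                                 .before = 1))
  })
  profiles <- purrr::list_rbind(purrr::map(runs, "profile"))
  barriers <- purrr::list_rbind(purrr::map(runs, "barrier"))

  comps <- dplyr::bind_rows(
    phase_curvatures("trans", config$overall_mixture,
                     curvatures = do.call(curvature_table,
                                          config$curvatures %||% list())),
    phase_curvatures("cis", config$overall_mixture,
                     curvatures = do.call(curvature_table,
                                          config$curvatures %||% list())))

  est <- add_merger_estimates(counts)
  smry <- barriers |>
    dplyr::mutate(phase = .data$pair, E_i = interaction_barrier(.data$E_B, l_R)) |>
    dplyr::left_join(est, by = c("photostate", "phase")) |>
    dplyr::left_join(
      dplyr::select(comps, "photostate", phase = "phase",
                    J0_weighted = "J0_nm1"),
      by = c("photostate", "phase")) |>
    dplyr::mutate(
      J0_used = purrr::map2_dbl(.data$photostate, .data$phase,
                                \(ps, ph) config$J0[[ps]][[ph]]),
      merging_rate = ifelse(is.na(.data$observation_time_s), NA_real_,
                            merging_rate(.data$n_merged,
                                         .data$observation_time_s)),
      l_R = l_R)

  fit <- fit_ln_A(dplyr::filter(smry, .data$p_hat > 0))
  smry <- dplyr::mutate(
    smry,
    p_model = merger_probability(.data$E_i, A = fit$A),
    kBT_lnA_minus_lnp = ifelse(.data$p_hat > 0, fit$ln_A - log(.data$p_hat),
                               NA_real_))

  structure(list(config = config,
                 profiles = profiles,
                 summary = dplyr::select(
                   smry, "photostate", "phase", "E_B", "D_star", "E_plateau",
                   "l_R", "E_i", "n_merged", "n_bounced", "n_events",
                   "p_hat", "se", "p_err", "p_err_2se", "p_pct", "p_err_pct",
                   "p_model", "kBT_lnA_minus_lnp", "merging_rate",
                   "J0_used", "J0_weighted"),
                 ln_A_fit = fit,
                 frustration = frustration_check(
                   kappa_b = 2 * config$B_o,
                   J0 = config$J0$cis$LDD,
                   seed = config$seed)),
            class = "domain_report")
}

#' @export
print.domain_report <- function(x, ...) {
  cat("<domain_report>\n")
  cat(sprintf("  ln A = %.3f (A = %.3f)\n", x$ln_A_fit$ln_A, x$ln_A_fit$A))
  print(dplyr::select(x$summary, "photostate", "phase", "E_B", "D_star",
                      "E_i", "p_hat", "p_err", "p_model", "J0_weighted"))
  invisible(x)
}

#' Condition-level summary of a pipeline report
#' @param x a [run_pipeline()] report.
#' @param ... unused.
#' @return The per-condition summary tibble.
#' @method tidy domain_report
#' @export
tidy.domain_report <- function(x, ...) x$summary

#' @method glance domain_report
#' @export
glance.domain_report <- function(x, ...) {
  tibble(n_conditions = nrow(x$summary),
         ln_A = x$ln_A_fit$ln_A, A = x$ln_A_fit$A,
         frustration_invariant = x$frustration$size_invariant)
}

#' Write a pipeline report to disk
#'
#' Profiles and the condition summary as CSV, everything (including the
#' resolved configuration, so the run is reproducible from the output alone)
#' as JSON. Output is byte-stable: rerunning the same configuration writes
#' identical files.
#'
#' @param report a [run_pipeline()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "domain_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(report$profiles),
                   file.path(dir, "profiles.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(report$summary),
                   file.path(dir, "summary.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(config = unclass(report$config),
         summary = report$summary,
         ln_A = report$ln_A_fit$ln_A,
         A = report$ln_A_fit$A,
         frustration = report$frustration),
    file.path(dir, "report.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
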