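#' Default run configuration
#'
#' The full parameter set of the analysis, defaulting to the study system:
#' splay moduli \eqn{B_o = 20}, \eqn{B_d = 10\,k_BT}; tilt modulus
#' \eqn{K_t = 10\,k_BT/\mathrm{nm}^2}; area-stretching modulus
#' \eqn{K_a = 30\,k_BT/\mathrm{nm}^2}; stretching-term modulus `K_stretch`
#' equal to \eqn{K_t} (the functional as printed; see the vignette);
#' per-monolayer tension \eqn{\sigma_0 = 0.1\,k_BT/\mathrm{nm}^2}; monolayer
#' thicknesses \eqn{h_o = 1.8}, \eqn{h_d = 1.3} nm; tabulated phase
#' spontaneous curvatures per photostate; overall 2:1:2:1 mixture; decay
#' length \eqn{l_c = 1} nm with the fixed \eqn{l_R = 8} nm policy.
#'
#' @return A named list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    config_version = 1L,
    B_o = 20, B_d = 10,
    Kt = 10, Ka = 30, K_stretch = 10,
    sigma0 = 0.1,
    h_o = 1.8, h_d = 1.3,
    J0 = list(trans = list(LOD = -0.26, LDD = -0.25),
              cis = list(LOD = -0.2, LDD = -0.4)),
    curvatures = list(DPhPC = -0.2, DPPC = 0.07, Chol = -0.37,
                      PhoDAG_trans = -0.2, PhoDAG_cis = -1),
    overall_mixture = "2:1:2:1",
    grid_spacing = 0.025, half_window = 15,
    D_grid = default_D_grid(),
    l_c = 1, l_R_policy = "fixed", l_R = 8, R0 = 8,
    kbt_joule = 4e-21,
    seed = 1L
  ), class = "run_config")
}

validate_run_config <- function(config) {
  needed <- c("B_o", "B_d", "Kt", "Ka", "K_stretch", "sigma0", "h_o", "h_d",
              "J0", "overall_mixture", "grid_spacing", "half_window",
              "D_grid", "l_c", "l_R_policy", "l_R", "R0", "seed")
  missing <- setdiff(needed, names(config))
  if (length(missing) > 0) {
    abort(paste0("run config is missing: ",
                 paste(missing, collapse = ", ")),
          class = "rafttrap_config_error")
  }
  if (!config$l_R_policy %in% c("fixed", "derjaguin")) {
    abort('`l_R_policy` must be "fixed" or "derjaguin".',
          class = "rafttrap_config_error")
  }
  for (ps in c("trans", "cis")) {
    for (ph in c("LOD", "LDD")) {
      if (is.null(config$J0[[ps]][[ph]])) {
        abort(sprintf("config$J0$%s$%s is missing.", ps, ph),
              class = "rafttrap_config_error")
      }
    }
  }
  invisible(config)
}

#' Read or write a run configuration
#'
#' JSON (`.json`) or YAML (`.yml`/`.yaml`), chosen by extension. Fields
#' missing from the file are filled from [default_run_config()], so a config
#' file only needs to state overrides; the fully resolved configuration is
#' what [run_pipeline()] echoes into its report.
#'
#' @param path file path.
#' @param config a `run_config` list (for writing).
#' @return The resolved `run_config` (reading); `path` invisibly (writing).
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  config <- utils::modifyList(default_run_config(), raw)
  class(config) <- "run_config"
  validate_run_config(config)
  config
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  validate_run_config(config)
  x <- unclass(config)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}
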