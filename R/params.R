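#' Elastic parameters of one monolayer phase
#'
#' Bundles the per-monolayer elastic constants of a single lipid phase
#' (liquid-ordered or liquid-disordered). All energies are in units of
#' \eqn{k_BT} and all lengths in nm, so moduli are \eqn{k_BT} (splay) or
#' \eqn{k_BT/\mathrm{nm}^2} (tilt, stretching).
#'
#' `K_stretch` is the modulus multiplying the stretching term
#' \eqn{(\alpha-\alpha_0)^2/2} of the energy functional. The functional is
#' written with the tilt modulus in that position, and reproducing the
#' published barrier heights requires taking it at face value, so the
#' default is `Kt`. Set `K_stretch = Ka` for the textbook area-stretching
#' reading. The equilibrium stretching \eqn{\alpha_0 = \sigma/K_a} always
#' uses `Ka`.
#'
#' @param B splay (monolayer bending) modulus, \eqn{k_BT}.
#' @param Kt tilt modulus, \eqn{k_BT/\mathrm{nm}^2}.
#' @param Ka area-stretching modulus, \eqn{k_BT/\mathrm{nm}^2}; enters the
#'   equilibrium stretching \eqn{\alpha_0 = \sigma_0/K_a}.
#' @param J0 spontaneous curvature of the monolayer, \eqn{\mathrm{nm}^{-1}}
#'   (negative for cone-shaped, tail-heavy compositions).
#' @param h0 unstressed hydrophobic monolayer thickness, nm.
#' @param K_stretch modulus of the stretching term in the functional,
#'   \eqn{k_BT/\mathrm{nm}^2}. Defaults to `Kt` (see Details).
#' @return An object of class `phase_params` (a named list).
#' @examples
#' lod <- phase_params(B = 20, Kt = 10, Ka = 30, J0 = -0.26, h0 = 1.8)
#' ldd <- phase_params(B = 10, Kt = 10, Ka = 30, J0 = -0.25, h0 = 1.3)
#' @export
phase_params <- function(B, Kt, Ka, J0, h0, K_stretch = Kt) {
  for (nm in c("B", "Kt", "Ka", "h0", "K_stretch")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      abort(sprintf("`%s` must be a single positive finite number.", nm),
            class = "rafttrap_parameter_error")
    }
  }
  if (!is.numeric(J0) || length(J0) != 1L || !is.finite(J0)) {
    abort("`J0` must be a single finite number.",
          class = "rafttrap_parameter_error")
  }
  structure(list(B = B, Kt = Kt, Ka = Ka, J0 = J0, h0 = h0,
                 K_stretch = K_stretch),
            class = "phase_params")
}

#' @export
print.phase_params <- function(x, ...) {
  cat(sprintf(
    "<phase_params> B=%g kBT, Kt=%g, Ka=%g, K_stretch=%g kBT/nm^2, J0=%g 1/nm, h0=%g nm\n",
    x$B, x$Kt, x$Ka, x$K_stretch, x$J0, x$h0))
  invisible(x)
}

# slowest tilt-splay relaxation length of a phase, used for window checks
decay_length <- function(phase) sqrt(phase$B / phase$Kt)

#' Two-domain geometry for the elastic boundary-value problem
#'
#' Describes two registered, mirror-symmetric domains of `domain` phase whose
#' boundaries face each other across a gap of width `D` filled with
#' `background` phase. Domain radii are assumed much larger than the
#' deformation decay length, so each domain is treated as semi-infinite and
#' the problem is one-dimensional along the axis normal to the boundaries.
#'
#' @param domain,background [phase_params()] of the domain and of the phase
#'   filling the gap (and, conceptually, surrounding the domains).
#' @param D gap between the facing domain boundaries, nm (\eqn{\ge 0}).
#' @param sigma0 lateral tension per monolayer, \eqn{k_BT/\mathrm{nm}^2}.
#' @param grid_spacing finite-element grid spacing, nm.
#' @param half_window solved region beyond each domain boundary, nm. Must be
#'   at least ten tilt-splay decay lengths \eqn{\sqrt{B/K_t}} so the far-field
#'   boundary conditions do not bias the energy.
#' @return An object of class `pair_geometry`.
#' @examples
#' lod <- phase_params(B = 20, Kt = 10, Ka = 30, J0 = -0.26, h0 = 1.8)
#' ldd <- phase_params(B = 10, Kt = 10, Ka = 30, J0 = -0.25, h0 = 1.3)
#' geom <- pair_geometry(lod, ldd, D = 5)
#' @export
pair_geometry <- function(domain, background, D,
                          sigma0 = 0.1, grid_spacing = 0.025,
                          half_window = 15) {
  stopifnot(inherits(domain, "phase_params"),
            inherits(background, "phase_params"))
  if (!is.numeric(D) || length(D) != 1L || !is.finite(D) || D < 0) {
    abort("`D` must be a single non-negative number (nm).",
          class = "rafttrap_parameter_error")
  }
  if (grid_spacing <= 0) {
    abort("`grid_spacing` must be positive.",
          class = "rafttrap_parameter_error")
  }
  if (sigma0 < 0) {
    abort("`sigma0` must be non-negative.",
          class = "rafttrap_parameter_error")
  }
  lmax <- max(decay_length(domain), decay_length(background))
  if (half_window < 10 * lmax) {
    abort(sprintf(
      "`half_window` = %g nm is below 10 decay lengths (%.2f nm); enlarge the window.",
      half_window, 10 * lmax), class = "rafttrap_geometry_error")
  }
  structure(list(domain = domain, background = background, D = D,
                 sigma0 = sigma0, grid_spacing = grid_spacing,
                 half_window = half_window),
            class = "pair_geometry")
}

#' @export
print.pair_geometry <- function(x, ...) {
  cat(sprintf("<pair_geometry> D=%g nm, sigma0=%g kBT/nm^2, ds=%g nm, window=%g nm\n",
              x$D, x$sigma0, x$grid_spacing, x$half_window))
  cat("domain:     "); print(x$domain)
  cat("background: "); print(x$background)
  invisible(x)
}

#' Default study phase parameters
#'
#' Elastic parameters of the liquid-ordered (LOD) and liquid-disordered (LDD)
#' phases of the DPhPC:DPPC:Chol:photolipid system: splay moduli 20 and 10
#' \eqn{k_BT}, tilt modulus 10 \eqn{k_BT/\mathrm{nm}^2}, stretching modulus
#' \eqn{K_a} = 30 \eqn{k_BT/\mathrm{nm}^2}, monolayer thicknesses 1.8 and
#' 1.3 nm, and photostate-dependent spontaneous curvatures (trans: LOD
#' \eqn{-0.26}, LDD \eqn{-0.25}; cis: LOD \eqn{-0.2}, LDD \eqn{-0.4}
#' \eqn{\mathrm{nm}^{-1}}).
#'
#' @param photostate `"trans"` or `"cis"` photolipid conformation.
#' @param phase `"LOD"` or `"LDD"`.
#' @param config a run configuration, see [default_run_config()].
#' @return A [phase_params()] object.
#' @examples
#' study_phase("trans", "LOD")
#' @export
study_phase <- function(photostate = c("trans", "cis"),
                        phase = c("LOD", "LDD"),
                        config = default_run_config()) {
  photostate <- match.arg(photostate)
  phase <- match.arg(phase)
  J0 <- config$J0[[photostate]][[phase]]
  if (phase == "LOD") {
    phase_params(B = config$B_o, Kt = config$Kt, Ka = config$Ka, J0 = J0,
                 h0 = config$h_o, K_stretch = config$K_stretch)
  } else {
    phase_params(B = config$B_d, Kt = config$Kt, Ka = config$Ka, J0 = J0,
                 h0 = config$h_d, K_stretch = config$K_stretch)
  }
}

#' Geometry template for a like-phase domain pair of the study system
#'
#' @inheritParams study_phase
#' @param pair `"LOD"` for two ordered domains in disordered background,
#'   `"LDD"` for the converse.
#' @param D gap distance, nm.
#' @return A [pair_geometry()] object.
#' @export
study_pair <- function(photostate = c("trans", "cis"),
                       pair = c("LOD", "LDD"), D = 30,
                       config = default_run_config()) {
  photostate <- match.arg(photostate)
  pair <- match.arg(pair)
  other <- if (pair == "LOD") "LDD" else "LOD"
  pair_geometry(domain = study_phase(photostate, pair, config),
                background = study_phase(photostate, other, config),
                D = D, sigma0 = config$sigma0,
                grid_spacing = config$grid_spacing,
                half_window = config$half_window)
}

#' Unit conversions
#'
#' Convert between the package's thermal units (\eqn{k_BT}, nm) and SI-derived
#' units, with \eqn{k_BT = 4\times10^{-21}} J at room temperature.
#' One \eqn{k_BT/\mathrm{nm}^2} equals 4 mN/m; one \eqn{k_BT/\mathrm{nm}}
#' equals 4 pN.
#'
#' @param x value(s) to convert.
#' @param kbt_joule thermal energy in joules.
#' @return Converted numeric vector.
#' @examples
#' kbt_per_nm2_to_mN_per_m(30)  # stretching modulus 120 mN/m
#' kbt_per_nm2_to_mN_per_m(0.1) # tension 0.4 mN/m
#' @export
kbt_per_nm2_to_mN_per_m <- function(x, kbt_joule = 4e-21) {
  x * kbt_joule * 1e21
}

#' @rdname kbt_per_nm2_to_mN_per_m
#' @export
kbt_per_nm_to_pN <- function(x, kbt_joule = 4e-21) {
  x * kbt_joule * 1e21
}
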