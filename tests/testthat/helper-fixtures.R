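# study-system phase parameters; J0 defaults to the trans state
study_lod <- function(J0 = -0.26, ...) {
  phase_params(B = 20, Kt = 10, Ka = 30, J0 = J0, h0 = 1.8, ...)
}
study_ldd <- function(J0 = -0.25, ...) {
  phase_params(B = 10, Kt = 10, Ka = 30, J0 = J0, h0 = 1.3, ...)
}

# coarse-grid geometry for fast tests; converged to well under 1%
quick_geom <- function(D, domain = study_lod(), background = study_ldd(),
                       grid_spacing = 0.1, ...) {
  pair_geometry(domain, background, D = D, grid_spacing = grid_spacing, ...)
}

# coarse D sweep reaching the 30 nm plateau
quick_D_grid <- function() c(seq(0.5, 10, by = 0.5), seq(12, 30, by = 3))
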