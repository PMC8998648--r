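#' Default gap-distance grid for interaction profiles
#'
#' 0.5 nm steps out to 10 nm where the interaction varies, then 2 nm steps to
#' the 30 nm reference plateau.
#'
#' @return Numeric vector of gap distances, nm.
#' @export
default_D_grid <- function() c(seq(0.5, 10, by = 0.5), seq(12, 30, by = 2))

#' Domain-domain interaction energy profile
#'
#' Sweeps the gap distance `D` and records the minimized bilayer elastic
#' energy per unit boundary length at each distance. The value at the largest
#' distance serves as the zero reference (plateau); it equals twice the
#' single-boundary line tension once the boundaries no longer interact.
#' After the coarse sweep, an optional refinement pass adds finely spaced
#' distances around the coarse maximum so the barrier is located to
#' `refine_step` resolution.
#'
#' @param geom a [pair_geometry()] template; its `D` is ignored.
#' @param D_values ascending gap distances, nm. The largest should be deep in
#'   the non-interacting regime (\eqn{\ge} 20 nm).
#' @param refine add a refinement pass around the coarse interior maximum.
#' @param refine_step,refine_span step (nm) and half-width (nm) of the
#'   refinement pass.
#' @return A tibble of class `energy_profile` with columns `D_nm` and
#'   `E_kBT_per_nm` (whole-system energy: both boundaries, both monolayers)
#'   and attribute `E_plateau` (energy at the largest distance).
#' @examples
#' lod <- phase_params(B = 20, Kt = 10, Ka = 30, J0 = -0.26, h0 = 1.8)
#' ldd <- phase_params(B = 10, Kt = 10, Ka = 30, J0 = -0.25, h0 = 1.3)
#' geom <- pair_geometry(lod, ldd, D = 0, grid_spacing = 0.1)
#' prof <- energy_profile(geom, D_values = c(seq(1, 10, 1), 20, 30),
#'                        refine = FALSE)
#' find_barrier(prof)
#' @export
energy_profile <- function(geom, D_values = default_D_grid(),
                           refine = TRUE, refine_step = 0.1,
                           refine_span = 0.6) {
  stopifnot(inherits(geom, "pair_geometry"))
  if (length(D_values) == 0 || is.unsorted(D_values, strictly = TRUE)) {
    abort("`D_values` must be non-empty and strictly increasing.",
          class = "rafttrap_parameter_error")
  }
  solve_at <- function(D) {
    g <- geom
    g$D <- D
    tryCatch(minimize_energy(g)$W_per_length,
             error = function(e) abort(
               sprintf("energy minimization failed at D = %g nm: %s",
                       D, conditionMessage(e)),
               class = "rafttrap_profile_error"))
  }
  E <- vapply(D_values, solve_at, numeric(1))
  if (refine) {
    i <- which.max(E)
    Dr <- seq(max(min(D_values), D_values[i] - refine_span),
              min(max(D_values), D_values[i] + refine_span),
              by = refine_step)
    Dr <- setdiff(round(Dr, 10), round(D_values, 10))
    if (length(Dr) > 0) {
      Er <- vapply(Dr, solve_at, numeric(1))
      D_values <- c(D_values, Dr)
      E <- c(E, Er)
      o <- order(D_values)
      D_values <- D_values[o]
      E <- E[o]
    }
  }
  out <- tibble(D_nm = D_values, E_kBT_per_nm = E)
  attr(out, "E_plateau") <- E[length(E)]
  class(out) <- c("energy_profile", class(out))
  out
}

#' Extract the fusion-opposing barrier from an interaction profile
#'
#' Finds the interior maximum of the interaction energy profile above its
#' large-distance plateau. By default the barrier is reported per domain:
#' each of the two approaching domains bears half of the excess boundary
#' energy of the pair, and the per-domain value is what enters the merger
#' kinetics. Set `per_domain = FALSE` for the raw whole-system excess.
#' Ties are broken toward the smallest distance. A profile without an
#' interior maximum above the plateau has zero barrier.
#'
#' @param profile an [energy_profile()] (or any data frame with columns
#'   `D_nm`, `E_kBT_per_nm`).
#' @param per_domain report the barrier per domain (half the system excess).
#' @return One-row tibble with `E_B` (\eqn{k_BT/\mathrm{nm}}), `D_star` (nm;
#'   `NA` when `E_B` is 0), `E_plateau` and `per_domain`.
#' @export
find_barrier <- function(profile, per_domain = TRUE) {
  stopifnot(all(c("D_nm", "E_kBT_per_nm") %in% names(profile)))
  D <- profile$D_nm
  E <- profile$E_kBT_per_nm
  plateau <- attr(profile, "E_plateau") %||% E[length(E)]
  m <- length(E)
  interior <- which(E >= c(-Inf, E[-m]) + 0 & E >= c(E[-1], -Inf))
  interior <- setdiff(interior, c(1L, m))
  interior <- interior[E[interior] > plateau + sqrt(.Machine$double.eps)]
  scale <- if (per_domain) 0.5 else 1
  if (length(interior) == 0) {
    return(tibble(E_B = 0, D_star = NA_real_, E_plateau = plateau,
                  per_domain = per_domain))
  }
  best <- interior[which.max(E[interior])]
  # first global maximum: smallest D among exact ties
  ties <- interior[abs(E[interior] - E[best]) <= 0]
  best <- ties[which.min(D[ties])]
  tibble(E_B = scale * (E[best] - plateau), D_star = D[best],
         E_plateau = plateau, per_domain = per_domain)
}

#' @method tidy energy_profile
#' @export
tidy.energy_profile <- function(x, ...) {
  out <- as_tibble(x)
  out$E_rel <- out$E_kBT_per_nm - (attr(x, "E_plateau") %||%
                                     out$E_kBT_per_nm[nrow(out)])
  out
}

#' @method glance energy_profile
#' @export
glance.energy_profile <- function(x, ...) {
  b <- find_barrier(x)
  tibble(n_D = nrow(x), E_plateau = b$E_plateau,
         E_B = b$E_B, D_star = b$D_star)
}

#' Plot an interaction energy profile
#'
#' Interaction energy relative to the large-distance plateau, with the
#' barrier position marked.
#'
#' @param object an [energy_profile()].
#' @param per_domain plot the per-domain energy (half the system energy).
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot energy_profile
#' @export
autoplot.energy_profile <- function(object, per_domain = TRUE, ...) {
  d <- tidy(object)
  scale <- if (per_domain) 0.5 else 1
  d$E <- scale * d$E_rel
  b <- find_barrier(object, per_domain = per_domain)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$D_nm, y = .data$E)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "gap between domain boundaries D (nm)",
      y = if (per_domain) {
        expression(E[TB] - E[plateau] ~ (k[B] * T / nm ~ "per domain"))
      } else {
        expression(E - E[plateau] ~ (k[B] * T / nm))
      })
  if (b$E_B > 0) {
    p <- p + ggplot2::annotate("point", x = b$D_star, y = b$E_B,
                               shape = 1, size = 3)
  }
  p
}
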