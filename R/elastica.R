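# Discretization of the monolayer elastic energy
#
# Per unit length of domain boundary, the monolayer energy density along the
# axis x normal to the boundary is
#
#   w = B/2 (n' + J0)^2 - B/2 J0^2 + Kt/2 (n - H')^2
#       + Ks/2 (alpha - alpha0)^2 + sigma0/2 (H')^2
#
# with director in-plane projection n(x) (directors point from heads to
# tails), neutral-surface height H(x) above the flat bilayer midplane, and
# the relative area change alpha eliminated through linearized volumetric
# incompressibility of the monolayer,
#
#   H = h0 (1 - alpha) - (h0^2/2) n'   =>   alpha = 1 - H/h0 - (h0/2) n'.
#
# alpha0 = sigma0/Ka. The bilayer is mirror-symmetric about a flat midplane,
# so one monolayer is solved and the energy doubled. Fields are linear on
# each grid interval; the energy is the midpoint-rule quadrature of w, which
# makes the discrete energy an exactly quadratic function of the nodal
# unknowns u = (n_1, H_1, n_2, H_2, ...).

# grid with phase interfaces exactly on nodes
build_grid <- function(geom) {
  D <- geom$D
  L <- D / 2 + geom$half_window
  brk <- unique(c(-L, -D / 2, D / 2, L))
  xs <- lapply(seq_len(length(brk) - 1L), function(r) {
    m <- max(1L, round((brk[r + 1L] - brk[r]) / geom$grid_spacing))
    seq(brk[r], brk[r + 1L], length.out = m + 1L)[-(m + 1L)]
  })
  x <- c(unlist(xs), L)
  mid <- (x[-1L] + x[-length(x)]) / 2
  list(x = x, len = diff(x), in_domain = abs(mid) > D / 2)
}

# local 4x4 energy block for one interval: variables (n_i, H_i, n_j, H_j);
# returns l * (Q, g, c) so that the contribution is 1/2 v'Qv + g'v + c
local_block <- function(phase, sigma0, Ka_global, l) {
  a0 <- sigma0 / Ka_global
  cc <- 1 - a0
  Tm <- rbind(c(0.5, 0, 0.5, 0),
              c(0, 0.5, 0, 0.5),
              c(-1 / l, 0, 1 / l, 0),
              c(0, -1 / l, 0, 1 / l))
  e1 <- c(1, 0, 0, 0); e3 <- c(0, 0, 1, 0); e4 <- c(0, 0, 0, 1)
  # alpha - alpha0 = cc - Hm/h0 - (h0/2) n'
  av <- c(0, -1 / phase$h0, -phase$h0 / 2, 0)
  tv <- e1 - e4                                   # tilt t = n - H'
  Qy <- phase$B * tcrossprod(e3) +
    phase$Kt * tcrossprod(tv) +
    phase$K_stretch * tcrossprod(av) +
    sigma0 * tcrossprod(e4)
  gy <- phase$B * phase$J0 * e3 + phase$K_stretch * cc * av
  list(Q = crossprod(Tm, Qy %*% Tm) * l,
       g = as.numeric(crossprod(Tm, gy)) * l,
       c = phase$K_stretch / 2 * cc^2 * l)
}

#' Assemble the discretized quadratic energy of a domain pair
#'
#' Builds the sparse quadratic form \eqn{W(u) = \tfrac12 u^T K u + f^T u + c}
#' equal to the midpoint-rule quadrature of the monolayer elastic energy
#' density over the finite-element grid (see the package vignette for the
#' functional and the incompressibility closure). The unknowns are the nodal
#' director projections and neutral-surface heights, interleaved as
#' \eqn{(n_1, H_1, n_2, H_2, \dots)}, which keeps the matrix banded.
#'
#' @param geom a [pair_geometry()].
#' @return An object of class `membrane_quadratic_form`: a list with the
#'   sparse symmetric matrix `K`, linear term `f`, constant `c`, node
#'   coordinates `x`, the per-interval phase indicator `in_domain`, and the
#'   Dirichlet data `fixed`/`fixed_values` (far-field clamps).
#' @seealso [minimize_energy()], [elastic_energy()]
#' @export
assemble_quadratic_form <- function(geom) {
  stopifnot(inherits(geom, "pair_geometry"))
  grid <- build_grid(geom)
  nn <- length(grid$x)
  ndof <- 2L * nn
  f <- numeric(ndof)
  cst <- 0
  ii <- vector("list", 0L); jj <- vector("list", 0L); vv <- vector("list", 0L)
  # intervals share a block within groups of equal (phase, length)
  key <- paste(grid$in_domain, signif(grid$len, 12))
  for (k in unique(key)) {
    idx <- which(key == k)
    phase <- if (grid$in_domain[idx[1L]]) geom$domain else geom$background
    blk <- local_block(phase, geom$sigma0, phase$Ka, grid$len[idx[1L]])
    base <- 2L * (idx - 1L)
    for (a in 1:4) {
      f[base + a] <- f[base + a] + blk$g[a]
      ii <- c(ii, list(rep(base + a, each = 4L) + 0L))
      jj <- c(jj, list(as.integer(outer(1:4, base, `+`))))
      vv <- c(vv, list(rep(blk$Q[a, ], times = length(idx))))
    }
    cst <- cst + blk$c * length(idx)
  }
  K <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(vv),
                            dims = c(ndof, ndof))
  a0 <- geom$sigma0 / geom$domain$Ka
  Hff <- geom$domain$h0 * (1 - a0)
  structure(list(K = K, f = f, c = cst, x = grid$x,
                 in_domain = grid$in_domain,
                 fixed = c(1L, 2L, ndof - 1L, ndof),
                 fixed_values = c(0, Hff, 0, Hff),
                 geom = geom),
            class = "membrane_quadratic_form")
}

# evaluate 2 * (1/2 u'Ku + f'u + c) for nodal fields (both monolayers)
qf_energy <- function(qf, n, H) {
  u <- numeric(length(qf$f))
  u[seq(1L, length(u), by = 2L)] <- n
  u[seq(2L, length(u), by = 2L)] <- H
  2 * (0.5 * sum(u * as.numeric(qf$K %*% u)) + sum(qf$f * u) + qf$c)
}

#' Elastic energy of a trial deformation by direct quadrature
#'
#' Evaluates the bilayer elastic energy per unit boundary length of arbitrary
#' nodal fields `n` (director projection) and `H` (neutral-surface height,
#' nm) by direct midpoint-rule quadrature of the energy density, without
#' forming the assembled quadratic form. Used as an independent check of
#' [assemble_quadratic_form()].
#'
#' @param geom a [pair_geometry()].
#' @param n,H numeric vectors of nodal values, one per grid node (see the
#'   `x` element of [assemble_quadratic_form()] for node positions).
#' @return Energy in \eqn{k_BT/\mathrm{nm}} (both monolayers, relative to the
#'   unperturbed far-field reference).
#' @export
elastic_energy <- function(geom, n, H) {
  stopifnot(inherits(geom, "pair_geometry"))
  grid <- build_grid(geom)
  nn <- length(grid$x)
  if (length(n) != nn || length(H) != nn) {
    abort(sprintf("`n` and `H` must have one value per grid node (%d).", nn),
          class = "rafttrap_parameter_error")
  }
  nm <- (n[-1L] + n[-nn]) / 2
  Hm <- (H[-1L] + H[-nn]) / 2
  np <- diff(n) / grid$len
  Hp <- diff(H) / grid$len
  dom <- geom$domain; bg <- geom$background
  B <- ifelse(grid$in_domain, dom$B, bg$B)
  J0 <- ifelse(grid$in_domain, dom$J0, bg$J0)
  h0 <- ifelse(grid$in_domain, dom$h0, bg$h0)
  Ks <- ifelse(grid$in_domain, dom$K_stretch, bg$K_stretch)
  Ka <- ifelse(grid$in_domain, dom$Ka, bg$Ka)
  a0 <- geom$sigma0 / Ka
  alpha <- 1 - Hm / h0 - (h0 / 2) * np
  w <- B / 2 * (np + J0)^2 - B / 2 * J0^2 +
    ifelse(grid$in_domain, dom$Kt, bg$Kt) / 2 * (nm - Hp)^2 +
    Ks / 2 * (alpha - a0)^2 +
    geom$sigma0 / 2 * Hp^2
  2 * sum(w * grid$len)
}

#' Minimize the elastic energy at fixed gap distance
#'
#' Solves the discrete Euler–Lagrange (stationarity) system of the assembled
#' quadratic energy with far-field Dirichlet conditions (director normal to
#' the membrane, neutral surface at the tension-relaxed thickness of the
#' outer phase), by a sparse banded solve. The reported energy is for the
#' whole mirror-symmetric bilayer: twice the monolayer minimum, covering both
#' facing domain boundaries.
#'
#' @param geom a [pair_geometry()].
#' @param dense use a dense LU solve of the same stationarity system instead
#'   of the sparse banded route (reference path for small grids).
#' @return An object of class `energy_result`: a list with `W_per_length`
#'   (\eqn{k_BT/\mathrm{nm}}, \eqn{\ge 0}), `D`, and `state`, a tibble of the
#'   minimizing deformation fields with columns `x_nm`, `n`, `H_nm`, `t`
#'   (tilt \eqn{t = n - H'}), `alpha`, `alpha0` and `phase`.
#' @examples
#' lod <- phase_params(B = 20, Kt = 10, Ka = 30, J0 = -0.26, h0 = 1.8)
#' ldd <- phase_params(B = 10, Kt = 10, Ka = 30, J0 = -0.25, h0 = 1.3)
#' res <- minimize_energy(pair_geometry(lod, ldd, D = 5, grid_spacing = 0.1))
#' res$W_per_length
#' @export
minimize_energy <- function(geom, dense = FALSE) {
  qf <- assemble_quadratic_form(geom)
  ndof <- length(qf$f)
  free <- setdiff(seq_len(ndof), qf$fixed)
  u <- numeric(ndof)
  u[qf$fixed] <- qf$fixed_values
  rhs <- -(qf$f[free] + as.numeric(qf$K[free, qf$fixed] %*% qf$fixed_values))
  Kff <- qf$K[free, free]
  sol <- if (dense) {
    tryCatch(solve(as.matrix(Kff), rhs),
             error = function(e) abort(
               paste0("degenerate elastic system: ", conditionMessage(e)),
               class = "rafttrap_numerical_error"))
  } else {
    tryCatch(as.numeric(Matrix::solve(Kff, rhs)),
             error = function(e) abort(
               paste0("degenerate elastic system: ", conditionMessage(e)),
               class = "rafttrap_numerical_error"))
  }
  if (any(!is.finite(sol))) {
    abort("elastic solve produced non-finite fields.",
          class = "rafttrap_numerical_error")
  }
  u[free] <- sol
  W <- 2 * (0.5 * sum(u * as.numeric(qf$K %*% u)) + sum(qf$f * u) + qf$c)
  n <- u[seq(1L, ndof, by = 2L)]
  H <- u[seq(2L, ndof, by = 2L)]
  x <- qf$x
  nn <- length(x)
  Hp <- c(diff(H[1:2]) / diff(x[1:2]),
          (H[-(1:2)] - H[1:(nn - 2L)]) / (x[-(1:2)] - x[1:(nn - 2L)]),
          diff(H[(nn - 1L):nn]) / diff(x[(nn - 1L):nn]))
  np <- c(diff(n[1:2]) / diff(x[1:2]),
          (n[-(1:2)] - n[1:(nn - 2L)]) / (x[-(1:2)] - x[1:(nn - 2L)]),
          diff(n[(nn - 1L):nn]) / diff(x[(nn - 1L):nn]))
  in_dom_node <- abs(x) > geom$D / 2 | abs(abs(x) - geom$D / 2) < 1e-12
  h0 <- ifelse(in_dom_node, geom$domain$h0, geom$background$h0)
  Ka <- ifelse(in_dom_node, geom$domain$Ka, geom$background$Ka)
  state <- tibble(
    x_nm = x, n = n, H_nm = H, t = n - Hp,
    alpha = 1 - H / h0 - (h0 / 2) * np,
    alpha0 = geom$sigma0 / Ka,
    phase = ifelse(in_dom_node, "domain", "background"))
  structure(list(W_per_length = W, D = geom$D, state = state, geom = geom),
            class = "energy_result")
}

#' @export
print.energy_result <- function(x, ...) {
  cat(sprintf("<energy_result> D = %g nm, W = %.6g kBT/nm (bilayer, both boundaries)\n",
              x$D, x$W_per_length))
  invisible(x)
}

#' @method tidy energy_result
#' @export
tidy.energy_result <- function(x, ...) x$state

#' @method glance energy_result
#' @export
glance.energy_result <- function(x, ...) {
  tibble(D_nm = x$D, W_per_length = x$W_per_length,
         n_nodes = nrow(x$state))
}

#' Elastic line tension of a single phase boundary
#'
#' Energy per unit length of one isolated domain/background boundary (the
#' mechanical component of the line tension), computed from a single-interface
#' boundary-value problem. Equals half the large-gap plateau of
#' [minimize_energy()], which contains two such boundaries.
#'
#' @inheritParams pair_geometry
#' @return Line tension, \eqn{k_BT/\mathrm{nm}} (non-negative).
#' @examples
#' lod <- phase_params(B = 20, Kt = 10, Ka = 30, J0 = -0.26, h0 = 1.8)
#' ldd <- phase_params(B = 10, Kt = 10, Ka = 30, J0 = -0.25, h0 = 1.3)
#' single_boundary_energy(lod, ldd, grid_spacing = 0.1)
#' @export
single_boundary_energy <- function(domain, background, sigma0 = 0.1,
                                   grid_spacing = 0.025, half_window = 15) {
  # a wide-gap pair has two non-interacting boundaries
  geom <- pair_geometry(domain, background,
                        D = 2 * half_window, sigma0 = sigma0,
                        grid_spacing = grid_spacing,
                        half_window = half_window)
  minimize_energy(geom)$W_per_length / 2
}
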