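#' Spontaneous curvatures of the mixture components
#'
#' Per-species monolayer spontaneous curvatures (\eqn{\mathrm{nm}^{-1}}):
#' cholesterol \eqn{-0.37}, DPPC \eqn{+0.07}, DPhPC \eqn{-0.2}, and the
#' photolipid at \eqn{-0.2} (near-cylindrical trans conformer) or \eqn{-1}
#' (cone-shaped cis conformer).
#'
#' @param DPhPC,DPPC,Chol,PhoDAG_trans,PhoDAG_cis override individual values.
#' @return Tibble with columns `species` and `J0_nm1`.
#' @export
curvature_table <- function(DPhPC = -0.2, DPPC = 0.07, Chol = -0.37,
                            PhoDAG_trans = -0.2, PhoDAG_cis = -1) {
  tibble(species = c("DPhPC", "DPPC", "Chol", "PhoDAG_trans", "PhoDAG_cis"),
         J0_nm1 = c(DPhPC, DPPC, Chol, PhoDAG_trans, PhoDAG_cis))
}

#' Parse a mole-ratio string
#'
#' @param x ratio string such as `"2:1:2:1"`, or a numeric vector of ratios.
#' @return Normalized numeric fractions summing to 1.
#' @examples
#' parse_ratio("2:1:2:1")
#' @export
parse_ratio <- function(x) {
  if (is.character(x)) {
    stopifnot(length(x) == 1L)
    x <- as.numeric(strsplit(x, ":", fixed = TRUE)[[1L]])
  }
  if (any(is.na(x)) || any(x < 0) || sum(x) <= 0) {
    abort("ratios must be non-negative numbers with a positive sum.",
          class = "rafttrap_parameter_error")
  }
  x / sum(x)
}

quaternary_species <- c("DPhPC", "DPPC", "Chol", "PhoDAG")
ternary_species <- c("DPhPC_like", "DPPC_like", "Chol")

#' Coerce to a quaternary composition
#'
#' A quaternary composition holds the mole fractions of DPhPC, DPPC,
#' cholesterol and photolipid, in that order, normalized to sum to 1.
#'
#' @param x a ratio string (`"2:1:2:1"`), numeric vector of length 4 (ratios,
#'   fractions or percentages), or a named numeric vector using the species
#'   names.
#' @return Named numeric vector of fractions (`DPhPC`, `DPPC`, `Chol`,
#'   `PhoDAG`).
#' @examples
#' as_quaternary("2:1:2:1")
#' @export
as_quaternary <- function(x) {
  v <- parse_ratio(x)
  if (length(v) != 4L) {
    abort("a quaternary composition needs 4 components.",
          class = "rafttrap_parameter_error")
  }
  if (!is.null(names(v)) && all(quaternary_species %in% names(v))) {
    v <- v[quaternary_species]
  }
  setNames(as.numeric(v), quaternary_species)
}

#' @rdname as_quaternary
#' @export
as_ternary <- function(x) {
  v <- parse_ratio(x)
  if (length(v) != 3L) {
    abort("a ternary composition needs 3 components.",
          class = "rafttrap_parameter_error")
  }
  if (!is.null(names(v)) && all(ternary_species %in% names(v))) {
    v <- v[ternary_species]
  }
  setNames(as.numeric(v), ternary_species)
}

check_photostate <- function(photostate) {
  if (!is.character(photostate) || length(photostate) != 1L ||
      !photostate %in% c("trans", "cis")) {
    abort('`photostate` must be "trans" or "cis".',
          class = "rafttrap_parameter_error")
  }
  photostate
}

#' Fold a quaternary mixture onto the ternary phase diagram
#'
#' The photolipid packs like DPPC in its trans conformation and like DPhPC in
#' its cis conformation, so for phase-diagram purposes its mole fraction is
#' pooled with the corresponding lipid. Totals are conserved.
#'
#' @param overall quaternary composition (see [as_quaternary()]).
#' @param photostate `"trans"` or `"cis"`.
#' @return Named ternary fractions (`DPhPC_like`, `DPPC_like`, `Chol`).
#' @examples
#' effective_ternary("2:1:2:1", "trans")  # 1:1:1
#' effective_ternary("2:1:2:1", "cis")    # 3:1:2
#' @export
effective_ternary <- function(overall, photostate) {
  q <- as_quaternary(overall)
  check_photostate(photostate)
  if (photostate == "trans") {
    t3 <- c(q[["DPhPC"]], q[["DPPC"]] + q[["PhoDAG"]], q[["Chol"]])
  } else {
    t3 <- c(q[["DPhPC"]] + q[["PhoDAG"]], q[["DPPC"]], q[["Chol"]])
  }
  setNames(t3, ternary_species)
}

#' Unfold a ternary phase composition into the quaternary mixture
#'
#' Given the ternary composition of one phase (a tie-line endpoint on the
#' DPhPC/DPPC/Chol diagram) and the overall quaternary mixture, splits the
#' pooled component back into lipid + photolipid assuming equal distribution
#' coefficients between the phases for the photolipid and its packing
#' analogue (DPPC in trans, DPhPC in cis).
#'
#' @param phase_ternary ternary composition of the phase
#'   (see [as_ternary()]).
#' @inheritParams effective_ternary
#' @return Named quaternary fractions summing to 1.
#' @examples
#' quaternary_phase_composition(c(3.5, 57, 39.5), "2:1:2:1", "trans")
#' @export
quaternary_phase_composition <- function(phase_ternary, overall, photostate) {
  t3 <- as_ternary(phase_ternary)
  q <- as_quaternary(overall)
  check_photostate(photostate)
  if (photostate == "trans") {
    pool <- q[["DPPC"]] + q[["PhoDAG"]]
    if (pool == 0 && q[["PhoDAG"]] > 0) {
      abort("overall DPPC-like pool is empty but PhoDAG is present.",
            class = "rafttrap_composition_error")
    }
    share <- if (pool > 0) q[["PhoDAG"]] / pool else 0
    out <- c(t3[["DPhPC_like"]],
             t3[["DPPC_like"]] * (1 - share),
             t3[["Chol"]],
             t3[["DPPC_like"]] * share)
  } else {
    pool <- q[["DPhPC"]] + q[["PhoDAG"]]
    if (pool == 0 && q[["PhoDAG"]] > 0) {
      abort("overall DPhPC-like pool is empty but PhoDAG is present.",
            class = "rafttrap_composition_error")
    }
    share <- if (pool > 0) q[["PhoDAG"]] / pool else 0
    out <- c(t3[["DPhPC_like"]] * (1 - share),
             t3[["DPPC_like"]],
             t3[["Chol"]],
             t3[["DPhPC_like"]] * share)
  }
  setNames(out, quaternary_species)
}

#' Composition-weighted spontaneous curvature
#'
#' Mole-fraction-weighted average of the component spontaneous curvatures,
#' using the photostate-appropriate photolipid entry.
#'
#' @param comp quaternary composition (see [as_quaternary()]).
#' @inheritParams effective_ternary
#' @param curvatures a [curvature_table()].
#' @return Weighted \eqn{J_0}, \eqn{\mathrm{nm}^{-1}}.
#' @examples
#' mean_spontaneous_curvature(c(45, 8, 25, 22), "cis")  # approx -0.4
#' @export
mean_spontaneous_curvature <- function(comp, photostate,
                                       curvatures = curvature_table()) {
  q <- as_quaternary(comp)
  check_photostate(photostate)
  j <- setNames(curvatures$J0_nm1, curvatures$species)
  dag <- if (photostate == "trans") j[["PhoDAG_trans"]] else j[["PhoDAG_cis"]]
  sum(q * c(j[["DPhPC"]], j[["DPPC"]], j[["Chol"]], dag))
}

#' Ternary tie-line endpoint compositions (synthetic fixture)
#'
#' Ternary compositions of the coexisting phases for the study mixture, one
#' per photostate and phase. These are not digitized from a phase diagram:
#' they are back-computed from the published quaternary phase compositions by
#' pooling the photolipid with its packing analogue, and serve as a packaged
#' stand-in for tie-line endpoints of the DPhPC/DPPC/Chol diagram.
#'
#' @return Tibble with columns `photostate`, `phase`, `DPhPC_like`,
#'   `DPPC_like`, `Chol` (fractions summing to 1 per row).
#' @export
tie_line_compositions <- function() {
  path <- system.file("extdata", "tie_lines_backcomputed.csv",
                      package = "rafttrap", mustWork = TRUE)
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Phase compositions and weighted curvatures of the study mixture
#'
#' Runs the composition workflow for both phases of one photostate: tie-line
#' ternary endpoints are unfolded into quaternary compositions of the
#' coexisting liquid-ordered and liquid-disordered phases, and the
#' composition-weighted spontaneous curvature of each phase is computed.
#'
#' @param photostate `"trans"` or `"cis"`.
#' @param overall overall quaternary mixture (default 2:1:2:1
#'   DPhPC:DPPC:Chol:PhoDAG).
#' @param tie_lines tie-line endpoints, see [tie_line_compositions()].
#' @param curvatures a [curvature_table()].
#' @return Tibble with one row per phase: mole fractions of the four species
#'   and the weighted `J0_nm1`.
#' @examples
#' phase_curvatures("cis")
#' @export
phase_curvatures <- function(photostate, overall = "2:1:2:1",
                             tie_lines = tie_line_compositions(),
                             curvatures = curvature_table()) {
  check_photostate(photostate)
  tl <- dplyr::filter(tie_lines, .data$photostate == !!photostate)
  purrr::pmap_dfr(tl, function(photostate, phase, DPhPC_like, DPPC_like,
                               Chol, ...) {
    q <- quaternary_phase_composition(
      c(DPhPC_like, DPPC_like, Chol), overall, photostate)
    tibble(photostate = photostate, phase = phase,
           DPhPC = q[["DPhPC"]], DPPC = q[["DPPC"]], Chol = q[["Chol"]],
           PhoDAG = q[["PhoDAG"]],
           J0_nm1 = mean_spontaneous_curvature(q, photostate, curvatures))
  })
}
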