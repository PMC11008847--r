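#' Model parameters
#'
#' Construct the full parameter set of the deformable-polygon model in
#' non-dimensional units. The defaults are the standard non-dimensionalized
#' values used throughout: preferred area `A0 = 1` (about 100 um^2 for an
#' MDCK cross-section, so one model length unit corresponds to 10 um), area
#' stiffness `k_A = 1`, cortical stiffness `k_L = 5e-4`, cell-cell adhesion
#' `gamma_cc = 1e-3`, cell-cell repulsion `R_cc = 0.05`, cell-substrate
#' adhesion `gamma_cs = 0.1`, interaction distances `d_cc = 0.16`,
#' `d_cs = 0.1`, rest lengths `l_cc = l_cs = 5e-3`, spreading strength
#' `C_s = 8e-3` and gravity `C_G = 1e-3`.
#'
#' Time is integrated with an explicit Euler step `dt = 1` under overdamped
#' dynamics `F = beta * v`; 750 steps correspond to one hour in culture.
#' `beta` only rescales time jointly with `dt` and defaults to 1.
#'
#' The active spreading force can be held `"constant"`, scaled `"linear"`ly
#' with `gamma_cs / gamma_cs_ref`, or `"nonlinear"`ly as
#' `(gamma_cs / gamma_cs_ref)^spreading_exponent` (exponent 0.2). Spreading
#' activates once `activation_fraction` (10%) of a cell's nodes touch the
#' substrate. On cell-cell contact the adhesion feedback multiplies
#' `gamma_cc` by `1 + fb_cc_per_bond * N_sub` (0.03 per substrate bond),
#' `gamma_cs` by `fb_cs_factor` (1.5) and `d_cc` by `fb_dcc_factor` (1.2).
#' A layer is classified Intermediate once the mean cell-cell connection
#' fraction reaches `cc_threshold` (0.10).
#'
#' @param A0 preferred cross-sectional area (model area units).
#' @param k_A area stiffness.
#' @param k_L cortical (perimeter) stiffness.
#' @param gamma_cc cell-cell adhesion strength.
#' @param R_cc cell-cell repulsion strength (used below `l_cc`).
#' @param gamma_cs cell-substrate adhesion strength.
#' @param d_cc,d_cs maximum interaction distances for cell-cell and
#'   cell-substrate springs.
#' @param l_cc,l_cs rest lengths of cell-cell and cell-substrate springs.
#' @param C_s active spreading force magnitude.
#' @param C_G gravitational force magnitude per node.
#' @param beta viscous drag coefficient.
#' @param dt integration timestep.
#' @param steps_per_hour calibration between timesteps and culture hours.
#' @param spreading_mode one of `"constant"`, `"linear"`, `"nonlinear"`.
#' @param gamma_cs_ref reference cell-substrate adhesion used by the scaled
#'   spreading modes.
#' @param spreading_exponent exponent of the nonlinear spreading scaling.
#' @param activation_fraction fraction of nodes that must contact the
#'   substrate before active spreading starts.
#' @param fb_cc_per_bond,fb_cs_factor,fb_dcc_factor adhesion feedback
#'   coefficients applied on cell-cell contact.
#' @param cc_threshold mean cell-cell connection fraction at which a layer
#'   is classified Intermediate.
#' @param ... unused; present so partially-specified parameter lists can be
#'   spliced with `do.call()`.
#'
#' @return An object of class `"model_params"` (a named list).
#' @examples
#' p <- model_params()
#' p$gamma_cs
#' p2 <- model_params(gamma_cc = 1e-5) # weak cell-cell adhesion
#' @export
model_params <- function(A0 = 1,
                         k_A = 1,
                         k_L = 5e-4,
                         gamma_cc = 1e-3,
                         R_cc = 0.05,
                         gamma_cs = 0.1,
                         d_cc = 0.16,
                         d_cs = 0.1,
                         l_cc = 5e-3,
                         l_cs = 5e-3,
                         C_s = 8e-3,
                         C_G = 1e-3,
                         beta = 1,
                         dt = 1,
                         steps_per_hour = 750,
                         spreading_mode = c("constant", "linear", "nonlinear"),
                         gamma_cs_ref = 0.1,
                         spreading_exponent = 0.2,
                         activation_fraction = 0.10,
                         fb_cc_per_bond = 0.03,
                         fb_cs_factor = 1.5,
                         fb_dcc_factor = 1.2,
                         cc_threshold = 0.10,
                         ...) {
  spreading_mode <- match.arg(spreading_mode)
  p <- list(
    A0 = A0, k_A = k_A, k_L = k_L,
    gamma_cc = gamma_cc, R_cc = R_cc, gamma_cs = gamma_cs,
    d_cc = d_cc, d_cs = d_cs, l_cc = l_cc, l_cs = l_cs,
    C_s = C_s, C_G = C_G, beta = beta, dt = dt,
    steps_per_hour = steps_per_hour,
    spreading_mode = spreading_mode,
    gamma_cs_ref = gamma_cs_ref,
    spreading_exponent = spreading_exponent,
    activation_fraction = activation_fraction,
    fb_cc_per_bond = fb_cc_per_bond,
    fb_cs_factor = fb_cs_factor,
    fb_dcc_factor = fb_dcc_factor,
    cc_threshold = cc_threshold
  )
  validate_model_params(p)
  structure(p, class = "model_params")
}

validate_model_params <- function(p) {
  num <- c("A0", "k_A", "k_L", "gamma_cc", "R_cc", "gamma_cs", "d_cc",
           "d_cs", "l_cc", "l_cs", "C_s", "C_G", "beta", "dt",
           "steps_per_hour", "gamma_cs_ref", "spreading_exponent",
           "activation_fraction", "fb_cc_per_bond", "fb_cs_factor",
           "fb_dcc_factor", "cc_threshold")
  for (nm in num) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a finite numeric scalar",
           call. = FALSE)
  }
  nonneg <- c("A0", "k_A", "k_L", "gamma_cc", "R_cc", "gamma_cs", "d_cc",
              "d_cs", "l_cc", "l_cs", "C_s", "C_G")
  for (nm in nonneg)
    if (p[[nm]] < 0) stop("parameter '", nm, "' must be >= 0", call. = FALSE)
  if (p$d_cc <= p$l_cc) stop("d_cc must exceed l_cc", call. = FALSE)
  if (p$d_cs <= p$l_cs) stop("d_cs must exceed l_cs", call. = FALSE)
  if (p$dt <= 0) stop("dt must be positive", call. = FALSE)
  if (p$beta <= 0) stop("beta must be positive", call. = FALSE)
  invisible(p)
}

#' @export
print.model_params <- function(x, ...) {
  cat("Deformable-polygon model parameters (non-dimensional):\n")
  flat <- unlist(x[!vapply(x, is.character, logical(1))])
  print(flat)
  cat("spreading_mode:", x$spreading_mode, "\n")
  invisible(x)
}

#' Convert non-dimensional parameters or lengths to dimensional units
#'
#' The non-dimensionalization is anchored by the typical MDCK cross-sectional
#' area of ~100 um^2, i.e. one model length unit is 10 um (1e-2 mm). Adhesion
#' and cortical strengths map through the reference stiffness so that the
#' standard non-dimensional `gamma_cs = 0.1` corresponds to 20 N/m and
#' `gamma_cc = 1e-3` to 0.2 N/m (strength unit: 200 N/m per model unit).
#'
#' @param length,area,strength non-dimensional values to convert (any may be
#'   vectors); supply only those needed.
#' @return A named list with the converted values: `length_um`, `area_um2`,
#'   `strength_N_per_m` (only the requested entries).
#' @examples
#' dimensional_units(strength = 0.1)$strength_N_per_m # 20 N/m
#' dimensional_units(length = 4.78)$length_um         # 47.8 um
#' @export
dimensional_units <- function(length = NULL, area = NULL, strength = NULL) {
  out <- list()
  if (!is.null(length)) out$length_um <- length * 10
  if (!is.null(area)) out$area_um2 <- area * 100
  if (!is.null(strength)) out$strength_N_per_m <- strength * 200
  out
}
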