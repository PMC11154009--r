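#' State variable names of the MPN model
#'
#' The eight compartments: healthy stem (`x0`), progenitor (`x1`) and mature
#' (`x2`) cells, their malignant (JAK2-mutant) counterparts (`y0`, `y1`,
#' `y2`), cellular debris (`a`) and the lumped cytokine signal (`s`). All are
#' dimensionless total counts / levels.
#'
#' @return Character vector of length 8.
#' @export
mpn_state_names <- function() {
  c("x0", "x1", "x2", "y0", "y1", "y2", "a", "s")
}

#' Construct a validated system state
#'
#' @param x0,x1,x2 Healthy stem / progenitor / mature cell counts.
#' @param y0,y1,y2 Malignant stem / progenitor / mature cell counts.
#' @param a Cellular debris level.
#' @param s Cytokine signal level.
#' @return Named numeric vector of length 8 in canonical order.
#' @export
mpn_state <- function(x0 = 0, x1 = 0, x2 = 0, y0 = 0, y1 = 0, y2 = 0,
                      a = 0, s = 0) {
  st <- c(x0 = x0, x1 = x1, x2 = x2, y0 = y0, y1 = y1, y2 = y2, a = a, s = s)
  if (anyNA(st) || any(!is.finite(st))) {
    stop("state components must be finite", call. = FALSE)
  }
  if (any(st < 0)) {
    stop("state components must be non-negative", call. = FALSE)
  }
  st
}

#' Stem-cell niche crowding feedback
#'
#' Occupancy feedback on stem-cell self-renewal modelling competition for
#' the bone-marrow niche: `1 / (1 + c_xx * x0 + c_xy * y0)` for the healthy
#' lineage and `1 / (1 + c_yx * x0 + c_yy * y0)` for the malignant one.
#' Strictly decreasing in both stem-cell counts, with value 1 in an empty
#' niche.
#'
#' @param kind `"healthy"` or `"malignant"`.
#' @param x0,y0 Healthy and malignant stem-cell counts, >= 0. Vectorised.
#' @param params An `mpn_params` object.
#' @return Crowding factor(s) in (0, 1].
#' @examples
#' crowding_phi("healthy", 9.9e4, 0, mpn_params())
#' @export
crowding_phi <- function(kind = c("healthy", "malignant"), x0, y0, params) {
  kind <- match.arg(kind)
  stopifnot(inherits(params, "mpn_params"))
  if (any(!is.finite(x0)) || any(!is.finite(y0)) ||
      any(x0 < 0) || any(y0 < 0)) {
    stop("stem-cell counts must be finite and non-negative", call. = FALSE)
  }
  if (kind == "healthy") {
    1 / (1 + params$c_xx * x0 + params$c_xy * y0)
  } else {
    1 / (1 + params$c_yx * x0 + params$c_yy * y0)
  }
}

#' Right-hand side of the MPN model
#'
#' Rates of change (per day) of the eight compartments. Stem cells divide at
#' rate `alpha`, each division either self-renewing (probability
#' `p * phi * s / (s_half + s)`, modulated by niche crowding and cytokine
#' saturation) or differentiating; differentiating divisions feed the
#' progenitor pool through the amplification factor with the division factor
#' 2, i.e. influx `2 * A * alpha * (1 - p * phi * s/(s_half + s)) * n`.
#' Progenitors behave analogously with constant self-renewal and death;
#' mature cells are produced by progenitor differentiation and die. Dead
#' cells accumulate as debris cleared proportionally to the cytokine level;
#' the cytokine is produced from debris, degraded, and driven by the
#' external inflammatory load `I`.
#'
#' The treated system is obtained by passing `effective_parameters()` output:
#' treatment acts purely through the two affected constants.
#'
#' This pure-R evaluation is the reference implementation used for Jacobians
#' and residual checks; time integration uses an identical compiled version.
#'
#' @param state Named state vector as from [mpn_state()].
#' @param params An `mpn_params` object.
#' @return Named numeric vector of 8 derivatives, per day.
#' @export
mpn_rhs <- function(state, params) {
  stopifnot(inherits(params, "mpn_params"))
  if (length(state) != 8L) stop("state must have 8 components", call. = FALSE)
  if (anyNA(state) || any(!is.finite(state))) {
    stop("state components must be finite", call. = FALSE)
  }
  st <- as.numeric(state)
  x0 <- st[1]; x1 <- st[2]; x2 <- st[3]
  y0 <- st[4]; y1 <- st[5]; y2 <- st[6]
  a <- st[7]; s <- st[8]
  p <- params

  phi_x <- 1 / (1 + p$c_xx * x0 + p$c_xy * y0)
  phi_y <- 1 / (1 + p$c_yx * x0 + p$c_yy * y0)
  rx <- p$p_x0 * phi_x * s / (p$s_x0 + s)
  ry <- p$p_y0 * phi_y * s / (p$s_y0 + s)

  d <- c(
    x0 = p$alpha_x0 * (2 * rx - 1) * x0,
    x1 = p$alpha_x1 * (2 * p$p_x1 - 1) * x1 +
      2 * p$A_x0 * p$alpha_x0 * (1 - rx) * x0 - p$d_x1 * x1,
    x2 = 2 * p$A_x1 * p$alpha_x1 * (1 - p$p_x1) * x1 - p$d_x2 * x2,
    y0 = p$alpha_y0 * (2 * ry - 1) * y0,
    y1 = p$alpha_y1 * (2 * p$p_y1 - 1) * y1 +
      2 * p$A_y0 * p$alpha_y0 * (1 - ry) * y0 - p$d_y1 * y1,
    y2 = 2 * p$A_y1 * p$alpha_y1 * (1 - p$p_y1) * y1 - p$d_y2 * y2,
    a = p$d_x1 * x1 + p$d_y1 * y1 + p$d_x2 * x2 + p$d_y2 * y2 - p$e_a * a * s,
    s = p$r_s * a - p$e_s * s + p$I
  )
  d
}

# Per-component flux scale: the sum of absolute values of the individual
# terms entering each equation. Used to normalise steady-state residuals,
# since the compartments span ~12 orders of magnitude.
rhs_flux_scale <- function(state, params) {
  st <- as.numeric(state)
  x0 <- st[1]; x1 <- st[2]; x2 <- st[3]
  y0 <- st[4]; y1 <- st[5]; y2 <- st[6]
  a <- st[7]; s <- st[8]
  p <- params
  phi_x <- 1 / (1 + p$c_xx * x0 + p$c_xy * y0)
  phi_y <- 1 / (1 + p$c_yx * x0 + p$c_yy * y0)
  rx <- p$p_x0 * phi_x * s / (p$s_x0 + s)
  ry <- p$p_y0 * phi_y * s / (p$s_y0 + s)
  c(
    x0 = p$alpha_x0 * (2 * rx + 1) * x0,
    x1 = abs(p$alpha_x1 * (2 * p$p_x1 - 1)) * x1 +
      2 * p$A_x0 * p$alpha_x0 * (1 + rx) * x0 + p$d_x1 * x1,
    x2 = 2 * p$A_x1 * p$alpha_x1 * (1 - p$p_x1) * x1 + p$d_x2 * x2,
    y0 = p$alpha_y0 * (2 * ry + 1) * y0,
    y1 = abs(p$alpha_y1 * (2 * p$p_y1 - 1)) * y1 +
      2 * p$A_y0 * p$alpha_y0 * (1 + ry) * y0 + p$d_y1 * y1,
    y2 = 2 * p$A_y1 * p$alpha_y1 * (1 - p$p_y1) * y1 + p$d_y2 * y2,
    a = p$d_x1 * x1 + p$d_y1 * y1 + p$d_x2 * x2 + p$d_y2 * y2 +
      p$e_a * abs(a) * abs(s),
    s = p$r_s * abs(a) + p$e_s * abs(s) + p$I
  )
}

#' JAK2 variant allele frequency readout
#'
#' The model's observable: the fraction of mature blood cells belonging to
#' the mutant clone, `y2 / (x2 + y2)`, which equals the measured VAF under
#' the assumption that all mutant cells are homozygous.
#'
#' @param x2,y2 Healthy and malignant mature cell counts. Vectorised.
#' @return VAF estimate(s) in \[0, 1\].
#' @examples
#' vaf_readout(6.3e11, 6.3e11)
#' @export
vaf_readout <- function(x2, y2) {
  if (any(!is.finite(x2)) || any(!is.finite(y2))) {
    stop("cell counts must be finite", call. = FALSE)
  }
  tot <- x2 + y2
  if (any(tot <= 0)) {
    stop("VAF undefined: total mature cell count is zero", call. = FALSE)
  }
  y2 / tot
}

#' Minimum homozygous fraction implied by a VAF measurement
#'
#' If all cells carry the mutation and a fraction `h` of them is homozygous,
#' the VAF is `V = (1 - h)/2 + h = (1 + h)/2`. Inverting gives the lower
#' bound `h = 2 V - 1` on the homozygous fraction: fewer mutated cells would
#' require an even larger homozygous share to produce the same VAF.
#'
#' @param V VAF in \[0.5, 1\]. Vectorised.
#' @return Minimum homozygous fraction(s) in \[0, 1\].
#' @examples
#' homozygous_fraction_bound(0.76)
#' @export
homozygous_fraction_bound <- function(V) {
  if (any(!is.finite(V)) || any(V < 0.5) || any(V > 1)) {
    stop("bound defined only for VAF in [0.5, 1]", call. = FALSE)
  }
  2 * V - 1
}
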