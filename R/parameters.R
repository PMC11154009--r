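#' Canonical parameter ordering of the MPN model
#'
#' The 26 rate and feedback constants of the model, in the fixed order used
#' by the compiled right-hand side. Naming follows the field's convention:
#' `alpha_*` proliferation rates (per day), `p_*` maximal self-renewal
#' fractions, `c_*` niche crowding coefficients, `s_x0`/`s_y0` cytokine
#' half-saturation constants, `A_*` amplification factors between maturity
#' stages, `d_*` death rates (per day), `e_a` debris degradation, `r_s`/`e_s`
#' cytokine production/degradation, and `I` external inflammatory
#' up-regulation.
#'
#' @return Character vector of length 26.
#' @export
mpn_param_names <- function() {
  c("alpha_x0", "alpha_x1", "alpha_y0", "alpha_y1",
    "p_x0", "p_x1", "p_y0", "p_y1",
    "c_xx", "c_xy", "c_yx", "c_yy",
    "s_x0", "s_y0",
    "A_x0", "A_x1", "A_y0", "A_y1",
    "d_x1", "d_x2", "d_y1", "d_y2",
    "e_a", "r_s", "e_s", "I")
}

.default_params <- list(
  alpha_x0 = 3.6e-3,  # HSC proliferation rate, /day
  alpha_x1 = 1.1e-2,  # HPC proliferation rate, /day
  alpha_y0 = 5.4e-3,  # malignant HSC proliferation rate, /day
  alpha_y1 = 1.7e-2,  # malignant HPC proliferation rate, /day
  p_x0 = 0.89,        # HSC max self-renewal fraction
  p_x1 = 0.445,       # HPC self-renewal fraction
  p_y0 = 0.97,        # mHSC max self-renewal fraction
  p_y1 = 0.485,       # mHPC self-renewal fraction
  c_xx = 5.6e-6,      # HSC -> HSC crowding inhibition
  c_xy = 5.4e-6,      # mHSC -> HSC crowding inhibition
  c_yx = 5.2e-6,      # HSC -> mHSC crowding inhibition
  c_yy = 5.0e-6,      # mHSC -> mHSC crowding inhibition
  s_x0 = 1.4e-1,      # cytokine half-saturation, HSC self-renewal
  s_y0 = 7.14e-2,     # cytokine half-saturation, mHSC self-renewal
  A_x0 = 3.4e1,       # amplification HSC -> HPC
  A_x1 = 3.2e6,       # amplification HPC -> MBC
  A_y0 = 3.4e1,       # amplification mHSC -> mHPC
  A_y1 = 3.2e6,       # amplification mHPC -> mMBC
  d_x1 = 3.7e-3,      # HPC death rate, /day
  d_x2 = 1.5e-1,      # MBC death rate, /day
  d_y1 = 3.7e-3,      # mHPC death rate, /day
  d_y2 = 1.5e-1,      # mMBC death rate, /day
  e_a = 1.2e8,        # debris degradation rate, /day
  r_s = 8.6e-2,       # cytokine production rate, /day
  e_s = 7.2e1,        # cytokine degradation rate, /day
  I = 2               # external inflammatory up-regulation, /day
)

#' Model parameters for the MPN haematopoiesis model
#'
#' Construct a validated parameter set. Without arguments the calibrated
#' default parameterisation of the model is returned, describing a typical
#' disease course in which the JAK2-mutant clone slowly outcompetes healthy
#' haematopoiesis. Any named subset of parameters can be overridden.
#'
#' @param ... Named parameter overrides, e.g. `mpn_params(s_y0 = 0.5)`.
#' @return An object of class `mpn_params`: a named list of 26 positive
#'   numerics. Self-renewal fractions are additionally required to be < 1.
#' @examples
#' p <- mpn_params()
#' p$s_y0
#' mpn_params(d_y1 = 6 * p$d_y1)$d_y1
#' @export
mpn_params <- function(...) {
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1]]) && is.null(names(over))) {
    over <- over[[1]]
  }
  p <- .default_params
  if (length(over)) {
    unknown <- setdiff(names(over), mpn_param_names())
    if (length(unknown) || is.null(names(over)) || any(names(over) == "")) {
      stop("unknown or unnamed parameter(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    p[names(over)] <- over
  }
  validate_params(p)
}

validate_params <- function(p) {
  nm <- mpn_param_names()
  missing <- setdiff(nm, names(p))
  if (length(missing)) {
    stop("missing parameter(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  p <- p[nm]
  vals <- unlist(p, use.names = FALSE)
  if (!is.numeric(vals) || anyNA(vals) || any(!is.finite(vals))) {
    stop("all parameters must be finite numerics", call. = FALSE)
  }
  if (any(vals <= 0)) {
    bad <- nm[vals <= 0]
    stop("parameters must be strictly positive: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  frac <- c("p_x0", "p_x1", "p_y0", "p_y1")
  if (any(unlist(p[frac]) >= 1)) {
    stop("self-renewal fractions must be < 1", call. = FALSE)
  }
  structure(p, class = "mpn_params")
}

#' @export
print.mpn_params <- function(x, ...) {
  cat("MPN model parameters (26 constants, rates per day):\n")
  print(data.frame(value = unlist(x)), ...)
  invisible(x)
}

param_vector <- function(params) {
  unlist(params[mpn_param_names()], use.names = TRUE)
}

#' Read or write a model parameter set as a flat YAML file
#'
#' Parameter files are flat key-value YAML with keys named exactly as the
#' model symbols (`alpha_x0`, `p_x0`, `c_xx`, `s_y0`, ...). The packaged
#' default file `system.file("extdata", "default_parameters.yaml",
#' package = "mpnrux")` reproduces the default parameterisation.
#'
#' @param path File path.
#' @return `read_params()` returns an `mpn_params` object.
#' @export
read_params <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("parameter file must be a flat key-value mapping")
  mpn_params(raw)
}

#' @rdname read_params
#' @param params An `mpn_params` object to serialise.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "mpn_params"))
  yaml::write_yaml(lapply(params, identity), path)
  invisible(path)
}

#' Patient-specific ruxolitinib treatment response
#'
#' The drug effect is parameterised by two non-negative response strengths
#' (units (mg/day)^-1) scaling dose-dependent increases of the malignant
#' stem-cell cytokine half-saturation constant `s_y0` and the malignant
#' progenitor death rate `d_y1`, together with the (constant) daily dose in
#' mg/day. Only relative changes in dose matter: rescaling the dose can be
#' absorbed into the response strengths.
#'
#' @param rho_sy0 Response strength on `s_y0`, >= 0, (mg/day)^-1.
#' @param rho_dy1 Response strength on `d_y1`, >= 0, (mg/day)^-1.
#' @param dose Daily dose in mg/day, >= 0.
#' @return An object of class `mpn_treatment`.
#' @examples
#' treatment_response(rho_sy0 = 0.959, rho_dy1 = 0.248, dose = 35)
#' @export
treatment_response <- function(rho_sy0 = 0, rho_dy1 = 0, dose = 0) {
  stopifnot(is.numeric(rho_sy0), length(rho_sy0) == 1L, is.finite(rho_sy0),
            is.numeric(rho_dy1), length(rho_dy1) == 1L, is.finite(rho_dy1),
            is.numeric(dose), length(dose) == 1L, is.finite(dose))
  if (rho_sy0 < 0 || rho_dy1 < 0) {
    stop("response strengths must be non-negative", call. = FALSE)
  }
  if (dose < 0) stop("dose must be non-negative", call. = FALSE)
  structure(list(rho_sy0 = rho_sy0, rho_dy1 = rho_dy1, dose = dose),
            class = "mpn_treatment")
}

#' @export
print.mpn_treatment <- function(x, ...) {
  cat(sprintf(
    "Ruxolitinib response: rho_sy0 = %g, rho_dy1 = %g (mg/day)^-1, dose = %g mg/day\n",
    x$rho_sy0, x$rho_dy1, x$dose))
  invisible(x)
}

#' Parameters in effect during treatment
#'
#' Maps a pre-treatment parameter set to the set in effect during therapy:
#' `s_y0 <- (1 + dose * rho_sy0) * s_y0` and
#' `d_y1 <- (1 + dose * rho_dy1) * d_y1`; all other constants are unchanged.
#' With both response strengths (or the dose) equal to zero the parameters
#' are returned unchanged.
#'
#' @param params An `mpn_params` object (pre-treatment values).
#' @param treat An `mpn_treatment` object.
#' @return An `mpn_params` object with the treated values.
#' @examples
#' p <- mpn_params()
#' effective_parameters(p, treatment_response(rho_dy1 = 0.122, dose = 35))$d_y1
#' @export
effective_parameters <- function(params, treat) {
  stopifnot(inherits(params, "mpn_params"), inherits(treat, "mpn_treatment"))
  params$s_y0 <- (1 + treat$dose * treat$rho_sy0) * params$s_y0
  params$d_y1 <- (1 + treat$dose * treat$rho_dy1) * params$d_y1
  validate_params(params)
}
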