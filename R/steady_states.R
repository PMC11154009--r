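#' Enumerate steady states of the MPN model
#'
#' Equilibria are found by branch enumeration on the two stem-cell
#' equations: each lineage either has zero stem cells or satisfies its
#' self-renewal balance `2 p phi s / (s_half + s) = 1`. On each of the four
#' branches the progenitor and mature compartments are linear in the
#' stem-cell influx and the debris level follows from the cytokine balance
#' (`a = (e_s s - I) / r_s`), so the remaining debris-balance equation
#' reduces to a single polynomial in `s` (degree 2, 3, 3 and 4 on the four
#' branches; 12 roots in total). The polynomial roots are computed exactly
#' via the companion matrix ([base::polyroot()]), so complex and negative
#' roots are part of the census rather than artefacts of a search grid.
#'
#' A root is biologically feasible when all eight components are real and
#' non-negative (within a small tolerance, then clamped to zero). Feasible
#' states are labelled by which lineages are populated and classified as
#' locally stable or unstable from the eigenvalues of the numerically
#' differentiated Jacobian.
#'
#' @param params An `mpn_params` object.
#' @param stability Compute local stability for feasible states (default
#'   TRUE).
#' @return An `mpn_steady_states` data frame with one row per root:
#'   `branch`, the 8 state components (real parts), `max_imag` (largest
#'   imaginary part across components), `feasible`, `label` (trivial /
#'   healthy / malignant / mixed), `residual` (relative right-hand-side
#'   residual, feasible rows), `stability` and `max_re_eigen`.
#' @examples
#' \donttest{
#' ss <- find_steady_states(mpn_params())
#' subset(ss, feasible)
#' }
#' @export
find_steady_states <- function(params, stability = TRUE) {
  stopifnot(inherits(params, "mpn_params"))
  roots <- rbind(
    branch_roots(params, healthy = FALSE, malignant = FALSE),
    branch_roots(params, healthy = TRUE, malignant = FALSE),
    branch_roots(params, healthy = FALSE, malignant = TRUE),
    branch_roots(params, healthy = TRUE, malignant = TRUE)
  )
  finalize_steady_states(roots, params, stability = stability,
                         reduced = FALSE)
}

#' Steady states of the healthy-only reduced model
#'
#' With the malignant compartments identically zero their equations can be
#' dropped, leaving a 5-variable system (`x0`, `x1`, `x2`, `a`, `s`). Its
#' steady states are the trivial and healthy rows of the full census, but
#' stability is judged from the 5x5 Jacobian of the reduced system: the
#' calibrated healthy state, unstable to invasion by malignant cells in the
#' full model, is locally stable here.
#'
#' @inheritParams find_steady_states
#' @return An `mpn_steady_states` data frame (reduced-system stability).
#' @export
reduced_healthy_steady_states <- function(params, stability = TRUE) {
  stopifnot(inherits(params, "mpn_params"))
  roots <- rbind(
    branch_roots(params, healthy = FALSE, malignant = FALSE),
    branch_roots(params, healthy = TRUE, malignant = FALSE)
  )
  finalize_steady_states(roots, params, stability = stability,
                         reduced = TRUE)
}

# ---- polynomial machinery ----------------------------------------------

pmul <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    idx <- i:(i + length(b) - 1L)
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

padd <- function(a, b) {
  n <- max(length(a), length(b))
  c(a, numeric(n - length(a))) + c(b, numeric(n - length(b)))
}

# Steady-state constants of one lineage: progenitors clear at net rate
# D = d1 - alpha1 (2 p1 - 1), which must be positive for a finite
# progenitor pool; at stem balance the influx is A0 alpha0 n0 (half of all
# divisions differentiate), giving n1 = k1 n0, n2 = k2 n1, and a total
# death flux K n0.
lineage_constants <- function(params, lineage = c("x", "y")) {
  lineage <- match.arg(lineage)
  g <- function(nm) params[[sub("L", lineage, nm)]]
  D <- g("d_L1") - g("alpha_L1") * (2 * g("p_L1") - 1)
  if (D <= 0) {
    warning(sprintf(
      "lineage %s: progenitor pool is self-sustaining (net clearance %.3g <= 0); branch skipped",
      lineage, D))
    return(NULL)
  }
  k1 <- g("A_L0") * g("alpha_L0") / D
  k2 <- 2 * g("A_L1") * g("alpha_L1") * (1 - g("p_L1")) / g("d_L2")
  K <- k1 * (g("d_L1") + 2 * g("A_L1") * g("alpha_L1") * (1 - g("p_L1")))
  list(D = D, k1 = k1, k2 = k2, K = K)
}

# Roots of the branch polynomial in s, mapped back to full states
# (possibly complex). healthy/malignant flag whether that lineage's
# stem-balance equation is active (stem count nonzero).
branch_roots <- function(params, healthy, malignant) {
  p <- params
  ea_rs <- p$e_a / p$r_s
  # Q(s) = (e_a / r_s) s (e_s s - I): debris clearance at cytokine balance
  Q <- c(0, -ea_rs * p$I, ea_rs * p$e_s)
  b_x <- c(-p$s_x0, 2 * p$p_x0 - 1)   # (s_x0 + s) * B_x(s)
  b_y <- c(-p$s_y0, 2 * p$p_y0 - 1)
  m_x <- c(p$s_x0, 1)
  m_y <- c(p$s_y0, 1)
  lx <- lineage_constants(p, "x")
  ly <- lineage_constants(p, "y")

  branch <- paste0(if (healthy) "healthy" else "none", "+",
                   if (malignant) "malignant" else "none")

  if (!healthy && !malignant) {
    poly <- c(0, -p$I, p$e_s)               # s (e_s s - I) = 0
    s_fun <- function(s) list(x0 = 0 + 0i, y0 = 0 + 0i)
  } else if (healthy && !malignant) {
    if (is.null(lx)) return(empty_roots())
    poly <- padd(pmul(Q, m_x), -(lx$K / p$c_xx) * b_x)
    s_fun <- function(s) {
      list(x0 = polyval_c(b_x, s) / (p$c_xx * polyval_c(m_x, s)),
           y0 = 0 + 0i)
    }
  } else if (!healthy && malignant) {
    if (is.null(ly)) return(empty_roots())
    poly <- padd(pmul(Q, m_y), -(ly$K / p$c_yy) * b_y)
    s_fun <- function(s) {
      list(x0 = 0 + 0i,
           y0 = polyval_c(b_y, s) / (p$c_yy * polyval_c(m_y, s)))
    }
  } else {
    if (is.null(lx) || is.null(ly)) return(empty_roots())
    det <- p$c_xx * p$c_yy - p$c_xy * p$c_yx
    if (det == 0) {
      warning("crowding matrix is singular; mixed branch skipped")
      return(empty_roots())
    }
    bxmy <- pmul(b_x, m_y)
    bymx <- pmul(b_y, m_x)
    poly <- padd(
      det * pmul(Q, pmul(m_x, m_y)),
      padd(-(lx$K) * padd(p$c_yy * bxmy, -p$c_xy * bymx),
           -(ly$K) * padd(p$c_xx * bymx, -p$c_yx * bxmy))
    )
    s_fun <- function(s) {
      Bx <- polyval_c(b_x, s) / polyval_c(m_x, s)
      By <- polyval_c(b_y, s) / polyval_c(m_y, s)
      list(x0 = (p$c_yy * Bx - p$c_xy * By) / det,
           y0 = (p$c_xx * By - p$c_yx * Bx) / det)
    }
  }

  s_roots <- polyroot(poly)
  rows <- lapply(s_roots, function(s) {
    stems <- s_fun(s)
    x0 <- stems$x0; y0 <- stems$y0
    x1 <- if (healthy) lx$k1 * x0 else 0 + 0i
    x2 <- if (healthy) lx$k2 * x1 else 0 + 0i
    y1 <- if (malignant) ly$k1 * y0 else 0 + 0i
    y2 <- if (malignant) ly$k2 * y1 else 0 + 0i
    a <- (p$e_s * s - p$I) / p$r_s
    data.frame(branch = branch,
               x0 = Re(x0), x1 = Re(x1), x2 = Re(x2),
               y0 = Re(y0), y1 = Re(y1), y2 = Re(y2),
               a = Re(a), s = Re(s),
               max_imag = max(abs(Im(c(x0, x1, x2, y0, y1, y2, a, s)))))
  })
  do.call(rbind, rows)
}

polyval_c <- function(coef, s) {
  # ascending-coefficient polynomial evaluation, complex-safe
  powers <- s ^ (seq_along(coef) - 1)
  sum(coef * powers)
}

empty_roots <- function() {
  data.frame(branch = character(), x0 = numeric(), x1 = numeric(),
             x2 = numeric(), y0 = numeric(), y1 = numeric(),
             y2 = numeric(), a = numeric(), s = numeric(),
             max_imag = numeric())
}

# Compartment scales (typical orders of magnitude) used for the
# feasibility tolerance: numerical roots may straddle zero.
.state_scales <- c(x0 = 1e5, x1 = 2.5e6, x2 = 6.4e11,
                   y0 = 1.7e5, y1 = 7.6e6, y2 = 2.7e12,
                   a = 1.7e3, s = 2)

finalize_steady_states <- function(roots, params, stability, reduced) {
  sn <- mpn_state_names()
  st_mat <- as.matrix(roots[sn])
  is_real <- roots$max_imag <= 1e-6 * (1 + apply(abs(st_mat), 1, max))
  nonneg <- apply(st_mat, 1, function(v) all(v >= -1e-6 * .state_scales))
  roots$feasible <- is_real & nonneg

  # clamp tiny negatives on feasible rows
  for (i in which(roots$feasible)) {
    st_mat[i, ] <- pmax(st_mat[i, ], 0)
    roots[i, sn] <- as.list(st_mat[i, ])
  }

  # merge duplicate feasible roots (relative distance on log1p scale)
  feas_idx <- which(roots$feasible)
  if (length(feas_idx) > 1) {
    keep <- rep(TRUE, length(feas_idx))
    lg <- log1p(st_mat[feas_idx, , drop = FALSE])
    for (i in seq_along(feas_idx)) {
      if (!keep[i]) next
      for (j in seq_len(i - 1L)) {
        if (keep[j] &&
            max(abs(lg[i, ] - lg[j, ])) <= 1e-4 * (1 + max(abs(lg[j, ])))) {
          keep[i] <- FALSE
          break
        }
      }
    }
    dup <- feas_idx[!keep]
    if (length(dup)) roots$feasible[dup] <- FALSE
  }

  roots$label <- NA_character_
  roots$residual <- NA_real_
  roots$stability <- NA_character_
  roots$max_re_eigen <- NA_real_

  for (i in which(roots$feasible)) {
    st <- stats::setNames(st_mat[i, ], sn)
    has_h <- sum(st[c("x0", "x1", "x2")]) > 0.5
    has_m <- sum(st[c("y0", "y1", "y2")]) > 0.5
    roots$label[i] <- if (!has_h && !has_m) "trivial"
      else if (has_h && !has_m) "healthy"
      else if (!has_h && has_m) "malignant"
      else "mixed"
    f <- mpn_rhs(st, params)
    sc <- rhs_flux_scale(st, params)
    roots$residual[i] <- max(abs(f) / pmax(sc, 1e-12))
    if (stability) {
      cls <- classify_stability(st, params, reduced = reduced)
      roots$stability[i] <- cls$stability
      roots$max_re_eigen[i] <- cls$max_re_eigen
    }
  }
  rownames(roots) <- NULL
  class(roots) <- c("mpn_steady_states", "data.frame")
  roots
}

#' Local stability of a steady state
#'
#' Builds the Jacobian of the model right-hand side by central finite
#' differences with component-relative steps and inspects the real parts of
#' its eigenvalues: locally stable iff all are negative. Eigenvalues whose
#' largest real part lies inside a small indeterminacy band are reported as
#' `"marginal"` rather than guessed.
#'
#' @param state Named state vector of length 8 (a steady state).
#' @param params An `mpn_params` object.
#' @param reduced Judge stability in the healthy-only 5-variable reduction
#'   (`x0`, `x1`, `x2`, `a`, `s`); the malignant components of `state` must
#'   then be zero.
#' @param band Indeterminacy half-width on the leading real part (per day).
#' @return A list with `stability` (`"stable"`, `"unstable"` or
#'   `"marginal"`), `max_re_eigen` and the full `eigenvalues`.
#' @export
classify_stability <- function(state, params, reduced = FALSE,
                               band = 1e-9) {
  stopifnot(inherits(params, "mpn_params"), length(state) == 8L)
  J <- mpn_jacobian(state, params)
  if (reduced) {
    if (any(state[c("y0", "y1", "y2")] != 0)) {
      stop("reduced stability requires zero malignant compartments",
           call. = FALSE)
    }
    idx <- c(1, 2, 3, 7, 8)
    J <- J[idx, idx]
  }
  ev <- eigen(J, only.values = TRUE)$values
  mre <- max(Re(ev))
  stab <- if (mre < -band) "stable" else if (mre > band) "unstable"
    else "marginal"
  list(stability = stab, max_re_eigen = mre, eigenvalues = ev)
}

#' Jacobian of the model right-hand side
#'
#' Central finite differences with steps relative to each component's
#' magnitude (absolute floor of one cell for the cell compartments).
#'
#' @inheritParams classify_stability
#' @return 8x8 numeric matrix, entries per day.
#' @export
mpn_jacobian <- function(state, params) {
  st <- stats::setNames(as.numeric(state), mpn_state_names())
  floors <- c(1, 1, 1, 1, 1, 1, 1e-3, 1e-4)
  J <- matrix(0, 8, 8, dimnames = list(mpn_state_names(), mpn_state_names()))
  for (j in 1:8) {
    h <- 1e-5 * max(abs(st[j]), floors[j])
    up <- st; up[j] <- st[j] + h
    dn <- st; dn[j] <- st[j] - h
    J[, j] <- (mpn_rhs(up, params) - mpn_rhs(dn, params)) / (2 * h)
  }
  J
}

#' @export
print.mpn_steady_states <- function(x, ...) {
  nf <- sum(x$feasible)
  cat(sprintf("Steady-state census: %d roots over %d stem-balance branches, %d biologically feasible\n",
              nrow(x), length(unique(x$branch)), nf))
  if (nf > 0) {
    cols <- c(mpn_state_names(), "label", "stability")
    print.data.frame(as.data.frame(x)[x$feasible, cols], digits = 3)
  }
  invisible(x)
}
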