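# Production-surviving fraction of the P gene under its two graded repressors.
p_repression_factor <- function(N, O, params) {
  if (params$p_repression == "product") {
    hill_repressor(N, params$N_crit, params$h1) *
      hill_repressor(O, params$O_crit, params$h2)
  } else {
    1 / (1 + (N / params$N_crit)^params$h1 + (O / params$O_crit)^params$h2)
  }
}

# Repression factors acting in the O and N equations.  In threshold mode each
# is a Heaviside step; in graded mode a Hill function.  `H` optionally freezes
# the threshold-mode steps at externally supplied 0/1 values (used by the
# event-driven integrator between switching events).
switch_factors <- function(P, O, N, params, H = NULL) {
  if (params$mode == "threshold") {
    if (is.null(H)) {
      c(PN = heaviside(params$P_crit1 - P),   # P silences N
        ON = heaviside(params$O_crit1 - O),   # O silences N
        NO = heaviside(params$N_crit1 - N))   # N silences O
    } else {
      c(PN = H[["PN"]], ON = H[["ON"]], NO = H[["NO"]])
    }
  } else {
    c(PN = hill_repressor(P, params$P_crit1, params$h3),
      ON = hill_repressor(O, params$O_crit1, params$h5),
      NO = hill_repressor(N, params$N_crit1, params$h4))
  }
}

#' Right-hand side of the circuit ODEs
#'
#' Time derivatives \code{(dP/dt, dO/dt, dN/dt)} of the three-gene circuit at
#' a given expression state and signal level. See
#' \code{\link{circuit_params}} for the model.
#'
#' @param state numeric state \code{c(P, O, N)}, nonnegative.
#' @param S signal level, \code{>= 0}.
#' @param params an \code{\link{circuit_params}} object.
#' @param H optional frozen Heaviside configuration (named 0/1 vector with
#'   elements \code{PN}, \code{ON}, \code{NO}); threshold mode only.
#' @return named numeric vector \code{c(P=, O=, N=)} of derivatives.
#' @examples
#' p <- load_preset("fig2a")
#' circuit_rhs(c(5, 0, 0), S = 1, p)
#' @export
circuit_rhs <- function(state, S, params, H = NULL) {
  stopifnot(inherits(params, "acdc_params"))
  if (length(state) != 3L || any(!is.finite(state)) || any(state < 0))
    stop("circuit_rhs(): state must be three finite nonnegative numbers")
  if (!is.null(H) && params$mode != "threshold")
    stop("circuit_rhs(): frozen Heaviside configuration requires threshold mode")
  P <- state[[1]]; O <- state[[2]]; N <- state[[3]]
  d <- induction_drive(S, params$S_half)
  r <- switch_factors(P, O, N, params, H)
  c(P = params$alpha * p_repression_factor(N, O, params) - params$k1 * P,
    O = params$beta * d * r[["NO"]] - params$k2 * O,
    N = params$gamma * d * r[["PN"]] * r[["ON"]] - params$k3 * N)
}

#' Jacobian of the circuit ODEs
#'
#' Analytic Jacobian of \code{\link{circuit_rhs}} with respect to the state.
#' In threshold mode the Heaviside factors are piecewise constant, so away
#' from the switching surfaces the Jacobian is triangular with eigenvalues
#' \code{-k1, -k2, -k3}.
#'
#' @inheritParams circuit_rhs
#' @return 3x3 numeric matrix, rows/columns ordered P, O, N.
#' @export
circuit_jacobian <- function(state, S, params, H = NULL) {
  stopifnot(inherits(params, "acdc_params"))
  P <- state[[1]]; O <- state[[2]]; N <- state[[3]]
  d <- induction_drive(S, params$S_half)
  J <- matrix(0, 3, 3, dimnames = list(c("P", "O", "N"), c("P", "O", "N")))
  # P equation
  if (params$p_repression == "product") {
    RN <- hill_repressor(N, params$N_crit, params$h1)
    RO <- hill_repressor(O, params$O_crit, params$h2)
    J["P", "N"] <- params$alpha * RO * hill_repressor_deriv(N, params$N_crit, params$h1)
    J["P", "O"] <- params$alpha * RN * hill_repressor_deriv(O, params$O_crit, params$h2)
  } else {
    den <- 1 + (N / params$N_crit)^params$h1 + (O / params$O_crit)^params$h2
    dN <- if (N == 0 && params$h1 == 1) 1 / params$N_crit else
      if (N == 0) 0 else (params$h1 / N) * (N / params$N_crit)^params$h1
    dO <- if (O == 0 && params$h2 == 1) 1 / params$O_crit else
      if (O == 0) 0 else (params$h2 / O) * (O / params$O_crit)^params$h2
    J["P", "N"] <- -params$alpha * dN / den^2
    J["P", "O"] <- -params$alpha * dO / den^2
  }
  J["P", "P"] <- -params$k1
  # O and N equations
  r <- switch_factors(P, O, N, params, H)
  J["O", "O"] <- -params$k2
  J["N", "N"] <- -params$k3
  if (params$mode == "graded") {
    J["O", "N"] <- params$beta * d *
      hill_repressor_deriv(N, params$N_crit1, params$h4)
    J["N", "P"] <- params$gamma * d * r[["ON"]] *
      hill_repressor_deriv(P, params$P_crit1, params$h3)
    J["N", "O"] <- params$gamma * d * r[["PN"]] *
      hill_repressor_deriv(O, params$O_crit1, params$h5)
  }
  J
}
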