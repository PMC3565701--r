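#' Circuit parameter set
#'
#' Construct and validate the full parameter set of the three-gene
#' cross-repression circuit: the constitutive gene P (Pax6) and the
#' signal-induced genes O (Olig2) and N (Nkx2.2).
#'
#' The model is
#' \deqn{dP/dt = \alpha / (1 + (N/N_{crit})^{h_1} + (O/O_{crit})^{h_2}) - k_1 P}
#' \deqn{dO/dt = \beta d(S) \rho_{N \dashv O}(N) - k_2 O}
#' \deqn{dN/dt = \gamma d(S) \rho_{P \dashv N}(P) \rho_{O \dashv N}(O) - k_3 N}
#' where \eqn{d(S)} is \code{\link{induction_drive}}, the \eqn{\rho}
#' repressions on the O and N equations are Heaviside steps
#' (\code{mode = "threshold"}) or Hill functions with coefficients
#' \code{h3}, \code{h4}, \code{h5} (\code{mode = "graded"}), and the P
#' production term is the additive two-repressor Hill form shown (see
#' \code{p_repression} for the independent-repressor product alternative).
#'
#' @param alpha,beta,gamma maximal production rates of P, O, N.
#' @param k1,k2,k3 first-order decay rates of P, O, N.
#' @param N_crit,O_crit half-maximal concentrations of the graded repression
#'   of P by N and by O.
#' @param h1,h2 Hill coefficients of the N-on-P and O-on-P repressions
#'   (\code{>= 1}).
#' @param P_crit1 critical P at which P switches off N production.
#' @param O_crit1 critical O at which O switches off N production.
#' @param N_crit1 critical N at which N switches off O production.
#' @param h3,h4,h5 Hill coefficients used in graded mode for the P-on-N,
#'   N-on-O and O-on-N repressions, respectively.
#' @param S_half signal at half-maximal induction drive, shared by O and N.
#' @param mode \code{"threshold"} (Heaviside repressions on O and N) or
#'   \code{"graded"} (Hill repressions).
#' @param p_repression how the two repressors combine in the P production
#'   term: a shared \code{"additive"} denominator
#'   \code{1/(1 + (N/N_crit)^h1 + (O/O_crit)^h2)} (competing repressors, the
#'   default) or a \code{"product"} of two independent Hill functions. The
#'   two agree whenever one repressor is absent, hence on branches B1 and B2
#'   and in every single-repressor criterion; they differ on the co-expressed
#'   branch and in the graded model's oscillatory ranges, where the additive
#'   form is the one that reproduces the circuit's documented behaviour.
#' @return object of class \code{acdc_params} (a validated named list).
#' @seealso \code{\link{load_preset}}, \code{\link{param_maxima}},
#'   \code{\link{circuit_rhs}}
#' @examples
#' p <- circuit_params(N_crit = 0.9)
#' param_maxima(p)
#' @export
circuit_params <- function(alpha = 5, beta = 5, gamma = 5,
                           k1 = 1, k2 = 1, k3 = 1,
                           N_crit = 0.9, O_crit = 1, h1 = 2, h2 = 2,
                           P_crit1 = 0.5, O_crit1 = 5, N_crit1 = 2,
                           h3 = 2, h4 = 2, h5 = 2,
                           S_half = 1,
                           mode = c("threshold", "graded"),
                           p_repression = c("additive", "product")) {
  mode <- match.arg(mode)
  p_repression <- match.arg(p_repression)
  p <- list(alpha = alpha, beta = beta, gamma = gamma,
            k1 = k1, k2 = k2, k3 = k3,
            N_crit = N_crit, O_crit = O_crit, h1 = h1, h2 = h2,
            P_crit1 = P_crit1, O_crit1 = O_crit1, N_crit1 = N_crit1,
            h3 = h3, h4 = h4, h5 = h5, S_half = S_half,
            mode = mode, p_repression = p_repression)
  pos <- c("alpha", "beta", "gamma", "k1", "k2", "k3", "N_crit", "O_crit",
           "P_crit1", "O_crit1", "N_crit1", "S_half")
  for (nm in pos) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("circuit_params(): '", nm, "' must be a single positive finite number")
  }
  for (nm in c("h1", "h2", "h3", "h4", "h5")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 1)
      stop("circuit_params(): Hill coefficient '", nm, "' must be >= 1")
  }
  class(p) <- "acdc_params"
  p
}

#' Derived expression maxima
#'
#' The saturated expression levels \code{P_max = alpha/k1},
#' \code{O_max = beta/k2}, \code{N_max = gamma/k3}.
#'
#' @param params an \code{\link{circuit_params}} object.
#' @return named numeric vector \code{c(P_max, O_max, N_max)}.
#' @export
param_maxima <- function(params) {
  stopifnot(inherits(params, "acdc_params"))
  c(P_max = params$alpha / params$k1,
    O_max = params$beta / params$k2,
    N_max = params$gamma / params$k3)
}

#' Modify a parameter set
#'
#' Return a copy of \code{params} with the named fields replaced, re-running
#' full validation.
#'
#' @param params an \code{\link{circuit_params}} object.
#' @param ... fields to replace, e.g. \code{N_crit = 1.1, mode = "graded"}.
#' @return a new \code{acdc_params} object.
#' @export
modify_params <- function(params, ...) {
  stopifnot(inherits(params, "acdc_params"))
  upd <- list(...)
  bad <- setdiff(names(upd), names(unclass(params)))
  if (length(bad)) stop("modify_params(): unknown field(s): ",
                        paste(bad, collapse = ", "))
  p <- unclass(params)
  p[names(upd)] <- upd
  do.call(circuit_params, p)
}

#' @export
print.acdc_params <- function(x, ...) {
  m <- param_maxima(x)
  cat("AC-DC circuit parameters (", x$mode, " mode)\n", sep = "")
  cat(sprintf("  production  alpha=%g beta=%g gamma=%g\n",
              x$alpha, x$beta, x$gamma))
  cat(sprintf("  decay       k1=%g k2=%g k3=%g\n", x$k1, x$k2, x$k3))
  cat(sprintf("  P repression  N_crit=%g (h1=%g)  O_crit=%g (h2=%g)  [%s]\n",
              x$N_crit, x$h1, x$O_crit, x$h2, x$p_repression))
  cat(sprintf("  switch thresholds  P_crit1=%g  O_crit1=%g  N_crit1=%g\n",
              x$P_crit1, x$O_crit1, x$N_crit1))
  if (x$mode == "graded")
    cat(sprintf("  graded coefficients  h3=%g h4=%g h5=%g\n", x$h3, x$h4, x$h5))
  cat(sprintf("  induction  S_half=%g\n", x$S_half))
  cat(sprintf("  maxima  P_max=%g O_max=%g N_max=%g\n", m[1], m[2], m[3]))
  invisible(x)
}

#' Pre-signal resting state
#'
#' The expression state of a cell that has never seen the signal:
#' \code{P = P_max}, all induced genes at zero. Used as the default initial
#' condition throughout.
#'
#' @param x an \code{\link{circuit_params}} object or a
#'   \code{\link{multigene_circuit}}.
#' @return named numeric state vector.
#' @export
initial_state <- function(x) {
  if (inherits(x, "acdc_params")) {
    return(c(P = x$alpha / x$k1, O = 0, N = 0))
  }
  if (inherits(x, "acdc_multigene")) {
    y <- numeric(nrow(x$genes))
    names(y) <- x$genes$name
    y[1] <- x$genes$production[1] / x$genes$decay[1]
    return(y)
  }
  stop("initial_state(): unsupported object")
}

#' Write a parameter set to a flat text config
#'
#' One \code{key: value} line per field, readable by
#' \code{\link{read_circuit_config}}. Numeric values are written with full
#' precision so that a round trip reproduces the parameter set exactly.
#'
#' @param params an \code{\link{circuit_params}} object.
#' @param path file to write.
#' @return \code{path}, invisibly.
#' @export
write_circuit_config <- function(params, path) {
  stopifnot(inherits(params, "acdc_params"))
  p <- unclass(params)
  lines <- vapply(names(p), function(nm) {
    v <- p[[nm]]
    if (is.character(v)) sprintf("%s: %s", nm, v)
    else sprintf("%s: %.17g", nm, v)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a parameter set from a flat text config
#'
#' @param path file of \code{key: value} lines with keys as in
#'   \code{\link{circuit_params}}.
#' @return an \code{acdc_params} object.
#' @export
read_circuit_config <- function(path) {
  vals <- yaml::read_yaml(path)
  vals <- lapply(vals, function(v) if (is.numeric(v)) as.numeric(v) else v)
  known <- names(formals(circuit_params))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("read_circuit_config(): unknown key(s): ",
                        paste(bad, collapse = ", "))
  do.call(circuit_params, vals)
}
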