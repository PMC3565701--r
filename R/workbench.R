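# ---- Parameter sampling and the regime census ------------------------------

#' Sample random valid parameter sets
#'
#' Rejection-samples circuit parameters for census and robustness
#' experiments: production rates and repression thresholds log-uniform on
#' \code{range}, a shared integer Hill coefficient \code{h1 = h2} uniform on
#' \code{hill_set}, decay rates fixed at 1 (which sets the time unit) and
#' \code{S_half = 1}. Only sets passing \code{constraints} (by default all
#' \code{\link{validity_conditions}}) are returned; the draw is a
#' deterministic function of \code{seed}.
#'
#' @param n number of parameter sets to return.
#' @param seed RNG seed.
#' @param range log-uniform range for rates and thresholds.
#' @param hill_set candidate values for the shared Hill coefficient.
#' @param constraints predicate \code{function(params) -> logical}.
#' @param max_tries draw budget; exceeded budget is an error with
#'   diagnostics.
#' @return list of \code{\link{circuit_params}} objects with attributes
#'   \code{seed} and \code{n_rejected}.
#' @export
sample_parameters <- function(n, seed = 1, range = c(0.1, 10),
                              hill_set = 1:5,
                              constraints = NULL, max_tries = 1000 * n) {
  if (n < 1) stop("sample_parameters(): n must be >= 1")
  if (is.null(constraints))
    constraints <- function(p) attr(validity_conditions(p), "valid")
  rlog <- function(k) exp(stats::runif(k, log(range[1]), log(range[2])))
  out <- vector("list", n)
  got <- 0L; tries <- 0L
  set.seed(as.integer(seed %% .Machine$integer.max))
  while (got < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("sample_parameters(): exhausted ", max_tries, " draws with only ",
           got, " valid sets; loosen constraints or raise max_tries")
    v <- rlog(8)
    h <- sample(hill_set, 1)
    p <- circuit_params(alpha = v[1], beta = v[2], gamma = v[3],
                        k1 = 1, k2 = 1, k3 = 1,
                        N_crit = v[4], O_crit = v[5], h1 = h, h2 = h,
                        P_crit1 = v[6], O_crit1 = v[7], N_crit1 = v[8],
                        S_half = 1, mode = "threshold")
    if (constraints(p)) {
      got <- got + 1L
      out[[got]] <- p
    }
  }
  attr(out, "seed") <- seed
  attr(out, "n_rejected") <- tries - got
  out
}

#' Classify the regime by brute-force simulation
#'
#' Independent, simulation-based counterpart of
#' \code{\link{classify_regime}}: sweeps the induction drive adiabatically
#' over a uniform grid (carrying the converged state forward), classifies
#' the occupied state at each step (N absent; O absent; co-expressed;
#' oscillating) and reads the behaviour sequence off the sweep. The
#' possibility number is 1 plus 1 if a co-expressed steady state was
#' visited plus 2 if an oscillatory window was crossed.
#'
#' An oscillating sweep step is only counted as part of an existence gap
#' after basin probing: the circuit can sustain a limit cycle coexisting
#' with a stable steady state, trapping the adiabatic path. At each
#' oscillatory step the classifier therefore also integrates from three
#' saturated corner states (P high with O at its drive level; O and N at
#' their drive levels; N alone at its drive level); the step counts as a
#' gap only if none of them converges, i.e. no stable steady state could be
#' found anywhere.
#'
#' @param params threshold-mode \code{\link{circuit_params}}.
#' @param d_grid increasing grid of induction-drive values in (0, 1).
#' @param t_step integration horizon per grid point (extended automatically
#'   where convergence or cycling cannot be decided within it).
#' @return list with \code{possibility}, \code{route}, \code{states}
#'   (data frame of d, S and state classification) and \code{undecided}
#'   (count of unclassifiable steps).
#' @export
simulate_regime <- function(params,
                            d_grid = seq(0.005, 0.995, length.out = 100),
                            t_step = 40) {
  stopifnot(inherits(params, "acdc_params"))
  require_threshold(params, "simulate_regime()")
  m <- unname(param_maxima(params))
  state <- initial_state(params)
  cls <- character(length(d_grid))
  und <- 0L
  probe_gap <- function(S, d) {
    # corner probes start at their saturated targets, so when a stable
    # steady state exists they settle within a few protein half-lives;
    # the N-saturated corner goes first, as it is the state most likely
    # to be stable beyond the loss of the N-silent branch
    probes <- list(c(0, 0, m[3] * d),
                   c(0, m[2] * d, m[3] * d),
                   c(m[1], m[2] * d, 0))
    for (y0 in probes) {
      tr <- integrate_circuit(params, S, init = y0, t_end = 25, dt = 1,
                              rtol = 1e-7, atol = 1e-9,
                              stop_at_steady = TRUE, ss_tol = 1e-8)
      if (isTRUE(attr(tr, "converged"))) return(FALSE)
    }
    TRUE
  }
  states <- matrix(NA_real_, length(d_grid), 3)
  gap_seen <- FALSE
  for (i in seq_along(d_grid)) {
    S <- s_from_drive(d_grid[i], params$S_half)
    st <- adiabatic_step(params, S, state, t_step, m,
                         rtol = 1e-7, atol = 1e-9, ss_tol = 1e-8)
    state <- st$state
    states[i, ] <- state
    cls[i] <- st$label
    if (st$label == "osc" && !gap_seen) {
      if (probe_gap(S, d_grid[i])) gap_seen <- TRUE
      else cls[i] <- "osc_coexist"
    }
    if (st$label == "undecided") und <- und + 1L
  }
  # refine direct steady -> B2 transitions: a co-expressed window or an
  # oscillatory gap narrower than the grid step would otherwise be skipped
  refined <- character(0)
  jumps <- which(cls[-length(cls)] %in% c("B1", "B3") &
                 cls[-1] == "B2" & cls[-length(cls)] != cls[-1])
  for (j in jumps) {
    sub_d <- seq(d_grid[j], d_grid[j + 1], length.out = 22)
    sub_d <- sub_d[-c(1, length(sub_d))]
    sub_state <- states[j, ]
    for (dd in sub_d) {
      st <- adiabatic_step(params, s_from_drive(dd, params$S_half),
                           sub_state, t_step, m,
                           rtol = 1e-7, atol = 1e-9, ss_tol = 1e-8)
      sub_state <- st$state
      lab <- st$label
      if (lab == "osc" && !gap_seen) {
        if (probe_gap(s_from_drive(dd, params$S_half), dd)) gap_seen <- TRUE
        else lab <- "osc_coexist"
      }
      refined <- c(refined, lab)
    }
  }
  decided <- c(cls[cls != "undecided"], refined[refined != "undecided"])
  has_b3 <- "B3" %in% decided
  has_osc <- "osc" %in% decided
  possibility <- 1L + as.integer(has_b3) + 2L * as.integer(has_osc)
  list(possibility = possibility,
       route = if (has_b3) "route2" else "route1",
       states = data.frame(d = d_grid,
                           S = s_from_drive(d_grid, params$S_half),
                           state = cls, stringsAsFactors = FALSE),
       undecided = und)
}

#' Regime census over random parameter sets
#'
#' Draws \code{n} valid parameter sets, classifies each both analytically
#' (\code{\link{classify_regime}}) and by adiabatic simulation
#' (\code{\link{simulate_regime}}), and tabulates agreement and the
#' inventory of distinct regimes observed. Draws whose simulation contains
#' undecided steps are reported and excluded from the agreement
#' denominator.
#'
#' @param n number of parameter sets.
#' @param seed RNG seed for the sampler.
#' @param d_steps grid resolution of the simulated sweep.
#' @param t_step integration horizon per sweep step.
#' @return object of class \code{acdc_census}: list with \code{draws}
#'   (data frame: analytic and simulated possibility and route, agreement
#'   flag), \code{agreement} (fraction agreeing among decided draws),
#'   \code{inventory} (sorted distinct analytic possibilities) and
#'   \code{n_undecided}.
#' @export
run_census <- function(n = 500, seed = 1, d_steps = 100, t_step = 40) {
  draws <- sample_parameters(n, seed = seed)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    p <- draws[[i]]
    an <- classify_regime(p)
    si <- simulate_regime(p, d_grid = seq(0.005, 0.995,
                                          length.out = d_steps),
                          t_step = t_step)
    rows[[i]] <- data.frame(
      draw = i,
      analytic = an$possibility, simulated = si$possibility,
      route_analytic = an$route, route_simulated = si$route,
      undecided = si$undecided > 0,
      agree = an$possibility == si$possibility,
      stringsAsFactors = FALSE)
  }
  d <- do.call(rbind, rows)
  dec <- d[!d$undecided, , drop = FALSE]
  out <- list(draws = d,
              agreement = mean(dec$agree),
              inventory = sort(unique(d$analytic)),
              n_undecided = sum(d$undecided),
              parameters = draws)
  class(out) <- "acdc_census"
  out
}

#' @export
print.acdc_census <- function(x, ...) {
  cat(sprintf("Regime census: %d draws, agreement %.1f%%, %d undecided\n",
              nrow(x$draws), 100 * x$agreement, x$n_undecided))
  cat("  analytic inventory:", paste(x$inventory, collapse = ", "), "\n")
  tab <- table(analytic = x$draws$analytic, simulated = x$draws$simulated)
  print(tab)
  invisible(x)
}
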