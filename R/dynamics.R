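# ---- Attractor detection, bifurcation scans, hysteresis sweeps -------------

# Local maxima of a sampled series; returns indices.
local_maxima <- function(v) {
  n <- length(v)
  if (n < 3) return(integer())
  which(v[2:(n - 1)] >= v[1:(n - 2)] & v[2:(n - 1)] > v[3:n]) + 1L
}

# Quadratic refinement of a sampled peak position.
refine_peak <- function(t, v, i) {
  if (i <= 1 || i >= length(v)) return(t[i])
  y1 <- v[i - 1]; y2 <- v[i]; y3 <- v[i + 1]
  den <- y1 - 2 * y2 + y3
  if (abs(den) < .Machine$double.eps) return(t[i])
  t[i] + 0.5 * (y1 - y3) / den * (t[i + 1] - t[i])
}

#' Classify the long-term behaviour of a trajectory
#'
#' Decides whether a trajectory has settled on a fixed point, a limit cycle,
#' or a fixed point approached through damped oscillations; anything that
#' cannot be decided at the given tolerances is reported as
#' \code{undecided}, never silently coerced.
#'
#' Fixed point: terminal RHS norm below \code{tol_ss} and the relative
#' amplitude over the analysis window below \code{tol_amp}. Limit cycle:
#' successive oscillation periods (from recorded switching events in
#' threshold mode, or quadratically refined peaks of the most active
#' variable in graded mode) agree within \code{tol_per} and the amplitude
#' exceeds \code{tol_amp}. The analysis window is the second half of the
#' trajectory (burn-in policy).
#'
#' @param traj an \code{acdc_trajectory} from \code{\link{integrate_circuit}}.
#' @param tol_ss steady-state tolerance on the RHS max-norm.
#' @param tol_amp amplitude tolerance, relative to each variable's maximum.
#' @param tol_per relative tolerance on period agreement.
#' @return object of class \code{acdc_attractor}: list with \code{type}
#'   (\code{fixed_point}, \code{limit_cycle},
#'   \code{damped_oscillation_to_fixed_point}, \code{undecided}),
#'   \code{state} (terminal state), \code{period} and \code{extrema}
#'   (per-variable min/max over the last cycles, limit cycles only),
#'   \code{residual}, \code{periods} (the inter-peak intervals examined).
#' @export
detect_attractor <- function(traj, tol_ss = 1e-8, tol_amp = 1e-3,
                             tol_per = 0.005) {
  stopifnot(inherits(traj, "acdc_trajectory"))
  x <- attr(traj, "model")
  model <- as_model(x)
  S <- attr(traj, "S")
  tt <- traj$t
  Y <- as.matrix(traj[, model$names, drop = FALSE])
  t_end <- tt[length(tt)]
  win <- tt >= t_end / 2
  scale <- pmax(model$maxima, 1e-12)

  y_end <- Y[nrow(Y), ]
  residual <- max(abs(model$rhs(pmax(y_end, 0), S)))
  amp_win <- apply(Y[win, , drop = FALSE], 2, function(v) diff(range(v))) / scale
  tail_win <- tt >= t_end - max(0.1 * t_end, 10 * mean(diff(tt)))
  amp_tail <- apply(Y[tail_win, , drop = FALSE], 2,
                    function(v) diff(range(v))) / scale

  # most active variable drives oscillation analysis (O for the 3-gene model)
  v_idx <- which.max(amp_win)
  peaks <- local_maxima(Y[, v_idx])
  peaks <- peaks[win[peaks]]
  # drop flat/noise peaks
  if (length(peaks)) {
    big <- (Y[peaks, v_idx] - min(Y[win, v_idx])) / scale[v_idx] > tol_amp / 2
    peaks <- peaks[big]
  }

  if (residual < tol_ss && all(amp_tail < tol_amp)) {
    type <- "fixed_point"
    # damped approach: at least four extrema above tol_amp whose deviations
    # from the end state decay (examined over the whole trajectory -- by the
    # time the residual has converged the analysis window is already flat)
    dev <- abs(Y[, v_idx] - y_end[v_idx]) / scale[v_idx]
    pk <- local_maxima(dev)
    pk <- pk[dev[pk] > tol_amp]
    h <- dev[pk]
    if (length(h) >= 4 && h[1] > 2 * h[length(h)] &&
        mean(diff(h) < 0) >= 0.6)
      type <- "damped_oscillation_to_fixed_point"
    out <- list(type = type, state = y_end, period = NA_real_,
                extrema = NULL, residual = residual, periods = numeric())
    class(out) <- "acdc_attractor"
    return(out)
  }

  # candidate cycle: period from events (threshold) or refined peaks (graded)
  periods <- numeric()
  ev <- attr(traj, "events")
  if (nrow(ev) > 0 && model$mode == "threshold") {
    ev_win <- ev[ev$time >= t_end / 2, , drop = FALSE]
    if (nrow(ev_win) > 0) {
      key <- paste(ev_win$label, ev_win$direction)
      main <- names(sort(table(key), decreasing = TRUE))[1]
      tms <- ev_win$time[key == main]
      if (length(tms) >= 4) periods <- diff(tms)
    }
  }
  if (length(periods) < 3 && length(peaks) >= 4) {
    ptimes <- vapply(peaks, function(i) refine_peak(tt, Y[, v_idx], i),
                     numeric(1))
    periods <- diff(ptimes)
  }
  # a slowly damping spiral has near-constant periods; require steady peak
  # heights as well before calling it a cycle (graded mode: smooth peaks)
  peaks_steady <- TRUE
  if (model$mode == "graded" && length(peaks) >= 4) {
    pv <- Y[utils::tail(peaks, 5), v_idx]
    drift <- (max(pv) - min(pv)) / max(abs(stats::median(pv)), 1e-12)
    peaks_steady <- drift < 5 * tol_per
  }
  if (length(periods) >= 3 && peaks_steady) {
    last <- utils::tail(periods, 5)
    spread <- (max(last) - min(last)) / stats::median(last)
    if (spread < tol_per && max(amp_win) >= tol_amp) {
      per <- mean(last)
      cyc <- tt >= t_end - 2 * per
      extrema <- data.frame(
        variable = model$names,
        min = apply(Y[cyc, , drop = FALSE], 2, min),
        max = apply(Y[cyc, , drop = FALSE], 2, max),
        stringsAsFactors = FALSE)
      out <- list(type = "limit_cycle", state = y_end, period = per,
                  extrema = extrema, residual = residual, periods = periods)
      class(out) <- "acdc_attractor"
      return(out)
    }
  }
  out <- list(type = "undecided", state = y_end, period = NA_real_,
              extrema = NULL, residual = residual, periods = periods)
  class(out) <- "acdc_attractor"
  out
}

#' @export
print.acdc_attractor <- function(x, ...) {
  cat("Attractor:", x$type, "\n")
  if (x$type == "limit_cycle") {
    cat(sprintf("  period = %.6g\n", x$period))
    print(x$extrema, row.names = FALSE)
  } else {
    cat("  state:", paste(sprintf("%.6g", x$state), collapse = ", "),
        sprintf(" (residual %.3g)\n", x$residual))
  }
  invisible(x)
}

#' Bifurcation scan over the signal level
#'
#' Integrates the circuit at each value of an increasing signal grid and
#' tabulates the detected attractor: the steady-state value of O where the
#' system converges, or the O maximum/minimum and period where it settles on
#' a limit cycle. This reproduces, as data, the structure of the model's
#' bifurcation diagrams.
#'
#' @param x an \code{\link{circuit_params}} or
#'   \code{\link{multigene_circuit}}.
#' @param S_values increasing signal grid (default 201 points on [0, 10]).
#' @param t_end integration horizon per signal value (default 500).
#' @param init_policy \code{"fixed"} restarts every run from the pre-signal
#'   state; \code{"adiabatic"} carries the final state to the next grid
#'   point.
#' @param include_unstable if \code{TRUE} (graded 3-gene circuits only),
#'   also tabulates all fixed points found by
#'   \code{\link{find_fixed_points}} with their stability, as attribute
#'   \code{fixed_points}.
#' @param ... passed to \code{\link{integrate_circuit}}.
#' @return data frame of class \code{acdc_bifurcation} with columns
#'   \code{S}, \code{type}, \code{O_ss}, \code{O_max}, \code{O_min},
#'   \code{period}, plus the terminal state of every gene.
#' @export
scan_bifurcation <- function(x, S_values = seq(0, 10, length.out = 201),
                             t_end = 500, init_policy = c("fixed", "adiabatic"),
                             include_unstable = FALSE, ...) {
  init_policy <- match.arg(init_policy)
  if (is.unsorted(S_values, strictly = TRUE))
    stop("scan_bifurcation(): S_values must be strictly increasing")
  model <- as_model(x)
  o_var <- if ("O" %in% model$names) "O" else model$names[min(2, model$n)]
  state <- initial_state(x)
  rows <- vector("list", length(S_values))
  fps <- list()
  for (i in seq_along(S_values)) {
    S <- S_values[i]
    init <- if (init_policy == "fixed") initial_state(x) else state
    tr <- integrate_circuit(x, S, init = init, t_end = t_end,
                            stop_at_steady = TRUE, ...)
    at <- detect_attractor(tr)
    state <- at$state
    is_cyc <- at$type == "limit_cycle"
    row <- data.frame(S = S, type = at$type,
                      O_ss = if (is_cyc) NA_real_ else at$state[[o_var]],
                      O_max = if (is_cyc)
                        at$extrema$max[at$extrema$variable == o_var] else NA_real_,
                      O_min = if (is_cyc)
                        at$extrema$min[at$extrema$variable == o_var] else NA_real_,
                      period = if (is_cyc) at$period else NA_real_,
                      stringsAsFactors = FALSE)
    fin <- as.data.frame(t(at$state))
    names(fin) <- paste0(model$names, "_end")
    rows[[i]] <- cbind(row, fin)
    if (include_unstable && inherits(x, "acdc_params") && x$mode == "graded") {
      fp <- find_fixed_points(x, S)
      if (nrow(fp)) fps[[length(fps) + 1]] <- cbind(S = S, fp)
    }
  }
  out <- do.call(rbind, rows)
  if (length(fps)) attr(out, "fixed_points") <- do.call(rbind, fps)
  class(out) <- c("acdc_bifurcation", "data.frame")
  out
}

#' Contiguous oscillatory interval of a bifurcation scan
#'
#' @param scan an \code{acdc_bifurcation} from \code{\link{scan_bifurcation}}.
#' @return list with \code{n_cycles} (number of limit-cycle rows),
#'   \code{S_lo}, \code{S_hi} (range of oscillatory S, NA if none) and
#'   \code{contiguous} (whether the limit-cycle rows form one block).
#' @export
oscillatory_interval <- function(scan) {
  stopifnot(inherits(scan, "acdc_bifurcation"))
  idx <- which(scan$type == "limit_cycle")
  if (!length(idx))
    return(list(n_cycles = 0L, S_lo = NA_real_, S_hi = NA_real_,
                contiguous = TRUE))
  list(n_cycles = length(idx), S_lo = scan$S[min(idx)],
       S_hi = scan$S[max(idx)],
       contiguous = all(diff(idx) == 1L))
}

# Classify a converged state by which induced genes are expressed: B1 (N
# absent), B2 (O absent) or B3 (co-expressed).  Robust at branch-boundary
# states where the strict existence predicates are momentarily all false.
occupied_branch <- function(state, maxima, on_tol = 1e-3) {
  o_on <- state[2] > on_tol * maxima[2]
  n_on <- state[3] > on_tol * maxima[3]
  if (!n_on) "B1" else if (!o_on) "B2" else "B3"
}

# One adiabatic step: integrate towards the attractor at signal S, extending
# the horizon once if undecided.  Returns the terminal state and a label in
# {B1, B2, B3, osc, undecided}.  A short first phase exits early on the two
# common outcomes: quick convergence (the step barely moved the attractor)
# or fast cycling (many switching events in a few half-lives).
adiabatic_step <- function(x, S, state, t_step, maxima, rtol, atol, ss_tol) {
  t1 <- max(t_step / 4, 10)
  tr <- integrate_circuit(x, S, init = state, t_end = t1, dt = 1,
                          rtol = rtol, atol = atol,
                          stop_at_steady = TRUE, ss_tol = ss_tol)
  y <- pmax(as.numeric(tr[nrow(tr), -1]), 0)
  if (isTRUE(attr(tr, "converged")))
    return(list(state = y, label = occupied_branch(y, maxima)))
  if (nrow(attr(tr, "events")) >= 6)
    return(list(state = y, label = "osc"))
  tr <- integrate_circuit(x, S, init = y, t_end = t_step, dt = 1,
                          rtol = rtol, atol = atol,
                          stop_at_steady = TRUE, ss_tol = ss_tol)
  y <- pmax(as.numeric(tr[nrow(tr), -1]), 0)
  if (isTRUE(attr(tr, "converged")))
    return(list(state = y, label = occupied_branch(y, maxima)))
  n_ev <- sum(attr(tr, "events")$time >= t_step / 2)
  if (n_ev >= 6) return(list(state = y, label = "osc"))
  # slow transient or long-period cycle: extend once
  tr <- integrate_circuit(x, S, init = y, t_end = 4 * t_step, dt = 1,
                          rtol = rtol, atol = atol,
                          stop_at_steady = TRUE, ss_tol = ss_tol)
  y <- pmax(as.numeric(tr[nrow(tr), -1]), 0)
  if (isTRUE(attr(tr, "converged")))
    return(list(state = y, label = occupied_branch(y, maxima)))
  if (sum(attr(tr, "events")$time >= 2 * t_step) >= 4)
    return(list(state = y, label = "osc"))
  list(state = y, label = "undecided")
}

#' Adiabatic hysteresis sweep
#'
#' Sweeps the signal up from zero and back down from \code{S_max}, carrying
#' the converged state from each grid point to the next, and records the
#' signal values at which the occupied steady-state branch changes. Because
#' stable branches overlap, the up- and down-transitions differ: the signal
#' needed to switch N on exceeds the signal needed to maintain it.
#'
#' @param params threshold-mode \code{\link{circuit_params}}.
#' @param S_max top of the sweep.
#' @param n_steps number of grid points per direction.
#' @param t_step integration horizon per grid point.
#' @return list of class \code{acdc_hysteresis}: \code{up}, \code{down}
#'   (data frames of S and occupied branch, in sweep order) and
#'   \code{transitions} (direction, from, to, S_lo, S_hi, S_mid), where
#'   \code{S_mid} is the midpoint of the bracketing grid interval.
#' @export
sweep_hysteresis <- function(params, S_max = 3, n_steps = 241, t_step = 60) {
  stopifnot(inherits(params, "acdc_params"))
  require_threshold(params, "sweep_hysteresis()")
  grid <- seq(0, S_max, length.out = n_steps)
  m <- unname(param_maxima(params))
  run <- function(S_seq, init) {
    state <- init
    lab <- character(length(S_seq))
    for (i in seq_along(S_seq)) {
      st <- adiabatic_step(params, S_seq[i], state, t_step, m,
                           rtol = 1e-8, atol = 1e-10, ss_tol = 1e-9)
      state <- st$state
      lab[i] <- st$label
    }
    list(labels = lab, state = state)
  }
  up <- run(grid, initial_state(params))
  down <- run(rev(grid), up$state)
  trans <- function(S_seq, lab, direction) {
    ch <- which(lab[-1] != lab[-length(lab)])
    if (!length(ch)) return(NULL)
    data.frame(direction = direction, from = lab[ch], to = lab[ch + 1],
               S_lo = pmin(S_seq[ch], S_seq[ch + 1]),
               S_hi = pmax(S_seq[ch], S_seq[ch + 1]),
               S_mid = (S_seq[ch] + S_seq[ch + 1]) / 2,
               stringsAsFactors = FALSE)
  }
  out <- list(up = data.frame(S = grid, branch = up$labels,
                              stringsAsFactors = FALSE),
              down = data.frame(S = rev(grid), branch = down$labels,
                                stringsAsFactors = FALSE),
              transitions = rbind(trans(grid, up$labels, "up"),
                                  trans(rev(grid), down$labels, "down")))
  class(out) <- "acdc_hysteresis"
  out
}

#' @export
print.acdc_hysteresis <- function(x, ...) {
  cat("Hysteresis sweep transitions:\n")
  print(x$transitions, row.names = FALSE)
  invisible(x)
}

#' Fixed points of the graded model
#'
#' Finds all roots of the graded-mode right-hand side at a given signal by
#' multi-start damped Newton iteration on the reduced (O, N) system (P is
#' explicit at steady state), annotates each with the eigenvalues of the
#' full Jacobian, and merges duplicates. Unstable fixed points inside an
#' oscillatory signal range typically carry a complex eigenvalue pair of
#' positive real part (unstable focus).
#'
#' @param params graded-mode \code{\link{circuit_params}}.
#' @param S signal level.
#' @param grid_n starts per axis of the (O, N) start grid.
#' @param tol Newton convergence tolerance on the residual max-norm.
#' @return data frame with columns \code{P}, \code{O}, \code{N},
#'   \code{stable}, \code{max_re_eig}, \code{focus} (complex eigenvalue
#'   pair); attribute \code{eigenvalues} holds the full eigenvalue list.
#' @export
find_fixed_points <- function(params, S, grid_n = 5, tol = 1e-11) {
  stopifnot(inherits(params, "acdc_params"))
  if (params$mode != "graded")
    stop("find_fixed_points() requires graded mode; threshold-mode fixed points are the analytic branches")
  m <- param_maxima(params)
  d <- induction_drive(S, params$S_half)
  P_of <- function(O, N) (params$alpha / params$k1) *
    p_repression_factor(N, O, params)
  G <- function(v) {
    O <- v[1]; N <- v[2]
    P <- P_of(O, N)
    c((params$beta / params$k2) * d *
        hill_repressor(N, params$N_crit1, params$h4) - O,
      (params$gamma / params$k3) * d *
        hill_repressor(P, params$P_crit1, params$h3) *
        hill_repressor(O, params$O_crit1, params$h5) - N)
  }
  scale <- max(m)
  newton <- function(v0) {
    v <- pmax(v0, 0)
    for (it in 1:80) {
      g <- G(v)
      if (max(abs(g)) < tol * scale) return(v)
      h <- 1e-7 * scale
      J <- matrix(0, 2, 2)
      for (j in 1:2) {
        e <- c(0, 0); e[j] <- h
        J[, j] <- (G(pmax(v + e, 0)) - G(pmax(v - e, 0))) / (2 * h)
      }
      step <- tryCatch(solve(J, -g), error = function(e) NULL)
      if (is.null(step)) return(NULL)
      lam <- 1
      for (k in 1:30) {
        vn <- pmax(v + lam * step, 0)
        if (max(abs(G(vn))) < max(abs(g))) break
        lam <- lam / 2
      }
      v <- pmax(v + lam * step, 0)
    }
    if (max(abs(G(v))) < tol * scale) v else NULL
  }
  starts <- expand.grid(
    O = seq(0, m[["O_max"]], length.out = grid_n),
    N = seq(0, m[["N_max"]], length.out = grid_n))
  # the threshold-limit branch values make good extra starts
  thr <- modify_params(params, mode = "threshold")
  for (l in c("B1", "B2", "B3")) {
    b <- branch_value(l, S, thr)
    starts <- rbind(starts, data.frame(O = b[["O"]], N = b[["N"]]))
  }
  roots <- list()
  for (i in seq_len(nrow(starts))) {
    v <- newton(as.numeric(starts[i, ]))
    if (is.null(v)) next
    dup <- any(vapply(roots, function(r)
      max(abs(r - v)) < 1e-6 * scale, logical(1)))
    if (!dup) roots[[length(roots) + 1]] <- v
  }
  if (!length(roots))
    return(data.frame(P = numeric(), O = numeric(), N = numeric(),
                      stable = logical(), max_re_eig = numeric(),
                      focus = logical()))
  eigs <- list()
  rows <- lapply(roots, function(v) {
    st <- c(P = P_of(v[1], v[2]), O = v[1], N = v[2])
    J <- circuit_jacobian(st, S, params)
    ev <- eigen(J, only.values = TRUE)$values
    eigs[[length(eigs) + 1]] <<- ev
    data.frame(P = st[["P"]], O = st[["O"]], N = st[["N"]],
               stable = all(Re(ev) < 0),
               max_re_eig = max(Re(ev)),
               focus = any(abs(Im(ev)) > 1e-9))
  })
  out <- do.call(rbind, rows)
  ord <- order(out$N, out$O)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "eigenvalues") <- eigs[ord]
  out
}
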