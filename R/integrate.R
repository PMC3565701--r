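# ---- Event-aware numerical integration -------------------------------------
#
# In threshold mode the vector field is discontinuous across the switching
# surfaces (a gene concentration crossing a Heaviside threshold).  Between
# crossings the field is smooth, so integration proceeds segment by segment:
# the Heaviside configuration is frozen at the segment start, lsodar locates
# the first threshold crossing as a root, and integration restarts there with
# the configuration re-evaluated.  Crossings in this circuit are transversal
# (no switching variable feeds back instantaneously on itself), so a small
# nudge along the new field moves the state off the surface.

# Uniform internal representation of an integrable system.  `core(y, d, H)`
# is an unvalidated fast right-hand side taking the precomputed induction
# drive d; `rhs(y, S, H)` is the same with the drive computed from S.
as_model <- function(x) {
  if (inherits(x, "acdc_params")) {
    thr <- if (x$mode == "threshold") {
      data.frame(var = c(1L, 2L, 3L), crit = c(x$P_crit1, x$O_crit1, x$N_crit1),
                 label = c("P_crit1", "O_crit1", "N_crit1"),
                 stringsAsFactors = FALSE)
    } else data.frame(var = integer(), crit = numeric(), label = character())
    product <- x$p_repression == "product"
    threshold <- x$mode == "threshold"
    alpha <- x$alpha; beta <- x$beta; gamma <- x$gamma
    k1 <- x$k1; k2 <- x$k2; k3 <- x$k3
    Ncr <- x$N_crit; Ocr <- x$O_crit; h1 <- x$h1; h2 <- x$h2
    Pc1 <- x$P_crit1; Oc1 <- x$O_crit1; Nc1 <- x$N_crit1
    h3 <- x$h3; h4 <- x$h4; h5 <- x$h5
    core <- function(y, d, H = NULL) {
      P <- y[1]; O <- y[2]; N <- y[3]
      if (P < 0) P <- 0
      if (O < 0) O <- 0
      if (N < 0) N <- 0
      if (threshold) {
        if (is.null(H)) {
          rPN <- if (P <= Pc1) 1 else 0
          rON <- if (O <= Oc1) 1 else 0
          rNO <- if (N <= Nc1) 1 else 0
        } else { rPN <- H[1]; rON <- H[2]; rNO <- H[3] }
      } else {
        rPN <- 1 / (1 + (P / Pc1)^h3)
        rON <- 1 / (1 + (O / Oc1)^h5)
        rNO <- 1 / (1 + (N / Nc1)^h4)
      }
      uN <- (N / Ncr)^h1; uO <- (O / Ocr)^h2
      rep <- if (product) 1 / ((1 + uN) * (1 + uO)) else 1 / (1 + uN + uO)
      c(alpha * rep - k1 * P,
        beta * d * rNO - k2 * O,
        gamma * d * rPN * rON - k3 * N)
    }
    list(n = 3L, names = c("P", "O", "N"),
         maxima = unname(param_maxima(x)),
         mode = x$mode, S_half = x$S_half,
         thresholds = thr,
         core = core,
         rhs = function(y, S, H = NULL)
           core(y, induction_drive(S, x$S_half), H),
         config = function(y) heaviside(thr$crit - y[thr$var]))
  } else if (inherits(x, "acdc_multigene")) {
    e <- x$edges
    thr_rows <- which(e$form == "threshold")
    g <- x$genes
    thr <- if (length(thr_rows)) {
      data.frame(var = match(e$source[thr_rows], g$name),
                 crit = e$crit[thr_rows],
                 label = paste0(e$source[thr_rows], "->", e$target[thr_rows]),
                 stringsAsFactors = FALSE)
    } else data.frame(var = integer(), crit = numeric(), label = character())
    src_idx <- match(e$source, g$name)
    is_thr <- e$form == "threshold"
    thr_pos <- match(seq_len(nrow(e)), thr_rows)  # edge -> H position
    acting <- lapply(g$name, function(nm) which(e$target == nm))
    base_const <- g$production * as.numeric(g$constitutive)
    base_ind <- g$production * as.numeric(!g$constitutive)
    e_crit <- e$crit; e_h <- e$h; n_edge <- nrow(e); decay <- g$decay
    core <- function(y, d, H = NULL) {
      y[y < 0] <- 0
      src <- y[src_idx]
      dy <- numeric(length(y))
      for (j in seq_along(y)) {
        thr_fac <- 1; hill_den <- 1
        for (i in acting[[j]]) {
          if (is_thr[i]) {
            thr_fac <- thr_fac * (if (is.null(H)) (src[i] <= e_crit[i]) + 0
                                  else H[thr_pos[i]])
          } else {
            hill_den <- hill_den + (src[i] / e_crit[i])^e_h[i]
          }
        }
        dy[j] <- (base_const[j] + base_ind[j] * d) * thr_fac / hill_den -
          decay[j] * y[j]
      }
      dy
    }
    list(n = nrow(g), names = g$name,
         maxima = g$production / g$decay,
         mode = "threshold", S_half = x$S_half,
         thresholds = thr,
         core = core,
         rhs = function(y, S, H = NULL)
           core(y, induction_drive(S, x$S_half), H),
         config = function(y) heaviside(thr$crit - y[thr$var]))
  } else stop("as_model(): unsupported object")
}

#' Integrate a circuit forward in time
#'
#' Numerical solution of the circuit ODEs at fixed signal level. Threshold
#' mode uses event-aware stepping: integration is restarted at every
#' crossing of a switching threshold, located by root finding, and the event
#' times are recorded. Graded mode integrates the smooth system directly.
#'
#' @param x an \code{\link{circuit_params}} or
#'   \code{\link{multigene_circuit}} object.
#' @param S signal level, \code{>= 0}.
#' @param init initial expression state; defaults to
#'   \code{\link{initial_state}(x)} (pre-signal resting state).
#' @param t_end end time, \code{> 0}.
#' @param dt output sampling interval.
#' @param rtol,atol solver tolerances (deSolve lsodar).
#' @param stop_at_steady if \code{TRUE}, stop early once the right-hand side
#'   norm falls below \code{ss_tol} (convergence treated as a root).
#' @param ss_tol steady-state detection tolerance on the RHS 2-norm.
#' @param max_events safety cap on threshold crossings.
#' @return object of class \code{acdc_trajectory}: data frame with column
#'   \code{t} and one column per gene, with attributes \code{S},
#'   \code{events} (data frame of crossing times and labels),
#'   \code{converged}, \code{model} (the input object).
#' @examples
#' tr <- integrate_circuit(load_preset("fig2a"), S = 5, t_end = 30)
#' tail(tr, 2)
#' @export
integrate_circuit <- function(x, S, init = initial_state(x), t_end,
                              dt = 0.05, rtol = 1e-9, atol = 1e-11,
                              stop_at_steady = FALSE, ss_tol = 1e-9,
                              max_events = 50000) {
  model <- as_model(x)
  if (!is.numeric(t_end) || t_end <= 0) stop("integrate_circuit(): t_end must be > 0")
  y <- as.numeric(init)
  if (length(y) != model$n || any(y < 0) || any(!is.finite(y)))
    stop("integrate_circuit(): init must be a nonnegative state of length ",
         model$n)
  n_thr <- nrow(model$thresholds)
  ev_time <- numeric(0); ev_label <- character(0); ev_dir <- numeric(0)
  converged <- FALSE

  drive <- induction_drive(S, model$S_half)
  thr_var <- model$thresholds$var
  thr_crit <- model$thresholds$crit
  core <- model$core
  rootfun_for <- function(H) {
    function(t, y, parms) {
      r <- numeric(0)
      if (n_thr > 0) r <- y[thr_var] - thr_crit
      if (stop_at_steady) {
        f <- core(y, drive, H)
        r <- c(r, sqrt(sum(f * f)) - ss_tol)
      }
      r
    }
  }
  derivfun_for <- function(H) {
    function(t, y, parms) list(core(y, drive, H))
  }
  config_of <- function(y) as.numeric(y[thr_var] <= thr_crit)

  has_roots <- n_thr > 0 || stop_at_steady
  t0 <- 0
  rows <- list()
  first_seg <- TRUE
  repeat {
    H <- if (n_thr > 0) config_of(y) else NULL
    # lsodar rejects roots sitting exactly at the initial point: stop here if
    # already converged, and step off any switching surface before starting
    f0 <- core(y, drive, H)
    if (stop_at_steady && sqrt(sum(f0 * f0)) <= ss_tol) {
      converged <- TRUE
      seg <- rbind(c(t0, y), c(t_end, y))
      if (!first_seg) seg <- seg[-1, , drop = FALSE]
      rows[[length(rows) + 1]] <- seg
      break
    }
    if (n_thr > 0) {
      rv <- y[thr_var] - thr_crit
      h <- 1e-9
      while (any(abs(rv) < 1e-11) && h < 1e-5) {
        y <- pmax(y + h * f0, 0)
        t0 <- t0 + h
        rv <- y[thr_var] - thr_crit
        h <- h * 10
        H <- config_of(y)
        f0 <- core(y, drive, H)
      }
    }
    times <- unique(c(seq(t0, t_end, by = dt), t_end))
    if (length(times) < 2) times <- c(t0, t_end)
    out <- if (has_roots) {
      deSolve::lsodar(y = y, times = times, func = derivfun_for(H),
                      parms = NULL, rootfunc = rootfun_for(H),
                      rtol = rtol, atol = atol)
    } else {
      deSolve::lsoda(y = y, times = times, func = derivfun_for(H),
                     parms = NULL, rtol = rtol, atol = atol)
    }
    troot <- attr(out, "troot")
    iroot <- which(attr(out, "iroot") == 1L)
    seg <- unclass(out)
    attributes(seg) <- list(dim = dim(out))
    if (!first_seg && nrow(seg) > 1) seg <- seg[-1, , drop = FALSE]
    rows[[length(rows) + 1]] <- seg
    first_seg <- FALSE
    t_last <- out[nrow(out), 1]
    y <- pmax(as.numeric(out[nrow(out), -1]), 0)

    if (is.null(troot) || length(troot) == 0 || t_last >= t_end - 1e-12) {
      if (!is.null(iroot) && stop_at_steady && any(iroot == n_thr + 1))
        converged <- TRUE
      break
    }
    # a root fired before t_end
    if (stop_at_steady && any(iroot == n_thr + 1)) { converged <- TRUE; break }
    hit <- iroot[iroot <= n_thr]
    f_new <- core(y, drive, NULL)   # field with configuration re-evaluated
    for (k in hit) {
      ev_time <- c(ev_time, t_last)
      ev_label <- c(ev_label, model$thresholds$label[k])
      ev_dir <- c(ev_dir, sign(f_new[thr_var[k]]))
    }
    if (length(ev_time) > max_events)
      stop("integrate_circuit(): exceeded max_events = ", max_events,
           " threshold crossings (possible chattering)")
    # nudge off the switching surface along the new field
    h <- 1e-9
    y <- pmax(y + h * f_new, 0)
    t0 <- t_last + h
    if (t0 >= t_end) break
  }
  traj <- as.data.frame(do.call(rbind, rows))
  names(traj) <- c("t", model$names)
  rownames(traj) <- NULL
  events <- data.frame(time = ev_time, label = ev_label, direction = ev_dir,
                       stringsAsFactors = FALSE)
  structure(traj, S = S, events = events, converged = converged,
            model = x, class = c("acdc_trajectory", "data.frame"))
}

#' @export
print.acdc_trajectory <- function(x, ...) {
  ev <- attr(x, "events")
  cat(sprintf("Trajectory: %d samples, t in [%g, %g], S = %g, %d switching events%s\n",
              nrow(x), x$t[1], x$t[nrow(x)], attr(x, "S"), nrow(ev),
              if (isTRUE(attr(x, "converged"))) ", converged" else ""))
  invisible(x)
}
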