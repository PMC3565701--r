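# ---- Closed-form steady-state branches of the threshold model -------------
#
# B1: N absent; B2: O absent; B3: O and N co-expressed.  Each branch value is
# an explicit function of the induction drive d(S); existence is
# self-consistency of the branch with the Heaviside configuration it assumes
# (H(0) = 1 convention, so a production term is OFF only for strictly
# negative arguments).

require_threshold <- function(params, what) {
  if (params$mode != "threshold")
    stop(what, " is defined for the threshold model (mode = \"threshold\")")
}

#' Steady-state branch value
#'
#' Closed-form expression state of branch \code{B1}, \code{B2} or \code{B3}
#' of the threshold model at signal \code{S}:
#' \itemize{
#'   \item B1: \code{N = 0}, \code{O = O_max d(S)},
#'     \code{P = P_max R(O; O_crit, h2)}
#'   \item B2: \code{O = 0}, \code{N = N_max d(S)},
#'     \code{P = P_max R(N; N_crit, h1)}
#'   \item B3: \code{O = O_max d(S)}, \code{N = N_max d(S)},
#'     \code{P = P_max R(N; N_crit, h1) R(O; O_crit, h2)}
#' }
#' Whenever the branch exists (\code{\link{branch_exists}}), the returned
#' state is an exact zero of \code{\link{circuit_rhs}}, and the Jacobian
#' there has eigenvalues \code{-k1, -k2, -k3}, so every branch is stable
#' where it exists.
#'
#' @param label one of \code{"B1"}, \code{"B2"}, \code{"B3"}.
#' @param S signal level, \code{>= 0}.
#' @param params threshold-mode \code{\link{circuit_params}}.
#' @return named numeric state \code{c(P, O, N)}.
#' @export
branch_value <- function(label, S, params) {
  stopifnot(inherits(params, "acdc_params"))
  require_threshold(params, "branch_value()")
  if (!label %in% c("B1", "B2", "B3"))
    stop("branch_value(): unknown branch label '", label, "'")
  m <- param_maxima(params)
  d <- induction_drive(S, params$S_half)
  switch(label,
    B1 = {
      O <- m[["O_max"]] * d
      c(P = m[["P_max"]] * hill_repressor(O, params$O_crit, params$h2),
        O = O, N = 0)
    },
    B2 = {
      N <- m[["N_max"]] * d
      c(P = m[["P_max"]] * hill_repressor(N, params$N_crit, params$h1),
        O = 0, N = N)
    },
    B3 = {
      O <- m[["O_max"]] * d
      N <- m[["N_max"]] * d
      c(P = m[["P_max"]] * p_repression_factor(N, O, params), O = O, N = N)
    })
}

#' Does a steady-state branch exist (and hence is stable)?
#'
#' Self-consistency of the branch with its Heaviside configuration under the
#' \code{H(0) = 1} convention:
#' \itemize{
#'   \item B1 requires N production OFF at its state: \code{P > P_crit1} or
#'     \code{O > O_crit1} (strict, since \code{H(0) = 1} keeps production ON
#'     at equality);
#'   \item B2 requires \code{N > N_crit1} (O production OFF) and
#'     \code{P <= P_crit1} (N production ON);
#'   \item B3 requires \code{N <= N_crit1}, \code{P <= P_crit1} and
#'     \code{O <= O_crit1} (both productions ON).
#' }
#' B2 and B3 can never coexist: they share the same N value and their
#' \code{N_crit1} requirements are complementary.
#'
#' @inheritParams branch_value
#' @return logical.
#' @export
branch_exists <- function(label, S, params) {
  v <- branch_value(label, S, params)
  switch(label,
    B1 = v[["P"]] > params$P_crit1 || v[["O"]] > params$O_crit1,
    B2 = v[["N"]] > params$N_crit1 && v[["P"]] <= params$P_crit1,
    B3 = v[["N"]] <= params$N_crit1 && v[["P"]] <= params$P_crit1 &&
         v[["O"]] <= params$O_crit1)
}

#' Parameter validity for biologically relevant switching
#'
#' The constraints under which the circuit behaves as a morphogen
#' interpreter: the constitutive gene silences N at zero signal, B1 is
#' eventually lost as the signal grows, B2 is attained (with O off) at high
#' signal, and O never represses N (required for tripartite behaviour under
#' all-or-nothing repression).
#'
#' @param params threshold-mode \code{\link{circuit_params}}.
#' @return data frame with one row per condition (\code{id},
#'   \code{description}, \code{pass}) and attribute \code{valid} (all pass);
#'   class \code{acdc_validity}.
#' @export
validity_conditions <- function(params) {
  stopifnot(inherits(params, "acdc_params"))
  require_threshold(params, "validity_conditions()")
  m <- param_maxima(params)
  out <- data.frame(
    id = c("n_silent_at_zero", "b1_eventually_lost",
           "b2_reachable", "b2_silences_p_gate", "o_never_represses_n"),
    description = c(
      "P_max > P_crit1: N silent before signal onset",
      "P_max R(O_max; O_crit, h2) < P_crit1: B1 lost at high signal",
      "N_max > N_crit1: N can switch O off",
      "P_max R(N_max; N_crit, h1) < P_crit1: B2 self-maintaining at high signal",
      "O_max <= O_crit1: O never represses N (tripartite realism)"),
    pass = c(
      m[["P_max"]] > params$P_crit1,
      m[["P_max"]] * hill_repressor(m[["O_max"]], params$O_crit, params$h2) <
        params$P_crit1,
      m[["N_max"]] > params$N_crit1,
      m[["P_max"]] * hill_repressor(m[["N_max"]], params$N_crit, params$h1) <
        params$P_crit1,
      m[["O_max"]] <= params$O_crit1),
    stringsAsFactors = FALSE)
  attr(out, "valid") <- all(out$pass)
  class(out) <- c("acdc_validity", "data.frame")
  out
}

#' @export
print.acdc_validity <- function(x, ...) {
  cat("Circuit validity:", if (attr(x, "valid")) "VALID" else "INVALID", "\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  [%s] %s\n", if (x$pass[i]) "ok" else "FAIL",
                x$description[i]))
  invisible(x)
}

# Drive levels at which the branch structure changes.  Everything depends on
# S only through d(S), so transition points are computed in drive space and
# mapped back through s_from_drive() (exact, as d is strictly monotone).
transition_drives <- function(params) {
  m <- param_maxima(params)
  ratio <- m[["P_max"]] / params$P_crit1      # > 1 for valid parameters
  O_dag <- params$O_crit * (ratio - 1)^(1 / params$h2)  # O at which B1's P hits P_crit1
  N_dag <- params$N_crit * (ratio - 1)^(1 / params$h1)  # N at which B2's P hits P_crit1
  d1 <- O_dag / m[["O_max"]]                  # B1 ceases
  dN <- params$N_crit1 / m[["N_max"]]         # N crosses its O-silencing threshold
  dNdag <- N_dag / m[["N_max"]]               # B2's P-gate opens
  d2 <- max(dN, dNdag)                        # B2 exists for d > d2
  # B3 onset: smallest d with P_B3(d) <= P_crit1 (P_B3 strictly decreasing in d)
  f <- function(d) {
    v <- branch_value("B3", s_from_drive(min(d, 1 - 1e-12), params$S_half), params)
    v[["P"]] - params$P_crit1
  }
  d0 <- NA_real_
  if (f(0) > 0 && f(1 - 1e-9) < 0)
    d0 <- stats::uniroot(f, c(0, 1 - 1e-9), tol = 1e-14)$root
  else if (f(0) <= 0) d0 <- 0
  list(d0 = d0, d1 = d1, dN = dN, dNdag = dNdag, d2 = d2)
}

#' Route through the steady states
#'
#' As the signal rises adiabatically from zero, the system leaves B1 either
#' directly for B2 (route 1) or via the co-expressed state B3 (route 2).
#' Route 2 is taken when B3 exists at the signal where B1 ceases, i.e. when
#' N is still below \code{N_crit1} there.
#'
#' @param params threshold-mode \code{\link{circuit_params}}.
#' @return \code{"route1"}, \code{"route2"} or \code{"invalid"} (parameters
#'   failing \code{\link{validity_conditions}}).
#' @export
classify_route <- function(params) {
  stopifnot(inherits(params, "acdc_params"))
  require_threshold(params, "classify_route()")
  if (!attr(validity_conditions(params), "valid")) return("invalid")
  td <- transition_drives(params)
  m <- param_maxima(params)
  if (m[["N_max"]] * td$d1 < params$N_crit1) "route2" else "route1"
}

#' Oscillation gap in the branch structure
#'
#' The open interval of signal values in which no stable steady state
#' exists, so the system settles on a limit cycle (N high, then P high,
#' then O high, repeating). On route 1 a gap opens when B2 gains existence
#' only after B1 is lost; on route 2 when, at the signal where N reaches
#' \code{N_crit1} and shuts O off, N's repression of P is still too weak to
#' keep P below \code{P_crit1}, i.e.
#' \code{P_max/P_crit1 > 1 + (N_crit1/N_crit)^h1}. For \code{h1 = h2} the
#' route-1 criterion reduces to \code{N_max/N_crit < O_max/O_crit}
#' (repression of P by O stronger than by N).
#'
#' @param params threshold-mode \code{\link{circuit_params}} passing
#'   \code{\link{validity_conditions}}.
#' @return list with \code{gap} (logical), and when a gap is present
#'   \code{S_lo}, \code{S_hi} (open interval of oscillatory signal) plus the
#'   corresponding drives \code{d_lo}, \code{d_hi}.
#' @export
oscillation_gap <- function(params) {
  stopifnot(inherits(params, "acdc_params"))
  require_threshold(params, "oscillation_gap()")
  if (!attr(validity_conditions(params), "valid"))
    stop("oscillation_gap(): parameters fail validity_conditions()")
  td <- transition_drives(params)
  route <- classify_route(params)
  d_lo <- if (route == "route1") td$d1 else td$dN
  if (td$d2 > d_lo) {
    list(gap = TRUE,
         S_lo = s_from_drive(d_lo, params$S_half),
         S_hi = s_from_drive(td$d2, params$S_half),
         d_lo = d_lo, d_hi = td$d2)
  } else {
    list(gap = FALSE)
  }
}

#' Classify the qualitative regime of the circuit
#'
#' Combines \code{\link{classify_route}} and \code{\link{oscillation_gap}}
#' into one of the four qualitative behaviour sequences as the signal is
#' raised adiabatically:
#' \enumerate{
#'   \item N off, then O off (direct switch, bistable overlap);
#'   \item N off, then N and O co-expressed, then O off;
#'   \item N off, then oscillations, then O off;
#'   \item N off, then co-expressed, then oscillations, then O off.
#' }
#' All transition signal values are reported, with overlap (bistable,
#' hysteretic) or gap (oscillatory) annotations.
#'
#' @param params threshold-mode \code{\link{circuit_params}}.
#' @return object of class \code{acdc_regime}: list with \code{route},
#'   \code{possibility} (1-4 or NA if invalid), \code{transitions}
#'   (data frame of named critical signal values) and \code{gap}.
#' @export
classify_regime <- function(params) {
  stopifnot(inherits(params, "acdc_params"))
  require_threshold(params, "classify_regime()")
  route <- classify_route(params)
  if (route == "invalid") {
    out <- list(route = "invalid", possibility = NA_integer_,
                transitions = data.frame(), gap = list(gap = FALSE),
                validity = validity_conditions(params))
    class(out) <- "acdc_regime"
    return(out)
  }
  td <- transition_drives(params)
  gp <- oscillation_gap(params)
  sh <- params$S_half
  if (route == "route1") {
    possibility <- if (gp$gap) 3L else 1L
    tr <- data.frame(
      event = c("B1_lost", "B2_onset"),
      S = c(s_from_drive(td$d1, sh), s_from_drive(td$d2, sh)),
      d = c(td$d1, td$d2), stringsAsFactors = FALSE)
    ann <- if (gp$gap) {
      data.frame(kind = "gap", S_lo = gp$S_lo, S_hi = gp$S_hi,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(kind = "overlap", S_lo = s_from_drive(td$d2, sh),
                 S_hi = s_from_drive(td$d1, sh), stringsAsFactors = FALSE)
    }
  } else {
    possibility <- if (gp$gap) 4L else 2L
    tr <- data.frame(
      event = c("B3_onset", "B1_lost", "B3_lost", "B2_onset"),
      S = c(s_from_drive(td$d0, sh), s_from_drive(td$d1, sh),
            s_from_drive(td$dN, sh), s_from_drive(td$d2, sh)),
      d = c(td$d0, td$d1, td$dN, td$d2), stringsAsFactors = FALSE)
    ann <- data.frame(kind = "overlap", S_lo = s_from_drive(td$d0, sh),
                      S_hi = s_from_drive(td$d1, sh), stringsAsFactors = FALSE)
    if (gp$gap)
      ann <- rbind(ann, data.frame(kind = "gap", S_lo = gp$S_lo,
                                   S_hi = gp$S_hi, stringsAsFactors = FALSE))
  }
  out <- list(route = route, possibility = possibility, transitions = tr,
              annotations = ann, gap = gp,
              validity = validity_conditions(params))
  class(out) <- "acdc_regime"
  out
}

#' @export
print.acdc_regime <- function(x, ...) {
  if (is.na(x$possibility)) {
    cat("Regime: INVALID parameters\n")
    print(x$validity)
    return(invisible(x))
  }
  seqs <- c("N off -> O off",
            "N off -> co-expressed -> O off",
            "N off -> oscillate -> O off",
            "N off -> co-expressed -> oscillate -> O off")
  cat(sprintf("Regime: possibility %d (%s), %s\n", x$possibility,
              seqs[x$possibility], x$route))
  for (i in seq_len(nrow(x$transitions)))
    cat(sprintf("  %-9s S = %.6g\n", x$transitions$event[i],
                x$transitions$S[i]))
  for (i in seq_len(nrow(x$annotations)))
    cat(sprintf("  %s on S in (%.6g, %.6g)\n", x$annotations$kind[i],
                x$annotations$S_lo[i], x$annotations$S_hi[i]))
  invisible(x)
}

#' Flatten a regime classification to a table
#'
#' One row per transition/annotation, suitable for CSV export.
#'
#' @param x an \code{acdc_regime} from \code{\link{classify_regime}}.
#' @param row.names,optional,... ignored (data frame method signature).
#' @return data frame with columns \code{route}, \code{possibility},
#'   \code{event}, \code{S_lo}, \code{S_hi}.
#' @export
as.data.frame.acdc_regime <- function(x, row.names = NULL, optional = FALSE, ...) {
  if (is.na(x$possibility))
    return(data.frame(route = "invalid", possibility = NA_integer_,
                      event = "invalid", S_lo = NA_real_, S_hi = NA_real_,
                      stringsAsFactors = FALSE))
  rbind(
    data.frame(route = x$route, possibility = x$possibility,
               event = x$transitions$event, S_lo = x$transitions$S,
               S_hi = NA_real_, stringsAsFactors = FALSE),
    data.frame(route = x$route, possibility = x$possibility,
               event = x$annotations$kind, S_lo = x$annotations$S_lo,
               S_hi = x$annotations$S_hi, stringsAsFactors = FALSE))
}
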