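# Named parameter presets. fig2*/fig3* are threshold-mode sets; fig4*/fig5*
# are their graded-mode counterparts with h3 = h4 = h5 of 2 and 5. Within each
# pair only N_crit differs, which flips the circuit between switch-like and
# oscillatory behaviour.
preset_table <- function() {
  fig2 <- list(alpha = 5, beta = 5, gamma = 5, h1 = 2, h2 = 2, O_crit = 1,
               P_crit1 = 0.5, O_crit1 = 5, N_crit1 = 2,
               k1 = 1, k2 = 1, k3 = 1, S_half = 1)
  fig3 <- list(alpha = 3, beta = 5, gamma = 4, h1 = 2, h2 = 2, O_crit = 1,
               P_crit1 = 1, O_crit1 = 5, N_crit1 = 2,
               k1 = 1, k2 = 1, k3 = 1, S_half = 1)
  mk <- function(base, N_crit, mode = "threshold", h = 2) {
    do.call(circuit_params,
            c(base, list(N_crit = N_crit, mode = mode,
                         h3 = h, h4 = h, h5 = h)))
  }
  list(
    fig2a = mk(fig2, 0.9),
    fig2b = mk(fig2, 1.1),
    fig3a = mk(fig3, 1),
    fig3b = mk(fig3, 2),
    fig4a = mk(fig2, 0.9, "graded", 2),
    fig4b = mk(fig2, 1.1, "graded", 2),
    fig5a = mk(fig2, 0.9, "graded", 5),
    fig5b = mk(fig2, 1.1, "graded", 5)
  )
}

#' Load a named parameter preset
#'
#' Ready-made parameter sets for the circuit's characteristic behaviours:
#' \describe{
#'   \item{fig2a}{threshold mode, \code{N_crit = 0.9}: sharp switch
#'     B1 to B2 with a bistable overlap.}
#'   \item{fig2b}{threshold mode, \code{N_crit = 1.1}: oscillations at
#'     intermediate signal.}
#'   \item{fig3a}{threshold mode, route through the co-expressed state
#'     (B1 to B3 to B2), direct.}
#'   \item{fig3b}{as fig3a but with an oscillatory gap between B3 and B2.}
#'   \item{fig4a/fig4b}{graded mode, \code{h3 = h4 = h5 = 2}, otherwise as
#'     fig2a/fig2b.}
#'   \item{fig5a/fig5b}{graded mode, \code{h3 = h4 = h5 = 5}, otherwise as
#'     fig2a/fig2b.}
#' }
#'
#' @param name preset name; see \code{\link{preset_names}}.
#' @return an \code{\link{circuit_params}} object.
#' @examples
#' load_preset("fig2a")
#' @export
load_preset <- function(name) {
  tab <- preset_table()
  if (!is.character(name) || length(name) != 1L || !(name %in% names(tab)))
    stop("load_preset(): unknown preset '", paste(name, collapse = ","),
         "'. Available: ", paste(names(tab), collapse = ", "))
  tab[[name]]
}

#' Names of the shipped parameter presets
#' @return character vector of preset names.
#' @export
preset_names <- function() names(preset_table())
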