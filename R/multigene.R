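# ---- Generalized n-gene stripe circuits ------------------------------------
#
# Gene G0 is constitutive; G1..G(n-1) are signal-induced.  In the canonical
# topology every gene represses all lower-indexed genes, and G0 additionally
# represses every gene with index >= 2.  Repressions acting on G0 are graded
# (Hill); all others are threshold (Heaviside).  n = 3 reproduces the AC-DC
# motif, n = 2 the minimal two-domain interpreter, and n = 4 the four-stripe
# extension.

default_gene_names <- function(n) {
  base <- c("P", "O", "N", "Q")
  if (n <= 4) base[seq_len(n)] else c(base, paste0("G", 5:n))[seq_len(n)]
}

#' Build a generalized stripe-interpreting circuit
#'
#' Constructs the gene list and repression edge set for an n-gene morphogen
#' interpretation circuit.
#'
#' Topologies:
#' \describe{
#'   \item{canonical}{gene \code{i} represses every gene \code{j < i};
#'     additionally the constitutive gene represses every gene with index
#'     \code{>= 2}. Repressions on the constitutive gene are graded, all
#'     others threshold. \code{n = 2} gives the two-domain circuit (O
#'     represses P), \code{n = 3} the AC-DC motif, \code{n = 4} the
#'     four-stripe circuit (Q represses P, O, N; P represses Q).}
#'   \item{fig7a}{alias for canonical \code{n = 2}.}
#'   \item{fig7bi}{the symmetric three-gene alternative: the signal induces
#'     both O and N, O and N repress each other (threshold) and both repress
#'     P (graded); P does not repress N. Under all-or-nothing repression this
#'     topology cannot produce three single-gene expression domains.}
#' }
#'
#' @param n number of genes, \code{>= 2} (canonical topology only; the named
#'   topologies fix their own \code{n}).
#' @param topology \code{"canonical"}, \code{"fig7a"} or \code{"fig7bi"}.
#' @param params optional \code{\link{circuit_params}} supplying the shared
#'   constants (production, decay, repression thresholds); defaults to
#'   \code{load_preset("fig2a")}. For canonical \code{n = 4} the additional
#'   fourth-gene constants default to the \code{fig8demo} values documented
#'   in the package vignette.
#' @return object of class \code{acdc_multigene}: list with \code{genes}
#'   (data frame: name, production, decay, constitutive), \code{edges}
#'   (data frame: source, target, form, crit, h) and \code{S_half}.
#' @examples
#' acdc <- multigene_circuit(3)
#' acdc$edges
#' @export
multigene_circuit <- function(n = 3,
                              topology = c("canonical", "fig7a", "fig7bi"),
                              params = NULL) {
  topology <- match.arg(topology)
  if (is.null(params)) params <- load_preset("fig2a")
  stopifnot(inherits(params, "acdc_params"))
  if (topology == "fig7a") { topology <- "canonical"; n <- 2L }
  if (topology == "fig7bi") n <- 3L
  if (!is.numeric(n) || length(n) != 1L || n < 2 || n != round(n))
    stop("multigene_circuit(): n must be an integer >= 2")
  n <- as.integer(n)
  nm <- default_gene_names(n)

  # genes beyond the third respond on a slower timescale (same saturated
  # level): brief dips of the constitutive gene below their activation
  # threshold during domain handovers then cannot capture the cell
  prod_rates <- c(params$alpha, params$beta, params$gamma, 2.5,
                  rep(2.5, max(0, n - 4)))[seq_len(n)]
  decay <- c(params$k1, params$k2, params$k3, 0.5,
             rep(0.5, max(0, n - 4)))[seq_len(n)]
  genes <- data.frame(name = nm, production = prod_rates, decay = decay,
                      constitutive = c(TRUE, rep(FALSE, n - 1)),
                      stringsAsFactors = FALSE)

  edge <- function(source, target, form, crit, h = NA_real_)
    data.frame(source = source, target = target, form = form, crit = crit,
               h = h, stringsAsFactors = FALSE)

  if (topology == "fig7bi") {
    edges <- rbind(
      edge("O", "P", "graded", params$O_crit, params$h2),
      edge("N", "P", "graded", params$N_crit, params$h1),
      edge("O", "N", "threshold", params$O_crit1),
      edge("N", "O", "threshold", params$N_crit1))
  } else {
    # graded half-max of gene i's repression of G0, and G0's threshold on
    # gene i; defaults follow the three-gene constants, then scale down so
    # consecutive stripe transitions stay separated
    g0_half <- c(NA, params$O_crit, params$N_crit, 0.5,
                 0.5 * 0.5^seq_len(max(0, n - 4)))[seq_len(n)]
    g0_hill <- c(NA, params$h2, params$h1, 2, rep(2, max(0, n - 4)))[seq_len(n)]
    p_thresh <- c(NA, NA, params$P_crit1, 0.25,
                  0.25 * 0.5^seq_len(max(0, n - 4)))[seq_len(n)]
    # induced-on-induced repression thresholds, per source gene; higher for
    # the slower genes so their transient excursions stay subcritical
    cross_thresh <- c(NA, NA, params$N_crit1, rep(3, max(0, n - 3)))[seq_len(n)]
    edges <- NULL
    for (i in 2:n) {         # gene i-1 (0-based) represses all lower genes
      src <- nm[i]
      edges <- rbind(edges, edge(src, nm[1], "graded", g0_half[i], g0_hill[i]))
      if (i > 2)
        for (j in 2:(i - 1))
          edges <- rbind(edges, edge(src, nm[j], "threshold", cross_thresh[i]))
    }
    if (n >= 3)
      for (i in 3:n)          # G0 represses every gene with index >= 2
        edges <- rbind(edges, edge(nm[1], nm[i], "threshold", p_thresh[i]))
  }
  out <- list(genes = genes, edges = edges, S_half = params$S_half,
              topology = if (n == 2) "fig7a" else topology)
  class(out) <- "acdc_multigene"
  out
}

#' @export
print.acdc_multigene <- function(x, ...) {
  cat(sprintf("%d-gene circuit (%s topology)\n", nrow(x$genes), x$topology))
  cat("  genes:", paste(x$genes$name, collapse = ", "), "\n")
  for (i in seq_len(nrow(x$edges)))
    cat(sprintf("  %s -| %s  (%s, crit = %g%s)\n",
                x$edges$source[i], x$edges$target[i], x$edges$form[i],
                x$edges$crit[i],
                if (x$edges$form[i] == "graded")
                  sprintf(", h = %g", x$edges$h[i]) else ""))
  invisible(x)
}

#' Right-hand side of a generalized circuit
#'
#' Derivative of every gene's concentration: constitutive genes produce at
#' their maximal rate, induced genes at rate scaled by the induction drive;
#' production is multiplied by every threshold (Heaviside) repression factor
#' acting on the gene, the graded repressors acting on a gene combine
#' through a shared additive Hill denominator (as in the three-gene
#' circuit's P equation), and decay is linear.
#'
#' @param state named or ordered numeric vector of gene concentrations.
#' @param S signal level, \code{>= 0}.
#' @param circuit an \code{\link{multigene_circuit}}.
#' @param H optional frozen 0/1 values for the threshold edges (in edge
#'   order), used by the event-driven integrator.
#' @return numeric derivative vector, in gene order.
#' @export
multigene_rhs <- function(state, S, circuit, H = NULL) {
  stopifnot(inherits(circuit, "acdc_multigene"))
  g <- circuit$genes
  if (length(state) != nrow(g))
    stop("multigene_rhs(): state length must equal the gene count")
  y <- as.numeric(state)
  names(y) <- g$name
  d <- induction_drive(S, circuit$S_half)
  e <- circuit$edges
  thr_idx <- which(e$form == "threshold")
  dy <- numeric(nrow(g))
  for (j in seq_len(nrow(g))) {
    base <- g$production[j] * if (g$constitutive[j]) 1 else d
    acting <- which(e$target == g$name[j])
    thr_fac <- 1; hill_den <- 1
    for (i in acting) {
      src <- y[[e$source[i]]]
      if (e$form[i] == "threshold") {
        thr_fac <- thr_fac * if (is.null(H)) heaviside(e$crit[i] - src) else
          H[match(i, thr_idx)]
      } else {
        hill_den <- hill_den + (src / e$crit[i])^e$h[i]
      }
    }
    dy[j] <- base * thr_fac / hill_den - g$decay[j] * y[j]
  }
  names(dy) <- g$name
  dy
}
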