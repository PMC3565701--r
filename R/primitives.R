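#' Heaviside step function
#'
#' All-or-nothing repression kernel of the threshold model. Uses the
#' convention \code{H(0) = 1}: a repressor sitting exactly at its critical
#' concentration still permits production.
#'
#' @param x numeric vector; must be finite.
#' @return numeric vector of 0/1, \code{1} iff \code{x >= 0}.
#' @examples
#' heaviside(c(-0.5, 0, 3))
#' @export
heaviside <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("heaviside(): input must be finite numeric")
  as.numeric(x >= 0)
}

#' Declining Hill repression function
#'
#' \code{1 / (1 + (c / c_half)^h)}: the fraction of maximal production that
#' survives repression by a factor at concentration \code{c}, half-maximal at
#' \code{c = c_half}. Approaches \code{\link{heaviside}(c_half - c)} as
#' \code{h} grows.
#'
#' @param c repressor concentration(s), \code{>= 0}.
#' @param c_half half-maximal repression concentration, \code{> 0}.
#' @param h Hill coefficient, \code{>= 1}.
#' @return numeric in \code{(0, 1]}, monotone decreasing in \code{c}.
#' @examples
#' hill_repressor(0, 1, 2)    # 1: no repressor
#' hill_repressor(1, 1, 2)    # 0.5: half-maximal
#' hill_repressor(2, 1, 2)    # 0.2
#' @export
hill_repressor <- function(c, c_half, h) {
  if (any(!is.finite(c)) || any(c < 0))
    stop("hill_repressor(): concentration must be finite and nonnegative")
  if (any(!is.finite(c_half)) || any(c_half <= 0))
    stop("hill_repressor(): c_half must be positive")
  if (any(!is.finite(h)) || any(h < 1))
    stop("hill_repressor(): Hill coefficient must be >= 1")
  1 / (1 + (c / c_half)^h)
}

# d/dc of hill_repressor; at c = 0 the limit is 0 for h > 1 and -1/c_half for h = 1
hill_repressor_deriv <- function(c, c_half, h) {
  if (c == 0) {
    if (h == 1) return(-1 / c_half) else return(0)
  }
  u <- (c / c_half)^h
  -(h / c) * u / (1 + u)^2
}

#' Michaelis-Menten induction drive
#'
#' Saturating transcriptional drive \code{S / (S_half + S)} exerted by the
#' signal (Gli activity downstream of Shh) on the induced genes. The same
#' half-maximal signal governs all induced genes.
#'
#' @param S signal level(s), \code{>= 0}.
#' @param S_half signal at half-maximal drive (default 1).
#' @return numeric in \code{[0, 1)}, monotone increasing, saturating at 1.
#' @seealso \code{\link{s_from_drive}} for the inverse map.
#' @examples
#' induction_drive(c(0, 1, 1e6))
#' @export
induction_drive <- function(S, S_half = 1) {
  if (any(!is.finite(S)) || any(S < 0))
    stop("induction_drive(): S must be finite and nonnegative")
  if (!is.finite(S_half) || S_half <= 0)
    stop("induction_drive(): S_half must be positive")
  S / (S_half + S)
}

#' Invert the induction drive
#'
#' Signal level at which the induction drive equals \code{d}; the exact
#' inverse of \code{\link{induction_drive}}. Used to convert analytically
#' known drive-level transition points into critical signal values.
#'
#' @param d drive fraction(s) in \code{[0, 1)}.
#' @param S_half signal at half-maximal drive (default 1).
#' @return signal level(s) \code{S_half * d / (1 - d)}.
#' @export
s_from_drive <- function(d, S_half = 1) {
  if (any(!is.finite(d)) || any(d < 0) || any(d >= 1))
    stop("s_from_drive(): drive must lie in [0, 1)")
  S_half * d / (1 - d)
}
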