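#' Parametric birth-death rate families
#'
#' Convenience constructors for the model families used throughout:
#' `constant_h_chain` (no autoregulation, Poisson stationary law),
#' `linear_autoreg_chain` with \eqn{f_n = k + b(n-1)}, \eqn{g_n = c}
#' (autoregulation strength `b`, valid for `c > 0`, `c - b > 0`; the
#' stationary VMR is \eqn{1 + b/(c-b)}), and `hill_autoreg_chain` with a
#' Hill-type synthesis rate.  For `b < 0` the synthesis rate is clamped
#' at zero; the closed-form VMR then holds exactly when `k/|b|` is an
#' integer, i.e. the rate reaches zero exactly at the support edge and
#' the stationary law is binomial.  Otherwise the clamped chain is a
#' slightly different (still valid) model and its VMR deviates from the
#' formula.
#'
#' @param h constant relative growth rate (`constant_h_chain`).
#' @param k basal synthesis rate.
#' @param b linear autoregulation strength (sign = direction).
#' @param c constant per-molecule degradation rate.
#' @param k0 basal synthesis rate (Hill family).
#' @param Vmax Hill amplitude.
#' @param K Hill half-saturation constant (> 0).
#' @param coef Hill coefficient (> 0).
#' @param activating `TRUE` for self-activation, `FALSE` for
#'   self-repression.
#' @param n_max truncation bound passed to [birth_death_chain()].
#' @return a [birth_death_chain()].
#' @name rate_families
NULL

#' @rdname rate_families
#' @export
constant_h_chain <- function(h, n_max = 1e5L) {
  if (h < 0) stop_fanoreg("h must be >= 0", "fanoreg_invalid_model")
  force(h)
  birth_death_chain(f = function(n) rep(h, length(n)),
                    g = function(n) rep(1, length(n)), n_max = n_max)
}

#' @rdname rate_families
#' @export
linear_autoreg_chain <- function(k, b, c, n_max = 1e5L) {
  if (!(c > 0) || !(c - b > 0))
    stop_fanoreg("linear family requires c > 0 and c - b > 0",
                 "fanoreg_invalid_model")
  if (k < 0) stop_fanoreg("k must be >= 0", "fanoreg_invalid_model")
  force(k); force(b); force(c)
  birth_death_chain(f = function(n) pmax(k + b * (n - 1), 0),
                    g = function(n) rep(c, length(n)), n_max = n_max)
}

#' @rdname rate_families
#' @export
hill_autoreg_chain <- function(k0, Vmax, K, coef, c, activating = TRUE,
                               n_max = 1e5L) {
  if (K <= 0 || coef <= 0 || c <= 0 || Vmax < 0 || k0 < 0)
    stop_fanoreg("hill family requires K, coef, c > 0 and k0, Vmax >= 0",
                 "fanoreg_invalid_model")
  force(k0); force(Vmax); force(K); force(coef); force(c); force(activating)
  f <- function(n) {
    x <- (n - 1)^coef
    frac <- if (activating) x / (K^coef + x) else K^coef / (K^coef + x)
    k0 + Vmax * frac
  }
  birth_death_chain(f = f, g = function(n) rep(c, length(n)), n_max = n_max)
}

#' Two-species regulatory cascade (parent -> child)
#'
#' Parent with constant relative growth rate `parent_h` (Poisson); child
#' synthesised at `a + b * n_parent` with constant per-molecule
#' degradation 1 and no autoregulation.  By the acyclic-network
#' dispersion bound the child's marginal VMR is >= 1.
#'
#' @param parent_h parent relative growth rate.
#' @param a child basal synthesis rate.
#' @param b child synthesis gain per parent molecule.
#' @param box optional per-species truncation bounds.
#' @return a [network_chain()].
#' @export
cascade_network <- function(parent_h, a = 1, b = 1, box = NULL) {
  if (parent_h < 0 || a < 0 || b < 0)
    stop_fanoreg("rates must be >= 0", "fanoreg_invalid_model")
  if (is.null(box)) {
    child_mean <- a + b * parent_h
    box <- c(ceiling(parent_h + 12 * sqrt(parent_h + 1) + 10),
             ceiling(child_mean + 15 * sqrt(child_mean + 1) + 10))
  }
  force(parent_h); force(a); force(b)
  network_chain(
    f = list(function(n) parent_h, function(n) a + b * n[1L]),
    g = list(function(n) 1, function(n) 1),
    box = box, init = c(0L, 0L))
}
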