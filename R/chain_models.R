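#' Single-gene birth-death chain
#'
#' Represents the continuous-time Markov chain for the expression count of
#' one gene with autonomous expression: the transition rate from \eqn{n-1}
#' to \eqn{n} is the synthesis rate \eqn{f_n \ge 0}, and with \eqn{n}
#' molecules each degrades at per-molecule rate \eqn{g_n > 0} (overall
#' degradation rate \eqn{g_n n}).  The relative growth rate is
#' \eqn{h_n = f_n / g_n}; a constant \eqn{h_n} corresponds to no
#' autoregulation and a Poisson stationary law.
#'
#' @param f synthesis rates: a numeric vector (`f[n]` is the rate of the
#'   transition `n-1 -> n`) or a vectorised function of `n >= 1`.
#' @param g per-molecule degradation rates, same conventions as `f`.
#' @param n_max hard cap on the number of states considered (truncation
#'   bound for function-valued rates; for vector rates the vector length
#'   is used if smaller).
#' @return an object of class `birth_death_chain`.
#' @examples
#' ch <- birth_death_chain(f = function(n) 5, g = function(n) 1)
#' relative_growth_rates(ch, n_upper = 3)
#' @export
birth_death_chain <- function(f, g, n_max = 1e5L) {
  if (!is.numeric(n_max) || length(n_max) != 1L || n_max < 1)
    stop_fanoreg("n_max must be a positive integer", "fanoreg_invalid_model")
  fl <- .as_rate_fun(f, tail_value = 0)       # beyond a rate vector, synthesis stops
  gl <- .as_rate_fun(g, tail_value = NA_real_) # last value carried forward
  len <- min(c(n_max, fl$len, gl$len), na.rm = TRUE)
  structure(list(f = fl$fun, g = gl$fun, n_max = as.integer(len)),
            class = "birth_death_chain")
}

# evaluate a user rate function over states n, guaranteeing length(n):
# scalar-returning (non-vectorised) functions are handled transparently
.eval_rates <- function(fun, n) {
  v <- as.numeric(fun(n))
  if (length(v) == length(n)) return(v)
  if (length(v) == 1L) return(rep(v, length(n)))
  vapply(n, function(i) as.numeric(fun(i))[1L], 0)
}

.as_rate_fun <- function(x, tail_value) {
  if (is.function(x)) return(list(fun = function(n) as.numeric(x(n)), len = NA_real_))
  if (!is.numeric(x) || length(x) < 1L)
    stop_fanoreg("rates must be a numeric vector or a function of n",
                 "fanoreg_invalid_model")
  v <- as.numeric(x)
  tl <- if (is.na(tail_value)) v[length(v)] else tail_value
  fun <- function(n) {
    out <- rep(tl, length(n))
    ok <- n >= 1 & n <= length(v)
    out[ok] <- v[n[ok]]
    out
  }
  list(fun = fun, len = length(v))
}

#' @method print birth_death_chain
#' @export
print.birth_death_chain <- function(x, ...) {
  cat("<birth_death_chain> n_max =", x$n_max, "\n")
  n <- seq_len(min(5L, x$n_max))
  cat("  f_n:", format(x$f(n), digits = 4), "...\n")
  cat("  g_n:", format(x$g(n), digits = 4), "...\n")
  invisible(x)
}

#' Relative growth rates h_n = f_n / g_n
#'
#' @param chain a [birth_death_chain()].
#' @param n_upper highest state to report (defaults to the chain's
#'   truncation bound, capped at 1000 for function-valued rates).
#' @return numeric vector `h[n]` for `n = 1..n_upper`.
#' @details States where `f_n = g_n = 0` are given `h_n = 0` with a
#'   warning: such a state terminates the support.  A positive `f_n` with
#'   non-positive `g_n` is an invalid model.
#' @export
relative_growth_rates <- function(chain, n_upper = NULL) {
  stopifnot(inherits(chain, "birth_death_chain"))
  if (is.null(n_upper)) n_upper <- min(chain$n_max, 1000L)
  n <- seq_len(n_upper)
  fn <- .eval_rates(chain$f, n)
  gn <- .eval_rates(chain$g, n)
  if (any(!is.finite(fn)) || any(fn < 0))
    stop_fanoreg("synthesis rates f_n must be finite and >= 0",
                 "fanoreg_invalid_model")
  bad <- gn <= 0 & fn > 0
  if (any(bad | !is.finite(gn)))
    stop_fanoreg(sprintf("per-molecule degradation rate g_n must be > 0 (first violation at n = %d)",
                         n[which(bad | !is.finite(gn))[1L]]),
                 "fanoreg_invalid_model")
  h <- numeric(n_upper)
  zz <- gn == 0  # here f_n is 0 too
  if (any(zz)) {
    warning("h_n undefined (0/0) at some states; treated as 0 (support ends there)")
    h[!zz] <- fn[!zz] / gn[!zz]
  } else {
    h <- fn / gn
  }
  h
}

#' Classify autoregulation at the level of the rate functions
#'
#' A gene has no autoregulation iff \eqn{h_n} is constant; positive
#' autoregulation means \eqn{h_n > h_{n-1}} somewhere, negative means
#' \eqn{h_n < h_{n-1}} somewhere; both can coexist (`"mixed"`).
#'
#' @inheritParams relative_growth_rates
#' @param tol relative tolerance for comparing successive `h_n`.
#' @return one of `"none"`, `"positive"`, `"negative"`, `"mixed"`.
#' @export
classify_rate_autoregulation <- function(chain, n_upper = NULL, tol = 1e-12) {
  stopifnot(inherits(chain, "birth_death_chain"))
  if (is.null(n_upper)) n_upper <- min(chain$n_max, 1000L)
  if (n_upper < 2)
    stop_fanoreg("need at least two states to classify autoregulation",
                 "fanoreg_insufficient_states")
  h <- relative_growth_rates(chain, n_upper)
  d <- diff(h)
  scale <- pmax(abs(h[-length(h)]), abs(h[-1L]), 1)
  up <- any(d > tol * scale)
  dn <- any(d < -tol * scale)
  if (up && dn) "mixed" else if (up) "positive" else if (dn) "negative" else "none"
}

#' Exact stationary distribution of a birth-death chain
#'
#' Uses the product-form recursion \eqn{P_n = P_{n-1} h_n / n}, i.e.
#' \eqn{P_n \propto \prod_{i \le n} h_i / n!}, computed in log space with
#' adaptive truncation: states are added until the relative unnormalised
#' mass increment falls below `tail_tol` in the decaying regime
#' (\eqn{h_{n+1}/(n+1) < 1}), up to the hard cap `max_states`.
#'
#' @inheritParams relative_growth_rates
#' @param tail_tol bound on the (relative) probability mass allowed beyond
#'   the truncation point.
#' @param max_states hard cap on the number of states.
#' @return an object of class `stationary_dist`: list with `states`
#'   (`0..n_trunc`), `probabilities` (summing to 1), and
#'   `tail_mass_bound` (geometric estimate of the truncated mass).
#' @examples
#' d <- stationary_birth_death(birth_death_chain(function(n) 5, function(n) 1))
#' distribution_moments(d)  # Poisson(5): mean 5, variance 5, VMR 1
#' @export
stationary_birth_death <- function(chain, tail_tol = 1e-12, max_states = 1e5L) {
  stopifnot(inherits(chain, "birth_death_chain"))
  cap <- min(chain$n_max, max_states)
  size <- 1024L
  logw <- numeric(size)   # logw[n+1] = log unnormalised P_n
  logw[1L] <- 0
  n_top <- 0L
  tail_ratio <- 0
  converged <- FALSE
  lse <- 0                # running log-sum-exp bookkeeping done at end
  repeat {
    n <- n_top + 1L
    if (n > cap) break
    fn <- chain$f(n); gn <- chain$g(n)
    if (!is.finite(fn) || fn < 0)
      stop_fanoreg(sprintf("invalid synthesis rate f_%d", n), "fanoreg_invalid_model")
    if (fn == 0) { converged <- TRUE; tail_ratio <- 0; break }
    if (!is.finite(gn) || gn <= 0)
      stop_fanoreg(sprintf("invalid degradation rate g_%d", n), "fanoreg_invalid_model")
    h <- fn / gn
    if (n + 1L > size) { size <- size * 2L; logw <- c(logw, numeric(size - length(logw))) }
    logw[n + 1L] <- logw[n] + log(h) - log(n)
    n_top <- n
    # convergence check in the decaying regime
    r <- h / (n + 1)
    if (r < 0.9 && logw[n + 1L] - max(logw[seq_len(n + 1L)]) < log(tail_tol) + log1p(-r)) {
      tail_ratio <- r
      converged <- TRUE
      break
    }
  }
  logw <- logw[seq_len(n_top + 1L)]
  m <- max(logw)
  w <- exp(logw - m)
  tot <- sum(w)
  tail_mass <- if (converged) w[length(w)] * tail_ratio / (1 - tail_ratio) / tot else NA_real_
  if (!converged)
    stop_fanoreg(sprintf(
      "stationary mass not converged within %d states; increase max_states or check that h_n/n decays",
      cap), "fanoreg_truncation_error")
  structure(list(states = 0:n_top,
                 probabilities = w / tot,
                 tail_mass_bound = tail_mass),
            class = "stationary_dist")
}

#' @method print stationary_dist
#' @export
print.stationary_dist <- function(x, ...) {
  mom <- distribution_moments(x)
  cat(sprintf("<stationary_dist> %d states, mean %.4g, VMR %.4g, tail bound %.2e\n",
              length(x$states), mom$mean, mom$vmr, x$tail_mass_bound))
  invisible(x)
}

#' Moments of a (truncated) stationary distribution
#'
#' @param dist a `stationary_dist` (or any list with `states` and
#'   `probabilities`).
#' @return list with `mean`, `var` and `vmr` (\eqn{\sigma^2/\mu}); `vmr`
#'   is `NA` with attribute `undefined = TRUE` when the mean is 0.
#' @export
distribution_moments <- function(dist) {
  s <- dist$states
  p <- dist$probabilities
  stopifnot(length(s) == length(p))
  mu <- sum(s * p)
  v <- sum(s^2 * p) - mu^2
  v <- max(v, 0)
  if (mu <= 0) {
    vmr <- structure(NA_real_, undefined = TRUE)
  } else {
    vmr <- v / mu
  }
  list(mean = mu, var = v, vmr = vmr)
}
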