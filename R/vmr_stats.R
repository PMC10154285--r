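#' Sample variance-to-mean ratio (Fano factor)
#'
#' Computes the sample VMR (unbiased sample variance divided by sample
#' mean) of a vector of expression counts.  The unbiased (n-1) variance
#' is used because the Gamma null \eqn{\Gamma[(n-1)/2,\ 2/(n-1)]} for a
#' Poisson sample then has mean exactly 1.
#'
#' @param samples numeric vector of non-negative counts, length >= 2.
#' @return an object of class `vmr_result` with fields `n`, `mean`,
#'   `var`, `vmr` and `flag` (`"undefined"` when the mean is 0,
#'   otherwise `"not_tested"` until [vmr_test()] fills the interval).
#' @export
sample_vmr <- function(samples) {
  samples <- as.numeric(samples)
  if (length(samples) < 2L)
    stop_fanoreg("need at least 2 samples to estimate a variance",
                 "fanoreg_insufficient_data")
  if (any(!is.finite(samples)) || any(samples < 0))
    stop_fanoreg("samples must be finite and non-negative", "fanoreg_data_error")
  n <- length(samples)
  mu <- mean(samples)
  v <- stats::var(samples)
  res <- list(n = n, mean = mu, var = v,
              vmr = if (mu > 0) v / mu else NA_real_,
              ci_low = NA_real_, ci_high = NA_real_,
              p_value = NA_real_, alpha = NA_real_,
              flag = if (mu > 0) "not_tested" else "undefined")
  structure(res, class = "vmr_result")
}

#' @method print vmr_result
#' @export
print.vmr_result <- function(x, ...) {
  cat(sprintf("<vmr_result> n = %d, mean = %.4g, VMR = %.4g", x$n, x$mean, x$vmr))
  if (!is.na(x$p_value))
    cat(sprintf(", null CI = [%.4g, %.4g], p = %.3g, flag = %s",
                x$ci_low, x$ci_high, x$p_value, x$flag))
  cat("\n")
  invisible(x)
}

#' Gamma null interval for the sample VMR of a Poisson gene
#'
#' For a gene with no autoregulation the stationary law is Poisson and
#' the sample VMR of `n` cells asymptotically follows
#' \eqn{\Gamma[(n-1)/2,\ 2/(n-1)]} (shape, scale), whose mean is exactly
#' 1.  The equal-tailed `alpha` interval always brackets 1.
#'
#' @param n number of cells.
#' @param alpha significance level in (0, 1).
#' @return numeric length-2 vector `(lo, hi)`.
#' @export
vmr_null_interval <- function(n, alpha = 0.05) {
  if (!is.numeric(n) || length(n) != 1L || n < 2)
    stop_fanoreg("n must be a single integer >= 2", "fanoreg_parameter_error")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop_fanoreg("alpha must be in (0, 1)", "fanoreg_parameter_error")
  shape <- (n - 1) / 2
  scale <- 2 / (n - 1)
  stats::qgamma(c(alpha / 2, 1 - alpha / 2), shape = shape, scale = scale)
}

#' Test whether a gene's VMR differs significantly from 1
#'
#' Combines [sample_vmr()] with the Gamma null: the flag is
#' `"significantly_below_1"` / `"significantly_above_1"` when the sample
#' VMR falls strictly outside the equal-tailed interval, otherwise
#' `"not_significant"` (boundary ties resolve to not significant).  The
#' two-sided p-value is \eqn{2\min(F(\hat v),\ 1-F(\hat v))} under the
#' Gamma null.  The null is asymptotic; a warning is emitted for
#' `n < 30`.
#'
#' @inheritParams sample_vmr
#' @param alpha significance level.
#' @param alternative `"two.sided"` (default), or one-sided `"less"` /
#'   `"greater"` against VMR below/above 1.
#' @return a `vmr_result`.
#' @examples
#' set.seed(1)
#' vmr_test(rpois(500, 10))        # typically not significant
#' @export
vmr_test <- function(samples, alpha = 0.05,
                     alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  res <- sample_vmr(samples)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop_fanoreg("alpha must be in (0, 1)", "fanoreg_parameter_error")
  res$alpha <- alpha
  if (res$flag == "undefined") return(res)
  n <- res$n
  if (n < 30)
    warning("Gamma null is asymptotic; n < 30 gives unreliable calibration")
  shape <- (n - 1) / 2
  scale <- 2 / (n - 1)
  Fv <- stats::pgamma(res$vmr, shape = shape, scale = scale)
  if (alternative == "two.sided") {
    ci <- vmr_null_interval(n, alpha)
    res$p_value <- min(1, 2 * min(Fv, 1 - Fv))
  } else if (alternative == "less") {
    ci <- c(stats::qgamma(alpha, shape, scale = scale), Inf)
    res$p_value <- Fv
  } else {
    ci <- c(0, stats::qgamma(1 - alpha, shape, scale = scale))
    res$p_value <- 1 - Fv
  }
  res$ci_low <- ci[1L]
  res$ci_high <- ci[2L]
  res$flag <- if (res$vmr < ci[1L]) "significantly_below_1"
              else if (res$vmr > ci[2L]) "significantly_above_1"
              else "not_significant"
  res
}

#' VMR of a mixture of cell populations
#'
#' For components with weights \eqn{w_i}, means \eqn{\mu_i} and VMRs
#' \eqn{v_i}, the mixture has \eqn{E = \sum w_i \mu_i},
#' \eqn{E_2 = \sum w_i (v_i \mu_i + \mu_i^2)} and VMR
#' \eqn{(E_2 - E^2)/E}.  If every component has VMR >= 1 the mixture has
#' VMR >= 1, so cell heterogeneity cannot produce a spurious
#' sub-Poissonian signal: VMR < 1 in a mixture implies VMR < 1 in at
#' least one component.
#'
#' @param weights positive weights summing to 1.
#' @param means component means (>= 0).
#' @param vmrs component VMRs (>= 0).
#' @return the mixture VMR.
#' @export
mixture_vmr <- function(weights, means, vmrs) {
  if (length(weights) != length(means) || length(weights) != length(vmrs))
    stop_fanoreg("weights, means and vmrs must have equal length",
                 "fanoreg_parameter_error")
  if (any(weights <= 0) || abs(sum(weights) - 1) > 1e-8)
    stop_fanoreg("weights must be positive and sum to 1", "fanoreg_parameter_error")
  if (any(means < 0) || any(vmrs < 0))
    stop_fanoreg("means and vmrs must be non-negative", "fanoreg_parameter_error")
  E <- sum(weights * means)
  if (E <= 0)
    stop_fanoreg("mixture mean must be positive", "fanoreg_parameter_error")
  E2 <- sum(weights * (vmrs * means + means^2))
  (E2 - E^2) / E
}

#' Intrinsic/extrinsic decomposition of the VMR
#'
#' Treating the group label as the extrinsic factor E, the pooled VMR
#' splits into
#' \deqn{VMR_{int} = [E_E(E_{I|E} X^2) - E_E(E_{I|E} X)^2] / E(X)}
#' \deqn{VMR_{ext} = [E_E(E_{I|E} X)^2 - (E_E E_{I|E} X)^2] / E(X)}
#' which sum exactly to the pooled population-moment VMR.  Population
#' (divide-by-n) moments are used, with groups weighted by their size;
#' this differs deliberately from the unbiased estimator used in the
#' inference path, where the Gamma null fixes the convention.
#'
#' @param grouped_samples a named or unnamed list of non-empty numeric
#'   vectors, one per group.
#' @return list with `vmr_int`, `vmr_ext` and `vmr_total`.
#' @export
decompose_vmr <- function(grouped_samples) {
  if (!is.list(grouped_samples) || length(grouped_samples) < 1L)
    stop_fanoreg("grouped_samples must be a non-empty list of vectors",
                 "fanoreg_data_error")
  if (any(lengths(grouped_samples) == 0L))
    stop_fanoreg("every group must be non-empty", "fanoreg_data_error")
  ns <- lengths(grouped_samples)
  w <- ns / sum(ns)
  mu_g <- vapply(grouped_samples, mean, 0)
  m2_g <- vapply(grouped_samples, function(x) mean(x^2), 0)
  EX <- sum(w * mu_g)
  if (EX <= 0)
    stop_fanoreg("pooled mean must be positive", "fanoreg_data_error")
  vmr_int <- (sum(w * m2_g) - sum(w * mu_g^2)) / EX
  vmr_ext <- (sum(w * mu_g^2) - EX^2) / EX
  list(vmr_int = vmr_int, vmr_ext = vmr_ext, vmr_total = vmr_int + vmr_ext)
}
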