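#' Compare the method's gene calls with a random classifier
#'
#' Against a reference set of `K` positives among `N` genes, a random
#' classifier picking `n_picked` genes hits a Hypergeometric(N, K,
#' n_picked) number of true positives.  With `k_hits` actual overlaps,
#' `p_worse = P(X < k_hits)` is the probability the random picker does
#' strictly worse, `p_better = P(X > k_hits)` strictly better; ties are
#' reported separately.
#'
#' @param N genes in the reference.
#' @param K reference-positive genes.
#' @param n_picked genes called by the method.
#' @param k_hits overlap between the method's calls and the reference
#'   positives.
#' @return an object of class `classifier_comparison` with `p_worse`,
#'   `p_better`, `p_tie` and the inputs.
#' @examples
#' random_classifier_comparison(39, 17, 5, 3)  # p_worse 62.55%, p_better 10.17%
#' @export
random_classifier_comparison <- function(N, K, n_picked, k_hits) {
  vals <- c(N, K, n_picked, k_hits)
  if (any(vals != round(vals)) || any(vals < 0))
    stop_fanoreg("arguments must be non-negative integers", "fanoreg_parameter_error")
  if (K > N || n_picked > N || k_hits > min(n_picked, K))
    stop_fanoreg("infeasible arguments (need K <= N, n_picked <= N, k_hits <= min(n_picked, K))",
                 "fanoreg_parameter_error")
  p_worse <- stats::phyper(k_hits - 1, K, N - K, n_picked)
  p_better <- stats::phyper(k_hits, K, N - K, n_picked, lower.tail = FALSE)
  p_tie <- stats::dhyper(k_hits, K, N - K, n_picked)
  structure(list(N = N, K = K, n_picked = n_picked, k_hits = k_hits,
                 p_worse = p_worse, p_better = p_better, p_tie = p_tie),
            class = "classifier_comparison")
}

#' @method print classifier_comparison
#' @export
print.classifier_comparison <- function(x, ...) {
  cat(sprintf(paste0("<classifier_comparison> N = %d, K = %d, picked %d, hit %d\n",
                     "  random classifier worse: %.2f%%, better: %.2f%%, tied: %.2f%%\n"),
              x$N, x$K, x$n_picked, x$k_hits,
              100 * x$p_worse, 100 * x$p_better, 100 * x$p_tie))
  invisible(x)
}

#' Cross-tabulate inference calls against synthetic truth labels
#'
#' `undetermined` is an abstention, not a negative prediction; the table
#' keeps it as its own row.
#'
#' @param report an `inference_report` from [infer_autoregulation()].
#' @param truth a truth data frame (columns `gene`, `label`) as produced
#'   by [generate_benchmark()], or a named character vector.
#' @return a contingency table call x truth.
#' @export
confusion_vs_truth <- function(report, truth) {
  if (!inherits(report, "inference_report"))
    stop_fanoreg("report must be an inference_report", "fanoreg_contract_error")
  if (is.data.frame(truth)) {
    labels <- stats::setNames(as.character(truth$label), truth$gene)
  } else if (!is.null(names(truth))) {
    labels <- truth
  } else {
    stop_fanoreg("truth must be a data frame or a named vector", "fanoreg_data_error")
  }
  if (!setequal(report$gene, names(labels)))
    stop_fanoreg("gene sets of report and truth do not match", "fanoreg_data_error")
  table(call = factor(report$call,
                      levels = c("positive_autoregulation_prop1",
                                 "autoregulation_prop2", "declared_in_grn",
                                 "undetermined")),
        truth = labels[report$gene])
}
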