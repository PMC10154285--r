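#' Call autoregulation for one gene from its VMR test and GRN status
#'
#' Implements the decision logic combining the dispersion bounds with GRN
#' topology, in this order:
#' \enumerate{
#'   \item status `absent` or `in_cycle` -> `undetermined` (neither bound
#'     applies inside a feedback loop or off the known network);
#'   \item status `self_loop_declared` -> `declared_in_grn` (the GRN
#'     already asserts autoregulation; nothing to infer);
#'   \item VMR significantly below 1 and the gene not in a cycle ->
#'     `autoregulation_prop2`: in the one-step model with unregulated
#'     degradation, no autoregulation forces VMR >= 1, so VMR < 1 implies
#'     autoregulation (negative if expression is autonomous).  This takes
#'     precedence over the autonomous-model route;
#'   \item VMR significantly above 1, no ancestors, and autonomy asserted
#'     -> `positive_autoregulation_prop1` (autonomy is unverifiable, so
#'     this call is caveated and opt-in);
#'   \item otherwise `undetermined`.
#' }
#' Negative results are never emitted: the method cannot establish the
#' absence of autoregulation.
#'
#' @param vmr a `vmr_result` from [vmr_test()].
#' @param status a status string from [grn_status()].
#' @param autonomous has the user asserted autonomous expression for this
#'   gene?
#' @return an object of class `gene_call`: list with `call`, `caveats`,
#'   `vmr`, `grn_status`.
#' @export
call_gene <- function(vmr, status, autonomous = FALSE) {
  if (!inherits(vmr, "vmr_result"))
    stop_fanoreg("vmr must be a vmr_result", "fanoreg_contract_error")
  ok_status <- c("absent", "in_cycle", "no_ancestors", "has_ancestors_acyclic",
                 "self_loop_declared")
  if (!(is.character(status) && length(status) == 1L && status %in% ok_status))
    stop_fanoreg("unknown grn status", "fanoreg_contract_error")
  caveats <- character()
  call <- "undetermined"
  if (status %in% c("absent", "in_cycle")) {
    call <- "undetermined"
    caveats <- if (status == "absent")
      "gene not in the known GRN; cycle membership unknown"
    else "gene lies in a feedback loop; dispersion bounds do not apply"
  } else if (status == "self_loop_declared") {
    call <- "declared_in_grn"
    caveats <- "autoregulation declared by a self-loop in the input GRN; excluded from VMR-based inference"
  } else if (identical(vmr$flag, "significantly_below_1")) {
    call <- "autoregulation_prop2"
    caveats <- c("constant unregulated degradation assumed",
                 "one-step model assumed",
                 "negative autoregulation if expression autonomous")
  } else if (identical(vmr$flag, "significantly_above_1") &&
             status == "no_ancestors" && isTRUE(autonomous)) {
    call <- "positive_autoregulation_prop1"
    caveats <- "autonomy unverifiable; less reliable"
  } else if (identical(vmr$flag, "undefined")) {
    caveats <- "VMR undefined (zero mean expression)"
  }
  structure(list(call = call, caveats = caveats, vmr = vmr, grn_status = status),
            class = "gene_call")
}

#' @method print gene_call
#' @export
print.gene_call <- function(x, ...) {
  cat(sprintf("<gene_call> %s (status %s, VMR %.4g)\n", x$call, x$grn_status,
              x$vmr$vmr))
  if (length(x$caveats)) cat("  caveats:", paste(x$caveats, collapse = "; "), "\n")
  invisible(x)
}

#' Infer autoregulation for every gene of an expression matrix
#'
#' For each gene: estimate the sample VMR, test it against the Gamma
#' null, look up the gene's topological status in the GRN, and apply
#' [call_gene()].  Counts should be raw molecule-count estimates; no
#' normalisation is applied internally (normalisation destroys the
#' meaning of the VMR), and non-integer matrices trigger a loud warning.
#'
#' @param expr numeric genes x cells matrix with gene ids as row names
#'   (at least 2 cells), or the result of [read_expression_matrix()].
#' @param grn a [grn()].
#' @param alpha per-gene significance level (no multiple-testing
#'   correction by default; the number of genes tested is recorded in
#'   the report parameters).  Set `p_adjust = "BH"` for an optional
#'   Benjamini-Hochberg pass whose adjusted p-values are appended.
#' @param autonomous character vector of gene ids whose expression the
#'   user asserts to be autonomous (empty by default: the
#'   autonomous-model route is opt-in).
#' @param p_adjust `"none"` or `"BH"`.
#' @return an `inference_report`: a data frame with one row per gene
#'   (columns gene, n, mean, var, vmr, ci_low, ci_high, p, grn_status,
#'   call, caveats) plus `parameters` and `summary` attributes.
#' @export
infer_autoregulation <- function(expr, grn, alpha = 0.05,
                                 autonomous = character(),
                                 p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  if (!inherits(grn, "grn"))
    stop_fanoreg("grn must be a grn object", "fanoreg_contract_error")
  expr <- as.matrix(expr)
  if (nrow(expr) == 0L || ncol(expr) < 2L)
    stop_fanoreg("need a non-empty matrix with at least 2 cells",
                 "fanoreg_data_error")
  if (is.null(rownames(expr)))
    stop_fanoreg("expression matrix must carry gene ids as row names",
                 "fanoreg_data_error")
  if (anyDuplicated(rownames(expr)))
    stop_fanoreg("duplicate gene ids in expression matrix", "fanoreg_data_error")
  if (any(expr < 0))
    stop_fanoreg("negative entries in expression matrix", "fanoreg_data_error")
  if (any(expr != round(expr)))
    warning("non-integer expression values: the theory concerns molecule counts; ",
            "convert indirect measurements to counts before trusting VMR calls")
  genes <- rownames(expr)
  rows <- vector("list", length(genes))
  calls <- character(length(genes))
  for (i in seq_along(genes)) {
    g <- genes[i]
    vt <- suppressWarnings(vmr_test(expr[i, ], alpha = alpha))
    st <- grn_status(grn, g)
    gc <- call_gene(vt, st, autonomous = g %in% autonomous)
    calls[i] <- gc$call
    rows[[i]] <- data.frame(
      gene = g, n = vt$n, mean = vt$mean, var = vt$var,
      vmr = as.numeric(vt$vmr), ci_low = vt$ci_low, ci_high = vt$ci_high,
      p = vt$p_value, grn_status = st, call = gc$call,
      caveats = paste(gc$caveats, collapse = "; "),
      stringsAsFactors = FALSE)
  }
  report <- do.call(rbind, rows)
  if (p_adjust == "BH") report$p_bh <- stats::p.adjust(report$p, method = "BH")
  params <- list(alpha = alpha, variance_estimator = "unbiased (n-1)",
                 null = "Gamma[(n-1)/2, 2/(n-1)]",
                 p_adjust = p_adjust,
                 n_genes_tested = length(genes),
                 autonomous_asserted = autonomous,
                 version = as.character(utils::packageVersion("fanoreg")))
  smry <- table(factor(calls, levels = c("positive_autoregulation_prop1",
                                         "autoregulation_prop2",
                                         "declared_in_grn", "undetermined")))
  structure(report, class = c("inference_report", "data.frame"),
            parameters = params, summary = smry)
}

#' @method print inference_report
#' @export
print.inference_report <- function(x, ...) {
  smry <- attr(x, "summary")
  cat(sprintf("<inference_report> %d genes (alpha = %g)\n", nrow(x),
              attr(x, "parameters")$alpha))
  for (nm in names(smry)) cat(sprintf("  %-32s %d\n", nm, smry[[nm]]))
  NextMethod()
}
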