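#' Read a genes x cells expression count matrix
#'
#' Accepts a TSV (first column gene ids, remaining columns cells, header
#' row with cell ids) or a MatrixMarket `.mtx` file with companion gene
#' and cell id files (one id per line).  Entries must be non-negative;
#' non-integer entries are accepted with a warning (the theory concerns
#' molecule counts).
#'
#' @param path matrix file (`.tsv`/`.txt` or `.mtx`).
#' @param gene_file,cell_file id files (required for `.mtx`).
#' @param transpose set if the file stores cells as rows.
#' @return numeric matrix with gene row names and cell column names.
#' @export
read_expression_matrix <- function(path, gene_file = NULL, cell_file = NULL,
                                   transpose = FALSE) {
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    if (is.null(gene_file) || is.null(cell_file))
      stop_fanoreg("MTX input needs gene_file and cell_file", "fanoreg_parse_error")
    m <- as.matrix(Matrix::readMM(path))
    genes <- readLines(gene_file, warn = FALSE)
    cells <- readLines(cell_file, warn = FALSE)
    if (transpose) m <- t(m)
    if (nrow(m) != length(genes) || ncol(m) != length(cells))
      stop_fanoreg(sprintf(
        "MTX shape %dx%d does not match %d gene ids / %d cell ids",
        nrow(m), ncol(m), length(genes), length(cells)), "fanoreg_parse_error")
    dimnames(m) <- list(genes, cells)
  } else {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
    ids <- as.character(df[[1L]])
    m <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- ids
    if (transpose) m <- t(m)
  }
  if (anyDuplicated(rownames(m)))
    stop_fanoreg("duplicate gene ids in expression matrix", "fanoreg_parse_error")
  neg <- which(m < 0, arr.ind = TRUE)
  if (nrow(neg) > 0L)
    stop_fanoreg(sprintf("negative entry at gene '%s', cell '%s'",
                         rownames(m)[neg[1L, 1L]], colnames(m)[neg[1L, 2L]]),
                 "fanoreg_data_error")
  if (any(m != round(m)))
    warning("non-integer entries: values should be molecule counts")
  m
}

#' Write a genes x cells matrix as TSV
#'
#' @param m matrix with gene row names.
#' @param path output path.
#' @export
write_expression_matrix <- function(m, path) {
  df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an inference report (TSV and/or JSON mirror)
#'
#' The TSV has a fixed, deterministic column order; tab or newline
#' characters inside caveat strings are replaced by spaces so the file
#' stays parseable.  The JSON mirror additionally carries the run
#' parameters for provenance.
#'
#' @param report an `inference_report`.
#' @param tsv,json output paths (`NULL` to skip either).
#' @return invisibly, the written paths.
#' @export
write_report <- function(report, tsv = NULL, json = NULL) {
  if (!inherits(report, "inference_report"))
    stop_fanoreg("report must be an inference_report", "fanoreg_contract_error")
  cols <- c("gene", "n", "mean", "var", "vmr", "ci_low", "ci_high", "p",
            "grn_status", "call", "caveats")
  extra <- setdiff(names(report), cols)
  df <- as.data.frame(report)[, c(cols, extra), drop = FALSE]
  df$caveats <- gsub("[\t\n\r]+", " ", df$caveats)
  if (!is.null(tsv))
    utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(list(parameters = attr(report, "parameters"),
                              summary = as.list(attr(report, "summary")),
                              calls = df),
                         json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(tsv = tsv, json = json))
}

#' Re-read a report TSV written by [write_report()]
#'
#' @param path TSV path.
#' @return data frame with the report columns.
#' @export
read_report <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Read a model specification file (JSON)
#'
#' Plain structured text describing a model to solve or simulate.  For
#' `type: "birth_death"`, `f` and `g` are either explicit arrays
#' (`f[n]` = rate of `n-1 -> n`) or named parametric families:
#' `{"family": "constant", "h": 5}`,
#' `{"family": "linear", "k": 2, "b": 1, "c": 2}`,
#' `{"family": "hill", "k0": ..., "Vmax": ..., "K": ..., "coef": ...,
#'   "c": ..., "activating": true}`.
#' For `type: "network"`, the presets `"example2"` (optional `box`) and
#' `"cascade"` (`parent_h`, `a`, `b`) are available, as well as
#' per-species rate lists where each entry is `{"family": "constant",
#' "rate": r}`, `{"family": "linear_in", "source": j, "a": ..., "b":
#' ...}` (rate `a + b * n_j`) or `{"family": "indicator", "source": j,
#' "value": v, "rate": r}` (rate `r` when `n_j == v`, else 0), plus
#' `box` and `initial_state`.  `type: "telegraph"` and
#' `type: "multistep_cycle"` carry their model parameters directly.
#'
#' @param path JSON file path.
#' @return one of [birth_death_chain()], [network_chain()],
#'   [telegraph_model()], [multistep_cycle_model()], with attribute
#'   `"spec"` holding the raw parsed list.
#' @export
read_model_spec <- function(path) {
  sp <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  model <- model_from_spec(sp)
  attr(model, "spec") <- sp
  model
}

#' Build a model object from a parsed specification list
#'
#' @param sp a list as documented in [read_model_spec()].
#' @return a model object.
#' @export
model_from_spec <- function(sp) {
  type <- sp$type %||% stop_fanoreg("model spec needs a 'type'", "fanoreg_parse_error")
  n_max <- sp$n_max %||% 1e5L
  if (type == "birth_death") {
    mk <- function(x, which) {
      if (is.numeric(x)) return(x)
      fam <- x$family %||% stop_fanoreg("rate entry needs a 'family'",
                                        "fanoreg_parse_error")
      switch(fam,
        constant = if (which == "f") {
          h <- x$h %||% x$rate
          function(n) rep(h, length(n))
        } else {
          r <- x$rate %||% 1
          function(n) rep(r, length(n))
        },
        linear = if (which == "f") {
          function(n) pmax(x$k + x$b * (n - 1), 0)
        } else {
          function(n) rep(x$c, length(n))
        },
        hill = if (which == "f") {
          function(n) {
            xx <- (n - 1)^x$coef
            fr <- if (isTRUE(x$activating %||% TRUE)) xx / (x$K^x$coef + xx)
                  else x$K^x$coef / (x$K^x$coef + xx)
            (x$k0 %||% 0) + x$Vmax * fr
          }
        } else {
          function(n) rep(x$c, length(n))
        },
        stop_fanoreg(paste("unknown rate family:", fam), "fanoreg_parse_error"))
    }
    fspec <- sp$f; gspec <- sp$g
    # a single parametric family may describe both f and g (linear, hill)
    if (is.null(gspec) && !is.null(fspec$family) &&
        fspec$family %in% c("linear", "hill")) gspec <- fspec
    return(birth_death_chain(mk(fspec, "f"), mk(gspec, "g"), n_max = n_max))
  }
  if (type == "network") {
    if (identical(sp$preset, "example2"))
      return(example2_network(box = sp$box %||% 30L))
    if (identical(sp$preset, "cascade"))
      return(cascade_network(sp$parent_h, sp$a %||% 1, sp$b %||% 1,
                             box = sp$box))
    mkn <- function(x) {
      fam <- x$family %||% stop_fanoreg("rate entry needs a 'family'",
                                        "fanoreg_parse_error")
      switch(fam,
        constant = { r <- x$rate; function(n) r },
        linear_in = { a <- x$a %||% 0; b <- x$b %||% 1; j <- x$source
                      function(n) max(a + b * n[j], 0) },
        indicator = { r <- x$rate %||% 1; j <- x$source; v <- x$value
                      function(n) if (n[j] == v) r else 0 },
        stop_fanoreg(paste("unknown rate family:", fam), "fanoreg_parse_error"))
    }
    aslist <- function(z) if (is.data.frame(z)) lapply(seq_len(nrow(z)), function(i)
      as.list(z[i, , drop = FALSE])) else z
    f <- lapply(aslist(sp$f), mkn)
    g <- lapply(aslist(sp$g), mkn)
    return(network_chain(f, g, box = sp$box,
                         init = sp$initial_state %||% NULL))
  }
  if (type == "telegraph")
    return(telegraph_model(sp$k_on, sp$k_off, sp$rho_on, sp$rho_off %||% 0,
                           sp$deg %||% 1))
  if (type == "multistep_cycle")
    return(multistep_cycle_model(sp$k, sp$stage_rate, sp$deg_rate))
  stop_fanoreg(paste("unknown model type:", type), "fanoreg_parse_error")
}
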