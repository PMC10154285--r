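#' Gene regulatory network (directed edge set)
#'
#' A GRN is a directed graph in which each vertex is a gene and each edge
#' `regulator -> target` a regulatory relationship.  Self-loops are
#' permitted: they declare autoregulation in the input and the gene is
#' then excluded from VMR-based inference.
#'
#' @param edges a two-column data frame or matrix (regulator, target);
#'   may have zero rows.
#' @param genes optional character vector of additional gene ids with no
#'   edges (isolated vertices).
#' @return an object of class `grn`.
#' @export
grn <- function(edges = NULL, genes = character()) {
  if (is.null(edges)) {
    ed <- data.frame(regulator = character(), target = character(),
                     stringsAsFactors = FALSE)
  } else {
    ed <- as.data.frame(edges, stringsAsFactors = FALSE)
    if (ncol(ed) != 2L)
      stop_fanoreg("edges must have exactly two columns (regulator, target)",
                   "fanoreg_parse_error")
    names(ed) <- c("regulator", "target")
    ed$regulator <- as.character(ed$regulator)
    ed$target <- as.character(ed$target)
    ed <- unique(ed)
  }
  verts <- unique(c(ed$regulator, ed$target, as.character(genes)))
  g <- igraph::graph_from_data_frame(ed, directed = TRUE,
                                     vertices = data.frame(name = verts))
  structure(list(genes = verts, edges = ed, graph = g), class = "grn")
}

#' @method print grn
#' @export
print.grn <- function(x, ...) {
  cat(sprintf("<grn> %d genes, %d edges\n", length(x$genes), nrow(x$edges)))
  invisible(x)
}

#' Read a GRN from a two-column TSV edge list
#'
#' Column 1 is the regulator, column 2 the target.  A header row is
#' skipped if it matches common column names (regulator/target, from/to,
#' source/target).  Duplicate edges are removed.  Gene identifiers are
#' case-sensitive strings; set `case_insensitive = TRUE` to fold all ids
#' to lower case (silent case-folding causes false joins, so this is off
#' by default).
#'
#' @param path path to the TSV file.
#' @param vertex_file optional file with one gene id per line, for genes
#'   with no edges.
#' @param case_insensitive fold identifiers to lower case.
#' @return a [grn()].
#' @export
read_grn_edgelist <- function(path, vertex_file = NULL, case_insensitive = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("empty GRN file: ", path)
    return(grn())
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  # tolerate whitespace-separated files
  if (any(lengths(parts) == 1L)) {
    alt <- strsplit(lines, "[[:space:]]+")
    fixable <- lengths(parts) == 1L & lengths(alt) >= 2L
    parts[fixable] <- alt[fixable]
  }
  hdr <- tolower(trimws(parts[[1L]]))
  header_like <- length(hdr) >= 2L &&
    (all(hdr[1:2] == c("regulator", "target")) || all(hdr[1:2] == c("from", "to")) ||
     all(hdr[1:2] == c("source", "target")))
  start <- if (header_like) 2L else 1L
  if (start > length(parts)) {
    warning("GRN file contains only a header: ", path)
    return(grn())
  }
  rows <- parts[start:length(parts)]
  bad <- which(lengths(rows) < 2L)
  if (length(bad) > 0L)
    stop_fanoreg(sprintf("malformed GRN row at line %d of %s (need 2 columns)",
                         bad[1L] + start - 1L, path), "fanoreg_parse_error")
  reg <- trimws(vapply(rows, `[[`, "", 1L))
  tgt <- trimws(vapply(rows, `[[`, "", 2L))
  extra <- character()
  if (!is.null(vertex_file)) {
    extra <- trimws(readLines(vertex_file, warn = FALSE))
    extra <- extra[nzchar(extra)]
  }
  if (case_insensitive) {
    reg <- tolower(reg); tgt <- tolower(tgt); extra <- tolower(extra)
  }
  out <- grn(data.frame(regulator = reg, target = tgt, stringsAsFactors = FALSE),
             genes = extra)
  message(sprintf("read_grn_edgelist: %d rows parsed, %d unique edges, %d genes",
                  length(reg), nrow(out$edges), length(out$genes)))
  out
}

.check_gene <- function(x, gene) {
  if (!(gene %in% x$genes))
    stop_fanoreg(sprintf("gene '%s' is not in the GRN", gene), "fanoreg_key_error")
}

#' Ancestors of a gene in the GRN
#'
#' All genes with a directed path to `gene`.  The gene itself is included
#' only when it lies on a directed cycle through itself (including a
#' self-loop).
#'
#' @param x a [grn()].
#' @param gene gene identifier.
#' @return character vector of ancestor ids (possibly empty).
#' @export
grn_ancestors <- function(x, gene) {
  stopifnot(inherits(x, "grn"))
  .check_gene(x, gene)
  anc <- names(igraph::subcomponent(x$graph, gene, mode = "in"))
  anc <- setdiff(anc, gene)
  preds <- names(igraph::neighbors(x$graph, gene, mode = "in"))
  if (length(preds) > 0L) {
    reach <- names(igraph::subcomponent(x$graph, gene, mode = "out"))
    if (length(intersect(preds, reach)) > 0L) anc <- union(anc, gene)
  }
  sort(anc)
}

#' Is a gene inside a feedback loop (directed cycle of length >= 2)?
#'
#' Computed via strongly connected components: the gene is in a feedback
#' loop iff its strong component has at least two vertices.  A self-loop
#' alone does not count; it is a declared autoregulation, reported
#' separately by [grn_status()].
#'
#' @inheritParams grn_ancestors
#' @return logical.
#' @export
in_feedback_loop <- function(x, gene) {
  stopifnot(inherits(x, "grn"))
  .check_gene(x, gene)
  comp <- igraph::components(x$graph, mode = "strong")
  sizes <- comp$csize[comp$membership]
  unname(sizes[match(gene, names(comp$membership))] >= 2L)
}

#' Topological status of a gene for the inference decision logic
#'
#' @inheritParams grn_ancestors
#' @return one of `"absent"` (not in the GRN), `"self_loop_declared"`,
#'   `"in_cycle"`, `"no_ancestors"`, `"has_ancestors_acyclic"`.
#' @export
grn_status <- function(x, gene) {
  stopifnot(inherits(x, "grn"))
  if (!(gene %in% x$genes)) return("absent")
  if (any(x$edges$regulator == gene & x$edges$target == gene))
    return("self_loop_declared")
  if (in_feedback_loop(x, gene)) return("in_cycle")
  anc <- grn_ancestors(x, gene)
  if (length(anc) == 0L) "no_ancestors" else "has_ancestors_acyclic"
}
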