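#' Specify a ground-truth-labelled synthetic benchmark
#'
#' A benchmark is a list of gene blocks, each drawn from one of the model
#' families the theory covers, simulated at stationarity by the exact
#' SSA kernels.  Families: `poisson_constant_h` (no autoregulation),
#' `linear_autoreg` (\eqn{f_n = k + b(n-1)}, \eqn{g_n = c}),
#' `hill_autoreg`, `telegraph` (bursting, no autoregulation),
#' `cascade_child` (parent -> child pair, no autoregulation),
#' `example2_pair` (the indicator-gated two-gene cycle), and
#' `multistep_cycle` (VMR < 1 with no autoregulation; breaks the
#' one-step assumption).
#'
#' @param n_cells number of cells to simulate.
#' @param blocks list of blocks, each `list(family = ..., count = ...,
#'   params = list(...))`; see [benchmark_block()].
#' @param seed integer seed; the whole benchmark is reproducible from it.
#' @return an object of class `benchmark_spec`.
#' @seealso [generate_benchmark()], [default_benchmark_spec()]
#' @export
benchmark_spec <- function(n_cells, blocks, seed = 1L) {
  if (!is.numeric(n_cells) || n_cells < 2)
    stop_fanoreg("n_cells must be >= 2", "fanoreg_spec_error")
  blocks <- lapply(blocks, function(b) {
    do.call(benchmark_block, c(list(family = b$family, count = b$count %||% 1L),
                               b$params %||% list()))
  })
  structure(list(n_cells = as.integer(n_cells), blocks = blocks,
                 seed = as.integer(seed)),
            class = "benchmark_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate one benchmark block
#'
#' @param family one of the family names listed in [benchmark_spec()].
#' @param ... family parameters; validity is enforced per family (e.g.
#'   the linear family requires `c > 0` and `c - b > 0`).  Placed before
#'   `count` so that the linear family's `c` parameter cannot partially
#'   match it.
#' @param count number of genes (or gene pairs, for the two-species
#'   families) drawn from this block.
#' @return a validated block description.
#' @export
benchmark_block <- function(family, ..., count = 1L) {
  families <- c("poisson_constant_h", "linear_autoreg", "hill_autoreg",
                "telegraph", "cascade_child", "example2_pair", "multistep_cycle")
  if (!(family %in% families))
    stop_fanoreg(paste("unknown family:", family), "fanoreg_spec_error")
  params <- list(...)
  # constructing the model validates the parameters up front
  truth <- switch(family,
    poisson_constant_h = {
      do.call(constant_h_chain, params["h"])
      list(label = "none", true_vmr = 1)
    },
    linear_autoreg = {
      ch <- do.call(linear_autoreg_chain, params[c("k", "b", "c")])
      lbl <- classify_rate_autoregulation(ch, n_upper = 50L)
      list(label = lbl, true_vmr = 1 + params$b / (params$c - params$b))
    },
    hill_autoreg = {
      ch <- do.call(hill_autoreg_chain,
                    params[intersect(names(params),
                                     c("k0", "Vmax", "K", "coef", "c", "activating"))])
      list(label = classify_rate_autoregulation(ch, n_upper = 50L),
           true_vmr = NA_real_)
    },
    telegraph = {
      do.call(telegraph_model,
              params[intersect(names(params),
                               c("k_on", "k_off", "rho_on", "rho_off", "deg"))])
      list(label = "none_bursting", true_vmr = NA_real_)
    },
    cascade_child = {
      do.call(cascade_network,
              params[intersect(names(params), c("parent_h", "a", "b"))])
      list(label = "none", true_vmr = NA_real_)
    },
    example2_pair = list(label = "none", true_vmr = 2 * exp(1) / (4 * exp(1) - 1)),
    multistep_cycle = {
      do.call(multistep_cycle_model,
              params[intersect(names(params), c("k", "stage_rate", "deg_rate"))])
      list(label = "none", true_vmr = NA_real_)
    })
  list(family = family, count = as.integer(count), params = params,
       label = truth$label, true_vmr = truth$true_vmr)
}

#' Default benchmark mirroring the qualitative landscape of real panels
#'
#' Most genes end up undetermined and a minority is detectable: 10
#' Poisson genes (h = 8), 3 positive and 3 negative linear-autoregulation
#' genes (stationary VMR 2 and 0.5), 3 bursting telegraph genes, 2
#' cascade parent/child pairs, and one indicator-gated pair sitting in a
#' feedback loop.
#'
#' @inheritParams benchmark_spec
#' @return a `benchmark_spec`.
#' @export
default_benchmark_spec <- function(n_cells = 1000L, seed = 1L) {
  benchmark_spec(n_cells, seed = seed, blocks = list(
    list(family = "poisson_constant_h", count = 10L, params = list(h = 8)),
    list(family = "linear_autoreg", count = 3L, params = list(k = 4, b = 1.5, c = 3)),
    list(family = "linear_autoreg", count = 3L, params = list(k = 18, b = -3, c = 3)),
    list(family = "telegraph", count = 3L,
         params = list(k_on = 0.1, k_off = 0.1, rho_on = 20, rho_off = 0, deg = 1)),
    list(family = "cascade_child", count = 2L,
         params = list(parent_h = 5, a = 1, b = 1)),
    list(family = "example2_pair", count = 1L)
  ))
}

#' Generate a labelled benchmark: counts, GRN and truth table
#'
#' Simulates every block at stationarity via the exact SSA kernels and
#' assembles a genes x cells count matrix, the true GRN (cascade edges
#' and the two-gene cycle; all genes appear as vertices), and a truth
#' table recording the rate-level ground truth of each gene (what the
#' synthesis/degradation rates do, not what is detectable at the given
#' sample size).
#'
#' @param spec a [benchmark_spec()].
#' @return list with `expr` (integer matrix, gene ids as row names),
#'   `grn` (a [grn()]), and `truth` (data frame: gene, label, family,
#'   true_vmr).
#' @export
generate_benchmark <- function(spec) {
  stopifnot(inherits(spec, "benchmark_spec"))
  set.seed(spec$seed)
  plan <- simulation_plan(spec$n_cells)  # seed managed here, not per call
  short <- c(poisson_constant_h = "pois", linear_autoreg = "lin",
             hill_autoreg = "hill", telegraph = "tel",
             cascade_child = "casc", example2_pair = "ex2",
             multistep_cycle = "mstep")
  rows <- list(); truth <- list(); edges <- list()
  counter <- stats::setNames(rep(0L, length(short)), names(short))
  for (blk in spec$blocks) {
    for (j in seq_len(blk$count)) {
      counter[blk$family] <- counter[blk$family] + 1L
      id <- sprintf("%s_%02d", short[[blk$family]], counter[blk$family])
      p <- blk$params
      if (blk$family == "poisson_constant_h") {
        x <- simulate_birth_death(constant_h_chain(p$h), plan)
        rows[[id]] <- x
        truth[[id]] <- data.frame(gene = id, label = blk$label,
                                  family = blk$family, true_vmr = blk$true_vmr)
      } else if (blk$family == "linear_autoreg") {
        x <- simulate_birth_death(linear_autoreg_chain(p$k, p$b, p$c), plan)
        rows[[id]] <- x
        truth[[id]] <- data.frame(gene = id, label = blk$label,
                                  family = blk$family, true_vmr = blk$true_vmr)
      } else if (blk$family == "hill_autoreg") {
        ch <- do.call(hill_autoreg_chain,
                      p[intersect(names(p), c("k0", "Vmax", "K", "coef", "c", "activating"))])
        rows[[id]] <- simulate_birth_death(ch, plan)
        truth[[id]] <- data.frame(gene = id, label = blk$label,
                                  family = blk$family, true_vmr = blk$true_vmr)
      } else if (blk$family == "telegraph") {
        md <- do.call(telegraph_model,
                      p[intersect(names(p), c("k_on", "k_off", "rho_on", "rho_off", "deg"))])
        # burn past both the switching and degradation time scales
        plan_t <- simulation_plan(spec$n_cells,
                                  burn_in = 20 / min(md$deg, md$k_on + md$k_off))
        rows[[id]] <- simulate_telegraph(md, plan_t)
        truth[[id]] <- data.frame(gene = id, label = blk$label,
                                  family = blk$family, true_vmr = blk$true_vmr)
      } else if (blk$family == "cascade_child") {
        net <- do.call(cascade_network,
                       p[intersect(names(p), c("parent_h", "a", "b"))])
        xy <- simulate_network(net, plan)
        pid <- paste0(id, "_parent"); cid <- paste0(id, "_child")
        rows[[pid]] <- xy[, 1L]; rows[[cid]] <- xy[, 2L]
        edges[[length(edges) + 1L]] <- data.frame(regulator = pid, target = cid)
        truth[[pid]] <- data.frame(gene = pid, label = "none",
                                   family = blk$family, true_vmr = 1)
        truth[[cid]] <- data.frame(gene = cid, label = "none",
                                   family = blk$family, true_vmr = NA_real_)
      } else if (blk$family == "example2_pair") {
        net <- example2_network(box = p$box %||% 25L)
        xy <- simulate_network(net, plan)
        aid <- paste0(id, "_a"); bid <- paste0(id, "_b")
        rows[[aid]] <- xy[, 1L]; rows[[bid]] <- xy[, 2L]
        edges[[length(edges) + 1L]] <- data.frame(regulator = c(aid, bid),
                                                  target = c(bid, aid))
        for (gid in c(aid, bid))
          truth[[gid]] <- data.frame(gene = gid, label = blk$label,
                                     family = blk$family, true_vmr = blk$true_vmr)
      } else if (blk$family == "multistep_cycle") {
        md <- do.call(multistep_cycle_model,
                      p[intersect(names(p), c("k", "stage_rate", "deg_rate"))])
        rows[[id]] <- simulate_multistep_cycle(md, plan)
        truth[[id]] <- data.frame(gene = id, label = blk$label,
                                  family = blk$family, true_vmr = blk$true_vmr)
      }
    }
  }
  expr <- do.call(rbind, rows)
  rownames(expr) <- names(rows)
  colnames(expr) <- sprintf("cell_%04d", seq_len(ncol(expr)))
  ed <- if (length(edges)) do.call(rbind, edges) else NULL
  list(expr = expr,
       grn = grn(ed, genes = names(rows)),
       truth = do.call(rbind, c(truth, list(make.row.names = FALSE))))
}
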