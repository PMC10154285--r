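fake_vmr <- function(flag, vmr = 0.5) {
  structure(list(n = 500L, mean = 5, var = vmr * 5, vmr = vmr,
                 ci_low = 0.88, ci_high = 1.13, p_value = 0.001, alpha = 0.05,
                 flag = flag), class = "vmr_result")
}

test_that("call_gene implements the decision order of the algorithm", {
  below <- fake_vmr("significantly_below_1", 0.5)
  above <- fake_vmr("significantly_above_1", 3)
  ns <- fake_vmr("not_significant", 1.01)

  expect_identical(call_gene(below, "has_ancestors_acyclic")$call,
                   "autoregulation_prop2")
  expect_identical(call_gene(below, "no_ancestors")$call, "autoregulation_prop2")
  # the acyclic-bound route takes precedence even when autonomy is asserted
  expect_identical(call_gene(below, "no_ancestors", autonomous = TRUE)$call,
                   "autoregulation_prop2")
  expect_identical(call_gene(below, "in_cycle")$call, "undetermined")
  expect_identical(call_gene(below, "absent")$call, "undetermined")
  expect_identical(call_gene(below, "self_loop_declared")$call, "declared_in_grn")

  expect_identical(call_gene(above, "no_ancestors", autonomous = TRUE)$call,
                   "positive_autoregulation_prop1")
  expect_identical(call_gene(above, "no_ancestors")$call, "undetermined")
  expect_identical(call_gene(above, "has_ancestors_acyclic", TRUE)$call,
                   "undetermined")
  expect_identical(call_gene(above, "in_cycle", TRUE)$call, "undetermined")

  expect_identical(call_gene(ns, "no_ancestors", TRUE)$call, "undetermined")
  expect_identical(call_gene(fake_vmr("undefined", NA), "no_ancestors")$call,
                   "undetermined")

  pc <- call_gene(above, "no_ancestors", TRUE)
  expect_match(pc$caveats, "autonomy", all = FALSE)
  p2 <- call_gene(below, "has_ancestors_acyclic")
  expect_match(p2$caveats, "one-step", all = FALSE)

  expect_error(call_gene(list(), "no_ancestors"), class = "fanoreg_contract_error")
  expect_error(call_gene(below, "weird"), class = "fanoreg_contract_error")
})

make_expr <- function(n = 400) {
  set.seed(71)
  expr <- rbind(
    root_pos = rnbinom(n, size = 3, mu = 9),        # Fano 4, no ancestors
    acyc_neg = {                                    # sub-Poissonian child
      x <- rbinom(n, 12, 0.5); x                    # VMR ~ 0.5
    },
    cyc_gene = rnbinom(n, size = 3, mu = 9),
    quiet = rpois(n, 6),
    ghost = rpois(n, 6),
    declared = rbinom(n, 12, 0.5),
    silent = rep(0L, n)
  )
  colnames(expr) <- paste0("c", seq_len(n))
  expr
}

make_grn <- function() {
  grn(data.frame(
    regulator = c("root_pos", "cyc_gene", "cyc_mate", "acyc_neg", "declared"),
    target    = c("acyc_neg", "cyc_mate", "cyc_gene", "cyc_gene", "declared")),
    genes = c("quiet", "silent"))
}

test_that("infer_autoregulation combines tests and topology per gene", {
  expr <- make_expr()
  rep <- suppressWarnings(
    infer_autoregulation(expr, make_grn(), autonomous = "root_pos"))
  calls <- setNames(rep$call, rep$gene)
  expect_identical(unname(calls["root_pos"]), "positive_autoregulation_prop1")
  expect_identical(unname(calls["acyc_neg"]), "autoregulation_prop2")
  expect_identical(unname(calls["cyc_gene"]), "undetermined")
  expect_identical(unname(calls["ghost"]), "undetermined")
  expect_identical(unname(calls["declared"]), "declared_in_grn")
  expect_identical(rep$grn_status[rep$gene == "ghost"], "absent")
  expect_identical(rep$grn_status[rep$gene == "silent"], "no_ancestors")

  smry <- attr(rep, "summary")
  expect_equal(sum(smry), nrow(rep))
  expect_equal(unname(smry[["autoregulation_prop2"]]),
               sum(rep$call == "autoregulation_prop2"))
  # no negative ("no autoregulation") verdict exists in the vocabulary
  expect_true(all(rep$call %in% c("positive_autoregulation_prop1",
                                  "autoregulation_prop2", "declared_in_grn",
                                  "undetermined")))
})

test_that("lowering alpha only moves calls toward undetermined", {
  expr <- make_expr()
  g <- make_grn()
  loose <- suppressWarnings(infer_autoregulation(expr, g, alpha = 0.05,
                                                 autonomous = "root_pos"))
  strict <- suppressWarnings(infer_autoregulation(expr, g, alpha = 1e-6,
                                                  autonomous = "root_pos"))
  for (gene in loose$gene) {
    lc <- loose$call[loose$gene == gene]
    sc <- strict$call[strict$gene == gene]
    if (sc != "undetermined") expect_identical(sc, lc)
  }
})

test_that("input validation matches the data contract", {
  g <- make_grn()
  expect_error(infer_autoregulation(matrix(1, 0, 5), g), class = "fanoreg_data_error")
  m <- matrix(c(1, 2, 3, 4), 2, 2, dimnames = list(c("a", "b"), NULL))
  expect_error(infer_autoregulation(m - 2, g), class = "fanoreg_data_error")
  expect_warning(infer_autoregulation(m + 0.5, g), "molecule counts")
  nodim <- matrix(1:4, 2, 2)
  expect_error(infer_autoregulation(nodim, g), class = "fanoreg_data_error")
})
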