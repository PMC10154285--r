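# Independent oracles used across the suite.  These deliberately avoid
# the package's own code paths (and igraph/Matrix) so that agreement is
# evidence, not tautology.

# reachability by brute-force adjacency-matrix powers on a small digraph;
# edges is a 2-column character matrix/data.frame
brute_ancestors <- function(edges, genes, gene) {
  n <- length(genes)
  A <- matrix(0L, n, n, dimnames = list(genes, genes))
  for (r in seq_len(nrow(edges))) A[edges[r, 1L], edges[r, 2L]] <- 1L
  reach <- A
  P <- A
  for (step in seq_len(n)) {
    P <- (P %*% A > 0) + 0L
    reach <- ((reach + P) > 0) + 0L
  }
  genes[reach[, gene] > 0]
}

brute_on_cycle <- function(edges, genes, gene, min_len = 2L) {
  anc <- brute_ancestors(edges, genes, gene)
  if (!(gene %in% anc)) return(FALSE)
  if (min_len <= 1L) return(TRUE)
  # exclude pure self-loop cycles: drop the self edge and re-test
  keep <- !(edges[, 1L] == gene & edges[, 2L] == gene)
  e2 <- edges[keep, , drop = FALSE]
  if (nrow(e2) == 0L) return(FALSE)
  gene %in% brute_ancestors(e2, genes, gene)
}

random_digraph <- function(n_vertices, p_edge) {
  genes <- paste0("g", seq_len(n_vertices))
  pairs <- expand.grid(from = genes, to = genes, stringsAsFactors = FALSE)
  pairs <- pairs[runif(nrow(pairs)) < p_edge, , drop = FALSE]
  as.matrix(pairs)
}

# exact stationary law of the two-gene indicator-gated chain on the
# "cross" reachable from (2,2): P(n1, 2) and P(2, n2) proportional to
# 1/n1! and 1/n2!, the shared state (2,2) counted once
example2_cross_oracle <- function(n_top = 30L) {
  states <- rbind(cbind(0:n_top, 2L), cbind(2L, setdiff(0:n_top, 2L)))
  w <- ifelse(states[, 1L] == 2L & states[, 2L] == 2L, 1 / 2,
              ifelse(states[, 2L] == 2L, 1 / factorial(states[, 1L]),
                     1 / factorial(states[, 2L])))
  list(states = states, probabilities = w / sum(w))
}

tv_distance <- function(p, q) sum(abs(p - q)) / 2

# empirical pmf of integer samples on 0..n_top
empirical_pmf <- function(x, n_top) {
  tabulate(pmin(x, n_top) + 1L, nbins = n_top + 1L) / length(x)
}

# population-moment VMR of raw pooled samples (oracle for decompose_vmr)
pop_vmr <- function(x) {
  mu <- mean(x)
  (mean(x^2) - mu^2) / mu
}

# a small random monotone-h birth-death chain; direction +1 or -1
random_monotone_chain <- function(direction, n_max = 150L) {
  # h varies where the stationary mass lives (small n), bounded
  n_knots <- sample(3:8, 1L)
  steps <- c(0, sort(sample(1:25, n_knots)))
  incr <- runif(n_knots + 1L, 0, 1.5)
  h_base <- runif(1, 0.5, 6)
  hfun <- function(n) {
    lvl <- vapply(n, function(k) sum(steps <= k), 0L)
    h <- h_base + direction * cumsum(incr)[pmax(lvl, 1L)]
    pmax(h, 0.05)
  }
  g <- runif(1, 0.5, 3)
  birth_death_chain(f = function(n) hfun(n) * g,
                    g = function(n) rep(g, length(n)),
                    n_max = n_max)
}

# random acyclic 2-3 gene network with global constant degradation and
# no autoregulation: f of gene k depends only on earlier genes.  Rate
# scales are kept modest so the truncated boxes stay desk-sized on one
# CPU; the solver's boundary-mass guard still verifies adequacy.
random_acyclic_network <- function(m = 2L) {
  sc <- if (m >= 3L) 0.6 else 1  # keep 3-gene boxes desk-sized on one CPU
  h_root <- runif(1, 0.8, 3 * sc)
  make_child_f <- function(parent) {
    kind <- sample(c("constant", "linear", "hill"), 1L)
    a <- runif(1, 0.4, 1.5 * sc); b <- runif(1, 0.1, 0.3)
    V <- runif(1, 0.8, 3 * sc); K <- runif(1, 1, 4)
    force(parent)
    switch(kind,
      constant = function(n) a + V / 2,
      linear = function(n) a + b * n[parent],
      hill = function(n) a + V * n[parent] / (K + n[parent]))
  }
  f <- list(function(n) h_root)
  means <- h_root
  for (k in 2:m) {
    parent <- k - 1L
    f[[k]] <- make_child_f(parent)
    probe <- rep(0, m); probe[parent] <- means[parent]
    means <- c(means, f[[k]](probe) * 1.5)  # crude upper scale for the box
  }
  g <- replicate(m, function(n) 1)
  box <- ceiling(means + (if (m >= 3L) 8 else 10) * sqrt(means + 1) + 6)
  network_chain(f, g, box = box, init = rep(0L, m))
}
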