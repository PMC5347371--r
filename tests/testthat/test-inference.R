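# hand-built minimal chain object for summary-level tests
mini_fit <- function(edge, beta, phenotypes = c("A", "B", "C"),
                     mean_e = NULL, mean_pair = NULL, logpost = NULL,
                     snp_ids = NULL) {
  n <- length(phenotypes)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  S <- nrow(edge)
  if (is.null(mean_e)) mean_e <- matrix(0.5, 2, n)
  if (is.null(mean_pair)) mean_pair <- matrix(0.25, 2, nrow(pairs))
  if (is.null(snp_ids)) snp_ids <- paste0("rs", seq_len(nrow(mean_e)))
  pn <- paste(phenotypes[pairs[, 1]], phenotypes[pairs[, 2]], sep = "__")
  colnames(mean_pair) <- pn
  rownames(mean_e) <- rownames(mean_pair) <- snp_ids
  colnames(mean_e) <- phenotypes
  structure(list(
    phenotypes = phenotypes, snp_ids = snp_ids, pairs = pairs,
    pair_names = pn,
    draws = list(alpha = matrix(0, S, n), mu = matrix(0, S, n),
                 sigma2 = matrix(1, S, n), beta = beta, edge = edge,
                 logpost = if (is.null(logpost)) rnorm(S) else logpost),
    mean_e = mean_e, mean_pair = mean_pair,
    accept = list(alpha = 0.4, beta = 0.3, graph = 0.05),
    config = list(), hyper = hyper_defaults(), independent = FALSE,
    field_draws = NULL), class = "hmrf_fit")
}

test_that("edge summaries report inclusion, exceedance and both coupling scales", {
  set.seed(51)
  S <- 10
  edge <- matrix(0L, S, 3); beta <- matrix(0, S, 3)
  edge[, 1] <- 1L; beta[, 1] <- 2               # pair (1,2): always present
  edge[1:4, 2] <- 1L; beta[1:4, 2] <- c(1, 2, 3, 4)  # pair (1,3): 40%
  summ <- summarize_edges(mini_fit(edge, beta))
  expect_equal(summ$post_edge_prob, c(1, 0.4, 0))
  expect_equal(summ$exceed_prob, c(1, 0.4, 0))
  expect_equal(summ$beta_mean_marginal[1], 2)
  expect_equal(summ$beta_mean_conditional[1], 2)
  expect_equal(summ$beta_mean_marginal[2], 1)   # zeros included
  expect_equal(summ$beta_mean_conditional[2], 2.5)
  expect_true(is.na(summ$beta_mean_conditional[3]))

  # quantiles agree with an interpolation-formula oracle
  b2 <- beta[, 2]
  expect_equal(summ$beta_q025_marginal[2], oracle_quantile(b2, 0.025))
  expect_equal(summ$beta_q975_marginal[2], oracle_quantile(b2, 0.975))
  expect_equal(summ$beta_q975_conditional[2], oracle_quantile(c(1, 2, 3, 4), 0.975))

  # exceedance can never exceed inclusion
  expect_true(all(summ$exceed_prob <= summ$post_edge_prob + 1e-12))
})

test_that("edge declaration applies both decision rules", {
  summ <- data.frame(i = c(1, 1, 2), j = c(2, 3, 3),
                     pheno_i = c("A", "A", "B"), pheno_j = c("B", "C", "C"),
                     post_edge_prob = c(0.99, 0.9, 0.4),
                     exceed_prob = c(0.99, 0.9, 0.4),
                     beta_q025_marginal = c(0.5, 0, 0),
                     beta_q975_marginal = c(3, 2, 1))
  g <- declare_edges(summ)
  expect_equal(sum(g$adj) / 2, 1)   # only the 0.99 pair passes 0.95
  expect_equal(g$adj[1, 2], 1L)
  summary_out <- attr(g, "summary")
  expect_identical(summary_out$selected, c(TRUE, FALSE, FALSE))

  g2 <- declare_edges(summ, rule = "ci")
  expect_equal(sum(g2$adj) / 2, 1)  # CI rule: only pair 1 excludes zero

  bad <- summ; bad$exceed_prob[3] <- 0.99
  expect_error(declare_edges(bad), "invalid")
})

test_that("local fdr is the complement of the accumulated posterior means", {
  me <- matrix(c(0.98, 0.4, 0, 0.6, 0.1, 0), 3, 2)
  mp <- matrix(c(0.59, 0.05, 0), 3, 1)
  fit <- mini_fit(matrix(1L, 5, 1), matrix(2, 5, 1),
                  phenotypes = c("A", "B"), mean_e = me, mean_pair = mp)
  expect_equal(unname(local_fdr(fit, phenotype = "A")), c(0.02, 0.6, 1))
  expect_equal(unname(local_fdr(fit, phenotype = 2)), c(0.4, 0.9, 1))
  expect_equal(unname(local_fdr(fit, pair = c("A", "B"))), c(0.41, 0.95, 1))
  expect_error(local_fdr(fit, phenotype = "Z"), "unknown")
  expect_error(local_fdr(fit), "exactly one")
  # joint association is at most each marginal: pairwise fdr >= marginals
  f_a <- local_fdr(fit, phenotype = "A"); f_b <- local_fdr(fit, phenotype = "B")
  f_ab <- local_fdr(fit, pair = c("A", "B"))
  expect_true(all(f_ab >= pmax(f_a, f_b) - 1e-12))
})

test_that("FDR control calls the largest admissible prefix", {
  ctrl <- control_fdr(c(0.01, 0.05, 0.2), 0.1)
  expect_identical(ctrl$called, c(TRUE, TRUE, TRUE))
  expect_equal(ctrl$kappa, 0.2)
  expect_equal(ctrl$Fdr, mean(c(0.01, 0.05, 0.2)))

  ctrl2 <- control_fdr(c(0.2, 0.3), 0.1)
  expect_identical(ctrl2$called, c(FALSE, FALSE))
  expect_equal(ctrl2$kappa, 0)
  expect_equal(ctrl2$n_called, 0L)

  expect_error(control_fdr(c(0.5, 1.2), 0.1), "0, 1")
  expect_error(control_fdr(c(0.5), 0), "tau")
})

test_that("FDR control agrees with exhaustive prefix search and is monotone", {
  set.seed(61)
  for (rep in 1:25) {
    v <- runif(sample(5:60, 1))^sample(1:3, 1)
    tau <- runif(1, 0.02, 0.5)
    ctrl <- control_fdr(v, tau)
    expect_identical(ctrl$n_called, brute_fdr_prefix(v, tau))
    if (ctrl$n_called > 0) {
      expect_lte(mean(v[ctrl$called]), tau)
      # called set is exactly the n_called smallest values (stable ties)
      expect_identical(sum(ctrl$called), ctrl$n_called)
      expect_lte(max(v[ctrl$called]), min(c(v[!ctrl$called], Inf)) + 1e-12)
    }
    ctrl_hi <- control_fdr(v, min(tau * 2, 0.9))
    expect_true(all(ctrl_hi$called[ctrl$called]))  # nested in tau
  }
})

test_that("diagnostics flag trends and pass white noise", {
  set.seed(71)
  fit_ok <- mini_fit(matrix(1L, 500, 3), matrix(1, 500, 3),
                     logpost = rnorm(500))
  d <- chain_diagnostics(fit_ok)
  expect_lt(abs(d$geweke_z_logpost), 3)
  expect_false(d$flagged)
  expect_identical(d$n_draws, 500L)
  expect_true(all(is.finite(unlist(d$accept_rates))))
  expect_length(d$edge_freq, 3L)

  # a level shift between the start and the end of the trace is flagged
  fit_trend <- mini_fit(matrix(1L, 500, 3), matrix(1, 500, 3),
                        logpost = c(rnorm(250), rnorm(250, 10)))
  expect_true(chain_diagnostics(fit_trend)$flagged)

  fit_short <- mini_fit(matrix(1L, 50, 3), matrix(1, 50, 3),
                        logpost = rnorm(50))
  expect_warning(chain_diagnostics(fit_short), "100")
})
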