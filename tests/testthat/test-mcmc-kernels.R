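make_params <- function(alpha, beta = NULL, adj = NULL) {
  n <- length(alpha)
  if (is.null(beta)) beta <- matrix(0, n, n)
  if (is.null(adj)) adj <- matrix(as.integer(beta != 0), n, n)
  list(alpha = alpha, beta = beta, adj = adj,
       mu = rep(0.2, n), sigma2 = rep(0.3, n))
}

test_that("baseline Metropolis ratio matches hand evaluation", {
  params <- make_params(c(-1.2, 0.4),
                        beta = matrix(c(0, 0.9, 0.9, 0), 2, 2))
  hyp <- hyper_defaults()
  S_i <- 3; T_snps <- 5; prop <- -0.7
  set.seed(1)
  up <- update_alpha(1, params, S_i, T_snps, hyp, proposal = prop)
  expected <- (prop - params$alpha[1]) * S_i -
    T_snps * (enum_logZ(c(prop, 0.4), params$beta) -
                enum_logZ(params$alpha, params$beta)) +
    dnorm(prop, 0, 100, log = TRUE) - dnorm(params$alpha[1], 0, 100, log = TRUE)
  expect_equal(up$log_ratio, expected, tolerance = 1e-10)

  # proposing the current value accepts with probability 1
  up0 <- update_alpha(1, params, S_i, T_snps, hyp,
                      proposal = params$alpha[1])
  expect_equal(up0$log_ratio, 0)
  expect_true(up0$accepted)
})

test_that("coupling Metropolis ratio matches hand evaluation", {
  beta <- matrix(c(0, 1.4, 1.4, 0), 2, 2)
  params <- make_params(c(-0.5, -0.8), beta = beta)
  hyp <- hyper_defaults()
  S_ij <- 2; T_snps <- 4; prop <- 2.2
  set.seed(2)
  up <- update_beta(1, 2, params, S_ij, T_snps, hyp, proposal = prop)
  bprop <- matrix(c(0, prop, prop, 0), 2, 2)
  expected <- (prop - 1.4) * S_ij -
    T_snps * (enum_logZ(params$alpha, bprop) -
                enum_logZ(params$alpha, beta)) +
    dgamma(prop, 4, rate = 2, log = TRUE) -
    dgamma(1.4, 4, rate = 2, log = TRUE) +
    log(prop) - log(1.4)
  expect_equal(up$log_ratio, expected, tolerance = 1e-10)

  up0 <- update_beta(1, 2, params, S_ij, T_snps, hyp, proposal = 1.4)
  expect_equal(up0$log_ratio, 0)
  expect_true(up0$accepted)

  # calling the coupling update on a non-edge is a contract violation
  params0 <- make_params(c(0, 0))
  expect_error(update_beta(1, 2, params0, 0, 0, hyp), "non-edge")
})

test_that("reversible-jump ratios follow the graph prior and reverse exactly", {
  hyp <- hyper_defaults()
  # birth with no data from a 1-edge graph: ratio is the graph prior alone,
  # max(1,1)/max(2,1) = 1/2
  beta <- matrix(0, 3, 3); beta[1, 2] <- beta[2, 1] <- 1.1
  params <- make_params(c(0, 0, 0), beta = beta)
  S0 <- matrix(0, 3, 3)
  set.seed(3)
  up <- rjmcmc_graph_move(params, S0, 0, hyp, pair = c(1, 3),
                          proposal_beta = 0.7)
  expect_equal(up$move, "birth")
  expect_equal(up$log_ratio, log(1 / 2), tolerance = 1e-10)

  # death then re-birth of the same edge with the same coupling cancels
  set.seed(4)
  S <- matrix(0, 3, 3); S[1, 2] <- S[2, 1] <- 7
  d <- rjmcmc_graph_move(params, S, 11, hyp, pair = c(1, 2))
  expect_equal(d$move, "death")
  params2 <- params
  params2$adj[1, 2] <- params2$adj[2, 1] <- 0L
  params2$beta[1, 2] <- params2$beta[2, 1] <- 0
  b <- rjmcmc_graph_move(params2, S, 11, hyp, pair = c(1, 2),
                         proposal_beta = 1.1)
  expect_equal(d$log_ratio + b$log_ratio, 0, tolerance = 1e-10)
})

test_that("with no data the Metropolis kernels sample their priors", {
  # tight priors so a random walk mixes well inside the test budget
  hyp <- hyper_defaults()
  hyp$tau2_alpha <- 1
  params <- make_params(c(0, 0))
  set.seed(6)
  n_iter <- 20000
  a_draws <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    up <- update_alpha(1, params, S_i = 0, T_snps = 0, hyp, prop_sd = 1.5)
    params$alpha <- up$alpha
    a_draws[it] <- params$alpha[1]
  }
  expect_equal(mean(a_draws), 0, tolerance = 0.1)
  expect_equal(sd(a_draws), 1, tolerance = 0.1)

  # coupling kernel at T = 0 leaves the Gamma(4, 2) prior invariant:
  # mean 2, variance 1
  beta <- matrix(0, 2, 2); beta[1, 2] <- beta[2, 1] <- 2
  params <- make_params(c(0, 0), beta = beta)
  hyp <- hyper_defaults()
  b_draws <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    up <- update_beta(1, 2, params, S_ij = 0, T_snps = 0, hyp, prop_sd = 0.8)
    params$beta <- up$beta
    b_draws[it] <- params$beta[1, 2]
  }
  expect_equal(mean(b_draws), 2, tolerance = 0.12)
  expect_equal(var(b_draws), 1, tolerance = 0.2)
})

test_that("signal-parameter Gibbs updates follow the conjugate forms", {
  # with no associated SNPs the update draws from the prior
  hyp <- hyper_defaults()
  hyp$tau2_mu <- 4; hyp$a_sigma <- 3; hyp$b_sigma <- 2
  dat <- sumstats(matrix(c(0.4, 0.6, 0.3, 0.7), 2, 2))
  field0 <- matrix(0L, 2, 2)
  params <- list(sigma2 = c(1, 1))
  set.seed(8)
  draws <- replicate(4000, unlist(update_signal_params(field0, dat, params, hyp)))
  expect_equal(mean(draws["mu1", ]), 0, tolerance = 0.12)
  expect_equal(sd(draws["mu1", ]), 2, tolerance = 0.15)
  # IG(3, 2): mean b/(a-1) = 1
  expect_equal(mean(draws["sigma21", ]), 1, tolerance = 0.1)

  # single observation z = 0 with unit prior and unit variance:
  # full conditional of mu is N(0, 1/2)
  hyp1 <- hyper_defaults(); hyp1$tau2_mu <- 1
  dat1 <- sumstats(matrix(c(pnorm(1, lower.tail = FALSE), 0.6,
                            0.3, 0.7), 2, 2))  # y[1,1] = 1, log y = 0
  field1 <- matrix(c(1L, 0L, 0L, 0L), 2, 2)
  set.seed(9)
  mu_draws <- replicate(4000,
    update_signal_params(field1, dat1, list(sigma2 = c(1, 1)), hyp1)$mu[1])
  expect_equal(mean(mu_draws), 0, tolerance = 0.05)
  expect_equal(var(mu_draws), 0.5, tolerance = 0.05)

  # conjugate limit: many identical observations pin mu at their log
  T_ <- 500
  yv <- rep(exp(0.7), T_)
  pm <- cbind(pnorm(yv, lower.tail = FALSE), runif(T_, 0.4, 0.9))
  datL <- sumstats(pm)
  fieldL <- cbind(rep(1L, T_), rep(0L, T_))
  set.seed(10)
  upL <- update_signal_params(fieldL, datL, list(sigma2 = c(0.01, 1)),
                              hyper_defaults())
  expect_equal(upL$mu[1], 0.7, tolerance = 0.02)
})
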