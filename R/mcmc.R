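#' Default hyperparameters
#'
#' Weakly informative priors: diffuse normals for the signal log-mean and
#' the MRF baselines (`tau2 = 10000`), IG(0.5, 0.5) on the signal log-scale
#' variance (substantial mass on modest variances), and Gamma(4, 2) on the
#' MRF couplings (mean 2, variance 1: couplings on present edges are a
#' priori distinct from zero).
#'
#' @return named list of hyperparameters: `theta_mu`, `tau2_mu`,
#'   `theta_alpha`, `tau2_alpha`, `a_sigma`, `b_sigma`, `a_beta`, `b_beta`.
#' @export
hyper_defaults <- function() {
  list(theta_mu = 0, tau2_mu = 10000, theta_alpha = 0, tau2_alpha = 10000,
       a_sigma = 0.5, b_sigma = 0.5, a_beta = 4, b_beta = 2)
}

check_hyper <- function(h) {
  need <- names(hyper_defaults())
  miss <- setdiff(need, names(h))
  if (length(miss)) stop("missing hyperparameters: ", paste(miss, collapse = ", "))
  sc <- c("tau2_mu", "tau2_alpha", "a_sigma", "b_sigma", "a_beta", "b_beta")
  if (any(unlist(h[sc]) <= 0)) stop("scale hyperparameters must be positive")
  h
}

rinvgamma <- function(n, shape, rate) 1 / stats::rgamma(n, shape = shape, rate = rate)

#' One Gibbs pass over the latent association field
#'
#' Redraws every indicator `e_it` from its Bernoulli full conditional
#' (see [conditional_assoc_prob()]) in a systematic scan over phenotypes,
#' independently across SNPs. Entries with `y <= 0` are forced to 0.
#'
#' @param field T x n binary matrix of association indicators.
#' @param data a [sumstats] object.
#' @param params list with `alpha`, `beta` (n x n, zero off the graph),
#'   `mu`, `sigma2`.
#' @param nsweep number of full sweeps (default 1).
#' @param method `"sitewise"` (default) redraws one indicator at a time in a
#'   systematic scan; `"block"` redraws each SNP's full n-vector from its
#'   exact conditional over all 2^n joint states. Both leave the same
#'   conditional law invariant; the block kernel crosses strongly coupled
#'   configurations faster.
#' @return updated T x n integer matrix.
#' @export
gibbs_update_efield <- function(field, data, params, nsweep = 1L,
                                method = c("sitewise", "block")) {
  method <- match.arg(method)
  stopifnot(all(dim(field) == dim(data$y)))
  eT <- t(matrix(as.integer(field), nrow(field), ncol(field)))
  lyT <- t(ifelse(data$y > 0, log(pmax(data$y, 1e-300)), -Inf))
  hy2T <- t(data$y^2 / 2)
  if (method == "block") {
    ss <- state_space(length(params$alpha))
    statesI <- ss$states; storage.mode(statesI) <- "integer"
    en <- as.vector(ss$states %*% params$alpha)
    if (nrow(ss$pairs))
      en <- en + as.vector(ss$pairprod %*% params$beta[ss$pairs])
    for (k in seq_len(nsweep))
      .block_sweep_cpp(eT, lyT, hy2T, params$mu, params$sigma2, statesI, en,
                       0L, 1L)
  } else {
    .mcmc_sweep_cpp(eT, lyT, hy2T, params$alpha, params$beta,
                    params$mu, params$sigma2, as.integer(nsweep),
                    matrix(0, 1, 1), matrix(0, 1, 1),
                    matrix(0L, 0, 2), FALSE)
  }
  t(eT)
}

#' Gibbs update of the signal-component parameters
#'
#' Conjugate update per phenotype: with `z = log y` over the currently
#' associated SNPs (m of them), `mu_i` is drawn from the precision-weighted
#' normal full conditional and `sigma2_i` from
#' IG(a + m/2, b + sum((z - mu_i)^2)/2). When no SNP is associated both are
#' drawn from their priors.
#'
#' @param field T x n binary indicator matrix (associated entries must have
#'   positive scores).
#' @param data a [sumstats] object.
#' @param params current parameter list (uses `sigma2`).
#' @param hyper hyperparameter list, see [hyper_defaults()].
#' @return list with updated `mu` and `sigma2` vectors.
#' @export
update_signal_params <- function(field, data, params, hyper = hyper_defaults()) {
  n <- ncol(data$y)
  m <- numeric(n); Slz <- numeric(n); Slz2 <- numeric(n)
  for (i in seq_len(n)) {
    sel <- field[, i] == 1 & data$y[, i] > 0
    z <- log(data$y[sel, i])
    m[i] <- length(z); Slz[i] <- sum(z); Slz2[i] <- sum(z^2)
  }
  draw_signal_params(m, Slz, Slz2, params$sigma2, hyper)
}

# conjugate draws from the sufficient statistics (m, sum log y,
# sum (log y)^2) over the associated entries of each phenotype
draw_signal_params <- function(m, Slz, Slz2, sigma2_cur, hyper) {
  n <- length(m)
  mu <- numeric(n); sigma2 <- numeric(n)
  for (i in seq_len(n)) {
    if (m[i] == 0) {
      mu[i] <- stats::rnorm(1, hyper$theta_mu, sqrt(hyper$tau2_mu))
      sigma2[i] <- rinvgamma(1, hyper$a_sigma, hyper$b_sigma)
    } else {
      s2 <- sigma2_cur[i]
      prec <- 1 / hyper$tau2_mu + m[i] / s2
      mean_post <- (hyper$theta_mu / hyper$tau2_mu + Slz[i] / s2) / prec
      mu[i] <- stats::rnorm(1, mean_post, sqrt(1 / prec))
      ssq <- max(Slz2[i] - 2 * mu[i] * Slz[i] + m[i] * mu[i]^2, 0)
      sigma2[i] <- rinvgamma(1, hyper$a_sigma + m[i] / 2,
                             hyper$b_sigma + 0.5 * ssq)
    }
  }
  list(mu = mu, sigma2 = sigma2)
}

#' Metropolis update of one MRF baseline propensity
#'
#' Gaussian random-walk proposal for `alpha_i`. The log acceptance ratio is
#' `(alpha' - alpha_i) * S_i - T * (logZ' - logZ)` plus the normal prior
#' log-ratio, where `S_i` is the current association count and `logZ` the
#' exact MRF log-normalizer.
#'
#' @param i phenotype index.
#' @param params list with `alpha`, `beta`, `adj`.
#' @param S_i current sufficient statistic `sum_t e_it`.
#' @param T_snps number of SNPs.
#' @param hyper hyperparameters.
#' @param prop_sd random-walk standard deviation.
#' @param logZ current log-normalizer (recomputed when `NULL`).
#' @param proposal optional fixed proposal value (for testing).
#' @return list: updated `alpha` vector, `logZ`, `accepted`, `log_ratio`.
#' @export
update_alpha <- function(i, params, S_i, T_snps, hyper = hyper_defaults(),
                         prop_sd = 0.1, logZ = NULL, proposal = NULL) {
  alpha <- params$alpha
  if (is.null(logZ)) logZ <- mrf_log_normalizer(alpha, params$beta, params$adj)
  a_new <- if (is.null(proposal)) alpha[i] + stats::rnorm(1, 0, prop_sd) else proposal
  alpha_prop <- alpha; alpha_prop[i] <- a_new
  logZ_prop <- mrf_log_normalizer(alpha_prop, params$beta, params$adj)
  log_ratio <- (a_new - alpha[i]) * S_i - T_snps * (logZ_prop - logZ) +
    stats::dnorm(a_new, hyper$theta_alpha, sqrt(hyper$tau2_alpha), log = TRUE) -
    stats::dnorm(alpha[i], hyper$theta_alpha, sqrt(hyper$tau2_alpha), log = TRUE)
  accepted <- log(stats::runif(1)) < log_ratio
  if (accepted) { alpha <- alpha_prop; logZ <- logZ_prop }
  list(alpha = alpha, logZ = logZ, accepted = accepted, log_ratio = log_ratio)
}

#' Metropolis update of one MRF coupling
#'
#' Positivity-respecting random walk on the log scale for the coupling of a
#' present edge (i, j). The log acceptance ratio combines the likelihood
#' term `(beta' - beta) * S_ij - T * (logZ' - logZ)`, the Gamma prior
#' log-ratio, and the log-scale proposal Jacobian `log(beta'/beta)`.
#'
#' @param i,j edge endpoints; the edge must be present in `params$adj`.
#' @param params list with `alpha`, `beta`, `adj`.
#' @param S_ij current pair count `sum_t e_it e_jt`.
#' @inheritParams update_alpha
#' @return list: updated `beta` matrix, `logZ`, `accepted`, `log_ratio`.
#' @export
update_beta <- function(i, j, params, S_ij, T_snps, hyper = hyper_defaults(),
                        prop_sd = 0.2, logZ = NULL, proposal = NULL) {
  if (params$adj[i, j] != 1L)
    stop("internal contract violation: coupling update on a non-edge (",
         i, ", ", j, ")")
  beta <- params$beta
  b_old <- beta[i, j]
  if (is.null(logZ)) logZ <- mrf_log_normalizer(params$alpha, beta, params$adj)
  b_new <- if (is.null(proposal)) b_old * exp(stats::rnorm(1, 0, prop_sd)) else proposal
  beta_prop <- beta; beta_prop[i, j] <- b_new; beta_prop[j, i] <- b_new
  logZ_prop <- mrf_log_normalizer(params$alpha, beta_prop, params$adj)
  log_ratio <- (b_new - b_old) * S_ij - T_snps * (logZ_prop - logZ) +
    (hyper$a_beta - 1) * (log(b_new) - log(b_old)) -
    hyper$b_beta * (b_new - b_old) +
    (log(b_new) - log(b_old))  # Jacobian of the log-scale walk
  accepted <- log(stats::runif(1)) < log_ratio
  if (accepted) { beta <- beta_prop; logZ <- logZ_prop }
  list(beta = beta, logZ = logZ, accepted = accepted, log_ratio = log_ratio)
}

#' Reversible-jump move on the phenotype graph
#'
#' Picks one unordered phenotype pair uniformly. If the edge is absent, a
#' birth is proposed with the coupling drawn from its Gamma prior (proposal
#' and prior densities cancel), so the log acceptance ratio is
#' `beta* x S_ij - T x (logZ' - logZ) + log p(G')/p(G)`; if present, a death
#' with the reciprocal ratio. The graph prior is `p(G) proportional to
#' 1/max(|E|, 1)` — the sparsity-favoring `1/|E|` form, regularized so the
#' empty graph remains reachable.
#'
#' @param params list with `alpha`, `beta`, `adj`.
#' @param S_pair n x n matrix of pair counts (see [sufficient_stats()]).
#' @param T_snps number of SNPs.
#' @param hyper hyperparameters.
#' @param logZ current log-normalizer (recomputed when `NULL`).
#' @param pair optional fixed pair `c(i, j)` (for testing).
#' @param proposal_beta optional fixed birth coupling (for testing).
#' @return list: updated `adj`, `beta`, `logZ`, `accepted`, `log_ratio`,
#'   `pair`, `move` ("birth" or "death").
#' @export
rjmcmc_graph_move <- function(params, S_pair, T_snps, hyper = hyper_defaults(),
                              logZ = NULL, pair = NULL, proposal_beta = NULL) {
  n <- length(params$alpha)
  pairs <- pair_index(n)
  if (nrow(pairs) == 0L) stop("graph moves need at least 2 phenotypes")
  if (is.null(pair)) {
    k <- sample.int(nrow(pairs), 1L)
    pair <- pairs[k, ]
  }
  i <- pair[1L]; j <- pair[2L]
  adj <- params$adj; beta <- params$beta
  if (is.null(logZ)) logZ <- mrf_log_normalizer(params$alpha, beta, adj)
  n_edges <- sum(adj) / 2
  if (adj[i, j] == 0L) {
    move <- "birth"
    b_star <- if (is.null(proposal_beta))
      stats::rgamma(1, hyper$a_beta, rate = hyper$b_beta) else proposal_beta
    adj_prop <- adj; adj_prop[i, j] <- 1L; adj_prop[j, i] <- 1L
    beta_prop <- beta; beta_prop[i, j] <- b_star; beta_prop[j, i] <- b_star
    logZ_prop <- mrf_log_normalizer(params$alpha, beta_prop, adj_prop)
    log_ratio <- b_star * S_pair[i, j] - T_snps * (logZ_prop - logZ) +
      log(max(n_edges, 1)) - log(max(n_edges + 1, 1))
  } else {
    move <- "death"
    adj_prop <- adj; adj_prop[i, j] <- 0L; adj_prop[j, i] <- 0L
    beta_prop <- beta; beta_prop[i, j] <- 0; beta_prop[j, i] <- 0
    logZ_prop <- mrf_log_normalizer(params$alpha, beta_prop, adj_prop)
    log_ratio <- -beta[i, j] * S_pair[i, j] - T_snps * (logZ_prop - logZ) +
      log(max(n_edges, 1)) - log(max(n_edges - 1, 1))
  }
  accepted <- log(stats::runif(1)) < log_ratio
  if (accepted) { adj <- adj_prop; beta <- beta_prop; logZ <- logZ_prop }
  list(adj = adj, beta = beta, logZ = logZ, accepted = accepted,
       log_ratio = log_ratio, pair = c(i, j), move = move)
}

# Data-driven starting state: liberal p-value cut seeds the field, moments of
# log y over the seeded set start the signal parameters, logit of the seeded
# fraction (clamped) starts the baselines; the graph starts empty.
init_state <- function(data, init_pval = 0.01) {
  y <- data$y; p <- data$p
  T_ <- nrow(y); n <- ncol(y)
  e <- matrix(0L, T_, n)
  e[p < init_pval & y > 0] <- 1L
  mu <- numeric(n); sigma2 <- numeric(n); alpha <- numeric(n)
  for (i in seq_len(n)) {
    sel <- e[, i] == 1L
    if (sum(sel) >= 5L) {
      z <- log(y[sel, i])
      mu[i] <- min(max(mean(z), 0), 2)
      sigma2[i] <- max(stats::var(z), 0.1)
    } else {
      mu[i] <- 0; sigma2[i] <- 1
    }
    frac <- mean(e[, i])
    alpha[i] <- min(max(stats::qlogis(max(frac, 1 / T_)), -10), -1)
  }
  list(e = e, alpha = alpha, mu = mu, sigma2 = sigma2,
       adj = matrix(0L, n, n), beta = matrix(0, n, n))
}

log_posterior <- function(S, S_pair, llr_active, null_const, params, hyper,
                          logZ, T_snps) {
  pairs <- graph_edges(params$adj)
  ll_mrf <- sum(params$alpha * S) - T_snps * logZ
  lp_beta <- 0
  if (nrow(pairs)) {
    bvals <- params$beta[pairs]
    ll_mrf <- ll_mrf + sum(bvals * S_pair[pairs])
    lp_beta <- sum(stats::dgamma(bvals, hyper$a_beta, rate = hyper$b_beta,
                                 log = TRUE))
  }
  lp <- null_const + llr_active + ll_mrf +
    sum(stats::dnorm(params$mu, hyper$theta_mu, sqrt(hyper$tau2_mu), log = TRUE)) +
    sum(stats::dnorm(params$alpha, hyper$theta_alpha, sqrt(hyper$tau2_alpha),
                     log = TRUE)) +
    sum(hyper$a_sigma * log(hyper$b_sigma) - lgamma(hyper$a_sigma) -
          (hyper$a_sigma + 1) * log(params$sigma2) -
          hyper$b_sigma / params$sigma2) +
    lp_beta - log(max(nrow(pairs), 1))
  lp
}

#' Fit the hidden-MRF model by MCMC
#'
#' Metropolis-Hastings-within-Gibbs sampler. Each sweep performs (in order):
#' a systematic-scan Gibbs pass over the latent T x n association field,
#' conjugate Gibbs updates of the signal parameters (`mu`, `sigma2`),
#' random-walk Metropolis updates of every baseline `alpha_i` and of the
#' coupling on every present edge, and (unless `independent = TRUE`)
#' reversible-jump birth/death proposals on the phenotype graph. After
#' burn-in, thinned parameter draws are stored and posterior means of
#' `e_it` and of the pairwise products `e_it e_jt` are accumulated over all
#' main iterations.
#'
#' `independent = TRUE` fixes the empty graph (all couplings at zero) and
#' skips coupling/graph moves; this is the no-interaction baseline,
#' equivalent to separate per-phenotype two-group analyses.
#'
#' @param data a [sumstats] object.
#' @param n_burnin,n_main burn-in and main iteration counts (defaults
#'   10000 and 40000).
#' @param thin store every `thin`-th main draw (default 1).
#' @param seed integer seed; the full archive is reproducible bitwise from
#'   (data, configuration, seed).
#' @param independent fit the no-interaction baseline instead.
#' @param hyper hyperparameters, see [hyper_defaults()].
#' @param prop_sd_alpha,prop_sd_beta random-walk proposal scales (the
#'   coupling walk is on the log scale).
#' @param graph_moves_per_iter reversible-jump proposals per sweep; the
#'   default `NULL` uses `n(n-1)/2`, one expected proposal per phenotype
#'   pair per sweep.
#' @param block_stride refresh 1/`block_stride` of the SNPs per sweep with a
#'   per-SNP block update of the field (exact 2^n-state conditional), cycling
#'   through strata so every SNP is block-refreshed once per `block_stride`
#'   sweeps; 0 disables. The block kernel decorrelates the field from the
#'   current graph, which speeds mixing of the edge indicators and of the
#'   baseline/coupling ridge.
#' @param store_field also store the thinned field draws (memory-heavy;
#'   for small problems only).
#' @param init_pval p-value cut seeding the initial field.
#' @param cap maximum number of phenotypes (exact normalizer enumeration).
#' @param verbose print progress every 1000 sweeps.
#' @return object of class `hmrf_fit`; see [summarize_edges()],
#'   [local_fdr()], [chain_diagnostics()].
#' @export
fit_hmrf <- function(data, n_burnin = 10000, n_main = 40000, thin = 1,
                     seed = 1, independent = FALSE,
                     hyper = hyper_defaults(),
                     prop_sd_alpha = 0.1, prop_sd_beta = 0.2,
                     graph_moves_per_iter = NULL, block_stride = 3L,
                     store_field = FALSE,
                     init_pval = 0.01, cap = 20L, verbose = FALSE) {
  stopifnot(inherits(data, "sumstats"))
  hyper <- check_hyper(hyper)
  stopifnot(n_burnin >= 0, n_main >= 1, thin >= 1, prop_sd_alpha > 0,
            prop_sd_beta > 0, block_stride >= 0)
  T_ <- nrow(data$y); n <- ncol(data$y)
  ss <- state_space(n, cap = cap)  # errors early above the enumeration cap
  statesI <- ss$states; storage.mode(statesI) <- "integer"
  if (is.null(graph_moves_per_iter)) graph_moves_per_iter <- n * (n - 1) / 2
  set.seed(as.integer(seed))

  st <- init_state(data, init_pval = init_pval)
  e <- st$e
  params <- list(alpha = st$alpha, beta = st$beta, adj = st$adj,
                 mu = st$mu, sigma2 = st$sigma2)
  logZ <- mrf_log_normalizer(params$alpha, params$beta, params$adj)
  null_const <- sum(stats::dnorm(data$y, log = TRUE))

  pairs <- pair_index(n)
  P <- nrow(pairs)
  n_store <- n_main %/% thin
  draws <- list(alpha = matrix(NA_real_, n_store, n),
                mu = matrix(NA_real_, n_store, n),
                sigma2 = matrix(NA_real_, n_store, n),
                beta = matrix(NA_real_, n_store, P),
                edge = matrix(0L, n_store, P),
                logpost = numeric(n_store))
  colnames(draws$alpha) <- colnames(draws$mu) <- colnames(draws$sigma2) <-
    data$phenotypes
  pair_names <- paste(data$phenotypes[pairs[, 1L]],
                      data$phenotypes[pairs[, 2L]], sep = "__")
  colnames(draws$beta) <- colnames(draws$edge) <- pair_names
  field_draws <- if (store_field) vector("list", n_store) else NULL

  # transposed working copies: one column per SNP (contiguous hot-loop access)
  eT <- t(e)
  lyT <- t(ifelse(data$y > 0, log(pmax(data$y, 1e-300)), -Inf))
  hy2T <- t(data$y^2 / 2)
  accET <- matrix(0, n, T_)
  accPT <- matrix(0, max(P, 1L), T_)
  pairs0 <- matrix(as.integer(pairs - 1L), ncol = 2L)
  acc <- c(alpha_prop = 0, alpha_acc = 0, beta_prop = 0, beta_acc = 0,
           graph_prop = 0, graph_acc = 0)

  n_iter <- n_burnin + n_main
  stored <- 0L
  for (it in seq_len(n_iter)) {
    if (block_stride > 0L) {
      en <- as.vector(ss$states %*% params$alpha)
      if (P > 0L) en <- en + as.vector(ss$pairprod %*% params$beta[pairs])
      .block_sweep_cpp(eT, lyT, hy2T, params$mu, params$sigma2, statesI, en,
                       as.integer(it %% block_stride), as.integer(block_stride))
    }
    sw <- .mcmc_sweep_cpp(eT, lyT, hy2T, params$alpha, params$beta,
                          params$mu, params$sigma2, 1L,
                          accET, accPT, pairs0, it > n_burnin)
    S <- sw$S; S_pair <- sw$S_pair

    sig <- draw_signal_params(sw$S, sw$Slz, sw$Slz2, params$sigma2, hyper)
    params$mu <- sig$mu; params$sigma2 <- sig$sigma2

    for (i in seq_len(n)) {
      up <- update_alpha(i, params, S[i], T_, hyper, prop_sd_alpha, logZ)
      params$alpha <- up$alpha; logZ <- up$logZ
      acc["alpha_prop"] <- acc["alpha_prop"] + 1
      acc["alpha_acc"] <- acc["alpha_acc"] + up$accepted
    }

    if (!independent) {
      ed <- graph_edges(params$adj)
      for (k in seq_len(nrow(ed))) {
        up <- update_beta(ed[k, 1L], ed[k, 2L], params,
                          S_pair[ed[k, 1L], ed[k, 2L]], T_, hyper,
                          prop_sd_beta, logZ)
        params$beta <- up$beta; logZ <- up$logZ
        acc["beta_prop"] <- acc["beta_prop"] + 1
        acc["beta_acc"] <- acc["beta_acc"] + up$accepted
      }
      for (g in seq_len(graph_moves_per_iter)) {
        up <- rjmcmc_graph_move(params, S_pair, T_, hyper, logZ)
        params$adj <- up$adj; params$beta <- up$beta; logZ <- up$logZ
        acc["graph_prop"] <- acc["graph_prop"] + 1
        acc["graph_acc"] <- acc["graph_acc"] + up$accepted
      }
    }

    if (it > n_burnin) {
      if ((it - n_burnin) %% thin == 0L) {
        stored <- stored + 1L
        draws$alpha[stored, ] <- params$alpha
        draws$mu[stored, ] <- params$mu
        draws$sigma2[stored, ] <- params$sigma2
        draws$beta[stored, ] <- params$beta[pairs]
        draws$edge[stored, ] <- params$adj[pairs]
        draws$logpost[stored] <- log_posterior(S, S_pair, sw$llr_active,
                                               null_const, params, hyper,
                                               logZ, T_)
        if (store_field) field_draws[[stored]] <- t(eT)
      }
    }
    if (!is.finite(logZ))
      stop("non-finite MRF log-normalizer at iteration ", it,
           "; alpha = ", paste(signif(params$alpha, 4), collapse = ", "))
    if (verbose && it %% 1000L == 0L)
      message(sprintf("iter %d/%d  edges=%d  acc(alpha)=%.2f acc(beta)=%.2f acc(graph)=%.3f",
                      it, n_iter, sum(params$adj) / 2,
                      acc["alpha_acc"] / max(acc["alpha_prop"], 1),
                      acc["beta_acc"] / max(acc["beta_prop"], 1),
                      acc["graph_acc"] / max(acc["graph_prop"], 1)))
  }

  mean_e <- t(accET) / n_main
  dimnames(mean_e) <- list(data$snp_ids, data$phenotypes)
  mean_pair <- t(accPT[seq_len(P), , drop = FALSE]) / n_main
  dimnames(mean_pair) <- list(data$snp_ids, pair_names)
  fit <- list(phenotypes = data$phenotypes, snp_ids = data$snp_ids,
              pairs = pairs, pair_names = pair_names, draws = draws,
              mean_e = mean_e, mean_pair = mean_pair,
              accept = list(
                alpha = unname(acc["alpha_acc"] / max(acc["alpha_prop"], 1)),
                beta = unname(acc["beta_acc"] / max(acc["beta_prop"], 1)),
                graph = unname(acc["graph_acc"] / max(acc["graph_prop"], 1))),
              config = list(n_burnin = n_burnin, n_main = n_main, thin = thin,
                            seed = seed, independent = independent,
                            prop_sd_alpha = prop_sd_alpha,
                            prop_sd_beta = prop_sd_beta,
                            graph_moves_per_iter = graph_moves_per_iter,
                            block_stride = block_stride,
                            init_pval = init_pval),
              hyper = hyper, independent = independent,
              field_draws = field_draws)
  class(fit) <- "hmrf_fit"
  fit
}

#' @export
print.hmrf_fit <- function(x, ...) {
  cat(sprintf("hmrf_fit: %d phenotypes, %d SNPs, %d stored draws%s\n",
              length(x$phenotypes), length(x$snp_ids),
              nrow(x$draws$alpha),
              if (x$independent) " (independence baseline)" else ""))
  cat(sprintf("  acceptance: alpha %.2f, beta %.2f, graph %.3f\n",
              x$accept$alpha, x$accept$beta, x$accept$graph))
  invisible(x)
}
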