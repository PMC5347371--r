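# Independent brute-force oracles used across tests. These deliberately
# avoid the package's own code paths (plain loops, expand.grid, direct
# density formulas).

# log of the MRF normalizing sum by direct enumeration
enum_logZ <- function(alpha, beta = NULL) {
  n <- length(alpha)
  states <- unname(as.matrix(expand.grid(rep(list(0:1), n))))
  tot <- 0
  for (r in seq_len(nrow(states))) {
    s <- states[r, ]
    en <- sum(alpha * s)
    if (!is.null(beta))
      for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n))
        en <- en + beta[i, j] * s[i] * s[j]
    tot <- tot + exp(en)
  }
  log(tot)
}

# unnormalized MRF log-weight of one configuration
enum_logweight <- function(e, alpha, beta = NULL) {
  n <- length(alpha)
  e <- unname(e)
  en <- sum(alpha * e)
  if (!is.null(beta))
    for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n))
      en <- en + beta[i, j] * e[i] * e[j]
  en
}

# exact per-SNP posterior over the 2^n joint association states given scores
enum_field_posterior <- function(y_t, alpha, beta, mu, sigma2) {
  n <- length(alpha)
  states <- unname(as.matrix(expand.grid(rep(list(0:1), n))))
  lw <- numeric(nrow(states))
  for (r in seq_len(nrow(states))) {
    s <- states[r, ]
    lw[r] <- enum_logweight(s, alpha, beta)
    for (i in seq_len(n)) {
      if (s[i] == 1) {
        lw[r] <- lw[r] + if (y_t[i] > 0)
          dlnorm(y_t[i], mu[i], sqrt(sigma2[i]), log = TRUE) else -Inf
      } else {
        lw[r] <- lw[r] + dnorm(y_t[i], log = TRUE)
      }
    }
  }
  w <- exp(lw - max(lw[is.finite(lw)]))
  w[!is.finite(w)] <- 0
  list(states = states, prob = w / sum(w))
}

# direct-posterior-probability FDR control by exhaustive prefix search:
# the largest k such that the mean of the k smallest values is <= tau
brute_fdr_prefix <- function(values, tau) {
  sorted <- sort(values)
  best <- 0L
  for (k in seq_along(sorted))
    if (mean(sorted[seq_len(k)]) <= tau) best <- k
  best
}

# interpolation quantile (type 7) written out directly
oracle_quantile <- function(x, p) {
  x <- sort(x); n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# rank-based AUC (Wilcoxon statistic)
rank_auc <- function(score, label) {
  r <- rank(score)
  n1 <- sum(label == 1); n0 <- sum(label == 0)
  (sum(r[label == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
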