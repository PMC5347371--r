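#' Construct a phenotype graph
#'
#' A symmetric binary adjacency over the n phenotypes: an edge between
#' phenotypes i and j states that they are genetically correlated in the
#' sense of conditional dependence of their latent association indicators.
#'
#' @param n number of phenotypes.
#' @param edges optional 2-column matrix (or data frame) of phenotype index
#'   pairs; `NULL` gives the empty graph.
#' @return object of class `phenotype_graph`: list with `n` and the n x n
#'   0/1 adjacency `adj`.
#' @export
phenotype_graph <- function(n, edges = NULL) {
  stopifnot(n >= 1)
  adj <- matrix(0L, n, n)
  if (!is.null(edges)) {
    edges <- as.matrix(edges)
    if (ncol(edges) != 2L) stop("edges must have 2 columns")
    for (k in seq_len(nrow(edges))) {
      i <- edges[k, 1L]; j <- edges[k, 2L]
      if (i == j || i < 1 || j < 1 || i > n || j > n)
        stop("invalid edge: (", i, ", ", j, ")")
      adj[i, j] <- 1L; adj[j, i] <- 1L
    }
  }
  structure(list(n = as.integer(n), adj = adj), class = "phenotype_graph")
}

#' @export
print.phenotype_graph <- function(x, ...) {
  e <- graph_edges(x$adj)
  cat(sprintf("phenotype_graph: %d phenotypes, %d edge(s)\n", x$n, nrow(e)))
  if (nrow(e)) cat(paste0("  ", e[, 1L], " -- ", e[, 2L], collapse = "\n"), "\n")
  invisible(x)
}

# upper-triangle edge list of an adjacency matrix (i < j)
graph_edges <- function(adj) {
  idx <- which(upper.tri(adj) & adj != 0, arr.ind = TRUE)
  idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
}

# all unordered pairs (i < j), fixed column-major order used throughout
pair_index <- function(n) {
  if (n < 2L) return(matrix(integer(0), 0L, 2L))
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  colnames(idx) <- c("i", "j")
  idx
}

#' Emission log-density of a probit score
#'
#' Two-group emission model: given the latent association indicator `e`, the
#' probit score is standard normal under the null (`e = 0`) and log-normal
#' with log-scale parameters (`mu`, `sigma2`) under association (`e = 1`).
#' The log-normal support is the positive reals, so a score `y <= 0` has
#' `-Inf` signal log-density: SNPs with p-values above 0.5 cannot be
#' attributed to the signal component.
#'
#' @param y numeric vector of probit scores.
#' @param e association indicator(s), 0 or 1 (recycled against `y`).
#' @param mu log-scale mean of the signal component.
#' @param sigma2 log-scale variance of the signal component (> 0).
#' @return log-density values.
#' @export
emission_logdensity <- function(y, e, mu, sigma2) {
  if (any(sigma2 <= 0)) stop("sigma2 must be strictly positive")
  if (!all(e %in% c(0, 1))) stop("e must be binary")
  len <- max(length(y), length(e), length(mu), length(sigma2))
  shape <- if (length(y) == len) attributes(y) else NULL
  yv <- rep_len(as.vector(y), len)
  ev <- rep_len(as.vector(e), len)
  out <- stats::dnorm(yv, log = TRUE)
  sig <- ev == 1
  if (any(sig)) {
    muv <- rep_len(mu, len); sdv <- rep_len(sqrt(sigma2), len)
    out[sig] <- ifelse(yv[sig] > 0,
                       stats::dlnorm(pmax(yv[sig], .Machine$double.xmin),
                                     meanlog = muv[sig], sdlog = sdv[sig],
                                     log = TRUE),
                       -Inf)
  }
  attributes(out) <- shape
  out
}

#' Mean of the signal-score distribution
#'
#' The log-normal signal component has mean `exp(mu + sigma2/2)` on the
#' score scale; this is the natural scale on which to read the strength of
#' association signals (a typical value for genuine GWAS signals is around
#' 1-2).
#'
#' @param mu log-scale mean.
#' @param sigma2 log-scale variance (>= 0).
#' @return `exp(mu + sigma2/2)`.
#' @export
signal_mean <- function(mu, sigma2) {
  if (any(sigma2 < 0)) stop("sigma2 must be nonnegative")
  exp(mu + sigma2 / 2)
}

#' Standard deviation of the signal-score distribution
#'
#' @inheritParams signal_mean
#' @return `exp(mu + sigma2/2) * sqrt(exp(sigma2) - 1)`.
#' @export
signal_sd <- function(mu, sigma2) {
  if (any(sigma2 < 0)) stop("sigma2 must be nonnegative")
  signal_mean(mu, sigma2) * sqrt(exp(sigma2) - 1)
}

# cache of binary state enumerations, keyed by n
.state_cache <- new.env(parent = emptyenv())

# 2^n x n matrix of all binary configurations, plus the 2^n x choose(n,2)
# matrix of pairwise products (columns in pair_index order)
state_space <- function(n, cap = 20L) {
  if (n > cap)
    stop("exact MRF normalizer enumerates 2^n configurations; n = ", n,
         " exceeds the cap of ", cap,
         " phenotypes - analyze fewer phenotypes at a time")
  key <- as.character(n)
  if (!is.null(.state_cache[[key]])) return(.state_cache[[key]])
  states <- as.matrix(expand.grid(rep(list(0:1), n))[, n:1, drop = FALSE])
  dimnames(states) <- NULL
  storage.mode(states) <- "double"
  pairs <- pair_index(n)
  pp <- matrix(0, nrow(states), nrow(pairs))
  for (k in seq_len(nrow(pairs)))
    pp[, k] <- states[, pairs[k, 1L]] * states[, pairs[k, 2L]]
  out <- list(states = states, pairprod = pp, pairs = pairs)
  .state_cache[[key]] <- out
  out
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Log normalizing constant of the auto-logistic MRF
#'
#' The auto-logistic model assigns each binary configuration e* the weight
#' `exp(sum_i alpha_i e*_i + sum_{i~j} beta_ij e*_i e*_j)`; this returns the
#' log of the sum of weights over all 2^n configurations, computed by exact
#' enumeration (feasible for moderate n; e.g. n = 12 enumerates 4,096
#' states).
#'
#' @param alpha length-n vector of baseline propensities.
#' @param beta n x n symmetric coupling matrix; entries off the graph must
#'   be zero (the adjacency is implied by the nonzero pattern unless `adj`
#'   is given).
#' @param adj optional n x n 0/1 adjacency restricting which couplings
#'   enter.
#' @param cap maximum n for enumeration (default 20).
#' @return the log normalizer (a scalar); the model's normalizing constant
#'   is `exp(-mrf_log_normalizer(...))`.
#' @export
mrf_log_normalizer <- function(alpha, beta = NULL, adj = NULL, cap = 20L) {
  n <- length(alpha)
  ss <- state_space(n, cap = cap)
  energy <- as.vector(ss$states %*% alpha)
  if (!is.null(beta) && nrow(ss$pairs)) {
    bvec <- beta[ss$pairs]
    if (!is.null(adj)) bvec <- bvec * adj[ss$pairs]
    if (any(bvec != 0)) energy <- energy + as.vector(ss$pairprod %*% bvec)
  }
  logsumexp(energy)
}

#' Log probability of a joint association configuration
#'
#' Auto-logistic MRF probability of one n-vector of association indicators:
#' `sum_i alpha_i e_i + sum_{i~j} beta_ij e_i e_j - mrf_log_normalizer(...)`.
#'
#' @param e_vec binary vector of length n.
#' @inheritParams mrf_log_normalizer
#' @return log probability.
#' @export
mrf_logprob <- function(e_vec, alpha, beta = NULL, adj = NULL, cap = 20L) {
  n <- length(alpha)
  if (length(e_vec) != n) stop("e_vec and alpha dimension mismatch")
  if (!all(e_vec %in% c(0, 1))) stop("e_vec must be binary")
  en <- sum(alpha * e_vec)
  if (!is.null(beta)) {
    b <- beta
    if (!is.null(adj)) b <- b * adj
    en <- en + 0.5 * as.numeric(t(e_vec) %*% b %*% e_vec)
  }
  en - mrf_log_normalizer(alpha, beta, adj, cap = cap)
}

#' Full-conditional association probability for one phenotype at one SNP
#'
#' Combining the MRF conditional with the emission likelihood ratio, the
#' probability that phenotype `i` is associated at a SNP given the other
#' phenotypes' indicators is logistic in
#' `alpha_i + sum_{j~i} beta_ij e_j + log LR(y)`, where `log LR` is the
#' signal-vs-null emission log-likelihood ratio. Scores `y <= 0` give
#' probability exactly 0 (the signal component has no support there).
#'
#' @param i phenotype index.
#' @param y_it probit score of the SNP for phenotype `i`.
#' @param e_others binary vector of length n with the current indicators of
#'   the other phenotypes (entry `i` is ignored).
#' @param alpha,beta MRF parameters (see [mrf_log_normalizer()]).
#' @param mu,sigma2 signal-component parameters for phenotype `i`.
#' @return probability in [0, 1].
#' @export
conditional_assoc_prob <- function(i, y_it, e_others, alpha, beta, mu, sigma2) {
  n <- length(alpha)
  stopifnot(i >= 1, i <= n, length(e_others) == n)
  if (y_it <= 0) return(0)
  llr <- emission_logdensity(y_it, 1, mu, sigma2) -
    emission_logdensity(y_it, 0, mu, sigma2)
  eo <- e_others; eo[i] <- 0
  eta <- alpha[i] + sum(beta[i, ] * eo) + llr
  stats::plogis(eta)
}

#' Sufficient statistics of a latent association field
#'
#' Per-phenotype counts `S_i = sum_t e_it` and all pairwise co-association
#' counts `S_ij = sum_t e_it e_jt` (computed for every unordered pair, not
#' only current graph edges, so they can serve birth proposals in the
#' reversible-jump move).
#'
#' @param e T x n binary matrix of association indicators.
#' @return list with `S` (length n) and `S_pair` (n x n symmetric matrix of
#'   pair counts, zero diagonal).
#' @export
sufficient_stats <- function(e) {
  e <- as.matrix(e)
  storage.mode(e) <- "double"
  S_pair <- crossprod(e)
  S <- diag(S_pair)
  diag(S_pair) <- 0
  list(S = S, S_pair = S_pair)
}
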