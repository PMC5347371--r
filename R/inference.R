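#' Posterior edge summaries
#'
#' For every unordered phenotype pair: the posterior edge-inclusion
#' probability (fraction of stored draws with the edge present), the
#' exceedance probability `P(beta_ij > 0 | Y)`, and posterior mean and 95%
#' quantiles of the coupling computed two ways — marginally over all stored
#' draws (draws without the edge contribute zero, the spike of the
#' spike-and-slab prior) and conditionally on edge presence. Because the
#' coupling is positive exactly when the edge is present, the exceedance
#' probability numerically equals the inclusion probability.
#'
#' @param fit an `hmrf_fit` object with at least one stored draw.
#' @return data frame with one row per pair: `i`, `j`, `pheno_i`,
#'   `pheno_j`, `post_edge_prob`, `exceed_prob`, `beta_mean_marginal`,
#'   `beta_mean_conditional`, `beta_q025_marginal`, `beta_q975_marginal`,
#'   `beta_q025_conditional`, `beta_q975_conditional`, `selected` (NA until
#'   [declare_edges()]).
#' @export
summarize_edges <- function(fit) {
  stopifnot(inherits(fit, "hmrf_fit"))
  S <- nrow(fit$draws$edge)
  if (S < 1L) stop("chain has no stored draws")
  P <- nrow(fit$pairs)
  out <- data.frame(i = fit$pairs[, 1L], j = fit$pairs[, 2L],
                    pheno_i = fit$phenotypes[fit$pairs[, 1L]],
                    pheno_j = fit$phenotypes[fit$pairs[, 2L]],
                    post_edge_prob = NA_real_, exceed_prob = NA_real_,
                    beta_mean_marginal = NA_real_,
                    beta_mean_conditional = NA_real_,
                    beta_q025_marginal = NA_real_,
                    beta_q975_marginal = NA_real_,
                    beta_q025_conditional = NA_real_,
                    beta_q975_conditional = NA_real_,
                    selected = NA, stringsAsFactors = FALSE)
  for (k in seq_len(P)) {
    ed <- fit$draws$edge[, k] == 1L
    b <- fit$draws$beta[, k]
    out$post_edge_prob[k] <- mean(ed)
    out$exceed_prob[k] <- mean(b > 0)
    out$beta_mean_marginal[k] <- mean(b)
    q <- stats::quantile(b, c(0.025, 0.975), names = FALSE)
    out$beta_q025_marginal[k] <- q[1L]; out$beta_q975_marginal[k] <- q[2L]
    if (any(ed)) {
      bc <- b[ed]
      out$beta_mean_conditional[k] <- mean(bc)
      qc <- stats::quantile(bc, c(0.025, 0.975), names = FALSE)
      out$beta_q025_conditional[k] <- qc[1L]
      out$beta_q975_conditional[k] <- qc[2L]
    }
  }
  out
}

#' Declare the phenotype graph from edge summaries
#'
#' Default rule: an edge is declared when the posterior inclusion
#' probability exceeds `prob_threshold` (0.5) and the coupling exceedance
#' probability exceeds `exceed_threshold` (0.95). The alternative
#' `rule = "ci"` declares an edge when the inclusion probability exceeds
#' `prob_threshold` and the 95% marginal credible interval of the coupling
#' (zeros from edge-absent draws included) excludes zero.
#'
#' @param summaries output of [summarize_edges()].
#' @param prob_threshold inclusion-probability threshold (default 0.5).
#' @param exceed_threshold exceedance-probability threshold (default 0.95).
#' @param rule `"exceedance"` (default) or `"ci"`.
#' @return a [phenotype_graph()] with the declared edges; the summary table
#'   with its `selected` column filled is attached as attribute
#'   `"summary"`.
#' @export
declare_edges <- function(summaries, prob_threshold = 0.5,
                          exceed_threshold = 0.95,
                          rule = c("exceedance", "ci")) {
  rule <- match.arg(rule)
  req <- c("i", "j", "post_edge_prob", "exceed_prob")
  stopifnot(all(req %in% names(summaries)))
  if (any(summaries$exceed_prob > summaries$post_edge_prob + 1e-12))
    stop("invalid summaries: exceedance probability above edge probability")
  sel <- if (rule == "exceedance") {
    summaries$post_edge_prob > prob_threshold &
      summaries$exceed_prob > exceed_threshold
  } else {
    summaries$post_edge_prob > prob_threshold &
      summaries$beta_q025_marginal > 0
  }
  summaries$selected <- sel
  n <- max(summaries$i, summaries$j)
  g <- phenotype_graph(n, edges = cbind(summaries$i[sel], summaries$j[sel]))
  attr(g, "summary") <- summaries
  g
}

#' Local false discovery rates
#'
#' Per-phenotype local fdr `f_it = 1 - P(e_it = 1 | Y)` from the accumulated
#' posterior mean field, or the pairwise version
#' `f_ijt = 1 - P(e_it = 1, e_jt = 1 | Y)` from the accumulated pairwise
#' products. SNPs whose score is nonpositive have association probability 0,
#' hence fdr exactly 1.
#'
#' @param fit an `hmrf_fit` object.
#' @param phenotype a phenotype name or index (mutually exclusive with
#'   `pair`).
#' @param pair length-2 vector of phenotype names or indices.
#' @return named numeric vector of local fdr values over SNPs.
#' @export
local_fdr <- function(fit, phenotype = NULL, pair = NULL) {
  stopifnot(inherits(fit, "hmrf_fit"))
  if (is.null(phenotype) == is.null(pair))
    stop("give exactly one of phenotype or pair")
  resolve <- function(x) {
    if (is.character(x)) {
      ix <- match(x, fit$phenotypes)
      if (anyNA(ix)) stop("unknown phenotype: ", paste(x[is.na(ix)], collapse = ", "))
      ix
    } else {
      if (any(x < 1 | x > length(fit$phenotypes))) stop("phenotype index out of range")
      as.integer(x)
    }
  }
  if (!is.null(phenotype)) {
    i <- resolve(phenotype)
    stopifnot(length(i) == 1L)
    return(1 - fit$mean_e[, i])
  }
  ij <- sort(resolve(pair))
  stopifnot(length(ij) == 2L, ij[1L] != ij[2L])
  k <- which(fit$pairs[, 1L] == ij[1L] & fit$pairs[, 2L] == ij[2L])
  1 - fit$mean_pair[, k]
}

#' FDR control by the direct posterior probability approach
#'
#' Sorts the local fdr values ascending (ties broken by input order) and
#' calls the largest prefix whose running mean stays at or below the nominal
#' global FDR level `tau`; the threshold `kappa` is the largest local fdr in
#' the called prefix (0 with an empty call set). The realized global FDR
#' estimate — the mean local fdr over the called set — is then at most
#' `tau` by construction.
#'
#' @param fdr_values numeric vector of local fdr values in [0, 1].
#' @param tau nominal global FDR bound in (0, 1).
#' @return list: `called` (logical, input order), `kappa`, `n_called`,
#'   `Fdr` (realized estimate; 0 when nothing is called).
#' @export
control_fdr <- function(fdr_values, tau) {
  stopifnot(is.numeric(fdr_values), tau > 0, tau < 1)
  if (any(fdr_values < 0 | fdr_values > 1 | !is.finite(fdr_values)))
    stop("fdr values must lie in [0, 1]")
  T_ <- length(fdr_values)
  ord <- order(fdr_values)          # radix sort: stable, ties by input index
  sorted <- fdr_values[ord]
  ok <- cumsum(sorted) / seq_len(T_) <= tau
  n_called <- if (any(ok)) max(which(ok)) else 0L
  called <- logical(T_)
  kappa <- 0
  Fdr <- 0
  if (n_called > 0L) {
    called[ord[seq_len(n_called)]] <- TRUE
    kappa <- sorted[n_called]
    Fdr <- mean(sorted[seq_len(n_called)])
  }
  list(called = called, kappa = kappa, n_called = n_called, Fdr = Fdr)
}

# Geweke-style convergence z-score: compares the mean of the first
# `frac1` of a trace against the last `frac2`, with variances from the
# spectral density at frequency zero (AR-fit estimator).
geweke_z <- function(x, frac1 = 0.1, frac2 = 0.5) {
  T_ <- length(x)
  if (T_ < 20L) return(NA_real_)
  x1 <- x[seq_len(floor(frac1 * T_))]
  x2 <- x[seq.int(T_ - floor(frac2 * T_) + 1L, T_)]
  spectrum0 <- function(v) {
    if (stats::var(v) == 0) return(0)
    f <- try(stats::ar(v, aic = TRUE), silent = TRUE)
    if (inherits(f, "try-error")) return(stats::var(v))
    f$var.pred / (1 - sum(f$ar))^2
  }
  (mean(x1) - mean(x2)) /
    sqrt(spectrum0(x1) / length(x1) + spectrum0(x2) / length(x2))
}

#' Chain diagnostics
#'
#' Acceptance rates per move type, a Geweke-style z-score on the
#' log-posterior trace (|z| > 3 flags a drifting chain), and per-pair edge
#' inclusion frequencies. Chains shorter than 100 stored draws produce a
#' warning and a partial report.
#'
#' @param fit an `hmrf_fit` object.
#' @return list with `n_draws`, `accept_rates`, `geweke_z_logpost`,
#'   `flagged` (logical), and `edge_freq`.
#' @export
chain_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "hmrf_fit"))
  S <- nrow(fit$draws$alpha)
  if (S < 100L) warning("fewer than 100 stored draws; diagnostics are partial")
  z <- geweke_z(fit$draws$logpost)
  list(n_draws = S,
       accept_rates = fit$accept,
       geweke_z_logpost = z,
       flagged = is.finite(z) && abs(z) > 3,
       edge_freq = colMeans(fit$draws$edge))
}
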