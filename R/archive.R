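#' Write a fitted chain archive to a directory
#'
#' Serializes an `hmrf_fit` as plain text: `draws.tsv` (one row per stored
#' draw: baselines, signal parameters, edge indicators, couplings,
#' log-posterior), `mean_e.tsv` and `mean_pair.tsv` (accumulated posterior
#' means with SNP identifiers), and `manifest.json` (dimensions,
#' configuration, seed, acceptance rates, package version). All numerics at
#' full precision, so [read_fit()] reproduces the object exactly.
#'
#' @param fit an `hmrf_fit` object.
#' @param dir output directory (created if missing).
#' @return invisibly, `dir`.
#' @export
write_fit <- function(fit, dir) {
  stopifnot(inherits(fit, "hmrf_fit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- fit$draws
  draw_df <- data.frame(
    stats::setNames(as.data.frame(d$alpha), paste0("alpha.", colnames(d$alpha))),
    stats::setNames(as.data.frame(d$mu), paste0("mu.", colnames(d$mu))),
    stats::setNames(as.data.frame(d$sigma2), paste0("sigma2.", colnames(d$sigma2))),
    stats::setNames(as.data.frame(d$edge), paste0("edge.", colnames(d$edge))),
    stats::setNames(as.data.frame(d$beta), paste0("beta.", colnames(d$beta))),
    logpost = d$logpost, check.names = FALSE)
  write_tsv(draw_df, file.path(dir, "draws.tsv"), digits = NA)
  write_tsv(data.frame(snp_id = fit$snp_ids, fit$mean_e, check.names = FALSE),
            file.path(dir, "mean_e.tsv"), digits = NA)
  write_tsv(data.frame(snp_id = fit$snp_ids, fit$mean_pair, check.names = FALSE),
            file.path(dir, "mean_pair.tsv"), digits = NA)
  manifest <- list(package = "pleiograph",
                   version = as.character(utils::packageVersion("pleiograph")),
                   phenotypes = fit$phenotypes,
                   pair_names = fit$pair_names,
                   n_snps = length(fit$snp_ids),
                   n_draws = nrow(d$alpha),
                   independent = fit$independent,
                   config = fit$config, hyper = fit$hyper,
                   accept = fit$accept)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(dir, "manifest.json"))
  invisible(dir)
}

#' Read a fitted chain archive from a directory
#'
#' @param dir directory written by [write_fit()].
#' @return an `hmrf_fit` object.
#' @export
read_fit <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("no chain archive at ", dir, " (manifest.json missing)")
  manifest <- jsonlite::fromJSON(mf, simplifyVector = TRUE)
  phen <- manifest$phenotypes
  pair_names <- manifest$pair_names
  draws_df <- utils::read.table(file.path(dir, "draws.tsv"), header = TRUE,
                                sep = "\t", check.names = FALSE)
  grab <- function(prefix, cols) {
    m <- as.matrix(draws_df[paste0(prefix, ".", cols)])
    colnames(m) <- cols
    m
  }
  me <- utils::read.table(file.path(dir, "mean_e.tsv"), header = TRUE,
                          sep = "\t", check.names = FALSE)
  mp <- utils::read.table(file.path(dir, "mean_pair.tsv"), header = TRUE,
                          sep = "\t", check.names = FALSE)
  snp_ids <- as.character(me$snp_id)
  mean_e <- as.matrix(me[phen]); rownames(mean_e) <- snp_ids
  mean_pair <- as.matrix(mp[pair_names]); rownames(mean_pair) <- snp_ids
  edge <- grab("edge", pair_names); storage.mode(edge) <- "integer"
  fit <- list(phenotypes = phen, snp_ids = snp_ids,
              pairs = pair_index(length(phen)), pair_names = pair_names,
              draws = list(alpha = grab("alpha", phen),
                           mu = grab("mu", phen),
                           sigma2 = grab("sigma2", phen),
                           beta = grab("beta", pair_names),
                           edge = edge,
                           logpost = draws_df$logpost),
              mean_e = mean_e, mean_pair = mean_pair,
              accept = manifest$accept,
              config = manifest$config, hyper = manifest$hyper,
              independent = isTRUE(manifest$independent),
              field_draws = NULL)
  class(fit) <- "hmrf_fit"
  fit
}
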