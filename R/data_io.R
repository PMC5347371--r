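#' Probit transformation of p-values
#'
#' Maps a p-value to the score `y = qnorm(1 - p)`, the upper-tail standard
#' normal quantile. Under the theoretical null (uniform p-values) the scores
#' are standard normal; small p-values map to large positive scores. The
#' transform is a strictly decreasing bijection from (0,1) onto the reals.
#'
#' @param p numeric vector or matrix of p-values, all strictly inside (0,1).
#' @return object of the same shape as `p` with the transformed scores.
#' @examples
#' probit_score(c(0.5, 0.025, 0.975))
#' @export
probit_score <- function(p) {
  if (!is.numeric(p)) stop("p must be numeric")
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    stop("p-values must lie strictly inside (0, 1)")
  }
  # qnorm(p, lower.tail = FALSE) == qnorm(1 - p) but keeps tail accuracy
  out <- stats::qnorm(p, lower.tail = FALSE)
  attributes(out) <- attributes(p)
  out
}

#' Construct a validated summary-statistic matrix
#'
#' Bundles a T x n matrix of GWAS association p-values (rows = SNPs, columns
#' = phenotypes) together with its probit-transformed score matrix. P-values
#' of exactly 0 or 1 are clamped into `[eps, 1 - eps]` (the probit transform
#' diverges at the endpoints); any value outside `[0, 1]` is an error.
#'
#' @param pvals numeric T x n matrix of p-values.
#' @param snp_ids character vector of T unique SNP identifiers; defaults to
#'   rownames of `pvals` or `snp1..snpT`.
#' @param phenotypes character vector of n unique phenotype names; defaults
#'   to colnames of `pvals` or `P1..Pn`.
#' @param eps clamping bound for p-values of exactly 0 or 1 (default 1e-12).
#' @return object of class `sumstats`: a list with elements `snp_ids`,
#'   `phenotypes`, `p` (clamped p-values), `y` (probit scores), and
#'   `n_clamped` (number of clamped cells).
#' @export
sumstats <- function(pvals, snp_ids = NULL, phenotypes = NULL, eps = 1e-12) {
  pvals <- as.matrix(pvals)
  if (!is.numeric(pvals)) stop("pvals must be a numeric matrix")
  T_ <- nrow(pvals); n <- ncol(pvals)
  if (T_ < 1L) stop("need at least one SNP")
  if (n < 2L) stop("need at least 2 phenotype columns")
  if (any(is.na(pvals))) stop("pvals contains missing values; drop or filter rows first")
  bad <- which(pvals < 0 | pvals > 1)
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(pvals))
    stop(sprintf("p-value outside [0, 1] at row %d, column %d", rc[1L], rc[2L]))
  }
  if (is.null(snp_ids)) snp_ids <- rownames(pvals)
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(T_))
  if (is.null(phenotypes)) phenotypes <- colnames(pvals)
  if (is.null(phenotypes)) phenotypes <- paste0("P", seq_len(n))
  snp_ids <- as.character(snp_ids); phenotypes <- as.character(phenotypes)
  if (length(snp_ids) != T_ || anyDuplicated(snp_ids))
    stop("snp_ids must be unique and match the number of rows")
  if (length(phenotypes) != n || anyDuplicated(phenotypes))
    stop("phenotypes must be unique and match the number of columns")
  stopifnot(eps > 0, eps < 0.5)
  n_clamped <- sum(pvals < eps | pvals > 1 - eps)
  pvals <- pmin(pmax(pvals, eps), 1 - eps)
  dimnames(pvals) <- list(snp_ids, phenotypes)
  obj <- list(snp_ids = snp_ids, phenotypes = phenotypes, p = pvals,
              y = probit_score(pvals), n_clamped = n_clamped, n_dropped = 0L)
  class(obj) <- "sumstats"
  obj
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("sumstats: %d SNPs x %d phenotypes (%s)\n",
              nrow(x$p), ncol(x$p), paste(x$phenotypes, collapse = ", ")))
  if (x$n_clamped > 0L) cat(sprintf("  %d p-value(s) clamped at the [eps, 1-eps] bounds\n", x$n_clamped))
  if (x$n_dropped > 0L) cat(sprintf("  %d row(s) dropped for missing/unparseable values\n", x$n_dropped))
  invisible(x)
}

#' @export
dim.sumstats <- function(x) dim(x$p)

#' Read a GWAS summary-statistic table
#'
#' Reads a delimited text file with one row per SNP: an identifier column and
#' one p-value column per phenotype. The delimiter is auto-detected (tab or
#' comma) from the header unless given. Rows containing missing or
#' unparseable p-values are dropped with a message; p-values of exactly 0 or
#' 1 are clamped (see [sumstats()]).
#'
#' @param path path to the table.
#' @param snp_col name of the SNP identifier column (default `"snp_id"`).
#' @param phenotype_cols character vector of p-value column names; default
#'   `NULL` uses every column other than `snp_col`.
#' @param delimiter field separator; `NULL` (default) auto-detects tab vs comma.
#' @param eps clamping bound passed to [sumstats()].
#' @return a [sumstats] object.
#' @export
read_sumstats <- function(path, snp_col = "snp_id", phenotype_cols = NULL,
                          delimiter = NULL, eps = 1e-12) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(delimiter)) {
    header <- readLines(path, n = 1L)
    delimiter <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "")
  if (!snp_col %in% names(df))
    stop("SNP identifier column not found: ", snp_col)
  if (is.null(phenotype_cols)) phenotype_cols <- setdiff(names(df), snp_col)
  missing_cols <- setdiff(phenotype_cols, names(df))
  if (length(missing_cols))
    stop("phenotype column(s) not found: ", paste(missing_cols, collapse = ", "))
  if (length(phenotype_cols) < 2L)
    stop("need at least 2 phenotype columns, got ", length(phenotype_cols))
  pm <- matrix(NA_real_, nrow(df), length(phenotype_cols),
               dimnames = list(NULL, phenotype_cols))
  for (cn in phenotype_cols) {
    col <- df[[cn]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      if (all(is.na(num) & !is.na(col)) && any(!is.na(col)))
        stop("phenotype column is not numeric: ", cn)
      col <- num
    }
    pm[, cn] <- col
  }
  keep <- stats::complete.cases(pm)
  n_dropped <- sum(!keep)
  if (n_dropped > 0L)
    message(n_dropped, " row(s) dropped for missing or unparseable p-values")
  if (!any(keep)) stop("no complete rows left after dropping missing values")
  pm <- pm[keep, , drop = FALSE]
  ids <- as.character(df[[snp_col]])[keep]
  out <- sumstats(pm, snp_ids = ids, phenotypes = phenotype_cols, eps = eps)
  if (out$n_clamped > 0L)
    warning(out$n_clamped, " p-value(s) of exactly 0 or 1 clamped to [eps, 1-eps]")
  out$n_dropped <- n_dropped
  out
}

#' Write a result table as delimited text
#'
#' Writes a data frame as TSV with a header, deterministic column and row
#' order, no quoting and no row names. Numeric columns are printed with
#' `digits` significant digits; `digits = NA` prints full double precision
#' (17 significant digits) so that values round-trip exactly through
#' [read_sumstats()] / `read.table`.
#'
#' @param records data frame with at least a header (zero rows allowed).
#' @param path output path.
#' @param digits significant digits for numeric columns (default 6; `NA` for
#'   full precision).
#' @return invisibly, `path`.
#' @export
write_tsv <- function(records, path, digits = 6) {
  if (!is.data.frame(records)) stop("records must be a data frame")
  if (ncol(records) == 0L) stop("records must have at least one column")
  out <- records
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      out[[j]] <- if (is.na(digits)) sprintf("%.17g", out[[j]])
                  else formatC(out[[j]], digits = digits, format = "g")
    }
  }
  ok <- tryCatch({
    suppressWarnings(utils::write.table(out, path, sep = "\t", quote = FALSE,
                                        row.names = FALSE, col.names = TRUE))
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write table to ", path, ": ", conditionMessage(ok))
  invisible(path)
}

#' Write a summary-statistic matrix to disk
#'
#' Full-precision TSV (`snp_id` column plus one p-value column per
#' phenotype); reading it back with [read_sumstats()] reproduces the stored
#' matrix exactly.
#'
#' @param x a [sumstats] object.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_sumstats <- function(x, path) {
  stopifnot(inherits(x, "sumstats"))
  df <- data.frame(snp_id = x$snp_ids, x$p, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path, digits = NA)
}
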