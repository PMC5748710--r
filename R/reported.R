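#' Read a reported per-gene result table
#'
#' Parses a TSV of published per-gene results with columns `class`,
#' `gene_symbol`, `mis`, `p_value`, where the p-value column may contain
#' censored entries like `<0.001`. With a 1000-permutation strict-exceedance
#' p-value the only attainable value below 1/1000 is exactly 0, so `<0.001`
#' is decoded as 0. A copy of the published significant-gene tables of the
#' obesity study that motivated this package ships at
#' `system.file("extdata", "reported_gene_tables.tsv", package = "misrank")`.
#'
#' @param path path to the TSV (default: the bundled table)
#' @return data.frame with `class`, `gene_symbol`, `mis` (integer),
#'   `p_value` (numeric), `p_reported` (the original string)
#' @export
read_reported_gene_table <- function(path = system.file(
    "extdata", "reported_gene_tables.tsv", package = "misrank")) {
  df <- utils::read.delim(path, colClasses = "character")
  stopifnot(all(c("class", "gene_symbol", "mis", "p_value") %in% names(df)))
  p <- df$p_value
  num <- suppressWarnings(as.numeric(p))
  censored <- grepl("^<", p)
  num[censored] <- 0
  if (anyNA(num)) stop("unparseable p-value: '", p[which(is.na(num))[1L]], "'")
  data.frame(class = df$class, gene_symbol = df$gene_symbol,
             mis = as.integer(df$mis), p_value = num, p_reported = p,
             stringsAsFactors = FALSE)
}

#' Interval of full-class AUCs consistent with a partial p-value list
#'
#' Published tables often print only a class's significant genes. Given the
#' `k = n_total - length(p_known)` unprinted p-values are only known to lie
#' in `[p_missing_min, p_missing_max]`, the exact PT-curve AUC of the full
#' class (`mean(1 - p)`) is bracketed by filling the missing values with the
#' two extremes. The bracket is sharp: both endpoints are attained.
#'
#' @param p_known numeric vector of printed p-values
#' @param n_total full class size (after network filtering)
#' @param p_missing_min,p_missing_max bounds on the unprinted p-values
#'   (defaults: a 0.05 reporting cutoff and the trivial upper bound 1)
#' @return named numeric vector `c(lower, upper)`
#' @export
partial_auc_interval <- function(p_known, n_total, p_missing_min = 0.05,
                                 p_missing_max = 1) {
  k <- n_total - length(p_known)
  if (k < 0L) stop("n_total smaller than the number of known p-values")
  if (k == 0L) {
    a <- pt_auc(p_known)
    return(c(lower = a, upper = a))
  }
  c(lower = pt_auc(c(p_known, rep(p_missing_max, k))),
    upper = pt_auc(c(p_known, rep(p_missing_min, k))))
}
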