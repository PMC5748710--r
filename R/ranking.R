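#' Proportion-threshold (PT) curve of a class's p-values
#'
#' For each threshold `t` the curve records the proportion of the class's
#' genes with p-value *strictly* below `t`. With strict inequality the
#' proportion at `t = 0` is always 0, and a gene at `p = 1` never enters the
#' curve on `[0, 1]`. The default threshold grid is the permutation grid
#' `{0, 1/n_perm, ..., 1}`, the only values at which the curve can step.
#'
#' @param p_values numeric vector of per-gene p-values in `[0, 1]`
#' @param thresholds sorted numeric vector in `[0, 1]`; computed from
#'   `n_perm` when omitted
#' @param n_perm permutation count defining the default grid
#' @return object of class `pt_curve`: list with `thresholds`, `proportions`,
#'   `n_genes`
#' @export
pt_curve <- function(p_values, thresholds = NULL, n_perm = NULL) {
  check_pvalues(p_values)
  if (is.null(thresholds)) {
    if (is.null(n_perm)) stop("supply `thresholds` or `n_perm`")
    thresholds <- seq(0, 1, by = 1 / n_perm)
  }
  if (is.unsorted(thresholds) || any(thresholds < 0 | thresholds > 1)) {
    stop("thresholds must be sorted and within [0, 1]")
  }
  prop <- vapply(thresholds, function(t) mean(p_values < t), numeric(1L))
  structure(list(thresholds = thresholds, proportions = prop,
                 n_genes = length(p_values)),
            class = "pt_curve")
}

#' @export
as.data.frame.pt_curve <- function(x, ...) {
  data.frame(threshold = x$thresholds, proportion = x$proportions)
}

#' @export
print.pt_curve <- function(x, ...) {
  cat("PT curve over", x$n_genes, "genes,", length(x$thresholds),
      "thresholds; AUC-relevant height at t=1:",
      x$proportions[length(x$proportions)], "\n")
  invisible(x)
}

check_pvalues <- function(p) {
  if (!length(p)) stop("p_values must be non-empty")
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  invisible(p)
}

#' Area under the PT curve
#'
#' `pt_auc()` is the exact integral over `[0, 1]` of the step function
#' `t -> #\{p < t\}/n`, which reduces in closed form to `mean(1 - p)`: the
#' region below the curve for gene `i` is exactly the interval `(p_i, 1]`.
#' The grid-free form removes any dependence on a plotting grid. An AUC of 1
#' means every gene has `p = 0`; under a null where p-values are uniform on
#' the permutation grid the expectation is close to 0.5.
#'
#' `pt_auc_grid()` is the trapezoid approximation on a regular grid of step
#' `step` (for plotting and cross-checks); for a monotone step function its
#' error is bounded by `step / 2`.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`
#' @param step grid spacing of the trapezoid variant
#' @return numeric AUC in `[0, 1]`
#' @export
pt_auc <- function(p_values) {
  check_pvalues(p_values)
  mean(1 - p_values)
}

#' @rdname pt_auc
#' @export
pt_auc_grid <- function(p_values, step = 0.001) {
  check_pvalues(p_values)
  grid <- seq(0, 1, by = step)
  f <- vapply(grid, function(t) mean(p_values < t), numeric(1L))
  sum((f[-1L] + f[-length(f)]) / 2) * step
}

#' Per-class association result
#'
#' Bundles one class's per-gene records with its PT curve and exact AUC.
#'
#' @param class_name class label
#' @param records data.frame from [score_disease_class()]
#' @param n_perm permutation count (sets the PT-curve grid)
#' @param n_genes_input class size before network filtering (for audit
#'   trails; defaults to the number of records)
#' @return object of class `class_result` with elements `class_name`,
#'   `records`, `curve`, `auc`, `n_genes_input`, `rank` (`NA` until
#'   [rank_classes()] assigns it)
#' @export
class_association <- function(class_name, records, n_perm,
                              n_genes_input = nrow(records)) {
  if (!nrow(records)) stop("class '", class_name, "' has no scored genes")
  structure(list(class_name = class_name, records = records,
                 curve = pt_curve(records$p_value, n_perm = n_perm),
                 auc = pt_auc(records$p_value),
                 n_genes_input = n_genes_input, rank = NA_integer_),
            class = "class_result")
}

#' @export
print.class_result <- function(x, ...) {
  cat("Class '", x$class_name, "': ", nrow(x$records), " genes, AUC = ",
      format(x$auc, digits = 4),
      if (!is.na(x$rank)) paste0(", rank ", x$rank) else "", "\n", sep = "")
  invisible(x)
}

#' Rank disease classes by AUC
#'
#' Sorts class results by AUC, highest first; ties are broken by class name
#' (ascending) so ranks are deterministic. Ranks `1..K` are written into each
#' result.
#'
#' @param results list of [class_association()] results with unique names
#' @return the reordered list, with `$rank` set
#' @export
rank_classes <- function(results) {
  nm <- vapply(results, function(r) r$class_name, character(1L))
  if (anyDuplicated(nm)) stop("duplicate class name: ", nm[duplicated(nm)][1L])
  auc <- vapply(results, function(r) r$auc, numeric(1L))
  o <- order(-auc, nm, method = "radix")
  results <- results[o]
  for (i in seq_along(results)) results[[i]]$rank <- i
  results
}

#' Class-level summary table
#'
#' @param results list of (ranked) [class_association()] results
#' @return data.frame: `class_name`, `n_genes_input`, `n_genes_in_network`,
#'   `auc`, `rank`
#' @export
class_summary <- function(results) {
  data.frame(
    class_name = vapply(results, function(r) r$class_name, character(1L)),
    n_genes_input = vapply(results, function(r) as.integer(r$n_genes_input),
                           integer(1L)),
    n_genes_in_network = vapply(results, function(r) nrow(r$records),
                                integer(1L)),
    auc = vapply(results, function(r) r$auc, numeric(1L)),
    rank = vapply(results, function(r) as.integer(r$rank), integer(1L)),
    stringsAsFactors = FALSE)
}
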