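#' Binned log-likelihood of observed heading changes under model PMFs
#'
#' Conditions and data points are conditionally independent, so the total
#' log-likelihood is the sum over conditions of the sum over data points of
#' the log of the PMF mass in the point's bin:
#' `lnP = sum_j sum_i ln pmf_j(bin(d_ij))`. The PMFs carry a Laplace floor
#' (see [bin_to_pmf()]) so no datum can land in a zero-mass bin.
#'
#' @param changes_by_condition named list of degree vectors (observed changes
#'   in heading), names matching `pmfs_by_condition`.
#' @param pmfs_by_condition named list of `population_pmf` objects for one
#'   model.
#' @return total log-likelihood in nats (`<= 0` for proper PMFs).
#' @export
data_log_likelihood <- function(changes_by_condition, pmfs_by_condition) {
  miss <- setdiff(names(changes_by_condition), names(pmfs_by_condition))
  if (length(miss))
    stop("data_log_likelihood(): no PMF for condition(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  lnp <- 0
  for (cid in names(changes_by_condition)) {
    d <- changes_by_condition[[cid]]
    if (!length(d)) next
    pmf <- pmfs_by_condition[[cid]]
    bw <- pmf$bin_right_deg[1] - pmf$bin_left_deg[1]
    mass <- pmf$mass[.pmf_bin_index(d, bw)]
    if (any(mass <= 0))
      stop("data_log_likelihood(): datum in a zero-mass bin (use the ",
           "Laplace floor when binning)", call. = FALSE)
    lnp <- lnp + sum(log(mass))
  }
  lnp
}

#' Likelihood, AIC and BIC comparison across models
#'
#' Builds the cross-model comparison table: log-likelihood ratios relative
#' to the maximally likely model (`LR = lnP(M) - lnP(best)`, so the best
#' model scores 0 and rivals are negative), `AIC = 2k - 2 lnP`,
#' `BIC = k ln(n) - 2 lnP`, and AIC/BIC *ratios* `AIC(M)/AIC(best)` and
#' `BIC(M)/BIC(best)` (best = maximally likely model), which equal 1 for the
#' best model and grow as fit worsens. Sorted by likelihood, descending.
#'
#' @param log_liks named numeric vector of per-model total log-likelihoods,
#'   all evaluated on the same data.
#' @param n_data total number of data points across all conditions (the BIC
#'   sample size).
#' @param k named vector of per-model free-parameter counts; defaults to
#'   [model_n_params()] for the named models.
#' @return data frame of class `model_comparison` with columns `model`,
#'   `n_params`, `log_likelihood`, `log_likelihood_ratio`, `AIC`,
#'   `AIC_ratio`, `BIC`, `BIC_ratio`, `n_data`.
#' @export
compare_models <- function(log_liks, n_data, k = NULL) {
  if (length(log_liks) < 2L)
    stop("compare_models(): need at least two models", call. = FALSE)
  if (is.null(names(log_liks)))
    stop("compare_models(): log_liks must be named by model", call. = FALSE)
  if (length(n_data) != 1L || n_data < 1)
    stop("compare_models(): n_data must be a single positive count",
         call. = FALSE)
  if (is.null(k)) k <- model_n_params()[names(log_liks)]
  if (anyNA(k))
    stop("compare_models(): missing parameter count for some model",
         call. = FALSE)
  k <- k[names(log_liks)]
  best <- which.max(log_liks)
  aic <- 2 * k - 2 * log_liks
  bic <- k * log(n_data) - 2 * log_liks
  tab <- data.frame(model = names(log_liks),
                    n_params = as.integer(k),
                    log_likelihood = unname(log_liks),
                    log_likelihood_ratio = unname(log_liks - log_liks[best]),
                    AIC = unname(aic),
                    AIC_ratio = unname(aic / aic[best]),
                    BIC = unname(bic),
                    BIC_ratio = unname(bic / bic[best]),
                    n_data = as.integer(n_data),
                    row.names = NULL)
  tab <- tab[order(-tab$log_likelihood), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("model_comparison", "data.frame")
  tab
}

#' Evaluate a set of models against observed heading changes
#'
#' Convenience wrapper: computes each model's [data_log_likelihood()] from a
#' PMF grid (as returned by [run_condition_grid()]) and tabulates the
#' comparison with [compare_models()].
#'
#' @param changes_by_condition named list of degree vectors.
#' @param pmf_grid nested list `pmfs[[model]][[condition_id]]`.
#' @return a `model_comparison` data frame.
#' @export
evaluate_models <- function(changes_by_condition, pmf_grid) {
  lnp <- vapply(pmf_grid, function(pmfs)
    data_log_likelihood(changes_by_condition, pmfs), numeric(1))
  n <- sum(lengths(changes_by_condition))
  compare_models(lnp, n)
}

#' @export
print.model_comparison <- function(x, digits = 6, ...) {
  cat("Cross-model comparison (best first):\n")
  print.data.frame(
    x[, c("model", "n_params", "log_likelihood_ratio", "AIC_ratio",
          "BIC_ratio")],
    digits = digits, row.names = FALSE)
  cat(sprintf("n = %d data points; lnP in nats\n", x$n_data[1]))
  invisible(x)
}
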