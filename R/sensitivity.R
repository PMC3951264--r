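# Global sensitivity: Latin hypercube sampling over the screened parameter
# ranges and partial rank correlation coefficients (PRCC) against the plaque
# weight at the horizon.

#' Latin hypercube sample over sensitivity ranges
#'
#' Stratified uniform design: for each parameter the n sampled values occupy
#' the n equiprobable strata of its `[lower, upper]` range exactly once, with
#' independent random permutations across parameters. Reproducible for a
#' fixed seed.
#'
#' @param ranges tibble from [sensitivity_ranges()] (columns `name`, `lower`,
#'   `upper`).
#' @param n number of samples (>= 2).
#' @param seed integer seed.
#' @return A `sample_design`: tibble of n rows, one column per parameter,
#'   with the seed and ranges as attributes.
#' @examples
#' d <- lhs_sample(sensitivity_ranges(), n = 10, seed = 1)
#' @export
lhs_sample <- function(ranges, n = 100, seed = 1) {
  stopifnot(nrow(ranges) > 0, n >= 2)
  set.seed(seed)
  cols <- lapply(seq_len(nrow(ranges)), function(j) {
    strata <- (sample.int(n) - stats::runif(n)) / n
    ranges$lower[j] + strata * (ranges$upper[j] - ranges$lower[j])
  })
  design <- tibble::as_tibble(stats::setNames(cols, ranges$name))
  structure(design, class = c("sample_design", class(design)),
            seed = seed, ranges = ranges)
}

#' Partial rank correlation coefficients
#'
#' For each input column: rank-transform all inputs and the output, regress
#' the column's ranks and the output's ranks on all other columns' ranks,
#' and correlate the two residual vectors. p-values come from the
#' t-statistic with `n - 2 - (k - 1)` degrees of freedom.
#'
#' @param design data frame of inputs (n x k).
#' @param outputs numeric vector of length n; `NA` rows are dropped pairwise
#'   with a warning.
#' @return A `prcc_result` tibble: `parameter`, `prcc`, `p_value`, `n`.
#' @examples
#' d <- lhs_sample(sensitivity_ranges(), n = 50, seed = 2)
#' y <- scale(d$L0)[, 1] + rnorm(50, sd = 0.01)
#' prcc(d, y)
#' @export
prcc <- function(design, outputs) {
  X <- as.matrix(as.data.frame(design))
  stopifnot(nrow(X) == length(outputs))
  ok <- stats::complete.cases(X) & is.finite(outputs)
  if (!all(ok)) {
    warning(sum(!ok), " failed sample(s) dropped")
    X <- X[ok, , drop = FALSE]
    outputs <- outputs[ok]
  }
  n <- nrow(X); k <- ncol(X)
  df <- n - 2 - (k - 1)
  if (df <= 0) stop("too few samples for ", k, " parameters")
  Xr <- apply(X, 2, rank)
  yr <- rank(outputs)
  out <- vapply(seq_len(k), function(j) {
    Z <- cbind(1, Xr[, -j, drop = FALSE])
    qz <- qr(Z)
    rx <- stats::residuals(stats::lm.fit(Z, Xr[, j]))
    ry <- stats::residuals(stats::lm.fit(Z, yr))
    if (stats::sd(rx) == 0 || stats::sd(ry) == 0) return(c(0, 1))
    r <- stats::cor(rx, ry)
    tstat <- r * sqrt(df / max(1 - r^2, 1e-300))
    # clamp: p-values live in (0, 1], even when the t statistic overflows
    c(r, max(2 * stats::pt(-abs(tstat), df), .Machine$double.xmin))
  }, numeric(2))
  structure(tibble::tibble(parameter = colnames(X), prcc = out[1, ],
                           p_value = out[2, ], n = n),
            class = c("prcc_result", "tbl_df", "tbl", "data.frame"))
}

#' Full sensitivity pipeline
#'
#' Latin hypercube sample over the screened ranges, one simulation per
#' sample (coarse meshes are supported through `config`), PRCC of the plaque
#' weight at the horizon against every parameter. Failed simulations are
#' dropped (the run is flagged when more than 10% fail).
#'
#' @param n number of LHS samples.
#' @param seed integer seed (the only source of randomness).
#' @param days horizon for the output weight.
#' @param config configuration for [run_scenario()] (use a coarse `h` for
#'   screening runs).
#' @param ranges sensitivity ranges (default [sensitivity_ranges()]).
#' @param .progress print one line per sample.
#' @return A `sensitivity_result`: `prcc` tibble, the `design`, per-sample
#'   weights `outputs`, `n_failed`, and `valid` (logical flag).
#' @export
run_sensitivity <- function(n = 100, seed = 1, days = 300, config = NULL,
                            ranges = sensitivity_ranges(),
                            .progress = FALSE) {
  design <- lhs_sample(ranges, n = n, seed = seed)
  cfg <- run_config(config)
  outputs <- vapply(seq_len(n), function(i) {
    ov <- as.list(design[i, ])
    L0 <- gcm3_to_mgdl(ov$L0); H0 <- gcm3_to_mgdl(ov$H0)
    ov$L0 <- NULL; ov$H0 <- NULL
    cfg_i <- config
    if (is.null(cfg_i)) cfg_i <- list()
    cfg_i$parameters <- utils::modifyList(
      if (is.null(cfg_i$parameters)) list() else cfg_i$parameters, ov)
    w <- tryCatch({
      res <- run_scenario(L0, H0, days = days, config = cfg_i)
      res$weights$W[nrow(res$weights)]
    }, error = function(e) NA_real_)
    if (.progress) message(sprintf("sample %d/%d: W = %.3e", i, n, w))
    w
  }, numeric(1))
  n_failed <- sum(!is.finite(outputs))
  pr <- tryCatch(
    suppressWarnings(prcc(design, outputs)),
    error = function(e) {
      # smoke-scale runs (n <= k+2) cannot support the partial regression;
      # report the full row set with undefined coefficients
      tibble::tibble(parameter = names(design), prcc = NA_real_,
                     p_value = NA_real_, n = sum(is.finite(outputs)))
    })
  structure(list(prcc = pr, design = design, outputs = outputs,
                 n_failed = n_failed, valid = n_failed <= 0.1 * n,
                 seed = seed, days = days),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat("<sensitivity_result> n = ", length(x$outputs), ", ", x$n_failed,
      " failed, horizon ", x$days, " d, seed ", x$seed,
      if (!x$valid) "  [FLAGGED: >10% failures]", "\n", sep = "")
  print(dplyr::arrange(x$prcc, dplyr::desc(abs(.data$prcc))), n = 6)
  invisible(x)
}

#' @export
tidy.sensitivity_result <- function(x, ...) x$prcc

#' @export
glance.sensitivity_result <- function(x, ...) {
  tibble::tibble(n = length(x$outputs), n_failed = x$n_failed,
                 valid = x$valid, days = x$days, seed = x$seed)
}

#' Tornado plot of PRCC values
#' @param object a `sensitivity_result`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.sensitivity_result <- function(object, ...) {
  d <- dplyr::mutate(object$prcc,
                     parameter = stats::reorder(.data$parameter, .data$prcc))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$prcc, y = .data$parameter,
                                  fill = .data$prcc > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = "PRCC of plaque weight", y = NULL) +
    ggplot2::theme_minimal()
}
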