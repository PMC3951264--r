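# (LDL, HDL) risk map: relative plaque-weight change at a fixed horizon over
# a grid of blood lipid levels, partitioned into risk regions.

#' Sweep an (LDL, HDL) grid into a risk map
#'
#' Runs [run_scenario()] for every pair of grid values and records the
#' relative plaque-weight change `R = (W(horizon) - W(0)) / W(0)`. The
#' reference grids are 121 equidistant LDL points on 70-190 mg/dL and 21
#' equidistant HDL points on 40-60 mg/dL; reduced grids are supported for
#' desk-scale runs. Individual scenario failures are recorded as missing
#' cells, not errors.
#'
#' @param L_grid ascending LDL levels (mg/dL).
#' @param H_grid ascending HDL levels (mg/dL).
#' @param days horizon (default 100).
#' @param config configuration passed to [run_scenario()].
#' @param t_high,t_none classification thresholds on `R`, see
#'   [classify_risk()].
#' @return A `risk_map`: tibble with columns `L0`, `H0`, `R`, `region`.
#' @examples
#' \donttest{
#' rm <- risk_map(c(70, 190), c(40, 60), days = 10, config = list(h = 0.004))
#' }
#' @export
risk_map <- function(L_grid = seq(70, 190, length.out = 121),
                     H_grid = seq(40, 60, length.out = 21),
                     days = 100, config = NULL,
                     t_high = 0.10, t_none = -0.10) {
  stopifnot(!is.unsorted(L_grid), !is.unsorted(H_grid))
  grid <- tidyr::expand_grid(H0 = H_grid, L0 = L_grid)
  R <- purrr::pmap_dbl(grid, function(H0, L0) {
    res <- tryCatch(run_scenario(L0, H0, days = days, config = config),
                    error = function(e) NULL)
    if (is.null(res)) return(NA_real_)
    res$weights$W_rel[nrow(res$weights)] - 1
  })
  out <- dplyr::mutate(grid, R = R)
  out <- classify_risk(out, t_high = t_high, t_none = t_none)
  structure(out, class = c("risk_map", class(out)),
            days = days, t_high = t_high, t_none = t_none)
}

#' Classify risk-map cells into regions I/II/III
#'
#' Region I (high risk) where `R >= t_high`, region III (no risk) where
#' `R <= t_none`, region II (low risk) in between. The thresholds are a
#' package convention (the reference work prints no numeric values);
#' defaults are +/-10% relative change at 100 days.
#'
#' @param data tibble with a numeric `R` column.
#' @param t_high,t_none thresholds, `t_high > t_none`.
#' @return The tibble with a `region` factor column (`I`, `II`, `III`).
#' @examples
#' classify_risk(tibble::tibble(R = c(1, 0, -0.9)))
#' @export
classify_risk <- function(data, t_high = 0.10, t_none = -0.10) {
  if (t_high <= t_none) stop("t_high must exceed t_none")
  region <- dplyr::case_when(
    is.na(data$R) ~ NA_character_,
    data$R >= t_high ~ "I",
    data$R <= t_none ~ "III",
    TRUE ~ "II"
  )
  dplyr::mutate(data, region = factor(region, levels = c("I", "II", "III")))
}

#' @export
print.risk_map <- function(x, ...) {
  cat("<risk_map> ", length(unique(x$L0)), " x ", length(unique(x$H0)),
      " (LDL x HDL) at ", attr(x, "days"), " days; regions: ",
      paste(names(table(x$region)), table(x$region), collapse = ", "),
      "\n", sep = "")
  NextMethod()
}

#' Plot a risk map
#' @param object a `risk_map`.
#' @param ... unused.
#' @return A ggplot heat map of relative weight change with region contours.
#' @export
autoplot.risk_map <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$L0, y = .data$H0)) +
    ggplot2::geom_tile(ggplot2::aes(fill = 100 * .data$R)) +
    ggplot2::geom_point(data = dplyr::filter(object, !is.na(.data$region)),
                        ggplot2::aes(shape = .data$region), size = 1.5) +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0,
                                  name = "plaque growth (%)") +
    ggplot2::labs(x = "LDL (mg/dL)", y = "HDL (mg/dL)",
                  title = sprintf("Risk of plaque development at %d days",
                                  attr(object, "days"))) +
    ggplot2::theme_minimal()
}
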