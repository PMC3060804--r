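#' Kolmogorov–Smirnov uniformity check
#'
#' One-sample KS statistic of a p-value sample against U(0, 1), with the
#' asymptotic Kolmogorov p-value (the study uses it at N in the thousands,
#' where the asymptotic distribution is accurate).
#'
#' @param pvals Numeric vector of p-values in (0, 1); `NA`s are dropped.
#' @return List with `D` (sup-distance to the uniform CDF) and `p`.
#' @export
ks_uniformity <- function(pvals) {
  pvals <- pvals[!is.na(pvals)]
  if (length(pvals) == 0) stop("no p-values to test", call. = FALSE)
  kt <- suppressWarnings(
    stats::ks.test(pvals, "punif", exact = FALSE)
  )
  list(D = unname(kt$statistic), p = unname(kt$p.value))
}

#' Randomized binomial test of the tail frequency
#'
#' Classifies p-values as "extreme" when they fall in the two symmetric
#' extremities of the unit interval of total mass `level` (below `level/2`
#' or above `1 - level/2`), and tests the extreme count against
#' `Binomial(N, level)`.  The test is *randomized*: a uniform draw
#' ventilates the probability mass of the observed count between the
#' "less extreme" and "more extreme" categories, so the two-sided test
#' p-value is exactly U(0, 1) under the null.  The beta posterior
#' `Beta(count + 1, N - count + 1)` of the underlying tail proportion is
#' summarized by a band code comparing its central 95% interval with
#' negligibility bands around the target: for `level = 0.05` the inner band
#' is (0.04, 0.06) and the outer band (0.03, 0.07); for `level = 0.01` the
#' cutoffs are divided by 5.  Codes: `zero_zero` (interval inside the inner
#' band), `zero` (inside the outer band), `plus_plus` / `minus_minus`
#' (entirely beyond the inner band edge), `plus` / `minus` (entirely above
#' or below the target), else `none`.
#'
#' @param pvals Numeric p-values; `NA`s are dropped.
#' @param level Total extremity mass, typically 0.05 or 0.01.
#' @return List with `count`, `N`, `freq`, `binom_p` (randomized two-sided),
#'   `beta_shape1`, `beta_shape2`, `band`.
#' @export
tail_frequency_test <- function(pvals, level = 0.05) {
  stopifnot(level > 0, level < 1)
  pvals <- pvals[!is.na(pvals)]
  N <- length(pvals)
  if (N == 0) stop("no p-values to test", call. = FALSE)
  count <- sum(pvals < level / 2 | pvals > 1 - level / 2)
  u <- stats::runif(1)
  lower <- stats::pbinom(count - 1, N, level) +
    u * stats::dbinom(count, N, level)
  binom_p <- min(1, 2 * min(lower, 1 - lower))
  list(count = count, N = N, freq = count / N, binom_p = binom_p,
       beta_shape1 = count + 1, beta_shape2 = N - count + 1,
       band = band_code(count, N, level))
}

band_code <- function(count, N, level) {
  d1 <- 0.01 * level / 0.05
  d2 <- 0.02 * level / 0.05
  lo <- stats::qbeta(0.025, count + 1, N - count + 1)
  hi <- stats::qbeta(0.975, count + 1, N - count + 1)
  if (lo > level - d1 && hi < level + d1) "zero_zero"
  else if (lo > level - d2 && hi < level + d2) "zero"
  else if (lo >= level + d1) "plus_plus"
  else if (lo >= level) "plus"
  else if (hi <= level - d1) "minus_minus"
  else if (hi <= level) "minus"
  else "none"
}

#' Estimate power (or size) from simulated p-values
#'
#' The rejection rule is two-sided surprise: a dataset is flagged when its
#' p-value lands in either extremity of the unit interval, with total
#' nominal mass `level`.  Under the null this estimates the test's size;
#' under an alternative, its power.
#'
#' @param pvals Numeric p-values; `NA`s are dropped.
#' @param level Nominal level (default 0.05).
#' @return A proportion in \[0, 1\].
#' @export
estimate_power <- function(pvals, level = 0.05) {
  stopifnot(level > 0, level <= 1)
  pvals <- pvals[!is.na(pvals)]
  if (level == 1) return(1)
  mean(pvals < level / 2 | pvals > 1 - level / 2)
}

#' Stratify a batch by prior sharpness and off-centering
#'
#' Adds the stratification columns used in the calibration tables:
#' `mu_bin` cuts the sharpness multiplier at 0.40, 1.01 and 2.59, and
#' `theta_bin` cuts `|log(theta0)|` at 0.14, 0.28, 0.47 and 1.73 (left
#' closed).
#'
#' @param data A [run_batch()] tibble with `mu_sigma0` and `theta0`.
#' @return `data` with factor columns `mu_bin` and `theta_bin`.
#' @export
add_strata <- function(data) {
  data |>
    dplyr::mutate(
      mu_bin = cut(.data$mu_sigma0, c(0, 0.40, 1.01, 2.59, Inf),
                   right = FALSE, include.lowest = TRUE),
      theta_bin = cut(abs(log(.data$theta0)),
                      c(0, 0.14, 0.28, 0.47, 1.73, Inf),
                      right = FALSE, include.lowest = TRUE)
    )
}

#' Calibration report for a batch of simulated p-values
#'
#' For each group (by default every engine × discrepancy combination, plus
#' any stratification columns passed in `by`), computes the sample size,
#' the KS distance and p-value against U(0, 1), and the 5% and 1% tail
#' frequencies with their randomized binomial test p-values and
#' beta-posterior band codes.
#'
#' @param data A tibble with a `p` column (e.g. from [run_batch()],
#'   possibly through [add_strata()]).
#' @param by Character vector of additional grouping columns (e.g.
#'   `c("mu_bin", "theta_bin")`).
#' @return A tibble with one row per group: `N`, `ks_D`, `ks_p`, `freq5`,
#'   `binom_p5`, `band5`, `freq1`, `binom_p1`, `band1`.
#' @export
calibrate_pvalues <- function(data, by = NULL) {
  stopifnot("p" %in% names(data))
  keys <- c(intersect(c("engine", "disc", "input_scale"), names(data)), by)
  data |>
    dplyr::filter(!is.na(.data$p)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_modify(function(d, g) {
      ks <- ks_uniformity(d$p)
      t5 <- tail_frequency_test(d$p, 0.05)
      t1 <- tail_frequency_test(d$p, 0.01)
      tibble::tibble(
        N = length(d$p), ks_D = ks$D, ks_p = ks$p,
        freq5 = t5$freq, binom_p5 = t5$binom_p, band5 = t5$band,
        freq1 = t1$freq, binom_p1 = t1$binom_p, band1 = t1$band
      )
    }) |>
    dplyr::ungroup()
}

signif_stars <- function(p) {
  if (p < 1e-4) "***" else if (p < 0.01) "**" else if (p < 0.05) "*"
  else if (p < 0.1) "(*)" else ""
}

band_symbol <- function(band) {
  switch(band, zero_zero = "00", zero = "0", plus_plus = "++", plus = "+",
         minus_minus = "--", minus = "-", none = "")
}

#' Render a calibration report as a plain-text table
#'
#' Lays out tail frequencies (with significance stars for the randomized
#' binomial test and band codes for the beta posterior) in a
#' rows-by-columns grid, mimicking the sharpness × off-centering summary
#' tables of the simulation study.
#'
#' @param report A [calibrate_pvalues()] tibble.
#' @param rows,cols Names of the report columns to use as table rows and
#'   columns (default `mu_bin` rows; a single column when `cols` is absent
#'   from the report).
#' @param value `"freq5"` or `"freq1"`.
#' @return The rendered table, invisibly (a character matrix); printed as a
#'   side effect.
#' @export
render_calibration <- function(report, rows = "mu_bin", cols = "theta_bin",
                               value = "freq5") {
  stopifnot(value %in% c("freq5", "freq1"))
  pcol <- if (value == "freq5") "binom_p5" else "binom_p1"
  bcol <- if (value == "freq5") "band5" else "band1"
  cell <- function(f, p, b) {
    ann <- paste0(signif_stars(p), band_symbol(b))
    paste0(formatC(f, digits = 3, format = "f"),
           if (nzchar(ann)) paste0("^", ann) else "")
  }
  report <- dplyr::mutate(
    report,
    .cell = mapply(cell, .data[[value]], .data[[pcol]], .data[[bcol]])
  )
  if (!is.null(cols) && cols %in% names(report)) {
    rlab <- sort(unique(report[[rows]]))
    clab <- sort(unique(report[[cols]]))
    m <- matrix("", length(rlab), length(clab),
                dimnames = list(as.character(rlab), as.character(clab)))
    for (i in seq_len(nrow(report))) {
      m[as.character(report[[rows]][i]), as.character(report[[cols]][i])] <-
        report$.cell[i]
    }
  } else {
    m <- matrix(report$.cell, ncol = 1,
                dimnames = list(as.character(report[[rows]]), value))
  }
  print(m, quote = FALSE)
  invisible(m)
}

#' Power summary of a batch run
#'
#' Groups a [run_batch()] result by engine, discrepancy and sample size and
#' estimates the power at the given level.
#'
#' @param data A [run_batch()] tibble.
#' @param level Nominal level.
#' @return A `gof_power` tibble with columns `engine`, `disc`, `n`,
#'   `n_datasets`, `power`.
#' @export
power_summary <- function(data, level = 0.05) {
  out <- data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(
      intersect(c("engine", "disc", "input_scale", "n"), names(data))))) |>
    dplyr::summarise(
      n_datasets = sum(!is.na(.data$p)),
      power = estimate_power(.data$p, level),
      .groups = "drop"
    )
  class(out) <- c("gof_power", class(out))
  attr(out, "level") <- level
  out
}

#' Plot power against sample size
#'
#' @param object A [power_summary()] tibble.
#' @param ... Unused.
#' @return A ggplot: power versus `n`, one line per engine, faceted by
#'   discrepancy, with the nominal level as a dashed baseline.
#' @export
autoplot.gof_power <- function(object, ...) {
  level <- attr(object, "level") %||% 0.05
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$n, y = .data$power, colour = .data$engine,
    linetype = .data$engine)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = level, linetype = "dotted") +
    ggplot2::facet_wrap(ggplot2::vars(.data$disc)) +
    ggplot2::labs(x = "sample size", y = "power",
                  title = "Power of goodness-of-fit p-values") +
    ggplot2::theme_minimal()
}

#' Histogram of simulated p-values
#'
#' A quick visual uniformity check for a batch of p-values.
#'
#' @param data A tibble with a `p` column.
#' @param bins Number of histogram bins.
#' @return A ggplot faceted by engine and discrepancy when present.
#' @export
plot_pvalue_hist <- function(data, bins = 40) {
  g <- ggplot2::ggplot(dplyr::filter(data, !is.na(.data$p)),
                       ggplot2::aes(x = .data$p)) +
    ggplot2::geom_histogram(bins = bins, boundary = 0, fill = "grey40") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "p-value", y = "count")
  if (all(c("engine", "disc") %in% names(data))) {
    g <- g + ggplot2::facet_grid(
      rows = ggplot2::vars(.data$engine), cols = ggplot2::vars(.data$disc))
  }
  g
}
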