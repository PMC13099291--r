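# Usability analysis: SUS scoring/banding, normality screening by
# skewness/kurtosis thresholds, Spearman rank correlations, cohort summary.

#' Score the System Usability Scale
#'
#' Canonical 0--100 SUS scoring: odd items contribute `rating - 1`, even
#' items `5 - rating`, and the adjusted sum is multiplied by 2.5, so scores
#' are always multiples of 2.5.
#'
#' @param ratings A numeric vector of 10 integer ratings in 1--5, or a
#'   matrix/data frame with 10 such columns (one row per respondent).
#' @return A numeric score in \[0, 100\] (vector for matrix input).
#' @examples
#' score_sus(rep(3, 10)) # 50
#' @export
score_sus <- function(ratings) {
  m <- if (is.data.frame(ratings) || is.matrix(ratings)) {
    as.matrix(ratings)
  } else {
    matrix(ratings, nrow = 1)
  }
  if (ncol(m) != 10) {
    abort_input("SUS responses must have exactly 10 items")
  }
  if (any(is.na(m)) || any(m < 1 | m > 5) || any(m != round(m))) {
    abort_input("SUS items must be integers in [1, 5] with no missing values",
                class = "tapbattery_validation_error")
  }
  odd <- seq(1, 9, by = 2)
  adj <- m
  adj[, odd] <- m[, odd] - 1
  adj[, -odd] <- 5 - m[, -odd]
  as.numeric(2.5 * rowSums(adj))
}

#' Band a SUS score
#'
#' Bands used in the usability study: scores of 67 or below are marginal,
#' 68--84 good, 85 and above excellent. Because SUS scores are multiples of
#' 2.5, the only score strictly between the bands is 67.5, which falls in
#' "good".
#'
#' @param score Numeric SUS score(s) in \[0, 100\].
#' @return Factor with levels `marginal`, `good`, `excellent`.
#' @examples
#' categorize_sus(c(67, 67.5, 85))
#' @export
categorize_sus <- function(score) {
  if (any(is.na(score)) || any(score < 0 | score > 100)) {
    abort_input("SUS scores must lie in [0, 100]")
  }
  factor(
    dplyr::case_when(score <= 67 ~ "marginal", score < 85 ~ "good",
                     TRUE ~ "excellent"),
    levels = c("marginal", "good", "excellent")
  )
}

#' Normality screen by skewness and kurtosis thresholds
#'
#' Computes the adjusted Fisher--Pearson sample skewness and excess kurtosis
#' (the SPSS convention) and flags a variable as non-normal when
#' `|skewness| > 1` or `|excess kurtosis| > 3`. A constant vector has
#' undefined moments and is flagged as such rather than classified.
#'
#' @param values Numeric vector, `n >= 4`.
#' @return One-row tibble: `n`, `skewness`, `kurtosis_excess`, `non_normal`
#'   (logical, `NA` when undefined), `defined`.
#' @export
normality_screen <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 4) {
    abort_input("normality screen needs at least 4 non-missing values")
  }
  if (stats::sd(values) == 0) {
    return(tibble::tibble(n = length(values), skewness = NA_real_,
                          kurtosis_excess = NA_real_, non_normal = NA,
                          defined = FALSE))
  }
  sk <- e1071::skewness(values, type = 2)
  ku <- e1071::kurtosis(values, type = 2)
  tibble::tibble(
    n = length(values), skewness = sk, kurtosis_excess = ku,
    non_normal = abs(sk) > 1 | abs(ku) > 3, defined = TRUE
  )
}

#' Spearman rank correlation with p-value and confidence interval
#'
#' The coefficient is the Pearson correlation of midranks (average ranks for
#' ties). The default p-value uses the t approximation with `n - 2` degrees
#' of freedom; for small samples (`n <= 8`) an exact permutation p-value is
#' available. The confidence interval uses the Fisher z transform with the
#' Bonett--Wright standard error `sqrt((1 + rho^2 / 2) / (n - 3))`.
#'
#' @param x,y Numeric vectors of equal length, `n >= 5` after pairwise
#'   deletion of missing values.
#' @param conf_level Confidence level of the interval (default 0.95).
#' @param p_method `"t"` (default) or `"exact"` (full permutation
#'   enumeration, only for `n <= 8`).
#' @return One-row tibble: `estimate`, `p_value`, `conf_low`, `conf_high`,
#'   `n`, `method`.
#' @examples
#' spearman_cor(1:5, c(2, 1, 4, 3, 5))$estimate # 0.8
#' @export
spearman_cor <- function(x, y, conf_level = 0.95, p_method = c("t", "exact")) {
  p_method <- match.arg(p_method)
  if (length(x) != length(y)) abort_input("x and y must have equal length")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 5) abort_input("Spearman correlation needs at least 5 complete pairs")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    abort_input("ranks are constant (all values tied); correlation undefined",
                class = "tapbattery_degenerate_error")
  }
  rho <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))

  p <- if (p_method == "exact") {
    if (n > 8) abort_input("exact permutation p-value limited to n <= 8")
    perms <- permutations_of(n)
    null_rho <- apply(perms, 1, function(pi) stats::cor(rx, ry[pi]))
    mean(abs(null_rho) >= abs(rho) - 1e-12)
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    if (!is.finite(tt)) 0 else 2 * stats::pt(-abs(tt), df = n - 2)
  }

  se <- sqrt((1 + rho^2 / 2) / (n - 3))
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- tanh(atanh(min(max(rho, -1 + 1e-15), 1 - 1e-15)) + c(-1, 1) * zq * se)
  tibble::tibble(estimate = rho, p_value = p, conf_low = ci[1],
                 conf_high = ci[2], n = n, method = p_method)
}

# All permutations of 1..n as a matrix (rows), n! rows. Recursive; intended
# for n <= 8.
permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Analyse a usability cohort
#'
#' Runs the study's usability analysis on a participant table: SUS scoring
#' (if only item columns are present), band counts, normality screening of
#' SUS and the covariates, Spearman correlations of SUS against age,
#' education and MoCA (pairwise deletion of missing values), and a
#' demographic summary in mean +/- SD (range) form.
#'
#' @param table Data frame with one row per participant: `sus` or
#'   `sus_q1`..`sus_q10`, plus any of `age`, `education_years`, `moca`, and
#'   optionally `sex`, `handedness`, `region`.
#' @param conf_level Confidence level for the correlation intervals.
#' @return A `usability_result`: list of tibbles `correlations`,
#'   `normality`, `categories`, `demographics`, plus `n`.
#' @examples
#' cohort <- simulate_cohort(40, sessions = FALSE, seed = 2)
#' analyze_cohort(cohort$participants)
#' @export
analyze_cohort <- function(table, conf_level = 0.95) {
  table <- tibble::as_tibble(table)
  if (!"sus" %in% names(table)) {
    items <- paste0("sus_q", 1:10)
    if (!all(items %in% names(table))) {
      abort_input("cohort table needs a `sus` column or `sus_q1`..`sus_q10`")
    }
    table$sus <- score_sus(table[items])
  }
  n <- nrow(table)
  if (n < 5) abort_input("cohort analysis needs at least 5 participants")

  category <- categorize_sus(table$sus)
  band_counts <- as.integer(table(category)) # table() respects level order
  categories <- tibble::tibble(
    category = levels(category), n = band_counts,
    fraction = band_counts / nrow(table)
  )

  covariates <- intersect(c("age", "education_years", "moca"), names(table))
  normality <- dplyr::bind_rows(purrr::map(
    c("sus", covariates),
    ~ dplyr::bind_cols(tibble::tibble(variable = .x),
                       normality_screen(table[[.x]]))
  ))
  correlations <- dplyr::bind_rows(purrr::map(
    covariates,
    ~ dplyr::bind_cols(tibble::tibble(variable = .x),
                       spearman_cor(table$sus, table[[.x]],
                                    conf_level = conf_level))
  ))

  summarise_num <- function(v) {
    sprintf("%.2f ± %.2f (%g–%g)", mean(v, na.rm = TRUE),
            stats::sd(v, na.rm = TRUE), min(v, na.rm = TRUE),
            max(v, na.rm = TRUE))
  }
  demo_vars <- intersect(c("age", "education_years", "moca", "sus"),
                         names(table))
  demographics <- tibble::tibble(
    variable = demo_vars,
    summary = purrr::map_chr(demo_vars, ~ summarise_num(table[[.x]]))
  )
  if ("sex" %in% names(table)) {
    demographics <- dplyr::add_row(
      demographics, variable = "sex (M/F)",
      summary = sprintf("%d/%d", sum(table$sex == "M"), sum(table$sex == "F"))
    )
  }

  structure(
    list(n = n, correlations = correlations, normality = normality,
         categories = categories, demographics = demographics,
         sus = table$sus),
    class = "usability_result"
  )
}

#' @export
print.usability_result <- function(x, ...) {
  cat(sprintf("<usability_result> n=%d\n\nSUS bands:\n", x$n))
  print(x$categories)
  cat("\nSpearman correlations with SUS:\n")
  print(x$correlations)
  invisible(x)
}

#' Tidy the correlation table of a usability analysis
#'
#' @param x A `usability_result`.
#' @param ... Unused.
#' @return The Spearman correlation tibble (one row per covariate).
#' @exportS3Method generics::tidy
tidy.usability_result <- function(x, ...) x$correlations

#' One-row summary of a usability analysis
#'
#' @param x A `usability_result`.
#' @param ... Unused.
#' @return One-row tibble: n, mean/median SUS, band fractions, and whether
#'   the SUS distribution failed the normality screen.
#' @exportS3Method generics::glance
glance.usability_result <- function(x, ...) {
  fr <- stats::setNames(x$categories$fraction, x$categories$category)
  tibble::tibble(
    n = x$n, mean_sus = mean(x$sus), median_sus = stats::median(x$sus),
    frac_marginal = fr[["marginal"]], frac_good = fr[["good"]],
    frac_excellent = fr[["excellent"]],
    sus_non_normal = x$normality$non_normal[x$normality$variable == "sus"]
  )
}

#' Plot a usability analysis
#'
#' @param object A `usability_result`.
#' @param ... Unused.
#' @return A ggplot of the SUS band counts.
#' @exportS3Method ggplot2::autoplot
autoplot.usability_result <- function(object, ...) {
  df <- object$categories
  df$category <- factor(df$category, levels = c("marginal", "good", "excellent"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$n)) +
    ggplot2::geom_col(fill = "darkseagreen4") +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%d (%.0f%%)", .data$n, 100 * .data$fraction)
    ), vjust = -0.4, size = 3.2) +
    ggplot2::labs(x = "SUS band", y = "participants",
                  title = sprintf("Perceived usability (n = %d)", object$n)) +
    ggplot2::theme_minimal()
}
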