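#' Two-sample t-test for group comparisons
#'
#' Unequal-variance (Welch) form by default, with the pooled-variance form
#' available via `var_equal = TRUE`. Degenerate zero-variance inputs are
#' handled explicitly: equal constant groups give p = 1; unequal constant
#' groups are flagged degenerate with p = 0.
#'
#' @param a,b Numeric vectors, each with >= 2 finite values.
#' @param var_equal Use the pooled-variance form.
#' @return An `ec_comparison`: list with `statistic`, `df`, `p_value`,
#'   `method`, `estimate` (mean difference a - b), `degenerate`.
#' @export
welch_t_test <- function(a, b, var_equal = FALSE) {
  stopifnot(length(a) >= 2, length(b) >= 2,
            all(is.finite(a)), all(is.finite(b)))
  method <- if (var_equal) "pooled t-test" else "Welch t-test"
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    equal <- isTRUE(all.equal(mean(a), mean(b)))
    return(new_comparison(statistic = if (equal) 0 else Inf,
                          df = NA_real_,
                          p_value = if (equal) 1 else 0,
                          method = method, estimate = mean(a) - mean(b),
                          degenerate = TRUE))
  }
  tt <- stats::t.test(a, b, var.equal = var_equal)
  new_comparison(statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value, method = method,
                 estimate = mean(a) - mean(b), degenerate = FALSE)
}

new_comparison <- function(statistic, df, p_value, method, estimate,
                           degenerate = FALSE, adjusted_p = NA_real_,
                           contrast = NA_character_) {
  structure(list(statistic = statistic, df = df, p_value = p_value,
                 adjusted_p = adjusted_p, method = method,
                 estimate = estimate, contrast = contrast,
                 degenerate = degenerate),
            class = "ec_comparison")
}

#' @export
print.ec_comparison <- function(x, ...) {
  cat(sprintf("<ec_comparison> %s: t = %.3f, df = %.2f, p = %.4g%s\n",
              x$method, x$statistic, x$df, x$p_value,
              ifelse(is.na(x$adjusted_p), "",
                     sprintf(" (adj. %.4g)", x$adjusted_p))))
  invisible(x)
}

#' Two-way ANOVA with Bonferroni-adjusted pairwise comparisons
#'
#' Fits `value ~ f1 * f2` (main effects and interaction) and reports the
#' F-tests, followed by pairwise Welch t-tests between factor-level cells
#' with Bonferroni adjustment (`p * m`, capped at 1) over the requested
#' comparison family. A factor with a single level reduces the model to a
#' one-way ANOVA with a warning.
#'
#' @param data Long-format data frame.
#' @param value,f1,f2 Column names (strings) of the response and the two
#'   crossed factors.
#' @param comparisons Optional list of length-2 character vectors naming the
#'   cell pairs to compare (cells labelled `"levelA:levelB"`). Default: all
#'   cell pairs.
#' @return List of class `anova2_result` with `anova` (tibble of F-tests)
#'   and `pairwise` (tibble of Bonferroni-adjusted cell comparisons).
#' @export
anova2_bonferroni <- function(data, value, f1, f2, comparisons = NULL) {
  stopifnot(all(c(value, f1, f2) %in% names(data)))
  v <- data[[value]]
  a <- factor(data[[f1]])
  b <- factor(data[[f2]])
  stopifnot(all(is.finite(v)))
  if (nlevels(a) < 2 && nlevels(b) < 2) {
    abort("at least one factor must have >= 2 levels.")
  }
  if (nlevels(a) < 2 || nlevels(b) < 2) {
    warn("a factor has a single level; reducing to a one-way ANOVA.")
    f <- if (nlevels(a) >= 2) a else b
    fit <- stats::aov(v ~ f)
  } else {
    fit <- stats::aov(v ~ a * b)
  }
  tab <- summary(fit)[[1]]
  terms <- trimws(rownames(tab))
  keep <- terms != "Residuals"
  anova_tbl <- tibble::tibble(
    term = sub("^a$", f1, sub("^b$", f2, sub("^a:b$", paste0(f1, ":", f2),
                                             terms[keep]))),
    df = tab$Df[keep], statistic = tab$`F value`[keep],
    p_value = tab$`Pr(>F)`[keep])
  # pairwise cell comparisons
  cell <- interaction(a, b, sep = ":", drop = TRUE)
  lv <- levels(cell)
  pairs <- if (is.null(comparisons)) {
    utils::combn(lv, 2, simplify = FALSE)
  } else {
    lapply(comparisons, function(p) {
      if (!all(p %in% lv)) abort(sprintf("unknown cell in comparison: %s",
                                         paste(p, collapse = " vs ")))
      p
    })
  }
  m <- length(pairs)
  pairwise <- purrr::map_dfr(pairs, function(p) {
    x <- v[cell == p[1]]; y <- v[cell == p[2]]
    cmp <- welch_t_test(x, y)
    tibble::tibble(contrast = paste(p, collapse = " vs "),
                   estimate = cmp$estimate, statistic = cmp$statistic,
                   df = cmp$df, p_value = cmp$p_value,
                   adjusted_p = pmin(1, cmp$p_value * m))
  })
  structure(list(anova = anova_tbl, pairwise = pairwise,
                 n_comparisons = m),
            class = "anova2_result")
}

#' @export
print.anova2_result <- function(x, ...) {
  cat("<anova2_result>\nF-tests:\n")
  print(as.data.frame(x$anova), row.names = FALSE)
  cat(sprintf("Pairwise (Bonferroni over %d comparisons):\n",
              x$n_comparisons))
  print(as.data.frame(x$pairwise), row.names = FALSE)
  invisible(x)
}

#' Group means with standard errors
#'
#' @param data Long-format data frame.
#' @param value Response column name (string).
#' @param ... Grouping columns (tidy-select).
#' @return Tibble with `n`, `mean`, `sd`, `sem` per group.
#' @export
group_summary <- function(data, value, ...) {
  data |>
    dplyr::group_by(...) |>
    dplyr::summarise(n = sum(is.finite(.data[[value]])),
                     mean = mean(.data[[value]], na.rm = TRUE),
                     sd = stats::sd(.data[[value]], na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::mutate(sem = .data$sd / sqrt(.data$n))
}
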