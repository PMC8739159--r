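#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @export
tidy.ec_comparison <- function(x, ...) {
  tibble::tibble(method = x$method, estimate = x$estimate,
                 statistic = x$statistic, df = x$df, p.value = x$p_value,
                 adj.p.value = x$adjusted_p, degenerate = x$degenerate)
}

#' @export
glance.ec_comparison <- function(x, ...) tidy(x)

#' @export
tidy.anova2_result <- function(x, which = c("pairwise", "anova"), ...) {
  which <- match.arg(which)
  out <- x[[which]]
  names(out)[names(out) == "p_value"] <- "p.value"
  names(out)[names(out) == "adjusted_p"] <- "adj.p.value"
  if (which == "pairwise") out <- dplyr::rename(out, term = "contrast")
  out
}

#' @export
glance.anova2_result <- function(x, ...) {
  tibble::tibble(n_terms = nrow(x$anova), n_comparisons = x$n_comparisons,
                 min_adjusted_p = suppressWarnings(min(x$pairwise$adjusted_p)))
}

#' @export
tidy.polarity_result <- function(x, ...) x$records

#' @export
glance.polarity_result <- function(x, ...) {
  tibble::tibble(n_cells_considered = x$n_cells_considered,
                 n_oriented = x$n_oriented,
                 oriented_fraction = x$oriented_fraction,
                 window_lo_deg = x$window_deg[1],
                 window_hi_deg = x$window_deg[2],
                 n_layers_used = x$n_layers_used)
}

#' @export
tidy.fraction_result <- function(x, ...) x$flags

#' @export
glance.fraction_result <- function(x, ...) {
  tibble::tibble(what = x$what, n_flagged = x$n_flagged,
                 n_valid = x$n_valid, fraction = x$fraction,
                 window_lo_deg = x$window_deg[1],
                 window_hi_deg = x$window_deg[2])
}

#' @export
tidy.sprout_result <- function(x, ...) {
  tibble::tibble(sprout_id = seq_along(x$sprout_lengths_um),
                 length_um = x$sprout_lengths_um)
}

#' @export
glance.sprout_result <- function(x, ...) {
  tibble::tibble(n_sprouts = x$n_sprouts,
                 mean_length_um = if (x$n_sprouts > 0) {
                   mean(x$sprout_lengths_um)
                 } else NA_real_,
                 body_radius_um = x$body_radius_um,
                 relative_length = x$relative_length)
}
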