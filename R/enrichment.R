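#' Expected category proportions from the background
#'
#' @param counts Output of [annotate_sets()] (or any tibble with `set`,
#'   `category`, `n`); the `background` set supplies the expected
#'   proportions.
#' @return Tibble with `category`, `n` and `prop` (proportions sum to 1).
#' @export
expected_proportions <- function(counts) {
  bg <- dplyr::filter(counts, .data$set == "background")
  if (nrow(bg) == 0L || sum(bg$n) == 0L) {
    stop("background category counts are empty", call. = FALSE)
  }
  dplyr::transmute(bg, category = .data$category, n = .data$n,
                   prop = .data$n / sum(.data$n))
}

#' Two-sided exact binomial p-value
#'
#' Minimum-likelihood two-sided exact test: the p-value is the sum of
#' `Binomial(n, p)` probabilities of all outcomes no more probable than the
#' observed count (the convention of [stats::binom.test()], which performs
#' the computation). Vectorised over `k`, `n`, `p`.
#'
#' @param k Observed successes, `0 <= k <= n`.
#' @param n Number of trials.
#' @param p Null success probability, strictly inside `(0, 1)`.
#' @return p-value(s) in `(0, 1]`.
#' @export
#' @examples
#' binom_two_sided(5, 10, 0.5)  # observed at the mode -> 1
#' binom_two_sided(0, 10, 0.5)  # 2/1024
binom_two_sided <- function(k, n, p) {
  m <- max(length(k), length(n), length(p))
  k <- rep_len(k, m); n <- rep_len(n, m); p <- rep_len(p, m)
  if (any(p <= 0 | p >= 1)) {
    stop("expected proportion must be strictly inside (0, 1)", call. = FALSE)
  }
  if (any(k < 0 | k > n)) stop("k must lie in [0, n]", call. = FALSE)
  vapply(seq_len(m), function(i) {
    stats::binom.test(k[i], n[i], p[i], alternative = "two.sided")$p.value
  }, numeric(1))
}

#' Enrichment of variant CpGs across annotation categories
#'
#' For each variant type and category, tests whether the observed category
#' count differs from the count expected under the background CpG
#' distribution, with a two-sided exact binomial test per (type, category)
#' cell. The reported effect is the proportion difference, signed as
#' expected minus observed (negative = over-represented relative to the
#' background). Raw exact p-values are reported; no multiple-testing
#' correction is applied.
#'
#' @param counts Output of [annotate_sets()]; sets other than `background`
#'   are tested (non-CpG variants included as a control when present).
#' @param expected Optional precomputed [expected_proportions()]; derived
#'   from `counts` when `NULL`.
#' @return Tibble of class `ep_enrichment`: `variant_type`, `category`,
#'   `observed`, `n`, `expected_prop`, `observed_prop`, `prop_difference`
#'   (expected - observed), `p_value`.
#' @export
enrichment_table <- function(counts, expected = NULL) {
  if (is.null(expected)) expected <- expected_proportions(counts)
  obs <- dplyr::filter(counts, .data$set != "background")
  out <- obs |>
    dplyr::group_by(.data$set) |>
    dplyr::mutate(n_total = sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::left_join(expected[, c("category", "prop")], by = "category") |>
    dplyr::transmute(
      variant_type = .data$set,
      category = .data$category,
      observed = .data$n,
      n = .data$n_total,
      expected_prop = .data$prop,
      observed_prop = ifelse(.data$n_total > 0,
                             .data$observed / .data$n_total, NA_real_),
      prop_difference = .data$expected_prop - .data$observed_prop
    )
  # exact test defined only for non-empty sets and non-degenerate expectations
  out$p_value <- NA_real_
  ok <- out$n > 0 & out$expected_prop > 0 & out$expected_prop < 1
  out$p_value[ok] <- binom_two_sided(out$observed[ok], out$n[ok],
                                     out$expected_prop[ok])
  class(out) <- c("ep_enrichment", class(out))
  out
}

#' Observed vs expected category distribution plot
#'
#' Bar chart of observed variant category proportions against the expected
#' (background) proportions, per variant type.
#'
#' @param x An `ep_enrichment` table from [enrichment_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_enrichment <- function(x, ...) {
  stopifnot(inherits(x, "ep_enrichment"))
  long <- tidyr::pivot_longer(
    x, c("expected_prop", "observed_prop"),
    names_to = "which", values_to = "prop") |>
    dplyr::mutate(which = ifelse(.data$which == "expected_prop",
                                 "expected", "observed"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$category, y = .data$prop,
                                     fill = .data$which)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(ggplot2::vars(.data$variant_type)) +
    ggplot2::labs(x = NULL, y = "proportion of sites", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @method autoplot ep_enrichment
#' @export
autoplot.ep_enrichment <- function(object, ...) plot_enrichment(object, ...)
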