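#' Model weights from genotype missingness
#'
#' Samples with lower missingness get more weight: `w = 1 - missingness`,
#' floored at a small positive epsilon so a (degenerate) fully-missing
#' sample cannot zero out. Samples hitting the floor are flagged in
#' `attr(w, "floored")`.
#'
#' @param missingness Missing-genotype fractions in `[0, 1]`.
#' @param floor Minimum weight.
#' @return Numeric weights, same length as `missingness`.
#' @export
weights_from_missingness <- function(missingness, floor = 1e-3) {
  stopifnot(all(missingness >= 0 & missingness <= 1), floor > 0)
  w <- pmax(1 - missingness, floor)
  attr(w, "floored") <- which(1 - missingness < floor)
  w
}

#' Dispersal group comparisons
#'
#' The three pairwise comparisons of the study design, each against the
#' philopatric reference group 1: habitat patch switching (group 2),
#' immigrants (group 3), and the colonisation-era cohort (group 4). Year
#' enters as a random intercept for the two spatial comparisons; the
#' colonisation comparison has single-year groups, so no year effect is
#' fitted there.
#'
#' @param name One of `"patch_switching"`, `"immigrants"`,
#'   `"colonisation"`.
#' @return A `comparison_spec` list: `name`, `groups` (two group ids,
#'   reference first), `include_year_random`.
#' @export
comparison_spec <- function(name = c("patch_switching", "immigrants",
                                     "colonisation")) {
  name <- match.arg(name)
  groups <- switch(name,
    patch_switching = c(1L, 2L),
    immigrants = c(1L, 3L),
    colonisation = c(1L, 4L)
  )
  structure(list(name = name, groups = groups,
                 include_year_random = name != "colonisation"),
            class = "comparison_spec")
}

#' Fit the weighted EP group-comparison model
#'
#' Fits `response ~ group * sex` on the two groups of a comparison, weighted
#' by `1 - missingness`. For comparisons with a year random intercept the
#' model is a weighted linear mixed model estimated by REML, with
#' Satterthwaite denominator degrees of freedom for the marginal
#' (type III-style) F test of each term; otherwise it is weighted least
#' squares with exact F tests. If the random effect cannot be estimated
#' (single year, singular fit, or non-convergence) the model falls back to
#' the fixed-effects-only fit with a warning, mirroring the removal of an
#' overfitted year effect. Reference levels are the philopatric group and
#' males, so the `group` estimate is the disperser-minus-reference
#' difference in males and the interaction is the extra female difference.
#'
#' @param profiles Per-sample profile tibble from [ep_profiles()] (or any
#'   tibble with `sample_id`, the response column and `missingness`).
#' @param metadata Sample metadata tibble: `sample_id`, `group` (1-4),
#'   `sex` (`"M"`/`"F"`), `year`.
#' @param comparison A [comparison_spec()] or its name.
#' @param response Response column name (e.g. `"ep_total"`, `"n_cpg"`,
#'   `"n_polycpg"`, `"n_noncpg"`, `"total_cpg"`, `"promoter_cpg"`).
#' @param min_cell Minimum samples required per group x sex cell.
#' @return An `ep_fit` object; see [tidy.ep_fit()] and [glance.ep_fit()].
#' @export
fit_ep_model <- function(profiles, metadata, comparison = "patch_switching",
                         response = "ep_total", min_cell = 2L) {
  if (!inherits(comparison, "comparison_spec")) {
    comparison <- comparison_spec(comparison)
  }
  d <- model_frame(profiles, metadata, comparison, response)
  if (any(table(d$group, d$sex) < min_cell)) {
    stop("need at least ", min_cell, " samples per group x sex cell for ",
         "the interaction model", call. = FALSE)
  }

  used_random <- FALSE
  fit <- NULL
  if (comparison$include_year_random && length(unique(d$year)) > 1L) {
    fit <- tryCatch({
      m <- suppressMessages(
        lmerTest::lmer(y ~ group * sex + (1 | year), data = d,
                       weights = w, REML = TRUE))
      if (lme4::isSingular(m, tol = 1e-5)) {
        warning("year random intercept is singular; refitting without it",
                call. = FALSE)
        NULL
      } else m
    }, error = function(e) {
      warning("mixed model failed (", conditionMessage(e),
              "); refitting without the year random effect", call. = FALSE)
      NULL
    })
    used_random <- !is.null(fit)
  } else if (comparison$include_year_random) {
    warning("only one sampling year present; fitting without the year ",
            "random effect", call. = FALSE)
  }

  if (used_random) {
    terms_tbl <- mixed_terms(fit)
  } else {
    fit <- stats::lm(y ~ group * sex, data = d, weights = w)
    terms_tbl <- wls_terms(fit, d)
  }

  structure(
    list(terms = terms_tbl, model = fit, data = d,
         comparison = comparison, response = response,
         used_year_random = used_random,
         converged = all(is.finite(terms_tbl$estimate), na.rm = TRUE)),
    class = "ep_fit"
  )
}

model_frame <- function(profiles, metadata, comparison, response) {
  if (!response %in% names(profiles)) {
    stop("response column not found in profiles: ", response, call. = FALSE)
  }
  d <- dplyr::inner_join(profiles, metadata, by = "sample_id")
  d <- d[d$group %in% comparison$groups, , drop = FALSE]
  if (length(unique(d$group)) < 2L) {
    stop("both comparison groups must be present in the data", call. = FALSE)
  }
  if (!all(d$sex %in% c("M", "F"))) {
    stop("sex must be coded 'M'/'F'", call. = FALSE)
  }
  tibble::tibble(
    sample_id = d$sample_id,
    y = d[[response]],
    group = factor(d$group, levels = comparison$groups),  # reference first
    sex = factor(d$sex, levels = c("M", "F")),
    year = factor(d$year),
    w = weights_from_missingness(d$missingness)
  )
}

# treatment-coded estimates + Satterthwaite type III F from one lmer fit
mixed_terms <- function(fit) {
  cf <- stats::coef(summary(fit))
  an <- stats::anova(fit, type = 3, ddf = "Satterthwaite")
  tibble::tibble(
    term = c("intercept", "group", "sex", "group_x_sex"),
    estimate = cf[, "Estimate"],
    se = cf[, "Std. Error"],
    f = c(NA_real_, an[, "F value"]),
    df_num = c(NA_real_, an[, "NumDF"]),
    df_den = c(NA_real_, an[, "DenDF"]),
    p_value = c(NA_real_, an[, "Pr(>F)"])
  )
}

# estimates from the treatment-coded WLS fit; marginal type III F from a
# sum-to-zero refit (interaction-F invariant to factor ordering)
wls_terms <- function(fit, d) {
  cf <- stats::coef(summary(fit))
  fit_sum <- stats::lm(y ~ group * sex, data = d, weights = w,
                       contrasts = list(group = "contr.sum",
                                        sex = "contr.sum"))
  an <- car::Anova(fit_sum, type = 3)
  rows <- c("group", "sex", "group:sex")
  tibble::tibble(
    term = c("intercept", "group", "sex", "group_x_sex"),
    estimate = cf[, "Estimate"],
    se = cf[, "Std. Error"],
    f = c(NA_real_, an[rows, "F value"]),
    df_num = c(NA_real_, an[rows, "Df"]),
    df_den = c(NA_real_, rep(an["Residuals", "Df"], 3)),
    p_value = c(NA_real_, an[rows, "Pr(>F)"])
  )
}

#' Sex-stratified follow-up fit
#'
#' The same comparison model restricted to one sex, without sex terms:
#' `response ~ group` (+ year random intercept when the comparison uses
#' one). Used to probe a group-by-sex interaction.
#'
#' @inheritParams fit_ep_model
#' @param sex `"M"` or `"F"`.
#' @return An `ep_fit` with terms `intercept` and `group`.
#' @export
sex_stratified_fit <- function(profiles, metadata,
                               comparison = "patch_switching",
                               response = "ep_total", sex = c("M", "F")) {
  sex <- match.arg(sex)
  if (!inherits(comparison, "comparison_spec")) {
    comparison <- comparison_spec(comparison)
  }
  d <- model_frame(profiles, metadata, comparison, response)
  d <- d[d$sex == sex, , drop = FALSE]
  if (length(unique(d$group)) < 2L) {
    stop("both comparison groups must be present in the ", sex, " subset",
         call. = FALSE)
  }

  used_random <- FALSE
  fit <- NULL
  if (comparison$include_year_random && length(unique(d$year)) > 1L) {
    fit <- tryCatch({
      m <- suppressMessages(
        lmerTest::lmer(y ~ group + (1 | year), data = d, weights = w,
                       REML = TRUE))
      if (lme4::isSingular(m, tol = 1e-5)) NULL else m
    }, error = function(e) NULL)
    used_random <- !is.null(fit)
  }

  if (used_random) {
    cf <- stats::coef(summary(fit))
    an <- stats::anova(fit, type = 3, ddf = "Satterthwaite")
    terms_tbl <- tibble::tibble(
      term = c("intercept", "group"),
      estimate = cf[, "Estimate"], se = cf[, "Std. Error"],
      f = c(NA_real_, an["group", "F value"]),
      df_num = c(NA_real_, an["group", "NumDF"]),
      df_den = c(NA_real_, an["group", "DenDF"]),
      p_value = c(NA_real_, an["group", "Pr(>F)"])
    )
  } else {
    fit <- stats::lm(y ~ group, data = d, weights = w)
    cf <- stats::coef(summary(fit))
    an <- stats::anova(fit)
    terms_tbl <- tibble::tibble(
      term = c("intercept", "group"),
      estimate = cf[, "Estimate"], se = cf[, "Std. Error"],
      f = c(NA_real_, an["group", "F value"]),
      df_num = c(NA_real_, an["group", "Df"]),
      df_den = c(NA_real_, an["Residuals", "Df"]),
      p_value = c(NA_real_, an["group", "Pr(>F)"])
    )
  }

  structure(
    list(terms = terms_tbl, model = fit, data = d,
         comparison = comparison, response = response, sex = sex,
         used_year_random = used_random,
         converged = all(is.finite(terms_tbl$estimate), na.rm = TRUE)),
    class = "ep_fit"
  )
}

#' @export
print.ep_fit <- function(x, ...) {
  cat("<ep_fit> ", x$comparison$name,
      if (!is.null(x$sex)) paste0(" (", x$sex, " only)"),
      ": ", x$response,
      if (x$used_year_random) " ~ group * sex + (1 | year)" else
        if (is.null(x$sex)) " ~ group * sex" else " ~ group",
      ", n = ", nrow(x$data), "\n", sep = "")
  print(x$terms)
  invisible(x)
}

#' Tidy an EP group-comparison fit
#'
#' @param x An `ep_fit`.
#' @param ... Unused.
#' @return Tibble with one row per model term: `term`, `estimate`, `se`,
#'   `f`, `df_num`, `df_den`, `p_value` (F columns are `NA` for the
#'   intercept).
#' @method tidy ep_fit
#' @export
tidy.ep_fit <- function(x, ...) x$terms

#' One-row summary of an EP group-comparison fit
#'
#' @param x An `ep_fit`.
#' @param ... Unused.
#' @return One-row tibble: comparison, response, n, whether the year random
#'   intercept was used, and the interaction (or group) F and p.
#' @method glance ep_fit
#' @export
glance.ep_fit <- function(x, ...) {
  key_term <- if ("group_x_sex" %in% x$terms$term) "group_x_sex" else "group"
  row <- x$terms[x$terms$term == key_term, ]
  tibble::tibble(
    comparison = x$comparison$name,
    response = x$response,
    n = nrow(x$data),
    year_random = x$used_year_random,
    key_term = key_term,
    f = row$f,
    df_num = row$df_num,
    df_den = row$df_den,
    p_value = row$p_value
  )
}

#' EP distribution by dispersal group
#'
#' Boxplot of a per-sample response across the four group categories.
#'
#' @param profiles Per-sample profile tibble.
#' @param metadata Sample metadata tibble.
#' @param response Column to plot.
#' @return A ggplot object.
#' @export
plot_ep_by_group <- function(profiles, metadata, response = "ep_total") {
  d <- dplyr::inner_join(profiles, metadata, by = "sample_id")
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$group),
                                  y = .data[[response]],
                                  fill = factor(.data$group))) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::labs(x = "group category", y = response) +
    ggplot2::theme_minimal()
}
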