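#' One-shot statistical evaluation of a graded cohort
#'
#' Runs the full evaluation pipeline on a per-patient table: grade under
#' the requested system(s), cross-tabulate against the LNM outcome, and
#' compute diagnostic metrics (low vs intermediate+high), crude
#' group odds ratios, the ordinal ROC AUC, the risk-group association
#' test and — when both systems are evaluated — Cohen's kappa between
#' them.
#'
#' @param data cohort table with `lnm`; see [read_cohort()] for the schema
#' @param system `"proposed"`, `"eau"` or `"both"`
#' @param ci_convention interval convention for the diagnostic metrics
#'   (see [diagnostic_metrics()]); both `cohort_n` and `wald` are always
#'   computed, this argument selects which one [tidy()] reports
#' @return object of class `risk_evaluation`
#' @export
#' @examples
#' cohort <- expand_counts(seed = 1)
#' ev <- evaluate_cohort(cohort, system = "proposed")
#' tidy(ev)
#' glance(ev)
evaluate_cohort <- function(data, system = c("proposed", "eau", "both"),
                            ci_convention = c("cohort_n", "wald", "wilson")) {
  system <- arg_match(system)
  ci_convention <- arg_match(ci_convention)
  systems <- if (system == "both") c("proposed", "eau") else system
  graded <- grade_cohort(data, system = system)
  graded <- graded[!is.na(graded$lnm), ]
  n <- nrow(graded)
  per_system <- lapply(setNames(systems, systems), function(sys) {
    cont <- crosstab(graded, sys)
    tab <- dichotomize(cont)
    list(
      contingency = cont,
      table2x2 = tab,
      metrics = dplyr::bind_rows(
        diagnostic_metrics(tab, "cohort_n", total_n = n),
        diagnostic_metrics(tab, "wald"),
        diagnostic_metrics(tab, "wilson")
      ),
      odds_ratios = group_odds_ratios(cont),
      auc = ordinal_auc(cont),
      association = tryCatch(
        association_test(cont),
        penrisk_empty_input_error = function(e) {
          tibble(method = "not_estimable", statistic = NA_real_,
                 df = NA_integer_, p.value = NA_real_)
        }
      )
    )
  })
  kappa <- NULL
  if (length(systems) == 2) {
    kappa <- cohens_kappa(graded$risk_group, graded$eau_group,
                          levels = RISK_LEVELS)
  }
  structure(
    list(systems = systems, n = n, per_system = per_system, kappa = kappa,
         ci_convention = ci_convention),
    class = "risk_evaluation"
  )
}

#' @export
print.risk_evaluation <- function(x, ...) {
  cat(sprintf("Risk grading evaluation: %d patients with outcome\n", x$n))
  for (sys in x$systems) {
    res <- x$per_system[[sys]]
    cat(sprintf("\n== %s grading ==\n", sys))
    m <- dplyr::filter(res$metrics, .data$ci_convention == x$ci_convention)
    r2 <- function(v) round_half_up(v, 2) # presentation: half-up, like the tables
    for (i in seq_len(nrow(m))) {
      cat(sprintf("  %-12s %6.2f%% (%.2f-%.2f)\n", m$metric[i],
                  r2(100 * m$estimate[i]), r2(100 * m$conf.low[i]),
                  r2(100 * m$conf.high[i])))
    }
    cat(sprintf("  %-12s %6.2f  (%.2f-%.2f)\n", "auc",
                r2(res$auc$estimate), r2(res$auc$conf.low), r2(res$auc$conf.high)))
    for (i in seq_len(nrow(res$odds_ratios))) {
      or <- res$odds_ratios[i, ]
      cat(sprintf("  OR %s vs low: %.2f (%.2f-%.2f)%s\n", or$term,
                  r2(or$estimate), r2(or$conf.low), r2(or$conf.high),
                  ifelse(is.na(or$note), "", paste0(" [", or$note, "]"))))
    }
    cat(sprintf("  association: %s p = %.3g\n",
                res$association$method, res$association$p.value))
  }
  if (!is.null(x$kappa)) {
    cat(sprintf("\nCohen's kappa between systems: %.3f\n", x$kappa$estimate))
  }
  cat(sprintf("\nDiagnostic-metric CI convention shown: %s\n", x$ci_convention))
  invisible(x)
}

#' @describeIn evaluate_cohort long tibble of every computed statistic:
#'   columns `system`, `statistic`, `term`, `estimate`, `conf.low`,
#'   `conf.high`, `note`. Diagnostic metrics use the evaluation's selected
#'   CI convention.
#' @param x a `risk_evaluation`
#' @param ... unused
#' @exportS3Method generics::tidy
tidy.risk_evaluation <- function(x, ...) {
  rows <- purrr::map_dfr(x$systems, function(sys) {
    res <- x$per_system[[sys]]
    m <- dplyr::filter(res$metrics, .data$ci_convention == x$ci_convention)
    dplyr::bind_rows(
      tibble(system = sys, statistic = "diagnostic", term = m$metric,
             estimate = m$estimate, conf.low = m$conf.low,
             conf.high = m$conf.high, note = m$note),
      tibble(system = sys, statistic = "odds_ratio",
             term = paste0(res$odds_ratios$term, "_vs_low"),
             estimate = res$odds_ratios$estimate,
             conf.low = res$odds_ratios$conf.low,
             conf.high = res$odds_ratios$conf.high,
             note = res$odds_ratios$note),
      tibble(system = sys, statistic = "auc", term = "auc",
             estimate = res$auc$estimate, conf.low = res$auc$conf.low,
             conf.high = res$auc$conf.high, note = NA_character_),
      tibble(system = sys, statistic = "association",
             term = res$association$method,
             estimate = res$association$p.value,
             conf.low = NA_real_, conf.high = NA_real_, note = NA_character_)
    )
  })
  if (!is.null(x$kappa)) {
    rows <- dplyr::bind_rows(rows, tibble(
      system = "both", statistic = "kappa", term = "kappa",
      estimate = x$kappa$estimate, conf.low = NA_real_, conf.high = NA_real_,
      note = x$kappa$note
    ))
  }
  rows
}

#' @describeIn evaluate_cohort one row per evaluated system with the
#'   headline numbers: `n`, `sensitivity`, `specificity`, `ppv`, `npv`,
#'   `auc`, `p_association`, `kappa` (NA unless both systems evaluated).
#' @exportS3Method generics::glance
glance.risk_evaluation <- function(x, ...) {
  purrr::map_dfr(x$systems, function(sys) {
    res <- x$per_system[[sys]]
    m <- dplyr::filter(res$metrics, .data$ci_convention == x$ci_convention)
    est <- setNames(m$estimate, m$metric)
    tibble(system = sys, n = x$n,
           sensitivity = est[["sensitivity"]], specificity = est[["specificity"]],
           ppv = est[["ppv"]], npv = est[["npv"]],
           auc = res$auc$estimate,
           p_association = res$association$p.value,
           kappa = if (is.null(x$kappa)) NA_real_ else x$kappa$estimate)
  })
}

#' ROC points of a grouped risk score
#'
#' The empirical ROC curve of a 3-level ordinal test has one point per
#' cutoff (plus the corners): each row gives the false- and true-positive
#' rates when "test positive" means at or above the named group.
#'
#' @param contingency a `risk_contingency`
#' @return tibble: `cutoff`, `fpr`, `tpr`
#' @export
roc_points <- function(contingency) {
  ct <- as_tibble(contingency)
  ct <- ct[order(ct$risk_group, decreasing = TRUE), ]
  n_pos <- sum(ct$lnm_pos); n_neg <- sum(ct$lnm_neg)
  tibble(
    cutoff = c("none", paste0(">=", as.character(ct$risk_group))),
    tpr = c(0, cumsum(ct$lnm_pos) / n_pos),
    fpr = c(0, cumsum(ct$lnm_neg) / n_neg)
  )
}

#' Plot ROC curves for an evaluation
#'
#' Draws the empirical three-point ROC curve of each evaluated grading
#' system, annotated with its tie-corrected AUC.
#'
#' @param object a `risk_evaluation`
#' @param ... unused
#' @return a ggplot object
#' @exportS3Method ggplot2::autoplot
autoplot.risk_evaluation <- function(object, ...) {
  curves <- purrr::map_dfr(object$systems, function(sys) {
    dplyr::mutate(
      roc_points(object$per_system[[sys]]$contingency),
      system = sprintf("%s (AUC %.2f)", sys,
                       object$per_system[[sys]]$auc$estimate)
    )
  })
  ggplot2::ggplot(curves, ggplot2::aes(.data$fpr, .data$tpr,
                                       colour = .data$system)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate (1 - specificity)",
                  y = "True positive rate (sensitivity)",
                  colour = NULL,
                  title = "ROC of risk grading for inguinal LNM") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the risk-group metastasis rates
#'
#' Bar chart of the observed LNM rate per risk group, the dose-response
#' the grading is built on.
#'
#' @param contingency a `risk_contingency`
#' @return a ggplot object
#' @export
plot_group_rates <- function(contingency) {
  ct <- as_tibble(contingency)
  ct$rate <- ct$lnm_pos / (ct$lnm_pos + ct$lnm_neg)
  ggplot2::ggplot(ct, ggplot2::aes(.data$risk_group, .data$rate)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%"),
                                limits = c(0, 1)) +
    ggplot2::labs(x = "Risk group", y = "LNM rate",
                  title = "Lymph node metastasis rate by risk group") +
    ggplot2::theme_minimal()
}
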