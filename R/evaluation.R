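#' Collapse a three-level contingency to a 2x2 diagnostic table
#'
#' For diagnostic metrics the three risk groups are dichotomised: the low
#' risk group is test-negative (surveillance), intermediate and high are
#' test-positive (lymph node surgery indicated). Disease status is LNM.
#'
#' @param contingency a `risk_contingency` (see [crosstab()])
#' @return named integer vector `c(tp, fp, fn, tn)`
#' @export
#' @examples
#' dichotomize(reference_counts()$proposed)
dichotomize <- function(contingency) {
  ct <- as_tibble(contingency)
  low <- ct$risk_group == "low"
  c(
    tp = sum(ct$lnm_pos[!low]),
    fp = sum(ct$lnm_neg[!low]),
    fn = sum(ct$lnm_pos[low]),
    tn = sum(ct$lnm_neg[low])
  )
}

wald_ci <- function(p, n) {
  half <- Z975 * sqrt(p * (1 - p) / n)
  c(pmax(0, p - half), pmin(1, p + half))
}

wilson_ci <- function(p, n) {
  z2 <- Z975^2
  centre <- (p + z2 / (2 * n)) / (1 + z2 / n)
  half <- Z975 * sqrt(p * (1 - p) / n + z2 / (4 * n^2)) / (1 + z2 / n)
  c(pmax(0, centre - half), pmin(1, centre + half))
}

#' Diagnostic metrics with confidence intervals
#'
#' Sensitivity, specificity, positive and negative predictive value from a
#' dichotomised 2x2 table, each with a 95% interval under one of three
#' conventions:
#'
#' * `"cohort_n"` — a Wald interval whose variance denominator is the full
#'   cohort size for every metric. This nonstandard convention is what the
#'   development study's printed intervals follow (verified to all printed
#'   decimals) and is the default for reproduction work; reports label it.
#' * `"wald"` — the conventional Wald interval on each metric's own
#'   denominator.
#' * `"wilson"` — the Wilson score interval, preferable near 0 or 1.
#'
#' Intervals are clipped to \[0, 1\]. A metric with a zero denominator is
#' returned as `NA` with its `note` set, never silently as 0.
#'
#' @param table 2x2 table as returned by [dichotomize()] (named vector
#'   with `tp`, `fp`, `fn`, `tn`)
#' @param ci_convention one of `"cohort_n"`, `"wald"`, `"wilson"`
#' @param total_n cohort size; required for `"cohort_n"`, defaults to the
#'   table total
#' @return tibble with one row per metric: `metric`, `estimate`,
#'   `conf.low`, `conf.high`, `denominator`, `ci_convention`, `note`
#' @export
#' @examples
#' diagnostic_metrics(dichotomize(reference_counts()$proposed))
diagnostic_metrics <- function(table,
                               ci_convention = c("cohort_n", "wald", "wilson"),
                               total_n = NULL) {
  ci_convention <- arg_match(ci_convention)
  stopifnot(all(c("tp", "fp", "fn", "tn") %in% names(table)))
  if (any(table < 0)) {
    abort("2x2 cells must be nonnegative.", class = "penrisk_validation_error")
  }
  tp <- table[["tp"]]; fp <- table[["fp"]]; fn <- table[["fn"]]; tn <- table[["tn"]]
  if (is.null(total_n)) total_n <- tp + fp + fn + tn
  defs <- tibble(
    metric = c("sensitivity", "specificity", "ppv", "npv"),
    num = c(tp, tn, tp, tn),
    denominator = c(tp + fn, tn + fp, tp + fp, tn + fn)
  )
  purrr::pmap_dfr(defs, function(metric, num, denominator) {
    if (denominator == 0) {
      return(tibble(metric = metric, estimate = NA_real_,
                    conf.low = NA_real_, conf.high = NA_real_,
                    denominator = 0L, ci_convention = ci_convention,
                    note = "undefined: zero denominator"))
    }
    p <- num / denominator
    ci <- switch(ci_convention,
                 cohort_n = wald_ci(p, total_n),
                 wald = wald_ci(p, denominator),
                 wilson = wilson_ci(p, denominator))
    tibble(metric = metric, estimate = p,
           conf.low = ci[1], conf.high = ci[2],
           denominator = as.integer(denominator),
           ci_convention = ci_convention, note = NA_character_)
  })
}

#' Odds ratio from two (pos, neg) count pairs
#'
#' Closed-form cross-product odds ratio of an exposed group against a
#' reference group, with the Wald interval
#' `exp(log OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. A zero LNM+ cell in
#' the exposed group yields OR 0 with an unbounded interval `(0, Inf)`,
#' matching how a structurally empty cell is reported rather than hidden;
#' the optional Haldane-Anscombe correction (+0.5 to every cell) is off by
#' default. A margin that is entirely zero leaves the OR undefined.
#'
#' @param exposed,reference length-2 vectors `(lnm_pos, lnm_neg)`
#' @param haldane add 0.5 to every cell before estimation
#' @return one-row tibble: `estimate`, `conf.low`, `conf.high`, `note`
#' @export
#' @examples
#' odds_ratio_2x2(c(35, 75), c(2, 109)) # OR 25.43
odds_ratio_2x2 <- function(exposed, reference, haldane = FALSE) {
  stopifnot(length(exposed) == 2, length(reference) == 2)
  if (any(c(exposed, reference) < 0)) {
    abort("Counts must be nonnegative.", class = "penrisk_validation_error")
  }
  a <- exposed[1]; b <- exposed[2]; c_ <- reference[1]; d <- reference[2]
  if (sum(exposed) == 0 || sum(reference) == 0 ||
      (a + c_) == 0 || (b + d) == 0) {
    return(tibble(estimate = NA_real_, conf.low = NA_real_,
                  conf.high = NA_real_, note = "undefined: empty margin"))
  }
  if (haldane) {
    a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5
  }
  if (a == 0 || d == 0) {
    return(tibble(estimate = 0, conf.low = 0, conf.high = Inf,
                  note = "zero cell: interval unbounded"))
  }
  if (b == 0 || c_ == 0) {
    return(tibble(estimate = Inf, conf.low = 0, conf.high = Inf,
                  note = "zero cell: interval unbounded"))
  }
  or <- (a * d) / (b * c_)
  se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  tibble(estimate = or,
         conf.low = exp(log(or) - Z975 * se),
         conf.high = exp(log(or) + Z975 * se),
         note = NA_character_)
}

#' Per-group odds ratios from a contingency table
#'
#' Crude odds ratios of the intermediate and high risk groups against the
#' low risk reference, via [odds_ratio_2x2()].
#'
#' @param contingency a `risk_contingency`
#' @inheritParams odds_ratio_2x2
#' @return tibble with rows `intermediate` and `high`: `term`, `estimate`,
#'   `conf.low`, `conf.high`, `note`
#' @export
#' @examples
#' group_odds_ratios(reference_counts()$proposed)
group_odds_ratios <- function(contingency, haldane = FALSE) {
  ct <- as_tibble(contingency)
  ref <- c(ct$lnm_pos[ct$risk_group == "low"], ct$lnm_neg[ct$risk_group == "low"])
  purrr::map_dfr(c("intermediate", "high"), function(g) {
    exp_ <- c(ct$lnm_pos[ct$risk_group == g], ct$lnm_neg[ct$risk_group == g])
    dplyr::mutate(odds_ratio_2x2(exp_, ref, haldane = haldane),
                  term = g, .before = 1)
  })
}

#' Logistic regression of metastasis on risk group
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares, convergence when the relative deviance change drops below
#' 1e-10 or after 50 iterations) of the LNM outcome on the risk group,
#' optionally adjusted for pT stage and/or age. Categorical predictors are
#' reference-coded with low risk and pT1 as reference levels. Coefficients
#' are returned as odds ratios with Wald intervals.
#'
#' Complete or quasi-complete separation (an empty outcome cell in some
#' group) is detected from boundary fitted probabilities and runaway
#' standard errors and reported in the `note` column and the
#' `separation` attribute, never passed off as an ordinary fit.
#'
#' @param data graded cohort table with `lnm` and the group column
#' @param group column holding the risk group (`"risk_group"` or
#'   `"eau_group"`)
#' @param covariates subset of `c("pt_stage", "age")`
#' @return tibble of model terms: `term`, `estimate` (odds ratio),
#'   `conf.low`, `conf.high`, `std.error` (log scale), `p.value`, `note`;
#'   attributes `model` (the `glm` fit) and `separation`
#' @export
#' @examples
#' cohort <- grade_cohort(expand_counts(seed = 1))
#' fit_logistic(cohort)
fit_logistic <- function(data, group = "risk_group", covariates = character()) {
  require_columns(data, c("lnm", group))
  if (length(covariates)) {
    covariates <- match.arg(covariates, c("pt_stage", "age"), several.ok = TRUE)
  }
  data <- normalize_cohort_columns(as_tibble(data))
  data <- data[!is.na(data$lnm) & !is.na(data[[group]]), ]
  if (!nrow(data)) {
    abort("No records with outcome available.", class = "penrisk_empty_input_error")
  }
  # unordered factor: reference-coded dummies, not polynomial contrasts
  data$.group <- factor(as.character(data[[group]]), levels = RISK_LEVELS)
  if ("pt_stage" %in% covariates) {
    data$pt_stage <- factor(as.character(data$pt_stage),
                            levels = intersect(PT_LEVELS, unique(as.character(data$pt_stage))))
    data$pt_stage <- stats::relevel(data$pt_stage, ref = if ("pT1" %in% levels(data$pt_stage)) "pT1" else levels(data$pt_stage)[1])
  }
  rhs <- paste(c(".group", covariates), collapse = " + ")
  if (length(unique(data$lnm)) < 2) {
    abort("Outcome is constant: the model is degenerate (complete separation).",
          class = "penrisk_separation_error")
  }
  # glm.fit's "fitted probabilities 0 or 1" warning is superseded by the
  # explicit separation diagnostic below
  fit <- suppressWarnings(
    glm(stats::as.formula(paste("lnm ~", rhs)), family = binomial(),
        data = data, control = stats::glm.control(epsilon = 1e-10, maxit = 50))
  )
  if (!fit$converged) {
    abort(sprintf("Logistic fit did not converge within %d iterations.", fit$iter),
          class = "penrisk_convergence_error")
  }
  eps <- 1e-8
  separated <- any(fit$fitted.values < eps | fit$fitted.values > 1 - eps)
  se <- sqrt(diag(vcov(fit)))
  huge_se <- se > 10 # log-odds scale; Wald inference meaningless beyond this
  est <- coef(fit)
  out <- tibble(
    term = names(est),
    estimate = unname(exp(est)),
    conf.low = unname(exp(est - Z975 * se)),
    conf.high = unname(exp(est + Z975 * se)),
    std.error = unname(se),
    p.value = unname(2 * pnorm(-abs(est / se))),
    note = dplyr::if_else(huge_se | (separated & grepl("^\\.group", names(est))),
                          "separation: estimate at or near boundary", NA_character_)
  )
  out$term <- sub("^\\.group", "", out$term)
  structure(out, model = fit, separation = separated)
}

#' Ordinal ROC AUC for a grouped risk score
#'
#' Area under the empirical ROC curve when the predictor is the 3-level
#' risk group ordered low < intermediate < high, via the tie-corrected
#' Mann-Whitney statistic: concordant case/control pairs count 1, tied
#' pairs 0.5, over all `n_pos x n_neg` pairs. This equals the trapezoidal
#' area under the three-point ROC curve. The 95% interval uses the
#' Hanley-McNeil variance approximation.
#'
#' @param contingency a `risk_contingency`
#' @return one-row tibble: `estimate`, `conf.low`, `conf.high`, `n_pos`,
#'   `n_neg`
#' @export
#' @examples
#' ordinal_auc(reference_counts()$proposed) # 0.8577
ordinal_auc <- function(contingency) {
  ct <- as_tibble(contingency)
  ct <- ct[order(ct$risk_group), ]
  pos <- ct$lnm_pos; neg <- ct$lnm_neg
  n_pos <- sum(pos); n_neg <- sum(neg)
  if (n_pos == 0 || n_neg == 0) {
    abort("AUC requires at least one case and one control.",
          class = "penrisk_empty_input_error")
  }
  concordant <- sum(vapply(seq_along(pos), function(i) {
    pos[i] * sum(neg[seq_len(i - 1)])
  }, numeric(1)))
  ties <- sum(pos * neg)
  auc <- (concordant + 0.5 * ties) / (n_pos * n_neg)
  # Hanley & McNeil (1982) variance approximation
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  v <- (auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
          (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg)
  half <- Z975 * sqrt(max(v, 0))
  tibble(estimate = auc,
         conf.low = max(0, auc - half), conf.high = min(1, auc + half),
         n_pos = n_pos, n_neg = n_neg)
}

#' Cohen's kappa for agreement between two categorical labelings
#'
#' Unweighted kappa `(p_o - p_e) / (1 - p_e)` over two equal-length label
#' sequences on the same category set, used here to quantify agreement
#' between the proposed and EAU risk groups on the same patients. When
#' both raters are constant and identical, chance agreement is 1 and
#' kappa is undefined; this is flagged rather than returned as a number.
#'
#' @param labels_a,labels_b vectors of equal length; coerced to factors
#'   over the union of observed (or supplied) levels
#' @param levels optional common category set
#' @return one-row tibble: `estimate`, `p_observed`, `p_expected`, `n`,
#'   `note`
#' @export
#' @examples
#' cohens_kappa(c("low", "high", "low"), c("low", "high", "high"))
cohens_kappa <- function(labels_a, labels_b, levels = NULL) {
  if (length(labels_a) != length(labels_b)) {
    abort("Label sequences must have equal length.",
          class = "penrisk_validation_error")
  }
  keep <- !is.na(labels_a) & !is.na(labels_b)
  labels_a <- labels_a[keep]; labels_b <- labels_b[keep]
  if (!length(labels_a)) {
    abort("No complete label pairs.", class = "penrisk_empty_input_error")
  }
  if (is.null(levels)) {
    levels <- union(as.character(unique(labels_a)), as.character(unique(labels_b)))
  }
  a <- factor(as.character(labels_a), levels = levels)
  b <- factor(as.character(labels_b), levels = levels)
  tab <- table(a, b)
  n <- sum(tab)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - p_e) < .Machine$double.eps^0.5) {
    return(tibble(estimate = NA_real_, p_observed = p_o, p_expected = p_e,
                  n = n, note = "undefined: chance agreement is 1"))
  }
  tibble(estimate = (p_o - p_e) / (1 - p_e), p_observed = p_o,
         p_expected = p_e, n = n, note = NA_character_)
}

#' Association test between risk group and metastasis
#'
#' Pearson chi-square test (without continuity correction) on the
#' risk-group-by-outcome table, falling back to Fisher's exact test (the
#' Freeman-Halton extension for tables wider than 2x2) whenever any
#' expected cell count falls below `min_expected`. Groups with no
#' patients are dropped with a warning before testing (an error under
#' `strict = TRUE`).
#'
#' @param contingency a `risk_contingency`
#' @param min_expected expected-count threshold triggering the exact test
#' @param strict error on empty rows instead of dropping them
#' @return one-row tibble: `method`, `statistic` (chi-square only),
#'   `df`, `p.value`
#' @export
#' @examples
#' association_test(reference_counts()$proposed)
association_test <- function(contingency, min_expected = 5, strict = FALSE) {
  ct <- as_tibble(contingency)
  m <- as.matrix(ct[, c("lnm_pos", "lnm_neg")])
  rownames(m) <- as.character(ct$risk_group)
  empty <- rowSums(m) == 0
  if (any(empty)) {
    msg <- sprintf("Empty risk group(s) dropped before testing: %s.",
                   paste(rownames(m)[empty], collapse = ", "))
    if (strict) abort(msg, class = "penrisk_validation_error") else warn(msg)
    m <- m[!empty, , drop = FALSE]
  }
  if (nrow(m) < 2 || any(colSums(m) == 0)) {
    abort("Association test needs at least two nonempty groups and both outcomes.",
          class = "penrisk_empty_input_error")
  }
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected < min_expected)) {
    ft <- fisher.test(m)
    tibble(method = "fisher_exact", statistic = NA_real_, df = NA_integer_,
           p.value = ft$p.value)
  } else {
    cs <- suppressWarnings(chisq.test(m, correct = FALSE))
    tibble(method = "pearson_chi_square",
           statistic = unname(cs$statistic), df = as.integer(cs$parameter),
           p.value = cs$p.value)
  }
}
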