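#' Histological point score for a tumour profile
#'
#' Sums the point assignment over the four scored features of the primary
#' tumour. Worst pattern of invasion (WPOI) contributes one point only for
#' type 4 (small tumour islands of at most 15 cells); lymphocytic host
#' response (LHR) contributes 0, 1 or 2 points for types 1-3 (strong to
#' little/no peritumoral infiltrate); lymphovascular invasion (LVI) and
#' perineural invasion (PNI) contribute one point each when present. The
#' total score therefore ranges over 0-5.
#'
#' All arguments are vectorised and recycled to a common length. A missing
#' value in any feature yields a missing score.
#'
#' @param wpoi integer 1-4, worst pattern of invasion type
#' @param lhr integer 1-3, lymphocytic host response type
#' @param lvi logical (or 0/1, present/absent, yes/no): lymphovascular invasion
#' @param pni logical (or 0/1, present/absent, yes/no): perineural invasion
#' @return integer vector of point scores in 0-5
#' @export
#' @examples
#' risk_score(wpoi = 1, lhr = 1, lvi = FALSE, pni = FALSE) # 0
#' risk_score(wpoi = 4, lhr = 3, lvi = TRUE, pni = TRUE)   # 5
risk_score <- function(wpoi, lhr, lvi, pni) {
  wpoi <- check_ordinal(wpoi, "wpoi", 1:4)
  lhr <- check_ordinal(lhr, "lhr", 1:3)
  lvi <- normalize_binary(lvi, "lvi")
  pni <- normalize_binary(pni, "pni")
  as.integer((wpoi == 4L) + c(0L, 1L, 2L)[lhr] + lvi + pni)
}

#' Map a point score to the proposed risk group
#'
#' The cutoffs of the proposed grading: score 0 is low risk, 1 or 2
#' intermediate risk, and 3 or more high risk for inguinal lymph node
#' metastasis. Only the histological point score is consulted; pT stage
#' and WHO grade play no role in this system.
#'
#' @param score integer vector of point scores in 0-5
#' @return ordered factor with levels low < intermediate < high
#' @export
#' @examples
#' risk_group_from_score(0:5)
risk_group_from_score <- function(score) {
  score <- suppressWarnings(as.integer(score))
  bad <- !is.na(score) & (score < 0L | score > 5L)
  if (any(bad)) {
    abort_invalid("score", score[bad][1], "expected integer in 0-5")
  }
  risk_factor(dplyr::case_when(
    is.na(score) ~ NA_character_,
    score == 0L ~ "low",
    score <= 2L ~ "intermediate",
    TRUE ~ "high"
  ))
}

#' EAU risk group from pT stage and WHO grade
#'
#' The European Association of Urology (2014) stratification used as the
#' comparator: pTa and pT1 G1 tumours are low risk, pT1 G2 intermediate,
#' and pT1 G3 or any stage above pT1 high risk. Grade is required only for
#' pT1 tumours; a pT1 tumour with missing grade is an error rather than a
#' guess, since the guideline gives no rule for it.
#'
#' @param pt_stage character or factor: pTa, pT1, pT2, pT3 or pT4
#' @param grade character or factor: G1, G2 or G3 (may be NA except for pT1)
#' @return ordered factor with levels low < intermediate < high
#' @export
#' @examples
#' eau_risk_group("pT1", "G2") # intermediate
#' eau_risk_group("pT3", "G1") # high
eau_risk_group <- function(pt_stage, grade = NA) {
  pt_stage <- normalize_pt_stage(pt_stage)
  grade <- normalize_grade(rep_len(grade, length(pt_stage)))
  needs_grade <- !is.na(pt_stage) & pt_stage == "pT1" & is.na(grade)
  if (any(needs_grade)) {
    abort(
      sprintf("EAU grading of a pT1 tumour requires WHO grade; missing for %d record(s).",
              sum(needs_grade)),
      class = "penrisk_missing_covariate_error"
    )
  }
  risk_factor(dplyr::case_when(
    is.na(pt_stage) ~ NA_character_,
    pt_stage == "pTa" ~ "low",
    pt_stage != "pT1" ~ "high",
    grade == "G1" ~ "low",
    grade == "G2" ~ "intermediate",
    TRUE ~ "high"
  ))
}

#' Subclassify pT1 tumours into pT1a / pT1b
#'
#' TNM subdivision of pT1 (invasion of subepithelial connective tissue):
#' pT1a is a G1-G2 tumour without lymphovascular or perineural invasion;
#' G3 or the presence of either invasion makes it pT1b.
#'
#' @param pt_stage must be "pT1" for every record
#' @param grade G1-G3, required
#' @param lvi,pni logical (or equivalent encodings)
#' @return factor with levels pT1a, pT1b
#' @export
#' @examples
#' subclassify_pt1("pT1", "G2", lvi = FALSE, pni = FALSE) # pT1a
#' subclassify_pt1("pT1", "G1", lvi = TRUE, pni = FALSE)  # pT1b
subclassify_pt1 <- function(pt_stage, grade, lvi, pni) {
  pt_stage <- normalize_pt_stage(pt_stage)
  if (any(is.na(pt_stage) | pt_stage != "pT1")) {
    abort("pT1 subclassification applies to pT1 tumours only.",
          class = "penrisk_precondition_error")
  }
  grade <- normalize_grade(grade)
  if (any(is.na(grade))) {
    abort("pT1 subclassification requires WHO grade.",
          class = "penrisk_missing_covariate_error")
  }
  lvi <- normalize_binary(lvi, "lvi")
  pni <- normalize_binary(pni, "pni")
  factor(ifelse(grade %in% c("G1", "G2") & !lvi & !pni, "pT1a", "pT1b"),
         levels = c("pT1a", "pT1b"))
}

#' Grade a cohort table
#'
#' Adds point scores and risk-group assignments to a per-patient table.
#' With `system = "proposed"` the columns `score` and `risk_group` are
#' added from the four histological features; with `"eau"` the column
#' `eau_group` is added from pT stage and grade; `"both"` adds all three.
#' Rows with a missing scored feature receive `NA` and a warning
#' (`strict = TRUE` turns this into an error), mirroring exclusion rather
#' than imputation.
#'
#' @param data data frame with the cohort schema (see [read_cohort()])
#' @param system which grading system(s) to apply
#' @param strict error (rather than warn) on rows that cannot be scored
#' @return the input as a tibble with grading columns appended
#' @export
#' @examples
#' cohort <- tibble::tibble(
#'   patient_id = c("a", "b"), pt_stage = c("pT1", "pT2"),
#'   grade = c("G1", "G3"), wpoi = c(1, 4), lhr = c(1, 3),
#'   lvi = c(0, 1), pni = c(0, 1)
#' )
#' grade_cohort(cohort, system = "both")
grade_cohort <- function(data, system = c("proposed", "eau", "both"),
                         strict = FALSE) {
  system <- arg_match(system)
  data <- as_tibble(data)
  if (system %in% c("proposed", "both")) {
    require_columns(data, c("wpoi", "lhr", "lvi", "pni"))
    data <- normalize_cohort_columns(data)
    incomplete <- is.na(data$wpoi) | is.na(data$lhr) |
      is.na(data$lvi) | is.na(data$pni)
    if (any(incomplete)) {
      msg <- sprintf("%d record(s) have missing scored features and were not scored.",
                     sum(incomplete))
      if (strict) abort(msg, class = "penrisk_validation_error") else warn(msg)
    }
    data$score <- NA_integer_
    data$score[!incomplete] <- risk_score(
      data$wpoi[!incomplete], data$lhr[!incomplete],
      data$lvi[!incomplete], data$pni[!incomplete]
    )
    data$risk_group <- risk_group_from_score(data$score)
  }
  if (system %in% c("eau", "both")) {
    require_columns(data, c("pt_stage", "grade"))
    data <- normalize_cohort_columns(data)
    data$eau_group <- eau_risk_group(data$pt_stage, data$grade)
  }
  data
}
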