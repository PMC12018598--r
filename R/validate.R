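# Internal input validation and value normalisation for cohort tables.
# Pathology exports encode the same fact many ways; everything funnels
# through these normalisers so the rest of the package sees one encoding.

PT_LEVELS <- c("pTa", "pT1", "pT2", "pT3", "pT4")
GRADE_LEVELS <- c("G1", "G2", "G3")
RISK_LEVELS <- c("low", "intermediate", "high")

COHORT_COLUMNS <- c("patient_id", "age", "pt_stage", "grade",
                    "wpoi", "lhr", "lvi", "pni", "lnm")
MANDATORY_COLUMNS <- c("patient_id", "pt_stage", "wpoi", "lhr", "lvi", "pni")

# Accepts 0/1, present/absent, yes/no, true/false (case-insensitive),
# returns logical with NA for missing markers.
normalize_binary <- function(x, field = "value") {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) {
    bad <- !is.na(x) & !x %in% c(0, 1)
    if (any(bad)) {
      abort_invalid(field, x[bad][1], "expected 0/1")
    }
    return(x == 1)
  }
  s <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(s))
  out[s %in% c("1", "present", "yes", "true", "y")] <- TRUE
  out[s %in% c("0", "absent", "no", "false", "n")] <- FALSE
  unknown <- !is.na(s) & s != "" & s != "na" & is.na(out)
  if (any(unknown)) {
    abort_invalid(field, s[unknown][1],
                  "expected one of 0/1, present/absent, yes/no, true/false")
  }
  out
}

normalize_pt_stage <- function(x) {
  s <- trimws(as.character(x))
  s[s %in% c("", "NA")] <- NA
  # tolerate "T1", "pt2" etc.
  s <- ifelse(is.na(s), NA,
              paste0("pT", sub("^p?t", "", s, ignore.case = TRUE)))
  if (any(!is.na(s) & s == "pTis")) {
    abort(
      "pTis (carcinoma in situ) is not gradable: the risk systems target invasive carcinoma.",
      class = "penrisk_validation_error"
    )
  }
  bad <- !is.na(s) & !s %in% PT_LEVELS
  if (any(bad)) {
    abort_invalid("pt_stage", s[bad][1],
                  paste("expected one of", paste(PT_LEVELS, collapse = ", ")))
  }
  factor(s, levels = PT_LEVELS)
}

normalize_grade <- function(x) {
  s <- toupper(trimws(as.character(x)))
  s[s %in% c("", "NA")] <- NA
  s <- ifelse(is.na(s), NA, ifelse(grepl("^[123]$", s), paste0("G", s), s))
  bad <- !is.na(s) & !s %in% GRADE_LEVELS
  if (any(bad)) abort_invalid("grade", s[bad][1], "expected G1, G2 or G3")
  factor(s, levels = GRADE_LEVELS)
}

check_ordinal <- function(x, field, range) {
  x <- suppressWarnings(as.numeric(as.character(x)))
  bad <- !is.na(x) & (!x %in% range)
  if (any(bad)) {
    abort_invalid(field, x[bad][1],
                  paste0("expected integer in ", min(range), "-", max(range)))
  }
  as.integer(x)
}

abort_invalid <- function(field, value, expectation) {
  abort(
    sprintf("Invalid `%s` value %s: %s.", field, deparse(as.vector(value)), expectation),
    class = "penrisk_validation_error",
    field = field
  )
}

# Normalises every recognised column in place; does not drop rows.
normalize_cohort_columns <- function(data) {
  data <- as_tibble(data)
  if ("wpoi" %in% names(data)) data$wpoi <- check_ordinal(data$wpoi, "wpoi", 1:4)
  if ("lhr" %in% names(data)) data$lhr <- check_ordinal(data$lhr, "lhr", 1:3)
  if ("lvi" %in% names(data)) data$lvi <- normalize_binary(data$lvi, "lvi")
  if ("pni" %in% names(data)) data$pni <- normalize_binary(data$pni, "pni")
  if ("lnm" %in% names(data)) data$lnm <- normalize_binary(data$lnm, "lnm")
  if ("pt_stage" %in% names(data)) data$pt_stage <- normalize_pt_stage(data$pt_stage)
  if ("grade" %in% names(data)) data$grade <- normalize_grade(data$grade)
  if ("age" %in% names(data)) {
    data$age <- suppressWarnings(as.numeric(data$age))
    if (any(!is.na(data$age) & data$age <= 0)) {
      abort_invalid("age", data$age[!is.na(data$age) & data$age <= 0][1],
                    "expected age > 0 years")
    }
  }
  data
}

require_columns <- function(data, cols, where = "cohort table") {
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    abort(
      sprintf("%s is missing mandatory column(s): %s.",
              where, paste0("`", missing, "`", collapse = ", ")),
      class = "penrisk_schema_error",
      missing_columns = missing
    )
  }
  invisible(data)
}

risk_factor <- function(x) factor(x, levels = RISK_LEVELS, ordered = TRUE)
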