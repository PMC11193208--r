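#' Baseline characteristics tracked by the package
#'
#' Seven pre-treatment characteristics are assessed: three continuous
#' (mean age in years, mean LDL-cholesterol in mg/dl, mean body mass index
#' in kg/m2, each with a standard deviation) and four binary, stored as
#' percentages on the 0--100 scale as printed in trial publications
#' (male sex, diabetes mellitus, smoking, hypertension).
#'
#' @return A data.frame with one row per characteristic and columns
#'   `characteristic`, `type` ("continuous" or "binary"), the summary
#'   columns holding it in the long trial table (`mean_col`, `sd_col`,
#'   `pct_col`), `unit`, and a human-readable `label`.
#' @export
#' @examples
#' baseline_characteristics()
baseline_characteristics <- function() {
  data.frame(
    characteristic = c("age", "male", "ldl", "bmi", "dm", "smoking", "htn"),
    type = c("continuous", "binary", "continuous", "continuous",
             "binary", "binary", "binary"),
    mean_col = c("age_mean", NA, "ldl_mean", "bmi_mean", NA, NA, NA),
    sd_col   = c("age_sd",   NA, "ldl_sd",   "bmi_sd",   NA, NA, NA),
    pct_col  = c(NA, "male_pct", NA, NA, "dm_pct", "smoking_pct", "htn_pct"),
    unit = c("years", "%", "mg/dl", "kg/m2", "%", "%", "%"),
    label = c("Age in years, mean", "Male gender, %", "LDL-c in mg/dl, mean",
              "Body mass index, mean", "Diabetes mellitus, %",
              "Smoking, %", "Hypertension, %"),
    stringsAsFactors = FALSE
  )
}

#' @rdname baseline_characteristics
#' @export
continuous_characteristics <- function() c("age", "ldl", "bmi")

# metadata row for one characteristic; errors on unknown labels
char_info <- function(characteristic) {
  chars <- baseline_characteristics()
  i <- match(characteristic, chars$characteristic)
  if (length(characteristic) != 1L || is.na(i)) {
    stop("unknown characteristic '", paste(characteristic, collapse = ", "),
         "'; expected one of: ", paste(chars$characteristic, collapse = ", "),
         call. = FALSE)
  }
  chars[i, , drop = FALSE]
}

# Outcomes the meta-regression grid knows about, with the outcome-table
# columns holding their per-arm counts (NA for the continuous LDL outcome).
outcome_registry <- function() {
  data.frame(
    outcome = c("ldl_reduction", "mace", "sae", "any_ae", "mortality"),
    count_col = c(NA, "mace_events", "sae_events", "ae_events", "deaths"),
    stringsAsFactors = FALSE
  )
}
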