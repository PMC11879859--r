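# Closed-form derived clinical quantities. All are pure, vectorized functions
# operating in the units the trial records: glucose mmol/l, insulin mIE/l,
# C-peptide nmol/l, triglycerides mmol/l, GGT ukat/l, weight kg, height cm.

#' Homeostasis model assessment indices (HOMA1 closed forms)
#'
#' Computes the classic closed-form homeostasis-model estimates of insulin
#' resistance (HOMA-IR) and beta-cell function (HOMA-B) from fasting glucose
#' and fasting insulin:
#' \deqn{HOMA\text{-}IR = \frac{G \times I}{22.5}, \qquad
#'       HOMA\text{-}B = \frac{20 \times I}{G - 3.5}}
#' with glucose \eqn{G} in mmol/l and insulin \eqn{I} in mIE/l. HOMA-B is
#' undefined at or below the 3.5 mmol/l glucose pivot; for such inputs
#' `homa_b` is `NA` with a warning (HOMA-IR is still returned).
#'
#' @param glucose Fasting glucose, mmol/l. Must be positive.
#' @param insulin Fasting insulin, mIE/l. Must be positive.
#' @return A data.frame with columns `homa_ir` and `homa_b`.
#' @examples
#' homa_indices(4.5, 5)   # calibration point: IR = 1, B = 100
#' homa_indices(6.4, 18.9)
#' @export
homa_indices <- function(glucose, insulin) {
  stopifnot(length(glucose) == length(insulin))
  if (any(!is.finite(glucose)) || any(glucose <= 0))
    stop("glucose must be positive and finite")
  if (any(!is.finite(insulin)) || any(insulin <= 0))
    stop("insulin must be positive and finite")
  homa_ir <- glucose * insulin / 22.5
  homa_b <- rep(NA_real_, length(glucose))
  ok <- glucose > 3.5
  if (any(!ok))
    warning("HOMA-B undefined for glucose <= 3.5 mmol/l; returning NA for ",
            sum(!ok), " value(s)")
  homa_b[ok] <- 20 * insulin[ok] / (glucose[ok] - 3.5)
  data.frame(homa_ir = homa_ir, homa_b = homa_b)
}

#' Fatty liver index
#'
#' Logistic 0-100 score for hepatic steatosis from BMI, waist circumference,
#' triglycerides and gamma-glutamyl transferase. The source formula takes
#' triglycerides in mg/dl and GGT in U/l; inputs here are in the trial's
#' units (mmol/l and ukat/l) and are converted internally
#' (1 mmol/l TG = 88.57 mg/dl; 1 ukat/l GGT = 60 U/l):
#' \deqn{L = 0.953\,\ln TG + 0.139\,BMI + 0.718\,\ln GGT + 0.053\,waist - 15.745}
#' \deqn{FLI = 100\, e^L / (1 + e^L)}
#'
#' @param bmi Body-mass index, kg/m^2.
#' @param waist Waist circumference, cm.
#' @param tg Triglycerides, mmol/l.
#' @param ggt Gamma-glutamyl transferase, ukat/l.
#' @return Fatty liver index in (0, 100).
#' @examples
#' fatty_liver_index(32.1, 110, 1.5, 0.7)
#' @export
fatty_liver_index <- function(bmi, waist, tg, ggt) {
  if (any(bmi <= 0) || any(waist <= 0) || any(tg <= 0) || any(ggt <= 0))
    stop("all fatty liver index inputs must be positive")
  tg_mgdl <- tg * 88.57
  ggt_ul <- ggt * 60
  l <- 0.953 * log(tg_mgdl) + 0.139 * bmi + 0.718 * log(ggt_ul) +
    0.053 * waist - 15.745
  100 * stats::plogis(l)
}

#' Du Bois body surface area
#'
#' \deqn{BSA = 0.007184 \times weight^{0.425} \times height^{0.725}}
#' with weight in kg, height in cm, result in m^2.
#'
#' @param weight Body weight, kg.
#' @param height Height, cm.
#' @return Body surface area, m^2.
#' @examples
#' bsa_du_bois(70, 170)
#' @export
bsa_du_bois <- function(weight, height) {
  if (any(weight <= 0) || any(height <= 0))
    stop("weight and height must be positive")
  0.007184 * weight^0.425 * height^0.725
}

#' IPAQ metabolic-equivalent task minutes per week
#'
#' Converts self-reported activity (days per week and minutes per day of
#' vigorous activity, moderate activity and walking) to MET-minutes per week
#' with the IPAQ scoring-protocol constants 8.0, 4.0 and 3.3. Per protocol,
#' minutes per day are capped at 180 for each activity before scoring.
#'
#' @param vigorous,moderate,walking Length-2 numeric vectors
#'   `c(days, minutes_per_day)`.
#' @param daily_cap Per-activity cap on minutes per day (protocol default 180).
#' @return MET-minutes per week.
#' @examples
#' ipaq_met_minutes(c(3, 30), c(5, 30), c(7, 30))  # 720 + 600 + 693
#' @export
ipaq_met_minutes <- function(vigorous = c(0, 0), moderate = c(0, 0),
                             walking = c(0, 0), daily_cap = 180) {
  check <- function(x, what) {
    if (length(x) != 2 || any(x < 0))
      stop(what, " must be c(days, minutes/day), both non-negative")
    if (x[1] > 7) stop(what, ": days per week cannot exceed 7")
    x[1] * min(x[2], daily_cap)
  }
  8.0 * check(vigorous, "vigorous") +
    4.0 * check(moderate, "moderate") +
    3.3 * check(walking, "walking")
}

#' Default food-frequency scoring map
#'
#' A stand-in 9-item map awarding one point per food-recommendation-adherent
#' response; the exact indicator mapping used by national dietary surveys is
#' instrument specific, so this default is an editable configuration, not a
#' validated instrument.
#'
#' @return Named list: per item, a named numeric vector of points by category.
#' @export
default_food_score_map <- function() {
  yes_no <- c(adherent = 1, nonadherent = 0)
  items <- c("vegetables", "fruit", "fish", "wholegrain", "legumes",
             "nuts", "red_meat", "sugary_drinks", "salt")
  stats::setNames(rep(list(yes_no), length(items)), items)
}

#' Food-frequency adherence score (0-9)
#'
#' Sums per-item points (9 items, one point each for an adherent response),
#' giving a 0-9 diet-quality score with 9 the most adherent to food
#' recommendations.
#'
#' @param responses Named character vector: per item, the response category.
#' @param scoring_map Named list mapping each item to a named numeric vector of
#'   points per category; see [default_food_score_map()].
#' @return Integer score in 0..9.
#' @export
food_frequency_score <- function(responses, scoring_map = default_food_score_map()) {
  unknown <- setdiff(names(responses), names(scoring_map))
  if (length(unknown))
    stop("unknown item(s): ", paste(unknown, collapse = ", "))
  pts <- vapply(names(responses), function(item) {
    cat_map <- scoring_map[[item]]
    resp <- responses[[item]]
    if (!resp %in% names(cat_map))
      stop("unknown category '", resp, "' for item '", item, "'")
    cat_map[[resp]]
  }, numeric(1))
  score <- sum(pts)
  as.integer(min(max(score, 0), 9))
}

#' Insulin clearance as the fasting C-peptide-to-insulin ratio
#'
#' @param c_peptide Fasting C-peptide, nmol/l.
#' @param insulin Fasting insulin, mIE/l. Must be positive.
#' @return The ratio (nmol/l)/(mIE/l).
#' @examples
#' insulin_clearance(1.22, 18.9)
#' @export
insulin_clearance <- function(c_peptide, insulin) {
  if (any(insulin <= 0)) stop("insulin must be positive")
  c_peptide / insulin
}

#' Append derived indices to a participant table
#'
#' Computes HOMA-IR/HOMA-B, fatty liver index, C-peptide-to-insulin ratio and
#' Du Bois body surface area from the baseline (and, where present, week-12)
#' columns of a trial table and returns the table with the derived columns
#' appended.
#'
#' @param dataset A trial dataset, see [read_trial_table()].
#' @return The dataset with derived columns (`baseline_homa_ir`,
#'   `baseline_homa_b`, `baseline_fli`, `baseline_cpep_insulin_ratio`, `bsa`,
#'   and week-12 analogues where week-12 inputs are present).
#' @export
derive_indices <- function(dataset) {
  d <- as.data.frame(dataset)
  h <- homa_indices(d$baseline_glucose, d$baseline_insulin)
  d$baseline_homa_ir <- h$homa_ir
  d$baseline_homa_b <- h$homa_b
  d$baseline_fli <- fatty_liver_index(d$baseline_bmi, d$baseline_waist,
                                      d$baseline_triglycerides, d$baseline_ggt)
  d$baseline_cpep_insulin_ratio <-
    insulin_clearance(d$baseline_c_peptide, d$baseline_insulin)
  d$bsa <- bsa_du_bois(d$baseline_weight, d$baseline_height)
  ok <- !is.na(d$week12_glucose) & !is.na(d$week12_insulin)
  d$week12_homa_ir <- NA_real_
  d$week12_homa_b <- NA_real_
  if (any(ok)) {
    h12 <- homa_indices(d$week12_glucose[ok], d$week12_insulin[ok])
    d$week12_homa_ir[ok] <- h12$homa_ir
    d$week12_homa_b[ok] <- h12$homa_b
  }
  d
}
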