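#' Motor-subtype classification rule
#'
#' Thresholds on the ratio of mean tremor item score (11 UPDRS items) to mean
#' postural-instability/gait-difficulty item score (5 items): ratio >= 1.15
#' is tremor-dominant (TD), <= 0.9 is PIGD, strictly between is intermediate.
#'
#' @param td_threshold Lower bound (inclusive) of the TD class.
#' @param pigd_threshold Upper bound (inclusive) of the PIGD class.
#' @param n_tremor,n_pigd Expected item counts.
#' @return Object of class `subtype_rule`.
#' @export
subtype_rule <- function(td_threshold = 1.15, pigd_threshold = 0.9,
                         n_tremor = 11L, n_pigd = 5L) {
  if (!(pigd_threshold < td_threshold))
    stop("PIGD threshold must be below the TD threshold")
  if (n_tremor < 1L || n_pigd < 1L) stop("item counts must be positive")
  structure(list(td_threshold = td_threshold,
                 pigd_threshold = pigd_threshold,
                 n_tremor = as.integer(n_tremor),
                 n_pigd = as.integer(n_pigd)),
            class = "subtype_rule")
}

#' Classify motor subtype from UPDRS item scores
#'
#' @param tremor_items Numeric vector of tremor item scores (length 11).
#' @param pigd_items Numeric vector of PIGD item scores (length 5).
#' @param rule A [subtype_rule()].
#' @return List with `subtype` ("TD", "PIGD" or "intermediate") and `ratio`.
#'   A zero PIGD mean with positive tremor mean gives ratio Inf, hence TD;
#'   both means zero is unclassifiable and errors.
#' @export
classify_motor_subtype <- function(tremor_items, pigd_items,
                                   rule = subtype_rule()) {
  if (length(tremor_items) != rule$n_tremor)
    stop("expected ", rule$n_tremor, " tremor items, got ",
         length(tremor_items))
  if (length(pigd_items) != rule$n_pigd)
    stop("expected ", rule$n_pigd, " PIGD items, got ", length(pigd_items))
  if (any(tremor_items < 0) || any(pigd_items < 0))
    stop("item scores must be non-negative")
  mt <- mean(tremor_items); mp <- mean(pigd_items)
  if (mt == 0 && mp == 0)
    stop("unclassifiable: both tremor and PIGD mean scores are zero")
  ratio <- mt / mp   # Inf when mp == 0, mt > 0
  subtype <- if (ratio >= rule$td_threshold) "TD"
             else if (ratio <= rule$pigd_threshold) "PIGD"
             else "intermediate"
  list(subtype = subtype, ratio = ratio)
}

#' Disease-stage rule by duration
#'
#' Early is strictly less than 2 years, late strictly more than 6 years, and
#' "2 to 6 years" is read as the closed interval (both boundaries middle).
#'
#' @param early_max Exclusive upper bound of the early stage (years).
#' @param late_min Exclusive lower bound of the late stage (years).
#' @return Object of class `stage_rule`.
#' @export
stage_rule <- function(early_max = 2, late_min = 6) {
  if (!(early_max < late_min))
    stop("early bound must be below the late bound")
  structure(list(early_max = early_max, late_min = late_min),
            class = "stage_rule")
}

#' Assign disease stage from duration
#'
#' @param duration_years Numeric vector of disease durations (years, >= 0).
#' @param rule A [stage_rule()].
#' @return Character vector: "early", "middle" or "late".
#' @export
assign_stage <- function(duration_years, rule = stage_rule()) {
  if (any(is.na(duration_years)) || any(duration_years < 0))
    stop("disease duration must be non-negative and non-missing")
  ifelse(duration_years < rule$early_max, "early",
         ifelse(duration_years > rule$late_min, "late", "middle"))
}

#' Lateralize hemispheric measures into more-/less-affected sides
#'
#' For patients, the more-affected side (MAS) is the hemisphere contralateral
#' to the body side of first motor symptoms (onset on the right implies the
#' left hemisphere is MAS); for controls, the dominant side (DS) is the
#' hemisphere contralateral to the dominant hand. The operation only permutes
#' the two hemisphere values; it never alters them.
#'
#' @param left_value,right_value Hemisphere measurements (scalars or equal-
#'   length vectors).
#' @param side "R" or "L": onset body side for patients, dominant hand for
#'   controls.
#' @param is_patient Logical; controls get DS/nDS naming.
#' @return List with `mas` and `las` (or `ds`/`nds` aliases for controls),
#'   plus `mas_hemisphere` recording the mapping.
#' @export
lateralize_measures <- function(left_value, right_value, side,
                                is_patient = TRUE) {
  if (is.na(side) || !side %in% c("R", "L"))
    stop("missing or invalid side label (need \"R\" or \"L\")")
  mas_hemi <- if (side == "R") "L" else "R"
  mas <- if (mas_hemi == "L") left_value else right_value
  las <- if (mas_hemi == "L") right_value else left_value
  out <- list(mas = mas, las = las, mas_hemisphere = mas_hemi)
  if (!is_patient) { out$ds <- mas; out$nds <- las }
  out
}
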