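#' Left-ventricular volume by the ellipsoid model
#'
#' V = (pi/6) * L * D^2 with one long-axis length L (apex to aortic root) and
#' one transverse diameter D, both in mm; the result in mm^3 is reported as
#' microlitres (1 mm^3 = 1 ul). An optional second transverse diameter gives
#' the two-diameter ellipsoid (pi/6 * L * D1 * D2).
#'
#' @param long_axis long-axis length, mm (> 0).
#' @param transverse transverse diameter, mm (> 0).
#' @param transverse2 optional second transverse diameter, mm; defaults to
#'   `transverse` (prolate spheroid).
#' @return volume in microlitres.
#' @export
ellipsoid_volume <- function(long_axis, transverse, transverse2 = transverse) {
  if (any(!is.finite(long_axis)) || any(!is.finite(transverse)) ||
      any(long_axis <= 0) || any(transverse <= 0) || any(transverse2 <= 0))
    stop("ellipsoid_volume: all dimensions must be finite and > 0")
  pi / 6 * long_axis * transverse * transverse2
}

#' Stroke volume
#'
#' SV = LVEDV - LVESV (ul). A negative result is returned as-is with a
#' warning (it flags inconsistent measurements, it is not clamped).
#'
#' @param lvedv,lvesv end-diastolic and end-systolic volume, ul (>= 0).
#' @return stroke volume, ul.
#' @export
stroke_volume <- function(lvedv, lvesv) {
  if (any(lvedv < 0) || any(lvesv < 0)) stop("volumes must be >= 0")
  sv <- lvedv - lvesv
  if (any(sv < 0)) warning("negative stroke volume: LVESV exceeds LVEDV")
  sv
}

#' Cardiac output
#'
#' CO = SV * HR, converted from ul/min to ml/min.
#'
#' @param sv stroke volume, ul.
#' @param heart_rate beats per minute (> 0).
#' @return cardiac output, ml/min.
#' @export
cardiac_output <- function(sv, heart_rate) {
  if (any(!is.finite(heart_rate)) || any(heart_rate <= 0))
    stop("heart rate must be finite and > 0")
  sv * heart_rate / 1000
}

#' Ejection fraction
#'
#' EF = 100 * (LVEDV - LVESV) / LVEDV, percent. Can be negative when LVESV
#' exceeds LVEDV (flagged upstream); never exceeds 100 for non-negative
#' LVESV.
#'
#' @param lvedv end-diastolic volume, ul (> 0).
#' @param lvesv end-systolic volume, ul (>= 0).
#' @return ejection fraction, percent.
#' @export
ejection_fraction <- function(lvedv, lvesv) {
  if (any(lvedv <= 0)) stop("LVEDV must be > 0")
  100 * (lvedv - lvesv) / lvedv
}

#' Left-ventricular mass by the cube-law (Devereux-type) formula
#'
#' mass = k * [(AWTd + PWTd + LVEDD)^3 - LVEDD^3], lengths in mm, mass in mg.
#' The multiplicative constant k defaults to 1.053 (myocardial density
#' convention in rodent echo, mg/mm^3 scale) and is exposed because the
#' convention varies between labs.
#'
#' @param awtd,pwtd diastolic anterior/posterior wall thickness, mm (>= 0).
#' @param lvedd end-diastolic diameter, mm (> 0).
#' @param k density constant, mg/mm^3.
#' @return LV mass, mg.
#' @export
devereux_mass <- function(awtd, pwtd, lvedd, k = 1.053) {
  if (any(awtd < 0) || any(pwtd < 0) || any(lvedd <= 0))
    stop("wall thicknesses must be >= 0 and LVEDD > 0")
  k * ((awtd + pwtd + lvedd)^3 - lvedd^3)
}

#' Organ-weight-to-tibial-length ratio
#'
#' @param weight organ weight (g), >= 0.
#' @param tibial_length tibial length (mm), > 0.
#' @return ratio, g/mm.
#' @export
organ_ratio <- function(weight, tibial_length) {
  if (any(weight < 0)) stop("weight must be >= 0")
  if (any(!is.finite(tibial_length)) || any(tibial_length <= 0))
    stop("tibial length must be > 0")
  weight / tibial_length
}

#' Assign an animal to a study arm
#'
#' Sham surgery always labels Sham. Banded survivors with terminal (week-12)
#' EF below the cutoff are heart-failure (AB_HF); at or above the cutoff,
#' compensated hypertrophy (AB_LVH). Non-survivors, or banded survivors with
#' missing terminal EF, are excluded (with the reason attached as an
#' attribute on the vectorized result).
#'
#' @param surgery "sham" or "AB" (vectorized).
#' @param survived logical, survived to terminal follow-up.
#' @param week12_ef terminal ejection fraction, percent; NA if missing.
#' @param ef_cutoff inclusion threshold for heart failure, percent
#'   (strict `<`).
#' @return character vector in {"Sham","AB_LVH","AB_HF","excluded"}.
#' @export
assign_group <- function(surgery, survived, week12_ef, ef_cutoff = 30) {
  if (!all(surgery %in% c("sham", "AB"))) stop("surgery must be sham or AB")
  n <- max(length(surgery), length(survived), length(week12_ef))
  surgery <- rep_len(surgery, n)
  survived <- rep_len(survived, n)
  week12_ef <- rep_len(week12_ef, n)
  out <- character(n)
  reason <- character(n)
  for (i in seq_len(n)) {
    if (!isTRUE(survived[i])) {
      out[i] <- "excluded"; reason[i] <- "did not survive follow-up"
    } else if (surgery[i] == "sham") {
      out[i] <- "Sham"
    } else if (is.na(week12_ef[i])) {
      out[i] <- "excluded"; reason[i] <- "missing terminal EF"
    } else if (week12_ef[i] < ef_cutoff) {
      out[i] <- "AB_HF"
    } else {
      out[i] <- "AB_LVH"
    }
  }
  structure(out, exclusion_reason = reason)
}

#' Compute derived cardiac indices for an echo measurement table
#'
#' Consumes one row per animal per week of raw measurements (as produced by
#' [generate_echo()] or read from TSV) and computes, per row: LVEDV and LVESV
#' by the ellipsoid model, SV, CO, EF, LV mass, and (where necropsy columns
#' are present) HW/TL and LW/TL. Group labels are re-derived from surgery and
#' terminal EF via [assign_group()]. Output units are declared in the column
#' names (volumes ul, CO ml/min, EF percent, LV mass mg, ratios g/mm).
#'
#' @param echo data.frame with columns animal_id, group, week, surgery,
#'   heart_rate, AWTd, PWTd, LVEDD, LVESD, long_axis_d, long_axis_s and
#'   optionally heart_weight, lung_weight, tibial_length.
#' @param ef_cutoff heart-failure EF threshold, percent.
#' @param devereux_k density constant passed to [devereux_mass()].
#' @return data.frame of per-row derived indices plus an `assigned_group`
#'   column (terminal assignment, repeated across the animal's rows).
#' @export
phenotype_table <- function(echo, ef_cutoff = 30, devereux_k = 1.053) {
  need <- c("animal_id", "week", "surgery", "heart_rate", "AWTd", "PWTd",
            "LVEDD", "LVESD", "long_axis_d", "long_axis_s")
  miss <- setdiff(need, names(echo))
  if (length(miss)) stop("echo table missing columns: ",
                         paste(miss, collapse = ", "))
  lvedv <- ellipsoid_volume(echo$long_axis_d, echo$LVEDD)
  lvesv <- ellipsoid_volume(echo$long_axis_s, echo$LVESD)
  sv <- suppressWarnings(stroke_volume(lvedv, lvesv))
  out <- data.frame(
    animal_id = echo$animal_id, week = echo$week,
    LVEDV_ul = lvedv, LVESV_ul = lvesv, SV_ul = sv,
    CO_ml_min = cardiac_output(sv, echo$heart_rate),
    EF_pct = ejection_fraction(lvedv, lvesv),
    LV_mass_mg = devereux_mass(echo$AWTd, echo$PWTd, echo$LVEDD,
                               k = devereux_k),
    stringsAsFactors = FALSE)
  if (all(c("heart_weight", "lung_weight", "tibial_length") %in% names(echo))) {
    has <- is.finite(echo$tibial_length)
    out$HW_TL_g_mm <- out$LW_TL_g_mm <- NA_real_
    out$HW_TL_g_mm[has] <- organ_ratio(echo$heart_weight[has],
                                       echo$tibial_length[has])
    out$LW_TL_g_mm[has] <- organ_ratio(echo$lung_weight[has],
                                       echo$tibial_length[has])
  }
  term <- out[out$week == 12, ]
  ef12 <- stats::setNames(term$EF_pct, term$animal_id)
  surg <- stats::setNames(echo$surgery, echo$animal_id)[names(ef12)]
  lab <- assign_group(unname(surg), TRUE, unname(ef12), ef_cutoff = ef_cutoff)
  out$assigned_group <- stats::setNames(lab, names(ef12))[out$animal_id]
  out
}

#' Randomly subsample one arm to a target size
#'
#' Seeded sampling without replacement, used to balance an oversized
#' compensated-hypertrophy arm against the other arms.
#'
#' @param ids candidate animal ids.
#' @param n target size (<= length(ids)).
#' @param seed RNG seed.
#' @return character vector of retained ids, in original order.
#' @export
subsample_arm <- function(ids, n, seed = 1L) {
  if (n > length(ids)) stop("cannot subsample ", length(ids), " ids to ", n)
  set.seed(seed)
  keep <- sample(ids, n)
  ids[ids %in% keep]
}
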