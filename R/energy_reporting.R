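# Schofield BMR coefficients, MJ/d = a * weight_kg + b, adult age bands.
.schofield <- data.frame(
  sex = rep(c("female", "male"), each = 3),
  age_lo = rep(c(18, 30, 60), 2),
  age_hi = rep(c(30, 60, Inf), 2),
  a = c(0.062, 0.034, 0.038, 0.063, 0.048, 0.049),
  b = c(2.036, 3.538, 2.755, 2.896, 3.653, 2.459),
  stringsAsFactors = FALSE
)

#' Schofield basal metabolic rate
#'
#' Adult Schofield weight-based equations; age bands 18-30, 30-60 and 60+
#' years (the 30- and 60-year boundaries belong to the older band).
#'
#' @param sex `"female"` or `"male"`.
#' @param age years (>= 18).
#' @param weight_kg body weight, kg (> 0).
#' @return BMR in kJ/d.
#' @examples
#' bmr_schofield("female", 45, 70)  # (0.034*70 + 3.538) MJ/d = 5918 kJ/d
#' @export
bmr_schofield <- function(sex, age, weight_kg) {
  n <- max(length(sex), length(age), length(weight_kg))
  sex <- rep_len(as.character(sex), n)
  age <- rep_len(age, n)
  weight_kg <- rep_len(weight_kg, n)
  if (any(weight_kg <= 0, na.rm = TRUE)) {
    stop("weight must be strictly positive", call. = FALSE)
  }
  if (any(age < 18, na.rm = TRUE)) {
    stop("unsupported age band: adult equations require age >= 18",
         call. = FALSE)
  }
  if (!all(sex %in% .schofield$sex)) {
    stop("sex must be 'female' or 'male'", call. = FALSE)
  }
  idx <- vapply(seq_len(n), function(i) {
    which(.schofield$sex == sex[i] & age[i] >= .schofield$age_lo &
            age[i] < .schofield$age_hi)[1]
  }, integer(1))
  1000 * (.schofield$a[idx] * weight_kg + .schofield$b[idx])
}

#' Goldberg confidence limits for the EI/BMR ratio
#'
#' The plausibility band around an assumed physical activity level:
#' `PAL * exp(+- z * s / (100 * sqrt(n)))` with
#' `s = sqrt(cv_ei^2 / n_days + cv_bmr^2 + cv_pal^2)`.
#'
#' @param pal assumed physical activity level (default 1.55, sedentary to
#'   lightly active adults).
#' @param cv_ei,cv_bmr,cv_pal within-subject coefficient of variation (%) of
#'   energy intake (23), of BMR (8.5), and between-subject variation of PAL
#'   (15).
#' @param n_days diet-assessment days; a one-month recall is treated as a
#'   single observation (1).
#' @param n subjects per evaluation unit (1 for individual classification).
#' @param z normal quantile (1.96 for 95% limits).
#' @return named vector `c(lower, upper)`.
#' @export
goldberg_limits <- function(pal = 1.55, cv_ei = 23, cv_bmr = 8.5,
                            cv_pal = 15, n_days = 1, n = 1, z = 1.96) {
  s <- sqrt(cv_ei^2 / n_days + cv_bmr^2 + cv_pal^2)
  hw <- z * s / (100 * sqrt(n))
  c(lower = pal * exp(-hw), upper = pal * exp(hw))
}

#' Classify energy-intake reporting plausibility
#'
#' Goldberg/Black classification of each subject: the ratio of reported
#' energy intake to basal metabolic rate is compared with confidence limits
#' around the assumed physical activity level; below the lower limit is
#' under-reporting, above the upper limit over-reporting, else plausible.
#'
#' @param energy_kj reported energy intake, kJ/d.
#' @param bmr_kj basal metabolic rate, kJ/d (> 0), e.g. from
#'   [bmr_schofield()].
#' @inheritParams goldberg_limits
#' @return data.frame: `bmr_kj`, `ei_bmr_ratio`, `status` (factor
#'   under/plausible/over), `lower`, `upper`.
#' @export
goldberg_classify <- function(energy_kj, bmr_kj, pal = 1.55, cv_ei = 23,
                              cv_bmr = 8.5, cv_pal = 15, n_days = 1,
                              z = 1.96) {
  if (any(bmr_kj <= 0, na.rm = TRUE)) {
    stop("bmr_kj must be strictly positive", call. = FALSE)
  }
  if (any(energy_kj <= 0, na.rm = TRUE)) {
    stop("energy_kj must be strictly positive", call. = FALSE)
  }
  lim <- goldberg_limits(pal = pal, cv_ei = cv_ei, cv_bmr = cv_bmr,
                         cv_pal = cv_pal, n_days = n_days, z = z)
  ratio <- energy_kj / bmr_kj
  status <- factor(ifelse(ratio < lim["lower"], "under",
                          ifelse(ratio > lim["upper"], "over", "plausible")),
                   levels = c("under", "plausible", "over"))
  data.frame(bmr_kj = bmr_kj, ei_bmr_ratio = ratio, status = status,
             lower = unname(lim["lower"]), upper = unname(lim["upper"]))
}

#' Add reporting status to a study's participant table
#'
#' Computes Schofield BMR from the participant anthropometry (all-female
#' study population by default) and classifies each subject's reported
#' energy intake.
#'
#' @param study a [safbdg_study()].
#' @param sex sex used for the BMR equations.
#' @inheritParams goldberg_limits
#' @return the participant table with `bmr_kj`, `ei_bmr_ratio` and
#'   `reporting_status` columns appended.
#' @export
classify_reporting <- function(study, sex = "female", pal = 1.55,
                               cv_ei = 23, cv_bmr = 8.5, cv_pal = 15,
                               n_days = 1) {
  p <- study$participants
  nu <- study$nutrients[match(p$subject_id, study$nutrients$subject_id), ]
  bmr <- bmr_schofield(sex, p$age, p$weight_kg)
  cls <- goldberg_classify(nu$energy_kj, bmr, pal = pal, cv_ei = cv_ei,
                           cv_bmr = cv_bmr, cv_pal = cv_pal, n_days = n_days)
  p$bmr_kj <- cls$bmr_kj
  p$ei_bmr_ratio <- cls$ei_bmr_ratio
  p$reporting_status <- cls$status
  p
}
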