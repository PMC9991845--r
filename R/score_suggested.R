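#' Default suggested adherence cut-points
#'
#' The published cut-points behind each SAFBDG recommendation, in the units
#' of the exposures from [aggregate_groups()]. All are configurable; the
#' defaults are: diversity score >= 4; >= 10 starchy units/d (anchored to an
#' 8500 kJ/d reference intake, applied as absolute units); >= 400 g/d fruit
#' and vegetables; >= 21.4 g/d legumes; >= 400 g/d milk/maas/yoghurt or
#' >= 50 g/d hard cheese; fish/chicken/lean meat above zero and under 90 g/d;
#' eggs >= 200/7 g/d (four 50 g eggs per week); total fat within 20-30 %TE;
#' saturated fat < 10 %TE; added sugar < 6 %TE for full and < 10 %TE for
#' partial credit. Ties at a cut-point follow the wording of each rule:
#' adherent for ">="-phrased rules, non-adherent for strict "<" rules.
#'
#' @return named list of cut-points.
#' @export
suggested_cuts <- function() {
  list(
    dds_min = 4,
    starchy_units_min = 10,
    fruitveg_min_g = 400,
    legume_min_g = 21.4,
    dairy_liquid_min_g = 400,
    cheese_min_g = 50,
    meat_max_g = 90,           # strictly below; strictly above zero
    egg_min_g = 200 / 7,       # 4 eggs/week x 50 g
    fat_lo_pct = 20, fat_hi_pct = 30,
    sfa_max_pct = 10,          # strictly below
    sugar_full_pct = 6,        # strictly below -> 1 point
    sugar_partial_pct = 10     # strictly below -> 0.5 point
  )
}

.guidelines <- c("variety", "active", "starchy", "fruitveg", "legumes",
                 "dairy", "protein", "fats", "sugar")

#' Score one SAFBDG recommendation against suggested cut-points
#'
#' Components are 0/1 for single-rule recommendations; the two
#' sub-recommendation guidelines (`protein`: fish/chicken/lean-meat and eggs;
#' `fats`: total-fat range and saturated fat) award 0.5 per satisfied sub;
#' `sugar` awards 1 below 6 %TE, 0.5 below 10 %TE, else 0.
#'
#' @param guideline_id one of `"variety"`, `"active"`, `"starchy"`,
#'   `"fruitveg"`, `"legumes"`, `"dairy"`, `"protein"`, `"fats"`, `"sugar"`.
#' @param exposures data.frame from [aggregate_groups()].
#' @param participants participant table (for the `pa_active` flag).
#' @param cuts cut-point list, default [suggested_cuts()].
#' @return numeric component score per subject.
#' @export
score_guideline_suggested <- function(guideline_id, exposures, participants,
                                      cuts = suggested_cuts()) {
  fg <- exposures
  p <- participants[match(fg$subject_id, participants$subject_id), ]
  switch(
    guideline_id,
    variety = as.numeric(fg$dds >= cuts$dds_min),
    active = as.numeric(p$pa_active %in% TRUE),
    starchy = as.numeric(fg$starchy_units >= cuts$starchy_units_min),
    fruitveg = as.numeric(fg$fruitveg_g >= cuts$fruitveg_min_g),
    legumes = as.numeric(fg$legume_g >= cuts$legume_min_g),
    dairy = as.numeric(fg$dairy_liquid_g >= cuts$dairy_liquid_min_g |
                         fg$cheese_g >= cuts$cheese_min_g),
    protein = 0.5 * (fg$fcl_meat_g > 0 & fg$fcl_meat_g < cuts$meat_max_g) +
      0.5 * (fg$egg_g >= cuts$egg_min_g),
    fats = 0.5 * (fg$fat_pct_te >= cuts$fat_lo_pct &
                    fg$fat_pct_te <= cuts$fat_hi_pct) +
      0.5 * (fg$sfa_pct_te < cuts$sfa_max_pct),
    sugar = ifelse(fg$sugar_pct_te < cuts$sugar_full_pct, 1,
                   ifelse(fg$sugar_pct_te < cuts$sugar_partial_pct, 0.5, 0)),
    stop("unknown guideline: ", guideline_id, call. = FALSE)
  )
}

#' Overall suggested-scheme adherence scores
#'
#' Sums the nine recommendation components (maximum 9) and flags subjects
#' adhering to at least half of the guidelines (overall score > 4.5).
#'
#' @inheritParams score_guideline_suggested
#' @return data.frame: `subject_id`, one column per guideline, sub-rule
#'   columns (`protein_meat_sub`, `protein_egg_sub`, `fats_range_sub`,
#'   `fats_sfa_sub`, each 0/0.5), `overall` and `half_adherent`.
#' @export
score_suggested <- function(exposures, participants, cuts = suggested_cuts()) {
  fg <- exposures
  p <- participants[match(fg$subject_id, participants$subject_id), ]
  comp <- sapply(.guidelines, score_guideline_suggested,
                 exposures = fg, participants = participants, cuts = cuts)
  if (is.null(dim(comp))) comp <- matrix(comp, nrow = 1,
                                         dimnames = list(NULL, .guidelines))
  out <- data.frame(subject_id = fg$subject_id, comp,
                    stringsAsFactors = FALSE)
  out$protein_meat_sub <-
    0.5 * (fg$fcl_meat_g > 0 & fg$fcl_meat_g < cuts$meat_max_g)
  out$protein_egg_sub <- 0.5 * (fg$egg_g >= cuts$egg_min_g)
  out$fats_range_sub <- 0.5 * (fg$fat_pct_te >= cuts$fat_lo_pct &
                                 fg$fat_pct_te <= cuts$fat_hi_pct)
  out$fats_sfa_sub <- 0.5 * (fg$sfa_pct_te < cuts$sfa_max_pct)
  out$overall <- rowSums(comp)
  out$half_adherent <- out$overall > 4.5
  out
}

#' Adherence prevalence by study arm
#'
#' Tabulates the percentage of cases and of controls adhering to each
#' recommendation (and sub-recommendation), plus the percentage adhering to
#' at least half of the guidelines (overall score > 4.5), in the layout of
#' the study's level-of-adherence table.
#'
#' @param scores data.frame from [score_suggested()].
#' @param participants participant table carrying `status`.
#' @return data.frame with `item`, `pct_cases`, `pct_controls`.
#' @export
adherence_prevalence <- function(scores, participants) {
  st <- participants$status[match(scores$subject_id,
                                  participants$subject_id)]
  if (!all(.status_levels %in% st)) {
    stop("both arms (case and control) must be non-empty", call. = FALSE)
  }
  rows <- list(
    variety = scores$variety == 1,
    active = scores$active == 1,
    starchy = scores$starchy == 1,
    fruitveg = scores$fruitveg == 1,
    legumes = scores$legumes == 1,
    dairy = scores$dairy == 1,
    protein_meat_sub = scores$protein_meat_sub == 0.5,
    protein_egg_sub = scores$protein_egg_sub == 0.5,
    fats_range_sub = scores$fats_range_sub == 0.5,
    fats_sfa_sub = scores$fats_sfa_sub == 0.5,
    sugar_full = scores$sugar == 1,
    sugar_partial = scores$sugar == 0.5,
    overall_half = scores$half_adherent
  )
  pct <- function(flag, arm) 100 * mean(flag[st == arm])
  data.frame(
    item = names(rows),
    pct_cases = vapply(rows, pct, numeric(1), arm = "case"),
    pct_controls = vapply(rows, pct, numeric(1), arm = "control"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
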