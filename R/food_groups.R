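# Energy conversion factors, kJ per gram (Atwater, kJ basis).
.kj_per_g <- c(fat = 37, sfa = 37, added_sugar = 17)

#' Percent of total energy contributed by a nutrient
#'
#' @param nutrient_g grams/day of the nutrient (nonnegative).
#' @param kj_per_g energy density, kJ per gram (fat and saturated fat 37,
#'   added sugar 17).
#' @param energy_kj total energy intake, kJ/day (positive).
#' @return percentage of total energy.
#' @examples
#' pct_total_energy(50, 17, 8500)  # added sugar at exactly 10 %TE
#' @export
pct_total_energy <- function(nutrient_g, kj_per_g, energy_kj) {
  if (any(nutrient_g < 0, na.rm = TRUE)) {
    stop("nutrient grams must be nonnegative", call. = FALSE)
  }
  if (any(energy_kj <= 0, na.rm = TRUE)) {
    stop("energy_kj must be positive", call. = FALSE)
  }
  100 * nutrient_g * kj_per_g / energy_kj
}

#' Dietary diversity score over the nine FAO food groups
#'
#' Counts the FAO groups consumed at or above a minimum daily amount. The
#' score ranges 0-9; below 4 is flagged as low dietary diversity.
#'
#' @param fao_grams numeric matrix (subjects x 9 groups) or a length-9 vector
#'   of group totals in g/d.
#' @param threshold_g minimum g/d for a group to count (default 15, the
#'   conventional minimum-intake rule; configurable).
#' @return data.frame with integer `dds` and logical `low_diversity`.
#' @export
compute_dds <- function(fao_grams, threshold_g = 15) {
  if (is.null(dim(fao_grams))) fao_grams <- matrix(fao_grams, nrow = 1)
  stopifnot(ncol(fao_grams) == 9)
  dds <- as.integer(rowSums(fao_grams >= threshold_g))
  data.frame(dds = dds, low_diversity = dds < 4L)
}

#' Aggregate item intakes into SAFBDG exposures
#'
#' Collapses item-level g/d intakes into the exposures the adherence rules
#' consume: grams per scored SAFBDG group, starchy food-guide units
#' (item grams divided by the item's unit weight, summed), the FAO dietary
#' diversity score, and fat/saturated-fat/added-sugar as percent of total
#' energy.
#'
#' @param study a [safbdg_study()].
#' @param mapping a [group_mapping()] covering every intake item.
#' @param dds_threshold_g minimum g/d for a FAO group to count toward the
#'   diversity score.
#' @return data.frame, one row per subject: `subject_id`, `fruitveg_g`,
#'   `legume_g`, `dairy_liquid_g`, `cheese_g`, `fcl_meat_g`, `egg_g`,
#'   `starchy_units`, `dds`, `low_diversity`, `fat_pct_te`, `sfa_pct_te`,
#'   `sugar_pct_te`.
#' @export
aggregate_groups <- function(study, mapping, dds_threshold_g = 15) {
  stopifnot(inherits(study, "safbdg_study"), inherits(mapping, "group_mapping"))
  item_cols <- setdiff(names(study$intakes), "subject_id")
  check_mapping_coverage(mapping, item_cols, action = "error")
  im <- as.matrix(study$intakes[item_cols])
  rownames(im) <- study$intakes$subject_id
  map <- mapping$items[match(item_cols, mapping$items$item_id), ]

  grp_sum <- function(flag) {
    sel <- map$group == flag
    if (!any(sel)) return(rep(0, nrow(im)))
    rowSums(im[, sel, drop = FALSE])
  }
  fruitveg_g <- grp_sum("fruit_veg")
  legume_g <- grp_sum("legume")
  dairy_liquid_g <- grp_sum("dairy_liquid")
  cheese_g <- grp_sum("hard_cheese")
  fcl_meat_g <- grp_sum("fish_chicken_leanmeat")
  egg_g <- grp_sum("egg")

  st <- map$group == "starchy"
  starchy_units <- if (any(st)) {
    rowSums(sweep(im[, st, drop = FALSE], 2, map$starchy_unit_g[st], "/"))
  } else rep(0, nrow(im))

  fao <- sapply(1:9, function(g) {
    sel <- !is.na(map$dds_group) & map$dds_group == g
    if (!any(sel)) rep(0, nrow(im)) else rowSums(im[, sel, drop = FALSE])
  })
  if (is.null(dim(fao))) fao <- matrix(fao, nrow = 1)
  dds <- compute_dds(fao, threshold_g = dds_threshold_g)

  nu <- study$nutrients[match(rownames(im), study$nutrients$subject_id), ]
  if (any(nu$energy_kj <= 0)) stop("energy_kj must be positive", call. = FALSE)
  out <- data.frame(
    subject_id = rownames(im),
    fruitveg_g = fruitveg_g,
    legume_g = legume_g,
    dairy_liquid_g = dairy_liquid_g,
    cheese_g = cheese_g,
    fcl_meat_g = fcl_meat_g,
    egg_g = egg_g,
    starchy_units = starchy_units,
    dds = dds$dds,
    low_diversity = dds$low_diversity,
    fat_pct_te = pct_total_energy(nu$fat_g, .kj_per_g[["fat"]], nu$energy_kj),
    sfa_pct_te = pct_total_energy(nu$sfa_g, .kj_per_g[["sfa"]], nu$energy_kj),
    sugar_pct_te = pct_total_energy(nu$added_sugar_g,
                                    .kj_per_g[["added_sugar"]], nu$energy_kj),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out
}
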