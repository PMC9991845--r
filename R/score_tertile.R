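# Sub-recommendation metrics entering the tertile scheme, with the direction
# in which larger values mean better compliance. The fat-range metric is the
# distance outside the 20-30 %TE band (0 inside the band).
.tertile_metrics <- data.frame(
  metric = c("variety", "active", "starchy", "fruitveg", "legumes", "dairy",
             "meat_sub", "egg_sub", "fat_sub", "sfa_sub", "sugar"),
  orientation = c("higher", "higher", "higher", "higher", "higher", "higher",
                  "lower", "higher", "lower", "lower", "lower"),
  guideline = c("variety", "active", "starchy", "fruitveg", "legumes",
                "dairy", "protein", "protein", "fats", "fats", "sugar"),
  stringsAsFactors = FALSE
)

#' Continuous compliance metrics for the tertile scoring scheme
#'
#' For each (sub-)recommendation, the continuous quantity whose
#' control-distribution tertiles define the data-driven cut-points:
#' diversity score, physical-activity measure, starchy units, group grams
#' (dairy counts liquid dairy plus hard cheese), meat grams (lower is
#' better), egg grams, distance of total fat outside the 20-30 %TE band
#' (lower is better), saturated fat %TE and added sugar %TE (lower is
#' better).
#'
#' @inheritParams score_guideline_suggested
#' @return data.frame of metrics, one row per subject; orientations are kept
#'   in `attr(, "orientation")`.
#' @export
compliance_metrics <- function(exposures, participants,
                               cuts = suggested_cuts()) {
  fg <- exposures
  p <- participants[match(fg$subject_id, participants$subject_id), ]
  out <- data.frame(
    subject_id = fg$subject_id,
    variety = as.numeric(fg$dds),
    active = as.numeric(p$pa_metric),
    starchy = fg$starchy_units,
    fruitveg = fg$fruitveg_g,
    legumes = fg$legume_g,
    dairy = fg$dairy_liquid_g + fg$cheese_g,
    meat_sub = fg$fcl_meat_g,
    egg_sub = fg$egg_g,
    fat_sub = pmax(0, cuts$fat_lo_pct - fg$fat_pct_te) +
      pmax(0, fg$fat_pct_te - cuts$fat_hi_pct),
    sfa_sub = fg$sfa_pct_te,
    sugar = fg$sugar_pct_te,
    stringsAsFactors = FALSE
  )
  attr(out, "orientation") <- stats::setNames(.tertile_metrics$orientation,
                                              .tertile_metrics$metric)
  out
}

#' Derive data-driven tertile cut-points from controls
#'
#' Empirical 33rd and 66th percentiles (i.e. the 1/3 and 2/3 quantiles,
#' linear interpolation between order statistics, `stats::quantile` type 7)
#' of each compliance metric among control participants only.
#'
#' @param metrics_controls metrics data.frame from [compliance_metrics()]
#'   restricted to controls.
#' @return data.frame: `metric`, `orientation`, `q33`, `q66`. A metric that
#'   is constant among controls yields a degenerate-cut-point warning.
#' @export
derive_cutpoints <- function(metrics_controls) {
  cols <- intersect(.tertile_metrics$metric, names(metrics_controls))
  out <- lapply(cols, function(mname) {
    v <- metrics_controls[[mname]]
    v <- v[is.finite(v)]
    if (length(v) < 3) {
      stop("need at least 3 controls with a finite '", mname, "' metric",
           call. = FALSE)
    }
    q <- unname(stats::quantile(v, c(1 / 3, 2 / 3), type = 7))
    if (q[1] == q[2]) {
      warning("degenerate tertile cut-points for metric '", mname,
              "' (both bounds equal ", format(q[1]), ")", call. = FALSE)
    }
    data.frame(metric = mname,
               orientation = .tertile_metrics$orientation[
                 .tertile_metrics$metric == mname],
               q33 = q[1], q66 = q[2], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Tertile class of one metric: 0 = lowest-adherence tertile, 0.5 = middle,
# 1 = highest. Ties at a cut-point fall to the lower-adherence side.
.tertile_score <- function(m, q33, q66, orientation) {
  s <- rep(NA_real_, length(m))
  ok <- is.finite(m)
  if (orientation == "higher") {
    s[ok] <- ifelse(m[ok] <= q33, 0, ifelse(m[ok] <= q66, 0.5, 1))
  } else {
    s[ok] <- ifelse(m[ok] >= q66, 0, ifelse(m[ok] >= q33, 0.5, 1))
  }
  s
}

#' Score subjects under the data-driven tertile scheme
#'
#' Each recommendation scores 1 in its highest-adherence tertile, 0.5 in the
#' middle and 0 in the lowest. The two fats sub-recommendations and the two
#' protein-food sub-recommendations are scored individually, halved
#' (0/0.25/0.5) and summed into their guideline, so every recommendation
#' contributes at most 1 point and the overall score lies in [0, 9].
#'
#' @param metrics metrics data.frame from [compliance_metrics()] for the
#'   subjects to score.
#' @param cutpoints cut-points from [derive_cutpoints()] (controls only).
#' @return data.frame: `subject_id`, the four halved sub columns, one column
#'   per guideline, and `overall`. Subjects with a non-finite metric carry NA
#'   for that component (and hence for the overall score).
#' @export
score_tertile <- function(metrics, cutpoints) {
  sc <- sapply(cutpoints$metric, function(mname) {
    r <- cutpoints[cutpoints$metric == mname, ]
    .tertile_score(metrics[[mname]], r$q33, r$q66, r$orientation)
  })
  if (is.null(dim(sc))) sc <- matrix(sc, nrow = 1,
                                     dimnames = list(NULL, cutpoints$metric))
  out <- data.frame(subject_id = metrics$subject_id,
                    stringsAsFactors = FALSE)
  out$protein_meat_sub <- sc[, "meat_sub"] / 2
  out$protein_egg_sub <- sc[, "egg_sub"] / 2
  out$fats_range_sub <- sc[, "fat_sub"] / 2
  out$fats_sfa_sub <- sc[, "sfa_sub"] / 2
  for (g in c("variety", "active", "starchy", "fruitveg", "legumes",
              "dairy", "sugar")) {
    out[[g]] <- sc[, g]
  }
  out$protein <- out$protein_meat_sub + out$protein_egg_sub
  out$fats <- out$fats_range_sub + out$fats_sfa_sub
  out <- out[c("subject_id", "protein_meat_sub", "protein_egg_sub",
               "fats_range_sub", "fats_sfa_sub", .guidelines)]
  out$overall <- rowSums(out[.guidelines])
  out
}

#' Overall adherence category from control-score tertiles
#'
#' Splits subjects into low/mid/high overall adherence at the 33rd and 66th
#' percentiles of the control participants' overall tertile-scheme scores;
#' `low` is score <= the 33rd percentile and `high` is score > the 66th
#' percentile (ties fall to the lower category).
#'
#' @param overall numeric overall tertile-scheme scores for all subjects.
#' @param overall_controls overall scores of controls only (>= 3 required).
#' @return factor with levels `low`, `mid`, `high`; the boundaries are
#'   attached as `attr(, "boundaries")`.
#' @export
overall_tertile_category <- function(overall, overall_controls) {
  v <- overall_controls[is.finite(overall_controls)]
  if (length(v) < 3) stop("need at least 3 control scores", call. = FALSE)
  q <- unname(stats::quantile(v, c(1 / 3, 2 / 3), type = 7))
  if (q[1] == q[2]) {
    warning("degenerate overall-score tertiles: all subjects fall in one ",
            "category", call. = FALSE)
  }
  cat <- factor(ifelse(overall <= q[1], "low",
                       ifelse(overall <= q[2], "mid", "high")),
                levels = c("low", "mid", "high"))
  attr(cat, "boundaries") <- c(low_max = q[1], high_min = q[2])
  cat
}

#' Flag recommendations with highly skewed suggested-scheme adherence
#'
#' A recommendation is flagged when a single score category holds at least
#' `threshold` (default 73%) of subjects in both the case arm and the
#' control arm - the skew regime that motivates data-driven tertiles.
#'
#' @param scores suggested-scheme scores from [score_suggested()].
#' @param participants participant table carrying `status`.
#' @param threshold dominant-category proportion triggering the flag.
#' @return data.frame: `guideline`, `max_share_cases`, `max_share_controls`,
#'   `skewed`.
#' @export
skewness_report <- function(scores, participants, threshold = 0.73) {
  st <- participants$status[match(scores$subject_id,
                                  participants$subject_id)]
  share <- function(v, arm) {
    tb <- table(v[st == arm])
    if (!length(tb)) return(NA_real_)
    max(tb) / sum(tb)
  }
  out <- data.frame(
    guideline = .guidelines,
    max_share_cases = vapply(.guidelines,
                             function(g) share(scores[[g]], "case"),
                             numeric(1)),
    max_share_controls = vapply(.guidelines,
                                function(g) share(scores[[g]], "control"),
                                numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  out$skewed <- out$max_share_cases >= threshold &
    out$max_share_controls >= threshold
  out
}
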