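# Ordinal 0/1/2 coding of a low/mid/high exposure (or any ordered factor).
.as_ordinal <- function(x) {
  if (is.numeric(x)) return(x)
  if (is.character(x)) x <- factor(x, levels = intersect(
    c("low", "mid", "high"), unique(x)))
  as.numeric(x) - 1
}

.fit_either <- function(formula, data, pair = NULL) {
  if (is.null(pair)) fit_logit(formula, data) else
    clogit_pair(formula, data, pair = pair)
}

#' Wald trend test over an ordinal exposure
#'
#' Codes the exposure 0/1/2 (low/mid/high), refits the model, and reports
#' the Wald test on the ordinal slope. Because "trend comparing highest v.
#' lowest tertiles" can also be read as a two-level contrast, the
#' high-vs-low Wald p-value (middle tertile excluded) is reported alongside,
#' labelled separately.
#'
#' @param data subject-level data.frame with a `status` column.
#' @param exposure name of the exposure column (factor low/mid/high or
#'   numeric ordinal).
#' @param pair pair-id column name for a conditional fit; `NULL` for an
#'   unconditional fit.
#' @param covariates character vector of adjustment covariate names.
#' @return list of class `safbdg_trend`: `slope`, `se`, `z`, `p_trend`,
#'   `p_high_vs_low`, `or_per_level`, `n`.
#' @export
trend_test <- function(data, exposure, pair = NULL,
                       covariates = character()) {
  d <- data
  d$.ord <- .as_ordinal(d[[exposure]])
  rhs <- paste(c(".ord", covariates), collapse = " + ")
  f <- stats::as.formula(paste("status == 'case' ~", rhs))
  fit <- .fit_either(f, d, pair)
  tab <- or_table(fit)
  row <- tab[tab$term == ".ord", ]

  # high-vs-low contrast: drop the middle level (for pairs, this drops any
  # pair with a mid-level member)
  ext <- d[d$.ord %in% range(d$.ord), ]
  if (!is.null(pair)) {
    full <- names(which(table(ext[[pair]]) == 2L))
    ext <- ext[ext[[pair]] %in% full, ]
  }
  ext$.hi <- as.numeric(ext$.ord == max(d$.ord))
  f2 <- stats::as.formula(paste("status == 'case' ~",
                                paste(c(".hi", covariates),
                                      collapse = " + ")))
  p_hvl <- tryCatch({
    t2 <- or_table(.fit_either(f2, ext, pair))
    t2$p[t2$term == ".hi"]
  }, error = function(e) NA_real_)

  structure(list(slope = row$beta, se = row$se, z = row$z,
                 p_trend = row$p, p_high_vs_low = p_hvl,
                 or_per_level = row$or,
                 n = if (is.null(pair)) fit$n_subjects else fit$n_pairs),
            class = "safbdg_trend")
}

#' @export
print.safbdg_trend <- function(x, ...) {
  cat(sprintf("ordinal trend: slope %.4f (se %.4f), OR/level %.3f, p = %.4g\n",
              x$slope, x$se, x$or_per_level, x$p_trend))
  cat(sprintf("high vs low contrast: p = %.4g\n", x$p_high_vs_low))
  invisible(x)
}

#' Wald test for exposure-by-stratum interaction
#'
#' Adds an exposure-by-stratifier product term and reports the Wald test on
#' it. In the conditional fit, a stratifier that is constant within pairs
#' contributes no main effect (it cancels in the within-pair differences)
#' and is dropped silently; the product term remains identifiable whenever
#' the exposure varies within pairs of both strata.
#'
#' @inheritParams trend_test
#' @param stratifier name of a binary stratum column (logical, 0/1 or
#'   two-level factor).
#' @return list: `estimate` (interaction log-OR), `se`, `z`, `p`.
#' @export
interaction_test <- function(data, exposure, stratifier, pair = NULL,
                             covariates = character()) {
  d <- data
  d$.ord <- .as_ordinal(d[[exposure]])
  s <- d[[stratifier]]
  if (is.factor(s) || is.character(s)) {
    lv <- sort(unique(as.character(s)))
    if (length(lv) != 2) stop("stratifier must be binary", call. = FALSE)
    s <- as.numeric(as.character(s) == lv[2])
  } else {
    s <- as.numeric(s)
  }
  d$.strat <- s
  is_case <- d$status == "case"
  for (lev in unique(s)) {
    if (length(unique(is_case[s == lev])) < 2) {
      stop("stratum ", lev, " holds a single outcome class", call. = FALSE)
    }
  }
  d$.prod <- d$.ord * d$.strat
  rhs <- paste(c(".ord", ".strat", ".prod", covariates), collapse = " + ")
  f <- stats::as.formula(paste("status == 'case' ~", rhs))
  fit <- withCallingHandlers(
    .fit_either(f, d, pair),
    warning = function(w) {
      if (grepl("constant within all pairs", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  tab <- or_table(fit)
  row <- tab[tab$term == ".prod", ]
  list(estimate = row$beta, se = row$se, z = row$z, p = row$p)
}

#' Change-in-estimate confounder screening
#'
#' Evaluates each candidate covariate one at a time against the crude
#' exposure model: a candidate is selected as a confounder when adding it
#' moves the crude exposure OR by more than `threshold` (relative change,
#' default 10%). A candidate whose adjusted model fails to converge is
#' flagged and excluded with a warning; a candidate collinear with the
#' exposure is flagged rather than silently selected.
#'
#' @inheritParams trend_test
#' @param candidates character vector of candidate covariate names.
#' @param threshold relative OR change above which a candidate is selected.
#' @return data.frame: `candidate`, `or_crude`, `or_adjusted`, `pct_change`,
#'   `selected`, `note`.
#' @export
confounder_screen <- function(data, exposure, candidates, pair = NULL,
                              threshold = 0.10) {
  d <- data
  d$.ord <- .as_ordinal(d[[exposure]])
  crude_fit <- .fit_either(status == "case" ~ .ord, d, pair)
  or_crude <- exp(crude_fit$coefficients[[".ord"]])
  out <- lapply(candidates, function(cand) {
    v <- d[[cand]]
    if (is.numeric(v) && stats::sd(v - d$.ord) == 0) {
      warning("candidate '", cand, "' is identical to the exposure; flagged",
              call. = FALSE)
      return(data.frame(candidate = cand, or_crude = or_crude,
                        or_adjusted = NA_real_, pct_change = NA_real_,
                        selected = FALSE, note = "collinear with exposure",
                        stringsAsFactors = FALSE))
    }
    f <- stats::as.formula(paste("status == 'case' ~ .ord +", cand))
    adj <- tryCatch(suppressWarnings(.fit_either(f, d, pair)),
                    error = function(e) e)
    if (inherits(adj, "error")) {
      warning("candidate '", cand, "' model did not converge; excluded (",
              conditionMessage(adj), ")", call. = FALSE)
      return(data.frame(candidate = cand, or_crude = or_crude,
                        or_adjusted = NA_real_, pct_change = NA_real_,
                        selected = FALSE, note = "did not converge",
                        stringsAsFactors = FALSE))
    }
    or_adj <- exp(adj$coefficients[[".ord"]])
    chg <- abs(or_adj - or_crude) / or_crude
    data.frame(candidate = cand, or_crude = or_crude, or_adjusted = or_adj,
               pct_change = 100 * chg, selected = chg > threshold,
               note = "", stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Paired descriptive comparisons between cases and controls
#'
#' Dispatches on the declared variable type: `"normal"` uses the paired
#' t-test (reported with arm means and SDs), `"skewed"` the Wilcoxon
#' signed-rank test (arm medians and quartiles), `"binary"` the paired
#' chi-square on discordant pairs (McNemar statistic `(b - c)^2 / (b + c)`
#' without continuity correction, reported with arm percentages).
#'
#' @param data subject-level data.frame with `status` and a pair column.
#' @param variable name of the column to compare.
#' @param type `"normal"`, `"skewed"` or `"binary"`.
#' @param pair pair-id column name.
#' @return list of class `paired_test`: per-arm summaries, `statistic`,
#'   `p.value` and a `note` when the test is degenerate (e.g. all-zero
#'   differences leave the signed-rank test undefined).
#' @export
paired_descriptives <- function(data, variable, type = c("normal", "skewed",
                                                         "binary"),
                                pair = "pair_id") {
  type <- match.arg(type)
  d <- data[order(data[[pair]], data$status != "case"), ]
  cs <- d[d$status == "case", ]
  ct <- d[d$status == "control", ]
  stopifnot(all(cs[[pair]] == ct[[pair]]))
  x <- cs[[variable]]; y <- ct[[variable]]
  note <- ""
  if (type == "normal") {
    smry <- list(cases = c(mean = mean(x), sd = stats::sd(x)),
                 controls = c(mean = mean(y), sd = stats::sd(y)))
    if (all(x == y)) {
      statistic <- 0; p <- 1
      note <- "all within-pair differences zero"
    } else {
      tt <- stats::t.test(x, y, paired = TRUE)
      statistic <- unname(tt$statistic); p <- tt$p.value
    }
  } else if (type == "skewed") {
    qs <- function(v) c(median = stats::median(v),
                        q25 = unname(stats::quantile(v, 0.25)),
                        q75 = unname(stats::quantile(v, 0.75)))
    smry <- list(cases = qs(x), controls = qs(y))
    if (all(x == y)) {
      statistic <- NA_real_; p <- NA_real_
      note <- "signed-rank test undefined: all differences zero"
    } else {
      wt <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE))
      statistic <- unname(wt$statistic); p <- wt$p.value
    }
  } else {
    x <- as.numeric(x); y <- as.numeric(y)
    smry <- list(cases = c(pct = 100 * mean(x)),
                 controls = c(pct = 100 * mean(y)))
    b <- sum(x == 1 & y == 0)
    cc <- sum(x == 0 & y == 1)
    if (b + cc == 0) {
      statistic <- 0; p <- 1
      note <- "no discordant pairs"
    } else {
      statistic <- (b - cc)^2 / (b + cc)
      p <- stats::pchisq(statistic, df = 1, lower.tail = FALSE)
    }
  }
  structure(list(variable = variable, type = type, summary = smry,
                 statistic = statistic, p.value = p,
                 n_pairs = nrow(cs), note = note),
            class = "paired_test")
}

#' @export
print.paired_test <- function(x, ...) {
  cat(sprintf("paired %s comparison of '%s' (%d pairs)\n", x$type,
              x$variable, x$n_pairs))
  print(lapply(x$summary, round, 3))
  cat(sprintf("statistic = %s, p = %s\n", format(x$statistic),
              format(x$p.value)))
  if (nzchar(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}
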