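# Exposure rows crafted directly (bypassing aggregation) so each rule's
# boundary behaviour can be pinned.
make_fg <- function(...) {
  base <- data.frame(
    subject_id = "S1", fruitveg_g = 0, legume_g = 0, dairy_liquid_g = 0,
    cheese_g = 0, fcl_meat_g = 0, egg_g = 0, starchy_units = 0, dds = 0L,
    low_diversity = TRUE, fat_pct_te = 0, sfa_pct_te = 0, sugar_pct_te = 0,
    stringsAsFactors = FALSE
  )
  over <- list(...)
  base[names(over)] <- over
  base
}
one_p <- make_participant("S1", "P1", "case")

test_that("the three-level sugar rule scores 1 / 0.5 / 0", {
  p <- one_p
  expect_equal(score_guideline_suggested("sugar", make_fg(sugar_pct_te = 5),
                                         p), 1)
  expect_equal(score_guideline_suggested("sugar", make_fg(sugar_pct_te = 8),
                                         p), 0.5)
  expect_equal(score_guideline_suggested("sugar", make_fg(sugar_pct_te = 12),
                                         p), 0)
  # strict "<" boundaries go to the lower score
  expect_equal(score_guideline_suggested("sugar", make_fg(sugar_pct_te = 6),
                                         p), 0.5)
  expect_equal(score_guideline_suggested("sugar", make_fg(sugar_pct_te = 10),
                                         p), 0)
})

test_that("sub-recommendation rules split 0.5 + 0.5", {
  p <- one_p
  # fat in range and SFA below 10 %TE
  expect_equal(score_guideline_suggested(
    "fats", make_fg(fat_pct_te = 25, sfa_pct_te = 8), p), 1.0)
  expect_equal(score_guideline_suggested(
    "fats", make_fg(fat_pct_te = 35, sfa_pct_te = 8), p), 0.5)
  expect_equal(score_guideline_suggested(
    "fats", make_fg(fat_pct_te = 20, sfa_pct_te = 10), p), 0.5)  # ties
  expect_equal(score_guideline_suggested(
    "fats", make_fg(fat_pct_te = 30, sfa_pct_te = 9.99), p), 1.0)
  # meat strictly between 0 and 90 g; egg at 4 x 50 g / 7 d
  expect_equal(score_guideline_suggested(
    "protein", make_fg(fcl_meat_g = 89.9, egg_g = 200 / 7), p), 1.0)
  expect_equal(score_guideline_suggested(
    "protein", make_fg(fcl_meat_g = 90, egg_g = 28), p), 0)
  expect_equal(score_guideline_suggested(
    "protein", make_fg(fcl_meat_g = 0, egg_g = 30), p), 0.5)
})

test_that("threshold rules honour their documented boundaries", {
  p <- one_p
  expect_equal(score_guideline_suggested("fruitveg", make_fg(), p), 0)
  expect_equal(score_guideline_suggested("fruitveg",
                                         make_fg(fruitveg_g = 400), p), 1)
  expect_equal(score_guideline_suggested("legumes",
                                         make_fg(legume_g = 21.4), p), 1)
  expect_equal(score_guideline_suggested("dairy",
                                         make_fg(cheese_g = 50), p), 1)
  expect_equal(score_guideline_suggested("dairy",
                                         make_fg(dairy_liquid_g = 399.9,
                                                 cheese_g = 49.9), p), 0)
  expect_equal(score_guideline_suggested("starchy",
                                         make_fg(starchy_units = 10), p), 1)
  expect_equal(score_guideline_suggested("variety", make_fg(dds = 4L), p), 1)
  expect_equal(score_guideline_suggested("variety", make_fg(dds = 3L), p), 0)
  expect_error(score_guideline_suggested("salt", make_fg(), p),
               "unknown guideline")
})

test_that("overall score spans 0 to 9 with half-adherence above 4.5", {
  full <- make_fg(dds = 9L, starchy_units = 12, fruitveg_g = 450,
                  legume_g = 30, dairy_liquid_g = 500, fcl_meat_g = 60,
                  egg_g = 30, fat_pct_te = 25, sfa_pct_te = 8,
                  sugar_pct_te = 4)
  p_active <- make_participant("S1", "P1", "case", pa_active = TRUE)
  sc <- score_suggested(full, p_active)
  expect_equal(sc$overall, 9)
  expect_true(sc$half_adherent)
  # "<"-phrased rules at literal zero still award their half/full point,
  # so the zero-adherence profile needs out-of-band %TE values
  empty <- score_suggested(make_fg(sfa_pct_te = 12, sugar_pct_te = 15),
                           one_p)
  expect_equal(empty$overall, 0)
  expect_false(empty$half_adherent)
  zero_te <- score_suggested(make_fg(), one_p)
  expect_equal(zero_te$overall, 1.5)  # SFA < 10 and sugar < 6 at zero
})

test_that("random profiles match an independent predicate oracle", {
  set.seed(11)
  for (i in 1:30) {
    fg <- make_fg(dds = sample(0:9, 1), starchy_units = runif(1, 0, 15),
                  fruitveg_g = runif(1, 0, 600), legume_g = runif(1, 0, 50),
                  dairy_liquid_g = runif(1, 0, 600),
                  cheese_g = runif(1, 0, 60), fcl_meat_g = runif(1, 0, 150),
                  egg_g = runif(1, 0, 50), fat_pct_te = runif(1, 5, 45),
                  sfa_pct_te = runif(1, 1, 15),
                  sugar_pct_te = runif(1, 0, 20))
    act <- runif(1) < 0.5
    p <- make_participant("S1", "P1", "case", pa_active = act)
    sc <- score_suggested(fg, p)
    # every predicate re-evaluated longhand
    oracle <- (fg$dds >= 4) + act + (fg$starchy_units >= 10) +
      (fg$fruitveg_g >= 400) + (fg$legume_g >= 21.4) +
      (fg$dairy_liquid_g >= 400 | fg$cheese_g >= 50) +
      0.5 * (fg$fcl_meat_g > 0 && fg$fcl_meat_g < 90) +
      0.5 * (fg$egg_g >= 200 / 7) +
      0.5 * (fg$fat_pct_te >= 20 && fg$fat_pct_te <= 30) +
      0.5 * (fg$sfa_pct_te < 10) +
      (if (fg$sugar_pct_te < 6) 1 else if (fg$sugar_pct_te < 10) 0.5 else 0)
    expect_equal(sc$overall, unname(oracle))
  }
})

test_that("components are monotone in the compliant direction", {
  p <- one_p
  fv <- sapply(seq(0, 600, by = 25), function(g)
    score_guideline_suggested("fruitveg", make_fg(fruitveg_g = g), p))
  expect_true(all(diff(fv) >= 0))
  su <- sapply(seq(0, 15, by = 0.5), function(s)
    score_guideline_suggested("sugar", make_fg(sugar_pct_te = s), p))
  expect_true(all(diff(su) <= 0))
})

test_that("a 7-point score without legumes/starchy ranks like the 9-point", {
  syn <- simulate_study(sim_config(n_pairs = 150, seed = 31))
  fg <- aggregate_groups(syn$study, syn$mapping)
  sc <- score_suggested(fg, syn$study$participants)
  seven <- sc$overall - sc$legumes - sc$starchy
  expect_gt(cor(seven, sc$overall, method = "spearman"), 0.5)
})

test_that("prevalence tabulates per-arm percentages in report order", {
  im <- matrix(0, 8, length(tiny_items()))
  im[1, 4:5] <- c(300, 150)  # one case adherent to fruit/veg
  st <- make_tiny_study(im)
  fg <- aggregate_groups(st, tiny_mapping())
  sc <- score_suggested(fg, st$participants)
  prev <- adherence_prevalence(sc, st$participants)
  expect_equal(prev$pct_cases[prev$item == "fruitveg"], 25)  # 1 of 4 cases
  expect_equal(prev$pct_controls[prev$item == "fruitveg"], 0)
  expect_equal(prev$item[1:6], c("variety", "active", "starchy", "fruitveg",
                                 "legumes", "dairy"))
  expect_true("overall_half" %in% prev$item)
  only_cases <- st$participants[st$participants$status == "case", ]
  expect_error(adherence_prevalence(sc[1:4, ], only_cases), "both arms")
})
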