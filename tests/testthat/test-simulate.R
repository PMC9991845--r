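test_that("the toy food list covers every group with published unit
           weights", {
  m <- toy_foods()
  expect_setequal(unique(stats::na.omit(m$items$dds_group)), 1:9)
  expect_setequal(setdiff(unique(m$items$group), "none"),
                  c("starchy", "fruit_veg", "legume", "dairy_liquid",
                    "hard_cheese", "fish_chicken_leanmeat", "egg"))
  st <- m$items[m$items$group == "starchy", ]
  expect_setequal(unique(st$starchy_unit_g),
                  c(125, 60, 45, 35, 100, 75, 25, 65))
  expect_true(all(!is.na(m$items$kj_per_100g)))
  # fixture survives the mapping validator via a YAML round trip
  path <- withr::local_tempfile(fileext = ".yaml")
  write_mapping(m, path)
  expect_s3_class(read_mapping(path), "group_mapping")
})

test_that("the generator is deterministic under a fixed seed", {
  a <- simulate_study(sim_config(n_pairs = 15, seed = 123))
  b <- simulate_study(sim_config(n_pairs = 15, seed = 123))
  expect_identical(a$study$participants, b$study$participants)
  expect_identical(a$study$intakes, b$study$intakes)
  expect_identical(a$study$nutrients, b$study$nutrients)
  expect_identical(a$truth$categories, b$truth$categories)
  c <- simulate_study(sim_config(n_pairs = 15, seed = 124))
  expect_false(identical(a$study$intakes, c$study$intakes))
})

test_that("generated intakes reproduce configured adherence probabilities",
          {
  cfg <- sim_config(n_pairs = 1500, seed = 131, or_high = 1)
  syn <- simulate_study(cfg)
  fg <- aggregate_groups(syn$study, syn$mapping)
  sc <- score_suggested(fg, syn$study$participants)
  # closed form from the zero-inflated log-normal channel parameters
  p_channel <- function(par, cut) {
    (1 - par$p_zero) * stats::pnorm((par$meanlog - log(cut)) / par$sdlog)
  }
  n <- nrow(sc)
  tol <- function(p) 3 * sqrt(p * (1 - p) / n) + 0.005
  p_leg <- p_channel(cfg$intake$legumes, 21.4)
  expect_lt(abs(mean(sc$legumes) - p_leg), tol(p_leg))
  p_dairy <- p_channel(cfg$intake$dairy_liquid, 400)  # cheese route rare
  expect_lt(abs(mean(fg$dairy_liquid_g >= 400) - p_dairy), tol(p_dairy))
  p_st <- p_channel(cfg$intake$starchy_units, 10)
  expect_lt(abs(mean(sc$starchy) - p_st), tol(p_st))
})

test_that("arm-level covariate moments match the configured conditions", {
  syn <- simulate_study(sim_config(n_pairs = 2000, seed = 137))
  p <- syn$study$participants
  cs <- p$status == "case"
  n <- sum(cs)
  expect_lt(abs(mean(p$waist_cm[cs]) - 93.3), 3 * 13.8 / sqrt(n) + 0.1)
  expect_lt(abs(mean(p$waist_cm[!cs]) - 95.8), 3 * 13.7 / sqrt(n) + 0.1)
  expect_lt(abs(sd(p$waist_cm[cs]) - 13.8), 0.7)
  expect_lt(abs(mean(p$hiv[cs] == "positive") - 0.165),
            3 * sqrt(0.165 * 0.835 / n))
  expect_lt(abs(mean(p$hiv[!cs] == "positive") - 0.226),
            3 * sqrt(0.226 * 0.774 / n))
})

test_that("configured legume zero-inflation drives the skew regime", {
  cfg <- sim_config(n_pairs = 800, seed = 139, or_high = 1,
                    intake = list(legumes = list(p_zero = 0.8,
                                                 meanlog = log(30),
                                                 sdlog = 0.8)))
  syn <- simulate_study(cfg)
  fg <- aggregate_groups(syn$study, syn$mapping)
  sc <- score_suggested(fg, syn$study$participants)
  ctrl <- syn$study$participants$status == "control"
  non_adh <- mean(sc$legumes[ctrl] == 0)
  # ~80% zero-inflation leaves at least ~80% of controls non-adherent
  expect_gt(non_adh, 0.78)
  skew <- skewness_report(sc, syn$study$participants)
  expect_true(skew$skewed[skew$guideline == "legumes"])
})

test_that("the empirical conditional OR converges to the configured OR", {
  syn <- simulate_study(sim_config(n_pairs = 5000, seed = 149))
  p <- syn$study$participants
  d <- merge(p[c("subject_id", "pair_id", "status")],
             syn$truth$categories)
  fit <- clogit_pair(status == "case" ~ true_cat, d, pair = "pair_id")
  b <- coef(fit)[["true_cathigh"]]
  expect_lt(abs(b - log(0.56)), 3 * fit$se[["true_cathigh"]])
  # the null configuration stays at OR ~ 1
  syn0 <- simulate_study(sim_config(n_pairs = 3000, seed = 151,
                                    or_high = 1))
  d0 <- merge(syn0$study$participants[c("subject_id", "pair_id",
                                        "status")],
              syn0$truth$categories)
  fit0 <- clogit_pair(status == "case" ~ true_cat, d0, pair = "pair_id")
  expect_lt(abs(coef(fit0)[["true_cathigh"]]),
            3 * fit0$se[["true_cathigh"]])
})

test_that("analysis-grade categories rederived from controls track the
           truth", {
  syn <- simulate_study(sim_config(n_pairs = 3000, seed = 157))
  st <- syn$study
  fg <- aggregate_groups(st, syn$mapping)
  m <- compliance_metrics(fg, st$participants)
  ctrl <- st$participants$status == "control"
  ter <- score_tertile(m, derive_cutpoints(m[ctrl, ]))
  cat_d <- overall_tertile_category(ter$overall, ter$overall[ctrl])
  agree <- mean(as.character(cat_d) ==
                  as.character(syn$truth$categories$true_cat))
  expect_gt(agree, 0.85)  # re-derived cut-points shift only at boundaries
  d <- data.frame(pair_id = st$participants$pair_id,
                  status = st$participants$status, cat = cat_d)
  fit <- clogit_pair(status == "case" ~ cat, d, pair = "pair_id")
  # estimand drift from outcome-tilted control cut-points is bounded
  expect_lt(abs(coef(fit)[["cathigh"]] - log(0.56)), 0.25)
})

test_that("stratum-specific ORs apply within their strata", {
  syn <- simulate_study(sim_config(n_pairs = 4000, seed = 163,
                                   or_high = 1, or_postmenopausal = 0.4))
  p <- syn$study$participants
  d <- merge(p[c("subject_id", "pair_id", "status", "age")],
             syn$truth$categories)
  ps <- syn$truth$pair_strata
  post <- ps$pair_id[ps$postmenopausal]
  fit_post <- clogit_pair(status == "case" ~ true_cat,
                          d[d$pair_id %in% post, ], pair = "pair_id")
  fit_pre <- clogit_pair(status == "case" ~ true_cat,
                         d[!d$pair_id %in% post, ], pair = "pair_id")
  expect_lt(abs(coef(fit_post)[["true_cathigh"]] - log(0.4)),
            3 * fit_post$se[["true_cathigh"]])
  expect_lt(abs(coef(fit_pre)[["true_cathigh"]]),
            3 * fit_pre$se[["true_cathigh"]])
})
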