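test_that("three hand-built pairs match grid maximisation of the written
           likelihood", {
  # exposure (binary): pairs with diffs +1, +1, -1
  x_case <- matrix(c(1, 1, 0))
  x_control <- matrix(c(0, 0, 1))
  d <- data.frame(
    pair_id = rep(1:3, each = 2),
    status = rep(c("case", "control"), 3),
    x = c(1, 0, 1, 0, 0, 1)
  )
  fit <- clogit_pair(status == "case" ~ x, d, pair = "pair_id")
  grid <- seq(-5, 5, by = 1e-4)
  ll <- vapply(grid, oracle_clogit_loglik, numeric(1),
               x_case = x_case, x_control = x_control)
  b_grid <- grid[which.max(ll)]
  b_ref <- oracle_clogit_mle(x_case, x_control)
  expect_equal(unname(coef(fit)), b_ref, tolerance = 1e-6)
  expect_equal(b_grid, b_ref, tolerance = 1e-3)  # grid resolution
  # closed form for this configuration: 2 e^b / (e^b+1) parts => b = log 2
  expect_equal(unname(coef(fit)), log(2), tolerance = 1e-6)
})

test_that("Newton MLE equals the written-likelihood optimum and the
           difference-logistic fit on random data", {
  set.seed(17)
  for (i in 1:12) {
    n_cov <- sample(1:2, 1)
    rp <- random_pair_data(sample(4:10, 1), n_cov)
    b_oracle <- oracle_clogit_mle(rp$x_case, rp$x_control)
    expect_equal(unname(coef(rp$fit)), unname(b_oracle), tolerance = 1e-6)
    # independent route: no-intercept logistic on within-pair differences
    D <- rp$x_case - rp$x_control
    g <- suppressWarnings(
      stats::glm.fit(D, rep(1, nrow(D)), family = stats::binomial(),
                     control = stats::glm.control(epsilon = 1e-12)))
    expect_equal(unname(coef(rp$fit)), unname(g$coefficients),
                 tolerance = 1e-8)
  }
})

test_that("the fit agrees with survival::clogit on a moderate dataset", {
  skip_if_not_installed("survival")
  withr::local_package("survival")
  set.seed(23)
  rp <- random_pair_data(80, 2)
  d <- rp$data
  d$case <- as.numeric(d$status == "case")
  sv <- survival::clogit(case ~ x1 + x2 + strata(pair_id), data = d)
  expect_equal(unname(coef(rp$fit)), unname(coef(sv)), tolerance = 1e-6)
  expect_equal(unname(rp$fit$se), unname(sqrt(diag(vcov(sv)))),
               tolerance = 1e-6)
})

test_that("swapping case/control labels flips the estimate exactly", {
  set.seed(29)
  rp <- random_pair_data(40, 2)
  d <- rp$data
  d$status <- ifelse(d$status == "case", "control", "case")
  fit2 <- clogit_pair(status == "case" ~ x1 + x2, d, pair = "pair_id")
  expect_equal(coef(fit2), -coef(rp$fit), tolerance = 1e-10)
})

test_that("degenerate designs raise diagnostic errors", {
  # exposure concordant within every pair: flat likelihood
  d <- data.frame(pair_id = rep(1:4, each = 2),
                  status = rep(c("case", "control"), 4),
                  x = rep(c(1, 1, 0, 0), 2))
  expect_error(clogit_pair(status == "case" ~ x, d, pair = "pair_id"),
               "non-identifiable")
  # perfectly separated exposure: case always exposed
  d2 <- data.frame(pair_id = rep(1:6, each = 2),
                   status = rep(c("case", "control"), 6),
                   x = rep(c(1, 0), 6))
  expect_error(clogit_pair(status == "case" ~ x, d2, pair = "pair_id"),
               "separation")
})

test_that("non-informative pairs are counted but not used", {
  d <- data.frame(pair_id = rep(1:4, each = 2),
                  status = rep(c("case", "control"), 4),
                  x = c(1, 0, 0, 1, 1, 1, 0.5, 0.5))
  fit <- clogit_pair(status == "case" ~ x, d, pair = "pair_id")
  expect_equal(fit$n_pairs, 4)
  expect_equal(fit$n_informative_pairs, 2)
})

test_that("missing model values drop the whole pair with a message", {
  set.seed(37)
  rp <- random_pair_data(20, 1)
  d <- rp$data
  d$x1[3] <- NA  # loses pair 2
  expect_message(fit <- clogit_pair(status == "case" ~ x1, d,
                                    pair = "pair_id"), "1 pair")
  expect_equal(fit$n_pairs, 19)
})

test_that("summary/confint expose Wald inference on the OR scale", {
  set.seed(43)
  rp <- random_pair_data(100, 1)
  fit <- rp$fit
  tab <- or_table(fit)
  expect_equal(tab$or, exp(tab$beta))
  expect_true(tab$ci_lo < tab$or && tab$or < tab$ci_hi)
  ci <- confint(fit)
  expect_equal(unname(ci[1, ]),
               unname(coef(fit) + c(-1, 1) * 1.96 * fit$se),
               tolerance = 1e-3)
  expect_output(print(summary(fit)), "Wald 95%")
  expect_length(predict(fit), fit$n_pairs)
  expect_equal(residuals(fit), 1 - predict(fit))
})

test_that("unconditional logistic matches the 2x2 closed form", {
  # cells (exposed case, exposed control, unexposed case, unexposed
  # control) = (10, 20, 20, 10): OR = ad/bc = 0.25
  d <- data.frame(
    status = rep(c("case", "control", "case", "control"),
                 c(30, 30, 0, 0))[1:60],
    x = c(rep(1, 10), rep(0, 20), rep(1, 20), rep(0, 10))
  )
  d$status <- rep(c("case", "control"), each = 30)
  fit <- fit_logit(status == "case" ~ x, d)
  expect_equal(exp(coef(fit)[["x"]]), 0.25, tolerance = 1e-6)
  # exposure independent of outcome in balanced data: OR ~ 1
  d2 <- data.frame(status = rep(c("case", "control"), each = 200),
                   x = rep(c(0, 1), 200))
  fit2 <- fit_logit(status == "case" ~ x, d2)
  expect_equal(exp(coef(fit2)[["x"]]), 1, tolerance = 1e-6)
  expect_error(fit_logit(status == "case" ~ x,
                         data.frame(status = "case", x = 1)),
               "both outcome classes")
  sep <- data.frame(status = rep(c("case", "control"), each = 20),
                    x = rep(c(1, 0), each = 20))
  expect_error(fit_logit(status == "case" ~ x, sep), "separation")
})

test_that("conditional and unconditional fits agree when matching is
           ignorable", {
  set.seed(53)
  n <- 1500
  x <- rnorm(n)
  # pairs formed at random (no shared pair effect), so both estimands agree
  beta <- 0.6
  d <- NULL
  for (i in seq_len(n / 2)) {
    xi <- x[c(2 * i - 1, 2 * i)]
    p1 <- exp(beta * xi[1]) / (exp(beta * xi[1]) + exp(beta * xi[2]))
    c1 <- runif(1) < p1
    d <- rbind(d, data.frame(pair_id = i, status = c("case", "control"),
                             x = if (c1) xi else rev(xi)))
  }
  fc <- clogit_pair(status == "case" ~ x, d, pair = "pair_id")
  fu <- fit_logit(status == "case" ~ x, d)
  expect_equal(sign(coef(fc)[["x"]]), sign(coef(fu)[["x"]]))
  expect_lt(abs(coef(fc)[["x"]] - beta), 3 * fc$se[["x"]])
})
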