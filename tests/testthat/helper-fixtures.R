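# Small in-code fixtures shared across test files.

# Minimal participant row with sane defaults; override any field.
make_participant <- function(subject_id, pair_id, status, ...) {
  p <- list(
    subject_id = subject_id, pair_id = pair_id, status = status,
    age = 50, menopausal = "post", er = "unknown", pr = "unknown",
    her2 = "unknown", ethnicity = "Sotho", income_band = "R1-R3000",
    education = "high school", smoker = FALSE, waist_cm = 95,
    height_cm = 160, weight_kg = 70, hiv = "negative",
    pa_metric = 20, pa_active = FALSE, alcohol_g = 0
  )
  p[names(list(...))] <- list(...)
  as.data.frame(p, stringsAsFactors = FALSE)
}

# A tiny hand-checkable mapping: three starchy items with the published
# unit weights plus one item per remaining scored group.
tiny_mapping <- function() {
  group_mapping(data.frame(
    item_id = c("porridge_soft", "bread", "rice", "spinach", "apple",
                "beans", "milk", "cheese", "chicken", "eggs", "oil"),
    dds_group = c(1L, 1L, 1L, 5L, 8L, 6L, 3L, 3L, 2L, 4L, 9L),
    group = c("starchy", "starchy", "starchy", "fruit_veg", "fruit_veg",
              "legume", "dairy_liquid", "hard_cheese",
              "fish_chicken_leanmeat", "egg", "none"),
    starchy_unit_g = c(125, 35, 65, NA, NA, NA, NA, NA, NA, NA, NA),
    stringsAsFactors = FALSE
  ))
}

tiny_items <- function() tiny_mapping()$items$item_id

# Study of n_pairs hand-set pairs over the tiny mapping. `intake_rows` is a
# matrix (subjects x items) in tiny_items() order; nutrient defaults give
# 25 %TE fat, 8 %TE saturated fat, 8.5 %TE added sugar at 8500 kJ.
make_tiny_study <- function(intake_rows, participants = NULL,
                            energy_kj = 8500, fat_g = NULL, sfa_g = NULL,
                            sugar_g = NULL) {
  n <- nrow(intake_rows)
  stopifnot(n %% 2 == 0)
  if (is.null(participants)) {
    participants <- do.call(rbind, lapply(seq_len(n), function(i) {
      make_participant(sprintf("S%02d", i), sprintf("P%02d", ceiling(i / 2)),
                       if (i %% 2 == 1) "case" else "control")
    }))
  }
  colnames(intake_rows) <- tiny_items()
  energy_kj <- rep_len(energy_kj, n)
  if (is.null(fat_g)) fat_g <- 25 / 100 * energy_kj / 37
  if (is.null(sfa_g)) sfa_g <- 8 / 100 * energy_kj / 37
  if (is.null(sugar_g)) sugar_g <- 8.5 / 100 * energy_kj / 17
  safbdg_study(
    participants,
    data.frame(subject_id = participants$subject_id, intake_rows,
               check.names = FALSE, stringsAsFactors = FALSE),
    data.frame(subject_id = participants$subject_id, energy_kj = energy_kj,
               fat_g = rep_len(fat_g, n), sfa_g = rep_len(sfa_g, n),
               added_sugar_g = rep_len(sugar_g, n),
               alcohol_g = 0, stringsAsFactors = FALSE)
  )
}

# Conditional log-likelihood written directly from the pair likelihood
# prod exp(b'x_case) / (exp(b'x_case) + exp(b'x_control)); independent of
# the package's difference-based implementation.
oracle_clogit_loglik <- function(beta, x_case, x_control) {
  num <- exp(drop(x_case %*% beta))
  den <- num + exp(drop(x_control %*% beta))
  sum(log(num / den))
}

# Brute-force maximiser of the written likelihood (grid + refine for one
# parameter, quasi-Newton on the written function for two).
oracle_clogit_mle <- function(x_case, x_control) {
  k <- ncol(x_case)
  b <- if (k == 1) {
    stats::optimize(function(b) oracle_clogit_loglik(b, x_case, x_control),
                    c(-10, 10), maximum = TRUE, tol = 1e-10)$maximum
  } else {
    stats::optim(rep(0, k),
                 function(b) -oracle_clogit_loglik(b, x_case, x_control),
                 method = "BFGS",
                 control = list(reltol = 1e-14, maxit = 500))$par
  }
  # polish with finite-difference Newton steps on the written likelihood
  h <- 1e-5
  for (it in 1:4) {
    g <- vapply(seq_len(k), function(j) {
      e <- replace(rep(0, k), j, h)
      (oracle_clogit_loglik(b + e, x_case, x_control) -
         oracle_clogit_loglik(b - e, x_case, x_control)) / (2 * h)
    }, numeric(1))
    H <- matrix(0, k, k)
    for (j in seq_len(k)) for (l in seq_len(k)) {
      ej <- replace(rep(0, k), j, h); el <- replace(rep(0, k), l, h)
      H[j, l] <- (oracle_clogit_loglik(b + ej + el, x_case, x_control) -
                    oracle_clogit_loglik(b + ej - el, x_case, x_control) -
                    oracle_clogit_loglik(b - ej + el, x_case, x_control) +
                    oracle_clogit_loglik(b - ej - el, x_case, x_control)) /
        (4 * h^2)
    }
    b <- b - solve(H, g)
  }
  b
}

# Random pair data with finite MLE: returns list(data, x_case, x_control).
random_pair_data <- function(n_pairs, n_cov, beta = NULL) {
  if (is.null(beta)) beta <- stats::runif(n_cov, -1, 1)
  repeat {
    x1 <- matrix(stats::rnorm(n_pairs * n_cov), n_pairs)
    x2 <- matrix(stats::rnorm(n_pairs * n_cov), n_pairs)
    p1 <- exp(x1 %*% beta) / (exp(x1 %*% beta) + exp(x2 %*% beta))
    case1 <- stats::runif(n_pairs) < p1
    xc <- ifelse(matrix(case1, n_pairs, n_cov), x1, x2)
    xo <- ifelse(matrix(case1, n_pairs, n_cov), x2, x1)
    d <- data.frame(
      pair_id = rep(seq_len(n_pairs), each = 2),
      status = as.vector(rbind(rep("case", n_pairs),
                               rep("control", n_pairs)))
    )
    X <- matrix(NA_real_, 2 * n_pairs, n_cov)
    X[seq(1, 2 * n_pairs, 2), ] <- xc
    X[seq(2, 2 * n_pairs, 2), ] <- xo
    colnames(X) <- paste0("x", seq_len(n_cov))
    d <- cbind(d, X)
    fit <- tryCatch(
      clogit_pair(stats::as.formula(
        paste("status == 'case' ~", paste(colnames(X), collapse = "+"))),
        d, pair = "pair_id"),
      error = function(e) NULL)
    if (!is.null(fit)) {
      return(list(data = d, x_case = xc, x_control = xo, fit = fit))
    }
  }
}
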