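#' 1:1 conditional logistic regression
#'
#' Fits the conditional likelihood for 1:1 matched case-control pairs,
#' `prod_i exp(b'x_case) / (exp(b'x_case) + exp(b'x_control))`, by
#' Newton-Raphson with analytic gradient and Hessian. This is numerically
#' identical to no-intercept logistic regression on the within-pair
#' covariate differences `x_case - x_control`; pairs whose members share
#' identical covariate values are non-informative and are counted but do not
#' contribute to the likelihood.
#'
#' The first term of `formula` is treated as the exposure of interest: if it
#' is concordant within every pair the model is non-identifiable and an
#' error is raised. Other model columns that are constant within every pair
#' (e.g. a matching variable) carry no conditional information and are
#' dropped with a warning. Rows with missing model variables are dropped
#' (complete-case within the model), together with their pair mates.
#'
#' @param formula model formula; left side is the case indicator (logical,
#'   0/1, or `"case"`/`"control"`).
#' @param data data.frame with one row per subject.
#' @param pair name of the pair-identifier column.
#' @param tol convergence criterion on `max(abs(step))` (default 1e-8).
#' @param max_iter maximum Newton iterations (default 50).
#' @return An object of class `c("pair_clogit", "safbdg_fit")` with
#'   `coefficients`, `vcov`, `se`, `loglik`, `n_pairs`,
#'   `n_informative_pairs`, `converged` and `iterations`; see
#'   [summary.safbdg_fit()].
#' @examples
#' d <- simulate_pairs(200, or_high = 0.5, seed = 1)
#' fit <- clogit_pair(status == "case" ~ adherence_cat, d, pair = "pair_id")
#' summary(fit)
#' @export
clogit_pair <- function(formula, data, pair, tol = 1e-8, max_iter = 50L) {
  stopifnot(is.character(pair), pair %in% names(data))
  cl <- match.call()
  mf <- stats::model.frame(formula, data, na.action = stats::na.pass)
  keep <- stats::complete.cases(mf)
  pid <- as.character(data[[pair]])
  y <- .as_case(stats::model.response(mf))
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  asgn <- attr(X, "assign")
  if ("(Intercept)" %in% colnames(X)) {
    X <- X[, -1, drop = FALSE]
    asgn <- asgn[-1]
  }
  if (!ncol(X)) stop("model has no covariates", call. = FALSE)

  # complete-case within the model, then require both pair members
  ok_pairs <- names(which(tapply(keep, pid, sum) == 2L &
                            tapply(pid, pid, length) == 2L))
  use <- keep & pid %in% ok_pairs
  n_dropped <- length(unique(pid)) - length(ok_pairs)
  if (n_dropped > 0) {
    message(n_dropped, " pair(s) dropped (missing values or incomplete pair)")
  }
  pid <- pid[use]; y <- y[use]; X <- X[use, , drop = FALSE]
  o <- order(pid, !y)  # case row first within each pair
  pid <- pid[o]; y <- y[o]; X <- X[o, , drop = FALSE]
  cs <- table(factor(y, c(TRUE, FALSE)), pid)
  if (any(cs != 1L)) {
    stop("pairing error: each pair must hold exactly one case and one ",
         "control; offending pair(s): ",
         paste(colnames(cs)[colSums(cs == 1L) != 2L], collapse = ", "),
         call. = FALSE)
  }
  idx_case <- seq(1, length(y), by = 2)
  D <- X[idx_case, , drop = FALSE] - X[idx_case + 1, , drop = FALSE]
  n_pairs <- nrow(D)

  zero_col <- apply(D == 0, 2, all)
  expo_cols <- asgn == asgn[1]
  if (all(zero_col[expo_cols])) {
    stop("exposure '", colnames(X)[1], "' is concordant within every pair: ",
         "conditional likelihood is flat (non-identifiable)", call. = FALSE)
  }
  if (any(zero_col)) {
    warning("dropping term(s) constant within all pairs: ",
            paste(colnames(D)[zero_col], collapse = ", "), call. = FALSE)
    D <- D[, !zero_col, drop = FALSE]
  }
  informative <- rowSums(D != 0) > 0
  n_info <- sum(informative)
  if (n_info < 1) stop("fewer than 1 informative pair", call. = FALSE)

  fit <- .newton_clogit(D, tol = tol, max_iter = max_iter)
  se <- sqrt(diag(fit$vcov))
  structure(
    list(coefficients = stats::setNames(fit$beta, colnames(D)),
         vcov = structure(fit$vcov, dimnames = list(colnames(D),
                                                    colnames(D))),
         se = stats::setNames(se, colnames(D)),
         loglik = fit$loglik,
         n_pairs = n_pairs, n_informative_pairs = n_info,
         n_dropped_pairs = n_dropped,
         converged = fit$converged, iterations = fit$iterations,
         diffs = D, call = cl, formula = formula),
    class = c("pair_clogit", "safbdg_fit")
  )
}

.as_case <- function(y) {
  if (is.logical(y)) return(y)
  if (is.factor(y)) y <- as.character(y)
  if (is.character(y)) {
    if (!all(y %in% .status_levels)) {
      stop("response must be logical, 0/1 or 'case'/'control'", call. = FALSE)
    }
    return(y == "case")
  }
  if (is.numeric(y) && all(y %in% 0:1)) return(y == 1)
  stop("response must be logical, 0/1 or 'case'/'control'", call. = FALSE)
}

# Newton-Raphson on l(b) = sum log plogis(D b). Gradient t(D)(1 - p),
# Hessian -t(D) W D with W = diag(p(1-p)).
.newton_clogit <- function(D, tol = 1e-8, max_iter = 50L) {
  beta <- rep(0, ncol(D))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(D %*% beta)
    p <- stats::plogis(eta)
    g <- drop(crossprod(D, 1 - p))
    W <- p * (1 - p)
    H <- crossprod(D * sqrt(W))
    step <- tryCatch(solve(H, g), error = function(e) {
      if (max(abs(beta)) > 8) {
        worst <- colnames(D)[which.max(abs(beta))]
        stop("no finite estimate: separation detected for term '", worst,
             "'", call. = FALSE)
      }
      stop("singular information matrix (collinear terms)", call. = FALSE)
    })
    # dampen absurd steps to keep the iteration stable near separation
    if (max(abs(step)) > 5) step <- step * 5 / max(abs(step))
    beta <- beta + step
    if (max(abs(step)) < tol) {
      converged <- TRUE
      break
    }
    if (max(abs(beta)) > 12 && max(abs(g)) > 1e-3) {
      worst <- colnames(D)[which.max(abs(beta))]
      stop("no finite estimate: separation detected for term '", worst, "'",
           call. = FALSE)
    }
  }
  if (!converged) {
    worst <- colnames(D)[which.max(abs(beta))]
    stop("Newton-Raphson failed to converge (suspected separation, term '",
         worst, "')", call. = FALSE)
  }
  eta <- drop(D %*% beta)
  p <- stats::plogis(eta)
  H <- crossprod(D * sqrt(p * (1 - p)))
  list(beta = beta, vcov = solve(H), loglik = sum(log(p)),
       converged = converged, iterations = it)
}

#' Unconditional logistic regression with the matched-fit result contract
#'
#' Thin wrapper around `stats::glm(..., family = binomial())` used for
#' strata that break the matching (e.g. menopausal or obesity strata).
#' Errors on apparent separation instead of returning divergent estimates.
#'
#' @param formula model formula with a case indicator response.
#' @param data data.frame, one row per subject.
#' @return An object of class `c("uncond_logit", "safbdg_fit")`.
#' @export
fit_logit <- function(formula, data) {
  mf <- stats::model.frame(formula, data)
  y <- .as_case(stats::model.response(mf))
  if (length(unique(y)) < 2) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  g <- suppressWarnings(
    stats::glm.fit(X, as.numeric(y), family = stats::binomial()))
  cf <- stats::setNames(g$coefficients, colnames(X))
  if (!g$converged || max(abs(cf), na.rm = TRUE) > 12) {
    worst <- names(which.max(abs(cf)))
    stop("no finite estimate: separation detected for term '", worst, "'",
         call. = FALSE)
  }
  w <- g$weights
  V <- solve(crossprod(X * sqrt(w)))
  dimnames(V) <- list(colnames(X), colnames(X))
  mu <- g$fitted.values
  structure(
    list(coefficients = cf, vcov = V, se = sqrt(diag(V)),
         loglik = sum(stats::dbinom(as.numeric(y), 1, mu, log = TRUE)),
         n_subjects = nrow(mf), converged = g$converged,
         iterations = g$iter, call = match.call(), formula = formula),
    class = c("uncond_logit", "safbdg_fit")
  )
}

#' @export
coef.safbdg_fit <- function(object, ...) object$coefficients

#' @export
vcov.safbdg_fit <- function(object, ...) object$vcov

#' @export
logLik.safbdg_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            class = "logLik")
}

#' @export
confint.safbdg_fit <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  est <- object$coefficients
  ci <- cbind(est - z * object$se, est + z * object$se)
  colnames(ci) <- sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                             1 - (1 - level) / 2))
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' Odds-ratio table for a fitted model
#'
#' @param object a fit from [clogit_pair()] or [fit_logit()].
#' @param level confidence level (default 0.95, Wald).
#' @return data.frame: `term`, `beta`, `se`, `or`, `ci_lo`, `ci_hi`, `z`,
#'   `p` (intercepts omitted).
#' @export
or_table <- function(object, level = 0.95) {
  est <- object$coefficients
  se <- object$se
  keep <- names(est) != "(Intercept)"
  est <- est[keep]; se <- se[keep]
  z <- est / se
  q <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(term = names(est), beta = unname(est), se = unname(se),
             or = exp(unname(est)),
             ci_lo = exp(unname(est - q * se)),
             ci_hi = exp(unname(est + q * se)),
             z = unname(z), p = 2 * stats::pnorm(-abs(unname(z))),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.safbdg_fit <- function(x, ...) {
  kind <- if (inherits(x, "pair_clogit")) {
    sprintf("1:1 conditional logistic fit (%d pairs, %d informative)",
            x$n_pairs, x$n_informative_pairs)
  } else {
    sprintf("unconditional logistic fit (%d subjects)", x$n_subjects)
  }
  cat(kind, "\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Summarise a fitted matched or unconditional logistic model
#'
#' @param object a `safbdg_fit`.
#' @param level Wald confidence level.
#' @param ... unused.
#' @export
summary.safbdg_fit <- function(object, level = 0.95, ...) {
  structure(list(fit = object, table = or_table(object, level = level),
                 level = level),
            class = "summary.safbdg_fit")
}

#' @export
print.summary.safbdg_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("\nWald %g%% intervals:\n", 100 * x$level))
  tab <- x$table
  tab[2:8] <- lapply(tab[2:8], function(v) signif(v, 4))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
predict.pair_clogit <- function(object, ...) {
  # fitted within-pair probability that the observed case is the case
  stats::plogis(drop(object$diffs %*% object$coefficients))
}

#' @export
residuals.pair_clogit <- function(object, ...) {
  1 - predict.pair_clogit(object)
}
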