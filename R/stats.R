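#' Recurrence by rotational-activity location class
#'
#' Tabulates post-ablation recurrence per RAc location class (no RAc / RAc
#' only inside the ablation line / RAc outside). Percentages are kept at
#' full precision; the display column rounds half-up to one decimal.
#'
#' @param cohort a `cohort_table` (or any data.frame with
#'   `rac_location_class` and logical `recurrence`)
#' @param blanking_days patients with follow-up at or below this are
#'   excluded (default 90, the 3-month blanking window); set to `NULL` or
#'   use a table without `follow_up_days` to skip
#' @return data.frame: `class`, `n`, `recurrence`, `recurrence_pct`,
#'   `recurrence_pct_display` (NA for empty classes)
#' @export
recurrence_by_rac_location <- function(cohort, blanking_days = 90) {
  if (!is.null(blanking_days) && "follow_up_days" %in% names(cohort)) {
    cohort <- cohort[cohort$follow_up_days > blanking_days, , drop = FALSE]
  }
  cls <- factor(cohort$rac_location_class,
                levels = c("none", "inside_only", "outside"))
  n <- as.integer(table(cls))
  rec <- as.integer(tapply(cohort$recurrence, cls, sum, default = 0L))
  pct <- ifelse(n > 0, 100 * rec / n, NA_real_)
  data.frame(class = levels(cls), n = n, recurrence = rec,
             recurrence_pct = pct,
             recurrence_pct_display = round_half_up(pct, 1L),
             stringsAsFactors = FALSE)
}

#' Round half away from zero (display convention of printed tables)
#' @param x numeric
#' @param digits decimal places
#' @return rounded numeric
#' @export
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Pearson chi-square test for a contingency table
#'
#' Continuity correction is off by default, matching the convention of
#' mapping-cohort reports.
#'
#' @param contingency matrix of non-negative integer counts
#' @param correct apply Yates continuity correction (default FALSE)
#' @return list `statistic`, `df`, `p`, `expected`
#' @export
chi_square_test <- function(contingency, correct = FALSE) {
  contingency <- as.matrix(contingency)
  .check_table(contingency)
  res <- stats::chisq.test(contingency, correct = correct)
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value, expected = res$expected)
}

#' Fisher's exact test for a contingency table
#'
#' @param contingency matrix of non-negative integer counts
#' @return list `p`, and for 2x2 tables `odds_ratio` (conditional MLE)
#' @export
fisher_exact <- function(contingency) {
  contingency <- as.matrix(contingency)
  .check_table(contingency)
  res <- stats::fisher.test(contingency)
  list(p = res$p.value,
       odds_ratio = if (!is.null(res$estimate)) unname(res$estimate))
}

#' Contingency test chosen by the expected-count rule
#'
#' Fisher's exact test when any expected cell of a 2x2 table is below 5,
#' Pearson chi-square otherwise.
#'
#' @param contingency matrix of counts
#' @return the chosen test's result with a `method` element
#' @export
contingency_test <- function(contingency) {
  contingency <- as.matrix(contingency)
  .check_table(contingency)
  expected <- outer(rowSums(contingency), colSums(contingency)) /
    sum(contingency)
  if (all(dim(contingency) == 2L) && any(expected < 5)) {
    c(fisher_exact(contingency), method = "fisher")
  } else {
    c(chi_square_test(contingency), method = "chi-square")
  }
}

.check_table <- function(tab) {
  if (any(tab < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("undefined test: zero margin in the contingency table", call. = FALSE)
  }
}

#' Welch's two-sample t-test
#'
#' @param x,y numeric samples (n >= 2 each)
#' @return list `statistic`, `df` (Welch-Satterthwaite), `p` (two-sided)
#' @export
welch_t_test <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) stop("need n >= 2 per arm", call. = FALSE)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) return(list(statistic = 0, df = NA_real_, p = 1))
    stop("undefined t: zero variance in both arms", call. = FALSE)
  }
  res <- stats::t.test(x, y)
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' Two-proportion z-test (pooled standard error)
#'
#' @param k1,n1,k2,n2 successes and sizes of the two arms
#' @return list `statistic` (z), `p` (two-sided)
#' @export
proportion_z_test <- function(k1, n1, k2, n2) {
  stopifnot(n1 >= 1L, n2 >= 1L, k1 <= n1, k2 <= n2)
  p1 <- k1 / n1; p2 <- k2 / n2
  p <- (k1 + k2) / (n1 + n2)
  se <- sqrt(p * (1 - p) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (p1 - p2) / se
  list(statistic = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Logistic odds ratio for a binary outcome
#'
#' Maximum-likelihood logistic regression; OR = exp(coefficient) with a Wald
#' 95% CI. The multivariate adjustment set of the recurrence analysis is
#' LA volume, LA area and the scar (< 0.5 mV) area fraction.
#' `method = "firth"` fits Firth's bias-reduced logistic regression
#' (Jeffreys-prior penalized score), whose Wald intervals are better
#' calibrated in small cohorts and which remains finite under separation.
#'
#' @param cohort data.frame
#' @param outcome name of the binary outcome column (default `"recurrence"`)
#' @param exposure name of the exposure column (logical/binary or numeric)
#' @param adjustment_set character vector of adjustment columns (NULL =
#'   univariate)
#' @param method `"ml"` (maximum likelihood, default) or `"firth"`
#' @param penalized under `"ml"` on separation, refit with a small ridge
#'   penalty instead of failing (CI not reported in that mode)
#' @return an `or_result`: `odds_ratio`, `ci_low`, `ci_high`, `p`,
#'   `exposure`, `adjustment_set`, `method`, `penalized`
#' @export
logistic_or <- function(cohort, outcome = "recurrence", exposure,
                        adjustment_set = NULL, method = c("ml", "firth"),
                        penalized = FALSE) {
  method <- match.arg(method)
  stopifnot(exposure %in% names(cohort), outcome %in% names(cohort))
  y <- cohort[[outcome]]
  if (!all(y %in% c(0, 1, TRUE, FALSE))) stop("outcome must be binary", call. = FALSE)
  rhs <- paste(c(exposure, adjustment_set), collapse = " + ")
  fml <- stats::as.formula(paste(outcome, "~", rhs))
  if (method == "firth") {
    X <- stats::model.matrix(fml, cohort)
    f <- .firth_logistic(X, as.numeric(cohort[[outcome]]))
    b <- f$beta[2L]; se <- f$se[2L]
    return(structure(list(odds_ratio = exp(b),
                          ci_low = exp(b - 1.96 * se),
                          ci_high = exp(b + 1.96 * se),
                          p = 2 * stats::pnorm(-abs(b / se)),
                          exposure = exposure,
                          adjustment_set = adjustment_set,
                          method = "firth",
                          penalized = FALSE),
                     class = "or_result"))
  }
  fit <- suppressWarnings(stats::glm(fml, family = stats::binomial(), data = cohort))
  co <- summary(fit)$coefficients
  b <- co[2L, 1L]; se <- co[2L, 2L]
  separated <- !fit$converged || abs(b) > 15 || se > 100
  if (separated) {
    if (!penalized) {
      stop("complete separation detected; refit with penalized = TRUE",
           call. = FALSE)
    }
    # weak ridge via prior pseudo-observations (Gaussian prior on coefficients)
    X <- stats::model.matrix(fml, cohort)
    yv <- as.numeric(cohort[[outcome]])
    ridge <- 1e-2
    fit2 <- stats::optim(rep(0, ncol(X)), function(beta) {
      eta <- X %*% beta
      -sum(yv * eta - log1p(exp(eta))) + ridge * sum(beta[-1L]^2)
    }, method = "BFGS")
    b <- fit2$par[2L]
    return(structure(list(odds_ratio = exp(b), ci_low = NA_real_,
                          ci_high = NA_real_, p = NA_real_,
                          exposure = exposure,
                          adjustment_set = adjustment_set,
                          method = "ml",
                          penalized = TRUE),
                     class = "or_result"))
  }
  structure(list(odds_ratio = exp(b),
                 ci_low = exp(b - 1.96 * se),
                 ci_high = exp(b + 1.96 * se),
                 p = co[2L, 4L],
                 exposure = exposure,
                 adjustment_set = adjustment_set,
                 method = "ml",
                 penalized = FALSE),
            class = "or_result")
}

# Firth bias-reduced logistic regression: Newton iterations on the
# Jeffreys-penalized score, Wald SEs from the observed information
.firth_logistic <- function(X, y, max_iter = 50L, tol = 1e-8) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- as.vector(X %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    XW <- X * w
    info_inv <- chol2inv(chol(crossprod(X, XW)))
    h <- rowSums((X %*% info_inv) * XW)          # hat diagonals
    score <- crossprod(X, y - mu + h * (0.5 - mu))
    delta <- info_inv %*% score
    beta <- beta + as.vector(delta)
    if (max(abs(delta)) < tol) break
  }
  eta <- as.vector(X %*% beta)
  w <- stats::plogis(eta) * (1 - stats::plogis(eta))
  se <- sqrt(diag(chol2inv(chol(crossprod(X, X * w)))))
  list(beta = as.vector(beta), se = se)
}

#' @export
print.or_result <- function(x, ...) {
  cat(sprintf("OR %.2f (95%% CI %.2f-%.2f), p = %.3g [%s%s]\n",
              x$odds_ratio, x$ci_low, x$ci_high, x$p, x$exposure,
              if (length(x$adjustment_set))
                paste0(" | ", paste(x$adjustment_set, collapse = ", "))
              else ""))
  invisible(x)
}

#' Propensity-score matching
#'
#' Logistic propensity model for group membership followed by greedy
#' nearest-neighbor 1:1 matching without replacement on the logit of the
#' propensity score, within a caliper of `caliper` times the SD of the
#' logit. Treated subjects with no control in the caliper are reported, not
#' silently dropped. Standardized mean differences (SMD) are reported before
#' and after matching.
#'
#' @param cohort data.frame
#' @param treatment column name; its second factor level (or TRUE) is
#'   "treated"
#' @param covariates character vector of covariate columns
#' @param caliper caliper in SD units of the logit propensity (default 0.2)
#' @return a `ps_match` object: `matched` (data.frame with `pair_id`),
#'   `unmatched_treated` (row indices), `balance` (SMD before/after per
#'   covariate and for the propensity score), `propensity`
#' @export
propensity_match <- function(cohort, treatment = "gender",
                             covariates = c("age", "hypertension",
                                            "chads_vasc", "bsa_m2"),
                             caliper = 0.2) {
  miss <- !stats::complete.cases(cohort[, c(treatment, covariates)])
  n_missing <- sum(miss)
  cohort <- cohort[!miss, , drop = FALSE]
  tr <- cohort[[treatment]]
  treated <- if (is.factor(tr)) tr == levels(tr)[2L] else as.logical(tr)
  fml <- stats::as.formula(paste(treatment, "~",
                                 paste(covariates, collapse = " + ")))
  ps_fit <- stats::glm(fml, family = stats::binomial(), data = cohort)
  logit <- stats::qlogis(pmin(1 - 1e-12, pmax(1e-12, stats::fitted(ps_fit))))
  cal <- caliper * stats::sd(logit)

  ti <- which(treated); ci <- which(!treated)
  used <- logical(length(ci))
  pairs <- list()
  unmatched <- integer(0)
  for (i in ti[order(-logit[ti])]) {
    d <- abs(logit[ci] - logit[i])
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && is.finite(d[j]) && d[j] <= cal) {
      used[j] <- TRUE
      pairs[[length(pairs) + 1L]] <- c(i, ci[j])
    } else {
      unmatched <- c(unmatched, i)
    }
  }
  midx <- if (length(pairs)) as.vector(t(do.call(rbind, pairs))) else integer(0)
  matched <- cohort[midx, , drop = FALSE]
  if (length(pairs)) matched$pair_id <- rep(seq_along(pairs), each = 2L)

  smd <- function(x, grp) {
    x <- as.numeric(x)
    m1 <- mean(x[grp]); m0 <- mean(x[!grp])
    s <- sqrt((stats::var(x[grp]) + stats::var(x[!grp])) / 2)
    if (!is.finite(s) || s == 0) return(0)
    (m1 - m0) / s
  }
  vars <- c(covariates, ".propensity")
  dat_before <- cbind(cohort[, covariates, drop = FALSE], .propensity = logit)
  balance <- data.frame(
    covariate = vars,
    smd_before = vapply(vars, function(v) smd(dat_before[[v]], treated), numeric(1)),
    smd_after = NA_real_, stringsAsFactors = FALSE)
  if (length(pairs)) {
    mt <- treated[midx]
    dat_after <- cbind(cohort[midx, covariates, drop = FALSE],
                       .propensity = logit[midx])
    balance$smd_after <- vapply(vars, function(v) smd(dat_after[[v]], mt), numeric(1))
  }
  structure(list(matched = matched,
                 unmatched_treated = unmatched,
                 n_missing_excluded = n_missing,
                 balance = balance,
                 propensity = logit,
                 caliper_logit = cal),
            class = "ps_match")
}

#' @export
print.ps_match <- function(x, ...) {
  cat("ps_match:", nrow(x$matched) / 2, "pairs,",
      length(x$unmatched_treated), "unmatched treated\n")
  print(x$balance, digits = 2)
  invisible(x)
}
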