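test_that("recurrence by driver location reproduces the worked example", {
  counts <- read.csv(system.file("extdata",
                                 "recurrence_by_rac_location_counts.csv",
                                 package = "afdm"))
  tab <- recurrence_by_rac_location(counts_to_cohort(counts),
                                    blanking_days = NULL)
  expect_equal(tab$class, c("none", "inside_only", "outside"))
  expect_equal(tab$n, c(29L, 9L, 41L))
  expect_equal(tab$recurrence_pct_display, c(31.0, 11.1, 63.4))
  # an all-recurrence cohort is 100% in every non-empty class
  all_rec <- counts_to_cohort(data.frame(class = c("none", "outside"),
                                         n = c(5, 4), recurrence = c(5, 4)))
  t2 <- recurrence_by_rac_location(all_rec, blanking_days = NULL)
  expect_equal(t2$recurrence_pct[t2$n > 0], c(100, 100))
  expect_true(is.na(t2$recurrence_pct[t2$class == "inside_only"]))
  # synthetic cohorts match a direct group-by oracle (after blanking)
  co <- simulate_cohort(cohort_spec(seed = 8))
  got <- recurrence_by_rac_location(co)
  kept <- co[co$follow_up_days > 90, ]
  oracle <- vapply(c("none", "inside_only", "outside"), function(cl)
    100 * sum(kept$recurrence[kept$rac_location_class == cl]) /
      sum(kept$rac_location_class == cl), numeric(1))
  expect_equal(got$recurrence_pct, unname(oracle))
})

test_that("chi-square equals the textbook statistic and the printed p-value", {
  tab <- matrix(c(47, 17, 8, 13), nrow = 2, byrow = TRUE)
  res <- chi_square_test(tab)
  # oracle: sum (O-E)^2 / E with expected counts from the margins
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(res$statistic, sum((tab - E)^2 / E), tolerance = 1e-12)
  expect_equal(round(res$p, 3), 0.003)
  # independent table -> statistic 0, p 1
  ind <- matrix(c(20, 40, 10, 20), 2, byrow = TRUE)
  res2 <- chi_square_test(ind)
  expect_equal(res2$statistic, 0, tolerance = 1e-12)
  expect_equal(res2$p, 1)
  expect_error(chi_square_test(matrix(c(0, 0, 3, 5), 2)), "zero margin")
  # random tables keep matching the oracle
  set.seed(11)
  for (i in 1:20) {
    t3 <- matrix(rpois(4, 15) + 1, 2)
    expect_equal(chi_square_test(t3)$statistic,
                 sum((t3 - outer(rowSums(t3), colSums(t3)) / sum(t3))^2 /
                       (outer(rowSums(t3), colSums(t3)) / sum(t3))),
                 tolerance = 1e-9)
  }
})

test_that("Fisher p equals full hypergeometric enumeration on small tables", {
  fisher_oracle <- function(tab) {
    # enumerate all tables with the observed margins
    r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
    ks <- max(0, c1 - (n - r1)):min(r1, c1)
    probs <- dhyper(ks, r1, n - r1, c1)
    sum(probs[probs <= dhyper(tab[1, 1], r1, n - r1, c1) * (1 + 1e-7)])
  }
  set.seed(12)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 4) + 1, 2)
    if (sum(tab) > 40) next
    expect_equal(fisher_exact(tab)$p, fisher_oracle(tab), tolerance = 1e-9)
  }
  # the expected-count rule picks Fisher for sparse 2x2 tables
  sparse <- matrix(c(1, 9, 8, 2), 2)
  expect_equal(contingency_test(sparse)$method, "fisher")
  dense <- matrix(c(30, 20, 25, 35), 2)
  expect_equal(contingency_test(dense)$method, "chi-square")
})

test_that("Welch t and proportion z behave at their fixed points", {
  x <- c(1.2, 1.7, 0.9, 1.4)
  res <- welch_t_test(x, x)
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
  # closed-form power check: two unit-variance arms one SD apart
  set.seed(13)
  a <- rnorm(1000, 0); b <- rnorm(1000, 1)
  expect_lt(welch_t_test(a, b)$p, 1e-10)
  # oracle: the Welch-Satterthwaite statistic by hand
  y <- c(2.1, 2.5, 3.0, 1.8, 2.2)
  byhand <- (mean(x) - mean(y)) / sqrt(var(x) / 4 + var(y) / 5)
  expect_equal(welch_t_test(x, y)$statistic, byhand, tolerance = 1e-12)
  expect_equal(proportion_z_test(25, 50, 10, 20)$statistic, 0)
  z <- proportion_z_test(30, 50, 15, 50)
  p <- 45 / 100
  se <- sqrt(p * (1 - p) * (2 / 50))
  expect_equal(z$statistic, (0.6 - 0.3) / se, tolerance = 1e-12)
  expect_error(welch_t_test(1, c(1, 2)), "n >= 2")
})

test_that("logistic ORs reduce to the 2x2 cross-product on binary exposure", {
  # collapsed contingency data (26,15 / 10,28): OR = 26*28 / (15*10)
  co <- data.frame(
    exposure = rep(c(TRUE, TRUE, FALSE, FALSE), c(26, 15, 10, 28)),
    recurrence = rep(c(TRUE, FALSE, TRUE, FALSE), c(26, 15, 10, 28)))
  fit <- logistic_or(co, exposure = "exposure")
  expect_equal(fit$odds_ratio, (26 * 28) / (15 * 10), tolerance = 1e-6)
  expect_lt(fit$ci_low, fit$odds_ratio)
  expect_gt(fit$ci_high, fit$odds_ratio)
  # null exposure at n = 10,000 gives OR ~ 1
  set.seed(14)
  nul <- data.frame(exposure = runif(10000) < 0.5,
                    recurrence = runif(10000) < 0.4)
  expect_equal(logistic_or(nul, exposure = "exposure")$odds_ratio, 1,
               tolerance = 0.12)
  # Firth fit on a single binary exposure equals the 0.5-corrected
  # cross-product (Haldane-Anscombe identity for the Jeffreys penalty)
  firth <- logistic_or(co, exposure = "exposure", method = "firth")
  expect_equal(firth$odds_ratio,
               (26.5 * 28.5) / (15.5 * 10.5), tolerance = 1e-5)
  expect_true(firth$ci_low < firth$odds_ratio)
  # complete separation is detected, penalized mode returns an estimate
  sep <- data.frame(exposure = rep(c(TRUE, FALSE), each = 20),
                    recurrence = rep(c(TRUE, FALSE), each = 20))
  expect_error(logistic_or(sep, exposure = "exposure"), "separation")
  pen <- logistic_or(sep, exposure = "exposure", penalized = TRUE)
  expect_true(pen$penalized)
  expect_true(is.finite(pen$odds_ratio))
})

test_that("propensity matching balances confounded cohorts", {
  co <- simulate_cohort(confounded_cohort_spec(seed = 15))
  pm <- propensity_match(co, caliper = 0.05)
  covs <- c("age", "hypertension", "chads_vasc", "bsa_m2")
  before <- pm$balance$smd_before[match(covs, pm$balance$covariate)]
  after <- pm$balance$smd_after[match(covs, pm$balance$covariate)]
  expect_gt(max(abs(before)), 0.3)           # genuinely confounded
  expect_true(all(abs(after) < 0.1))
  # matching never worsens the propensity-score imbalance
  ps_row <- pm$balance$covariate == ".propensity"
  expect_lte(abs(pm$balance$smd_after[ps_row]),
             abs(pm$balance$smd_before[ps_row]))
  # caliper 0 keeps only exact-score matches
  pm0 <- propensity_match(co, caliper = 0)
  if (nrow(pm0$matched)) {
    tr <- pm0$matched$gender == "women"
    expect_equal(pm0$propensity[as.integer(rownames(pm0$matched))[tr]],
                 pm0$propensity[as.integer(rownames(pm0$matched))[!tr]],
                 tolerance = 1e-12)
  }
  # an unconfounded treatment retains nearly all treated
  set.seed(16)
  rnd <- data.frame(gender = factor(sample(c("men", "women"), 400, TRUE,
                                           prob = c(0.7, 0.3)),
                                    levels = c("men", "women")),
                    age = rnorm(400, 60, 9),
                    hypertension = runif(400) < 0.5,
                    chads_vasc = rpois(400, 2),
                    bsa_m2 = rnorm(400, 2, 0.2))
  pm_r <- propensity_match(rnd)
  expect_gt(nrow(pm_r$matched) / 2 / sum(rnd$gender == "women"), 0.95)
})

test_that("cohort tables recompute their cells and flag degenerate input", {
  co <- simulate_cohort(cohort_spec(seed = 17))
  t1 <- build_table(co, "table1")
  row <- t1[t1$variable == "age", ]
  expect_equal(row$overall, sprintf("%.1f (%.1f)", mean(co$age), sd(co$age)))
  oracle_p <- welch_t_test(co$age[co$gender == "men"],
                           co$age[co$gender == "women"])$p
  expect_equal(row$p, oracle_p)
  t3 <- build_table(co, "table3")
  loc <- attr(t3, "rac_location")
  expect_s3_class(loc, "data.frame")
  kept <- co[co$follow_up_days > 90, ]
  expect_equal(sum(loc$n), nrow(kept))
  men <- co[co$gender == "men", ]
  t1m <- build_table(men, "table1")
  expect_true(all(is.na(t1m$p)))
  expect_match(attr(t1m, "flag"), "single-group")
  expect_error(build_table(co[, setdiff(names(co), "age")], "table1"),
               "age")
})
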