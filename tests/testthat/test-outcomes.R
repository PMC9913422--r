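test_that("best response follows the mRECIST ordering with the earliest achieving day", {
  r <- best_response(data.frame(day = c(90, 180),
                                mrecist = c("SD", "CR")))
  expect_equal(r$best, "CR"); expect_equal(r$day, 180)
  expect_true(r$complete_response); expect_true(r$objective_response)

  r2 <- best_response(data.frame(day = 90, mrecist = "PR"))
  expect_equal(r2$best, "PR"); expect_equal(r2$day, 90)
  expect_false(r2$complete_response); expect_true(r2$objective_response)

  r3 <- best_response(data.frame(day = c(90, 180, 270),
                                 mrecist = c("PD", "SD", "SD")))
  expect_equal(r3$best, "SD"); expect_equal(r3$day, 180)
  expect_false(r3$objective_response)

  expect_equal(best_response("90:SD;180:CR")$best, "CR")
  expect_error(best_response(data.frame(day = 90, mrecist = "XX")),
               "unknown mRECIST")
  expect_error(best_response(data.frame(day = numeric(0),
                                        mrecist = character(0))), "empty")
  # objective response is implied by complete response for every category
  for (lab in c("CR", "PR", "SD", "PD")) {
    b <- best_response(data.frame(day = 30, mrecist = lab))
    expect_true(!b$complete_response || b$objective_response)
  }
})

test_that("the univariate screen keeps separating features, drops constants, obeys alpha", {
  set.seed(20)
  n <- 60
  d <- data.frame(y = rep(c(0, 1), each = n / 2))
  d$sep <- ifelse(d$y == 1, rnorm(n / 2, 10), rnorm(n / 2, 0))
  d$null <- rnorm(n)
  d$const <- 5
  expect_warning(scr <- univariate_screen(d, c("sep", "null", "const"),
                                          outcome = "y"), "constant")
  expect_true(scr$selected[scr$feature == "sep"])
  expect_false(scr$selected[scr$feature == "const"])

  scr_all <- suppressWarnings(
    univariate_screen(d, c("sep", "null"), outcome = "y", alpha = 1))
  expect_true(all(scr_all$selected))
  expect_error(univariate_screen(data.frame(y = rep(1, 10), x = rnorm(10)),
                                 "x", outcome = "y"), "classes")
})

test_that("a null feature passes the 0.20 screen at roughly the nominal rate", {
  set.seed(33)
  n <- 80
  hits <- vapply(1:300, function(i) {
    d <- data.frame(y = rbinom(n, 1, 0.5), x = rnorm(n))
    univariate_screen(d, "x", outcome = "y")$selected
  }, logical(1))
  rate <- mean(hits)
  expect_gt(rate, 0.20 - 3 * sqrt(0.2 * 0.8 / 300))
  expect_lt(rate, 0.20 + 3 * sqrt(0.2 * 0.8 / 300))
})

test_that("logistic MVA: null intercept, closed-form 2x2 coefficient, guards", {
  d <- data.frame(y = rep(c(0, 1), 50))
  m0 <- logistic_mva(d, character(0), "y")
  expect_lt(abs(m0$coefficients[1, "estimate"]), 1e-8)

  # single binary predictor: coefficient is the log odds ratio of the table
  set.seed(8)
  n <- 400
  x <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, ifelse(x == 1, 0.7, 0.4))
  d2 <- data.frame(x = x, y = y)
  m <- logistic_mva(d2, "x", "y")
  tab <- table(x, y)
  lor <- log(tab["1", "1"] * tab["0", "0"] / (tab["1", "0"] * tab["0", "1"]))
  expect_equal(unname(m$coefficients["x", "estimate"]), lor,
               tolerance = 1e-6)
  expect_true(all(m$fitted_probabilities > 0 & m$fitted_probabilities < 1))
  expect_gt(m$auc, 0.5)

  expect_error(logistic_mva(d2[1:10, ], c("x"), "y"), "10 x")
  sep <- data.frame(y = rep(c(0, 1), each = 30),
                    x = c(rnorm(30, 0, 0.1), rnorm(30, 10, 0.1)))
  expect_error(suppressWarnings(logistic_mva(sep, "x", "y")), "separation")
})

test_that("logistic MVA prunes near-duplicate dosimetric features", {
  set.seed(10)
  n <- 300
  x1 <- rnorm(n)
  d <- data.frame(x1 = x1, x2 = x1 + rnorm(n, 0, 0.01), x3 = rnorm(n))
  d$y <- rbinom(n, 1, plogis(x1))
  expect_message(m <- logistic_mva(d, c("x1", "x2", "x3"), "y"),
                 "collinear")
  expect_identical(m$dropped, "x2")
  expect_identical(m$features, c("x1", "x3"))
})

test_that("Cox MVA: null effect inside 3 SE, duplication near-invariance, error when all censored", {
  set.seed(15)
  n <- 1000
  d <- data.frame(x = rnorm(n), t = rexp(n, 0.1),
                  e = runif(n) < 0.8)
  m <- cox_mva(d, "x", "t", "e")
  expect_lt(abs(m$coefficients["x", "coef"]),
            3 * m$coefficients["x", "se"])

  d2 <- d[1:100, ]
  m1 <- cox_mva(d2, "x", "t", "e")
  mdup <- cox_mva(rbind(d2, d2), "x", "t", "e")
  expect_equal(unname(mdup$coefficients["x", "coef"]),
               unname(m1$coefficients["x", "coef"]), tolerance = 0.05)

  dc <- data.frame(x = rnorm(20), t = rexp(20), e = FALSE)
  expect_error(cox_mva(dc, "x", "t", "e"), "censored")
  expect_error(cox_mva(data.frame(x = 1:5, t = c(-1, 1, 2, 3, 4),
                                  e = TRUE), "x", "t", "e"), "> 0")
})

test_that("Cox recovers a known hazard ratio of 2", {
  set.seed(44)
  n <- 1000
  grp <- rep(c(0, 1), each = n / 2)
  t <- rexp(n, 0.05 * 2^grp)
  d <- data.frame(grp = grp, t = t, e = TRUE)
  m <- cox_mva(d, "grp", "t", "e")
  hr <- m$coefficients["grp", "hazard_ratio"]
  expect_gt(hr, 1.7); expect_lt(hr, 2.35)
})

test_that("KM and log-rank: identical groups give a null test; no censoring is exact", {
  t0 <- c(1, 2, 3, 4, 6, 9, 12, 15)
  d <- data.frame(t = rep(t0, 2), e = TRUE,
                  g = rep(c("a", "b"), each = length(t0)))
  km <- km_logrank(d$t, d$e, d$g)
  expect_lt(km$logrank_chisq, 1e-10)
  expect_equal(km$p_value, 1, tolerance = 1e-6)

  # no censoring, times 1..4: survival after time 2 is 0.5
  km2 <- km_logrank(c(1, 2, 3, 4, 1, 2, 3, 4), rep(TRUE, 8),
                    rep(c("a", "b"), each = 4))
  cv <- km2$curves[["a"]]
  expect_equal(cv$surv[cv$time == 2], 0.5)
  # KM with no censoring equals the empirical survivor function
  set.seed(3)
  tt <- rexp(100, 0.2)
  kme <- km_logrank(c(tt, tt + 0.01), rep(TRUE, 200),
                    rep(c("a", "b"), each = 100))
  cva <- kme$curves[["a"]]
  emp <- vapply(cva$time, function(x) mean(tt > x), numeric(1))
  expect_equal(cva$surv, emp, tolerance = 1e-12)

  expect_error(km_logrank(c(1, 2, 3), c(TRUE, TRUE, TRUE),
                          c("a", "a", "a")), "two")
})

test_that("KM median lands near the truth for exponential survival", {
  set.seed(17)
  n <- 2000
  t <- rexp(n, log(2) / 20)   # true median 20 months
  km <- km_logrank(c(t, t), rep(TRUE, 2 * n), rep(c("a", "b"), each = n))
  expect_gt(km$medians[["a"]], 18)
  expect_lt(km$medians[["a"]], 22)
})

test_that("one-way ANOVA with LSD: null case, t-squared identity, one-sided halving", {
  v <- c(10, 12, 14, 10, 12, 14)
  g <- rep(c("a", "b"), each = 3)
  a0 <- suppressWarnings(anova_lsd(v, g))   # base R warns on an exact null fit
  expect_equal(a0$F, 0)
  expect_equal(a0$p_value, 1)

  set.seed(9)
  v2 <- c(rnorm(12, 5), rnorm(15, 6))
  g2 <- rep(c("a", "b"), c(12, 15))
  a2 <- anova_lsd(v2, g2)
  tt <- t.test(v2[g2 == "a"], v2[g2 == "b"], var.equal = TRUE)
  expect_equal(a2$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(a2$p_value, tt$p.value, tolerance = 1e-10)
  expect_equal(a2$pairwise$p_value, tt$p.value, tolerance = 1e-10)

  a1 <- anova_lsd(v2, g2, one_sided = TRUE)
  if (mean(v2[g2 == "a"]) > mean(v2[g2 == "b"])) {
    expect_equal(a1$pairwise$p_value, a2$pairwise$p_value / 2)
  } else {
    expect_equal(a1$pairwise$p_value, 1 - a2$pairwise$p_value / 2)
  }
  expect_error(anova_lsd(c(1, 1, 1, 1), rep(c("a", "b"), each = 2)),
               "variance")
  expect_error(anova_lsd(c(1, 2), c("a", "b")), ">= 2")
})

test_that("dose-difference ANOVA has power at the clinical group profile", {
  # responders ~ N(95, 40) n = 27 vs non-responders ~ N(60, 40) n = 24
  set.seed(26)
  hits <- vapply(1:100, function(i) {
    v <- c(rnorm(27, 95, 40), rnorm(24, 60, 40))
    g <- rep(c("resp", "nonresp"), c(27, 24))
    g <- factor(g, levels = c("resp", "nonresp"))  # hypothesized direction
    anova_lsd(v, g, one_sided = TRUE)$pairwise$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.80)
})

test_that("ROC AUC is the Mann-Whitney statistic and auto-orients", {
  y <- rep(c(FALSE, TRUE), each = 50)
  s <- c(rnorm(50, 0), rnorm(50, 10))
  expect_equal(roc_auc(s, y)$auc, 1.0)

  set.seed(29)
  y2 <- rbinom(2000, 1, 0.5) == 1
  s2 <- rnorm(2000)
  a2 <- roc_auc(s2, y2)
  expect_gte(a2$auc, 0.5)
  expect_lt(a2$auc, 0.55)

  # ties: trapezoidal AUC equals the rank-statistic form to 1e-12
  set.seed(30)
  s3 <- sample(1:10, 300, TRUE)
  y3 <- rbinom(300, 1, plogis((s3 - 5) / 3)) == 1
  a3 <- roc_auc(s3, y3)
  r <- rank(s3)                       # mid-ranks handle ties as 1/2
  n1 <- sum(y3); n0 <- sum(!y3)
  u_auc <- (sum(r[y3]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  expect_equal(a3$auc, max(u_auc, 1 - u_auc), tolerance = 1e-12)

  neg <- roc_auc(-s3, y3)
  expect_equal(neg$auc, a3$auc, tolerance = 1e-12)
  expect_error(roc_auc(s3, rep(TRUE, 300)), "both")
})

test_that("screening end-to-end on simulated cohorts retains the linked feature", {
  set.seed(55)
  keep_linked <- logical(40); keep_null <- logical(40)
  for (i in 1:40) {
    cohort <- simulate_cohort(cohort_gen_params(n_treatments = 120,
                                                seed = 1000 + i))
    cohort$null_feature <- rnorm(nrow(cohort))
    scr <- suppressWarnings(
      univariate_screen(cohort, c("v_lt_100_cc", "null_feature"),
                        outcome = "objective_response"))
    keep_linked[i] <- scr$selected[scr$feature == "v_lt_100_cc"]
    keep_null[i] <- scr$selected[scr$feature == "null_feature"]
  }
  expect_gte(mean(keep_linked), 0.95)
  expect_lt(mean(keep_null), 0.45)
  expect_true(all(!is.na(keep_null)))
})
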