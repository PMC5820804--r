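test_that("rank-based AUC equals exhaustive pair enumeration", {
  expect_equal(auc_mw(c(1, 2, 2, 3), c(0, 1, 0, 1)), 0.875)
  expect_equal(auc_enum(c(1, 2, 2, 3), c(0, 1, 0, 1)), 0.875)
  set.seed(41)
  for (rep in 1:20) {
    n <- sample(10:200, 1)
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    s <- sample(1:8, n, replace = TRUE) + rnorm(n, sd = 0.01 * rbinom(1, 1, 0.5))
    expect_equal(auc_mw(s, y), auc_enum(s, y), tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly increasing score transforms", {
  set.seed(42)
  y <- rbinom(60, 1, 0.5)
  s <- rnorm(60, mean = y)
  a <- auc_mw(s, y)
  expect_equal(auc_mw(exp(s), y), a, tolerance = 1e-12)
  expect_equal(auc_mw(rank(s, ties.method = "average"), y), a,
               tolerance = 1e-12)
})

test_that("AUC boundary behaviour: separation 1, independence 0.5", {
  y <- rep(c(0, 1), each = 25)
  expect_equal(auc_mw(seq_len(50), y), 1)
  set.seed(43)
  y2 <- rbinom(4000, 1, 0.5)
  expect_lt(abs(auc_mw(rnorm(4000), y2) - 0.5), 0.03)
  expect_error(auc_mw(rnorm(5), rep(TRUE, 5)), "both outcome classes")
})

test_that("ROC curves are monotone and auto-oriented", {
  set.seed(44)
  y <- rbinom(100, 1, 0.5)
  gcs_like <- rnorm(100, mean = ifelse(y == 1, 5, 7))  # low score = event
  rc <- roc_curve(gcs_like, y, name = "gcs", direction = "auto")
  expect_equal(rc$direction, "<")
  expect_gte(rc$auc, 0.5)
  expect_true(all(diff(rc$sensitivity) >= 0))
  expect_true(all(diff(rc$specificity) <= 0))
  expect_true(rc$ci[1] <= rc$auc && rc$auc <= rc$ci[2])
})

test_that("DeLong comparison is degenerate-safe and antisymmetric", {
  set.seed(45)
  y <- rbinom(40, 1, 0.5)
  s <- rnorm(40, mean = y)
  same <- delong_test(s, s, y)
  expect_equal(same$delta, 0)
  expect_equal(same$p, 1)
  expect_true(same$degenerate)

  s2 <- rnorm(40, mean = 0.5 * y)
  ab <- delong_test(s, s2, y)
  ba <- delong_test(s2, s, y)
  expect_equal(ab$z, -ba$z, tolerance = 1e-12)
  expect_equal(ab$p, ba$p, tolerance = 1e-12)
})

test_that("DeLong z and p agree with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(46)
  y <- rbinom(80, 1, 0.45)
  a <- rnorm(80, mean = 1.0 * y)
  b <- 0.6 * a + rnorm(80, mean = 0.4 * y)
  ours <- delong_test(a, b, y)
  ref <- pROC::roc.test(pROC::roc(y, a, quiet = TRUE, direction = "<"),
                        pROC::roc(y, b, quiet = TRUE, direction = "<"),
                        method = "delong")
  expect_equal(abs(ours$z), abs(unname(ref$statistic)), tolerance = 1e-9)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-9)
})

test_that("DeLong variance shrinks at the 1/n parametric rate", {
  set.seed(47)
  se_at <- function(n) {
    y <- rep(c(0, 1), each = n / 2)
    a <- rnorm(n, mean = y)
    b <- rnorm(n, mean = 0.8 * y)
    delong_test(a, b, y)$se
  }
  r <- mean(replicate(20, se_at(100))) / mean(replicate(20, se_at(400)))
  expect_gt(r, 1.5)   # sqrt(4) = 2 expected
  expect_lt(r, 2.6)
})

test_that("backward elimination honours its boundary thresholds", {
  set.seed(48)
  n <- 300
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- rbinom(n, 1, plogis(-1 + x1))
  dat <- data.frame(died90 = y == 1, x1 = x1, x2 = x2)
  full <- suppressWarnings(backward_logistic(dat, c("x1", "x2"),
                                             removal_alpha = 1))
  expect_setequal(full$retained, c("x1", "x2"))
  none <- suppressWarnings(backward_logistic(dat, c("x1", "x2"),
                                             removal_alpha = 0))
  expect_length(none$retained, 0)
  expect_equal(none$coefficients$term, "(Intercept)")
})

test_that("stepwise elimination recovers the generating model", {
  set.seed(49)
  n <- 500
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- rbinom(n, 1, plogis(-2 + x1))
  dat <- data.frame(died90 = y == 1, x1 = x1, x2 = x2)
  m <- backward_logistic(dat, c("x1", "x2"))
  expect_false("x2" %in% m$retained)
  expect_true("x1" %in% m$retained)
  row <- m$coefficients[m$coefficients$term == "x1", ]
  expect_equal(row$or, exp(row$estimate), tolerance = 1e-9)
  expect_true(row$ci_lo < exp(1) && exp(1) < row$ci_hi)
  expect_true(all(m$fitted > 0 & m$fitted < 1))
  expect_equal(m$steps$removed, "x2")
})

test_that("separation is reported with the offending variable", {
  n <- 40
  x <- c(rnorm(n / 2, -3), rnorm(n / 2, 3))
  dat <- data.frame(died90 = x > 0, x = x, z = rnorm(n))
  expect_error(suppressWarnings(backward_logistic(dat, c("x", "z"))),
               "offending variable: x")
})

test_that("five-model comparison ranks the combined model first", {
  co <- gen_cohort(cohort_gen_spec(600, 600, seed = 50))
  mc <- compare_five_models(co)
  expect_setequal(mc$aucs$model, c("gcs", "volume", "upi", "dar", "combined"))
  expect_equal(nrow(mc$comparisons), 4)
  expect_true(all(mc$comparisons$delta > 0))
  expect_equal(mc$aucs$auc[mc$aucs$model == "combined"],
               max(mc$aucs$auc))
})

test_that("a null feature adds nothing to the combined model", {
  par <- default_cohort_params()
  par$dar$nonsurvivor <- par$dar$survivor
  co <- gen_cohort(cohort_gen_spec(1500, 1500, params = par, seed = 51))
  mc <- compare_five_models(co)
  aucs <- setNames(mc$aucs$auc, mc$aucs$model)
  expect_lt(abs(aucs[["dar"]] - 0.5), 0.03)
  expect_lt(abs(aucs[["combined"]] - aucs[["upi"]]), 0.02)
})
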