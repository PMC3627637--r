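test_that("pearson correlation matches the direct covariance formula", {
  expect_equal(pearson_correlation(1:10, 3 * (1:10) + 1)$r, 1.0)
  expect_equal(pearson_correlation(1:10, -(1:10))$r, -1.0)
  set.seed(50)
  x <- rnorm(50); y <- 0.4 * x + rnorm(50)
  got <- pearson_correlation(x, y)
  oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(got$r, oracle, tolerance = 1e-10)
  expect_error(pearson_correlation(rep(1, 10), 1:10), "zero variance")
})

test_that("spearman correlation is the Pearson correlation of mid-ranks", {
  x <- sort(runif(20, -2, 2))
  expect_equal(spearman_correlation(x, exp(x))$rho, 1.0)
  expect_equal(spearman_correlation(x, rev(sort(x)))$rho, -1.0)
  # tied data against an explicit mid-rank-then-Pearson oracle
  set.seed(3)
  xt <- sample(c(1, 2, 2, 3, 3, 3, 4, 5), 40, replace = TRUE)
  yt <- sample(c(10, 10, 20, 30), 40, replace = TRUE)
  got <- spearman_correlation(xt, yt)$rho
  midrank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v))
      r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    r
  }
  rx <- midrank(xt); ry <- midrank(yt)
  oracle <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(got, oracle, tolerance = 1e-12)
})

test_that("standardization yields exact z-scores and is idempotent", {
  expect_equal(standardize(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(4)
  x <- rnorm(100, 50, 7)
  z <- standardize(x)
  expect_lt(abs(mean(z)), 1e-10)
  expect_lt(abs(sd(z) - 1), 1e-10)
  expect_equal(standardize(z), z, tolerance = 1e-10)
  expect_error(standardize(rep(2, 5)), "zero variance")
})

test_that("joint model recovers a noiseless linear combination exactly", {
  set.seed(12)
  n <- 400
  d <- data.frame(insp_950 = rgamma(n, 0.4, 0.07))
  d$ei_mla <- 0.87 + 0.07 * (0.5 * standardize(d$insp_950) +
                               sqrt(0.75) * rnorm(n))
  d$y <- -0.3 * standardize(d$insp_950) - 0.3 * standardize(d$ei_mla)
  fit <- suppressWarnings(joint_outcome_model(d, "y", "ei_mla"))
  expect_equal(fit$beta_emphysema, -0.3, tolerance = 1e-10)
  expect_equal(fit$beta_gastrap, -0.3, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1.0, tolerance = 1e-10)
})

test_that("joint model is invariant to positive rescaling of raw predictors", {
  set.seed(13)
  n <- 300
  d <- data.frame(insp_950 = rgamma(n, 0.5, 0.08))
  d$exp_856 <- 20 + 15 * standardize(d$insp_950) + rnorm(n, sd = 9)
  d$y <- 2 - 0.4 * standardize(d$insp_950) -
    0.2 * standardize(d$exp_856) + rnorm(n, sd = 0.3)
  base <- joint_outcome_model(d, "y", "exp_856")
  d2 <- d
  d2$insp_950 <- d$insp_950 * 13.7
  d2$exp_856 <- d$exp_856 * 0.001
  scaled <- joint_outcome_model(d2, "y", "exp_856")
  expect_equal(scaled$beta_emphysema, base$beta_emphysema, tolerance = 1e-10)
  expect_equal(scaled$beta_gastrap, base$beta_gastrap, tolerance = 1e-10)
  expect_equal(scaled$p_emphysema, base$p_emphysema, tolerance = 1e-10)
  expect_equal(scaled$r_squared, base$r_squared, tolerance = 1e-10)
  # R^2 equals the squared correlation of fitted with observed
  expect_equal(base$r_squared, cor(fitted(base$fit), d$y)^2, tolerance = 1e-10)
})

test_that("permuted outcomes explain essentially nothing", {
  set.seed(14)
  n <- 250
  d <- data.frame(insp_950 = rgamma(n, 0.4, 0.07))
  d$ei_mla <- 0.87 + 0.03 * standardize(d$insp_950) + rnorm(n, sd = 0.06)
  d$y <- 1 - 0.5 * standardize(d$insp_950) + rnorm(n, sd = 0.4)
  observed <- joint_outcome_model(d, "y", "ei_mla")$r_squared
  null_r2 <- replicate(199, {
    d$yp <- sample(d$y)
    joint_outcome_model(d, "yp", "ei_mla")$r_squared
  })
  expect_gt(observed, quantile(null_r2, 0.99))
  d$yperm <- sample(d$y)
  expect_lt(joint_outcome_model(d, "yperm", "ei_mla")$r_squared,
            quantile(null_r2, 0.99))
})

test_that("collinear predictors are named in the error", {
  set.seed(15)
  d <- data.frame(insp_950 = rgamma(50, 0.5, 0.08))
  d$gas <- 2 * d$insp_950
  d$y <- rnorm(50)
  expect_error(joint_outcome_model(d, "y", "gas"), "collinear")
})

test_that("stratification partitions the cohort by severity class", {
  co <- data.frame(insp_950 = rep(20, 5),
                   smoking_status = rep("former", 5))
  s <- stratify_cohort(co)
  expect_equal(nrow(s$severe_emphysema), 5)
  co2 <- data.frame(insp_950 = rep(3, 7),
                    smoking_status = rep("current", 7))
  expect_equal(nrow(stratify_cohort(co2)$no_emphysema), 7)
  set.seed(16)
  co3 <- data.frame(insp_950 = runif(200, 0, 40),
                    smoking_status = sample(c("current", "former"), 200,
                                            replace = TRUE))
  s3 <- stratify_cohort(co3)
  expect_equal(nrow(s3$severe_emphysema) + nrow(s3$no_emphysema) +
                 nrow(s3$intermediate), 200)
})

test_that("GOLD staging follows the spirometric rules", {
  expect_equal(as.character(gold_stage(0.65, 55)), "GOLD2")
  expect_equal(as.character(gold_stage(0.75, 70)), "unclassified")
  expect_equal(as.character(gold_stage(0.75, 90)), "GOLD0")
  expect_equal(as.character(gold_stage(0.5, c(85, 60, 40, 20))),
               c("GOLD1", "GOLD2", "GOLD3", "GOLD4"))
  # a preserved ratio never yields an obstruction stage
  set.seed(17)
  r <- runif(200, 0.7, 1.0); p <- runif(200, 10, 150)
  expect_false(any(gold_stage(r, p) %in% c("GOLD1", "GOLD2", "GOLD3", "GOLD4")))
  expect_error(gold_stage(1.5, 80), "fev1_fvc")
})

test_that("duplicate-scan reproducibility is a rank statistic", {
  set.seed(18)
  t1 <- data.frame(exp_856 = runif(18, 0, 60),
                   ei_mla = runif(18, 0.7, 1),
                   rvc_856_950 = runif(18, -0.8, 0))
  same <- duplicate_reproducibility(t1, t1)
  expect_equal(same$rho, rep(1, 3))
  # monotone transforms leave the rank correlation at 1
  t2 <- data.frame(exp_856 = t1$exp_856^2,
                   ei_mla = exp(t1$ei_mla),
                   rvc_856_950 = 2 * t1$rvc_856_950 + 1)
  expect_equal(duplicate_reproducibility(t1, t2)$rho, rep(1, 3))
  # noisy revisit agrees with the package spearman on each column
  t3 <- t1 + rnorm(18 * 3, sd = 0.2)
  rep3 <- duplicate_reproducibility(t1, t3)
  for (i in 1:3) {
    m <- rep3$measure[i]
    expect_identical(rep3$rho[i], spearman_correlation(t1[[m]], t3[[m]])$rho)
  }
  expect_error(duplicate_reproducibility(t1[1:2, ], t1[1:2, ]),
               "insufficient duplicates")
})

test_that("correlation matrix handles identity, symmetry and degenerate cells", {
  set.seed(19)
  co <- data.frame(a = rnorm(100), b = rnorm(100))
  co$c <- 0.5 * co$a + rnorm(100)
  cm <- correlation_matrix(co, measures = c("a", "b", "c"),
                           outcomes = c("a", "b", "c"))
  expect_equal(cm$r[cm$measure == "a" & cm$outcome == "a"], 1.0)
  ab <- cm$r[cm$measure == "a" & cm$outcome == "b"]
  ba <- cm$r[cm$measure == "b" & cm$outcome == "a"]
  expect_identical(ab, ba)
  # null columns stay near zero at large n
  set.seed(20)
  big <- data.frame(x = rnorm(1e4), y = rnorm(1e4))
  expect_lt(abs(correlation_matrix(big, "x", "y")$r), 0.05)
  # a constant column is reported as missing with the reason, not an error
  co$flat <- 1
  cm2 <- correlation_matrix(co, c("a", "flat"), "b")
  expect_true(is.na(cm2$r[cm2$measure == "flat"]))
  expect_match(cm2$note[cm2$measure == "flat"], "zero variance")
})

test_that("residual measure is uncorrelated with emphysema in the matrix", {
  set.seed(21)
  n <- 800
  co <- data.frame(insp_950 = rgamma(n, 0.4, 0.065))
  co$exp_856 <- 10 + 1.6 * co$insp_950 + rnorm(n, sd = 8)
  co$residual <- fit_gas_trapping_residuals(co$exp_856, co$insp_950)$residuals
  cell <- correlation_matrix(co, "residual", "insp_950")
  expect_lt(abs(cell$r), 1e-8)
})
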