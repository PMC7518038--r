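# SAR congruency statistics: Pearson r, OLS diagnostics, LOO q2,
# Y-scrambling, pose ranking and outlier re-assessment, each against
# independently coded oracles.

# covariance-formula Pearson r
pearsonOracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  (n * sum(x * y) - sx * sy) /
    sqrt((n * sum(x^2) - sx^2) * (n * sum(y^2) - sy^2))
}

# normal-equations OLS of y on x
olsOracle <- function(x, y) {
  n <- length(x)
  b <- (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
  a <- mean(y) - b * mean(x)
  res <- y - (a + b * x)
  list(slope = b, intercept = a, RMSE = sqrt(mean(res^2)),
       r2 = 1 - sum(res^2) / sum((y - mean(y))^2))
}

# explicit refit-per-point LOO
looOracle <- function(x, y) {
  press <- 0
  for (i in seq_along(x)) {
    f <- olsOracle(x[-i], y[-i])
    press <- press + (y[i] - (f$intercept + f$slope * x[i]))^2
  }
  1 - press / sum((y - mean(y))^2)
}

test_that("perfect anticorrelation gives R_SAR of exactly -1", {
  a <- c(4.2, 5.1, 5.9, 6.4, 7.0)
  expect_equal(as.numeric(rSar(-a, a)), -1.0)
  expect_error(rSar(rep(1, 5), a), "zero variance")
  expect_error(rSar(c(-1, 1), c(1, 2)), "fewer than 3")
})

test_that("Pearson r matches the covariance-formula oracle", {
  set.seed(3)
  x <- rnorm(6); y <- 0.4 * x + rnorm(6, sd = 0.3)
  expect_equal(as.numeric(rSar(x, y)), pearsonOracle(x, y), tolerance = 1e-12)
  # sign antisymmetry
  expect_equal(as.numeric(rSar(-x, y)), -as.numeric(rSar(x, y)),
               tolerance = 1e-12)
  # missing values dropped pairwise, with the effective n reported
  x2 <- c(x, NA); y2 <- c(y, 5)
  r <- rSar(x2, y2)
  expect_equal(attr(r, "n"), 6L)
  expect_equal(as.numeric(r), pearsonOracle(x, y), tolerance = 1e-12)
})

test_that("regression diagnostics match the normal equations", {
  set.seed(4)
  x <- rnorm(7); y <- -0.8 * x + rnorm(7, sd = 0.2) + 5
  d <- regressionDiagnostics(x, y)
  o <- olsOracle(x, y)
  expect_equal(d$slope, o$slope, tolerance = 1e-12)
  expect_equal(d$intercept, o$intercept, tolerance = 1e-12)
  expect_equal(d$RMSE, o$RMSE, tolerance = 1e-12)
  expect_equal(d$r2, o$r2, tolerance = 1e-12)
  # perfectly linear data: zero residual, unit r2
  dl <- regressionDiagnostics(x, 2 * x + 1)
  expect_equal(dl$RMSE, 0, tolerance = 1e-12)
  expect_equal(dl$r2, 1, tolerance = 1e-12)
})

test_that("residual ranking exposes planted outliers", {
  set.seed(5)
  x <- seq(-2, 2, length.out = 10)
  y <- -x + rnorm(10, sd = 0.05)
  y[c(3, 8)] <- y[c(3, 8)] + c(2.5, -2.5)
  d <- regressionDiagnostics(x, y)
  worst <- order(-abs(d$residuals))[1:2]
  expect_setequal(worst, c(3L, 8L))
})

test_that("LOO q2 matches an explicit refit loop and never beats r2", {
  set.seed(6)
  x <- rnorm(8); y <- 0.9 * x + rnorm(8, sd = 0.4)
  expect_equal(looQ2(x, y), looOracle(x, y), tolerance = 1e-12)
  expect_equal(looQ2(x, 3 * x - 2), 1, tolerance = 1e-12)
  for (k in 1:5) {
    xx <- rnorm(9); yy <- 0.5 * xx + rnorm(9, sd = 0.5)
    expect_lte(looQ2(xx, yy), cor(xx, yy)^2 + 1e-12)
  }
})

test_that("Y-scrambling reproduces the analytic null and add-one p-value", {
  tab <- pqTable()
  act <- tab$pEC50_a1b3
  pred <- seq_along(act)  # any fixed non-constant predictor
  ys <- yScramble(pred, act, nIterations = 1000L, seed = 99L)
  # null mean of r2 is 1/(n-1) for n = 19
  expect_lt(abs(ys$yscr_r2_mean - 1 / 18), 0.012)
  expect_lt(abs(ys$yscr_q2_mean), 0.25)
  # perfect observed fit: no permutation can match, add-one rule applies
  perf <- yScramble(-act, act, nIterations = 1000L, seed = 7L)
  expect_equal(perf$p_value, 1 / 1001)
  # determinism under a fixed seed
  ys2 <- yScramble(pred, act, nIterations = 1000L, seed = 99L)
  expect_identical(ys, ys2)
  expect_error(yScramble(pred, act, nIterations = 1000L), "seed")
  expect_error(yScramble(pred, act, nIterations = 0L, seed = 1L), "at least 1")
})

test_that("poses are ranked by most-negative R_SAR with stable ties", {
  act <- c(4, 5, 6, 7, 8)
  mkE <- function(pose, e) data.frame(pose_id = paste0(pose, ":", 1:5),
                                      compound_id = 1:5, dG_bind = e)
  en <- rbind(mkE("A", -0.9 * act + rnorm(5, sd = 0.2)),
              mkE("B", -0.1 * act + rnorm(5, sd = 1.5)))
  recs <- data.frame(compound_id = 1:5, pEC50_a1b3 = act)
  a <- assessPoses(en, recs, yscramble = FALSE)
  expect_equal(a$pose_id[a$rank == 1], "A")
  # permutation invariance of the ranking
  a2 <- assessPoses(en[sample(nrow(en)), ], recs, yscramble = FALSE)
  expect_equal(a2$pose_id, a$pose_id)
  expect_equal(a2$R_SAR, a$R_SAR, tolerance = 1e-12)
  # scree attribute mirrors the ranking
  scree <- attr(a, "scree")
  expect_equal(scree$pose_id, a$pose_id)
  # adding a pose cannot reorder the existing ones
  en3 <- rbind(en, mkE("C", -0.5 * act))
  a3 <- assessPoses(en3, recs, yscramble = FALSE)
  expect_equal(match("A", a3$pose_id) < match("B", a3$pose_id), TRUE)
  # ragged tables are refused with the offending pose named
  expect_error(assessPoses(en[-1, ], recs, yscramble = FALSE), "A")
})

test_that("excluding outliers strengthens the congruency", {
  set.seed(8)
  act <- c(4.1, 4.6, 5.0, 5.6, 6.1, 6.6, 7.0, 7.4)
  e <- -act + rnorm(8, sd = 0.1)
  e[c(2, 7)] <- e[c(2, 7)] + c(1.5, -1.5)  # planted outliers
  names(e) <- names(act) <- as.character(1:8)
  full <- rSar(e, act)
  d <- regressionDiagnostics(e, act)
  out <- names(e)[order(-abs(d$residuals))[1:2]]
  red <- reassessWithout(e, act, exclude = out)
  expect_gt(abs(red$R_SAR), abs(as.numeric(full)))
  # exclusion bookkeeping and oracle agreement on the reduced set
  keep <- setdiff(names(e), out)
  expect_equal(red$R_SAR, pearsonOracle(e[keep], act[keep]),
               tolerance = 1e-12)
  expect_setequal(attr(red, "excluded"), out)
  # excluding nothing reproduces the full assessment
  same <- reassessWithout(e, act)
  expect_equal(same$R_SAR, as.numeric(full), tolerance = 1e-12)
  expect_error(reassessWithout(e, act, exclude = as.character(1:6)),
               "fewer than 3")
})

test_that("r2 equals squared R_SAR and the null mean converges", {
  set.seed(9)
  x <- rnorm(12); y <- rnorm(12)
  en <- data.frame(pose_id = paste0("P:", 1:12), compound_id = 1:12,
                   dG_bind = x)
  recs <- data.frame(compound_id = 1:12, pEC50_a1b3 = y)
  a <- assessPoses(en, recs, yscramble = TRUE, nIterations = 400L,
                   seed = 13L)
  expect_equal(a$r2, a$R_SAR^2, tolerance = 1e-12)
  expect_lt(abs(a$yscr_r2_mean - 1 / 11), 0.03)
  expect_gte(a$p_value, 1 / 401)
})
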