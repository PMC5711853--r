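# Statistical layer: ANOVA, correlation tables, stepwise regression,
# variance portions, delta notation.

test_that("treatment ANOVA: degenerate, separated and hand-worked cases", {
  eq <- data.frame(treatment = rep(c("NPF", "OP"), each = 3),
                   y = rep(c(1, 2, 3), 2))
  a <- treatment_anova(eq, "y")
  expect_equal(a$F, 0)
  expect_equal(a$p, 1)

  set.seed(1)
  sep <- data.frame(treatment = rep(c("NPF", "OP"), each = 3),
                    y = c(0, 0, 0, 1, 1, 1) + rnorm(6, 0, 1e-4))
  expect_lt(treatment_anova(sep, "y")$p, 0.001)

  # textbook sum-of-squares oracle on a 3 + 3 example
  dat <- data.frame(treatment = rep(c("A", "B"), each = 3),
                    y = c(4, 6, 5, 9, 7, 11))
  gm <- mean(dat$y)
  ssb <- 3 * ((5 - gm)^2 + (9 - gm)^2)
  ssw <- sum((dat$y - rep(c(5, 9), each = 3))^2)
  f_hand <- (ssb / 1) / (ssw / 4)
  a2 <- treatment_anova(dat, "y")
  expect_equal(a2$F, f_hand, tolerance = 1e-12)
  expect_equal(a2$p, stats::pf(f_hand, 1, 4, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(a2$means$mean, c(5, 9))
  expect_equal(a2$means$se, c(stats::sd(c(4, 6, 5)) / sqrt(3),
                              stats::sd(c(9, 7, 11)) / sqrt(3)))
  expect_error(treatment_anova(dat[-(1:2), ], "y"), "fewer than 2")
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  set.seed(7)
  dat <- data.frame(treatment = rep(c("NPF", "OP"), each = 10),
                    y = rnorm(20, rep(c(0, 1), each = 10)))
  a <- treatment_anova(dat, "y")
  tt <- stats::t.test(y ~ treatment, dat, var.equal = TRUE)
  expect_equal(a$F, unname(tt$statistic)^2, tolerance = 1e-10)
})

test_that("pearson_table: exact, orthogonal and hand-computed cells", {
  rec <- data.frame(treatment = rep(c("NPF", "OP"), each = 6),
                    x = 1:12, y = 2 * (1:12))
  tab <- pearson_table(rec, "x", "y")
  expect_equal(tab$r, rep(1, 3), tolerance = 1e-12)
  expect_true(all(tab$p < 1e-6))
  expect_equal(tab$n, rep(c(6, 12), c(2, 1)))

  # orthogonal by construction over a balanced design
  rec2 <- data.frame(treatment = "NPF", x = c(-1, 1, -1, 1), y = c(1, 1, -1, -1))
  t2 <- pearson_table(rec2, "x", "y", groups = "Combined")
  expect_equal(t2$r, 0, tolerance = 1e-12)

  # 5-point arithmetic oracle: covariance ratio definition
  x <- c(1, 3, 4, 6, 8); y <- c(2, 3, 7, 8, 9)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t3 <- pearson_table(data.frame(treatment = "OP", x = x, y = y), "x", "y",
                      groups = "Combined")
  expect_equal(t3$r, r_hand, tolerance = 1e-12)

  # fewer than 3 complete pairs: flagged NA, not fabricated
  rec4 <- data.frame(treatment = "NPF", x = c(1, 2, NA, NA), y = c(1, NA, 2, 3))
  t4 <- pearson_table(rec4, "x", "y", groups = "NPF")
  expect_true(is.na(t4$r))
  expect_equal(t4$n, 1)
})

test_that("Pearson r is affine-invariant and flips sign under negation", {
  set.seed(8)
  rec <- data.frame(treatment = "NPF", x = rnorm(20), y = rnorm(20))
  r0 <- pearson_table(rec, "x", "y", groups = "Combined")$r
  rec$x2 <- 3 * rec$x + 7
  rec$x3 <- -rec$x
  expect_equal(pearson_table(rec, "x2", "y", groups = "Combined")$r, r0)
  expect_equal(pearson_table(rec, "x3", "y", groups = "Combined")$r, -r0)
})

test_that("forward stepwise recovers an exact single-predictor model", {
  set.seed(9)
  rec <- data.frame(x1 = rnorm(30), x2 = rnorm(30))
  rec$y <- 3 * rec$x1
  # the noiseless fit is intentional; lm warns about it
  fit <- suppressWarnings(forward_stepwise(rec, "y", c("x1", "x2")))
  expect_equal(fit$terms, "x1")
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(unname(fit$coefficients["x1"]), 3, tolerance = 1e-9)
  expect_equal(unname(fit$portions["x1"]), 1)
})

test_that("under a planted null the stepwise stays intercept-only >= 90%", {
  expect_gte(null_intercept_only_rate(), 0.90)
})

test_that("stepwise with alpha 1 terminates, R^2 non-decreasing in entry order", {
  set.seed(10)
  rec <- data.frame(x1 = rnorm(40), x2 = rnorm(40), x3 = rnorm(40))
  rec$y <- rec$x1 + 0.5 * rec$x2 + rnorm(40)
  fit <- forward_stepwise(rec, "y", c("x1", "x2", "x3"), alpha_enter = 1)
  expect_lte(length(fit$terms), 3)
  r2s <- vapply(seq_along(fit$terms), function(k) {
    summary(stats::lm(stats::reformulate(fit$terms[1:k], "y"), rec))$r.squared
  }, numeric(1))
  expect_true(all(diff(c(0, r2s)) >= -1e-12))
})

test_that("two-predictor recovery within 3 fitted standard errors", {
  ok <- vapply(1:50, function(s) {
    set.seed(3000 + s)
    rec <- data.frame(x1 = rnorm(52, 0.15, 0.07), x2 = rnorm(52))
    rec$y <- 6 + 12 * rec$x1 + 0.8 * rec$x2 + rnorm(52, 0, 0.45)
    fit <- forward_stepwise(rec, "y", c("x1", "x2"))
    if (!setequal(fit$terms, c("x1", "x2"))) return(FALSE)
    se <- summary(fit$model)$coefficients[c("x1", "x2"), "Std. Error"]
    all(abs(fit$coefficients[c("x1", "x2")] - c(12, 0.8)) < 3 * se)
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("variance portions: single term, orthogonal split, normalisation", {
  set.seed(11)
  rec <- data.frame(x1 = rnorm(60))
  rec$y <- 2 * rec$x1 + rnorm(60)
  expect_equal(variance_portions(rec, "y", "x1"), c(x1 = 1))

  # two orthogonalised standardised predictors with equal coefficients
  x1 <- scale(rnorm(100))[, 1]
  x2 <- stats::residuals(stats::lm(rnorm(100) ~ x1))
  x2 <- scale(x2)[, 1]
  rec2 <- data.frame(x1 = x1, x2 = x2)
  rec2$y <- x1 + x2 + rnorm(100, 0, 0.3)
  p <- variance_portions(rec2, "y", c("x1", "x2"))
  expect_equal(unname(p[1]), 0.5, tolerance = 0.1)
  expect_equal(sum(p), 1, tolerance = 1e-9)

  # orthogonal design: portions equal incremental R^2 over total R^2
  inc1 <- summary(stats::lm(y ~ x1, rec2))$r.squared
  inc2 <- summary(stats::lm(y ~ x2, rec2))$r.squared
  expect_equal(unname(p), c(inc1, inc2) / (inc1 + inc2), tolerance = 1e-6)

  # random fits: portions always sum to 1
  for (k in 1:5) {
    rec3 <- data.frame(a = rnorm(30), b = rnorm(30), c = rnorm(30))
    rec3$y <- rec3$a + 0.4 * rec3$b - 0.2 * rec3$c + rnorm(30)
    expect_equal(sum(variance_portions(rec3, "y", c("a", "b", "c"))), 1,
                 tolerance = 1e-9)
  }

  rec4 <- data.frame(x1 = 1:20, x2 = 2 * (1:20))
  rec4$y <- rnorm(20) + rec4$x1
  expect_error(variance_portions(rec4, "y", c("x1", "x2")), "collinear")
})

test_that("delta notation follows the per-mil definition", {
  expect_equal(delta_notation(1, 1), 0)
  expect_equal(delta_notation(1.001, 1), 1, tolerance = 1e-9)
  expect_equal(delta_notation(0.5, 1), -500)
  expect_equal(delta_notation(0.0112372 * 1.001, 0.0112372), 1, tolerance = 1e-9)
  expect_error(delta_notation(1, 0), "positive")
})
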