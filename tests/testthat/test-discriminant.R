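# Fisher discriminant closed forms, D-scores, confusion arithmetic,
# Mahalanobis separation and Hotelling significance.

test_that("fit_lda matches the 1-D and 2-D closed forms", {
  # one feature, group means +/- 1, unit pooled variance -> coefficient 2
  g1 <- unit_cov_group(1)
  g2 <- unit_cov_group(-1)
  fit <- fit_lda(g1, g2, ridge = 0)
  expect_equal(unname(fit$coefficients), 2, tolerance = 1e-12)
  expect_equal(fit$discriminant_point, 0, tolerance = 1e-12)

  # two features, identity pooled covariance, means (1,0) vs (0,0)
  f2 <- fit_lda(unit_cov_group(c(1, 0)), unit_cov_group(c(0, 0)), ridge = 0)
  expect_equal(unname(f2$coefficients), c(1, 0), tolerance = 1e-12)
  expect_equal(f2$discriminant_point, 0.5, tolerance = 1e-12)
})

test_that("identical groups give a degenerate zero model", {
  g <- unit_cov_group(c(2, 3))
  fit <- fit_lda(g, g, ridge = 0)
  expect_true(fit$degenerate)
  expect_true(all(fit$coefficients == 0))
  expect_equal(mahalanobis_distance(fit), 0)
})

test_that("D-scores are signed by group mean and vanish at the midpoint", {
  set.seed(301)
  X1 <- matrix(rnorm(40 * 3), 40) + matrix(rep(c(2, 0, 1), each = 40), 40)
  X2 <- matrix(rnorm(40 * 3), 40)
  fit <- fit_lda(X1, X2, ridge = 0)
  expect_gt(d_score(fit, colMeans(X1)), 0)
  expect_lt(d_score(fit, colMeans(X2)), 0)
  expect_lt(abs(d_score(fit, (colMeans(X1) + colMeans(X2)) / 2)), 1e-9)
  # training means project to +/- md^2 / 2
  md <- mahalanobis_distance(fit)
  expect_equal(d_score(fit, colMeans(X1)), md^2 / 2, tolerance = 1e-9)
  expect_equal(d_score(fit, colMeans(X2)), -md^2 / 2, tolerance = 1e-9)
  expect_error(d_score(fit, c(1, 2)), "does not match")
})

test_that("classification counts use the D = 0 tie rule deterministically", {
  g1 <- unit_cov_group(1)
  g2 <- unit_cov_group(-1)
  fit <- fit_lda(g1, g2, ridge = 0, group_pair = c("A", "B"))
  ct <- classify_cohort(fit, rbind(g1, g2), rep(c("A", "B"), each = 4))
  expect_equal(ct$fn + ct$fp, 0)
  # a former-group subject exactly at the midpoint scores 0 -> counted fn
  ct2 <- classify_cohort(fit, matrix(0, 1, 1), "A")
  expect_equal(ct2$fn, 1)
  expect_equal(ct2$tp, 0)
  expect_error(classify_cohort(fit, matrix(1, 1, 1), "C"), "outside")
  expect_error(classify_cohort(fit, matrix(numeric(0), 0, 1), character(0)), "empty")
})

test_that("sensitivity and specificity follow the counting convention", {
  ss <- sens_spec(confusion_table(tp = 9, fn = 3, fp = 3, tn = 30))
  expect_equal(ss$sensitivity, 75.0)
  expect_equal(ss$specificity, 90.9)
  expect_error(sens_spec(confusion_table(0, 0, 1, 1)), "undefined")
  expect_error(confusion_table(-1, 0, 0, 1), "non-negative")
})

test_that("Mahalanobis distance equals the brute-force quadratic form", {
  set.seed(302)
  for (rep in 1:10) {
    X1 <- matrix(rnorm(30 * 3), 30) %*% matrix(rnorm(9), 3) +
      matrix(rep(rnorm(3, 0, 2), each = 30), 30)
    X2 <- matrix(rnorm(25 * 3), 25) %*% matrix(rnorm(9), 3)
    fit <- fit_lda(X1, X2, ridge = 0)
    S <- (29 * stats::cov(X1) + 24 * stats::cov(X2)) / 53
    delta <- colMeans(X1) - colMeans(X2)
    brute <- sqrt(drop(t(delta) %*% solve(S) %*% delta))
    expect_equal(mahalanobis_distance(fit), brute, tolerance = 1e-9)
  }
  # unit covariance, means one unit apart -> md = 1
  f1 <- fit_lda(unit_cov_group(c(1, 0)), unit_cov_group(c(0, 0)), ridge = 0)
  expect_equal(mahalanobis_distance(f1), 1, tolerance = 1e-9)
})

test_that("classification and md are invariant under affine feature rescaling", {
  set.seed(303)
  X1 <- matrix(rnorm(30 * 4), 30) + 1.5
  X2 <- matrix(rnorm(30 * 4), 30)
  A <- matrix(rnorm(16), 4)
  A <- A + diag(4) * 2            # well-conditioned invertible map
  b <- rnorm(4)
  tf <- function(X) sweep(X %*% A, 2, b, `+`)
  fit <- fit_lda(X1, X2, ridge = 0, group_pair = c("A", "B"))
  fit_t <- fit_lda(tf(X1), tf(X2), ridge = 0, group_pair = c("A", "B"))
  X <- rbind(X1, X2)
  expect_identical(d_score(fit, X) > 0, d_score(fit_t, tf(X)) > 0)
  expect_equal(mahalanobis_distance(fit), mahalanobis_distance(fit_t),
               tolerance = 1e-8)
})

test_that("the discriminant direction agrees with an independent LDA implementation", {
  skip_if_not_installed("MASS")
  set.seed(304)
  X1 <- matrix(rnorm(40 * 3), 40) + matrix(rep(c(1, 0, 0.5), each = 40), 40)
  X2 <- matrix(rnorm(40 * 3), 40)
  fit <- fit_lda(X1, X2, ridge = 0)
  m <- MASS::lda(rbind(X1, X2), rep(c("a", "b"), each = 40))
  # same direction up to scale and sign
  v1 <- fit$coefficients / sqrt(sum(fit$coefficients^2))
  v2 <- drop(m$scaling) / sqrt(sum(m$scaling^2))
  expect_equal(abs(sum(v1 * v2)), 1, tolerance = 1e-8)
})

test_that("Hotelling T^2 significance matches an independent F-tail quadrature", {
  h0 <- hotelling_p(0, 20, 20, 2)
  expect_equal(h0$t2, 0)
  expect_equal(h0$p, 1)

  h <- hotelling_p(1, 20, 20, 2)
  quad <- stats::integrate(function(x) stats::df(x, h$df[1], h$df[2]),
                           h$f, Inf, rel.tol = 1e-10)$value
  expect_equal(h$p, quad, tolerance = 1e-6)

  # p decreases monotonically in md
  ps <- vapply(c(0.5, 1, 1.5, 2), function(md) hotelling_p(md, 20, 20, 2)$p,
               numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_error(hotelling_p(1, 3, 3, 12), "degrees of freedom")
})

test_that("singular covariance without ridge errors; ridge rescues it", {
  X1 <- cbind(unit_cov_group(1), 5)   # constant second feature
  X2 <- cbind(unit_cov_group(-1), 5)
  expect_error(fit_lda(X1, X2, ridge = 0), "ridge")
  fit <- fit_lda(X1, X2, ridge = 1e-8)
  expect_equal(unname(fit$coefficients[1]), 2, tolerance = 1e-4)
})

test_that("hrv_lda wraps the fit with scores, performance and separation", {
  set.seed(305)
  n <- 30
  feats <- data.frame(group = rep(c("PPD", "AJD"), each = n))
  X <- matrix(rnorm(2 * n * 12), 2 * n)
  X[feats$group == "PPD", 1:3] <- X[feats$group == "PPD", 1:3] + 2
  colnames(X) <- FEATURE_NAMES
  feats <- cbind(feats, X)
  fit <- hrv_lda(group ~ ., data = feats, pair = c("PPD", "AJD"))
  expect_s3_class(fit, "hrv_lda")
  expect_length(coef(fit), 12)
  expect_equal(fit$confusion$tp + fit$confusion$fn, n)
  expect_identical(predict(fit, type = "class"),
                   ifelse(fit$scores > 0, "PPD", "AJD"))
  expect_equal(predict(fit, newdata = feats[1:5, ]), fit$scores[1:5])
  sim <- simulate(fit, nsim = 10, seed = 1)
  expect_equal(dim(sim), c(20, 13))
  ser <- withr::local_tempfile(fileext = ".json")
  write_model(fit, ser)
  js <- jsonlite::read_json(ser)
  expect_equal(js$group_pair[[1]], "PPD")
  expect_length(js$coefficients, 12)
})
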