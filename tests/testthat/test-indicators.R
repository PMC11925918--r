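# Normalization, adequacy diagnostics and PCA weighting.

test_that("normalization maps endpoints to 0.01 / 1.01 in both directions", {
  g <- hr_grid(matrix(c(0, 5, 10, NA), 2, 2))
  pos <- normalize_indicator(g, "positive")
  expect_equal(min(pos$values, na.rm = TRUE), 0.01)
  expect_equal(max(pos$values, na.rm = TRUE), 1.01)
  neg <- normalize_indicator(g, "negative")
  expect_equal(sort(neg$values[!is.na(neg$values)]), c(0.01, 0.51, 1.01))
  expect_equal(neg$values[1, 1], 1.01)   # raw minimum, reversed
  expect_error(normalize_indicator(hr_grid(matrix(3, 4, 4))), "constant")
})

test_that("normalization is invariant to positive affine transforms", {
  g <- random_grid(20, 20, seed = 8, holes = 5)
  h <- g
  h$values <- 3.7 * h$values + 11
  expect_equal(normalize_indicator(g, "positive")$values,
               normalize_indicator(h, "positive")$values)
  expect_equal(normalize_indicator(g, "negative")$values,
               normalize_indicator(h, "negative")$values)
})

test_that("KMO is 0.5 for two indicators and separates factor structure from noise", {
  set.seed(100)
  two <- matrix(rnorm(400), 200, 2) %*% matrix(c(1, 0.6, 0, 1), 2, 2)
  expect_equal(kmo_test(two)$kmo, 0.5, tolerance = 1e-12)

  indep <- matrix(rnorm(2000 * 6), 2000, 6)
  expect_lt(kmo_test(indep)$kmo, 0.55)

  f <- rnorm(2000)
  common <- sapply(1:6, function(i) 0.9 * f + sqrt(1 - 0.81) * rnorm(2000))
  expect_gt(kmo_test(common)$kmo, 0.7)
})

test_that("Bartlett sphericity matches a step-by-step evaluation of the statistic", {
  set.seed(7)
  X <- matrix(rnorm(50 * 3), 50, 3)
  X[, 2] <- X[, 2] + 0.5 * X[, 1]
  res <- bartlett_sphericity(X)
  # independent evaluation from first principles
  R <- cor(X)
  chi2_hand <- -((50 - 1) - (2 * 3 + 5) / 6) * log(det(R))
  expect_equal(res$chi2, chi2_hand, tolerance = 1e-12)
  expect_equal(res$df, 3)
  expect_equal(res$p_value, pchisq(chi2_hand, 3, lower.tail = FALSE))

  # 12 indicators give the familiar 66 degrees of freedom
  expect_equal(bartlett_sphericity(matrix(rnorm(30 * 12), 30, 12))$df, 66)

  # exactly uncorrelated (orthogonal, centred) data: chi2 = 0
  orth <- unclass(poly(1:20, 3))
  expect_equal(bartlett_sphericity(orth)$chi2, 0, tolerance = 1e-8)
})

test_that("pca_weights satisfies the correlation-PCA identities", {
  set.seed(11)
  f <- rnorm(3000)
  specs <- canonical_indicators()
  specs <- specs[specs$category != "hazard", ]
  X <- sapply(seq_len(nrow(specs)), function(i)
    0.7 * f + rnorm(3000))
  colnames(X) <- specs$name
  w <- pca_weights(X, specs)
  p <- ncol(X)
  expect_equal(sum(w$eigenvalues), p, tolerance = 1e-8)
  expect_equal(sum(w$contribution), 100, tolerance = 1e-8)
  expect_equal(w$cumulative, cumsum(w$contribution))
  expect_true(all(w$weights >= 0))
  for (cat in unique(specs$category))
    expect_equal(sum(w$weights[specs$name[specs$category == cat]]), 1,
                 tolerance = 1e-6)
})

test_that("symmetric indicators share weight equally; order does not matter", {
  set.seed(12)
  f <- rnorm(5000)
  a <- 0.8 * f + 0.6 * rnorm(5000)
  b <- 0.8 * f + 0.6 * rnorm(5000)
  X <- cbind(sv1 = a, sv2 = b)
  specs <- list(indicator_spec("sv1", "social_vulnerability", "positive"),
                indicator_spec("sv2", "social_vulnerability", "positive"))
  w <- pca_weights(X, specs, retention = 1)
  expect_equal(unname(w$weights), c(0.5, 0.5), tolerance = 1e-6)

  # column-order invariance up to the matching permutation
  set.seed(13)
  X3 <- cbind(sv1 = rnorm(1000) + f[1:1000],
              sv2 = 0.5 * f[1:1000] + rnorm(1000),
              ex1 = 0.8 * f[1:1000] + rnorm(1000))
  specs3 <- list(indicator_spec("sv1", "social_vulnerability", "positive"),
                 indicator_spec("sv2", "social_vulnerability", "positive"),
                 indicator_spec("ex1", "exposure", "positive"))
  w1 <- pca_weights(X3, specs3, retention = 2)
  w2 <- pca_weights(X3[, c(3, 1, 2)], specs3, retention = 2)
  expect_equal(w1$weights, w2$weights[names(w1$weights)], tolerance = 1e-10)
})

test_that("single-indicator categories get weight 1", {
  set.seed(14)
  X <- cbind(only = rnorm(500), ex = rnorm(500))
  specs <- list(indicator_spec("only", "social_vulnerability", "positive"),
                indicator_spec("ex", "exposure", "positive"))
  w <- pca_weights(X, specs, retention = 1)
  expect_equal(unname(w$weights["only"]), 1)
  expect_equal(unname(w$weights["ex"]), 1)
})

test_that("weights recover the ground-truth loading order under one dominant factor", {
  set.seed(15)
  loadings <- seq(0.35, 0.9, length.out = 8)
  rhos <- replicate(20, {
    f <- rnorm(1500)
    X <- sapply(loadings, function(l) l * f + sqrt(1 - l^2) * rnorm(1500))
    colnames(X) <- paste0("sv", 1:8)
    specs <- lapply(colnames(X), function(nm)
      indicator_spec(nm, "social_vulnerability", "positive"))
    w <- pca_weights(X, specs, retention = 1)
    cor(rank(w$weights), rank(loadings))
  })
  expect_gt(mean(rhos > 0.8), 0.9)
})

test_that("composite_score is the cellwise weighted sum", {
  m1 <- hr_grid(matrix(1, 2, 2)); m2 <- hr_grid(matrix(0, 2, 2))
  m3 <- hr_grid(matrix(1, 2, 2))
  specs <- list(indicator_spec("a", "social_vulnerability", "positive"),
                indicator_spec("b", "social_vulnerability", "positive"),
                indicator_spec("c", "social_vulnerability", "positive"))
  st <- hr_stack(list(m1, m2, m3), specs)
  sc <- composite_score(st, c(a = 0.5, b = 0.3, c = 0.2),
                        "social_vulnerability")
  expect_true(all(sc$values == 0.7))

  sc1 <- composite_score(st, c(a = 0, b = 1, c = 0), "social_vulnerability")
  expect_equal(sc1$values, m2$values)
  expect_error(composite_score(st, c(a = 1, b = 1), "social_vulnerability"),
               "missing.*c")
})
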