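# gaussian feature clouds with controllable centroid separation (in units of
# the within-group SD)
gaussian_groups <- function(n_per, p = 5, sep = 0, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * p), n_per),
             matrix(rnorm(n_per * p, mean = sep / sqrt(p)), n_per))
  colnames(x) <- paste0("f", seq_len(p))
  list(data = as.data.frame(x),
       labels = rep(c("g1", "g2"), each = n_per),
       features = colnames(x))
}

test_that("the number of canonical functions follows the rank rule", {
  g2 <- gaussian_groups(15, sep = 3, seed = 50)
  m2 <- fit_discriminant(g2$data, g2$labels, features = g2$features)
  expect_identical(ncol(m2$coefficients), 1L)

  set.seed(51)
  x3 <- data.frame(f1 = rnorm(30), f2 = rnorm(30), f3 = rnorm(30))
  lab3 <- rep(c("a", "b", "c"), each = 10)
  x3$f1 <- x3$f1 + c(0, 4, 8)[as.integer(factor(lab3))]
  m3 <- fit_discriminant(x3, lab3, features = c("f1", "f2", "f3"))
  expect_lte(ncol(m3$coefficients), 2L)
  # canonical variates have unit pooled within-group variance
  sc <- discriminant_scores(m3, x3)
  pooled_var <- vapply(seq_len(ncol(sc)), function(j) {
    res <- sc[, j] - ave(sc[, j], lab3)
    sum(res^2) / (30 - 3)
  }, 0)
  expect_equal(pooled_var, rep(1, ncol(sc)), tolerance = 1e-6)
})

test_that("the canonical axis matches the whitened centroid difference", {
  # two anisotropic 2-D clouds, 10 within-SD separation: the closed form is
  # W^-1 (m2 - m1) up to scale
  set.seed(52)
  n <- 200
  base <- cbind(rnorm(2 * n, sd = 2), rnorm(2 * n, sd = 0.5))
  base[, 2] <- base[, 2] + 0.6 * base[, 1] # correlated noise
  shift <- c(10 * 2, 0)
  x <- base
  x[(n + 1):(2 * n), ] <- x[(n + 1):(2 * n), ] + rep(shift, each = n)
  colnames(x) <- c("f1", "f2")
  lab <- rep(c("g1", "g2"), each = n)
  m <- fit_discriminant(as.data.frame(x), lab, features = c("f1", "f2"))

  z <- scale(x, center = m$center, scale = m$scale)
  m1 <- colMeans(z[lab == "g1", ]); m2 <- colMeans(z[lab == "g2", ])
  zc <- z - rbind(matrix(m1, n, 2, byrow = TRUE),
                  matrix(m2, n, 2, byrow = TRUE))
  W <- crossprod(zc) / (2 * n - 2)
  want <- solve(W, m2 - m1)
  got <- m$coefficients[, 1]
  cosine <- abs(sum(want * got)) / sqrt(sum(want^2) * sum(got^2))
  expect_gt(cosine, cos(5 * pi / 180)) # within 5 degrees
})

test_that("reclassification separates what is separable", {
  g <- gaussian_groups(20, sep = 10, seed = 53)
  m <- fit_discriminant(g$data, g$labels, features = g$features)
  rc <- reclassify(m, g$data, g$labels)
  expect_identical(rc$percent_correct, 100)
  # a row sitting exactly on a centroid is assigned to that group
  cvec <- m$coefficients[, 1]
  z_row <- m$centroids[1, 1] * cvec / sum(cvec^2) # scores back onto centroid
  x_cen <- as.data.frame(as.list(z_row * m$scale + m$center))
  names(x_cen) <- g$features
  expect_identical(as.character(reclassify(m, x_cen)$predicted), m$levels[1])
})

test_that("accuracy is invariant to affine rescaling of a feature", {
  g <- gaussian_groups(25, sep = 2.5, seed = 54)
  m <- fit_discriminant(g$data, g$labels, features = g$features)
  acc1 <- reclassify(m, g$data, g$labels)$percent_correct
  scaled <- g$data
  scaled$f2 <- scaled$f2 * 1e4 + 900
  m2 <- fit_discriminant(scaled, g$labels, features = g$features)
  acc2 <- reclassify(m2, scaled, g$labels)$percent_correct
  expect_identical(acc1, acc2)
})

test_that("canonical scores agree with the established LDA cross-check", {
  g <- gaussian_groups(30, sep = 3, seed = 55)
  m <- fit_discriminant(g$data, g$labels, features = g$features)
  sc <- discriminant_scores(m, g$data)[, 1]
  ld <- MASS::lda(as.matrix(g$data), grouping = g$labels)
  sc_mass <- as.matrix(g$data) %*% ld$scaling[, 1]
  expect_gt(abs(cor(sc, sc_mass)), 1 - 1e-8)
  expect_identical(
    as.character(reclassify(m, g$data)$predicted),
    as.character(predict(ld, g$data)$class)
  )
})

test_that("leave-one-out is more conservative than resubstitution", {
  g <- gaussian_groups(15, sep = 1.5, seed = 56)
  m <- fit_discriminant(g$data, g$labels, features = g$features)
  resub <- reclassify(m, g$data, g$labels)$percent_correct
  loo <- reclassify(m, g$data, g$labels, method = "loo")$percent_correct
  expect_lte(loo, resub)
})

test_that("group envelopes are centered on centroids with chi-square radii", {
  # three groups give two canonical dimensions, so the ellipse lives in the
  # plane the figure convention draws
  set.seed(57)
  n <- 2000
  x <- data.frame(f1 = c(rnorm(n), rnorm(n, 15), rnorm(n)),
                  f2 = c(rnorm(n), rnorm(n), rnorm(n, 15)))
  lab <- rep(c("g1", "g2", "g3"), each = n)
  m <- fit_discriminant(x, lab, features = c("f1", "f2"))
  env <- group_envelopes(m, x, lab)
  sc <- discriminant_scores(m, x)
  for (g in unique(lab)) {
    expect_equal(env$center1[env$group == g], mean(sc[lab == g, 1]),
                 tolerance = 1e-8)
    expect_equal(env$center2[env$group == g], mean(sc[lab == g, 2]),
                 tolerance = 1e-8)
  }
  # near-isotropic unit within-group variance: both half-axes near
  # sqrt(qchisq(.95, 2))
  expect_equal(env$axis1, rep(sqrt(qchisq(0.95, 2)), 3), tolerance = 0.1)
  expect_equal(env$axis2, rep(sqrt(qchisq(0.95, 2)), 3), tolerance = 0.1)
  # Monte-Carlo coverage of the 95% ellipse
  g1_scores <- sc[lab == "g1", , drop = FALSE]
  d2 <- mahalanobis(g1_scores, colMeans(g1_scores), cov(g1_scores))
  coverage <- mean(d2 <= qchisq(0.95, 2))
  expect_gte(coverage, 0.92)
  expect_lte(coverage, 0.98)

  # two-group models pad the second dimension with zeros, without complaint
  x2 <- x[1:(2 * n), ]
  lab2 <- lab[1:(2 * n)]
  m2 <- fit_discriminant(x2, lab2, features = c("f1", "f2"))
  expect_silent(env2 <- group_envelopes(m2, x2, lab2))
  expect_equal(env2$axis2, c(0, 0))
})

test_that("degenerate inputs are rejected with useful errors", {
  g <- gaussian_groups(10, sep = 2, seed = 58)
  bad <- g$data
  bad$f1 <- 1 # constant column
  expect_error(fit_discriminant(bad, g$labels, features = g$features),
               "constant")
  expect_error(fit_discriminant(g$data[1:10, ], g$labels[1:10],
                                features = g$features), "2 groups")
  nad <- g$data
  nad$f2[3] <- NA
  expect_error(fit_discriminant(nad, g$labels, features = g$features),
               "missing")
  expect_error(discriminant_scores(
    fit_discriminant(g$data, g$labels, features = g$features),
    g$data[, 1:3]
  ), "missing feature columns")
})
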