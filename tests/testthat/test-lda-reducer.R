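test_that("fisher ratio matches direct arithmetic, including degenerate inputs", {
  expect_equal(fisher_ratio(0, 2, 1, 1), 2)
  expect_equal(fisher_ratio(5, 5, 3, 7), 0)
  expect_equal(fisher_ratio(1, 3, 0, 0), Inf)   # perfect separation
  expect_equal(fisher_ratio(2, 2, 0, 0), 0)     # coincident degenerate
  expect_error(fisher_ratio(0, 1, -1, 1), "non-negative")
  # random draws against an independently coded oracle
  withr::with_seed(101, {
    for (i in 1:50) {
      mu <- rnorm(2); v <- rexp(2)
      oracle <- ((mu[1] - mu[2]) * (mu[1] - mu[2])) / (v[1] + v[2])
      expect_equal(fisher_ratio(mu[1], mu[2], v[1], v[2]), oracle)
    }
  })
})

test_that("scatter matrices decompose the total scatter and detect degenerate classes", {
  toy <- toy_gaussian(n_per_class = 15L, p = 3L, seed = 7)
  sc <- compute_scatter(toy$X, toy$y)
  expect_equal(sc$within, t(sc$within))
  expect_true(all(eigen(sc$within, symmetric = TRUE,
                        only.values = TRUE)$values > -1e-10))
  # total-scatter decomposition: S_T = S_W + S_B
  centred <- sweep(toy$X, 2L, colMeans(toy$X))
  expect_equal(sc$within + sc$between, crossprod(centred),
               tolerance = 1e-10)
  expect_lte(qr(sc$between)$rank, sc$n_classes - 1L)

  # two constant classes: zero within, rank-1 between
  Xc <- rbind(matrix(1, 3, 2), matrix(5, 3, 2))
  scc <- compute_scatter(Xc, rep(c("a", "b"), each = 3))
  expect_equal(scc$within, matrix(0, 2, 2))
  expect_equal(qr(scc$between)$rank, 1L)

  expect_error(compute_scatter(toy$X, rep("PD", nrow(toy$X))),
               "two classes")
  expect_error(compute_scatter(toy$X[1:5, ], c("a", "a", "a", "a", "b")),
               "b")
})

test_that("single-feature scatter reproduces the one-dimensional Fisher structure", {
  # brute-force on a fixed 6-point set
  x <- matrix(c(0, 1, 2, 10, 11, 12), ncol = 1)
  y <- rep(c("h", "p"), each = 3)
  sc <- compute_scatter(x, y)
  mu <- tapply(x[, 1], y, mean)
  expect_equal(sc$within[1, 1],
               sum((x[1:3] - mu["h"])^2) + sum((x[4:6] - mu["p"])^2))
  expect_equal(sc$between[1, 1],
               3 * (mu["h"] - mean(x))^2 + 3 * (mu["p"] - mean(x))^2,
               ignore_attr = TRUE)
})

test_that("auto dimensionality follows the class-count law", {
  toy <- toy_gaussian(n_per_class = 20L, p = 5L, seed = 3)
  proj <- fit_projection(toy$X, toy$y)
  expect_equal(proj$k, 1L)                 # binary: k = C - 1 = 1

  withr::with_seed(5, {
    y4 <- rep(c("PD", "MSA_C", "MSA_P", "healthy"), each = 15L)
    X4 <- matrix(rnorm(60 * 6), ncol = 6) +
      outer(as.numeric(factor(y4)), rep(1, 6))
    proj4 <- fit_projection(X4, y4)
    expect_equal(proj4$k, 3L)              # four classes: k = 3
    expect_true(all(diff(proj4$eigenvalues) <= 1e-8))  # decreasing order
    expect_true(all(proj4$eigenvalues >= 0))
  })
  expect_error(fit_projection(toy$X, toy$y, k = 2), "C-1")
})

test_that("spherical two-class data recovers the mean-difference direction", {
  withr::with_seed(11, {
    p <- 6L
    y <- rep(c("PD", "healthy"), each = 400L)
    mu <- rnorm(p)
    X <- matrix(rnorm(800 * p), ncol = p)
    X[y == "PD", ] <- sweep(X[y == "PD", , drop = FALSE], 2L, mu, `+`)
    proj <- fit_projection(X, y, scale = FALSE)
    cosine <- abs(sum(proj$directions * mu) /
                    sqrt(sum(proj$directions^2) * sum(mu^2)))
    expect_gt(cosine, 0.99)
  })
})

test_that("fitted direction beats random directions and grid maximization agrees", {
  # random-direction oracle over several seeded toy datasets
  for (seed in 1:5) {
    toy <- toy_gaussian(n_per_class = 25L, p = 4L, seed = seed)
    proj <- fit_projection(toy$X, toy$y, scale = FALSE)
    sc <- compute_scatter(toy$X, toy$y)
    fitted_ratio <- projected_scatter_ratio(sc, proj$directions[, 1])
    rand <- withr::with_seed(seed + 100, {
      matrix(rnorm(1000 * 4), ncol = 4)
    })
    rand_ratios <- apply(rand, 1L, function(w)
      projected_scatter_ratio(sc, w))
    expect_gte(fitted_ratio, max(rand_ratios))
  }

  # 2-feature problems: dense angular grid maximization of the ratio
  for (seed in 6:8) {
    toy <- toy_gaussian(n_per_class = 30L, p = 2L, seed = seed)
    sc <- compute_scatter(toy$X, toy$y)
    theta <- seq(0, pi, length.out = 20000L)
    ratios <- vapply(theta, function(t)
      projected_scatter_ratio(sc, c(cos(t), sin(t))), 0)
    w_grid <- c(cos(theta[which.max(ratios)]),
                sin(theta[which.max(ratios)]))
    proj <- fit_projection(toy$X, toy$y, scale = FALSE)
    cosine <- abs(sum(w_grid * proj$directions[, 1]))
    expect_gt(cosine, 0.999)
  }
})

test_that("projection agrees with the reference generalized-eigen solver", {
  skip_if_not_installed("MASS")
  toy <- toy_gaussian(n_per_class = 40L, p = 5L, seed = 13)
  proj <- fit_projection(toy$X, toy$y, scale = FALSE)
  ref <- MASS::lda(toy$X, grouping = toy$y)$scaling[, 1]
  cosine <- abs(sum(proj$directions[, 1] * ref) /
                  sqrt(sum(proj$directions^2) * sum(ref^2)))
  expect_gt(cosine, 1 - 1e-8)
})

test_that("transform is linear, deterministic and shape-checked", {
  toy <- toy_gaussian(n_per_class = 20L, p = 3L, seed = 21)
  proj <- fit_projection(toy$X, toy$y)
  A <- toy$X[1:5, ]
  B <- toy$X[6:10, ]
  # linearity holds in the centred coordinates the projection uses
  lin <- lda_transform(proj, 2 * A + 3 * B) + 4 * lda_transform(proj, 0 * A)
  expect_equal(lin,
               2 * lda_transform(proj, A) + 3 * lda_transform(proj, B),
               tolerance = 1e-10)
  expect_identical(lda_transform(proj, A), lda_transform(proj, A))
  expect_error(lda_transform(proj, toy$X[, 1:2]), "columns")

  # one-feature data: projection is the data up to affine rescale
  x1 <- withr::with_seed(22, matrix(c(rnorm(10), rnorm(10) + 3), ncol = 1))
  y1 <- rep(c("a", "b"), each = 10)
  p1 <- fit_projection(x1, y1)
  z <- lda_transform(p1, x1)
  expect_gt(abs(cor(z[, 1], x1[, 1])), 1 - 1e-12)
})

test_that("class relabelling changes projected coordinates at most in sign", {
  toy <- toy_gaussian(n_per_class = 20L, p = 4L, seed = 31)
  proj1 <- fit_projection(toy$X, toy$y)
  relabel <- ifelse(toy$y == "PD", "healthy", "PD")
  proj2 <- fit_projection(toy$X, relabel)
  z1 <- lda_transform(proj1, toy$X)
  z2 <- lda_transform(proj2, toy$X)
  expect_true(isTRUE(all.equal(z1, z2, tolerance = 1e-8)) ||
                isTRUE(all.equal(z1, -z2, tolerance = 1e-8)))
})

test_that("sign convention fixes the first nonzero component positive", {
  for (seed in 1:4) {
    toy <- toy_gaussian(n_per_class = 15L, p = 3L, seed = seed)
    proj <- fit_projection(toy$X, toy$y)
    first_nz <- proj$directions[which(abs(proj$directions[, 1]) > 1e-12)[1], 1]
    expect_gt(first_nz, 0)
  }
})

test_that("singular within-scatter is handled by shrinkage, not a crash", {
  # p > n guarantees singular S_W
  withr::with_seed(41, {
    X <- matrix(rnorm(8 * 12), nrow = 8)
    y <- rep(c("a", "b"), each = 4)
    proj <- fit_projection(X, y)
    expect_equal(proj$k, 1L)
    expect_true(all(is.finite(proj$directions)))
  })
})

test_that("Ledoit-Wolf shrinkage improves holdout separation near n ~ p", {
  withr::with_seed(51, {
    p <- 26L; d <- rep(0.6, p)
    gen <- function(n) {
      y <- rep(c("PD", "healthy"), each = n / 2)
      X <- matrix(rnorm(n * p), ncol = p)
      X[y == "PD", ] <- sweep(X[y == "PD", , drop = FALSE], 2L, d, `+`)
      list(X = X, y = y)
    }
    deltas <- vapply(1:5, function(i) {
      trn <- gen(40L); tst <- gen(2000L)
      hold <- function(shr) {
        pr <- fit_projection(trn$X, trn$y, shrinkage = shr)
        z <- lda_transform(pr, tst$X)
        abs(mean(z[tst$y == "PD", 1]) - mean(z[tst$y == "healthy", 1])) /
          sqrt((var(z[tst$y == "PD", 1]) + var(z[tst$y == "healthy", 1])) / 2)
      }
      hold("ledoit_wolf") - hold(1e-6)
    }, 0)
    expect_gt(mean(deltas), 0)
  })
})

test_that("projection serializes to JSON and back", {
  toy <- toy_gaussian(n_per_class = 15L, p = 4L, seed = 61)
  proj <- fit_projection(toy$X, toy$y)
  path <- withr::local_tempfile(fileext = ".json")
  projection_to_json(proj, path)
  back <- projection_from_json(path)
  expect_equal(back$directions, proj$directions, ignore_attr = TRUE)
  expect_equal(back$center, proj$center, ignore_attr = TRUE)
  expect_equal(lda_transform(back, toy$X), lda_transform(proj, toy$X))
})
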