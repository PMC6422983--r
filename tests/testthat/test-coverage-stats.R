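test_that("gc_normalize implements the per-band median equation", {
  # all amplicons in one band: output equals input
  counts <- matrix(c(10, 20, 30, 40), ncol = 1,
                   dimnames = list(paste0("a", 1:4), "s1"))
  gc <- c(0.41, 0.42, 0.43, 0.44)
  expect_equal(unclass(gc_normalize(counts, gc))[, 1], counts[, 1])

  # a band with median 2m is scaled by 0.5
  counts2 <- matrix(c(10, 10, 10, 20, 20, 20), ncol = 1,
                    dimnames = list(paste0("a", 1:6), "s1"))
  gc2 <- c(0.30, 0.31, 0.32, 0.60, 0.61, 0.62)
  m <- median(counts2[, 1])  # 15
  norm <- gc_normalize(counts2, gc2)
  expect_equal(unname(norm[4:6, 1]), rep(20 * m / 20, 3))
  expect_equal(unname(norm[1:3, 1]), rep(10 * m / 10, 3))

  expect_error(gc_normalize(matrix(c(0, 0, 1, 2), ncol = 1),
                            c(0.1, 0.12, 0.6, 0.62)),
               "all-zero median")
})

test_that("per-band medians of normalized counts equal the raw global median", {
  set.seed(21)
  for (r in 1:20) {
    n <- sample(20:60, 1)
    k <- sample(2:4, 1)
    counts <- matrix(rpois(n * k, 100) + 1, n, k,
                     dimnames = list(sprintf("a%02d", 1:n),
                                     sprintf("s%d", 1:k)))
    gc <- runif(n, 0.2, 0.8)
    norm <- gc_normalize(counts, gc)
    band <- attr(norm, "gc_band")
    for (j in 1:k) {
      m <- median(counts[, j])
      for (b in unique(band)) {
        expect_equal(median(norm[band == b, j]), m)
      }
    }
  }
})

test_that("gc_normalize is idempotent and preserves within-band ranks", {
  set.seed(22)
  n <- 50
  counts <- matrix(rgamma(n * 3, 20, 0.1), n, 3,
                   dimnames = list(sprintf("a%02d", 1:n), c("s1", "s2", "s3")))
  gc <- runif(n, 0.25, 0.75)
  once <- gc_normalize(counts, gc)
  twice <- gc_normalize(once, gc)
  expect_equal(unclass(twice), unclass(once), tolerance = 1e-12)

  band <- attr(once, "gc_band")
  for (b in unique(band)) {
    expect_equal(order(once[band == b, 1]), order(counts[band == b, 1]))
  }
})

test_that("length-coverage regression recovers exact and null slopes", {
  x <- 1:10
  # noiseless input: lm warns about the exact fit, which is the point here
  fit <- suppressWarnings(length_coverage_regression(x, -2 * x + 5))
  expect_equal(fit$slope, -2, tolerance = 1e-10)
  expect_lt(fit$p_value, 1e-12)

  expect_error(length_coverage_regression(rep(100, 5), rnorm(5)),
               "identical")
  expect_error(length_coverage_regression(1:2, 1:2), ">= 3")
})

test_that("broken-stick regression recovers piecewise structure", {
  set.seed(23)
  len <- seq(100, 250, length.out = 120)
  cov <- ifelse(len <= 170, 50, 50 - 5 * (len - 170)) + rnorm(120, 0, 3)
  bs <- broken_stick_regression(len, cov, breakpoint = 170)
  expect_equal(bs$above$slope, -5, tolerance = 0.5)
  expect_gt(bs$below$p_value, 0.05)

  # globally linear data: both segments agree within joint CI
  cov2 <- 3 - 0.2 * len + rnorm(120, 0, 0.5)
  bs2 <- broken_stick_regression(len, cov2, breakpoint = 170)
  expect_lt(abs(bs2$below$slope - bs2$above$slope),
            3 * (bs2$below$se + bs2$above$se))

  expect_error(broken_stick_regression(len, cov, breakpoint = max(len)),
               "segment")
})

test_that("polynomial GC regression matches closed-form least squares", {
  gc <- c(0.2, 0.4, 0.6, 0.8)
  y <- 1 + 2 * gc - 3 * gc^2
  fit <- suppressWarnings(polynomial_gc_regression(gc, y))
  expect_equal(fit$coefficients, c(1, 2, -3), tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)

  # normal-equations oracle on a hand-checkable 4-point problem
  y2 <- c(2, 1, 3, 5)
  X <- cbind(1, gc, gc^2)
  beta <- solve(t(X) %*% X, t(X) %*% y2)
  fit2 <- polynomial_gc_regression(gc, y2)
  expect_equal(fit2$coefficients, as.numeric(beta), tolerance = 1e-8)

  set.seed(24)
  noise <- rnorm(500)
  fit3 <- polynomial_gc_regression(runif(500), noise)
  expect_lt(fit3$r_squared, 0.05)

  expect_error(polynomial_gc_regression(rep(0.5, 10), rnorm(10)),
               "degenerate")
})

test_that("equal-frequency discretization splits at quantiles", {
  g <- equal_frequency_discretize(c(5, 1, 9, 3, 7, 2, 8, 4, 6), 3)
  expect_equal(g[order(c(5, 1, 9, 3, 7, 2, 8, 4, 6))],
               rep(1:3, each = 3))
  expect_error(equal_frequency_discretize(rep(1, 9), 3), "ties")
  expect_error(equal_frequency_discretize(1:9, 1), ">= 2")

  set.seed(25)
  for (r in 1:25) {
    n <- sample(10:80, 1)
    k <- sample(2:5, 1)
    v <- runif(n)
    g <- equal_frequency_discretize(v, k)
    sizes <- table(g)
    expect_lte(max(sizes) - min(sizes), 1)
    # sort-based oracle: group boundaries respect value order
    expect_true(all(diff(g[order(v)]) >= 0))
  }
})

test_that("one-way ANOVA matches hand computation and the t-test identity", {
  y <- c(1, 2, 3, 2, 4, 6, 5, 7, 9)
  lab <- rep(c("a", "b", "c"), each = 3)
  grand <- mean(y)
  ssb <- sum(3 * (tapply(y, lab, mean) - grand)^2)
  ssw <- sum((y - ave(y, lab))^2)
  f_oracle <- (ssb / 2) / (ssw / 6)
  res <- anova_between_groups(y, lab)
  expect_equal(res$f_statistic, f_oracle, tolerance = 1e-12)
  expect_equal(res$p_value, pf(f_oracle, 2, 6, lower.tail = FALSE))

  set.seed(26)
  y2 <- rnorm(30)
  lab2 <- rep(c("a", "b"), 15)
  tt <- t.test(y2 ~ lab2, var.equal = TRUE)
  expect_equal(anova_between_groups(y2, lab2)$f_statistic,
               unname(tt$statistic)^2, tolerance = 1e-10)

  expect_error(anova_between_groups(1:5, c("a", "a", "a", "a", "b")),
               ">= 2 members")
})

test_that("coverage uniformity equals the two-pass CV oracle", {
  same <- matrix(rep(c(3, 7, 11), 4), ncol = 4)
  expect_true(all(coverage_uniformity(same) == 0))

  two <- matrix(c(100, 200), 1, 2)
  expect_equal(unname(coverage_uniformity(two)), 0.4714045,
               tolerance = 1e-6, ignore_attr = TRUE)

  set.seed(27)
  m <- matrix(rgamma(200, 5), 20, 10)
  expect_equal(unname(coverage_uniformity(m)),
               apply(m, 1, cv_oracle), ignore_attr = TRUE)
  expect_error(coverage_uniformity(m[, 1, drop = FALSE]), ">= 2 samples")
})

test_that("regression suite recovers the availability-shock pattern", {
  # analysis chain: mean coverage across samples, then GC-band factors
  # estimated from the amplicon set under analysis
  ok <- 0L
  for (r in 1:5) {
    gl <- generate_nucleosome_landscape(2e5, 190, 20, seed = 100 + r)
    pan <- simulate_panel(gl, 200, seed = 200 + r)
    cfg <- simulation_config(n_samples = 10, seed = 300 + r)
    sim <- simulate_amplicon_counts(pan, gl, cfg)
    len <- pan$outer_end - pan$outer_start
    mc <- rowMeans(sim$counts)
    full <- length_coverage_regression(
      len, gc_normalize(mc, pan$gc_fraction))
    sub <- len <= 170
    restr <- length_coverage_regression(
      len[sub], gc_normalize(mc[sub], pan$gc_fraction[sub]))
    if (full$slope < 0 && full$p_value < 0.05 && restr$p_value > 0.05) {
      ok <- ok + 1L
    }
  }
  expect_gte(ok, 4L)
})
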