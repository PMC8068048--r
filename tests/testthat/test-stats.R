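test_that("Dahlberg method error follows the duplicate-measurement formula", {
  expect_equal(dahlberg_error(1:10, 1:10), 0)
  expect_equal(dahlberg_error(2:8, 1:7), 1 / sqrt(2))
  set.seed(21)
  a <- rnorm(40); b <- rnorm(40)
  expect_equal(dahlberg_error(a, b), sqrt(sum((a - b)^2) / (2 * 40)))
  expect_error(dahlberg_error(1:5, 1:4), class = "length_mismatch")
})

test_that("paired comparison handles identical, shifted and degenerate columns", {
  set.seed(22)
  x <- rnorm(20, 50, 5)
  co <- data.frame(A_DS = x, A_NDS = x,            # identical
                   B_DS = x + rnorm(20, 2, 1), B_NDS = x,
                   C_DS = x + 1, C_NDS = x)        # constant nonzero diff
  r <- paired_compare(co, c("A", "B"))
  expect_equal(r$t[1], 0)
  expect_equal(r$p[1], 1)
  tt <- t.test(co$B_DS, co$B_NDS, paired = TRUE)
  expect_equal(r$t[2], unname(tt$statistic))
  expect_equal(r$p[2], tt$p.value)
  expect_true(all(is.na(r$normality_p) | (r$normality_p >= 0 & r$normality_p <= 1)))
  expect_error(paired_compare(co, "C"), class = "degenerate_variance")
})

test_that("paired t-test rejects at the nominal rate under permuted-label null data", {
  set.seed(23)
  rej <- replicate(2000, {
    d <- rnorm(30)
    t.test(d)$p.value < 0.05
  })
  expect_lt(abs(mean(rej) - 0.05), 0.02)
})

test_that("correlation tables reproduce exact and null relationships", {
  set.seed(24)
  x <- rnorm(30)
  co <- data.frame(X_DS = x, Y_DS = 2 * x + 3, X_NDS = x, Y_NDS = x,
                   K_DS = rep(1, 30), K_NDS = rep(1, 30))
  ct <- correlation_table(co, "X", "Y", "DS")
  expect_equal(unname(ct$r[1, 1]), 1, tolerance = 1e-12)
  xx <- rnorm(1e4); yy <- rnorm(1e4)
  co2 <- data.frame(X_DS = xx, Y_DS = yy)
  expect_lt(abs(correlation_table(co2, "X", "Y", "DS")$r[1, 1]), 0.05)
  expect_error(correlation_table(co, "K", "Y", "DS"), class = "constant_column")
})

test_that("principal-component loadings reconstruct the correlation matrix", {
  set.seed(25)
  x <- rnorm(50)
  X2 <- cbind(x, x + 1e-9 * rnorm(50))   # two perfectly correlated variables
  fm <- pca_loadings(X2, k = 1)
  expect_equal(fm$eigenvalues[1], 2, tolerance = 1e-6)
  expect_equal(abs(unname(fm$loadings[, 1])), c(1, 1), tolerance = 1e-6)
  X <- matrix(rnorm(200), 50, 4)
  fm2 <- pca_loadings(X, k = 4)
  expect_lt(max(abs(fm2$loadings %*% t(fm2$loadings) - cor(X))), 1e-9)
})

test_that("loadings recover a planted two-factor block structure", {
  set.seed(26)
  n <- 400
  f1 <- rnorm(n); f2 <- rnorm(n)
  X <- cbind(sapply(1:3, function(i) 0.9 * f1 + sqrt(1 - 0.81) * rnorm(n)),
             sapply(1:3, function(i) 0.9 * f2 + sqrt(1 - 0.81) * rnorm(n)))
  fm <- factor_analysis(data.frame(
    A_DS = X[, 1], B_DS = X[, 2], C_DS = X[, 3],
    D_DS = X[, 4], E_DS = X[, 5], F_DS = X[, 6]),
    c("A", "B", "C", "D", "E", "F"), "DS", k = 2)
  L <- abs(fm$loadings)
  block <- apply(L, 1, which.max)
  expect_equal(block[1:3], rep(block[1], 3), ignore_attr = TRUE)
  expect_equal(block[4:6], rep(block[4], 3), ignore_attr = TRUE)
  expect_true(all(apply(L, 1, max) > 0.7))
  expect_true(all(apply(L, 1, min) < 0.3))
})

test_that("varimax preserves communalities, finds simple structure and matches stats::varimax", {
  blockL <- rbind(c(0.9, 0), c(0.85, 0), c(0, 0.9), c(0, 0.8))
  vr <- varimax_rotate(blockL, kaiser_normalize = FALSE)
  # fixed point up to column order/sign
  expect_lt(max(abs(abs(vr$loadings) - abs(blockL))), 1e-6)
  set.seed(27)
  for (i in 1:10) {
    L <- matrix(runif(24, -1, 1), 8, 3)
    L <- L / sqrt(rowSums(L^2)) * runif(8, 0.3, 1)
    vr <- varimax_rotate(L)
    expect_lt(max(abs(rowSums(vr$loadings^2) - rowSums(L^2))), 1e-9)
    expect_lt(max(abs(crossprod(vr$rotmat) - diag(3))), 1e-9)
    # independent oracle: stats::varimax reaches the same criterion value
    sv <- stats::varimax(L, normalize = TRUE, eps = 1e-10)
    h <- sqrt(rowSums(L^2))
    expect_equal(varimax_criterion(vr$loadings / h),
                 varimax_criterion(unclass(sv$loadings) / h),
                 tolerance = 1e-6)
  }
})

test_that("two-component varimax attains the brute-force grid optimum", {
  set.seed(28)
  for (i in 1:5) {
    L <- matrix(runif(12, -1, 1), 6, 2)
    vr <- varimax_rotate(L, kaiser_normalize = FALSE)
    grid <- seq(0, pi / 2, by = 1e-4)
    crit <- vapply(grid, function(a) {
      G <- matrix(c(cos(a), -sin(a), sin(a), cos(a)), 2, 2)
      varimax_criterion(L %*% G)
    }, numeric(1))
    expect_gte(vr$criterion, max(crit) - 1e-7)
  }
})

test_that("paired power analysis is monotone and calibrated at the null", {
  expect_equal(power_paired_t(0, 25), 0.05, tolerance = 1e-9)
  ns <- c(5, 10, 20, 40, 80)
  expect_true(all(diff(power_paired_t(0.5, ns)) > 0))
  dzs <- c(0.2, 0.4, 0.8, 1.6)
  expect_true(all(diff(sapply(dzs, power_paired_t, n = 20)) > 0))
  expect_true(all(diff(sapply(dzs, min_n_paired_t)) < 0))
  expect_lte(min_n_paired_t(3), min_n_paired_t(1))
  expect_error(min_n_paired_t(0), class = "invalid_spec")
})

test_that("analytic paired power matches a Monte-Carlo oracle", {
  set.seed(29)
  dz <- 0.6763; n <- 30
  rej <- mean(replicate(20000, {
    d <- rnorm(n, dz, 1)
    abs(mean(d) / (sd(d) / sqrt(n))) > qt(0.975, n - 1)
  }))
  expect_lt(abs(rej - power_paired_t(dz, n)), 0.01)
})
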