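test_that("balanced one-way REML equals the closed-form ANOVA estimators", {
  vc <- reml_variance_components(c(1, 1, 3, 3), c("A", "A", "B", "B"))
  expect_equal(vc$sigma2_G, 2, tolerance = 1e-10)
  expect_equal(vc$sigma2_e, 0, tolerance = 1e-10)
  # negative between-group contrast clamps the genetic component at zero
  vc2 <- reml_variance_components(c(0, 2, 1, 3), c("A", "A", "B", "B"))
  expect_equal(vc2$sigma2_G, 0, tolerance = 1e-10)
  expect_equal(vc2$sigma2_e, 2, tolerance = 1e-10)
  # generic balanced case against the MSB/MSE identity
  set.seed(4)
  g <- rep(sprintf("g%02d", 1:40), each = 3)
  y <- rnorm(40)[rep(1:40, each = 3)] + rnorm(120)
  vc3 <- reml_variance_components(y, g)
  means <- tapply(y, g, mean)
  msb <- 3 * var(means)
  mse <- sum((y - means[g])^2) / (120 - 40)
  expect_equal(vc3$sigma2_e, mse, tolerance = 1e-8)
  expect_equal(vc3$sigma2_G, max(0, (msb - mse) / 3), tolerance = 1e-8)
})

test_that("degenerate designs raise informative errors", {
  expect_error(reml_variance_components(1:4, rep("A", 4)), "2 genotypes")
  expect_error(reml_variance_components(1:4, c("A", "B", "C", "D")),
               "2 reps")
})

test_that("the sub-block model recovers its generating components", {
  set.seed(6)
  est <- replicate(15, {
    n_e <- 250
    g_eff <- rnorm(n_e, 0, 1)
    sub <- rep(1:50, each = 10)
    sub_eff <- rnorm(50, 0, sqrt(0.2))
    idx <- sample(rep(1:n_e, 2))
    y <- g_eff[idx] + sub_eff[sub] + rnorm(2 * n_e, 0, 1)
    vc <- reml_variance_components(y, idx, factor(sub))
    c(vc$sigma2_G, vc$sigma2_M, vc$sigma2_e)
  })
  m <- rowMeans(est)
  se <- apply(est, 1, sd) / sqrt(ncol(est))
  expect_lt(abs(m[1] - 1), 3 * se[1] + 0.02)
  expect_lt(abs(m[2] - 0.2), 3 * se[2] + 0.02)
  expect_lt(abs(m[3] - 1), 3 * se[3] + 0.02)
})

test_that("REML components scale quadratically with the response", {
  set.seed(44)
  g <- rep(sprintf("g%02d", 1:30), each = 2)
  y <- rnorm(30)[rep(1:30, each = 2)] + rnorm(60)
  vc1 <- reml_variance_components(y, g)
  vc2 <- reml_variance_components(3 * y, g)
  expect_equal(vc2$sigma2_G, 9 * vc1$sigma2_G, tolerance = 1e-8)
  expect_equal(vc2$sigma2_e, 9 * vc1$sigma2_e, tolerance = 1e-8)
})

test_that("entry-mean heritability follows its defining formula", {
  expect_equal(entry_mean_heritability(list(sigma2_G = 2, sigma2_e = 0),
                                       2)$H2, 1)
  expect_equal(entry_mean_heritability(list(sigma2_G = 0, sigma2_e = 1),
                                       2)$H2, 0)
  expect_equal(entry_mean_heritability(list(sigma2_G = 1, sigma2_e = 1),
                                       2)$H2, 2 / 3)
})

test_that("BLUEs behave like generalized least squares", {
  set.seed(7)
  n_e <- 100
  u <- rnorm(n_e)
  scores <- data.frame(
    entry_id = rep(sprintf("e%03d", 1:n_e), 2),
    trial = 1L, rep = rep(1:2, each = n_e),
    subblock = rep(rep(1:10, each = 10), 2))
  scores$y <- u[rep(1:n_e, 2)] + rnorm(2 * n_e, 0, sqrt(2 * 0.4 / 0.6))
  b <- compute_blues(scores, "y")
  expect_length(b, n_e)
  # location equivariance
  scores$y2 <- scores$y + 5
  b2 <- compute_blues(scores, "y2")
  expect_equal(unname(b2 - b), rep(5, n_e), tolerance = 1e-6)
  # entry ranking tracks the simulated truth (~sqrt(H2) attenuation)
  u_matched <- u[match(names(b), sprintf("e%03d", 1:n_e))]
  expect_gt(cor(b, u_matched, method = "spearman"), 0.6)
  # absent entries give NA, not zero
  b3 <- compute_blues(scores, "y", entries = c("e001", "nope"))
  expect_true(is.na(b3["nope"]))
  expect_false(is.na(b3["e001"]))
})

test_that("BLUEs reduce to entry means when random variances vanish", {
  # deterministic response: all random effects estimate to zero
  scores <- data.frame(entry_id = rep(c("a", "b", "c"), each = 4),
                       trial = rep(1:2, 6), rep = rep(1:2, each = 2),
                       subblock = 1L)
  scores$y <- rep(c(1, 4, 7), each = 4)
  b <- compute_blues(scores, "y")
  expect_equal(unname(b[c("a", "b", "c")]), c(1, 4, 7), tolerance = 1e-8)
})

test_that("two-step adjusted means remove the year effect", {
  set.seed(8)
  g <- rep(sprintf("g%02d", 1:30), 2)
  year <- rep(c("Y1", "Y2"), each = 30)
  base <- rnorm(30)
  y <- base[rep(1:30, 2)] + ifelse(year == "Y2", 10, 0) + rnorm(60, 0, 0.1)
  am <- adjusted_means_two_step(y, g, year)
  # balanced 2-year data: adjusted mean = mean of within-year means
  wy <- (tapply(y[year == "Y1"], g[year == "Y1"], mean) +
           tapply(y[year == "Y2"], g[year == "Y2"], mean)) / 2
  expect_equal(as.numeric(am[dimnames(wy)[[1]]]), as.numeric(wy),
               tolerance = 1e-10)
  # adding a year constant leaves genotype contrasts unchanged
  y2 <- y + ifelse(year == "Y2", 7, 0)
  am2 <- adjusted_means_two_step(y2, g, year)
  expect_equal(diff(am2), diff(am), tolerance = 1e-10)
  # one year only: plain entry means
  am1 <- adjusted_means_two_step(y[1:30], g[1:30], year[1:30])
  expect_equal(as.numeric(am1), as.numeric(tapply(y[1:30], g[1:30], mean)))
})

test_that("genetic correlations respect their algebraic limits", {
  set.seed(9)
  W <- random_markers(80, 200, seed = 9)
  K <- genomic_relationship(W)
  tr <- polygenic_trait(W, h2 = 0.7, seed = 9)
  self <- genetic_correlation(tr$y, tr$y, K)
  expect_equal(self$rg, 1, tolerance = 1e-6)
  neg <- genetic_correlation(tr$y, -tr$y, K)
  expect_equal(neg$rg, -1, tolerance = 1e-6)
  expect_error(genetic_correlation(tr$y, tr$y, -K), "positive semi-definite")
})

test_that("genetic correlation recovers a simulated genetic overlap", {
  set.seed(10)
  rgs <- vapply(1:8, function(s) {
    W <- random_markers(300, 400, seed = 100 + s)
    K <- genomic_relationship(W)
    set.seed(200 + s)
    b1 <- rnorm(400); b2 <- 0.9 * b1 + sqrt(1 - 0.81) * rnorm(400)
    g1 <- scale(W %*% b1); g2 <- scale(W %*% b2)
    e_sd <- sqrt(0.4 / 0.6)
    x <- drop(g1) + rnorm(300, 0, e_sd)
    y <- drop(g2) + rnorm(300, 0, e_sd)
    genetic_correlation(x, y, K)$rg
  }, numeric(1))
  expect_lt(abs(mean(rgs) - 0.9), 0.1)
  expect_true(all(rgs >= -1 & rgs <= 1))
})

test_that("pearson_matrix reports correlations, p-values and gaps", {
  set.seed(11)
  x <- rnorm(100)
  df <- data.frame(x = x, lin = 2 * x + 1, z = rnorm(100),
                   flat = rep(1, 100))
  pm <- pearson_matrix(df)
  expect_equal(pm$r["x", "lin"], 1, tolerance = 1e-12)
  expect_lt(pm$p["x", "lin"], 1e-10)
  expect_true(is.na(pm$r["x", "flat"]))  # constant column: missing, no error
  # independent normals rarely exceed |r| = 0.1 at n = 1000
  hits <- vapply(1:40, function(s) {
    set.seed(s)
    abs(cor(rnorm(1000), rnorm(1000))) < 0.1
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("the two-group test separates shifted populations", {
  x <- c(1, 2, 3, 1, 2, 3)
  g <- rep(c("a", "b"), each = 3)
  res <- group_difference_test(x, g)
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  set.seed(12)
  ps <- vapply(1:10, function(s) {
    set.seed(s)
    v <- c(rnorm(500), rnorm(500, 1))
    group_difference_test(v, rep(c("a", "b"), each = 500))$p
  }, numeric(1))
  expect_true(all(ps < 1e-10))
  # singleton group: flagged NA rather than an error
  res1 <- group_difference_test(c(1, 2, 3, 9), c("a", "a", "a", "b"))
  expect_true(res1$degenerate)
  expect_true(is.na(res1$p))
})
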