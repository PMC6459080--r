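test_that("marker filters apply strict missing/het bounds", {
  # marker with exactly 40% missing is dropped (strict less-than)
  G <- matrix(1L, 10, 3, dimnames = list(sprintf("l%02d", 1:10),
                                         c("m1", "m2", "m3")))
  G[1:4, 1] <- NA_integer_  # 40% missing
  G[1:3, 2] <- NA_integer_  # 30% missing
  G[6:10, 2] <- -1L
  out <- filter_markers(G)
  expect_equal(colnames(out), c("m2", "m3"))
  # het filter: 3 of 10 markers exceed 10% het
  set.seed(1)
  H <- matrix(sample(c(-1L, 1L), 200, TRUE), 20, 10,
              dimnames = list(sprintf("l%02d", 1:20), sprintf("m%02d", 1:10)))
  H[1:5, 1:3] <- 0L  # 25% het on markers 1-3
  expect_equal(ncol(filter_markers(H)), 7L)
  # clean matrix passes unchanged
  expect_identical(filter_markers(H[, 4:10]), H[, 4:10],
                   ignore_attr = TRUE)
  # lines beyond 50% missing are removed after marker filtering
  L <- matrix(sample(c(-1L, 1L), 100, TRUE), 10, 10)
  rownames(L) <- sprintf("l%02d", 1:10); colnames(L) <- sprintf("m%02d", 1:10)
  L[1, 1:6] <- NA_integer_
  expect_equal(nrow(filter_markers(L)), 9L)
})

test_that("mode imputation removes het and missing codes deterministically", {
  g <- matrix(c(1L, 1L, NA, -1L), 4, 1)
  expect_equal(impute_and_clean(g)[3, 1], 1L)  # mode is 1
  g2 <- matrix(c(1L, 0L, 1L, 1L), 4, 1)
  expect_equal(impute_and_clean(g2)[2, 1], 1L)  # het -> missing -> mode
  g3 <- matrix(c(1L, 1L, -1L, -1L, NA), 5, 1)
  expect_equal(impute_and_clean(g3)[5, 1], -1L)  # tie breaks to -1
  # idempotence of the filter-impute pipeline
  set.seed(2)
  M <- matrix(sample(c(-1L, 0L, 1L, NA), 400, TRUE,
                     prob = c(0.4, 0.05, 0.4, 0.15)), 20, 20,
              dimnames = list(sprintf("l%02d", 1:20),
                              sprintf("m%02d", 1:20)))
  once <- impute_and_clean(filter_markers(M))
  twice <- impute_and_clean(filter_markers(once))
  attr(once, "qc") <- attr(twice, "qc") <- NULL
  expect_identical(once, twice)
  expect_false(any(is.na(once)))
  expect_false(any(once == 0L))
})

test_that("the genomic relationship matrix has VanRaden structure", {
  W <- hwe_markers(200, 500, seed = 3)
  K <- genomic_relationship(W)
  expect_equal(K, t(K), tolerance = 1e-12)
  expect_equal(mean(diag(K)), 1, tolerance = 0.05)  # HWE-like markers
  expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
             -1e-8)
  # identical lines share their self-relationship
  W2 <- rbind(W, W[1, , drop = FALSE])
  rownames(W2)[201] <- "dup"
  K2 <- genomic_relationship(W2)
  expect_equal(K2["dup", rownames(W)[1]], K2["dup", "dup"],
               tolerance = 1e-12)
})

test_that("principal components are orthonormal and separate populations", {
  set.seed(4)
  # two diverged subpopulations
  p1 <- runif(300, 0.1, 0.9); p2 <- pmin(0.95, pmax(0.05, p1 + 0.4))
  g1 <- vapply(1:300, function(j) 2L * rbinom(60, 1, p1[j]) - 1L,
               integer(60))
  g2 <- vapply(1:300, function(j) 2L * rbinom(60, 1, p2[j]) - 1L,
               integer(60))
  W <- rbind(g1, g2)
  rownames(W) <- sprintf("l%03d", 1:120)
  K <- genomic_relationship(W)
  V <- pc_covariates(K, 3)
  expect_equal(unname(crossprod(V)), diag(3), tolerance = 1e-10)
  pop <- rep(c(1, 2), each = 60)
  # silhouette of PC1 split
  d1 <- abs(V[, 1] - mean(V[pop == 1, 1]))
  d2 <- abs(V[, 1] - mean(V[pop == 2, 1]))
  own <- ifelse(pop == 1, d1, d2); other <- ifelse(pop == 1, d2, d1)
  sil <- mean((other - own) / pmax(own, other))
  expect_gt(sil, 0.8)
  expect_equal(ncol(pc_covariates(K, 0)), 0L)
})

test_that("the mixed-model scan matches OLS when K is the identity", {
  set.seed(5)
  W <- random_markers(50, 20, seed = 5)
  y <- setNames(rnorm(50) + 0.8 * W[, 3], rownames(W))
  res <- gwas_scan(y, W, K = diag(50), n_pc = 0)
  ols <- t(vapply(seq_len(ncol(W)), function(j) {
    s <- W[, j]
    if (length(unique(s)) < 2) return(c(NA_real_, NA_real_))
    f <- summary(lm(y ~ s))$coefficients
    c(f[2, 1], f[2, 4])
  }, numeric(2)))
  expect_equal(res$effect, ols[, 1], tolerance = 1e-8)
  expect_equal(res$p, ols[, 2], tolerance = 1e-8)
})

test_that("monomorphic markers are reported missing", {
  W <- random_markers(40, 5, seed = 6)
  W[, 2] <- 1L
  y <- setNames(rnorm(40), rownames(W))
  res <- gwas_scan(y, W, K = diag(40), n_pc = 0)
  expect_true(is.na(res$p[2]))
  expect_false(anyNA(res$p[-2]))
})

test_that("P3D and exact per-marker REML agree on small instances", {
  set.seed(7)
  W <- random_markers(60, 15, seed = 7)
  K <- genomic_relationship(W)
  tr <- polygenic_trait(W, h2 = 0.5, seed = 7)
  a <- gwas_scan(tr$y, W, K = K, n_pc = 0, exact = FALSE)
  b <- gwas_scan(tr$y, W, K = K, n_pc = 0, exact = TRUE)
  expect_lt(max(abs(a$effect - b$effect)), 0.05 * sd(tr$y))
  expect_gt(cor(a$effect, b$effect), 0.999)
  expect_gt(cor(-log10(a$p), -log10(b$p)), 0.99)
})

test_that("null p-values are approximately uniform", {
  set.seed(8)
  W <- random_markers(200, 300, seed = 8)
  K <- genomic_relationship(W)
  ps <- c()
  for (s in 1:5) {
    set.seed(400 + s)
    y <- setNames(rnorm(200), rownames(W))
    ps <- c(ps, gwas_scan(y, W, K = K, n_pc = 2)$p)
  }
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("Storey q-values follow the brute-force definition", {
  q <- qvalue_fdr(c(0.001, 0.5, 0.9, 0.95))
  expect_equal(q$q, c(0.004, 0.95, 0.95, 0.95), tolerance = 1e-12)
  expect_equal(q$pi0, 1)
  expect_equal(qvalue_fdr(rep(1, 10))$q, rep(1, 10))
  # monotone non-decreasing in sorted p
  set.seed(9)
  p <- runif(500)^1.5
  qs <- qvalue_fdr(p)$q
  expect_true(all(diff(qs[order(p)]) >= -1e-12))
  expect_true(all(qs <= 1))
  # brute-force cross-check on a random vector
  pi0 <- max(min(1, sum(p > 0.5) / (0.5 * length(p))), 1 / length(p))
  brute <- vapply(seq_along(p), function(i) {
    ranks <- rank(p, ties.method = "max")
    min(pi0 * length(p) * p[p >= p[i]] /
          ranks[p >= p[i]])
  }, numeric(1))
  expect_equal(qs, brute, tolerance = 1e-10)
})

test_that("the tag-ratio caller applies threshold and depth rules", {
  tags <- data.frame(line_id = c("a", "b", "c"),
                     alien_count = c(95L, 2L, 1L),
                     wheat_count = c(5L, 98L, 1L))
  res <- call_2ns(tags)
  expect_equal(res$status, c("positive", "negative", "missing"))
  # accuracy on the synthetic tag model exceeds 99%
  set.seed(10)
  truth <- runif(1000) < 0.75
  tc <- simulate_tag_counts(sprintf("l%04d", 1:1000), truth, depth = 100,
                            seed = 10)
  calls <- call_2ns(tc)
  acc <- mean((calls$status == "positive") == truth)
  expect_gt(acc, 0.99)
})

test_that("a simulated major locus is found on its chromosome", {
  cfg <- sim_config(seed = 21, n_markers = 600,
                    major_locus_effect = 3, n_qtl = 30)
  G <- simulate_genotypes(cfg, line_ids = sprintf("L%03d", 1:300))
  bv <- simulate_breeding_values(G, h2 = 0.8, n_qtl = 30,
                                 major_effect = 3, seed = 21)
  set.seed(51)
  y <- setNames(bv$u + rnorm(300, 0, 0.5), names(bv$u))
  res <- gwas_scan(y, G, n_pc = 3)
  major_chr <- G$map$chrom[G$map$marker_id == bv$major_marker]
  top <- res[order(res$p)[1:5], ]
  expect_true(major_chr %in% top$chrom)
  expect_true(bv$major_marker %in% res$marker_id[order(res$p)[1:5]])
})
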