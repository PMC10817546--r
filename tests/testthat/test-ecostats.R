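test_that("total-sum scaling produces unit row sums", {
  m <- rbind(S1 = c(2, 3, 5), S2 = c(1, 0, 0))
  r <- tss_normalize(m)
  expect_equal(unname(r["S1", ]), c(0.2, 0.3, 0.5))
  expect_equal(unname(r["S2", ]), c(1, 0, 0))
  expect_true(all(abs(rowSums(r) - 1) < 1e-12))
  m0 <- rbind(S1 = c(1, 1), S2 = c(0, 0))
  expect_warning(r0 <- tss_normalize(m0), "zero-sum")
  expect_equal(nrow(r0), 1)
})

test_that("pearson_r reproduces perfect and degenerate correlations", {
  x <- c(1, 3, 4, 7, 9, 12, 15)
  out <- pearson_r(x, 2 * x + 1)
  expect_equal(out$r, 1)
  expect_true(out$significant)
  flat <- pearson_r(x, rep(2, 7))
  expect_true(is.na(flat$r))
})

test_that("the n = 9 significance threshold stars |r| > 0.6664", {
  # construct vectors with prescribed correlations near the critical value
  rcrit <- qt(0.975, 7) / sqrt(qt(0.975, 7)^2 + 7)
  expect_equal(rcrit, 0.66638, tolerance = 1e-4)
  make_pair <- function(r) {
    set.seed(40)
    x <- scale(rnorm(9))[, 1]
    e <- scale(resid(lm(rnorm(9) ~ x)))[, 1]
    y <- r * x + sqrt(1 - r^2) * e
    list(x = x, y = y)
  }
  p64 <- make_pair(0.64)
  expect_false(pearson_r(p64$x, p64$y)$significant)
  p68 <- make_pair(0.68)
  expect_true(pearson_r(p68$x, p68$y)$significant)
})

test_that("correlation matrices respect invariance properties", {
  set.seed(41)
  tab <- data.frame(a = rnorm(12), b = rnorm(12), c = rnorm(12))
  cm <- correlation_matrix(tab)
  expect_equal(diag(cm$r), c(1, 1, 1), ignore_attr = TRUE)
  expect_equal(cm$r, t(cm$r))
  # Pearson invariant to affine rescaling
  tab2 <- tab; tab2$a <- 3 * tab$a - 7
  expect_equal(correlation_matrix(tab2)$r, cm$r)
  # Spearman invariant to monotone transforms
  tab3 <- tab; tab3$a <- exp(tab$a)
  expect_equal(correlation_matrix(tab3, "spearman")$r,
               correlation_matrix(tab, "spearman")$r)
})

test_that("Spearman distances hit the exact rank-based endpoints", {
  x <- rbind(s1 = c(1, 5, 9, 12), s2 = c(2, 6, 10, 20), s3 = c(20, 10, 6, 2))
  d <- spearman_distance_matrix(x)
  expect_equal(d["s1", "s2"], 0)   # identical rank order
  expect_equal(d["s1", "s3"], 2)   # exactly reversed
  # hand-computed rank correlation for a tied-free pair
  a <- c(3, 1, 4, 2); b <- c(2, 1, 4, 3)
  rho <- 1 - 6 * sum((rank(a) - rank(b))^2) / (4 * (16 - 1))
  d2 <- spearman_distance_matrix(rbind(a = a, b = b))
  expect_equal(d2["a", "b"], 1 - rho, tolerance = 1e-12)
})

test_that("ANOSIM detects perfect separation and respects the permutation floor", {
  set.seed(42)
  g1 <- matrix(rnorm(3 * 8, 0), 3)
  g2 <- matrix(rnorm(3 * 8, 8), 3)
  x <- rbind(g1, g2)
  d <- dist(x)
  res <- anosim_test(d, rep(c("a", "b"), each = 3), n_perm = 99, seed = 7)
  expect_equal(res$R, 1)
  expect_gte(res$p, 1 / 100)
  res2 <- anosim_test(d, rep(c("a", "b"), each = 3), n_perm = 99, seed = 7)
  expect_identical(res$p, res2$p)
  expect_error(anosim_test(d, c("a", rep("b", 5))), "at least 2 members")
})

test_that("metric MDS reconstructs Euclidean configurations", {
  set.seed(43)
  pts <- matrix(rnorm(10 * 2), 10)
  d <- as.matrix(dist(pts))
  fit <- classical_mds(d, k = 2)
  expect_equal(as.matrix(dist(fit$points)), d, tolerance = 1e-9,
               ignore_attr = TRUE)
  # 3-sample toy distance vs hand eigendecomposition of -J D2 J / 2
  d3 <- matrix(c(0, 1, 2, 1, 0, 1.5, 2, 1.5, 0), 3)
  J <- diag(3) - 1 / 3
  B <- -J %*% (d3^2) %*% J / 2
  ev <- eigen(B, symmetric = TRUE)
  want <- abs(ev$values[1:2])
  got <- classical_mds(d3, k = 2)$eig[1:2]
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("PCA captures a single-axis signal completely", {
  set.seed(44)
  x <- cbind(seq_len(12), rep(2, 12), rep(5, 12))
  fit <- pca_scores(x, k = 2)
  expect_equal(fit$variance_fraction[1], 1, tolerance = 1e-12)
  # sign convention: dominant loading positive
  expect_gt(fit$loadings[which.max(abs(fit$loadings[, 1])), 1], 0)
})

test_that("Ward clustering splits planted groups at the top", {
  set.seed(45)
  a <- matrix(rnorm(4 * 6, 0, 0.2), 4)
  b <- matrix(rnorm(4 * 6, 10, 0.2), 4)
  x <- rbind(a, b); rownames(x) <- paste0("s", 1:8)
  w <- ward_clustering(dist(x))
  top <- cutree(w$hclust, k = 2)
  expect_equal(length(unique(top[1:4])), 1)
  expect_equal(length(unique(top[5:8])), 1)
  expect_true(startsWith(w$newick, "("))
})

test_that("group tests match the hand-computed one-way F statistic", {
  y <- c(1.1, 1.3, 1.2, 3.9, 4.1, 4.0, 8.8, 9.1, 9.0)
  g <- rep(c("a", "b", "c"), each = 3)
  # hand computation
  gm <- mean(y)
  ssb <- sum(3 * (tapply(y, g, mean) - gm)^2)
  ssw <- sum((y - ave(y, g))^2)
  f <- (ssb / 2) / (ssw / 6)
  p_hand <- pf(f, 2, 6, lower.tail = FALSE)
  res <- group_difference_tests(matrix(y, ncol = 1), g)
  expect_equal(res$p, p_hand, tolerance = 1e-9)

  same <- group_difference_tests(matrix(rep(1, 9), ncol = 1), g)
  expect_equal(same$p, 1)
  sep <- group_difference_tests(matrix(c(0, 0, 0, 1.001, 1.002, 1.001),
                                       ncol = 1),
                                rep(c("a", "b"), each = 3))
  expect_lt(sep$p, 1e-3)
})

test_that("summary statistics reproduce the expected arithmetic", {
  stp <- data.frame(amf_reads_its1 = c(10, 20, 30),
                    amf_reads_its2 = c(5, 10, 15))
  bio <- data.frame(biotope = c("river_valley", "forest", "subalpine_meadow"),
                    otus_its1 = c(10, 10, 10), otus_its2 = c(4, 4, 4))
  s <- summary_tables(stp, bio)
  expect_equal(unname(s$mean_reads["ITS1"]), 20)
  expect_equal(unname(s$marker_read_ratio), 2)
  expect_equal(unname(s$otu_ratio["ITS1", "river_over_forest"]), 1.0)
  expect_equal(unname(s$otu_ratio["ITS2", "meadow_over_forest"]), 1.0)
})
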