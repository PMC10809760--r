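test_that("Bray-Curtis handles identical, disjoint and mixed rows", {
  x <- rbind(s1 = c(1, 1, 0), s2 = c(0, 1, 1), s3 = c(1, 1, 0),
             s4 = c(0, 0, 2))
  d <- bray_curtis(x)
  expect_equal(d["s1", "s2"], 0.5)        # 2/4 by hand
  expect_equal(d["s1", "s3"], 0)
  expect_equal(d["s1", "s4"], 1)
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0 & d <= 1))
  zz <- rbind(a = c(0, 0), b = c(0, 0))
  expect_warning(d0 <- bray_curtis(zz), "all-zero")
  expect_equal(d0["a", "b"], 0)
})

test_that("Bray-Curtis agrees with the vegan implementation", {
  skip_if_not_installed("vegan")
  withr::local_seed(61)
  x <- matrix(rlnorm(60), 6, 10,
              dimnames = list(paste0("s", 1:6), NULL))
  expect_equal(bray_curtis(x),
               as.matrix(vegan::vegdist(x, "bray")),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("Hellinger rows are unit in square and match the composition distance", {
  expect_equal(unname(hellinger(rbind(c(1, 0, 0)))[1, ]), c(1, 0, 0))
  expect_equal(unname(hellinger(rbind(c(1, 1, 1, 1)))[1, ]), rep(0.5, 4))
  withr::local_seed(9)
  x <- matrix(rlnorm(40), 5, 8, dimnames = list(paste0("s", 1:5), NULL))
  h <- hellinger(x)
  expect_equal(unname(rowSums(h^2)), rep(1, 5), tolerance = 1e-12)
  # Euclidean distance on the transform = Hellinger distance on compositions
  p <- sweep(x, 1, rowSums(x), "/")
  dh <- as.matrix(dist(sqrt(p)))
  expect_equal(as.matrix(dist(h)), dh, tolerance = 1e-12)
  bad <- x; bad[2, ] <- 0
  err <- tryCatch(hellinger(bad), error = identity)
  expect_match(conditionMessage(err), "s2")
})

test_that("PCoA of Euclidean distances reproduces the configuration", {
  withr::local_seed(33)
  pts <- matrix(rnorm(10), 5, 2, dimnames = list(paste0("s", 1:5), NULL))
  d <- as.matrix(dist(pts))
  ord <- pcoa(d)
  # all-axes coordinates reproduce the distances
  expect_equal(as.matrix(dist(ord$coordinates)), d, tolerance = 1e-9,
               ignore_attr = TRUE)
  # Procrustes-style check against the centered original configuration
  k <- ncol(pts)
  ctr <- scale(pts, scale = FALSE)
  co <- ord$coordinates[, 1:k]
  rot <- svd(t(co) %*% ctr)
  aligned <- co %*% rot$u %*% t(rot$v)
  expect_lt(sqrt(sum((aligned - ctr)^2)), 1e-9)
  expect_true(all(diff(ord$eigenvalues) <= 1e-9))
  expect_equal(unname(colMeans(ord$coordinates)),
               rep(0, ncol(ord$coordinates)), tolerance = 1e-9)
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("negative PCoA eigenvalues are reported, not dropped", {
  x <- matrix(c(0, 0.23, 0.62, 1.52, 0, 0.9, 0, 0.95, 0.25, 0.66,
                0.67, 0, 0, 0, 0.85, 0, 2.01, 0, 0.5, 0.49),
              5, 4, dimnames = list(paste0("s", 1:5), NULL))
  d <- bray_curtis(x)
  ord <- pcoa(d)
  expect_true(any(ord$eigenvalues < 0))
  # the Cailliez-corrected variant makes the matrix Euclidean
  ordc <- pcoa(d, correction = "cailliez")
  expect_true(min(ordc$eigenvalues) > -1e-8)
})

test_that("PCA is covariance-based with centered scores", {
  withr::local_seed(12)
  u <- rnorm(6); v <- rnorm(4)
  rank1 <- u %*% t(v)
  ord <- pca(rank1)
  expect_equal(sum(ord$eigenvalues > 1e-12), 1L)
  x <- matrix(rnorm(48), 8, 6)
  ord <- pca(x)
  expect_equal(unname(colMeans(ord$coordinates)), rep(0, 6), tolerance = 1e-9)
  expect_equal(sum(ord$prop_variance), 1, tolerance = 1e-12)
  expect_equal(ord$eigenvalues, sort(ord$eigenvalues, decreasing = TRUE))
})

test_that("PERMANOVA separates distinct clouds and hits the minimal p", {
  withr::local_seed(55)
  a <- matrix(rnorm(30, 0, 0.1), 10, 3)
  b <- matrix(rnorm(30, 50, 0.1), 10, 3)
  x <- rbind(a, b)
  rownames(x) <- sprintf("s%02d", 1:20)
  d <- as.matrix(dist(x))
  res <- permanova(d, rep(c("g1", "g2"), each = 10), n_perm = 999, seed = 42)
  expect_equal(res$p_value, 1 / 1000)
  expect_gt(res$pseudo_f, 100)
})

test_that("PERMANOVA pseudo-F matches vegan::adonis2", {
  skip_if_not_installed("vegan")
  withr::local_seed(18)
  x <- matrix(rlnorm(20 * 6), 20, 6, dimnames = list(sprintf("s%02d", 1:20), NULL))
  g <- rep(c("u", "v"), each = 10)
  d <- bray_curtis(x)
  res <- permanova(d, g, n_perm = 99, seed = 1)
  ad <- vegan::adonis2(as.dist(d) ~ g, permutations = 99)
  expect_equal(res$pseudo_f, ad$F[1], tolerance = 1e-9)
})

test_that("PERMANOVA p is invariant to sample order under the same seed", {
  withr::local_seed(7)
  x <- matrix(rnorm(60), 20, 3)
  rownames(x) <- sprintf("s%02d", 1:20)
  g <- rep(c("g1", "g2"), 10)
  names(g) <- rownames(x)
  d <- as.matrix(dist(x))
  res1 <- permanova(d, g, n_perm = 199, seed = 5)
  perm <- sample.int(20)
  res2 <- permanova(d[perm, perm], g[perm], n_perm = 199, seed = 5)
  expect_identical(res1$p_value, res2$p_value)
  expect_equal(res1$pseudo_f, res2$pseudo_f, tolerance = 1e-12)
  expect_error(permanova(d, rep(c("a", "b", "c"), c(10, 9, 1)), 99, 1),
               "size")
})

test_that("pairwise PERMANOVA adjusts p-values with Benjamini-Hochberg", {
  withr::local_seed(27)
  x <- rbind(matrix(rnorm(24, 0), 8, 3), matrix(rnorm(24, 4), 8, 3),
             matrix(rnorm(24, 8), 8, 3))
  rownames(x) <- sprintf("s%02d", 1:24)
  g <- rep(c("A", "B", "C"), each = 8)
  d <- as.matrix(dist(x))
  pw <- pairwise_permanova(d, g, n_perm = 199, seed = 3)
  expect_equal(nrow(pw), 3L)
  expect_equal(pw$p_adjusted, p.adjust(pw$p_value, "BH"))
  expect_true(all(pw$p_adjusted >= pw$p_value))
})

test_that("Welch's t handles identical, separated and textbook cases", {
  expect_equal(welch_t(c(1, 2, 3), c(1, 2, 3))$t, 0)
  expect_equal(welch_t(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_lt(welch_t(c(1, 2, 3), c(11, 12, 13))$p_value, 0.01)
  a <- c(27.5, 21.0, 19.0, 23.6, 17.0, 17.9, 16.9, 20.1, 21.9, 22.6, 23.1, 19.6)
  b <- c(27.1, 22.0, 20.8, 23.4, 23.4, 23.5, 25.8, 22.0, 24.8, 20.2, 21.9, 22.1)
  res <- welch_t(a, b)
  # high-precision two-sided p by numerical integration of the t density
  dens <- function(x) stats::dt(x, df = res$df)
  p_int <- 2 * stats::integrate(dens, abs(res$t), Inf, rel.tol = 1e-13)$value
  expect_equal(res$p_value, p_int, tolerance = 1e-10)
  expect_error(welch_t(1, c(1, 2)), "n >= 2")
})

test_that("Ward ordering merges coincident profiles first, distant last", {
  x <- rbind(a = c(0, 0, 0), b = c(0, 0, 0), c = c(9, 9, 9))
  wo <- ward_order(x)
  merges <- hclust_merges(wo$hclust)
  expect_equal(merges[[1]], c("a", "b"))
  expect_equal(merges[[2]], c("a", "b", "c"))
  expect_true(all(c("a", "b", "c") %in% wo$order))
})

test_that("Ward merge tree equals the brute-force agglomeration oracle", {
  withr::local_seed(44)
  for (i in 1:5) {
    x <- matrix(rnorm(40), 8, 5, dimnames = list(letters[1:8], NULL))
    wo <- ward_order(x)
    expect_identical(hclust_merges(wo$hclust), oracle_ward_merges(x))
  }
})
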