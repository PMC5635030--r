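test_that("distance matrices obey metric sanity checks and closed forms", {
  m <- matrix(c(0.5, 0.5, 1, 0, 0.5, 0.5), 2, 3,
              dimnames = list(c("f1", "f2"), c("s1", "s2", "s3")))
  bc <- distance_matrix(m, "bray_curtis")
  expect_equal(unname(bc["s1", "s2"]), 0.5)      # 1 - 2*0.5/2
  expect_equal(unname(bc["s1", "s3"]), 0)        # identical samples
  disj <- matrix(c(1, 0, 0, 1), 2, 2,
                 dimnames = list(c("f1", "f2"), c("s1", "s2")))
  expect_equal(unname(distance_matrix(disj, "bray_curtis")["s1", "s2"]), 1)

  jd <- distance_matrix(m, "jensen_shannon")
  expect_true(isSymmetric(jd))
  expect_equal(unname(diag(jd)), rep(0, 3))
  expect_equal(unname(jd["s1", "s3"]), 0, tolerance = 1e-9)
  expect_true(all(jd <= log(2) + 1e-9))
  # metric form is the square root
  expect_equal(distance_matrix(m, "jensen_shannon", sqrt = TRUE)^2, jd,
               tolerance = 1e-12)

  neg <- m; neg[1, 1] <- -0.1
  expect_error(distance_matrix(neg, "bray_curtis"), "negative")
})

test_that("PERMANOVA pseudo-F matches vegan and p hits its floor on separation", {
  set.seed(9)
  m <- matrix(abs(rnorm(80)), 8, 10,
              dimnames = list(sprintf("f%d", 1:8), sprintf("s%02d", 1:10)))
  d <- distance_matrix(m, "bray_curtis")
  g <- rep(c("a", "b"), each = 5)
  pv <- permanova(d, g, n_perm = 199, seed = 3)
  ref <- vegan::adonis2(as.dist(d) ~ grp,
                        data = data.frame(grp = g), permutations = 99)
  expect_equal(pv$pseudo_F, ref$F[1], tolerance = 1e-10)
  expect_equal(pv$r_squared, ref$R2[1], tolerance = 1e-10)
  expect_gte(pv$p_value, 1 / 200)

  # two tight, well-separated clusters labeled by cluster
  sep <- cbind(matrix(abs(rnorm(40, 1, 0.01)), 4, 10),
               matrix(abs(rnorm(40, 10, 0.01)), 4, 10))
  dimnames(sep) <- list(sprintf("f%d", 1:4), sprintf("s%02d", 1:20))
  ds <- distance_matrix(sep, "bray_curtis")
  ps <- permanova(ds, rep(c("a", "b"), each = 10), n_perm = 999, seed = 4)
  expect_equal(ps$p_value, 1 / 1000)

  expect_error(permanova(d, rep("a", 10)), "2 levels")
})

test_that("PERMANOVA permutation p matches exhaustive enumeration on a toy", {
  set.seed(10)
  m <- matrix(abs(rnorm(24)) + 0.1, 4, 6,
              dimnames = list(sprintf("f%d", 1:4), sprintf("s%d", 1:6)))
  d <- distance_matrix(m, "bray_curtis")
  g <- factor(rep(c("a", "b"), each = 3))
  # all C(6,3) = 20 label reassignments
  Fstat <- function(lab) mlgmwas:::permanova_F(d * d, factor(lab))$F
  obs <- Fstat(g)
  splits <- utils::combn(6, 3)
  null_F <- apply(splits, 2, function(ix) {
    lab <- rep("b", 6); lab[ix] <- "a"; Fstat(lab)
  })
  exact <- mean(null_F >= obs - 1e-12)
  got <- permanova(d, g, n_perm = 4999, seed = 5)
  expect_equal(got$p_value, exact, tolerance = 0.03)
})

test_that("PCA explains planted covariance and fixes loading signs", {
  set.seed(11)
  x <- rnorm(30)
  m <- rbind(f1 = x - min(x) + 0.1, f2 = 2 * (x - min(x) + 0.1))
  colnames(m) <- sprintf("s%02d", 1:30)
  pc <- pca_ordination(m)
  expect_equal(pc$explained_variance[1], 1, tolerance = 1e-12)

  # closed-form eigenvalues of a known 2x2 covariance
  n <- 5000
  z <- matrix(rnorm(2 * n), 2, n)
  A <- matrix(c(2, 1, 0, 1), 2, 2)     # cov = A A' = [[4,2],[2,2]] -> eig 3+sqrt(5), 3-sqrt(5)
  m2 <- A %*% z
  m2 <- m2 - min(m2)
  dimnames(m2) <- list(c("f1", "f2"), sprintf("s%04d", 1:n))
  pc2 <- pca_ordination(m2)
  ev <- pc2$explained_variance * sum(apply(t(m2), 2, var))
  expect_equal(sort(ev, decreasing = TRUE),
               c(3 + sqrt(5), 3 - sqrt(5)), tolerance = 0.15)
  # sign convention: largest-magnitude loading positive on every PC
  for (j in seq_len(ncol(pc2$loadings)))
    expect_gt(pc2$loadings[which.max(abs(pc2$loadings[, j])), j], 0)

  flat <- matrix(1, 3, 4, dimnames = list(letters[1:3], LETTERS[1:4]))
  expect_error(pca_ordination(flat), "variance")
})

test_that("dbRDA separates planted groups and matches the two-step oracle", {
  set.seed(12)
  g <- rep(c("a", "b"), each = 5)
  m <- matrix(abs(rnorm(60, 2)), 6, 10,
              dimnames = list(sprintf("f%d", 1:6), sprintf("s%02d", 1:10)))
  m[1:3, g == "a"] <- m[1:3, g == "a"] + 4
  d <- distance_matrix(m, "bray_curtis")
  cap <- dbrda(d, g, features = m)
  expect_equal(sign(cap$centroids[1]) * sign(cap$centroids[2]), -1)
  expect_equal(nrow(cap$feature_weights), 6L)

  # oracle: cmdscale PCoA then linear regression on the indicator, principal
  # axis of the fitted values
  pc <- suppressWarnings(cmdscale(as.dist(d), k = 9, eig = TRUE))
  keep <- pc$eig > max(abs(pc$eig)) * 1e-10
  Y <- pc$points[, keep[seq_len(ncol(pc$points))], drop = FALSE]
  X <- scale(model.matrix(~g)[, -1, drop = FALSE], scale = FALSE)
  fit <- lm.fit(cbind(1, X), Y)
  Yhat <- cbind(1, X) %*% fit$coefficients
  Yhat <- scale(Yhat, scale = FALSE)
  ax <- svd(Yhat)$v[, 1]
  oracle_scores <- drop(Y %*% ax)
  got <- cap$scores[, 1]
  if (cor(oracle_scores, got) < 0) oracle_scores <- -oracle_scores
  expect_equal(unname(got), unname(oracle_scores), tolerance = 1e-8)

  # permuting labels destroys the centroid separation on average
  seps <- vapply(1:20, function(s) {
    set.seed(100 + s)
    cp <- dbrda(d, sample(g))
    abs(diff(cp$centroids))
  }, 0)
  expect_gt(abs(diff(cap$centroids)), mean(seps))
})
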