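test_that("community matrix has one IV row per field summing to 3", {
  sim <- simulate_seedbank(survey_design(), seed = 3)
  cm <- community_matrix(sim$survey, sim$practices)
  expect_equal(nrow(cm), 36)  # 12 sites x 3 fields
  expect_true(all(abs(rowSums(cm) - 3) < 1e-9))
  expect_true(all(cm >= 0))
  meta <- attr(cm, "meta")
  expect_equal(nrow(meta), 36)
  expect_true(all(meta$mode %in% c("RG", "RM", "RC", "RD")))
  expect_true(all(meta$region %in% c("north", "middle", "south")))
  # two identical fields produce identical rows
  m <- cbind(spA = c(2, 2), spB = c(4, 0))
  s1 <- as.data.frame(matrix_to_survey(m, field = 1))
  s2 <- as.data.frame(matrix_to_survey(m, field = 2))
  cm2 <- community_matrix(as_survey(rbind(s1, s2)))
  expect_equal(unname(cm2[1, ]), unname(cm2[2, ]))
  expect_error(community_matrix(matrix_to_survey(m)), "at least 2 fields")
})

test_that("Bray-Curtis examples, bounds and oracles", {
  m <- rbind(a = c(1, 2), b = c(2, 1), c = c(1, 2))
  d <- bray_curtis(m)
  expect_equal(d["a", "b"], 1 / 3, tolerance = 1e-12)
  expect_equal(d["a", "c"], 0)
  disjoint <- rbind(c(3, 0), c(0, 5))
  expect_equal(bray_curtis(disjoint)[1, 2], 1)
  expect_error(bray_curtis(rbind(c(0, 0), c(0, 0))), "all-zero")
  expect_error(bray_curtis(rbind(c(-1, 2), c(1, 1))), "negative")

  set.seed(8)
  for (rep in 1:10) {
    x <- matrix(runif(5 * 6, 0, 10), 5, 6)
    got <- bray_curtis(x)
    expect_equal(unname(got), naive_bray_curtis(x), tolerance = 1e-12)
    expect_true(all(got >= 0 & got <= 1))
    expect_equal(unname(got), unname(t(got)))
    # agrees with the vegan implementation
    expect_equal(unname(got[lower.tri(got)]),
                 as.numeric(vegan::vegdist(x, method = "bray")),
                 tolerance = 1e-12)
  }
})

test_that("NMDS recovers rank-preserving configurations at low stress", {
  # six collinear points: their distance matrix is exactly 2-embeddable
  x <- c(0, 1, 2.5, 4, 7, 11)
  d <- as.matrix(dist(x))
  fit <- nmds(d, k = 2, n_runs = 10, seed = 1)
  expect_lt(fit$stress, 0.01)
  expect_true(fit$converged)
  # coordinates centered and principal-axis aligned
  expect_equal(colMeans(fit$points), c(NMDS1 = 0, NMDS2 = 0),
               tolerance = 1e-8)
  # determinism under a fixed seed
  fit2 <- nmds(d, k = 2, n_runs = 10, seed = 1)
  expect_equal(fit$points, fit2$points)
  expect_equal(fit$stress, fit2$stress)
  expect_error(nmds(matrix(1, 3, 4)), "symmetric")
})

test_that("NMDS stress is non-increasing in k and rigid-motion invariant", {
  set.seed(21)
  y <- matrix(rnorm(8 * 4), 8, 4)
  d <- as.matrix(dist(y))
  s2 <- nmds(d, k = 2, n_runs = 30, seed = 2)$stress
  s3 <- nmds(d, k = 3, n_runs = 30, seed = 2)$stress
  expect_lte(s3, s2 + 1e-8)
  # stress of a configuration is invariant to rotation/translation of the
  # input coordinates generating the distances
  theta <- 0.7
  R <- rbind(c(cos(theta), -sin(theta)), c(sin(theta), cos(theta)))
  y2 <- matrix(rnorm(8 * 2), 8, 2)
  d_a <- as.matrix(dist(y2))
  d_b <- as.matrix(dist(sweep(y2 %*% R, 2, c(3, -1), "+")))
  fa <- nmds(d_a, n_runs = 5, seed = 3)
  fb <- nmds(d_b, n_runs = 5, seed = 3)
  expect_equal(fa$stress, fb$stress, tolerance = 1e-8)
})

test_that("PERMANOVA reproduces classical ANOVA in the Euclidean case", {
  set.seed(5)
  x <- rnorm(18)
  g <- rep(c("A", "B", "C"), each = 6)
  d <- as.matrix(dist(x))
  fit <- permanova(d, g, n_perm = 99, seed = 1)
  classical <- anova(lm(x ~ g))
  expect_equal(fit$F, classical[["F value"]][1], tolerance = 1e-9)
  expect_equal(fit$df, c(between = 2L, within = 15L))
  # R^2 equals the classical eta-squared and survives distance scaling
  ss <- classical[["Sum Sq"]]
  expect_equal(fit$R2, ss[1] / sum(ss), tolerance = 1e-9)
  fit_scaled <- permanova(7.3 * d, g, n_perm = 99, seed = 1)
  expect_equal(fit_scaled$R2, fit$R2, tolerance = 1e-12)
  expect_equal(fit_scaled$F, fit$F, tolerance = 1e-9)
  # brute-force pseudo-F oracle
  expect_equal(fit$F, naive_permanova_F(d, g), tolerance = 1e-9)
})

test_that("PERMANOVA agrees with vegan::adonis2 on community data", {
  sim <- simulate_seedbank(survey_design(sites_per_mode = 2), seed = 13)
  cm <- community_matrix(sim$survey)
  meta <- attr(cm, "meta")
  d <- bray_curtis(cm)
  fit <- permanova(d, meta$mode, n_perm = 199, seed = 9)
  ref <- vegan::adonis2(as.dist(d) ~ mode, data = meta, permutations = 199)
  expect_equal(fit$F, ref$F[1], tolerance = 1e-9)
  expect_equal(fit$R2, ref$R2[1], tolerance = 1e-9)
})

test_that("PERMANOVA p attains its floor on separated clusters", {
  set.seed(11)
  pts <- rbind(matrix(rnorm(24, 0, 0.05), ncol = 2),
               matrix(rnorm(24, 10, 0.05), ncol = 2))
  g <- rep(c("a", "b"), each = 12)
  fit <- permanova(as.matrix(dist(pts)), g, n_perm = 999, seed = 2)
  expect_equal(fit$p_value, 0.001)
  # identical points split in halves: no structure at all
  same <- matrix(1, 8, 2)
  fit0 <- permanova(as.matrix(dist(same)), rep(c("a", "b"), each = 4),
                    n_perm = 99, seed = 1)
  expect_equal(fit0$F, 0)
  expect_equal(fit0$R2, 0)
  expect_error(permanova(as.matrix(dist(pts)), rep("a", 24)), "2 groups")
  expect_error(permanova(as.matrix(dist(pts[1:3, ])), c("a", "b", "c")),
               "singleton")
})

test_that("confidence ellipses reflect group covariance", {
  set.seed(17)
  xy <- matrix(rnorm(400), ncol = 2)
  ell <- confidence_ellipse(xy, rep("g", 200))
  expect_false(ell$degenerate)
  expect_lt(abs(ell$a / ell$b - 1), 0.25)  # isotropic cloud: near-circular
  expect_equal(ell$cx, mean(xy[, 1]), tolerance = 1e-9)
  # level 0 collapses the ellipse to a point
  e0 <- confidence_ellipse(xy, rep("g", 200), level = 0)
  expect_equal(c(e0$a, e0$b), c(0, 0))
  # rank-deficient covariance is flagged and omitted
  degen <- rbind(c(0, 0), c(0, 0), c(1, 1))
  e2 <- confidence_ellipse(rbind(degen, xy[1:3, ]),
                           rep(c("bad", "ok"), each = 3))
  expect_true(e2$degenerate[e2$group == "bad"])
  expect_true(is.na(e2$a[e2$group == "bad"]))
})
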