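test_that("index values match hand-worked examples", {
  expect_equal(shannon_index(7), 0)
  expect_equal(shannon_index(c(10, 10)), log(2))
  expect_equal(shannon_index(c(1, 2, 3)), 1.011404, tolerance = 1e-6)

  expect_equal(simpson_index(7), 0)
  expect_equal(simpson_index(c(10, 10)), 0.5)
  expect_equal(simpson_index(c(1, 2, 3)), 1 - 14 / 36)

  expect_equal(dominance_index(5), 1)
  expect_equal(dominance_index(c(1, 1)), 0)
  expect_equal(dominance_index(c(2, 2)), 1 / 3)

  # perfectly even communities have evenness 1 under the default variant
  for (S in 2:20)
    expect_equal(evenness_index(rep(10, S)), 1, tolerance = 1e-12)
  # complement variant on (10,10): (1/0.5 - 1) / (e^log2 - 1) = 1
  expect_equal(evenness_index(c(10, 10), variant = "complement"), 1)
  # oracle-computed value for a skewed quadrat
  expect_equal(evenness_index(c(1, 9)), 0.5714298, tolerance = 1e-6)
  expect_equal(evenness_index(c(1, 9)), naive_evenness(c(1, 9)),
               tolerance = 1e-12)
})

test_that("degenerate quadrats raise the documented errors", {
  expect_error(shannon_index(c(0, 0)), "empty quadrat")
  expect_error(simpson_index(numeric(0)), "empty quadrat")
  expect_error(evenness_index(7), "single-species")
  expect_error(dominance_index(1), "fewer than 2 seeds")
  expect_error(shannon_index(-1), "negative")
})

test_that("indices match brute-force oracles on random quadrats", {
  set.seed(13)
  for (rep in 1:100) {
    n <- rpois(sample(2:6, 1), lambda = 5) + c(2, rep(0, 0))
    n <- n[n >= 0]
    if (sum(n) < 2 || sum(n > 0) < 2) n <- c(n, 3, 4)
    expect_equal(shannon_index(n), naive_shannon(n), tolerance = 1e-12)
    expect_equal(simpson_index(n), naive_simpson(n), tolerance = 1e-12)
    expect_equal(evenness_index(n), naive_evenness(n), tolerance = 1e-12)
    expect_equal(evenness_index(n, "complement"),
                 naive_evenness(n, "complement"), tolerance = 1e-12)
    expect_equal(dominance_index(n), naive_dominance(n), tolerance = 1e-12)
  }
})

test_that("index structure: lambda + D = 1, C -> D, invariances", {
  set.seed(29)
  for (rep in 1:25) {
    n <- rpois(6, 20) + 1
    p <- n / sum(n)
    D <- sum(p^2)
    expect_equal(simpson_index(n) + D, 1, tolerance = 1e-12)
    # dominance approaches the concentration D at large N
    expect_lt(abs(dominance_index(n) - D), 3 / sum(n))
    # permutation invariance of H', scale invariance of H', not of C
    perm <- sample(n)
    expect_equal(shannon_index(perm), shannon_index(n), tolerance = 1e-12)
    expect_equal(shannon_index(n * 7), shannon_index(n), tolerance = 1e-12)
  }
  expect_false(isTRUE(all.equal(dominance_index(c(2, 2)),
                                dominance_index(c(20, 20)))))
})

test_that("Shannon and Simpson agree with vegan on random quadrats", {
  set.seed(31)
  m <- matrix(rpois(60, 8) + 1, nrow = 10)
  expect_equal(apply(m, 1, shannon_index),
               as.numeric(vegan::diversity(m, index = "shannon")),
               tolerance = 1e-12)
  expect_equal(apply(m, 1, simpson_index),
               as.numeric(vegan::diversity(m, index = "simpson")),
               tolerance = 1e-12)
})

test_that("diversity_profile yields one validated record per quadrat", {
  set.seed(37)
  m <- random_count_matrix(5, 4) + 1L  # ensure no degenerate quadrat
  sv <- matrix_to_survey(m)
  prof <- diversity_profile(sv)
  expect_equal(nrow(prof), nrow(m))
  for (q in seq_len(nrow(m))) {
    counts <- m[q, ]
    row <- prof[prof$quadrat == q, ]
    expect_equal(row$N, sum(counts))
    expect_equal(row$S, sum(counts > 0))
    expect_equal(row$shannon, naive_shannon(counts), tolerance = 1e-12)
    expect_equal(row$lambda, naive_simpson(counts), tolerance = 1e-12)
    expect_equal(row$evenness, naive_evenness(counts), tolerance = 1e-12)
    expect_equal(row$dominance, naive_dominance(counts), tolerance = 1e-12)
    expect_equal(row$total_density, sum(counts) / 0.048, tolerance = 1e-12)
  }
  # identical quadrats give zero variance of every index
  m2 <- matrix(rep(c(3L, 5L, 9L), each = 4), nrow = 4)
  colnames(m2) <- c("a", "b", "c")
  prof2 <- diversity_profile(matrix_to_survey(m2))
  for (col in c("shannon", "lambda", "evenness", "dominance"))
    expect_equal(stats::var(prof2[[col]]), 0)
  # degenerate quadrat errors carry the quadrat identity
  m3 <- cbind(a = c(5L, 0L), b = c(3L, 0L))
  expect_error(diversity_profile(matrix_to_survey(m3)), "quadrat 2")
  prof3 <- diversity_profile(matrix_to_survey(m3), strict = FALSE)
  expect_true(is.na(prof3$shannon[prof3$quadrat == 2]))
})
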