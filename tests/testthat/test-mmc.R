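test_that("Kingman closed form gives the harmonic spectrum", {
  k4 <- kingman_expected_nsfs(4)
  expect_equal(k4$norm_unfolded, c(6, 3, 2) / 11)
  expect_equal(k4$norm_folded, c(8, 3) / 11)
  expect_equal(kingman_expected_nsfs(2)$norm_folded, 1)
  expect_equal(sum(kingman_expected_nsfs(17)$norm_unfolded), 1)
  expect_error(kingman_expected_nsfs(1), "at least 2")
})

test_that("Beta merger rates obey the algebraic identities and limits", {
  for (a in c(1.1, 1.5, 1.9)) expect_equal(beta_merger_rate(2, 2, a), 1)
  # alpha -> 1+: lambda_{3,3} -> B(2,1)/B(1,1) = 0.5
  expect_lt(abs(beta_merger_rate(3, 3, 1.0001) - 0.5), 1e-3)
  # alpha -> 2-: multi-mergers vanish
  expect_lt(beta_merger_rate(10, 5, 1.999), 1e-3)
  expect_error(beta_merger_rate(3, 3, 2.1), "alpha")
  expect_error(beta_merger_rate(3, 7, 1.5), "k must")
})

test_that("pairwise coalescence happens at rate one", {
  # n = 2: height is exponential(1) on the pair-coalescence scale
  h <- vapply(1:3000, function(s) simulate_xi_beta_genealogy(2, 1.3, seed = s)$height, numeric(1))
  expect_lt(abs(mean(h) - 1), 3 * stats::sd(h) / sqrt(length(h)))
  # deterministic under a fixed seed
  expect_identical(
    simulate_xi_beta_genealogy(8, 1.4, seed = 99),
    simulate_xi_beta_genealogy(8, 1.4, seed = 99)
  )
  # B accounts for every leaf: total singleton support >= n external branches
  tr <- simulate_xi_beta_genealogy(6, 1.2, seed = 1)
  expect_true(all(tr$B >= 0))
  expect_gt(sum(tr$B), 0)
})

test_that("the exact first-step oracle pins down the process semantics", {
  # n = 2: expected height exactly 1, so total branch length exactly 2
  expect_equal(small_n_exact_oracle(2, 1.5)$B_total, 2)
  expect_equal(small_n_exact_oracle(2, 1.1)$B_total, 2)
  # Kingman limit: alpha -> 2 reproduces the closed form
  o4 <- small_n_exact_oracle(4, 1.99)
  expect_lt(max(abs(o4$norm_unfolded - kingman_expected_nsfs(4)$norm_unfolded)), 1e-3)
  expect_error(small_n_exact_oracle(6, 1.5), "n in")
})

test_that("Monte-Carlo spectra agree with the exact oracle", {
  mc <- xi_beta_expected_nsfs(3, 1.5, replicates = 10000, seed = 7)
  o <- small_n_exact_oracle(3, 1.5)
  expect_lt(max(abs(mc$norm_unfolded - o$norm_unfolded) / mc$se_unfolded), 3)
  expect_equal(sum(mc$norm_unfolded), 1, tolerance = 1e-12)
  expect_equal(sum(mc$norm_folded), 1, tolerance = 1e-12)
})

test_that("multiple-merger intensity raises the folded singleton class", {
  alphas <- c(1.1, 1.5, 1.9)
  sing <- vapply(alphas, function(a) {
    xi_beta_expected_nsfs(20, a, replicates = 3000, seed = 11)$norm_folded[1]
  }, numeric(1))
  ses <- vapply(alphas, function(a) {
    xi_beta_expected_nsfs(20, a, replicates = 3000, seed = 11)$se_folded[1]
  }, numeric(1))
  # non-increasing in alpha, allowing Monte-Carlo error
  expect_gt(sing[1], sing[2] - 2 * (ses[1] + ses[2]))
  expect_gt(sing[2], sing[3] - 2 * (ses[2] + ses[3]))
  # and the Kingman folded singleton sits below the alpha = 1.1 value
  expect_gt(sing[1], kingman_expected_nsfs(20)$norm_folded[1])
})

test_that("l2 is the plain sum of squared differences", {
  expect_equal(l2_distance(c(1, 0), c(0, 1)), 2)
  expect_equal(l2_distance(c(0.3, 0.7), c(0.3, 0.7)), 0)
  x <- runif(5); y <- runif(5)
  expect_equal(l2_distance(x, y), l2_distance(y, x))
  expect_error(l2_distance(1:3, 1:4), "length")
})

test_that("model comparison recovers the generating model", {
  # an exactly-Kingman spectrum selects Kingman (l2 = 0 vs positive)
  emp_k <- kingman_expected_nsfs(12)$norm_folded
  f_k <- fit_sfs(emp_k, alpha_grid = c(1.2, 1.6), replicates = 1000, seed = 3, n = 12)
  expect_equal(f_k$best_model, "kingman")
  expect_equal(f_k$l2_kingman, 0)

  # a Xi-Beta(alpha = 1.3) spectrum recovers alpha within one grid step
  emp_x <- xi_beta_expected_nsfs(20, 1.3, replicates = 6000, seed = 5)$norm_folded
  f_x <- fit_sfs(emp_x, alpha_grid = c(1.1, 1.3, 1.5, 1.7, 1.9), replicates = 4000, seed = 6, n = 20)
  expect_equal(f_x$best_model, "xi_beta")
  expect_lte(abs(f_x$best_alpha - 1.3), 0.2)

  expect_error(fit_sfs(emp_k, alpha_grid = numeric(0), n = 12), "empty")
  expect_error(fit_sfs(emp_k, alpha_grid = c(0.9, 1.5), n = 12), "alpha grid")
  expect_error(fit_sfs(c(0.5, 0.2), n = 6), "normalized")

  # the fitted object supports the standard model-object verbs
  expect_equal(unname(coef(f_x)["alpha"]), f_x$best_alpha)
  expect_length(predict(f_x), 10)
  expect_equal(residuals(f_x), f_x$empirical - predict(f_x))
  s <- summary(f_x)
  expect_s3_class(s, "summary.sfs_fit")
  expect_equal(nrow(s), 6)
})
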