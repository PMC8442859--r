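test_that("IBS counts are exhaustive and exclude missing loci", {
  c1 <- ibs_counts(c(0L, 1L, 2L), c(2L, 1L, 2L))
  expect_equal(c1$ibs0, 1) # 0 vs 2: opposite homozygotes
  expect_equal(c1$ibs2, 2)
  expect_equal(c1$n_AAaa, 1)
  expect_equal(c1$n_AaAa, 1)
  expect_equal(c1$ibs0 + c1$ibs1 + c1$ibs2, c1$n_loci)

  c2 <- ibs_counts(c(0L, NA, 1L), c(0L, 1L, NA))
  expect_equal(c2$n_loci, 1)

  g <- c(0L, 1L, 2L, 1L)
  cid <- ibs_counts(g, g)
  expect_equal(cid$ibs2, 4)
  expect_equal(cid$n_AAaa, 0)

  expect_error(ibs_counts(c(1L, 2L), c(1L)), "length")
})

test_that("moment IBD and robust kinship recover pedigree expectations", {
  pool <- draw_founder_frequencies(3000, "uniform", a = 0.05, b = 0.95, seed = 31)
  kp <- simulate_kinship_pairs(pool, n_pairs = 10, seed = 32)
  freqs <- colMeans(kp$geno) / 2
  exp_z <- list(
    "parent-offspring" = c(0, 1, 0), "full-sib" = c(0.25, 0.5, 0.25),
    "half-sib" = c(0.5, 0.5, 0), "unrelated" = c(1, 0, 0)
  )
  exp_phi <- c("parent-offspring" = 0.25, "full-sib" = 0.25, "half-sib" = 0.125, "unrelated" = 0)
  res <- do.call(rbind, lapply(seq_len(nrow(kp$pairs)), function(k) {
    gi <- kp$geno[kp$pairs$id1[k], ]
    gj <- kp$geno[kp$pairs$id2[k], ]
    m <- ibd_moments(gi, gj, freqs)
    r <- robust_kinship(gi, gj)
    data.frame(
      truth = kp$pairs$truth[k], Z0 = m$Z0, Z1 = m$Z1, Z2 = m$Z2,
      PI = m$PI_HAT, phi = r$phi,
      cat = classify_kinship(m$Z0, m$Z1, m$Z2, r$phi)
    )
  }))
  # at this reduced scale (L = 3000, 10 pairs/class) allow wider bands than
  # the full-scale recovery checked in the acceptance suite
  for (cl in names(exp_z)) {
    sub <- res[res$truth == cl, ]
    expect_lt(max(abs(colMeans(sub[, c("Z0", "Z1", "Z2")]) - exp_z[[cl]])), 0.08)
    expect_lt(abs(mean(sub$phi) - exp_phi[cl]), 0.04)
  }
  # classification recovery
  map <- c(
    "parent-offspring" = "parent-offspring", "full-sib" = "full-sib",
    "half-sib" = "half-sib/2nd-degree", "unrelated" = "unrelated/5th+"
  )
  expect_gte(mean(res$cat == map[res$truth]), 0.9)
  # phi and PI_HAT track each other across relationship classes
  expect_gt(stats::cor(res$phi, res$PI, method = "spearman"), 0.85)
})

test_that("duplicate genotypes sit at the estimator limits", {
  pool <- tiny_pool(2000, seed = 1)
  g <- sample_founders(pool, 1, seed = 2)[1, ]
  freqs <- pool$frequencies
  m <- ibd_moments(g, g, freqs)
  expect_gt(m$Z2, 0.95)
  expect_gt(m$PI_HAT, 0.95)
  expect_equal(robust_kinship(g, g)$phi, 0.5)
  expect_equal(classify_kinship(m$Z0, m$Z1, m$Z2, 0.5), "duplicate/MZ")
})

test_that("classification uses the powers-of-two phi bounds and the Z0 split", {
  expect_equal(classify_kinship(0, 1, 0, 0.25), "parent-offspring")
  expect_equal(classify_kinship(0.25, 0.5, 0.25, 0.25), "full-sib")
  expect_equal(classify_kinship(0.5, 0.5, 0, 0.125), "half-sib/2nd-degree")
  expect_equal(classify_kinship(0.75, 0.25, 0, 0.0625), "3rd-degree")
  expect_equal(classify_kinship(0.9, 0.1, 0, 0.03), "4th-degree")
  expect_equal(classify_kinship(1, 0, 0, 0.01), "unrelated/5th+")
  # half-open boundaries: a value exactly at 2^(-5/2) stays 2nd degree
  expect_equal(classify_kinship(0.5, 0.5, 0, 2^(-5 / 2)), "half-sib/2nd-degree")
  expect_equal(classify_kinship(NA, NA, NA, NA), "unclassified")
  expect_equal(classify_kinship(0, 1, 0, 0.25, reliable = FALSE), "unclassified")
})

test_that("estimators are symmetric and robust to missingness", {
  pool <- tiny_pool(2000, seed = 5)
  kp <- simulate_kinship_pairs(pool, n_pairs = 6, seed = 6)
  freqs <- colMeans(kp$geno) / 2
  set.seed(77)
  dphi <- numeric(nrow(kp$pairs))
  for (k in seq_len(nrow(kp$pairs))) {
    gi <- kp$geno[kp$pairs$id1[k], ]
    gj <- kp$geno[kp$pairs$id2[k], ]
    # symmetry
    expect_equal(ibd_moments(gi, gj, freqs), ibd_moments(gj, gi, freqs))
    expect_equal(robust_kinship(gi, gj)$phi, robust_kinship(gj, gi)$phi)
    # 10% missingness moves phi very little
    gi2 <- gi; gi2[sample(length(gi), 200)] <- NA
    gj2 <- gj; gj2[sample(length(gj), 200)] <- NA
    dphi[k] <- robust_kinship(gi2, gj2)$phi - robust_kinship(gi, gj)$phi
  }
  expect_lt(abs(mean(dphi)), 0.02)

  # too few joint loci flags the estimate
  expect_false(robust_kinship(c(1L, 0L), c(1L, 1L), min_loci = 100)$reliable)
})

test_that("cohort summaries count all pairs and map categories correctly", {
  cfg <- list(L = 2500, cohorts = data.frame(
    name = c("rose", "ur"), size = 10, structure = c("sweepstake", "unrelated")
  ))
  d <- make_study_like_dataset(cfg, seed = 41)
  s_fam <- cohort_kinship_summary(d$geno, d$cohorts, "rose")
  expect_equal(s_fam$n_pairs, 45)
  expect_equal(unname(s_fam$proportions["half-sib"] + s_fam$proportions["full-sib"]), 1)
  s_ur <- cohort_kinship_summary(d$geno, d$cohorts, "ur")
  expect_gt(unname(s_ur$proportions["unrelated"]), 0.95)
  expect_error(cohort_kinship_summary(d$geno, d$cohorts, "nope"), "at least two")
})
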