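test_that("stacks are balanced partitions with the leftover rule", {
  p <- sexed_pop(50, 50)
  s <- build_stacks(p, St = 10, seed = 1)
  expect_length(s$stacks, 10)
  expect_true(all(vapply(s$stacks, function(x) length(x$females) == 5 && length(x$males) == 5, logical(1))))
  expect_length(s$unstacked, 0)

  # 7F/5M at St=10: one complete stack, two females unstacked
  p2 <- sexed_pop(7, 5)
  s2 <- build_stacks(p2, St = 10, seed = 2)
  expect_length(s2$stacks, 1)
  expect_true(s2$stacks[[1]]$complete)
  expect_length(s2$unstacked, 2)
  expect_true(all(p2$sex[s2$unstacked] == "F"))

  # 8F/7M at St=10: one complete stack plus a smaller balanced stack (3F/2M -> 2F/2M), 1 F unstacked
  s3 <- build_stacks(sexed_pop(8, 7), St = 10, seed = 3)
  expect_length(s3$stacks, 2)
  expect_false(s3$stacks[[2]]$complete)
  expect_equal(length(s3$stacks[[2]]$females), length(s3$stacks[[2]]$males))

  expect_error(build_stacks(p, St = 9, seed = 1), "even")
  expect_identical(build_stacks(p, 10, seed = 5), build_stacks(p, 10, seed = 5))
})

test_that("sweepstake reproduction enforces the single-family structure", {
  pool <- tiny_pool(100, seed = 1)
  founders <- founder_population(200, pool = pool, seed = 2)
  off <- sweepstake_generation(founders, sweepstake_params(F = 1, K = 500, St = 10), seed = 3)
  expect_equal(length(off$id), 500) # regulation: exactly K offspring
  expect_equal(length(unique(off$mother)), 1) # single reproducing female
  expect_lte(length(unique(off$father)), 5) # fathers from the focal stack
  expect_true(all(off$generation == 1L))

  # every pair full- or half-sib by pedigree
  expect_identical(pedigree_kinship(off, 1, 2), pedigree_kinship(off, 2, 1))
  cats <- vapply(2:50, function(j) pedigree_kinship(off, 1, j), character(1))
  expect_true(all(cats %in% c("full-sib", "half-sib")))

  # pedigree categories from explicit parent records
  pp <- new_pedpop_for_tests(c("F", "F", "F"), mother = c(4, 4, 5), father = c(6, 7, 8))
  expect_equal(pedigree_kinship(pp, 1, 2), "half-sib")
  expect_equal(pedigree_kinship(pp, 2, 3), "unrelated")
  pp2 <- new_pedpop_for_tests(c("F", "F"), mother = c(4, 4), father = c(6, 6))
  expect_equal(pedigree_kinship(pp2, 1, 2), "full-sib")
  founders_only <- sexed_pop(2, 2)
  expect_error(pedigree_kinship(founders_only, 1, 2), "recorded parents")
})

test_that("full-sib pair fraction matches the 1/5 same-father oracle", {
  # F=1, St=10: fathers drawn uniformly from 5 males, so P(same father) = 1/5
  pool <- tiny_pool(10, seed = 1)
  fs <- numeric(8)
  for (r in 1:8) {
    founders <- founder_population(1000, pool = NULL, seed = 400 + r)
    off <- sweepstake_generation(founders, sweepstake_params(1, 1000, 10), seed = 500 + r)
    counts <- table(off$father)
    fs[r] <- sum(choose(counts, 2)) / choose(1000, 2)
  }
  se <- stats::sd(fs) / sqrt(length(fs))
  expect_lt(abs(mean(fs) - 0.2), 3 * se + 0.005)
})

test_that("single-population experiments behave at the design extremes", {
  sw <- sweepstake_params(1, 300, 10)
  r <- run_single_pop_experiment(sw, replicates = 20, sample_size = 10, seed = 1)
  expect_equal(r$success, 1) # single female: certainty
  expect_true(all(r$composition[, "unrelated"] == 0))
  expect_equal(rowSums(r$composition), rep(1, 20))

  rr <- run_single_pop_experiment(sw, replicates = 20, mode = "relaxed", seed = 2)
  expect_lt(rr$success, 0.1) # many breeding females: failure

  # determinism of the full experiment object
  expect_identical(
    run_single_pop_experiment(sw, replicates = 5, seed = 9),
    run_single_pop_experiment(sw, replicates = 5, seed = 9)
  )

  # offspring diversity below founder diversity when tracking genotypes
  rg <- run_single_pop_experiment(sw, replicates = 10, L = 300, seed = 3)
  expect_true(all(rg$pi_offspring < rg$pi_founder))
})

test_that("metapopulation generations regulate sizes and move families", {
  pool <- tiny_pool(150, seed = 1)
  sw <- sweepstake_params(1, 200, 10)
  meta <- init_metapop(200, pool = pool, seed = 2)
  expect_true(all(table(meta$deme) == 200))

  # CD=1, m=0: the sink offspring are exactly the source's family
  mp <- metapop_params(CD = 1, m = 0)
  off <- metapop_generation(meta, mp, sw, seed = 3)
  expect_true(all(table(off$deme) == 200)) # regulation everywhere
  sink <- which(off$deme == mp$sink_index)
  expect_equal(length(unique(off$mother[sink])), 1)
  comp <- vapply(sink[2:50], function(j) pedigree_kinship(off, sink[1], j), character(1))
  expect_true(all(comp %in% c("full-sib", "half-sib")))

  # CD=0, m=0: sink untouched by the source family (relaxed-mode structure)
  off0 <- metapop_generation(meta, metapop_params(CD = 0, m = 0), sw, seed = 4)
  sink0 <- which(off0$deme == mp$sink_index)
  expect_gt(length(unique(off0$mother[sink0])), 10)

  # stepping-stone exchange preserves sizes
  offm <- metapop_generation(meta, metapop_params(CD = 0.5, m = 0.1), sw, seed = 5)
  expect_true(all(table(offm$deme) == 200))
})

test_that("post-event decay removes close kin before diversity recovers", {
  de <- run_decay_experiment(
    mp = metapop_params(CD = 1, m = 0.1),
    sw = sweepstake_params(1, 200, 10),
    replicates = 4, L = 200, seed = 6
  )
  tr <- de$trajectory
  sink0 <- tr[tr$role == "sink" & tr$generation == 0, ]
  sink2 <- tr[tr$role == "sink" & tr$generation == 2, ]
  src2 <- tr[tr$role == "source" & tr$generation == 2, ]
  expect_gt(mean(sink0$close_kin), 0.3) # event generation: close kin abundant
  expect_lt(mean(sink2$close_kin), mean(sink0$close_kin) / 4) # then largely gone
  expect_lt(mean(sink2$pi), mean(src2$pi)) # while diversity stays depressed
})
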