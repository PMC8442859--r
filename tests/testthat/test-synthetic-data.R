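test_that("founder frequency pools honour their distribution and seed", {
  # degenerate uniform support collapses every frequency onto 0.5
  p <- draw_founder_frequencies(5, "uniform", a = 0.5, b = 0.5, seed = 1)
  expect_equal(p$frequencies, rep(0.5, 5))

  # law of large numbers: mean of 1000 Uniform(0.05, 0.95) draws near 0.5
  p2 <- draw_founder_frequencies(1000, "uniform", a = 0.05, b = 0.95, seed = 1)
  se <- 0.26 / sqrt(1000)
  expect_lt(abs(mean(p2$frequencies) - 0.5), 3 * se)
  expect_true(all(p2$frequencies > 0 & p2$frequencies < 1))

  # determinism and stream separation
  expect_identical(
    draw_founder_frequencies(100, "uniform", seed = 7)$frequencies,
    draw_founder_frequencies(100, "uniform", seed = 7)$frequencies
  )
  expect_false(identical(
    draw_founder_frequencies(100, "uniform", seed = 7)$frequencies,
    draw_founder_frequencies(100, "uniform", seed = 8)$frequencies
  ))

  expect_error(draw_founder_frequencies(10, "uniform", a = 0.9, b = 0.1), "uniform")
  expect_error(draw_founder_frequencies(10, "beta", shape1 = -1), "beta")
  expect_error(draw_founder_frequencies(0, "uniform"), "L must")
})

test_that("founder genotypes are Hardy-Weinberg binomial draws", {
  pool <- draw_founder_frequencies(1, "uniform", a = 0.5, b = 0.5, seed = 1)
  g <- sample_founders(pool, 1000, seed = 3)
  # Binomial(2, 0.5) moments: mean dosage 1, sd sqrt(0.5)
  expect_lt(abs(mean(g) - 1), 3 * sqrt(0.5 / 1000))
  # genotype class frequencies within 3 SE of (1/4, 1/2, 1/4)
  freq <- tabulate(as.vector(g) + 1L, 3L) / 1000
  expect_lt(abs(freq[1] - 0.25), 3 * sqrt(0.25 * 0.75 / 1000))
  expect_lt(abs(freq[2] - 0.50), 3 * sqrt(0.25 / 1000))
  expect_false(anyNA(g))
  expect_identical(sample_founders(pool, 10, seed = 5), sample_founders(pool, 10, seed = 5))
})

test_that("Mendelian transmission respects parental dosages", {
  expect_identical(breed_offspring(c(2L, 0L), c(0L, 0L), seed = 1), c(1L, 0L))
  # AA x aa -> always Aa; aa x aa -> always aa
  off <- breed_offspring(rep(2L, 100), rep(0L, 100), seed = 2)
  expect_true(all(off == 1L))

  # Aa x Aa over many loci: half the offspring loci heterozygous
  off2 <- breed_offspring(rep(1L, 10000), rep(1L, 10000), seed = 3)
  expect_lt(abs(mean(off2 == 1L) - 0.5), 0.015)
  expect_gt(min(table(off2)), 0) # all three classes appear

  # compatibility bounds for arbitrary parents (no impossible dosage)
  pool <- tiny_pool(1000, seed = 4)
  m <- sample_founders(pool, 1, seed = 5)[1, ]
  f <- sample_founders(pool, 1, seed = 6)[1, ]
  o <- breed_offspring(m, f, seed = 7)
  lo <- (m == 2L) + (f == 2L)
  hi <- 2L - ((m == 0L) + (f == 0L))
  expect_true(all(o >= lo & o <= hi))

  expect_error(breed_offspring(c(1L, 1L), c(1L)), "length")
  # missing loci transmit missing
  expect_true(is.na(breed_offspring(c(NA_integer_), c(1L), seed = 1)))
})

test_that("family cohorts carry correct pedigree truth", {
  pool <- tiny_pool(300, seed = 1)
  fam <- data.frame(mother = "M", father = c("P1", "P2"), n_offspring = c(5, 5))
  d <- make_family_cohort(pedigree_spec("rg", fam), pool, seed = 2)
  expect_equal(nrow(d$truth), choose(10, 2))
  expect_true(all(d$truth$category %in% c("full-sib", "half-sib")))
  # 2 x C(5,2) full-sib pairs, 25 half-sib pairs
  expect_equal(sum(d$truth$category == "full-sib"), 20)
  expect_equal(sum(d$truth$category == "half-sib"), 25)

  d2 <- make_family_cohort(pedigree_spec("ur", n_unrelated = 10), pool, seed = 3)
  expect_true(all(d2$truth$category == "unrelated"))

  expect_error(pedigree_spec("bad", data.frame(mother = "A", father = "A", n_offspring = 2)), "distinct")
})

test_that("single-mother cohorts have depressed diversity", {
  pool <- tiny_pool(400, seed = 9)
  pi_fam <- pi_ur <- numeric(30)
  for (r in 1:30) {
    fam <- data.frame(mother = "M", father = paste0("P", 1:5), n_offspring = c(2, 2, 2, 2, 2))
    df <- make_family_cohort(pedigree_spec("f", fam), pool, seed = 100 + r)
    du <- make_family_cohort(pedigree_spec("u", n_unrelated = 10), pool, seed = 200 + r)
    pi_fam[r] <- nucleotide_diversity(df$geno, df$cohorts, "f")
    pi_ur[r] <- nucleotide_diversity(du$geno, du$cohorts, "u")
  }
  expect_lt(mean(pi_fam), mean(pi_ur))
})

test_that("study-like dataset reproduces the cohort design", {
  d <- make_study_like_dataset(list(L = 100), seed = 1)
  expect_equal(length(unique(d$cohorts)), 14)
  expect_true(all(table(d$cohorts) == 10))
  # exactly the sweepstake-tagged cohort is all full/half-sib in truth
  per <- tapply(d$truth$category, d$truth$cohort, function(x) all(x %in% c("full-sib", "half-sib")))
  expect_equal(sum(per), 1)
  expect_false(anyNA(d$geno))

  dm <- make_study_like_dataset(list(L = 300, missingness = 0.1), seed = 1)
  expect_lt(abs(mean(is.na(dm$geno)) - 0.1), 0.01)

  expect_error(make_study_like_dataset(list(bogus = 1)), "unknown config")
})

test_that("VCF round trip is lossless and rejects malformed input", {
  d <- make_study_like_dataset(
    list(L = 60, missingness = 0.05, cohorts = data.frame(
      name = c("a", "b"), size = 5, structure = c("sweepstake", "unrelated")
    )),
    seed = 4
  )
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(d, path)
  back <- read_vcf(path)
  expect_identical(unname(back$geno), unname(d$geno))
  expect_identical(rownames(back$geno), rownames(d$geno))
  expect_identical(back$cohorts, d$cohorts)
  expect_true(any(grepl("^##fileformat=VCFv4.2", readLines(path, n = 1))))

  # multiallelic ALT rejected, naming the record
  lines <- readLines(path)
  bad <- sub("\tA\tC\t", "\tA\tC,G\t", lines[grep("^chrSyn\t3\t", lines)][1])
  lines[grep("^chrSyn\t3\t", lines)[1]] <- bad
  bad_path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(lines, bad_path)
  file.copy(paste0(sub("\\.vcf$", "", path), ".samples.tsv"),
    paste0(sub("\\.vcf$", "", bad_path), ".samples.tsv"))
  expect_error(read_vcf(bad_path), "multiallelic")

  # sample missing from metadata
  meta_path <- paste0(sub("\\.vcf$", "", path), ".samples.tsv")
  meta <- utils::read.table(meta_path, header = TRUE, sep = "\t")
  utils::write.table(meta[-1, ], meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_vcf(path), "missing from metadata")
})
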