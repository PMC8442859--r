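# Shared small fixtures, built in code at test time.

# a small uniform founder pool
tiny_pool <- function(L = 200L, seed = 1L) {
  draw_founder_frequencies(L, "uniform", a = 0.05, b = 0.95, seed = seed)
}

# a pedigreed population with fixed sex counts (founders, no genotypes)
sexed_pop <- function(n_f, n_m) {
  new_pedpop_for_tests(
    sex = c(rep("F", n_f), rep("M", n_m))
  )
}

# minimal pedpop constructor for tests (ids sequential, founders)
new_pedpop_for_tests <- function(sex, mother = NULL, father = NULL) {
  n <- length(sex)
  structure(
    list(
      id = seq_len(n), sex = sex,
      mother = if (is.null(mother)) rep(NA_integer_, n) else as.integer(mother),
      father = if (is.null(father)) rep(NA_integer_, n) else as.integer(father),
      deme = rep(1L, n), generation = rep(0L, n), geno = NULL
    ),
    class = "pedpop"
  )
}

# single-cohort genotype matrix + labels from a dosage matrix
as_cohort <- function(geno, name = "x") {
  if (is.null(rownames(geno))) rownames(geno) <- paste0("s", seq_len(nrow(geno)))
  list(geno = geno, cohorts = stats::setNames(rep(name, nrow(geno)), rownames(geno)))
}
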