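#' Parameters of sweepstake reproduction in a spawning stack
#'
#' @param F Number of reproducing females in the focal stack
#'   (1 <= F <= St/2).
#' @param K Carrying capacity: offspring produced per population per
#'   generation.
#' @param St Stack size (individuals per spawning aggregation), even,
#'   between 2 and 20 (stacks hold up to 20 limpets at a 1:1 sex ratio).
#' @return Object of class \code{sweepstake_params}.
#' @examples
#' sweepstake_params(F = 1, K = 1000, St = 10)
#' @export
sweepstake_params <- function(F = 1L, K = 1000L, St = 10L) {
  if (St %% 2 != 0) stop("St must be even: balanced 1:1 stacks are impossible otherwise", call. = FALSE)
  if (St < 2 || St > 20) stop("St must be between 2 and 20", call. = FALSE)
  if (F < 1 || F > St / 2) stop("F must satisfy 1 <= F <= St/2", call. = FALSE)
  if (K < 1) stop("K must be >= 1", call. = FALSE)
  structure(list(F = as.integer(F), K = as.integer(K), St = as.integer(St)),
    class = "sweepstake_params"
  )
}

# Pedigreed population: parallel vectors + optional dosage matrix.
# mother/father are ids (NA for founders); geno rows align with id order.
new_pedpop <- function(id, sex, mother, father, deme, generation, geno = NULL) {
  structure(
    list(
      id = as.integer(id), sex = sex,
      mother = as.integer(mother), father = as.integer(father),
      deme = as.integer(deme), generation = as.integer(generation),
      geno = geno
    ),
    class = "pedpop"
  )
}

#' Create a founder population
#'
#' Founders have no recorded parents, random Bernoulli(0.5) sexes and,
#' when a founder pool is supplied, Hardy-Weinberg genotypes.
#'
#' @param n Number of individuals.
#' @param pool Optional \code{founder_pool} for genotypes (NULL = pedigree
#'   only).
#' @param deme Deme index for all founders.
#' @param seed Integer seed.
#' @param id_offset First id minus one.
#' @return A \code{pedpop}.
#' @export
founder_population <- function(n, pool = NULL, deme = 1L, seed = 1L, id_offset = 0L) {
  with_seed(substream_seed(seed, "founder_population"), {
    sex <- ifelse(stats::runif(n) < 0.5, "F", "M")
    geno <- if (!is.null(pool)) {
      g <- matrix(stats::rbinom(n * pool$L, 2L, rep(pool$frequencies, each = n)), nrow = n)
      storage.mode(g) <- "integer"
      g
    }
    new_pedpop(
      id = id_offset + seq_len(n), sex = sex,
      mother = rep(NA_integer_, n), father = rep(NA_integer_, n),
      deme = rep(deme, n), generation = rep(0L, n), geno = geno
    )
  })
}

#' @export
print.pedpop <- function(x, ...) {
  cat(sprintf(
    "pedpop: %d individuals (%d F / %d M), generation(s) %s, deme(s) %s%s\n",
    length(x$id), sum(x$sex == "F"), sum(x$sex == "M"),
    paste(unique(x$generation), collapse = ","),
    paste(unique(x$deme), collapse = ","),
    if (is.null(x$geno)) "" else sprintf(", %d loci", ncol(x$geno))
  ))
  invisible(x)
}

# subset a pedpop by positional index
pedpop_subset <- function(pop, idx) {
  new_pedpop(
    pop$id[idx], pop$sex[idx], pop$mother[idx], pop$father[idx],
    pop$deme[idx], pop$generation[idx],
    if (!is.null(pop$geno)) pop$geno[idx, , drop = FALSE]
  )
}

#' Randomly partition a population into balanced spawning stacks
#'
#' Individuals are shuffled and grouped into stacks of St/2 females and
#' St/2 males (without replacement). Leftovers that cannot fill a complete
#' stack form one final smaller balanced stack (equal numbers of each
#' sex); any unpairable remainder stays unstacked.
#'
#' @param pop A \code{pedpop} (one deme's worth of individuals).
#' @param St Even stack size.
#' @param seed Integer seed.
#' @return List with \code{stacks} (each a list with integer position
#'   vectors \code{females}, \code{males}, and flag \code{complete}) and
#'   \code{unstacked} (positions).
#' @examples
#' p <- founder_population(24, seed = 1)
#' s <- build_stacks(p, St = 10, seed = 2)
#' length(s$stacks)
#' @export
build_stacks <- function(pop, St, seed = 1L) {
  if (St %% 2 != 0) stop("St must be even: balanced 1:1 stacks are impossible otherwise", call. = FALSE)
  if (!length(pop$id)) stop("empty population", call. = FALSE)
  h <- St %/% 2
  with_seed(substream_seed(seed, "build_stacks"), {
    fem <- sample(which(pop$sex == "F"))
    mal <- sample(which(pop$sex == "M"))
    n_full <- min(length(fem) %/% h, length(mal) %/% h)
    stacks <- vector("list", n_full)
    for (s in seq_len(n_full)) {
      stacks[[s]] <- list(
        females = fem[((s - 1L) * h + 1L):(s * h)],
        males = mal[((s - 1L) * h + 1L):(s * h)],
        complete = TRUE
      )
    }
    fem_left <- if (n_full * h < length(fem)) fem[(n_full * h + 1L):length(fem)] else integer()
    mal_left <- if (n_full * h < length(mal)) mal[(n_full * h + 1L):length(mal)] else integer()
    paired <- min(length(fem_left), length(mal_left))
    if (paired > 0L) {
      stacks[[n_full + 1L]] <- list(
        females = fem_left[seq_len(paired)],
        males = mal_left[seq_len(paired)],
        complete = FALSE
      )
    }
    unstacked <- c(
      if (paired < length(fem_left)) fem_left[(paired + 1L):length(fem_left)] else integer(),
      if (paired < length(mal_left)) mal_left[(paired + 1L):length(mal_left)] else integer()
    )
    list(stacks = stacks, unstacked = unstacked)
  })
}

# breed K offspring given parallel vectors of parental positions
.make_offspring <- function(pop, mothers, fathers, deme, id_offset, mu = 0) {
  K <- length(mothers)
  geno <- if (!is.null(pop$geno)) .breed_matrix(pop$geno, mothers, fathers, mu = mu)
  new_pedpop(
    id = id_offset + seq_len(K),
    sex = ifelse(stats::runif(K) < 0.5, "F", "M"),
    mother = pop$id[mothers], father = pop$id[fathers],
    deme = rep(deme, K), generation = rep(pop$generation[1L] + 1L, K),
    geno = geno
  )
}

#' One generation of sweepstake reproduction
#'
#' A focal stack is chosen uniformly among complete stacks; F of its
#' females are designated breeders. Exactly K offspring are produced, each
#' with its mother drawn uniformly from the breeders and its father drawn
#' uniformly (with replacement) from the focal stack's males; genotypes
#' follow Mendelian transmission and sexes are Bernoulli(0.5).
#'
#' @param pop A \code{pedpop} (the deme's adults).
#' @param params A [sweepstake_params()].
#' @param seed Integer seed.
#' @param id_offset First offspring id minus one (default: after the
#'   adults' ids).
#' @param mu Per-allele, per-transmission symmetric mutation probability
#'   (default 0; used by the multi-generation spectrum experiments).
#' @return Offspring \code{pedpop} of size exactly K.
#' @export
sweepstake_generation <- function(pop, params, seed = 1L, id_offset = NULL, mu = 0) {
  stopifnot(inherits(params, "sweepstake_params"))
  if (is.null(id_offset)) id_offset <- max(pop$id)
  st <- build_stacks(pop, params$St, seed = substream_seed(seed, "sg/stacks"))
  complete <- Filter(function(s) s$complete, st$stacks)
  if (!length(complete)) stop("no complete stack can be formed", call. = FALSE)
  with_seed(substream_seed(seed, "sg/breeding"), {
    focal <- complete[[sample.int(length(complete), 1L)]]
    if (params$F > length(focal$females)) {
      stop("F exceeds the number of females in the focal stack", call. = FALSE)
    }
    breeders <- focal$females[sample.int(length(focal$females), params$F)]
    mothers <- breeders[sample.int(params$F, params$K, replace = TRUE)]
    fathers <- focal$males[sample.int(length(focal$males), params$K, replace = TRUE)]
    .make_offspring(pop, mothers, fathers, deme = pop$deme[1L], id_offset = id_offset, mu = mu)
  })
}

#' One generation of relaxed (multi-stack, multi-female) reproduction
#'
#' The permissive regime of non-source demes: every complete stack
#' breeds, each offspring's mother is drawn uniformly from all stacked
#' females and its father uniformly from the males of the mother's stack.
#'
#' @inheritParams sweepstake_generation
#' @param K Offspring produced.
#' @param St Even stack size.
#' @return Offspring \code{pedpop} of size exactly K.
#' @export
relaxed_generation <- function(pop, K, St, seed = 1L, id_offset = NULL, mu = 0) {
  if (is.null(id_offset)) id_offset <- max(pop$id)
  st <- build_stacks(pop, St, seed = substream_seed(seed, "rg/stacks"))
  complete <- Filter(function(s) s$complete, st$stacks)
  if (!length(complete)) stop("no complete stack can be formed", call. = FALSE)
  h <- St %/% 2
  fem <- unlist(lapply(complete, `[[`, "females"))
  male_mat <- do.call(rbind, lapply(complete, `[[`, "males")) # stacks x h
  stack_of <- rep(seq_along(complete), each = h)
  with_seed(substream_seed(seed, "rg/breeding"), {
    mi <- sample.int(length(fem), K, replace = TRUE)
    mothers <- fem[mi]
    fathers <- male_mat[cbind(stack_of[mi], sample.int(h, K, replace = TRUE))]
    .make_offspring(pop, mothers, fathers, deme = pop$deme[1L], id_offset = id_offset, mu = mu)
  })
}

#' Classify a pair of individuals by pedigree
#'
#' Full-sib if both parents are shared, half-sib if exactly one is,
#' otherwise unrelated. Only one generation of pedigree memory is used
#' (grandparental links are ignored; founders are mutually unrelated).
#'
#' @param pop A \code{pedpop}.
#' @param i,j Positional indices of the two individuals.
#' @return One of "full-sib", "half-sib", "unrelated".
#' @export
pedigree_kinship <- function(pop, i, j) {
  m1 <- pop$mother[i]; f1 <- pop$father[i]
  m2 <- pop$mother[j]; f2 <- pop$father[j]
  if (anyNA(c(m1, f1, m2, f2))) stop("pedigree_kinship requires recorded parents", call. = FALSE)
  shared <- (m1 == m2) + (f1 == f2)
  c("unrelated", "half-sib", "full-sib")[shared + 1L]
}

# kinship composition of all pairs among positions `idx`
.kin_composition <- function(pop, idx) {
  m <- pop$mother[idx]; f <- pop$father[idx]
  pr <- utils::combn(length(idx), 2L)
  shared <- (m[pr[1L, ]] == m[pr[2L, ]]) + (f[pr[1L, ]] == f[pr[2L, ]])
  n <- ncol(pr)
  c(
    unrelated = sum(shared == 0L) / n,
    `half-sib` = sum(shared == 1L) / n,
    `full-sib` = sum(shared == 2L) / n
  )
}

# mean per-SNP nucleotide diversity over the fixed simulated panel
.pi_panel <- function(geno) {
  n <- 2L * nrow(geno)
  p <- colMeans(geno) / 2
  mean(n / (n - 1L) * 2 * p * (1 - p))
}

#' Replicated single-population sweepstake experiment
#'
#' Per replicate, a fresh founder population of size K is created, one
#' generation is run (sweepstake or relaxed mode), \code{sample_size}
#' offspring are drawn at random, and every sampled pair is classified by
#' pedigree. A replicate is successful when the sample contains only full-
#' and half-siblings.
#'
#' @param params A [sweepstake_params()] (St and K are also used in
#'   relaxed mode).
#' @param replicates Number of replicate simulations.
#' @param sample_size Offspring sampled per replicate (<= K).
#' @param mode "sweepstake" (one focal stack, F breeders) or "relaxed"
#'   (all stacks, all stacked females).
#' @param L Loci for genotype tracking (0 = pedigree only, fastest); when
#'   L > 0 the result also carries founder and offspring diversity.
#' @param seed Integer seed.
#' @return Object of class \code{sim_experiment}: success proportion,
#'   per-replicate kinship composition matrix, optional per-replicate
#'   founder/offspring nucleotide diversity.
#' @examples
#' r <- run_single_pop_experiment(sweepstake_params(1, 200, 10),
#'   replicates = 5, seed = 1
#' )
#' r$success
#' @export
run_single_pop_experiment <- function(params, replicates = 100L, sample_size = 10L,
                                      mode = c("sweepstake", "relaxed"), L = 0L,
                                      seed = 1L) {
  stopifnot(inherits(params, "sweepstake_params"), sample_size <= params$K)
  mode <- match.arg(mode)
  pool <- if (L > 0L) {
    draw_founder_frequencies(L, "uniform", a = 0.05, b = 0.95, seed = substream_seed(seed, "sp/pool"))
  }
  comp <- matrix(NA_real_, nrow = replicates, ncol = 3L,
    dimnames = list(NULL, c("unrelated", "half-sib", "full-sib"))
  )
  success <- logical(replicates)
  pi_founder <- pi_offspring <- rep(NA_real_, replicates)
  for (r in seq_len(replicates)) {
    rs <- substream_seed(seed, paste0("sp/rep/", r))
    founders <- founder_population(params$K, pool = pool, seed = substream_seed(rs, "founders"))
    off <- if (mode == "sweepstake") {
      sweepstake_generation(founders, params, seed = substream_seed(rs, "gen"))
    } else {
      relaxed_generation(founders, params$K, params$St, seed = substream_seed(rs, "gen"))
    }
    idx <- with_seed(substream_seed(rs, "sampling"), sample.int(params$K, sample_size))
    comp[r, ] <- .kin_composition(off, idx)
    success[r] <- comp[r, "unrelated"] == 0
    if (L > 0L) {
      pi_founder[r] <- .pi_panel(founders$geno)
      pi_offspring[r] <- .pi_panel(off$geno)
    }
  }
  structure(
    list(
      success = mean(success), successes = success, composition = comp,
      pi_founder = pi_founder, pi_offspring = pi_offspring,
      params = params, mode = mode, replicates = replicates,
      sample_size = as.integer(sample_size), seed = as.integer(seed)
    ),
    class = "sim_experiment"
  )
}

#' @export
print.sim_experiment <- function(x, ...) {
  cat(sprintf(
    "sim_experiment (%s mode): %d replicates, F=%d K=%d St=%d\n",
    x$mode, x$replicates, x$params$F, x$params$K, x$params$St
  ))
  cat(sprintf("  success proportion: %.3f\n", x$success))
  cm <- colMeans(x$composition)
  cat(sprintf(
    "  mean sampled kinship: %.3f unrelated / %.3f half-sib / %.3f full-sib\n",
    cm[1L], cm[2L], cm[3L]
  ))
  if (!all(is.na(x$pi_offspring))) {
    cat(sprintf(
      "  mean pi offspring/founder: %.4f / %.4f\n",
      mean(x$pi_offspring), mean(x$pi_founder)
    ))
  }
  invisible(x)
}

#' Simulate a cohort under recurrent sweepstake reproduction with mutation
#'
#' Runs a single population forward for several generations, each one a
#' sweepstake event (one focal stack, F breeding females), with a
#' symmetric per-allele mutation probability per transmission. After
#' enough generations the standing variation carried over from the
#' founders is lost to the recurrent bottlenecks and every segregating
#' site is a recent mutation shaped by the multiple-merger genealogy of
#' the population --- giving the singleton-rich, star-like spectra that
#' distinguish sweepstakes reproduction from Kingman-like variation. A
#' cohort sampled here is the forward-simulation analog of an empirical
#' cohort from a species with recurrent sweepstakes.
#'
#' One-generation family cohorts sampled on neutral standing variation do
#' NOT show this signature (their spectra are intermediate-shifted, with
#' a singleton deficit); the spectrum signal requires mutation
#' accumulating on the post-event genealogy.
#'
#' @param sw A [sweepstake_params()].
#' @param generations Number of forward generations (default 25).
#' @param L Number of loci tracked (default 20000).
#' @param mu Per-allele per-transmission mutation probability
#'   (default 5e-4).
#' @param sample_size Individuals sampled at the end (default 10).
#' @param seed Integer seed.
#' @return List with \code{geno} (sample dosage matrix with rownames),
#'   \code{cohorts} (named labels, single cohort "sweepstake"), and the
#'   full final \code{pop}.
#' @export
simulate_sweepstake_cohort <- function(sw = sweepstake_params(1L, 200L, 10L),
                                       generations = 25L, L = 20000L, mu = 5e-4,
                                       sample_size = 10L, seed = 1L) {
  pool <- draw_founder_frequencies(L, "neutral",
    p_min = 1e-3,
    seed = substream_seed(seed, "ssc/pool")
  )
  pop <- founder_population(sw$K, pool = pool, seed = substream_seed(seed, "ssc/founders"))
  for (g in seq_len(generations)) {
    pop <- sweepstake_generation(pop, sw,
      seed = substream_seed(seed, paste0("ssc/gen/", g)), mu = mu
    )
  }
  idx <- with_seed(substream_seed(seed, "ssc/sample"), sample.int(sw$K, sample_size))
  geno <- pop$geno[idx, , drop = FALSE]
  rownames(geno) <- sprintf("sw%02d", seq_len(sample_size))
  list(
    geno = geno,
    cohorts = stats::setNames(rep("sweepstake", sample_size), rownames(geno)),
    pop = pop
  )
}
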