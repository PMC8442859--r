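#' Mendelian transmission of unlinked biallelic loci
#'
#' Produces one offspring genotype from two parental dosage vectors: at
#' every locus one allele is drawn uniformly from the mother's two alleles
#' and one from the father's, independently across loci (free
#' recombination). A locus missing (NA) in either parent is transmitted as
#' missing.
#'
#' @param mother,father Integer dosage vectors of equal length (0/1/2, NA
#'   allowed).
#' @param seed Integer seed.
#' @return Integer dosage vector of the offspring.
#' @examples
#' breed_offspring(c(2L, 1L, 0L), c(0L, 1L, 0L), seed = 1)
#' @export
breed_offspring <- function(mother, father, seed = 1L) {
  if (length(mother) != length(father)) {
    stop("parental genotype vectors differ in length", call. = FALSE)
  }
  with_seed(substream_seed(seed, "breed_offspring"), .transmit(mother, father))
}

# core Mendelian draw; caller owns the RNG state
.transmit <- function(mother, father) {
  L <- length(mother)
  off <- (stats::runif(L) < mother / 2) + (stats::runif(L) < father / 2)
  storage.mode(off) <- "integer"
  off
}

# vectorised breeding: mothers/fathers are row indices into geno (n x L);
# returns length(mothers) x L offspring dosage matrix. mu is the
# per-allele per-transmission symmetric mutation probability (0 = off).
.breed_matrix <- function(geno, mothers, fathers, mu = 0) {
  gm <- geno[mothers, , drop = FALSE]
  gf <- geno[fathers, , drop = FALSE]
  am <- stats::runif(length(gm)) < gm / 2
  af <- stats::runif(length(gf)) < gf / 2
  if (mu > 0) {
    am <- xor(am, stats::runif(length(am)) < mu)
    af <- xor(af, stats::runif(length(af)) < mu)
  }
  off <- am + af
  dim(off) <- dim(gm)
  storage.mode(off) <- "integer"
  off
}

#' Specify the pedigree of one synthetic cohort
#'
#' @param cohort Cohort name.
#' @param families Data frame with columns \code{mother}, \code{father}
#'   (founder ids, character) and \code{n_offspring}; may have zero rows.
#' @param n_unrelated Number of additional unrelated founder individuals
#'   placed in the cohort.
#' @return Object of class \code{pedigree_spec}.
#' @export
pedigree_spec <- function(cohort, families = NULL, n_unrelated = 0L) {
  if (is.null(families)) {
    families <- data.frame(mother = character(), father = character(), n_offspring = integer())
  }
  stopifnot(is.data.frame(families), all(c("mother", "father", "n_offspring") %in% names(families)))
  if (any(families$n_offspring < 0) || n_unrelated < 0) {
    stop("offspring and unrelated counts must be non-negative", call. = FALSE)
  }
  if (nrow(families) == 0L && n_unrelated == 0L) {
    stop("empty cohort specification", call. = FALSE)
  }
  if (any(families$mother == families$father)) {
    stop("a family's mother and father must be distinct founders", call. = FALSE)
  }
  structure(
    list(
      cohort = as.character(cohort), families = families,
      n_unrelated = as.integer(n_unrelated),
      n_total = as.integer(sum(families$n_offspring) + n_unrelated)
    ),
    class = "pedigree_spec"
  )
}

# pedigree category for two individuals given parent ids (NA = founder)
.pedigree_category <- function(m1, f1, m2, f2) {
  if (is.na(m1) || is.na(m2)) return("unrelated") # founders are mutually unrelated
  shared <- (m1 == m2) + (f1 == f2)
  c("unrelated", "half-sib", "full-sib")[shared + 1L]
}

#' Build a cohort with known pedigree structure
#'
#' Founder parents are drawn from the pool under Hardy-Weinberg
#' proportions; offspring are produced by Mendelian transmission
#' ([breed_offspring] semantics). The truth kinship map classifies every
#' within-cohort pair from the pedigree: full-sib if both parents are
#' shared, half-sib if exactly one is, otherwise unrelated (founders are
#' treated as mutually unrelated).
#'
#' @param spec A [pedigree_spec()].
#' @param pool A [draw_founder_frequencies()] pool.
#' @param seed Integer seed.
#' @return Object of class \code{synth_dataset}: list with \code{geno}
#'   (dosage matrix, rows = cohort members), \code{cohorts} (named
#'   character vector), \code{pedigree} (data frame id/mother/father) and
#'   \code{truth} (data frame id1/id2/category for all within-cohort
#'   pairs).
#' @examples
#' pool <- draw_founder_frequencies(200, "uniform", seed = 1)
#' fam <- data.frame(mother = "M1", father = c("P1", "P2"), n_offspring = c(3, 3))
#' d <- make_family_cohort(pedigree_spec("fam", fam), pool, seed = 1)
#' table(d$truth$category)
#' @export
make_family_cohort <- function(spec, pool, seed = 1L) {
  stopifnot(inherits(spec, "pedigree_spec"), inherits(pool, "founder_pool"))
  parent_ids <- unique(c(spec$families$mother, spec$families$father))
  with_seed(substream_seed(seed, paste0("family_cohort/", spec$cohort)), {
    parents <- if (length(parent_ids)) {
      g <- matrix(
        stats::rbinom(length(parent_ids) * pool$L, 2L, rep(pool$frequencies, each = length(parent_ids))),
        nrow = length(parent_ids)
      )
      rownames(g) <- parent_ids
      g
    } else {
      NULL
    }
    ids <- character(spec$n_total)
    mo <- fa <- rep(NA_character_, spec$n_total)
    geno <- matrix(NA_integer_, nrow = spec$n_total, ncol = pool$L)
    k <- 0L
    if (nrow(spec$families)) {
      for (r in seq_len(nrow(spec$families))) {
        fm <- spec$families[r, ]
        for (o in seq_len(fm$n_offspring)) {
          k <- k + 1L
          ids[k] <- sprintf("%s_%02d", spec$cohort, k)
          mo[k] <- fm$mother
          fa[k] <- fm$father
          geno[k, ] <- .transmit(parents[fm$mother, ], parents[fm$father, ])
        }
      }
    }
    if (spec$n_unrelated > 0L) {
      ur <- matrix(
        stats::rbinom(spec$n_unrelated * pool$L, 2L, rep(pool$frequencies, each = spec$n_unrelated)),
        nrow = spec$n_unrelated
      )
      for (o in seq_len(spec$n_unrelated)) {
        k <- k + 1L
        ids[k] <- sprintf("%s_%02d", spec$cohort, k)
        geno[k, ] <- ur[o, ]
      }
    }
    storage.mode(geno) <- "integer"
    rownames(geno) <- ids
    cohorts <- stats::setNames(rep(spec$cohort, spec$n_total), ids)
    pedigree <- data.frame(
      id = ids, mother = mo, father = fa,
      cohort = spec$cohort, stringsAsFactors = FALSE
    )
    truth <- .truth_pairs(pedigree)
    structure(
      list(geno = geno, cohorts = cohorts, pedigree = pedigree, truth = truth),
      class = "synth_dataset"
    )
  })
}

# all unordered within-cohort pairs with pedigree categories
.truth_pairs <- function(pedigree) {
  out <- list()
  for (co in unique(pedigree$cohort)) {
    p <- pedigree[pedigree$cohort == co, ]
    n <- nrow(p)
    if (n < 2L) next
    idx <- utils::combn(n, 2L)
    cat_ <- vapply(seq_len(ncol(idx)), function(j) {
      i1 <- idx[1L, j]; i2 <- idx[2L, j]
      .pedigree_category(p$mother[i1], p$father[i1], p$mother[i2], p$father[i2])
    }, character(1L))
    out[[co]] <- data.frame(
      id1 = p$id[idx[1L, ]], id2 = p$id[idx[2L, ]],
      cohort = co, category = cat_, stringsAsFactors = FALSE
    )
  }
  if (!length(out)) {
    return(data.frame(id1 = character(), id2 = character(), cohort = character(), category = character()))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' @export
print.synth_dataset <- function(x, ...) {
  cat(sprintf(
    "synth_dataset: %d individuals x %d loci, %d cohort(s), %.2f%% missing\n",
    nrow(x$geno), ncol(x$geno), length(unique(x$cohorts)),
    100 * mean(is.na(x$geno))
  ))
  invisible(x)
}

#' Generate a study-like multi-cohort SNP dataset
#'
#' Emulates the structure of a cohort-labelled RAD SNP dataset: by default
#' 14 cohorts of 10 diploid individuals at 5,000 biallelic loci, with
#' exactly one cohort ("sweepstake"-tagged) composed of the offspring of a
#' single mother mated to a few males --- so that all of its within-cohort
#' pairs are full- or half-siblings and its diversity is depressed --- and
#' the remaining cohorts made of unrelated founders.
#'
#' @param config List with elements \code{cohorts} (data frame
#'   \code{name}, \code{size}, \code{structure} in {"unrelated",
#'   "sweepstake"}), \code{L} (loci), \code{n_fathers} (males mated to the
#'   single mother of a sweepstake cohort, default 5), \code{missingness}
#'   (per-genotype missing probability, default 0), and optional founder
#'   distribution settings \code{dist}, \code{a}, \code{b}, \code{shape1},
#'   \code{shape2}, \code{p_min}. \code{NULL} gives the default design.
#' @param seed Integer seed.
#' @return A \code{synth_dataset} covering all cohorts.
#' @examples
#' d <- make_study_like_dataset(list(L = 200), seed = 1)
#' table(d$cohorts)[1:3]
#' @export
make_study_like_dataset <- function(config = NULL, seed = 1L) {
  cfg <- .study_config(config)
  pool <- draw_founder_frequencies(
    cfg$L,
    dist = cfg$dist, a = cfg$a, b = cfg$b,
    shape1 = cfg$shape1, shape2 = cfg$shape2, p_min = cfg$p_min,
    seed = substream_seed(seed, "study/pool")
  )
  parts <- vector("list", nrow(cfg$cohorts))
  for (i in seq_len(nrow(cfg$cohorts))) {
    co <- cfg$cohorts[i, ]
    sub <- substream_seed(seed, paste0("study/cohort/", co$name))
    if (co$structure == "sweepstake") {
      fathers <- paste0(co$name, "_sire", seq_len(cfg$n_fathers))
      # per-offspring father drawn uniformly from the mother's mates
      fcount <- with_seed(substream_seed(seed, paste0("study/fathers/", co$name)), {
        tabulate(sample.int(cfg$n_fathers, co$size, replace = TRUE), cfg$n_fathers)
      })
      fam <- data.frame(
        mother = paste0(co$name, "_dam"),
        father = fathers[fcount > 0], n_offspring = fcount[fcount > 0]
      )
      spec <- pedigree_spec(co$name, fam)
    } else {
      spec <- pedigree_spec(co$name, n_unrelated = co$size)
    }
    parts[[i]] <- make_family_cohort(spec, pool, seed = sub)
  }
  ds <- structure(
    list(
      geno = do.call(rbind, lapply(parts, `[[`, "geno")),
      cohorts = do.call(c, lapply(parts, `[[`, "cohorts")),
      pedigree = do.call(rbind, c(lapply(parts, `[[`, "pedigree"), list(make.row.names = FALSE))),
      truth = do.call(rbind, c(lapply(parts, `[[`, "truth"), list(make.row.names = FALSE)))
    ),
    class = "synth_dataset"
  )
  if (cfg$missingness > 0) {
    ds$geno <- with_seed(substream_seed(seed, "study/missingness"), {
      g <- ds$geno
      g[stats::runif(length(g)) < cfg$missingness] <- NA_integer_
      g
    })
  }
  ds$pool <- pool
  ds
}

.study_config <- function(config) {
  cfg <- list(
    cohorts = NULL, L = 5000L, n_fathers = 5L, missingness = 0,
    dist = "uniform", a = 0.05, b = 0.95, shape1 = 1, shape2 = 1, p_min = 1e-3
  )
  if (!is.null(config)) {
    stopifnot(is.list(config))
    unknown <- setdiff(names(config), names(cfg))
    if (length(unknown)) stop("unknown config fields: ", paste(unknown, collapse = ", "), call. = FALSE)
    cfg[names(config)] <- config
  }
  if (is.null(cfg$cohorts)) {
    cfg$cohorts <- data.frame(
      name = sprintf("C%02d", 1:14), size = 10L,
      structure = c("sweepstake", rep("unrelated", 13L)),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(
    is.data.frame(cfg$cohorts),
    all(c("name", "size", "structure") %in% names(cfg$cohorts)),
    all(cfg$cohorts$structure %in% c("unrelated", "sweepstake")),
    all(cfg$cohorts$size >= 1),
    cfg$missingness >= 0, cfg$missingness < 1
  )
  cfg$L <- as.integer(cfg$L)
  cfg$n_fathers <- as.integer(cfg$n_fathers)
  cfg
}

#' Simulate pedigreed pairs for kinship-estimator validation
#'
#' Builds independent families yielding pairs with known relationship:
#' parent-offspring, full-sib, half-sib and unrelated. All founders are
#' Hardy-Weinberg draws from the pool; offspring follow Mendelian
#' transmission. The returned genotype matrix contains every pair member
#' (plus, implicitly, no one else), so pooled allele frequencies can be
#' estimated from the analysis sample as in a real dataset.
#'
#' @param pool A \code{founder_pool}.
#' @param n_pairs Pairs per relationship class.
#' @param classes Character vector of classes to generate.
#' @param seed Integer seed.
#' @return List with \code{geno} and \code{pairs} (data frame id1, id2,
#'   truth).
#' @export
simulate_kinship_pairs <- function(pool, n_pairs = 20L,
                                   classes = c("parent-offspring", "full-sib", "half-sib", "unrelated"),
                                   seed = 1L) {
  stopifnot(inherits(pool, "founder_pool"), n_pairs >= 1)
  with_seed(substream_seed(seed, "kinship_pairs"), {
    founder <- function() stats::rbinom(pool$L, 2L, pool$frequencies)
    geno <- list(); pairs <- list(); k <- 0L
    add <- function(id, g) geno[[id]] <<- g
    for (cl in classes) {
      for (i in seq_len(n_pairs)) {
        k <- k + 1L
        tag <- sprintf("%s%03d", substr(gsub("[^a-z]", "", cl), 1, 2), k)
        if (cl == "parent-offspring") {
          a <- founder(); b <- founder()
          add(paste0(tag, "_a"), a)
          add(paste0(tag, "_b"), .transmit(a, b))
        } else if (cl == "full-sib") {
          a <- founder(); b <- founder()
          add(paste0(tag, "_a"), .transmit(a, b))
          add(paste0(tag, "_b"), .transmit(a, b))
        } else if (cl == "half-sib") {
          m <- founder(); f1 <- founder(); f2 <- founder()
          add(paste0(tag, "_a"), .transmit(m, f1))
          add(paste0(tag, "_b"), .transmit(m, f2))
        } else if (cl == "unrelated") {
          add(paste0(tag, "_a"), founder())
          add(paste0(tag, "_b"), founder())
        } else {
          stop("unknown class: ", cl, call. = FALSE)
        }
        pairs[[k]] <- data.frame(
          id1 = paste0(tag, "_a"), id2 = paste0(tag, "_b"),
          truth = cl, stringsAsFactors = FALSE
        )
      }
    }
    g <- do.call(rbind, geno)
    storage.mode(g) <- "integer"
    list(geno = g, pairs = do.call(rbind, c(pairs, list(make.row.names = FALSE))))
  })
}
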