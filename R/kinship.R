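#' Identity-by-state counts for one pair of individuals
#'
#' Counts, over loci non-missing in both individuals, how often the pair
#' shares 0, 1 or 2 alleles identical by state, plus the heterozygote
#' bookkeeping needed by the robust kinship estimator: both-heterozygous
#' loci, opposite-homozygote loci, and each individual's heterozygous
#' locus count.
#'
#' @param gi,gj Equal-length dosage vectors (0/1/2, NA allowed).
#' @return List with \code{ibs0}, \code{ibs1}, \code{ibs2},
#'   \code{n_AaAa}, \code{n_AAaa}, \code{n_Aa_i}, \code{n_Aa_j},
#'   \code{n_loci} (jointly non-missing count) and \code{used} (logical
#'   index of the loci counted).
#' @examples
#' ibs_counts(c(0L, 1L, 2L), c(2L, 1L, 2L))
#' @export
ibs_counts <- function(gi, gj) {
  if (length(gi) != length(gj)) stop("genotype vectors differ in length", call. = FALSE)
  ok <- !is.na(gi) & !is.na(gj)
  a <- gi[ok]; b <- gj[ok]
  d <- abs(a - b)
  list(
    ibs0 = sum(d == 2L), ibs1 = sum(d == 1L), ibs2 = sum(d == 0L),
    n_AaAa = sum(a == 1L & b == 1L), n_AAaa = sum(d == 2L),
    n_Aa_i = sum(a == 1L), n_Aa_j = sum(b == 1L),
    n_loci = length(a), used = ok
  )
}

#' Method-of-moments IBD coefficients (Z0, Z1, Z2) and PI_HAT
#'
#' Estimates the probabilities that a pair of individuals shares 0, 1 or
#' 2 alleles identical by descent from the observed identity-by-state
#' class counts, given reference allele frequencies. The expected IBS
#' class proportions are linear in (Z0, Z1, Z2) with closed-form
#' coefficients in the allele frequencies (the classic genome-wide IBD
#' moment estimator); the resulting 3x3 linear system is solved, the
#' estimates clamped to [0, 1] and renormalised to the simplex, and
#' PI_HAT = Z2 + Z1/2.
#'
#' Allele frequencies should come from the pooled analysis sample, not
#' from a single (possibly family-structured) cohort. Loci with minor
#' allele frequency below \code{maf_min} are excluded: near-monomorphic
#' sites carry no IBS information and destabilise the moment system.
#'
#' @param gi,gj Dosage vectors.
#' @param freqs Alternative-allele frequencies, same length as the
#'   genotypes.
#' @param maf_min Minor-allele-frequency threshold (default 0.01).
#' @param min_loci Minimum jointly non-missing loci below which the
#'   estimate is flagged unreliable (default 100).
#' @return List with \code{Z0}, \code{Z1}, \code{Z2}, \code{PI_HAT},
#'   \code{n_loci}, \code{reliable}.
#' @export
ibd_moments <- function(gi, gj, freqs, maf_min = 0.01, min_loci = 100L) {
  if (length(freqs) != length(gi)) stop("freqs must match genotype length", call. = FALSE)
  keep <- pmin(freqs, 1 - freqs) >= maf_min
  cnt <- ibs_counts(gi[keep], gj[keep])
  p <- freqs[keep][cnt$used]
  q <- 1 - p
  # expected per-locus IBS-class probabilities given IBD state
  e0_ibd0 <- sum(2 * p^2 * q^2)
  e1_ibd0 <- sum(4 * p^3 * q + 4 * p * q^3)
  e2_ibd0 <- sum(p^4 + q^4 + 4 * p^2 * q^2)
  e1_ibd1 <- sum(2 * p^2 * q + 2 * p * q^2)
  e2_ibd1 <- sum(p^3 + q^3 + p^2 * q + p * q^2)
  e2_ibd2 <- cnt$n_loci
  A <- rbind(
    c(e0_ibd0, 0, 0),
    c(e1_ibd0, e1_ibd1, 0),
    c(e2_ibd0, e2_ibd1, e2_ibd2)
  )
  z <- tryCatch(
    solve(A, c(cnt$ibs0, cnt$ibs1, cnt$ibs2)),
    error = function(e) c(NA_real_, NA_real_, NA_real_)
  )
  if (anyNA(z)) {
    return(list(Z0 = NA_real_, Z1 = NA_real_, Z2 = NA_real_, PI_HAT = NA_real_,
      n_loci = cnt$n_loci, reliable = FALSE
    ))
  }
  z <- pmin(pmax(z, 0), 1)
  s <- sum(z)
  z <- if (s > 0) z / s else c(0, 1, 0) # degenerate: resolve toward Z1
  list(
    Z0 = z[1L], Z1 = z[2L], Z2 = z[3L],
    PI_HAT = z[3L] + z[2L] / 2,
    n_loci = cnt$n_loci,
    reliable = cnt$n_loci >= min_loci
  )
}

#' Robust within-pair kinship coefficient
#'
#' Allele-frequency-free kinship estimator based on heterozygote
#' concordance: \deqn{\phi = (N_{AaAa} - 2 N_{AA,aa}) /
#' (N_{Aa}^{(i)} + N_{Aa}^{(j)})} where the counts are taken over loci
#' non-missing in both individuals. Expected values: 0.5 for duplicates,
#' 0.25 for parent-offspring and full sibs, 0.125 for second-degree
#' pairs, ~0 for unrelated pairs.
#'
#' @inheritParams ibd_moments
#' @return List with \code{phi}, \code{n_loci}, \code{reliable}.
#' @examples
#' pool <- draw_founder_frequencies(2000, "uniform", seed = 1)
#' g <- sample_founders(pool, 2, seed = 2)
#' robust_kinship(g[1, ], g[1, ])$phi # duplicate -> 0.5
#' @export
robust_kinship <- function(gi, gj, min_loci = 100L) {
  cnt <- ibs_counts(gi, gj)
  den <- cnt$n_Aa_i + cnt$n_Aa_j
  if (den == 0L) {
    return(list(phi = NA_real_, n_loci = cnt$n_loci, reliable = FALSE))
  }
  list(
    phi = (cnt$n_AaAa - 2 * cnt$n_AAaa) / den,
    n_loci = cnt$n_loci,
    reliable = cnt$n_loci >= min_loci
  )
}

#' Classify a pair into a relatedness category
#'
#' Degrees of relatedness are inferred from the robust kinship
#' coefficient using the standard powers-of-two bounds: phi in
#' (2^-3/2, Inf) duplicate/MZ; (2^-5/2, 2^-3/2] first degree;
#' (2^-7/2, 2^-5/2] second degree (reported as half-sib);
#' (2^-9/2, 2^-7/2] third degree; (2^-11/2, 2^-9/2] fourth degree;
#' otherwise unrelated/5th+. First-degree pairs are split by Z0:
#' parent-offspring pairs have Z0 = 0 barring genotyping error, so
#' Z0 < 0.1 gives parent-offspring, else full-sib.
#'
#' @param Z0,Z1,Z2 IBD coefficients (only Z0 is used, for the
#'   first-degree split).
#' @param phi Robust kinship coefficient.
#' @param reliable Logical; unreliable inputs yield "unclassified".
#' @return Category string.
#' @export
classify_kinship <- function(Z0, Z1, Z2, phi, reliable = TRUE) {
  if (!isTRUE(reliable) || is.na(phi)) return("unclassified")
  b <- 2^(-(seq(3, 11, by = 2)) / 2) # 0.3536 0.1768 0.0884 0.0442 0.0221
  if (phi > b[1L]) {
    "duplicate/MZ"
  } else if (phi > b[2L]) {
    if (!is.na(Z0) && Z0 < 0.1) "parent-offspring" else "full-sib"
  } else if (phi > b[3L]) {
    "half-sib/2nd-degree"
  } else if (phi > b[4L]) {
    "3rd-degree"
  } else if (phi > b[5L]) {
    "4th-degree"
  } else {
    "unrelated/5th+"
  }
}

#' Pairwise kinship estimates for all within-cohort pairs
#'
#' Runs [ibd_moments()] and [robust_kinship()] on every unordered pair
#' within each cohort, with allele frequencies estimated once from the
#' pooled analysis sample (all cohorts), and classifies each pair.
#'
#' @param geno Dosage matrix (individuals x loci, rownames = ids).
#' @param cohorts Named character vector of cohort labels (names = ids).
#' @param maf_min,min_loci See [ibd_moments()].
#' @return Data frame: sample_i, sample_j, cohort, n_loci, Z0, Z1, Z2,
#'   PI_HAT, phi, category.
#' @export
kinship_pairs <- function(geno, cohorts, maf_min = 0.01, min_loci = 100L) {
  stopifnot(is.matrix(geno), !is.null(rownames(geno)))
  cohorts <- cohorts[rownames(geno)]
  freqs <- colMeans(geno, na.rm = TRUE) / 2
  out <- list()
  for (co in unique(cohorts)) {
    ids <- rownames(geno)[cohorts == co]
    if (length(ids) < 2L) next
    pr <- utils::combn(length(ids), 2L)
    for (k in seq_len(ncol(pr))) {
      i <- ids[pr[1L, k]]; j <- ids[pr[2L, k]]
      mom <- ibd_moments(geno[i, ], geno[j, ], freqs, maf_min = maf_min, min_loci = min_loci)
      rob <- robust_kinship(geno[i, ], geno[j, ], min_loci = min_loci)
      out[[length(out) + 1L]] <- data.frame(
        sample_i = i, sample_j = j, cohort = co, n_loci = mom$n_loci,
        Z0 = mom$Z0, Z1 = mom$Z1, Z2 = mom$Z2, PI_HAT = mom$PI_HAT,
        phi = rob$phi,
        category = classify_kinship(mom$Z0, mom$Z1, mom$Z2, rob$phi,
          reliable = mom$reliable && rob$reliable
        ),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Kinship composition of one cohort
#'
#' Evaluates all unordered within-cohort pairs and reports the
#' proportions of the three summary classes: unrelated, half-sib and
#' full-sib. First-degree categories (full-sib and parent-offspring) map
#' to the full-sib class, second degree to half-sib, and more distant
#' categories to unrelated; duplicate pairs are excluded with a warning.
#'
#' @param geno Pooled dosage matrix (used for allele frequencies).
#' @param cohorts Named cohort labels.
#' @param cohort The cohort to summarise (>= 2 members).
#' @param ... Passed to [kinship_pairs()].
#' @return List with \code{proportions} (named numeric, sums to 1 over
#'   evaluated pairs), \code{n_pairs}, and the per-pair \code{pairs}
#'   table.
#' @export
cohort_kinship_summary <- function(geno, cohorts, cohort, ...) {
  cohorts <- cohorts[rownames(geno)]
  ids <- rownames(geno)[cohorts == cohort]
  if (length(ids) < 2L) stop("cohort must have at least two members", call. = FALSE)
  pairs <- kinship_pairs(geno, cohorts, ...)
  pairs <- pairs[pairs$cohort == cohort, , drop = FALSE]
  dup <- pairs$category == "duplicate/MZ"
  if (any(dup)) {
    warning(sum(dup), " duplicate/MZ pair(s) excluded from the cohort summary")
    pairs_used <- pairs[!dup, , drop = FALSE]
  } else {
    pairs_used <- pairs
  }
  cls <- c(
    "parent-offspring" = "full-sib", "full-sib" = "full-sib",
    "half-sib/2nd-degree" = "half-sib",
    "3rd-degree" = "unrelated", "4th-degree" = "unrelated",
    "unrelated/5th+" = "unrelated", "unclassified" = "unclassified"
  )
  mapped <- cls[pairs_used$category]
  props <- c(
    unrelated = mean(mapped == "unrelated"),
    `half-sib` = mean(mapped == "half-sib"),
    `full-sib` = mean(mapped == "full-sib")
  )
  list(proportions = props, n_pairs = nrow(pairs), pairs = pairs)
}
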