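#' Mean per-SNP nucleotide diversity of a cohort
#'
#' Per SNP with within-cohort sample allele count \eqn{n_s} (non-missing
#' allele copies) and alt-allele frequency \eqn{\hat p_s}, the unbiased
#' per-site diversity is \eqn{\pi_s = n_s/(n_s - 1) \cdot 2 \hat p_s (1 -
#' \hat p_s)}. The cohort value is the mean of \eqn{\pi_s} over the SNPs
#' segregating in the pooled dataset (the fixed SNP panel), so values are
#' comparable across cohorts; sites monomorphic within a cohort
#' contribute zero. Missing genotypes reduce \eqn{n_s} locally; panel
#' sites with fewer than two non-missing allele copies in the cohort are
#' dropped from the mean.
#'
#' @param geno Pooled dosage matrix (individuals x loci).
#' @param cohorts Named cohort labels aligned to rownames.
#' @param cohort Cohort to evaluate (>= 2 individuals).
#' @return Mean per-SNP nucleotide diversity (numeric scalar).
#' @examples
#' g <- rbind(a = c(1L, 0L), b = c(1L, 2L))
#' nucleotide_diversity(g, c(a = "x", b = "x"), "x") # mean(2/3 + ...)
#' @export
nucleotide_diversity <- function(geno, cohorts, cohort) {
  cohorts <- cohorts[rownames(geno)]
  sub <- geno[cohorts == cohort, , drop = FALSE]
  if (nrow(sub) < 2L) stop("cohort must have at least two individuals", call. = FALSE)
  panel <- .segregating_pooled(geno)
  sub <- sub[, panel, drop = FALSE]
  n <- 2L * colSums(!is.na(sub))
  p <- colMeans(sub, na.rm = TRUE) / 2
  ok <- n >= 2L
  mean((n[ok] / (n[ok] - 1L)) * 2 * p[ok] * (1 - p[ok]))
}

# panel definition: loci segregating in the pooled dataset
.segregating_pooled <- function(geno) {
  p <- colMeans(geno, na.rm = TRUE) / 2
  !is.na(p) & p > 0 & p < 1
}

#' Pairwise linkage-disequilibrium r-squared within a cohort
#'
#' Composite LD: the squared Pearson correlation of genotype-dosage
#' vectors for pairs of loci segregating within the cohort (no phasing
#' required). When the number of pairs exceeds \code{max_pairs} a seeded
#' uniform subsample of pairs is evaluated. Zero-variance pairs (after
#' missingness) are skipped.
#'
#' @param geno Dosage matrix.
#' @param cohorts Named cohort labels.
#' @param cohort Cohort to evaluate.
#' @param max_pairs Cap on the number of locus pairs (default 50000).
#' @param seed Seed for the pair subsample.
#' @return Numeric vector of r-squared values.
#' @export
ld_r2 <- function(geno, cohorts, cohort, max_pairs = 50000L, seed = 1L) {
  cohorts <- cohorts[rownames(geno)]
  sub <- geno[cohorts == cohort, , drop = FALSE]
  p <- colMeans(sub, na.rm = TRUE) / 2
  seg <- which(!is.na(p) & p > 0 & p < 1)
  if (length(seg) < 2L) stop("need at least two segregating loci in the cohort", call. = FALSE)
  n_pairs <- choose(length(seg), 2)
  if (n_pairs <= max_pairs) {
    pr <- utils::combn(seg, 2L)
  } else {
    pr <- with_seed(substream_seed(seed, "ld_pairs"), {
      # sample unordered pairs uniformly by index into the implicit pair list
      k <- sort(sample(n_pairs, max_pairs))
      .pair_from_index(k, length(seg))
    })
    pr[] <- seg[pr]
  }
  r2 <- rep(NA_real_, ncol(pr))
  for (k in seq_len(ncol(pr))) {
    x <- sub[, pr[1L, k]]; y <- sub[, pr[2L, k]]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 2L) next
    sx <- stats::sd(x[ok]); sy <- stats::sd(y[ok])
    if (sx == 0 || sy == 0) next
    r2[k] <- stats::cor(x[ok], y[ok])^2
  }
  r2[!is.na(r2)]
}

# unrank unordered pairs: k-th pair (1-based, row-major over i<j) of n items
.pair_from_index <- function(k, n) {
  i <- findInterval(k - 1, cumsum(c(0, (n - 1):1)), rightmost.closed = FALSE)
  first_of_i <- cumsum(c(0, (n - 1):1))[i] + 1
  j <- i + (k - first_of_i) + 1
  rbind(i, j)
}

#' Pairwise Weir-Cockerham Fst with bootstrap significance
#'
#' Computes the Weir-Cockerham theta estimator per locus and combines
#' loci as the ratio of summed variance components; negative multilocus
#' estimates are reported as computed. Significance per cohort pair is
#' assessed by bootstrap resampling of loci (with replacement): the
#' one-sided p-value is the proportion of bootstrap replicates with
#' Fst <= 0, Bonferroni-corrected over the number of pairs.
#'
#' @param geno Dosage matrix.
#' @param cohorts Named cohort labels (>= 2 cohorts, each >= 2
#'   individuals).
#' @param n_boot Bootstrap replicates (default 10000).
#' @param seed Integer seed; fixed seeds reproduce identical p-values.
#' @return Object of class \code{fst_result}: symmetric \code{fst}
#'   matrix (diagonal 0), \code{p} matrix, logical \code{significant}
#'   matrix (Bonferroni), \code{n_boot}.
#' @export
pairwise_fst <- function(geno, cohorts, n_boot = 10000L, seed = 1L) {
  cohorts <- cohorts[rownames(geno)]
  labs <- unique(cohorts)
  if (length(labs) < 2L) stop("need at least two cohorts", call. = FALSE)
  sizes <- table(cohorts)
  if (any(sizes < 2L)) stop("every cohort needs at least two individuals", call. = FALSE)
  np <- choose(length(labs), 2)
  fst <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
  pval <- matrix(NA_real_, length(labs), length(labs), dimnames = list(labs, labs))
  pr <- utils::combn(length(labs), 2L)
  for (k in seq_len(ncol(pr))) {
    c1 <- labs[pr[1L, k]]; c2 <- labs[pr[2L, k]]
    comp <- .wc_components(
      geno[cohorts == c1, , drop = FALSE],
      geno[cohorts == c2, , drop = FALSE]
    )
    theta <- sum(comp$a) / sum(comp$abc)
    boot <- with_seed(substream_seed(seed, paste0("fst/", c1, "/", c2)), {
      L <- length(comp$a)
      out <- numeric(n_boot)
      chunk <- 1000L
      done <- 0L
      while (done < n_boot) {
        nb <- min(chunk, n_boot - done)
        w <- stats::rmultinom(nb, L, rep.int(1 / L, L)) # L x nb resample weights
        out[done + seq_len(nb)] <- as.numeric(crossprod(w, comp$a)) /
          as.numeric(crossprod(w, comp$abc))
        done <- done + nb
      }
      out
    })
    p <- mean(boot <= 0)
    fst[c1, c2] <- fst[c2, c1] <- theta
    pval[c1, c2] <- pval[c2, c1] <- p
  }
  structure(
    list(
      fst = fst, p = pval,
      significant = pval < 0.05 / np,
      n_boot = as.integer(n_boot), n_pairs = np, seed = as.integer(seed)
    ),
    class = "fst_result"
  )
}

# Weir & Cockerham (1984) per-locus variance components for two samples.
# Returns a (among-population) and abc (total) per usable locus.
.wc_components <- function(g1, g2) {
  n1 <- colSums(!is.na(g1)); n2 <- colSums(!is.na(g2))
  if (all(n1 == 0) || all(n2 == 0)) stop("a cohort has no genotyped locus", call. = FALSE)
  usable <- n1 >= 1 & n2 >= 1
  if (!any(usable)) stop("no locus genotyped in both cohorts", call. = FALSE)
  g1 <- g1[, usable, drop = FALSE]; g2 <- g2[, usable, drop = FALSE]
  n1 <- n1[usable]; n2 <- n2[usable]
  r <- 2
  p1 <- colMeans(g1, na.rm = TRUE) / 2
  p2 <- colMeans(g2, na.rm = TRUE) / 2
  h1 <- colMeans(g1 == 1L, na.rm = TRUE)
  h2 <- colMeans(g2 == 1L, na.rm = TRUE)
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  keep <- is.finite(a) & is.finite(b) & is.finite(cc)
  list(a = a[keep], abc = (a + b + cc)[keep])
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf("Weir-Cockerham pairwise Fst (%d bootstrap replicates)\n", x$n_boot))
  print(round(x$fst, 4))
  cat("Bonferroni-significant pairs:", sum(x$significant[upper.tri(x$significant)], na.rm = TRUE),
    "of", x$n_pairs, "\n"
  )
  invisible(x)
}

#' Empirical folded site-frequency spectrum of a cohort
#'
#' For every site segregating within the cohort (and fully genotyped in
#' it: sites with any missing cohort genotype are excluded so that every
#' counted site has the same sample size n = 2 x cohort size), the
#' minor-allele count j in [1, n/2] increments the folded count Y_j. The
#' normalised spectrum is Z_j = Y_j / sum(Y). The fold includes j = n/2
#' for even n (Y_{n/2} = X_{n/2}).
#'
#' @param geno Dosage matrix.
#' @param cohorts Named cohort labels.
#' @param cohort Cohort to evaluate (>= 2 individuals... n >= 2
#'   sequences).
#' @return Object of class \code{spectrum_counts}: \code{n} (sequences),
#'   \code{Y} (folded counts, length floor(n/2)), \code{Z} (normalised),
#'   \code{n_segregating}.
#' @export
folded_sfs <- function(geno, cohorts, cohort) {
  cohorts <- cohorts[rownames(geno)]
  sub <- geno[cohorts == cohort, , drop = FALSE]
  if (nrow(sub) < 1L || 2L * nrow(sub) < 2L) stop("cohort must contribute n >= 2 sequences", call. = FALSE)
  complete <- colSums(is.na(sub)) == 0L
  sub <- sub[, complete, drop = FALSE]
  n <- 2L * nrow(sub)
  ac <- colSums(sub)
  seg <- ac > 0L & ac < n
  if (!any(seg)) stop("no segregating site in the cohort", call. = FALSE)
  minor <- pmin(ac[seg], n - ac[seg])
  Y <- tabulate(minor, nbins = n %/% 2L)
  structure(
    list(n = n, Y = Y, Z = Y / sum(Y), n_segregating = sum(seg), cohort = cohort),
    class = "spectrum_counts"
  )
}

#' @export
print.spectrum_counts <- function(x, ...) {
  cat(sprintf(
    "folded spectrum%s: n = %d sequences, %d segregating sites\n",
    if (is.null(x$cohort)) "" else paste0(" (", x$cohort, ")"), x$n, x$n_segregating
  ))
  print(round(x$Z, 4))
  invisible(x)
}
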