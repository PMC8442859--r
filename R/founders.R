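#' Draw a founder pool of SNP allele frequencies
#'
#' Creates the per-locus alternative-allele frequencies of an idealised
#' source population from which founder genotypes are sampled under
#' Hardy-Weinberg proportions. Monomorphic loci are excluded by
#' construction: every frequency is strictly inside (0, 1).
#'
#' Three frequency distributions are supported:
#' \describe{
#'   \item{\code{uniform}}{frequencies Uniform(a, b) with 0 <= a <= b <= 1;
#'     boundary values 0/1 are resampled away by clamping the support to
#'     the open interval.}
#'   \item{\code{beta}}{frequencies Beta(shape1, shape2), truncated to
#'     (0, 1) by resampling exact 0/1 draws.}
#'   \item{\code{neutral}}{log-uniform on (p_min, 1), i.e. density
#'     proportional to 1/p. This is the standing-variation frequency
#'     profile of a neutral, constant-size Wright-Fisher population, so a
#'     sample of n founder sequences has an unfolded site-frequency
#'     spectrum proportional to 1/j --- the Kingman expectation. Use it
#'     when downstream spectra should look "neutral".}
#' }
#'
#' @param L Number of biallelic loci (>= 1).
#' @param dist Distribution name: "uniform", "beta" or "neutral".
#' @param a,b Uniform support (dist = "uniform").
#' @param shape1,shape2 Beta shapes (dist = "beta").
#' @param p_min Lower truncation for dist = "neutral" (default 1e-3).
#' @param seed Integer seed; identical seeds give identical pools.
#' @return An object of class \code{founder_pool}: list with elements
#'   \code{frequencies} (numeric length L, all in (0,1)), \code{L},
#'   \code{dist}, \code{seed}.
#' @examples
#' pool <- draw_founder_frequencies(100, "uniform", a = 0.05, b = 0.95, seed = 1)
#' range(pool$frequencies)
#' @export
draw_founder_frequencies <- function(L, dist = c("uniform", "beta", "neutral"),
                                     a = 0.05, b = 0.95,
                                     shape1 = 1, shape2 = 1,
                                     p_min = 1e-3, seed = 1L) {
  if (!is.numeric(L) || length(L) != 1L || L < 1 || L != round(L)) {
    stop("L must be a single integer >= 1", call. = FALSE)
  }
  dist <- match.arg(dist)
  freqs <- with_seed(substream_seed(seed, paste0("founder_freqs/", dist)), {
    switch(dist,
      uniform = {
        if (!is.finite(a) || !is.finite(b) || a > b || a < 0 || b > 1) {
          stop("uniform founder distribution requires 0 <= a <= b <= 1", call. = FALSE)
        }
        # clamp to the open interval so degenerate calls like uniform(0,0) fail loudly
        if (b == 0 || a == 1) stop("uniform support collapses onto a monomorphic boundary", call. = FALSE)
        stats::runif(L, min = a, max = b)
      },
      beta = {
        if (!is.finite(shape1) || !is.finite(shape2) || shape1 <= 0 || shape2 <= 0) {
          stop("beta founder distribution requires positive shapes", call. = FALSE)
        }
        x <- stats::rbeta(L, shape1, shape2)
        while (any(bad <- (x <= 0 | x >= 1))) x[bad] <- stats::rbeta(sum(bad), shape1, shape2)
        x
      },
      neutral = {
        if (!is.finite(p_min) || p_min <= 0 || p_min >= 1) {
          stop("neutral founder distribution requires 0 < p_min < 1", call. = FALSE)
        }
        exp(stats::runif(L, min = log(p_min), max = 0))
      }
    )
  })
  freqs <- pmin(pmax(freqs, .Machine$double.eps), 1 - 1e-12)
  structure(
    list(frequencies = freqs, L = as.integer(L), dist = dist, seed = as.integer(seed)),
    class = "founder_pool"
  )
}

#' @export
print.founder_pool <- function(x, ...) {
  cat(sprintf(
    "founder_pool: %d loci, %s frequencies in [%.4g, %.4g], seed %d\n",
    x$L, x$dist, min(x$frequencies), max(x$frequencies), x$seed
  ))
  invisible(x)
}

#' Sample unrelated founder genotypes under Hardy-Weinberg proportions
#'
#' Each individual's dosage at a locus with alternative-allele frequency p
#' is drawn Binomial(2, p), independently across loci and individuals.
#'
#' @param pool A \code{founder_pool}.
#' @param n Number of diploid individuals (>= 1).
#' @param seed Integer seed.
#' @param ids Optional character vector of sample ids (default F1..Fn).
#' @return Integer matrix n x L of alt-allele dosages in {0,1,2}, rownames
#'   = sample ids; no missing data.
#' @examples
#' pool <- draw_founder_frequencies(10, "uniform", seed = 1)
#' g <- sample_founders(pool, 4, seed = 2)
#' dim(g)
#' @export
sample_founders <- function(pool, n, seed = 1L, ids = NULL) {
  stopifnot(inherits(pool, "founder_pool"))
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    stop("n must be a single integer >= 1", call. = FALSE)
  }
  n <- as.integer(n)
  g <- with_seed(substream_seed(seed, "sample_founders"), {
    matrix(
      stats::rbinom(n * pool$L, 2L, rep(pool$frequencies, each = n)),
      nrow = n, ncol = pool$L
    )
  })
  storage.mode(g) <- "integer"
  rownames(g) <- if (is.null(ids)) paste0("F", seq_len(n)) else ids
  g
}
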