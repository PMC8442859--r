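# Expected site-frequency spectra under the Kingman and Xi-Beta(2-alpha,
# alpha) coalescents, and the l2 machinery to compare them with data.
#
# Time convention: throughout this module genealogies are measured on the
# pair-coalescence scale -- two active lineages merge at rate
# lambda_{2,2} = 1. Normalized spectra are invariant to this choice; it
# only fixes absolute branch lengths and tree heights.

# fold an unfolded spectrum x_1..x_{n-1}: Y_j = x_j + x_{n-j} (j < n/2),
# Y_{n/2} = x_{n/2} for even n
fold_spectrum <- function(x, n) {
  half <- n %/% 2L
  vapply(seq_len(half), function(j) {
    if (j < n - j) x[j] + x[n - j] else x[j]
  }, numeric(1L))
}

new_branch_spectrum <- function(n, family, alpha = NA_real_, method = "closed_form",
                                replicates = NA_integer_, seed = NA_integer_,
                                B, se_B = NULL) {
  B_total <- sum(B)
  se_B <- if (is.null(se_B)) rep(0, length(B)) else se_B
  structure(
    list(
      n = as.integer(n), family = family, alpha = alpha, method = method,
      replicates = replicates, seed = seed,
      B = B, B_total = B_total,
      norm_unfolded = B / B_total,
      norm_folded = fold_spectrum(B, n) / B_total,
      se_unfolded = as.numeric(se_B), # delta-method SEs of norm_unfolded (0 for closed form)
      se_folded = attr(se_B, "folded") %||% rep(0, n %/% 2L)
    ),
    class = "branch_spectrum"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.branch_spectrum <- function(x, ...) {
  cat(sprintf(
    "%s expected spectrum, n = %d%s (%s%s)\n",
    x$family, x$n,
    if (is.na(x$alpha)) "" else sprintf(", alpha = %g", x$alpha),
    x$method,
    if (is.na(x$replicates)) "" else sprintf(", %d replicates", x$replicates)
  ))
  cat("normalized folded spectrum:\n")
  print(round(x$norm_folded, 4))
  invisible(x)
}

#' Expected normalized site-frequency spectrum under the Kingman coalescent
#'
#' Closed form: the expected branch length supporting i leaves is
#' proportional to 1/i, so the normalized unfolded spectrum is
#' (1/i) / H_{n-1} with H the harmonic number; folding combines classes j
#' and n-j.
#'
#' @param n Number of sequences (>= 2).
#' @return Object of class \code{branch_spectrum} with closed-form
#'   \code{norm_unfolded} and \code{norm_folded} entries (Monte-Carlo SEs
#'   are zero).
#' @examples
#' kingman_expected_nsfs(4)$norm_unfolded # 6/11 3/11 2/11
#' @export
kingman_expected_nsfs <- function(n) {
  if (n < 2) stop("n must be at least 2", call. = FALSE)
  i <- seq_len(n - 1L)
  new_branch_spectrum(n, family = "kingman", B = 2 / i)
}

#' Beta-coalescent merger rate
#'
#' Rate at which a fixed set of k of b active lineages participates in a
#' merger event under the Lambda = Beta(2-alpha, alpha) measure:
#' \deqn{\lambda_{b,k} = B(k - \alpha, b - k + \alpha) / B(2 - \alpha,
#' \alpha)}.
#'
#' @param b Active lineages (>= 2).
#' @param k Merger size, 2 <= k <= b.
#' @param alpha Stability parameter in (1, 2).
#' @return Rate (numeric scalar).
#' @examples
#' beta_merger_rate(2, 2, 1.5) # 1 for any alpha
#' @export
beta_merger_rate <- function(b, k, alpha) {
  if (alpha <= 1 || alpha >= 2) stop("alpha must lie in (1, 2)", call. = FALSE)
  if (k < 2 || k > b) stop("k must satisfy 2 <= k <= b", call. = FALSE)
  exp(lbeta(k - alpha, b - k + alpha) - lbeta(2 - alpha, alpha))
}

# memoised per-b candidate-event rates on the pair-coalescence time scale:
# rate of a k-participant candidate event = 4 * choose(b,k) * lambda_{b,k}
.xi_rate_table <- function(n, alpha) {
  lapply(seq_len(n), function(b) {
    if (b < 2L) return(NULL)
    k <- 2:b
    r <- 4 * choose(b, k) * exp(lbeta(k - alpha, b - k + alpha) - lbeta(2 - alpha, alpha))
    list(k = k, rate = r, total = sum(r), prob = r / sum(r))
  })
}

# one genealogy; rates = .xi_rate_table(n, alpha); returns c(B_1..B_{n-1},
# height): branch lengths by leaf support plus time to the MRCA
.xi_tree <- function(n, rates) {
  leaf <- rep(1L, n)
  b <- n
  B <- numeric(n - 1L)
  height <- 0
  while (b > 1L) {
    rt <- rates[[b]]
    t <- stats::rexp(1L, rt$total)
    height <- height + t
    tab <- tabulate(leaf, nbins = n - 1L)
    B <- B + t * tab
    k <- if (b == 2L) 2L else rt$k[sample.int(b - 1L, 1L, prob = rt$prob)]
    part <- if (k == b) seq_len(b) else sample.int(b, k)
    grp <- sample.int(4L, k, replace = TRUE)
    drop <- integer(0L)
    for (g in unique(grp)) {
      mem <- part[grp == g]
      if (length(mem) >= 2L) {
        leaf[mem[1L]] <- sum(leaf[mem])
        drop <- c(drop, mem[-1L])
      }
    }
    if (length(drop)) {
      leaf <- leaf[-drop]
      b <- length(leaf)
    }
  }
  c(B, height)
}

#' Simulate one Xi-Beta(2-alpha, alpha) genealogy
#'
#' Event-driven simulation of the simultaneous multiple-merger coalescent
#' arising from diploid sweepstakes reproduction. With b active lineages,
#' a candidate event with k participants occurs at rate proportional to
#' choose(b, k) * lambda_{b,k} (see [beta_merger_rate()]); at an event
#' each participant is assigned independently and uniformly to one of
#' four parental groups and every group with at least two members merges
#' simultaneously (an event in which no group reaches size two changes
#' nothing but its holding time still elapses). Time is on the
#' pair-coalescence scale: two lineages merge at rate 1.
#'
#' @param n Sample size (sequences, >= 2).
#' @param alpha Stability parameter in (1, 2); alpha near 2 approaches
#'   the Kingman coalescent, smaller alpha gives stronger multiple
#'   mergers.
#' @param seed Integer seed.
#' @return List with \code{B} (realized branch lengths supporting 1..n-1
#'   leaves) and \code{height} (time to the most recent common ancestor).
#' @export
simulate_xi_beta_genealogy <- function(n, alpha, seed = 1L) {
  if (n < 2) stop("n must be at least 2", call. = FALSE)
  if (alpha <= 1 || alpha >= 2) stop("alpha must lie in (1, 2)", call. = FALSE)
  rates <- .xi_rate_table(n, alpha)
  res <- with_seed(substream_seed(seed, "xi_tree"), .xi_tree(n, rates))
  list(B = res[seq_len(n - 1L)], height = res[n])
}

#' Monte-Carlo expected normalized spectrum under Xi-Beta(2-alpha, alpha)
#'
#' Averages branch-length spectra over replicate genealogies:
#' E[Z_i] is approximated by mean(B_i) / mean(B_total), folded. Delta-
#' method Monte-Carlo standard errors are attached per class.
#'
#' @param n Sample size (sequences).
#' @param alpha Stability parameter in (1, 2).
#' @param replicates Number of genealogies (default 20000, giving class
#'   SEs below ~0.002 for n <= 40).
#' @param seed Integer seed; fixed seeds give identical spectra.
#' @return A \code{branch_spectrum} with Monte-Carlo \code{se_unfolded} /
#'   \code{se_folded}.
#' @export
xi_beta_expected_nsfs <- function(n, alpha, replicates = 20000L, seed = 1L) {
  if (n < 2) stop("n must be at least 2", call. = FALSE)
  if (alpha <= 1 || alpha >= 2) stop("alpha must lie in (1, 2)", call. = FALSE)
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  key <- sprintf("%d/%.10g/%d/%d", n, alpha, as.integer(replicates), as.integer(seed))
  hit <- get0(key, envir = .spectrum_cache, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  rates <- .xi_rate_table(n, alpha)
  Bmat <- with_seed(substream_seed(seed, sprintf("xi_nsfs/%d/%g", n, alpha)), {
    m <- matrix(0, nrow = replicates, ncol = n - 1L)
    for (r in seq_len(replicates)) m[r, ] <- .xi_tree(n, rates)[seq_len(n - 1L)]
    m
  })
  Bbar <- colMeans(Bmat)
  tot <- rowSums(Bmat)
  mtot <- mean(tot)
  z_unf <- Bbar / mtot
  se_unf <- vapply(seq_len(n - 1L), function(i) {
    stats::sd(Bmat[, i] - z_unf[i] * tot) / (mtot * sqrt(replicates))
  }, numeric(1L))
  half <- n %/% 2L
  Fmat <- vapply(seq_len(half), function(j) {
    if (j < n - j) Bmat[, j] + Bmat[, n - j] else Bmat[, j]
  }, numeric(nrow(Bmat)))
  z_fold <- colMeans(Fmat) / mtot
  se_fold <- vapply(seq_len(half), function(j) {
    stats::sd(Fmat[, j] - z_fold[j] * tot) / (mtot * sqrt(replicates))
  }, numeric(1L))
  se_B <- se_unf
  attr(se_B, "folded") <- se_fold
  out <- new_branch_spectrum(n,
    family = "xi_beta", alpha = alpha, method = "monte_carlo",
    replicates = as.integer(replicates), seed = as.integer(seed),
    B = Bbar, se_B = se_B
  )
  assign(key, out, envir = .spectrum_cache)
  out
}

# session cache of Monte-Carlo expected spectra, keyed by (n, alpha,
# replicates, seed); results are deterministic given the key
.spectrum_cache <- new.env(parent = emptyenv())

#' Exact small-sample spectrum by first-step analysis
#'
#' Independent oracle for the Monte-Carlo generator: for n <= 5 the
#' configuration space of lineage leaf-support multisets (integer
#' partitions of n) is enumerated; exact transition rates of the
#' four-group merger process are obtained by summing, over all
#' k-participant subsets and all 4^k group assignments, the candidate
#' event rates times assignment probabilities; the linear first-step
#' equations give the expected time spent in every configuration, from
#' which exact E[B_i] are assembled. Same pair-coalescence time scale as
#' the simulator.
#'
#' @param n Sample size, 2..5 (the state space grows too fast beyond).
#' @param alpha Stability parameter in (1, 2).
#' @return A \code{branch_spectrum} (method "first_step_exact").
#' @export
small_n_exact_oracle <- function(n, alpha) {
  if (!n %in% 2:5) stop("the exact oracle supports n in {2, 3, 4, 5} only", call. = FALSE)
  if (alpha <= 1 || alpha >= 2) stop("alpha must lie in (1, 2)", call. = FALSE)
  states <- .partitions(n)
  states <- Filter(function(v) length(v) >= 2L, states) # transient configs
  key <- vapply(states, paste, character(1L), collapse = ",")
  ns <- length(states)
  Q <- matrix(0, ns, ns, dimnames = list(key, key))
  for (si in seq_len(ns)) {
    v <- states[[si]]
    b <- length(v)
    for (k in 2:b) {
      lam4 <- 4 * beta_merger_rate(b, k, alpha) # per-subset candidate rate
      subsets <- utils::combn(b, k)
      assigns <- as.matrix(expand.grid(rep(list(1:4), k)))
      w <- lam4 / 4^k
      for (sc in seq_len(ncol(subsets))) {
        S <- subsets[, sc]
        for (ac in seq_len(nrow(assigns))) {
          res <- .merge_partition(v, S, assigns[ac, ])
          rk <- paste(res, collapse = ",")
          if (rk != key[si]) {
            if (length(res) >= 2L) {
              Q[si, rk] <- Q[si, rk] + w
            } # absorbing single-lineage state: exit only
            Q[si, si] <- Q[si, si] - w
          }
        }
      }
    }
  }
  start <- paste(rep(1L, n), collapse = ",")
  e0 <- as.numeric(key == start)
  tau <- solve(t(-Q), e0) # occupation times per transient configuration
  B <- vapply(seq_len(n - 1L), function(i) {
    sum(tau * vapply(states, function(v) sum(v == i), numeric(1L)))
  }, numeric(1L))
  new_branch_spectrum(n,
    family = "xi_beta", alpha = alpha, method = "first_step_exact", B = B
  )
}

# integer partitions of n as sorted (decreasing) vectors
.partitions <- function(n, max_part = n) {
  if (n == 0L) return(list(integer(0L)))
  out <- list()
  for (p in seq_len(min(n, max_part))) {
    for (rest in .partitions(n - p, p)) out[[length(out) + 1L]] <- c(p, rest)
  }
  out
}

# apply a 4-group merger to partition v: subset S of parts, assignment a
.merge_partition <- function(v, S, a) {
  merged <- integer(0L)
  drop <- integer(0L)
  for (g in unique(a)) {
    mem <- S[a == g]
    if (length(mem) >= 2L) {
      merged <- c(merged, sum(v[mem]))
      drop <- c(drop, mem)
    }
  }
  if (!length(drop)) return(v)
  sort(c(v[-drop], merged), decreasing = TRUE)
}

#' Squared-distance metric between two spectra
#'
#' The sum of squared coordinate-wise differences (no square root), used
#' to compare normalized folded spectra.
#'
#' @param x,y Equal-length numeric vectors.
#' @return Numeric scalar.
#' @examples
#' l2_distance(c(1, 0), c(0, 1)) # 2
#' @export
l2_distance <- function(x, y) {
  if (length(x) != length(y)) stop("spectra differ in length", call. = FALSE)
  sum((x - y)^2)
}
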