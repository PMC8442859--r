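#' Fit coalescent models to an empirical folded spectrum
#'
#' Compares a cohort's normalized folded site-frequency spectrum with the
#' expectations of the Kingman coalescent (closed form) and the
#' Xi-Beta(2-alpha, alpha) multiple-merger coalescent (Monte-Carlo
#' expectation on a grid of alpha), using the l2 metric --- the sum of
#' squared coordinate-wise differences of the normalized spectra. The
#' better-fitting model is the one with the smaller minimal l2; ties
#' within 1e-12 go to Kingman on parsimony grounds.
#'
#' The Monte-Carlo uncertainty of each xi l2 value is propagated into
#' \code{mc_tol}: a fit is only called decisively better than Kingman
#' when the l2 difference exceeds this tolerance (see
#' \code{summary.sfs_fit}).
#'
#' @param empirical A [folded_sfs()] result (class \code{spectrum_counts})
#'   or a normalized folded spectrum vector (then \code{n} is required).
#' @param alpha_grid Grid of alpha values, all in (1, 2); default 1.05 to
#'   1.95 in steps of 0.05.
#' @param replicates Monte-Carlo genealogies per alpha (default 20000).
#' @param seed Integer seed.
#' @param n Sample size in sequences (only when \code{empirical} is a
#'   bare vector).
#' @return Object of class \code{sfs_fit} with components
#'   \code{l2_kingman}, \code{l2_xi} (named by alpha), \code{best_alpha},
#'   \code{best_model}, \code{mc_tol}, \code{decisive}, plus the spectra
#'   used.
#' @examples
#' emp <- kingman_expected_nsfs(10)$norm_folded
#' f <- fit_sfs(emp, alpha_grid = c(1.2, 1.8), replicates = 500, seed = 1, n = 10)
#' f$best_model
#' @export
fit_sfs <- function(empirical, alpha_grid = seq(1.05, 1.95, by = 0.05),
                    replicates = 20000L, seed = 1L, n = NULL) {
  if (inherits(empirical, "spectrum_counts")) {
    z <- empirical$Z
    n <- empirical$n
  } else {
    if (is.null(n)) stop("n (number of sequences) is required with a bare spectrum", call. = FALSE)
    z <- empirical
    if (abs(sum(z) - 1) > 1e-8) stop("empirical spectrum must be normalized", call. = FALSE)
  }
  if (!length(alpha_grid)) stop("alpha grid is empty", call. = FALSE)
  if (any(alpha_grid <= 1 | alpha_grid >= 2)) stop("alpha grid must lie inside (1, 2)", call. = FALSE)
  king <- kingman_expected_nsfs(n)
  l2_k <- l2_distance(z, king$norm_folded)
  l2_xi <- se_term <- numeric(length(alpha_grid))
  spectra <- vector("list", length(alpha_grid))
  for (i in seq_along(alpha_grid)) {
    sp <- xi_beta_expected_nsfs(n, alpha_grid[i],
      replicates = replicates,
      seed = substream_seed(seed, sprintf("fit/alpha/%g", alpha_grid[i]))
    )
    spectra[[i]] <- sp
    l2_xi[i] <- l2_distance(z, sp$norm_folded)
    # MC noise on l2: variance term from the linear expansion plus the
    # positive bias sum(se^2) of a squared-error statistic
    dev <- z - sp$norm_folded
    se_term[i] <- 3 * sqrt(sum((2 * dev * sp$se_folded)^2)) + sum(sp$se_folded^2)
  }
  names(l2_xi) <- names(se_term) <- format(alpha_grid)
  best_i <- which.min(l2_xi)
  best_model <- if (l2_k <= l2_xi[best_i] + 1e-12) "kingman" else "xi_beta"
  mc_tol <- se_term[best_i]
  structure(
    list(
      l2_kingman = l2_k, l2_xi = l2_xi,
      alpha_grid = alpha_grid,
      best_alpha = alpha_grid[best_i],
      l2_best_xi = unname(l2_xi[best_i]),
      best_model = best_model,
      mc_tol = unname(mc_tol),
      decisive = best_model == "xi_beta" && (l2_k - l2_xi[best_i]) > mc_tol,
      empirical = z, n = as.integer(n),
      kingman = king, xi_spectra = spectra,
      replicates = as.integer(replicates), seed = as.integer(seed)
    ),
    class = "sfs_fit"
  )
}

#' @export
print.sfs_fit <- function(x, ...) {
  cat(sprintf("Coalescent model comparison (folded spectrum, n = %d)\n", x$n))
  cat(sprintf("  l2 Kingman:              %.6f\n", x$l2_kingman))
  cat(sprintf(
    "  l2 Xi-Beta (best alpha): %.6f at alpha = %.2f\n",
    x$l2_best_xi, x$best_alpha
  ))
  cat(sprintf(
    "  better fit: %s%s\n", x$best_model,
    if (x$best_model == "xi_beta" && !x$decisive) " (within Monte-Carlo tolerance of Kingman)" else ""
  ))
  invisible(x)
}

#' @export
summary.sfs_fit <- function(object, ...) {
  out <- data.frame(
    model = c("kingman", paste0("xi_beta(", format(object$alpha_grid), ")")),
    alpha = c(NA_real_, object$alpha_grid),
    l2 = c(object$l2_kingman, unname(object$l2_xi))
  )
  attr(out, "best_model") <- object$best_model
  attr(out, "best_alpha") <- object$best_alpha
  attr(out, "decisive") <- object$decisive
  class(out) <- c("summary.sfs_fit", "data.frame")
  out
}

#' @export
print.summary.sfs_fit <- function(x, ...) {
  print.data.frame(x, row.names = FALSE, digits = 5)
  cat(sprintf(
    "best: %s (alpha = %s), decisively better than Kingman: %s\n",
    attr(x, "best_model"),
    ifelse(attr(x, "best_model") == "xi_beta", format(attr(x, "best_alpha")), "-"),
    attr(x, "decisive")
  ))
  invisible(x)
}

#' @export
coef.sfs_fit <- function(object, ...) {
  c(alpha = if (object$best_model == "xi_beta") object$best_alpha else NA_real_)
}

#' @export
predict.sfs_fit <- function(object, ...) {
  if (object$best_model == "kingman") {
    object$kingman$norm_folded
  } else {
    object$xi_spectra[[which(object$alpha_grid == object$best_alpha)]]$norm_folded
  }
}

#' @export
residuals.sfs_fit <- function(object, ...) {
  object$empirical - predict(object)
}

#' @export
plot.sfs_fit <- function(x, ...) {
  graphics::plot(x$alpha_grid, x$l2_xi,
    type = "b", pch = 19,
    xlab = expression(alpha), ylab = expression(l[2]),
    main = "Fit of folded spectrum to coalescent models", ...
  )
  graphics::abline(h = x$l2_kingman, lty = 2)
  graphics::legend("topleft",
    legend = c("Xi-Beta(2-alpha, alpha)", "Kingman"),
    lty = c(1, 2), pch = c(19, NA), bty = "n"
  )
  invisible(x)
}
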