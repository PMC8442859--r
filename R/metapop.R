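#' Parameters of the five-deme source-sink metapopulation
#'
#' Demes form a linear stepping-stone chain. The defaults place the sink
#' at position 3 (so it has two neighbours) and the source at the end of
#' the chain (position 5); the chain layout itself is a modelling choice,
#' as only "source", "sink" and "adjacent to the sink" roles matter.
#'
#' @param CD Proportion of source offspring collectively dispersing to
#'   the sink, in [0, 1].
#' @param m Stepping-stone exchange proportion per adjacent deme pair, in
#'   [0, 0.5).
#' @param n_demes Number of demes (fixed at 5).
#' @param source_index,sink_index Positions of source and sink demes.
#' @param post_event_generations Relaxed generations simulated after the
#'   sweepstake event in [run_decay_experiment()].
#' @return Object of class \code{metapop_params}.
#' @export
metapop_params <- function(CD = 1, m = 0.1, n_demes = 5L,
                           source_index = 5L, sink_index = 3L,
                           post_event_generations = 3L) {
  if (n_demes != 5L) stop("the metapopulation model uses exactly five demes", call. = FALSE)
  if (CD < 0 || CD > 1) stop("CD must lie in [0, 1]", call. = FALSE)
  if (m < 0 || m >= 0.5) stop("m must lie in [0, 0.5)", call. = FALSE)
  if (source_index == sink_index) stop("source and sink demes must differ", call. = FALSE)
  if (source_index < 1 || source_index > n_demes || sink_index < 1 || sink_index > n_demes) {
    stop("source/sink indices out of range", call. = FALSE)
  }
  structure(
    list(
      CD = CD, m = m, n_demes = as.integer(n_demes),
      source_index = as.integer(source_index), sink_index = as.integer(sink_index),
      post_event_generations = as.integer(post_event_generations)
    ),
    class = "metapop_params"
  )
}

#' Initialise a five-deme metapopulation of founders
#'
#' @param K Individuals per deme.
#' @param pool Optional \code{founder_pool} for genotypes.
#' @param n_demes Number of demes.
#' @param seed Integer seed.
#' @return A \code{pedpop} with \code{deme} labels 1..n_demes.
#' @export
init_metapop <- function(K, pool = NULL, n_demes = 5L, seed = 1L) {
  demes <- lapply(seq_len(n_demes), function(d) {
    founder_population(K,
      pool = pool, deme = d,
      seed = substream_seed(seed, paste0("init_deme/", d)),
      id_offset = (d - 1L) * K
    )
  })
  .pedpop_bind(demes)
}

.pedpop_bind <- function(pops) {
  new_pedpop(
    unlist(lapply(pops, `[[`, "id")),
    unlist(lapply(pops, `[[`, "sex")),
    unlist(lapply(pops, `[[`, "mother")),
    unlist(lapply(pops, `[[`, "father")),
    unlist(lapply(pops, `[[`, "deme")),
    unlist(lapply(pops, `[[`, "generation")),
    if (!is.null(pops[[1L]]$geno)) do.call(rbind, lapply(pops, `[[`, "geno"))
  )
}

#' One metapopulation generation with collective dispersal
#'
#' Executes, in order: (1) sweepstake reproduction in the source deme
#' (or relaxed mode everywhere when \code{relax_source = TRUE}); (2)
#' relaxed reproduction in every other deme; (3) collective dispersal:
#' \code{round(CD*K)} source offspring, chosen uniformly, are exchanged
#' with an equal number of uniformly chosen sink-born offspring (the
#' displaced sink offspring take the dispersers' place in the source, so
#' every deme stays at exactly K); (4) stepping-stone exchange: each
#' adjacent deme pair swaps \code{round(m*K)} offspring, selections made
#' simultaneously and disjointly before any move.
#'
#' @param metapop A \code{pedpop} spanning all demes (one generation).
#' @param mp A [metapop_params()].
#' @param sw A [sweepstake_params()] for the source deme; its K and St
#'   also parameterise relaxed reproduction elsewhere.
#' @param seed Integer seed.
#' @param relax_source If TRUE, the source deme also reproduces in
#'   relaxed mode and no collective dispersal occurs (the post-event
#'   regime, CD forced to 0).
#' @return Offspring \code{pedpop} spanning all demes, each of size K.
#' @export
metapop_generation <- function(metapop, mp, sw, seed = 1L, relax_source = FALSE) {
  stopifnot(inherits(mp, "metapop_params"), inherits(sw, "sweepstake_params"))
  K <- sw$K
  offs <- vector("list", mp$n_demes)
  id_offset <- max(metapop$id)
  for (d in seq_len(mp$n_demes)) {
    adults <- pedpop_subset(metapop, which(metapop$deme == d))
    ds <- substream_seed(seed, paste0("mg/deme/", d))
    offs[[d]] <- if (d == mp$source_index && !relax_source) {
      sweepstake_generation(adults, sw, seed = ds, id_offset = id_offset + (d - 1L) * K)
    } else {
      relaxed_generation(adults, K, sw$St, seed = ds, id_offset = id_offset + (d - 1L) * K)
    }
  }
  # (3) collective dispersal as an exchange between source and sink
  cd_n <- if (relax_source) 0L else as.integer(round(mp$CD * K))
  if (cd_n > 0L) {
    with_seed(substream_seed(seed, "mg/cd"), {
      src <- sample.int(K, cd_n)
      snk <- sample.int(K, cd_n)
      offs <- .swap_members(offs, mp$source_index, src, mp$sink_index, snk)
    })
  }
  # (4) simultaneous stepping-stone exchange along the chain
  mig_n <- as.integer(round(mp$m * K))
  if (mig_n > 0L) {
    with_seed(substream_seed(seed, "mg/migration"), {
      # disjoint migrant sets per deme: a permutation sliced per neighbour
      perms <- lapply(seq_len(mp$n_demes), function(d) sample.int(K))
      used <- integer(mp$n_demes)
      for (d in seq_len(mp$n_demes - 1L)) {
        a <- d; b <- d + 1L
        ia <- perms[[a]][(used[a] + 1L):(used[a] + mig_n)]
        ib <- perms[[b]][(used[b] + 1L):(used[b] + mig_n)]
        used[a] <- used[a] + mig_n
        used[b] <- used[b] + mig_n
        offs <- .swap_members(offs, a, ia, b, ib)
      }
      offs
    }) -> offs
  }
  out <- .pedpop_bind(offs)
  out$deme <- rep(seq_len(mp$n_demes), each = K)
  out
}

# swap the listed positions between demes a and b of a per-deme pop list
.swap_members <- function(offs, a, ia, b, ib) {
  pa <- offs[[a]]; pb <- offs[[b]]
  for (field in c("id", "sex", "mother", "father", "generation")) {
    va <- pa[[field]]; vb <- pb[[field]]
    va[ia] <- pb[[field]][ib]
    vb[ib] <- pa[[field]][ia]
    pa[[field]] <- va; pb[[field]] <- vb
  }
  if (!is.null(pa$geno)) {
    ga <- pa$geno; gb <- pb$geno
    ga[ia, ] <- pb$geno[ib, , drop = FALSE]
    gb[ib, ] <- pa$geno[ia, , drop = FALSE]
    pa$geno <- ga; pb$geno <- gb
  }
  offs[[a]] <- pa; offs[[b]] <- pb
  offs
}

#' Collective-dispersal sweep experiment
#'
#' For each CD value, replicate metapopulation generations are run; per
#' replicate a sample of \code{sample_size} sink offspring is classified
#' by pedigree (success = only full-/half-sibs), and the nucleotide
#' diversity of the full sink offspring cohort is recorded relative to
#' the standing (parental) diversity of the source population --- the
#' source offspring cohort is itself always a single sweepstake family,
#' so the parental generation is the meaningful baseline for the
#' "reduction in pi" at the sink.
#'
#' The default \code{m = 0} isolates collective dispersal, so that CD = 1
#' reduces exactly to the single-population sweepstake case; set m > 0 to
#' add stepping-stone mixing.
#'
#' @param cd_grid CD values in [0, 1].
#' @param replicates Replicates per CD value.
#' @param sample_size Sink offspring sampled per replicate.
#' @param sw Source-deme [sweepstake_params()].
#' @param m Stepping-stone exchange proportion.
#' @param L Loci used for diversity tracking.
#' @param seed Integer seed.
#' @return Object of class \code{cd_experiment}: per-CD success
#'   proportions, kinship composition (mean and SD), and mean
#'   pi_sink/pi_source ratio.
#' @export
run_cd_experiment <- function(cd_grid = c(0, 0.25, 0.5, 0.75, 0.9, 1),
                              replicates = 100L, sample_size = 10L,
                              sw = sweepstake_params(1L, 1000L, 10L),
                              m = 0, L = 1000L, seed = 1L) {
  if (any(cd_grid < 0 | cd_grid > 1)) stop("CD grid values must lie in [0, 1]", call. = FALSE)
  pool <- draw_founder_frequencies(L, "uniform", a = 0.05, b = 0.95,
    seed = substream_seed(seed, "cd/pool")
  )
  res <- vector("list", length(cd_grid))
  for (ci in seq_along(cd_grid)) {
    mp <- metapop_params(CD = cd_grid[ci], m = m)
    success <- logical(replicates)
    comp <- matrix(NA_real_, replicates, 3L,
      dimnames = list(NULL, c("unrelated", "half-sib", "full-sib"))
    )
    ratio <- rep(NA_real_, replicates)
    for (r in seq_len(replicates)) {
      rs <- substream_seed(seed, sprintf("cd/%g/rep/%d", cd_grid[ci], r))
      meta <- init_metapop(sw$K, pool = pool, seed = substream_seed(rs, "init"))
      off <- metapop_generation(meta, mp, sw, seed = substream_seed(rs, "gen"))
      sink_idx <- which(off$deme == mp$sink_index)
      samp <- with_seed(substream_seed(rs, "sampling"), sample(sink_idx, sample_size))
      comp[r, ] <- .kin_composition(off, samp)
      success[r] <- comp[r, "unrelated"] == 0
      # pi decline at the sink relative to the source population's standing
      # (parental) diversity; the source OFFSPRING cohort is itself a single
      # sweepstake family, so it is not a meaningful baseline
      ratio[r] <- .pi_panel(off$geno[sink_idx, , drop = FALSE]) /
        .pi_panel(meta$geno[meta$deme == mp$source_index, , drop = FALSE])
    }
    res[[ci]] <- list(
      CD = cd_grid[ci], success = mean(success),
      comp_mean = colMeans(comp), comp_sd = apply(comp, 2L, stats::sd),
      pi_ratio_mean = mean(ratio), pi_ratio_sd = stats::sd(ratio)
    )
  }
  structure(
    list(
      cd_grid = cd_grid,
      success = vapply(res, `[[`, numeric(1L), "success"),
      pi_ratio = vapply(res, `[[`, numeric(1L), "pi_ratio_mean"),
      detail = res, replicates = as.integer(replicates),
      sw = sw, m = m, L = as.integer(L), seed = as.integer(seed)
    ),
    class = "cd_experiment"
  )
}

#' @export
print.cd_experiment <- function(x, ...) {
  cat(sprintf(
    "cd_experiment: %d replicates per CD, F=%d K=%d St=%d, m=%g\n",
    x$replicates, x$sw$F, x$sw$K, x$sw$St, x$m
  ))
  print(data.frame(
    CD = x$cd_grid, success = x$success,
    pi_sink_over_source = round(x$pi_ratio, 4)
  ), row.names = FALSE)
  invisible(x)
}

#' Post-event decay of sweepstake signatures
#'
#' Runs the sweepstake event generation (high CD into the sink), then
#' \code{post_event_generations} further generations with every deme in
#' relaxed mode, CD set to zero and stepping-stone migration active, and
#' reports the sampled kinship composition and nucleotide diversity of
#' every deme at every time point.
#'
#' @param mp A [metapop_params()]; \code{CD} should be in the successful
#'   regime (>= 0.95).
#' @param sw Source-deme [sweepstake_params()].
#' @param replicates Number of replicate trajectories.
#' @param sample_size Individuals sampled per deme per generation.
#' @param L Loci used for diversity tracking.
#' @param seed Integer seed.
#' @return Object of class \code{decay_experiment} with a long-format
#'   data frame \code{trajectory} (replicate, generation, deme, pi,
#'   close_kin = sampled full+half-sib pair proportion).
#' @export
run_decay_experiment <- function(mp = metapop_params(CD = 1, m = 0.1),
                                 sw = sweepstake_params(1L, 1000L, 10L),
                                 replicates = 50L, sample_size = 10L,
                                 L = 1000L, seed = 1L) {
  if (mp$CD < 0.95) stop("the decay experiment starts from the successful regime (CD >= 0.95)", call. = FALSE)
  pool <- draw_founder_frequencies(L, "uniform", a = 0.05, b = 0.95,
    seed = substream_seed(seed, "decay/pool")
  )
  rows <- list()
  for (r in seq_len(replicates)) {
    rs <- substream_seed(seed, paste0("decay/rep/", r))
    meta <- init_metapop(sw$K, pool = pool, seed = substream_seed(rs, "init"))
    cur <- metapop_generation(meta, mp, sw, seed = substream_seed(rs, "gen0"))
    rows[[length(rows) + 1L]] <- .decay_snapshot(cur, mp, r, 0L, sample_size,
      seed = substream_seed(rs, "snap0")
    )
    for (g in seq_len(mp$post_event_generations)) {
      cur <- metapop_generation(cur, mp, sw,
        seed = substream_seed(rs, paste0("gen", g)),
        relax_source = TRUE
      )
      rows[[length(rows) + 1L]] <- .decay_snapshot(cur, mp, r, g, sample_size,
        seed = substream_seed(rs, paste0("snap", g))
      )
    }
  }
  structure(
    list(
      trajectory = do.call(rbind, c(rows, list(make.row.names = FALSE))),
      mp = mp, sw = sw, replicates = as.integer(replicates),
      sample_size = as.integer(sample_size), L = as.integer(L), seed = as.integer(seed)
    ),
    class = "decay_experiment"
  )
}

.decay_snapshot <- function(pop, mp, rep, gen, sample_size, seed) {
  out <- vector("list", mp$n_demes)
  for (d in seq_len(mp$n_demes)) {
    idx <- which(pop$deme == d)
    samp <- with_seed(substream_seed(seed, paste0("deme", d)), sample(idx, sample_size))
    comp <- .kin_composition(pop, samp)
    out[[d]] <- data.frame(
      replicate = rep, generation = gen, deme = d,
      role = if (d == mp$source_index) "source" else if (d == mp$sink_index) "sink" else "other",
      pi = .pi_panel(pop$geno[samp, , drop = FALSE]),
      close_kin = unname(comp["half-sib"] + comp["full-sib"])
    )
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' @export
print.decay_experiment <- function(x, ...) {
  cat(sprintf(
    "decay_experiment: %d replicates, CD=%g m=%g, %d post-event generations\n",
    x$replicates, x$mp$CD, x$mp$m, x$mp$post_event_generations
  ))
  agg <- stats::aggregate(cbind(pi, close_kin) ~ generation + role,
    data = x$trajectory, FUN = mean
  )
  print(agg, row.names = FALSE)
  invisible(x)
}
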