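#' Validate a pipeline configuration
#'
#' Reads a YAML configuration (or takes a list), checks it against the
#' schema, fills defaults and returns a normalized \code{run_config}.
#' Validation failures are collected and reported together.
#'
#' Schema (all sections optional except \code{seed}):
#' \preformatted{
#' seed: 1                 # required master seed
#' out_dir: "cgp_run"      # where stage outputs are written
#' synth:    L, missingness, n_fathers, cohorts (list of name/size/structure)
#' kinship:  maf_min, min_loci
#' stats:    max_pairs, n_boot
#' sfs:      alpha_from, alpha_to, alpha_by, replicates
#' simulate: enabled, F, K, St, cd_grid, m, replicates, sample_size, L
#' }
#'
#' @param path YAML file path, or a list with the same structure.
#' @return Object of class \code{run_config}.
#' @export
validate_config <- function(path) {
  raw <- if (is.character(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    yaml::read_yaml(path)
  } else if (is.list(path)) {
    path
  } else {
    stop("config must be a YAML path or a list", call. = FALSE)
  }
  defaults <- list(
    seed = NULL, out_dir = "cgp_run",
    synth = list(L = 5000L, missingness = 0, n_fathers = 5L, cohorts = NULL),
    kinship = list(maf_min = 0.01, min_loci = 100L),
    stats = list(max_pairs = 50000L, n_boot = 10000L),
    sfs = list(alpha_from = 1.05, alpha_to = 1.95, alpha_by = 0.05, replicates = 20000L),
    simulate = list(
      enabled = FALSE, F = 1L, K = 1000L, St = 10L,
      cd_grid = c(0, 0.25, 0.5, 0.75, 0.9, 1), m = 0,
      replicates = 100L, sample_size = 10L, L = 1000L
    )
  )
  errors <- character(0)
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown)) errors <- c(errors, paste0("unknown top-level key(s): ", paste(unknown, collapse = ", ")))
  cfg <- defaults
  for (sec in intersect(names(raw), names(defaults))) {
    if (sec %in% c("seed", "out_dir")) {
      cfg[[sec]] <- raw[[sec]]
      next
    }
    bad <- setdiff(names(raw[[sec]]), names(defaults[[sec]]))
    if (length(bad)) errors <- c(errors, paste0("unknown key(s) in ", sec, ": ", paste(bad, collapse = ", ")))
    cfg[[sec]][names(raw[[sec]])] <- raw[[sec]]
  }
  if (is.null(cfg$seed)) {
    errors <- c(errors, "seed: required, missing")
  } else if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L || cfg$seed != round(cfg$seed)) {
    errors <- c(errors, "seed: must be a single integer")
  }
  s <- cfg$simulate
  if (s$St %% 2 != 0) errors <- c(errors, "simulate.St: must be even (balanced 1:1 stacks)")
  if (s$St < 2 || s$St > 20) errors <- c(errors, "simulate.St: must lie in [2, 20]")
  if (s$F < 1 || s$F > s$St / 2) errors <- c(errors, "simulate.F: must satisfy 1 <= F <= St/2")
  if (any(s$cd_grid < 0 | s$cd_grid > 1)) errors <- c(errors, "simulate.cd_grid: values must lie in [0, 1]")
  if (s$m < 0 || s$m >= 0.5) errors <- c(errors, "simulate.m: must lie in [0, 0.5)")
  f <- cfg$sfs
  grid <- tryCatch(seq(f$alpha_from, f$alpha_to, by = f$alpha_by), error = function(e) numeric(0))
  if (!length(grid) || any(grid <= 1 | grid >= 2)) {
    errors <- c(errors, "sfs.alpha_from/alpha_to/alpha_by: grid must lie inside (1, 2)")
  }
  if (cfg$synth$missingness < 0 || cfg$synth$missingness >= 1) {
    errors <- c(errors, "synth.missingness: must lie in [0, 1)")
  }
  if (length(errors)) {
    stop("invalid configuration:\n  - ", paste(errors, collapse = "\n  - "), call. = FALSE)
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg$sfs$alpha_grid <- grid
  cfg$version <- as.character(utils::packageVersion("cgpsim"))
  structure(cfg, class = "run_config")
}

#' Run the full synthetic analysis pipeline
#'
#' Executes, in dependency order: dataset synthesis (written as VCF +
#' sample metadata), pairwise kinship estimation, cohort statistics
#' (nucleotide diversity, LD r-squared, folded spectra, pairwise Fst),
#' coalescent model fitting per cohort, optional forward-simulation
#' experiments, and a final report. All stage outputs are CSV/text files
#' under \code{out_dir}, with an md5 checksum manifest; every stochastic
#' stage derives its own substream from the master seed, so a rerun with
#' the same configuration reproduces every table byte for byte.
#'
#' @param config A \code{run_config}, a list, or a YAML path (passed to
#'   [validate_config()]).
#' @return Object of class \code{cgp_report}: per-cohort table, fst
#'   result, optional simulation summaries, and output paths.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  # -- synth ----------------------------------------------------------
  ds <- stage("synth", {
    make_study_like_dataset(
      list(
        L = cfg$synth$L, missingness = cfg$synth$missingness,
        n_fathers = cfg$synth$n_fathers, cohorts = cfg$synth$cohorts
      ),
      seed = substream_seed(cfg$seed, "pipeline/synth")
    )
  })
  paths$vcf <- file.path(cfg$out_dir, "synthetic.vcf")
  stage("synth", write_vcf(ds, paths$vcf))
  paths$meta <- file.path(cfg$out_dir, "synthetic.samples.tsv")

  # -- kinship --------------------------------------------------------
  pairs <- stage("kinship", {
    kinship_pairs(ds$geno, ds$cohorts,
      maf_min = cfg$kinship$maf_min, min_loci = cfg$kinship$min_loci
    )
  })
  paths$kinship <- file.path(cfg$out_dir, "kinship_pairs.csv")
  utils::write.csv(pairs, paths$kinship, row.names = FALSE)

  # -- stats ----------------------------------------------------------
  cohorts <- unique(ds$cohorts)
  cls_map <- c(
    "parent-offspring" = "full-sib", "full-sib" = "full-sib",
    "half-sib/2nd-degree" = "half-sib",
    "3rd-degree" = "unrelated", "4th-degree" = "unrelated",
    "unrelated/5th+" = "unrelated", "unclassified" = "unclassified",
    "duplicate/MZ" = "duplicate"
  )
  cohort_tab <- stage("stats", {
    do.call(rbind, lapply(cohorts, function(co) {
      r2 <- ld_r2(ds$geno, ds$cohorts, co,
        max_pairs = cfg$stats$max_pairs,
        seed = substream_seed(cfg$seed, paste0("pipeline/ld/", co))
      )
      mapped <- cls_map[pairs$category[pairs$cohort == co]]
      data.frame(
        cohort = co,
        n = sum(ds$cohorts == co),
        pi = nucleotide_diversity(ds$geno, ds$cohorts, co),
        r2_mean = mean(r2), r2_median = stats::median(r2),
        r2_p90 = unname(stats::quantile(r2, 0.9)),
        kin_unrelated = mean(mapped == "unrelated"),
        kin_half_sib = mean(mapped == "half-sib"),
        kin_full_sib = mean(mapped == "full-sib"),
        stringsAsFactors = FALSE
      )
    }))
  })
  fst <- stage("stats", {
    pairwise_fst(ds$geno, ds$cohorts,
      n_boot = cfg$stats$n_boot,
      seed = substream_seed(cfg$seed, "pipeline/fst")
    )
  })
  paths$fst <- file.path(cfg$out_dir, "fst_matrix.csv")
  utils::write.csv(round(fst$fst, 6), paths$fst)
  paths$fst_p <- file.path(cfg$out_dir, "fst_pvalues.csv")
  utils::write.csv(fst$p, paths$fst_p)

  # -- sfs fit --------------------------------------------------------
  fits <- stage("sfs", {
    lapply(cohorts, function(co) {
      sp <- folded_sfs(ds$geno, ds$cohorts, co)
      fit_sfs(sp,
        alpha_grid = cfg$sfs$alpha_grid, replicates = cfg$sfs$replicates,
        seed = substream_seed(cfg$seed, "pipeline/sfs") # shared spectra across cohorts
      )
    })
  })
  cohort_tab$best_model <- vapply(fits, `[[`, character(1L), "best_model")
  cohort_tab$best_alpha <- vapply(fits, function(f) {
    if (f$best_model == "xi_beta") f$best_alpha else NA_real_
  }, numeric(1L))
  cohort_tab$l2_kingman <- vapply(fits, `[[`, numeric(1L), "l2_kingman")
  cohort_tab$l2_best_xi <- vapply(fits, `[[`, numeric(1L), "l2_best_xi")
  paths$cohorts <- file.path(cfg$out_dir, "cohort_table.csv")
  utils::write.csv(cohort_tab, paths$cohorts, row.names = FALSE)

  # -- simulate (optional) -------------------------------------------
  sim <- NULL
  if (isTRUE(cfg$simulate$enabled)) {
    sim <- stage("simulate", {
      sw <- sweepstake_params(cfg$simulate$F, cfg$simulate$K, cfg$simulate$St)
      single <- run_single_pop_experiment(sw,
        replicates = cfg$simulate$replicates,
        sample_size = cfg$simulate$sample_size,
        seed = substream_seed(cfg$seed, "pipeline/sim/single")
      )
      cd <- run_cd_experiment(cfg$simulate$cd_grid,
        replicates = cfg$simulate$replicates,
        sample_size = cfg$simulate$sample_size, sw = sw,
        m = cfg$simulate$m, L = cfg$simulate$L,
        seed = substream_seed(cfg$seed, "pipeline/sim/cd")
      )
      list(single = single, cd = cd)
    })
    cd_tab <- data.frame(
      CD = sim$cd$cd_grid, success = sim$cd$success,
      pi_sink_over_source = sim$cd$pi_ratio
    )
    paths$cd <- file.path(cfg$out_dir, "cd_sweep.csv")
    utils::write.csv(cd_tab, paths$cd, row.names = FALSE)
  }

  # -- report ---------------------------------------------------------
  paths$summary <- file.path(cfg$out_dir, "summary.txt")
  con <- file(paths$summary, "w")
  writeLines(c(
    sprintf("cgpsim %s pipeline run (seed %d)", cfg$version, cfg$seed),
    sprintf("cohorts: %d, loci: %d", length(cohorts), ncol(ds$geno)),
    sprintf(
      "cohorts with only close kin (full+half-sib pairs = 100%%): %s",
      paste(cohort_tab$cohort[cohort_tab$kin_unrelated == 0], collapse = ", ")
    ),
    sprintf(
      "cohorts better fit by Xi-Beta: %d of %d",
      sum(cohort_tab$best_model == "xi_beta"), length(cohorts)
    ),
    if (!is.null(sim)) sprintf("single-pop sweepstake success: %.2f", sim$single$success)
  ), con)
  close(con)
  files <- unlist(paths)
  manifest <- data.frame(file = basename(files), md5 = unname(tools::md5sum(files)))
  paths$checksums <- file.path(cfg$out_dir, "checksums.csv")
  utils::write.csv(manifest, paths$checksums, row.names = FALSE)

  structure(
    list(
      cohort_table = cohort_tab, fst = fst, kinship_pairs = pairs,
      fits = fits, simulation = sim, paths = paths, config = cfg
    ),
    class = "cgp_report"
  )
}

#' @export
print.cgp_report <- function(x, ...) {
  cat(sprintf(
    "cgp_report: %d cohorts, outputs in %s\n",
    nrow(x$cohort_table), x$config$out_dir
  ))
  print(x$cohort_table[, c("cohort", "n", "pi", "kin_unrelated", "kin_half_sib", "kin_full_sib", "best_model")],
    row.names = FALSE, digits = 4
  )
  invisible(x)
}
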