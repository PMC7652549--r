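# Study configurations --------------------------------------------------------

REPRO_KEYS <- c("study", "n_per_site", "n_layers", "sites", "generator",
                "alpha", "intersite_test")
FURO_KEYS <- c("study", "n_animals", "n_layers", "washout", "serum",
               "generator", "alpha")

#' Multi-site reproducibility study configuration
#'
#' Defaults mirror the volunteer study design: two sites with 6 subjects
#' each, site-level regional means (medulla 137/133, cortex 72/70 mmol/L),
#' 12 onion layers, 5 percent inter-subject variability, and an unpaired
#' rank-sum intersite test (a `"signed_rank"` mode pairing subjects by
#' index is available).
#'
#' @param n_per_site subjects per site.
#' @param n_layers onion layers for the profile.
#' @param sites named list of per-site lists with `medulla` and `cortex`
#'   means (mmol/L).
#' @param generator list of overrides passed to [human_subject_config()].
#' @param alpha significance level.
#' @param intersite_test `"rank_sum"` or `"signed_rank"`.
#' @return A list of class `study_config`.
#' @export
reproducibility_config <- function(n_per_site = 6, n_layers = 12,
                                   sites = list(
                                     A = list(medulla = 137, cortex = 72),
                                     B = list(medulla = 133, cortex = 70)),
                                   generator = list(), alpha = 0.05,
                                   intersite_test = c("rank_sum",
                                                      "signed_rank")) {
  cfg <- list(study = "reproducibility", n_per_site = n_per_site,
              n_layers = n_layers, sites = sites, generator = generator,
              alpha = alpha, intersite_test = match.arg(intersite_test))
  validate_study_config(cfg)
}

#' Furosemide dynamic study configuration
#'
#' Defaults mirror the porcine diuresis design: 6 animals, 7 onion layers,
#' imaging at 5-min intervals over 30 min, medullary washout from 92
#' towards 69 mmol/L, flat serum electrolytes.
#'
#' @param n_animals number of animals.
#' @param n_layers onion layers.
#' @param washout list of overrides for [washout_config()].
#' @param serum list with `baseline` (named vector) and `noise_cv`.
#' @param generator list of overrides for [porcine_subject_config()].
#' @param alpha significance level.
#' @return A list of class `study_config`.
#' @export
furosemide_config <- function(n_animals = 6, n_layers = 7,
                              washout = list(), serum = list(),
                              generator = list(), alpha = 0.05) {
  cfg <- list(study = "furosemide", n_animals = n_animals,
              n_layers = n_layers, washout = washout, serum = serum,
              generator = generator, alpha = alpha)
  validate_study_config(cfg)
}

validate_study_config <- function(cfg) {
  if (is.null(cfg$study) ||
      !cfg$study %in% c("reproducibility", "furosemide"))
    stop_config("study must be 'reproducibility' or 'furosemide'",
                offending = "study")
  allowed <- if (cfg$study == "reproducibility") REPRO_KEYS else FURO_KEYS
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop_config("unknown config key(s): ", paste(unknown, collapse = ", "),
                offending = unknown)
  if (cfg$study == "reproducibility") {
    if (!is.numeric(cfg$n_per_site) || cfg$n_per_site < 0)
      stop_config("n_per_site must be a nonnegative count",
                  offending = "n_per_site")
    bad <- names(cfg$sites)[!vapply(cfg$sites, function(s)
      is.list(s) && all(c("medulla", "cortex") %in% names(s)), logical(1))]
    if (length(bad) || length(cfg$sites) < 1)
      stop_config("each site needs 'medulla' and 'cortex' means",
                  offending = paste0("sites$", bad))
  } else {
    if (!is.numeric(cfg$n_animals) || cfg$n_animals < 1)
      stop_config("n_animals must be a positive count",
                  offending = "n_animals")
  }
  if (!is.numeric(cfg$n_layers) || cfg$n_layers < 3)
    stop_config("n_layers must be at least 3", offending = "n_layers")
  structure(cfg, class = "study_config")
}

stop_config <- function(..., offending = NULL) {
  cond <- structure(class = c("nephna_config_error", "error", "condition"),
                    list(message = paste0(...), call = NULL,
                         offending = offending))
  stop(cond)
}

#' Load a study configuration from YAML
#'
#' The YAML must carry a `study:` discriminator
#' (`reproducibility`/`furosemide`); remaining keys mirror
#' [reproducibility_config()] / [furosemide_config()].
#'
#' @param path YAML file path.
#' @return A validated `study_config`.
#' @export
load_study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$serum$baseline)) cfg$serum$baseline <-
    unlist(cfg$serum$baseline)
  ctor <- switch(cfg$study %||% "",
                 reproducibility = reproducibility_config,
                 furosemide = furosemide_config,
                 stop_config("study must be 'reproducibility' or 'furosemide'",
                             offending = "study"))
  do.call(ctor, cfg[setdiff(names(cfg), "study")])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_hash <- function(cfg) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(unclass(cfg), f)
  unname(tools::md5sum(f))
}

provenance <- function(cfg, seed) {
  list(config_hash = config_hash(cfg), seed = as.integer(seed),
       package_version = as.character(utils::packageVersion("nephna")))
}

# Reproducibility study --------------------------------------------------------

#' Run the multi-site reproducibility study
#'
#' Generates (or accepts) a two-site cohort, runs every subject through the
#' full quantification chain (phantom calibration with B1 and saturation
#' correction, onion-layer segmentation, regional means, layer profile),
#' and assembles per-site summaries with CoV, intersite tests, pooled
#' means, region comparisons, the cohort-averaged layer profile and its
#' gradient fit.
#'
#' @param config a `study_config` from [reproducibility_config()], or a
#'   YAML path for [load_study_config()].
#' @param seed root seed; all randomness (anatomy draws, noise) derives
#'   from it via named substreams.
#' @param out_dir optional output directory: writes `report.json` and
#'   `tables/*.csv` (and `volumes/*.nii.gz` when `write_volumes`).
#' @param write_volumes also write per-subject NIfTI volumes.
#' @return A `study_report` list; see Details in [print.study_report()].
#' @examples
#' \donttest{
#' rep <- run_reproducibility_study(seed = 1)
#' rep$pooled
#' }
#' @export
run_reproducibility_study <- function(config = reproducibility_config(),
                                      seed = 1L, out_dir = NULL,
                                      write_volumes = FALSE) {
  if (is.character(config)) config <- load_study_config(config)
  config <- validate_study_config(config)
  if (config$study != "reproducibility")
    stop_config("config is not a reproducibility study", offending = "study")

  site_configs <- lapply(config$sites, function(s) {
    do.call(human_subject_config,
            utils::modifyList(list(medulla_conc = s$medulla,
                                   cortex_conc = s$cortex),
                              config$generator))
  })
  cohort <- generate_cohort(config$n_per_site, site_configs,
                            substream_seed(seed, "subjects"))

  per_subject <- list(); profiles <- list()
  for (i in seq_along(cohort)) {
    subj <- cohort[[i]]
    q <- quantify_subject(subj)
    layers <- onion_layers(kidney_mask(subj), config$n_layers,
                           subj$config$spacing)
    profiles[[i]] <- layer_profile(q$conc, layers)
    rs <- q$regions
    rs$site <- subj$site_name
    rs$subject <- i
    per_subject[[i]] <- rs
    if (isTRUE(write_volumes) && !is.null(out_dir))
      write_subject(subj, file.path(out_dir, "volumes",
                                    sprintf("subject%02d", i)))
  }
  subj_tab <- do.call(rbind, per_subject)

  regions <- unique(subj_tab$region)
  sites <- unique(subj_tab$site)
  site_summary <- do.call(rbind, lapply(sites, function(s)
    do.call(rbind, lapply(regions, function(r) {
      v <- subj_tab$mean[subj_tab$site == s & subj_tab$region == r]
      data.frame(site = s, region = r, mean = mean(v), sd = sd(v),
                 cov_pct = cov_percent(v), n = length(v))
    }))))

  intersite <- NULL
  if (length(sites) == 2 && config$n_per_site >= 2) {
    intersite <- do.call(rbind, lapply(regions, function(r) {
      a <- subj_tab$mean[subj_tab$site == sites[1] & subj_tab$region == r]
      b <- subj_tab$mean[subj_tab$site == sites[2] & subj_tab$region == r]
      res <- if (config$intersite_test == "rank_sum") rank_sum(a, b)
             else wilcoxon_signed_rank(a, b)
      data.frame(region = r, test = res$method, statistic = res$statistic,
                 p_value = res$p_value,
                 significant = res$p_value < config$alpha)
    }))
  }

  pooled <- do.call(rbind, lapply(regions, function(r) {
    v <- subj_tab$mean[subj_tab$region == r]
    data.frame(region = r, mean = mean(v), sd = sd(v), n = length(v))
  }))

  # region comparisons on pooled per-subject means: Kruskal-Wallis
  # gatekeeper, then pairwise paired signed-rank, Bonferroni over the pairs
  by_region <- lapply(regions, function(r)
    subj_tab$mean[subj_tab$region == r])
  names(by_region) <- regions
  region_tests <- NULL
  if (length(cohort) >= 3) {
    kw <- kruskal_wallis(by_region)
    pairs <- combn(regions, 2, simplify = FALSE)
    praw <- vapply(pairs, function(pr)
      wilcoxon_signed_rank(by_region[[pr[1]]],
                           by_region[[pr[2]]])$p_value, numeric(1))
    padj <- bonferroni_adjust(praw, m = length(pairs))
    region_tests <- list(
      kruskal_wallis = data.frame(statistic = kw$statistic,
                                  p_value = kw$p_value),
      pairwise = data.frame(
        region_a = vapply(pairs, `[`, character(1), 1),
        region_b = vapply(pairs, `[`, character(1), 2),
        p_raw = praw, p_adj = padj,
        significant = padj < config$alpha))
  }

  # cohort-averaged layer profile (geometry shared, so depths align)
  prof_mat <- vapply(profiles, function(p) p$mean,
                     numeric(nrow(profiles[[1]])))
  prof_mat <- matrix(prof_mat, nrow = nrow(profiles[[1]]))
  avg_profile <- profiles[[1]]
  avg_profile$mean <- rowMeans(prof_mat)
  avg_profile$sd <- apply(prof_mat, 1, sd)
  grad <- fit_gradient(avg_profile)
  grad_by_subject <- vapply(profiles, function(p) fit_gradient(p)$slope,
                            numeric(1))

  report <- structure(list(
    study = "reproducibility",
    subjects = subj_tab, site_summary = site_summary,
    intersite_tests = intersite, pooled = pooled,
    region_tests = region_tests,
    profile = avg_profile, gradient = grad,
    gradient_by_subject = data.frame(subject = seq_along(cohort),
                                     slope = grad_by_subject),
    provenance = provenance(config, seed), config = config
  ), class = "study_report")
  if (!is.null(out_dir)) write_study_report(report, out_dir)
  report
}

# Furosemide study -------------------------------------------------------------

#' Run the furosemide dynamic study
#'
#' For each animal, generates a dynamic series with exponential medullary
#' washout, quantifies every time point through calibration, computes
#' regional means and onion-layer profiles, fits the gradient time course
#' with paired comparisons against baseline (Bonferroni over post-baseline
#' times), tests the per-region baseline-vs-final change (each region a
#' prespecified hypothesis, raw two-sided p), simulates an independent
#' serum panel per animal, and correlates the gradient slope with serum
#' percentage changes across animal-time observations.
#'
#' @inheritParams run_reproducibility_study
#' @param config a `study_config` from [furosemide_config()] or YAML path.
#' @return A `study_report` list.
#' @export
run_furosemide_study <- function(config = furosemide_config(), seed = 1L,
                                 out_dir = NULL, write_volumes = FALSE) {
  if (is.character(config)) config <- load_study_config(config)
  config <- validate_study_config(config)
  if (config$study != "furosemide")
    stop_config("config is not a furosemide study", offending = "study")

  base_gen <- do.call(porcine_subject_config, config$generator)
  base_wash <- do.call(washout_config, config$washout)
  times <- base_wash$times
  nt <- length(times)
  n_an <- config$n_animals
  serum_baseline <- config$serum$baseline %||%
    c(sodium = 139, potassium = 4.0, chloride = 103)
  serum_cv <- config$serum$noise_cv %||% 0.01

  region_means <- array(NA_real_, c(n_an, nt, 3),
                        dimnames = list(NULL, NULL,
                                        c("cortex", "medulla",
                                          "whole_kidney")))
  profiles_by_time <- rep(list(vector("list", n_an)), nt)
  serum_panels <- vector("list", n_an)

  for (a in seq_len(n_an)) {
    a_seed <- substream_seed(seed, paste0("animal", a))
    cov <- base_gen$intersubject_cov
    z <- with_seed(substream_seed(a_seed, "regional-conc"), rnorm(2))
    gen_a <- base_gen
    gen_a$cortex_conc <- base_gen$cortex_conc * (1 + cov * z[1])
    wash_a <- base_wash
    wash_a$baseline_medulla <- base_wash$baseline_medulla * (1 + cov * z[2])
    wash_a$plateau_medulla <- base_wash$plateau_medulla * (1 + cov * z[2])
    dyn <- generate_dynamic_study(gen_a, wash_a, a_seed)
    layers <- onion_layers(kidney_mask(dyn$subjects[[1]]), config$n_layers,
                           gen_a$spacing)
    for (j in seq_len(nt)) {
      q <- quantify_subject(dyn$subjects[[j]])
      region_means[a, j, "cortex"] <-
        q$regions$mean[q$regions$region == "cortex"]
      region_means[a, j, "medulla"] <-
        q$regions$mean[q$regions$region == "medulla"]
      region_means[a, j, "whole_kidney"] <-
        q$regions$mean[q$regions$region == "whole_kidney"]
      profiles_by_time[[j]][[a]] <- layer_profile(q$conc, layers)
      if (isTRUE(write_volumes) && !is.null(out_dir))
        write_subject(dyn$subjects[[j]],
                      file.path(out_dir, "volumes",
                                sprintf("animal%02d_t%02d", a, times[j])))
    }
    serum_panels[[a]] <- simulate_serum(serum_baseline, serum_cv, times,
                                        seed = substream_seed(a_seed, "serum"))
  }

  grad <- dynamic_gradient_series(profiles_by_time, times,
                                  alpha = config$alpha)

  # per-region time course with paired tests vs baseline
  region_tab <- do.call(rbind, lapply(dimnames(region_means)[[3]],
                                      function(r) {
    do.call(rbind, lapply(seq_len(nt), function(j) {
      v <- region_means[, j, r]
      p <- if (j > 1 && n_an >= 3)
        wilcoxon_signed_rank(v, region_means[, 1, r])$p_value else NA_real_
      data.frame(region = r, time = times[j], mean = mean(v), sd = sd(v),
                 p_raw = p)
    }))
  }))
  region_tab$p_adj <- NA_real_
  for (r in unique(region_tab$region)) {
    sel <- region_tab$region == r & region_tab$time > 0
    region_tab$p_adj[sel] <- bonferroni_adjust(region_tab$p_raw[sel],
                                               m = nt - 1L)
  }

  # headline baseline-vs-final change per region (prespecified, raw p)
  final_tests <- do.call(rbind, lapply(dimnames(region_means)[[3]],
                                       function(r) {
    v0 <- region_means[, 1, r]; v1 <- region_means[, nt, r]
    res <- wilcoxon_signed_rank(v1, v0)
    data.frame(region = r, baseline_mean = mean(v0), final_mean = mean(v1),
               p_value = res$p_value,
               significant = res$p_value < config$alpha,
               direction = sign(mean(v1) - mean(v0)))
  }))

  # serum: per-analyte % change vs own baseline, final-vs-baseline test,
  # and gradient-vs-serum linear fits across animal x post-baseline points
  analytes <- setdiff(names(serum_panels[[1]]), "time")
  serum_mat <- lapply(analytes, function(an)
    t(vapply(serum_panels, function(p) p[[an]], numeric(nt))))
  names(serum_mat) <- analytes
  serum_tab <- do.call(rbind, lapply(analytes, function(an) {
    m <- serum_mat[[an]]
    pct <- 100 * (m - m[, 1]) / m[, 1]
    p <- if (n_an >= 3) wilcoxon_signed_rank(m[, nt], m[, 1])$p_value
         else NA_real_
    data.frame(analyte = an, baseline_mean = mean(m[, 1]),
               final_mean = mean(m[, nt]),
               max_abs_pct_change = max(abs(pct)),
               p_final_vs_baseline = p,
               significant = !is.na(p) & p < config$alpha)
  }))
  serum_correlation <- do.call(rbind, lapply(analytes, function(an) {
    m <- serum_mat[[an]]
    pct <- 100 * (m - m[, 1]) / m[, 1]
    x <- as.vector(grad$slopes[, -1]); y <- as.vector(pct[, -1])
    f <- linear_fit_r2(x, y)
    data.frame(analyte = an, slope = f$slope, r_squared = f$r_squared,
               p_value = f$p_value, n = f$n)
  }))

  report <- structure(list(
    study = "furosemide",
    times = times,
    region_time_course = region_tab,
    final_vs_baseline = final_tests,
    gradient = grad,
    serum = serum_tab,
    serum_correlation = serum_correlation,
    serum_panels = serum_panels,
    region_means = region_means,
    provenance = provenance(config, seed), config = config
  ), class = "study_report")
  if (!is.null(out_dir)) write_study_report(report, out_dir)
  report
}

# Report output ----------------------------------------------------------------

#' Write a study report to disk
#'
#' `report.json` (machine-readable; schema-versioned via the package
#' version in provenance) plus `tables/*.csv`.
#'
#' @param report a `study_report`.
#' @param out_dir output directory, created if needed.
#' @return `out_dir`, invisibly.
#' @export
write_study_report <- function(report, out_dir) {
  dir.create(file.path(out_dir, "tables"), recursive = TRUE,
             showWarnings = FALSE)
  json <- report
  json$serum_panels <- NULL
  json$region_means <- NULL
  json$config <- unclass(json$config)
  json$gradient <- if (inherits(json$gradient, "dynamic_gradient_series"))
    list(table = json$gradient$table,
         first_significant_time = json$gradient$first_significant_time)
  else unclass(json$gradient)
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE, na = "null")
  tabs <- Filter(is.data.frame, report)
  for (nm in names(tabs))
    utils::write.csv(tabs[[nm]],
                     file.path(out_dir, "tables", paste0(nm, ".csv")),
                     row.names = FALSE)
  invisible(out_dir)
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %s study (seed %d, config %s)\n", x$study,
              x$provenance$seed, substr(x$provenance$config_hash, 1, 8)))
  if (x$study == "reproducibility") {
    cat("pooled regional means (mmol/L):\n")
    print(transform(x$pooled, mean = round(mean, 1), sd = round(sd, 1)))
    cat(sprintf("averaged %d-layer gradient: %.2f mmol/L/mm (R2 = %.3f)\n",
                x$gradient$n_layers, x$gradient$slope, x$gradient$r_squared))
  } else {
    cat("baseline vs final regional means (mmol/L):\n")
    print(transform(x$final_vs_baseline,
                    baseline_mean = round(baseline_mean, 1),
                    final_mean = round(final_mean, 1)))
    cat("gradient first significant change at",
        x$gradient$first_significant_time, "min\n")
  }
  invisible(x)
}
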