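# End-to-end orchestration: simulate -> harmonize -> screen (average and
# change) -> call signals -> prioritize -> report, with a run manifest
# (config snapshot, seed, stage timings, record counts and file digests)
# sufficient to re-run the deterministic stages bit-identically.

#' Pipeline configuration
#'
#' One nested configuration covering every stage. Defaults are the
#' screening protocol's published constants and thresholds (FDR level 0.05,
#' top 5 per category per trait, at least 5 of 9 traits, 10-year pairing
#' window with +/- 2 years tolerance).
#'
#' @param simulate A [generator_config()] (used when no cohort files are
#'   supplied).
#' @param harmonize A [harmonize_config()].
#' @param traits Traits to screen.
#' @param modes Analysis modes to run (`"average"`, `"change"`).
#' @param target_years,tolerance_years Change-screen pairing window.
#' @param alpha Tentative-signal FDR level.
#' @param top_k Variables per category per trait in the ranking step.
#' @param min_traits Cross-trait prioritization threshold.
#' @param cluster_groups Optional number of flat target groups cut from the
#'   dendrogram.
#' @param seed Run seed (overrides the generator seed).
#' @return List of class `exposcan_pipeline_config`.
#' @export
pipeline_config <- function(simulate = generator_config(),
                            harmonize = harmonize_config(),
                            traits = cardiometabolic_traits(),
                            modes = c("average", "change"),
                            target_years = 10, tolerance_years = 2,
                            alpha = 0.05, top_k = 5L, min_traits = 5L,
                            cluster_groups = NULL,
                            seed = NULL) {
  if (!all(modes %in% c("average", "change")))
    stop_field("modes", "must be a subset of {average, change}")
  if (min_traits > length(traits))
    stop_field("min_traits",
               sprintf("cannot exceed the number of traits (%d)",
                       length(traits)))
  if (!is.null(seed)) simulate$seed <- as.integer(seed)
  structure(list(simulate = simulate, harmonize = harmonize,
                 traits = traits, modes = modes,
                 target_years = target_years,
                 tolerance_years = tolerance_years,
                 alpha = alpha, top_k = as.integer(top_k),
                 min_traits = as.integer(min_traits),
                 cluster_groups = cluster_groups,
                 seed = simulate$seed),
            class = "exposcan_pipeline_config")
}

#' A small demonstration configuration
#'
#' A deliberately small simulated study (2 traits, 40 exposures in 4
#' categories, 400 participants) for smoke tests and examples; finishes in
#' seconds.
#'
#' @param seed Run seed.
#' @return An `exposcan_pipeline_config`.
#' @export
demo_pipeline_config <- function(seed = 1L) {
  n_expo <- c(alcohol = 0L, beverage = 10L, food = 0L, nutrient = 0L,
              general_health = 10L, physical_activity = 10L,
              psychosocial = 0L, sleep = 0L, social = 0L, tobacco = 10L)
  planted <- data.frame(
    exposure = c("physical_activity_01", "physical_activity_01",
                 "tobacco_01"),
    trait = c("bmi", "triglycerides", "triglycerides"),
    slope = c(-0.6, -0.4, 0.3), stringsAsFactors = FALSE)
  pipeline_config(
    simulate = generator_config(n_participants = 400L,
                                n_exposures_per_category = n_expo,
                                planted_effects = planted, seed = seed),
    traits = c("bmi", "triglycerides"),
    min_traits = 2L, seed = seed)
}

stage_time <- function(expr) {
  t0 <- proc.time()[["elapsed"]]
  value <- expr
  list(value = value, seconds = proc.time()[["elapsed"]] - t0)
}

#' Run the full screening pipeline
#'
#' Executes the stages in protocol order - simulate (or load), harmonize,
#' screen in the requested modes, call tentative signals, rank and
#' prioritize, cluster the prioritized set - writing every stage artifact
#' under `out_dir` and returning a run manifest. Identical configuration and
#' seed give byte-identical outputs.
#'
#' @param config An `exposcan_pipeline_config`, or a path to a YAML/JSON file
#'   with arguments for [pipeline_config()].
#' @param out_dir Output directory.
#' @param cohort,catalog Optional pre-existing cohort/catalog data frames (or
#'   CSV paths); when absent a cohort is simulated.
#' @return The manifest (class `exposcan_manifest`), invisibly; all stage
#'   outputs are files under `out_dir`.
#' @export
run_pipeline <- function(config = demo_pipeline_config(), out_dir,
                         cohort = NULL, catalog = NULL) {
  if (is.character(config)) config <- load_pipeline_config(config)
  if (!inherits(config, "exposcan_pipeline_config"))
    stop("config must be an exposcan_pipeline_config or a file path",
         call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("exposcan")),
                   seed = config$seed, stages = list(), files = list(),
                   counts = list())
  truth <- NULL

  if (is.null(cohort)) {
    st <- stage_time(generate_cohort(config$simulate))
    sim <- st$value
    cohort <- sim$cohort; catalog <- sim$catalog; truth <- sim$truth
    write_cohort_sim(sim, out_dir)
    manifest$stages$simulate <- st$seconds
  } else {
    if (is.character(cohort)) cohort <- read_cohort(cohort)
    if (is.character(catalog)) catalog <- read_catalog(catalog)
  }
  manifest$counts$input_visits <- nrow(cohort)
  manifest$counts$input_exposures <- nrow(catalog)

  st <- stage_time(harmonize_cohort(cohort, catalog, config$harmonize))
  harm <- st$value
  manifest$stages$harmonize <- st$seconds
  manifest$counts$clean_visits <- nrow(harm$table)
  manifest$counts$clean_exposures <- nrow(harm$catalog)
  utils::write.csv(harm$table, file.path(out_dir, "clean.csv"),
                   row.names = FALSE)
  write_exclusion_log(harm$log, file.path(out_dir, "exclusion_log.json"),
                      file.path(out_dir, "exclusion_log.txt"))

  traits <- intersect(config$traits, names(harm$table))
  results <- list()
  if ("average" %in% config$modes) {
    st <- stage_time(screen_average(harm$table, harm$catalog, traits))
    results$average <- st$value
    manifest$stages$screen_average <- st$seconds
    write_screen_results(st$value, file.path(out_dir, "results_average.csv"))
  }
  if ("change" %in% config$modes) {
    st <- stage_time(screen_change(harm$table, harm$catalog, traits,
                                   config$target_years,
                                   config$tolerance_years))
    results$change <- st$value
    manifest$stages$screen_change <- st$seconds
    write_screen_results(st$value, file.path(out_dir, "results_change.csv"))
  }
  all_results <- do.call(rbind, results)

  signals <- call_signals(all_results, config$alpha)
  manifest$counts$tentative_signals <- sum(signals$tentative)
  utils::write.csv(signals, file.path(out_dir, "signals.csv"),
                   row.names = FALSE)

  top_sets <- rank_and_select(signals, config$top_k)
  report <- prioritize(top_sets, config$min_traits, harm$catalog)
  manifest$counts$prioritized <- nrow(report$prioritized)
  utils::write.csv(report$candidates, file.path(out_dir, "priority.csv"),
                   row.names = FALSE)

  cluster_out <- NULL
  pri_vars <- intersect(unique(report$prioritized$variable),
                        names(harm$table))
  if (length(pri_vars) >= 2) {
    R <- correlation_matrix(harm$table, pri_vars)
    dendro <- hcluster(R, k = config$cluster_groups)
    cluster_out <- list(variables = pri_vars,
                        clusters = as.list(dendro$clusters %||% setNames(
                          rep(1L, 0), character(0))),
                        leaf_order = dendro$labels[dendro$order],
                        heights = dendro$heights)
    utils::write.csv(as.data.frame(R),
                     file.path(out_dir, "priority_correlations.csv"))
    if (requireNamespace("ape", quietly = TRUE))
      dendrogram_newick(dendro, file.path(out_dir, "priority_dendrogram.nwk"))
  }
  jsonlite::write_json(
    list(prioritized = report$prioritized, candidates = report$candidates,
         min_traits = report$min_traits, clustering = cluster_out),
    file.path(out_dir, "priority.json"), auto_unbox = TRUE, digits = NA)

  write_report_md(file.path(out_dir, "report.md"), signals, report,
                  manifest, config)

  files <- list.files(out_dir, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest$files <- as.list(tools::md5sum(files))
  manifest$config <- config_snapshot(config)
  class(manifest) <- "exposcan_manifest"
  jsonlite::write_json(unclass(manifest),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}

config_snapshot <- function(config) {
  snap <- unclass(config)
  snap$simulate <- unclass(snap$simulate)
  snap$simulate$trait_model <- NULL
  snap$harmonize <- unclass(snap$harmonize)
  snap
}

#' @rdname run_pipeline
#' @param path YAML or JSON file of [pipeline_config()] arguments.
#' @export
load_pipeline_config <- function(path) {
  args <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package", call. = FALSE)
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(args$simulate))
    args$simulate <- do.call(generator_config, args$simulate)
  if (!is.null(args$harmonize))
    args$harmonize <- do.call(harmonize_config, args$harmonize)
  do.call(pipeline_config, args)
}

#' @export
print.exposcan_manifest <- function(x, ...) {
  cat("exposcan run manifest\n")
  cat(sprintf("  seed: %d, package %s\n", x$seed, x$package_version))
  for (s in names(x$stages))
    cat(sprintf("  stage %-16s %.2fs\n", s, x$stages[[s]]))
  for (cname in names(x$counts))
    cat(sprintf("  %-22s %d\n", cname, x$counts[[cname]]))
  invisible(x)
}

write_report_md <- function(path, signals, report, manifest, config) {
  con <- file(path, "w"); on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("# Exposome screen report")
  w("")
  w("- seed: %d", manifest$seed)
  w("- visits analysed: %d (of %d input)",
    manifest$counts$clean_visits, manifest$counts$input_visits)
  w("- exposures analysed: %d (of %d input)",
    manifest$counts$clean_exposures, manifest$counts$input_exposures)
  w("- tentative signals (FDR < %.3g): %d", config$alpha,
    manifest$counts$tentative_signals)
  w("")
  w("## Tentative signals per trait and category")
  w("")
  sig <- signals[signals$tentative, , drop = FALSE]
  if (!nrow(sig)) w("(none)")
  else {
    counts <- stats::aggregate(list(n = sig$p),
                               by = list(mode = sig$mode, trait = sig$trait,
                                         category = sig$category),
                               FUN = length)
    w("| mode | trait | category | signals |")
    w("|---|---|---|---|")
    for (i in seq_len(nrow(counts)))
      w("| %s | %s | %s | %d |", counts$mode[i], counts$trait[i],
        counts$category[i], counts$n[i])
  }
  w("")
  w("## Prioritized modifiable exposures (top-ranked in >= %d traits)",
    report$min_traits)
  w("")
  if (!nrow(report$candidates)) w("(none)")
  else {
    w("| mode | variable | category | traits | status |")
    w("|---|---|---|---|---|")
    for (i in seq_len(nrow(report$candidates))) {
      cd <- report$candidates[i, ]
      w("| %s | %s | %s | %d | %s |", cd$mode, cd$variable, cd$category,
        cd$n_traits, if (cd$modifiable) "prioritized" else cd$reason)
    }
  }
  invisible(path)
}
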