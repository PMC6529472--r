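#' Run a simulate-analyze-report pipeline from a configuration
#'
#' Executes any ordered subset of the four analysis stages on synthetic
#' inputs generated with per-stage child seeds derived from the global seed.
#' Each stage writes its result files into `out_dir`; a manifest records
#' every file with an MD5 checksum, so identical configurations and seeds
#' produce identical manifests for the deterministic artifacts.
#'
#' @param config Either a path to a YAML file or a list with elements
#'   `stages` (character subset of `"stretcher"`, `"migration"`,
#'   `"invasion"`, `"expression"`), `seed` (integer), `out_dir`, and
#'   optional per-stage parameter blocks (`stretcher = list(n_cells = ...,
#'   effect = ..., n_bootstrap = ...)`, `migration = list(n_cells, speed_ratio)`,
#'   `invasion = list(n_cells, invaded_fraction)`,
#'   `expression = list(n_genes, de_fraction, effect_log2fc)`).
#' @return An object of class `report_bundle`: per-stage results, the list
#'   of written files, warnings, and the manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  stages <- config$stages %||% c("stretcher", "migration", "invasion", "expression")
  known <- c("stretcher", "migration", "invasion", "expression")
  bad <- setdiff(stages, known)
  if (length(bad) > 0) {
    stop("unknown stage name(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  for (p in unlist(config$inputs)) {
    if (!file.exists(p)) stop("input path does not exist: ", p, call. = FALSE)
  }
  seed <- config$seed %||% 1L
  out_dir <- config$out_dir %||% tempfile("mechpheno_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  files <- character(0)
  warns <- list()
  note <- function(stage, msg) {
    warns[[length(warns) + 1L]] <<- list(stage = stage, message = msg)
  }

  run_one <- function(stage) {
    pars <- config[[stage]] %||% list()
    switch(stage,
      stretcher = {
        prm <- creep_params()
        pro <- stretch_protocol()
        n <- pars$n_cells %||% 300
        eff <- pars$effect %||% 34
        B <- pars$n_bootstrap %||% 1000
        ctrl <- simulate_creep_population(prm, pro, n, NULL,
                                          derive_seed(seed, 11L))
        trt <- simulate_creep_population(prm, pro, n, eff,
                                         derive_seed(seed, 12L))
        cmp <- compare_rigidity(ctrl$curves, trt$curves, n_bootstrap = B,
                                seed = derive_seed(seed, 13L))
        f1 <- file.path(out_dir, "stretcher_control_curve.csv")
        f2 <- file.path(out_dir, "stretcher_treated_curve.csv")
        f3 <- file.path(out_dir, "stretcher_comparison.json")
        write_bootstrap_curve_csv(cmp$curve_control, f1)
        write_bootstrap_curve_csv(cmp$curve_treated, f2)
        jsonlite::write_json(
          list(epsilon_max_control = cmp$epsilon_max_control,
               epsilon_max_treated = cmp$epsilon_max_treated,
               percent_reduction = cmp$percent_reduction,
               mw_p_value = cmp$mw_p_value,
               planted_effect_percent = eff, n_cells = n, seed = seed),
          f3, auto_unbox = TRUE, digits = NA)
        files <<- c(files, f1, f2, f3)
        results$stretcher <<- cmp
      },
      migration = {
        n <- pars$n_cells %||% 300
        ratio <- pars$speed_ratio %||% 1.5
        ctrl <- simulate_tracks(n, mean_speed = 20, persistence_time = 2,
                                dropout_hazard = 0.02,
                                seed = derive_seed(seed, 21L))
        trt <- simulate_tracks(n, mean_speed = 20 * ratio, persistence_time = 4,
                               dropout_hazard = 0.02,
                               seed = derive_seed(seed, 22L))
        mc <- track_metrics(ctrl$tracks)
        mt <- track_metrics(trt$tracks)
        cmp <- compare_migration(mc, mt)
        f1 <- file.path(out_dir, "migration_metrics_control.tsv")
        f2 <- file.path(out_dir, "migration_metrics_treated.tsv")
        f3 <- file.path(out_dir, "migration_summary.json")
        write.table(mc, f1, sep = "\t", quote = FALSE, row.names = FALSE)
        write.table(mt, f2, sep = "\t", quote = FALSE, row.names = FALSE)
        box <- function(v) unclass(summarize_condition(v, "p5p95"))
        jsonlite::write_json(
          list(comparison = cmp,
               box_speed_control = box(mc$speed),
               box_speed_treated = box(mt$speed),
               box_persistence_control = box(mc$persistence),
               box_persistence_treated = box(mt$persistence)),
          f3, auto_unbox = TRUE, digits = NA, dataframe = "rows")
        files <<- c(files, f1, f2, f3)
        results$migration <<- cmp
      },
      invasion = {
        n <- pars$n_cells %||% 500
        f <- pars$invaded_fraction %||% 0.3
        sim <- simulate_invasion_spots(n, invaded_fraction = f,
                                       seed = derive_seed(seed, 31L))
        summ <- invasion_summary(sim$spots,
                                 z_threshold = sim$truth$invasion_front)
        f1 <- file.path(out_dir, "invasion_spots.tsv")
        f2 <- file.path(out_dir, "invasion_summary.json")
        write_spots_tsv(sim$spots, f1)
        jsonlite::write_json(
          list(n_total = summ$n_total, n_invaded = summ$n_invaded,
               percent_invaded = summ$percent_invaded,
               z_threshold = summ$z_threshold,
               depth_histogram = list(breaks = summ$breaks,
                                      counts = summ$counts)),
          f2, auto_unbox = TRUE, digits = NA)
        files <<- c(files, f1, f2)
        results$invasion <<- summ
      },
      expression = {
        n <- pars$n_genes %||% 1000
        sim <- simulate_expression_timecourse(
          n, de_fraction = pars$de_fraction %||% 0.05,
          effect_log2fc = pars$effect_log2fc %||% 2,
          seed = derive_seed(seed, 41L))
        fc <- gp_smooth_timecourse(fold_change_matrix(sim$expr))
        de <- call_differential_genes(fc, pars$log2fc_threshold %||% 1)
        universe <- rownames(sim$expr$values)
        set <- pars$gene_set %||% list(
          name = "synthetic_mechanics",
          members = universe[sim$truth$is_de | seq_along(universe) %% 7 == 0]
        )
        enr_up <- hypergeometric_enrichment(set, de$up, universe, "up")
        enr_down <- hypergeometric_enrichment(set, de$down, universe, "down")
        f1 <- file.path(out_dir, "expression_de_genes.json")
        f2 <- file.path(out_dir, "expression_enrichment.json")
        jsonlite::write_json(de, f1, auto_unbox = TRUE, digits = NA)
        jsonlite::write_json(list(up = unclass(enr_up), down = unclass(enr_down)),
                             f2, auto_unbox = TRUE, digits = NA)
        files <<- c(files, f1, f2)
        results$expression <<- list(de = de, up = enr_up, down = enr_down)
      }
    )
  }

  for (stage in stages) {
    withCallingHandlers(
      run_one(stage),
      warning = function(w) {
        note(stage, conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    )
  }

  manifest <- data.frame(
    file = basename(files),
    md5 = unname(tools::md5sum(files)),
    stringsAsFactors = FALSE
  )
  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(
    list(package_version = as.character(utils::packageVersion("mechpheno")),
         seed = seed, stages = stages, files = manifest,
         warnings = warns),
    mf, auto_unbox = TRUE, dataframe = "rows")
  structure(
    list(stages = stages, results = results, files = c(files, mf),
         manifest = manifest, warnings = warns, out_dir = out_dir,
         seed = seed),
    class = "report_bundle"
  )
}

#' Write a human-readable summary of a pipeline run
#'
#' One section per executed stage with its headline numbers (maximum
#' strains and percent reduction, median speed and persistence, percent
#' invaded, enrichment fractions and p-values); skipped stages are noted in
#' the footer and warnings are reproduced verbatim.
#'
#' @param bundle A `report_bundle` from [run_pipeline()].
#' @param path Optional output path; when `NULL` the report is returned
#'   only.
#' @return The report as a character vector of lines, invisibly if written.
#' @export
write_report <- function(bundle, path = NULL) {
  stopifnot(inherits(bundle, "report_bundle"))
  if (length(bundle$results) == 0) stop("empty bundle", call. = FALSE)
  lines <- c("mechpheno pipeline report",
             sprintf("seed: %d", bundle$seed), "")
  if ("stretcher" %in% names(bundle$results)) {
    x <- bundle$results$stretcher
    lines <- c(lines, "== Optical stretcher rigidity ==",
               sprintf("eps_max control: %.4f", x$epsilon_max_control),
               sprintf("eps_max treated: %.4f", x$epsilon_max_treated),
               sprintf("percent reduction in maximum strain: %.1f%%",
                       x$percent_reduction),
               sprintf("Mann-Whitney p: %.3g", x$mw_p_value), "")
  }
  if ("migration" %in% names(bundle$results)) {
    x <- bundle$results$migration
    for (i in seq_len(nrow(x))) {
      lines <- c(lines, sprintf(
        "== Migration: %s == median %.2f -> %.2f (%s), Mann-Whitney p = %.3g",
        x$metric[i], x$median_control[i], x$median_treated[i],
        x$direction[i], x$mw_p_value[i]))
    }
    lines <- c(lines, "")
  }
  if ("invasion" %in% names(bundle$results)) {
    x <- bundle$results$invasion
    lines <- c(lines, "== 3D invasion ==",
               sprintf("invaded: %d/%d (%.1f%%) below %g um",
                       x$n_invaded, x$n_total, x$percent_invaded,
                       x$z_threshold), "")
  }
  if ("expression" %in% names(bundle$results)) {
    x <- bundle$results$expression
    lines <- c(lines, "== Expression / enrichment ==",
               sprintf("up:   %d/%d set genes (%.0f%%), p = %.3g",
                       x$up$overlap, x$up$set_size, x$up$fraction_of_set,
                       x$up$p_value),
               sprintf("down: %d/%d set genes (%.0f%%), p = %.3g",
                       x$down$overlap, x$down$set_size,
                       x$down$fraction_of_set, x$down$p_value), "")
  }
  skipped <- setdiff(c("stretcher", "migration", "invasion", "expression"),
                     bundle$stages)
  if (length(skipped) > 0) {
    lines <- c(lines, sprintf("stages not run: %s",
                              paste(skipped, collapse = ", ")))
  }
  if (length(bundle$warnings) > 0) {
    lines <- c(lines, "warnings:")
    for (w in bundle$warnings) {
      lines <- c(lines, sprintf("  [%s] %s", w$stage, w$message))
    }
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
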