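# End-to-end pipeline: simulate -> prepare -> fit -> classify -> compare ->
# report.  Every output embeds the configuration hash and seed; re-running
# with the same pair reproduces the files byte for byte.

#' Configure a pipeline run
#'
#' @param out_dir output directory (created if needed).
#' @param generator a [generator_config()] (ignored when `cohort_csv` given).
#' @param cohort_csv optional path to an existing cohort CSV; when supplied
#'   the simulate stage is skipped and growth references must be supplied or
#'   derivable from `generator`.
#' @param criteria exclusion criteria, see [exclusion_criteria()].
#' @param guidelines character vector of comparator guidelines ("aap",
#'   "esc", "esh") and/or paths to custom guideline reference JSONs.
#' @param taus quantile grid for the reference fit.
#' @param ages integer ages of the emitted reference table.
#' @param percentiles percentiles of the emitted reference table.
#' @param seed overrides the generator seed when not NULL.
#' @param acceptable_detection detection-rate acceptability bound (percent).
#' @param compare_max_age named numeric: upper (exclusive) age bound per
#'   guideline for the percentile-vs-percentile comparison.  Defaults
#'   restrict the AAP comparison to < 13 years (its fixed-threshold branch
#'   starts at 13) and the others to < 16.
#' @return a `bp_pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            generator = generator_config(),
                            cohort_csv = NULL,
                            criteria = exclusion_criteria(),
                            guidelines = c("aap", "esc", "esh"),
                            taus = seq(0.05, 0.95, by = 0.05),
                            ages = 4:15,
                            percentiles = c(50, 90, 95),
                            seed = NULL,
                            acceptable_detection = 85,
                            compare_max_age = c(aap = 13, esc = 16, esh = 16)) {
  if (!is.null(seed)) generator$seed <- as.integer(seed)
  validate_generator_config(generator)
  structure(list(out_dir = out_dir, generator = generator,
                 cohort_csv = cohort_csv, criteria = criteria,
                 guidelines = guidelines, taus = taus, ages = ages,
                 percentiles = percentiles,
                 acceptable_detection = acceptable_detection,
                 compare_max_age = compare_max_age),
            class = "bp_pipeline_config")
}

pipeline_stages <- function() {
  c("simulate", "prepare", "fit", "classify", "compare", "report")
}

write_json_artifact <- function(obj, path, meta) {
  obj <- c(list(seed = meta$seed, config_hash = meta$hash), obj)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", force = TRUE)
  invisible(path)
}

write_csv_artifact <- function(df, path, meta) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(sprintf("# pedbpref seed=%s config_hash=%s", meta$seed, meta$hash), con)
  utils::write.csv(df, con, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Run the analysis pipeline
#'
#' Stages: `simulate` (synthetic cohort + growth references), `prepare`
#' (mean BP, BMI SDS, weight class, exclusions), `fit` (model comparison,
#' quantile fits, reference table), `classify` (per-guideline status),
#' `compare` (reclassification against the fitted reference as benchmark),
#' `report` (summary).  `steps = "all"` runs everything.  Errors propagate
#' with the failing stage's name.
#'
#' @param config a [pipeline_config()].
#' @param steps subset of stages, or "all".
#' @return invisibly, a list with the in-memory artifacts and file paths.
#' @export
run_pipeline <- function(config, steps = "all") {
  stopifnot(inherits(config, "bp_pipeline_config"))
  if (identical(steps, "all")) steps <- pipeline_stages()
  unknown <- setdiff(steps, pipeline_stages())
  if (length(unknown))
    bp_stop("bp_config_error", "unknown pipeline step(s): %s",
            paste(unknown, collapse = ", "))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  # hash the scientific configuration only: output location must not change it
  hashable <- unclass(config)
  hashable$out_dir <- NULL
  meta <- list(seed = config$generator$seed, hash = config_hash(hashable))
  art <- list(paths = character(0))
  path <- function(name) file.path(config$out_dir, name)
  stage <- function(name, expr) {
    bp_log("info", "stage %s", name)
    tryCatch(expr, error = function(e) {
      bp_stop("bp_data_error", "stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  # always derive the growth references (cheap, needed by most stages)
  height_ref <- make_growth_reference(config$generator, "height")
  bmi_ref <- make_growth_reference(config$generator, "bmi")

  if ("simulate" %in% steps) {
    art$cohort <- stage("simulate", generate_cohort(config$generator))
    write_cohort_csv(art$cohort, path("cohort.csv"))
    write_growth_csv(height_ref, path("growth_height.csv"))
    write_growth_csv(bmi_ref, path("growth_bmi.csv"))
    art$paths <- c(art$paths, path(c("cohort.csv", "growth_height.csv",
                                     "growth_bmi.csv")))
  }

  need_cohort <- function() {
    if (!is.null(art$cohort)) return(art$cohort)
    src <- config$cohort_csv %||% path("cohort.csv")
    read_cohort_csv(src)
  }

  if ("prepare" %in% steps) {
    art$prepared <- stage("prepare",
      prepare_cohort(need_cohort(), bmi_ref = bmi_ref,
                     criteria = config$criteria))
    log <- attr(art$prepared, "exclusion_log")
    write_csv_artifact(as.data.frame(art$prepared), path("prepared.csv"), meta)
    write_json_artifact(log, path("exclusion_log.json"), meta)
    art$paths <- c(art$paths, path(c("prepared.csv", "exclusion_log.json")))
  }

  analysis_rows <- function() {
    p <- art$prepared
    if (is.null(p)) bp_stop("bp_config_error", "prepare stage has not run")
    p[p$included & p$weight_class == "normal", , drop = FALSE]
  }

  if ("fit" %in% steps) {
    stage("fit", {
      rows <- analysis_rows()
      art$comparison <- compare_models(art$prepared, height_ref)
      fits <- list()
      for (outcome in c("sbp", "dbp")) for (s in c("female", "male"))
        fits[[outcome]][[s]] <-
          fit_quantile_set(rows, outcome, s, taus = config$taus)
      art$fits <- fits
      art$reference <- quantile_set_reference(fits, name = "fitted_cohort")
      art$table <- build_reference_table(fits, ages = config$ages,
                                         percentiles = config$percentiles)
      write_csv_artifact(as.data.frame(art$table), path("reference_table.csv"), meta)
      write_reference_model(art$reference, path("quantile_fits.json"))
      write_json_artifact(
        list(adj_r2 = art$comparison$adj_r2,
             height_gap = art$comparison$height_gap,
             detection = art$comparison$detection),
        path("model_comparison.json"), meta)
      art$paths <- c(art$paths, path(c("reference_table.csv",
                                       "quantile_fits.json",
                                       "model_comparison.json")))
    })
  }

  load_guideline <- function(g) {
    if (g %in% c("aap", "esc", "esh", "danish")) guideline(g)
    else if (grepl("^custom:", g)) {
      ref <- read_reference_model(sub("^custom:", "", g))
      guideline_spec(paste0("custom_", ref$name), ref)
    } else bp_stop("bp_config_error", "unknown guideline '%s'", g)
  }

  if ("classify" %in% steps || "compare" %in% steps) {
    stage("classify", {
      rows <- analysis_rows()
      if (is.null(art$reference))
        bp_stop("bp_config_error", "fit stage has not run")
      bench_g <- guideline_spec("fitted_benchmark", art$reference,
                                evaluation_age_window = c(config$generator$age_range[1],
                                                          config$generator$age_range[2]))
      art$benchmark_labels <- classify_bp(rows, bench_g)
      if ("classify" %in% steps)
        write_csv_artifact(art$benchmark_labels,
                           path("classification_benchmark.csv"), meta)
      art$guidelines <- lapply(stats::setNames(nm = config$guidelines), load_guideline)
      art$labels <- list()
      for (g in names(art$guidelines)) {
        lab <- classify_bp(rows, art$guidelines[[g]], growth_ref = height_ref)
        art$labels[[g]] <- lab
        if ("classify" %in% steps) {
          write_csv_artifact(lab, path(sprintf("classification_%s.csv", g)), meta)
          art$paths <- c(art$paths, path(sprintf("classification_%s.csv", g)))
        }
      }
      if ("classify" %in% steps)
        art$paths <- c(art$paths, path("classification_benchmark.csv"))
    })
  }

  if ("compare" %in% steps) {
    stage("compare", {
      rows <- analysis_rows()
      reports <- list()
      txt <- character(0)
      for (g in names(art$guidelines)) {
        max_age <- if (g %in% names(config$compare_max_age))
          config$compare_max_age[[g]] else 16
        keep <- rows$age_years < max_age
        bench <- art$benchmark_labels$status[keep]
        comp <- art$labels[[g]]$status[keep]
        rep <- concordance(bench, comp, sex = rows$sex[keep],
                           acceptable_detection = config$acceptable_detection)
        # model-vs-model 95th-percentile agreement per (age, sex) stratum
        ba_pairs <- do.call(rbind, lapply(c("female", "male"), function(s)
          diff_at_p95(art$reference, art$guidelines[[g]]$reference,
                      ages = config$ages[config$ages < max_age], sex = s)))
        ba <- bland_altman(ba_pairs$value_a, ba_pairs$value_b)
        reports[[g]] <- list(
          n = rep$table$n, counts = rep$table[c("a", "b", "c", "d")],
          detection_percent = rep$detection$percent,
          detection_percent_rounded = rep$detection$percent_rounded,
          fn_percent = rep$fn_percent, fp_percent = rep$fp_percent,
          by_sex = lapply(rep$by_sex, function(x) list(
            detection_percent_rounded = x$detection$percent_rounded)),
          threshold_pass = rep$threshold_pass,
          p95_diff = ba_pairs,
          bland_altman = unclass(ba))
        txt <- c(txt, sprintf("== %s (age < %g) ==", g, max_age),
                 utils::capture.output(print(rep)), "")
      }
      art$concordance <- reports
      write_json_artifact(list(guidelines = reports), path("concordance.json"), meta)
      writeLines(txt, path("concordance.txt"))
      art$paths <- c(art$paths, path(c("concordance.json", "concordance.txt")))
    })
  }

  if ("report" %in% steps) {
    stage("report", {
      summary <- list(
        n_children = if (!is.null(art$prepared)) nrow(art$prepared) else NA,
        n_included = if (!is.null(art$prepared))
          sum(art$prepared$included) else NA,
        n_analysis = if (!is.null(art$prepared)) nrow(analysis_rows()) else NA,
        guidelines = config$guidelines,
        stages_run = steps)
      write_json_artifact(summary, path("summary.json"), meta)
      art$paths <- c(art$paths, path("summary.json"))
    })
  }

  bp_log("info", "pipeline done (%d artifact files)", length(art$paths))
  invisible(art)
}
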