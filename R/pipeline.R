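study_table_columns <- c("subject", "position", "art", "focus", "setting",
                         "repetition", "section", "vri", "vitreous_mean",
                         "rpe_mean", "failed")

#' Write / read a study table as CSV
#'
#' The on-disk schema is the long-format table keyed by (subject, setting,
#' repetition, section) with the measurement columns `vri`,
#' `vitreous_mean`, `rpe_mean` and the `failed` flag. `read_study_table()`
#' validates the schema: required columns present, unique keys, and failed
#' rows carrying no measurement; violations raise an error naming the
#' column and row.
#'
#' @param table A study table.
#' @param path CSV path.
#' @return `write_study_table()` returns `path` invisibly;
#'   `read_study_table()` the validated data.frame. Round-trip stable.
#' @export
write_study_table <- function(table, path) {
  miss <- setdiff(study_table_columns, names(table))
  if (length(miss))
    stop("study table is missing column(s): ", paste(miss, collapse = ", "))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  write.csv(table[, study_table_columns], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_study_table
#' @export
read_study_table <- function(path) {
  if (!file.exists(path)) stop("study table not found: ", path)
  t <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(study_table_columns, names(t))
  if (length(miss))
    stop("study table is missing column(s): ", paste(miss, collapse = ", "))
  t$failed <- as.logical(t$failed)
  key <- sprintf("%s|sec%d", scan_id(t), t$section)
  if (anyDuplicated(key))
    stop("duplicate study-table key at row ", which(duplicated(key))[1])
  bad <- which(t$failed & !is.na(t$vri))
  if (length(bad))
    stop("schema violation in column 'vri' at row ", bad[1],
         ": failed rows must carry no measurement")
  t
}

#' Pipeline configuration
#'
#' Assembles and validates the configuration driving [run_pipeline()]:
#' protocol size, phantom geometry/optics (used when images are rendered),
#' setting means, variance components, failure probabilities, segmentation
#' config and explicit seeds (wall-clock seeding is deliberately not
#' supported; identical config implies identical output).
#'
#' @param n_subjects,repetitions,sections Design counts.
#' @param geometry,optics,segmentation Component configs.
#' @param mu_by_setting Named mean-VRI vector (see
#'   [reference_setting_means()]).
#' @param vc A [variance_components()].
#' @param failure_probs Named per-setting failure probabilities.
#' @param seed_study,seed_failures Integer seeds.
#' @param render Render phantom images and measure them with the VITAN
#'   stage (slow), instead of simulating VRI values directly?
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(n_subjects = 15L, repetitions = 3L,
                            sections = 7L,
                            geometry = phantom_geometry(),
                            optics = phantom_optics(),
                            segmentation = seg_config(),
                            mu_by_setting = reference_setting_means(),
                            vc = variance_components(),
                            failure_probs = default_failure_probs(),
                            seed_study = 20180126L, seed_failures = 46L,
                            render = FALSE) {
  stopifnot(inherits(geometry, "phantom_geometry"),
            inherits(optics, "phantom_optics"),
            inherits(segmentation, "seg_config"),
            inherits(vc, "variance_components"))
  if (!is.numeric(seed_study) || !is.numeric(seed_failures))
    stop("seeds must be explicit integers")
  structure(list(
    protocol = list(n_subjects = as.integer(n_subjects),
                    repetitions = as.integer(repetitions),
                    sections = as.integer(sections)),
    geometry = geometry, optics = optics, segmentation = segmentation,
    mu_by_setting = mu_by_setting, variance_components = vc,
    failure_probs = failure_probs,
    seeds = list(study = as.integer(seed_study),
                 failures = as.integer(seed_failures)),
    render = isTRUE(render)
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Any block omitted from the file keeps its [pipeline_config()] default.
#' Recognised top-level keys: `protocol` (n_subjects, repetitions,
#' sections), `geometry`, `optics` (focus maps as `offset: value`
#' mappings), `segmentation`, `mu_by_setting`, `variance_components`
#' (sigma_subject, sigma_scan, sigma_section), `failure_probs`, `seeds`
#' (study, failures), `render`.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$protocol)) {
    for (k in c("n_subjects", "repetitions", "sections"))
      if (!is.null(y$protocol[[k]])) args[[k]] <- y$protocol[[k]]
  }
  if (!is.null(y$geometry)) args$geometry <- do.call(phantom_geometry,
                                                     y$geometry)
  if (!is.null(y$optics)) {
    o <- y$optics
    for (k in c("focus_gain_map", "focus_blur_map"))
      if (!is.null(o[[k]])) o[[k]] <- unlist(o[[k]])
    args$optics <- do.call(phantom_optics, o)
  }
  if (!is.null(y$segmentation)) args$segmentation <- do.call(seg_config,
                                                             y$segmentation)
  if (!is.null(y$mu_by_setting)) args$mu_by_setting <- unlist(y$mu_by_setting)
  if (!is.null(y$variance_components))
    args$vc <- do.call(variance_components, y$variance_components)
  if (!is.null(y$failure_probs)) args$failure_probs <- unlist(y$failure_probs)
  if (!is.null(y$seeds)) {
    if (!is.null(y$seeds$study)) args$seed_study <- y$seeds$study
    if (!is.null(y$seeds$failures)) args$seed_failures <- y$seeds$failures
  }
  if (!is.null(y$render)) args$render <- y$render
  do.call(pipeline_config, args)
}

render_and_measure <- function(design, study, cfg) {
  # calibrate the phantom haze so the measured VRI tracks the simulated
  # target: vitreous_mean = target * rpe_mean / (focus gain x bottom gain)
  o <- cfg$optics
  rows <- lapply(seq_len(nrow(design)), function(i) {
    d <- design[i, ]
    target <- study$vri[i]
    setting <- acquisition_setting(d$position, d$art, d$focus)
    gain <- lookup_focus(o$focus_gain_map, d$focus, "gain") *
      if (d$position == "bottom") o$bottom_vitreous_gain else 1
    vit <- max(min(target * o$rpe_mean / gain, 0.99 * o$rpe_mean),
               o$background_mean * 1.01)
    oo <- o
    oo$vitreous_mean <- vit
    b <- make_phantom(cfg$geometry, oo, setting,
                      seed = keyed_seed(cfg$seeds$study, d$slot),
                      subject = d$subject, repetition = d$repetition,
                      section = d$section)
    b
  })
  analyse_batch(rows, cfg$segmentation)
}

#' Run the study pipeline end-to-end
#'
#' Simulate (or render and measure), inject failures, apply exclusions,
#' fit the mean and variability models per acquisition factor, and write
#' every artifact: study table CSV, mean-effects CSV, variability CSV,
#' pairwise-contrast CSV, box-plot JSON, failure summary CSV and a plain
#' text report listing seeds, exclusions and the analysis decisions in
#' effect. Identical config and seeds produce byte-identical outputs.
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a list with the in-memory results (`study`,
#'   `excluded`, `failure`, `mean_fits`, `variability`, `pairwise`,
#'   `boxplots`) and the written `paths`.
#' @export
run_pipeline <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    message("[octhaze] stage: ", name)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  design <- stage("enumerate",
                  enumerate_protocol(cfg$protocol$n_subjects,
                                     cfg$protocol$repetitions,
                                     cfg$protocol$sections))
  study <- stage("simulate",
                 generate_study(design, cfg$mu_by_setting,
                                cfg$variance_components,
                                seed = cfg$seeds$study,
                                rpe_mean = cfg$optics$rpe_mean))
  if (cfg$render)
    study <- stage("render+measure", {
      measured <- render_and_measure(design, study, cfg)
      measured$slot <- design$slot
      measured
    })
  study <- stage("inject_failures",
                 inject_failures(study, cfg$failure_probs,
                                 seed = cfg$seeds$failures))
  failure <- stage("failure_summary", failure_summary(design, study))
  excluded <- stage("apply_exclusions", apply_exclusions(study))

  factors <- c("art", "focus", "position")
  mean_fits <- stage("fit_mean_models",
                     setNames(lapply(factors, function(f)
                       fit_mean_model(excluded, f)), factors))
  var_tables <- stage("fit_variability",
                      setNames(lapply(factors, function(f)
                        variability_table(excluded, f)), factors))
  pw <- stage("pairwise",
              do.call(rbind, lapply(factors, function(f) {
                p <- pairwise_compare(mean_fits[[f]])
                p$factor <- f
                p
              })))
  box <- stage("boxplots",
               setNames(lapply(factors, function(f)
                 summarise_boxplots(excluded, f)), factors))

  paths <- list(
    study = file.path(out_dir, "study.csv"),
    mean_effects = file.path(out_dir, "mean_effects.csv"),
    variability = file.path(out_dir, "variability.csv"),
    pairwise = file.path(out_dir, "pairwise_contrasts.csv"),
    boxplots = file.path(out_dir, "boxplots.json"),
    failure = file.path(out_dir, "failure_summary.csv"),
    report = file.path(out_dir, "report.txt"))

  stage("write_outputs", {
    write_study_table(study, paths$study)
    me <- do.call(rbind, lapply(factors, function(f) {
      e <- mean_fits[[f]]$estimates
      e$factor <- f
      e$p_overall <- mean_fits[[f]]$p_overall
      e
    }))
    write.csv(me, paths$mean_effects, row.names = FALSE)
    write.csv(do.call(rbind, var_tables), paths$variability,
              row.names = FALSE)
    write.csv(pw, paths$pairwise, row.names = FALSE)
    jsonlite::write_json(box, paths$boxplots, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    write.csv(failure, paths$failure, row.names = FALSE)
    writeLines(format_report(cfg, failure, mean_fits, var_tables,
                             attr(excluded, "exclusion_log")),
               paths$report)
  })

  invisible(list(design = design, study = study, excluded = excluded,
                 failure = failure, mean_fits = mean_fits,
                 variability = var_tables, pairwise = pw, boxplots = box,
                 paths = paths))
}
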