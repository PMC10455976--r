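#' Default run configuration
#'
#' Single source of truth for an end-to-end run: synthetic-data generation
#' (or an input file), preprocessing, the three QDA pipelines, Monte Carlo
#' cross-validation, bootstrap robustness and the Mann-Whitney band check.
#' All randomness derives from one root seed (generator, splits, selection
#' and bootstrap use consecutive derived seeds).
#'
#' @param seed Root integer seed.
#' @param iterations Monte Carlo iterations.
#' @param models Character subset of `c("pca-qda", "spa-qda", "ga-qda")`.
#' @param ga A [ga_config()] used inside `"ga-qda"`.
#' @param pca_components Principal components retained by the PCA-QDA
#'   front-end (the study operating point is six).
#' @param spa_max_vars Longest SPA chain examined.
#' @param bootstrap_replicates Bootstrap replicates for the robustness
#'   estimate.
#' @param generator A [generator_config()] (its seed is overridden by the
#'   derived generator seed), or `NULL` with `input` set.
#' @param input Optional path to a wide-layout CSV to analyse instead of
#'   generating data.
#' @param preprocess A [preprocess_config()].
#' @return Nested list of class `run_config`.
#' @export
run_config <- function(seed = 1, iterations = 100,
                       models = c("pca-qda", "spa-qda", "ga-qda"),
                       ga = ga_config(generations = 30, population = 60,
                                      restarts = 2, min_vars = 2,
                                      max_vars = 25),
                       pca_components = 6,
                       spa_max_vars = 6, bootstrap_replicates = 200,
                       generator = generator_config(), input = NULL,
                       preprocess = preprocess_config()) {
  structure(list(seed = as.integer(seed), iterations = iterations,
                 models = models, ga = ga, pca_components = pca_components,
                 spa_max_vars = spa_max_vars,
                 bootstrap_replicates = bootstrap_replicates,
                 generator = generator, input = input,
                 preprocess = preprocess),
            class = "run_config")
}

model_spec_from_config <- function(cfg, method) {
  model_spec(method = method, n_components = cfg$pca_components,
             max_vars = cfg$spa_max_vars, ga = cfg$ga)
}

#' Run the full discrimination pipeline
#'
#' simulate/read -> preprocess -> replicate averaging -> {PCA-QDA, SPA-QDA,
#' GA-QDA} under Monte Carlo cross-validation -> figures of merit,
#' confusion matrices, selected-wavenumber tables, bootstrap robustness,
#' Mann-Whitney band confirmation, and a YAML run manifest. All artefacts
#' are CSV or plain text.
#'
#' @param cfg A [run_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a named list of the result objects
#'   (`dataset`, `mccv` per model, `robustness` per model, `selection` per
#'   selector, `mann_whitney`, `manifest`).
#' @export
run_pipeline <- function(cfg = run_config(), out_dir) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- list(generator = cfg$seed, splits = cfg$seed + 1L,
                bootstrap = cfg$seed + 2L)

  if (!is.null(cfg$input)) {
    ds_raw <- read_dataset(cfg$input, layout = "wide")
  } else {
    gen <- cfg$generator
    gen$seed <- seeds$generator
    sim <- generate_spectra(gen)
    ds_raw <- sim$dataset
  }
  ds <- average_replicates(preprocess_pipeline(ds_raw, cfg$preprocess))
  utils::write.csv(data.frame(class = names(class_counts(ds)),
                              n = class_counts(ds)),
                   file.path(out_dir, "class_counts.csv"), row.names = FALSE)

  plan <- mc_plan(iterations = cfg$iterations, seed = seeds$splits)
  results <- list(dataset = ds)
  fom_rows <- list()
  for (method in cfg$models) {
    spec <- model_spec_from_config(cfg, method)
    fit <- run_mccv(ds, spec, plan)
    results[[method]] <- fit
    tag <- gsub("-", "_", method)
    utils::write.csv(as.data.frame(fit$confusion),
                     file.path(out_dir, paste0("confusion_", tag, ".csv")))
    utils::write.csv(cbind(fit$fom, accuracy = fit$accuracy_mean),
                     file.path(out_dir, paste0("fom_", tag, ".csv")),
                     row.names = FALSE)
    rob <- bootstrap_misclassification(ds, spec,
                                       replicates = cfg$bootstrap_replicates,
                                       seed = seeds$bootstrap)
    results[[paste0("robustness_", tag)]] <- rob

    if (method != "pca-qda") {
      set.seed(seeds$splits + match(method, cfg$models))
      vars <- select_variables(ds$absorbance, as.character(ds$meta$class), spec)
      rep_tab <- selection_report(list(selected = vars, G = NA_real_),
                                  ds$wavenumbers)
      utils::write.csv(rep_tab,
                       file.path(out_dir, paste0("selected_", tag, ".csv")),
                       row.names = FALSE)
      results[[paste0("selection_", tag)]] <- rep_tab
      mw <- mann_whitney_bands(ds, rep_tab$index,
                               c("normal", "inflammatory"))
      utils::write.csv(mw,
                       file.path(out_dir, paste0("mann_whitney_", tag, ".csv")),
                       row.names = FALSE)
      results[[paste0("mann_whitney_", tag)]] <- mw
    }
  }
  rob_tab <- data.frame(
    model = cfg$models,
    misclassification_probability = vapply(cfg$models, function(m) {
      results[[paste0("robustness_", gsub("-", "_", m))]]$probability
    }, numeric(1)))
  utils::write.csv(rob_tab, file.path(out_dir, "robustness.csv"),
                   row.names = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("ftirqda")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    root_seed = cfg$seed, derived_seeds = seeds,
    iterations = cfg$iterations, models = cfg$models,
    hold_out_fraction = plan$hold_out_fraction,
    pca_components = cfg$pca_components,
    spa_max_vars = cfg$spa_max_vars,
    ga = unclass(cfg$ga)[c("generations", "population", "p_crossover",
                           "p_mutation", "restarts", "min_vars", "max_vars")],
    bootstrap_replicates = cfg$bootstrap_replicates,
    preprocess = unclass(cfg$preprocess),
    generator = if (is.null(cfg$input)) {
      g <- cfg$generator
      list(class_sizes = as.list(g$class_sizes), replicates = g$replicates,
           separation = g$separation, overlap = g$overlap,
           gain_sd = g$gain_sd, noise_sd = g$noise_sd,
           baseline_sd = g$baseline_sd,
           n_wavenumbers = length(g$axis))
    } else NULL,
    input = cfg$input,
    input_checksum = if (!is.null(cfg$input)) unname(tools::md5sum(cfg$input)) else NULL)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  results$manifest <- manifest
  invisible(results)
}

#' Human-readable summary of a pipeline run
#'
#' Renders the figures-of-merit block (one decimal, per class) and the
#' averaged confusion matrix (integer counts) for every model found in an
#' output directory written by [run_pipeline()].
#'
#' @param out_dir Directory holding `fom_*.csv` / `confusion_*.csv`.
#' @return Invisibly, the list of tables printed. Errors list any missing
#'   artefacts.
#' @export
pipeline_report <- function(out_dir) {
  fom_files <- list.files(out_dir, "^fom_.*\\.csv$", full.names = TRUE)
  if (!length(fom_files)) {
    ftir_error(paste("no figures-of-merit artefacts in", out_dir), "io_error")
  }
  out <- list()
  for (f in fom_files) {
    tag <- sub("^fom_(.*)\\.csv$", "\\1", basename(f))
    fom <- utils::read.csv(f)
    cmf <- file.path(out_dir, paste0("confusion_", tag, ".csv"))
    cat(sprintf("== %s (overall accuracy %.1f%%) ==\n",
                toupper(gsub("_", "-", tag)), fom$accuracy[1]))
    show <- fom[, c("class", "sensitivity", "specificity", "fscore")]
    show[-1] <- round(show[-1], 1)
    print(show, row.names = FALSE)
    if (file.exists(cmf)) {
      cm <- utils::read.csv(cmf, row.names = 1)
      cat("confusion (rows = true class):\n")
      print(cm)
    } else {
      cat("missing artefact:", cmf, "\n")
    }
    cat("\n")
    out[[tag]] <- fom
  }
  invisible(out)
}
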