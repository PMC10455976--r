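#' Monte Carlo cross-validation plan
#'
#' Repeated random hold-out validation: per iteration 20% of specimens
#' (rounded per class under stratification) are left out, by default over
#' 1000 iterations.
#'
#' @param hold_out_fraction Fraction held out per iteration, in (0, 1).
#' @param iterations Number of random splits (>= 1).
#' @param stratified Hold out `round(fraction * n_k)` specimens per class
#'   (default) rather than a single unstratified draw.
#' @param seed Integer seed; the whole split sequence is reproducible.
#' @return A list of class `mc_plan`.
#' @export
mc_plan <- function(hold_out_fraction = 0.2, iterations = 1000,
                    stratified = TRUE, seed = 1) {
  if (hold_out_fraction <= 0 || hold_out_fraction >= 1) {
    ftir_error("hold_out_fraction must lie in (0, 1)", "plan_error")
  }
  if (iterations < 1) ftir_error("iterations must be >= 1", "plan_error")
  structure(list(hold_out_fraction = hold_out_fraction,
                 iterations = iterations, stratified = stratified,
                 seed = as.integer(seed)),
            class = "mc_plan")
}

#' Generate Monte Carlo train/validation splits
#'
#' Stratified: each class contributes `round(fraction * n_k)` held-out
#' specimens (never the whole class; at least one training specimen is
#' retained). For the study class sizes 35/13/26/4/9/22 at fraction 0.2
#' the per-iteration held-out counts are 7/3/5/1/2/4.
#'
#' @param labels Class label vector (one entry per specimen).
#' @param plan An [mc_plan()].
#' @return List of length `plan$iterations`; each element has integer index
#'   vectors `train` and `validation` (disjoint, covering all specimens).
#' @export
make_splits <- function(labels, plan) {
  stopifnot(inherits(plan, "mc_plan"))
  labels <- as.character(labels)
  n <- length(labels)
  classes <- unique(labels)
  if (plan$stratified && any(table(labels) < 2)) {
    ftir_error("stratified splitting needs every class size >= 2", "plan_error")
  }
  hold <- if (plan$stratified) {
    vapply(classes, function(k) {
      nk <- sum(labels == k)
      min(round(plan$hold_out_fraction * nk), nk - 1L)
    }, numeric(1))
  } else {
    min(round(plan$hold_out_fraction * n), n - 1L)
  }
  if (sum(hold) < 1) {
    ftir_error("hold-out fraction leaves every validation set empty", "plan_error")
  }
  set.seed(plan$seed)
  lapply(seq_len(plan$iterations), function(i) {
    va <- if (plan$stratified) {
      unlist(lapply(seq_along(classes), function(j) {
        resample(which(labels == classes[j]), hold[j])
      }), use.names = FALSE)
    } else {
      sample.int(n, hold)
    }
    va <- sort(va)
    list(train = setdiff(seq_len(n), va), validation = va)
  })
}

#' Model specification for the QDA pipelines
#'
#' Bundles the front-end (PCA scores, SPA- or GA-selected wavenumbers) with
#' the QDA settings, for use by [run_mccv()], [bootstrap_misclassification()]
#' and [run_pipeline()].
#'
#' @param method `"pca-qda"`, `"spa-qda"` or `"ga-qda"`.
#' @param var_target,max_components PCA operating point (defaults: smallest
#'   component count reaching 93.5% cumulative variance, capped at 6).
#' @param n_components Optional fixed PCA component count (overrides the
#'   variance target).
#' @param max_vars Longest SPA chain examined (default 6).
#' @param ga A [ga_config()] for `"ga-qda"`.
#' @param covariance_mode Metric for the selection cost [risk_G()].
#' @param selection_fraction Fraction of the training block held out (by a
#'   stratified inner split) as the selection validation set.
#' @param selection_mode `"refit"` reruns selection/PCA inside every outer
#'   iteration (no information leakage, default); `"once"` selects a single
#'   time on the full dataset before the loop (legacy behaviour, kept to
#'   probe how leakage inflates figures of merit).
#' @param lambda,priors Passed to [fit_qda()].
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(method = c("pca-qda", "spa-qda", "ga-qda"),
                       var_target = 0.935, max_components = 6,
                       n_components = NULL, max_vars = 6,
                       ga = ga_config(), covariance_mode = "pooled",
                       selection_fraction = 0.3,
                       selection_mode = c("refit", "once"),
                       lambda = 0.5, priors = "empirical") {
  method <- match.arg(method)
  structure(list(method = method, var_target = var_target,
                 max_components = max_components, n_components = n_components,
                 max_vars = max_vars, ga = ga,
                 covariance_mode = covariance_mode,
                 selection_fraction = selection_fraction,
                 selection_mode = match.arg(selection_mode),
                 lambda = lambda, priors = priors),
            class = "model_spec")
}

# stratified inner split of a training block for the selection cost
inner_split <- function(labels, fraction) {
  labels <- as.character(labels)
  va <- unlist(lapply(unique(labels), function(k) {
    idx <- which(labels == k)
    nh <- min(max(round(fraction * length(idx)), 1L), length(idx) - 1L)
    resample(idx, nh)
  }), use.names = FALSE)
  list(train = setdiff(seq_along(labels), va), validation = sort(va))
}

# run selection (if any) on the training block; returns the selected
# variable indices, or NULL for pca-qda
select_variables <- function(X, y, spec) {
  if (spec$method == "pca-qda") return(NULL)
  sp <- inner_split(y, spec$selection_fraction)
  if (spec$method == "spa-qda") {
    spa_select(X[sp$train, , drop = FALSE], y[sp$train],
               X[sp$validation, , drop = FALSE], y[sp$validation],
               max_vars = spec$max_vars,
               covariance_mode = spec$covariance_mode)$selected
  } else {
    cfg <- spec$ga
    cfg$seed <- NULL # stay on the caller's RNG stream
    ga_select(X[sp$train, , drop = FALSE], y[sp$train],
              X[sp$validation, , drop = FALSE], y[sp$validation],
              cfg = cfg, covariance_mode = spec$covariance_mode)$selected
  }
}

# fit the full model on (trX, trY) and predict vaX; `variables` overrides
# refitting the selection step
fit_and_predict <- function(trX, trY, vaX, spec, variables = NULL) {
  if (spec$method == "pca-qda") {
    pca <- fit_pca(trX, n_components = spec$n_components,
                   var_target = spec$var_target,
                   max_components = spec$max_components)
    m <- fit_qda(pca_project(pca, trX), trY, priors = spec$priors,
                 lambda = spec$lambda)
    predict(m, pca_project(pca, vaX))$class
  } else {
    vars <- variables %||% select_variables(trX, trY, spec)
    m <- fit_qda(trX[, vars, drop = FALSE], trY, priors = spec$priors,
                 lambda = spec$lambda)
    predict(m, vaX[, vars, drop = FALSE])$class
  }
}

#' Monte Carlo cross-validation of a QDA pipeline
#'
#' For each iteration the full model (PCA or wavenumber selection included,
#' unless `selection_mode = "once"`) is refit on the training specimens and
#' the held-out specimens are predicted. Confusion counts are accumulated
#' over all iterations and rescaled so each class row sums to its specimen
#' count (largest-remainder integerisation); figures of merit are averaged
#' across iterations.
#'
#' @param ds Preprocessed per-specimen [spectral_dataset()] (see
#'   [average_replicates()]).
#' @param spec A [model_spec()].
#' @param plan An [mc_plan()].
#' @return Object of class `mccv_result`: `confusion` (rescaled integer
#'   matrix), `confusion_raw` (accumulated counts), `fom` (per-class mean
#'   and sd of sensitivity/specificity/F-score across iterations),
#'   `accuracy_mean`, `accuracy_sd`, `n_failures`, `plan`, `spec`.
#' @export
run_mccv <- function(ds, spec, plan) {
  stopifnot(inherits(ds, "spectral_dataset"), inherits(spec, "model_spec"),
            inherits(plan, "mc_plan"))
  X <- ds$absorbance
  y <- ds$meta$class
  lev <- levels(y)
  splits <- make_splits(as.character(y), plan) # also seeds the RNG stream
  fixed_vars <- NULL
  if (spec$method != "pca-qda" && spec$selection_mode == "once") {
    fixed_vars <- select_variables(X, as.character(y), spec)
  }

  K <- length(lev)
  cm <- matrix(0, K, K, dimnames = list(lev, lev))
  accs <- numeric(0)
  fom_iter <- array(NA_real_, c(plan$iterations, K, 3),
                    dimnames = list(NULL, lev, c("sens", "spec", "fscore")))
  failures <- 0
  for (i in seq_len(plan$iterations)) {
    sp <- splits[[i]]
    pred <- tryCatch(
      fit_and_predict(X[sp$train, , drop = FALSE],
                      as.character(y[sp$train]),
                      X[sp$validation, , drop = FALSE],
                      spec, variables = fixed_vars),
      error = function(e) NULL)
    if (is.null(pred)) {
      failures <- failures + 1
      if (failures > 0.05 * plan$iterations) {
        ftir_error("more than 5% of Monte Carlo iterations failed", "mccv_error")
      }
      next
    }
    truth <- factor(y[sp$validation], levels = lev)
    pred <- factor(as.character(pred), levels = lev)
    ci <- table(truth, pred)
    cm <- cm + ci
    f <- figures_of_merit(ci)
    accs <- c(accs, f$accuracy)
    fom_iter[i, , ] <- cbind(f$sensitivity, f$specificity, f$fscore)
  }

  counts <- class_counts(ds)[lev]
  cm_avg <- t(vapply(seq_len(K), function(k) {
    if (sum(cm[k, ]) == 0) return(rep(0L, K))
    largest_remainder(cm[k, ], counts[k])
  }, integer(K)))
  dimnames(cm_avg) <- dimnames(cm)

  slice <- function(k) matrix(fom_iter[, , k], ncol = K)
  fom <- data.frame(
    class = lev,
    sensitivity = colMeans(slice("sens"), na.rm = TRUE),
    specificity = colMeans(slice("spec"), na.rm = TRUE),
    fscore = colMeans(slice("fscore"), na.rm = TRUE),
    sensitivity_sd = apply(slice("sens"), 2, stats::sd, na.rm = TRUE),
    specificity_sd = apply(slice("spec"), 2, stats::sd, na.rm = TRUE),
    fscore_sd = apply(slice("fscore"), 2, stats::sd, na.rm = TRUE),
    row.names = NULL)

  structure(list(confusion = cm_avg, confusion_raw = cm, fom = fom,
                 accuracy_mean = mean(accs), accuracy_sd = stats::sd(accs),
                 n_failures = failures, selected = fixed_vars,
                 plan = plan, spec = spec),
            class = "mccv_result")
}

#' @export
print.mccv_result <- function(x, ...) {
  cat(sprintf("<mccv_result> %s, %d iterations, overall accuracy %.1f%% (sd %.1f)\n",
              x$spec$method, x$plan$iterations, x$accuracy_mean,
              x$accuracy_sd))
  print(x$confusion)
  print(x$fom, digits = 4)
  invisible(x)
}

# integerise `row` scaled to sum `target`, conserving the total exactly
largest_remainder <- function(row, target) {
  scaled <- row * target / sum(row)
  base <- floor(scaled)
  rem <- as.integer(round(target - sum(base)))
  if (rem > 0) {
    extra <- order(scaled - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Figures of merit from a confusion matrix
#'
#' One-vs-rest per class: sensitivity `TP / (TP + FN) * 100`, specificity
#' `TN / (TN + FP) * 100` and their harmonic-mean F-score; overall accuracy
#' `100 * trace / total`. Classes with an empty denominator are reported as
#' `NA` (undefined), not 0.
#'
#' @param cm Square count matrix, rows = true class, columns = predicted.
#' @return Object of class `figures_of_merit`: per-class `sensitivity`,
#'   `specificity`, `fscore` (all percent), `accuracy`, and the `tp`, `fn`,
#'   `fp`, `tn` counts.
#' @export
figures_of_merit <- function(cm) {
  cm <- as.matrix(unclass(cm))
  if (nrow(cm) != ncol(cm)) ftir_error("confusion matrix must be square", "format_error")
  total <- sum(cm)
  if (total <= 0) ftir_error("empty confusion matrix", "format_error")
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  tn <- total - tp - fn - fp
  sens <- ifelse(tp + fn > 0, 100 * tp / (tp + fn), NA_real_)
  spc <- ifelse(tn + fp > 0, 100 * tn / (tn + fp), NA_real_)
  structure(list(sensitivity = sens, specificity = spc,
                 fscore = fscore(sens, spc),
                 accuracy = 100 * sum(tp) / total,
                 tp = tp, fn = fn, fp = fp, tn = tn),
            class = "figures_of_merit")
}

#' @export
print.figures_of_merit <- function(x, ...) {
  df <- data.frame(sensitivity = x$sensitivity, specificity = x$specificity,
                   fscore = x$fscore)
  print(round(df, 1))
  cat(sprintf("overall accuracy: %.1f%%\n", x$accuracy))
  invisible(x)
}

#' Harmonic-mean F-score of sensitivity and specificity
#'
#' `F = 2 * SENS * SPEC / (SENS + SPEC)`, in percent. `fscore(s, s) = s`;
#' the degenerate case `SENS = SPEC = 0` is defined as 0 and flagged via
#' the `"degenerate"` attribute.
#'
#' @param sens,spec Sensitivity and specificity in percent (vectorised).
#' @return F-score in percent.
#' @export
fscore <- function(sens, spec) {
  out <- ifelse(is.na(sens) | is.na(spec), NA_real_,
                ifelse(sens + spec > 0, 2 * sens * spec / (sens + spec), 0))
  deg <- !is.na(sens) & !is.na(spec) & sens + spec == 0
  if (any(deg)) attr(out, "degenerate") <- which(deg)
  out
}

#' Bootstrap misclassification probability
#'
#' Out-of-bag robustness estimate: specimens are resampled with replacement
#' within each class, the model is refit on the bootstrap sample and the
#' out-of-bag specimens are predicted. Each specimen's misclassification
#' probability is the fraction of replicates (in which it was out-of-bag)
#' that misclassified it; the reported estimate is the mean over specimens.
#' Values above 0.5 indicate high model uncertainty in future predictions.
#'
#' @param ds Preprocessed per-specimen [spectral_dataset()].
#' @param spec A [model_spec()].
#' @param replicates Bootstrap replicates (>= 100 recommended).
#' @param seed Integer seed.
#' @return Object of class `robustness_estimate`: `probability` (the mean),
#'   `per_specimen`, `replicates`, `n_never_oob`, `seed`.
#' @export
bootstrap_misclassification <- function(ds, spec, replicates = 200, seed = 1) {
  stopifnot(inherits(ds, "spectral_dataset"), inherits(spec, "model_spec"))
  X <- ds$absorbance
  y <- as.character(ds$meta$class)
  n <- length(y)
  set.seed(seed)
  wrong <- times <- numeric(n)
  for (b in seq_len(replicates)) {
    boot <- unlist(lapply(unique(y), function(k) {
      idx <- which(y == k)
      idx[sample.int(length(idx), length(idx), replace = TRUE)]
    }), use.names = FALSE)
    oob <- setdiff(seq_len(n), unique(boot))
    if (!length(oob)) next
    pred <- tryCatch(
      fit_and_predict(X[boot, , drop = FALSE], y[boot],
                      X[oob, , drop = FALSE], spec),
      error = function(e) NULL)
    if (is.null(pred)) next
    hit <- as.character(pred) != y[oob]
    wrong[oob] <- wrong[oob] + hit
    times[oob] <- times[oob] + 1
  }
  never <- sum(times == 0)
  if (never > 0) {
    warning(sprintf("%d specimen(s) never out-of-bag; excluded", never))
  }
  per <- ifelse(times > 0, wrong / times, NA_real_)
  structure(list(probability = mean(per, na.rm = TRUE), per_specimen = per,
                 replicates = replicates, n_never_oob = never, seed = seed),
            class = "robustness_estimate")
}

#' @export
print.robustness_estimate <- function(x, ...) {
  cat(sprintf("<robustness_estimate> misclassification probability %.3f (%d bootstrap replicates)\n",
              x$probability, x$replicates))
  invisible(x)
}

#' Mann-Whitney confirmation of selected wavenumbers
#'
#' Two-tailed rank-sum test of the preprocessed absorbance at each selected
#' wavenumber between two tissue classes: exact null distribution when both
#' groups have at most 8 specimens (and no ties), normal approximation with
#' tie correction otherwise. Wavenumbers with p < 0.05 are flagged as
#' confirmed discriminators.
#'
#' @param ds Preprocessed per-specimen [spectral_dataset()].
#' @param variables Column indices of the wavenumbers to test.
#' @param class_pair Character vector of two class labels.
#' @param alpha Significance level for the flag (default 0.05).
#' @param adjust Optional p-value adjustment method passed to
#'   [stats::p.adjust()] (e.g. `"BH"`); default `"none"`.
#' @return Data frame with `wavenumber`, `p_value`, `significant`, and
#'   `degenerate` (both groups constant and equal, reported as p = 1).
#' @export
mann_whitney_bands <- function(ds, variables, class_pair, alpha = 0.05,
                               adjust = "none") {
  stopifnot(inherits(ds, "spectral_dataset"), length(class_pair) == 2)
  y <- as.character(ds$meta$class)
  ga <- ds$absorbance[y == class_pair[1], variables, drop = FALSE]
  gb <- ds$absorbance[y == class_pair[2], variables, drop = FALSE]
  if (nrow(ga) < 2 || nrow(gb) < 2) {
    ftir_error("both classes need at least 2 specimens", "plan_error")
  }
  p <- deg <- numeric(length(variables))
  for (j in seq_along(variables)) {
    a <- ga[, j]; b <- gb[, j]
    if (length(unique(c(a, b))) == 1) {
      p[j] <- 1; deg[j] <- 1
    } else {
      exact <- length(a) <= 8 && length(b) <= 8
      p[j] <- suppressWarnings(
        stats::wilcox.test(a, b, exact = exact, correct = TRUE)$p.value)
    }
  }
  p <- stats::p.adjust(p, method = adjust)
  data.frame(wavenumber = ds$wavenumbers[variables], p_value = p,
             significant = p < alpha, degenerate = as.logical(deg))
}
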