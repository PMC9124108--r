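#' Control parameters for [anfis_fs()]
#'
#' Collects the tunable parameters of the three stochastic stages with
#' their defaults.  Feature selection: `pack_size` wolves for `fs_iters`
#' iterations, fitness weight `alpha_weight` on wrapper accuracy (the
#' complement rewards short subsets), binarization `threshold`, and the
#' adaptive beta-hill-climbing controls `abhc_k`, `abhc_beta_rate`,
#' `abhc_inner`.  Classifier: `n_rules` fuzzy rules, consequents handled
#' per `mode` (`"hybrid"`: least-squares refit inside every objective
#' evaluation; `"full"`: searched jointly).  Tuning: `coa_pop` agents for
#' `coa_iters` iterations with chaotic reset value `chaotic_seed`.
#'
#' @param pack_size,fs_iters,alpha_weight,threshold grey wolf search, see
#'   [igwo_fs()].
#' @param abhc_k,abhc_beta_rate,abhc_inner local refinement, see
#'   [abhc_refine()].
#' @param cv_k internal wrapper cross-validation folds.
#' @param n_rules,mode classifier structure, see [anfis_init()] and
#'   [anfis_tune()].
#' @param coa_pop,coa_iters,chaotic_seed parameter tuning, see
#'   [coa_optimize()].
#' @return A list of class `"anfis_fs_control"`.
#' @export
anfis_fs_control <- function(pack_size = 20, fs_iters = 300,
                             alpha_weight = 0.9, threshold = 0.5,
                             abhc_k = 4, abhc_beta_rate = NULL,
                             abhc_inner = 50, cv_k = 3,
                             n_rules = 4, mode = c("hybrid", "full"),
                             coa_pop = 20, coa_iters = 40,
                             chaotic_seed = 0.7) {
  mode <- match.arg(mode)
  stopifnot(pack_size >= 4, fs_iters >= 0, alpha_weight >= 0,
            alpha_weight <= 1, threshold > 0, threshold < 1,
            abhc_k >= 1, n_rules >= 1, coa_pop >= 4, coa_iters >= 0,
            chaotic_seed > 0, chaotic_seed < 1)
  structure(as.list(environment()), class = "anfis_fs_control")
}

#' Fit a feature-selecting neuro-fuzzy classifier
#'
#' The full modelling pipeline on one training set: (1) gene-wise z-score
#' standardization, (2) grey wolf wrapper feature selection with adaptive
#' beta-hill-climbing refinement ([igwo_fs()]), (3) a Sugeno ANFIS
#' initialized by scatter partitioning on the selected genes
#' ([anfis_init()]), and (4) premise-parameter tuning by the chimp-style
#' optimizer with least-squares consequents ([anfis_tune()]).  Each stage
#' consumes its own RNG stream derived from the master seed
#' ([derive_seed()]), so the fit is fully reproducible.
#'
#' @param x an [expression_set()], or a samples-by-genes numeric matrix.
#' @param y 0/1 labels (ignored when `x` is an expression set).
#' @param control an [anfis_fs_control()] list.
#' @param normalize standardize genes before fitting (default `TRUE`; set
#'   `FALSE` when `x` is already standardized — the stored transform is
#'   then the identity).
#' @param seed master seed for the run.
#' @return An object of class `"anfis_fs"` with components `fs` (the
#'   `"igwo_fs"` search result), `model` (the tuned `"anfis"`), `selected`
#'   (gene ids), `center`/`scale` (stored standardization), `fitted.values`
#'   (training outputs), `labels`, `control`, `seed`, `call`.  Supports
#'   `print`, `summary`, `coef`, `predict`, `fitted`, `residuals`, `plot`.
#' @export
#' @examples
#' \donttest{
#' es <- synthetic_expression(40, 30, n_informative = 5, shift = 2, seed = 3)
#' fit <- anfis_fs(es, control = anfis_fs_control(fs_iters = 5,
#'                                                coa_iters = 5), seed = 1)
#' mean(predict(fit, es) == es$labels)
#' }
anfis_fs <- function(x, y = NULL, control = anfis_fs_control(),
                     normalize = TRUE, seed = 1) {
  cl <- match.call()
  if (!inherits(x, "expression_set")) {
    if (is.null(y)) stop_invalid("`y` is required when `x` is a matrix")
    x <- expression_set(as.matrix(x), y)
  }
  p <- ncol(x$values)
  if (normalize) {
    nx <- zscore_normalize(x)
    center <- attr(nx, "center"); scale <- attr(nx, "scale")
  } else {
    nx <- x
    center <- rep(0, p); scale <- rep(1, p)
  }
  fs <- igwo_fs(nx, pack_size = control$pack_size,
                max_iter = control$fs_iters,
                alpha_weight = control$alpha_weight,
                threshold = control$threshold, K = control$abhc_k,
                beta_rate = control$abhc_beta_rate,
                inner_iters = control$abhc_inner, cv_k = control$cv_k,
                seed = derive_seed(seed, "fs"))
  Xs <- nx$values[, fs$subset$mask, drop = FALSE]
  model <- anfis_init(Xs, nx$labels,
                      n_rules = min(control$n_rules, nrow(Xs)),
                      seed = derive_seed(seed, "init"))
  model <- anfis_tune(model, Xs, nx$labels, mode = control$mode,
                      population = control$coa_pop,
                      max_iter = control$coa_iters,
                      chaotic_seed = control$chaotic_seed,
                      seed = derive_seed(seed, "tune"))
  fitted <- anfis_forward(model, Xs)
  structure(list(fs = fs, model = model, selected = fs$selected,
                 mask = fs$subset$mask, center = center, scale = scale,
                 gene_ids = x$gene_ids, fitted.values = fitted,
                 labels = nx$labels, control = control, seed = seed,
                 call = cl),
            class = "anfis_fs")
}

#' @export
print.anfis_fs <- function(x, ...) {
  cat("Feature-selecting neuro-fuzzy classifier\n\nCall:\n")
  print(x$call)
  cat(sprintf("\nSelected genes: %d of %d\n", sum(x$mask), length(x$mask)))
  cat(sprintf("Rules: %d (%s consequents)\n", x$model$n_rules,
              x$control$mode))
  acc <- mean(predict_label(x$fitted.values) == x$labels)
  cat(sprintf("Training accuracy: %.4f\n", acc))
  invisible(x)
}

#' @export
summary.anfis_fs <- function(object, ...) {
  pred <- predict_label(object$fitted.values)
  cm <- confusion_matrix(object$labels, pred)
  out <- list(call = object$call, n_selected = sum(object$mask),
              n_genes = length(object$mask),
              fs_fitness = object$fs$subset$fitness,
              fs_quality = object$fs$subset$quality,
              train_mse = mean((object$fitted.values - object$labels)^2),
              train_report = macro_metrics(cm),
              selected = object$selected)
  class(out) <- "summary.anfis_fs"
  out
}

#' @export
print.summary.anfis_fs <- function(x, ...) {
  cat("Feature-selecting neuro-fuzzy classifier\n\nCall:\n")
  print(x$call)
  cat(sprintf("\nSelected %d of %d genes (subset fitness %.4f, wrapper quality %.4f)\n",
              x$n_selected, x$n_genes, x$fs_fitness, x$fs_quality))
  cat(sprintf("Training MSE: %.4f\n\nTraining ", x$train_mse))
  print(x$train_report)
  invisible(x)
}

#' @export
coef.anfis_fs <- function(object, ...) {
  m <- object$model
  list(centers = m$centers, widths = m$widths, shapes = m$shapes,
       consequent_slopes = m$coefs, consequent_bias = m$bias)
}

#' @export
fitted.anfis_fs <- function(object, ...) object$fitted.values

#' @export
residuals.anfis_fs <- function(object, ...)
  object$labels - object$fitted.values

#' Predict from a fitted feature-selecting classifier
#'
#' New samples are standardized with the training-set gene means/SDs,
#' restricted to the selected genes, and pushed through the tuned ANFIS.
#'
#' @param object an `"anfis_fs"` fit.
#' @param newdata an [expression_set()] or samples-by-genes matrix with the
#'   same gene columns as the training data.
#' @param type `"class"` (0/1 labels) or `"response"` (crisp output).
#' @param ... unused.
#' @export
predict.anfis_fs <- function(object, newdata,
                             type = c("class", "response"), ...) {
  type <- match.arg(type)
  X <- if (inherits(newdata, "expression_set")) newdata$values
       else as.matrix(newdata)
  if (ncol(X) != length(object$mask))
    stop_invalid("newdata has ", ncol(X), " genes, the fit used ",
                 length(object$mask))
  X <- sweep(X, 2L, object$center, "-")
  sc <- ifelse(object$scale > 0, object$scale, 1)
  X <- sweep(X, 2L, sc, "/")
  f <- anfis_forward(object$model, X[, object$mask, drop = FALSE])
  if (type == "response") f else predict_label(f)
}

#' @export
plot.anfis_fs <- function(x, ...) {
  op <- par(mfrow = c(1, 2)); on.exit(par(op))
  plot(seq_along(x$fs$history) - 1L, x$fs$history, type = "s",
       xlab = "iteration", ylab = "best subset fitness",
       main = "Feature selection")
  h <- attr(x$model, "history")
  plot(seq_along(h) - 1L, h, type = "s", xlab = "iteration",
       ylab = "best training MSE", main = "Parameter tuning")
  invisible(x)
}

#' @importFrom graphics par plot
NULL

#' Cross-validated or holdout evaluation of the full pipeline
#'
#' Runs the complete fit ([anfis_fs()]) inside a resampling protocol and
#' pools the test predictions into a single confusion matrix.  With
#' `protocol = "kfold"`, the model is refit on each training fold
#' (stratified folds, [stratified_kfold()]); with `"holdout"`, a single
#' stratified split is used.  By default the z-score standardization is fit
#' once on the full matrix before splitting (preprocessing-first; its mild
#' leakage is the conventional microarray practice); set
#' `normalize_per_fold = TRUE` to fit the transform on each training fold
#' only.
#'
#' @param ds an [expression_set()] (raw, unnormalized scale is fine).
#' @param protocol `"kfold"` or `"holdout"`.
#' @param folds number of folds for `"kfold"` (default 10).
#' @param test_fraction held-out fraction for `"holdout"` (default 0.3).
#' @param control an [anfis_fs_control()].
#' @param normalize_per_fold see Description.
#' @param fit_fun the per-fold fitting routine, by default [anfis_fs()].
#'   Any `function(train, control, normalize, seed)` returning either an
#'   object with a `predict(object, newdata)` method or a
#'   `function(newdata)` of raw (unnormalized) sample rows can be
#'   substituted, e.g. to benchmark a reference classifier under the same
#'   protocol.
#' @param seed master seed: fold assignment and every per-fold fit derive
#'   their streams from it.
#' @return A `"pipeline_eval"`: list with `report` (a `"metrics_report"`
#'   from the pooled confusion matrix), `cm`, `predictions` (data frame of
#'   sample, fold, truth, predicted), `protocol`, `control`, `seed`.
#' @export
evaluate_pipeline <- function(ds, protocol = c("kfold", "holdout"),
                              folds = 10, test_fraction = 0.3,
                              control = anfis_fs_control(),
                              normalize_per_fold = FALSE,
                              fit_fun = anfis_fs, seed = 1) {
  protocol <- match.arg(protocol)
  stopifnot(inherits(ds, "expression_set"))
  if (!normalize_per_fold) ds <- zscore_normalize(ds)
  split_seed <- derive_seed(seed, "split")
  test_sets <- if (protocol == "kfold")
    stratified_kfold(ds$labels, folds, split_seed)
  else list(stratified_holdout(ds$labels, test_fraction, split_seed)$test)
  truth <- integer(0); pred <- integer(0)
  sample_id <- character(0); fold_id <- integer(0)
  for (i in seq_along(test_sets)) {
    test_idx <- test_sets[[i]]
    train <- expression_set(ds$values[-test_idx, , drop = FALSE],
                            ds$labels[-test_idx],
                            gene_ids = ds$gene_ids,
                            sample_ids = ds$sample_ids[-test_idx])
    fit <- fit_fun(train, control = control,
                   normalize = normalize_per_fold,
                   seed = derive_seed(seed, paste0("fold-", i)))
    newX <- ds$values[test_idx, , drop = FALSE]
    p <- if (is.function(fit)) fit(newX) else predict(fit, newX)
    truth <- c(truth, ds$labels[test_idx])
    pred <- c(pred, p)
    sample_id <- c(sample_id, ds$sample_ids[test_idx])
    fold_id <- c(fold_id, rep(i, length(test_idx)))
  }
  cm <- confusion_matrix(truth, pred)
  structure(list(report = macro_metrics(cm), cm = cm,
                 predictions = data.frame(sample = sample_id,
                                          fold = fold_id, truth = truth,
                                          predicted = pred),
                 protocol = protocol, control = control, seed = seed),
            class = "pipeline_eval")
}

#' @export
print.pipeline_eval <- function(x, ...) {
  cat(sprintf("Pipeline evaluation (%s, %d test predictions)\n\n",
              x$protocol, nrow(x$predictions)))
  print(x$cm)
  cat("\n")
  print(x$report)
  invisible(x)
}

#' Run the full pipeline from a dataset file and write all artifacts
#'
#' Executes preprocess, feature selection, classifier training and the
#' evaluation protocol, then writes into `out_dir`: `selected_genes.tsv`
#' (the subset with position ranks), `model.json` (the tuned ANFIS),
#' `metrics.txt` / `metrics.json`, `fs_trace.tsv` and `coa_trace.tsv`
#' (convergence traces), `predictions.csv`, and `manifest.json` (full
#' configuration, master and derived stage seeds, package version).
#' Re-running with the same manifest configuration reproduces every output.
#'
#' @param data path to a delimited dataset ([read_expression()]) or an
#'   [expression_set()].
#' @param out_dir output directory (created if missing).
#' @param orientation,label,sep passed to [read_expression()].
#' @param protocol,folds,test_fraction,normalize_per_fold passed to
#'   [evaluate_pipeline()].
#' @param control an [anfis_fs_control()].
#' @param seed master seed.
#' @return (Invisibly) a list with the final full-data `fit`, the
#'   `evaluation`, and the `manifest`.
#' @export
run_pipeline <- function(data, out_dir, orientation = "samples-rows",
                         label = "class", sep = ",",
                         protocol = "kfold", folds = 10,
                         test_fraction = 0.3,
                         control = anfis_fs_control(),
                         normalize_per_fold = FALSE, seed = 1) {
  ds <- if (inherits(data, "expression_set")) data
        else read_expression(data, orientation, label, sep)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ev <- evaluate_pipeline(ds, protocol = protocol, folds = folds,
                          test_fraction = test_fraction, control = control,
                          normalize_per_fold = normalize_per_fold,
                          seed = seed)
  fit <- anfis_fs(ds, control = control, seed = derive_seed(seed, "final"))
  write_feature_subset(fit$fs, file.path(out_dir, "selected_genes.tsv"))
  write_anfis(fit$model, file.path(out_dir, "model.json"))
  write_metrics_report(ev$report, file.path(out_dir, "metrics"))
  write.table(data.frame(iteration = seq_along(fit$fs$history) - 1L,
                         best_fitness = fit$fs$history),
              file.path(out_dir, "fs_trace.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  h <- attr(fit$model, "history")
  write.table(data.frame(iteration = seq_along(h) - 1L,
                         best_mse = h,
                         f = c(NA, attr(fit$model, "f_trace"))),
              file.path(out_dir, "coa_trace.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.csv(ev$predictions, file.path(out_dir, "predictions.csv"),
            row.names = FALSE)
  manifest <- list(
    package = "anfisFS",
    version = as.character(utils::packageVersion("anfisFS")),
    data = if (is.character(data)) data else "<in-memory expression_set>",
    orientation = orientation, label = label,
    protocol = protocol, folds = folds, test_fraction = test_fraction,
    normalize_per_fold = normalize_per_fold,
    control = unclass(control), seed = seed,
    stage_seeds = list(split = derive_seed(seed, "split"),
                       final = derive_seed(seed, "final"),
                       fs = derive_seed(derive_seed(seed, "final"), "fs"),
                       init = derive_seed(derive_seed(seed, "final"), "init"),
                       tune = derive_seed(derive_seed(seed, "final"), "tune")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(fit = fit, evaluation = ev, manifest = manifest))
}
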