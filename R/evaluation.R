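# Classification accuracy P_A = 100 * N_C / N_T and K x K confusion
# matrices (rows = true class, columns = predicted class), plus the
# three-model comparison driver (1-D CNN vs 2-D CNN vs PLS-DA).

#' Evaluate a multiclass prediction
#'
#' Computes the percent classification accuracy `P_A = 100 * N_C / N_T`,
#' the K x K confusion matrix (rows are true classes, columns predicted)
#' and per-class accuracies.
#'
#' @param truth,predicted Equal-length integer label vectors with values
#'   in `1..K`.
#' @param n_classes Number of classes K.
#' @param class_names Optional K names for the classes (default
#'   `C1..CK`).
#' @return An `eval_report`: list with `accuracy` (percent), `n_correct`,
#'   `n_total`, `confusion`, `per_class_accuracy` and `class_names`.
#' @examples
#' evaluate(c(1, 1, 2, 2), c(1, 2, 2, 2), n_classes = 2)
#' @export
evaluate <- function(truth, predicted, n_classes,
                     class_names = paste0("C", seq_len(n_classes))) {
  if (length(truth) != length(predicted)) {
    abort("`truth` and `predicted` must have the same length.")
  }
  truth <- as.integer(truth); predicted <- as.integer(predicted)
  if (any(truth < 1L | truth > n_classes) ||
      any(predicted < 1L | predicted > n_classes)) {
    abort(sprintf("Labels must lie in 1..%d.", n_classes))
  }
  if (length(class_names) != n_classes) {
    abort("`class_names` must have one entry per class.")
  }
  cf <- table(factor(truth, levels = seq_len(n_classes)),
              factor(predicted, levels = seq_len(n_classes)))
  confusion <- matrix(as.integer(cf), n_classes, n_classes,
                      dimnames = list(true = class_names,
                                      predicted = class_names))
  n_correct <- sum(diag(confusion))
  n_total <- length(truth)
  per_class <- ifelse(rowSums(confusion) > 0,
                      100 * diag(confusion) / rowSums(confusion), NA_real_)
  structure(list(accuracy = 100 * n_correct / n_total,
                 n_correct = n_correct, n_total = n_total,
                 confusion = confusion,
                 per_class_accuracy = setNames(per_class, class_names),
                 class_names = class_names),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> accuracy %.2f%% (%d / %d correct), %d classes\n",
              x$accuracy, x$n_correct, x$n_total, length(x$class_names)))
  invisible(x)
}

#' @rdname evaluate
#' @param x An `eval_report`.
#' @param ... Unused.
#' @export
tidy.eval_report <- function(x, ...) {
  as_tibble(as.data.frame(as.table(x$confusion), stringsAsFactors = FALSE)) |>
    setNames(c("true", "predicted", "n")) |>
    as_tibble()
}

#' @rdname evaluate
#' @export
glance.eval_report <- function(x, ...) {
  tibble(accuracy = x$accuracy, n_correct = x$n_correct, n_total = x$n_total,
         n_classes = length(x$class_names))
}

#' @rdname evaluate
#' @param object An `eval_report`.
#' @export
autoplot.eval_report <- function(object, ...) {
  df <- tidy(object)
  df$true <- factor(df$true, levels = rev(object$class_names))
  df$predicted <- factor(df$predicted, levels = object$class_names)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2c7fb8") +
    ggplot2::labs(x = "Predicted class", y = "True class", fill = "Count",
                  title = sprintf("Confusion matrix (accuracy %.2f%%)",
                                  object$accuracy)) +
    ggplot2::theme_minimal()
}

#' Compare the 1-D CNN, 2-D CNN and PLS-DA on one dataset
#'
#' Trains the three classifiers on the training split of a preprocessed
#' dataset under one shared seed, evaluates each on the test split, and
#' returns their percent accuracies plus confusion matrices. The 2-D CNN
#' sees the spectra reshaped into `image_side x image_side` images; the
#' PLS-DA baseline sees the same spectral prefix (the
#' `image_side^2`-point feature segment).
#'
#' @param ds A preprocessed [spectra_dataset].
#' @param cnn1d_cfg Architecture for the 1-D CNN ([cnn1d_config()]).
#' @param lenet_cfg Architecture for the 2-D CNN ([lenet_config()]);
#'   its `input_side` fixes the image size and the feature segment.
#' @param plsda_ncomp Latent components for the PLS-DA baseline.
#' @param spec Shared [train_spec()].
#' @param monitor Early-stopping monitor, see [train_cnn1d()].
#' @return A `model_comparison`: `results` tibble (model, test accuracy)
#'   plus the three `eval_report`s and fitted objects.
#' @export
compare_models <- function(ds, cnn1d_cfg = cnn1d_config(),
                           lenet_cfg = lenet_config(),
                           plsda_ncomp = 7L, spec = train_spec(),
                           monitor = c("validation", "test")) {
  monitor <- match.arg(monitor)
  side <- lenet_cfg$input_side
  cnn1d_cfg$input_length <- n_points(ds)
  cnn1d_cfg$n_classes <- n_classes(ds)
  lenet_cfg$n_classes <- n_classes(ds)

  fit1 <- train_cnn1d(ds, cnn1d_cfg, spec = spec, monitor = monitor)
  fit2 <- train_lenet(ds, lenet_cfg, spec = spec, monitor = monitor)

  seg <- seq_len(side^2)
  tr <- ds$split == "train"
  fitp <- fit_plsda(ds$absorbance[tr, seg, drop = FALSE], ds$labels[tr],
                    n_components = plsda_ncomp)
  predp <- predict_plsda(fitp, ds$absorbance[!tr, seg, drop = FALSE])
  repp <- evaluate(ds$labels[!tr], predp, n_classes(ds), ds$class_names)

  reports <- list(`1D_CNN` = fit1$report, `2D_LeNet5` = fit2$report,
                  PLS_DA = repp)
  results <- tibble(
    model = names(reports),
    test_accuracy = vapply(reports, function(r) r$accuracy, numeric(1L)))
  structure(list(results = results, reports = reports,
                 fits = list(`1D_CNN` = fit1, `2D_LeNet5` = fit2,
                             PLS_DA = fitp)),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison>\n")
  print(x$results)
  invisible(x)
}

#' @rdname compare_models
#' @param x A `model_comparison`.
#' @param ... Unused.
#' @export
tidy.model_comparison <- function(x, ...) x$results

#' @rdname compare_models
#' @param object A `model_comparison`.
#' @export
autoplot.model_comparison <- function(object, ...) {
  ggplot2::ggplot(object$results,
                  ggplot2::aes(x = .data$model, y = .data$test_accuracy)) +
    ggplot2::geom_col(fill = "#2c7fb8", width = 0.6) +
    ggplot2::labs(x = NULL, y = "Test set accuracy (%)") +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}
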