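## Cross-validated discrimination of the fitted model.

#' Rank-based AUC (Mann-Whitney with ties averaged)
#'
#' @param score Numeric predictions.
#' @param label 0/1 outcomes.
#' @return Scalar AUC, or NA when only one class is present.
#' @export
auc_rank <- function(score, label) {
  stopifnot(length(score) == length(label))
  n1 <- sum(label == 1); n0 <- sum(label == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score, ties.method = "average")
  (sum(r[label == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cross-validated AUC of the occupancy-abundance model
#'
#' Partitions the plots into folds, refits the model on the training plots
#' of each fold, predicts the detection probability of each held-out plot
#' record, and computes the area under the ROC curve of the held-out
#' detections. Records whose (species, cell) pair has an
#' auxiliary-indicated absence are excluded from the AUC, to avoid
#' rewarding structurally trivial predictions. Folds whose held-out
#' outcomes are single-class are skipped with a warning.
#'
#' @param data As in [fit_abundance()].
#' @param n_folds Number of folds (>= 2); plots are partitioned at random.
#' @param seed Integer seed for the fold assignment.
#' @param model,covariates Passed to [fit_abundance()].
#' @return List with `mean` and `sd` of the per-fold AUCs, and the vector
#'   `auc` itself.
#' @export
crossvalidate_auc <- function(data, n_folds = 10, seed = 1,
                              model = "integrated", covariates = TRUE) {
  stopifnot(n_folds >= 2)
  det <- data$detections
  plots <- unique(det$plot)
  if (length(plots) < n_folds) stop("fewer plots than folds")
  set.seed(seed)
  fold <- sample(rep_len(seq_len(n_folds), length(plots)))
  names(fold) <- plots

  ## auxiliary-indicated absences, excluded from the AUC
  aux <- data$aux
  abs_key <- character(0)
  if (!is.null(aux) && nrow(aux)) {
    res <- validate_inputs(det, data$cells, aux)$aux
    abs_key <- paste(res$species[res$z == 0], res$cell[res$z == 0])
  }

  aucs <- numeric(0)
  for (k in seq_len(n_folds)) {
    hold <- det$plot %in% plots[fold == k]
    train <- data
    train$detections <- det[!hold, , drop = FALSE]
    fk <- fit_abundance(train, model = model, covariates = covariates,
                        se = FALSE)
    test <- det[hold, , drop = FALSE]
    keep <- !(paste(test$species, test$cell) %in% abs_key) &
      test$species %in% fk$species
    test <- test[keep, , drop = FALSE]
    p <- predict(fk, newdata = test, type = "detection")
    a <- auc_rank(p, test$y)
    if (is.na(a)) {
      warning(sprintf("fold %d held out a single outcome class; skipped", k))
      next
    }
    aucs <- c(aucs, a)
  }
  list(mean = mean(aucs), sd = sd(aucs), auc = aucs)
}
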