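#' Classification metrics from confusion counts
#'
#' Patient is the positive class: \code{sensitivity = TP/(TP+FN)} is the
#' proportion of patients classified correctly, \code{specificity =
#' TN/(TN+FP)} the proportion of controls classified correctly, \code{PPV =
#' TP/(TP+FP)}, \code{NPV = TN/(TN+FN)}, \code{accuracy =
#' (TP+TN)/total}.
#'
#' @param tp,fn,tn,fp confusion counts.
#' @return named list of the five proportions.
#' @examples
#' unlist(classifier_metrics(35, 8, 27, 16))  # accuracy 0.7209, ...
#' @export
classifier_metrics <- function(tp, fn, tn, fp) {
  list(accuracy = (tp + tn) / (tp + fn + tn + fp),
       sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp),
       ppv = if (tp + fp > 0) tp / (tp + fp) else NaN,
       npv = if (tn + fn > 0) tn / (tn + fn) else NaN)
}

# Rank-based AUC of decision values for the positive (+1) class.
auc_score <- function(decision, labels) {
  pos <- labels == 1
  np <- sum(pos); nc <- sum(!pos)
  if (np == 0 || nc == 0) return(NaN)
  r <- rank(decision)
  (sum(r[pos]) - np * (np + 1) / 2) / (np * nc)
}

# One linear-SVM fit; returns the weight vector, intercept and a function
# scoring new rows so that positive decision values favor the +1 class.
fit_linear_svm <- function(x, y, cost) {
  fit <- e1071::svm(x = x, y = factor(y, levels = c(1, -1)),
                    kernel = "linear", cost = cost, scale = FALSE)
  w <- drop(crossprod(fit$coefs, fit$SV))
  b <- -fit$rho
  # e1071 orients the decision function toward the first factor level
  # seen in the data; flip if that was -1.
  if (fit$labels[1] == 2L) { w <- -w; b <- -b }
  list(w = w, b = b)
}

#' Leave-one-out cross-validated linear SVM
#'
#' Holds out each subject in turn, trains a linear soft-margin SVM on the
#' rest (features standardized by the training fold's mean/SD by default),
#' and scores the held-out subject. Pooled held-out predictions give the
#' confusion counts and metrics; pooled decision values give the AUC; each
#' fold's weight vector is kept and aggregated into a discriminative-weight
#' table.
#'
#' @param features numeric matrix or data frame, subjects x features
#'   (no missing values).
#' @param labels +1 (patient) / -1 (control) per subject, at least 2 per
#'   class.
#' @param cost soft-margin cost parameter (default 1).
#' @param standardize standardize features by training-fold mean/SD.
#' @return an \code{sn_svm}: \code{predictions} (data frame with label,
#'   predicted label, decision value per subject), \code{confusion}
#'   (tp, fn, tn, fp), \code{metrics} (accuracy, sensitivity, specificity,
#'   ppv, npv, auc), \code{fold_weights} (folds x features, signed, on the
#'   standardized scale when \code{standardize}), \code{weight_table}
#'   (see \code{\link{aggregate_weights}}).
#' @export
loocv_svm <- function(features, labels, cost = 1, standardize = TRUE) {
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  labels <- as.numeric(labels)
  if (!all(labels %in% c(-1, 1))) stopf("labels must be +1/-1")
  if (anyNA(x)) stopf("features contain missing values")
  n <- nrow(x)
  if (length(labels) != n) stopf("labels length must match feature rows")
  if (sum(labels == 1) < 2 || sum(labels == -1) < 2)
    stopf("need at least 2 subjects per class")

  dv <- numeric(n)
  W <- matrix(NA_real_, n, ncol(x),
              dimnames = list(NULL, colnames(x)))
  for (k in seq_len(n)) {
    xtr <- x[-k, , drop = FALSE]; ytr <- labels[-k]
    if (length(unique(ytr)) < 2L)
      stopf("single-class training fold at subject %d", k)
    if (standardize) {
      mu <- colMeans(xtr)
      sdv <- apply(xtr, 2L, stats::sd)
      sdv[sdv == 0] <- 1
      xtr <- sweep(sweep(xtr, 2L, mu), 2L, sdv, "/")
      xte <- (x[k, ] - mu) / sdv
    } else xte <- x[k, ]
    fit <- fit_linear_svm(xtr, ytr, cost)
    W[k, ] <- fit$w
    dv[k] <- sum(fit$w * xte) + fit$b
  }
  pred <- ifelse(dv >= 0, 1, -1)
  tp <- sum(pred == 1 & labels == 1); fn <- sum(pred == -1 & labels == 1)
  tn <- sum(pred == -1 & labels == -1); fp <- sum(pred == 1 & labels == -1)
  metrics <- classifier_metrics(tp, fn, tn, fp)
  metrics$auc <- auc_score(dv, labels)
  structure(list(
    predictions = data.frame(label = labels, predicted = pred,
                             decision_value = dv),
    confusion = c(tp = tp, fn = fn, tn = tn, fp = fp),
    metrics = metrics, fold_weights = W,
    weight_table = aggregate_weights(W),
    cost = cost, standardize = standardize), class = "sn_svm")
}

#' Permutation significance of LOOCV classification metrics
#'
#' Re-runs the full leave-one-out procedure under random permutations of
#' the group labels and reports, for each metric,
#' \code{p = (1 + #\{null >= observed\}) / (N + 1)}.
#'
#' @inheritParams loocv_svm
#' @param n_permutations number of label permutations (default 5000).
#' @param seed integer seed for the permutation stream.
#' @return an \code{sn_svm_perm}: the observed \code{sn_svm} fit plus
#'   \code{permutation_p} (named per metric), \code{null_metrics}
#'   (permutations x metrics matrix) and \code{n_permutations}.
#' @export
svm_permutation_test <- function(features, labels, n_permutations = 5000L,
                                 cost = 1, standardize = TRUE, seed = 1L) {
  observed <- loocv_svm(features, labels, cost, standardize)
  obs <- unlist(observed$metrics)
  null_m <- with_seed(seed, {
    t(vapply(seq_len(n_permutations), function(b) {
      fit <- loocv_svm(features, sample(labels), cost, standardize)
      unlist(fit$metrics)
    }, obs))
  })
  p <- vapply(names(obs), function(m)
    (1 + sum(null_m[, m] >= obs[[m]], na.rm = TRUE)) / (n_permutations + 1),
    numeric(1))
  structure(list(observed = observed, permutation_p = p,
                 null_metrics = null_m,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed)),
            class = "sn_svm_perm")
}

#' Aggregate per-fold SVM weights into a discriminative-weight table
#'
#' A feature's discriminative weight is the average of the absolute value
#' of its SVM coefficient across all LOOCV folds; the sign-preserving mean
#' is kept alongside. Features whose mean absolute weight strictly exceeds
#' the column mean plus one sample SD (n - 1 denominator) are flagged as
#' highly contributing.
#'
#' @param fold_weights folds x features numeric matrix of signed weights.
#' @return an \code{sn_weight_table}: data frame with \code{feature},
#'   \code{mean_abs_weight}, \code{mean_signed_weight}, \code{rank}
#'   (1 = largest mean absolute weight), \code{selected}; attributes
#'   \code{threshold}, \code{mean}, \code{sd}.
#' @examples
#' aggregate_weights(matrix(c(1, -1, 0.2, 0.2), 2, 2))
#' @export
aggregate_weights <- function(fold_weights) {
  W <- as.matrix(fold_weights)
  if (nrow(W) < 1L) stopf("need at least one fold")
  if (anyNA(W)) stopf("inconsistent feature counts across folds")
  mean_abs <- colMeans(abs(W))
  mean_signed <- colMeans(W)
  mu <- mean(mean_abs); sdv <- stats::sd(mean_abs)
  if (is.na(sdv)) sdv <- 0
  thr <- mu + sdv
  nm <- colnames(W)
  if (is.null(nm)) nm <- sprintf("f%d", seq_along(mean_abs))
  out <- data.frame(feature = nm, mean_abs_weight = mean_abs,
                    mean_signed_weight = mean_signed,
                    rank = rank(-mean_abs, ties.method = "first"),
                    selected = mean_abs > thr,
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, class = c("sn_weight_table", "data.frame"),
            threshold = thr, mean = mu, sd = sdv)
}

#' Top-fraction edges by statistic
#'
#' Sorts edges by their t value (descending) and keeps the top
#' \code{floor(fraction * n)} of them — at least one when the list is
#' non-empty. Ties in t are broken deterministically by (i, j)
#' lexicographic order when index columns are present, otherwise by the
#' edge name.
#'
#' @param edge_stats data frame with a \code{t} column, optionally
#'   \code{i}/\code{j} index columns and an \code{edge} label column.
#' @param fraction proportion in (0, 1] (default 0.20).
#' @return the retained rows of \code{edge_stats}, ordered by descending t.
#' @export
top_fraction_edges <- function(edge_stats, fraction = 0.20) {
  if (fraction <= 0 || fraction > 1) stopf("fraction must be in (0, 1]")
  edge_stats <- as.data.frame(edge_stats)
  n <- nrow(edge_stats)
  if (n == 0L) return(edge_stats)
  tie <- if (all(c("i", "j") %in% names(edge_stats)))
    order(edge_stats$i, edge_stats$j) else seq_len(n)
  ord <- order(-edge_stats$t, tie)
  keep <- max(1L, floor(fraction * n))
  edge_stats[ord[seq_len(keep)], , drop = FALSE]
}

#' @export
print.sn_svm <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(paste0("LOOCV linear SVM (cost %g): accuracy %.2f%%, ",
                     "sensitivity %.2f%%, specificity %.2f%%,\n",
                     "  PPV %.2f%%, NPV %.2f%%, AUC %.4f\n"),
              x$cost, 100 * m$accuracy, 100 * m$sensitivity,
              100 * m$specificity, 100 * m$ppv, 100 * m$npv, m$auc))
  cat(sprintf("Confusion (patient positive): TP %d, FN %d, TN %d, FP %d\n",
              x$confusion["tp"], x$confusion["fn"], x$confusion["tn"],
              x$confusion["fp"]))
  invisible(x)
}

#' @export
print.sn_svm_perm <- function(x, ...) {
  print(x$observed)
  cat(sprintf("Permutation p (%d permutations):\n", x$n_permutations))
  print(round(x$permutation_p, 4))
  invisible(x)
}

#' @export
print.sn_weight_table <- function(x, digits = 3, ...) {
  cat(sprintf("Discriminative weights: mean %.3f, SD %.3f, threshold %.3f\n",
              attr(x, "mean"), attr(x, "sd"), attr(x, "threshold")))
  df <- as.data.frame(x)
  df <- df[order(df$rank), ]
  df$mean_abs_weight <- round(df$mean_abs_weight, digits)
  df$mean_signed_weight <- round(df$mean_signed_weight, digits)
  print.data.frame(df, row.names = FALSE, ...)
  invisible(x)
}

#' @export
plot.sn_svm <- function(x, ...) {
  lab <- x$predictions$label
  dv <- x$predictions$decision_value
  thr <- sort(unique(c(-Inf, dv, Inf)), decreasing = TRUE)
  tpr <- vapply(thr, function(s) mean(dv[lab == 1] >= s), numeric(1))
  fpr <- vapply(thr, function(s) mean(dv[lab == -1] >= s), numeric(1))
  graphics::plot(fpr, tpr, type = "s", xlab = "1 - specificity",
                 ylab = "sensitivity",
                 main = sprintf("LOOCV ROC (AUC = %.3f)", x$metrics$auc),
                 ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}
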