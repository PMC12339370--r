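# Stress/control classification from marker-set expression: SVM with
# leave-one-out cross-validation, ROC/AUC metrics, and permutation-based
# significance with FDR across marker sets.

#' Build a classification feature matrix from counts
#'
#' `log2(normalised count + 1)` per marker feature. Standardisation is NOT
#' applied here: it happens inside cross-validation using training folds
#' only, to avoid information leaking from the held-out sample.
#'
#' @param counts count matrix, features x samples.
#' @param sf size factors.
#' @param marker_set character vector of marker feature ids.
#' @return samples x markers numeric matrix.
#' @export
build_features <- function(counts, sf, marker_set) {
  missing_ids <- setdiff(marker_set, rownames(counts))
  if (length(missing_ids)) {
    stop("marker(s) absent from the count matrix: ",
         paste(utils::head(missing_ids, 5L), collapse = ", "), call. = FALSE)
  }
  q <- sweep(counts[marker_set, , drop = FALSE], 2L, sf, "/")
  t(log2(q + 1))
}

# median-heuristic RBF bandwidth: gamma = 1 / median squared distance
median_heuristic_gamma <- function(x) {
  d2 <- as.vector(stats::dist(x))^2
  d2 <- d2[d2 > 0]
  if (!length(d2)) return(1 / max(1L, ncol(x)))
  1 / stats::median(d2)
}

#' SVM classification config
#'
#' @param kernel `"radial"` (default) or `"linear"`.
#' @param cost soft-margin cost C (default 1).
#' @param gamma RBF width; `NULL` (default) uses the median heuristic on
#'   the training fold.
#' @param center_scores subtract each fold's decision value at the
#'   standardised-training-data origin (default `TRUE`). Leave-one-out
#'   training folds are always slightly imbalanced against the held-out
#'   sample's class; when the fit is weak the decision function collapses
#'   toward a composition-dependent constant, which anti-predicts the
#'   held-out label and drags null AUC far below 0.5. Centering removes
#'   that offset while leaving informative score differences intact.
#' @return a `svm_config` list.
#' @export
svm_config <- function(kernel = c("radial", "linear"), cost = 1, gamma = NULL,
                       center_scores = TRUE) {
  kernel <- match.arg(kernel)
  structure(list(kernel = kernel, cost = cost, gamma = gamma,
                 center_scores = center_scores),
            class = "svm_config")
}

#' Leave-one-out cross-validated SVM decision scores
#'
#' For each sample, an SVM is trained on all other samples (features
#' standardised with training-fold statistics) and produces a continuous
#' decision score for the held-out sample, oriented so larger scores mean
#' the positive class (`"stress"`). Deterministic given data and config.
#'
#' @param x samples x features matrix (see [build_features()]).
#' @param y labels, coercible to a factor with the positive class
#'   `"stress"` and negative `"control"` (any two-level factor works; the
#'   second level is treated as positive).
#' @param config [svm_config()].
#' @return numeric vector of out-of-fold decision scores.
#' @export
loocv_svm <- function(x, y, config = svm_config()) {
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2L) stop("need exactly two classes", call. = FALSE)
  if (min(table(y)) < 2L) stop("both classes need at least 2 samples", call. = FALSE)
  pos <- levels(y)[2L]
  n <- nrow(x)
  scores <- numeric(n)
  for (i in seq_len(n)) {
    xtr <- x[-i, , drop = FALSE]
    ytr <- y[-i]
    mu <- colMeans(xtr)
    sdv <- apply(xtr, 2L, stats::sd)
    sdv[sdv == 0 | !is.finite(sdv)] <- 1
    xtr_s <- sweep(sweep(xtr, 2L, mu), 2L, sdv, "/")
    xte_s <- (x[i, ] - mu) / sdv
    gamma <- if (is.null(config$gamma) && config$kernel == "radial") {
      median_heuristic_gamma(xtr_s)
    } else if (is.null(config$gamma)) 1 / ncol(x) else config$gamma
    fit <- e1071::svm(xtr_s, ytr, kernel = config$kernel, cost = config$cost,
                      gamma = gamma, scale = FALSE)
    # decision value computed directly from the support vectors:
    # f(x) = sum_i coef_i K(sv_i, x) - rho, positive toward the class
    # libsvm saw first in the training fold (fit$labels[1])
    f_dec <- function(z) {
      k <- if (config$kernel == "radial") {
        exp(-gamma * colSums((t(fit$SV) - z)^2))
      } else {
        as.vector(fit$SV %*% z)
      }
      sum(fit$coefs * k) - fit$rho
    }
    dv <- f_dec(xte_s)
    if (isTRUE(config$center_scores)) dv <- dv - f_dec(numeric(ncol(x)))
    orient <- fit$levels[fit$labels[1L]]
    scores[i] <- if (orient == pos) dv else -dv
  }
  scores
}

#' ROC/AUC and threshold metrics
#'
#' AUC by the rank (Mann-Whitney) formulation with half credit for ties;
#' accuracy, precision, recall and F1 at the decision threshold 0.
#'
#' @param scores continuous decision scores (larger = more positive).
#' @param labels two-level labels; second factor level is positive.
#' @return list `auc, accuracy, precision, recall, f1`.
#' @export
roc_metrics <- function(scores, labels) {
  labels <- droplevels(as.factor(labels))
  stopifnot(nlevels(labels) == 2L)
  pos <- labels == levels(labels)[2L]
  n1 <- sum(pos); n0 <- sum(!pos)
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  pred <- scores > 0
  tp <- sum(pred & pos); fp <- sum(pred & !pos)
  fn <- sum(!pred & pos)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- tp / (tp + fn)
  f1 <- if (!is.na(precision) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  list(auc = auc, accuracy = mean(pred == pos), precision = precision,
       recall = recall, f1 = f1)
}

#' ROC curve points
#'
#' @param scores decision scores.
#' @param labels two-level labels (second level positive).
#' @return data.frame `threshold, fpr, tpr` suitable for plotting.
#' @export
roc_points <- function(scores, labels) {
  labels <- droplevels(as.factor(labels))
  pos <- labels == levels(labels)[2L]
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(th, function(t) mean(scores[pos] >= t), numeric(1L))
  fpr <- vapply(th, function(t) mean(scores[!pos] >= t), numeric(1L))
  data.frame(threshold = th, fpr = fpr, tpr = tpr)
}

#' Permutation significance of a classifier's AUC
#'
#' Re-runs the full LOOCV under `B` label permutations that preserve class
#' sizes and reports the add-one permutation p-value
#' `p = (1 + #\{AUC_perm >= AUC_obs\}) / (1 + B)` together with the null
#' AUC distribution.
#'
#' @param x samples x features matrix.
#' @param y labels.
#' @param B number of permutations (default 10000; reduce for desk-scale
#'   runs).
#' @param seed integer seed for the permutations.
#' @param config [svm_config()].
#' @return list `auc, p, null_auc, B, seed`.
#' @export
permutation_significance <- function(x, y, B = 10000L, seed = 1L,
                                     config = svm_config()) {
  stopifnot(B >= 1L)
  obs <- roc_metrics(loocv_svm(x, y, config), y)$auc
  null_auc <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      yp <- sample(y)
      roc_metrics(loocv_svm(x, yp, config), yp)$auc
    }, numeric(1L))
  })
  p <- (1 + sum(null_auc >= obs)) / (1 + B)
  list(auc = obs, p = p, null_auc = null_auc, B = B, seed = seed)
}

#' Evaluate several marker sets with LOOCV SVM and permutation FDR
#'
#' Runs the full classification pipeline for each marker set (e.g. all DE
#' tRFs, female DE tRFs, CholinotRFs, all DE miRs, CholinomiRs), computes
#' ROC/AUC metrics and permutation p-values, and applies Benjamini-Hochberg
#' FDR across the evaluated sets.
#'
#' @param counts count matrix.
#' @param sf size factors.
#' @param marker_sets named list of feature-id vectors.
#' @param labels stress/control labels per sample.
#' @param B permutations per marker set.
#' @param seed integer seed.
#' @param config [svm_config()].
#' @return data.frame, one row per marker set: `marker_set, n_markers, auc,
#'   accuracy, precision, recall, f1, p_perm, fdr, B, seed`.
#' @export
classify_markers <- function(counts, sf, marker_sets, labels, B = 10000L,
                             seed = 1L, config = svm_config()) {
  stopifnot(length(marker_sets) >= 1L, !is.null(names(marker_sets)))
  rows <- lapply(names(marker_sets), function(nm) {
    x <- build_features(counts, sf, marker_sets[[nm]])
    scores <- loocv_svm(x, labels, config)
    met <- roc_metrics(scores, labels)
    perm <- permutation_significance(x, labels, B = B, seed = seed,
                                     config = config)
    data.frame(marker_set = nm, n_markers = length(marker_sets[[nm]]),
               auc = met$auc, accuracy = met$accuracy,
               precision = met$precision, recall = met$recall, f1 = met$f1,
               p_perm = perm$p, B = B, seed = seed, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p_perm, method = "BH")
  rownames(out) <- NULL
  out[, c("marker_set", "n_markers", "auc", "accuracy", "precision",
          "recall", "f1", "p_perm", "fdr", "B", "seed")]
}
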