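# Differential expression: prefiltering, median-of-ratios normalisation,
# and a simplified negative-binomial Wald test (vectorised IRLS across
# features sharing one two-level design).

#' Prefilter a count matrix
#'
#' Retains a feature iff at least `smallest_group_size` samples have a count
#' of at least `min_count`. With the study defaults (`min_count = 10`,
#' `smallest_group_size` = size of the smallest design group) this is the
#' standard low-count filter applied before dispersion estimation.
#'
#' @param counts non-negative integer matrix, features x samples.
#' @param smallest_group_size required number of samples at or above
#'   `min_count`.
#' @param min_count per-sample count threshold (default 10).
#' @return character vector of retained feature ids (rownames).
#' @export
prefilter <- function(counts, smallest_group_size, min_count = 10L) {
  stopifnot(is.matrix(counts), all(counts >= 0))
  if (smallest_group_size > ncol(counts)) {
    stop("smallest_group_size exceeds the number of samples", call. = FALSE)
  }
  keep <- rowSums(counts >= min_count) >= smallest_group_size
  rownames(counts)[keep]
}

#' Median-of-ratios size factors
#'
#' For each sample, the median over features of the ratio between its count
#' and the feature's geometric mean across samples, computed over features
#' with strictly positive counts in every sample.
#'
#' @param counts count matrix, features x samples.
#' @return named numeric vector of positive size factors.
#' @export
size_factors <- function(counts) {
  stopifnot(is.matrix(counts))
  pos <- rowSums(counts <= 0) == 0
  if (!any(pos)) {
    stop(paste("no feature has positive counts in every sample;",
               "median-of-ratios is undefined (consider a pseudo-reference",
               "over positive counts)"), call. = FALSE)
  }
  logc <- log(counts[pos, , drop = FALSE])
  ref <- rowMeans(logc)
  sf <- apply(logc, 2L, function(col) exp(stats::median(col - ref)))
  stats::setNames(sf, colnames(counts))
}

#' Normalised counts
#'
#' @param counts count matrix.
#' @param sf size factors (default computed by [size_factors()]).
#' @return matrix of counts divided by their sample's size factor.
#' @export
normalize_counts <- function(counts, sf = size_factors(counts)) {
  sweep(counts, 2L, sf, "/")
}

# Method-of-moments dispersion per feature, shrunk toward a fitted
# mean-dispersion trend phi(mu) = a0 + a1/mu. Grouped residual variances
# avoid absorbing the group effect into the dispersion.
estimate_dispersions <- function(counts, sf, group) {
  q <- sweep(counts, 2L, sf, "/")
  xim <- mean(1 / sf)
  lv <- split(seq_along(group), group)
  ss <- 0; mm <- 0; df <- 0
  mu_bar <- rowMeans(q)
  raw_num <- rep(0, nrow(counts))
  for (idx in lv) {
    if (length(idx) < 2L) next
    qg <- q[, idx, drop = FALSE]
    mg <- rowMeans(qg)
    vg <- apply(qg, 1L, stats::var)
    raw_num <- raw_num + (length(idx) - 1L) * (vg - xim * mg)
    df <- df + (length(idx) - 1L)
  }
  raw <- raw_num / df / pmax(mu_bar, 1e-8)^2
  raw <- pmin(pmax(raw, 1e-8), 10)
  # robust trend fit a0 + a1/mu on features with informative raw estimates
  use <- raw > 1e-6 & mu_bar > 0
  a <- c(0.1, 1)
  if (sum(use) >= 10L) {
    x <- 1 / mu_bar[use]
    y <- raw[use]
    for (it in 1:5) {   # IRLS approximation to a gamma-family trend fit
      w <- 1 / pmax(a[1] + a[2] * x, 1e-6)^2
      X <- cbind(1, x)
      fit <- tryCatch(stats::lm.wfit(X, y, w)$coefficients, error = function(e) a)
      if (any(!is.finite(fit))) break
      a <- pmax(fit, c(1e-4, 0))
    }
  }
  trend <- pmin(pmax(a[1] + a[2] / pmax(mu_bar, 1e-8), 1e-8), 10)
  # shrink log-dispersion halfway to the trend (simplified empirical Bayes)
  exp(0.5 * log(raw) + 0.5 * log(trend))
}

# Vectorised IRLS for the per-feature NB GLM
#   log mu_ij = log sf_j + b0_i + b1_i x_j,   x two-level group indicator.
# All features share the design, so the 2x2 weighted normal equations are
# solved in closed form across features simultaneously.
nb_irls <- function(counts, sf, x, phi, maxit = 50L, tol = 1e-8) {
  p <- nrow(counts); n <- ncol(counts)
  off <- matrix(log(sf), nrow = p, ncol = n, byrow = TRUE)
  X <- matrix(x, nrow = n)
  q <- sweep(counts, 2L, sf, "/")
  m0 <- pmax(rowMeans(q[, x == 0, drop = FALSE]), 1e-8)
  m1 <- pmax(rowMeans(q[, x == 1, drop = FALSE]), 1e-8)
  b0 <- log(m0)
  b1 <- log(m1) - log(m0)
  for (it in seq_len(maxit)) {
    eta <- off + b0 + outer(b1, x)
    eta <- pmin(pmax(eta, -30), 30)
    mu <- exp(eta)
    w <- mu / (1 + outer(phi, rep(1, n)) * mu)
    z <- (eta - off) + (counts - mu) / mu
    S0 <- rowSums(w)
    S1 <- rowSums(w * rep(x, each = p))
    S2 <- S1                      # x is 0/1 so sum(w x^2) = sum(w x)
    T0 <- rowSums(w * z)
    T1 <- rowSums(w * z * rep(x, each = p))
    det <- S0 * S2 - S1^2
    det[det < 1e-12] <- NA
    b0_new <- (S2 * T0 - S1 * T1) / det
    b1_new <- (S0 * T1 - S1 * T0) / det
    bad <- !is.finite(b0_new) | !is.finite(b1_new)
    b0_new[bad] <- b0[bad]; b1_new[bad] <- b1[bad]
    delta <- max(abs(b0_new - b0), abs(b1_new - b1))
    b0 <- b0_new; b1 <- b1_new
    if (delta < tol) break
  }
  eta <- pmin(pmax(off + b0 + outer(b1, x), -30), 30)
  mu <- exp(eta)
  w <- mu / (1 + outer(phi, rep(1, n)) * mu)
  S0 <- rowSums(w); S1 <- rowSums(w * rep(x, each = p))
  det <- S0 * S1 - S1^2
  se_b1 <- sqrt(ifelse(det > 1e-12, S0 / det, NA_real_))
  list(b0 = b0, b1 = b1, se_b1 = se_b1)
}

#' Negative-binomial Wald differential expression
#'
#' Simplified NB Wald pipeline for a two-level contrast: median-of-ratios
#' size factors as offsets, per-feature method-of-moments dispersion shrunk
#' toward a fitted mean-dispersion trend, a per-feature NB GLM with log link
#' fitted by IRLS (all features share the design, so fitting is vectorised),
#' and a Wald test on the group coefficient referred to a t distribution
#' with `n - 2` degrees of freedom (finite-sample calibration at the study's
#' sample sizes). Benjamini-Hochberg FDR within the contrast.
#'
#' Features whose fit degenerates (e.g. a group with all-zero counts causing
#' separation) fall back to a moderated log2 fold change computed from group
#' means with a 0.5 pseudo-mean, are flagged, and get `p = NA` (excluded
#' from the FDR step).
#'
#' @param counts prefiltered count matrix, features x samples.
#' @param metadata sample table with columns `sample_id`, `group`
#'   (`"stress"`/`"control"`) and `sex` (`"F"`/`"M"`); column order must
#'   match `colnames(counts)`.
#' @param subgroup `"all"` (default), `"female"` or `"male"`: restrict the
#'   contrast to one newborn sex.
#' @param sf optional externally computed size factors.
#' @param alpha FDR significance threshold (default 0.05).
#' @return data.frame of class `de_result`: `id, baseMean, log2FC, lfcSE,
#'   stat, pvalue, padj, significant, flagged`.
#' @export
nb_wald_de <- function(counts, metadata, subgroup = c("all", "female", "male"),
                       sf = NULL, alpha = 0.05) {
  subgroup <- match.arg(subgroup)
  stopifnot(is.matrix(counts), nrow(metadata) == ncol(counts),
            all(metadata$sample_id == colnames(counts)))
  keep <- switch(subgroup, all = rep(TRUE, nrow(metadata)),
                 female = metadata$sex == "F", male = metadata$sex == "M")
  counts <- counts[, keep, drop = FALSE]
  metadata <- metadata[keep, , drop = FALSE]
  x <- as.integer(metadata$group == "stress")
  if (sum(x == 1L) < 2L || sum(x == 0L) < 2L) {
    stop("both contrast levels need at least 2 samples after subgroup filtering",
         call. = FALSE)
  }
  if (is.null(sf)) sf <- size_factors(counts) else sf <- sf[keep]
  n <- ncol(counts)
  phi <- estimate_dispersions(counts, sf, metadata$group)
  fit <- nb_irls(counts, sf, x, phi)

  q <- sweep(counts, 2L, sf, "/")
  base_mean <- rowMeans(q)
  log2fc <- fit$b1 / log(2)
  se2 <- fit$se_b1 / log(2)

  # separation fallback: group means with 0.5 pseudo-mean, flagged, p = NA
  m0 <- rowMeans(q[, x == 0, drop = FALSE])
  m1 <- rowMeans(q[, x == 1, drop = FALSE])
  flagged <- !is.finite(fit$b1) | !is.finite(fit$se_b1) | (m0 == 0) | (m1 == 0)
  log2fc[flagged] <- log2((m1[flagged] + 0.5) / (m0[flagged] + 0.5))
  stat <- ifelse(flagged, NA_real_, log2fc / se2)
  pvalue <- 2 * stats::pt(abs(stat), df = n - 2L, lower.tail = FALSE)
  padj <- rep(NA_real_, length(pvalue))
  ok <- !is.na(pvalue)
  padj[ok] <- stats::p.adjust(pvalue[ok], method = "BH")
  out <- data.frame(
    id = rownames(counts), baseMean = base_mean, log2FC = log2fc,
    lfcSE = se2, stat = stat, pvalue = pvalue, padj = padj,
    significant = !is.na(padj) & padj <= alpha,
    flagged = flagged, stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("de_result", "data.frame")
  out
}

#' Read an externally produced differential-expression table
#'
#' The family-trend stage needs only fold-change signs and significance, so
#' a DE table computed by any external tool can be slotted in, provided it
#' carries columns `id, baseMean, log2FC, stat, pvalue, padj`.
#'
#' @param path TSV path.
#' @return `de_result` data.frame.
#' @export
read_de_table <- function(path) {
  de <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("id", "baseMean", "log2FC", "pvalue", "padj")
  miss <- setdiff(req, names(de))
  if (length(miss)) {
    stop("DE table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"significant" %in% names(de)) de$significant <- !is.na(de$padj) & de$padj <= 0.05
  if (!"flagged" %in% names(de)) de$flagged <- FALSE
  class(de) <- c("de_result", "data.frame")
  de
}
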