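# Ellman-assay cholinesterase kinetics: slopes from 21-cycle absorbance
# traces under selective inhibitors, activity assembly, outlier handling,
# and the group/dyad statistics.

#' Fit a catalytic rate from a kinetic trace
#'
#' Ordinary-least-squares slope of absorbance against time over the chosen
#' window, reported in mOD/min scaled by the sample dilution factor, with
#' the fit's R-squared (1 by convention for an exactly constant trace,
#' whose residual variance is zero) and the OLS standard error of the rate.
#'
#' @param absorbance numeric vector of readings (OD units), one per cycle.
#' @param time time per reading in minutes (default `0:(n-1)`, one-minute
#'   cycles).
#' @param window optional `(start, end)` pair of cycle indices (1-based)
#'   restricting the fit; at least 3 points required.
#' @param dilution dilution factor multiplying the rate (default 1).
#' @return list `rate` (mOD/min x dilution), `r2`, `se` (same units as
#'   rate).
#' @export
fit_slope <- function(absorbance, time = seq_along(absorbance) - 1,
                      window = NULL, dilution = 1) {
  stopifnot(length(absorbance) == length(time), dilution > 0,
            all(is.finite(absorbance)))
  if (!is.null(window)) {
    stopifnot(length(window) == 2L, window[1] >= 1L,
              window[2] <= length(absorbance))
    idx <- seq(window[1], window[2])
    absorbance <- absorbance[idx]
    time <- time[idx]
  }
  n <- length(absorbance)
  if (n < 3L) stop("need at least 3 points to fit a slope", call. = FALSE)
  fit <- stats::lm.fit(cbind(1, time), absorbance)
  slope <- fit$coefficients[2L]
  res <- fit$residuals
  sst <- sum((absorbance - mean(absorbance))^2)
  r2 <- if (sum(res^2) < 1e-24) 1 else if (sst == 0) 1 else 1 - sum(res^2) / sst
  sxx <- sum((time - mean(time))^2)
  se <- sqrt(sum(res^2) / (n - 2L) / sxx)
  list(rate = unname(slope) * 1000 * dilution, r2 = r2,
       se = se * 1000 * dilution)
}

#' Compute AChE/BChE activities from a sample's inhibitor traces
#'
#' Resolves the two cholinesterases by selective inhibition: the iso-OMPA
#' condition (BChE inhibited) gives the AChE rate, the BW284c51 condition
#' (AChE inhibited) gives the BChE rate, and the uninhibited trace gives
#' total activity. Also reports the additivity gap
#' `|total - (AChE + BChE)| / total`, a quality diagnostic, and the minimum
#' R-squared across conditions as a linearity diagnostic. Negative rates
#' are reported but flagged. Missing conditions yield a partial result with
#' explicit NA fields.
#'
#' @param traces long data.frame `sample_id, condition, cycle, absorbance`
#'   (conditions `uninhibited`, `iso-OMPA`, `BW284c51`), one sample or
#'   many.
#' @param window optional fit window, see [fit_slope()].
#' @param dilution dilution factor (default 1; use 20 for the 1:20 serum
#'   dilution when absolute units matter).
#' @return data.frame `sample_id, ache, bche, total, additivity_gap,
#'   min_r2, flagged`.
#' @export
compute_activities <- function(traces, window = NULL, dilution = 1) {
  stopifnot(all(c("sample_id", "condition", "cycle", "absorbance") %in%
                  names(traces)))
  rows <- lapply(split(traces, traces$sample_id), function(tr) {
    one <- function(cond) {
      sub <- tr[tr$condition == cond, , drop = FALSE]
      if (!nrow(sub)) return(NA_real_)
      sub <- sub[order(sub$cycle), ]
      fit_slope(sub$absorbance, time = sub$cycle, window = window,
                dilution = dilution)
    }
    f_total <- one("uninhibited"); f_ache <- one("iso-OMPA")
    f_bche <- one("BW284c51")
    g <- function(f) if (is.list(f)) f$rate else NA_real_
    r <- function(f) if (is.list(f)) f$r2 else NA_real_
    total <- g(f_total); ache <- g(f_ache); bche <- g(f_bche)
    gap <- if (!anyNA(c(total, ache, bche)) && abs(total) > 0) {
      abs(total - (ache + bche)) / abs(total)
    } else NA_real_
    data.frame(sample_id = tr$sample_id[1L], ache = ache, bche = bche,
               total = total, additivity_gap = gap,
               min_r2 = suppressWarnings(min(c(r(f_total), r(f_ache), r(f_bche)),
                                             na.rm = TRUE)),
               flagged = isTRUE(any(c(total, ache, bche) < 0)) ||
                 anyNA(c(total, ache, bche)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Interquartile-range outlier filter
#'
#' Drops values outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`, with quartiles by
#' linear interpolation between order statistics (the default convention
#' of [stats::quantile()], type 7). With fewer than 4 values no filtering
#' is applied (a warning is raised): quartiles would be meaningless.
#'
#' @param values numeric vector.
#' @return the retained values, in input order.
#' @export
iqr_filter <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 4L) {
    warning("fewer than 4 values; IQR filter not applied")
    return(values)
  }
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  values[values >= q[1] - 1.5 * iqr & values <= q[2] + 1.5 * iqr]
}

#' Rank-based two-group comparison
#'
#' Mann-Whitney U (unpaired) or Wilcoxon signed-rank (paired), two-sided;
#' exact for small tie-free samples, otherwise a normal approximation with
#' tie and continuity correction (the [stats::wilcox.test()] conventions).
#' Identical paired vectors have no informative pairs and return `p = 1`.
#'
#' @param a,b numeric vectors (aligned dyads when `paired`).
#' @param paired logical.
#' @return list `statistic, p`.
#' @export
group_compare <- function(a, b, paired = FALSE) {
  if (paired && length(a) != length(b)) {
    stop("paired comparison needs equal-length, dyad-aligned vectors",
         call. = FALSE)
  }
  if (paired && all(a == b)) {
    return(list(statistic = 0, p = 1))
  }
  wt <- suppressWarnings(stats::wilcox.test(a, b, paired = paired,
                                            alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p = wt$p.value)
}

#' Newborn/mother dyad activity ratios
#'
#' Per-dyad ratio of the newborn's enzyme rate to the mother's. Dyads with
#' a non-positive rate on either side are excluded (a ratio of error-level
#' rates is meaningless); exclusions are reported.
#'
#' @param newborn,mother activity data.frames from [compute_activities()],
#'   aligned by row (one dyad per row).
#' @param enzyme `"ache"` or `"bche"`.
#' @return list `ratios` (named by newborn sample id), `excluded`
#'   (data.frame of dropped dyads with reasons).
#' @export
dyad_ratio <- function(newborn, mother, enzyme = c("ache", "bche")) {
  enzyme <- match.arg(enzyme)
  stopifnot(nrow(newborn) == nrow(mother))
  nb <- newborn[[enzyme]]; mo <- mother[[enzyme]]
  ok <- !is.na(nb) & !is.na(mo) & nb > 0 & mo > 0
  excluded <- data.frame(
    newborn_id = newborn$sample_id[!ok],
    reason = ifelse(is.na(nb[!ok]) | is.na(mo[!ok]), "missing rate",
                    "non-positive rate"),
    stringsAsFactors = FALSE
  )
  list(ratios = stats::setNames(nb[ok] / mo[ok], newborn$sample_id[ok]),
       excluded = excluded)
}

#' Test dyad ratios against unity
#'
#' Wilcoxon signed-rank test of log-ratios against zero, i.e. of ratios
#' against 1 (equal activity in newborn and mother).
#'
#' @param ratios positive ratios from [dyad_ratio()].
#' @return list `statistic, p`.
#' @export
ratio_vs_one <- function(ratios) {
  stopifnot(all(ratios > 0))
  lr <- log(ratios)
  if (all(lr == 0)) return(list(statistic = 0, p = 1))
  wt <- suppressWarnings(stats::wilcox.test(lr, mu = 0,
                                            alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p = wt$p.value)
}

#' Spearman correlations between enzyme activities and tRF levels
#'
#' For each requested (activity column, tRF feature) pair, the Spearman
#' rank correlation across matched samples with a two-sided p-value,
#' Benjamini-Hochberg-adjusted across pairs. Pairs with a constant vector
#' have an undefined correlation and are flagged.
#'
#' @param activities data.frame with `sample_id` and rate columns.
#' @param trf_levels normalised tRF matrix, features x samples.
#' @param pairs data.frame `activity, feature` naming the pairs to test.
#' @return data.frame `activity, feature, rho, pvalue, padj, flagged`.
#' @export
activity_trf_correlation <- function(activities, trf_levels, pairs) {
  common <- intersect(activities$sample_id, colnames(trf_levels))
  if (length(common) < 4L) stop("need >= 4 matched samples", call. = FALSE)
  act <- activities[match(common, activities$sample_id), , drop = FALSE]
  lev <- trf_levels[, common, drop = FALSE]
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- act[[pairs$activity[i]]]
    f <- lev[pairs$feature[i], ]
    if (length(unique(a)) == 1L || length(unique(f)) == 1L) {
      return(data.frame(activity = pairs$activity[i],
                        feature = pairs$feature[i], rho = NA_real_,
                        pvalue = NA_real_, flagged = TRUE,
                        stringsAsFactors = FALSE))
    }
    ct <- suppressWarnings(stats::cor.test(a, f, method = "spearman",
                                           alternative = "two.sided"))
    data.frame(activity = pairs$activity[i], feature = pairs$feature[i],
               rho = unname(ct$estimate), pvalue = ct$p.value,
               flagged = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- NA_real_
  ok <- !is.na(out$pvalue)
  out$padj[ok] <- stats::p.adjust(out$pvalue[ok], method = "BH")
  rownames(out) <- NULL
  out[, c("activity", "feature", "rho", "pvalue", "padj", "flagged")]
}
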