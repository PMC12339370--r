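# Family-level directional trend analysis: exact binomial sign test over
# fold-change directions within tRF families, plus length-distribution
# profiling and Kruskal-Wallis tests of family length across groups.

#' Count fold-change directions within families
#'
#' For each family, counts members with a finite, nonzero log2 fold change
#' (`n`) and those moving down (`k_down`). Members with zero or missing
#' log2FC carry no directional information for a sign test and are excluded
#' (and reported in the `n_excluded` column).
#'
#' @param de `de_result` data.frame (needs `id` and `log2FC`).
#' @param index [build_family_index()] result covering every DE feature.
#' @return data.frame `family, n, k_down, n_excluded` in the index's
#'   deterministic family order.
#' @export
family_direction_counts <- function(de, index) {
  stopifnot(inherits(index, "family_index"))
  absent <- setdiff(de$id, names(index$membership))
  if (length(absent)) {
    stop("DE feature(s) absent from the family index: ",
         paste(utils::head(absent, 5L), collapse = ", "), call. = FALSE)
  }
  fam <- index$membership[de$id]
  informative <- is.finite(de$log2FC) & de$log2FC != 0
  keys <- index$families$family
  n <- vapply(keys, function(k) sum(informative & fam == k), integer(1L))
  k_down <- vapply(keys, function(k) {
    sum(informative & fam == k & de$log2FC < 0)
  }, integer(1L))
  excl <- vapply(keys, function(k) sum(!informative & fam == k), integer(1L))
  data.frame(family = keys, n = n, k_down = k_down, n_excluded = excl,
             stringsAsFactors = FALSE)
}

#' Exact binomial sign test
#'
#' Tests the observed number of "down" members `k` out of `n` against
#' Binomial(n, 1/2). The two-sided p-value uses the central method,
#' `min(1, 2 min(P(X <= k), P(X >= k)))`; under the symmetric null this
#' coincides with the minimum-likelihood method. One-sided alternatives are
#' available for testing a stated direction.
#'
#' @param n number of informative members (>= 1).
#' @param k number of members with negative fold change, `0 <= k <= n`.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`
#'   (tail of `k`).
#' @return p-value in `(0, 1]`.
#' @export
exact_binomial_test <- function(n, k, alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  stopifnot(length(n) == 1L, length(k) == 1L)
  if (n < 1L) stop("exact binomial test undefined for n = 0", call. = FALSE)
  if (k < 0L || k > n) stop("need 0 <= k <= n", call. = FALSE)
  lower <- stats::pbinom(k, n, 0.5)
  upper <- stats::pbinom(k - 1L, n, 0.5, lower.tail = FALSE)
  switch(alternative,
         two.sided = min(1, 2 * min(lower, upper)),
         less = lower,
         greater = upper)
}

#' Family trend table
#'
#' The core family-level statistic: per testable family, the exact binomial
#' test on the fraction of members with negative fold change, with
#' Benjamini-Hochberg FDR across testable families and a direction call
#' (`down` if FDR <= alpha and more than half the members decrease, `up`
#' if FDR <= alpha and fewer than half do, otherwise `none`). The
#' `signed_size` column (family size, negative when the trend is down) is
#' the bar-plot-ready summary.
#'
#' @param de `de_result` table for one contrast.
#' @param index family index (families below its `min_size` are reported
#'   with `NA` p-values, not tested).
#' @param alpha FDR threshold for direction calls (default 0.05).
#' @param alternative sidedness passed to [exact_binomial_test()].
#' @return data.frame `family, genome_origin, amino_acid, cleavage_type, n,
#'   k_down, prop_down, pvalue, padj, direction, signed_size`.
#' @export
family_trend_table <- function(de, index, alpha = 0.05,
                               alternative = "two.sided") {
  counts <- family_direction_counts(de, index)
  fam <- index$families
  out <- merge(fam, counts, by = "family", sort = FALSE)
  out <- out[match(fam$family, out$family), ]
  testable <- out$testable & out$n >= index$min_size
  out$prop_down <- ifelse(out$n > 0, out$k_down / out$n, NA_real_)
  out$pvalue <- NA_real_
  out$pvalue[testable] <- mapply(function(n, k) {
    exact_binomial_test(n, k, alternative = alternative)
  }, out$n[testable], out$k_down[testable])
  out$padj <- NA_real_
  out$padj[testable] <- stats::p.adjust(out$pvalue[testable], method = "BH")
  out$direction <- "none"
  sig <- !is.na(out$padj) & out$padj <= alpha
  out$direction[sig & out$prop_down > 0.5] <- "down"
  out$direction[sig & out$prop_down < 0.5] <- "up"
  out$signed_size <- ifelse(out$direction == "down", -out$n, out$n)
  rownames(out) <- NULL
  out[, c("family", "genome_origin", "amino_acid", "cleavage_type", "n",
          "k_down", "prop_down", "pvalue", "padj", "direction", "signed_size")]
}

#' Super-family trend table
#'
#' The same directional statistic at coarser grouping granularity: all
#' fragments sharing a genome origin, a cleavage type, or an amino acid,
#' regardless of the other two key components.
#'
#' @param de `de_result` table.
#' @param annotations annotation table covering every DE feature.
#' @param by grouping granularity: `"genome_origin"`, `"cleavage_type"` or
#'   `"amino_acid"`.
#' @param alpha FDR threshold.
#' @param alternative sidedness of the binomial test.
#' @param min_size minimum informative members to test (default 2).
#' @return data.frame `group, n, k_down, prop_down, pvalue, padj, direction`.
#' @export
superfamily_trend_table <- function(de, annotations,
                                    by = c("genome_origin", "cleavage_type",
                                           "amino_acid"),
                                    alpha = 0.05, alternative = "two.sided",
                                    min_size = 2L) {
  by <- match.arg(by)
  idx <- match(de$id, annotations$id)
  if (anyNA(idx)) {
    stop("DE feature(s) missing from annotations: ",
         paste(utils::head(de$id[is.na(idx)], 5L), collapse = ", "),
         call. = FALSE)
  }
  grp <- annotations[[by]][idx]
  informative <- is.finite(de$log2FC) & de$log2FC != 0
  lv <- if (by == "genome_origin") GENOME_ORIGINS
        else if (by == "cleavage_type") CLEAVAGE_TYPES
        else sort(unique(grp))
  lv <- intersect(lv, unique(grp))
  n <- vapply(lv, function(g) sum(informative & grp == g), integer(1L))
  k <- vapply(lv, function(g) sum(informative & grp == g & de$log2FC < 0),
              integer(1L))
  pvalue <- rep(NA_real_, length(lv))
  test <- n >= min_size
  pvalue[test] <- mapply(function(nn, kk) {
    exact_binomial_test(nn, kk, alternative = alternative)
  }, n[test], k[test])
  padj <- rep(NA_real_, length(lv))
  padj[test] <- stats::p.adjust(pvalue[test], method = "BH")
  prop <- ifelse(n > 0, k / n, NA_real_)
  dir <- rep("none", length(lv))
  sig <- !is.na(padj) & padj <= alpha
  dir[sig & prop > 0.5] <- "down"
  dir[sig & prop < 0.5] <- "up"
  data.frame(group = lv, n = n, k_down = k, prop_down = prop, pvalue = pvalue,
             padj = padj, direction = dir, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Mean expression by fragment length
#'
#' For each sample group, the mean over its samples of total normalised
#' expression per fragment length on the 16-50 nt grid, plus the fraction
#' of group signal falling in the 16-28 nt window where microRNA lengths
#' live.
#'
#' @param counts_normalized normalised count matrix (see
#'   [normalize_counts()]).
#' @param annotations annotation table with `id` and `length`.
#' @param groups character/factor of group labels, one per sample (column).
#' @return list with `profile` (data.frame `length` x one column per group)
#'   and `mir_window_fraction` (named vector: share of signal in 16-28 nt).
#' @export
mean_length_profile <- function(counts_normalized, annotations, groups) {
  stopifnot(ncol(counts_normalized) == length(groups))
  idx <- match(rownames(counts_normalized), annotations$id)
  if (anyNA(idx)) stop("features missing from annotations", call. = FALSE)
  len <- annotations$length[idx]
  stopifnot(all(len >= TRF_LENGTH_RANGE[1] & len <= TRF_LENGTH_RANGE[2]))
  grid <- seq(TRF_LENGTH_RANGE[1], TRF_LENGTH_RANGE[2])
  agg <- rowsum(counts_normalized, group = len)
  by_len <- matrix(0, nrow = length(grid), ncol = ncol(counts_normalized),
                   dimnames = list(grid, colnames(counts_normalized)))
  by_len[rownames(agg), ] <- agg
  lv <- unique(as.character(groups))
  prof <- sapply(lv, function(g) {
    rowMeans(by_len[, groups == g, drop = FALSE])
  })
  prof[is.na(prof)] <- 0
  mir <- grid >= 16 & grid <= 28
  frac <- colSums(prof[mir, , drop = FALSE]) / pmax(colSums(prof), .Machine$double.eps)
  list(profile = data.frame(length = grid, prof, check.names = FALSE),
       mir_window_fraction = frac)
}

#' Expression-weighted mean fragment length per family and sample
#'
#' @param counts_normalized normalised count matrix.
#' @param annotations annotation table.
#' @param index family index.
#' @return matrix families x samples of weighted mean member lengths (NA
#'   when a family has zero signal in a sample).
#' @export
weighted_family_length <- function(counts_normalized, annotations, index) {
  idx <- match(rownames(counts_normalized), annotations$id)
  if (anyNA(idx)) stop("features missing from annotations", call. = FALSE)
  len <- annotations$length[idx]
  fam <- index$membership[rownames(counts_normalized)]
  keys <- index$families$family
  num_agg <- rowsum(counts_normalized * len, group = fam)
  den_agg <- rowsum(counts_normalized, group = fam)
  num <- matrix(NA_real_, nrow = length(keys), ncol = ncol(counts_normalized),
                dimnames = list(keys, colnames(counts_normalized)))
  den <- num
  num[rownames(num_agg), ] <- num_agg
  den[rownames(den_agg), ] <- den_agg
  out <- num / den
  out[!is.na(den) & den == 0] <- NA_real_
  out
}

#' Kruskal-Wallis test of family length across groups
#'
#' Summarises each family in each sample by its expression-weighted mean
#' member length, then tests that summary across the (typically four
#' stress-by-sex) groups with the Kruskal-Wallis rank-sum test,
#' Benjamini-Hochberg-adjusted across families. Families whose summaries
#' are tied across all samples are reported with `H = 0, p = 1`.
#'
#' @param counts_normalized normalised count matrix.
#' @param annotations annotation table.
#' @param index family index.
#' @param groups group label per sample.
#' @return data.frame `family, H, pvalue, padj` for testable families with
#'   at least 2 members and complete summaries in at least 2 groups.
#' @export
kw_family_length <- function(counts_normalized, annotations, index, groups) {
  stopifnot(ncol(counts_normalized) == length(groups))
  wml <- weighted_family_length(counts_normalized, annotations, index)
  fams <- index$families
  keep <- fams$size >= 2L
  res <- lapply(fams$family[keep], function(k) {
    y <- wml[k, ]
    ok <- !is.na(y)
    g <- factor(groups[ok])
    if (length(unique(g)) < 2L) return(NULL)
    if (length(unique(y[ok])) == 1L) {
      return(data.frame(family = k, H = 0, pvalue = 1, stringsAsFactors = FALSE))
    }
    kt <- stats::kruskal.test(y[ok], g)
    data.frame(family = k, H = unname(kt$statistic), pvalue = kt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    return(data.frame(family = character(), H = numeric(), pvalue = numeric(),
                      padj = numeric(), stringsAsFactors = FALSE))
  }
  out$padj <- stats::p.adjust(out$pvalue, method = "BH")
  rownames(out) <- NULL
  out
}
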