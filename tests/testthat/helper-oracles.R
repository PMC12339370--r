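# Independent oracles used across the suite. These deliberately use brute
# force / direct enumeration, not the package's own code paths.

# two-sided sign-test p by full 2^n enumeration: sum the probability of
# every outcome sequence whose down-count is at least as extreme (central
# two-tail) as k
enum_binom_p <- function(n, k) {
  counts <- vapply(0:(2^n - 1), function(b) {
    sum(bitwAnd(b, 2^(0:(n - 1))) > 0)
  }, numeric(1))
  lower <- mean(counts <= k)
  upper <- mean(counts >= k)
  min(1, 2 * min(lower, upper))
}

# Fisher two-sided p by hypergeometric enumeration over the fixed margins;
# same <= comparison fudge as the reference implementation
enum_fisher_p <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); kk <- sum(tab[, 1])
  support <- max(0, kk - n):min(kk, m)
  probs <- stats::dhyper(support, m, n, kk)
  p_obs <- stats::dhyper(tab[1, 1], m, n, kk)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# hypergeometric upper tail by direct summation
enum_hyper_tail <- function(universe, n_chol, n_draw, k) {
  kk <- k:min(n_chol, n_draw)
  sum(choose(n_chol, kk) * choose(universe - n_chol, n_draw - kk)) /
    choose(universe, n_draw)
}

# Benjamini-Hochberg by literal step-up
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# trapezoidal AUC from an ROC curve's points
trapezoid_auc <- function(scores, labels) {
  pts <- roc_points(scores, labels)
  sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
}

# small catalog + counts bundle for fast tests
tiny_cohort <- function(seed = 1, n_families = 8, n_trfs = 60,
                        design = cohort_design(3, 3, 3, 3), effects = NULL) {
  catalog <- simulate_catalog(n_families, n_trfs, seed = seed)
  sim <- simulate_counts(catalog, design, effects, seed = seed + 1)
  list(catalog = catalog, sim = sim,
       index = build_family_index(catalog))
}
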