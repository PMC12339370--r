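# Synthetic cohort generator: seeded inputs with the statistical structure
# the family-level analysis assumes (NB counts with planted family trends,
# fragment-length structure, target-prediction tables, kinetic traces).

AMINO_ACIDS <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly",
                 "His", "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser",
                 "Thr", "Trp", "Tyr", "Val")

# Evaluate expr under a fixed RNG state, restoring the caller's afterwards,
# so every generator is a pure function of (parameters, seed).
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

#' Cohort design: group sizes and stress-assignment rule
#'
#' Defaults reproduce the umbilical-cord-serum study design: four groups
#' crossing newborn sex with maternal perceived-stress status, sized
#' 6 (female stress), 8 (male stress), 11 (female control), 10 (male
#' control). Mothers are assigned to the control group for PSS-10 scores
#' of at most 10 and to the stress group for scores of at least 19.
#'
#' @param female_stress,male_stress,female_control,male_control group sizes
#'   (each at least 2).
#' @param cohort `"newborn"` or `"mother"`.
#' @return a `cohort_design` list.
#' @export
cohort_design <- function(female_stress = 6L, male_stress = 8L,
                          female_control = 11L, male_control = 10L,
                          cohort = c("newborn", "mother")) {
  cohort <- match.arg(cohort)
  sizes <- c(female_stress = female_stress, male_stress = male_stress,
             female_control = female_control, male_control = male_control)
  if (any(sizes < 2L)) stop("all group sizes must be >= 2", call. = FALSE)
  storage.mode(sizes) <- "integer"
  structure(list(sizes = sizes, cohort = cohort,
                 pss_control_max = 10L, pss_stress_min = 19L),
            class = "cohort_design")
}

# default fragment-length peaks (nt) per cleavage type; chosen to reproduce
# the length landscape of serum tRF data: a dominant 23-24 nt mode, smaller
# modes near 18-19 and 31-32 nt, and a 36 nt peak carried by 3'-halves.
default_length_peaks <- function() {
  list("5p-tRF"  = c(mean = 18.5, sd = 1.0),
       "5p-half" = c(mean = 31.5, sd = 1.5),
       "i-tRF"   = c(mean = 23.5, sd = 2.0),
       "3p-half" = c(mean = 36.0, sd = 1.5),
       "3p-tRF"  = c(mean = 23.5, sd = 2.0))
}

#' Simulate a tRF catalog with family structure
#'
#' Draws `n_families` distinct (origin, amino acid, cleavage type) keys and
#' distributes `n_trfs` member fragments over them. Member lengths are drawn
#' from cleavage-type-specific normal modes (rounded, clamped to 16-50 nt)
#' and identifiers follow the tDR grammar. Reproducible from the seed.
#'
#' @param n_families number of families (default 45, the newborn-cohort
#'   scale).
#' @param n_trfs total number of fragments (default 565).
#' @param seed integer seed.
#' @param prob_mt probability a family is mitochondrial (default 0.4).
#' @param length_peaks named list of `c(mean, sd)` per cleavage type.
#' @return annotation data.frame (passes [validate_annotations()]).
#' @export
simulate_catalog <- function(n_families = 45L, n_trfs = 565L, seed = 1L,
                             prob_mt = 0.4, length_peaks = default_length_peaks()) {
  stopifnot(n_families >= 1L, n_trfs >= n_families)
  max_keys <- 2L * length(AMINO_ACIDS) * length(CLEAVAGE_TYPES)
  if (n_families > max_keys) {
    stop("n_families exceeds the number of distinct family keys (", max_keys, ")",
         call. = FALSE)
  }
  with_seed(seed, {
    keys <- expand.grid(genome_origin = GENOME_ORIGINS,
                        amino_acid = AMINO_ACIDS,
                        cleavage_type = CLEAVAGE_TYPES,
                        stringsAsFactors = FALSE)
    w <- ifelse(keys$genome_origin == "MT", prob_mt, 1 - prob_mt)
    pick <- sample.int(nrow(keys), n_families, prob = w)
    keys <- keys[pick, , drop = FALSE]
    # family sizes: at least one member each, remainder multinomial with
    # heavy-tailed weights so a few families dominate, as in real catalogs
    alpha <- stats::rgamma(n_families, shape = 0.8)
    alpha <- alpha / sum(alpha)
    extra <- as.vector(stats::rmultinom(1L, n_trfs - n_families, alpha))
    sizes <- extra + 1L

    rows <- vector("list", n_families)
    for (f in seq_len(n_families)) {
      k <- keys[f, ]
      pk <- length_peaks[[k$cleavage_type]]
      len <- pmin(pmax(round(stats::rnorm(sizes[f], pk["mean"], pk["sd"])),
                       TRF_LENGTH_RANGE[1]), TRF_LENGTH_RANGE[2])
      anticodon <- paste(sample(c("A", "C", "G", "T"), 3L, replace = TRUE),
                         collapse = "")
      start <- switch(k$cleavage_type,
                      "5p-tRF" = rep(1L, sizes[f]),
                      "5p-half" = rep(1L, sizes[f]),
                      sample(10:40, sizes[f], replace = TRUE))
      seqs <- vapply(len, function(n) {
        paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
      }, character(1L))
      rows[[f]] <- data.frame(
        id = format_tdr_name(k$genome_origin, start, start + len - 1L,
                             k$amino_acid, anticodon,
                             suffix = sprintf("f%dm%d", f, seq_len(sizes[f]))),
        sequence = seqs,
        length = as.integer(len),
        genome_origin = k$genome_origin,
        amino_acid = k$amino_acid,
        anticodon = anticodon,
        cleavage_type = k$cleavage_type,
        parents = "",
        stringsAsFactors = FALSE
      )
    }
    ann <- do.call(rbind, rows)
    rownames(ann) <- NULL
    validate_annotations(ann)
  })
}

#' Specify planted family-level directional effects
#'
#' Each row plants a directional expression trend in one family: a fraction
#' `fraction_down` of its members decrease by `log2fc` (log2 fold change) in
#' the stress group, the remainder increase by the same magnitude. The
#' `subgroup` column restricts the effect to female or male samples.
#'
#' @param family family keys (as in [family_key()]).
#' @param fraction_down fraction of members moving down, in `[0, 1]`.
#' @param log2fc effect magnitude (positive).
#' @param subgroup `"all"`, `"female"` or `"male"`.
#' @return effect-specification data.frame.
#' @export
effect_spec <- function(family, fraction_down, log2fc, subgroup = "all") {
  stopifnot(all(fraction_down >= 0 & fraction_down <= 1), all(log2fc >= 0),
            all(subgroup %in% c("all", "female", "male")))
  data.frame(family = family, fraction_down = fraction_down,
             log2fc = log2fc, subgroup = subgroup, stringsAsFactors = FALSE)
}

#' Simulate a serum small-RNA count matrix with planted family trends
#'
#' Counts are negative binomial: feature base means drawn log-uniformly,
#' dispersion a decreasing function of the mean (default
#' `phi(mu) = 0.1 + 1/mu`, typical of serum small-RNA data), per-sample
#' library-size factors log-normal. Planted effects multiply stress-group
#' means by `2^(+-log2fc)` member-wise. PSS-10 scores are drawn uniformly in
#' `[0, 10]` for control and `[19, 40]` for stress mothers; only the group
#' label is used downstream.
#'
#' @param catalog annotation data.frame from [simulate_catalog()].
#' @param design a [cohort_design()].
#' @param effects effect table from [effect_spec()], or `NULL` for a global
#'   null.
#' @param seed integer seed.
#' @param mean_range range of feature base means (log-uniform draw).
#' @param dispersion function mapping mean to NB dispersion `phi`.
#' @param libsize_sd standard deviation of log library-size factors.
#' @return list with `counts` (integer matrix features x samples),
#'   `metadata` (sample table: `sample_id, cohort, group, sex, birth_type,
#'   pss`), `truth` (per feature: family, base mean, true log2 fold change
#'   per contrast, true dispersion) and `size_factors_true`.
#' @export
simulate_counts <- function(catalog, design = cohort_design(), effects = NULL,
                            seed = 1L, mean_range = c(5, 2000),
                            dispersion = function(mu) 0.1 + 1 / mu,
                            libsize_sd = 0.2) {
  validate_annotations(catalog)
  fams <- family_key(catalog)
  if (!is.null(effects) && nrow(effects)) {
    missing_fam <- setdiff(effects$family, unique(fams))
    if (length(missing_fam)) {
      stop("effect references absent family(ies): ",
           paste(missing_fam, collapse = ", "), call. = FALSE)
    }
  }
  with_seed(seed, {
    sizes <- design$sizes
    n <- sum(sizes)
    sex <- rep(c("F", "M", "F", "M"), times = sizes)
    group <- rep(c("stress", "stress", "control", "control"), times = sizes)
    meta <- data.frame(
      sample_id = sprintf("%s_%02d", design$cohort, seq_len(n)),
      cohort = design$cohort,
      group = group,
      sex = sex,
      birth_type = "vaginal",
      pss = ifelse(group == "stress",
                   sample(19:40, n, replace = TRUE),
                   sample(0:10, n, replace = TRUE)),
      stringsAsFactors = FALSE
    )
    p <- nrow(catalog)
    mu0 <- exp(stats::runif(p, log(mean_range[1]), log(mean_range[2])))
    phi <- dispersion(mu0)
    sf <- exp(stats::rnorm(n, 0, libsize_sd))

    lfc <- matrix(0, nrow = p, ncol = 3,
                  dimnames = list(catalog$id, c("all", "female", "male")))
    if (!is.null(effects) && nrow(effects)) {
      for (e in seq_len(nrow(effects))) {
        members <- which(fams == effects$family[e])
        down <- stats::runif(length(members)) < effects$fraction_down[e]
        delta <- ifelse(down, -effects$log2fc[e], effects$log2fc[e])
        cols <- switch(effects$subgroup[e], all = "all",
                       female = "female", male = "male")
        lfc[members, cols] <- lfc[members, cols] + delta
      }
    }
    # per-sample expected mean: stress samples get the sex-appropriate shift
    shift <- matrix(0, nrow = p, ncol = n)
    is_stress <- meta$group == "stress"
    shift[, is_stress & meta$sex == "F"] <- lfc[, "all"] + lfc[, "female"]
    shift[, is_stress & meta$sex == "M"] <- lfc[, "all"] + lfc[, "male"]
    mu <- (mu0 * 2^shift) %*% diag(sf)
    counts <- matrix(stats::rnbinom(p * n, mu = mu, size = rep(1 / phi, n)),
                     nrow = p, ncol = n,
                     dimnames = list(catalog$id, meta$sample_id))
    # the realised stress-vs-control log2FC per contrast includes "all" + sex
    truth <- data.frame(
      id = catalog$id,
      family = fams,
      base_mean = mu0,
      dispersion = phi,
      true_log2fc_all = lfc[, "all"] +
        (sizes["female_stress"] * lfc[, "female"] +
           sizes["male_stress"] * lfc[, "male"]) /
        (sizes["female_stress"] + sizes["male_stress"]),
      true_log2fc_female = lfc[, "all"] + lfc[, "female"],
      true_log2fc_male = lfc[, "all"] + lfc[, "male"],
      stringsAsFactors = FALSE
    )
    rownames(truth) <- NULL
    list(counts = counts, metadata = meta, truth = truth,
         size_factors_true = stats::setNames(sf, meta$sample_id))
  })
}

#' Simulate a weighted cholinergic gene list
#'
#' Synthetic stand-in for a curated cholinergic gene panel: `n_core` core
#' genes (weight 5) and `n_peripheral` peripheral genes (weight 1) drawn
#' from a universe of `universe_size` symbols (`G0001`, `G0002`, ...).
#'
#' @param universe_size number of genes in the prediction universe.
#' @param n_core,n_peripheral panel tier sizes (defaults 15 + 87 = 102, the
#'   scale of curated cholinergic panels).
#' @param seed integer seed.
#' @return list with `gene_list` (data.frame `gene, tier, weight,
#'   functional_class`) and `universe` (character vector).
#' @export
simulate_gene_universe <- function(universe_size = 2000L, n_core = 15L,
                                   n_peripheral = 87L, seed = 1L) {
  stopifnot(n_core + n_peripheral <= universe_size)
  with_seed(seed, {
    universe <- sprintf("G%04d", seq_len(universe_size))
    chol <- sample(universe, n_core + n_peripheral)
    gene_list <- data.frame(
      gene = chol,
      tier = rep(c("core", "peripheral"), c(n_core, n_peripheral)),
      weight = rep(c(5L, 1L), c(n_core, n_peripheral)),
      functional_class = rep(c("esterase/synthesis", "auxiliary"),
                             c(n_core, n_peripheral)),
      stringsAsFactors = FALSE
    )
    list(gene_list = gene_list, universe = universe)
  })
}

#' Simulate a target-prediction table with planted cholinergic RNAs
#'
#' Emulates a sequence-based target predictor's output: each RNA receives a
#' Poisson number of predicted gene targets with scores in `[50, 100]`.
#' RNAs named in `planted_cholino` additionally receive at least one core
#' cholinergic target with score at least 80, so that the downstream
#' designation rule must recover them.
#'
#' @param rna_ids character vector of RNA identifiers.
#' @param universe gene universe (character).
#' @param gene_list weighted cholinergic gene list (see
#'   [simulate_gene_universe()]).
#' @param planted_cholino subset of `rna_ids` to plant as cholinergic.
#' @param mean_targets Poisson mean of predicted targets per RNA.
#' @param seed integer seed.
#' @return data.frame `rna_id, gene, score`.
#' @export
simulate_prediction_table <- function(rna_ids, universe, gene_list,
                                      planted_cholino = character(),
                                      mean_targets = 30, seed = 1L) {
  stopifnot(all(gene_list$gene %in% universe),
            all(planted_cholino %in% rna_ids))
  with_seed(seed, {
    core <- gene_list$gene[gene_list$tier == "core"]
    rows <- lapply(rna_ids, function(r) {
      k <- stats::rpois(1L, mean_targets)
      if (k == 0L && !(r %in% planted_cholino)) return(NULL)
      genes <- if (k > 0L) sample(universe, min(k, length(universe))) else character()
      score <- stats::runif(length(genes), 50, 100)
      if (r %in% planted_cholino) {
        g <- sample(core, 1L)
        genes <- c(genes, g)
        score <- c(score, stats::runif(1L, 80, 100))
      }
      data.frame(rna_id = r, gene = genes, score = score,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Simulate Ellman-assay kinetic traces
#'
#' For each sample, three 21-cycle absorbance traces (one reading per
#' minute) under the assay's inhibitor conditions: uninhibited (slope =
#' AChE + BChE), iso-OMPA which inhibits BChE (slope = AChE), and BW284c51
#' which inhibits AChE (slope = BChE). Rates are in mOD/min; readings get
#' additive Gaussian noise and are clamped at zero (absorbance cannot be
#' negative).
#'
#' @param true_rates data.frame `sample_id, ache, bche` (mOD/min, >= 0),
#'   optionally `role` (`"mother"`/`"newborn"`).
#' @param noise_sd absorbance noise standard deviation (OD units).
#' @param seed integer seed.
#' @param baseline initial absorbance (OD).
#' @param n_cycles number of one-minute kinetic cycles (default 21).
#' @return long data.frame `sample_id, role, condition, cycle, absorbance`
#'   with `cycle` in `0:(n_cycles-1)` minutes.
#' @export
simulate_ellman_traces <- function(true_rates, noise_sd = 0.002, seed = 1L,
                                   baseline = 0.1, n_cycles = 21L) {
  stopifnot(all(c("sample_id", "ache", "bche") %in% names(true_rates)),
            all(true_rates$ache >= 0), all(true_rates$bche >= 0))
  role <- if ("role" %in% names(true_rates)) true_rates$role else "newborn"
  with_seed(seed, {
    tt <- seq_len(n_cycles) - 1L
    conds <- c("uninhibited", "iso-OMPA", "BW284c51")
    rows <- lapply(seq_len(nrow(true_rates)), function(i) {
      slopes <- c(uninhibited = true_rates$ache[i] + true_rates$bche[i],
                  `iso-OMPA` = true_rates$ache[i],
                  BW284c51 = true_rates$bche[i])
      do.call(rbind, lapply(conds, function(cn) {
        abs_clean <- baseline + slopes[[cn]] / 1000 * tt
        noise <- if (noise_sd > 0) stats::rnorm(n_cycles, 0, noise_sd) else 0
        data.frame(sample_id = true_rates$sample_id[i],
                   role = if (length(role) > 1L) role[i] else role,
                   condition = cn, cycle = tt,
                   absorbance = pmax(abs_clean + noise, 0),
                   stringsAsFactors = FALSE)
      }))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
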