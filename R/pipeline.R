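# Pipeline orchestration: tabular I/O, input validation, a default
# synthetic study bundle, and the seeded end-to-end run.

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

write_counts_tsv <- function(counts, path) {
  df <- data.frame(id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read a counts TSV (features in rows, first column `id`)
#' @param path TSV path.
#' @return integer matrix with feature rownames.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

#' Read a sample metadata CSV
#'
#' Columns: `sample_id, cohort, group, sex, birth_type, pss`.
#' @param path CSV path.
#' @return data.frame.
#' @export
read_metadata <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Assign stress/control groups from PSS-10 scores
#'
#' Control for scores at or below `control_max` (default 10), stress at or
#' above `stress_min` (default 19); scores in between are left `NA`
#' (excluded from sequencing in the study design).
#'
#' @param pss integer PSS-10 scores.
#' @param control_max,stress_min thresholds.
#' @return character vector `"control"`/`"stress"`/`NA`.
#' @export
assign_groups <- function(pss, control_max = 10L, stress_min = 19L) {
  out <- rep(NA_character_, length(pss))
  out[pss <= control_max] <- "control"
  out[pss >= stress_min] <- "stress"
  out
}

#' Validate a bundle of pipeline inputs
#'
#' Schema checks on every provided file plus cross-file referential
#' integrity: count features must be annotated, metadata samples must match
#' count columns, annotation lengths must lie in 16-50 nt. Errors are
#' collected and reported together, not one at a time.
#'
#' @param paths named list with any of `counts`, `metadata`, `annotations`,
#'   `predictions`, `gene_list`, `kinetics`.
#' @return character vector of error messages (empty when all inputs are
#'   valid).
#' @export
validate_inputs <- function(paths) {
  errs <- character()
  note <- function(...) errs <<- c(errs, sprintf(...))
  ann <- counts <- meta <- NULL
  if (!is.null(paths$annotations)) {
    ann <- tryCatch(read_annotations(paths$annotations), error = function(e) {
      note("annotations: %s", conditionMessage(e)); NULL
    })
  }
  if (!is.null(paths$counts)) {
    counts <- tryCatch(read_counts(paths$counts), error = function(e) {
      note("counts: %s", conditionMessage(e)); NULL
    })
    if (!is.null(counts) && any(counts < 0, na.rm = TRUE)) {
      note("counts: negative values present")
    }
  }
  if (!is.null(paths$metadata)) {
    meta <- tryCatch(read_metadata(paths$metadata), error = function(e) {
      note("metadata: %s", conditionMessage(e)); NULL
    })
    if (!is.null(meta)) {
      req <- c("sample_id", "cohort", "group", "sex")
      miss <- setdiff(req, names(meta))
      if (length(miss)) note("metadata: missing column(s) %s",
                             paste(miss, collapse = ", "))
    }
  }
  if (!is.null(counts) && !is.null(meta) &&
      all(c("sample_id") %in% names(meta))) {
    extra <- setdiff(colnames(counts), meta$sample_id)
    if (length(extra)) note("sample(s) in counts missing from metadata: %s",
                            paste(extra, collapse = ", "))
    extra2 <- setdiff(meta$sample_id, colnames(counts))
    if (length(extra2)) note("sample(s) in metadata missing from counts: %s",
                             paste(extra2, collapse = ", "))
  }
  if (!is.null(counts) && !is.null(ann)) {
    unann <- setdiff(rownames(counts), ann$id)
    if (length(unann)) note("feature(s) in counts missing from annotations: %s",
                            paste(utils::head(unann, 5L), collapse = ", "))
  }
  if (!is.null(paths$gene_list)) {
    tryCatch(read_gene_list(paths$gene_list), error = function(e) {
      note("gene_list: %s", conditionMessage(e))
    })
  }
  if (!is.null(paths$predictions)) {
    pred <- tryCatch(utils::read.delim(paths$predictions,
                                       stringsAsFactors = FALSE),
                     error = function(e) { note("predictions: %s",
                                                conditionMessage(e)); NULL })
    if (!is.null(pred) &&
        !all(c("rna_id", "gene", "score") %in% names(pred))) {
      note("predictions: need columns rna_id, gene, score")
    }
  }
  if (!is.null(paths$kinetics)) {
    kin <- tryCatch(utils::read.csv(paths$kinetics, stringsAsFactors = FALSE),
                    error = function(e) { note("kinetics: %s",
                                               conditionMessage(e)); NULL })
    if (!is.null(kin) &&
        !all(c("sample_id", "condition", "cycle", "absorbance") %in% names(kin))) {
      note("kinetics: need columns sample_id, condition, cycle, absorbance")
    }
  }
  errs
}

#' Default planted effects emulating the study's family trends
#'
#' Mitochondrial families decline in stressed newborns: almost every member
#' down in females (fraction 0.99) and 90 percent down in males.
#' Nuclear Asp i-tRFs rise in both sexes (83 percent of members up).
#' Families not present in the catalog are skipped.
#'
#' @param catalog annotation data.frame.
#' @return effect-specification data.frame (see [effect_spec()]).
#' @export
default_study_effects <- function(catalog) {
  fams <- unique(family_key(catalog))
  origin <- sub("-.*", "", fams)
  mt <- fams[origin == "MT"]
  eff <- rbind(
    if (length(mt)) effect_spec(mt, 0.99, 1.0, "female"),
    if (length(mt)) effect_spec(mt, 0.90, 0.75, "male"),
    if ("Nuc-Asp-i-tRF" %in% fams) effect_spec("Nuc-Asp-i-tRF", 0.17, 0.8, "all")
  )
  eff
}

#' Simulate and write a complete study bundle
#'
#' Generates the synthetic newborn cohort (catalog, counts with planted
#' family trends, metadata, truth table), a target-prediction table with a
#' weighted cholinergic gene universe, and Ellman kinetic traces for
#' mother/newborn dyads, writing everything in the same plain-text formats
#' the real-data mode reads.
#'
#' @param dir output directory (created if needed).
#' @param seed integer master seed.
#' @param n_families,n_trfs catalog scale (defaults 45 families, 565
#'   fragments: the newborn-cohort scale).
#' @param design a [cohort_design()].
#' @param effects planted effects; default [default_study_effects()].
#' @param n_dyads number of mother/newborn dyads with kinetic traces
#'   (default 70).
#' @return invisibly, the list of written file paths.
#' @export
simulate_study <- function(dir, seed = 1L, n_families = 45L, n_trfs = 565L,
                           design = cohort_design(), effects = NULL,
                           n_dyads = 70L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  catalog <- simulate_catalog(n_families, n_trfs, seed = seed)
  if (is.null(effects)) effects <- default_study_effects(catalog)
  sim <- simulate_counts(catalog, design, effects, seed = seed + 1L)
  uni <- simulate_gene_universe(seed = seed + 2L)
  # cholinergic fragments planted mostly among MT tRFs, mirroring the
  # mitochondrial skew of cholinergic-targeting fragments in serum data
  short <- catalog[catalog$length >= 17 & catalog$length <= 28, ]
  planted <- with_seed(seed + 3L, {
    w <- ifelse(short$genome_origin == "MT", 4, 1)
    sample(short$id, size = max(1L, round(0.1 * nrow(short))), prob = w)
  })
  pred <- simulate_prediction_table(catalog$id, uni$universe, uni$gene_list,
                                    planted_cholino = planted, seed = seed + 4L)
  rates <- with_seed(seed + 5L, {
    data.frame(
      sample_id = c(sprintf("dyad%02d_newborn", seq_len(n_dyads)),
                    sprintf("dyad%02d_mother", seq_len(n_dyads))),
      role = rep(c("newborn", "mother"), each = n_dyads),
      ache = c(stats::rlnorm(n_dyads, log(3), 0.35),
               stats::rlnorm(n_dyads, log(2), 0.35)),
      bche = c(stats::rlnorm(n_dyads, log(5), 0.35),
               stats::rlnorm(n_dyads, log(5), 0.35)),
      stringsAsFactors = FALSE
    )
  })
  kin <- simulate_ellman_traces(rates, noise_sd = 0.002, seed = seed + 6L)

  paths <- list(
    annotations = file.path(dir, "annotations.tsv"),
    counts = file.path(dir, "counts.tsv"),
    metadata = file.path(dir, "metadata.csv"),
    truth = file.path(dir, "truth.tsv"),
    predictions = file.path(dir, "predictions.tsv"),
    gene_list = file.path(dir, "gene_list.csv"),
    kinetics = file.path(dir, "kinetics.csv"),
    kinetics_truth = file.path(dir, "kinetics_truth.csv")
  )
  write_tsv(catalog, paths$annotations)
  write_counts_tsv(sim$counts, paths$counts)
  utils::write.csv(sim$metadata, paths$metadata, row.names = FALSE)
  write_tsv(sim$truth, paths$truth)
  write_tsv(pred, paths$predictions)
  utils::write.csv(uni$gene_list[, c("gene", "tier", "functional_class")],
                   paths$gene_list, row.names = FALSE)
  utils::write.csv(kin, paths$kinetics, row.names = FALSE)
  utils::write.csv(rates, paths$kinetics_truth, row.names = FALSE)
  invisible(paths)
}

default_config <- function() {
  list(
    version = 1L,
    seed = 1L,
    inputs = list(counts = NULL, metadata = NULL, annotations = NULL,
                  predictions = NULL, gene_list = NULL, kinetics = NULL,
                  de_table = NULL),
    de = list(min_count = 10L, smallest_group_size = NULL),
    family = list(min_size = 2L, alternative = "two.sided"),
    scoring = list(min_len = 17L, max_len = 28L, min_score = 80),
    classifier = list(kernel = "radial", cost = 1, B = 199L),
    alpha = 0.05,
    output_dir = "trfam_results"
  )
}

#' Load and validate a pipeline run configuration
#'
#' YAML with the sections of `default_config()`; unknown keys are rejected
#' so typos cannot silently fall back to defaults. Thresholds are echoed
#' verbatim into the run manifest.
#'
#' @param path YAML path, or `NULL` for the defaults.
#' @param overrides named list merged over the file's values.
#' @return config list.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  merge_strict <- function(base, new, where = "config") {
    for (nm in names(new)) {
      if (!nm %in% names(base)) {
        stop(sprintf("unknown %s key: '%s'", where, nm), call. = FALSE)
      }
      if (is.list(base[[nm]]) && is.list(new[[nm]])) {
        base[[nm]] <- merge_strict(base[[nm]], new[[nm]],
                                   paste0(where, "$", nm))
      } else {
        base[[nm]] <- new[[nm]]
      }
    }
    base
  }
  if (!is.null(path)) {
    cfg <- merge_strict(cfg, yaml::read_yaml(path))
  }
  merge_strict(cfg, overrides)
}

#' Run the full family-level analysis pipeline
#'
#' Stage order: load and validate inputs, prefilter, size factors,
#' differential expression for the overall and per-sex stress contrasts
#' (or import an external DE table for the overall contrast), family and
#' super-family trend tables, length profiling with Kruskal-Wallis family
#' tests, cholinergic scoring with enrichment, marker-set classification,
#' and (when kinetic traces are provided) cholinesterase activities with
#' group statistics. Every output table is written under
#' `config$output_dir` and a JSON manifest records the config echo, seeds,
#' package version and per-stage row counts, so that identical config plus
#' seed reproduces identical files.
#'
#' @param config list from [load_config()].
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  t0 <- Sys.time()
  outdir <- config$output_dir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  errs <- validate_inputs(config$inputs)
  if (length(errs)) {
    stop("input validation failed:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  }
  manifest <- list(config = config,
                   package_version = as.character(utils::packageVersion("trfam")),
                   stages = list(), warnings = character())
  log_stage <- function(name, ...) {
    manifest$stages[[name]] <<- list(...)
  }

  ann <- read_annotations(config$inputs$annotations)
  counts <- read_counts(config$inputs$counts)
  meta <- read_metadata(config$inputs$metadata)
  meta <- meta[match(colnames(counts), meta$sample_id), ]
  log_stage("load", features = nrow(counts), samples = ncol(counts))

  sgs <- config$de$smallest_group_size
  if (is.null(sgs)) sgs <- min(table(paste(meta$group, meta$sex)))
  kept <- prefilter(counts, sgs, config$de$min_count)
  counts_f <- counts[kept, , drop = FALSE]
  log_stage("prefilter", features_in = nrow(counts),
            features_out = length(kept), smallest_group_size = sgs)

  sf <- size_factors(counts_f)
  norm <- normalize_counts(counts_f, sf)
  ann_f <- ann[ann$id %in% kept, , drop = FALSE]
  index <- build_family_index(ann_f, min_size = config$family$min_size)

  contrasts <- c("all", "female", "male")
  de <- list()
  for (ctr in contrasts) {
    de[[ctr]] <- if (ctr == "all" && !is.null(config$inputs$de_table)) {
      read_de_table(config$inputs$de_table)
    } else {
      nb_wald_de(counts_f, meta, subgroup = ctr, sf = sf,
                 alpha = config$alpha)
    }
    write_tsv(de[[ctr]], file.path(outdir, sprintf("de_%s.tsv", ctr)))
  }
  log_stage("de", contrasts = length(de),
            significant = vapply(de, function(d) sum(d$significant),
                                 integer(1L)))

  for (ctr in contrasts) {
    ft <- family_trend_table(de[[ctr]], index, alpha = config$alpha,
                             alternative = config$family$alternative)
    write_tsv(ft, file.path(outdir, sprintf("family_trend_%s.tsv", ctr)))
    for (by in c("genome_origin", "cleavage_type", "amino_acid")) {
      sft <- superfamily_trend_table(de[[ctr]], ann_f, by = by,
                                     alpha = config$alpha,
                                     alternative = config$family$alternative)
      write_tsv(sft, file.path(outdir,
                               sprintf("superfamily_%s_%s.tsv", by, ctr)))
    }
  }
  log_stage("family_trend", families = nrow(index$families),
            testable = sum(index$families$testable))

  grp4 <- paste(meta$sex, meta$group, sep = "_")
  prof <- mean_length_profile(norm, ann_f, grp4)
  write_tsv(prof$profile, file.path(outdir, "length_profile.tsv"))
  kw <- kw_family_length(norm, ann_f, index, grp4)
  write_tsv(kw, file.path(outdir, "family_length_kw.tsv"))
  log_stage("lengths", families_tested = nrow(kw),
            mir_window_fraction = as.list(prof$mir_window_fraction))

  gl <- read_gene_list(config$inputs$gene_list)
  pred <- utils::read.delim(config$inputs$predictions,
                            stringsAsFactors = FALSE)
  qual <- filter_candidates(ann, pred, config$scoring$min_len,
                            config$scoring$max_len, config$scoring$min_score)
  scores <- cholinergic_scores(qual, gl, rna_ids = ann$id)
  write_tsv(scores, file.path(outdir, "cholinergic_scores.tsv"))
  fis <- fisher_origin_enrichment(
    scores$is_cholino, ann$genome_origin[match(scores$rna_id, ann$id)])
  n_pred_targets <- length(unique(qual$gene))
  n_overlap <- length(unique(qual$gene[toupper(qual$gene) %in% gl$gene]))
  universe_size <- length(unique(c(pred$gene, gl$gene)))
  hyp <- hypergeom_target_enrichment(universe_size, nrow(gl),
                                     n_pred_targets, n_overlap)
  log_stage("cholinergic", n_cholino = sum(scores$is_cholino),
            fisher_p = fis$p, hypergeom_p = hyp)

  marker_sets <- list(
    all_de_trfs = unique(c(de$all$id[de$all$significant],
                           de$female$id[de$female$significant])),
    female_de_trfs = de$female$id[de$female$significant],
    cholinotrfs = intersect(scores$rna_id[scores$is_cholino], kept)
  )
  marker_sets <- marker_sets[lengths(marker_sets) >= 2L]
  cls <- NULL
  if (length(marker_sets)) {
    fem <- meta$sex == "F"
    cls <- classify_markers(counts_f[, fem, drop = FALSE], sf[fem],
                            marker_sets,
                            factor(meta$group[fem],
                                   levels = c("control", "stress")),
                            B = config$classifier$B, seed = config$seed,
                            config = svm_config(config$classifier$kernel,
                                                config$classifier$cost))
    write_tsv(cls, file.path(outdir, "classification_female.tsv"))
  }
  log_stage("classification",
            marker_sets = length(marker_sets),
            best_auc = if (!is.null(cls)) max(cls$auc) else NA_real_)

  if (!is.null(config$inputs$kinetics)) {
    kin <- utils::read.csv(config$inputs$kinetics, stringsAsFactors = FALSE)
    act <- compute_activities(kin)
    write_tsv(act, file.path(outdir, "activities.tsv"))
    stats_out <- list()
    if ("role" %in% names(kin)) {
      role <- kin$role[match(act$sample_id, kin$sample_id)]
      nb <- act[role == "newborn", , drop = FALSE]
      mo <- act[role == "mother", , drop = FALSE]
      for (enz in c("ache", "bche")) {
        a <- iqr_filter(nb[[enz]]); b <- iqr_filter(mo[[enz]])
        stats_out[[paste0(enz, "_newborn_vs_mother")]] <-
          group_compare(a, b, paired = FALSE)
        if (nrow(nb) == nrow(mo)) {
          dr <- dyad_ratio(nb, mo, enz)
          rr <- iqr_filter(dr$ratios)
          stats_out[[paste0(enz, "_ratio_vs_one")]] <- ratio_vs_one(rr)
        }
      }
    }
    jsonlite::write_json(stats_out, file.path(outdir, "kinetics_stats.json"),
                         auto_unbox = TRUE, digits = NA)
    log_stage("kinetics", samples = nrow(act))
  }

  manifest$elapsed_sec <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  manifest$n_stages <- length(manifest$stages)
  # manifest without the timing field is the determinism contract
  jsonlite::write_json(manifest[c("config", "package_version", "stages",
                                  "warnings", "n_stages")],
                       file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
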