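# Weighted cholinergic target scoring: CholinotRF/CholinomiR designation
# from target-prediction tables, plus enrichment statistics.

#' Read a weighted cholinergic gene list
#'
#' CSV with columns `gene, tier, functional_class`; `tier` is `core`
#' (weight 5) or `peripheral` (weight 1). Symbols are upper-cased and must
#' be unique.
#'
#' @param path CSV path.
#' @return validated data.frame with a `weight` column.
#' @export
read_gene_list <- function(path) {
  gl <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_gene_list(gl)
}

#' Validate a weighted cholinergic gene list
#'
#' @param gene_list data.frame with `gene` and `tier` columns.
#' @return the list with case-normalised symbols and a `weight` column.
#' @export
validate_gene_list <- function(gene_list) {
  stopifnot(all(c("gene", "tier") %in% names(gene_list)))
  if (!all(gene_list$tier %in% c("core", "peripheral"))) {
    stop("tier must be 'core' or 'peripheral'", call. = FALSE)
  }
  gene_list$gene <- toupper(gene_list$gene)
  if (anyDuplicated(gene_list$gene)) {
    stop("duplicate gene symbol(s) in cholinergic list", call. = FALSE)
  }
  gene_list$weight <- ifelse(gene_list$tier == "core", 5L, 1L)
  gene_list
}

#' Filter candidate RNA-target pairs
#'
#' Applies the designation pre-filters: the RNA must be 17-28 nt long (the
#' length window of microRNA-like targeting) and the prediction score must
#' be at least 80. Duplicate (RNA, gene) predictions are collapsed to their
#' maximum score before the score filter. Predictions for RNAs absent from
#' the length table are skipped with a message.
#'
#' @param rna_lengths data.frame `id, length` (tRF annotation tables work
#'   as-is).
#' @param predictions data.frame `rna_id, gene, score`.
#' @param min_len,max_len RNA length window (defaults 17 and 28 nt).
#' @param min_score minimum prediction score (default 80).
#' @return data.frame of qualifying `rna_id, gene, score` pairs.
#' @export
filter_candidates <- function(rna_lengths, predictions, min_len = 17L,
                              max_len = 28L, min_score = 80) {
  stopifnot(all(c("rna_id", "gene", "score") %in% names(predictions)),
            all(c("id", "length") %in% names(rna_lengths)))
  known <- predictions$rna_id %in% rna_lengths$id
  if (!all(known)) {
    message("skipping ", sum(!known), " prediction(s) for unknown RNA id(s)")
    predictions <- predictions[known, , drop = FALSE]
  }
  # collapse duplicates to max score first, then filter
  key <- paste(predictions$rna_id, predictions$gene, sep = "\r")
  best <- tapply(predictions$score, key, max)
  first <- predictions[!duplicated(key), c("rna_id", "gene")]
  first$score <- as.numeric(best[paste(first$rna_id, first$gene, sep = "\r")])
  len <- rna_lengths$length[match(first$rna_id, rna_lengths$id)]
  out <- first[len >= min_len & len <= max_len & first$score >= min_score, ,
               drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cholinergic scores and CholinotRF/CholinomiR designation
#'
#' For each RNA, sums the weights of its qualifying cholinergic targets
#' (core genes weigh 5, peripheral genes 1; genes outside the list
#' contribute nothing) and designates the RNA cholinergic
#' ("CholinotRF"/"CholinomiR") iff it targets at least one core gene or at
#' least five peripheral genes.
#'
#' @param qualifying qualifying pairs from [filter_candidates()].
#' @param gene_list validated weighted gene list.
#' @param rna_ids optional vector of RNAs to report (RNAs with no
#'   qualifying targets then appear with zero scores); defaults to RNAs in
#'   `qualifying`.
#' @param rna_class optional class label per reported RNA (`"tRF"` or
#'   `"miR"`).
#' @return data.frame `rna_id, class, n_core, n_peripheral, score,
#'   is_cholino`.
#' @export
cholinergic_scores <- function(qualifying, gene_list, rna_ids = NULL,
                               rna_class = NULL) {
  gene_list <- validate_gene_list(gene_list)
  if (is.null(rna_ids)) rna_ids <- sort(unique(qualifying$rna_id))
  tier <- gene_list$tier[match(toupper(qualifying$gene), gene_list$gene)]
  f <- factor(qualifying$rna_id, levels = rna_ids)
  n_core <- as.integer(tapply(tier == "core", f, function(z) sum(z, na.rm = TRUE)))
  n_periph <- as.integer(tapply(tier == "peripheral", f,
                                function(z) sum(z, na.rm = TRUE)))
  n_core[is.na(n_core)] <- 0L
  n_periph[is.na(n_periph)] <- 0L
  out <- data.frame(
    rna_id = rna_ids,
    class = if (is.null(rna_class)) {
      ifelse(grepl("miR|let-", rna_ids, ignore.case = TRUE), "miR", "tRF")
    } else rna_class,
    n_core = n_core,
    n_peripheral = n_periph,
    score = 5L * n_core + n_periph,
    stringsAsFactors = FALSE
  )
  out$is_cholino <- out$n_core >= 1L | out$n_peripheral >= 5L
  rownames(out) <- NULL
  out
}

#' Fisher's exact test for cholinergic enrichment by genome origin
#'
#' Two-sided Fisher's exact test of the 2x2 table cholinergic-designation
#' by genome origin (MT vs Nuc), the check that mitochondrial tRFs are
#' over-represented among CholinotRFs. The p-value sums hypergeometric
#' probabilities no larger than that of the observed table; the odds ratio
#' is the sample odds ratio with a Haldane 0.5 correction when a cell is
#' zero. A zero margin makes the table uninformative: `p = 1` and an
#' undefined (NA) odds ratio.
#'
#' @param is_cholino logical vector of designations.
#' @param origin genome origin per RNA (`"MT"`/`"Nuc"`).
#' @return list `odds_ratio`, `p`, `table`.
#' @export
fisher_origin_enrichment <- function(is_cholino, origin) {
  stopifnot(length(is_cholino) == length(origin),
            all(origin %in% GENOME_ORIGINS))
  tab <- table(factor(origin, levels = c("MT", "Nuc")),
               factor(is_cholino, levels = c(TRUE, FALSE)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(odds_ratio = NA_real_, p = 1, table = tab))
  }
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  or <- if (any(tab == 0)) {
    unname((tab[1, 1] + 0.5) * (tab[2, 2] + 0.5) /
             ((tab[1, 2] + 0.5) * (tab[2, 1] + 0.5)))
  } else {
    unname(tab[1, 1] * tab[2, 2] / (tab[1, 2] * tab[2, 1]))
  }
  list(odds_ratio = or, p = p, table = tab)
}

#' Hypergeometric enrichment of cholinergic genes among predicted targets
#'
#' Upper-tail probability `P(X >= n_overlap)` that a draw of
#' `n_predicted_targets` genes from a universe containing `n_cholinergic`
#' cholinergic genes hits at least the observed overlap.
#'
#' @param universe_size number of genes in the prediction universe.
#' @param n_cholinergic cholinergic genes in the universe.
#' @param n_predicted_targets distinct genes predicted as targets.
#' @param n_overlap predicted targets that are cholinergic.
#' @return p-value.
#' @export
hypergeom_target_enrichment <- function(universe_size, n_cholinergic,
                                        n_predicted_targets, n_overlap) {
  if (n_overlap > min(n_cholinergic, n_predicted_targets) ||
      n_cholinergic > universe_size || n_predicted_targets > universe_size ||
      any(c(universe_size, n_cholinergic, n_predicted_targets, n_overlap) < 0)) {
    stop("inconsistent hypergeometric counts", call. = FALSE)
  }
  stats::phyper(n_overlap - 1L, n_cholinergic, universe_size - n_cholinergic,
                n_predicted_targets, lower.tail = FALSE)
}
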