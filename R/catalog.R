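# tRF catalog: identifier parsing, annotation validation, family indexing.

#' Cleavage types in 5'-to-3' order along the mature tRNA
#'
#' The five canonical fragment classes: 5'-tRFs and 5'-halves start at the
#' 5' end of the mature tRNA, i-tRFs are internal, 3'-halves and 3'-tRFs end
#' at the 3' terminus. The order given here defines the deterministic sort
#' order used throughout the package.
#'
#' @export
CLEAVAGE_TYPES <- c("5p-tRF", "5p-half", "i-tRF", "3p-half", "3p-tRF")

#' Genome origins of tRNA genes
#' @export
GENOME_ORIGINS <- c("Nuc", "MT")

#' Bounds (nt) on fragment length for a sequence to count as a tRF
#' @export
TRF_LENGTH_RANGE <- c(16L, 50L)

#' Parse a tDR-style tRF identifier
#'
#' Identifiers follow the grammar
#' `(mtDR|tDR)-<start>:<end>-<AminoAcid>-<anticodon>-<suffix>`, e.g.
#' `mtDR-36:57-Gly-TCC-1`. The `mtDR` prefix marks a mitochondrial
#' genome origin, `tDR` a nuclear one. The start/end coordinates use the
#' structural numbering of the parental tRNA and are retained verbatim as
#' *name coordinates*; they are never used to compute fragment length,
#' because structural numbering can skip or insert positions (a fragment
#' named `36:57` can be 21 nt long). Cleavage type is not encoded in the
#' name and is left unset.
#'
#' @param name character vector of identifiers.
#' @return a data.frame with one row per identifier and columns `id`,
#'   `genome_origin` (`"Nuc"` or `"MT"`), `name_start`, `name_end`,
#'   `amino_acid`, `anticodon`, `suffix`.
#' @examples
#' parse_tdr_name("mtDR-36:57-Gly-TCC-1")
#' @export
parse_tdr_name <- function(name) {
  stopifnot(is.character(name), length(name) >= 1L)
  rx <- "^(mtDR|tDR)-([0-9]+):([0-9]+)-([A-Za-z]{3})-([ACGTU]{3})-([A-Za-z0-9]+)$"
  ok <- grepl(rx, name)
  if (!all(ok)) {
    bad <- name[!ok][1L]
    # point at the first token that breaks the grammar, for actionable errors
    parts <- strsplit(bad, "-", fixed = TRUE)[[1L]]
    token <- if (!parts[1L] %in% c("tDR", "mtDR")) {
      parts[1L]
    } else if (length(parts) < 5L) {
      bad
    } else if (!grepl("^[0-9]+:[0-9]+$", parts[2L])) {
      parts[2L]
    } else if (!grepl("^[A-Za-z]{3}$", parts[3L])) {
      parts[3L]
    } else if (!grepl("^[ACGTU]{3}$", parts[4L])) {
      parts[4L]
    } else {
      parts[length(parts)]
    }
    stop(sprintf("malformed tDR name '%s': offending token '%s'", bad, token),
         call. = FALSE)
  }
  m <- regmatches(name, regexec(rx, name))
  fields <- function(i) vapply(m, `[[`, character(1L), i + 1L)
  data.frame(
    id            = name,
    genome_origin = ifelse(fields(1L) == "mtDR", "MT", "Nuc"),
    name_start    = as.integer(fields(2L)),
    name_end      = as.integer(fields(3L)),
    amino_acid    = fields(4L),
    anticodon     = toupper(fields(5L)),
    suffix        = fields(6L),
    stringsAsFactors = FALSE
  )
}

#' Format a tDR-style identifier
#'
#' Inverse of [parse_tdr_name()] on its grammar.
#'
#' @param genome_origin `"Nuc"` or `"MT"` (vectorised).
#' @param name_start,name_end positive integer name coordinates.
#' @param amino_acid three-letter amino-acid code.
#' @param anticodon 3-nt anticodon.
#' @param suffix disambiguating suffix (default `"1"`).
#' @return character vector of identifiers.
#' @export
format_tdr_name <- function(genome_origin, name_start, name_end,
                            amino_acid, anticodon, suffix = "1") {
  stopifnot(all(genome_origin %in% GENOME_ORIGINS))
  prefix <- ifelse(genome_origin == "MT", "mtDR", "tDR")
  sprintf("%s-%d:%d-%s-%s-%s", prefix, as.integer(name_start),
          as.integer(name_end), amino_acid, anticodon, suffix)
}

#' Classify a fragment's cleavage type from mature-tRNA coordinates
#'
#' Rule-based assignment against the anticodon loop: fragments anchored at
#' position 1 are 5'-halves if they end inside the loop and 5'-tRFs if they
#' end before it; fragments anchored at the 3' terminus are 3'-halves if
#' they start inside the loop and 3'-tRFs if they start after it; everything
#' else is an i-tRF.
#'
#' @param start,end 1-based fragment coordinates on the mature tRNA
#'   (vectorised).
#' @param trna_len length of the mature tRNA.
#' @param anticodon_loop integer pair `(first, last)` position of the
#'   anticodon loop.
#' @return character vector of cleavage types.
#' @export
classify_cleavage <- function(start, end, trna_len, anticodon_loop) {
  stopifnot(length(anticodon_loop) == 2L, anticodon_loop[1] <= anticodon_loop[2],
            anticodon_loop[1] >= 1L, anticodon_loop[2] <= trna_len)
  if (any(start < 1L | end > trna_len | start > end)) {
    stop("fragment coordinates outside the tRNA (need 1 <= start <= end <= trna_len)",
         call. = FALSE)
  }
  lo <- anticodon_loop[1]; hi <- anticodon_loop[2]
  out <- rep("i-tRF", length(start))
  out[start == 1L & end >= lo & end <= hi] <- "5p-half"
  out[start == 1L & end < lo]              <- "5p-tRF"
  out[end == trna_len & start >= lo & start <= hi] <- "3p-half"
  out[end == trna_len & start > hi]        <- "3p-tRF"
  out
}

#' Validate a tRF annotation table
#'
#' Checks the invariants of the annotation schema: unique ids, lengths in
#' 16-50 nt, known origins and cleavage types, and, where a sequence is
#' present, agreement between `length` and the number of nucleotides.
#'
#' @param annotations data.frame with columns `id`, `length`,
#'   `genome_origin`, `amino_acid`, `anticodon`, `cleavage_type`, and
#'   optionally `sequence` and `parents`.
#' @return the validated annotation data.frame (invisibly unchanged).
#' @export
validate_annotations <- function(annotations) {
  req <- c("id", "length", "genome_origin", "amino_acid", "anticodon",
           "cleavage_type")
  miss <- setdiff(req, names(annotations))
  if (length(miss)) {
    stop("annotation table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(annotations$id)) {
    stop("duplicate tRF id(s): ",
         paste(unique(annotations$id[duplicated(annotations$id)]), collapse = ", "),
         call. = FALSE)
  }
  len <- annotations$length
  bad <- which(is.na(len) | len < TRF_LENGTH_RANGE[1] | len > TRF_LENGTH_RANGE[2])
  if (length(bad)) {
    stop(sprintf("fragment length outside %d-%d nt for id(s): %s",
                 TRF_LENGTH_RANGE[1], TRF_LENGTH_RANGE[2],
                 paste(utils::head(annotations$id[bad], 5L), collapse = ", ")),
         call. = FALSE)
  }
  if (!all(annotations$genome_origin %in% GENOME_ORIGINS)) {
    stop("genome_origin must be one of: ", paste(GENOME_ORIGINS, collapse = ", "),
         call. = FALSE)
  }
  if (!all(annotations$cleavage_type %in% CLEAVAGE_TYPES)) {
    stop("cleavage_type must be one of: ", paste(CLEAVAGE_TYPES, collapse = ", "),
         call. = FALSE)
  }
  if ("sequence" %in% names(annotations)) {
    has_seq <- !is.na(annotations$sequence) & nzchar(annotations$sequence)
    mism <- has_seq & nchar(annotations$sequence) != annotations$length
    if (any(mism)) {
      stop("length column disagrees with sequence for id(s): ",
           paste(utils::head(annotations$id[mism], 5L), collapse = ", "),
           call. = FALSE)
    }
  }
  invisible(annotations)
}

#' Read a tRF annotation TSV
#'
#' Expected columns: `id, sequence, length, origin, amino_acid, anticodon,
#' cleavage_type, parents` (header required; `origin` in `Nuc`/`MT`;
#' `parents` a comma-separated list, possibly empty).
#'
#' @param path path to the TSV file.
#' @return validated annotation data.frame with a `genome_origin` column.
#' @export
read_annotations <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if ("origin" %in% names(ann) && !"genome_origin" %in% names(ann)) {
    names(ann)[names(ann) == "origin"] <- "genome_origin"
  }
  validate_annotations(ann)
}

#' Family key strings for annotated fragments
#'
#' A family is the triple (genome origin, parental amino acid, cleavage
#' type); keys render as e.g. `"MT-Gly-i-tRF"`.
#'
#' @param annotations annotation data.frame.
#' @return character vector of family keys, one per fragment.
#' @export
family_key <- function(annotations) {
  paste(annotations$genome_origin, annotations$amino_acid,
        annotations$cleavage_type, sep = "-")
}

#' Build the family index over an annotation table
#'
#' Partitions all annotated fragments into families keyed by genome origin,
#' parental amino acid and cleavage type. Families are ordered
#' deterministically: origin (`Nuc` before `MT`), then amino acid
#' alphabetically, then cleavage type 5' to 3'. Families smaller than
#' `min_size` are retained for reporting but flagged untestable, since a
#' directional sign test over a single member is uninformative.
#'
#' @param annotations validated annotation data.frame.
#' @param min_size minimum number of members for a family to be testable
#'   (default 2).
#' @return an object of class `family_index`: a list with `families` (one
#'   row per family: key, origin, amino acid, cleavage type, size,
#'   testable), `members` (named list key -> member ids) and `membership`
#'   (named character vector id -> key).
#' @export
build_family_index <- function(annotations, min_size = 2L) {
  validate_annotations(annotations)
  stopifnot(min_size >= 1L)
  key <- family_key(annotations)
  if (nrow(annotations) == 0L) {
    fam <- data.frame(family = character(), genome_origin = character(),
                      amino_acid = character(), cleavage_type = character(),
                      size = integer(), testable = logical(),
                      stringsAsFactors = FALSE)
    return(structure(list(families = fam, members = list(),
                          membership = character(), min_size = min_size),
                     class = "family_index"))
  }
  members <- split(annotations$id, key)
  fam <- data.frame(
    family = names(members),
    size   = lengths(members),
    stringsAsFactors = FALSE
  )
  first <- annotations[!duplicated(key), , drop = FALSE]
  ord_meta <- match(fam$family, family_key(first))
  fam$genome_origin <- first$genome_origin[ord_meta]
  fam$amino_acid    <- first$amino_acid[ord_meta]
  fam$cleavage_type <- first$cleavage_type[ord_meta]
  o <- order(match(fam$genome_origin, GENOME_ORIGINS), fam$amino_acid,
             match(fam$cleavage_type, CLEAVAGE_TYPES))
  fam <- fam[o, c("family", "genome_origin", "amino_acid", "cleavage_type",
                  "size")]
  rownames(fam) <- NULL
  fam$testable <- fam$size >= min_size
  members <- lapply(members[fam$family], sort)
  membership <- stats::setNames(key, annotations$id)
  structure(list(families = fam, members = members, membership = membership,
                 min_size = as.integer(min_size)),
            class = "family_index")
}

#' @export
print.family_index <- function(x, ...) {
  cat(sprintf("family_index: %d fragments in %d families (%d testable, min_size = %d)\n",
              length(x$membership), nrow(x$families), sum(x$families$testable),
              x$min_size))
  print(utils::head(x$families, 10L))
  invisible(x)
}
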