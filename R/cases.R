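#' @useDynLib repotriad, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

MODALITIES <- c("small_molecule", "antibody", "protein", "other")
MOLECULE_KINDS <- c("protein", "nucleic_acid", "other", "unknown")

CASE_COLUMNS <- c("drug_name", "modality", "original_label", "original_mesh",
                  "secondary_label", "secondary_mesh", "original_targets",
                  "secondary_targets")

#' Build a target set
#'
#' A target set is a data.frame with one row per molecular target of a drug
#' in one indication context.
#'
#' @param target_id Character vector of identifiers (UniProt accessions or
#'   gene symbols). Normalised to uppercase with surrounding whitespace
#'   stripped; must be non-empty and contain no internal whitespace.
#' @param organism Species name(s), recycled.
#' @param molecule_kind One of `"protein"`, `"nucleic_acid"`, `"other"`,
#'   `"unknown"`; recycled. Only protein targets participate in
#'   classification.
#' @return A data.frame with columns `target_id`, `organism`, `molecule_kind`.
#' @export
target_set <- function(target_id = character(), organism = "Homo sapiens",
                       molecule_kind = "protein") {
  target_id <- toupper(trimws(as.character(target_id)))
  n <- length(target_id)
  if (n == 0L) {
    return(data.frame(target_id = character(), organism = character(),
                      molecule_kind = character(), stringsAsFactors = FALSE))
  }
  if (any(!nzchar(target_id)) || any(grepl("\\s", target_id))) {
    stop("target_id must be non-empty and contain no whitespace", call. = FALSE)
  }
  molecule_kind <- rep_len(as.character(molecule_kind), n)
  bad <- setdiff(molecule_kind, MOLECULE_KINDS)
  if (length(bad)) {
    stop("unknown molecule_kind: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  data.frame(target_id = target_id,
             organism = rep_len(as.character(organism), n),
             molecule_kind = molecule_kind,
             stringsAsFactors = FALSE)
}

#' Construct a table of repositioning cases
#'
#' Validates and assembles the package's central data structure: one row per
#' repositioning case (a drug moving from an original to a secondary
#' indication), with list-columns holding the per-indication target sets.
#'
#' @param drug_name Character vector, unique within the table.
#' @param modality Drug modality, one of `"small_molecule"`, `"antibody"`,
#'   `"protein"`, `"other"`.
#' @param original_label,secondary_label Free-text indication names.
#' @param original_mesh,secondary_mesh Top-level MeSH keys (or full tree
#'   numbers, truncated via [parse_mesh_root_key()]).
#' @param original_targets,secondary_targets Lists of target sets (see
#'   [target_set()]), one per case. May be empty for disease-centric cases,
#'   whose targets are never examined.
#' @return A data.frame of class `repo_cases`.
#' @export
repo_cases <- function(drug_name, modality, original_label, original_mesh,
                       secondary_label, secondary_mesh,
                       original_targets = NULL, secondary_targets = NULL) {
  n <- length(drug_name)
  drug_name <- trimws(as.character(drug_name))
  if (any(!nzchar(drug_name))) stop("empty drug_name", call. = FALSE)
  dup <- unique(drug_name[duplicated(drug_name)])
  if (length(dup)) {
    stop("duplicate drug name(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  modality <- as.character(modality)
  bad <- setdiff(modality, MODALITIES)
  if (length(bad)) {
    stop("unknown modality: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  norm_key <- function(x, what) {
    vapply(seq_along(x), function(i) {
      tryCatch(parse_mesh_root_key(x[i])$code, error = function(e) {
        stop(sprintf("case '%s': %s key: %s", drug_name[i], what,
                     conditionMessage(e)), call. = FALSE)
      })
    }, character(1))
  }
  original_mesh <- norm_key(as.character(original_mesh), "original")
  secondary_mesh <- norm_key(as.character(secondary_mesh), "secondary")
  empty_ts <- function() replicate(n, target_set(), simplify = FALSE)
  if (is.null(original_targets)) original_targets <- empty_ts()
  if (is.null(secondary_targets)) secondary_targets <- empty_ts()
  stopifnot(length(original_targets) == n, length(secondary_targets) == n)
  out <- data.frame(drug_name = drug_name, modality = modality,
                    original_label = as.character(original_label),
                    original_mesh = original_mesh,
                    secondary_label = as.character(secondary_label),
                    secondary_mesh = secondary_mesh,
                    stringsAsFactors = FALSE)
  out$original_targets <- original_targets
  out$secondary_targets <- secondary_targets
  class(out) <- c("repo_cases", "data.frame")
  out
}

# "ID|organism|kind" triples, ";"-separated, into a target set.
parse_target_field <- function(field, drug = "?") {
  field <- trimws(field)
  if (is.na(field) || !nzchar(field)) return(target_set())
  parts <- strsplit(strsplit(field, ";", fixed = TRUE)[[1]], "|", fixed = TRUE)
  ids <- character(0); orgs <- character(0); kinds <- character(0)
  for (p in parts) {
    p <- trimws(p)
    if (length(p) < 1L || length(p) > 3L || !nzchar(p[1])) {
      stop(sprintf("case '%s': malformed target triple '%s'", drug,
                   paste(p, collapse = "|")), call. = FALSE)
    }
    ids <- c(ids, p[1])
    orgs <- c(orgs, if (length(p) >= 2L) p[2] else "")
    kinds <- c(kinds, if (length(p) >= 3L) p[3] else "unknown")
  }
  tryCatch(target_set(ids, orgs, kinds), error = function(e) {
    stop(sprintf("case '%s': %s", drug, conditionMessage(e)), call. = FALSE)
  })
}

format_target_field <- function(ts) {
  if (nrow(ts) == 0L) return("")
  paste(sprintf("%s|%s|%s", ts$target_id, ts$organism, ts$molecule_kind),
        collapse = ";")
}

#' Read a repositioning case table
#'
#' Reads the tab-separated case-table format: one case per row, columns
#' `drug_name`, `modality`, `original_label`, `original_mesh`,
#' `secondary_label`, `secondary_mesh`, `original_targets`,
#' `secondary_targets`. Target sets are `";"`-separated
#' `"ID|organism|kind"` triples. Row order is preserved; duplicate drug
#' names and malformed MeSH keys are rejected.
#'
#' @param path Path to a UTF-8 TSV file with a header row.
#' @return A `repo_cases` table.
#' @seealso [write_cases()], [repo_cases()]
#' @export
read_cases <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", quote = "",
                           na.strings = NULL, fileEncoding = "UTF-8",
                           check.names = FALSE)
  missing <- setdiff(CASE_COLUMNS, names(raw))
  if (length(missing)) {
    stop("case table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(raw) == 0L) {
    return(repo_cases(character(), character(), character(), character(),
                      character(), character()))
  }
  ot <- lapply(seq_len(nrow(raw)), function(i)
    parse_target_field(raw$original_targets[i], raw$drug_name[i]))
  st <- lapply(seq_len(nrow(raw)), function(i)
    parse_target_field(raw$secondary_targets[i], raw$drug_name[i]))
  repo_cases(raw$drug_name, raw$modality, raw$original_label,
             raw$original_mesh, raw$secondary_label, raw$secondary_mesh,
             ot, st)
}

#' Write a repositioning case table
#'
#' Inverse of [read_cases()]: `read_cases(write_cases(x, f))` restores `x`
#' field for field.
#'
#' @param cases A `repo_cases` table.
#' @param path Output path (TSV, UTF-8).
#' @return `path`, invisibly.
#' @export
write_cases <- function(cases, path) {
  stopifnot(inherits(cases, "repo_cases"))
  flat <- data.frame(
    drug_name = cases$drug_name, modality = cases$modality,
    original_label = cases$original_label,
    original_mesh = cases$original_mesh,
    secondary_label = cases$secondary_label,
    secondary_mesh = cases$secondary_mesh,
    original_targets = vapply(cases$original_targets, format_target_field, ""),
    secondary_targets = vapply(cases$secondary_targets, format_target_field, ""),
    stringsAsFactors = FALSE
  )
  utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' The packaged 128-case repositioning corpus
#'
#' Loads the curated corpus of 128 small-molecule/protein-target
#' repositioning cases shipped with the package (transcribed from the
#' published disease-, target-, and drug-centric case listings), together
#' with the synthetic stand-in sequences for its five cross-organism
#' ortholog target pairs.
#'
#' @return A list with elements `cases` (a `repo_cases` table of 128 rows)
#'   and `sequences` (a named character vector of amino-acid sequences,
#'   keyed by target identifier).
#' @examples
#' corp <- rdd_corpus()
#' nrow(corp$cases)
#' @export
rdd_corpus <- function() {
  cases <- read_cases(system.file("extdata", "rdd128_cases.tsv",
                                  package = "repotriad", mustWork = TRUE))
  seqs <- read_sequences(system.file("extdata",
                                     "ortholog_sequences_synthetic.fasta",
                                     package = "repotriad", mustWork = TRUE))
  list(cases = cases, sequences = seqs)
}

#' @export
print.repo_cases <- function(x, ...) {
  cat(sprintf("<repo_cases> %d case(s)\n", nrow(x)))
  if (nrow(x)) {
    show <- utils::head(x, 6)
    cat(sprintf("  %-28s %s -> %s\n", show$drug_name, show$original_mesh,
                show$secondary_mesh), sep = "")
    if (nrow(x) > 6) cat("  ...\n")
  }
  invisible(x)
}
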