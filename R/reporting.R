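#' Original-by-secondary indication contingency matrix
#'
#' Counts repositioning cases for every (original, secondary) top-level
#' MeSH key pair. The diagonal holds within-class repositionings, so its
#' total equals the number of disease-centric cases.
#'
#' @param cases A `repo_cases` table.
#' @return An object of class `repo_contingency`: list with `counts`
#'   (integer matrix, rows = original keys, columns = secondary keys, both
#'   sorted), and `diagonal_total`.
#' @examples
#' m <- contingency_matrix(rdd_corpus()$cases)
#' m$counts["C04", "C04"]
#' @export
contingency_matrix <- function(cases) {
  stopifnot(inherits(cases, "repo_cases"))
  keys <- sort(unique(c(cases$original_mesh, cases$secondary_mesh)))
  counts <- matrix(0L, length(keys), length(keys),
                   dimnames = list(original = keys, secondary = keys))
  for (i in seq_len(nrow(cases))) {
    o <- cases$original_mesh[i]
    s <- cases$secondary_mesh[i]
    counts[o, s] <- counts[o, s] + 1L
  }
  structure(list(counts = counts,
                 diagonal_total = if (length(keys)) sum(diag(counts)) else 0L),
            class = "repo_contingency")
}

#' Write a contingency matrix as TSV (with a JSON mirror)
#'
#' @param m A [contingency_matrix()] result.
#' @param path Output TSV path; a `.json` sibling is written alongside when
#'   `json = TRUE`.
#' @param json Also write the JSON mirror.
#' @return `path`, invisibly.
#' @export
write_contingency <- function(m, path, json = TRUE) {
  stopifnot(inherits(m, "repo_contingency"))
  utils::write.table(m$counts, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  if (json) {
    jpath <- sub("\\.tsv$", ".json", path)
    if (identical(jpath, path)) jpath <- paste0(path, ".json")
    jsonlite::write_json(
      list(keys = colnames(m$counts), counts = m$counts,
           diagonal_total = m$diagonal_total),
      jpath, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' Tally disease-centric cases by shared disease group
#'
#' Groups the disease-centric cases by their shared top-level MeSH key.
#' Grouping target- or drug-centric cases by "the" key is undefined (those
#' classes have two distinct keys) and raises an error.
#'
#' @param cases The classified `repo_cases` table.
#' @param classification The matching [classify_all()] result.
#' @param label_filter Class to tally; only `"disease_centric"` is defined.
#' @return A data.frame sorted by descending count with columns `code`,
#'   `name`, `n`, and `drugs` (comma-joined, alphabetical within a group).
#' @export
category_tally <- function(cases, classification,
                           label_filter = "disease_centric") {
  stopifnot(inherits(cases, "repo_cases"),
            inherits(classification, "repo_classification"))
  if (!identical(label_filter, "disease_centric")) {
    stop("category_tally is defined only for disease-centric cases ",
         "(other classes have two distinct keys)", call. = FALSE)
  }
  dc <- cases_by_label(cases, classification, "disease_centric")
  if (nrow(dc) == 0L) {
    return(data.frame(code = character(), name = character(), n = integer(),
                      drugs = character(), stringsAsFactors = FALSE))
  }
  groups <- split(dc$drug_name, dc$original_mesh)
  tab <- mesh_key_table()
  out <- data.frame(
    code = names(groups),
    name = tab$name[match(names(groups), tab$code)],
    n = vapply(groups, length, 0L),
    drugs = vapply(groups, function(d) paste(sort(d), collapse = ", "), ""),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$n, out$code), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a local drug-target complex table
#'
#' An offline snapshot of structure availability: one row per deposited
#' complex, columns `drug_name`, `target_id`, `structure_id` (e.g. a PDB
#' code). Replaces any live structure-database query.
#'
#' @param path TSV path with a header row.
#' @return A data.frame with the three columns, identifiers normalised the
#'   same way as case-table targets.
#' @export
read_complex_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", quote = "",
                           na.strings = NULL, check.names = FALSE)
  need <- c("drug_name", "target_id", "structure_id")
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    stop("complex table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad <- which(!nzchar(trimws(raw$drug_name)) |
                 !nzchar(trimws(raw$target_id)))
  if (length(bad)) {
    stop("malformed complex table row(s): ",
         paste(utils::head(bad, 3), collapse = ", "), call. = FALSE)
  }
  data.frame(drug_name = trimws(raw$drug_name),
             target_id = toupper(trimws(raw$target_id)),
             structure_id = trimws(raw$structure_id),
             stringsAsFactors = FALSE)
}

#' Structural coverage of repositioning cases
#'
#' Checks, against a local complex table, whether each case has at least one
#' deposited structure of the drug bound to some original target and to some
#' secondary target. Matching is on normalised drug name (case-insensitive)
#' plus target identifier. Intended for the drug-centric cases, which are
#' the ones structure-based target prediction could serve.
#'
#' @param cases A `repo_cases` table (typically the drug-centric subset).
#' @param complexes A [read_complex_table()] data.frame.
#' @return An object of class `structural_coverage_report`: list with
#'   `per_case` (data.frame: `drug_name`, `has_original_complex`,
#'   `has_secondary_complex`, `fully_covered`) and `n_fully_covered`.
#' @export
structural_coverage <- function(cases, complexes) {
  stopifnot(inherits(cases, "repo_cases"), is.data.frame(complexes),
            all(c("drug_name", "target_id") %in% names(complexes)))
  ckey <- paste(tolower(trimws(complexes$drug_name)),
                toupper(trimws(complexes$target_id)))
  has_structure <- function(drug, ts) {
    ids <- protein_ids(ts)
    length(ids) > 0L && any(paste(tolower(trimws(drug)), ids) %in% ckey)
  }
  per_case <- data.frame(
    drug_name = cases$drug_name,
    has_original_complex = vapply(seq_len(nrow(cases)), function(i)
      has_structure(cases$drug_name[i], cases$original_targets[[i]]), TRUE),
    has_secondary_complex = vapply(seq_len(nrow(cases)), function(i)
      has_structure(cases$drug_name[i], cases$secondary_targets[[i]]), TRUE),
    stringsAsFactors = FALSE
  )
  per_case$fully_covered <- per_case$has_original_complex &
    per_case$has_secondary_complex
  structure(list(per_case = per_case,
                 n_fully_covered = sum(per_case$fully_covered)),
            class = "structural_coverage_report")
}

#' @export
print.structural_coverage_report <- function(x, ...) {
  cat(sprintf("<structural_coverage_report> %d case(s), %d fully covered\n",
              nrow(x$per_case), x$n_fully_covered))
  invisible(x)
}
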