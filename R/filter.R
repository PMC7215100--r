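#' Restrict a corpus to small-molecule drugs acting on protein targets
#'
#' A case is kept only if its drug modality is `small_molecule` and its
#' targets are proteins. Reasons are assigned with fixed precedence so
#' reports are deterministic: modality is checked first
#' (`non_small_molecule`), then target kind (`non_protein_target`).
#'
#' Mixed target sets are resolved in favour of the protein mechanism: a case
#' is excluded only when a non-empty target set contains *no* protein at all;
#' otherwise its non-protein members are dropped and the case is kept (e.g. a
#' drug whose secondary mechanism lists both a protein and an RNA species).
#' Empty target sets are vacuously acceptable — disease-centric cases carry
#' no examined targets.
#'
#' @param cases A `repo_cases` table.
#' @return An object of class `repo_filter_report`: list with `kept`
#'   (a `repo_cases` table, non-protein members removed), `removed`
#'   (a `repo_cases` table), `reasons` (character, parallel to `removed`),
#'   and counts `n_input`, `n_kept`, `n_removed`.
#' @export
filter_eligible <- function(cases) {
  stopifnot(inherits(cases, "repo_cases"))
  n <- nrow(cases)
  reason <- rep(NA_character_, n)
  keep_protein <- function(ts) ts[ts$molecule_kind == "protein", , drop = FALSE]
  all_nonprotein <- function(ts) {
    nrow(ts) > 0L && !any(ts$molecule_kind == "protein")
  }
  for (i in seq_len(n)) {
    if (cases$modality[i] != "small_molecule") {
      reason[i] <- "non_small_molecule"
    } else if (all_nonprotein(cases$original_targets[[i]]) ||
               all_nonprotein(cases$secondary_targets[[i]])) {
      reason[i] <- "non_protein_target"
    }
  }
  kept <- cases[is.na(reason), , drop = FALSE]
  kept$original_targets <- lapply(kept$original_targets, keep_protein)
  kept$secondary_targets <- lapply(kept$secondary_targets, keep_protein)
  removed <- cases[!is.na(reason), , drop = FALSE]
  rownames(kept) <- NULL
  rownames(removed) <- NULL
  structure(list(kept = kept, removed = removed,
                 reasons = reason[!is.na(reason)],
                 n_input = n, n_kept = nrow(kept), n_removed = nrow(removed)),
            class = "repo_filter_report")
}

#' @export
print.repo_filter_report <- function(x, ...) {
  cat(sprintf("<repo_filter_report> input %d, kept %d, removed %d\n",
              x$n_input, x$n_kept, x$n_removed))
  if (x$n_removed) {
    tab <- table(x$reasons)
    cat(sprintf("  %s: %d\n", names(tab), as.integer(tab)), sep = "")
  }
  invisible(x)
}

#' Serialise a filter report to JSON
#'
#' @param report A [filter_eligible()] report.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  stopifnot(inherits(report, "repo_filter_report"))
  obj <- list(
    n_input = report$n_input, n_kept = report$n_kept,
    n_removed = report$n_removed,
    removed = if (report$n_removed) {
      data.frame(drug_name = report$removed$drug_name,
                 reason = report$reasons, stringsAsFactors = FALSE)
    } else {
      data.frame(drug_name = character(), reason = character())
    }
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
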