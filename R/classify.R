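CLASS_LABELS <- c("disease_centric", "target_centric", "drug_centric")

round_half_up <- function(x) floor(x + 0.5)

#' Classifier configuration
#'
#' @param identity_threshold Ortholog identity threshold in (0, 1);
#'   default 0.30 (strict inequality, see [ortholog_decision()]).
#' @param target_match_mode How target identifiers must overlap for the
#'   shared-target rule: `"any_shared"` (default; one common identifier
#'   suffices, matching corpora where only a subset of receptors carries
#'   over) or `"all_shared"` (every secondary target identifier must occur
#'   among the original targets).
#' @param scoring Alignment scoring for the ortholog branch
#'   (see [align_scoring()]).
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(identity_threshold = 0.30,
                              target_match_mode = c("any_shared",
                                                    "all_shared"),
                              scoring = align_scoring()) {
  target_match_mode <- match.arg(target_match_mode)
  stopifnot(is.numeric(identity_threshold), length(identity_threshold) == 1L,
            identity_threshold > 0, identity_threshold < 1,
            inherits(scoring, "align_scoring"))
  structure(list(identity_threshold = identity_threshold,
                 target_match_mode = target_match_mode,
                 scoring = scoring),
            class = "classifier_config")
}

protein_ids <- function(ts) unique(ts$target_id[ts$molecule_kind == "protein"])

# Step-wise rule evaluation for one case. Returns label plus provenance of
# the firing rule; `sequences` is a named amino-acid vector keyed by target
# identifier (absent sequences simply disable the ortholog branch for that
# pair, mirroring a manual workflow where alignment is run only for
# candidate ortholog pairs).
classify_case_impl <- function(drug_name, original_mesh, secondary_mesh,
                               original_targets, secondary_targets,
                               sequences, cfg) {
  # Rule 1: same top-level disease key; targets are never examined.
  if (original_mesh == secondary_mesh) {
    return(list(label = "disease_centric", rule = "shared_mesh_key",
                match_type = NA_character_, match = NA_character_,
                identity = NA_real_))
  }
  ot <- protein_ids(original_targets)
  st <- protein_ids(secondary_targets)
  if (length(ot) == 0L && length(st) == 0L) {
    stop(sprintf(
      "case '%s': target rule reached with both target sets empty (literature augmentation missing)",
      drug_name), call. = FALSE)
  }
  # Rule 2a: shared identifier.
  shared <- intersect(ot, st)
  id_match <- switch(cfg$target_match_mode,
    any_shared = length(shared) > 0L,
    all_shared = length(st) > 0L && all(st %in% ot)
  )
  if (id_match) {
    return(list(label = "target_centric", rule = "shared_target",
                match_type = "identical_id",
                match = paste(sort(shared), collapse = ","),
                identity = NA_real_))
  }
  # Rule 2b: cross-identifier ortholog pair, where sequences allow it.
  for (o in ot) {
    for (s in st) {
      if (o == s) next
      if (is.na(sequences[o]) || is.na(sequences[s])) next
      r <- global_align(sequences[[o]], sequences[[s]], cfg$scoring)
      idf <- identity_fraction(r)
      if (ortholog_decision(idf, cfg$identity_threshold)$is_ortholog) {
        return(list(label = "target_centric", rule = "shared_target",
                    match_type = "ortholog",
                    match = paste(o, s, sep = "~"), identity = idf))
      }
    }
  }
  # Rule 3: residual.
  list(label = "drug_centric", rule = "residual", match_type = NA_character_,
       match = NA_character_, identity = NA_real_)
}

lookup_vec <- function(sequences) {
  if (is.null(sequences) || length(sequences) == 0L) {
    return(structure(character(), names = character()))
  }
  stopifnot(is.character(sequences), !is.null(names(sequences)))
  sequences
}

#' Classify one repositioning case
#'
#' Applies the step-wise, short-circuiting rules: (1) identical original and
#' secondary top-level MeSH keys make a case disease-centric (targets are
#' not examined); (2) otherwise a shared protein-target identifier, or a
#' cross-identifier target pair whose sequence identity strictly exceeds the
#' ortholog threshold, makes it target-centric; (3) the residual is
#' drug-centric.
#'
#' @param case A single-row `repo_cases` table (one case).
#' @param sequences Optional named character vector of amino-acid sequences
#'   keyed by target identifier; enables the ortholog branch.
#' @param cfg A [classifier_config()].
#' @return A list with `label` (one of `disease_centric`, `target_centric`,
#'   `drug_centric`), the firing `rule`, `match_type` (`identical_id` or
#'   `ortholog` for target-centric cases), `match`, and `identity`.
#' @export
classify_case <- function(case, sequences = NULL, cfg = classifier_config()) {
  stopifnot(inherits(case, "repo_cases"), nrow(case) == 1L,
            inherits(cfg, "classifier_config"))
  classify_case_impl(case$drug_name, case$original_mesh, case$secondary_mesh,
                     case$original_targets[[1]], case$secondary_targets[[1]],
                     lookup_vec(sequences), cfg)
}

#' Classify a whole corpus
#'
#' Applies [classify_case()] to every case and aggregates counts, raw
#' fractions, and integer percentages (rounded half-up). Per-case errors are
#' collected and reported together.
#'
#' @inheritParams classify_case
#' @param cases A `repo_cases` table (all cases must already have passed
#'   [filter_eligible()]).
#' @return An object of class `repo_classification`: list with `n_total`,
#'   `n_disease`, `n_target`, `n_drug`, integer `pct_*` fields, raw `frac_*`
#'   fields, `empty` flag (percentages are reported as 0 with `empty = TRUE`
#'   on an empty corpus), and `per_case` (data.frame with one row per case:
#'   `drug_name`, `label`, `rule`, `match_type`, `match`, `identity`).
#' @export
classify_all <- function(cases, sequences = NULL, cfg = classifier_config()) {
  stopifnot(inherits(cases, "repo_cases"), inherits(cfg, "classifier_config"))
  seqs <- lookup_vec(sequences)
  n <- nrow(cases)
  rows <- vector("list", n)
  errors <- character(0)
  for (i in seq_len(n)) {
    res <- tryCatch(
      classify_case_impl(cases$drug_name[i], cases$original_mesh[i],
                         cases$secondary_mesh[i], cases$original_targets[[i]],
                         cases$secondary_targets[[i]], seqs, cfg),
      error = function(e) conditionMessage(e)
    )
    if (is.character(res)) errors <- c(errors, res) else rows[[i]] <- res
  }
  if (length(errors)) {
    stop("classification failed for ", length(errors), " case(s):\n  ",
         paste(errors, collapse = "\n  "), call. = FALSE)
  }
  per_case <- data.frame(
    drug_name = cases$drug_name,
    label = vapply(rows, `[[`, "", "label"),
    rule = vapply(rows, `[[`, "", "rule"),
    match_type = vapply(rows, `[[`, "", "match_type"),
    match = vapply(rows, `[[`, "", "match"),
    identity = vapply(rows, `[[`, 0, "identity"),
    stringsAsFactors = FALSE
  )
  counts <- vapply(CLASS_LABELS, function(l) sum(per_case$label == l), 0L)
  pct <- if (n > 0L) round_half_up(100 * counts / n) else c(0L, 0L, 0L)
  frac <- if (n > 0L) counts / n else c(0, 0, 0)
  structure(list(
    n_total = n,
    n_disease = counts[["disease_centric"]],
    n_target = counts[["target_centric"]],
    n_drug = counts[["drug_centric"]],
    pct_disease = as.integer(pct[[1]]), pct_target = as.integer(pct[[2]]),
    pct_drug = as.integer(pct[[3]]),
    frac_disease = frac[[1]], frac_target = frac[[2]], frac_drug = frac[[3]],
    empty = n == 0L,
    per_case = per_case
  ), class = "repo_classification")
}

#' Count target-centric cases resting on an ortholog pair
#'
#' Among target-centric cases, counts those whose classification fired on a
#' cross-identifier ortholog pair (two homologous targets in different
#' organisms) rather than on an identical target identifier.
#'
#' @param classification A [classify_all()] result.
#' @return A non-negative integer.
#' @export
count_ortholog_cases <- function(classification) {
  stopifnot(inherits(classification, "repo_classification"))
  pc <- classification$per_case
  sum(pc$label == "target_centric" &
        !is.na(pc$match_type) & pc$match_type == "ortholog")
}

#' Subset cases by assigned class
#'
#' @param cases The classified `repo_cases` table.
#' @param classification The matching [classify_all()] result.
#' @param label One of `"disease_centric"`, `"target_centric"`,
#'   `"drug_centric"`.
#' @return The `repo_cases` rows carrying `label`, in corpus order.
#' @export
cases_by_label <- function(cases, classification, label) {
  stopifnot(inherits(cases, "repo_cases"),
            inherits(classification, "repo_classification"),
            label %in% CLASS_LABELS,
            identical(cases$drug_name, classification$per_case$drug_name))
  out <- cases[classification$per_case$label == label, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.repo_classification <- function(x, ...) {
  cat(sprintf("<repo_classification> %d case(s)%s\n", x$n_total,
              if (x$empty) " (empty corpus)" else ""))
  if (!x$empty) {
    cat(sprintf("  disease-centric: %3d (%d%%, raw %.4f)\n", x$n_disease,
                x$pct_disease, x$frac_disease))
    cat(sprintf("  target-centric:  %3d (%d%%, raw %.4f)\n", x$n_target,
                x$pct_target, x$frac_target))
    cat(sprintf("  drug-centric:    %3d (%d%%, raw %.4f)\n", x$n_drug,
                x$pct_drug, x$frac_drug))
  }
  invisible(x)
}

#' Serialise a classification to JSON
#'
#' @param classification A [classify_all()] result.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_classification <- function(classification, path) {
  stopifnot(inherits(classification, "repo_classification"))
  x <- classification
  obj <- list(
    n_total = x$n_total, n_disease = x$n_disease, n_target = x$n_target,
    n_drug = x$n_drug,
    pct = list(disease = x$pct_disease, target = x$pct_target,
               drug = x$pct_drug),
    frac = list(disease = x$frac_disease, target = x$frac_target,
                drug = x$frac_drug),
    empty = x$empty,
    n_ortholog_target_centric = count_ortholog_cases(x),
    per_case = x$per_case
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       na = "null", digits = NA)
  invisible(path)
}
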