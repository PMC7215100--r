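#' Load a packaged substitution matrix
#'
#' The package ships the standard NCBI BLOSUM62 matrix (20 amino acids plus
#' X) as a plain-text table so that no network access is ever needed.
#'
#' @param name Matrix name; currently only `"BLOSUM62"`.
#' @return A symmetric integer matrix with residue row/column names.
#' @export
read_substitution_matrix <- function(name = "BLOSUM62") {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".tsv"), package = "repotriad",
                      mustWork = TRUE)
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   row.names = 1, check.names = FALSE))
  storage.mode(m) <- "integer"
  m
}

#' Alignment scoring configuration
#'
#' @param matrix Substitution matrix name (see [read_substitution_matrix()])
#'   or a symmetric named integer matrix.
#' @param gap Linear gap penalty per gap column (a negative number; default
#'   -8). The package deliberately uses a linear rather than affine gap
#'   model: the downstream consumer is a coarse 30% identity threshold, and
#'   a linear model admits an exhaustive enumeration oracle.
#' @return An object of class `align_scoring`.
#' @export
align_scoring <- function(matrix = "BLOSUM62", gap = -8) {
  if (is.character(matrix)) matrix <- read_substitution_matrix(matrix)
  stopifnot(is.matrix(matrix), !is.null(rownames(matrix)),
            identical(rownames(matrix), colnames(matrix)),
            is.numeric(gap), length(gap) == 1L, gap < 0)
  structure(list(matrix = matrix, gap = as.numeric(gap)),
            class = "align_scoring")
}

encode_seq <- function(s, alphabet) {
  chars <- strsplit(toupper(s), "")[[1]]
  idx <- match(chars, alphabet)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    stop(sprintf("residue '%s' (position %d) not in substitution matrix",
                 chars[bad], bad), call. = FALSE)
  }
  idx - 1L
}

#' Global pairwise alignment
#'
#' Computes the optimal Needleman-Wunsch global alignment of two amino-acid
#' sequences under a substitution matrix and a linear gap penalty, with
#' deterministic traceback (diagonal preferred over a gap in the second
#' sequence, preferred over a gap in the first). Alongside the aligned
#' strings it tallies the two quantities the ortholog criterion consumes:
#' identical columns, and non-identical gap-free columns whose substitution
#' score is strictly positive ("similar"). Gap columns count as neither.
#'
#' @param seq_a,seq_b Non-empty amino-acid strings.
#' @param scoring An [align_scoring()] object.
#' @return An object of class `alignment_result`: list with `aligned_a`,
#'   `aligned_b` (gapped strings of equal length), `alignment_length`,
#'   `n_identical`, `n_similar`, and `score`.
#' @examples
#' r <- global_align("HEAGAWGHEE", "PAWHEAE", align_scoring())
#' identity_fraction(r)
#' @export
global_align <- function(seq_a, seq_b, scoring = align_scoring()) {
  stopifnot(inherits(scoring, "align_scoring"),
            is.character(seq_a), length(seq_a) == 1L,
            is.character(seq_b), length(seq_b) == 1L)
  if (!nzchar(seq_a) || !nzchar(seq_b)) {
    stop("sequences must be non-empty", call. = FALSE)
  }
  alpha <- rownames(scoring$matrix)
  ea <- encode_seq(seq_a, alpha)
  eb <- encode_seq(seq_b, alpha)
  raw <- .nw_align(ea, eb, scoring$matrix, scoring$gap)
  decode <- function(idx) {
    out <- rep("-", length(idx))
    out[idx >= 0L] <- alpha[idx[idx >= 0L] + 1L]
    out
  }
  ga <- decode(raw$a)
  gb <- decode(raw$b)
  no_gap <- raw$a >= 0L & raw$b >= 0L
  ident <- no_gap & raw$a == raw$b
  pair_scores <- rep(NA_integer_, length(raw$a))
  pair_scores[no_gap] <- scoring$matrix[cbind(raw$a[no_gap] + 1L,
                                              raw$b[no_gap] + 1L)]
  simil <- no_gap & !ident & !is.na(pair_scores) & pair_scores > 0L
  structure(list(
    aligned_a = paste(ga, collapse = ""),
    aligned_b = paste(gb, collapse = ""),
    alignment_length = length(raw$a),
    n_identical = sum(ident),
    n_similar = sum(simil),
    score = raw$score
  ), class = "alignment_result")
}

#' Sequence identity of an alignment
#'
#' The identity statistic used by the ortholog criterion: identical plus
#' similar aligned residues, divided by the total alignment length
#' (including gap columns).
#'
#' @param r An [global_align()] result.
#' @return A number in \[0, 1\].
#' @export
identity_fraction <- function(r) {
  stopifnot(inherits(r, "alignment_result"))
  (r$n_identical + r$n_similar) / r$alignment_length
}

#' Ortholog decision at an identity threshold
#'
#' Two targets are treated as orthologs when their pairwise identity
#' fraction strictly exceeds the threshold (default 30%, the classical
#' homology-detection cutoff); identity exactly at the threshold is not
#' enough.
#'
#' @param identity Identity fraction in \[0, 1\].
#' @param threshold Threshold in (0, 1); default 0.30.
#' @return An object of class `ortholog_decision`: list with
#'   `identity_fraction`, `threshold`, `is_ortholog`.
#' @export
ortholog_decision <- function(identity, threshold = 0.30) {
  stopifnot(is.numeric(identity), length(identity) == 1L,
            is.numeric(threshold), length(threshold) == 1L)
  if (is.na(identity) || identity < 0 || identity > 1) {
    stop("identity must lie in [0, 1]", call. = FALSE)
  }
  if (is.na(threshold) || threshold <= 0 || threshold >= 1) {
    stop("threshold must lie in (0, 1)", call. = FALSE)
  }
  structure(list(identity_fraction = identity, threshold = threshold,
                 is_ortholog = identity > threshold),
            class = "ortholog_decision")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf(
    "<alignment_result> length %d, identical %d, similar %d, score %g\n",
    x$alignment_length, x$n_identical, x$n_similar, x$score))
  invisible(x)
}
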