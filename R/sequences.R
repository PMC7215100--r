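AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V", "X")

# Reject anything outside the 20 standard residues plus X; reports the first
# offending record and 1-based position.
validate_residues <- function(seqs) {
  pat <- sprintf("[^%s]", paste(AA_ALPHABET, collapse = ""))
  for (i in seq_along(seqs)) {
    m <- regexpr(pat, seqs[[i]])
    if (m > 0L) {
      stop(sprintf("illegal residue '%s' in record '%s' at position %d",
                   substr(seqs[[i]], m, m), names(seqs)[i], m), call. = FALSE)
    }
  }
  invisible(seqs)
}

#' Read a protein sequence store from FASTA
#'
#' Sequences are upper-cased and restricted to the 20 standard amino acids
#' plus `X`; the header token before the first whitespace becomes the key.
#'
#' @param path Path to a FASTA file (single-line or wrapped records).
#' @return A named character vector of amino-acid sequences.
#' @export
read_sequences <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  keys <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1)
  if (anyDuplicated(keys)) {
    stop("duplicate FASTA header(s): ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "),
         call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- keys
  validate_residues(seqs)
  seqs
}

#' Write a protein sequence store to FASTA
#'
#' @param seqs Named character vector of amino-acid sequences.
#' @param path Output path.
#' @param width Line-wrap width for the sequence body.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(seqs, path, width = 60L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)),
            all(nzchar(names(seqs))))
  validate_residues(toupper(seqs))
  set <- Biostrings::BStringSet(toupper(seqs))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}
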