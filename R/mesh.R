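#' Top-level MeSH disease-group keys
#'
#' The 26 top-level Medical Subject Headings (MeSH) tree keys under which
#' repositioning indications are grouped, with their display names. Twenty of
#' the keys sit in the disease branch (C); the remainder (E01, F01, F03, G07,
#' G08, G11) cover diagnosis, behaviour, mental disorders and physiological
#' phenomena, and are treated identically to C-branch codes throughout the
#' package.
#'
#' @return A data.frame with columns `code` (3-character key, e.g. `"C04"`)
#'   and `name` (display name, e.g. `"Neoplasms"`).
#' @examples
#' mesh_key_table()[1:3, ]
#' @export
mesh_key_table <- function() {
  df <- data.frame(
    code = c("C01", "C02", "C03", "C04", "C06", "C07", "C08", "C10",
             "C11", "C12", "C13", "C14", "C15", "C16", "C17", "C18",
             "C19", "C20", "C23", "C25", "E01", "F01", "F03", "G07",
             "G08", "G11"),
    name = c(
      "Bacterial Infections and Mycoses",
      "Virus Diseases",
      "Parasitic Diseases",
      "Neoplasms",
      "Digestive System Diseases",
      "Stomatognathic Diseases",
      "Respiratory Tract Diseases",
      "Nervous System Diseases",
      "Eye Diseases",
      "Male Urogenital Diseases",
      "Female Urogenital Diseases and Pregnancy Complications",
      "Cardiovascular Diseases",
      "Hemic and Lymphatic Diseases",
      "Congenital, Hereditary, and Neonatal Diseases and Abnormalities",
      "Skin and Connective Tissue Diseases",
      "Nutritional and Metabolic Diseases",
      "Endocrine System Diseases",
      "Immune System Diseases",
      "Pathological Conditions, Signs and Symptoms",
      "Chemically-Induced Disorders",
      "Diagnosis",
      "Behaviour Mechanisms",
      "Mental Disorders",
      "Physiological processes",
      "Reproductive and Urinary Physiological Phenomena",
      "Musculoskeletal and Neural Physiological Phenomena"
    ),
    stringsAsFactors = FALSE
  )
  df
}

#' Parse a MeSH tree number or root key
#'
#' Truncates a full MeSH tree number (e.g. `"C04.557"`) at the first `"."`
#' and validates the remaining top-level key: one uppercase letter followed
#' by exactly two digits. The display name is filled in from
#' [mesh_key_table()] when the code is one of the 26 packaged disease-group
#' keys, and left empty otherwise.
#'
#' @param raw A non-empty character scalar: a tree number or a bare 3-char key.
#' @return An object of class `mesh_root_key`: a list with `code` and `name`.
#' @examples
#' parse_mesh_root_key("C04.557")  # code "C04", name "Neoplasms"
#' parse_mesh_root_key("C04")      # idempotent on root keys
#' @export
parse_mesh_root_key <- function(raw) {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw) || !nzchar(raw)) {
    stop("MeSH key must be a single non-empty string", call. = FALSE)
  }
  code <- sub("\\..*$", "", trimws(raw))
  if (!grepl("^[A-Z][0-9]{2}$", code)) {
    stop(sprintf("malformed MeSH root key: '%s' (from input '%s')", code, raw),
         call. = FALSE)
  }
  tab <- mesh_key_table()
  i <- match(code, tab$code)
  structure(
    list(code = code, name = if (is.na(i)) "" else tab$name[i]),
    class = "mesh_root_key"
  )
}

#' @export
print.mesh_root_key <- function(x, ...) {
  cat(sprintf("<mesh_root_key> %s%s\n", x$code,
              if (nzchar(x$name)) paste0(" (", x$name, ")") else ""))
  invisible(x)
}

# Resolve a display name to its root key code; exact match after whitespace
# normalisation, NA when unknown.
mesh_name_to_code <- function(name) {
  tab <- mesh_key_table()
  i <- match(tolower(trimws(name)), tolower(tab$name))
  if (is.na(i)) NA_character_ else tab$code[i]
}
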