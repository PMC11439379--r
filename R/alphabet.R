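#' Amino-acid alphabets
#'
#' The 20-letter standard amino-acid alphabet and the reduced 18-letter
#' alphabet (omitting isoleucine and valine) that some published substitution
#' screens enumerate. An alphabet is an ordered set of single-letter residue
#' codes with a name attribute; it is always a subset of the standard 20.
#'
#' @param name `"standard20"` or `"paper18"`, or a character vector of
#'   residue codes to build a custom alphabet from (duplicates are an error).
#' @param residues for a custom alphabet, the residue codes (ignored when
#'   `name` is one of the built-ins).
#' @return A character vector of residue codes with class `"aa_alphabet"`.
#' @examples
#' aa_alphabet("standard20")
#' aa_alphabet("paper18")
#' @export
aa_alphabet <- function(name = "standard20", residues = NULL) {
  if (is.null(residues)) {
    residues <- switch(name,
      standard20 = AA_STANDARD20,
      paper18 = setdiff(AA_STANDARD20, c("I", "V")),
      stop("unknown built-in alphabet '", name, "'; supply `residues` for a custom one",
           call. = FALSE)
    )
  }
  residues <- as.character(residues)
  if (anyDuplicated(residues)) {
    stop("alphabet contains duplicate residues", call. = FALSE)
  }
  bad <- setdiff(residues, AA_STANDARD20)
  if (length(bad)) {
    stop("alphabet contains non-standard residues: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!length(residues)) stop("alphabet is empty", call. = FALSE)
  structure(residues, class = "aa_alphabet", name = name)
}

#' The 20 standard amino acids, alphabetical by one-letter code
#' @export
AA_STANDARD20 <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

#' @export
print.aa_alphabet <- function(x, ...) {
  cat("<aa_alphabet '", attr(x, "name"), "'> ", paste(unclass(x), collapse = ""),
      " (", length(x), " residues)\n", sep = "")
  invisible(x)
}
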