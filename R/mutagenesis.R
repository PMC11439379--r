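#' Deterministic identifier for a single-substitution variant
#'
#' @param template_id identifier of the template peptide.
#' @param position 1-based substituted position; must lie within
#'   `template_length` when that is supplied.
#' @param sub substituted residue (single letter).
#' @param template_length optional template length for bounds checking.
#' @return `"<template_id>_p<position><sub>"`, e.g. `"AtMP1_p13Y"`.
#' @examples
#' variant_id("AtMP1", 13, "Y")
#' @export
variant_id <- function(template_id, position, sub, template_length = NULL) {
  position <- as.integer(position)
  if (position < 1L) stop("position must be >= 1 (positions are 1-based)", call. = FALSE)
  if (!is.null(template_length) && position > template_length) {
    stop("position ", position, " exceeds template length ", template_length,
         call. = FALSE)
  }
  sprintf("%s_p%d%s", template_id, position, sub)
}

#' Exhaustive single-residue substitution library
#'
#' Enumerates every peptide that differs from the template at exactly one
#' position, substituting each residue in turn with each letter of the
#' alphabet. Variants are generated in scan order: position ascending, then
#' alphabet order within a position. Self-substitutions (substituting a
#' residue with itself), which would duplicate the template, are dropped by
#' default; with `exclude_self = FALSE` they are still removed as duplicates
#' of the template, matching the requirement that all library members be
#' distinct sequences.
#'
#' With `exclude_self = TRUE` the library size is the sum over positions of
#' `|alphabet| - [template residue in alphabet]`; for a template of length L
#' whose residues all belong to an alphabet of size k this is `L * (k - 1)`
#' (e.g. 456 for a 24-mer over the standard 20).
#'
#' @param template a `"peptide"` object (see [parse_peptide()]) or sequence
#'   string.
#' @param alphabet an [aa_alphabet()]; default the standard 20.
#' @param exclude_self drop substitutions by the template's own residue.
#' @return An object of class `"substitution_library"`: a list with the
#'   `template` peptide, the `alphabet`, and `variants`, a data frame with
#'   columns `id`, `sequence`, `parent`, `position`, `from`, `to`.
#' @examples
#' lib <- single_substitution_library(parse_peptide("AtMP1", "THPP"))
#' nrow(lib$variants) # 4 * 19
#' @export
single_substitution_library <- function(template,
                                        alphabet = aa_alphabet("standard20"),
                                        exclude_self = TRUE) {
  if (!inherits(template, "peptide")) template <- parse_peptide("template", template)
  if (!inherits(alphabet, "aa_alphabet")) alphabet <- aa_alphabet(residues = alphabet)
  if (!length(alphabet)) stop("alphabet is empty", call. = FALSE)

  seq <- template$sequence
  L <- nchar(seq)
  res <- strsplit(seq, "", fixed = TRUE)[[1L]]
  ab <- as.character(alphabet)

  pos <- rep(seq_len(L), each = length(ab))
  sub <- rep(ab, times = L)
  keep <- sub != res[pos]
  if (!exclude_self) {
    # self-substitutions reproduce the template; drop them as duplicates
    keep <- keep
  }
  pos <- pos[keep]
  sub <- sub[keep]

  seqs <- vapply(seq_along(pos), function(i) {
    paste0(substr(seq, 1L, pos[i] - 1L), sub[i], substr(seq, pos[i] + 1L, L))
  }, character(1L))

  variants <- data.frame(
    id = vapply(seq_along(pos),
                function(i) variant_id(template$id, pos[i], sub[i], L),
                character(1L)),
    sequence = seqs,
    parent = template$id,
    position = pos,
    from = res[pos],
    to = sub,
    stringsAsFactors = FALSE
  )
  structure(list(template = template, alphabet = alphabet, variants = variants),
            class = "substitution_library")
}

#' @export
print.substitution_library <- function(x, ...) {
  cat("<substitution_library> template ", x$template$id, " (",
      nchar(x$template$sequence), " aa), alphabet '",
      attr(x$alphabet, "name"), "' (", length(x$alphabet), "), ",
      nrow(x$variants), " variants\n", sep = "")
  invisible(x)
}
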