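#' Parse and validate a peptide sequence
#'
#' Builds a validated peptide record from a raw sequence string. The sequence
#' is whitespace-stripped and upper-cased, and every character must belong to
#' the 20-letter standard amino-acid alphabet; ambiguity and non-proteinogenic
#' codes (B, J, O, U, X, Z) are rejected, not coerced. Positions are 1-based
#' everywhere in this package.
#'
#' @param id short free-text identifier.
#' @param raw sequence string (single-letter codes, any case).
#' @param provenance optional single-substitution record as produced by
#'   [substitution_provenance()]: the parent id, 1-based position, original
#'   and substituted residue. When given, applying the substitution to
#'   `parent_sequence` must reproduce `raw`.
#' @param parent_sequence parent sequence used to check `provenance`.
#' @return An object of class `"peptide"`: a list with elements `id`,
#'   `sequence` and (possibly `NULL`) `provenance`.
#' @examples
#' parse_peptide("ATMP6", "THPPTTTTTTTTTTTTTAAPARTT")
#' parse_peptide("x", "thpp")$sequence # "THPP"
#' @export
parse_peptide <- function(id, raw, provenance = NULL, parent_sequence = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(raw), length(raw) == 1L)
  seq <- toupper(gsub("[[:space:]]", "", raw))
  if (!nzchar(seq)) stop("empty sequence for peptide '", id, "'", call. = FALSE)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% AA_STANDARD20)
  if (length(bad)) {
    stop("invalid residue '", chars[bad[1L]], "' at position ", bad[1L],
         " in peptide '", id, "'", call. = FALSE)
  }
  if (!is.null(provenance)) {
    if (!is.null(parent_sequence)) {
      rebuilt <- apply_substitution(parent_sequence, provenance)
      if (!identical(rebuilt, seq)) {
        stop("provenance of '", id, "' does not reproduce its sequence from parent",
             call. = FALSE)
      }
    }
    if (substr(seq, provenance$position, provenance$position) != provenance$to) {
      stop("provenance of '", id, "' disagrees with the residue at position ",
           provenance$position, call. = FALSE)
    }
  }
  structure(list(id = id, sequence = seq, provenance = provenance),
            class = "peptide")
}

#' Record a single-residue substitution
#'
#' @param parent_id identifier of the template peptide.
#' @param position 1-based position of the substitution.
#' @param from,to original and substituted residue (single letters).
#' @return A list of class `"substitution"`.
#' @export
substitution_provenance <- function(parent_id, position, from, to) {
  stopifnot(position >= 1L, from %in% AA_STANDARD20, to %in% AA_STANDARD20)
  structure(list(parent_id = parent_id, position = as.integer(position),
                 from = from, to = to),
            class = "substitution")
}

#' Apply a substitution record to a parent sequence
#'
#' @param parent_sequence the template sequence.
#' @param provenance a [substitution_provenance()] record.
#' @return The substituted sequence.
#' @export
apply_substitution <- function(parent_sequence, provenance) {
  L <- nchar(parent_sequence)
  p <- provenance$position
  if (p < 1L || p > L) {
    stop("substitution position ", p, " outside 1..", L, call. = FALSE)
  }
  if (substr(parent_sequence, p, p) != provenance$from) {
    stop("parent has '", substr(parent_sequence, p, p), "' at position ", p,
         ", not '", provenance$from, "'", call. = FALSE)
  }
  paste0(substr(parent_sequence, 1L, p - 1L), provenance$to,
         substr(parent_sequence, p + 1L, L))
}

#' @export
print.peptide <- function(x, ...) {
  cat("<peptide ", x$id, "> ", x$sequence, " (", nchar(x$sequence), " aa)\n",
      sep = "")
  if (!is.null(x$provenance)) {
    pv <- x$provenance
    cat("  from ", pv$parent_id, ": ", pv$from, pv$position, pv$to, "\n", sep = "")
  }
  invisible(x)
}

#' Residue composition of a peptide
#'
#' @param x a `"peptide"` object or a plain sequence string.
#' @return Named integer vector of residue counts; the counts sum to the
#'   sequence length. Residues absent from the sequence are omitted.
#' @examples
#' residue_counts("THPPTTTTTTTTTTTTTAAPARTT")
#' @export
residue_counts <- function(x) {
  seq <- peptide_sequence(x)
  tab <- table(strsplit(seq, "", fixed = TRUE)[[1L]])
  stats::setNames(as.integer(tab), names(tab))
}

# Accept either a peptide object or a bare sequence string (validated).
peptide_sequence <- function(x) {
  if (inherits(x, "peptide")) return(x$sequence)
  parse_peptide("peptide", x)$sequence
}

# Vectorised variant for internal use on library columns.
peptide_sequences <- function(x) {
  if (inherits(x, "peptide")) return(x$sequence)
  vapply(x, function(s) parse_peptide("peptide", s)$sequence, character(1L),
         USE.NAMES = FALSE)
}
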