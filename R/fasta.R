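#' Read a peptide library from FASTA
#'
#' Reads standard FASTA into a peptide-library data frame. The description
#' line may carry single-substitution provenance in the form
#' `parent=<id> pos=<n> <orig>><sub>` (as written by
#' [write_peptide_fasta()]), which is parsed back into the `parent`,
#' `position`, `from` and `to` columns.
#'
#' @param path FASTA file of amino-acid sequences.
#' @return A data frame with columns `id`, `sequence`, `parent`, `position`,
#'   `from`, `to` (provenance columns are `NA` where absent).
#' @export
read_peptide_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  if (!length(aa)) stop("no sequences in ", path, call. = FALSE)
  headers <- names(aa)
  ids <- sub("[[:space:]].*$", "", headers)
  desc <- sub("^[^[:space:]]+[[:space:]]*", "", headers)

  lib <- data.frame(
    id = ids,
    sequence = as.character(aa),
    parent = NA_character_, position = NA_integer_,
    from = NA_character_, to = NA_character_,
    stringsAsFactors = FALSE
  )
  pat <- "parent=([^[:space:]]+)[[:space:]]+pos=([0-9]+)[[:space:]]+([A-Z])>([A-Z])"
  hit <- regexec(pat, desc)
  for (i in seq_along(hit)) {
    m <- regmatches(desc[i], hit[i])[[1L]]
    if (length(m) == 5L) {
      lib$parent[i] <- m[2L]
      lib$position[i] <- as.integer(m[3L])
      lib$from[i] <- m[4L]
      lib$to[i] <- m[5L]
    }
  }
  # validate every sequence through the standard parser
  for (i in seq_len(nrow(lib))) parse_peptide(lib$id[i], lib$sequence[i])
  if (anyDuplicated(lib$id)) {
    stop("duplicate peptide ids in ", path, call. = FALSE)
  }
  lib
}

#' Write a peptide library to FASTA
#'
#' Provenance, where present, is written on the description line as
#' `parent=<id> pos=<n> <orig>><sub>` so that [read_peptide_fasta()]
#' round-trips it.
#'
#' @param lib a peptide-library data frame (`id`, `sequence`, optional
#'   provenance columns) or a [single_substitution_library()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_peptide_fasta <- function(lib, path) {
  lib <- as_peptide_library(lib)
  headers <- lib$id
  has_prov <- !is.na(lib$parent)
  headers[has_prov] <- sprintf(
    "%s parent=%s pos=%d %s>%s",
    lib$id[has_prov], lib$parent[has_prov], lib$position[has_prov],
    lib$from[has_prov], lib$to[has_prov]
  )
  aa <- Biostrings::AAStringSet(lib$sequence)
  names(aa) <- headers
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

# Coerce the objects this package passes around into the canonical
# peptide-library data frame.
as_peptide_library <- function(x) {
  if (inherits(x, "substitution_library")) x <- x$variants
  if (inherits(x, "peptide")) {
    x <- data.frame(id = x$id, sequence = x$sequence, stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(x), all(c("id", "sequence") %in% names(x)))
  for (col in c("parent", "from", "to")) {
    if (is.null(x[[col]])) x[[col]] <- rep(NA_character_, nrow(x))
  }
  if (is.null(x$position)) x$position <- rep(NA_integer_, nrow(x))
  x
}
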