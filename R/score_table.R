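#' Score tables from external predictors
#'
#' The selection cascade never reimplements the external machine-learning
#' predictors (antimicrobial, anticancer, toxicity, allergenicity servers);
#' it consumes their exported per-peptide scores and flags through a uniform
#' score-table interface. A score table is a data frame with one row per
#' peptide id and any of the recognised columns:
#'
#' * `amp_probability` — antimicrobial probability in \[0, 1\]
#' * `amp_flag` — `"AMP"` / `"non-AMP"`
#' * `anticancer_score` — anticancer classifier score in \[0, 1\]
#' * `toxicity_score` — real-valued toxicity score
#' * `toxicity_flag` — `"toxic"` / `"non-toxic"`
#' * `allergen_flag` — `"allergen"` / `"non-allergen"`
#' * `source` — label of the predictor that produced the row
#'
#' Unrecognised columns are preserved as opaque annotations.
#' @name score_tables
NULL

SCORE_FLAG_LEVELS <- list(
  amp_flag = c("AMP", "non-AMP"),
  toxicity_flag = c("toxic", "non-toxic"),
  allergen_flag = c("allergen", "non-allergen")
)

#' Read a delimited predictor score table
#'
#' Reads a comma- or tab-separated file (the delimiter is sniffed from the
#' header line) with an `id` column and at least one score or flag column,
#' and validates it into a score table: probabilities must lie in \[0, 1\],
#' flags must come from their enumerations, ids must be unique.
#'
#' @param path delimited text file.
#' @param source optional source label recorded on every row (defaults to an
#'   existing `source` column, else the file name).
#' @return A validated score-table data frame of class `"score_table"`.
#' @export
read_score_table <- function(path, source = NULL) {
  header <- readLines(path, n = 1L)
  if (!length(header) || !nzchar(header)) {
    stop("empty score table: ", path, call. = FALSE)
  }
  sep <- if (lengths(regmatches(header, gregexpr("\t", header))) > 0) "\t" else ","
  df <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE)
  if (is.null(source) && is.null(df$source)) {
    source <- basename(path)
  }
  as_score_table(df, source = source)
}

#' @rdname read_score_table
#' @param df data frame to validate as a score table.
#' @export
as_score_table <- function(df, source = NULL) {
  stopifnot(is.data.frame(df))
  if (is.null(df$id)) stop("score table lacks an 'id' column", call. = FALSE)
  if (!nrow(df)) stop("score table is empty", call. = FALSE)
  df$id <- as.character(df$id)
  if (anyDuplicated(df$id)) {
    stop("duplicate peptide ids in score table: ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "), call. = FALSE)
  }
  known <- c("amp_probability", "anticancer_score", "toxicity_score",
             names(SCORE_FLAG_LEVELS))
  if (!any(known %in% names(df))) {
    stop("score table has no recognised score or flag column", call. = FALSE)
  }
  for (col in c("amp_probability", "anticancer_score")) {
    v <- df[[col]]
    if (!is.null(v) && any(!is.na(v) & (v < 0 | v > 1))) {
      stop("'", col, "' values outside [0, 1]", call. = FALSE)
    }
  }
  for (col in names(SCORE_FLAG_LEVELS)) {
    v <- df[[col]]
    if (!is.null(v)) {
      bad <- !is.na(v) & !v %in% SCORE_FLAG_LEVELS[[col]]
      if (any(bad)) {
        stop("'", col, "' contains values outside {",
             paste(SCORE_FLAG_LEVELS[[col]], collapse = ", "), "}: ",
             paste(unique(v[bad]), collapse = ", "), call. = FALSE)
      }
    }
  }
  if (!is.null(source)) df$source <- source
  if (is.null(df$source)) df$source <- NA_character_
  class(df) <- c("score_table", "data.frame")
  df
}

#' Anticancer classification at a score threshold
#'
#' Peptides scoring below the threshold are classified non-anticancer;
#' scores at or above it (the boundary inclusive) are anticancer. Monotone
#' in the score for a fixed threshold.
#'
#' @param score numeric scores in \[0, 1\] (`NA` propagates).
#' @param threshold classification threshold in (0, 1); default 0.5.
#' @return Character vector, `"anticancer"` or `"non-anticancer"`.
#' @examples
#' classify_anticancer(c(0.59, 0.49, 0.5))
#' @export
classify_anticancer <- function(score, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  ifelse(score >= threshold, "anticancer", "non-anticancer")
}

#' Merge score tables from several predictors
#'
#' Combines per-source score tables into one record per peptide id. On a
#' field conflict the source earliest in `precedence` wins; conflicts are
#' recorded in the `"conflicts"` attribute and reported as a message.
#' Per-source values are retained in the `"per_source"` attribute, so
#' disagreeing predictors (a common occurrence for allergenicity calls) are
#' never silently collapsed. For the antimicrobial flag an optional
#' consensus vote across sources replaces pure precedence.
#'
#' Merging a table with itself returns the same table (idempotence).
#'
#' @param tables list of score tables (see [as_score_table()]).
#' @param precedence character vector of source labels, highest precedence
#'   first; must cover every source present.
#' @param amp_rule how to reconcile disagreeing `amp_flag` calls across
#'   sources: `"precedence"` (default), or a `"majority"` / `"all"` /
#'   `"any"` consensus vote (ties and non-votes fall back to precedence).
#' @return A merged `"score_table"`.
#' @export
merge_score_tables <- function(tables, precedence,
                               amp_rule = c("precedence", "majority", "all", "any")) {
  amp_rule <- match.arg(amp_rule)
  stopifnot(is.list(tables), length(tables) >= 1L)
  tables <- lapply(tables, as_score_table)
  cols <- unique(unlist(lapply(tables, names)))
  all_rows <- do.call(rbind, lapply(tables, function(t) {
    for (col in setdiff(cols, names(t))) t[[col]] <- NA
    as.data.frame(t)[cols]
  }))
  seen <- unique(all_rows$source)
  missing <- setdiff(seen[!is.na(seen)], precedence)
  if (length(missing)) {
    stop("precedence omits observed sources: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  all_rows$.prec <- match(all_rows$source, precedence)
  fields <- setdiff(names(all_rows), c("id", "source", ".prec"))
  ids <- unique(all_rows$id)

  conflicts <- list()
  out <- lapply(ids, function(i) {
    rows <- all_rows[all_rows$id == i, , drop = FALSE]
    rows <- rows[order(rows$.prec), , drop = FALSE]
    rec <- list(id = i)
    for (f in fields) {
      vals <- rows[[f]][!is.na(rows[[f]])]
      srcs <- rows$source[!is.na(rows[[f]])]
      if (!length(vals)) {
        rec[[f]] <- rows[[f]][1L]
        next
      }
      if (length(unique(vals)) > 1L) {
        conflicts[[length(conflicts) + 1L]] <<- data.frame(
          id = i, field = f,
          kept = as.character(vals[1L]), kept_source = srcs[1L],
          dropped = paste(as.character(vals[-1L]), collapse = ";"),
          stringsAsFactors = FALSE
        )
      }
      rec[[f]] <- vals[1L]
    }
    if (f_has_amp_vote(amp_rule, rows)) {
      vote <- amp_consensus(rows$amp_flag[!is.na(rows$amp_flag)], amp_rule)
      if (!is.na(vote)) rec$amp_flag <- vote
    }
    rec$source <- paste(unique(rows$source[!is.na(rows$source)]), collapse = "+")
    as.data.frame(rec, stringsAsFactors = FALSE)
  })
  merged <- do.call(rbind, out)
  merged <- as_score_table(merged)
  conflicts <- if (length(conflicts)) do.call(rbind, conflicts) else NULL
  if (!is.null(conflicts)) {
    message(nrow(conflicts), " field conflict(s) resolved by precedence/consensus")
  }
  attr(merged, "conflicts") <- conflicts
  attr(merged, "per_source") <- all_rows[setdiff(names(all_rows), ".prec")]
  merged
}

f_has_amp_vote <- function(amp_rule, rows) {
  amp_rule != "precedence" && !is.null(rows$amp_flag) && any(!is.na(rows$amp_flag))
}

#' Consensus vote over antimicrobial flags
#'
#' @param flags character vector of `"AMP"` / `"non-AMP"` calls.
#' @param rule `"majority"` (strict majority; ties give `NA`), `"all"`, or
#'   `"any"`.
#' @return `"AMP"`, `"non-AMP"`, or `NA` on a majority tie.
#' @export
amp_consensus <- function(flags, rule = c("majority", "all", "any")) {
  rule <- match.arg(rule)
  flags <- flags[!is.na(flags)]
  if (!length(flags)) return(NA_character_)
  n_amp <- sum(flags == "AMP")
  switch(rule,
    majority = if (2 * n_amp > length(flags)) "AMP"
               else if (2 * n_amp < length(flags)) "non-AMP"
               else NA_character_,
    all = if (n_amp == length(flags)) "AMP" else "non-AMP",
    any = if (n_amp > 0) "AMP" else "non-AMP"
  )
}
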