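#' Selection criteria for the screening funnel
#'
#' Thresholds for the staged candidate triage: antimicrobial status, a net
#' charge window, a hydrophobic-percentage window, and an anticancer score
#' threshold, followed by a ranked top-k selection.
#'
#' Two named presets mirror the two windows screening studies quote:
#' `"paper-selected"` (the default: charge in (0, +9\], hydrophobic percent
#' in \[13, 50\] on the rounded integer percent — the window the selected
#' reference candidates actually satisfy) and `"paper-optimal"` (the stated
#' textbook optimum, hydrophobic percent in \[17, 50\]).
#'
#' @param require_amp drop peptides not called antimicrobial.
#' @param charge_min,charge_max net-charge window (e units); the lower edge
#'   is exclusive when `charge_min_inclusive = FALSE` (default, "favourable"
#'   means strictly positive), the upper edge inclusive.
#' @param charge_min_inclusive include the lower charge edge.
#' @param hydrophobic_percent_min,hydrophobic_percent_max window on the
#'   rounded integer hydrophobic percentage, both edges inclusive by
#'   default.
#' @param hydrophobic_min_inclusive include the lower hydrophobicity edge
#'   (default `TRUE`: a 12.5% peptide printing as 13% passes).
#' @param anticancer_threshold minimum anticancer score (inclusive).
#' @param amp_threshold probability threshold used when only
#'   `amp_probability` (not `amp_flag`) is available.
#' @param charge_convention fixed-contribution convention the charge stage
#'   reads from the property panel (default `"quarter_ph7"`).
#' @param top_k size of the final ranked selection.
#' @param stage_order order of the four filter stages; per-stage counts
#'   depend on it, the surviving set does not.
#' @param preset `"paper-selected"` or `"paper-optimal"`; overrides the
#'   hydrophobicity window.
#' @return A list of class `"filter_criteria"`.
#' @export
filter_criteria <- function(require_amp = TRUE,
                            charge_min = 0, charge_max = 9,
                            charge_min_inclusive = FALSE,
                            hydrophobic_percent_min = 13,
                            hydrophobic_percent_max = 50,
                            hydrophobic_min_inclusive = TRUE,
                            anticancer_threshold = 0.5,
                            amp_threshold = 0.5,
                            charge_convention = c("quarter_ph7", "anticp_integer"),
                            top_k = 2L,
                            stage_order = c("amp", "charge", "hydrophobicity",
                                            "anticancer"),
                            preset = NULL) {
  charge_convention <- match.arg(charge_convention)
  stage_order <- as.character(unlist(stage_order))
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("paper-selected", "paper-optimal"))
    hydrophobic_percent_min <- if (preset == "paper-optimal") 17 else 13
    hydrophobic_percent_max <- 50
  }
  stopifnot(
    charge_min < charge_max,
    hydrophobic_percent_min < hydrophobic_percent_max,
    anticancer_threshold > 0, anticancer_threshold < 1,
    top_k >= 1L,
    setequal(stage_order, c("amp", "charge", "hydrophobicity", "anticancer"))
  )
  structure(list(
    require_amp = require_amp,
    charge_min = charge_min, charge_max = charge_max,
    charge_min_inclusive = charge_min_inclusive,
    hydrophobic_percent_min = hydrophobic_percent_min,
    hydrophobic_percent_max = hydrophobic_percent_max,
    hydrophobic_min_inclusive = hydrophobic_min_inclusive,
    anticancer_threshold = anticancer_threshold,
    amp_threshold = amp_threshold,
    charge_convention = charge_convention,
    top_k = as.integer(top_k),
    stage_order = stage_order
  ), class = "filter_criteria")
}

#' Run the staged selection funnel
#'
#' Applies the filter stages in the configured order — antimicrobial status,
#' net-charge window, hydrophobic-percentage window, anticancer score — with
#' per-stage exclusion bookkeeping, then ranks the survivors (anticancer
#' score descending, net charge descending, id ascending) and keeps the top
#' k. Peptides without the score a stage needs are excluded at that stage
#' and logged as unscored. At every stage the input count equals kept plus
#' excluded, and each stage's input is the previous stage's kept set.
#'
#' @param panels property-panel data frame from [property_panel()] (one row
#'   per peptide, `id` column).
#' @param scores a score table (see [read_score_table()]); may cover only
#'   part of the library.
#' @param criteria a [filter_criteria()].
#' @return An object of class `"cascade_result"`: list with `stages` (data
#'   frame: `stage`, `criterion`, `n_in`, `n_kept`, `n_excluded`), `kept`
#'   and `excluded` (per-stage id lists), `unscored` (ids excluded for
#'   missing scores, per stage), `survivors`, and `final_ranking` (data
#'   frame: `rank`, `id`, `anticancer_score`, `net_charge`).
#' @export
run_cascade <- function(panels, scores = NULL, criteria = filter_criteria()) {
  stopifnot(inherits(criteria, "filter_criteria"))
  stopifnot(is.data.frame(panels), all(c("id") %in% names(panels)))
  if (anyDuplicated(panels$id)) stop("duplicate ids in property panels", call. = FALSE)
  if (!is.null(scores)) scores <- as_score_table(scores)

  charge_col <- switch(criteria$charge_convention,
                       quarter_ph7 = "net_charge_quarter",
                       anticp_integer = "net_charge_anticp")
  sc <- function(col) {
    if (is.null(scores) || is.null(scores[[col]])) {
      rep(NA, nrow(panels))
    } else {
      scores[[col]][match(panels$id, scores$id)]
    }
  }
  amp_flag <- sc("amp_flag")
  amp_prob <- sc("amp_probability")
  amp_ok <- ifelse(!is.na(amp_flag), amp_flag == "AMP",
                   ifelse(!is.na(amp_prob), amp_prob >= criteria$amp_threshold, NA))
  anticancer <- as.numeric(sc("anticancer_score"))

  lo_ok <- if (criteria$charge_min_inclusive) {
    panels[[charge_col]] >= criteria$charge_min
  } else {
    panels[[charge_col]] > criteria$charge_min
  }
  hp_lo <- if (criteria$hydrophobic_min_inclusive) {
    panels$hydrophobic_percent >= criteria$hydrophobic_percent_min
  } else {
    panels$hydrophobic_percent > criteria$hydrophobic_percent_min
  }

  stage_pass <- list(
    amp = if (criteria$require_amp) amp_ok else rep(TRUE, nrow(panels)),
    charge = lo_ok & panels[[charge_col]] <= criteria$charge_max,
    hydrophobicity = hp_lo &
      panels$hydrophobic_percent <= criteria$hydrophobic_percent_max,
    anticancer = anticancer >= criteria$anticancer_threshold
  )
  stage_text <- c(
    amp = sprintf("antimicrobial call (flag or probability >= %.2f)",
                  criteria$amp_threshold),
    charge = sprintf("net charge (%s) in %s%.2f, %.2f]", criteria$charge_convention,
                     if (criteria$charge_min_inclusive) "[" else "(",
                     criteria$charge_min, criteria$charge_max),
    hydrophobicity = sprintf("hydrophobic percent in %s%d, %d]",
                             if (criteria$hydrophobic_min_inclusive) "[" else "(",
                             criteria$hydrophobic_percent_min,
                             criteria$hydrophobic_percent_max),
    anticancer = sprintf("anticancer score >= %.2f", criteria$anticancer_threshold)
  )

  current <- panels$id
  stages <- data.frame()
  kept_ids <- list()
  excluded_ids <- list()
  unscored_ids <- list()
  names(stage_pass) <- names(stage_pass)
  for (st in criteria$stage_order) {
    pass <- stage_pass[[st]][match(current, panels$id)]
    unscored <- current[is.na(pass)]
    keep <- current[!is.na(pass) & pass]
    drop <- setdiff(current, keep)
    stages <- rbind(stages, data.frame(
      stage = st, criterion = stage_text[[st]],
      n_in = length(current), n_kept = length(keep),
      n_excluded = length(drop), stringsAsFactors = FALSE
    ))
    kept_ids[[st]] <- keep
    excluded_ids[[st]] <- drop
    unscored_ids[[st]] <- unscored
    if (length(unscored) && st %in% c("amp", "anticancer")) {
      message("stage '", st, "': ", length(unscored),
              " peptide(s) excluded as unscored")
    }
    current <- keep
  }

  ranking <- rank_candidates(
    current,
    anticancer_score = anticancer[match(current, panels$id)],
    net_charge = panels[[charge_col]][match(current, panels$id)]
  )
  ranking <- utils::head(ranking, criteria$top_k)

  structure(list(
    criteria = criteria,
    stages = stages,
    kept = kept_ids,
    excluded = excluded_ids,
    unscored = unscored_ids,
    survivors = current,
    final_ranking = ranking
  ), class = "cascade_result")
}

#' Rank surviving candidates
#'
#' Deterministic total order: anticancer score descending, then net charge
#' descending, then id ascending (lexicographic tie-break).
#'
#' @param ids candidate identifiers.
#' @param anticancer_score,net_charge ranking keys, parallel to `ids`.
#' @return Data frame `rank`, `id`, `anticancer_score`, `net_charge`.
#' @examples
#' rank_candidates(c("ATMP5", "ATMP6"), c(0.57, 0.59), c(0.25, 1.25))
#' @export
rank_candidates <- function(ids, anticancer_score, net_charge) {
  df <- data.frame(id = as.character(ids),
                   anticancer_score = as.numeric(anticancer_score),
                   net_charge = as.numeric(net_charge),
                   stringsAsFactors = FALSE)
  ord <- order(-df$anticancer_score, -df$net_charge, df$id, method = "radix")
  df <- df[ord, , drop = FALSE]
  df <- cbind(rank = seq_len(nrow(df)), df)
  rownames(df) <- NULL
  df
}

#' Tabular funnel report
#'
#' One row per stage (stage name, criterion, input, kept, excluded) plus a
#' final-selection row; the excluded column sums to the difference between
#' the initial library and the surviving set.
#'
#' @param result a `"cascade_result"` from [run_cascade()].
#' @return Data frame with columns `stage`, `criterion`, `n_in`, `n_kept`,
#'   `n_excluded`.
#' @export
funnel_report <- function(result) {
  stopifnot(inherits(result, "cascade_result"))
  rep <- result$stages
  rep <- rbind(rep, data.frame(
    stage = "final_ranking",
    criterion = sprintf("top %d by anticancer score, net charge, id",
                        result$criteria$top_k),
    n_in = length(result$survivors),
    n_kept = nrow(result$final_ranking),
    n_excluded = length(result$survivors) - nrow(result$final_ranking),
    stringsAsFactors = FALSE
  ))
  rep
}

#' @export
print.cascade_result <- function(x, ...) {
  cat("<cascade_result> ", x$stages$n_in[1L], " peptides in, ",
      length(x$survivors), " survivor(s), top ", nrow(x$final_ranking),
      " ranked\n", sep = "")
  print(funnel_report(x), row.names = FALSE)
  if (nrow(x$final_ranking)) {
    cat("final ranking:\n")
    print(x$final_ranking, row.names = FALSE)
  }
  invisible(x)
}
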