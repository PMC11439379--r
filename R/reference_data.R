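#' Reference peptides from the AtMP1 screen
#'
#' The published worked example this package is calibrated against: the
#' Anabas testudineus mucus peptide AtMP1 and the candidates derived from it
#' by single-residue substitution. `atmp_templates()` returns the 26-residue
#' AtMP1 template and the 24-residue parent of the reported candidate set
#' (the candidate backbone without its substitution); `atmp_candidates()`
#' returns the ten reported single-substitution candidates with their
#' published quarter-convention net charges, including the two peptides
#' carried forward (ATMP5, tyrosine at position 16; ATMP6, arginine at
#' position 22).
#'
#' @return A peptide-library data frame (`id`, `sequence`, and for
#'   `atmp_candidates()` a `reported_net_charge` column).
#' @examples
#' atmp_candidates()
#' @export
atmp_candidates <- function() {
  df <- data.frame(
    id = c("seq_3541", "seq_3577", "seq_3628", "seq_3668", "seq_3690",
           "seq_3712", "seq_3738", "seq_3760", "seq_3785", "seq_3833"),
    sequence = c(
      "THPPTTTTTTTTYTTTTAAPATTT",
      "THPPTTTTTTTTTYTTTAAPATTT",
      "THPPTTTTTTTTTHTTTAAPATTT",
      "THPPTTTTTTTTTTHTTAAPATTT",
      "THPPTTTTTTTTKTTTTAAPATTT",
      "THPPTTTTTTTTTKTTTAAPATTT",
      "THPPTTTTTTTTTTTTTAAPATTK",
      "THPPTTTTTTTTTTTYTAAPATTT",
      "THPPTTTTTTTTTTTTTAAPAKTT",
      "THPPTTTTTTTTTTTTTAAPARTT"
    ),
    reported_net_charge = c(0.25, 0.25, 0.50, 0.50, 1.25,
                            1.25, 1.25, 0.25, 1.25, 1.25),
    stringsAsFactors = FALSE
  )
  df$alias <- NA_character_
  df$alias[df$id == "seq_3760"] <- "ATMP5"
  df$alias[df$id == "seq_3833"] <- "ATMP6"
  df
}

#' @rdname atmp_candidates
#' @export
atmp_templates <- function() {
  data.frame(
    id = c("AtMP1", "AtMP1_24"),
    sequence = c("THPPTTTTTTTTTTTTTTTAAPATTT",
                 "THPPTTTTTTTTTTTTTAAPATTT"),
    stringsAsFactors = FALSE
  )
}

#' Published predictor scores for the reference candidates
#'
#' The external predictor outputs reported for the candidate set, transcribed
#' as a score-table fixture: all ten candidates were called antimicrobial;
#' antimicrobial probabilities and anticancer scores were reported only for
#' the two carried forward (ATMP5: probability 0.519, anticancer 0.57;
#' ATMP6: probability 0.512, anticancer 0.59), together with their toxicity
#' (both non-toxic) and allergenicity calls. Candidates without a reported
#' anticancer score are left `NA` and so drop out of the anticancer stage as
#' unscored.
#'
#' @return A `"score_table"` keyed by the [atmp_candidates()] ids.
#' @export
atmp_scores <- function() {
  cand <- atmp_candidates()
  df <- data.frame(
    id = cand$id,
    amp_flag = "AMP",
    amp_probability = NA_real_,
    anticancer_score = NA_real_,
    toxicity_flag = NA_character_,
    allergen_flag = NA_character_,
    stringsAsFactors = FALSE
  )
  df$amp_probability[df$id == "seq_3760"] <- 0.519
  df$amp_probability[df$id == "seq_3833"] <- 0.512
  df$anticancer_score[df$id == "seq_3760"] <- 0.57
  df$anticancer_score[df$id == "seq_3833"] <- 0.59
  df$toxicity_flag[df$id %in% c("seq_3760", "seq_3833")] <- "non-toxic"
  df$allergen_flag[df$id == "seq_3760"] <- "non-allergen"
  df$allergen_flag[df$id == "seq_3833"] <- "allergen"
  as_score_table(df, source = "reported")
}
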