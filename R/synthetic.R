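#' Specification for synthetic libraries and score tables
#'
#' Describes the statistical structure of a synthetic screening experiment:
#' peptide length and residue composition bias (default threonine-rich,
#' mimicking a substitution library over a low-complexity Thr-rich
#' template), the number of peptides, the rate at which external predictors
#' call peptides antimicrobial, a Beta distribution for anticancer scores
#' (defaults put only a few percent of its mass at or above the 0.5
#' classification threshold), and toxicity/allergenicity flag rates. All
#' randomness flows through the mandatory seed; there is no unseeded
#' generation and no global RNG state is disturbed.
#'
#' The default rates emulate the funnel proportions of the reference screen
#' (about half of a substitution library called non-antimicrobial, few
#' anticancer scores above threshold); they are an emulation of that
#' statistical shape, not a reproduction of any particular predictor.
#'
#' @param seed integer seed (mandatory).
#' @param length peptide length in residues.
#' @param n_variants number of peptides to generate.
#' @param composition named numeric vector of residue weights (needs no
#'   normalisation); default is threonine-rich with a small uniform floor
#'   over the remaining standard residues.
#' @param amp_positive_rate probability a peptide is called antimicrobial.
#' @param anticancer_beta length-2 vector, the Beta(alpha, beta) shape
#'   parameters for anticancer scores.
#' @param toxic_rate,allergen_rate probabilities of a `"toxic"` /
#'   `"allergen"` flag.
#' @return A list of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(seed,
                           length = 24L,
                           n_variants = 456L,
                           composition = default_composition(),
                           amp_positive_rate = 0.505,
                           anticancer_beta = c(2, 10),
                           toxic_rate = 0.05,
                           allergen_rate = 0.5) {
  stopifnot(!missing(seed), is.numeric(seed), length(seed) == 1L, is.finite(seed))
  rates <- c(amp_positive_rate, toxic_rate, allergen_rate)
  stopifnot(all(rates >= 0 & rates <= 1), all(anticancer_beta > 0),
            length > 0, n_variants >= 0)
  bad <- setdiff(names(composition), AA_STANDARD20)
  if (length(bad)) stop("composition names non-standard residues: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  structure(list(seed = as.integer(seed), length = as.integer(length),
                 n_variants = as.integer(n_variants), composition = composition,
                 amp_positive_rate = amp_positive_rate,
                 anticancer_beta = anticancer_beta,
                 toxic_rate = toxic_rate, allergen_rate = allergen_rate),
            class = "synthetic_spec")
}

#' @rdname synthetic_spec
#' @export
default_composition <- function() {
  w <- stats::setNames(rep(0.2 / 17, 20), AA_STANDARD20)
  w["T"] <- 0.60
  w["P"] <- 0.10
  w["A"] <- 0.10
  w[!names(w) %in% c("T", "P", "A")] <- 0.2 / 17
  w
}

# Run `expr` under a fixed seed without touching the caller's RNG state.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic peptide library
#'
#' Draws `n_variants` sequences of the configured length, residue by
#' residue, from the composition bias. Deterministic for a fixed seed; all
#' sequences are valid standard-alphabet peptides.
#'
#' @param spec a [synthetic_spec()].
#' @return A peptide-library data frame (`id`, `sequence`).
#' @examples
#' lib <- generate_library(synthetic_spec(seed = 1, n_variants = 5))
#' @export
generate_library <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  w <- spec$composition / sum(spec$composition)
  with_local_seed(spec$seed, {
    seqs <- vapply(seq_len(spec$n_variants), function(i) {
      paste(sample(names(w), spec$length, replace = TRUE, prob = w),
            collapse = "")
    }, character(1L))
    data.frame(
      id = sprintf("syn_%04d", seq_len(spec$n_variants)),
      sequence = seqs, stringsAsFactors = FALSE
    )
  })
}

#' Generate a synthetic predictor score table
#'
#' Per peptide: an antimicrobial flag drawn Bernoulli(`amp_positive_rate`)
#' (with a consistent `amp_probability` drawn uniformly from the matching
#' half of \[0, 1\]), an anticancer score drawn Beta(alpha, beta), and
#' toxicity/allergenicity flags drawn Bernoulli. Deterministic per seed; a
#' fixed offset keeps the score stream independent of the library stream so
#' the same spec can seed both.
#'
#' @param library a peptide-library data frame (`id` column).
#' @param spec a [synthetic_spec()].
#' @return A `"score_table"` with one row per library peptide.
#' @export
generate_scores <- function(library, spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  lib <- as_peptide_library(library)
  n <- nrow(lib)
  with_local_seed(spec$seed + 1L, {
    amp <- stats::runif(n) < spec$amp_positive_rate
    amp_prob <- ifelse(amp, stats::runif(n, 0.5, 1), stats::runif(n, 0, 0.5))
    as_score_table(data.frame(
      id = lib$id,
      amp_flag = ifelse(amp, "AMP", "non-AMP"),
      amp_probability = amp_prob,
      anticancer_score = stats::rbeta(n, spec$anticancer_beta[1L],
                                      spec$anticancer_beta[2L]),
      toxicity_flag = ifelse(stats::runif(n) < spec$toxic_rate,
                             "toxic", "non-toxic"),
      allergen_flag = ifelse(stats::runif(n) < spec$allergen_rate,
                             "allergen", "non-allergen"),
      stringsAsFactors = FALSE
    ), source = "synthetic")
  })
}
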