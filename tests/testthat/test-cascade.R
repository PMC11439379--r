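# A small constructed library where exactly one peptide fails each of the
# first three stages and one survives everything.
toy_setup <- function() {
  lib <- data.frame(
    id = c("fails_amp", "fails_charge", "fails_hydro", "survivor"),
    sequence = c(
      "KTTTTTTTTTTTTTTTTTTTTTTA",  # amp-negative
      "TTTTTTTTTTTTTTTTTTTTTAAA",  # charge 0 -> fails exclusive lower edge
      "KTTTTTTTTTTTTTTTTTTTTTTT",  # 0% hydrophobic
      "KTTTTTTTTTTTTTTTTTTTTAAA"   # charge +1, 3/24 = 13%
    ),
    stringsAsFactors = FALSE
  )
  scores <- as_score_table(data.frame(
    id = lib$id,
    amp_flag = c("non-AMP", "AMP", "AMP", "AMP"),
    anticancer_score = c(0.9, 0.9, 0.9, 0.66),
    stringsAsFactors = FALSE
  ), source = "toy")
  list(panels = property_panel(lib), scores = scores)
}

test_that("each stage excludes the constructed failure and bookkeeping balances", {
  ts <- toy_setup()
  res <- run_cascade(ts$panels, ts$scores, filter_criteria(top_k = 5))

  expect_equal(res$stages$n_in, c(4L, 3L, 2L, 1L))
  expect_equal(res$stages$n_kept, c(3L, 2L, 1L, 1L))
  expect_equal(res$excluded$amp, "fails_amp")
  expect_equal(res$excluded$charge, "fails_charge")
  expect_equal(res$excluded$hydrophobicity, "fails_hydro")
  expect_equal(res$survivors, "survivor")
  expect_equal(res$final_ranking$id, "survivor")

  # conservation at every stage and globally
  expect_equal(res$stages$n_in, res$stages$n_kept + res$stages$n_excluded)
  expect_equal(res$stages$n_in[1],
               length(res$survivors) + sum(res$stages$n_excluded))
})

test_that("the reference candidate screen selects ATMP6 then ATMP5", {
  panels <- property_panel(atmp_candidates())
  res <- suppressMessages(
    run_cascade(panels, atmp_scores(), filter_criteria(top_k = 2))
  )
  expect_equal(res$stages$n_kept, c(10L, 10L, 10L, 2L))
  expect_equal(res$final_ranking$id, c("seq_3833", "seq_3760")) # ATMP6, ATMP5
  expect_equal(res$final_ranking$anticancer_score, c(0.59, 0.57))
  expect_equal(res$unscored$anticancer,
               setdiff(panels$id, c("seq_3833", "seq_3760")))
})

test_that("an empty library yields empty stages and an empty ranking", {
  empty <- property_panel(data.frame(id = character(0), sequence = character(0),
                                     stringsAsFactors = FALSE))
  res <- run_cascade(empty, NULL, filter_criteria())
  expect_equal(res$stages$n_in, rep(0L, 4L))
  expect_equal(nrow(res$final_ranking), 0L)
})

test_that("ranking is anticancer desc, charge desc, then id lexicographic", {
  r <- rank_candidates(c("ATMP5", "ATMP6"), c(0.57, 0.59), c(0.25, 1.25))
  expect_equal(r$id, c("ATMP6", "ATMP5"))
  r2 <- rank_candidates(c("b", "a", "c"), c(0.5, 0.5, 0.5), c(1, 1, 2))
  expect_equal(r2$id, c("c", "a", "b"))
  r3 <- rank_candidates("only", 0.9, 1)
  expect_equal(r3$id, "only")
  expect_equal(r3$rank, 1L)
})

test_that("relaxing any single threshold never shrinks the survivor set", {
  spec <- synthetic_spec(seed = 402, n_variants = 300)
  lib <- generate_library(spec)
  panels <- property_panel(lib)
  scores <- generate_scores(lib, spec)
  base_crit <- filter_criteria(anticancer_threshold = 0.3)
  base <- run_cascade(panels, scores, base_crit)

  relaxed <- list(
    filter_criteria(anticancer_threshold = 0.3, charge_max = 12),
    filter_criteria(anticancer_threshold = 0.3, charge_min = -1,
                    charge_min_inclusive = TRUE),
    filter_criteria(anticancer_threshold = 0.3, hydrophobic_percent_min = 5),
    filter_criteria(anticancer_threshold = 0.2),
    filter_criteria(anticancer_threshold = 0.3, require_amp = FALSE)
  )
  for (crit in relaxed) {
    res <- run_cascade(panels, scores, crit)
    expect_true(all(base$survivors %in% res$survivors))
  }
})

test_that("stage order changes per-stage counts but never the survivor set", {
  spec <- synthetic_spec(seed = 77, n_variants = 250)
  lib <- generate_library(spec)
  panels <- property_panel(lib)
  scores <- generate_scores(lib, spec)
  crit <- filter_criteria(anticancer_threshold = 0.3)
  base <- run_cascade(panels, scores, crit)

  set.seed(5)
  for (rep in 1:4) {
    ord <- sample(c("amp", "charge", "hydrophobicity", "anticancer"))
    res <- run_cascade(panels, scores,
                       filter_criteria(anticancer_threshold = 0.3,
                                       stage_order = ord))
    expect_setequal(res$survivors, base$survivors)
  }
})

test_that("funnel report reconciles totals and serialises stably", {
  ts <- toy_setup()
  res <- run_cascade(ts$panels, ts$scores, filter_criteria(top_k = 5))
  rep <- funnel_report(res)
  expect_equal(nrow(rep), 5L) # four stages + final ranking row
  expect_equal(sum(rep$n_excluded[1:4]), rep$n_in[1] - length(res$survivors))
  expect_true(all(rep$n_excluded >= 0))

  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(rep, path, row.names = FALSE)
  expect_identical(read.csv(path, stringsAsFactors = FALSE), rep)
})

test_that("criteria presets encode the selected and optimal hydrophobicity windows", {
  sel <- filter_criteria(preset = "paper-selected")
  opt <- filter_criteria(preset = "paper-optimal")
  expect_equal(sel$hydrophobic_percent_min, 13)
  expect_equal(opt$hydrophobic_percent_min, 17)
  # the reference candidates (13%) pass the selected window, fail the optimal
  panels <- property_panel(atmp_candidates())
  res_sel <- suppressMessages(run_cascade(panels, atmp_scores(), sel))
  res_opt <- suppressMessages(run_cascade(panels, atmp_scores(), opt))
  expect_equal(length(res_sel$survivors), 2L)
  expect_equal(length(res_opt$survivors), 0L)
  expect_error(filter_criteria(charge_min = 5, charge_max = 2))
})
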