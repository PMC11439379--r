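write_scores <- function(lines, ext = ".csv") {
  path <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("score tables read from CSV and TSV with validation", {
  csv <- write_scores(c("id,anticancer_score", "ATMP5,0.57", "ATMP6,0.59"))
  tab <- read_score_table(csv, source = "anticancer_server")
  expect_s3_class(tab, "score_table")
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$anticancer_score[tab$id == "ATMP6"], 0.59)

  tsv <- write_scores(c("id\tamp_probability", "a\t0.9"), ext = ".tsv")
  expect_equal(read_score_table(tsv)$amp_probability, 0.9)

  expect_error(read_score_table(write_scores(c("id,amp_probability", "a,1.2"))),
               "outside \\[0, 1\\]")
  expect_error(read_score_table(write_scores(c("pep,score", "a,0.5"))), "'id'")
  expect_error(read_score_table(write_scores(c("id,anticancer_score",
                                               "a,0.5", "a,0.6"))),
               "duplicate")
  expect_error(read_score_table(write_scores("id,anticancer_score")), "empty")
  expect_error(read_score_table(write_scores(c("id,toxicity_flag", "a,maybe"))),
               "toxicity_flag")
})

test_that("anticancer classification has an inclusive threshold and is monotone", {
  expect_equal(classify_anticancer(0.59), "anticancer")
  expect_equal(classify_anticancer(0.49), "non-anticancer")
  expect_equal(classify_anticancer(0.5), "anticancer") # boundary passes
  expect_error(classify_anticancer(0.5, threshold = 0))

  scores <- sort(runif(25))
  calls <- classify_anticancer(scores, 0.4)
  expect_true(!is.unsorted(rev(calls == "non-anticancer")))
})

test_that("merging is precedence-driven, idempotent, and keeps per-source calls", {
  a <- as_score_table(data.frame(id = c("p1", "p2"),
                                 toxicity_flag = c("toxic", "non-toxic")),
                      source = "srvA")
  b <- as_score_table(data.frame(id = c("p2", "p3"),
                                 toxicity_flag = c("toxic", "non-toxic")),
                      source = "srvB")

  m <- suppressMessages(merge_score_tables(list(a, b), precedence = c("srvA", "srvB")))
  expect_setequal(m$id, c("p1", "p2", "p3"))
  expect_equal(m$toxicity_flag[m$id == "p2"], "non-toxic") # srvA wins
  expect_equal(attr(m, "conflicts")$id, "p2")
  expect_true(all(c("srvA", "srvB") %in% attr(m, "per_source")$source))

  # reversed precedence flips the conflicting call
  m2 <- suppressMessages(merge_score_tables(list(a, b), precedence = c("srvB", "srvA")))
  expect_equal(m2$toxicity_flag[m2$id == "p2"], "toxic")

  # idempotence: a table merged with itself is itself
  self <- merge_score_tables(list(a, a), precedence = "srvA")
  expect_equal(as.data.frame(self)[names(a)], as.data.frame(a)[names(a)])

  expect_error(merge_score_tables(list(a, b), precedence = "srvA"), "omits")
})

test_that("disagreeing allergenicity calls keep both per-source values", {
  fp <- as_score_table(data.frame(id = "ATMP5", allergen_flag = "non-allergen"),
                       source = "fingerprint")
  kt <- as_score_table(data.frame(id = "ATMP5", allergen_flag = "allergen"),
                       source = "knn")
  m <- suppressMessages(merge_score_tables(list(kt, fp), precedence = c("knn", "fingerprint")))
  expect_equal(m$allergen_flag, "allergen")
  ps <- attr(m, "per_source")
  expect_setequal(ps$allergen_flag, c("allergen", "non-allergen"))
})

test_that("antimicrobial consensus voting follows the configured rule", {
  expect_equal(amp_consensus(c("AMP", "AMP", "non-AMP"), "majority"), "AMP")
  expect_equal(amp_consensus(c("AMP", "non-AMP"), "majority"), NA_character_)
  expect_equal(amp_consensus(c("AMP", "non-AMP"), "all"), "non-AMP")
  expect_equal(amp_consensus(c("AMP", "non-AMP"), "any"), "AMP")

  t1 <- as_score_table(data.frame(id = "p", amp_flag = "AMP"), source = "s1")
  t2 <- as_score_table(data.frame(id = "p", amp_flag = "non-AMP"), source = "s2")
  t3 <- as_score_table(data.frame(id = "p", amp_flag = "non-AMP"), source = "s3")
  m <- suppressMessages(merge_score_tables(list(t1, t2, t3),
                                           precedence = c("s1", "s2", "s3"),
                                           amp_rule = "majority"))
  expect_equal(m$amp_flag, "non-AMP") # vote overrides precedence
})
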