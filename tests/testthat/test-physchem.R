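test_that("fixed-contribution net charge reproduces both reported conventions", {
  expect_equal(net_charge_fixed(ATMP6, "quarter_ph7"), 1.25)
  expect_equal(net_charge_fixed(ATMP6, "anticp_integer"), 1.50)
  expect_equal(net_charge_fixed(ATMP5, "quarter_ph7"), 0.25)
  expect_equal(net_charge_fixed(ATMP5, "anticp_integer"), 0.50)
  expect_equal(net_charge_fixed("GGGG", "quarter_ph7"), 0)
  expect_equal(net_charge_fixed("GGGG", "anticp_integer"), 0)
  expect_error(net_charge_fixed("GGGG", "nonsense"))
})

test_that("substituting T by K/H/Y shifts the quarter charge by +1/+0.25/0", {
  parent <- atmp_templates()$sequence[2]
  base <- net_charge_fixed(parent)
  for (pos in c(1L, 10L, 24L)) {
    for (case in list(c("K", 1), c("H", 0.25), c("Y", 0))) {
      prov <- substitution_provenance("t", pos, substr(parent, pos, pos), case[1])
      mutant <- apply_substitution(parent, prov)
      expect_equal(net_charge_fixed(mutant), base + as.numeric(case[2]))
    }
  }
  # and the full reported candidate panel reproduces
  cand <- atmp_candidates()
  expect_equal(net_charge_fixed(cand$sequence), cand$reported_net_charge)
})

test_that("Henderson-Hasselbalch charge matches the group-sum oracle and its limits", {
  pka <- pka_set("calibrated")
  set.seed(7)
  for (rep in 1:12) {
    s <- random_peptide(sample(2:30, 1))
    pH <- runif(1, 0, 14)
    expect_equal(net_charge_hh(s, pka, pH), oracle_hh_charge(s, pka, pH),
                 tolerance = 1e-12)
  }
  # full-protonation limit: charge ~ 1 + #K + #R + #H at pH 0
  s <- "KRHKTA"
  cnt <- residue_counts(s)
  expect_equal(net_charge_hh(s, pka, 0),
               1 + cnt[["K"]] + cnt[["R"]] + cnt[["H"]],
               tolerance = 0.01)
  expect_error(net_charge_hh(s, pka, 14.5), "pH")
})

test_that("HH charge is strictly decreasing in pH for random peptides", {
  pka <- pka_set("calibrated")
  grid <- seq(0.5, 13.5, by = 0.5)
  set.seed(19)
  for (rep in 1:10) {
    s <- random_peptide(sample(2:25, 1))
    q <- net_charge_hh(rep(s, length(grid))[1], pka, grid[1])
    qs <- vapply(grid, function(p) net_charge_hh(s, pka, p), numeric(1))
    expect_true(all(diff(qs) < 0))
  }
})

test_that("isoelectric point: closed form for two-group peptides, printed values for references", {
  gg <- register_or_get("gg_test", c(D = 4, E = 4, C = 9, Y = 10, H = 6, K = 10, R = 12),
                        n_terminus = 9.0, c_terminus = 2.0)
  expect_equal(isoelectric_point("GG", gg, tol = 1e-6), 5.5, tolerance = 1e-4)

  # no ionizable side chains: pI = (pKaN + pKaC)/2 regardless of length
  expect_equal(isoelectric_point("GAGA", gg, tol = 1e-6), 5.5, tolerance = 1e-4)

  expect_equal(isoelectric_point(ATMP5), 7.09, tolerance = 0.05)
  expect_equal(isoelectric_point(ATMP6), 10.11, tolerance = 0.05)
  # the root actually zeroes the charge
  expect_equal(net_charge_hh(ATMP6, pH = isoelectric_point(ATMP6)), 0,
               tolerance = 1e-3)
})

test_that("scale means match the summation oracle; GRAVY composes by length-weighting", {
  expect_equal(gravy(ATMP6), -0.7625, tolerance = 1e-12)   # prints as -0.76
  expect_equal(gravy(ATMP5), -0.6291667, tolerance = 1e-6) # prints as -0.63
  expect_equal(gravy("AG"), 0.70)
  expect_equal(hydrophilicity("R"), 3.0)

  kd <- scale_table("kyte_doolittle")
  hw <- scale_table("hopp_woods")
  set.seed(31)
  for (rep in 1:10) {
    s <- random_peptide(sample(1:40, 1))
    expect_equal(gravy(s), oracle_scale_mean(s, kd), tolerance = 1e-12)
    expect_equal(hydrophilicity(s), oracle_scale_mean(s, hw), tolerance = 1e-12)
  }

  a <- random_peptide(7); b <- random_peptide(13)
  expect_equal(gravy(paste0(a, b)),
               (7 * gravy(a) + 13 * gravy(b)) / 20, tolerance = 1e-12)
})

test_that("hydrophobic percentage uses the calibrated set and half-up rounding", {
  expect_equal(hydrophobic_fraction(ATMP6), 3 / 24)
  expect_equal(hydrophobic_percent(ATMP6), 13)
  expect_equal(hydrophobic_percent(ATMP5), 13)
  expect_equal(hydrophobic_percent("AAAA"), 100)
  expect_equal(hydrophobic_percent("TTTT"), 0)
  # half-up, not banker's rounding: 2.5% -> 3%... 1 of 40 = 2.5
  expect_equal(hydrophobic_percent(paste0("A", strrep("T", 39))), 3)
  expect_error(hydrophobic_fraction("AAAA", set = c("A", "B")))
})

test_that("molecular weight is residue masses plus one water", {
  expect_equal(molecular_weight("G"), 75.0672, tolerance = 1e-4)
  expect_equal(molecular_weight("GG"), 132.1191, tolerance = 1e-4)
  masses <- scale_table("residue_mass_average")
  expect_equal(molecular_weight(ATMP6),
               24 * oracle_scale_mean(ATMP6, masses) + 18.0153,
               tolerance = 1e-9)
})

test_that("instability and aliphatic indices follow their published formulas", {
  expect_equal(instability_index("AA"), 5.0)
  set.seed(43)
  for (rep in 1:5) {
    s <- random_peptide(10)
    expect_equal(instability_index(s), oracle_instability(s), tolerance = 1e-9)
  }
  expect_error(instability_index("A"), "length")

  expect_equal(aliphatic_index("AAAA"), 100)
  expect_equal(aliphatic_index("TTTT"), 0)
  expect_equal(aliphatic_index("AVIL"), 292.5)
})

test_that("the property panel is complete, deterministic and consistent", {
  panel <- property_panel(atmp_candidates())
  expect_equal(nrow(panel), 10L)
  atmp6 <- panel[panel$id == "seq_3833", ]
  expect_equal(atmp6$net_charge_quarter, 1.25)
  expect_equal(atmp6$net_charge_anticp, 1.50)
  expect_equal(round(atmp6$gravy, 2), -0.76)
  expect_equal(atmp6$hydrophobic_percent, 13)
  atmp5 <- panel[panel$id == "seq_3760", ]
  expect_equal(round(atmp5$gravy, 2), -0.63)
  expect_equal(atmp5$pI, 7.09, tolerance = 0.05)

  expect_identical(panel, property_panel(atmp_candidates()))
})

test_that("scale registry is immutable and rejects incomplete tables", {
  expect_error(register_scale_table("kyte_doolittle", scale_table("kyte_doolittle")),
               "already registered")
  expect_error(register_scale_table("partial", c(A = 1)), "does not cover")
  expect_error(scale_table("no_such_scale"), "unknown scale")
  expect_error(pka_set("no_such_set"), "unknown pKa set")
})
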