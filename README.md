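# pepscan

In silico saturation mutagenesis and staged selection of antimicrobial /
anticancer peptide candidates.

Short antimicrobial peptides (AMPs) are promising anticancer leads, and a
standard way to improve one is an in silico directed-evolution screen:
enumerate every single-residue substitution of a template, compute each
variant's physicochemical profile, score the variants with external
predictors, and triage them through a filter funnel down to a ranked
shortlist for synthesis. `pepscan` implements that desk pipeline end to end
for researchers running or auditing such screens — with every convention
(charge model, pKa set, hydrophobic residue set, rounding) explicit,
because published screening tables routinely mix them.

The core pieces:

* **Substitution scan** — every Hamming-distance-1 variant of a template
  over a chosen alphabet, with provenance tracking; a 24-mer over the
  standard 20 amino acids gives 24 × 19 = 456 variants.
* **Property engine** — net charge under a quarter-unit fixed-contribution
  convention (K/R +1, D/E −1, H +0.25), an integer-plus-half convention
  (H +0.5), and the continuous Henderson–Hasselbalch model
  Q(pH) = Σ_basic 1/(1+10^(pH−pKa)) − Σ_acidic 1/(1+10^(pKa−pH));
  isoelectric point as the unique root of Q by bisection; GRAVY
  (mean Kyte–Doolittle hydropathy); hydrophobic percent (half-up rounding);
  hydrophilicity; average molecular weight; Guruprasad instability index;
  aliphatic index.
* **Score tables** — a uniform reader/merger for exported predictor scores
  (antimicrobial probability, anticancer score, toxicity and allergenicity
  flags); the external ML predictors themselves are never reimplemented.
* **Selection cascade** — conjunctive stages (AMP call → net charge in
  (0, +9] → hydrophobic percent in [13, 50] → anticancer score ≥ 0.5) with
  per-stage exclusion bookkeeping and a deterministic ranked top-k.
* **Synthetic data** — seeded generators for Thr-rich libraries and
  predictor score tables, so the whole funnel is testable offline.

## Worked example

The package ships the reference screen it is calibrated against: the ten
single-substitution candidates derived from the *Anabas testudineus* mucus
peptide AtMP1, with their reported predictor scores.

```r
library(pepscan)

panels <- property_panel(atmp_candidates())
result <- run_cascade(panels, atmp_scores(), filter_criteria(top_k = 2))
result
#> <cascade_result> 10 peptides in, 2 survivor(s), top 2 ranked
#>           stage                                        criterion n_in n_kept n_excluded
#>             amp antimicrobial call (flag or probability >= 0.50)   10     10          0
#>          charge         net charge (quarter_ph7) in (0.00, 9.00]   10     10          0
#>  hydrophobicity                  hydrophobic percent in [13, 50]   10     10          0
#>      anticancer                         anticancer score >= 0.50   10      2          8
#>   final_ranking        top 2 by anticancer score, net charge, id    2      2          0
#> final ranking:
#>  rank       id anticancer_score net_charge
#>     1 seq_3833             0.59       1.25
#>     2 seq_3760             0.57       0.25
```

All ten candidates pass the antimicrobial, charge and hydrophobicity
stages; only the two with a reported anticancer score at or above the 0.5
threshold survive the anticancer stage (the other eight are excluded as
unscored), and the funnel selects seq_3833 (ATMP6, score 0.59, charge
+1.25) ahead of seq_3760 (ATMP5, score 0.57, charge +0.25) — the same two
candidates, in the same order, that the screen carried forward to
synthesis. The property panel reproduces the printed values behind those
decisions:

```r
atmp6 <- panels[panels$id == "seq_3833", ]
round(atmp6$gravy, 2)            #> -0.76   (mean Kyte-Doolittle hydropathy)
atmp6$net_charge_quarter          #> 1.25    (quarter convention)
atmp6$net_charge_anticp           #> 1.5     (integer-plus-half convention)
atmp6$hydrophobic_percent         #> 13      (3 alanines / 24 residues, half-up)
round(atmp6$pI, 2)                #> 10.1    (bisection, calibrated pKa set)
```

An end-to-end run from a template (scan → properties → filter → report,
writing FASTA/CSV artifacts and a config-echoing log):

```r
res <- run_pipeline(parse_peptide("AtMP1_24", atmp_templates()$sequence[2]),
                    run_config(), scores = atmp_scores(), out_dir = "run1")
```

A thin command-line wrapper with `scan`, `props`, `filter`, `synth` and
`run` subcommands is installed at `exec/pepscan` inside the package
directory.

See `vignettes/pepscan-methods.Rmd` for the conventions, the pKa
calibration, the open threshold decisions and the generator's assumptions.

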