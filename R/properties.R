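#' Grand average of hydropathy (GRAVY)
#'
#' Mean Kyte-Doolittle hydropathy over all residues. Negative values mark
#' hydrophilic peptides; the low-complexity threonine-rich templates this
#' package targets sit around -0.6 to -0.8.
#'
#' @param x a `"peptide"`, a sequence string, or a character vector of
#'   sequences (vectorised).
#' @return Numeric vector of mean hydropathies (Kyte-Doolittle units).
#' @examples
#' gravy("THPPTTTTTTTTTTTTTAAPARTT") # -0.7625
#' @export
gravy <- function(x) scale_mean(x, "kyte_doolittle")

#' Mean hydrophilicity over a residue scale
#'
#' Mean of a per-residue hydrophilicity scale over the sequence; defaults to
#' Hopp-Woods. Any registered scale (see [scale_table()]) may be named.
#'
#' @inheritParams gravy
#' @param scale registered scale name or named numeric vector.
#' @return Numeric vector of scale means.
#' @export
hydrophilicity <- function(x, scale = "hopp_woods") scale_mean(x, scale)

#' Mean of an arbitrary residue scale
#'
#' @inheritParams hydrophilicity
#' @return Numeric vector of per-peptide scale means.
#' @export
scale_mean <- function(x, scale) {
  values <- scale_table(scale)
  seqs <- peptide_sequences(x)
  vapply(seqs, function(s) {
    mean(values[strsplit(s, "", fixed = TRUE)[[1L]]])
  }, numeric(1L), USE.NAMES = FALSE)
}

#' Default hydrophobic residue set
#'
#' A, C, F, I, L, M, V, W: the aliphatic/aromatic residues counted as
#' hydrophobic when reporting a peptide's hydrophobic percentage. Glycine
#' and proline are excluded (see the methods vignette for the calibration
#' against the reference peptides, whose 3 alanines in 24 residues give
#' 12.5%, reported as 13%).
#' @return Character vector of residue codes.
#' @export
hydrophobic_residues <- function() c("A", "C", "F", "I", "L", "M", "V", "W")

#' Hydrophobic fraction and rounded percentage
#'
#' Proportion of residues belonging to a designated hydrophobic set.
#' `hydrophobic_percent()` reports it the way screening tables print it: as
#' a percentage rounded half-up to the nearest integer (so 12.5% prints as
#' 13%).
#'
#' @inheritParams gravy
#' @param set hydrophobic residue set; default [hydrophobic_residues()].
#' @return `hydrophobic_fraction()`: proportions in \[0, 1\];
#'   `hydrophobic_percent()`: integer percentages.
#' @examples
#' hydrophobic_percent("THPPTTTTTTTTTTTTTAAPARTT") # 13
#' @export
hydrophobic_fraction <- function(x, set = hydrophobic_residues()) {
  stopifnot(all(set %in% AA_STANDARD20))
  seqs <- peptide_sequences(x)
  vapply(seqs, function(s) {
    res <- strsplit(s, "", fixed = TRUE)[[1L]]
    sum(res %in% set) / length(res)
  }, numeric(1L), USE.NAMES = FALSE)
}

#' @rdname hydrophobic_fraction
#' @export
hydrophobic_percent <- function(x, set = hydrophobic_residues()) {
  round_half_up(100 * hydrophobic_fraction(x, set))
}

# Screening tables round half-up; base round() rounds half to even.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Average molecular weight
#'
#' Sum of average residue masses plus one water (18.0153 Da).
#'
#' @inheritParams gravy
#' @param masses residue-mass scale; default the shipped average masses.
#' @return Numeric vector of molecular weights in Daltons.
#' @examples
#' molecular_weight("G") # 75.07
#' @export
molecular_weight <- function(x, masses = "residue_mass_average") {
  values <- scale_table(masses)
  seqs <- peptide_sequences(x)
  vapply(seqs, function(s) {
    sum(values[strsplit(s, "", fixed = TRUE)[[1L]]]) + 18.0153
  }, numeric(1L), USE.NAMES = FALSE)
}

#' Guruprasad instability index
#'
#' \eqn{(10/L) \sum_{i=1}^{L-1} \mathrm{DIWV}(x_i, x_{i+1})} over the
#' published 400-entry dipeptide instability weight table. Values above 40
#' conventionally denote an unstable peptide.
#'
#' @inheritParams gravy
#' @return Numeric vector of instability indices; peptides must have at
#'   least two residues.
#' @export
instability_index <- function(x) {
  dw <- diwv_matrix()
  seqs <- peptide_sequences(x)
  vapply(seqs, function(s) {
    L <- nchar(s)
    if (L < 2L) stop("instability index requires length >= 2", call. = FALSE)
    res <- strsplit(s, "", fixed = TRUE)[[1L]]
    (10 / L) * sum(dw[cbind(res[-L], res[-1L])])
  }, numeric(1L), USE.NAMES = FALSE)
}

#' Aliphatic index
#'
#' \eqn{100 (f_A + 2.9 f_V + 3.9 (f_I + f_L))} with \eqn{f} the mole
#' fractions of alanine, valine, isoleucine and leucine; a thermostability
#' proxy.
#'
#' @inheritParams gravy
#' @return Numeric vector of aliphatic indices.
#' @examples
#' aliphatic_index("AVIL") # 292.5
#' @export
aliphatic_index <- function(x) {
  seqs <- peptide_sequences(x)
  vapply(seqs, function(s) {
    cnt <- residue_counts(s)
    L <- nchar(s)
    f <- function(r) if (r %in% names(cnt)) cnt[[r]] / L else 0
    100 * (f("A") + 2.9 * f("V") + 3.9 * (f("I") + f("L")))
  }, numeric(1L), USE.NAMES = FALSE)
}

#' Configuration for the property panel
#'
#' Bundles the scale/convention choices behind [property_panel()]: the pKa
#' set, the pH at which the Henderson-Hasselbalch charge is evaluated, the
#' hydrophilicity scale and the hydrophobic residue set.
#'
#' @param pka pKa set name or object (default `"calibrated"`).
#' @param pH pH for the continuous net charge (default 7.0, physiological).
#' @param hydrophilicity_scale registered scale name (default
#'   `"hopp_woods"`).
#' @param hydrophobic_set residue set for the hydrophobic fraction.
#' @param pi_tol bisection tolerance for the isoelectric point.
#' @return A list of class `"panel_config"`.
#' @export
panel_config <- function(pka = "calibrated", pH = 7.0,
                         hydrophilicity_scale = "hopp_woods",
                         hydrophobic_set = hydrophobic_residues(),
                         pi_tol = 1e-4) {
  structure(list(pka = pka_set(pka), pH = pH,
                 hydrophilicity_scale = hydrophilicity_scale,
                 hydrophobic_set = hydrophobic_set, pi_tol = pi_tol),
            class = "panel_config")
}

#' Full physicochemical property panel
#'
#' Computes, per peptide, every property the selection cascade and the
#' standard screening reports consume: length, net charge under both fixed
#' conventions and under the Henderson-Hasselbalch model at the configured
#' pH, isoelectric point, GRAVY, hydrophilicity, hydrophobic fraction and
#' rounded percentage, molecular weight, and (for peptides of length >= 2)
#' instability and aliphatic indices. Deterministic for a fixed
#' configuration.
#'
#' @param x a peptide-library data frame (`id`, `sequence`), a
#'   [single_substitution_library()], a `"peptide"`, or a character vector
#'   of sequences.
#' @param config a [panel_config()].
#' @return A data frame with one row per peptide and columns `id`,
#'   `sequence`, `length`, `net_charge_quarter`, `net_charge_anticp`,
#'   `net_charge_hh`, `pI`, `gravy`, `hydrophilicity`,
#'   `hydrophobic_fraction`, `hydrophobic_percent`, `molecular_weight`,
#'   `instability_index`, `aliphatic_index`.
#' @examples
#' property_panel(parse_peptide("ATMP6", "THPPTTTTTTTTTTTTTAAPARTT"))
#' @export
property_panel <- function(x, config = panel_config()) {
  stopifnot(inherits(config, "panel_config"))
  if (is.character(x) && is.null(dim(x))) {
    x <- data.frame(id = if (!is.null(names(x))) names(x) else
                      sprintf("pep%d", seq_along(x)),
                    sequence = as.vector(x), stringsAsFactors = FALSE)
  }
  lib <- as_peptide_library(x)
  seqs <- lib$sequence
  data.frame(
    id = lib$id,
    sequence = seqs,
    length = nchar(seqs),
    net_charge_quarter = net_charge_fixed(seqs, "quarter_ph7"),
    net_charge_anticp = net_charge_fixed(seqs, "anticp_integer"),
    net_charge_hh = net_charge_hh(seqs, config$pka, config$pH),
    pI = isoelectric_point(seqs, config$pka, config$pi_tol),
    gravy = gravy(seqs),
    hydrophilicity = hydrophilicity(seqs, config$hydrophilicity_scale),
    hydrophobic_fraction = hydrophobic_fraction(seqs, config$hydrophobic_set),
    hydrophobic_percent = hydrophobic_percent(seqs, config$hydrophobic_set),
    molecular_weight = molecular_weight(seqs),
    instability_index = vapply(seqs, function(s)
      if (nchar(s) >= 2L) instability_index(s) else NA_real_,
      numeric(1L), USE.NAMES = FALSE),
    aliphatic_index = aliphatic_index(seqs),
    stringsAsFactors = FALSE
  )
}
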