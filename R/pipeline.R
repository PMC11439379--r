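#' Run configuration
#'
#' A serialisable bundle of every choice a screening run depends on: the
#' substitution alphabet, the charge convention the cascade filters on, the
#' pKa set, hydrophilicity scale and hydrophobic residue set behind the
#' property panel, and the filter criteria. Because published tables mix
#' charge conventions, the run log always echoes these names.
#'
#' @param alphabet alphabet name (`"standard20"` or `"paper18"`).
#' @param charge_convention convention for the cascade's charge stage.
#' @param pka pKa set name.
#' @param hydrophilicity_scale registered scale name.
#' @param hydrophobic_set hydrophobic residue set.
#' @param criteria a [filter_criteria()].
#' @param preset optional criteria preset (see [filter_criteria()]).
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(alphabet = "standard20",
                       charge_convention = c("quarter_ph7", "anticp_integer"),
                       pka = "calibrated",
                       hydrophilicity_scale = "hopp_woods",
                       hydrophobic_set = hydrophobic_residues(),
                       criteria = NULL,
                       preset = NULL) {
  charge_convention <- match.arg(charge_convention)
  if (is.null(criteria)) {
    criteria <- filter_criteria(charge_convention = charge_convention,
                                preset = preset)
  }
  stopifnot(inherits(criteria, "filter_criteria"))
  aa_alphabet(alphabet)           # validate the name resolves
  pka_set(pka)
  scale_table(hydrophilicity_scale)
  structure(list(alphabet = alphabet, charge_convention = charge_convention,
                 pka = pka, hydrophilicity_scale = hydrophilicity_scale,
                 hydrophobic_set = hydrophobic_set, criteria = criteria),
            class = "run_config")
}

#' Serialise / parse a run configuration
#'
#' YAML round-trip for [run_config()]: `write_run_config()` then
#' `read_run_config()` is the identity, and re-serialising a parsed config
#' reproduces the file byte for byte.
#'
#' @param config a `"run_config"`.
#' @param path YAML file path.
#' @return `read_run_config()` returns the `"run_config"`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  lst <- unclass(config)
  lst$criteria <- unclass(lst$criteria)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lst <- yaml::read_yaml(path)
  crit <- do.call(filter_criteria, lst$criteria)
  run_config(alphabet = lst$alphabet,
             charge_convention = lst$charge_convention,
             pka = lst$pka,
             hydrophilicity_scale = lst$hydrophilicity_scale,
             hydrophobic_set = unlist(lst$hydrophobic_set),
             criteria = crit)
}

#' End-to-end screening pipeline
#'
#' Scan, property panel, filter, rank, report: generates the
#' single-substitution library from the template (or takes a ready-made
#' library), computes the property panel, runs the selection cascade
#' against the supplied scores, and writes the artifacts to `out_dir`:
#' `variants.fasta`, `properties.csv`, `funnel.csv`, `selection.fasta` and
#' `run_log.txt` (with a config echo). Re-running with identical inputs and
#' configuration reproduces the CSVs byte for byte. A missing score table
#' is a defined degradation: with the antimicrobial stage enabled every
#' peptide is excluded there as unscored (and a warning is logged), and the
#' empty result is still written.
#'
#' @param template a `"peptide"`, sequence string, or a peptide-library
#'   data frame to screen as-is.
#' @param config a [run_config()].
#' @param scores optional score table.
#' @param out_dir output directory (created if needed).
#' @return The `"cascade_result"`, invisibly, with the property panel in
#'   attribute `"panels"`.
#' @export
run_pipeline <- function(template, config = run_config(), scores = NULL,
                         out_dir) {
  stopifnot(inherits(config, "run_config"))
  if (missing(out_dir)) stop("out_dir is required", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  if (is.data.frame(template)) {
    lib <- as_peptide_library(template)
  } else {
    if (!inherits(template, "peptide")) {
      template <- parse_peptide("template", template)
    }
    lib <- single_substitution_library(template, aa_alphabet(config$alphabet))
    lib <- as_peptide_library(lib)
  }
  write_peptide_fasta(lib, file.path(out_dir, "variants.fasta"))

  pconf <- panel_config(pka = config$pka,
                        hydrophilicity_scale = config$hydrophilicity_scale,
                        hydrophobic_set = config$hydrophobic_set)
  panels <- property_panel(lib, pconf)
  write_properties_csv(panels, file.path(out_dir, "properties.csv"))

  if (is.null(scores)) {
    warning("no score table supplied; all peptides fail scored stages as unscored",
            call. = FALSE)
  }
  result <- run_cascade(panels, scores, config$criteria)
  utils::write.csv(funnel_report(result), file.path(out_dir, "funnel.csv"),
                   row.names = FALSE)

  sel <- lib[lib$id %in% result$final_ranking$id, , drop = FALSE]
  sel <- sel[match(result$final_ranking$id, sel$id), , drop = FALSE]
  if (nrow(sel)) {
    write_peptide_fasta(sel, file.path(out_dir, "selection.fasta"))
  } else {
    writeLines(character(0), file.path(out_dir, "selection.fasta"))
  }

  log <- c(
    "pepscan run log",
    paste0("alphabet: ", config$alphabet),
    paste0("charge_convention: ", config$charge_convention),
    paste0("pka_set: ", config$pka),
    paste0("hydrophilicity_scale: ", config$hydrophilicity_scale),
    paste0("hydrophobic_set: ", paste(config$hydrophobic_set, collapse = "")),
    paste0("library_size: ", nrow(lib)),
    paste0("survivors: ", length(result$survivors)),
    paste0("selection: ", paste(result$final_ranking$id, collapse = ", "))
  )
  writeLines(log, file.path(out_dir, "run_log.txt"))

  attr(result, "panels") <- panels
  invisible(result)
}

#' Write a property panel as a fixed-precision CSV
#'
#' Charges, scale means and the isoelectric point are formatted to two
#' decimals (the precision screening tables print); fractions to four.
#'
#' @param panels data frame from [property_panel()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_properties_csv <- function(panels, path) {
  out <- panels
  two <- c("net_charge_quarter", "net_charge_anticp", "net_charge_hh", "pI",
           "gravy", "hydrophilicity", "molecular_weight", "instability_index",
           "aliphatic_index")
  for (col in intersect(two, names(out))) {
    out[[col]] <- sprintf("%.2f", out[[col]])
  }
  if ("hydrophobic_fraction" %in% names(out)) {
    out$hydrophobic_fraction <- sprintf("%.4f", out$hydrophobic_fraction)
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
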