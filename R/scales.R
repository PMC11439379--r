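#' Residue scale tables and pKa sets
#'
#' Per-residue numeric lookup tables (hydropathy, hydrophilicity, average
#' residue masses) and ionizable-group pKa sets are held in a package-level
#' registry, populated at load time from the plain-text tables shipped with
#' the package. Registered tables are immutable: re-registering a name is an
#' error.
#'
#' Shipped scales: `"kyte_doolittle"` (hydropathy), `"hopp_woods"`
#' (hydrophilicity) and `"residue_mass_average"` (average residue masses,
#' Da). Shipped pKa sets: `"calibrated"` (the package default, chosen to
#' reproduce the isoelectric points of the ATMP5/ATMP6 reference peptides;
#' see the methods vignette), `"emboss"` and `"lehninger"`.
#'
#' @param name registry name.
#' @param values named numeric vector covering all 20 standard residues.
#' @return `scale_table()` returns the named numeric vector; `scale_names()`
#'   the registered scale names.
#' @name scales
NULL

#' @rdname scales
#' @export
scale_table <- function(name) {
  if (is.numeric(name) && !is.null(names(name))) return(check_scale(name))
  val <- get0(name, envir = .pepscan_registry$scales, inherits = FALSE)
  if (is.null(val)) {
    stop("unknown scale '", name, "'; registered: ",
         paste(scale_names(), collapse = ", "), call. = FALSE)
  }
  val
}

#' @rdname scales
#' @export
scale_names <- function() sort(ls(.pepscan_registry$scales))

#' @rdname scales
#' @export
register_scale_table <- function(name, values) {
  if (!is.null(get0(name, envir = .pepscan_registry$scales, inherits = FALSE))) {
    stop("scale '", name, "' is already registered (scales are immutable)",
         call. = FALSE)
  }
  assign(name, check_scale(values), envir = .pepscan_registry$scales)
  invisible(name)
}

check_scale <- function(values) {
  missing <- setdiff(AA_STANDARD20, names(values))
  if (length(missing)) {
    stop("scale does not cover residues: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  values[AA_STANDARD20]
}

#' Ionizable-group pKa sets
#'
#' A pKa set gives the acid dissociation constants of the seven ionizable
#' side chains (D, E, C, Y, H, K, R) and the free N- and C-termini, all in
#' (0, 14). The default `"calibrated"` set underlies the package's
#' Henderson-Hasselbalch net charge and isoelectric point.
#'
#' @param name registered set name (`"calibrated"`, `"emboss"`,
#'   `"lehninger"`), or an existing `"pka_set"` object (returned unchanged).
#' @param side_chain named numeric vector of side-chain pKas for
#'   D, E, C, Y, H, K, R.
#' @param n_terminus,c_terminus terminal pKas.
#' @return A list of class `"pka_set"` with elements `name`, `side_chain`,
#'   `n_terminus`, `c_terminus`.
#' @export
pka_set <- function(name = "calibrated") {
  if (inherits(name, "pka_set")) return(name)
  val <- get0(name, envir = .pepscan_registry$pka, inherits = FALSE)
  if (is.null(val)) {
    stop("unknown pKa set '", name, "'; registered: ",
         paste(sort(ls(.pepscan_registry$pka)), collapse = ", "), call. = FALSE)
  }
  val
}

#' @rdname pka_set
#' @export
register_pka_set <- function(name, side_chain, n_terminus, c_terminus) {
  need <- c("D", "E", "C", "Y", "H", "K", "R")
  missing <- setdiff(need, names(side_chain))
  if (length(missing)) {
    stop("pKa set lacks side chains: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  all_pka <- c(side_chain[need], n_terminus, c_terminus)
  if (any(all_pka <= 0 | all_pka >= 14)) {
    stop("all pKas must lie in (0, 14)", call. = FALSE)
  }
  if (!is.null(get0(name, envir = .pepscan_registry$pka, inherits = FALSE))) {
    stop("pKa set '", name, "' is already registered", call. = FALSE)
  }
  obj <- structure(
    list(name = name, side_chain = side_chain[need],
         n_terminus = n_terminus, c_terminus = c_terminus),
    class = "pka_set"
  )
  assign(name, obj, envir = .pepscan_registry$pka)
  invisible(obj)
}

# Guruprasad dipeptide instability weights as a 20 x 20 matrix
# (rows = first residue, columns = second residue).
diwv_matrix <- function() .pepscan_registry$diwv
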