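# Independent brute-force oracles, kept deliberately naive and separate from
# the implementation paths they check.

# Mean of a residue scale by explicit per-character summation.
oracle_scale_mean <- function(seq, values) {
  total <- 0
  for (i in seq_len(nchar(seq))) {
    total <- total + values[[substr(seq, i, i)]]
  }
  total / nchar(seq)
}

# Henderson-Hasselbalch net charge by explicit per-group summation.
oracle_hh_charge <- function(seq, pka, pH) {
  q <- 1 / (1 + 10^(pH - pka$n_terminus)) - 1 / (1 + 10^(pka$c_terminus - pH))
  for (i in seq_len(nchar(seq))) {
    r <- substr(seq, i, i)
    if (r %in% c("H", "K", "R")) {
      q <- q + 1 / (1 + 10^(pH - pka$side_chain[[r]]))
    } else if (r %in% c("D", "E", "C", "Y")) {
      q <- q - 1 / (1 + 10^(pka$side_chain[[r]] - pH))
    }
  }
  q
}

# Every Hamming-distance-1 neighbour over an alphabet, by nested loops.
oracle_single_substitutions <- function(seq, alphabet) {
  out <- character(0)
  for (i in seq_len(nchar(seq))) {
    for (a in alphabet) {
      cand <- paste0(substr(seq, 1, i - 1), a, substr(seq, i + 1, nchar(seq)))
      if (cand != seq) out <- c(out, cand)
    }
  }
  unique(out)
}

# Instability index by summing raw table rows read straight from the shipped
# dipeptide weight file (bypasses the package's matrix lookup).
oracle_instability <- function(seq) {
  dw <- read.delim(system.file("extdata", "diwv.tsv", package = "pepscan"),
                   stringsAsFactors = FALSE)
  total <- 0
  for (i in seq_len(nchar(seq) - 1)) {
    a <- substr(seq, i, i)
    b <- substr(seq, i + 1, i + 1)
    total <- total + dw$weight[dw$first == a & dw$second == b]
  }
  10 / nchar(seq) * total
}

# pKa registration is immutable; across repeated in-session test runs, reuse.
register_or_get <- function(name, side_chain, n_terminus, c_terminus) {
  tryCatch(register_pka_set(name, side_chain, n_terminus, c_terminus),
           error = function(e) pka_set(name))
}

random_peptide <- function(len) {
  paste(sample(AA_STANDARD20, len, replace = TRUE), collapse = "")
}

ATMP5 <- "THPPTTTTTTTTTTTYTAAPATTT"
ATMP6 <- "THPPTTTTTTTTTTTTTAAPARTT"
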