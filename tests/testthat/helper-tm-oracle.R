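# Independent nearest-neighbor Tm oracle. Same published unified
# thermodynamic parameters, but coded from the complementary-strand
# orientation: each top-strand step XY is scored via the parameter of the
# duplex written 5'-XY-3'/3'-(comp X)(comp Y)-5', looked up from a table
# keyed on both strands, with totals accumulated in a different traversal
# order than the package implementation.

oracle_tm <- function(seq, primer_conc = 0.25e-6, na_conc = 0.05) {
  duplex <- list(
    "AA/TT" = c(-7.9, -22.2), "AT/TA" = c(-7.2, -20.4),
    "TA/AT" = c(-7.2, -21.3), "CA/GT" = c(-8.5, -22.7),
    "GT/CA" = c(-8.4, -22.4), "CT/GA" = c(-7.8, -21.0),
    "GA/CT" = c(-8.2, -22.2), "CG/GC" = c(-10.6, -27.2),
    "GC/CG" = c(-9.8, -24.4), "GG/CC" = c(-8.0, -19.9),
    # reverse-orientation aliases (reading the bottom strand 5'->3')
    "TT/AA" = c(-7.9, -22.2), "TG/AC" = c(-8.5, -22.7),
    "AC/TG" = c(-8.4, -22.4), "AG/TC" = c(-7.8, -21.0),
    "TC/AG" = c(-8.2, -22.2), "CC/GG" = c(-8.0, -19.9))
  comp <- c(A = "T", T = "A", G = "C", C = "G")
  chars <- strsplit(toupper(seq), "")[[1]]
  n <- length(chars)
  dH <- 0; dS <- 0
  for (i in rev(seq_len(n - 1))) {  # traverse 3' -> 5'
    top <- paste0(chars[i], chars[i + 1])
    key <- paste0(top, "/", comp[chars[i]], comp[chars[i + 1]])
    p <- duplex[[key]]
    dH <- dH + p[1]; dS <- dS + p[2]
  }
  init <- function(b) if (b %in% c("G", "C")) c(0.1, -2.8) else c(2.3, 4.1)
  p <- init(chars[n]); dH <- dH + p[1]; dS <- dS + p[2]
  p <- init(chars[1]); dH <- dH + p[1]; dS <- dS + p[2]
  dS_salt <- dS + 0.368 * (n - 1) * log(na_conc)
  1000 * dH / (dS_salt + 1.987 * log(primer_conc / 4)) - 273.15
}
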