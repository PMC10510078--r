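# Codon machinery: genetic code via Biostrings, packaged E. coli K-12 usage.

# Codon usage of E. coli K-12 (frequency per thousand codons, Kazusa-style
# counts); normalized per amino acid on construction.
.ECOLI_K12_PER_THOUSAND <- c(
  TTT = 22.2, TTC = 16.6, TTA = 13.9, TTG = 13.7,
  CTT = 11.0, CTC = 11.0, CTA = 3.9,  CTG = 52.6,
  ATT = 30.3, ATC = 25.1, ATA = 4.4,  ATG = 27.9,
  GTT = 18.3, GTC = 15.3, GTA = 10.9, GTG = 26.4,
  TCT = 8.5,  TCC = 8.6,  TCA = 7.2,  TCG = 8.9,
  CCT = 7.0,  CCC = 5.5,  CCA = 8.4,  CCG = 23.2,
  ACT = 9.0,  ACC = 23.4, ACA = 7.1,  ACG = 14.4,
  GCT = 15.3, GCC = 25.5, GCA = 20.1, GCG = 33.6,
  TAT = 16.2, TAC = 12.2,
  CAT = 12.9, CAC = 9.7,  CAA = 15.3, CAG = 28.8,
  AAT = 17.7, AAC = 21.7, AAA = 33.6, AAG = 10.3,
  GAT = 32.1, GAC = 19.1, GAA = 39.4, GAG = 17.8,
  TGT = 5.2,  TGC = 6.4,  TGG = 15.2,
  CGT = 20.9, CGC = 22.0, CGA = 3.6,  CGG = 5.4,
  AGT = 8.8,  AGC = 16.1, AGA = 2.1,  AGG = 1.2,
  GGT = 24.7, GGC = 29.6, GGA = 8.0,  GGG = 11.1
)

#' Codon usage table
#'
#' Relative synonymous codon frequencies for an organism: for each of the 61
#' sense codons, its frequency among the codons of its amino acid (per-amino-
#' acid weights sum to 1). Used to pick codons when encoding protein-level
#' mutations into oligos.
#'
#' @param per_thousand named numeric vector of codon frequencies (any
#'   positive scale; normalized per amino acid). Names are the 61 sense
#'   codons.
#' @param organism label.
#' @return object of class `codon_usage_table` with fields `organism`,
#'   `codons` (data.frame codon/aa/weight) and `by_aa` (list of named weight
#'   vectors per amino acid).
#' @export
codon_usage_table <- function(per_thousand, organism = "custom") {
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  missing <- setdiff(sense, names(per_thousand))
  if (length(missing) > 0) {
    stop_(sprintf("codon usage table missing sense codons: %s",
                  paste(missing, collapse = ", ")))
  }
  per_thousand <- per_thousand[sense]
  if (any(!is.finite(per_thousand)) || any(per_thousand < 0)) {
    stop_("codon frequencies must be finite and non-negative")
  }
  aa <- unname(code[sense])
  weight <- unsplit(lapply(split(per_thousand, aa), function(v) v / sum(v)), aa)
  codons <- data.frame(codon = sense, aa = aa, weight = unname(weight),
                       stringsAsFactors = FALSE)
  by_aa <- lapply(split(codons, codons$aa), function(d) {
    stats::setNames(d$weight, d$codon)
  })
  structure(list(organism = organism, codons = codons, by_aa = by_aa),
            class = "codon_usage_table")
}

#' Packaged E. coli K-12 codon usage
#'
#' @return a [codon_usage_table()] for E. coli K-12.
#' @export
ecoli_codon_usage <- function() {
  codon_usage_table(.ECOLI_K12_PER_THOUSAND, organism = "E. coli K-12")
}

#' Select a codon for an amino acid
#'
#' Two policies: `"max_usage"` (default) picks the most frequent codon of the
#' target amino acid in the usage table; `"min_edit"` picks the codon with
#' the fewest nucleotide changes from the wild-type codon, breaking ties by
#' usage frequency (then alphabetically, for determinism).
#'
#' @param mut_aa target amino-acid letter.
#' @param wt_codon wild-type codon (required for `"min_edit"`).
#' @param table a [codon_usage_table()].
#' @param policy `"max_usage"` or `"min_edit"`.
#' @return a 3-letter codon string whose translation is `mut_aa`.
#' @export
select_codon <- function(mut_aa, wt_codon = NULL,
                         table = ecoli_codon_usage(),
                         policy = c("max_usage", "min_edit")) {
  policy <- match.arg(policy)
  if (!mut_aa %in% AA_ALPHABET) stop_(sprintf("'%s' is not a canonical residue", mut_aa))
  w <- table$by_aa[[mut_aa]]
  if (is.null(w)) stop_(sprintf("no codons for amino acid %s in table", mut_aa))
  cands <- names(w)
  if (policy == "max_usage") {
    cands <- cands[order(-w, cands)]
    return(cands[1])
  }
  stopifnot(!is.null(wt_codon), nchar(wt_codon) == 3L)
  wt_chars <- strsplit(toupper(wt_codon), "")[[1]]
  edits <- vapply(cands, function(cd) {
    sum(strsplit(cd, "")[[1]] != wt_chars)
  }, integer(1))
  cands[order(edits, -w, cands)][1]
}

#' Translate a codon
#'
#' @param codon 3-letter DNA codon.
#' @return amino-acid letter (`*` for stop).
#' @export
translate_codon <- function(codon) {
  codon <- toupper(codon)
  stopifnot(nchar(codon) == 3L)
  unname(Biostrings::GENETIC_CODE[codon])
}

#' Reverse complement of a DNA string
#'
#' @param seq DNA string (ACGT).
#' @return reverse-complemented string.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}
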