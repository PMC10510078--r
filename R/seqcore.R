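# Sequence domain types, FASTA I/O and sequence-space arithmetic.
#
# Coordinates are 1-based and inclusive throughout, for both residues and
# bases. Parsers accept an `index_base` argument so externally produced
# 0-based tables can be ingested; the internal representation is fixed.

#' Protein sequence
#'
#' A validated protein sequence over the 20 canonical amino-acid letters.
#' Lengths outside 80-600 residues are legal but flagged (`in_range = FALSE`)
#' because several upstream predictors only accept that range; under
#' `strict = TRUE` they are rejected.
#'
#' @param residues single string of amino-acid letters (upper-cased).
#' @param id text label.
#' @param strict error (rather than warn) on lengths outside 80-600.
#' @return an object of class `protein_sequence` with fields `id`, `residues`,
#'   `length`, `in_range`.
#' @export
protein_sequence <- function(residues, id = "protein", strict = FALSE) {
  stopifnot(is.character(residues), length(residues) == 1L)
  residues <- toupper(residues)
  if (nchar(residues) < 1L) stop_("protein sequence must be non-empty")
  letters <- strsplit(residues, "")[[1]]
  bad <- which(!letters %in% AA_ALPHABET)
  if (length(bad) > 0) {
    stop_(sprintf("illegal residue '%s' at position %d in '%s'",
                  letters[bad[1]], bad[1], id))
  }
  n <- nchar(residues)
  in_range <- n >= 80L && n <= 600L
  if (!in_range) {
    msg <- sprintf("protein '%s' has %d residues, outside the 80-600 range", id, n)
    if (strict) stop_(msg) else warn_(msg)
  }
  structure(list(id = id, residues = residues, length = n, in_range = in_range),
            class = "protein_sequence")
}

#' Gene (DNA) sequence
#'
#' A validated DNA sequence over ACGT. `U` is transliterated to `T` with a
#' warning; degenerate IUPAC codes are rejected (the oligo design pipeline
#' requires concrete parent sequences). `frame_offset` gives the number of
#' bases before the first complete codon (0 by default); overall length need
#' not be a multiple of 3 - codon-aware operations validate locally.
#'
#' @param bases single string of DNA bases.
#' @param id text label.
#' @param frame_offset bases preceding the first codon (>= 0).
#' @return an object of class `gene_sequence` with fields `id`, `bases`,
#'   `length`, `frame_offset`.
#' @export
gene_sequence <- function(bases, id = "gene", frame_offset = 0L) {
  stopifnot(is.character(bases), length(bases) == 1L)
  bases <- toupper(bases)
  if (grepl("U", bases, fixed = TRUE)) {
    warn_(sprintf("RNA bases (U) in '%s' transliterated to T", id))
    bases <- gsub("U", "T", bases, fixed = TRUE)
  }
  if (nchar(bases) < 1L) stop_("gene sequence must be non-empty")
  letters <- strsplit(bases, "")[[1]]
  bad <- which(!letters %in% DNA_BASES)
  if (length(bad) > 0) {
    stop_(sprintf("illegal base '%s' at position %d in '%s'",
                  letters[bad[1]], bad[1], id))
  }
  stopifnot(frame_offset >= 0)
  structure(list(id = id, bases = bases, length = nchar(bases),
                 frame_offset = as.integer(frame_offset)),
            class = "gene_sequence")
}

#' @export
print.protein_sequence <- function(x, ...) {
  cat(sprintf("<protein_sequence> %s: %d aa%s\n", x$id, x$length,
              if (x$in_range) "" else " (outside 80-600 range)"))
  invisible(x)
}

#' @export
print.gene_sequence <- function(x, ...) {
  cat(sprintf("<gene_sequence> %s: %d bp (frame offset %d)\n",
              x$id, x$length, x$frame_offset))
  invisible(x)
}

#' Single-mutation specification
#'
#' One amino-acid substitution: 1-based residue index, wild-type residue and
#' target residue. Identity specs (`mut_aa == wt_aa`) are rejected unless
#' `allow_identity = TRUE`.
#'
#' @param site 1-based residue index.
#' @param wt_aa wild-type residue letter.
#' @param mut_aa target residue letter.
#' @param allow_identity permit `mut_aa == wt_aa`.
#' @return an object of class `mutation_spec`.
#' @export
mutation_spec <- function(site, wt_aa, mut_aa, allow_identity = FALSE) {
  site <- as.integer(site)
  wt_aa <- toupper(wt_aa); mut_aa <- toupper(mut_aa)
  stopifnot(length(site) == 1L, site >= 1L,
            wt_aa %in% AA_ALPHABET, mut_aa %in% AA_ALPHABET)
  identity <- wt_aa == mut_aa
  if (identity && !allow_identity) {
    stop_(sprintf("identity mutation %s%d%s not allowed", wt_aa, site, mut_aa))
  }
  structure(list(site = site, wt_aa = wt_aa, mut_aa = mut_aa,
                 identity = identity, level = "protein"),
            class = "mutation_spec")
}

#' DNA-level mutation unit
#'
#' A contiguous same-length replacement of bases, e.g. three consecutive
#' adenines at bases 30-32. `start` is 1-based inclusive.
#'
#' @param start 1-based index of the first replaced base.
#' @param replacement replacement base string (same length as replaced span).
#' @param id optional label (e.g. "SeqA").
#' @return an object of class `dna_unit`.
#' @export
dna_unit <- function(start, replacement, id = NULL) {
  start <- as.integer(start)
  replacement <- toupper(replacement)
  stopifnot(length(start) == 1L, start >= 1L, nchar(replacement) >= 1L)
  letters <- strsplit(replacement, "")[[1]]
  if (!all(letters %in% DNA_BASES)) stop_("replacement must be ACGT only")
  structure(list(start = start, end = start + nchar(replacement) - 1L,
                 replacement = replacement, level = "dna",
                 id = id %||% sprintf("u%d", start)),
            class = "dna_unit")
}

#' @export
format.mutation_spec <- function(x, ...) sprintf("%s%d%s", x$wt_aa, x$site, x$mut_aa)

#' @export
format.dna_unit <- function(x, ...) sprintf("%d-%d>%s", x$start, x$end, x$replacement)

#' @export
print.mutation_spec <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' @export
print.dna_unit <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' Read sequences from a FASTA file
#'
#' Multi-record FASTA reader. The alphabet is auto-detected per file (a record
#' set consisting only of ACGTU characters is read as DNA, otherwise protein)
#' and can be overridden with `alphabet`. Returns a list of
#' [protein_sequence()] or [gene_sequence()] objects; descriptions are kept
#' as ids.
#'
#' @param path FASTA file.
#' @param alphabet `"auto"`, `"dna"` or `"protein"`.
#' @param strict enforce the 80-600 residue bound as an error (protein only).
#' @return list of sequence objects.
#' @export
read_fasta <- function(path, alphabet = c("auto", "dna", "protein"),
                       strict = FALSE) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop_(sprintf("file not found: %s", path))
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop_(sprintf("no FASTA records in %s", path))
  seqs <- unname(toupper(as.character(raw)))
  ids <- names(raw)
  if (any(nchar(seqs) == 0L)) {
    stop_(sprintf("empty record '%s' in %s", ids[which(nchar(seqs) == 0L)[1]], path))
  }
  if (alphabet == "auto") {
    dna_like <- all(grepl("^[ACGTU]+$", seqs))
    alphabet <- if (dna_like) "dna" else "protein"
  }
  if (alphabet == "dna") {
    lapply(seq_along(seqs), function(i) gene_sequence(seqs[i], id = ids[i]))
  } else {
    lapply(seq_along(seqs), function(i) {
      suppressWarnings(protein_sequence(seqs[i], id = ids[i], strict = strict))
    })
  }
}

#' Write sequences to a FASTA file
#'
#' Wraps at 60 columns. Accepts a list of sequence objects or a named
#' character vector.
#'
#' @param seqs list of `protein_sequence`/`gene_sequence`, or named character.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.list(seqs)) {
    chars <- vapply(seqs, function(s) s$residues %||% s$bases, character(1))
    names(chars) <- vapply(seqs, function(s) s$id, character(1))
    seqs <- chars
  }
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Size of the unconstrained sequence space
#'
#' Number of distinct sequences of a given length over a given alphabet,
#' `alphabet_size ^ length`, computed exactly in arbitrary precision, with
#' its base-10 logarithm. A 100-residue protein can be altered in 20^100
#' ways (log10 ~ 130.103).
#'
#' @param length sequence length (>= 0).
#' @param alphabet_size alphabet size (default 20 amino acids).
#' @return list with `value` (exact decimal string), `log10` (numeric) and
#'   `numeric` (possibly `Inf` for very large spaces).
#' @export
sequence_space_size <- function(length, alphabet_size = 20L) {
  length <- as.integer(length)
  if (is.na(length) || length < 0L) stop_("length must be >= 0")
  stopifnot(alphabet_size >= 1L)
  value <- big_to_string(big_pow(alphabet_size, length))
  list(value = value,
       log10 = length * log10(alphabet_size),
       numeric = alphabet_size^length)
}

#' Size of a full single-mutation stability scan
#'
#' A full per-site scan over all 20 residues of an L-residue protein holds
#' 20 x L predicted values (including the wild-type identity cell at each
#' site); of these, 19 x L are true substitutions - the single-substitution
#' sequence space that filtering operates on.
#'
#' @param length protein length in residues (>= 1).
#' @return list with `scan_entries` (20L) and `true_substitutions` (19L).
#' @export
ddg_scan_size <- function(length) {
  length <- as.integer(length)
  if (is.na(length) || length < 1L) stop_("length must be >= 1")
  list(scan_entries = 20L * length, true_substitutions = 19L * length)
}

#' Apply a mutation to a sequence
#'
#' Protein-level [mutation_spec()] objects apply to protein sequences;
#' DNA-level [dna_unit()] objects apply to gene sequences. The wild-type
#' residue/span is validated against the parent; the returned sequence
#' differs from the parent exactly on the mutation span.
#'
#' @param seq a `protein_sequence` or `gene_sequence`.
#' @param m a `mutation_spec` or `dna_unit`.
#' @return mutated sequence of the same class; attribute `identity` is TRUE
#'   when the replacement equals the wild-type span.
#' @export
apply_mutation <- function(seq, m) {
  if (inherits(m, "mutation_spec")) {
    if (!inherits(seq, "protein_sequence")) {
      stop_("protein-level mutation requires a protein_sequence")
    }
    if (m$site > seq$length) stop_(sprintf("site %d beyond length %d", m$site, seq$length))
    wt <- substr(seq$residues, m$site, m$site)
    if (wt != m$wt_aa) {
      stop_(sprintf("wild-type mismatch at site %d: sequence has %s, spec says %s",
                    m$site, wt, m$wt_aa))
    }
    res <- seq$residues
    substr(res, m$site, m$site) <- m$mut_aa
    out <- suppressWarnings(
      protein_sequence(res, id = sprintf("%s_%s", seq$id, format(m))))
    attr(out, "identity") <- m$identity
    out
  } else if (inherits(m, "dna_unit")) {
    if (!inherits(seq, "gene_sequence")) {
      stop_("DNA-level mutation requires a gene_sequence")
    }
    if (m$end > seq$length) {
      stop_(sprintf("unit %d-%d beyond gene length %d", m$start, m$end, seq$length))
    }
    current <- substr(seq$bases, m$start, m$end)
    bases <- seq$bases
    substr(bases, m$start, m$end) <- m$replacement
    out <- gene_sequence(bases, id = sprintf("%s_%s", seq$id, m$id),
                         frame_offset = seq$frame_offset)
    attr(out, "identity") <- identical(current, m$replacement)
    out
  } else {
    stop_("m must be a mutation_spec or dna_unit")
  }
}

#' Hamming distance between two equal-length sequences
#'
#' @param a,b sequence objects or plain strings of equal length.
#' @return integer count of differing positions.
#' @export
hamming_distance <- function(a, b) {
  sa <- if (is.character(a)) a else (a$residues %||% a$bases)
  sb <- if (is.character(b)) b else (b$residues %||% b$bases)
  if (nchar(sa) != nchar(sb)) stop_("sequences differ in length")
  sum(strsplit(sa, "")[[1]] != strsplit(sb, "")[[1]])
}

#' Read a mutation list from TSV
#'
#' Protein dialect has columns `site`, `wt`, `mut` (optionally `activity`);
#' DNA dialect has `start`, `end`, `replacement`. `#`-prefixed lines are
#' comments. `index_base = 0` shifts incoming coordinates to the internal
#' 1-based convention.
#'
#' @param path TSV file.
#' @param index_base 0 or 1; base of the coordinates in the file.
#' @return list of `mutation_spec` (protein dialect) or `dna_unit` (DNA
#'   dialect); protein-dialect activities, when present, are attached as the
#'   `activity` attribute.
#' @export
read_mutations <- function(path, index_base = 1L) {
  stopifnot(index_base %in% c(0L, 1L))
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  shift <- 1L - as.integer(index_base)
  if (all(c("site", "wt", "mut") %in% names(df))) {
    specs <- lapply(seq_len(nrow(df)), function(i) {
      mutation_spec(df$site[i] + shift, df$wt[i], df$mut[i])
    })
    if ("activity" %in% names(df)) attr(specs, "activity") <- df$activity
    specs
  } else if (all(c("start", "end", "replacement") %in% names(df))) {
    lapply(seq_len(nrow(df)), function(i) {
      u <- dna_unit(df$start[i] + shift, df$replacement[i])
      if (u$end != df$end[i] + shift) {
        stop_(sprintf("row %d: replacement length disagrees with start/end", i))
      }
      u
    })
  } else {
    stop_("mutation TSV must have columns site/wt/mut or start/end/replacement")
  }
}
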