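# Oligo-pool design: gene fragmentation, one-mutation-per-oligo encoding,
# nearest-neighbor Tm and sub-pool amplification primers.

# 5'-fragment of the Kemp eliminase HG3 gene used as the packaged worked
# example (156 nt as bundled). Four 3-base regions replaced by AAA runs give
# the classic 4-variant QC pool.
.HG3_FRAGMENT <- paste0(
  "TGGCAGAAGCAGCACAGAGCGTTGACCAGCTGATTAAAGCACGTGGTAAAGTTTATTTTG",
  "GTGTTGCCACCGATCAGAATCGTCTGACCACCGGTAAAAATGCAGCAATTATTCAGGCAG",
  "ATTTTGGTATGGTTTGGCCTGAAAATAGCATGAAAT")

#' Packaged HG3 gene fragment
#'
#' The 5' fragment of the Kemp eliminase HG3 gene used as the package's
#' worked oligo-pool example.
#'
#' @return a [gene_sequence()].
#' @export
hg3_fragment <- function() gene_sequence(.HG3_FRAGMENT, id = "HG3_5prime")

#' The four triple-adenine QC mutation units for the HG3 fragment
#'
#' SeqA-SeqD: three consecutive adenines at bases 30-32, 62-64, 93-95 and
#' 124-126 of the packaged HG3 fragment.
#'
#' @return list of four [dna_unit()] objects.
#' @export
hg3_qc_units <- function() {
  list(dna_unit(30L, "AAA", id = "SeqA"),
       dna_unit(62L, "AAA", id = "SeqB"),
       dna_unit(93L, "AAA", id = "SeqC"),
       dna_unit(124L, "AAA", id = "SeqD"))
}

#' Split a gene into even fragments for oligo synthesis
#'
#' Oligo synthesis caps sequence length, so the gene is split into the
#' smallest number n of fragments such that `ceil(L / n) + 2 * overlap_len
#' <= max_oligo_len`. Core lengths differ by at most 1 bp, with remainder
#' bases given to the earliest fragments. Adjacent fragments share
#' `overlap_len` bases of flanking sequence (copies of the neighboring
#' core's terminus) for reassembly by overlap-extension PCR; terminal
#' fragments carry one overlap only.
#'
#' @param gene a [gene_sequence()].
#' @param max_oligo_len maximum synthesizable length in bp (default 300).
#' @param overlap_len SOEing overlap length in bp (default 20).
#' @return list of `fragment` objects with fields `index`, `core_start`,
#'   `core_end`, `left_overlap`, `right_overlap`, `sequence`.
#' @export
fragment_gene <- function(gene, max_oligo_len = 300L, overlap_len = 20L) {
  stopifnot(inherits(gene, "gene_sequence"))
  max_oligo_len <- as.integer(max_oligo_len)
  overlap_len <- as.integer(overlap_len)
  if (overlap_len < 0) stop_("overlap_len must be >= 0")
  if (max_oligo_len < 2L * overlap_len + 30L) {
    stop_("max_oligo_len must be at least 2*overlap_len + 30")
  }
  L <- gene$length
  if (L < 30L) stop_("gene too short to fragment")
  n <- 1L
  while (ceiling(L / n) + 2L * overlap_len > max_oligo_len) n <- n + 1L
  base_len <- L %/% n
  rem <- L %% n
  core_len <- rep(base_len, n) + c(rep(1L, rem), rep(0L, n - rem))
  core_end <- cumsum(core_len)
  core_start <- core_end - core_len + 1L
  lapply(seq_len(n), function(i) {
    lo <- if (i == 1L) "" else substr(gene$bases, core_start[i] - overlap_len,
                                      core_start[i] - 1L)
    ro <- if (i == n) "" else substr(gene$bases, core_end[i] + 1L,
                                     core_end[i] + overlap_len)
    core <- substr(gene$bases, core_start[i], core_end[i])
    structure(list(index = i, core_start = core_start[i], core_end = core_end[i],
                   left_overlap = lo, right_overlap = ro,
                   sequence = paste0(lo, core, ro)),
              class = "fragment")
  })
}

#' @export
print.fragment <- function(x, ...) {
  cat(sprintf("<fragment %d> core %d-%d, %d bp with overlaps (%d|%d)\n",
              x$index, x$core_start, x$core_end, nchar(x$sequence),
              nchar(x$left_overlap), nchar(x$right_overlap)))
  invisible(x)
}

# locate gene coordinates within a fragment's sequence (including overlaps)
fragment_span <- function(fragment) {
  start <- fragment$core_start - nchar(fragment$left_overlap)
  end <- fragment$core_end + nchar(fragment$right_overlap)
  c(start = start, end = end)
}

# fragment whose core wholly contains gene positions [start, end];
# NULL when the span straddles a core boundary
fragment_for_span <- function(fragments, start, end) {
  for (f in fragments) {
    if (start >= f$core_start && end <= f$core_end) return(f)
  }
  NULL
}

#' Encode one mutation on an oligo
#'
#' Produces the oligo for a single mutation on its fragment. A protein-level
#' [mutation_spec()] has its wild-type codon (located via the gene's frame
#' offset) replaced by a codon for the target residue chosen by
#' [select_codon()]; a DNA-level [dna_unit()] is spliced in verbatim. The
#' mutated span must lie wholly inside one fragment core - overlap copies
#' always stay wild-type so SOEing junctions reassemble cleanly; a codon
#' straddling a core boundary is an error (refragment with different
#' parameters).
#'
#' @param gene a [gene_sequence()].
#' @param fragments result of [fragment_gene()].
#' @param m a [mutation_spec()] or [dna_unit()]; identity specs allowed
#'   when flagged via `mutation_spec(..., allow_identity = TRUE)`.
#' @param codon_table a [codon_usage_table()].
#' @param codon_policy `"max_usage"` or `"min_edit"`, see [select_codon()].
#' @param replicate_count copies of this oligo ordered in the pool.
#' @return an `oligo` object with fields `id`, `fragment_index`, `mutation`,
#'   `sequence`, `replicate_count`, `identity`.
#' @export
encode_mutation <- function(gene, fragments, m,
                            codon_table = ecoli_codon_usage(),
                            codon_policy = "max_usage",
                            replicate_count = 1L) {
  stopifnot(inherits(gene, "gene_sequence"), replicate_count >= 1L)
  if (inherits(m, "mutation_spec")) {
    codon_start <- gene$frame_offset + 3L * (m$site - 1L) + 1L
    codon_end <- codon_start + 2L
    if (codon_end > gene$length) {
      stop_(sprintf("codon of site %d extends beyond the gene", m$site))
    }
    wt_codon <- substr(gene$bases, codon_start, codon_end)
    wt_aa <- translate_codon(wt_codon)
    if (wt_aa != m$wt_aa) {
      stop_(sprintf("gene codon %s at site %d encodes %s, spec says %s",
                    wt_codon, m$site, wt_aa, m$wt_aa))
    }
    new_codon <- if (m$identity) wt_codon else {
      select_codon(m$mut_aa, wt_codon = wt_codon, table = codon_table,
                   policy = codon_policy)
    }
    start <- codon_start; end <- codon_end; replacement <- new_codon
    label <- format(m)
  } else if (inherits(m, "dna_unit")) {
    start <- m$start; end <- m$end; replacement <- m$replacement
    if (end > gene$length) stop_(sprintf("unit %s beyond gene end", format(m)))
    label <- m$id
  } else {
    stop_("m must be a mutation_spec or dna_unit")
  }
  frag <- fragment_for_span(fragments, start, end)
  if (is.null(frag)) {
    stop_(sprintf(
      "mutated span %d-%d straddles a fragment boundary; no fragment core contains it",
      start, end))
  }
  span <- fragment_span(frag)
  off <- start - span[["start"]] + 1L
  seq <- frag$sequence
  substr(seq, off, off + (end - start)) <- replacement
  identity <- identical(seq, frag$sequence)
  structure(list(id = label, fragment_index = frag$index,
                 mutation = m, sequence = seq,
                 replicate_count = as.integer(replicate_count),
                 identity = identity,
                 unit = list(start_frag = unname(off),
                             end_frag = unname(off + (end - start)),
                             start_gene = unname(start),
                             end_gene = unname(end),
                             replacement = replacement)),
            class = "oligo")
}

# ---- nearest-neighbor melting temperature ------------------------------------

# Unified nearest-neighbor parameters (SantaLucia 1998): dH in kcal/mol,
# dS in cal/(mol K), Watson-Crick stacks keyed by the top-strand dinucleotide.
.NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
            CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
            CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
            CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
.NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
            CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
            CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
            CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)

#' Nearest-neighbor melting temperature
#'
#' Duplex Tm from the unified nearest-neighbor thermodynamic parameters:
#' stacking enthalpies/entropies summed over dinucleotide steps plus
#' terminal initiation terms (G/C terminus: dH 0.1 kcal/mol, dS -2.8
#' cal/mol/K; A/T terminus: dH 2.3, dS 4.1), entropy salt-corrected by
#' `0.368 * (len - 1) * ln[Na+]`, and `Tm = 1000 * dH / (dS + R *
#' ln(CT / 4)) - 273.15` for non-self-complementary duplexes (CT the total
#' strand concentration).
#'
#' @param seq primer sequence, ACGT only, length >= 8.
#' @param primer_conc total strand concentration in molar (default 0.25e-6).
#' @param na_conc monovalent cation concentration in molar (default 0.05).
#' @return Tm in degrees Celsius.
#' @export
tm_nearest_neighbor <- function(seq, primer_conc = 0.25e-6, na_conc = 0.05) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < 8L) stop_("primer must be at least 8 nt for the duplex model")
  chars <- strsplit(seq, "")[[1]]
  if (!all(chars %in% DNA_BASES)) stop_("ambiguous bases not supported")
  steps <- paste0(chars[-n], chars[-1])
  dH <- sum(.NN_DH[steps])
  dS <- sum(.NN_DS[steps])
  for (term in chars[c(1L, n)]) {
    if (term %in% c("G", "C")) { dH <- dH + 0.1; dS <- dS - 2.8 }
    else                       { dH <- dH + 2.3; dS <- dS + 4.1 }
  }
  dS <- dS + 0.368 * (n - 1L) * log(na_conc)
  R <- 1.987  # cal/(mol K)
  1000 * dH / (dS + R * log(primer_conc / 4)) - 273.15
}

#' Design amplification primers for a fragment
#'
#' The forward primer is a 5' prefix of the fragment and the reverse primer
#' the reverse complement of its 3' suffix; each length in `[len_min,
#' len_max]` is scored by [tm_nearest_neighbor()] and the length whose Tm is
#' closest to `tm_target` is chosen (ties towards shorter primers). When no
#' length reaches `tm_target +/- tm_tol`, the best-effort pair is returned
#' with a warning (or an error under `strict`).
#'
#' @param fragment a fragment from [fragment_gene()].
#' @param len_min,len_max primer length bounds (default 18-30).
#' @param tm_target target melting temperature in degrees Celsius
#'   (default 60).
#' @param tm_tol acceptable deviation from `tm_target` (default 3).
#' @param strict error instead of warn when the target is unreachable.
#' @param primer_conc,na_conc passed to [tm_nearest_neighbor()].
#' @return a `primer_pair` with fields `fragment_index`, `forward`,
#'   `reverse`, `tm_forward`, `tm_reverse`, `in_spec`.
#' @export
design_primers <- function(fragment, len_min = 18L, len_max = 30L,
                           tm_target = 60, tm_tol = 3, strict = FALSE,
                           primer_conc = 0.25e-6, na_conc = 0.05) {
  stopifnot(inherits(fragment, "fragment"))
  seq <- fragment$sequence
  if (nchar(seq) < 2L * len_min) stop_("fragment shorter than two minimal primers")
  pick <- function(candidate) {
    lens <- seq.int(len_min, min(len_max, nchar(seq)))
    tms <- vapply(candidate(lens), tm_nearest_neighbor, numeric(1),
                  primer_conc = primer_conc, na_conc = na_conc)
    best <- which.min(abs(tms - tm_target))  # first (shortest) wins ties
    list(seq = candidate(lens)[best], tm = tms[best])
  }
  fwd <- pick(function(l) substr(rep(seq, length(l)), 1L, l))
  rev <- pick(function(l) {
    vapply(l, function(k) revcomp(substr(seq, nchar(seq) - k + 1L, nchar(seq))),
           character(1))
  })
  in_spec <- abs(fwd$tm - tm_target) <= tm_tol && abs(rev$tm - tm_target) <= tm_tol
  if (!in_spec) {
    msg <- sprintf("fragment %d: no primer length reaches Tm %.1f +/- %.1f (best %.1f / %.1f)",
                   fragment$index, tm_target, tm_tol, fwd$tm, rev$tm)
    if (strict) stop_(msg) else warn_(msg)
  }
  structure(list(fragment_index = fragment$index,
                 forward = fwd$seq, reverse = rev$seq,
                 tm_forward = fwd$tm, tm_reverse = rev$tm,
                 in_spec = in_spec),
            class = "primer_pair")
}

#' Screen sub-pool primers for cross-binding
#'
#' Exact-match screen of each primer's 3' terminal 12-mer against every
#' other fragment's sequence (both strands). A hit means a sub-pool primer
#' could prime on the wrong fragment during sub-pool isolation. Full
#' thermodynamic cross-dimer prediction is deliberately out of scope; this
#' catches the hard failures.
#'
#' @param primers list of [design_primers()] results.
#' @param fragments list of fragments from [fragment_gene()].
#' @param k length of the 3' seed to screen (default 12).
#' @return data.frame of clashes (`primer_fragment`, `primer`,
#'   `hits_fragment`); zero rows when orthogonal.
#' @export
check_primer_orthogonality <- function(primers, fragments, k = 12L) {
  clashes <- list()
  for (pp in primers) {
    for (dir in c("forward", "reverse")) {
      p <- pp[[dir]]
      seed <- substr(p, nchar(p) - k + 1L, nchar(p))
      for (f in fragments) {
        if (f$index == pp$fragment_index) next
        if (grepl(seed, f$sequence, fixed = TRUE) ||
            grepl(seed, revcomp(f$sequence), fixed = TRUE)) {
          clashes[[length(clashes) + 1L]] <- data.frame(
            primer_fragment = pp$fragment_index, primer = dir,
            hits_fragment = f$index, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(clashes) == 0) {
    data.frame(primer_fragment = integer(0), primer = character(0),
               hits_fragment = integer(0))
  } else {
    do.call(rbind, clashes)
  }
}

#' Build an oligo pool from a variant list
#'
#' Fragments the gene, encodes each variant on one oligo (replicated
#' `replicate_count` times in the ordered pool), designs sub-pool
#' amplification primers per fragment, and assembles a manifest.
#'
#' @param gene a [gene_sequence()].
#' @param variants non-empty list of [mutation_spec()] / [dna_unit()]
#'   objects (or an [allowed_mutation_set()], which is enumerated).
#' @param replicate_count copies of each oligo ordered (default 1).
#' @param max_oligo_len,overlap_len see [fragment_gene()].
#' @param codon_table,codon_policy see [encode_mutation()].
#' @param include_wt also order the unmutated fragment oligos.
#' @param primer_params list of arguments forwarded to [design_primers()].
#' @return an `oligo_pool` with fields `gene_id`, `fragments`, `oligos`,
#'   `primers`, `manifest` (data.frame), `total_count`.
#' @export
build_pool <- function(gene, variants, replicate_count = 1L,
                       max_oligo_len = 300L, overlap_len = 20L,
                       codon_table = ecoli_codon_usage(),
                       codon_policy = "max_usage",
                       include_wt = FALSE,
                       primer_params = list()) {
  stopifnot(inherits(gene, "gene_sequence"))
  if (inherits(variants, "allowed_mutation_set")) {
    variants <- enumerate_variants(variants)
  }
  if (length(variants) == 0L && !include_wt) stop_("no variants to encode")
  keys <- vapply(variants, format, character(1))
  if (any(duplicated(keys))) {
    stop_(sprintf("duplicate variant spec(s): %s",
                  paste(unique(keys[duplicated(keys)]), collapse = ", ")))
  }
  fragments <- fragment_gene(gene, max_oligo_len, overlap_len)
  oligos <- lapply(variants, function(m) {
    encode_mutation(gene, fragments, m, codon_table = codon_table,
                    codon_policy = codon_policy,
                    replicate_count = replicate_count)
  })
  if (include_wt) {
    wt <- lapply(fragments, function(f) {
      structure(list(id = sprintf("wt_frag%d", f$index),
                     fragment_index = f$index, mutation = NULL,
                     sequence = f$sequence,
                     replicate_count = as.integer(replicate_count),
                     identity = TRUE),
                class = "oligo")
    })
    oligos <- c(oligos, wt)
  }
  over <- vapply(oligos, function(o) nchar(o$sequence), integer(1)) > max_oligo_len
  if (any(over)) {
    stop_(sprintf("oligo(s) over max length: %s",
                  paste(vapply(oligos[over], `[[`, character(1), "id"), collapse = ", ")))
  }
  primers <- lapply(fragments, function(f) {
    do.call(design_primers, c(list(fragment = f), primer_params))
  })
  clashes <- check_primer_orthogonality(primers, fragments)
  if (nrow(clashes) > 0) {
    warn_(sprintf("%d sub-pool primer(s) share an exact 3' 12-mer with another fragment",
                  nrow(clashes)))
  }
  manifest <- data.frame(
    oligo_id = vapply(oligos, `[[`, character(1), "id"),
    fragment = vapply(oligos, `[[`, integer(1), "fragment_index"),
    mutation = vapply(oligos, function(o) {
      if (is.null(o$mutation)) "wt" else format(o$mutation)
    }, character(1)),
    replicate_count = vapply(oligos, `[[`, integer(1), "replicate_count"),
    length = vapply(oligos, function(o) nchar(o$sequence), integer(1)),
    sequence = vapply(oligos, `[[`, character(1), "sequence"),
    stringsAsFactors = FALSE)
  structure(list(gene_id = gene$id, fragments = fragments, oligos = oligos,
                 primers = primers, manifest = manifest,
                 total_count = sum(manifest$replicate_count)),
            class = "oligo_pool")
}

#' @export
print.oligo_pool <- function(x, ...) {
  cat(sprintf("<oligo_pool> %s: %d distinct oligos on %d fragment(s), %d ordered\n",
              x$gene_id, nrow(x$manifest), length(x$fragments), x$total_count))
  invisible(x)
}

#' Write an oligo pool to disk
#'
#' Emits `<prefix>_oligos.fasta` (one record per distinct oligo),
#' `<prefix>_manifest.tsv` and `<prefix>_primers.tsv`.
#'
#' @param pool an [build_pool()] result.
#' @param prefix output path prefix.
#' @return character vector of the three written paths, invisibly.
#' @export
write_pool <- function(pool, prefix) {
  fa <- paste0(prefix, "_oligos.fasta")
  seqs <- stats::setNames(pool$manifest$sequence, pool$manifest$oligo_id)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), fa, width = 60L)
  mf <- paste0(prefix, "_manifest.tsv")
  utils::write.table(pool$manifest, mf, sep = "\t", quote = FALSE, row.names = FALSE)
  pr <- paste0(prefix, "_primers.tsv")
  pdf <- data.frame(
    fragment = vapply(pool$primers, `[[`, integer(1), "fragment_index"),
    fwd = vapply(pool$primers, `[[`, character(1), "forward"),
    fwd_tm = round(vapply(pool$primers, `[[`, numeric(1), "tm_forward"), 2),
    rev = vapply(pool$primers, `[[`, character(1), "reverse"),
    rev_tm = round(vapply(pool$primers, `[[`, numeric(1), "tm_reverse"), 2),
    stringsAsFactors = FALSE)
  utils::write.table(pdf, pr, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fa, mf, pr))
}
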