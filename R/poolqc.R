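# QC of sequenced pool members: classify reads against the design as
# wild-type / one designed mutation / multiple, plus the error-model
# simulators used to exercise the classifier and the filtering stack.

# designed units of a pool, per fragment: data.frame of fragment-local spans
design_units <- function(design) {
  rows <- lapply(design$oligos, function(o) {
    if (o$identity || is.null(o$unit)) return(NULL)
    data.frame(oligo_id = o$id, fragment = o$fragment_index,
               start = o$unit$start_frag, end = o$unit$end_frag,
               replacement = o$unit$replacement, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Classify one read against an oligo-pool design
#'
#' The read is globally aligned (match +1, mismatch -1, gap open -2, gap
#' extend -1, both ends anchored) against each wild-type fragment sequence
#' and assigned to the best-scoring fragment. Each designed mutation unit of
#' that fragment is called present only when every base of the unit matches
#' the designed replacement with no indel inside the unit. Any other
#' mismatch column, or contiguous gap run, counts as one extra difference
#' (so a partially present unit contributes its changed bases as extra
#' differences). Classes: `wildtype` (0 units, 0 extras), `one_mutation`
#' (exactly 1 unit, 0 extras), `multiple` (anything else that aligns), and
#' `unalignable` (short reads or alignment score below
#' `score_floor_frac * fragment length`).
#'
#' @param read character string (or `gene_sequence`).
#' @param design an [build_pool()] result.
#' @param min_read_len reads shorter than this are `unalignable`
#'   (default 30).
#' @param score_floor_frac alignment-score floor as a fraction of the
#'   fragment length (default 0.5).
#' @return a `classification_result`: `read_id`, `matched_variant`,
#'   `fragment`, `n_designed_units_found`, `n_extra_differences`, `class`.
#' @export
classify_read <- function(read, design, min_read_len = 30L,
                          score_floor_frac = 0.5) {
  read_id <- if (is.character(read)) names(read) %||% "read" else read$id
  seq <- if (is.character(read)) unname(toupper(read)) else read$bases
  res <- function(class, matched = NA_character_, frag = NA_integer_,
                  units = 0L, extras = 0L) {
    structure(list(read_id = read_id, matched_variant = matched,
                   fragment = frag, n_designed_units_found = units,
                   n_extra_differences = extras, class = class),
              class = "classification_result")
  }
  if (nchar(seq) < min_read_len) return(res("unalignable"))
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  align_one <- function(frag_seq) {
    # equal-length, high-identity reads: the ungapped alignment is optimal
    # under this scoring (a substitution column outscores any gapped detour)
    if (nchar(seq) == nchar(frag_seq)) {
      p <- strsplit(seq, "")[[1]]
      s <- strsplit(frag_seq, "")[[1]]
      sc <- sum(p == s) - sum(p != s)
      if (sc >= score_floor_frac * nchar(frag_seq)) {
        return(list(score = sc, pat = p, sub = s))
      }
    }
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(seq), Biostrings::DNAString(frag_seq),
      substitutionMatrix = submat, gapOpening = 2, gapExtension = 1,
      type = "global")
    list(score = Biostrings::score(aln),
         pat = strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]],
         sub = strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]])
  }
  alns <- lapply(design$fragments, function(f) align_one(f$sequence))
  scores <- vapply(alns, `[[`, numeric(1), "score")
  best <- which.max(scores)
  frag <- design$fragments[[best]]
  if (scores[best] < score_floor_frac * nchar(frag$sequence)) {
    return(res("unalignable"))
  }
  pat <- alns[[best]]$pat
  sub <- alns[[best]]$sub
  # fragment-local coordinate of each alignment column (NA in insertions)
  wt_pos <- cumsum(sub != "-")
  wt_pos[sub == "-"] <- NA_integer_
  read_at <- function(p) {  # read base aligned to fragment position p
    col <- match(p, wt_pos)
    if (is.na(col)) NA_character_ else pat[col]
  }
  units <- design_units(design)
  if (!is.null(units)) units <- units[units$fragment == frag$index, , drop = FALSE]
  found <- character(0)
  covered <- integer(0)  # fragment positions explained by matched units
  if (!is.null(units) && nrow(units) > 0) {
    for (i in seq_len(nrow(units))) {
      span <- units$start[i]:units$end[i]
      repl <- strsplit(units$replacement[i], "")[[1]]
      obs <- vapply(span, read_at, character(1))
      # insertions inside the unit also fail it
      cols <- match(span, wt_pos)
      no_insert <- all(diff(cols) == 1L)
      if (!anyNA(obs) && no_insert && all(obs == repl)) {
        found <- c(found, units$oligo_id[i])
        covered <- c(covered, span)
      }
    }
  }
  # extra differences outside matched units: mismatch columns count one
  # each, each contiguous gap run counts once
  is_diff <- (pat != sub) & pat != "-" & sub != "-"
  in_covered <- !is.na(wt_pos) & wt_pos %in% covered
  extras <- sum(is_diff & !in_covered)
  gap <- (pat == "-") | (sub == "-")
  gap_runs <- rle(gap)
  extras <- extras + sum(gap_runs$values)
  units_n <- length(found)
  class <- if (units_n == 1L && extras == 0L) "one_mutation"
  else if (units_n == 0L && extras == 0L) "wildtype"
  else "multiple"
  res(class,
      matched = if (units_n == 1L) found else NA_character_,
      frag = frag$index, units = units_n, extras = extras)
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification> %s: %s (units %d, extras %d)\n",
              x$read_id, x$class, x$n_designed_units_found,
              x$n_extra_differences))
  invisible(x)
}

#' Classify many reads
#'
#' @param reads named character vector, list of sequences, or a FASTA/FASTQ
#'   path (qualities ignored).
#' @param design an [build_pool()] result.
#' @param ... passed to [classify_read()].
#' @return data.frame with one row per read: `read_id`, `matched_variant`,
#'   `fragment`, `n_designed_units_found`, `n_extra_differences`, `class`.
#' @export
classify_pool <- function(reads, design, ...) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    set <- if (grepl("\\.f(ast)?q$", reads, ignore.case = TRUE)) {
      Biostrings::readDNAStringSet(reads, format = "fastq")
    } else {
      Biostrings::readDNAStringSet(reads)
    }
    reads <- stats::setNames(as.character(set), names(set))
  }
  if (is.list(reads)) {
    reads <- vapply(reads, function(r) if (is.character(r)) r else r$bases,
                    character(1))
  }
  if (is.null(names(reads))) names(reads) <- sprintf("read%d", seq_along(reads))
  rows <- lapply(seq_along(reads), function(i) {
    r <- classify_read(stats::setNames(reads[i], names(reads)[i]), design, ...)
    data.frame(read_id = r$read_id, matched_variant = r$matched_variant,
               fragment = r$fragment,
               n_designed_units_found = r$n_designed_units_found,
               n_extra_differences = r$n_extra_differences,
               class = r$class, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Summarize classifications into a QC report
#'
#' Counts and fractions per class. `unalignable` reads are reported
#' separately and excluded from the three-way fractions unless
#' `fold_in_unalignable = TRUE`.
#'
#' @param results data.frame from [classify_pool()] (or a list of
#'   `classification_result`).
#' @param fold_in_unalignable include unalignable reads in the denominator.
#' @return a `poolqc_report`: `counts`, `fractions` (sum to 1), `n_reads`,
#'   `n_unalignable`.
#' @export
qc_report <- function(results, fold_in_unalignable = FALSE) {
  if (is.list(results) && !is.data.frame(results)) {
    results <- data.frame(
      class = vapply(results, `[[`, character(1), "class"),
      stringsAsFactors = FALSE)
  }
  if (nrow(results) == 0L) stop_("no classification results")
  classes <- c("one_mutation", "wildtype", "multiple")
  n_unalign <- sum(results$class == "unalignable")
  counted <- if (fold_in_unalignable) results else {
    results[results$class != "unalignable", , drop = FALSE]
  }
  lv <- if (fold_in_unalignable) c(classes, "unalignable") else classes
  counts <- table(factor(counted$class, levels = lv))
  if (sum(counts) == 0L) stop_("all reads unalignable")
  structure(list(counts = as.integer(counts),
                 classes = lv,
                 fractions = as.numeric(counts) / sum(counts),
                 n_reads = nrow(results),
                 n_unalignable = n_unalign),
            class = "poolqc_report")
}

#' @export
print.poolqc_report <- function(x, ...) {
  cat(sprintf("<poolqc_report> %d reads (%d unalignable)\n",
              x$n_reads, x$n_unalignable))
  for (i in seq_along(x$classes)) {
    cat(sprintf("  %-12s %6d  %5.1f%%\n", x$classes[i], x$counts[i],
                100 * x$fractions[i]))
  }
  invisible(x)
}

#' Write a QC report to TSV
#'
#' @param report a [qc_report()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  df <- data.frame(class = report$classes, count = report$counts,
                   fraction = report$fractions, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Simulate reads from an oligo pool under a PCR-style error model
#'
#' Emulates the failure modes of pool amplification: truncated products
#' re-priming on other molecules either revert the designed mutation to
#' wild-type (probability `dropout_to_wt_rate`) or splice in a second
#' designed unit from another oligo of the same fragment (probability
#' `chimera_rate`, producing a multiple-point variant); residual polymerase
#' errors add substitutions at `sub_rate` per base. Oligos are drawn with
#' probability proportional to their replicate counts. The three outcomes
#' are mutually exclusive per read, so truth labels follow the
#' `(1 - d - c, d, c)` mixture.
#'
#' @param design an [build_pool()] result.
#' @param n_reads number of reads (>= 1).
#' @param sub_rate per-base substitution rate in `[0, 1]`.
#' @param chimera_rate probability of splicing in a second designed unit.
#' @param dropout_to_wt_rate probability of reverting to wild-type.
#' @param seed integer seed; identical seeds give identical read sets.
#' @return list with `reads` (named character vector) and `truth`
#'   (data.frame `read_id`, `source_oligo`, `label`).
#' @export
simulate_pool_reads <- function(design, n_reads, sub_rate = 0,
                                chimera_rate = 0, dropout_to_wt_rate = 0,
                                seed = 1L) {
  stopifnot(n_reads >= 1)
  rates <- c(sub_rate, chimera_rate, dropout_to_wt_rate)
  if (any(rates < 0 | rates > 1)) stop_("rates must be in [0, 1]")
  if (chimera_rate + dropout_to_wt_rate > 1) {
    stop_("chimera_rate + dropout_to_wt_rate must be <= 1")
  }
  if (length(design$oligos) == 0L) stop_("empty design")
  set.seed(seed)
  units <- design_units(design)
  frag_seq <- stats::setNames(
    vapply(design$fragments, `[[`, character(1), "sequence"),
    vapply(design$fragments, `[[`, integer(1), "index"))
  weights <- vapply(design$oligos, `[[`, integer(1), "replicate_count")
  picks <- sample.int(length(design$oligos), n_reads, replace = TRUE,
                      prob = weights)
  u <- stats::runif(n_reads)
  reads <- character(n_reads)
  labels <- character(n_reads)
  src <- character(n_reads)
  for (i in seq_len(n_reads)) {
    o <- design$oligos[[picks[i]]]
    wt <- frag_seq[[as.character(o$fragment_index)]]
    src[i] <- o$id
    if (o$identity) {
      reads[i] <- wt; labels[i] <- "wildtype"
    } else if (u[i] < dropout_to_wt_rate) {
      reads[i] <- wt; labels[i] <- "wildtype"
    } else if (u[i] < dropout_to_wt_rate + chimera_rate) {
      others <- if (is.null(units)) integer(0) else {
        which(units$fragment == o$fragment_index & units$oligo_id != o$id)
      }
      if (length(others) == 0L) {  # nothing to splice; read stays clean
        reads[i] <- o$sequence; labels[i] <- "one_mutation"
      } else {
        j <- others[sample.int(length(others), 1L)]
        s <- o$sequence
        substr(s, units$start[j], units$end[j]) <- units$replacement[j]
        reads[i] <- s; labels[i] <- "multiple"
      }
    } else {
      reads[i] <- o$sequence; labels[i] <- "one_mutation"
    }
    if (sub_rate > 0) {
      chars <- strsplit(reads[i], "")[[1]]
      hit <- which(stats::runif(length(chars)) < sub_rate)
      for (p in hit) {
        chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1L)
      }
      reads[i] <- paste(chars, collapse = "")
    }
  }
  ids <- sprintf("read%d", seq_len(n_reads))
  list(reads = stats::setNames(reads, ids),
       truth = data.frame(read_id = ids, source_oligo = src, label = labels,
                          stringsAsFactors = FALSE))
}

#' Simulate a ddG matrix with planted beneficial mutations
#'
#' Generates a synthetic single-substitution stability scan emulating the
#' empirical shape of such data: a destabilizing subpopulation (each
#' substitution destabilizing with probability `p_destab`, drawn from
#' `Normal(destab_mean, destab_sd)`) against a neutral background
#' (`Normal(0, neutral_sd)`). Beneficial "hits" are sampled uniformly from
#' the substitutions whose ddG falls inside `hit_ddg_range` - the band where
#' experimentally improved variants concentrate - with activities drawn
#' log-normally and independent of ddG.
#'
#' @param length protein length L (19L substitutions are scored).
#' @param p_destab probability a substitution is destabilizing
#'   (default 0.4; empirically 30-50%).
#' @param destab_mean,destab_sd destabilizing component, in REU
#'   (default 15, 3).
#' @param neutral_sd neutral component spread (default 2).
#' @param n_hits number of planted beneficial mutations (default 20).
#' @param hit_ddg_range ddG band hits are confined to
#'   (default c(-7.5, 4.7)).
#' @param seed integer seed.
#' @param wt_residues optional wild-type string (random when NULL).
#' @return list with `ddg` (a [ddg_matrix()]) and `hits` (a [hit_set()]
#'   with activities).
#' @export
simulate_ddg_matrix <- function(length, p_destab = 0.4, destab_mean = 15,
                                destab_sd = 3, neutral_sd = 2,
                                n_hits = 20L, hit_ddg_range = c(-7.5, 4.7),
                                seed = 1L, wt_residues = NULL) {
  stopifnot(length >= 1, p_destab >= 0, p_destab <= 1, n_hits >= 1)
  set.seed(seed)
  L <- as.integer(length)
  wt <- if (is.null(wt_residues)) {
    paste(sample(AA_ALPHABET, L, replace = TRUE), collapse = "")
  } else {
    stopifnot(nchar(wt_residues) == L)
    toupper(wt_residues)
  }
  wt_chars <- strsplit(wt, "")[[1]]
  vals <- matrix(0, L, 20L, dimnames = list(NULL, AA_ALPHABET))
  n_cells <- L * 19L
  destab <- stats::runif(n_cells) < p_destab
  draws <- ifelse(destab,
                  stats::rnorm(n_cells, destab_mean, destab_sd),
                  stats::rnorm(n_cells, 0, neutral_sd))
  k <- 0L
  for (i in seq_len(L)) {
    for (a in seq_len(20L)) {
      if (AA_ALPHABET[a] == wt_chars[i]) next
      k <- k + 1L
      vals[i, a] <- draws[k]
    }
  }
  ddg <- ddg_matrix(vals, wt, protein_id = "synthetic", units = "REU",
                    source = "simulated")
  subs <- ddg_substitutions(ddg)
  in_band <- which(subs$ddg >= hit_ddg_range[1] & subs$ddg <= hit_ddg_range[2])
  if (length(in_band) == 0L) stop_("no substitutions inside hit_ddg_range")
  if (length(in_band) < n_hits) {
    stop_(sprintf("only %d substitutions inside hit_ddg_range, need %d",
                  length(in_band), n_hits))
  }
  pick <- sample(in_band, n_hits)
  hits <- lapply(pick, function(i) {
    mutation_spec(subs$site[i], subs$wt[i], subs$mut[i])
  })
  activity <- stats::rlnorm(n_hits, meanlog = 0.5, sdlog = 0.5)
  list(ddg = ddg, hits = hit_set(hits, label = "synthetic", activity = activity))
}
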