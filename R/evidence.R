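# Evidence layers: stability (ddG) matrices, MSA conservation, flexibility.

#' Construct a ddG matrix
#'
#' An L x 20 grid of predicted folding free-energy changes upon single
#' substitution, one row per position, one column per target residue in
#' fixed alphabetical order. Lower values are more stabilizing; strongly
#' positive values flag destabilizing substitutions. Wild-type identity
#' cells must be 0 (tolerance 1e-6) or NA.
#'
#' @param values L x 20 numeric matrix, columns named by residue.
#' @param wt_residues length-L string of wild-type residues.
#' @param protein_id label.
#' @param units `"REU"` or `"kcal/mol"` - declared, never converted.
#' @param source free-text provenance (e.g. "rosetta_cartesian", "acdc-nn").
#' @return object of class `ddg_matrix`.
#' @export
ddg_matrix <- function(values, wt_residues, protein_id = "protein",
                       units = c("REU", "kcal/mol"), source = "unknown") {
  units <- match.arg(units)
  values <- as.matrix(values)
  L <- nchar(wt_residues)
  if (nrow(values) != L) {
    stop_(sprintf("matrix has %d rows but wild-type sequence has %d residues",
                  nrow(values), L))
  }
  if (is.null(colnames(values))) colnames(values) <- AA_ALPHABET
  missing <- setdiff(AA_ALPHABET, colnames(values))
  if (length(missing) > 0) {
    stop_(sprintf("missing residue column(s): %s", paste(missing, collapse = ", ")))
  }
  values <- values[, AA_ALPHABET, drop = FALSE]
  wt <- strsplit(toupper(wt_residues), "")[[1]]
  if (!all(wt %in% AA_ALPHABET)) stop_("wild-type sequence has non-canonical residues")
  id_cells <- values[cbind(seq_len(L), match(wt, AA_ALPHABET))]
  bad_id <- which(!is.na(id_cells) & abs(id_cells) > 1e-6)
  if (length(bad_id) > 0) {
    stop_(sprintf("identity cell at site %d is %g, expected 0 (or NA)",
                  bad_id[1], id_cells[bad_id[1]]))
  }
  off <- values; off[cbind(seq_len(L), match(wt, AA_ALPHABET))] <- 0
  if (any(!is.finite(off))) stop_("non-finite ddG value in substitution cell")
  rownames(values) <- NULL
  structure(list(protein_id = protein_id, length = L, values = values,
                 wt_residues = paste(wt, collapse = ""), units = units,
                 source = source),
            class = "ddg_matrix")
}

#' @export
print.ddg_matrix <- function(x, ...) {
  cat(sprintf("<ddg_matrix> %s: %d sites x 20 residues [%s, source: %s]\n",
              x$protein_id, x$length, x$units, x$source))
  invisible(x)
}

# long view of the 19L true substitutions, in canonical order
# (site ascending, residue alphabetical); identity cells excluded
ddg_substitutions <- function(ddg) {
  L <- ddg$length
  wt <- strsplit(ddg$wt_residues, "")[[1]]
  site <- rep(seq_len(L), each = 20L)
  mut <- rep(AA_ALPHABET, times = L)
  keep <- mut != wt[site]
  data.frame(site = site[keep], wt = wt[site][keep], mut = mut[keep],
             ddg = as.vector(t(ddg$values))[keep], stringsAsFactors = FALSE)
}

#' Load a ddG matrix from TSV
#'
#' Expects columns `site`, `wt`, then the 20 residue columns `A` ... `Y` in
#' alphabetical order. A "wide replicate" dialect with repeated residue
#' columns (e.g. `A`, `A.1`, `A.2` after R name mangling, or `A_1`, `A_2`)
#' is accepted: the per-mutation minimum over replicates is stored, matching
#' the convention of taking the lowest of several relaxation runs.
#'
#' @param path TSV file; `#` lines are comments.
#' @param units declared units, `"REU"` or `"kcal/mol"`.
#' @param wt_sequence optional protein sequence to validate the `wt` column
#'   against.
#' @param source provenance label (defaults to a `# source:` header line
#'   when present).
#' @return a [ddg_matrix()].
#' @export
load_ddg_matrix <- function(path, units = c("REU", "kcal/mol"),
                            wt_sequence = NULL, source = NULL) {
  units <- match.arg(units)
  if (!file.exists(path)) stop_(sprintf("file not found: %s", path))
  header <- readLines(path, n = 20L)
  src_line <- grep("^#\\s*source:", header, value = TRUE)
  if (is.null(source)) {
    source <- if (length(src_line) > 0) {
      trimws(sub("^#\\s*source:", "", src_line[1]))
    } else "unknown"
  }
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          check.names = TRUE)
  if (!all(c("site", "wt") %in% names(df))) {
    stop_("ddG TSV must have 'site' and 'wt' columns")
  }
  if (is.unsorted(df$site) || any(duplicated(df$site))) {
    stop_("sites must be unique and ascending")
  }
  if (!identical(df$site, seq_len(nrow(df)))) {
    stop_("sites must run 1..L without gaps")
  }
  res_cols <- setdiff(names(df), c("site", "wt"))
  # map each column to its residue letter: 'A', 'A.1', 'A_2' -> 'A'
  res_of <- sub("^([A-Za-z])[._]?[0-9]*$", "\\1", res_cols)
  res_of <- toupper(res_of)
  bad <- res_cols[!res_of %in% AA_ALPHABET]
  if (length(bad) > 0) {
    stop_(sprintf("unrecognized residue column(s): %s", paste(bad, collapse = ", ")))
  }
  missing <- setdiff(AA_ALPHABET, res_of)
  if (length(missing) > 0) {
    stop_(sprintf("missing residue column(s): %s", paste(missing, collapse = ", ")))
  }
  vals <- matrix(NA_real_, nrow(df), 20L, dimnames = list(NULL, AA_ALPHABET))
  for (aa in AA_ALPHABET) {
    cols <- res_cols[res_of == aa]
    block <- as.matrix(df[cols])
    if (!is.numeric(block)) stop_(sprintf("non-numeric cell in column(s) for %s", aa))
    vals[, aa] <- if (length(cols) == 1L) block[, 1] else do.call(pmin, df[cols])
  }
  wt_residues <- paste(toupper(df$wt), collapse = "")
  if (!is.null(wt_sequence)) {
    ref <- if (is.character(wt_sequence)) toupper(wt_sequence) else wt_sequence$residues
    if (!identical(wt_residues, ref)) {
      diffpos <- which(strsplit(wt_residues, "")[[1]] != strsplit(ref, "")[[1]])[1]
      stop_(sprintf("wt column disagrees with supplied sequence (first at site %s)",
                    diffpos %||% "length"))
    }
  }
  ddg_matrix(vals, wt_residues, units = units, source = source)
}

#' Write a ddG matrix to TSV
#'
#' Emits a `# source:` provenance header and full-precision values, so that
#' [load_ddg_matrix()] round-trips exactly.
#'
#' @param ddg a [ddg_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ddg_matrix <- function(ddg, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# source: %s", ddg$source), con)
  writeLines(sprintf("# units: %s", ddg$units), con)
  writeLines(paste(c("site", "wt", AA_ALPHABET), collapse = "\t"), con)
  wt <- strsplit(ddg$wt_residues, "")[[1]]
  for (i in seq_len(ddg$length)) {
    writeLines(paste(c(i, wt[i], sprintf("%.17g", ddg$values[i, ])),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Per-position conservation profile from an MSA
#'
#' Columns are anchored on the query row: alignment columns where the query
#' has a gap are dropped, so profile positions map 1:1 onto query residues.
#' At each position, residue fractions are computed over the rows that are
#' not gapped there (gaps appear in neither numerator nor denominator);
#' `depth` records that non-gap row count. The consensus residue is the
#' argmax of the fractions, ties broken alphabetically.
#'
#' @param path aligned FASTA (all rows equal length; gaps as `-` or `.`).
#' @param query_id id of the query row (prefix match on the FASTA header).
#' @return object of class `conservation_profile` with fields `length`,
#'   `freqs` (L x 20), `counts` (L x 20 integer), `depth`, `consensus`,
#'   `query` (ungapped query string).
#' @export
conservation_from_msa <- function(path, query_id) {
  if (!file.exists(path)) stop_(sprintf("file not found: %s", path))
  aln <- Biostrings::readBStringSet(path)
  if (length(aln) == 0L) stop_("empty alignment")
  widths <- Biostrings::width(aln)
  if (length(unique(widths)) != 1L) stop_("ragged alignment: rows differ in length")
  ids <- names(aln)
  qi <- which(ids == query_id)
  if (length(qi) == 0L) qi <- which(startsWith(ids, query_id))
  if (length(qi) == 0L) stop_(sprintf("query '%s' not found in alignment", query_id))
  qi <- qi[1]
  mat <- do.call(rbind, strsplit(toupper(as.character(aln)), ""))
  gap <- mat %in% c("-", ".")
  dim(gap) <- dim(mat)
  keep_cols <- which(!gap[qi, ])
  L <- length(keep_cols)
  if (L == 0L) stop_("query row is all gaps")
  counts <- matrix(0L, L, 20L, dimnames = list(NULL, AA_ALPHABET))
  depth <- integer(L)
  for (j in seq_len(L)) {
    col <- mat[, keep_cols[j]]
    col <- col[!col %in% c("-", ".")]
    col <- col[col %in% AA_ALPHABET]  # X and other ambiguity codes ignored
    depth[j] <- length(col)
    tab <- table(factor(col, levels = AA_ALPHABET))
    counts[j, ] <- as.integer(tab)
  }
  freqs <- counts / pmax(depth, 1L)
  consensus <- vapply(seq_len(L), function(j) {
    if (depth[j] == 0L) return("-")
    AA_ALPHABET[which.max(freqs[j, ])]  # which.max takes first: alphabetical tie-break
  }, character(1))
  query <- paste(mat[qi, keep_cols], collapse = "")
  structure(list(length = L, freqs = freqs, counts = counts, depth = depth,
                 consensus = paste(consensus, collapse = ""), query = query),
            class = "conservation_profile")
}

#' @export
print.conservation_profile <- function(x, ...) {
  cat(sprintf("<conservation_profile> %d positions, depth %d-%d\n",
              x$length, min(x$depth), max(x$depth)))
  invisible(x)
}

#' Residues never (or rarely) observed at each position
#'
#' For each position, the set of residues whose observed count in the
#' alignment is below `min_count`. These are exclusion candidates: residues
#' absent from closely related natural sequences have often been purged by
#' selection. `min_count = 0` flags nothing.
#'
#' @param profile a [conservation_from_msa()] result.
#' @param min_count minimum observation count for a residue to escape
#'   flagging (>= 0).
#' @return list of character vectors, one per position.
#' @export
never_observed <- function(profile, min_count = 1L) {
  stopifnot(inherits(profile, "conservation_profile"))
  if (min_count < 0) stop_("min_count must be >= 0")
  lapply(seq_len(profile$length), function(j) {
    AA_ALPHABET[profile$counts[j, ] < min_count]
  })
}

#' Load a per-position flexibility profile
#'
#' TSV with columns `site` and `value` (predicted B-factor-like flexibility,
#' unitless, higher = more flexible). Sites must cover 1..L exactly.
#'
#' @param path TSV file.
#' @param source provenance label (defaults to a `# source:` header line).
#' @return object of class `flexibility_profile` with fields `length`,
#'   `bfactor`, `source`.
#' @export
load_flexibility <- function(path, source = NULL) {
  if (!file.exists(path)) stop_(sprintf("file not found: %s", path))
  header <- readLines(path, n = 5L)
  src_line <- grep("^#\\s*source:", header, value = TRUE)
  if (is.null(source)) {
    source <- if (length(src_line) > 0) {
      trimws(sub("^#\\s*source:", "", src_line[1]))
    } else "unknown"
  }
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("site", "value") %in% names(df))) {
    stop_("flexibility TSV must have 'site' and 'value' columns")
  }
  L <- max(df$site)
  missing <- setdiff(seq_len(L), df$site)
  if (length(missing) > 0) {
    stop_(sprintf("missing site(s): %s", paste(missing, collapse = ", ")))
  }
  if (any(duplicated(df$site))) {
    stop_(sprintf("duplicate site(s): %s",
                  paste(unique(df$site[duplicated(df$site)]), collapse = ", ")))
  }
  vals <- df$value[order(df$site)]
  if (any(!is.finite(vals))) stop_("non-finite flexibility value")
  structure(list(length = L, bfactor = vals, source = source),
            class = "flexibility_profile")
}

#' Most flexible sites
#'
#' Ranks positions by predicted flexibility, descending; ties broken by
#' ascending site index.
#'
#' @param profile a [load_flexibility()] result.
#' @param k number of sites to return.
#' @return integer vector of the k most flexible site indices.
#' @export
top_flexible_sites <- function(profile, k) {
  stopifnot(inherits(profile, "flexibility_profile"), k >= 1, k <= profile$length)
  order(-profile$bfactor, seq_len(profile$length))[seq_len(k)]
}
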