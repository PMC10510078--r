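# Retrospective retention analysis: how many known beneficial mutations
# survive graded cuts of the substitution space.

#' Hit set of known beneficial mutations
#'
#' Unique beneficial single substitutions from an evolution campaign,
#' optionally with per-hit fold-improvement over wild-type.
#'
#' @param hits list of [mutation_spec()].
#' @param label dataset label.
#' @param activity optional positive numeric vector aligned 1:1 with hits.
#' @return object of class `hit_set`.
#' @export
hit_set <- function(hits, label = "hits", activity = NULL) {
  stopifnot(is.list(hits), length(hits) >= 1L)
  keys <- vapply(hits, format, character(1))
  if (any(duplicated(keys))) {
    stop_(sprintf("duplicate hit(s): %s", paste(unique(keys[duplicated(keys)]), collapse = ", ")))
  }
  if (!is.null(activity)) {
    stopifnot(length(activity) == length(hits))
    if (any(!is.finite(activity)) || any(activity <= 0)) {
      stop_("activities must be positive and finite")
    }
  }
  structure(list(label = label, hits = hits, activity = activity,
                 n_hits = length(hits)),
            class = "hit_set")
}

#' Read a hit list from TSV
#'
#' Columns `site`, `wt`, `mut` and optionally `activity`.
#'
#' @param path TSV file.
#' @param label dataset label (defaults to the file name).
#' @return a [hit_set()].
#' @export
read_hits <- function(path, label = NULL) {
  specs <- read_mutations(path)
  hit_set(specs, label = label %||% sub("\\.[^.]*$", "", basename(path)),
          activity = attr(specs, "activity"))
}

# validate hits against the matrix wild-type; return row indices into the
# canonical substitution table
hit_indices <- function(subs, hits) {
  vapply(hits$hits, function(h) {
    i <- which(subs$site == h$site & subs$mut == h$mut_aa)
    if (length(i) != 1L) {
      stop_(sprintf("hit %s not found in substitution space", format(h)))
    }
    if (subs$wt[i] != h$wt_aa) {
      stop_(sprintf("hit %s: wild-type mismatch (matrix has %s at site %d)",
                    format(h), subs$wt[i], h$site))
    }
    i
  }, integer(1))
}

#' Retention curve of a hit set under graded ddG cuts
#'
#' For each sequence-space fraction f in `fractions`, the most destabilizing
#' `1 - f` of the 19L substitutions is removed (via
#' [filter_by_ddg_fraction()]) and the percentage of hits still inside the
#' remaining space is reported, rounded to one decimal (half away from
#' zero). An analytic random baseline (f x 100) is included for comparison.
#'
#' @param ddg a [ddg_matrix()].
#' @param hits a [hit_set()] validated against the matrix wild-type.
#' @param fractions descending grid of fractions in (0, 1]; default 1.0
#'   down to 0.1 in 10% steps.
#' @return object of class `retention_report`: data.frame `table` with
#'   columns `fraction`, `retained_count`, `retained_pct`,
#'   `random_baseline`, plus `label`, `n_hits`.
#' @export
retention_curve <- function(ddg, hits, fractions = seq(1, 0.1, by = -0.1)) {
  stopifnot(inherits(ddg, "ddg_matrix"), inherits(hits, "hit_set"))
  fractions <- round(fractions, 10)
  if (any(fractions <= 0 | fractions > 1)) stop_("fractions must be in (0, 1]")
  subs <- ddg_substitutions(ddg)
  idx <- hit_indices(subs, hits)
  counts <- vapply(fractions, function(f) {
    s <- filter_by_ddg_fraction(ddg, f)
    sum(vapply(idx, function(i) {
      subs$mut[i] %in% s$allowed[[subs$site[i]]]
    }, logical(1)))
  }, integer(1))
  pct <- round_half_away(100 * counts / hits$n_hits, 1)
  structure(list(label = hits$label, n_hits = hits$n_hits,
                 table = data.frame(fraction = fractions,
                                    retained_count = counts,
                                    retained_pct = pct,
                                    random_baseline = round_half_away(100 * fractions, 1))),
            class = "retention_report")
}

#' @export
print.retention_report <- function(x, ...) {
  cat(sprintf("<retention_report> %s (%d hits)\n", x$label, x$n_hits))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Retention grid over several datasets, with average row
#'
#' Stacks retention rows of several datasets over a shared fraction grid and
#' appends an `average` row: the unweighted arithmetic mean of the dataset
#' rows per column, rounded to one decimal (half away from zero).
#'
#' Input rows may be [retention_curve()] reports or pre-computed numeric
#' rows (as from a published analysis); mixing is allowed.
#'
#' @param reports list of `retention_report` objects, or a numeric matrix
#'   with datasets as rows and fractions as columns.
#' @param fractions fraction grid (required when `reports` is a matrix).
#' @return object of class `retention_grid`: numeric matrix `grid`
#'   (datasets + `average` as rows, fractions as columns) and `fractions`.
#' @export
retention_grid <- function(reports, fractions = NULL) {
  if (is.matrix(reports)) {
    stopifnot(!is.null(fractions), ncol(reports) == length(fractions))
    rows <- reports
  } else {
    stopifnot(is.list(reports), length(reports) >= 1L)
    fr <- lapply(reports, function(r) r$table$fraction)
    if (length(unique(lapply(fr, round, 10))) != 1L) {
      stop_("reports use different fraction grids")
    }
    fractions <- fr[[1]]
    rows <- do.call(rbind, lapply(reports, function(r) r$table$retained_pct))
    rownames(rows) <- vapply(reports, function(r) r$label, character(1))
  }
  avg <- round_half_away(colMeans(rows), 1)
  grid <- rbind(rows, average = avg)
  colnames(grid) <- sprintf("%g", fractions)
  structure(list(grid = grid, fractions = fractions), class = "retention_grid")
}

#' @export
print.retention_grid <- function(x, ...) {
  cat("<retention_grid> sequence-space fractions as columns\n")
  print(x$grid)
  invisible(x)
}

#' Write a retention grid to TSV
#'
#' Fractions as columns, datasets as rows, final `average` row.
#'
#' @param grid a [retention_grid()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_retention_grid <- function(grid, path) {
  df <- data.frame(dataset = rownames(grid$grid), grid$grid,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Bundled retention rows of four published evolution campaigns
#'
#' Retention percentages of the beneficial single substitutions found in
#' four enzyme-engineering campaigns - the transaminase ATA-217 (26
#' mutations), the Kemp eliminase HG3.17 (17), the carbonic anhydrase DvCA
#' (36) and the squalene-hopene cyclase AciSHC (4) - as the most
#' destabilizing predicted substitutions are removed in 10% steps. These
#' rows summarize full-scale stability scans of the wild-type enzymes and
#' are bundled as reference data; the per-cell values are not recomputable
#' without those scans and the campaigns' hit lists.
#'
#' @return list with `rows` (4 x 10 numeric matrix, fractions 1.0..0.1 as
#'   columns), `fractions`, and `n_hits` (named integer vector).
#' @export
campaign_retention_rows <- function() {
  fractions <- seq(1, 0.1, by = -0.1)
  rows <- rbind(
    ATA217 = c(100, 100, 96.2, 92.3, 88.5, 73.1, 73.1, 61.5, 53.8, 42.3),
    HG3.17 = c(100, 100, 100, 100, 100, 82.4, 52.9, 52.9, 47.1, 41.2),
    DvCA   = c(100, 100, 100, 97.2, 91.7, 77.8, 61.1, 44.4, 38.9, 13.9),
    AciSHC = c(100, 75, 75, 75, 75, 75, 75, 50, 50, 50))
  colnames(rows) <- sprintf("%g", fractions)
  list(rows = rows, fractions = fractions,
       n_hits = c(ATA217 = 26L, HG3.17 = 17L, DvCA = 36L, AciSHC = 4L))
}

#' Expected retention under random sequence-space reduction
#'
#' If a fraction f of the substitution space is kept at random, each hit
#' survives independently with probability f, so expected retention is
#' f x 100. Also simulates the binomial sampling distribution for a
#' Monte-Carlo mean and normal-approximation confidence band.
#'
#' @param fractions fraction grid in (0, 1].
#' @param n_hits number of hits.
#' @param reps Monte-Carlo replicates (>= 1).
#' @param seed integer seed.
#' @param conf confidence level for the band.
#' @return data.frame with `fraction`, `expected` (analytic, percent),
#'   `simulated_mean`, `ci_lo`, `ci_hi`, `se`.
#' @export
random_baseline <- function(fractions = seq(1, 0.1, by = -0.1), n_hits,
                            reps = 1000L, seed = 1L, conf = 0.95) {
  stopifnot(n_hits >= 1, reps >= 1)
  if (any(fractions <= 0 | fractions > 1)) stop_("fractions must be in (0, 1]")
  rng <- local({ set.seed(seed); NULL })
  z <- stats::qnorm(1 - (1 - conf) / 2)
  out <- lapply(fractions, function(f) {
    retained <- stats::rbinom(reps, n_hits, f) / n_hits * 100
    m <- mean(retained)
    se <- stats::sd(retained) / sqrt(reps)
    data.frame(fraction = f, expected = 100 * f, simulated_mean = m,
               ci_lo = m - z * se, ci_hi = m + z * se, se = se)
  })
  do.call(rbind, out)
}

#' Correlation between hit activity and predicted ddG
#'
#' Pearson correlation between the fold-improvement of beneficial mutations
#' and their predicted ddG, with the observed hit ddG range. Within the
#' stability band where hits live, activity is typically uncorrelated with
#' ddG - stability filtering ranks what to exclude, not what to keep.
#'
#' @param ddg a [ddg_matrix()].
#' @param hits a [hit_set()] with activities (>= 3 hits).
#' @return list with `pearson_r` (NA with `defined = FALSE` when either
#'   vector has zero variance), `defined`, `ddg_range` (min/max hit ddG),
#'   `n`.
#' @export
hit_ddg_correlation <- function(ddg, hits) {
  stopifnot(inherits(ddg, "ddg_matrix"), inherits(hits, "hit_set"))
  if (is.null(hits$activity)) stop_("hit set has no activities")
  if (hits$n_hits < 3L) stop_("need at least 3 hits with activity")
  subs <- ddg_substitutions(ddg)
  idx <- hit_indices(subs, hits)
  x <- subs$ddg[idx]
  y <- hits$activity
  defined <- stats::sd(x) > 0 && stats::sd(y) > 0
  list(pearson_r = if (defined) stats::cor(x, y) else NA_real_,
       defined = defined,
       ddg_range = range(x),
       n = hits$n_hits)
}
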