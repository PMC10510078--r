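# Allowed-mutation sets: excluding predicted-deleterious substitutions.

#' Allowed-mutation set
#'
#' Per-site sets of permitted target residues after evidence filtering (the
#' wild-type residue is always implicitly allowed and never listed). `size`
#' counts allowed true substitutions across all sites. `provenance` records
#' the applied filters in order, for audit.
#'
#' @param allowed list of character vectors, one per site.
#' @param wt_residues length-L wild-type string.
#' @param protein_id label.
#' @param provenance character vector of applied-filter descriptions.
#' @return object of class `allowed_mutation_set`.
#' @export
allowed_mutation_set <- function(allowed, wt_residues, protein_id = "protein",
                                 provenance = character()) {
  wt <- strsplit(wt_residues, "")[[1]]
  stopifnot(length(allowed) == length(wt))
  allowed <- lapply(seq_along(allowed), function(i) {
    a <- sort(unique(allowed[[i]]))
    if (!all(a %in% AA_ALPHABET)) stop_(sprintf("non-canonical residue at site %d", i))
    setdiff(a, wt[i])  # wild-type is implicit, never listed
  })
  structure(list(protein_id = protein_id,
                 allowed = allowed,
                 wt_residues = paste(wt, collapse = ""),
                 provenance = provenance,
                 size = sum(lengths(allowed))),
            class = "allowed_mutation_set")
}

#' @export
print.allowed_mutation_set <- function(x, ...) {
  cat(sprintf("<allowed_mutation_set> %s: %d allowed substitutions over %d sites\n",
              x$protein_id, x$size, length(x$allowed)))
  for (p in x$provenance) cat("  -", p, "\n")
  invisible(x)
}

#' Keep the least destabilizing fraction of the substitution space
#'
#' Ranks all 19L true substitutions by predicted ddG and excludes the most
#' destabilizing `1 - keep_fraction` of them, so e.g. `keep_fraction = 0.9`
#' removes the highest-ddG 10% of the substitution space. The retained count
#' is `round(keep_fraction * 19L)` (half away from zero); ties at the cut
#' are broken by site ascending then residue alphabetical. Identity cells
#' never participate. Sites in `protected_sites` are exempt from exclusion
#' (all their substitutions stay allowed), for catalytic or otherwise
#' must-keep positions.
#'
#' @param ddg a [ddg_matrix()].
#' @param keep_fraction fraction of the substitution space to retain, in
#'   (0, 1].
#' @param protected_sites integer sites exempt from ddG exclusion.
#' @return an [allowed_mutation_set()].
#' @export
filter_by_ddg_fraction <- function(ddg, keep_fraction, protected_sites = integer()) {
  stopifnot(inherits(ddg, "ddg_matrix"))
  assert_scalar_number(keep_fraction, "keep_fraction")
  if (keep_fraction <= 0 || keep_fraction > 1) {
    stop_("keep_fraction must be in (0, 1]")
  }
  subs <- ddg_substitutions(ddg)
  n <- nrow(subs)
  if (n == 0L) stop_("empty ddG matrix")
  n_keep <- round_half_away(keep_fraction * n)
  # most destabilizing first; deterministic tie-break
  ord <- order(-subs$ddg, subs$site, subs$mut)
  n_excl <- n - n_keep
  excluded <- rep(FALSE, n)
  if (n_excl > 0) excluded[ord[seq_len(n_excl)]] <- TRUE
  if (length(protected_sites) > 0) {
    if (any(protected_sites < 1 | protected_sites > ddg$length)) {
      stop_("protected site out of range")
    }
    excluded[subs$site %in% protected_sites] <- FALSE
  }
  allowed <- split(subs$mut[!excluded],
                   factor(subs$site[!excluded], levels = seq_len(ddg$length)))
  allowed_mutation_set(
    allowed, ddg$wt_residues, ddg$protein_id,
    provenance = sprintf(
      "ddg_fraction: keep_fraction=%g (%d of %d substitutions)%s",
      keep_fraction, sum(!excluded), n,
      if (length(protected_sites) > 0) {
        sprintf(", protected_sites=[%s]", paste(protected_sites, collapse = ","))
      } else ""))
}

#' Keep substitutions at or below a ddG threshold
#'
#' Allows substitutions with predicted ddG <= `max_ddg` (in the matrix's
#' declared units). Strongly destabilizing substitutions are often
#' function-killing, so a hard cap is the simplest exclusion rule.
#'
#' @param ddg a [ddg_matrix()].
#' @param max_ddg threshold in the matrix's units; `Inf` allows everything.
#' @param protected_sites integer sites exempt from exclusion.
#' @return an [allowed_mutation_set()].
#' @export
filter_by_ddg_threshold <- function(ddg, max_ddg, protected_sites = integer()) {
  stopifnot(inherits(ddg, "ddg_matrix"), is.numeric(max_ddg), length(max_ddg) == 1L)
  subs <- ddg_substitutions(ddg)
  keep <- subs$ddg <= max_ddg
  if (length(protected_sites) > 0) {
    if (any(protected_sites < 1 | protected_sites > ddg$length)) {
      stop_("protected site out of range")
    }
    keep[subs$site %in% protected_sites] <- TRUE
  }
  allowed <- split(subs$mut[keep],
                   factor(subs$site[keep], levels = seq_len(ddg$length)))
  allowed_mutation_set(
    allowed, ddg$wt_residues, ddg$protein_id,
    provenance = sprintf("ddg_threshold: max_ddg=%g %s (%d of %d substitutions)",
                         max_ddg, ddg$units, sum(keep), nrow(subs)))
}

#' Restrict an allowed set by MSA conservation
#'
#' Removes, at each site, the residues flagged by [never_observed()]: target
#' residues observed fewer than `min_count` times among aligned homologs are
#' dropped from the allowed set. `min_count = 0` is a no-op.
#'
#' @param s an [allowed_mutation_set()].
#' @param profile a [conservation_from_msa()] result of matching length.
#' @param min_count minimum observation count (>= 0).
#' @return a restricted [allowed_mutation_set()].
#' @export
restrict_by_conservation <- function(s, profile, min_count = 1L) {
  stopifnot(inherits(s, "allowed_mutation_set"),
            inherits(profile, "conservation_profile"))
  if (profile$length != length(s$allowed)) {
    stop_(sprintf("profile has %d positions but set has %d sites",
                  profile$length, length(s$allowed)))
  }
  flagged <- never_observed(profile, min_count)
  allowed <- lapply(seq_along(s$allowed), function(i) {
    setdiff(s$allowed[[i]], flagged[[i]])
  })
  allowed_mutation_set(
    allowed, s$wt_residues, s$protein_id,
    provenance = c(s$provenance,
                   sprintf("conservation: min_count=%d", as.integer(min_count))))
}

#' Restrict an allowed set to listed sites
#'
#' Empties the allowed sets of all sites not listed - the hook for injecting
#' external knowledge (catalytic pocket, tunnels, hotspots) as a site list.
#'
#' @param s an [allowed_mutation_set()].
#' @param sites integer site indices to keep mutable.
#' @return a restricted [allowed_mutation_set()].
#' @export
restrict_to_sites <- function(s, sites) {
  stopifnot(inherits(s, "allowed_mutation_set"))
  sites <- as.integer(sites)
  if (any(sites < 1 | sites > length(s$allowed))) stop_("site out of range")
  allowed <- lapply(seq_along(s$allowed), function(i) {
    if (i %in% sites) s$allowed[[i]] else character(0)
  })
  allowed_mutation_set(
    allowed, s$wt_residues, s$protein_id,
    provenance = c(s$provenance,
                   sprintf("sites: restricted to %d site(s)", length(unique(sites)))))
}

#' Enumerate an allowed set as mutation specs
#'
#' Deterministic order: site ascending, target residue alphabetical.
#'
#' @param s an [allowed_mutation_set()].
#' @return list of [mutation_spec()] of length `s$size`.
#' @export
enumerate_variants <- function(s) {
  stopifnot(inherits(s, "allowed_mutation_set"))
  wt <- strsplit(s$wt_residues, "")[[1]]
  out <- vector("list", s$size)
  k <- 0L
  for (i in seq_along(s$allowed)) {
    for (aa in s$allowed[[i]]) {  # already sorted alphabetically
      k <- k + 1L
      out[[k]] <- mutation_spec(i, wt[i], aa)
    }
  }
  out
}

#' Write an allowed set to TSV
#'
#' One row per site: `site`, `wt`, `allowed` (concatenated residue letters,
#' `-` when empty), preceded by `#` provenance header lines.
#'
#' @param s an [allowed_mutation_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_allowed_set <- function(s, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# protein: %s", s$protein_id), con)
  for (p in s$provenance) writeLines(sprintf("# filter: %s", p), con)
  writeLines("site\twt\tallowed", con)
  wt <- strsplit(s$wt_residues, "")[[1]]
  for (i in seq_along(s$allowed)) {
    a <- if (length(s$allowed[[i]]) == 0) "-" else paste(s$allowed[[i]], collapse = "")
    writeLines(sprintf("%d\t%s\t%s", i, wt[i], a), con)
  }
  invisible(path)
}
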