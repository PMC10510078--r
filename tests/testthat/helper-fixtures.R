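# Fixture builders shared across test files. Everything is generated in
# code; nothing binary is stored.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# ddG matrix with all substitution cells at `fill`, identity cells 0
flat_ddg <- function(wt, fill = 0, units = "REU") {
  L <- nchar(wt)
  vals <- matrix(fill, L, 20, dimnames = list(NULL, AA20))
  wtc <- strsplit(wt, "")[[1]]
  vals[cbind(seq_len(L), match(wtc, AA20))] <- 0
  ddg_matrix(vals, wt, units = units, source = "fixture")
}

# set specific substitution cells: spots = data.frame(site, mut, ddg)
spot_ddg <- function(wt, spots, fill = 0) {
  m <- flat_ddg(wt, fill)
  vals <- m$values
  for (i in seq_len(nrow(spots))) {
    vals[spots$site[i], spots$mut[i]] <- spots$ddg[i]
  }
  ddg_matrix(vals, wt, units = "REU", source = "fixture")
}

# random ddG matrix over a random wild-type, reproducible
random_ddg <- function(L, seed, sd = 5) {
  set.seed(seed)
  wt <- paste(sample(AA20, L, replace = TRUE), collapse = "")
  wtc <- strsplit(wt, "")[[1]]
  vals <- matrix(round(rnorm(L * 20, sd = sd), 3), L, 20,
                 dimnames = list(NULL, AA20))
  vals[cbind(seq_len(L), match(wtc, AA20))] <- 0
  ddg_matrix(vals, wt, units = "REU", source = "fixture")
}

# write a ddG TSV by hand (optionally with replicate columns per residue)
write_ddg_tsv <- function(path, wt, value_rows, header_cols) {
  lines <- c("# source: fixture",
             paste(c("site", "wt", header_cols), collapse = "\t"))
  wtc <- strsplit(wt, "")[[1]]
  for (i in seq_along(wtc)) {
    lines <- c(lines, paste(c(i, wtc[i], value_rows[[i]]), collapse = "\t"))
  }
  writeLines(lines, path)
  path
}

write_msa <- function(path, rows) {
  writeLines(unlist(lapply(names(rows), function(id) {
    c(paste0(">", id), rows[[id]])
  })), path)
  path
}

# brute-force allowed set: rank the 19L substitutions by ddG (destabilizing
# first, ties site asc / residue asc), drop the top n - round(f * n)
brute_force_allowed <- function(ddg, keep_fraction) {
  wtc <- strsplit(ddg$wt_residues, "")[[1]]
  rows <- do.call(rbind, lapply(seq_len(ddg$length), function(i) {
    data.frame(site = i, mut = AA20[AA20 != wtc[i]],
               ddg = ddg$values[i, AA20 != wtc[i]],
               stringsAsFactors = FALSE)
  }))
  n <- nrow(rows)
  n_keep <- sign(keep_fraction * n) * floor(abs(keep_fraction * n) + 0.5)
  ord <- order(-rows$ddg, rows$site, rows$mut)
  kept <- rows[setdiff(seq_len(n), ord[seq_len(n - n_keep)]), ]
  kept[order(kept$site, kept$mut), ]
}

as_key <- function(s) {
  unlist(lapply(seq_along(s$allowed), function(i) {
    if (length(s$allowed[[i]]) == 0) character(0)
    else paste0(i, ":", s$allowed[[i]])
  }))
}
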