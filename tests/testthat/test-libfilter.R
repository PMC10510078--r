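# Allowed-set construction from ddG, conservation and site evidence.

test_that("keep_fraction = 1 allows all 19L substitutions", {
  m <- random_ddg(6, seed = 1)
  s <- filter_by_ddg_fraction(m, 1.0)
  expect_identical(s$size, 19L * 6L)
  wt <- strsplit(m$wt_residues, "")[[1]]
  for (i in 1:6) expect_false(wt[i] %in% s$allowed[[i]])
})

test_that("fraction filter excludes exactly the most destabilizing entries", {
  # 2-site toy: 38 substitutions, 4 planted at +20 REU, rest 0
  spots <- data.frame(site = c(1, 1, 2, 2), mut = c("C", "W", "D", "Y"),
                      ddg = 20)
  m <- spot_ddg("AG", spots)
  s <- filter_by_ddg_fraction(m, 0.9)
  expect_identical(s$size, 34L)  # round(0.9 * 38) = 34
  expect_false("C" %in% s$allowed[[1]])
  expect_false("W" %in% s$allowed[[1]])
  expect_false("D" %in% s$allowed[[2]])
  expect_false("Y" %in% s$allowed[[2]])
  # matches the brute-force sort of all 38 entries
  bf <- brute_force_allowed(m, 0.9)
  expect_identical(as_key(s), paste0(bf$site, ":", bf$mut))
})

test_that("a half/half matrix splits exactly at keep_fraction = 0.5", {
  # one site: 19 substitutions can't split in half; use 2 sites (38):
  # 19 at +12 REU, 19 at -1
  m <- random_ddg(2, seed = 7, sd = 0)  # all zeros
  vals <- m$values
  wt <- strsplit(m$wt_residues, "")[[1]]
  subs <- expand.grid(site = 1:2, mut = AA20, stringsAsFactors = FALSE)
  subs <- subs[subs$mut != wt[subs$site], ]
  subs <- subs[order(subs$site, subs$mut), ]
  vals[cbind(subs$site[1:19], match(subs$mut[1:19], AA20))] <- 12
  vals[cbind(subs$site[20:38], match(subs$mut[20:38], AA20))] <- -1
  m2 <- ddg_matrix(vals, m$wt_residues, units = "REU")
  s <- filter_by_ddg_fraction(m2, 0.5)
  expect_identical(s$size, 19L)
  kept_ddg <- unlist(lapply(seq_along(s$allowed), function(i) {
    m2$values[i, s$allowed[[i]]]
  }))
  expect_true(all(kept_ddg <= 0))
})

test_that("fraction filters nest and match brute force on random matrices", {
  for (seed in 1:5) {
    m <- random_ddg(sample(2:5, 1), seed = seed + 100)
    prev <- NULL
    for (f in seq(0.1, 1, by = 0.1)) {
      s <- filter_by_ddg_fraction(m, f)
      bf <- brute_force_allowed(m, f)
      expect_identical(as_key(s), paste0(bf$site, ":", bf$mut))
      if (!is.null(prev)) expect_true(all(prev %in% as_key(s)))
      prev <- as_key(s)
    }
  }
})

test_that("fraction filter agrees with the threshold filter at the empirical quantile", {
  for (seed in 1:4) {
    L <- sample(2:5, 1)
    m <- random_ddg(L, seed = seed + 200)
    subs_ddg <- sort(unlist(lapply(seq_len(L), function(i) {
      wt <- substr(m$wt_residues, i, i)
      m$values[i, setdiff(AA20, wt)]
    })))
    for (f in c(0.3, 0.5, 0.8)) {
      n_keep <- round_half_away(f * length(subs_ddg))
      cutoff <- subs_ddg[n_keep]  # ddG values are distinct a.s.
      s_frac <- filter_by_ddg_fraction(m, f)
      s_thr <- filter_by_ddg_threshold(m, cutoff)
      expect_identical(as_key(s_frac), as_key(s_thr))
    }
  }
})

test_that("threshold filter honors the cap and protected sites", {
  m <- flat_ddg("ACDEF", fill = 1)
  vals <- m$values
  vals[3, "W"] <- 21.5  # destabilizing outlier
  m <- ddg_matrix(vals, "ACDEF", units = "REU")
  s <- filter_by_ddg_threshold(m, 10)
  expect_false("W" %in% s$allowed[[3]])
  expect_identical(s$size, 19L * 5L - 1L)

  expect_identical(filter_by_ddg_threshold(m, Inf)$size, 19L * 5L)
  expect_identical(filter_by_ddg_threshold(m, -5)$size, 0L)

  # a protected site is exempt from exclusion
  sp <- filter_by_ddg_threshold(m, 10, protected_sites = 3)
  expect_true("W" %in% sp$allowed[[3]])
})

test_that("conservation restriction intersects with observed residues", {
  msa <- withr::local_tempfile(fileext = ".fasta")
  # 5-site protein; site 5 shows A(wt), S, V across rows; site 2 only wt
  write_msa(msa, list(q = "ACDEA", h1 = "ACDES", h2 = "ACDEV", h3 = "ACDES"))
  prof <- conservation_from_msa(msa, "q")
  m <- flat_ddg("ACDEA")
  s <- filter_by_ddg_fraction(m, 1.0)
  r <- restrict_by_conservation(s, prof, min_count = 1)
  expect_identical(r$allowed[[5]], c("S", "V"))
  expect_identical(r$allowed[[2]], character(0))  # MSA shows only wild-type
  expect_length(r$provenance, 2)

  # min_count = 0 is a no-op
  r0 <- restrict_by_conservation(s, prof, min_count = 0)
  expect_identical(as_key(r0), as_key(s))

  # toy from a hand-worked set intersection: allowed {S,T,V}, observed {A,S,V}
  s2 <- allowed_mutation_set(
    c(rep(list(character(0)), 4), list(c("S", "T", "V"))),
    "ACDEA", provenance = "manual")
  r2 <- restrict_by_conservation(s2, prof, min_count = 1)
  expect_identical(r2$allowed[[5]], c("S", "V"))
})

test_that("site restriction empties unlisted sites", {
  m <- flat_ddg(paste(rep("A", 10), collapse = ""))
  s <- filter_by_ddg_fraction(m, 1.0)
  expect_identical(as_key(restrict_to_sites(s, 1:10)), as_key(s))
  expect_identical(restrict_to_sites(s, integer(0))$size, 0L)
  expect_identical(restrict_to_sites(s, c(1, 2))$size, 38L)
  expect_error(restrict_to_sites(s, 11), "out of range")
})

test_that("conservation and site restrictions commute", {
  msa <- withr::local_tempfile(fileext = ".fasta")
  set.seed(9)
  rows <- lapply(1:6, function(i) paste(sample(AA20[1:5], 8, replace = TRUE),
                                        collapse = ""))
  names(rows) <- c("q", paste0("h", 1:5))
  write_msa(msa, rows)
  prof <- conservation_from_msa(msa, "q")
  m <- flat_ddg(rows$q)
  s <- filter_by_ddg_fraction(m, 1.0)
  ab <- restrict_to_sites(restrict_by_conservation(s, prof, 1), c(2, 5, 7))
  ba <- restrict_by_conservation(restrict_to_sites(s, c(2, 5, 7)), prof, 1)
  expect_identical(as_key(ab), as_key(ba))
})

test_that("enumeration is deterministic, complete and idempotent", {
  spots <- data.frame(site = c(1, 1, 2, 2), mut = c("C", "W", "D", "Y"),
                      ddg = 20)
  m <- spot_ddg("AG", spots)
  s <- filter_by_ddg_fraction(m, 0.9)
  v1 <- enumerate_variants(s)
  v2 <- enumerate_variants(s)
  expect_length(v1, 34)
  expect_identical(vapply(v1, format, character(1)),
                   vapply(v2, format, character(1)))
  # ordered by site then residue
  sites <- vapply(v1, `[[`, integer(1), "site")
  expect_true(!is.unsorted(sites))

  empty <- restrict_to_sites(s, integer(0))
  expect_length(enumerate_variants(empty), 0)
})

test_that("allowed sets serialize with provenance headers", {
  m <- random_ddg(4, seed = 5)
  s <- filter_by_ddg_fraction(m, 0.6)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_allowed_set(s, tsv)
  lines <- readLines(tsv)
  expect_true(any(grepl("^# filter: ddg_fraction", lines)))
  df <- read.delim(tsv, comment.char = "#")
  expect_identical(nrow(df), 4L)
  listed <- sum(nchar(gsub("-", "", df$allowed)))
  expect_identical(listed, s$size)
})

test_that("invalid filter parameters are rejected", {
  m <- random_ddg(3, seed = 2)
  expect_error(filter_by_ddg_fraction(m, 0), "in \\(0, 1\\]")
  expect_error(filter_by_ddg_fraction(m, 1.2), "in \\(0, 1\\]")
  expect_error(filter_by_ddg_fraction(m, 0.5, protected_sites = 99), "out of range")
})
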