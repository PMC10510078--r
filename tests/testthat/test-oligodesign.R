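# Gene fragmentation, mutation encoding, Tm and primer design.

test_that("fragmentation minimizes fragment count and keeps cores even", {
  g <- hg3_fragment()
  frags <- fragment_gene(g, max_oligo_len = 200, overlap_len = 20)
  expect_length(frags, 1)
  expect_identical(frags[[1]]$sequence, g$bases)
  expect_identical(frags[[1]]$left_overlap, "")
  expect_identical(frags[[1]]$right_overlap, "")

  set.seed(1)
  g600 <- gene_sequence(paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE),
                              collapse = ""))
  f3 <- fragment_gene(g600, max_oligo_len = 300, overlap_len = 20)
  expect_length(f3, 3)
  cores <- vapply(f3, function(f) f$core_end - f$core_start + 1L, integer(1))
  expect_identical(cores, c(200L, 200L, 200L))

  g100 <- gene_sequence(paste(rep("ACGT", 25), collapse = ""))
  f1 <- fragment_gene(g100, max_oligo_len = 300, overlap_len = 0)
  expect_length(f1, 1)
  expect_identical(f1[[1]]$sequence, g100$bases)
})

test_that("fragment cores reassemble the gene and overlaps match neighbors", {
  set.seed(8)
  for (L in c(123, 400, 731)) {
    g <- gene_sequence(paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                             collapse = ""))
    frags <- fragment_gene(g, max_oligo_len = 150, overlap_len = 15)
    cores <- vapply(frags, function(f) {
      substr(g$bases, f$core_start, f$core_end)
    }, character(1))
    expect_identical(paste(cores, collapse = ""), g$bases)
    core_lens <- nchar(cores)
    expect_lte(max(core_lens) - min(core_lens), 1L)
    expect_true(all(vapply(frags, function(f) nchar(f$sequence), integer(1)) <= 150))
    for (i in seq_along(frags)[-1]) {
      # left overlap of fragment i is the tail of core i-1
      prev_core <- cores[i - 1]
      expect_identical(frags[[i]]$left_overlap,
                       substr(prev_core, nchar(prev_core) - 14, nchar(prev_core)))
      expect_identical(frags[[i - 1]]$right_overlap, substr(cores[i], 1, 15))
    }
  }
  expect_error(fragment_gene(hg3_fragment(), max_oligo_len = 60, overlap_len = 20),
               "2\\*overlap_len")
})

test_that("DNA-level units encode verbatim on their fragment", {
  g <- hg3_fragment()
  frags <- fragment_gene(g, 200, 20)
  oligo <- encode_mutation(g, frags, hg3_qc_units()[[1]])
  expect_identical(substr(oligo$sequence, 30, 32), "AAA")
  expect_identical(hamming_distance(oligo$sequence, g$bases),
                   hamming_distance(substr(g$bases, 30, 32), "AAA"))
})

test_that("protein-level encoding picks the most frequent codon with min-edit fallback", {
  # gene with V at codon 2 encoded GTT
  g <- gene_sequence(paste0("ATGGTTAAA", paste(rep("GCA", 30), collapse = "")))
  frags <- fragment_gene(g, 300, 0)
  m <- mutation_spec(2, "V", "A")
  oligo <- encode_mutation(g, frags, m)  # default: max usage
  expect_identical(substr(oligo$sequence, 4, 6), "GCG")  # top E. coli Ala codon
  oligo2 <- encode_mutation(g, frags, m, codon_policy = "min_edit")
  expect_identical(substr(oligo2$sequence, 4, 6), "GCT")  # one edit from GTT
  # identity request with allow_identity reproduces the fragment
  id <- encode_mutation(g, frags, mutation_spec(2, "V", "V", allow_identity = TRUE))
  expect_identical(id$sequence, frags[[1]]$sequence)
  expect_true(id$identity)
  # wild-type residue is validated against the gene's codon
  expect_error(encode_mutation(g, frags, mutation_spec(2, "L", "A")), "encodes V")
})

test_that("encoded codons always translate to the requested residue", {
  # exhaustive over all 61 sense wild-type codons x all 19 target residues
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  usage <- ecoli_codon_usage()
  for (wt_codon in sense) {
    wt_aa <- unname(code[wt_codon])
    for (mut_aa in setdiff(AA20, wt_aa)) {
      for (policy in c("max_usage", "min_edit")) {
        cd <- select_codon(mut_aa, wt_codon = wt_codon, table = usage,
                           policy = policy)
        expect_identical(translate_codon(cd), mut_aa)
      }
    }
  }
})

test_that("codons straddling a fragment boundary are rejected", {
  set.seed(4)
  g <- gene_sequence(paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                           collapse = ""))
  frags <- fragment_gene(g, max_oligo_len = 130, overlap_len = 10)
  expect_length(frags, 2)
  boundary <- frags[[1]]$core_end  # core 1 is 100 bp; codon 34 spans 100-102
  expect_identical(boundary, 100L)
  straddle <- dna_unit(boundary, "AAA")
  expect_error(encode_mutation(g, frags, straddle), "straddles")
})

test_that("pools count oligos correctly and enforce uniqueness", {
  g <- hg3_fragment()
  pool <- build_pool(g, hg3_qc_units(), replicate_count = 50,
                     max_oligo_len = 200, overlap_len = 20)
  expect_identical(pool$total_count, 200L)
  expect_identical(nrow(pool$manifest), 4L)
  expect_identical(sum(pool$manifest$replicate_count), pool$total_count)
  expect_true(all(pool$manifest$length < 200))

  one <- build_pool(g, hg3_qc_units()[1], replicate_count = 1,
                    max_oligo_len = 200, overlap_len = 20)
  expect_identical(one$total_count, 1L)

  expect_error(build_pool(g, c(hg3_qc_units(), hg3_qc_units()[1]),
                          max_oligo_len = 200),
               "duplicate")
})

test_that("an allowed set expands into one oligo per substitution", {
  # 2-site toy with 4 exclusions leaves 34 allowed substitutions; encode
  # them on a gene whose first two codons carry the toy's residues
  spots <- data.frame(site = c(1, 1, 2, 2), mut = c("C", "W", "D", "Y"),
                      ddg = 20)
  m <- spot_ddg("AG", spots)
  s <- filter_by_ddg_fraction(m, 0.9)
  g <- gene_sequence(paste0("GCAGGT", paste(rep("ACC", 20), collapse = "")))
  pool <- build_pool(g, s, replicate_count = 2, max_oligo_len = 200,
                     overlap_len = 0)
  expect_identical(nrow(pool$manifest), 34L)
  expect_identical(pool$total_count, 68L)
})

test_that("nearest-neighbor Tm behaves physically and matches the oracle", {
  # GC pairs melt higher than AT at fixed length
  at <- "ATATATATATATATATATAT"
  gc_one <- "ATATATATATGTATATATAT"  # one A->G
  expect_gt(tm_nearest_neighbor(gc_one), tm_nearest_neighbor(at))

  # Tm of a duplex equals that of its reverse complement
  probe <- "ACGGTCAGTTGACCTAGGCT"
  expect_equal(tm_nearest_neighbor(probe), tm_nearest_neighbor(revcomp(probe)),
               tolerance = 1e-9)

  # independent oracle agreement on fixed and random sequences
  expect_lt(abs(tm_nearest_neighbor(probe) - oracle_tm(probe)), 0.5)
  set.seed(12)
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(12:30, 1), replace = TRUE),
               collapse = "")
    expect_lt(abs(tm_nearest_neighbor(s) - oracle_tm(s)), 0.5)
  }
  expect_error(tm_nearest_neighbor("ACGTACG"), "at least 8")
  expect_error(tm_nearest_neighbor("ACGTACGN"), "ambiguous")
})

test_that("primers anchor the fragment termini near the target Tm", {
  g <- hg3_fragment()
  frag <- fragment_gene(g, 200, 20)[[1]]
  pp <- design_primers(frag, tm_target = 60, tm_tol = 5)
  expect_identical(pp$forward, substr(frag$sequence, 1, nchar(pp$forward)))
  tail <- substr(frag$sequence, nchar(frag$sequence) - nchar(pp$reverse) + 1,
                 nchar(frag$sequence))
  expect_identical(revcomp(pp$reverse), tail)
  expect_true(nchar(pp$forward) >= 18 && nchar(pp$forward) <= 30)
  expect_lte(abs(pp$tm_forward - 60), 5)
  expect_lte(abs(pp$tm_reverse - 60), 5)

  # a GC-rich terminus reaches the target with a shorter primer
  gc <- gene_sequence(paste(rep(c("G", "C"), 50), collapse = ""))
  atg <- gene_sequence(paste(rep(c("A", "T"), 50), collapse = ""))
  p_gc <- design_primers(fragment_gene(gc, 200, 0)[[1]], tm_target = 60,
                         tm_tol = 30)
  p_at <- suppressWarnings(
    design_primers(fragment_gene(atg, 200, 0)[[1]], tm_target = 60, tm_tol = 30))
  expect_lte(nchar(p_gc$forward), nchar(p_at$forward))

  # unreachable targets warn (or error under strict)
  expect_warning(design_primers(fragment_gene(atg, 200, 0)[[1]],
                                tm_target = 80, tm_tol = 1), "no primer length")
  expect_error(design_primers(fragment_gene(atg, 200, 0)[[1]],
                              tm_target = 80, tm_tol = 1, strict = TRUE))
})

test_that("primer orthogonality screen flags repeated fragments", {
  set.seed(77)
  half <- paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE),
                collapse = "")
  distinct <- gene_sequence(paste(sample(c("A", "C", "G", "T"), 300,
                                         replace = TRUE), collapse = ""))
  frags <- fragment_gene(distinct, 170, 10)
  primers <- suppressWarnings(lapply(frags, design_primers, tm_tol = 30))
  expect_identical(nrow(check_primer_orthogonality(primers, frags)), 0L)

  # a tandem duplication makes fragment primers prime on both halves
  dup <- gene_sequence(paste0(half, half))
  dfrags <- fragment_gene(dup, 170, 10)
  dprimers <- suppressWarnings(lapply(dfrags, design_primers, tm_tol = 30))
  expect_gt(nrow(check_primer_orthogonality(dprimers, dfrags)), 0)
})

test_that("pool export writes FASTA, manifest and primer TSVs", {
  g <- hg3_fragment()
  pool <- build_pool(g, hg3_qc_units(), replicate_count = 50,
                     max_oligo_len = 200, overlap_len = 20)
  prefix <- file.path(withr::local_tempdir(), "pool")
  paths <- write_pool(pool, prefix)
  fa <- Biostrings::readDNAStringSet(paste0(prefix, "_oligos.fasta"))
  expect_length(fa, 4)
  expect_setequal(names(fa), c("SeqA", "SeqB", "SeqC", "SeqD"))
  mf <- read.delim(paste0(prefix, "_manifest.tsv"))
  expect_identical(sum(mf$replicate_count), 200L)
  pr <- read.delim(paste0(prefix, "_primers.tsv"))
  expect_identical(nrow(pr), 1L)
})
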