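test_that("nucleotide diversity follows its definition", {
  a <- dna_alignment(c(s1 = "ACGTACGT", s2 = "ACGTACGT", s3 = "ACGTACGT"))
  expect_equal(as.numeric(nucleotide_diversity(a)), 0)

  two <- dna_alignment(c(s1 = strrep("A", 425),
                         s2 = paste0(strrep("A", 424), "C")))
  expect_equal(as.numeric(nucleotide_diversity(two)), 1 / 425)

  expect_error(nucleotide_diversity(dna_alignment(c(x = "ACGT"))), "at least 2")
  expect_error(dna_alignment(c(a = "ACGT", b = "ACG")), "same length")
})

test_that("gap and N columns are removed under complete deletion", {
  a <- dna_alignment(c(s1 = "ACGTA", s2 = "ACGTC", s3 = "ANG-C"))
  th <- nucleotide_diversity(a)  # columns 2 and 4 dropped, 3 remain
  expect_equal(attr(th, "sites_used"), 3L)
  # remaining columns give AGA / AGC / AGC: pairwise diffs 1, 1, 0 of 3 sites
  expect_equal(as.numeric(th), mean(c(1, 1, 0) / 3))
  # pairwise deletion keeps per-pair usable sites (5, 3 and 3)
  thp <- nucleotide_diversity(a, deletion = "pairwise")
  expect_equal(as.numeric(thp), mean(c(1 / 5, 1 / 3, 0 / 3)))
})

test_that("diversity is invariant to order and combinatorial under duplication", {
  set.seed(3)
  seqs <- vapply(1:6, function(i)
    paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE), collapse = ""), "")
  names(seqs) <- paste0("s", 1:6)
  a <- dna_alignment(seqs)
  th <- as.numeric(nucleotide_diversity(a))
  shuffled <- dna_alignment(seqs[c(4, 2, 6, 1, 3, 5)])
  expect_equal(as.numeric(nucleotide_diversity(shuffled)), th)
  # duplicating every sequence: identical pairs contribute zeros, so
  # theta scales by exactly 2(n-1)/(2n-1)
  dup <- dna_alignment(c(seqs, stats::setNames(seqs, paste0("d", 1:6))))
  n <- 6
  expect_equal(as.numeric(nucleotide_diversity(dup)),
               th * 2 * (n - 1) / (2 * n - 1), tolerance = 1e-12)
})

test_that("effective size arithmetic inverts theta = 2 Ne mu", {
  expect_equal(effective_size_from_diversity(0.017, 2.13e-7), 39906.1,
               tolerance = 1e-4)
  expect_equal(display_ne(effective_size_from_diversity(0.017)), 40000)
  expect_equal(display_ne(effective_size_from_diversity(0.015)), 35000)
  expect_equal(effective_size_from_diversity(0, 1e-7), 0)
  # Ne halves exactly when mu doubles
  expect_equal(effective_size_from_diversity(0.01, 2 * 2.13e-7),
               effective_size_from_diversity(0.01, 2.13e-7) / 2)
  expect_error(effective_size_from_diversity(0.01, 0), "positive")
})

test_that("haplotype collapsing groups exact strings and flags novelty", {
  a <- dna_alignment(c(x1 = "AAAA", x2 = "AAAA", x3 = "AAAA"))
  tab <- collapse_haplotypes(a)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$count, 3)
  expect_true(tab$novel)
  expect_identical(attr(tab, "members")$H1, c("x1", "x2", "x3"))

  b <- dna_alignment(c(y1 = "AANA", y2 = "AANA", y3 = "AAAA"))
  expect_warning(tabb <- collapse_haplotypes(b), "literal")
  expect_equal(nrow(tabb), 2)  # N is a literal character
  expect_equal(sum(tabb$count), 3)

  ref <- c("AAAA")
  tabr <- suppressWarnings(collapse_haplotypes(b, reference = ref))
  expect_identical(tabr$novel, c(TRUE, FALSE))
})

test_that("novelty percentages reproduce the published arithmetic", {
  set.seed(9)
  haps <- vapply(1:40, function(i)
    paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE), collapse = ""), "")
  a <- dna_alignment(stats::setNames(haps, paste0("h", 1:40)))
  tab <- collapse_haplotypes(a, reference = haps[1:17])
  nf <- novel_fraction(tab)
  expect_equal(nf$n_haplotypes, 40)
  expect_equal(nf$n_novel, 23)
  expect_equal(nf$percent_novel, 57.5)
  expect_equal(percent(8, 13), 62)
})

test_that("alignments round-trip through FASTA with metadata", {
  a <- dna_alignment(c(m1 = "ACGTAC", a1 = "ACCTAC", m2 = "ACGTAA"),
                     epoch = c("modern", "ancient", "modern"),
                     region = c("mexico", "peru", "canada"))
  fa <- withr::local_tempfile(fileext = ".fasta")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_fasta_alignment(a, fa, meta = tsv)
  back <- read_fasta_alignment(fa, meta = tsv)
  expect_identical(back$seq, a$seq)
  expect_identical(back$meta, a$meta)
  # metadata-driven geographic exclusion
  south <- subset_alignment(back, exclude_region = "canada")
  expect_identical(south$meta$id, c("m1", "a1"))
  anc <- subset_alignment(back, epoch = "ancient")
  expect_identical(anc$meta$id, "a1")
})

test_that("the diversity pipeline recovers theta = 2 Ne mu on synthetic data", {
  ne <- 5000
  mu <- 2.13e-7
  reps <- 50
  cfg <- validate_config(constant_model(ne), sampling_scheme(50, 0, 0))
  th <- vapply(seq_len(reps), function(r) {
    tr <- simulate_genealogy(cfg, seed = 400, replicate = r - 1)
    aln <- drop_mutations(tr, mutation_model(mu, 425), seed = 500 + r)
    as.numeric(nucleotide_diversity(aln))
  }, numeric(1))
  se <- stats::sd(th) / sqrt(reps)
  expect_lt(abs(mean(th) - 2 * ne * mu), 3 * se)
})
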