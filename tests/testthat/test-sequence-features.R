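test_that("minimal and absent ORFs are handled", {
  orf <- find_longest_orf("ATGAAATAG")
  expect_equal(orf[c("start", "end", "strand", "codon_count")],
               list(start = 0L, end = 9L, strand = "+", codon_count = 3L))
  expect_null(find_longest_orf("CCCCCCCCC"))
  expect_null(find_longest_orf("ATGAAA"))   # start but no stop
  expect_error(find_longest_orf(""), "non-empty")
})

test_that("ORF finder matches the exhaustive six-frame oracle", {
  set.seed(42)
  for (i in 1:100) {
    s <- rand_seq(300)
    got <- find_longest_orf(s)
    exp <- oracle_longest_orf(s)
    if (is.null(exp)) {
      expect_null(got)
    } else {
      expect_equal(got[c("start", "end", "strand", "length_nt")], exp,
                   info = paste("seq", i))
    }
  }
})

test_that("reported ORFs satisfy their structural invariants", {
  set.seed(7)
  for (i in 1:60) {
    s <- rand_seq(sample(60:400, 1), alphabet = c("A", "C", "G", "T", "N"))
    orf <- find_longest_orf(s)
    if (is.null(orf)) next
    expect_identical(orf$end - orf$start, orf$length_nt)
    expect_gte(orf$length_nt, 6L)
    expect_identical(orf$length_nt %% 3L, 0L)
    os <- nmfinder:::orf_sequence(s, orf)
    codons <- substring(os, seq(1, nchar(os), 3), seq(3, nchar(os), 3))
    expect_identical(codons[1], "ATG")
    expect_true(codons[length(codons)] %in% c("TAA", "TAG", "TGA"))
    expect_false(any(codons[-length(codons)] %in% c("TAA", "TAG", "TGA")))
  }
})

test_that("reverse-complementing flips strand but preserves ORF length", {
  set.seed(11)
  for (i in 1:40) {
    s <- rand_seq(200)
    a <- find_longest_orf(s)
    b <- find_longest_orf(oracle_revcomp(s))
    if (is.null(a)) {
      expect_null(b)
    } else {
      expect_identical(a$length_nt, b$length_nt)
      # strands flip unless both strands tie at the maximal length, in
      # which case the tie-break reports '+' for both orientations
      if (a$strand == b$strand) expect_identical(a$strand, "+")
    }
  }
})

test_that("codon-position G+C matches direct counting", {
  gc <- gc_by_codon_position("ATGGGCTAA")
  expect_equal(c(gc$gc1, gc$gc2, gc$gc3), c(1 / 3, 1 / 3, 2 / 3))
  gc <- gc_by_codon_position("GGGCCC")
  expect_equal(c(gc$gc1, gc$gc2, gc$gc3), c(1, 1, 1))
  expect_error(gc_by_codon_position("ATGA"), "multiple of 3")

  set.seed(5)
  for (i in 1:50) {
    s <- rand_seq(3 * sample(1:60, 1),
                  alphabet = c("A", "C", "G", "T", "N"))
    got <- gc_by_codon_position(s)
    exp <- oracle_gc_positions(s)
    expect_equal(c(got$gc1, got$gc2, got$gc3), exp, info = s)
  }
})

test_that("codon-position G+C is invariant to codon order", {
  set.seed(9)
  for (i in 1:20) {
    s <- rand_seq(3 * 40)
    codons <- substring(s, seq(1, 120, 3), seq(3, 120, 3))
    shuf <- paste(sample(codons), collapse = "")
    expect_equal(gc_by_codon_position(s)[c("gc1", "gc2", "gc3")],
                 gc_by_codon_position(shuf)[c("gc1", "gc2", "gc3")])
  }
})

test_that("pooled set G+C% equals the single-pass count oracle", {
  expect_equal(gc_percent_of_set("GGCC"), 100)
  expect_equal(gc_percent_of_set(c("AATT", "GGCC")), 50)
  expect_error(gc_percent_of_set(character(0)), "nonempty")
  set.seed(3)
  for (i in 1:10) {
    seqs <- replicate(sample(2:6, 1),
                      rand_seq(sample(10:80, 1),
                               alphabet = c("A", "C", "G", "T", "N")))
    expect_equal(gc_percent_of_set(seqs), oracle_gc_percent(seqs))
  }
})

test_that("the feature table excludes the stop codon from G+C by default", {
  tr <- c(t1 = "ATGGGGTAA") # internal codon GGG, stop TAA
  tab <- orf_feature_table(tr)
  expect_equal(tab$gc3, 1)          # stop excluded: only GGG counted
  expect_equal(tab$length_nt, 9L)   # but the stop still counts in length
  tab2 <- orf_feature_table(tr, count_stop_codon = TRUE)
  expect_equal(tab2$gc3, 2 / 3)
})

test_that("FASTA round trip preserves ids and uppercases sequences", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">tx1 some description", "atggga", "taa", ">tx2", "CCCC"), fa)
  tr <- read_transcripts(fa)
  expect_identical(names(tr), c("tx1", "tx2"))
  expect_identical(unname(tr["tx1"]), "ATGGGATAA")
})
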