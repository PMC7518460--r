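test_that("simulated transcripts honour GC targets and ORF structure", {
  set.seed(81)
  s <- simulate_transcript(0.5, 1.0, 10)
  codons <- substring(s, seq(1, 28, 3), seq(3, 30, 3))
  third <- substr(codons[2:9], 3, 3)
  expect_true(all(third %in% c("G", "C"))) # boundary target gc3 = 1

  set.seed(82)
  big <- simulate_transcript(0.5, 0.3, 10000)
  gc <- gc_by_codon_position(substr(big, 1, nchar(big) - 3))
  expect_lt(abs(gc$gc3 - 0.3), 0.02)

  set.seed(83)
  for (i in 1:20) {
    tr <- simulate_transcript(runif(1, 0.1, 0.9), runif(1, 0.1, 0.9),
                              sample(2:50, 1))
    orf <- find_longest_orf(tr)
    expect_identical(orf$start, 0L)
    expect_identical(orf$end, nchar(tr))
    expect_identical(orf$strand, "+")
  }
  expect_error(simulate_transcript(1.5, 0.5, 10), "\\[0, 1\\]")
  expect_error(simulate_transcript(0.5, 0.5, 1), "at least 2")
})

test_that("the dataset generator is deterministic and bookkeeps truth", {
  cfg <- nm_sim_config(seed = 7, n_nucleomorph = 30, n_nuclear = 70,
                       n_decoy_nongreen = 20,
                       orf_codon_count_range = c(50L, 120L))
  d1 <- file.path(tempdir(), "simA")
  d2 <- file.path(tempdir(), "simB")
  s1 <- simulate_dataset(cfg, d1)
  s2 <- simulate_dataset(cfg, d2)
  expect_equal(sum(s1$truth$population == "nucleomorph"), 30)
  expect_equal(sum(s1$truth$population == "nuclear"), 70)
  expect_equal(sum(s1$truth$population == "decoy"), 20)
  for (f in names(s1$paths)) {
    expect_identical(unname(tools::md5sum(s1$paths[[f]])),
                     unname(tools::md5sum(s2$paths[[f]])),
                     info = f)
  }
  # every emitted transcript passes the pipeline's own validation
  tr <- read_transcripts(s1$paths$fasta)
  expect_equal(length(tr), 120)
  orfs <- orf_feature_table(tr)
  expect_equal(nrow(orfs), 120)
})

test_that("realized population features converge to configured targets", {
  cfg <- nm_sim_config(seed = 13, n_nucleomorph = 2500, n_nuclear = 2500,
                       n_decoy_nongreen = 0, variant_duplication_rate = 0,
                       orf_codon_count_range = c(150L, 250L))
  d <- file.path(tempdir(), "simC")
  sim <- simulate_dataset(cfg, d)
  tr <- read_transcripts(sim$paths$fasta)
  gc3 <- vapply(tr, function(s)
    gc_by_codon_position(substr(s, 1, nchar(s) - 3))$gc3, numeric(1))
  low <- sim$truth$population == "nucleomorph"
  # stop-codon redraws bias realized GC3 upward by ~0.01 at low GC
  expect_lt(abs(mean(gc3[sim$truth$transcript_id[low]]) -
                  cfg$gc3_low_mean), 0.02)
  expect_lt(abs(mean(gc3[sim$truth$transcript_id[!low]]) -
                  cfg$gc3_high_mean), 0.02)
  ab <- compute_tpm(read_abundance(sim$paths$abundance))
  lt <- stats::setNames(ln_tpm(ab$tpm), ab$transcript_id)
  delta <- mean(lt[sim$truth$transcript_id[low]]) -
    mean(lt[sim$truth$transcript_id[!low]])
  expect_lt(abs(delta - (cfg$ln_tpm_low_pop_mean -
                           cfg$ln_tpm_high_pop_mean)), 0.15)
})

test_that("variant duplicates are truncated copies linked by strong hits", {
  bundle <- default_bundle()
  self <- read_blast_tab(bundle$paths$self_hits)
  strong <- self[self$query_id != self$subject_id & self$bitscore > 100, ]
  expect_gt(nrow(strong), 0)
  tr <- read_transcripts(bundle$paths$fasta)
  for (i in seq_len(nrow(strong))) {
    a <- tr[[strong$query_id[i]]]; b <- tr[[strong$subject_id[i]]]
    shorter <- if (nchar(a) < nchar(b)) a else b
    longer <- if (nchar(a) < nchar(b)) b else a
    expect_identical(substr(longer, 1, nchar(shorter) - 3),
                     substr(shorter, 1, nchar(shorter) - 3))
    # same generating population
    pop <- bundle$truth$population[match(c(strong$query_id[i],
                                           strong$subject_id[i]),
                                         bundle$truth$transcript_id)]
    expect_identical(pop[1], pop[2])
  }
})
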