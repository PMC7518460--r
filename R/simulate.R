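#' Configuration for the synthetic transcriptome generator
#'
#' Defaults describe two transcript populations that differ in codon-level
#' G+C and in expression: a low-G+C, highly expressed "nucleomorph"
#' population and a higher-G+C, less expressed "nuclear" population, plus
#' non-green decoys. GC targets are per-population normal distributions of
#' per-transcript target fractions; ln-TPM parameters are means/sds of
#' log relative expression (TPM renormalisation adds one dataset-wide
#' additive constant, identical for both populations).
#'
#' @param seed Integer seed; all emitted files are byte-identical for
#'   identical seeds.
#' @param n_nucleomorph,n_nuclear,n_decoy_nongreen Population sizes
#'   (transcripts, including any splice-variant duplicates within the
#'   green populations).
#' @param gc3_low_mean,gc3_low_sd,gc3_high_mean,gc3_high_sd GC3 target
#'   distributions for the low/high-G+C populations.
#' @param gc1_low_mean,gc1_low_sd,gc1_high_mean,gc1_high_sd Same for GC1.
#' @param ln_tpm_low_pop_mean,ln_tpm_low_pop_sd Log relative expression of
#'   the low-G+C population (given the higher mean).
#' @param ln_tpm_high_pop_mean,ln_tpm_high_pop_sd Same for the high-G+C
#'   population.
#' @param orf_codon_count_range Integer pair: uniform range of ORF codon
#'   counts (including start and stop codons).
#' @param variant_duplication_rate Fraction of each green population
#'   re-emitted as a truncated splice variant of another member.
#' @param plastid_decoy_rate Fraction of the nuclear population given an
#'   additional hit to a plastid-genome-encoded subject.
#' @return A validated list of class `nm_sim_config`.
#' @export
nm_sim_config <- function(seed = 7L,
                          n_nucleomorph = 150L,
                          n_nuclear = 350L,
                          n_decoy_nongreen = 100L,
                          gc3_low_mean = 0.25, gc3_low_sd = 0.05,
                          gc3_high_mean = 0.55, gc3_high_sd = 0.05,
                          gc1_low_mean = 0.40, gc1_low_sd = 0.05,
                          gc1_high_mean = 0.52, gc1_high_sd = 0.05,
                          ln_tpm_low_pop_mean = 7.5,
                          ln_tpm_low_pop_sd = 1.0,
                          ln_tpm_high_pop_mean = 5.5,
                          ln_tpm_high_pop_sd = 1.0,
                          orf_codon_count_range = c(100L, 400L),
                          variant_duplication_rate = 0.1,
                          plastid_decoy_rate = 0.05) {
  cfg <- as.list(environment())
  with(cfg, {
    stopifnot(n_nucleomorph >= 0, n_nuclear >= 0, n_decoy_nongreen >= 0,
              gc3_low_sd > 0, gc3_high_sd > 0, gc1_low_sd > 0,
              gc1_high_sd > 0, ln_tpm_low_pop_sd > 0,
              ln_tpm_high_pop_sd > 0,
              gc3_low_mean > 0, gc3_low_mean < 1,
              gc3_high_mean > 0, gc3_high_mean < 1,
              gc1_low_mean > 0, gc1_low_mean < 1,
              gc1_high_mean > 0, gc1_high_mean < 1,
              length(orf_codon_count_range) == 2L,
              orf_codon_count_range[1L] >= 2L,
              orf_codon_count_range[2L] >= orf_codon_count_range[1L],
              variant_duplication_rate >= 0, variant_duplication_rate <= 1,
              plastid_decoy_rate >= 0, plastid_decoy_rate <= 1)
  })
  structure(cfg, class = "nm_sim_config")
}

#' Simulate one transcript with target codon-position G+C
#'
#' Builds `ATG` + (codon_count - 2) sense codons + a stop codon. Bases at
#' codon positions 1 and 3 are drawn G/C with the target probabilities
#' (G vs C, and A vs T, equiprobable within each class); position 2 is
#' uniform over A,C,G,T. Any internal codon that would spell a stop is
#' redrawn. Uses the current RNG state.
#'
#' @param target_gc1,target_gc3 Target G+C probabilities in \[0, 1\].
#' @param codon_count Total codons including start and stop; >= 2.
#' @return A nucleotide string whose longest ORF spans the whole sequence.
#' @export
simulate_transcript <- function(target_gc1, target_gc3, codon_count) {
  if (!is.finite(target_gc1) || target_gc1 < 0 || target_gc1 > 1 ||
      !is.finite(target_gc3) || target_gc3 < 0 || target_gc3 > 1)
    stop("GC targets must lie in [0, 1]")
  if (codon_count < 2L) stop("'codon_count' must be at least 2")
  m <- codon_count - 2L
  draw <- function(n, p_gc) {
    gc <- stats::runif(n) < p_gc
    ifelse(gc, c("G", "C")[sample.int(2L, n, replace = TRUE)],
           c("A", "T")[sample.int(2L, n, replace = TRUE)])
  }
  codons <- character(0)
  if (m > 0L) {
    codons <- paste0(draw(m, target_gc1),
                     sample(c("A", "C", "G", "T"), m, replace = TRUE),
                     draw(m, target_gc3))
    for (round in 1:100) {
      bad <- which(codons %in% .STOP_CODONS)
      if (!length(bad)) break
      codons[bad] <- paste0(
        draw(length(bad), target_gc1),
        sample(c("A", "C", "G", "T"), length(bad), replace = TRUE),
        draw(length(bad), target_gc3))
    }
    if (any(codons %in% .STOP_CODONS))
      stop("config error: GC targets incompatible with stop-codon avoidance")
  }
  paste0("ATG", paste(codons, collapse = ""),
         sample(.STOP_CODONS, 1L))
}

.rtrunc_norm <- function(n, mean, sd, lo = 0.02, hi = 0.98) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

.fmt_ev <- function(x) formatC(x, format = "e", digits = 2)

#' Simulate a complete, truth-labelled input bundle
#'
#' Emits every file the pipeline consumes: a transcript FASTA, an RSEM-like
#' abundance TSV, a protein homology hit table with a subject-to-taxon map
#' and a plastid subject list, an all-vs-all nucleotide self-hit table for
#' variant binning, KO annotation maps, and a `truth.tsv` with the
#' generating population of every transcript. Green transcripts receive
#' Viridiplantae hits inside their top 5; decoys receive non-green top-5
#' hits (with a Viridiplantae hit at a worse rank, so the top-5 rule is
#' actually exercised); a fraction of nuclear transcripts additionally hit
#' plastid-genome-encoded subjects. Splice-variant duplicates are truncated
#' re-emissions of a same-population parent, linked by a bit-score-200
#' self-hit. All output is deterministic given `cfg$seed`.
#'
#' @param cfg An [nm_sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the emitted `paths` and the `truth`
#'   data.frame.
#' @export
simulate_dataset <- function(cfg, dir) {
  stopifnot(inherits(cfg, "nm_sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)

  pops <- data.frame(
    population = rep(c("nucleomorph", "nuclear", "decoy"),
                     c(cfg$n_nucleomorph, cfg$n_nuclear,
                       cfg$n_decoy_nongreen)),
    stringsAsFactors = FALSE)
  n_total <- nrow(pops)
  if (n_total == 0L) stop("empty simulation: all population sizes are 0")
  # neutral ids in shuffled order so id order carries no label signal
  pops$transcript_id <- sprintf("tr%05d", sample.int(n_total))
  pops <- pops[order(pops$transcript_id, method = "radix"), ,
               drop = FALSE]
  rownames(pops) <- NULL

  low <- pops$population == "nucleomorph"
  high <- !low # nuclear and decoy share the high-GC compositional regime
  n <- n_total
  pops$gc1_target <- NA_real_
  pops$gc3_target <- NA_real_
  pops$gc1_target[low] <- .rtrunc_norm(sum(low), cfg$gc1_low_mean,
                                       cfg$gc1_low_sd)
  pops$gc3_target[low] <- .rtrunc_norm(sum(low), cfg$gc3_low_mean,
                                       cfg$gc3_low_sd)
  pops$gc1_target[high] <- .rtrunc_norm(sum(high), cfg$gc1_high_mean,
                                        cfg$gc1_high_sd)
  pops$gc3_target[high] <- .rtrunc_norm(sum(high), cfg$gc3_high_mean,
                                        cfg$gc3_high_sd)
  pops$codon_count <- sample(cfg$orf_codon_count_range[1L]:
                               cfg$orf_codon_count_range[2L],
                             n, replace = TRUE)
  pops$ln_expr <- NA_real_
  pops$ln_expr[low] <- stats::rnorm(sum(low), cfg$ln_tpm_low_pop_mean,
                                    cfg$ln_tpm_low_pop_sd)
  pops$ln_expr[high] <- stats::rnorm(sum(high), cfg$ln_tpm_high_pop_mean,
                                     cfg$ln_tpm_high_pop_sd)

  # splice-variant duplicates within each green population
  pops$variant_of <- NA_character_
  for (p in c("nucleomorph", "nuclear")) {
    idx <- which(pops$population == p)
    n_dup <- round(cfg$variant_duplication_rate * length(idx))
    if (n_dup >= 1L && length(idx) >= 2L * n_dup) {
      dup <- sample(idx, n_dup)
      parents <- sample(setdiff(idx, dup), n_dup,
                        replace = length(setdiff(idx, dup)) < n_dup)
      pops$variant_of[dup] <- pops$transcript_id[parents]
    }
  }

  seqs <- character(n)
  names(seqs) <- pops$transcript_id
  primary <- which(is.na(pops$variant_of))
  for (i in primary)
    seqs[i] <- simulate_transcript(pops$gc1_target[i], pops$gc3_target[i],
                                   pops$codon_count[i])
  for (i in which(!is.na(pops$variant_of))) {
    parent_seq <- seqs[[pops$variant_of[i]]]
    cc <- nchar(parent_seq) %/% 3L
    dup_cc <- max(2L, floor(cc * stats::runif(1L, 0.4, 0.8)))
    seqs[i] <- paste0(substr(parent_seq, 1L, 3L * (dup_cc - 1L)),
                      sample(.STOP_CODONS, 1L))
    pops$codon_count[i] <- dup_cc
  }

  # abundance: counts proportional to weight * effective length
  len <- nchar(seqs)
  eff_len <- pmax(len - 100L, 1L)
  w <- exp(pops$ln_expr)
  counts <- w * eff_len
  counts <- round(counts * 2e6 / sum(counts), 2)
  rate <- counts / eff_len
  tpm <- 1e6 * rate / sum(rate)
  abundance <- data.frame(transcript_id = pops$transcript_id,
                          length = len, effective_length = eff_len,
                          expected_count = counts,
                          TPM = round(tpm, 2))

  # subject pools and taxonomy
  viridi <- sprintf("viridi_%03d", 1:80)
  nongreen <- c(sprintf("bact_%03d", 1:80), sprintf("opis_%03d", 1:60),
                sprintf("arch_%03d", 1:40))
  plastid <- sprintf("pmin_plastid_%02d", 1:20)
  taxon_map <- data.frame(
    subject_id = c(viridi, nongreen, plastid),
    taxon_group = c(rep("Viridiplantae", length(viridi)),
                    rep(c("Bacteria", "Opisthokonta", "Archaea"),
                        c(80L, 60L, 40L)),
                    rep("Viridiplantae", length(plastid))))

  mk_hits <- function(qid, subjects, exps, qlen) {
    k <- length(subjects)
    al <- pmax(30L, round(qlen / 3 * stats::runif(k, 0.3, 0.9)))
    data.frame(query_id = qid, subject_id = subjects,
               percent_identity = round(stats::runif(k, 35, 95), 1),
               align_length = al,
               mismatches = round(al * stats::runif(k, 0.05, 0.5)),
               gap_opens = sample(0:5, k, replace = TRUE),
               q_start = 1L, q_end = al * 3L,
               s_start = 1L, s_end = al,
               evalue = 10^(-exps), bitscore = round(40 + 2 * exps, 1))
  }

  plastid_flag <- pops$population == "nuclear" &
    stats::runif(n) < cfg$plastid_decoy_rate
  hit_blocks <- vector("list", n)
  for (i in seq_len(n)) {
    qid <- pops$transcript_id[i]
    qlen <- len[i]
    if (pops$population[i] %in% c("nucleomorph", "nuclear")) {
      k <- sample(6:10, 1L)
      exps <- sort(stats::runif(k, 12, 150), decreasing = TRUE)
      subjects <- c(sample(viridi, 1L), sample(nongreen, k - 1L))
      # occasionally a second viridiplant subject further down
      if (stats::runif(1L) < 0.3 && k >= 4L)
        subjects[sample(3:k, 1L)] <- sample(viridi, 1L)
      h <- mk_hits(qid, subjects, exps, qlen)
      if (plastid_flag[i]) {
        h <- rbind(h, mk_hits(qid, sample(plastid, 1L),
                              stats::runif(1L, 30, 60), qlen))
      }
      # one sub-threshold hit that the e-value cutoff must remove
      h <- rbind(h, mk_hits(qid, sample(nongreen, 1L),
                            stats::runif(1L, 2, 8), qlen))
    } else {
      exps <- sort(stats::runif(8L, 12, 120), decreasing = TRUE)
      subjects <- c(sample(nongreen, 7L), sample(viridi, 1L))
      h <- mk_hits(qid, subjects, exps, qlen) # viridi hit is rank 8
    }
    hit_blocks[[i]] <- h
  }
  hits <- do.call(rbind, hit_blocks)

  # all-vs-all nucleotide self-hits
  self_rows <- list(
    data.frame(query_id = pops$transcript_id,
               subject_id = pops$transcript_id,
               percent_identity = 100, align_length = len,
               mismatches = 0L, gap_opens = 0L, q_start = 1L, q_end = len,
               s_start = 1L, s_end = len, evalue = 0,
               bitscore = round(1.8 * len, 1)))
  dup_idx <- which(!is.na(pops$variant_of))
  if (length(dup_idx))
    self_rows[[2L]] <- data.frame(
      query_id = pops$transcript_id[dup_idx],
      subject_id = pops$variant_of[dup_idx],
      percent_identity = 100,
      align_length = len[dup_idx], mismatches = 0L, gap_opens = 0L,
      q_start = 1L, q_end = len[dup_idx], s_start = 1L,
      s_end = len[dup_idx], evalue = 1e-80, bitscore = 200)
  n_noise <- min(200L, n_total * (n_total - 1L) %/% 2L)
  if (n_noise > 0L) {
    a <- sample(pops$transcript_id, n_noise, replace = TRUE)
    b <- sample(pops$transcript_id, n_noise, replace = TRUE)
    keep <- a != b
    self_rows[[length(self_rows) + 1L]] <- data.frame(
      query_id = a[keep], subject_id = b[keep],
      percent_identity = round(stats::runif(sum(keep), 70, 90), 1),
      align_length = 40L, mismatches = 5L, gap_opens = 1L,
      q_start = 1L, q_end = 40L, s_start = 1L, s_end = 40L,
      evalue = 1e-4,
      bitscore = round(stats::runif(sum(keep), 20, 95), 1))
  }
  self_hits <- do.call(rbind, self_rows)

  # KO annotation, consistent with the generating truth
  green <- pops$population %in% c("nucleomorph", "nuclear")
  annotated <- green & stats::runif(n) < 0.9
  ko_ids <- sprintf("K%05d", seq_len(sum(annotated)))
  cat_probs <- function(pop) {
    if (pop == "nucleomorph")
      c(housekeeping = 0.60, splicing = 0.20, photosynthesis = 0.10,
        metabolic_other = 0.10)
    else
      c(housekeeping = 0.30, splicing = 0.05, photosynthesis = 0.25,
        metabolic_other = 0.40)
  }
  cats <- vapply(pops$population[annotated], function(p) {
    pr <- cat_probs(p)
    sample(names(pr), 1L, prob = pr)
  }, character(1L))
  ko_map <- data.frame(transcript_id = pops$transcript_id[annotated],
                       ko = ko_ids)
  ko_categories <- data.frame(ko = ko_ids, category = unname(cats))

  truth <- pops[, c("transcript_id", "population")]

  paths <- list(
    fasta = file.path(dir, "transcripts.fasta"),
    abundance = file.path(dir, "abundance.tsv"),
    hits = file.path(dir, "provenance_hits.tsv"),
    taxon_map = file.path(dir, "taxon_map.tsv"),
    plastid = file.path(dir, "plastid_subjects.txt"),
    self_hits = file.path(dir, "self_hits.tsv"),
    ko_map = file.path(dir, "ko_map.tsv"),
    ko_categories = file.path(dir, "ko_categories.tsv"),
    truth = file.path(dir, "truth.tsv"))

  fa <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(fa, paths$fasta, width = 70L)
  write_tsv <- function(df, path, col.names = TRUE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = col.names)
  write_tsv(abundance, paths$abundance)
  hits$evalue <- .fmt_ev(hits$evalue)
  write_tsv(hits, paths$hits, col.names = FALSE)
  write_tsv(taxon_map, paths$taxon_map)
  writeLines(plastid, paths$plastid)
  self_hits$evalue <- .fmt_ev(self_hits$evalue)
  write_tsv(self_hits, paths$self_hits, col.names = FALSE)
  write_tsv(ko_map, paths$ko_map)
  write_tsv(ko_categories, paths$ko_categories)
  write_tsv(truth, paths$truth)

  invisible(list(paths = paths, truth = truth))
}
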