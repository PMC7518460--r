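.stage_msg <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

.write_tsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1L))
  df[num] <- lapply(df[num], function(x) sprintf("%.10g", x))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  path
}

#' Run the full nucleomorph-candidate prediction pipeline
#'
#' Orchestrates every stage: longest-ORF features, TPM, green-algal
#' provenance filtering, plastid exclusion, splice-variant binning,
#' mixture classification and (optionally) the annotation summary. All
#' stage outputs are written as TSV/JSON under `out_dir` and a run
#' manifest records the configuration, input digests and the record-count
#' funnel; reruns with identical inputs and seed are byte-identical.
#'
#' @param fasta,abundance,hits,taxon_map,plastid,self_hits Input paths
#'   (FASTA; RSEM-like TSV; BLAST outfmt-6 protein hits; subject-to-taxon
#'   TSV; plastid subject-id list, one per line; outfmt-6 all-vs-all
#'   nucleotide self-hits).
#' @param ko_map,ko_categories Optional annotation map paths; the summary
#'   stage is skipped when either is `NULL`.
#' @param out_dir Output directory (created if needed).
#' @param evalue_cutoff,top_n,bitscore_min,threshold Filtering and calling
#'   parameters (defaults 1e-10, 5, 100, 0.95).
#' @param seed,n_init,tol,max_iter,reg EM parameters, see
#'   [fit_gmm_tied()].
#' @param rank_by Hit-ranking key, see [rank_hits()].
#' @param count_stop_codon Include the stop codon in G+C counts?
#' @param use_input_tpm Pass through an input TPM column instead of
#'   recomputing, see [compute_tpm()].
#' @return Invisibly, a list of class `nm_manifest`: `params`, `inputs`
#'   (md5 digests), `counts` (the filter funnel), `outputs` (paths) and
#'   the fitted `nm_fit` object under `$fit`.
#' @export
nm_run_pipeline <- function(fasta, abundance, hits, taxon_map, plastid,
                            self_hits, ko_map = NULL, ko_categories = NULL,
                            out_dir,
                            evalue_cutoff = 1e-10, top_n = 5L,
                            bitscore_min = 100, threshold = 0.95,
                            seed = 1L, n_init = 10L, tol = 1e-6,
                            max_iter = 500L, reg = 1e-6,
                            rank_by = "evalue",
                            count_stop_codon = FALSE,
                            use_input_tpm = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  in_paths <- c(fasta = fasta, abundance = abundance, hits = hits,
                taxon_map = taxon_map, plastid = plastid,
                self_hits = self_hits)
  if (!is.null(ko_map)) in_paths["ko_map"] <- ko_map
  if (!is.null(ko_categories)) in_paths["ko_categories"] <- ko_categories
  missing_in <- in_paths[!file.exists(in_paths)]
  if (length(missing_in))
    stop("missing input file(s): ", paste(missing_in, collapse = ", "))

  .stage_msg("features", "reading transcripts and locating ORFs")
  transcripts <- read_transcripts(fasta)
  orfs <- orf_feature_table(transcripts,
                            count_stop_codon = count_stop_codon)
  .write_tsv(orfs[, c("transcript_id", "start", "end", "strand",
                      "length_nt", "gc1", "gc2", "gc3", "gc_overall")],
             file.path(out_dir, "orfs.tsv"))

  .stage_msg("tpm", "computing TPM")
  ab <- compute_tpm(read_abundance(abundance),
                    use_input_tpm = use_input_tpm)
  ab$ln_tpm <- ln_tpm(ab$tpm)
  .write_tsv(ab[, c("transcript_id", "effective_length", "expected_count",
                    "tpm", "ln_tpm")],
             file.path(out_dir, "abundance.tsv"))
  unexpressed <- ab$transcript_id[!is.na(ab$tpm) & ab$tpm == 0]
  writeLines(unexpressed, file.path(out_dir, "unexpressed.tsv"))

  .stage_msg("filter-provenance", "selecting green-algal candidates")
  ranked <- rank_hits(read_blast_tab(hits),
                      evalue_cutoff = evalue_cutoff, rank_by = rank_by)
  taxa <- read_taxon_map(taxon_map)
  plastid_subjects <- readLines(plastid)
  green <- select_green_candidates(ranked, taxa, top_n = top_n)
  px <- exclude_plastid(green, ranked, plastid_subjects)
  writeLines(px$kept, file.path(out_dir, "green_candidates.txt"))
  writeLines(px$removed, file.path(out_dir, "excluded_plastid.txt"))

  .stage_msg("dedup", "binning splice variants")
  orf_len <- stats::setNames(orfs$length_nt, orfs$transcript_id)
  graph <- build_variant_graph(read_blast_tab(self_hits), px$kept,
                               bitscore_min = bitscore_min)
  bins <- bins_from_graph(graph, orf_len)
  .write_tsv(bins, file.path(out_dir, "bins.tsv"))
  reps <- bins$member_id[bins$is_representative]

  .stage_msg("cluster", "fitting the mixture classifier")
  feats <- data.frame(transcript_id = reps, stringsAsFactors = FALSE)
  feats$gc1 <- orfs$gc1[match(reps, orfs$transcript_id)]
  feats$gc3 <- orfs$gc3[match(reps, orfs$transcript_id)]
  feats$ln_tpm <- ab$ln_tpm[match(reps, ab$transcript_id)]
  feats <- feats[stats::complete.cases(feats), , drop = FALSE]
  if (nrow(feats) <= 2L)
    stop("stage cluster: fewer than 3 representatives with complete ",
         "features (", nrow(feats), ")")
  fit <- nm_classify(feats, threshold = threshold, seed = seed,
                     n_init = n_init, tol = tol, max_iter = max_iter,
                     reg = reg)
  .write_tsv(fit$calls, file.path(out_dir, "calls.tsv"))
  model_out <- list(
    weights = fit$model$weights, means = fit$model$means,
    covariance = fit$model$covariance,
    standardization = fit$standardization,
    low_component = fit$low_component, threshold = threshold,
    seed = seed, log_likelihood = fit$model$log_likelihood,
    converged = fit$model$converged)
  jsonlite::write_json(model_out, file.path(out_dir, "model.json"),
                       auto_unbox = TRUE, digits = NA)

  summary_obj <- NULL
  if (!is.null(ko_map) && !is.null(ko_categories)) {
    .stage_msg("summarize", "building the annotation summary")
    summary_obj <- summarize_candidates(fit$calls, read_ko_map(ko_map),
                                        read_ko_categories(ko_categories),
                                        transcripts)
    .write_tsv(as.data.frame(summary_obj),
               file.path(out_dir, "summary.tsv"))
  }

  counts <- c(
    n_input = length(transcripts),
    n_with_orf = nrow(orfs),
    n_green = length(green),
    n_after_plastid = length(px$kept),
    n_representatives = length(reps),
    n_clustered = nrow(feats),
    n_nm_candidates = sum(fit$calls$is_nm_candidate))
  manifest <- structure(list(
    package_version = as.character(utils::packageVersion("nmfinder")),
    params = list(evalue_cutoff = evalue_cutoff, top_n = top_n,
                  bitscore_min = bitscore_min, threshold = threshold,
                  seed = seed, n_init = n_init, tol = tol,
                  max_iter = max_iter, reg = reg, rank_by = rank_by,
                  count_stop_codon = count_stop_codon,
                  use_input_tpm = use_input_tpm),
    inputs = as.list(tools::md5sum(in_paths)),
    counts = as.list(counts),
    outputs = list(dir = out_dir),
    fit = fit, summary = summary_obj
  ), class = "nm_manifest")
  jsonlite::write_json(manifest[c("package_version", "params", "inputs",
                                  "counts")],
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .stage_msg("done", sprintf(
    "%d transcripts -> %d clustered -> %d Nm-candidates",
    counts[["n_input"]], counts[["n_clustered"]],
    counts[["n_nm_candidates"]]))
  invisible(manifest)
}

#' @export
print.nm_manifest <- function(x, ...) {
  cat("nmfinder run manifest\n")
  f <- x$counts
  cat(sprintf(
    "  funnel: %d input -> %d with ORF -> %d green -> %d post-plastid -> %d representatives -> %d clustered -> %d Nm-candidates\n",
    f$n_input, f$n_with_orf, f$n_green, f$n_after_plastid,
    f$n_representatives, f$n_clustered, f$n_nm_candidates))
  invisible(x)
}

#' Precision and recall of candidate calls against truth labels
#'
#' Evaluated over the clustered transcripts (bin representatives with
#' complete features): a true positive is a nucleomorph-labelled
#' representative called as candidate.
#'
#' @param calls Calls data.frame (`transcript_id`, `is_nm_candidate`).
#' @param truth Data.frame `transcript_id`, `population` with population
#'   `"nucleomorph"` marking true positives.
#' @return List with `precision`, `recall`, `tp`, `fp`, `fn`.
#' @export
nm_evaluate <- function(calls, truth) {
  pop <- truth$population[match(calls$transcript_id,
                                truth$transcript_id)]
  if (any(is.na(pop))) stop("calls contain ids absent from truth")
  is_nm <- pop == "nucleomorph"
  tp <- sum(calls$is_nm_candidate & is_nm)
  fp <- sum(calls$is_nm_candidate & !is_nm)
  fn <- sum(!calls$is_nm_candidate & is_nm)
  list(precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       tp = tp, fp = fp, fn = fn)
}
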