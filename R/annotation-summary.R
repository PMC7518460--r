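.NM_CATEGORIES <- c("housekeeping", "photosynthesis", "splicing",
                    "metabolic_other", "unknown")

#' Summarize candidate calls against KEGG-orthology annotation
#'
#' Produces the per-category gene counts and pooled candidate-set G+C%
#' reported for putative nucleomorph genomes: number of candidate protein
#' genes, how many carry a KO annotation, and how many fall into the
#' photosynthesis, splicing and housekeeping categories. Counts are over
#' nucleomorph candidates only.
#'
#' @param calls Calls data.frame (from [nm_classify()]'s `$calls` or
#'   `calls.tsv`) with `transcript_id` and `is_nm_candidate`.
#' @param ko_map Data.frame `transcript_id`, `ko` (transcripts without a KO
#'   are simply absent).
#' @param ko_categories Data.frame `ko`, `category` with categories among
#'   housekeeping, photosynthesis, splicing, metabolic_other, unknown;
#'   unmapped KOs count as unknown.
#' @param transcripts Named character vector of transcript sequences; every
#'   candidate id must be present (used for the pooled G+C%).
#' @return An object of class `nm_summary`: list with `n_candidates`,
#'   `n_annotated`, `n_photosynthesis`, `n_splicing`, `n_housekeeping`,
#'   `n_metabolic_other`, `n_unknown_annotated`, `housekeeping_fraction`
#'   (of annotated candidates) and `candidate_gc_percent`.
#' @export
summarize_candidates <- function(calls, ko_map, ko_categories,
                                 transcripts) {
  cand <- calls$transcript_id[calls$is_nm_candidate]
  if (!all(cand %in% names(transcripts)))
    stop("candidate id(s) missing from the transcript FASTA: ",
         paste(utils::head(setdiff(cand, names(transcripts))),
               collapse = ", "))
  ko <- ko_map$ko[match(cand, ko_map$transcript_id)]
  annotated <- !is.na(ko)
  cat_of <- ko_categories$category[match(ko[annotated], ko_categories$ko)]
  cat_of[is.na(cat_of) | !(cat_of %in% .NM_CATEGORIES)] <- "unknown"
  counts <- table(factor(cat_of, levels = .NM_CATEGORIES))
  n_annotated <- sum(annotated)
  out <- list(
    n_candidates = length(cand),
    n_annotated = n_annotated,
    n_photosynthesis = unname(counts["photosynthesis"]),
    n_splicing = unname(counts["splicing"]),
    n_housekeeping = unname(counts["housekeeping"]),
    n_metabolic_other = unname(counts["metabolic_other"]),
    n_unknown_annotated = unname(counts["unknown"]),
    housekeeping_fraction =
      if (n_annotated > 0) unname(counts["housekeeping"]) / n_annotated
      else NA_real_,
    candidate_gc_percent =
      if (length(cand) > 0) gc_percent_of_set(transcripts[cand])
      else NA_real_
  )
  class(out) <- "nm_summary"
  out
}

#' @export
print.nm_summary <- function(x, ...) {
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' @export
#' @method as.data.frame nm_summary
as.data.frame.nm_summary <- function(x, ...) {
  data.frame(
    row_label = c("# protein genes", "# function annotated protein genes",
                  "# photosynthesis-related protein genes",
                  "# splicing-related protein genes",
                  "# housekeeping protein genes",
                  "housekeeping fraction of annotated", "G + C%"),
    value = c(x$n_candidates, x$n_annotated, x$n_photosynthesis,
              x$n_splicing, x$n_housekeeping,
              round(x$housekeeping_fraction, 4),
              round(x$candidate_gc_percent, 2)),
    stringsAsFactors = FALSE
  )
}

#' Read a transcript-to-KO map
#' @param path TSV with columns transcript_id, ko (header optional).
#' @return Data.frame `transcript_id`, `ko`.
#' @export
read_ko_map <- function(path) {
  header <- grepl("transcript_id", readLines(path, n = 1L), fixed = TRUE)
  m <- utils::read.delim(path, header = header, stringsAsFactors = FALSE)
  m <- m[, 1:2]
  names(m) <- c("transcript_id", "ko")
  m
}

#' Read a KO-to-functional-category map
#' @param path TSV with columns ko, category (header optional).
#' @return Data.frame `ko`, `category`.
#' @export
read_ko_categories <- function(path) {
  header <- grepl("ko", readLines(path, n = 1L), fixed = TRUE)
  m <- utils::read.delim(path, header = header, stringsAsFactors = FALSE)
  m <- m[, 1:2]
  names(m) <- c("ko", "category")
  m
}
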