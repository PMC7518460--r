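.BLAST6_COLS <- c("query_id", "subject_id", "percent_identity",
                  "align_length", "mismatches", "gap_opens",
                  "q_start", "q_end", "s_start", "s_end",
                  "evalue", "bitscore")

#' Read a BLAST tabular (outfmt 6) hit table
#'
#' Twelve standard columns, no header.
#'
#' @param path Path to the tabular file.
#' @return A data.frame with named columns (`query_id`, `subject_id`,
#'   `percent_identity`, `align_length`, ..., `evalue`, `bitscore`).
#' @export
read_blast_tab <- function(path) {
  hits <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(hits) != 12L)
    stop("expected 12 tab-separated columns (BLAST outfmt 6), got ",
         ncol(hits))
  names(hits) <- .BLAST6_COLS
  hits
}

#' Read a subject-to-taxon-group map
#'
#' @param path TSV with columns `subject_id`, `taxon_group` (header
#'   optional; detected by the literal column names on the first line).
#' @return A data.frame with columns `subject_id`, `taxon_group`.
#' @export
read_taxon_map <- function(path) {
  first <- readLines(path, n = 1L)
  header <- grepl("subject_id", first, fixed = TRUE)
  tm <- utils::read.delim(path, header = header, stringsAsFactors = FALSE)
  tm <- tm[, 1:2]
  names(tm) <- c("subject_id", "taxon_group")
  tm
}

#' Filter, deduplicate and rank homology hits per query
#'
#' Hits with `evalue` above the cutoff are removed; the survivors are
#' collapsed to one best hit per (query, subject) pair and ranked within
#' each query. The default ranking key is ascending e-value, ties broken by
#' descending bit-score, then ascending subject id, which is deterministic
#' across BLAST versions; `rank_by = "bitscore"` swaps the first two keys.
#'
#' @param hits Data.frame as from [read_blast_tab()]; may contain many
#'   queries.
#' @param evalue_cutoff Retain hits with `evalue <= evalue_cutoff`
#'   (default `1e-10`).
#' @param rank_by `"evalue"` (default) or `"bitscore"`.
#' @return The filtered data.frame with an integer `rank` column (1 = best
#'   within its query), sorted by query then rank.
#' @export
rank_hits <- function(hits, evalue_cutoff = 1e-10,
                      rank_by = c("evalue", "bitscore")) {
  rank_by <- match.arg(rank_by)
  stopifnot(is.data.frame(hits))
  hits <- hits[hits$evalue <= evalue_cutoff, , drop = FALSE]
  if (nrow(hits) == 0L) {
    hits$rank <- integer(0)
    return(hits)
  }
  key <- if (rank_by == "evalue") {
    order(hits$query_id, hits$evalue, -hits$bitscore, hits$subject_id,
          method = "radix")
  } else {
    order(hits$query_id, -hits$bitscore, hits$evalue, hits$subject_id,
          method = "radix")
  }
  hits <- hits[key, , drop = FALSE]
  # best hit per (query, subject): first occurrence after sorting
  hits <- hits[!duplicated(hits[, c("query_id", "subject_id")]), ,
               drop = FALSE]
  hits$rank <- stats::ave(seq_len(nrow(hits)), hits$query_id,
                          FUN = seq_along)
  rownames(hits) <- NULL
  hits
}

#' Select queries with green-algal provenance
#'
#' A query is retained iff at least one of its top `top_n` ranked hits maps
#' to the Viridiplantae taxon group. Subjects missing from the map are
#' treated as `"unknown"`.
#'
#' @param ranked Ranked hit table from [rank_hits()].
#' @param taxon_map Data.frame with columns `subject_id`, `taxon_group`.
#' @param top_n How many top hits to inspect (default 5).
#' @return Sorted character vector of retained query ids.
#' @export
select_green_candidates <- function(ranked, taxon_map, top_n = 5L) {
  stopifnot(top_n >= 1L)
  grp <- taxon_map$taxon_group[match(ranked$subject_id,
                                     taxon_map$subject_id)]
  grp[is.na(grp)] <- "unknown"
  hit <- ranked$rank <= top_n & grp == "Viridiplantae"
  sort(unique(ranked$query_id[hit]), method = "radix")
}

#' Remove candidates with hits to plastid-genome-encoded proteins
#'
#' A candidate is removed if *any* of its surviving (post-cutoff) hits, at
#' any rank, is to a subject in the plastid set — such transcripts are
#' likely plastid-genome-encoded rather than nucleomorph-encoded.
#'
#' @param candidates Character vector of query ids.
#' @param ranked Ranked hit table from [rank_hits()].
#' @param plastid_subjects Character vector of plastid protein subject ids.
#' @return A list with sorted character vectors `kept` and `removed`.
#' @export
exclude_plastid <- function(candidates, ranked, plastid_subjects) {
  flagged <- unique(ranked$query_id[ranked$subject_id %in% plastid_subjects])
  removed <- intersect(candidates, flagged)
  list(kept = sort(setdiff(candidates, removed), method = "radix"),
       removed = sort(removed, method = "radix"))
}
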