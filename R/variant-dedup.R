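#' Build the splice-variant similarity graph
#'
#' Nodes are all candidate transcript ids; an undirected edge joins two
#' distinct transcripts whenever some nucleotide self-search hit between
#' them has bit-score strictly greater than `bitscore_min`. Self-hits are
#' ignored.
#'
#' @param self_hits Data.frame of all-vs-all nucleotide hits (as from
#'   [read_blast_tab()]) of the candidate set against itself.
#' @param ids Character vector of candidate transcript ids (the node set;
#'   hits involving other ids are dropped).
#' @param bitscore_min Edge threshold; the inequality is strict, so a hit
#'   at exactly this bit-score creates no edge. Default 100.
#' @return An undirected [igraph::graph] on `ids`.
#' @export
build_variant_graph <- function(self_hits, ids, bitscore_min = 100) {
  stopifnot(is.character(ids), !anyDuplicated(ids))
  e <- self_hits[self_hits$query_id != self_hits$subject_id &
                   self_hits$bitscore > bitscore_min &
                   self_hits$query_id %in% ids &
                   self_hits$subject_id %in% ids,
                 c("query_id", "subject_id"), drop = FALSE]
  # collapse duplicate/reciprocal pairs
  key <- ifelse(e$query_id < e$subject_id,
                paste(e$query_id, e$subject_id, sep = "\r"),
                paste(e$subject_id, e$query_id, sep = "\r"))
  e <- e[!duplicated(key), , drop = FALSE]
  igraph::graph_from_data_frame(e, directed = FALSE,
                                vertices = data.frame(name = ids))
}

#' Partition transcripts into splice-variant bins
#'
#' Bins are the connected components of the variant graph (transitive
#' merging: a-b and b-c put a, b, c in one bin even without an a-c hit).
#' The representative of each bin is the member with the longest ORF, ties
#' broken by lexicographically smallest id; transcripts without an ORF
#' count as length 0.
#'
#' @param graph Variant graph from [build_variant_graph()].
#' @param orf_lengths Named numeric vector mapping transcript id to ORF
#'   length in nt (missing ids default to 0).
#' @return Data.frame `bin_id`, `member_id`, `is_representative`; bins are
#'   numbered by their lexicographically smallest member so output is
#'   independent of input edge order.
#' @export
bins_from_graph <- function(graph, orf_lengths) {
  comp <- igraph::components(graph)
  ids <- igraph::V(graph)$name
  len <- orf_lengths[ids]
  len[is.na(len)] <- 0
  names(len) <- ids
  groups <- split(ids, comp$membership)
  # deterministic bin order: by smallest member id
  groups <- lapply(groups, sort, method = "radix")
  groups <- groups[order(vapply(groups, `[[`, character(1L), 1L),
                         method = "radix")]
  rows <- lapply(seq_along(groups), function(i) {
    m <- groups[[i]]
    lm <- len[m]
    rep_id <- m[order(-lm, m, method = "radix")][1L]
    data.frame(bin_id = i, member_id = m,
               is_representative = m == rep_id,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
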