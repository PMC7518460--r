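# Independent brute-force oracles. These deliberately share no code with
# the package internals: reverse complement goes through Biostrings, sums
# are plain loops, sorting is re-derived from the stated rules.

rand_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

oracle_revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Enumerate every (strand, frame, ATG, first downstream in-frame stop)
# and keep the maximum length; ties: '+' before '-', then smaller start.
oracle_longest_orf <- function(seq) {
  stops <- c("TAA", "TAG", "TGA")
  best <- NULL
  better <- function(cand, best) {
    if (is.null(best)) return(TRUE)
    if (cand$length_nt != best$length_nt)
      return(cand$length_nt > best$length_nt)
    if (cand$strand != best$strand) return(cand$strand == "+")
    cand$start < best$start
  }
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else oracle_revcomp(seq)
    n <- nchar(s)
    for (frame in 0:2) {
      i <- frame + 1L
      while (i + 2L <= n) {
        if (substr(s, i, i + 2L) == "ATG") {
          j <- i + 3L
          while (j + 2L <= n) {
            if (substr(s, j, j + 2L) %in% stops) {
              cand <- list(start = i - 1L, end = j + 2L,
                           strand = strand, length_nt = j + 3L - i)
              if (better(cand, best)) best <- cand
              break
            }
            j <- j + 3L
          }
        }
        i <- i + 3L
      }
    }
  }
  best
}

oracle_gc_positions <- function(orf_seq) {
  ch <- strsplit(orf_seq, "")[[1]]
  gc <- c(0, 0, 0); valid <- c(0, 0, 0)
  for (i in seq_along(ch)) {
    k <- ((i - 1L) %% 3L) + 1L
    if (ch[i] %in% c("A", "C", "G", "T")) valid[k] <- valid[k] + 1
    if (ch[i] %in% c("G", "C")) gc[k] <- gc[k] + 1
  }
  gc / valid
}

oracle_gc_percent <- function(seqs) {
  gc <- 0; tot <- 0
  for (s in seqs) for (ch in strsplit(s, "")[[1]]) {
    if (ch %in% c("A", "C", "G", "T")) tot <- tot + 1
    if (ch %in% c("G", "C")) gc <- gc + 1
  }
  100 * gc / tot
}

oracle_tpm <- function(counts, lengths) {
  r <- numeric(length(counts))
  for (i in seq_along(counts)) r[i] <- counts[i] / lengths[i]
  out <- numeric(length(counts))
  for (i in seq_along(counts)) out[i] <- 1e6 * r[i] / sum(r)
  out
}

# connected components by boolean transitive closure of the adjacency
oracle_components <- function(ids, edges) {
  n <- length(ids)
  A <- diag(TRUE, n)
  dimnames(A) <- list(ids, ids)
  if (nrow(edges)) for (i in seq_len(nrow(edges))) {
    A[edges[i, 1], edges[i, 2]] <- TRUE
    A[edges[i, 2], edges[i, 1]] <- TRUE
  }
  repeat {
    A2 <- (A %*% A) > 0
    if (all(A2 == A)) break
    A <- A2
  }
  membership <- integer(n)
  next_lab <- 0L
  for (i in seq_len(n)) {
    if (membership[i] == 0L) {
      next_lab <- next_lab + 1L
      membership[A[i, ]] <- next_lab
    }
  }
  split(ids, membership)
}

# exhaustive application of the provenance rules for one hit table
oracle_green_filter <- function(hits, taxon_map, plastid_subjects,
                                cutoff = 1e-10, top_n = 5L) {
  kept_q <- character(0)
  for (q in unique(hits$query_id)) {
    h <- hits[hits$query_id == q & hits$evalue <= cutoff, , drop = FALSE]
    if (!nrow(h)) next
    h <- h[order(h$evalue, -h$bitscore, h$subject_id, method = "radix"), ,
           drop = FALSE]
    h <- h[!duplicated(h$subject_id), , drop = FALSE]
    grp <- taxon_map$taxon_group[match(h$subject_id, taxon_map$subject_id)]
    grp[is.na(grp)] <- "unknown"
    green <- any(grp[seq_len(min(top_n, nrow(h)))] == "Viridiplantae")
    has_plastid <- any(h$subject_id %in% plastid_subjects)
    if (green && !has_plastid) kept_q <- c(kept_q, q)
  }
  sort(kept_q, method = "radix")
}

# multivariate normal density through solve()/det(), not Cholesky
oracle_mvn_density <- function(x, mu, sigma) {
  d <- length(mu)
  q <- as.numeric(t(x - mu) %*% solve(sigma) %*% (x - mu))
  exp(-0.5 * q) / sqrt((2 * pi)^d * det(sigma))
}

rand_hit_table <- function(queries, subjects, n) {
  data.frame(
    query_id = sample(queries, n, replace = TRUE),
    subject_id = sample(subjects, n, replace = TRUE),
    percent_identity = round(runif(n, 30, 100), 1),
    align_length = sample(30:300, n, replace = TRUE),
    mismatches = sample(0:50, n, replace = TRUE),
    gap_opens = sample(0:5, n, replace = TRUE),
    q_start = 1L, q_end = 100L, s_start = 1L, s_end = 100L,
    evalue = 10^-runif(n, 0, 40),
    bitscore = round(runif(n, 30, 400), 1),
    stringsAsFactors = FALSE)
}

sim_two_gaussians <- function(n_per, mu1, mu2, d = 3L) {
  X <- rbind(
    matrix(rnorm(n_per * d), n_per, d) + rep(mu1, each = n_per),
    matrix(rnorm(n_per * d), n_per, d) + rep(mu2, each = n_per))
  list(X = X, truth = rep(1:2, each = n_per))
}

default_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "nmfinder-default-bundle")
      cache <<- simulate_dataset(nm_sim_config(), dir)
    }
    cache
  }
})
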