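# Reference deduplication methods used as independent comparators: a
# directional UMI-network clusterer (coded independently of the PUG
# machinery) and a naive per-equivalence-class UMI counter. Both are
# exported so that analyses can reproduce the method comparisons.

#' Directional UMI deduplication (independent implementation)
#'
#' Classic directional UMI-network collapsing on a vector of per-UMI read
#' counts within one gene: a directed edge runs from UMI u to UMI v when
#' they differ at exactly one position and `count[u] > 2*count[v] - 1`;
#' UMIs are visited in order of decreasing count (ties lexicographic) and
#' each unvisited UMI seeds a cluster grown by following directed edges
#' through unvisited UMIs. The number of clusters is the molecule count.
#'
#' This implementation shares no code with the PUG pipeline and serves as
#' the independent comparator for single-transcript data.
#'
#' @param counts named integer vector: read count per UMI sequence.
#' @return Integer number of clusters (deduplicated molecules).
#' @export
dedup_directional <- function(counts) {
  n <- length(counts)
  if (n == 0L) return(0L)
  umis <- names(counts)
  if (is.null(umis) || length(unique(nchar(umis))) != 1L)
    stop("counts must be named by UMIs of uniform length")
  ord <- order(-as.integer(counts), umis)
  umis <- umis[ord]
  cnt <- as.integer(counts)[ord]
  chars <- matrix(unlist(strsplit(umis, "", fixed = TRUE)),
                  nrow = n, byrow = TRUE)
  ham1 <- function(i, j) sum(chars[i, ] != chars[j, ]) == 1L
  visited <- logical(n)
  clusters <- 0L
  for (s in seq_len(n)) {
    if (visited[s]) next
    clusters <- clusters + 1L
    queue <- s
    visited[s] <- TRUE
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      for (v in seq_len(n)) {
        if (!visited[v] && cnt[u] > 2L * cnt[v] - 1L && ham1(u, v)) {
          visited[v] <- TRUE
          queue <- c(queue, v)
        }
      }
    }
  }
  clusters
}

#' Naive per-equivalence-class UMI counting (foil)
#'
#' Treats each equivalence class independently and counts its distinct
#' UMIs, ignoring that the same UMI split across transcript-overlapping
#' classes can stem from one molecule fragmented at different positions.
#' Over-counts in exactly those cases; kept as the baseline the PUG
#' covering improves on.
#'
#' @param umi,tx,count vertex data as for [build_pug()].
#' @param t2g transcript-to-gene map (named character vector).
#' @return List with `total` (molecule count) and `per_gene` (named
#'   numeric; multi-gene classes split uniformly).
#' @export
naive_eqclass_count <- function(umi, tx, count, t2g) {
  keys <- vapply(tx, function(t) paste(sort(t), collapse = ","), character(1))
  pairs <- !duplicated(paste(keys, umi))
  total <- sum(pairs)
  per_gene <- numeric(0)
  for (i in which(pairs)) {
    genes <- sort(unique(unname(t2g[tx[[i]]])))
    for (g in genes) {
      per_gene[g] <- (if (g %in% names(per_gene)) per_gene[[g]] else 0) +
        1 / length(genes)
    }
  }
  list(total = total, per_gene = per_gene)
}
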