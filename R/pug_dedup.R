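# Parsimonious UMI graph (PUG) deduplication. Each vertex is a
# (UMI, transcript equivalence class) pair with a read count. Edges connect
# vertices that could share a pre-PCR molecule of origin: a directed edge
# v_i -> v_j when c_i > 2*c_j - 1, the transcript sets overlap and the UMIs
# are at Hamming distance 1 (PCR/sequencing error with a clear direction of
# duplication); otherwise a bi-directed edge when the Hamming distance is
# <= 1 and the transcript sets overlap (same molecule sampled at different
# fragmentation positions, or an error without a clear direction). After
# edge formation the counts play no further role: deduplication is a
# minimum-cardinality covering of the graph by vertex-disjoint
# monochromatic arborescences, each arborescence one pre-PCR molecule.

hamming_matrix <- function(umi) {
  n <- length(umi)
  L <- nchar(umi[1])
  M <- matrix(unlist(strsplit(umi, "", fixed = TRUE)), nrow = n, byrow = TRUE)
  D <- matrix(0L, n, n)
  for (l in seq_len(L)) D <- D + outer(M[, l], M[, l], "!=")
  D
}

#' Construct a PUG from explicit components
#'
#' Low-level constructor used by [build_pug()] and by callers that need a
#' graph with prescribed edges (e.g. the dominating-set reduction used to
#' exercise [brute_force_cover()]). Most users want [build_pug()].
#'
#' @param umi character vector of UMI sequences (one per vertex).
#' @param tx list of transcript-id character vectors (vertex colors).
#' @param count integer read counts per vertex.
#' @param edges_dir 2-column integer matrix of directed edges (from, to).
#' @param edges_bi 2-column integer matrix of bi-directed edges.
#' @return An object of class `pug`.
#' @export
pug <- function(umi, tx, count, edges_dir = NULL, edges_bi = NULL) {
  n <- length(umi)
  stopifnot(length(tx) == n, length(count) == n)
  if (n > 0 && any(count < 1)) stop("vertex counts must be >= 1")
  fix_edges <- function(e) {
    if (is.null(e) || NROW(e) == 0L)
      return(matrix(integer(0), ncol = 2L))
    e <- matrix(as.integer(e), ncol = 2L)
    if (any(e < 1L | e > n)) stop("edge endpoint out of range")
    if (any(e[, 1] == e[, 2])) stop("self-edges are not allowed")
    e
  }
  structure(list(umi = umi, tx = lapply(tx, sort), count = as.integer(count),
                 edges_dir = fix_edges(edges_dir),
                 edges_bi = fix_edges(edges_bi)),
            class = "pug")
}

#' @export
print.pug <- function(x, ...) {
  cat(sprintf("PUG: %d vertices, %d directed / %d bi-directed edges\n",
              length(x$umi), nrow(x$edges_dir), nrow(x$edges_bi)))
  invisible(x)
}

n_vertices <- function(pug) length(pug$umi)

#' Build the parsimonious UMI graph of one cell
#'
#' Vertices are the distinct (UMI, equivalence class) pairs of the cell
#' with their read counts. A directed edge runs i -> j when
#' `count[i] > 2*count[j] - 1`, the transcript sets intersect and the UMIs
#' are at Hamming distance 1. Pairs with transcript overlap and Hamming
#' distance <= 1 that carry no directed edge get one bi-directed edge
#' (Hamming-0 pairs arise from the same UMI split across different
#' equivalence classes by fragmentation position).
#'
#' @param umi character vector of UMIs (uniform length), one per vertex.
#' @param tx list of transcript-id vectors (equivalence classes).
#' @param count positive integer read counts.
#' @return An object of class `pug`.
#' @export
build_pug <- function(umi, tx, count) {
  n <- length(umi)
  stopifnot(length(tx) == n, length(count) == n)
  if (n == 0L) return(pug(character(0), list(), integer(0)))
  if (length(unique(nchar(umi))) != 1L) stop("inconsistent UMI lengths")
  key <- paste(umi, vapply(tx, function(t) paste(sort(t), collapse = ","),
                           character(1)))
  if (anyDuplicated(key)) stop("duplicate (UMI, equivalence class) vertices")
  count <- as.integer(count)
  if (any(count < 1L)) stop("vertex counts must be >= 1")
  D <- hamming_matrix(umi)
  ed <- matrix(integer(0), ncol = 2)
  eb <- matrix(integer(0), ncol = 2)
  if (n > 1L) {
    pr <- which(upper.tri(D) & D <= 1L, arr.ind = TRUE)
    if (nrow(pr)) {
      keep <- vapply(seq_len(nrow(pr)), function(r) {
        length(intersect(tx[[pr[r, 1]]], tx[[pr[r, 2]]])) > 0L
      }, logical(1))
      pr <- pr[keep, , drop = FALSE]
    }
    if (nrow(pr)) {
      for (r in seq_len(nrow(pr))) {
        i <- pr[r, 1]; j <- pr[r, 2]
        if (D[i, j] == 1L) {
          ij <- count[i] > 2L * count[j] - 1L
          ji <- count[j] > 2L * count[i] - 1L
          if (ij) ed <- rbind(ed, c(i, j))
          if (ji) ed <- rbind(ed, c(j, i))
          if (!ij && !ji) eb <- rbind(eb, c(i, j))
        } else {
          eb <- rbind(eb, c(i, j))  # Hamming 0: different classes, same UMI
        }
      }
    }
  }
  pug(umi, tx, count, ed, eb)
}

# out-adjacency usable during arborescence growth: directed edges forward,
# bi-directed edges in either direction
pug_out_adjacency <- function(pug) {
  n <- n_vertices(pug)
  adj <- replicate(n, integer(0), simplify = FALSE)
  ed <- pug$edges_dir
  for (r in seq_len(nrow(ed))) adj[[ed[r, 1]]] <- c(adj[[ed[r, 1]]], ed[r, 2])
  eb <- pug$edges_bi
  for (r in seq_len(nrow(eb))) {
    adj[[eb[r, 1]]] <- c(adj[[eb[r, 1]]], eb[r, 2])
    adj[[eb[r, 2]]] <- c(adj[[eb[r, 2]]], eb[r, 1])
  }
  lapply(adj, function(v) sort(unique(v)))
}

# weakly connected components, ordered by smallest contained vertex index
pug_components <- function(pug) {
  n <- n_vertices(pug)
  if (n == 0L) return(list())
  sym <- replicate(n, integer(0), simplify = FALSE)
  alledges <- rbind(pug$edges_dir, pug$edges_bi)
  for (r in seq_len(nrow(alledges))) {
    a <- alledges[r, 1]; b <- alledges[r, 2]
    sym[[a]] <- c(sym[[a]], b)
    sym[[b]] <- c(sym[[b]], a)
  }
  seen <- logical(n)
  comps <- list()
  for (v in seq_len(n)) {
    if (seen[v]) next
    queue <- v; seen[v] <- TRUE; comp <- integer(0)
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      comp <- c(comp, u)
      for (w in sym[[u]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}

# BFS from root over `adj`, restricted to vertices in `alive` whose color
# set contains `t`; returns the reached vertex set
reach_with_color <- function(adj, tx, alive, root, t) {
  reached <- integer(0)
  inset <- logical(length(adj))
  queue <- root
  inset[root] <- TRUE
  while (length(queue)) {
    u <- queue[1]; queue <- queue[-1]
    reached <- c(reached, u)
    for (w in adj[[u]]) {
      if (!inset[w] && alive[w] && t %in% tx[[w]]) {
        inset[w] <- TRUE
        queue <- c(queue, w)
      }
    }
  }
  reached
}

#' Greedy minimum-cardinality covering by monochromatic arborescences
#'
#' Processes each weakly connected component independently. Repeatedly, for
#' every remaining (vertex, transcript-in-its-class) pair, a breadth-first
#' search grows the largest arborescence rooted at that vertex and
#' consistently colorable by that transcript (directed edges traversed
#' forward, bi-directed edges in either direction); the largest one is
#' emitted, its vertices removed, and the procedure repeats until the
#' component is exhausted. Ties on cardinality are broken deterministically
#' by smallest root index, then lexicographically smallest transcript.
#'
#' @param pug a [build_pug()] result.
#' @return An object of class `pug_covering`: list of arborescences, each
#'   a list with `root`, `label`, `vertices` (sorted indices) and
#'   `feasible` (all transcripts able to color it).
#' @export
greedy_cover <- function(pug) {
  stopifnot(inherits(pug, "pug"))
  n <- n_vertices(pug)
  res <- list()
  if (n == 0L) return(structure(res, class = "pug_covering"))
  adj <- pug_out_adjacency(pug)
  for (comp in pug_components(pug)) {
    alive <- logical(n)
    alive[comp] <- TRUE
    while (any(alive)) {
      best_size <- 0L; best <- NULL
      for (v in which(alive)) {
        for (t in pug$tx[[v]]) {  # tx sets are stored sorted
          reached <- reach_with_color(adj, pug$tx, alive, v, t)
          if (length(reached) > best_size) {
            best_size <- length(reached)
            best <- list(root = v, label = t, vertices = sort(reached))
          }
          if (best_size == sum(alive)) break
        }
        if (best_size == sum(alive)) break
      }
      best$feasible <- sort(Reduce(intersect, pug$tx[best$vertices]))
      res[[length(res) + 1L]] <- best
      alive[best$vertices] <- FALSE
    }
  }
  structure(res, class = "pug_covering")
}

#' @export
print.pug_covering <- function(x, ...) {
  cat(sprintf("PUG covering: %d arborescence(s)\n", length(x)))
  invisible(x)
}

#' Validate a covering against its PUG
#'
#' Checks vertex-disjointness, completeness, monochromaticity (the feasible
#' set equals the non-empty intersection of the vertex colors) and root
#' reachability within each arborescence's vertex set.
#'
#' @param pug the graph.
#' @param covering a [greedy_cover()] result.
#' @return `TRUE` (invisibly) or an error describing the violation.
#' @export
validate_covering <- function(pug, covering) {
  n <- n_vertices(pug)
  verts <- unlist(lapply(covering, `[[`, "vertices"))
  if (anyDuplicated(verts)) stop("covering is not vertex-disjoint")
  if (!setequal(verts, seq_len(n))) stop("covering does not cover all vertices")
  adj <- pug_out_adjacency(pug)
  for (a in covering) {
    inter <- sort(Reduce(intersect, pug$tx[a$vertices]))
    if (length(inter) == 0L) stop("arborescence is not monochromatic")
    if (!identical(inter, a$feasible)) stop("feasible set is not the color intersection")
    if (!(a$label %in% inter)) stop("chosen label not in the feasible set")
    alive <- logical(n); alive[a$vertices] <- TRUE
    reached <- reach_with_color(adj, pug$tx, alive, a$root, a$label)
    if (!setequal(reached, a$vertices))
      stop("arborescence vertices not reachable from its root")
  }
  invisible(TRUE)
}

#' Exact minimum covering cardinality (small-instance oracle)
#'
#' Exhaustive subset dynamic program over vertex subsets: a subset is
#' feasible as a single monochromatic arborescence when its color
#' intersection is non-empty and some member reaches all others within the
#' subset; the minimum partition into feasible subsets is then computed.
#' Guarded to graphs with at most 12 vertices; intended as a test oracle
#' for [greedy_cover()], not for production use.
#'
#' @param pug the graph (<= 12 vertices).
#' @return Integer minimum number of monochromatic arborescences.
#' @export
brute_force_cover <- function(pug) {
  stopifnot(inherits(pug, "pug"))
  n <- n_vertices(pug)
  if (n == 0L) return(0L)
  if (n > 12L) stop("brute_force_cover is guarded to at most 12 vertices")
  adj <- pug_out_adjacency(pug)
  # out-neighbor bitmasks
  out_mask <- vapply(seq_len(n), function(v) {
    Reduce(bitwOr, c(0L, bitwShiftL(1L, adj[[v]] - 1L)))
  }, integer(1))
  # color bitmasks over the (small) transcript universe
  univ <- sort(unique(unlist(pug$tx)))
  col_mask <- NULL
  use_bits <- length(univ) <= 30L
  if (use_bits)
    col_mask <- vapply(pug$tx, function(t) {
      Reduce(bitwOr, c(0L, bitwShiftL(1L, match(t, univ) - 1L)))
    }, integer(1))
  full <- bitwShiftL(1L, n) - 1L
  bit_of <- bitwShiftL(1L, seq_len(n) - 1L)
  members <- function(S) which(bitwAnd(S, bit_of) != 0L)
  feas <- logical(full + 1L)
  for (S in seq_len(full)) {
    idx <- members(S)
    ok_color <- if (use_bits)
      Reduce(bitwAnd, col_mask[idx]) != 0L
    else
      length(Reduce(intersect, pug$tx[idx])) > 0L
    if (!ok_color) next
    for (r in idx) {
      reached <- bit_of[r]
      repeat {
        nxt <- reached
        for (v in members(reached))
          nxt <- bitwOr(nxt, bitwAnd(out_mask[v], S))
        if (nxt == reached) break
        reached <- nxt
      }
      if (reached == S) { feas[S + 1L] <- TRUE; break }
    }
  }
  dp <- rep.int(.Machine$integer.max, full + 1L)
  dp[1L] <- 0L
  for (S in seq_len(full)) {
    low <- bitwAnd(S, -S)
    sub <- S
    best <- .Machine$integer.max
    while (sub > 0L) {
      if (bitwAnd(sub, low) != 0L && feas[sub + 1L]) {
        rest <- dp[S - sub + 1L]
        if (rest < .Machine$integer.max && rest + 1L < best)
          best <- rest + 1L
      }
      sub <- bitwAnd(sub - 1L, S)
    }
    dp[S + 1L] <- best
  }
  dp[full + 1L]
}

#' Gene-level molecule counts from a covering
#'
#' Each arborescence is one pre-PCR molecule. Its feasible transcript set
#' is mapped to genes: a single gene increments that gene's unique count by
#' one; several genes append the gene set to the ambiguous list, later
#' resolved by [em_resolve()].
#'
#' @param covering a [greedy_cover()] result.
#' @param t2g transcript-to-gene map (named character vector).
#' @return List with `unique` (named numeric gene counts) and `ambiguous`
#'   (list of sorted gene-set character vectors).
#' @export
label_arborescences <- function(covering, t2g) {
  uniq <- numeric(0)
  amb <- list()
  for (a in covering) {
    if (length(a$feasible) == 0L)
      stop("arborescence with empty feasible set (invalid covering)")
    genes <- sort(unique(unname(t2g[a$feasible])))
    if (anyNA(genes)) stop("transcript without gene mapping in covering")
    if (length(genes) == 1L) {
      uniq[genes] <- (if (genes %in% names(uniq)) uniq[[genes]] else 0) + 1
    } else {
      amb[[length(amb) + 1L]] <- genes
    }
  }
  list(unique = uniq, ambiguous = amb)
}
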