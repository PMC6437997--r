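# EM resolution of gene-ambiguous molecules, per-gene evidence tiers, and
# per-cell bootstrap variances. The EM is the standard equivalence-class
# mixture EM with no effective-length term: in tagged-end droplet
# protocols the fragment generation probability is taken directly
# proportional to abundance.

#' Distribute gene-ambiguous molecules by EM
#'
#' Starting from the uniquely assigned per-gene molecule counts, each
#' ambiguous molecule (a gene set) is fractionally assigned to its genes in
#' proportion to the current abundances (uniformly while all its genes sit
#' at zero); the M-step resets each abundance to unique count plus assigned
#' fractions. Iteration stops when the largest absolute count change drops
#' below `tol` or after `max_iter` rounds. Total counts are conserved:
#' the output sums to `sum(unique) + length(ambiguous)`.
#'
#' @param unique_counts named numeric vector of unambiguous molecule counts.
#' @param ambiguous list of character vectors (gene sets), one per
#'   ambiguous molecule.
#' @param tol absolute count-change convergence tolerance (default 1e-3).
#' @param max_iter iteration cap (default 1000).
#' @param trace record the multinomial log-likelihood path in attribute
#'   `loglik`?
#' @return Named numeric vector of per-gene molecule counts over all genes
#'   seen in either input.
#' @export
em_resolve <- function(unique_counts, ambiguous = list(), tol = 1e-3,
                       max_iter = 1000L, trace = FALSE) {
  if (any(unique_counts < 0)) stop("unique counts must be >= 0")
  if (any(lengths(ambiguous) == 0L)) stop("empty ambiguous gene set")
  genes <- sort(unique(c(names(unique_counts), unlist(ambiguous))))
  base <- setNames(numeric(length(genes)), genes)
  base[names(unique_counts)] <- unique_counts
  if (length(ambiguous) == 0L) return(base)
  # collapse identical gene sets, keep multiplicities
  keys <- vapply(ambiguous, paste, character(1), collapse = "\r")
  mult <- table(keys)
  sets <- strsplit(names(mult), "\r", fixed = TRUE)
  wts <- as.numeric(mult)
  abund <- base
  ll <- numeric(0)
  loglik <- function(a) {
    theta <- a / sum(a)
    sum(ifelse(base > 0, base * log(theta), 0)) +
      sum(wts * log(vapply(sets, function(g) sum(theta[g]), numeric(1))))
  }
  for (it in seq_len(max_iter)) {
    if (trace) ll <- c(ll, loglik(abund))
    new <- base
    for (s in seq_along(sets)) {
      g <- sets[[s]]
      w <- abund[g]
      w <- if (sum(w) == 0) rep(1 / length(g), length(g)) else w / sum(w)
      new[g] <- new[g] + wts[s] * w
    }
    delta <- max(abs(new - abund))
    abund <- new
    if (delta < tol) break
  }
  if (trace) attr(abund, "loglik") <- c(ll, loglik(abund))
  abund
}

#' Assign per-gene evidence tiers for one cell
#'
#' Tier 0: no read evidence in the cell. Classes are sized in genes; the
#' genes of single-gene classes are marked tier 1. Over the multi-gene
#' classes a graph on transcripts is built (two transcripts connected when
#' they co-occur in a class); any connected component containing a
#' tier-1-marked gene sends that gene and every other gene of the
#' component to tier 2 (EM-resolvable); genes of the remaining components
#' are tier 3 (no unique anchor, EM splits them uninformatively).
#'
#' @param classes list of transcript-id vectors: the equivalence classes
#'   observed in the cell (one entry per distinct class is sufficient).
#' @param t2g transcript-to-gene map (named character vector).
#' @return Named integer vector of tiers over all genes in `t2g`.
#' @export
assign_tiers <- function(classes, t2g) {
  genes <- sort(unique(unname(t2g)))
  tier <- setNames(rep(0L, length(genes)), genes)
  if (length(classes) == 0L) return(tier)
  cls_genes <- lapply(classes, function(ts) sort(unique(unname(t2g[ts]))))
  if (anyNA(unlist(cls_genes))) stop("transcript without gene mapping")
  marked <- unique(unlist(cls_genes[lengths(cls_genes) == 1L]))
  tier[marked] <- 1L
  multi <- which(lengths(cls_genes) > 1L)
  if (length(multi)) {
    edges <- do.call(rbind, lapply(classes[multi], function(ts) {
      ts <- sort(unique(ts))
      if (length(ts) == 1L) cbind(ts, ts) else cbind(ts[-length(ts)], ts[-1])
    }))
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    memb <- igraph::components(g)$membership
    comp_genes <- split(unname(t2g[names(memb)]), memb)
    tier2 <- unique(unlist(comp_genes[vapply(comp_genes, function(cg)
      any(cg %in% marked), logical(1))]))
    tier3 <- setdiff(unique(unlist(comp_genes)), tier2)
    tier[tier3] <- 3L
    tier[tier2] <- 2L
  }
  tier
}

#' Quantify one cell
#'
#' Runs the per-cell deduplication stack: [build_pug()] on the cell's
#' (UMI, class, count) records, [greedy_cover()], [label_arborescences()],
#' [em_resolve()] for gene-ambiguous molecules, and [assign_tiers()].
#'
#' @param umi,tx,count the cell's vertex records (as for [build_pug()]).
#' @param t2g transcript-to-gene map (named character vector).
#' @param tol,max_iter EM controls, see [em_resolve()].
#' @param multigene `"em"` (default) resolves gene-ambiguous molecules by
#'   EM; `"discard"` drops multi-gene vertices before deduplication (the
#'   information-discarding baseline other pipelines use).
#' @return List with `counts` (named numeric over all genes of `t2g`),
#'   `tiers`, `n_molecules`, and `covering`.
#' @export
quantify_cell <- function(umi, tx, count, t2g, tol = 1e-3, max_iter = 1000L,
                          multigene = c("em", "discard")) {
  multigene <- match.arg(multigene)
  if (multigene == "discard") {
    keep <- vapply(tx, function(ts)
      length(unique(unname(t2g[ts]))) == 1L, logical(1))
    umi <- umi[keep]; tx <- tx[keep]; count <- count[keep]
  }
  genes <- sort(unique(unname(t2g)))
  p <- build_pug(umi, tx, count)
  cov <- greedy_cover(p)
  lab <- label_arborescences(cov, t2g)
  est <- em_resolve(lab$unique, lab$ambiguous, tol = tol,
                    max_iter = max_iter)
  counts <- setNames(numeric(length(genes)), genes)
  counts[names(est)] <- est
  tiers <- assign_tiers(unique(lapply(tx, sort)), t2g)
  list(counts = counts, tiers = tiers, n_molecules = length(cov),
       covering = cov)
}

#' Bootstrap variance of per-gene counts within one cell
#'
#' Resamples the cell's reads (multinomial over its (UMI, class) records,
#' weighted by read count, total preserved), reruns the full deduplication
#' and EM per replicate, and returns the per-gene sample variance of the
#' counts. Read-level resampling lets the error-edge structure of the PUG
#' change across replicates.
#'
#' @inheritParams quantify_cell
#' @param n_boot number of bootstrap replicates (>= 2).
#' @param seed RNG seed.
#' @return Named numeric vector of per-gene count variances.
#' @export
bootstrap_cell_variance <- function(umi, tx, count, t2g, n_boot = 20L,
                                    seed = 1L, tol = 1e-3,
                                    max_iter = 1000L) {
  if (n_boot < 2L) stop("n_boot must be >= 2")
  genes <- sort(unique(unname(t2g)))
  total <- sum(count)
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  reps <- matrix(0, nrow = n_boot, ncol = length(genes),
                 dimnames = list(NULL, genes))
  for (b in seq_len(n_boot)) {
    cnt <- as.integer(rmultinom(1L, total, prob = count)[, 1])
    keep <- cnt > 0L
    q <- quantify_cell(umi[keep], tx[keep], cnt[keep], t2g,
                       tol = tol, max_iter = max_iter)
    reps[b, ] <- q$counts[genes]
  }
  apply(reps, 2L, var)
}
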