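# Shared fixtures and independent oracles used across the suite.

# random PUG with short two-letter UMIs (so Hamming-1 pairs are common),
# a small transcript pool and counts 1..8
rand_pug <- function(n_max = 8L) {
  n <- sample(2:n_max, 1L)
  pool <- c("t1", "t2", "t3", "t4")
  umi <- character(0)
  tx <- list()
  while (length(umi) < n) {
    u <- paste(sample(c("A", "C"), 4, TRUE), collapse = "")
    t <- sort(sample(pool, sample(1:3, 1L)))
    key <- paste(u, paste(t, collapse = ","))
    seen <- paste(umi, vapply(tx, paste, "", collapse = ","))
    if (!key %in% seen) {
      umi <- c(umi, u)
      tx <- c(tx, list(t))
    }
  }
  build_pug(umi, tx, sample(1:8, n, TRUE))
}

# exhaustive minimum dominating set of an undirected graph given as an
# adjacency list (independent of the package's covering machinery)
min_dominating_set <- function(adj) {
  n <- length(adj)
  best <- n
  for (S in seq_len(2^n - 1L)) {
    idx <- which(bitwAnd(S, bitwShiftL(1L, 0:(n - 1L))) != 0L)
    if (length(idx) >= best) next
    dominated <- rep(FALSE, n)
    for (v in idx) {
      dominated[v] <- TRUE
      dominated[adj[[v]]] <- TRUE
    }
    if (all(dominated)) best <- length(idx)
  }
  best
}

# random undirected graph plus its closed-neighborhood PUG (all edges
# bi-directed, vertex i labeled with its closed neighborhood)
rand_domset_instance <- function(n_max = 8L, p_edge = 0.35) {
  n <- sample(3:n_max, 1L)
  adj <- replicate(n, integer(0), simplify = FALSE)
  eb <- NULL
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    if (runif(1) < p_edge) {
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
      eb <- rbind(eb, c(i, j))
    }
  }
  labels <- lapply(seq_len(n), function(v) sort(sprintf("t%d", c(v, adj[[v]]))))
  list(adj = adj,
       pug = pug(umi = rep("A", n), tx = labels, count = rep(1L, n),
                 edges_bi = eb))
}

# independent one-edit predicates (string comparisons, no enumeration of
# edit results) used as the brute-force oracle for one_edit_neighbors()
is_one_substitution <- function(w, x) {
  nchar(w) == nchar(x) &&
    sum(strsplit(w, "")[[1]] != strsplit(x, "")[[1]]) == 1L
}
is_insertion_clip <- function(w, x) {
  n <- nchar(w)
  if (nchar(x) != n || x == w) return(FALSE)
  for (i in seq_len(n)) {
    pre_ok <- i == 1L || substr(x, 1, i - 1) == substr(w, 1, i - 1)
    post_ok <- substr(x, i + 1, n) == substr(w, i, n - 1)
    if (pre_ok && post_ok) return(TRUE)
  }
  FALSE
}
is_deletion_append <- function(w, x) {
  n <- nchar(w)
  if (nchar(x) != n || x == w) return(FALSE)
  for (i in seq_len(n)) {
    pre_ok <- i == 1L || substr(x, 1, i - 1) == substr(w, 1, i - 1)
    post_ok <- substr(x, i, n - 1) == substr(w, i + 1, n)
    if (pre_ok && post_ok) return(TRUE)
  }
  FALSE
}

all_strings <- function(len, alphabet = c("A", "C", "G", "T")) {
  do.call(paste0, do.call(expand.grid, replicate(len, alphabet,
                                                 simplify = FALSE)))
}

# tiny two-gene transcriptome with an exactly known shared block
shared_block_txome <- function(len_unique = 60L, len_shared = 60L,
                               seed = 1L) {
  set.seed(seed)
  rs <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                          collapse = "")
  shared <- rs(len_shared)
  seqs <- c(gA.t1 = paste0(rs(len_unique), shared),
            gB.t1 = paste0(rs(len_unique), shared))
  list(seqs = seqs, t2g = c(gA.t1 = "gA", gB.t1 = "gB"), shared = shared)
}

# zero-error closed-loop configuration at a given size
closed_loop_config <- function(seed, ...) {
  sim_config(seed = seed, pcr_cycles = 0L, capture_prob = 1,
             pcr_error_rate = 0, tag_error_rate = 0, cdna_error_rate = 0,
             ...)
}

sim_paths <- function(sim, dir = tempfile()) {
  write_sim(sim, dir)
  list(r1 = file.path(dir, "reads_1.fastq"),
       r2 = file.path(dir, "reads_2.fastq"),
       fasta = file.path(dir, "transcriptome.fa"),
       t2g = file.path(dir, "t2g.tsv"),
       whitelist = file.path(dir, "whitelist.txt"),
       dir = dir)
}
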