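# Droplet scRNA-seq protocol simulator: synthetic transcriptome with
# controllable inter-gene sequence sharing and 3'-anchored isoforms,
# per-cell molecule sampling, PCR amplification with tag (CB+UMI) errors,
# 3'-biased fragmentation, sequencing errors, and ambient (empty-droplet)
# barcodes. Emits FASTQ plus full ground truth so every pipeline stage has
# a closed-loop test.

#' Simulation configuration
#'
#' Defaults describe a desk-scale 10x-Chromium-v3-like experiment: 50
#' cells, a 100-gene transcriptome of 500-bp single-isoform genes, 16-base
#' cell barcodes with 12-base UMIs, ~100 molecules per cell, four PCR
#' cycles at 90% per-copy duplication efficiency, 60% per-copy capture,
#' and mild tag/cDNA sequencing error rates.
#'
#' @param seed integer RNG seed (recorded in the manifest).
#' @param n_cells number of real cells.
#' @param n_ambient_barcodes number of ambient (empty-droplet) barcodes.
#' @param n_genes,transcripts_per_gene,transcript_length transcriptome shape.
#' @param gene_pair_sharing inter-gene sequence sharing: scalar or
#'   per-pair vector of shared k-mer fractions in \[0, 1\]; consecutive
#'   gene pairs (1,2), (3,4), ... share a 3' sequence block sized so the
#'   shared fraction of distinct `kmer_k`-mers matches the request.
#' @param isoform_overlap fraction of the transcript length shared as a 3'
#'   suffix by additional isoforms of a gene.
#' @param cb_length,umi_length barcode geometry emitted in read 1.
#' @param molecules_per_cell Poisson mean of pre-PCR molecules per cell.
#' @param ambient_molecules Poisson mean of molecules per ambient barcode.
#' @param gene_weight_shape Gamma shape of the per-gene expression weights.
#' @param pcr_cycles,pcr_dup_prob PCR rounds and per-copy duplication
#'   probability per round.
#' @param pcr_error_rate per-base, per-cycle substitution rate on the
#'   CB+UMI tag of newly created copies.
#' @param capture_prob probability that an amplified copy is sequenced.
#' @param tag_error_rate per-base sequencing substitution rate on read 1.
#' @param cdna_error_rate per-base sequencing substitution rate on read 2.
#' @param frag_mean,frag_sd fragment length distribution (bases).
#' @param three_prime_bias 3' bias strength in \[0, 1\]: 0 = uniform
#'   fragment placement; larger values pull fragment ends toward the 3'
#'   terminus (exponential offset with mean `100 / bias` bases).
#' @param read_length read 2 length (bases).
#' @param kmer_k k-mer size used to calibrate sequence sharing.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_cells = 50L, n_ambient_barcodes = 400L,
                       n_genes = 100L, transcripts_per_gene = 1L,
                       transcript_length = 500L, gene_pair_sharing = 0,
                       isoform_overlap = 0.5, cb_length = 16L,
                       umi_length = 12L, molecules_per_cell = 100,
                       ambient_molecules = 5, gene_weight_shape = 3,
                       pcr_cycles = 4L, pcr_dup_prob = 0.9,
                       pcr_error_rate = 1e-4, capture_prob = 0.6,
                       tag_error_rate = 8.4e-4, cdna_error_rate = 1e-3,
                       frag_mean = 350, frag_sd = 50,
                       three_prime_bias = 0.8, read_length = 91L,
                       kmer_k = 31L) {
  cfg <- list(seed = as.integer(seed), n_cells = as.integer(n_cells),
              n_ambient_barcodes = as.integer(n_ambient_barcodes),
              n_genes = as.integer(n_genes),
              transcripts_per_gene = as.integer(transcripts_per_gene),
              transcript_length = as.integer(transcript_length),
              gene_pair_sharing = gene_pair_sharing,
              isoform_overlap = isoform_overlap,
              cb_length = as.integer(cb_length),
              umi_length = as.integer(umi_length),
              molecules_per_cell = molecules_per_cell,
              ambient_molecules = ambient_molecules,
              gene_weight_shape = gene_weight_shape,
              pcr_cycles = as.integer(pcr_cycles),
              pcr_dup_prob = pcr_dup_prob,
              pcr_error_rate = pcr_error_rate,
              capture_prob = capture_prob,
              tag_error_rate = tag_error_rate,
              cdna_error_rate = cdna_error_rate,
              frag_mean = frag_mean, frag_sd = frag_sd,
              three_prime_bias = three_prime_bias,
              read_length = as.integer(read_length),
              kmer_k = as.integer(kmer_k))
  rates <- c(cfg$pcr_dup_prob, cfg$pcr_error_rate, cfg$capture_prob,
             cfg$tag_error_rate, cfg$cdna_error_rate, cfg$three_prime_bias,
             cfg$isoform_overlap, cfg$gene_pair_sharing)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  if (any(c(cfg$n_cells, cfg$n_genes, cfg$transcript_length, cfg$cb_length,
            cfg$umi_length, cfg$read_length) < 1L))
    stop("counts and lengths must be positive")
  structure(cfg, class = "sim_config")
}

random_seqs <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

# per-base substitutions at `rate` on a character vector of sequences
mutate_seqs <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0L) return(seqs)
  lens <- nchar(seqs)
  nmut <- rbinom(length(seqs), lens, rate)
  hit <- which(nmut > 0L)
  for (i in hit) {
    ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    pos <- sample.int(lens[i], nmut[i])
    for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

#' Simulate a transcriptome with controllable sequence sharing
#'
#' Gene pairs (1,2), (3,4), ... share a 3'-terminal sequence block sized so
#' that the shared fraction of each gene's distinct `kmer_k`-mers matches
#' `gene_pair_sharing` (0 = fully independent sequences, 1 = identical
#' genes). Additional isoforms of a gene share a 3' suffix of fractional
#' length `isoform_overlap` and carry their own random 5' region.
#'
#' @param config a [sim_config()].
#' @return List with `seqs` (named character) and `t2g` (named character,
#'   gene ids named by transcript ids).
#' @export
simulate_transcriptome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(config$seed)
  L <- config$transcript_length
  k <- config$kmer_k
  ng <- config$n_genes
  sharing <- config$gene_pair_sharing
  n_pairs <- ng %/% 2L
  if (length(sharing) == 1L) sharing <- rep(sharing, n_pairs)
  if (length(sharing) != n_pairs)
    stop("gene_pair_sharing must be scalar or one value per gene pair")
  if (any(sharing < 0 | sharing > 1)) stop("infeasible sharing fraction")
  genes <- sprintf("g%04d", seq_len(ng))
  base_seq <- character(ng)
  for (p in seq_len(n_pairs)) {
    i <- 2L * p - 1L; j <- 2L * p
    s <- sharing[p]
    if (s <= 0) {
      base_seq[i] <- random_seqs(1, L)
      base_seq[j] <- random_seqs(1, L)
    } else {
      m <- min(L, round(s * (L - k + 1L)) + k - 1L)
      shared <- random_seqs(1, m)
      base_seq[i] <- paste0(random_seqs(1, L - m), shared)
      base_seq[j] <- paste0(random_seqs(1, L - m), shared)
    }
  }
  if (ng %% 2L == 1L) base_seq[ng] <- random_seqs(1, L)
  tpg <- config$transcripts_per_gene
  seqs <- character(0)
  t2g <- character(0)
  for (g in seq_len(ng)) {
    for (iso in seq_len(tpg)) {
      id <- sprintf("%s.t%d", genes[g], iso)
      if (iso == 1L) {
        seqs[id] <- base_seq[g]
      } else {
        m3 <- round(config$isoform_overlap * L)
        suffix <- substr(base_seq[g], L - m3 + 1L, L)
        seqs[id] <- paste0(random_seqs(1, L - m3), suffix)
      }
      t2g[id] <- genes[g]
    }
  }
  list(seqs = seqs, t2g = t2g)
}

# distinct barcodes with pairwise Hamming distance >= min_dist
sample_separated_barcodes <- function(n, len, min_dist = 3L,
                                      avoid = character(0)) {
  out <- character(0)
  guard <- 0L
  while (length(out) < n) {
    guard <- guard + 1L
    if (guard > 100L * n) stop("cannot place separated barcodes")
    cand <- random_seqs(1, len)
    pool <- c(out, avoid)
    ok <- TRUE
    for (b in pool) {
      if (sum(strsplit(cand, "")[[1]] != strsplit(b, "")[[1]]) < min_dist) {
        ok <- FALSE; break
      }
    }
    if (ok) out <- c(out, cand)
  }
  out
}

#' Simulate a droplet scRNA-seq experiment
#'
#' Per cell: molecules are drawn from Gamma-weighted gene propensities and
#' tagged with uniform random UMIs (collisions possible); each molecule is
#' amplified through `pcr_cycles` rounds of per-copy duplication, new
#' copies inheriting the CB+UMI tag with per-base substitution errors;
#' each amplified copy is sequenced with probability `capture_prob`, the
#' read-2 fragment drawn with a 3'-biased end position and truncated
#' normal length; sequencing errors hit both reads per base. Ambient
#' barcodes emit low-count molecules from the pooled (library-wide)
#' abundance profile. Real-cell barcodes are sampled with pairwise Hamming
#' distance >= 3 so that one-edit correction is well posed.
#'
#' @param config a [sim_config()].
#' @param txome optional [simulate_transcriptome()] result (regenerated
#'   from `config` when missing).
#' @return An object of class `sim_experiment`: list with `r1`, `r2`
#'   (named read vectors), `txome`, `truth` (list: `counts` cells x genes
#'   true pre-PCR molecule matrix, `molecules` and `reads` data.tables,
#'   `whitelist`, `ambient`), and `config`.
#' @export
simulate_reads <- function(config, txome = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(txome)) txome <- simulate_transcriptome(config)
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(config$seed + 1L)
  genes <- sort(unique(unname(txome$t2g)))
  ng <- length(genes)
  tx_by_gene <- split(names(txome$t2g), unname(txome$t2g))
  cbs <- sample_separated_barcodes(config$n_cells, config$cb_length)
  ambient <- character(0)
  if (config$n_ambient_barcodes > 0L) {
    ambient <- unique(random_seqs(config$n_ambient_barcodes,
                                  config$cb_length))
    ambient <- setdiff(ambient, cbs)
  }
  w <- rgamma(ng, shape = config$gene_weight_shape, rate = 1)
  w <- pmax(w, 1e-6)
  p_gene <- w / sum(w)

  draw_molecules <- function(barcode, n_mol, is_cell) {
    if (n_mol == 0L) return(NULL)
    gs <- sample(genes, n_mol, replace = TRUE, prob = p_gene)
    txs <- vapply(gs, function(g) {
      iso <- tx_by_gene[[g]]
      if (length(iso) == 1L) iso else sample(iso, 1L)
    }, character(1))
    data.table(cb = barcode, umi = random_seqs(n_mol, config$umi_length),
               tx = txs, gene = gs, is_cell = is_cell)
  }
  mols <- rbindlist(c(
    lapply(cbs, function(b)
      draw_molecules(b, rpois(1L, config$molecules_per_cell), TRUE)),
    lapply(ambient, function(b)
      draw_molecules(b, rpois(1L, config$ambient_molecules), FALSE))))
  if (is.null(mols) || nrow(mols) == 0L) stop("simulation produced no molecules")
  mols[, mol_id := seq_len(.N)]

  truth_counts <- matrix(0L, nrow = config$n_cells, ncol = ng,
                         dimnames = list(cbs, genes))
  cellmols <- mols[mols$is_cell]
  if (nrow(cellmols)) {
    tc <- cellmols[, .N, by = c("cb", "gene")]
    truth_counts[cbind(match(tc$cb, cbs), match(tc$gene, genes))] <- tc$N
  }

  # PCR amplification of the CB+UMI tag, then per-copy capture
  tags0 <- paste0(mols$cb, mols$umi)
  read_mol <- integer(0)
  read_tag <- character(0)
  for (i in seq_len(nrow(mols))) {
    tags <- tags0[i]
    for (cy in seq_len(config$pcr_cycles)) {
      dup <- runif(length(tags)) < config$pcr_dup_prob
      if (any(dup))
        tags <- c(tags, mutate_seqs(tags[dup], config$pcr_error_rate))
    }
    seqd <- runif(length(tags)) < config$capture_prob
    if (any(seqd)) {
      read_mol <- c(read_mol, rep.int(i, sum(seqd)))
      read_tag <- c(read_tag, tags[seqd])
    }
  }
  if (length(read_mol) == 0L) stop("simulation produced no reads")

  # fragmentation (3'-biased) and read-2 extraction
  tx_len <- setNames(nchar(txome$seqs), names(txome$seqs))
  rtx <- mols$tx[read_mol]
  Ls <- unname(tx_len[rtx])
  nr <- length(read_mol)
  fl <- pmin(pmax(round(rnorm(nr, config$frag_mean, config$frag_sd)),
                  pmin(config$read_length, Ls)), Ls)
  if (config$three_prime_bias > 0) {
    e <- round(rexp(nr, rate = config$three_prime_bias / 100))
  } else {
    e <- floor(runif(nr) * (Ls - fl + 1L))
  }
  e <- pmin(e, Ls - fl)
  endp <- Ls - e
  startp <- endp - fl + 1L
  r2 <- substr(txome$seqs[rtx], startp, pmin(startp + config$read_length - 1L,
                                             endp))
  r1 <- mutate_seqs(read_tag, config$tag_error_rate)
  r2 <- mutate_seqs(unname(r2), config$cdna_error_rate)

  ord <- sample.int(nr)  # shuffle into library order
  ids <- sprintf("read%07d", seq_len(nr))
  reads <- data.table(read_id = ids, mol_id = mols$mol_id[read_mol[ord]],
                      cb = mols$cb[read_mol[ord]],
                      umi = mols$umi[read_mol[ord]],
                      tx = rtx[ord], gene = mols$gene[read_mol[ord]],
                      is_cell = mols$is_cell[read_mol[ord]])
  structure(list(
    r1 = setNames(r1[ord], ids), r2 = setNames(r2[ord], ids),
    txome = txome,
    truth = list(counts = truth_counts, molecules = mols, reads = reads,
                 whitelist = cbs, ambient = ambient),
    config = config), class = "sim_experiment")
}

#' @export
print.sim_experiment <- function(x, ...) {
  cat(sprintf(
    "sim_experiment: %d cells (+%d ambient), %d genes, %d molecules, %d reads\n",
    x$config$n_cells, length(x$truth$ambient), ncol(x$truth$counts),
    nrow(x$truth$molecules), length(x$r1)))
  invisible(x)
}

#' Simulate and write a complete experiment to disk
#'
#' Emits `reads_1.fastq`/`reads_2.fastq`, `transcriptome.fa`, `t2g.tsv`,
#' truth tables (`truth_counts.tsv`, `truth_reads.tsv`), the true
#' whitelist and a JSON manifest of the configuration including the seed.
#'
#' @param sim a [simulate_reads()] result.
#' @param dir output directory.
#' @param compress gzip the FASTQ files?
#' @return The directory, invisibly.
#' @export
write_sim <- function(sim, dir, compress = FALSE) {
  stopifnot(inherits(sim, "sim_experiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (compress) ".fastq.gz" else ".fastq"
  write_fastq(sim$r1, file.path(dir, paste0("reads_1", ext)), compress)
  write_fastq(sim$r2, file.path(dir, paste0("reads_2", ext)), compress)
  write_transcriptome(sim$txome$seqs, file.path(dir, "transcriptome.fa"))
  write_t2g(sim$txome$t2g, file.path(dir, "t2g.tsv"))
  tc <- as.data.frame(sim$truth$counts)
  write.table(tc, file.path(dir, "truth_counts.tsv"), sep = "\t",
              quote = FALSE, col.names = NA)
  fwrite(sim$truth$reads, file.path(dir, "truth_reads.tsv"), sep = "\t")
  write_whitelist(sim$truth$whitelist, file.path(dir, "whitelist.txt"))
  manifest <- c(unclass(sim$config),
                list(n_reads = length(sim$r1),
                     n_molecules = nrow(sim$truth$molecules)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Simulate a bimodal barcode count tally
#'
#' The classic knee-detection scenario: `n_real` cell barcodes with
#' normally distributed read counts and `n_ambient` empty-droplet barcodes
#' with geometric counts.
#'
#' @param n_real,n_ambient numbers of real and ambient barcodes.
#' @param real_mean,real_sd Normal parameters of real-cell counts.
#' @param ambient_mean mean of the (shifted) geometric ambient counts.
#' @param cb_length barcode length.
#' @param seed RNG seed.
#' @return List with `tally` (as from [tally_barcodes()]) and `real`
#'   (the true cell barcodes).
#' @export
simulate_barcode_tally <- function(n_real = 100L, n_ambient = 10000L,
                                   real_mean = 1e4, real_sd = 1e3,
                                   ambient_mean = 10, cb_length = 16L,
                                   seed = 1L) {
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  bcs <- character(0)
  while (length(bcs) < n_real + n_ambient)
    bcs <- unique(c(bcs, random_seqs(n_real + n_ambient - length(bcs) + 10L,
                                     cb_length)))
  bcs <- bcs[seq_len(n_real + n_ambient)]
  real <- bcs[seq_len(n_real)]
  counts <- c(pmax(1L, round(rnorm(n_real, real_mean, real_sd))),
              rgeom(n_ambient, prob = 1 / ambient_mean) + 1L)
  tally <- setNames(as.integer(counts), bcs)
  tally <- tally[order(-tally, names(tally))]
  list(tally = tally, real = real)
}

#' Simulate the observed UMI counts of one gene
#'
#' Single-gene, single-transcript view used for comparisons with
#' directional UMI collapsing: molecules get uniform random UMIs, each
#' molecule yields `1 + Poisson(reads_per_mol - 1)` reads, and each read's
#' UMI is substituted at one random position with probability
#' `umi_error_prob`. Returns the observed per-UMI read counts and the true
#' molecule count.
#'
#' @param n_mols_mean Poisson mean of the (>= 1) molecule count.
#' @param reads_per_mol mean reads per molecule.
#' @param umi_length UMI length in bases.
#' @param umi_error_prob per-read probability of a single-base UMI error.
#' @param seed RNG seed.
#' @return List with `counts` (named integer per observed UMI) and
#'   `n_true` molecules.
#' @export
simulate_gene_umis <- function(n_mols_mean = 3, reads_per_mol = 10,
                               umi_length = 12L, umi_error_prob = 0.01,
                               seed = 1L) {
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  m <- max(1L, rpois(1L, n_mols_mean))
  umis <- random_seqs(m, umi_length)
  obs <- character(0)
  for (i in seq_len(m)) {
    nr <- 1L + rpois(1L, reads_per_mol - 1)
    for (r in seq_len(nr)) {
      u <- umis[i]
      if (runif(1L) < umi_error_prob) {
        p <- sample.int(umi_length, 1L)
        ch <- substr(u, p, p)
        substr(u, p, p) <- sample(setdiff(c("A", "C", "G", "T"), ch), 1L)
      }
      obs <- c(obs, u)
    }
  }
  tab <- table(obs)
  list(counts = setNames(as.integer(tab), names(tab)), n_true = m)
}
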