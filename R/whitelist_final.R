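# Final whitelisting: after quantification, barcodes above the knee are
# split into a high-quality upper half and an ambiguous lower half; a
# Gaussian naive Bayes classifier trained on the high-quality half versus
# a low-quality set just below the knee labels each ambiguous barcode.

#' Split barcodes into high-quality, ambiguous and low-quality regions
#'
#' Barcodes at or above the knee threshold are ordered by descending count
#' (ties lexicographic) and split into two equal regions: high-quality
#' (upper half, H) and ambiguous (lower half, L). The low-quality training
#' set takes `n_l = max(0.2 * |H|, 1000)` barcodes immediately below the
#' knee (all available, with a warning, when fewer exist).
#'
#' @param tally named counts from [tally_barcodes()].
#' @param threshold knee count threshold (see [find_knee()]).
#' @return List with `high`, `ambiguous`, `low`, `threshold`, `n_l`.
#' @export
split_regions <- function(tally, threshold) {
  counts <- as.numeric(tally)
  ord <- order(-counts, names(tally))
  bcs <- names(tally)[ord]
  cnt <- counts[ord]
  above <- bcs[cnt >= threshold]
  below <- bcs[cnt < threshold]
  if (length(above) == 0L) stop("no barcodes above the knee threshold")
  n_high <- ceiling(length(above) / 2)
  high <- above[seq_len(n_high)]
  ambiguous <- above[-seq_len(n_high)]
  n_l <- max(ceiling(0.2 * length(high)), 1000L)
  if (length(below) < n_l) {
    if (length(below) < n_l)
      warning("only ", length(below), " barcodes below the knee; ",
              "using all of them as the low-quality training set ",
              "(wanted ", n_l, ")")
    low <- below
  } else {
    low <- below[seq_len(n_l)]
  }
  list(high = high, ambiguous = ambiguous, low = low,
       threshold = threshold, n_l = length(low))
}

#' Per-cell classifier features from quantification results
#'
#' Computes, per barcode: fraction of reads mapped, duplication rate
#' `(mapped reads - deduplicated molecules) / mapped reads`, mean gene
#' count after deduplication (`molecules / genes expressed`), optional
#' fractions of mitochondrial and rRNA reads (given gene lists), and
#' optionally the maximum Spearman correlation of `log1p` gene counts with
#' the high-quality cells (restricted, per pair, to genes expressed in
#' either cell). Cells with zero mapped reads get all-zero features and
#' are flagged.
#'
#' @param counts cells-by-genes count matrix (rows named by barcode).
#' @param stats data.frame with columns `barcode`, `reads_total`,
#'   `reads_mapped`, and optionally `reads_mito`, `reads_rrna`.
#' @param high_cells barcodes of the high-quality region (enables the
#'   correlation feature when `use_correlation = TRUE`).
#' @param use_correlation add the max-correlation feature?
#' @return data.frame of features, rows named by barcode, with a logical
#'   `flagged` column for zero-mapped cells.
#' @export
extract_features <- function(counts, stats, high_cells = NULL,
                             use_correlation = FALSE) {
  counts <- as.matrix(counts)
  m <- match(rownames(counts), stats$barcode)
  if (anyNA(m)) stop("missing mapping stats for some barcodes")
  reads_total <- stats$reads_total[m]
  reads_mapped <- stats$reads_mapped[m]
  molecules <- rowSums(counts)
  genes_expressed <- rowSums(counts > 0)
  mapped_frac <- ifelse(reads_total > 0, reads_mapped / reads_total, 0)
  dup_rate <- ifelse(reads_mapped > 0,
                     pmax(0, (reads_mapped - molecules) / reads_mapped), 0)
  mean_gene <- ifelse(genes_expressed > 0, molecules / genes_expressed, 0)
  feat <- data.frame(mapped_frac = mapped_frac, dup_rate = dup_rate,
                     mean_gene = mean_gene,
                     row.names = rownames(counts))
  if (!is.null(stats$reads_mito))
    feat$mito_frac <- ifelse(reads_mapped > 0,
                             stats$reads_mito[m] / reads_mapped, 0)
  if (!is.null(stats$reads_rrna))
    feat$rrna_frac <- ifelse(reads_mapped > 0,
                             stats$reads_rrna[m] / reads_mapped, 0)
  if (use_correlation) {
    if (is.null(high_cells) || !length(high_cells))
      stop("use_correlation requires high_cells")
    H <- counts[intersect(high_cells, rownames(counts)), , drop = FALSE]
    lg <- log1p(counts)
    lH <- log1p(H)
    feat$max_cor <- vapply(seq_len(nrow(counts)), function(i) {
      best <- -1
      for (j in seq_len(nrow(lH))) {
        sel <- counts[i, ] > 0 | H[j, ] > 0
        if (sum(sel) < 2L) next
        r <- suppressWarnings(
          cor(lg[i, sel], lH[j, sel], method = "spearman"))
        if (is.finite(r) && r > best) best <- r
      }
      if (best < -1 + 1e-12 && nrow(lH) == 0L) 0 else best
    }, numeric(1))
  }
  feat$flagged <- reads_mapped == 0
  feat
}

# Gaussian naive Bayes with explicit variance smoothing: the per-feature,
# per-class variances get 1e-9 * (largest feature variance) added so that
# constant features never produce degenerate densities.
nb_train <- function(X, y) {
  X <- as.matrix(X)
  y <- as.factor(y)
  if (any(table(y) < 2L)) stop("need >= 2 training examples per class")
  mu <- t(vapply(levels(y), function(cl)
    colMeans(X[y == cl, , drop = FALSE]), numeric(ncol(X))))
  v <- t(vapply(levels(y), function(cl)
    apply(X[y == cl, , drop = FALSE], 2, var), numeric(ncol(X))))
  smooth <- 1e-9 * max(v, 0)
  if (!is.finite(smooth) || smooth <= 0) smooth <- 1e-12
  v <- v + smooth
  prior <- as.numeric(table(y)) / length(y)
  list(levels = levels(y), mu = mu, var = v, prior = prior,
       features = colnames(X))
}

nb_posterior <- function(model, X) {
  X <- as.matrix(X)
  lp <- vapply(seq_along(model$levels), function(ci) {
    ll <- rep(log(model$prior[ci]), nrow(X))
    for (j in seq_len(ncol(X)))
      ll <- ll + dnorm(X[, j], model$mu[ci, j],
                       sqrt(model$var[ci, j]), log = TRUE)
    ll
  }, numeric(nrow(X)))
  lp <- matrix(lp, nrow = nrow(X))
  m <- apply(lp, 1, max)
  p <- exp(lp - m)
  p / rowSums(p)
}

#' Classify ambiguous barcodes and finalize the whitelist
#'
#' Trains a Gaussian naive Bayes classifier on the high-quality region
#' (positives) versus the low-quality training set (negatives) and labels
#' each ambiguous barcode high-confidence when its posterior for the
#' positive class is at least `posterior_threshold`. The final whitelist
#' is the high-quality region plus the positively classified ambiguous
#' barcodes; H is always a subset of the output.
#'
#' @param features_high,features_low,features_ambiguous numeric feature
#'   data.frames/matrices with identical columns (see
#'   [extract_features()]; the `flagged` column is dropped automatically),
#'   rows named by barcode.
#' @param posterior_threshold classification threshold (default 0.5).
#' @return List with `whitelist` (character), `posterior` (named numeric
#'   for the ambiguous barcodes), and the fitted `model`.
#' @export
classify_ambiguous_barcodes <- function(features_high, features_low,
                                        features_ambiguous,
                                        posterior_threshold = 0.5) {
  drop_flag <- function(f) {
    f <- as.data.frame(f)
    f$flagged <- NULL
    as.matrix(f)
  }
  Xh <- drop_flag(features_high)
  Xl <- drop_flag(features_low)
  Xa <- drop_flag(features_ambiguous)
  model <- nb_train(rbind(Xh, Xl),
                    rep(c("high", "low"), c(nrow(Xh), nrow(Xl))))
  keep <- character(0)
  post <- numeric(0)
  if (nrow(Xa)) {
    p <- nb_posterior(model, Xa)[, match("high", model$levels)]
    post <- setNames(p, rownames(Xa))
    keep <- rownames(Xa)[p >= posterior_threshold]
  }
  list(whitelist = c(rownames(Xh), keep), posterior = post, model = model)
}
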