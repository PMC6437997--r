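# Initial whitelisting: tally cell barcodes, find the knee of the barcode
# frequency distribution by Gaussian KDE on log10 counts, and correct
# erroneous barcodes to whitelisted labels within one edit.

#' Tally observed cell barcodes
#'
#' Counts every observed barcode regardless of putative errors. Barcodes
#' containing N should be removed upstream (see [read_fastq_pairs()]).
#'
#' @param cb character vector of cell barcodes (one per read), or a
#'   data.frame with a `cb` column.
#' @return Named integer vector of read counts, sorted by decreasing count
#'   (ties broken lexicographically by barcode).
#' @export
tally_barcodes <- function(cb) {
  if (is.data.frame(cb)) cb <- cb$cb
  if (length(cb) == 0L) stop("no barcodes to tally")
  if (length(unique(nchar(cb))) != 1L) stop("barcodes have mixed lengths")
  tab <- table(cb)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  counts[order(-counts, names(counts))]
}

# local-extrema positions of a density curve, robust to flat (zero) plateaus:
# sign of dy is propagated through flat stretches; a minimum is reported at
# the right edge of its plateau, a maximum at the left edge.
density_extrema <- function(x, y) {
  s <- sign(diff(y))
  n <- length(s)
  for (i in seq_len(n)[-1]) if (s[i] == 0) s[i] <- s[i - 1]
  minima <- integer(0); maxima <- integer(0)
  for (i in seq_len(n - 1)) {
    if (s[i] == -1 && s[i + 1] == 1) minima <- c(minima, i + 1L)
    if (s[i] == 1 && s[i + 1] == -1) maxima <- c(maxima, i + 1L)
  }
  list(minima = x[minima], maxima = x[maxima])
}

#' Find the knee of the barcode frequency distribution
#'
#' Fits a Gaussian kernel density (Scott's-rule bandwidth) to the log10
#' read counts of the distinct barcodes and takes as threshold the count at
#' the largest local minimum of the density below the mode of the
#' high-count component (the rightmost density mode). Barcodes with counts
#' at or above the threshold form the initial whitelist; the split is
#' deliberately liberal and refined later by [classify_ambiguous_barcodes()].
#'
#' When the density has no interior local minimum (unimodal or degenerate
#' count distributions), the threshold falls back to
#' `max(10, 0.01 * max(count))`, capped at `max(count)` so the whitelist is
#' never empty.
#'
#' @param tally named counts from [tally_barcodes()].
#' @return An object of class `whitelist_partition`: a list with `whitelist`,
#'   `erroneous` (the complement), `threshold`, and `method`
#'   (`"kde"` or `"fallback"`).
#' @export
find_knee <- function(tally) {
  if (length(tally) == 0L) stop("empty barcode tally")
  counts <- as.numeric(tally)
  fallback <- function() {
    thr <- min(max(10, 0.01 * max(counts)), max(counts))
    whitelist_partition(tally, thr, method = "fallback")
  }
  lx <- log10(counts)
  if (length(unique(lx)) < 3L) return(fallback())
  d <- tryCatch(stats::density(lx, bw = "nrd", n = 512),
                error = function(e) stats::density(lx, n = 512))
  ext <- density_extrema(d$x, d$y)
  if (length(ext$maxima) == 0L || length(ext$minima) == 0L) return(fallback())
  high_mode <- max(ext$maxima)
  cand <- ext$minima[ext$minima < high_mode]
  if (length(cand) == 0L) return(fallback())
  whitelist_partition(tally, 10^max(cand), method = "kde")
}

#' Partition a barcode tally into whitelist and erroneous sets
#'
#' @param tally named counts from [tally_barcodes()].
#' @param threshold count threshold; barcodes with `count >= threshold`
#'   form the whitelist.
#' @param method how the threshold was obtained (bookkeeping only).
#' @return An object of class `whitelist_partition`.
#' @export
whitelist_partition <- function(tally, threshold, method = "manual") {
  keep <- as.numeric(tally) >= threshold
  if (!any(keep)) stop("threshold leaves the whitelist empty")
  structure(list(whitelist = names(tally)[keep],
                 erroneous = names(tally)[!keep],
                 threshold = threshold, method = method, tally = tally),
            class = "whitelist_partition")
}

#' @export
print.whitelist_partition <- function(x, ...) {
  cat(sprintf(
    "whitelist partition (%s): %d whitelisted, %d erroneous, threshold %.3g\n",
    x$method, length(x$whitelist), length(x$erroneous), x$threshold))
  invisible(x)
}

#' All barcodes within one edit of a barcode
#'
#' Enumerates, for a barcode `w`, every distinct same-length string
#' obtainable by (a) one substitution, (b) one insertion followed by
#' clipping of the terminal base, or (c) one deletion followed by appending
#' a base at the end. `w` itself is never included.
#'
#' @param w a barcode over A/C/G/T.
#' @return Character vector of neighbors.
#' @seealso [one_edit_table()] for the edit-kind attribution used during
#'   correction.
#' @export
one_edit_neighbors <- function(w) {
  unique(one_edit_table(w)$neighbor)
}

#' One-edit neighbors with edit kinds
#'
#' Like [one_edit_neighbors()] but keeps, for each neighbor, the highest
#' priority edit kind that generates it (substitution beats insertion beats
#' deletion), which is the priority used by [correct_barcodes()].
#'
#' @param w a barcode over A/C/G/T.
#' @return data.frame with columns `neighbor`, `kind`.
#' @export
one_edit_table <- function(w) {
  bases <- c("A", "C", "G", "T")
  ch <- strsplit(w, "", fixed = TRUE)[[1]]
  n <- length(ch)
  subs <- character(0); inss <- character(0); dels <- character(0)
  for (i in seq_len(n)) {
    pre <- if (i > 1) paste(ch[seq_len(i - 1)], collapse = "") else ""
    post <- if (i < n) paste(ch[seq(i + 1, n)], collapse = "") else ""
    for (b in bases) {
      if (b != ch[i])  # substitution at i
        subs <- c(subs, paste0(pre, b, post))
      # insertion of b before position i, then clip the terminal base
      ins <- paste0(pre, b, paste(ch[seq(i, n)], collapse = ""))
      inss <- c(inss, substr(ins, 1L, n))
      # deletion of position i, then append b
      dels <- c(dels, paste0(pre, post, b))
    }
  }
  df <- data.frame(
    neighbor = c(subs, inss, dels),
    kind = rep(c("substitution", "insertion", "deletion"),
               c(length(subs), length(inss), length(dels))))
  df <- df[df$neighbor != w, ]
  # one row per neighbor, substitution > insertion > deletion
  df$kind <- factor(df$kind, levels = c("substitution", "insertion",
                                        "deletion"))
  df <- df[order(df$neighbor, df$kind), ]
  df <- df[!duplicated(df$neighbor), ]
  df$kind <- as.character(df$kind)
  rownames(df) <- NULL
  df
}

#' Correct erroneous barcodes to whitelisted labels
#'
#' For each erroneous barcode, collects every whitelisted barcode of which
#' it is a one-edit neighbor. Substitution labels take priority over
#' insertion/deletion labels; remaining ties are broken uniformly at random
#' under `seed`. Barcodes with no candidate are noise and are discarded
#' (label `NA`).
#'
#' @param partition a `whitelist_partition` (from [find_knee()] or
#'   [whitelist_partition()]).
#' @param seed integer seed for the tie-break RNG.
#' @return data.frame of class `correction_map` with columns `barcode`,
#'   `label` (NA = discard), `kind`.
#' @export
correct_barcodes <- function(partition, seed = 1L) {
  stopifnot(inherits(partition, "whitelist_partition"))
  W <- partition$whitelist
  E <- sort(partition$erroneous)
  out <- data.frame(barcode = E, label = rep(NA_character_, length(E)),
                    kind = rep(NA_character_, length(E)))
  class(out) <- c("correction_map", "data.frame")
  if (length(E) == 0L) return(out)
  nb <- rbindlist(lapply(W, function(w) {
    tb <- one_edit_table(w)
    data.table(h = tb$neighbor, label = w, kind = tb$kind)
  }))
  nb <- nb[nb$h %in% E]
  if (nrow(nb) == 0L) return(out)
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  picks <- nb[, {
    cand <- .SD[order(label)]
    if (any(cand$kind == "substitution"))
      cand <- cand[cand$kind == "substitution"]
    j <- if (nrow(cand) == 1L) 1L else sample.int(nrow(cand), 1L)
    list(label = cand$label[j], kind = cand$kind[j])
  }, keyby = "h"]
  m <- match(out$barcode, picks$h)
  hit <- !is.na(m)
  out$label[hit] <- picks$label[m[hit]]
  out$kind[hit] <- picks$kind[m[hit]]
  out
}
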