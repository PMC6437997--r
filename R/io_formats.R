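# On-disk formats: FASTQ pairs, FASTA, t2g, whitelists, MatrixMarket output.
# Coordinates are 0-based half-open throughout (geometry offsets included);
# MTX uses the 1-based indices the MatrixMarket standard mandates.

#' Barcode geometry of read 1
#'
#' Describes where the cell barcode (CB) and UMI live within read 1 of a
#' droplet protocol. Offsets are 0-based; spans are half-open. The default
#' is the 10x Chromium V2 layout: a 16-base CB followed by a 10-base UMI.
#'
#' @param cb_length,umi_length integer lengths in bases (>= 1).
#' @param cb_offset 0-based offset of the CB within read 1.
#' @param umi_offset 0-based offset of the UMI; defaults to immediately
#'   after the CB.
#' @return An object of class `barcode_geometry`.
#' @export
#' @examples
#' barcode_geometry(16, 10)
barcode_geometry <- function(cb_length = 16L, umi_length = 10L,
                             cb_offset = 0L, umi_offset = NULL) {
  cb_length <- as.integer(cb_length)
  umi_length <- as.integer(umi_length)
  cb_offset <- as.integer(cb_offset)
  if (is.null(umi_offset)) umi_offset <- cb_offset + cb_length
  umi_offset <- as.integer(umi_offset)
  if (cb_length < 1L || umi_length < 1L)
    stop("cb_length and umi_length must be >= 1")
  if (cb_offset < 0L || umi_offset < 0L) stop("offsets must be >= 0")
  # half-open spans must not overlap
  cb_end <- cb_offset + cb_length
  umi_end <- umi_offset + umi_length
  if (max(cb_offset, umi_offset) < min(cb_end, umi_end))
    stop("cell-barcode and UMI spans overlap")
  structure(list(cb_length = cb_length, umi_length = umi_length,
                 cb_offset = cb_offset, umi_offset = umi_offset,
                 min_r1_length = max(cb_end, umi_end)),
            class = "barcode_geometry")
}

#' @export
print.barcode_geometry <- function(x, ...) {
  cat(sprintf("barcode geometry: CB %d bp @%d, UMI %d bp @%d (0-based)\n",
              x$cb_length, x$cb_offset, x$umi_length, x$umi_offset))
  invisible(x)
}

# gzip is detected by magic bytes, never by extension
is_gzip <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 2L)
  length(magic) == 2L && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b)
}

#' Read a demultiplexed FASTQ pair and extract barcode, UMI and cDNA
#'
#' Read 1 carries the cell barcode and UMI (per `geometry`); read 2 carries
#' the cDNA sequence. Records are returned in file order. Records whose CB
#' or UMI contains an ambiguous base (N) are flagged via `has_n`; callers
#' normally discard those before tallying.
#'
#' @param path_r1,path_r2 FASTQ files (plain or gzip, detected by content).
#' @param geometry a [barcode_geometry()].
#' @return A `data.frame` with columns `cb`, `umi`, `cdna`, `has_n`.
#' @export
read_fastq_pairs <- function(path_r1, path_r2, geometry = barcode_geometry()) {
  stopifnot(inherits(geometry, "barcode_geometry"))
  r1 <- tryCatch(Biostrings::readDNAStringSet(path_r1, format = "fastq"),
                 error = function(e) stop("malformed FASTQ in ", path_r1,
                                          ": ", conditionMessage(e)))
  r2 <- tryCatch(Biostrings::readDNAStringSet(path_r2, format = "fastq"),
                 error = function(e) stop("malformed FASTQ in ", path_r2,
                                          ": ", conditionMessage(e)))
  if (length(r1) != length(r2))
    stop(sprintf("mismatched record counts: %d in read 1, %d in read 2",
                 length(r1), length(r2)))
  if (length(r1) == 0L)
    return(data.frame(cb = character(0), umi = character(0),
                      cdna = character(0), has_n = logical(0)))
  w <- Biostrings::width(r1)
  bad <- which(w < geometry$min_r1_length)
  if (length(bad))
    stop("read 1 record ", bad[1], " is shorter (", w[bad[1]],
         " bp) than the barcode geometry requires (",
         geometry$min_r1_length, " bp)")
  s1 <- as.character(r1)
  cbs <- substr(s1, geometry$cb_offset + 1L,
                geometry$cb_offset + geometry$cb_length)
  umis <- substr(s1, geometry$umi_offset + 1L,
                 geometry$umi_offset + geometry$umi_length)
  data.frame(cb = cbs, umi = umis, cdna = as.character(r2),
             has_n = grepl("N", cbs, fixed = TRUE) |
                     grepl("N", umis, fixed = TRUE),
             row.names = NULL)
}

#' Write a FASTQ file (constant qualities)
#'
#' @param seqs named character vector of sequences (names become record ids).
#' @param path output path; compressed when `compress = TRUE`.
#' @param compress write gzip output.
#' @export
write_fastq <- function(seqs, path, compress = FALSE) {
  x <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(x))) names(x) <- sprintf("read%d", seq_along(x))
  q <- Biostrings::BStringSet(strrep("I", Biostrings::width(x)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q,
                              compress = compress)
  invisible(path)
}

#' Read a transcriptome FASTA
#'
#' @param path FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_transcriptome <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  if (anyDuplicated(names(x))) stop("duplicate transcript ids in ", path)
  setNames(toupper(as.character(x)), names(x))
}

#' Write a transcriptome FASTA
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @export
write_transcriptome <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a transcript-to-gene map (2-column TSV, no header)
#'
#' @param path TSV with columns transcript id, gene id.
#' @return Named character vector: gene id named by transcript id.
#' @export
read_t2g <- function(path) {
  con <- if (is_gzip(path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  df <- read.table(con, sep = "\t", header = FALSE,
                   colClasses = "character", quote = "")
  if (ncol(df) < 2L) stop("t2g file must have two tab-separated columns")
  if (anyDuplicated(df[[1]]))
    stop("transcript id(s) mapped more than once in ", path)
  setNames(df[[2]], df[[1]])
}

#' Write a transcript-to-gene map
#' @param t2g named character vector (gene named by transcript).
#' @param path output path.
#' @export
write_t2g <- function(t2g, path) {
  write.table(data.frame(names(t2g), unname(t2g)), path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a barcode whitelist (one barcode per line)
#'
#' Duplicates are collapsed; mixed barcode lengths or an empty file are
#' errors.
#'
#' @param path whitelist file (plain or gzip).
#' @return Character vector of unique barcodes.
#' @export
read_whitelist <- function(path) {
  con <- if (is_gzip(path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  x <- trimws(readLines(con))
  x <- x[nzchar(x)]
  if (length(x) == 0L) stop("empty whitelist file: ", path)
  if (length(unique(nchar(x))) != 1L)
    stop("whitelist barcodes have mixed lengths in ", path)
  unique(x)
}

#' Write a barcode whitelist
#' @param barcodes character vector.
#' @param path output path.
#' @export
write_whitelist <- function(barcodes, path) {
  writeLines(barcodes, path)
  invisible(path)
}

#' Quantification result container
#'
#' Bundles the cells-by-genes molecule count matrix, the evidence tier
#' matrix (integers 0-3, same dimensions) and an optional bootstrap
#' variance matrix. Rows are cell barcodes, columns gene ids. Tier 0
#' entries must have count 0 (no read evidence).
#'
#' @param counts numeric matrix or sparse Matrix, cells x genes,
#'   non-negative (EM yields fractional counts).
#' @param tiers integer matrix in \{0,1,2,3\}, same dimensions.
#' @param variance optional non-negative matrix, same dimensions.
#' @return An object of class `quant_output`.
#' @export
quant_output <- function(counts, tiers, variance = NULL) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have cell-barcode rownames and gene colnames")
  tiers <- as.matrix(tiers)
  storage.mode(tiers) <- "integer"
  if (!identical(dim(counts), dim(tiers)))
    stop("counts and tiers dimensions differ")
  if (any(!tiers %in% 0:3)) stop("tiers must be integers in 0..3")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts[tiers == 0L] != 0))
    stop("tier-0 entries must have zero counts")
  if (!is.null(variance)) {
    variance <- methods::as(methods::as(Matrix::Matrix(variance, sparse = TRUE),
                                        "generalMatrix"), "CsparseMatrix")
    if (!identical(dim(variance), dim(counts)))
      stop("variance dimensions differ from counts")
    if (any(variance < 0)) stop("variance must be non-negative")
  }
  structure(list(counts = counts, tiers = tiers, variance = variance),
            class = "quant_output")
}

#' @export
print.quant_output <- function(x, ...) {
  cat(sprintf("quant_output: %d cells x %d genes, %.1f molecules total%s\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts),
              if (is.null(x$variance)) "" else ", with bootstrap variance"))
  invisible(x)
}

#' Write quantification results to a directory
#'
#' Counts go to MatrixMarket coordinate format (`quants_mat.mtx`) with the
#' cell barcodes in `quants_mat_rows.txt` and gene ids in
#' `quants_mat_cols.txt`; tiers to a dense TSV (`quants_tier_mat.tsv`);
#' the variance matrix, when present, to `quants_var_mat.mtx`.
#'
#' @param quant a [quant_output()].
#' @param dir output directory (created if absent).
#' @export
write_quant <- function(quant, dir) {
  stopifnot(inherits(quant, "quant_output"))
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", dir)
  # re-validate the tier invariant on write
  if (any(!quant$tiers %in% 0:3)) stop("tiers must be integers in 0..3")
  Matrix::writeMM(quant$counts, file.path(dir, "quants_mat.mtx"))
  writeLines(rownames(quant$counts), file.path(dir, "quants_mat_rows.txt"))
  writeLines(colnames(quant$counts), file.path(dir, "quants_mat_cols.txt"))
  tier_df <- as.data.frame(quant$tiers)
  write.table(tier_df, file.path(dir, "quants_tier_mat.tsv"), sep = "\t",
              quote = FALSE, row.names = TRUE, col.names = NA)
  if (!is.null(quant$variance))
    Matrix::writeMM(quant$variance, file.path(dir, "quants_var_mat.mtx"))
  invisible(dir)
}

#' Read quantification results written by [write_quant()]
#' @param dir directory containing the output files.
#' @return A [quant_output()].
#' @export
read_quant <- function(dir) {
  counts <- as(Matrix::readMM(file.path(dir, "quants_mat.mtx")),
               "CsparseMatrix")
  rn <- readLines(file.path(dir, "quants_mat_rows.txt"))
  cn <- readLines(file.path(dir, "quants_mat_cols.txt"))
  dimnames(counts) <- list(rn, cn)
  tiers <- as.matrix(read.table(file.path(dir, "quants_tier_mat.tsv"),
                                sep = "\t", header = TRUE, row.names = 1,
                                check.names = FALSE))
  variance <- NULL
  vp <- file.path(dir, "quants_var_mat.mtx")
  if (file.exists(vp)) {
    variance <- as(Matrix::readMM(vp), "CsparseMatrix")
    dimnames(variance) <- dimnames(counts)
  }
  quant_output(counts, tiers, variance)
}
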