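make_tally <- function(n_above, n_below, above_count = 100L,
                       below_count = 10L) {
  n <- n_above + n_below
  bcs <- sprintf("BC%06d", seq_len(n))
  setNames(rep(c(above_count, below_count), c(n_above, n_below)), bcs)
}

test_that("region split sizes follow the n_l = max(0.2|H|, 1000) rule", {
  r <- split_regions(make_tally(4000, 3000), threshold = 50)
  expect_length(r$high, 2000L)
  expect_length(r$ambiguous, 2000L)
  expect_equal(r$n_l, 1000L)
  r2 <- split_regions(make_tally(12000, 3000), threshold = 50)
  expect_length(r2$high, 6000L)
  expect_equal(r2$n_l, 1200L)
  # fewer below-knee barcodes than requested: use all, warn
  expect_warning(r3 <- split_regions(make_tally(4000, 200), threshold = 50),
                 "below the knee")
  expect_equal(r3$n_l, 200L)
  expect_error(split_regions(make_tally(10, 10), threshold = 1e6),
               "no barcodes above")
})

test_that("region split is deterministic with count-then-lexicographic order", {
  tal <- setNames(c(9L, 9L, 7L, 3L, 1L), c("CC", "AA", "GG", "TT", "AT"))
  r <- suppressWarnings(split_regions(tal, threshold = 5))
  expect_equal(r$high, c("AA", "CC"))
  expect_equal(r$ambiguous, "GG")
  expect_equal(r$low, c("TT", "AT"))
})

test_that("features compute mapped fraction, duplication rate and mean gene count", {
  counts <- rbind(c1 = c(g1 = 25, g2 = 15), c2 = c(g1 = 10, g2 = 0))
  stats <- data.frame(barcode = c("c1", "c2"),
                      reads_total = c(120L, 10L),
                      reads_mapped = c(100L, 10L))
  f <- extract_features(counts, stats)
  # 100 mapped reads, 40 molecules -> duplication rate 0.6
  expect_equal(f["c1", "dup_rate"], 0.6)
  expect_equal(f["c1", "mapped_frac"], 100 / 120)
  expect_equal(f["c1", "mean_gene"], 20)
  # every mapped read its own molecule -> duplication rate 0
  expect_equal(f["c2", "dup_rate"], 0)
  # zero-mapped cells are flagged with zero features
  stats0 <- data.frame(barcode = "c0", reads_total = 0L, reads_mapped = 0L)
  f0 <- extract_features(matrix(0, 1, 2, dimnames = list("c0", c("g1", "g2"))),
                         stats0)
  expect_true(f0$flagged)
  expect_equal(unlist(f0[1, c("mapped_frac", "dup_rate", "mean_gene")]),
               c(mapped_frac = 0, dup_rate = 0, mean_gene = 0))
})

test_that("a cell identical to a high-quality cell has max correlation 1", {
  counts <- rbind(h1 = c(5, 0, 2, 7), h2 = c(1, 1, 0, 0),
                  a1 = c(5, 0, 2, 7), a2 = c(0, 3, 0, 1))
  colnames(counts) <- sprintf("g%d", 1:4)
  stats <- data.frame(barcode = rownames(counts),
                      reads_total = rep(50L, 4), reads_mapped = rep(40L, 4))
  f <- extract_features(counts, stats, high_cells = c("h1", "h2"),
                        use_correlation = TRUE)
  expect_equal(f["a1", "max_cor"], 1)
  expect_lte(f["a2", "max_cor"], 1)
})

test_that("naive Bayes recovers centroid labels and keeps H in the whitelist", {
  set.seed(3)
  n <- 100
  mk <- function(mu, ids) {
    X <- data.frame(f1 = rnorm(n, mu), f2 = rnorm(n, mu))
    rownames(X) <- ids
    X
  }
  fh <- mk(5, sprintf("h%03d", 1:n))
  fl <- mk(0, sprintf("l%03d", 1:n))
  fa <- data.frame(f1 = c(5, 0), f2 = c(5, 0))
  rownames(fa) <- c("amb_high", "amb_low")
  cls <- classify_ambiguous_barcodes(fh, fl, fa)
  expect_true("amb_high" %in% cls$whitelist)
  expect_false("amb_low" %in% cls$whitelist)
  expect_true(all(rownames(fh) %in% cls$whitelist))
})

test_that("classification agrees with the Bayes rule and e1071 on separated Gaussians", {
  set.seed(31)
  n <- 300
  p <- 3
  # two classes separated by 4 sigma in every feature
  Xh <- matrix(rnorm(n * p, 4), ncol = p)
  Xl <- matrix(rnorm(n * p, 0), ncol = p)
  colnames(Xh) <- colnames(Xl) <- sprintf("f%d", 1:p)
  rownames(Xh) <- sprintf("h%03d", 1:n)
  rownames(Xl) <- sprintf("l%03d", 1:n)
  # test points from the same mixture (half high, half low depth)
  na <- 200
  Xa <- rbind(matrix(rnorm(na / 2 * p, 4), ncol = p),
              matrix(rnorm(na / 2 * p, 0), ncol = p))
  colnames(Xa) <- colnames(Xh)
  rownames(Xa) <- sprintf("a%03d", 1:na)
  cls <- classify_ambiguous_barcodes(as.data.frame(Xh), as.data.frame(Xl),
                                     as.data.frame(Xa))
  # Bayes-optimal rule under the generating parameters (equal priors,
  # unit variance): classify high when sum(x) > p * 2
  bayes <- rowSums(Xa) > p * 2
  agreement <- mean((cls$posterior >= 0.5) == bayes)
  expect_gte(agreement, 0.99)
  # recall of true cells placed in the ambiguous region
  expect_gte(mean(cls$posterior[1:(na / 2)] >= 0.5), 0.9)
  skip_if_not_installed("e1071")
  fit <- e1071::naiveBayes(data.frame(rbind(Xh, Xl)),
                           factor(rep(c("high", "low"), each = n)))
  pred <- predict(fit, data.frame(Xa))
  expect_gte(mean((cls$posterior >= 0.5) == (pred == "high")), 0.995)
})

test_that("constant features are handled by variance smoothing", {
  fh <- data.frame(f1 = rep(1, 10), f2 = rnorm(10, 5))
  fl <- data.frame(f1 = rep(1, 10), f2 = rnorm(10, 0))
  rownames(fh) <- sprintf("h%d", 1:10)
  rownames(fl) <- sprintf("l%d", 1:10)
  fa <- data.frame(f1 = 1, f2 = 5)
  rownames(fa) <- "a1"
  cls <- classify_ambiguous_barcodes(fh, fl, fa)
  expect_true("a1" %in% cls$whitelist)
})
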