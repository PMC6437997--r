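test_that("barcode tallying counts multiplicities and ignores order", {
  expect_equal(tally_barcodes(c("AAAA", "AAAA", "CCCC")),
               c(AAAA = 2L, CCCC = 1L))
  set.seed(1)
  cb <- sample(rep(c("AAAA", "CCCC", "GGGG"), c(5, 3, 1)))
  expect_equal(tally_barcodes(cb), tally_barcodes(rev(cb)))
  expect_error(tally_barcodes(character(0)), "no barcodes")
  expect_error(tally_barcodes(c("AAAA", "CCC")), "mixed lengths")
})

test_that("tally matches simulator per-barcode read truth", {
  cfg <- closed_loop_config(seed = 3, n_cells = 5, n_genes = 8,
                            n_ambient_barcodes = 20, molecules_per_cell = 20)
  sim <- simulate_reads(cfg)
  p <- sim_paths(sim)
  recs <- read_fastq_pairs(p$r1, p$r2,
                           barcode_geometry(cfg$cb_length, cfg$umi_length))
  tal <- tally_barcodes(recs$cb)
  truth <- table(sim$truth$reads$cb)
  expect_equal(as.integer(tal[names(truth)]), as.integer(truth),
               ignore_attr = TRUE)
})

test_that("knee handles degenerate tallies via the fallback branch", {
  one <- setNames(5L, "ACGT")
  p1 <- find_knee(one)
  expect_equal(p1$whitelist, "ACGT")
  flat <- setNames(rep(7L, 50), all_strings(3)[1:50])
  pf <- find_knee(flat)
  expect_equal(pf$method, "fallback")
  expect_setequal(pf$whitelist, names(flat))
})

test_that("knee recovers the real-cell mode on a bimodal tally", {
  bt <- simulate_barcode_tally(seed = 2)
  part <- find_knee(bt$tally)
  expect_equal(part$method, "kde")
  expect_lte(abs(length(part$whitelist) - 100L), 2L)
  expect_gte(length(intersect(part$whitelist, bt$real)), 98L)
  # partition invariants
  expect_setequal(c(part$whitelist, part$erroneous), names(bt$tally))
  expect_length(intersect(part$whitelist, part$erroneous), 0L)
  expect_true(all(bt$tally[part$whitelist] >= part$threshold))
})

test_that("one-edit neighborhoods match the brute-force edit predicates", {
  expect_setequal(one_edit_neighbors("A"), c("C", "G", "T"))
  w <- "ACGT"
  nbs <- one_edit_neighbors(w)
  expect_false(w %in% nbs)
  oracle <- Filter(function(x) {
    is_one_substitution(w, x) || is_insertion_clip(w, x) ||
      is_deletion_append(w, x)
  }, setdiff(all_strings(4), w))
  expect_setequal(nbs, oracle)
})

test_that("correction prefers substitutions, discards distance-2 noise, and is deterministic", {
  tal <- setNames(c(100L, 100L, 1L, 1L),
                  c("AAAA", "AACC", "AAAT", "GGTT"))
  part <- whitelist_partition(tal, 50)
  cm <- correct_barcodes(part, seed = 7)
  # unique substitution candidate
  expect_equal(cm$label[cm$barcode == "AAAT"], "AAAA")
  expect_equal(cm$kind[cm$barcode == "AAAT"], "substitution")
  # distance >= 2 from every whitelisted barcode: noise
  expect_true(is.na(cm$label[cm$barcode == "GGTT"]))
  # substitution label beats an indel label: AAAT is a substitution
  # neighbor of AAAA and a deletion(+append) neighbor of TAAA
  expect_true(is_deletion_append("TAAA", "AAAT"))
  tal3 <- setNames(c(50L, 50L, 1L), c("AAAA", "TAAA", "AAAT"))
  part3 <- whitelist_partition(tal3, 10)
  cm3 <- correct_barcodes(part3, seed = 1)
  expect_equal(cm3$kind[cm3$barcode == "AAAT"], "substitution")
  expect_equal(cm3$label[cm3$barcode == "AAAT"], "AAAA")
  # determinism under a fixed seed
  expect_identical(correct_barcodes(part, seed = 7),
                   correct_barcodes(part, seed = 7))
  # every corrected barcode is a one-edit neighbor of its label
  hit <- !is.na(cm$label)
  expect_true(all(mapply(function(h, w) h %in% one_edit_neighbors(w),
                         cm$barcode[hit], cm$label[hit])))
})

test_that("indel labels are used when no substitution candidate exists", {
  # h = shift of w: w = AAAACC, h = AAACCA arises by deletion of one A and
  # appending A? deletion at pos 1 of AAAACC -> AAACC + A = AAACCA: yes
  tal <- setNames(c(50L, 1L), c("AAAACC", "AAACCA"))
  part <- whitelist_partition(tal, 10)
  cm <- correct_barcodes(part, seed = 1)
  expect_equal(cm$label[cm$barcode == "AAACCA"], "AAAACC")
  expect_true(cm$kind[cm$barcode == "AAACCA"] %in% c("insertion", "deletion"))
})

test_that("nearly all error-bearing reads are reassigned to their barcode of origin", {
  set.seed(11)
  wl <- dropquant:::sample_separated_barcodes(20, 16)
  reads <- rep(wl, each = 500)
  origin <- reads
  err <- which(runif(length(reads)) < 0.01)
  for (i in err) {
    p <- sample.int(16, 1)
    ch <- substr(reads[i], p, p)
    substr(reads[i], p, p) <- sample(setdiff(c("A", "C", "G", "T"), ch), 1)
  }
  tal <- tally_barcodes(reads)
  part <- whitelist_partition(tal, threshold = 250)
  cm <- correct_barcodes(part, seed = 1)
  lab <- setNames(cm$label, cm$barcode)
  changed <- err[reads[err] != origin[err]]
  frac <- mean(lab[reads[changed]] == origin[changed], na.rm = FALSE)
  expect_gte(frac, 0.99)
})
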