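test_that("edge predicates follow the count, overlap and Hamming rules", {
  # c_i > 2 c_j - 1 with overlap and Hamming 1: directed edge
  p1 <- build_pug(c("ACGT", "ACGA"), list("t1", "t1"), c(5L, 1L))
  expect_equal(p1$edges_dir, matrix(c(1L, 2L), ncol = 2))
  expect_equal(nrow(p1$edges_bi), 0L)
  # near-tie counts: bi-directed (3 > 3 fails both ways)
  p2 <- build_pug(c("ACGT", "ACGA"), list("t1", "t1"), c(3L, 2L))
  expect_equal(nrow(p2$edges_dir), 0L)
  expect_equal(p2$edges_bi, matrix(c(1L, 2L), ncol = 2))
  # disjoint transcript sets: no edge at all
  p3 <- build_pug(c("ACGT", "ACGA"), list("t1", "t2"), c(5L, 1L))
  expect_equal(nrow(p3$edges_dir) + nrow(p3$edges_bi), 0L)
  # Hamming 0 (same UMI, different classes, shared transcript): bi-directed
  p4 <- build_pug(c("ACGT", "ACGT"), list(c("t1", "t2"), "t2"), c(2L, 3L))
  expect_equal(p4$edges_bi, matrix(c(1L, 2L), ncol = 2))
  # Hamming 2: no edge
  p5 <- build_pug(c("ACGT", "TCGA"), list("t1", "t1"), c(5L, 1L))
  expect_equal(nrow(p5$edges_dir) + nrow(p5$edges_bi), 0L)
  expect_error(build_pug(c("ACGT", "ACG"), list("t1", "t1"), c(1L, 1L)),
               "UMI lengths")
  expect_error(build_pug(c("ACGT", "ACGT"), list("t1", "t1"), c(1L, 1L)),
               "duplicate")
})

test_that("UMI collision worked examples resolve as expected", {
  t2g <- c(t1 = "G1", t2 = "G2")
  # same UMI tagging transcripts of two different genes: two molecules
  pa <- build_pug(c("AAAA", "AAAA"), list("t1", "t2"), c(3L, 2L))
  cva <- greedy_cover(pa)
  expect_length(cva, 2L)
  lab <- label_arborescences(cva, t2g)
  expect_equal(lab$unique, c(G1 = 1, G2 = 1))
  # one molecule per transcript of one gene, distant UMIs, disjoint classes:
  # both the PUG and the naive per-class method report two molecules
  t2g_same <- c(t1 = "G1", t2 = "G1")
  pb <- build_pug(c("AAAA", "TTTT"), list("t1", "t2"), c(2L, 2L))
  expect_length(greedy_cover(pb), 2L)
  expect_equal(naive_eqclass_count(c("AAAA", "TTTT"), list("t1", "t2"),
                                   c(2L, 2L), t2g_same)$total, 2L)
  # one UMI shared across classes {t1,t2} and {t2}: one molecule under the
  # PUG covering, while the per-class counter reports two
  pc <- build_pug(c("AAAA", "AAAA"), list(c("t1", "t2"), "t2"), c(2L, 3L))
  cvc <- greedy_cover(pc)
  expect_length(cvc, 1L)
  expect_equal(cvc[[1]]$feasible, "t2")
  expect_equal(naive_eqclass_count(c("AAAA", "AAAA"),
                                   list(c("t1", "t2"), "t2"),
                                   c(2L, 3L), t2g_same)$total, 2L)
})

test_that("greedy covering handles simple chains and components", {
  # single vertex
  p <- build_pug("AAAA", list("t1"), 4L)
  expect_length(greedy_cover(p), 1L)
  # 3-vertex bi-directed path, all same transcript: one arborescence,
  # confirmed minimal by the exact solver
  p3 <- build_pug(c("AAAA", "AAAT", "AATT"), list("t1", "t1", "t1"),
                  c(2L, 2L, 2L))
  expect_equal(nrow(p3$edges_bi), 2L)
  cv <- greedy_cover(p3)
  expect_length(cv, 1L)
  expect_equal(brute_force_cover(p3), 1L)
  # empty graph
  expect_length(greedy_cover(build_pug(character(0), list(), integer(0))), 0L)
  expect_equal(brute_force_cover(build_pug(character(0), list(), integer(0))), 0L)
  # two isolated vertices
  iso <- build_pug(c("AAAA", "GGGG"), list("t1", "t1"), c(1L, 1L))
  expect_equal(brute_force_cover(iso), 2L)
  expect_length(greedy_cover(iso), 2L)
})

test_that("bi-directed single-color components collapse to one arborescence per component", {
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(2:7, 1)
    # UMIs along a Hamming-1 path with equal counts: all edges bi-directed
    base <- rep("A", 8)
    umis <- vapply(seq_len(n), function(i) {
      v <- base
      if (i > 1) v[seq_len(i - 1)] <- "C"
      paste(v, collapse = "")
    }, character(1))
    p <- build_pug(umis, replicate(n, "t1", simplify = FALSE),
                   rep(2L, n))
    expect_equal(nrow(p$edges_dir), 0L)
    expect_length(greedy_cover(p), 1L)
  }
})

test_that("greedy coverings are valid and never beat the exact minimum", {
  set.seed(33)
  n_match <- 0L
  N <- 150L
  for (i in seq_len(N)) {
    p <- rand_pug()
    cv <- greedy_cover(p)
    expect_no_error(validate_covering(p, cv))
    bf <- brute_force_cover(p)
    expect_gte(length(cv), bf)
    if (length(cv) == bf) n_match <- n_match + 1L
  }
  expect_gte(n_match / N, 0.9)
})

test_that("each greedy iteration removes at least one vertex (termination)", {
  set.seed(44)
  for (i in 1:20) {
    p <- rand_pug()
    cv <- greedy_cover(p)
    expect_true(all(lengths(lapply(cv, `[[`, "vertices")) >= 1L))
    expect_equal(sum(lengths(lapply(cv, `[[`, "vertices"))),
                 length(p$umi))
  }
})

test_that("covering the dominating-set reduction recovers the dominating number", {
  set.seed(55)
  for (rep in 1:20) {
    inst <- rand_domset_instance()
    expect_equal(brute_force_cover(inst$pug), min_dominating_set(inst$adj))
  }
})

test_that("PUG molecule counts match directional clustering on single-transcript genes", {
  n_eq <- 0L
  N <- 40L
  for (g in seq_len(N)) {
    gi <- simulate_gene_umis(seed = 500 + g)
    cnt <- gi$counts
    p <- build_pug(names(cnt),
                   replicate(length(cnt), "t1", simplify = FALSE), cnt)
    if (length(greedy_cover(p)) == dedup_directional(cnt)) n_eq <- n_eq + 1L
  }
  expect_equal(n_eq, N)
})

test_that("arborescence labels split unique and gene-ambiguous molecules", {
  t2g <- c(t1 = "gA", t2 = "gA", t3 = "gB")
  # feasible {t1}: unique gA
  cv <- structure(list(list(root = 1L, label = "t1", vertices = 1L,
                            feasible = "t1")), class = "pug_covering")
  expect_equal(label_arborescences(cv, t2g)$unique, c(gA = 1))
  # feasible {t1,t2}, same gene: still unique gA
  cv2 <- structure(list(list(root = 1L, label = "t1", vertices = 1L,
                             feasible = c("t1", "t2"))),
                   class = "pug_covering")
  expect_equal(label_arborescences(cv2, t2g)$unique, c(gA = 1))
  # feasible spans gA and gB: ambiguous
  cv3 <- structure(list(list(root = 1L, label = "t2", vertices = 1L,
                             feasible = c("t2", "t3"))),
                   class = "pug_covering")
  lab3 <- label_arborescences(cv3, t2g)
  expect_length(lab3$unique, 0L)
  expect_equal(lab3$ambiguous, list(c("gA", "gB")))
})
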