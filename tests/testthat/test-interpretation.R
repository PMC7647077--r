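test_that("sample splits follow rank, median and tie-break contracts", {
  sc <- setNames(as.numeric(1:10), sprintf("s%02d", 1:10))
  sp <- split_samples(sc, "top_bottom_N", N = 2)
  expect_identical(sort(sp$high_ids), c("s09", "s10"))
  expect_identical(sort(sp$low_ids), c("s01", "s02"))
  spm <- split_samples(sc, "median")
  expect_identical(sort(spm$high_ids), sprintf("s%02d", 6:10))
  expect_identical(sort(spm$low_ids), sprintf("s%02d", 1:5))
  # boundary ties resolved by ascending sample ID, reproducibly
  tied <- setNames(c(1, 2, 2, 2, 3, 4), paste0("s", 1:6))
  spt <- split_samples(tied, "top_bottom_N", N = 2)
  expect_identical(spt$high_ids, c("s6", "s5"))
  expect_identical(spt$low_ids, c("s1", "s2"))
  expect_identical(split_samples(tied, "top_bottom_N", N = 2)$low_ids,
                   spt$low_ids)
  expect_error(split_samples(sc, "top_bottom_N", N = 6), "<= n/2")
  expect_warning(split_samples(setNames(rep(1, 4), paste0("s", 1:4)), "median"),
                 "degenerate split")
  # partition properties
  expect_identical(sort(c(spm$high_ids, spm$low_ids)), sort(names(sc)))
  expect_length(c(spt$high_ids, spt$low_ids), 4L)
})

test_that("binary adjacency is the union of nonzero edges over samples", {
  co <- array(0, c(2, 3, 4))
  nt <- mk_tensor(co)
  A0 <- binary_adjacency(nt, nt$sample_ids)
  expect_true(all(A0 == 0))
  co[2, 1, 3] <- 0.7
  nt1 <- mk_tensor(co)
  A1 <- binary_adjacency(nt1, nt1$sample_ids)
  expect_identical(sum(A1), 1L)
  expect_identical(A1["T02", "R01"], 1L)
  # random sparse tensor equals the elementwise OR oracle
  set.seed(1)
  co2 <- array(rbinom(5 * 4 * 6, 1, 0.2) * rnorm(120), c(5, 4, 6))
  nt2 <- mk_tensor(co2)
  keep <- c("S02", "S05")
  A2 <- binary_adjacency(nt2, keep)
  or_oracle <- (co2[, , 2] != 0) | (co2[, , 5] != 0)
  expect_identical(A2[nt2$target_ids, nt2$regulator_ids],
                   array(as.integer(or_oracle), dim(or_oracle),
                         dimnames = list(nt2$target_ids, nt2$regulator_ids)))
  expect_error(binary_adjacency(nt2, "nope"), "unknown sample")
  expect_error(binary_adjacency(nt2, character(0)), "nonempty")
})

test_that("differential edge scores count incident differing edges once", {
  co <- array(0, c(3, 3, 2))
  nt <- mk_tensor(co, target_ids = c("a", "b", "c"),
                  regulator_ids = c("a", "b", "c"))
  A <- binary_adjacency(nt, "S01")
  expect_identical(unname(differential_edge_score(A, A)),
                   rep(0, 3))
  B <- A; B["b", "a"] <- 1L
  sc <- differential_edge_score(A, B)
  expect_identical(sc[c("a", "b", "c")], c(a = 1, b = 1, c = 0))
  # symmetry and brute-force count on random pairs
  set.seed(2)
  for (rep in 1:5) {
    A1 <- matrix(rbinom(36, 1, 0.4), 6, 6,
                 dimnames = list(letters[1:6], letters[1:6]))
    A2 <- matrix(rbinom(36, 1, 0.4), 6, 6, dimnames = dimnames(A1))
    s12 <- differential_edge_score(A1, A2)
    expect_identical(s12, differential_edge_score(A2, A1))
    loop <- setNames(numeric(6), letters[1:6])
    for (i in 1:6) for (j in 1:6) {
      if (i == j) next
      if (A1[i, j] != A2[i, j]) {
        loop[i] <- loop[i] + 1
        loop[j] <- loop[j] + 1
      }
    }
    expect_equal(s12, loop)
  }
  expect_error(differential_edge_score(A1, A1[1:5, 1:5]), "gene universe")
})

test_that("top-k marker extraction is ordered and tie-broken by gene ID", {
  sc <- c(g3 = 5, g1 = 2, g2 = 5, g4 = 0, g5 = 1)
  expect_identical(top_k_markers(sc, 3), c("g2", "g3", "g1"))
  expect_identical(top_k_markers(setNames(rep(1, 4), c("d", "b", "a", "c")), 2),
                   c("a", "b"))
  expect_identical(top_k_markers(sc, 5), c("g2", "g3", "g1", "g5", "g4"))
  expect_error(top_k_markers(sc, 6), "exceeds")
})

test_that("target network expansion walks the declared number of hops", {
  # chain a -> b -> c (a regulates b, b regulates c)
  co <- array(0, c(3, 3, 1))
  co[2, 1, 1] <- 1    # b regulated by a
  co[3, 2, 1] <- 1    # c regulated by b
  nt <- mk_tensor(co, target_ids = c("a", "b", "c"),
                  regulator_ids = c("a", "b", "c"))
  el <- expand_target_network("a", nt, "S01", hops = 2)
  expect_identical(el$from, c("a", "b"))
  expect_identical(el$to, c("b", "c"))
  expect_identical(el$hop, c(1L, 2L))
  # isolated seed: empty edge list
  expect_identical(nrow(expand_target_network("c", nt, "S01", hops = 2)), 0L)
  expect_error(expand_target_network(character(0), nt, "S01"), "nonempty")
  expect_error(expand_target_network("zz", nt, "S01"), "not in universe")
  # random DAG: reached node set equals a BFS truncated at depth 2
  set.seed(3)
  co2 <- array(0, c(8, 8, 2))
  for (s in 1:2) co2[, , s] <- matrix(rbinom(64, 1, 0.15), 8, 8) *
    lower.tri(matrix(1, 8, 8))
  ids <- sprintf("g%d", 1:8)
  nt2 <- mk_tensor(co2, target_ids = ids, regulator_ids = ids)
  el2 <- expand_target_network("g1", nt2, nt2$sample_ids, hops = 2)
  A <- binary_adjacency(nt2, nt2$sample_ids)
  lvl1 <- rownames(A)[A[, "g1"] == 1]
  lvl2 <- unique(unlist(lapply(lvl1, function(g) rownames(A)[A[, g] == 1])))
  bfs_nodes <- if (length(lvl1) == 0) character(0) else
    Reduce(union, list("g1", lvl1, setdiff(lvl2, "g1")))
  expect_setequal(unique(c(el2$from, el2$to)), bfs_nodes)
})

test_that("regulatory effects are coefficient times regulator expression", {
  set.seed(4)
  co <- array(rnorm(3 * 2 * 4) * rbinom(24, 1, 0.5), c(3, 2, 4))
  nt <- mk_tensor(co)
  vals <- matrix(rnorm(5 * 4), 5, 4)
  data <- expression_dataset(vals,
                             gene_ids = c(nt$target_ids, nt$regulator_ids),
                             roles = c(rep("target", 3), rep("regulator", 2)),
                             modulator = nt$modulator,
                             sample_ids = nt$sample_ids)
  re <- regulatory_effect(nt, data)
  X <- vals[4:5, ]
  for (l in 1:3) for (j in 1:2) for (a in 1:4)
    expect_equal(re[l, j, a], co[l, j, a] * X[j, a])
  expect_true(all(re[co == 0] == 0))
  data2 <- data; data2$sample_ids <- rev(data2$sample_ids)
  expect_error(regulatory_effect(nt, data2), "misaligned")
})

test_that("REC is the exact per-edge range of regulatory effects", {
  re <- array(0, c(2, 2, 3))
  re[1, 1, ] <- c(-1, 2, 0.5)
  re[2, 2, ] <- 4
  rc <- rec(re)
  expect_equal(rc[1, 1], 3)
  expect_equal(rc[2, 2], 0)      # constant over samples
  expect_equal(rc[1, 2], 0)
  set.seed(5)
  re2 <- array(rnorm(5 * 4 * 7), c(5, 4, 7))
  rc2 <- rec(re2)
  for (l in 1:5) for (j in 1:4)
    expect_equal(rc2[l, j], max(re2[l, j, ]) - min(re2[l, j, ]))
  expect_true(all(rc2 >= 0))
})

test_that("mean RE summaries average and prune exact cancellations", {
  re <- array(0, c(2, 1, 4))
  re[1, 1, ] <- c(1, -1, 2, -2)   # symmetric: exact zero mean
  re[2, 1, ] <- c(1, 2, 3, 4)
  M <- mean_re_summary(re, 1:4, prune_zero_mean = TRUE)
  expect_true(is.na(M[1, 1]))
  expect_equal(M[2, 1], 2.5)
  expect_equal(mean_re_summary(re, 2)[2, 1], 2)   # singleton mean
  set.seed(6)
  re3 <- array(rnorm(3 * 2 * 10), c(3, 2, 10))
  expect_equal(mean_re_summary(re3, 1:10),
               apply(re3, c(1, 2), mean))
})

test_that("REC PCA groups duplicated and clustered markers together", {
  set.seed(7)
  base <- matrix(rnorm(40), 20, 2)
  rcm <- cbind(base[, 1], base[, 1], base[, 2])
  colnames(rcm) <- c("m1", "m2", "m3")
  out <- rec_pca(rcm, c("m1", "m2", "m3"))
  expect_equal(out$loadings["m1", ], out$loadings["m2", ], tolerance = 1e-10)
  expect_true(all(diff(out$variance_explained) <= 1e-12))
  expect_equal(sum(out$variance_explained), 1, tolerance = 1e-8)
  # rank-one REC: a single component carries everything
  r1 <- outer(rnorm(15), c(1, 2, 3)); colnames(r1) <- c("a", "b", "c")
  expect_equal(rec_pca(r1, c("a", "b", "c"))$variance_explained[1L], 1,
               tolerance = 1e-8)
  # planted two-cluster markers separate in the first two PCs
  cl <- cbind(base[, 1] + rnorm(20, 0, 0.05), base[, 1] + rnorm(20, 0, 0.05),
              base[, 2] + rnorm(20, 0, 0.05), base[, 2] + rnorm(20, 0, 0.05))
  colnames(cl) <- c("x1", "x2", "y1", "y2")
  o2 <- rec_pca(cl, colnames(cl))
  d_within <- dist(o2$loadings)[c(1, 6)]   # (x1,x2) and (y1,y2)
  d_across <- dist(o2$loadings)[c(2, 3, 4, 5)]
  expect_lt(max(d_within), min(d_across))
  expect_error(rec_pca(rcm, "m1"), "at least 2")
  expect_error(rec_pca(rcm, c("m1", "zz")), "not in REC columns")
})

test_that("tissue association reproduces the Pearson chi-squared statistic", {
  ids <- sprintf("s%02d", 1:60)
  sp <- list(high_ids = ids[1:30], low_ids = ids[31:60], mode = "median",
             N = NULL)
  class(sp) <- "region_split"
  # identical tissue proportions: no association
  lab <- setNames(rep(c("brain", "other"), 30), ids)
  t0 <- tissue_association_test(lab, sp, "brain")
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p_value, 1)
  # perfectly separated 30/30 table
  lab2 <- setNames(rep(c("brain", "other"), each = 30), ids)
  t1 <- tissue_association_test(lab2, sp, "brain")
  expect_equal(t1$statistic, 60)
  expect_identical(t1$stars, "****")
  # random tables match the textbook formula
  set.seed(8)
  for (rep in 1:20) {
    lab3 <- setNames(sample(c("lung", "skin"), 60, replace = TRUE,
                            prob = c(runif(1, 0.2, 0.8), 1)), ids)
    tt <- tissue_association_test(lab3, sp, "lung")
    expect_equal(tt$statistic, chisq_oracle(tt$table), tolerance = 1e-10)
  }
  lab4 <- setNames(rep("lung", 60), ids)
  expect_error(tissue_association_test(lab4, sp, "lung"), "degenerate table")
  expect_error(tissue_association_test(lab4[1:10], sp, "lung"), "unlabeled")
})
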