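test_that("concordance matrices evaluate the scaled outer product", {
  expect_equal(concordance_matrix(c(0L, 0L, 0L)), matrix(0, 3, 3))
  expect_equal(concordance_matrix(c(4L, 0L)),
               matrix(c(0.16, 0, 0, 0), 2, 2))
  m <- concordance_matrix(c(1L, 2L, 3L))
  expect_equal(m[2, 3], 0.06)
  expect_equal(m[1, 1], 0.01)
  expect_equal(m, t(m))
  expect_error(concordance_matrix(c(1L, 5L)), "0..4")
})

test_that("matrix ARI has the identity and degenerate-case behaviour", {
  a <- concordance_matrix(c(1L, 2L, 0L, 3L))
  expect_equal(ari_between_matrices(a, a), 1)
  z <- concordance_matrix(c(0L, 0L, 0L))
  expect_equal(ari_between_matrices(z, z), 1)
  # constant-but-different labelings are maximally dissimilar
  o <- concordance_matrix(c(0L, 0L, 1L))
  expect_error(ari_between_matrices(z, concordance_matrix(c(0L, 0L))),
               "dimension")
  expect_true(ari_between_matrices(z, o) < 1)
})

test_that("matrix ARI equals the brute-force pair-counting oracle", {
  # the hand-sized example first
  x <- c(1L, 2L, 0L)
  y <- c(2L, 1L, 0L)
  got <- ari_between_matrices(concordance_matrix(x), concordance_matrix(y))
  expect_equal(got, brute_ari(brute_cells(x), brute_cells(y)),
               tolerance = 1e-12)
  # randomized severity vectors, p up to 6
  set.seed(71)
  for (trial in 1:200) {
    p <- sample(2:6, 1)
    x <- sample(0:4, p, replace = TRUE)
    y <- sample(0:4, p, replace = TRUE)
    got <- ari_between_matrices(concordance_matrix(x), concordance_matrix(y))
    expect_equal(got, brute_ari(brute_cells(x), brute_cells(y)),
                 tolerance = 1e-12)
  }
})

test_that("matrix ARI is invariant to the /100 scaling", {
  set.seed(73)
  x <- sample(0:4, 6, replace = TRUE)
  y <- sample(0:4, 6, replace = TRUE)
  scaled <- ari_between_matrices(concordance_matrix(x), concordance_matrix(y))
  unscaled <- ari_between_matrices(outer(x, x), outer(y, y))
  expect_equal(scaled, unscaled, tolerance = 1e-12)
})

test_that("partition ARI agrees with an independent implementation", {
  skip_if_not_installed("mclust")
  set.seed(79)
  for (trial in 1:50) {
    a <- sample(1:4, 30, replace = TRUE)
    b <- sample(1:3, 30, replace = TRUE)
    expect_equal(ari_partition(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
})

test_that("the similarity matrix is consistent with per-pair ARI calls", {
  set.seed(83)
  sev <- matrix(sample(0:4, 3 * 6, replace = TRUE), 3, 6)
  sim <- patient_similarity(sev)
  for (i in 1:2) for (j in (i + 1):3) {
    expect_equal(
      sim[i, j],
      ari_between_matrices(concordance_matrix(sev[i, ]),
                           concordance_matrix(sev[j, ])),
      tolerance = 1e-12
    )
  }
  expect_equal(sim, t(sim))
})

test_that("duplicated patients have similarity 1", {
  set.seed(89)
  row <- sample(0:4, 8, replace = TRUE)
  sev <- rbind(row, row, sample(0:4, 8, replace = TRUE))
  sim <- patient_similarity(sev)
  expect_equal(sim[1, 2], 1)
})

test_that("planted subgroups separate in similarity space", {
  co <- generate_cohort(subgroup_cohort_spec(150, seed = 97))
  sim <- patient_similarity(co$severity)
  tr <- co$true_subgroups$labels
  same <- outer(tr, tr, "==") & upper.tri(sim)
  diff <- outer(tr, tr, "!=") & upper.tri(sim)
  expect_gt(mean(sim[same]), mean(sim[diff]))
})

test_that("block-diagonal similarity yields the two blocks with consistency 1", {
  sim <- matrix(0, 6, 6)
  sim[1:3, 1:3] <- 1
  sim[4:6, 4:6] <- 1
  diag(sim) <- 1
  det <- detect_patient_subgroups(sim, runs = 5, seed = 1)
  expect_equal(det$assignment$n_communities, 2L)
  expect_equal(ari_partition(det$assignment$labels, rep(1:2, each = 3)), 1)
  expect_true(all(det$consistency == 1))
})

test_that("eleven runs on a fixed input agree exactly", {
  co <- generate_cohort(subgroup_cohort_spec(120, seed = 101))
  sim <- patient_similarity(co$severity)
  det <- detect_patient_subgroups(sim, runs = 11, seed = 5)
  expect_equal(dim(det$consistency), c(11L, 11L))
  expect_true(all(det$consistency == 1))
})

test_that("subgroup detection is invariant to patient reordering", {
  co <- generate_cohort(subgroup_cohort_spec(120, seed = 103))
  sim <- patient_similarity(co$severity)
  d1 <- detect_patient_subgroups(sim, runs = 1, seed = 7)
  set.seed(11)
  perm <- sample(nrow(sim))
  d2 <- detect_patient_subgroups(sim[perm, perm], runs = 1, seed = 7)
  back <- integer(length(perm))
  back[perm] <- seq_along(perm)
  expect_equal(
    ari_partition(d1$assignment$labels, d2$assignment$labels[back]), 1
  )
})

test_that("an all-zero similarity matrix is rejected", {
  expect_error(detect_patient_subgroups(matrix(0, 4, 4), runs = 1, seed = 1),
               "no positive")
})

test_that("subgroup profiles compute means and normal intervals", {
  sev <- rbind(
    c(0, 2, 4), c(0, 2, 4),                 # subgroup 1: identical rows
    c(1, 1, 1), c(3, 1, 0), c(2, 1, 2), c(0, 1, 1)   # subgroup 2
  )
  colnames(sev) <- c("s1", "s2", "s3")
  labels <- c(1, 1, 2, 2, 2, 2)
  pr <- subgroup_profiles(sev, labels)
  g1 <- pr[pr$subgroup == 1, ]
  expect_equal(g1$mean, c(0, 2, 4))
  expect_equal(g1$ci_hi - g1$ci_lo, c(0, 0, 0))   # identical rows
  g2 <- pr[pr$subgroup == 2, ]
  expect_equal(g2$mean, colMeans(sev[3:6, ]), ignore_attr = TRUE)
  se <- apply(sev[3:6, ], 2, sd) / 2
  expect_equal(g2$ci_lo, unname(colMeans(sev[3:6, ]) - 1.96 * se))
  expect_equal(pr$cohort_mean[1:3], unname(colMeans(sev)))
  # single subgroup: profile is the column means
  pr1 <- subgroup_profiles(sev, rep(1, 6))
  expect_equal(pr1$mean, unname(colMeans(sev)))
  # singleton subgroup: missing interval
  pr2 <- subgroup_profiles(sev, c(1, rep(2, 5)))
  expect_true(all(is.na(pr2$ci_lo[pr2$subgroup == 1])))
})
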