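test_that("wTO matches the brute-force double loop on random fixtures", {
  set.seed(42)
  for (trial in 1:5) {
    x <- matrix(sample(0:4, 5 * 40, replace = TRUE), 40, 5)
    expect_equal(unname(weighted_topological_overlap(x)), brute_wto(x),
                 tolerance = 1e-12)
  }
})

test_that("a duplicated symptom attains the maximal overlap", {
  set.seed(7)
  base <- sample(0:4, 200, replace = TRUE)
  x <- cbind(a = base, b = base,
             c = sample(0:4, 200, replace = TRUE),
             d = sample(0:4, 200, replace = TRUE),
             e = sample(0:4, 200, replace = TRUE))
  wto <- weighted_topological_overlap(x)
  expect_equal(which(wto == max(wto), arr.ind = TRUE)[1, ],
               c(row = 2L, col = 1L), ignore_attr = TRUE)
})

test_that("independent symptoms stay below the conventional 0.25 threshold", {
  set.seed(11)
  x <- matrix(sample(0:4, 6 * 1000, replace = TRUE), 1000, 6)
  expect_lt(max(weighted_topological_overlap(x)), 0.25)
})

test_that("wTO with two symptoms reduces to |w12|", {
  # the cross-product sum vanishes on a zero-diagonal 2x2 association matrix,
  # leaving |w12| / (|w12| + 1 - |w12|) = |w12|
  set.seed(3)
  x <- cbind(sample(0:4, 100, replace = TRUE), sample(0:4, 100, replace = TRUE))
  w12 <- cor(x)[1, 2]
  wto <- weighted_topological_overlap(x)
  expect_equal(wto[1, 2], abs(w12), tolerance = 1e-12)
})

test_that("constant columns are rejected by name", {
  x <- cbind(a = rep(2L, 20), b = sample(0:4, 20, replace = TRUE))
  expect_error(weighted_topological_overlap(x), "a")
  expect_error(nonparanormal_transform(x), "a")
})

test_that("redundant-pair selection is greedy by descending overlap", {
  m <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  m["a", "b"] <- m["b", "a"] <- 0.4
  m["b", "c"] <- m["c", "b"] <- 0.3
  rep_ <- detect_redundant_pairs(m, 0.25)
  expect_equal(nrow(rep_$flagged_pairs), 1L)
  expect_equal(rep_$flagged_pairs$a, "a")
  expect_equal(rep_$flagged_pairs$b, "b")

  # single qualifying cell
  m2 <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  m2[1, 3] <- m2[3, 1] <- 0.9
  rep2 <- detect_redundant_pairs(m2, 0.25)
  expect_equal(nrow(rep2$flagged_pairs), 1L)
  expect_equal(rep2$flagged_pairs$overlap, 0.9)

  # threshold no pair can reach
  expect_equal(nrow(detect_redundant_pairs(m, 0.999)$flagged_pairs), 0L)
})

test_that("consolidating identical columns preserves rank order exactly", {
  set.seed(5)
  x <- sample(0:4, 120, replace = TRUE)
  out <- consolidate_pair(x, x)
  expect_equal(rank(out), rank(x))
  expect_equal(range(out), c(0, 4))
})

test_that("negatively correlated pairs refuse consolidation", {
  x <- rep(0:4, 20)
  expect_error(consolidate_pair(x, 4L - x), "non-positive")
})

test_that("the consolidated score tracks the generating latent factor", {
  set.seed(9)
  n <- 1000
  f <- rnorm(n)
  cutf <- function(e) findInterval(f + e, c(-0.8, 0, 0.8, 1.6))
  xa <- cutf(rnorm(n, sd = 0.25))
  xb <- cutf(rnorm(n, sd = 0.25))
  out <- consolidate_pair(xa, xb)
  expect_gt(cor(out, f), 0.95)
})

test_that("consolidation map arithmetic is consistent", {
  set.seed(13)
  base <- sample(0:4, 300, replace = TRUE)
  noise <- pmin(4L, pmax(0L, base + sample(c(-1L, 0L, 0L, 1L), 300, replace = TRUE)))
  x <- cbind(s1 = base, s2 = noise,
             s3 = sample(0:4, 300, replace = TRUE),
             s4 = sample(0:4, 300, replace = TRUE))
  rep_ <- detect_redundant_pairs(weighted_topological_overlap(x), 0.25)
  cons <- consolidate_redundant(x, rep_)
  expect_equal(cons$map$resulting_symptom_count,
               ncol(x) - length(cons$map$merged))
  expect_equal(ncol(cons$severity), cons$map$resulting_symptom_count)
  expect_true("s1+s2" %in% colnames(cons$severity))
})

test_that("nonparanormal transform maps average ranks through normal quantiles", {
  # hand-computed: {0,0,1,2} -> average ranks {1.5,1.5,3,4} over n+1 = 5
  x <- cbind(a = c(0, 0, 1, 2), b = c(3, 1, 0, 2))
  out <- nonparanormal_transform(x)
  q <- qnorm(c(1.5, 1.5, 3, 4) / 5)
  expect_equal(out[, "a"], q / sd(q), ignore_attr = TRUE)
  expect_equal(sd(out[, "a"]), 1)

  # strictly increasing input -> Phi^-1(i/(n+1)) up to scale
  y <- matrix(c(1:9, 9:1), 9, 2)
  ty <- nonparanormal_transform(y)
  expect_true(all(diff(ty[, 1]) > 0))
  expect_equal(ty[, 1], qnorm((1:9) / 10) / sd(qnorm((1:9) / 10)),
               ignore_attr = TRUE)
})

test_that("transform is idempotent up to scaling and monotone-invariant", {
  set.seed(17)
  x <- matrix(sample(0:4, 5 * 50, replace = TRUE), 50, 5)
  t1 <- nonparanormal_transform(x)
  t2 <- nonparanormal_transform(t1)
  expect_equal(t1, t2, tolerance = 1e-10)
  # strictly monotone recoding leaves the result unchanged
  recoded <- (x + 1)^3
  expect_equal(nonparanormal_transform(recoded), t1, tolerance = 1e-10)
})

test_that("the preprocess module commutes with patient reordering", {
  set.seed(19)
  base <- sample(0:4, 200, replace = TRUE)
  x <- cbind(s1 = base,
             s2 = pmin(4L, base + sample(0:1, 200, replace = TRUE)),
             s3 = sample(0:4, 200, replace = TRUE),
             s4 = sample(0:4, 200, replace = TRUE))
  rownames(x) <- sprintf("P%03d", 1:200)
  perm <- sample(200)
  run <- function(m) {
    rep_ <- detect_redundant_pairs(weighted_topological_overlap(m), 0.25)
    nonparanormal_transform(consolidate_redundant(m, rep_)$severity)
  }
  direct <- run(x)[perm, ]
  permuted <- run(x[perm, ])
  expect_equal(direct, permuted, tolerance = 1e-12)
})

test_that("the normality screen reports a statistic per symptom", {
  set.seed(23)
  x <- matrix(sample(0:4, 4 * 60, replace = TRUE), 60, 4,
              dimnames = list(NULL, paste0("s", 1:4)))
  sc <- shapiro_screen(x)
  expect_equal(sc$symptom, paste0("s", 1:4))
  expect_true(all(sc$W > 0 & sc$W <= 1))
  # heavily tied ordinal data is flagged non-normal
  expect_true(all(sc$p_value < 0.01))
})
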