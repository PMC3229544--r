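test_that("rank normalization matches the mid-rank definition", {
  expect_equal(as.vector(rank_normalize(matrix(c(5, 2, 9), ncol = 1))),
               c(2/3, 1/3, 1))
  expect_equal(as.vector(rank_normalize(matrix(c(4, 4, 8), ncol = 1))),
               c(0.5, 0.5, 1))
  # distinct values: sorted relative ranks are (1/P, ..., 1)
  x <- matrix(sample(seq(1, 100, length.out = 17)), ncol = 1)
  expect_equal(sort(as.vector(rank_normalize(x))), (1:17) / 17)
  expect_error(rank_normalize(matrix(c(1, 0, 3), ncol = 1)), "row 2")
  expect_error(rank_normalize(matrix(c(1, NA, 3), ncol = 1)), "non-positive|missing")
})

test_that("per-array relative-rank sums equal (P+1)/2 with and without ties", {
  probeRank:::with_seed(61L, {
    for (i in 1:20) {
      P <- sample(3:40, 1L)
      mat <- matrix(exp(rnorm(P * 4L)), P, 4L)
      if (i %% 2L == 0L) mat[sample(P, 2L), 1L] <- mat[1L, 1L]  # force ties
      rr <- rank_normalize(mat)
      expect_equal(colSums(rr), rep((P + 1) / 2, 4L), tolerance = 0)
      expect_true(all(rr > 0 & rr <= 1))
    }
  })
})

test_that("exact Mann-Whitney tails match hand-derived enumerations", {
  # complete separation, 5 vs 3: a single extreme assignment out of C(8,3)=56
  p <- mw_exact(c(0.4, 0.5, 0.6, 0.7, 0.8), c(0.1, 0.2, 0.3))
  expect_equal(unname(p["p_upper"]), 1 / 56)

  # x at pooled rank positions {2,4,6,7,8}, y at {1,3,5}: upper tail 7/56
  x <- c(0.2, 0.4, 0.6, 0.7, 0.8); y <- c(0.1, 0.3, 0.5)
  p2 <- mw_exact(x, y)
  expect_equal(unname(p2["p_upper"]), 7 / 56)
  expect_identical(unname(assign_letter(p2["p_upper"], p2["p_lower"])), "E")

  # all values tied: both tails are 1
  p3 <- mw_exact(rep(1, 4), rep(1, 5))
  expect_equal(unname(p3), c(1, 1))

  expect_error(mw_exact(1, c(1, 2)), "at least 2")
})

test_that("mw_exact equals full-assignment enumeration at the design's group sizes", {
  sizes <- list(c(3L, 5L), c(5L, 5L), c(5L, 4L))
  probeRank:::with_seed(62L, {
    for (s in sizes) {
      for (i in 1:25) {
        x <- round(runif(s[1L]), 2L)  # rounding induces frequent ties
        y <- round(runif(s[2L]), 2L)
        expect_equal(mw_exact(x, y), oracle_mw(x, y), tolerance = 0)
      }
    }
  })
})

test_that("exact tails satisfy p_upper + p_lower = 1 + P(W = obs) without ties", {
  probeRank:::with_seed(63L, {
    for (i in 1:10) {
      x <- runif(5L); y <- runif(4L)
      p <- mw_exact(x, y)
      r <- rank(c(x, y))
      A <- probeRank:::assignment_matrix(5L, 4L)
      W <- as.vector(r %*% A)
      point <- mean(W == sum(r[1:5]))
      expect_equal(unname(p["p_upper"] + p["p_lower"]), 1 + point)
    }
  })
})

test_that("mw_exact agrees with wilcox.test on tie-free inputs", {
  probeRank:::with_seed(64L, {
    for (i in 1:10) {
      x <- runif(5L); y <- runif(5L)
      p <- mw_exact(x, y)
      w_greater <- wilcox.test(x, y, alternative = "greater", exact = TRUE)
      expect_equal(unname(p["p_upper"]), w_greater$p.value)
    }
  })
})

test_that("letters obey the inclusive 0.05 threshold and exclusivity", {
  expect_identical(assign_letter(0.0179, 0.996), "H")
  expect_identical(assign_letter(0.996, 0.0179), "L")
  expect_identical(assign_letter(0.125, 0.93), "E")
  expect_identical(assign_letter(0.05, 0.96), "H")  # inclusive threshold
  expect_error(assign_letter(0.01, 0.99, alpha = 0.6), "alpha")
  expect_error(assign_letter(0.01, 0.99, alpha = 0), "alpha")
})

test_that("noiseless planted effects yield the end-to-end expression string", {
  # +2 log2FC planted for tx1 at the wt hypoxia comparisons (positions 4, 5).
  # The shifted wt-90min/24h arrays are simultaneously the control groups of
  # genotype comparisons 2-3, so those separate too: the derived string is
  # ELLHHEE, and the naive and knockout-timecourse comparisons stay E (ties).
  pe <- data.frame(transcript_id = c("tx1", "tx1"), position = c(4L, 5L),
                   log2_fc = c(2, 2))
  sim <- small_sim(seed = 71L, planted = pe, noise_sd = 0)
  res <- suppressMessages(run_pipeline(sim$probes, sim$transcripts,
                                       sim$intensities, sim$design))
  tx1_probes <- names(sim$origin)[sim$origin == "tx1"]
  strs <- res$strings$strings[tx1_probes]
  expect_true(all(strs == "ELLHHEE"))
  # plan of length 7 implies strings of length 7
  expect_true(all(nchar(res$strings$strings) == 7L))

  # null case: no planted effects, no noise -> every probe is tied on every
  # array and every string is all-E
  sim0 <- small_sim(seed = 71L, planted = NULL, noise_sd = 0)
  s0 <- build_expression_strings(rank_normalize(sim0$intensities), sim0$design)
  expect_true(all(s0$strings == "EEEEEEE"))
})

test_that("letters are invariant under strictly monotone intensity transforms", {
  sim <- small_sim(seed = 72L,
                   planted = data.frame(transcript_id = "tx1", position = 2L,
                                        log2_fc = 1.5))
  design <- sim$design
  s1 <- build_expression_strings(rank_normalize(sim$intensities), design)
  for (f in list(function(x) x^3, function(x) log(x), function(x) 5 * x + 2)) {
    s2 <- build_expression_strings(rank_normalize(f(sim$intensities)), design)
    expect_identical(s1$strings, s2$strings)
  }
})

test_that("probe clustering partitions probes by exact string identity", {
  strings <- c(p1 = "EEE", p2 = "EEE", p3 = "HEE")
  cl <- cluster_probes(strings)
  expect_setequal(cl[["EEE"]], c("p1", "p2"))
  expect_identical(cl[["HEE"]], "p3")
  expect_identical(sum(lengths(cl)), length(strings))

  same <- setNames(rep("HLE", 5L), sprintf("p%d", 1:5))
  expect_identical(lengths(cluster_probes(same)), c(HLE = 5L))
})
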