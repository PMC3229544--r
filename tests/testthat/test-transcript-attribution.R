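make_records <- function(...) {
  df <- data.frame(..., stringsAsFactors = FALSE)
  df
}

test_that("hypergeometric attribution tail matches hand-derived values", {
  expect_equal(hypergeom_tail(0, 5, 9, 20), 1)          # whole support
  expect_equal(hypergeom_tail(9, 20, 9, 20), 1)         # A_size = T
  expect_equal(hypergeom_tail(4, 5, 9, 20), 1512 / 15504)
  # 7 of a transcript's 9 probes inside a cluster of size 7, T = 100
  expect_equal(hypergeom_tail(7, 7, 9, 100),
               choose(9, 7) * choose(91, 0) / choose(100, 7))
  expect_error(hypergeom_tail(5, 4, 9, 20), "invalid")
  expect_error(hypergeom_tail(1, 4, 21, 20), "invalid")
})

test_that("hypergeometric tail equals subset enumeration for small universes", {
  for (T_total in c(5L, 8L, 11L)) {
    for (X_T in 1:T_total) {
      for (A_size in 1:T_total) {
        for (X_A in 0:min(A_size, X_T)) {
          expect_equal(hypergeom_tail(X_A, A_size, X_T, T_total),
                       oracle_hyper_tail(X_A, A_size, X_T, T_total),
                       tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("attribution assembles counts, excludes all-E, shares multi-mappers", {
  strings <- c(p1 = "HEE", p2 = "HEE", p3 = "EEE", p4 = "LEE", p5 = "HEE")
  clusters <- cluster_probes(strings)
  hits <- data.frame(
    probe_id = c("p1", "p2", "p3", "p4", "p5", "p5"),
    transcript_id = c("tx1", "tx1", "tx1", "tx2", "tx2", "tx3"),
    t_start = 1L, t_end = 22L, match_len = 22L, stringsAsFactors = FALSE)
  index <- suppressMessages(build_probe_index(hits, names(strings)))
  rec <- attribute(clusters, index)
  expect_false(any(rec$profile == "EEE"))     # all-E excluded
  r_tx1 <- rec[rec$transcript == "tx1" & rec$profile == "HEE", ]
  expect_identical(r_tx1$X_A, 2L)
  expect_identical(r_tx1$A_size, 3L)
  expect_identical(r_tx1$X_T, 3L)
  expect_identical(r_tx1$T, 5L)
  expect_equal(r_tx1$p_raw, hypergeom_tail(2, 3, 3, 5))
  # multi-mapping p5 contributes to both tx2 and tx3
  expect_identical(rec$X_A[rec$transcript == "tx3" & rec$profile == "HEE"], 1L)
  expect_identical(rec$X_A[rec$transcript == "tx2" & rec$profile == "HEE"], 1L)
  # partition conservation: per transcript, sum of X_A over all profiles
  # (including the untested all-E cluster) equals X_T
  for (tx in names(index$targets)) {
    all_e <- sum(vapply(clusters[grepl("^E+$", names(clusters))], function(pr) {
      sum(vapply(pr, function(p) tx %in% index$hits[[p]], logical(1)))
    }, numeric(1)))
    expect_identical(sum(rec$X_A[rec$transcript == tx]) + as.integer(all_e),
                     as.integer(index$targets[tx]))
  }
  # universe mismatch is rejected
  expect_error(attribute(clusters[-1L], index), "universe")
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4L))
  expect_equal(bh_adjust(c(0.005, 0.1, 0.2)), c(0.015, 0.15, 0.2))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_error(bh_adjust(c(0.1, 0)), "0, 1")
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
  probeRank:::with_seed(81L, {
    for (i in 1:20) {
      p <- runif(sample(1:50, 1L))
      expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
      expect_true(all(bh_adjust(p) >= p))
    }
  })
})

test_that("DE calls honour the strict threshold and resolve conflicts by minimal p", {
  rec <- make_records(
    transcript = c("tx1", "tx2", "tx3", "tx3", "tx4"),
    profile = c("EEEHEEE", "EEEHEEE", "EEEHEEE", "EEELEEE", "EEEHEEE"),
    p_adj = c(0.01, 0.05, 0.02, 0.001, 0.2))
  de_h <- call_de(rec, position = 4L, letter = "H")
  expect_identical(de_h$transcript, "tx1")       # 0.05 exactly is excluded
  expect_false(de_h$ambiguous)
  de_l <- call_de(rec, position = 4L, letter = "L")
  expect_identical(de_l$transcript, "tx3")       # conflict -> minimal p wins
  expect_true(de_l$ambiguous)
  # no significant records -> empty list
  expect_identical(nrow(call_de(make_records(transcript = "t", profile = "HEE",
                                             p_adj = 0.9), 1L, "H")), 0L)
  expect_error(call_de(rec, position = 9L, letter = "H"), "position")
})

test_that("effect size is the mean relative-rank difference of supporting probes", {
  design <- default_design()
  plan <- default_plan()
  arrs <- comparison_arrays(plan, design)[[4L]]
  probes <- c("p1", "p2")
  ranks <- matrix(0.3, nrow = 2L, ncol = nrow(design),
                  dimnames = list(probes, design$array_id))
  ranks["p1", arrs$exp] <- 0.8
  ranks["p1", arrs$ctrl] <- 0.3
  ranks["p2", arrs$exp] <- 0.6
  ranks["p2", arrs$ctrl] <- 0.4
  hits <- data.frame(probe_id = probes, transcript_id = "tx1",
                     t_start = 1L, t_end = 22L, match_len = 22L,
                     stringsAsFactors = FALSE)
  index <- suppressMessages(build_probe_index(hits, probes))
  clusters <- list("EEEHEEE" = probes)
  expect_equal(effect_size("tx1", "EEEHEEE", 4L, ranks, plan, design, index,
                           clusters), mean(c(0.5, 0.2)))
  expect_error(effect_size("tx1", "EEEHEEE", 1L, ranks, plan, design, index,
                           clusters), "letter E")
})

test_that("p-product ranking orders by ascending product with id tie-breaks", {
  a <- make_records(transcript = c("tx1", "tx2", "tx3"), profile = "H",
                    p_adj = c(0.001, 0.02, 0.03))
  b <- make_records(transcript = c("tx1", "tx2", "tx4"), profile = "H",
                    p_adj = c(0.01, 0.02, 0.001))
  r <- p_product_ranking(a, b)
  expect_identical(r$transcript, c("tx1", "tx2"))  # tx3/tx4 excluded
  expect_equal(r$p_product, c(1e-5, 4e-4))
  # equal products: deterministic id order
  a2 <- make_records(transcript = c("txB", "txA"), profile = "H",
                     p_adj = c(0.01, 0.01))
  r2 <- p_product_ranking(a2, a2)
  expect_identical(r2$transcript, c("txA", "txB"))
})

test_that("contrast sets partition transcripts by genotype-difference timing", {
  rec <- make_records(
    transcript = c("tx1", "tx2", "tx3", "tx4", "tx5"),
    profile = c("EHHEEEE",   # consistent (up in knockout at both timepoints)
                "EHEEEEE",   # only at 90 min
                "LEEEEEE",   # already different in naive animals
                "EELEEEE",   # only at 24 h
                "LHHEEEE"),  # naive difference trumps consistency
    p_adj = c(0.01, 0.01, 0.01, 0.01, 0.01))
  cs <- contrast_sets(rec)
  expect_identical(cs$consistent, "tx1")
  expect_identical(cs$only_90, "tx2")
  expect_setequal(cs$naive_diff, c("tx3", "tx5"))
  expect_identical(cs$only_24, "tx4")
  expect_false("tx5" %in% cs$consistent)
  expect_length(intersect(cs$only_90, cs$only_24), 0L)
})
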