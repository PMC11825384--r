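test_that("candidate enumeration is the full Cartesian product, wild type included", {
  expect_identical(enumerate_candidates("ACGT", 2),
                   c("AAGT", "ACGT", "AGGT", "ATGT"))
  for (m in 1:5) {
    wt <- strrep("ACGT", 3)
    cands <- enumerate_candidates(wt, seq_len(m))
    expect_length(cands, 4L^m)
    expect_identical(anyDuplicated(cands), 0L)
    expect_true(wt %in% cands)
    expect_identical(cands, sort(cands, method = "radix"))  # lexicographic
  }
  # candidates differ from the wild type only at the selected positions
  wt <- "ACGTACGTAC"
  positions <- c(2, 5, 9)
  for (cand in enumerate_candidates(wt, positions)) {
    diff <- which(strsplit(cand, "")[[1]] != strsplit(wt, "")[[1]])
    expect_true(all(diff %in% positions))
  }
})

test_that("enumeration enforces the seven-position limit and coordinates", {
  wt <- strrep("ACGT", 5)
  expect_error(enumerate_candidates(wt, 1:8), "position limit")
  expect_error(enumerate_candidates(wt, c(1, 25)), "coordinate error")
  expect_error(enumerate_candidates(wt, c(3, 3)), "distinct")
})

test_that("focal indices map positions to steps by the either-endpoint rule", {
  expect_identical(focal_indices(c(3, 4, 5), "GROOVE", 10), c(3L, 4L, 5L))
  expect_identical(focal_indices(c(3, 4, 5), "INTRA_BP", 10), c(3L, 4L, 5L))
  # brute force over steps 1..9: keep steps with an endpoint in {3,4,5}
  focal <- c(3, 4, 5)
  manual <- Filter(function(t) t %in% focal || (t + 1) %in% focal, 1:9)
  expect_identical(focal_indices(focal, "INTER_BP", 10), as.integer(manual))
  expect_identical(focal_indices(1, "INTER_BP", 10), 1L)
  expect_identical(focal_indices(10, "INTER_BP", 10), 9L)
})

test_that("Euclidean shape distance matches hand computation", {
  cfg <- distance_config(features = "MGW")
  p1 <- fake_profile(5, MGW = c(5, 5, 5, 5, 5))
  expect_identical(as.numeric(shape_distance_euclidean(p1, p1, cfg)), 0)
  # 3-4-5 triangle over two focal indices
  p2 <- fake_profile(5, MGW = c(5, 8, 5, 9, 5))
  cfg2 <- distance_config(features = "MGW", focal = c(2, 4))
  expect_equal(as.numeric(shape_distance_euclidean(p1, p2, cfg2)), 5)
  # engine result equals an independent recomputation from raw table lookups
  tab <- synth_table(5, "MGW", seed = 42)
  wt <- "ACGTACGTACGTACG"
  mut <- sub("^ACGTACG", "ACGTACC", wt)
  d <- shape_distance_euclidean(predict_shape(wt, tab),
                                predict_shape(mut, tab),
                                distance_config(features = "MGW"))
  manual <- sqrt(sum((unname(predict_shape(wt, tab)$MGW) -
                        unname(predict_shape(mut, tab)$MGW))^2))
  expect_equal(as.numeric(d), manual)
})

test_that("enlarging the focal region never shrinks the Euclidean distance", {
  tab <- synth_table(5, c("MGW", "Roll"), seed = 47)
  set.seed(707)
  for (i in 1:5) {
    wt <- random_dna(15)
    mut <- enumerate_candidates(wt, c(7, 8))[sample(16, 1)]
    pw <- predict_shape(wt, tab); pm <- predict_shape(mut, tab)
    small <- sample(3:12, 4)
    big <- union(small, sample(3:12, 3))
    d_small <- shape_distance_euclidean(pw, pm,
      distance_config(features = c("MGW", "Roll"), focal = small,
                      normalize = FALSE))
    d_big <- shape_distance_euclidean(pw, pm,
      distance_config(features = c("MGW", "Roll"), focal = big,
                      normalize = FALSE))
    expect_gte(as.numeric(d_big), as.numeric(d_small))
  }
})

test_that("Pearson distance tracks pattern, not level", {
  cfg <- distance_config(shape_metric = "PEARSON", features = "MGW")
  base <- c(4.8, 5.6, 5.1, 4.2, 5.9, 5.0)
  p1 <- fake_profile(6, MGW = base)
  expect_equal(as.numeric(shape_distance_pearson(p1, p1, cfg)), 0)
  # constant offset leaves the pattern identical
  p_off <- fake_profile(6, MGW = base + 2.5)
  expect_equal(as.numeric(shape_distance_pearson(p1, p_off, cfg)), 0)
  # negating the centred profile inverts the pattern completely
  p_neg <- fake_profile(6, MGW = mean(base) - (base - mean(base)))
  expect_equal(as.numeric(shape_distance_pearson(p1, p_neg, cfg)), 2)
  # degenerate inputs are errors, not silent zeros
  p_const <- fake_profile(6, MGW = rep(5, 6))
  expect_error(shape_distance_pearson(p1, p_const, cfg),
               "degenerate correlation")
  cfg2 <- distance_config(shape_metric = "PEARSON", features = "MGW",
                          focal = c(2, 3))
  expect_error(shape_distance_pearson(p1, p_off, cfg2),
               "insufficient focal")
})

test_that("run_design returns a complete, deterministic ranked panel", {
  tab <- synth_table(5, "MGW", seed = 42)
  wt <- "ACGTACGTAC"
  res <- run_design(wt, 5, distance_config(features = "MGW"), tab)
  expect_identical(nrow(res), 4L)
  expect_identical(sum(res$is_wildtype), 1L)
  wt_row <- res[res$is_wildtype, ]
  expect_identical(wt_row$base_distance, 0)
  expect_identical(wt_row$shape_distance, 0)
  expect_identical(wt_row$substitutions, "")
  expect_identical(res$rank, 1:4)

  res2 <- run_design(wt, 5, distance_config(features = "MGW"), tab)
  expect_identical(as.data.frame(res), as.data.frame(res2))

  # two positions: 16 candidates, physchem distances are sums of the
  # per-substitution costs {6, 8}
  res16 <- run_design(wt, c(3, 5), distance_config(features = "MGW"), tab)
  expect_identical(nrow(res16), 16L)
  expect_true(all(res16$base_distance %in% c(0, 6, 8, 12, 14, 16)))
  expect_true(all(res16$base_distance %in% c(0, 4, 6, 8, 10, 12, 14, 16)))
})

test_that("design runs are strand-invariant with parity-consistent tables", {
  set.seed(808)
  for (i in 1:5) {
    tab <- synth_table(5, "MGW", seed = 900 + i)
    n <- 12
    wt <- random_dna(n)
    positions <- sort(sample(3:10, 2))
    cfg <- distance_config(features = "MGW", normalize = FALSE)
    res_fwd <- run_design(wt, positions, cfg, tab)
    res_rev <- run_design(reverse_complement(wt), n + 1 - positions, cfg, tab)
    key <- function(r) sort(paste(r$base_distance,
                                  sprintf("%.9f", r$shape_distance)))
    expect_identical(key(res_fwd), key(res_rev))
  }
})

test_that("substitutions beyond the window's reach leave the focal distance at zero", {
  k <- 5; h <- (k - 1) %/% 2
  tab <- synth_table(k, "MGW", seed = 53)
  wt <- strrep("ACGT", 6)  # n = 24
  focal <- 12:14
  cfg <- distance_config(features = "MGW", focal = focal, normalize = FALSE)
  # groove features reach h positions: mutations at distance >= h + 1 are silent
  res <- run_design(wt, c(2, 20), cfg, tab)
  expect_true(all(res$shape_distance == 0))
  # with a step feature the reach extends one more position to the right
  cfg_step <- distance_config(features = "Roll", focal = focal,
                              normalize = FALSE)
  tab2 <- synth_table(k, "Roll", seed = 53)
  res2 <- run_design(wt, c(2, 20), cfg_step, tab2)
  expect_true(all(res2$shape_distance == 0))
})

test_that("ensemble z-normalization pools statistics across the candidate panel", {
  tab <- synth_table(5, c("MGW", "Roll"), seed = 59)
  wt <- "ACGTACGTACGT"
  res_raw <- run_design(wt, 6, distance_config(features = c("MGW", "Roll"),
                                               normalize = FALSE), tab)
  res_norm <- run_design(wt, 6, distance_config(features = c("MGW", "Roll")),
                         tab)  # normalize = NULL -> auto on for 2 features
  expect_false(isTRUE(all.equal(res_raw$shape_distance,
                                res_norm$shape_distance)))
  st <- attr(res_norm, "norm_stats")
  expect_named(st, c("MGW", "Roll"))
  # wild type still at zero either way
  expect_identical(res_norm$shape_distance[res_norm$is_wildtype], 0)
})

test_that("the Pareto front keeps exactly the non-dominated candidates", {
  mk <- function(base, shape) {
    data.frame(sequence = paste0("s", seq_along(base)),
               base_distance = base, shape_distance = shape,
               is_wildtype = base == 0 & shape == 0,
               stringsAsFactors = FALSE)
  }
  # exhaustive-dominance example
  front <- pareto_front(mk(c(1, 2, 3), c(5, 9, 8)), "maximize")
  expect_setequal(front$sequence, c("s1", "s2"))
  # equal base distance: single best-shape candidate plus ties
  front2 <- pareto_front(mk(c(2, 2, 2, 2), c(1, 7, 7, 3)), "maximize")
  expect_setequal(front2$sequence, c("s2", "s3"))
  # single candidate is its own front
  front3 <- pareto_front(mk(4, 2.5), "maximize")
  expect_identical(nrow(front3), 1L)
  # the wild type is excluded when maximizing
  with_wt <- mk(c(0, 6, 8), c(0, 2, 1))
  expect_false(any(pareto_front(with_wt, "maximize")$is_wildtype))
  # agreement with a brute-force dominance check on a random panel
  set.seed(909)
  panel <- mk(sample(0:10, 40, TRUE), round(runif(40, 0, 5), 2))
  panel$is_wildtype <- FALSE
  front4 <- pareto_front(panel, "maximize")
  dominated <- vapply(seq_len(nrow(panel)), function(i) {
    any(panel$base_distance <= panel$base_distance[i] &
          panel$shape_distance >= panel$shape_distance[i] &
          (panel$base_distance < panel$base_distance[i] |
             panel$shape_distance > panel$shape_distance[i]))
  }, logical(1))
  expect_setequal(front4$sequence, panel$sequence[!dominated])
})
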