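planted_struct_matrix <- function(seed = 1) {
  ## a planted scoring-energy grid wrapped as a StructMatrix: exp(-E) are
  ## legal frequencies, so rebuilding with zero pseudocount reproduces E
  build_matrix(exp(-default_planted_matrix(seed)), pseudocount = 0,
               observable = "hbonds", strategy = "all")
}

test_that("experimental and matrix signs follow the nM orientation", {
  expect_equal(experimental_sign(50, 500), 1L)
  expect_equal(experimental_sign(500, 50), -1L)
  expect_equal(experimental_sign(50, 50), 0L)
  expect_error(experimental_sign(-1, 50), "positive")

  m <- planted_struct_matrix()
  j <- order(m$E[4, ])
  best <- colnames(m$E)[j[1]]
  worst <- colnames(m$E)[j[20]]
  expect_equal(matrix_sign(m, 4, best, worst), 1L)
  expect_equal(matrix_sign(m, 4, worst, best), -1L)
  expect_warning(s0 <- matrix_sign(m, 4, "A", "A"), "degenerate")
  expect_equal(s0, 0L)
  expect_error(matrix_sign(m, 10, "A", "C"), "out of range")

  ## antisymmetry under wt <-> mut swap
  set.seed(5)
  for (rep in 1:50) {
    pos <- sample(9, 1)
    ab <- sample(aa_alphabet(), 2)
    expect_equal(matrix_sign(m, pos, ab[1], ab[2]),
                 -matrix_sign(m, pos, ab[2], ab[1]))
    aw <- runif(2, 1, 1e4)
    expect_equal(experimental_sign(aw[1], aw[2]),
                 -experimental_sign(aw[2], aw[1]))
  }
})

test_that("pair assembly finds exactly the single-core-substitution pairs", {
  peps <- data.frame(sequence = c("AAAAAAAAA", "AAAACAAAA"),
                     activity_nM = c(10, 100), core_start = 0)
  pairs <- make_pairs(peps)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$core_position, 5)
  expect_equal(pairs$wt_aa, "A")
  expect_equal(pairs$mut_aa, "C")
  expect_equal(pairs$wt_sequence, "AAAAAAAAA")  # stronger binder is wt

  ## two differing positions: no pair
  peps2 <- data.frame(sequence = c("AAAAAAAAA", "AACACAAAA"),
                      activity_nM = c(10, 100), core_start = 0)
  expect_equal(nrow(make_pairs(peps2)), 0)

  ## random dataset equals the brute-force Hamming scan
  set.seed(6)
  n <- 60
  seqs <- unique(vapply(seq_len(n), function(k)
    paste(sample(c("A", "C", "D"), 9, replace = TRUE), collapse = ""),
    character(1)))
  peps3 <- data.frame(sequence = seqs, activity_nM = runif(length(seqs), 1, 1e4),
                      core_start = 0)
  pairs3 <- make_pairs(peps3)
  expected <- 0
  for (a in seq_len(length(seqs) - 1)) {
    for (b in (a + 1):length(seqs)) {
      d <- sum(strsplit(seqs[a], "")[[1]] != strsplit(seqs[b], "")[[1]])
      if (d == 1) expected <- expected + 1
    }
  }
  expect_equal(nrow(pairs3), expected)
  expect_true(all(pairs3$activity_wt <= pairs3$activity_mut))
  ## each pair really differs at exactly its recorded position
  for (k in seq_len(min(nrow(pairs3), 20))) {
    diffs <- which(strsplit(pairs3$wt_sequence[k], "")[[1]] !=
                   strsplit(pairs3$mut_sequence[k], "")[[1]])
    expect_equal(diffs, pairs3$core_position[k])
  }
})

test_that("the >= min-agree consensus counts agreeing functions", {
  pairs <- data.frame(pair_id = "p1", wt_sequence = "AAAAAAAAA",
                      mut_sequence = "AAAACAAAA", core_position = 5,
                      activity_wt = 10, activity_mut = 100)   # exp sign +1
  mk_scores <- function(signs) {
    do.call(rbind, lapply(seq_along(signs), function(f) {
      data.frame(pair_id = "p1", role = rep(c("wt", "mut"), each = 3),
                 function_name = paste0("fn", f), frame = rep(0:2, 2),
                 score = c(0, 0, 0, rep(signs[f], 3)))
    }))
  }
  ## 4 of 6 agree -> match
  res4 <- consensus_sign(mk_scores(c(1, 1, 1, 1, -1, -1)), pairs)
  expect_true(res4$match)
  expect_equal(res4$n_agree, 4L)
  ## 2 of 6 agree -> no match
  res2 <- consensus_sign(mk_scores(c(1, 1, -1, -1, -1, -1)), pairs)
  expect_false(res2$match)

  ## orientation flips a higher-is-better function
  sc <- mk_scores(c(1, 1, -1, -1, -1, -1))
  res_flip <- consensus_sign(sc, pairs,
                             orientation = c(fn3 = FALSE, fn4 = FALSE))
  expect_true(res_flip$match)   # fn3, fn4 now agree: 4 of 6

  ## missing role fails loudly
  expect_error(consensus_sign(sc[sc$role == "wt", ], pairs), "incomplete pair")
})

test_that("OR-combination is a monotone union", {
  a <- c(TRUE, FALSE, FALSE)
  b <- c(FALSE, TRUE, FALSE)
  expect_equal(combine_or(a, b), c(TRUE, TRUE, FALSE))
  expect_equal(combine_or(a, rep(FALSE, 3)), a)
  expect_error(combine_or(a, b[1:2]), "mismatched")

  set.seed(12)
  for (rep in 1:200) {
    x <- runif(20) < 0.5
    y <- runif(20) < 0.5
    z <- combine_or(x, y)
    expect_gte(sum(z), max(sum(x), sum(y)))
  }
})

test_that("match-rate evaluation reports the 3-decimal fractions", {
  res <- evaluate_matches(c(rep(TRUE, 33), rep(FALSE, 23)))
  expect_equal(res$n_pairs, 56)
  expect_equal(round(res$match_fraction, 3), 0.589)
  expect_equal(evaluate_matches(rep(TRUE, 10))$match_fraction, 1)
  expect_equal(evaluate_matches(rep(FALSE, 10))$match_fraction, 0)
  expect_error(evaluate_matches(logical(0)), "no pairs")
  ## tie pairs drop out of the denominator
  res2 <- evaluate_matches(c(TRUE, TRUE, FALSE, FALSE),
                           usable = c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(res2$n_pairs, 3)
})

test_that("bootstrap resampling is reproducible and well-calibrated", {
  ## degenerate all-true vector
  res <- bootstrap_matches(rep(TRUE, 56), n_replicas = 50, seed = 3)
  expect_equal(res$bootstrap_mean, 1)
  expect_equal(res$bootstrap_sd, 0)

  matches <- c(rep(TRUE, 33), rep(FALSE, 23))
  r1 <- bootstrap_matches(matches, 50, seed = 7)
  r2 <- bootstrap_matches(matches, 50, seed = 7)
  expect_identical(r1[c("bootstrap_mean", "bootstrap_sd")],
                   r2[c("bootstrap_mean", "bootstrap_sd")])
  r3 <- bootstrap_matches(matches, 50, seed = 8)
  expect_false(identical(r1$bootstrap_mean, r3$bootstrap_mean))
  expect_error(bootstrap_matches(matches, n_replicas = 1), "at least 2")

  ## replicate mean converges to the point estimate; replicate SD matches
  ## the binomial sampling formula sqrt(p(1-p)/n)
  big <- bootstrap_matches(matches, 10000, seed = 9)
  p_hat <- mean(matches)
  n <- length(matches)
  se_mean <- sqrt(p_hat * (1 - p_hat) / n) / sqrt(10000)
  expect_lt(abs(big$bootstrap_mean - p_hat), 3 * se_mean)
  expect_lt(abs(big$bootstrap_sd - sqrt(p_hat * (1 - p_hat) / n)),
            0.05 * sqrt(p_hat * (1 - p_hat) / n))
})
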