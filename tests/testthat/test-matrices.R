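## Frame selection, observable accumulation and the scoring-energy
## transform.

make_table <- function(core, counts_per_frame, run_id = "r1") {
  ## counts_per_frame: list of length-9 integer vectors, one per frame
  rows <- lapply(seq_along(counts_per_frame), function(f) {
    data.frame(run_id = run_id, frame = f - 1L, core_position = 1:9,
               amino_acid = strsplit(core, "")[[1]],
               hbonds = as.integer(counts_per_frame[[f]]),
               contacts = as.integer(counts_per_frame[[f]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_frames") <- length(counts_per_frame)
  out
}

test_that("frame selection implements the four strategies with stable ties", {
  toy <- make_toy_complex(toy_complex_spec(
    n_frames = 4, peptide_length = 9, core_start = 0,
    planted_contacts = rep(0L, 9), planted_hbonds = rep(0L, 9),
    jitter_sd = 0, seed = 1))
  ens <- toy$ensemble

  ens$energies <- c(3, 1, 4, 2)
  expect_equal(select_frames(ens, "all")$selected_frames, 0:3)
  expect_equal(select_frames(ens, "last_half")$selected_frames, 2:3)
  expect_equal(select_frames(ens, "best_energy_half")$selected_frames, c(1L, 3L))
  expect_equal(select_frames(ens, "best_energy_one")$selected_frames, 1L)

  ## ties at the half boundary: energies (1,2,2,3), select 2 -> earlier frame
  ens$energies <- c(1, 2, 2, 3)
  expect_equal(select_frames(ens, "best_energy_half")$selected_frames, c(0L, 1L))

  ens$energies <- NULL
  expect_error(select_frames(ens, "best_energy_half"), "requires per-frame energies")

  ## odd frame counts take the ceiling
  toy5 <- make_toy_complex(toy_complex_spec(
    n_frames = 5, peptide_length = 9, core_start = 0,
    planted_contacts = rep(0L, 9), planted_hbonds = rep(0L, 9),
    jitter_sd = 0, seed = 2))
  expect_equal(select_frames(toy5$ensemble, "last_half")$selected_frames, 2:4)

  ## selected best-energy-half energies never exceed the median
  set.seed(31)
  for (rep in 1:20) {
    toy5$ensemble$energies <- rnorm(5)
    sel <- select_frames(toy5$ensemble, "best_energy_half")
    expect_true(all(toy5$ensemble$energies[sel$selected_frames + 1] <=
                    median(toy5$ensemble$energies)))
  }
})

test_that("accumulation implements the per-run frame-average sum over runs", {
  ## one run, one frame, poly-A core with 2 H-bonds everywhere
  t1 <- make_table("AAAAAAAAA", list(rep(2L, 9)))
  O <- accumulate_observables(list(t1), "hbonds")
  expect_equal(unname(O[, "A"]), rep(2, 9))
  expect_equal(sum(O[, setdiff(colnames(O), "A")]), 0)

  ## two runs with different cores: frequency weighting emerges from the
  ## sum over runs (Nf = 1 per run)
  t2 <- make_table("CCCCCCCCC", list(rep(4L, 9)), run_id = "r2")
  O2 <- accumulate_observables(list(t1, t2), "hbonds")
  expect_equal(unname(O2[, "A"]), rep(2, 9))
  expect_equal(unname(O2[, "C"]), rep(4, 9))

  ## runs with differing selected-frame counts fail loudly
  t3 <- make_table("AAAAAAAAA", list(rep(1L, 9), rep(3L, 9)), run_id = "r3")
  expect_error(accumulate_observables(list(t1, t3), "hbonds"),
               "normalization failure")

  ## multi-frame run: per-run Nf divides the frame sum
  O3 <- accumulate_observables(list(t3), "hbonds")
  expect_equal(unname(O3[, "A"]), rep(2, 9))   # (1+3)/2

  ## the run and global Nf conventions give identical E after normalization
  O_run <- accumulate_observables(list(t1, t2), "hbonds", nf_convention = "run")
  O_glob <- accumulate_observables(list(t1, t2), "hbonds", nf_convention = "global")
  expect_equal(build_matrix(O_run, pseudocount = 1e-9)$E,
               build_matrix(O_glob, pseudocount = 5e-10)$E, tolerance = 1e-6)
})

test_that("the scoring-energy transform normalizes every position", {
  ## uniform O: E is ln 20 everywhere
  O <- matrix(3.7, 9, 20, dimnames = list(1:9, aa_alphabet()))
  m <- build_matrix(O)
  expect_equal(unname(m$E), matrix(log(20), 9, 20), tolerance = 1e-12)
  expect_equal(rowSums(exp(-m$E)), setNames(rep(1, 9), 1:9), tolerance = 1e-12)

  ## closed form on a reduced 2-letter alphabet with zero pseudocount
  O2 <- matrix(c(3, 1), nrow = 1, dimnames = list(1, c("A", "C")))
  m2 <- build_matrix(O2, pseudocount = 0)
  expect_equal(unname(m2$E[1, ]), c(-log(0.75), -log(0.25)), tolerance = 1e-12)
  expect_equal(round(unname(m2$E[1, ]), 4), c(0.2877, 1.3863))

  ## a single observed amino acid scores best; unseen ones tie
  O3 <- matrix(0, 1, 20, dimnames = list(1, aa_alphabet()))
  O3[1, "A"] <- 1
  m3 <- build_matrix(O3)
  expect_true(all(m3$E[1, "A"] < m3$E[1, colnames(m3$E) != "A"]))
  expect_equal(length(unique(round(m3$E[1, colnames(m3$E) != "A"], 9))), 1)
  expect_true(all(is.finite(m3$E)))

  ## degenerate inputs
  expect_error(build_matrix(O3 * 0, pseudocount = 0), "all-zero position")
  expect_error(build_matrix(O3 - 5), "non-negative")

  ## E is invariant under global rescaling of O (pseudocount scaled too)
  set.seed(8)
  O4 <- matrix(runif(180), 9, 20, dimnames = list(1:9, aa_alphabet()))
  m4a <- build_matrix(O4, pseudocount = 1e-4)
  m4b <- build_matrix(10 * O4, pseudocount = 1e-3)
  expect_equal(m4a$E, m4b$E, tolerance = 1e-10)
})

test_that("core scores are additive position sums over E", {
  O <- matrix(1, 9, 20, dimnames = list(1:9, aa_alphabet()))
  uni <- build_matrix(O)
  expect_equal(score_core(uni, "ACDEFGHIK"), 9 * log(20), tolerance = 1e-9)

  set.seed(9)
  O2 <- matrix(runif(180, 0.1, 2), 9, 20, dimnames = list(1:9, aa_alphabet()))
  m <- build_matrix(O2)
  base <- "ACDEFGHIK"
  ## single-position change shifts the score by the single-cell difference
  mut <- "ACDEFGHIY"
  expect_equal(score_core(m, mut) - score_core(m, base),
               m$E[9, "Y"] - m$E[9, "K"], tolerance = 1e-12)
  ## exhaustive single-position variants rank exactly as that E column
  variants <- vapply(aa_alphabet(), function(a) {
    s <- base
    substr(s, 5, 5) <- a
    score_core(m, s)
  }, numeric(1))
  expect_equal(order(variants), order(m$E[5, ]))
  expect_error(score_core(m, "ACDEFGHIZ"), "nonstandard")
})

test_that("frequency export inverts the transform and round-trips", {
  O <- matrix(1, 9, 20, dimnames = list(1:9, aa_alphabet()))
  expect_equal(unname(export_frequency_logo(build_matrix(O))),
               matrix(0.05, 9, 20), tolerance = 1e-12)

  ## identical peptides give one-hot columns
  f <- export_frequency_logo(rep("ACDEFGHIK", 5))
  expect_equal(unname(f[1, "A"]), 1)
  expect_equal(rowSums(f), setNames(rep(1, 9), 1:9))

  ## rebuild from exported frequencies: identical E
  set.seed(10)
  O2 <- matrix(runif(180, 0.05, 3), 9, 20, dimnames = list(1:9, aa_alphabet()))
  m <- build_matrix(O2)
  m2 <- build_matrix(export_frequency_logo(m), pseudocount = 0)
  expect_equal(m2$E, m$E, tolerance = 1e-12)
})

test_that("matrix serialization round-trips through TSV + JSON", {
  set.seed(11)
  O <- matrix(runif(180, 0, 2), 9, 20, dimnames = list(1:9, aa_alphabet()))
  m <- build_matrix(O, observable = "contacts", strategy = "last_half")
  prefix <- tempfile()
  write_struct_matrix(m, prefix)
  back <- read_struct_matrix(prefix)
  expect_equal(back$E, m$E, tolerance = 1e-9)
  expect_equal(back$O, m$O, tolerance = 1e-9)
  expect_equal(back$observable, "contacts")
  expect_equal(back$strategy, "last_half")
})
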