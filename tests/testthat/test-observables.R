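## Fixtures: small hand-built frames where counts are forced, plus the toy
## generator whose planted counts are known by construction.

two_atom_ensemble <- function(d) {
  at <- data.frame(
    chain = c(rep("P", 36), "R"),
    resno = c(rep(1:9, each = 4), 100),
    resid = c(rep("ALA", 36), "GLY"),
    elety = c(rep(c("N", "CA", "C", "O"), 9), "CA"),
    elesy = c(rep(c("N", "C", "C", "O"), 9), "C"),
    stringsAsFactors = FALSE)
  ## residues spread far apart along x; the single receptor atom is placed
  ## d Angstrom from residue 1's CA in y
  co <- matrix(0, nrow = 37, ncol = 3)
  for (r in 1:9) {
    co[(r - 1) * 4 + 1:4, ] <- cbind(20 * (r - 1) + c(0, 1.45, 2.4, 2.4),
                                     c(0, 0, 0.8, 2.03), 0)
  }
  co[37, ] <- c(1.45, -d, 0)
  ensemble_complex(at, matrix(as.vector(t(co)), nrow = 1), "P", "R", 0)
}

test_that("contact counting respects the inclusive 4 A boundary", {
  expect_equal(count_contacts(two_atom_ensemble(5.0))$total, 0)
  exactly4 <- count_contacts(two_atom_ensemble(4.0))
  expect_equal(exactly4$total, 1)
  expect_equal(unname(exactly4$per_position["1"]), 1L)
  expect_equal(count_contacts(two_atom_ensemble(3.99))$total, 1)
  expect_error(count_contacts(two_atom_ensemble(3), cutoff = -1), "positive")
})

test_that("contact counts equal the brute-force all-pairs oracle", {
  for (seed in 1:25) {
    ens <- random_box_ensemble(seed, n_receptor = 60)
    got <- count_contacts(ens, 0)
    expect_identical(unname(got$per_position), oracle_contact_counts(ens, 0))
  }
})

test_that("contacts and H-bonds are invariant under rigid-body motion", {
  toy <- make_toy_complex(toy_complex_spec(
    n_frames = 2, peptide_length = 11, core_start = 1,
    planted_contacts = c(4, 2, 5, 0, 4, 3, 2, 2, 2),
    planted_hbonds = c(1, 0, 1, 0, 2, 0, 0, 1, 0),
    jitter_sd = 0.02, seed = 9))
  ens <- toy$ensemble
  moved <- rigid_transform(ens, axis = c(2, -1, 3), angle = 71,
                           shift = c(-8, 4, 13))
  for (f in 0:1) {
    expect_equal(count_contacts(moved, f)$per_position,
                 count_contacts(ens, f)$per_position)
    expect_equal(count_backbone_hbonds(moved, f)$per_position,
                 count_backbone_hbonds(ens, f)$per_position)
  }
})

test_that("an idealized near-linear amide-carbonyl pair is one H-bond", {
  toy <- make_toy_complex(toy_complex_spec(
    n_frames = 1, peptide_length = 11, core_start = 1,
    planted_contacts = rep(2L, 9), planted_hbonds = rep(0L, 9),
    jitter_sd = 0, seed = 1))
  ens <- toy$ensemble
  at <- ens$atoms
  co <- frame_coords(ens, 0)
  ## construct an acceptor 2.9 A from the amide N of core position 3,
  ## along the N-H direction (near-linear N-H...O geometry)
  rn <- ens$core$core_resno[3]
  n_pos <- co[at$chain == "C" & at$resno == rn & at$elety == "N", ]
  ca <- co[at$chain == "C" & at$resno == rn & at$elety == "CA", ]
  cprev <- co[at$chain == "C" & at$resno == rn - 1 & at$elety == "C", ]
  h <- place_amide_hydrogen(n_pos, ca, cprev)
  place_acc <- function(dist) {
    acc_pos <- n_pos + dist * (h - n_pos) / sqrt(sum((h - n_pos)^2))
    atoms <- rbind(at, data.frame(chain = "B", resno = 900, resid = "GLY",
                                  elety = "O1", elesy = "O"))
    ensemble_complex(atoms, matrix(as.vector(t(rbind(co, acc_pos))), nrow = 1),
                     "C", c("A", "B"), 1)
  }
  near <- count_backbone_hbonds(place_acc(2.9))
  expect_equal(unname(near$per_position["3"]), 1L)
  ## same geometry at 5.0 A fails the distance criterion
  far <- count_backbone_hbonds(place_acc(5.0))
  expect_equal(unname(far$per_position["3"]), 0L)
})

test_that("planted H-bonds are found and single-criterion decoys are not", {
  toy <- make_toy_complex(toy_complex_spec(
    n_frames = 4, peptide_length = 11, core_start = 1,
    planted_contacts = c(4, 4, 6, 2, 4, 4, 4, 2, 4),
    planted_hbonds = c(1, 0, 2, 0, 1, 0, 0, 1, 0),
    decoy_hbonds =   c(0, 1, 0, 0, 0, 1, 1, 0, 1),
    jitter_sd = 0.02, seed = 13))
  for (f in 0:3) {
    hb <- count_backbone_hbonds(toy$ensemble, f)
    expect_equal(unname(hb$per_position), unname(toy$truth$hbonds))
  }
})

test_that("H-bond counts equal the independent donor-acceptor enumerator", {
  for (seed in 1:20) {
    ens <- random_hbond_ensemble(seed, n_acceptors = 25)
    got <- count_backbone_hbonds(ens, 0)
    expect_identical(unname(got$per_position), oracle_hbond_counts(ens, 0))
  }
})

test_that("amide hydrogen placement obeys its geometric constraints", {
  n <- c(0, 0, 0); ca <- c(1.45, 0.3, -0.2); cprev <- c(-1.1, 0.8, 0.4)
  h <- place_amide_hydrogen(n, ca, cprev)
  expect_equal(sqrt(sum((h - n)^2)), 1.0, tolerance = 1e-9)
  ## bisector symmetry: angle C(i-1)-N-H equals angle CA-N-H
  ang <- function(a, b, c) {
    u <- (a - b) / sqrt(sum((a - b)^2)); w <- (c - b) / sqrt(sum((c - b)^2))
    acos(sum(u * w)) * 180 / pi
  }
  expect_equal(ang(cprev, n, h), ang(ca, n, h), tolerance = 1e-6)
  ## H is coplanar with C(i-1), N, CA
  nrm <- pracma_cross <- function(u, v) c(u[2]*v[3]-u[3]*v[2],
                                          u[3]*v[1]-u[1]*v[3],
                                          u[1]*v[2]-u[2]*v[1])
  plane_normal <- nrm(cprev - n, ca - n)
  expect_equal(abs(sum((h - n) * plane_normal / sqrt(sum(plane_normal^2)))),
               0, tolerance = 1e-9)
  ## colinear backbone is degenerate
  expect_error(place_amide_hydrogen(n, c(1, 0, 0), c(-1, 0, 0)), "degenerate")
})

test_that("proline and chain-start residues never donate", {
  toy <- make_toy_complex(toy_complex_spec(
    n_frames = 1, peptide_length = 9, core_start = 0,
    planted_contacts = rep(0L, 9), planted_hbonds = rep(0L, 9),
    peptide_sequence = "PAAAAAAAA", jitter_sd = 0, seed = 2))
  ens <- toy$ensemble
  ## smother the first two residues' amide regions with acceptors; no
  ## donor exists there (position 1 = chain start AND proline)
  at <- ens$atoms
  co <- frame_coords(ens, 0)
  n1 <- co[at$chain == "C" & at$resno == 1 & at$elety == "N", ]
  acc <- rbind(n1 + c(0, -2.5, 0), n1 + c(0, 0, 2.5))
  atoms <- rbind(at, data.frame(chain = "B", resno = c(901, 902),
                                resid = "GLY", elety = "O1", elesy = "O"))
  ens2 <- ensemble_complex(atoms, matrix(as.vector(t(rbind(co, acc))), nrow = 1),
                           "C", c("A", "B"), 0)
  expect_equal(unname(count_backbone_hbonds(ens2)$per_position["1"]), 0L)
})

test_that("ensemble summaries average per-frame totals", {
  toy <- make_toy_complex(toy_complex_spec(
    n_frames = 6, peptide_length = 11, core_start = 1,
    planted_contacts = c(2, 0, 1, 0, 1, 1, 0, 1, 1),
    planted_hbonds = rep(0L, 9), jitter_sd = 0.02, seed = 4))
  tab <- observable_table(toy$ensemble, run_id = "r1")
  s <- summarize_ensemble(tab)
  expect_equal(s$mean_contacts, 7)   # constant per-frame total: planted sum
  expect_equal(s$sd_contacts, 0)
  expect_equal(s$mean_hbonds, 0)
  expect_error(summarize_ensemble(tab[0, ]), "empty")

  ## grand average = column means of the per-ensemble summaries, 1 decimal
  sums <- data.frame(mean_contacts = c(10, 11, 14), sd_contacts = c(1, 2, 3))
  expect_equal(unname(grand_average(sums)["mean_contacts"]), 11.7)
})
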