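## Synthetic-data generators: toy peptide--receptor ensembles whose
## contact / hydrogen-bond counts are known by construction, peptide
## cohorts with activities produced by a planted scoring matrix, and
## synthetic per-method score tables. Everything is bit-reproducible under
## a seed and requires no external inputs.
##
## Toy geometry: an extended 9-mer-core peptide backbone laid along the x
## axis (residue spacing 7 A; per-residue N, CA, C, O), with receptor probe
## atoms placed at exact distances realizing planted per-position contact
## counts and receptor acceptor oxygens placed on the amide N-H axes to
## realize planted hydrogen-bond counts. Planted acceptors necessarily sit
## inside the 4 A contact shell of their residue, so the generator first
## counts those induced contacts (internal brute-force scan) and only
## plants the remainder as probes. Per-frame jitter is norm-clamped at
## JITTER_CLAMP per atom and the base geometry is validated to keep every
## pair far enough from every criterion boundary that no planted count can
## flip under jitter.

RES_SPACING <- 7.0     # A between consecutive residues along x
JITTER_CLAMP <- 0.1    # max per-atom displacement per frame, A
CONTACT_MARGIN <- 0.22 # min distance of any pair from the 4.0 A boundary
PROBE_RADIUS <- 3.3    # contact probe distance from the carbonyl O
N_PROBE_SLOTS <- 15

#' Specification of a toy peptide--receptor ensemble
#'
#' @param n_frames number of frames (>= 1).
#' @param peptide_length peptide length, 9..15.
#' @param core_start 0-based offset of the 9-mer core.
#' @param planted_contacts integer vector of length 9: target contact count
#'   per core position.
#' @param planted_hbonds integer vector of length 9: target main-chain
#'   hydrogen-bond count per core position (0..2; positions whose residue
#'   has no preceding residue cannot donate and must be 0).
#' @param decoy_hbonds integer vector of length 9: acceptors placed to
#'   violate exactly the donor-H-acceptor angle criterion (0..2).
#' @param peptide_sequence optional peptide sequence (default poly-Ala).
#' @param jitter_sd per-coordinate Gaussian jitter (A) applied to every
#'   frame; displacements are norm-clamped so planted counts never change.
#' @param seed RNG seed for jitter and per-frame energies.
#' @return List of class `ToyComplexSpec`.
#' @export
toy_complex_spec <- function(n_frames = 10, peptide_length = 11,
                             core_start = 1,
                             planted_contacts = rep(2L, 9),
                             planted_hbonds = rep(0L, 9),
                             decoy_hbonds = rep(0L, 9),
                             peptide_sequence = NULL,
                             jitter_sd = 0.02, seed = 1) {
  if (n_frames < 1) stop("need at least one frame")
  if (peptide_length < 9 || peptide_length > 15) stop("peptide_length must be 9..15")
  if (core_start < 0 || core_start + 9 > peptide_length) stop("core window out of range")
  for (v in list(planted_contacts, planted_hbonds, decoy_hbonds)) {
    if (length(v) != 9 || any(v < 0) || any(v != round(v))) {
      stop("planted counts must be length-9 non-negative integer vectors")
    }
  }
  peptide_sequence <- peptide_sequence %||%
    paste(rep("A", peptide_length), collapse = "")
  if (nchar(peptide_sequence) != peptide_length) {
    stop("peptide_sequence length disagrees with peptide_length")
  }
  check_sequence(peptide_sequence)
  if (jitter_sd < 0) stop("jitter_sd must be non-negative")
  structure(list(n_frames = as.integer(n_frames),
                 peptide_length = as.integer(peptide_length),
                 core_start = as.integer(core_start),
                 planted_contacts = as.integer(planted_contacts),
                 planted_hbonds = as.integer(planted_hbonds),
                 decoy_hbonds = as.integer(decoy_hbonds),
                 peptide_sequence = peptide_sequence,
                 jitter_sd = jitter_sd, seed = as.integer(seed)),
            class = "ToyComplexSpec")
}

## base backbone coordinates for residue index r (1-based within peptide)
toy_backbone <- function(r) {
  x0 <- RES_SPACING * (r - 1)
  rbind(N  = c(x0, 0, 0),
        CA = c(x0 + 1.45, 0, 0),
        C  = c(x0 + 2.40, 0.80, 0),
        O  = c(x0 + 2.40, 2.03, 0))
}

## direction of the amide hydrogen for residue r (unit vector from N)
toy_h_direction <- function(r) {
  bb <- toy_backbone(r)
  bb_prev <- toy_backbone(r - 1)
  h <- place_amide_hydrogen(bb["N", ], bb["CA", ], bb_prev["C", ])
  unit_vec(h - bb["N", ])
}

## brute-force per-core-position contact count of a coordinate set
bf_contact_counts <- function(atoms, coords, peptide_chain, receptor_chains,
                              core_resno, cutoff = 4.0) {
  counts <- integer(9)
  rec <- which(atoms$chain %in% receptor_chains & atoms$elesy != "H")
  for (i in 1:9) {
    pep <- which(atoms$chain == peptide_chain &
                 atoms$resno == core_resno[i] & atoms$elesy != "H")
    for (p in pep) for (q in rec) {
      if (vnorm(coords[p, ] - coords[q, ]) <= cutoff) counts[i] <- counts[i] + 1L
    }
  }
  counts
}

#' Generate a toy ensemble with known observable counts
#'
#' Builds the rigid two-chain scaffold described in [toy_complex_spec()],
#' realizes the planted counts exactly, validates them (and their jitter
#' margins) with an internal brute-force scan, and attaches per-frame
#' energies drawn from a standard normal. Unachievable planted counts
#' raise a capacity failure explaining the limit.
#'
#' @param spec a `ToyComplexSpec`.
#' @return List with `ensemble` (an `EnsembleComplex`; peptide chain "C",
#'   receptor chains "A", "B") and `truth` (list with per-position
#'   `contacts` and `hbonds`, valid for every frame).
#' @export
make_toy_complex <- function(spec) {
  stopifnot(inherits(spec, "ToyComplexSpec"))
  L <- spec$peptide_length
  core_res <- spec$core_start + 1:9        # 1-based residue indices of core
  seq1 <- strsplit(spec$peptide_sequence, "")[[1]]

  atoms <- list()
  coords <- list()
  add_atom <- function(chain, resno, resid, elety, elesy, pos) {
    atoms[[length(atoms) + 1]] <<- data.frame(
      chain = chain, resno = resno, resid = resid, elety = elety,
      elesy = elesy, stringsAsFactors = FALSE)
    coords[[length(coords) + 1]] <<- pos
  }

  for (r in seq_len(L)) {
    bb <- toy_backbone(r)
    for (nm in rownames(bb)) {
      add_atom("C", r, AA1TO3[seq1[r]], nm, substr(nm, 1, 1), bb[nm, ])
    }
  }
  ## receptor anchors so both chains always exist
  add_atom("A", 999, "GLY", "CA", "C", c(-10, -20, 0))
  add_atom("B", 998, "GLY", "CA", "C", c(10 + RES_SPACING * L, -20, 0))

  ## hydrogen-bond acceptors (chain B) and angle-violating decoys
  for (i in 1:9) {
    k <- spec$planted_hbonds[i]
    kd <- spec$decoy_hbonds[i]
    if (k == 0 && kd == 0) next
    r <- core_res[i]
    if (r < 2) {
      stop("capacity failure: position ", i, " has no preceding residue, ",
           "its amide cannot donate a hydrogen bond")
    }
    if (seq1[r] == "P") {
      stop("capacity failure: proline at position ", i, " cannot donate")
    }
    if (k > 2 || kd > 2) {
      stop("capacity failure: at most 2 planted (and 2 decoy) hydrogen ",
           "bonds per position")
    }
    bb <- toy_backbone(r)
    hdir <- toy_h_direction(r)
    h <- bb["N", ] + hdir
    dirs <- list(hdir, rotate_about_axis(hdir, c(1, 0, 0), 35))
    for (j in seq_len(k)) {
      add_atom("B", 200 + 10 * i + j, "GLY", "O1", "O", h + 2.0 * dirs[[j]])
    }
    ddirs <- list(rotate_about_axis(-hdir, c(1, 0, 0), 60),
                  rotate_about_axis(-hdir, c(1, 0, 0), -60))
    for (j in seq_len(kd)) {
      add_atom("B", 300 + 10 * i + j, "GLY", "O1", "O", h + 2.0 * ddirs[[j]])
    }
  }

  ## contacts induced by the acceptor/decoy atoms, then probe placement
  at0 <- do.call(rbind, atoms)
  co0 <- do.call(rbind, coords)
  induced <- bf_contact_counts(at0, co0, "C", c("A", "B"), core_res)
  probe_dirs <- expand.grid(phi = c(0, 15, -15, 30, -30), dx = c(0, 0.8, -0.8))
  for (i in 1:9) {
    need <- spec$planted_contacts[i] - induced[i]
    if (need < 0) {
      stop("capacity failure: planted hydrogen bonds at position ", i,
           " already induce ", induced[i], " contacts, more than the ",
           spec$planted_contacts[i], " planted")
    }
    if (need > N_PROBE_SLOTS) {
      stop("capacity failure: at most ", N_PROBE_SLOTS,
           " probe contacts per position (need ", need, " at position ", i, ")")
    }
    if (need == 0) next
    bb <- toy_backbone(core_res[i])
    for (j in seq_len(need)) {
      phi <- probe_dirs$phi[j] * pi / 180
      pos <- bb["O", ] + c(probe_dirs$dx[j],
                           PROBE_RADIUS * cos(phi), PROBE_RADIUS * sin(phi))
      add_atom("A", 100 + i, "GLY", paste0("C", j), "C", pos)
    }
  }

  at <- do.call(rbind, atoms)
  co <- do.call(rbind, coords)

  ## --- validation of the base geometry against the planted truth ---
  got_contacts <- bf_contact_counts(at, co, "C", c("A", "B"), core_res)
  if (!identical(got_contacts, spec$planted_contacts)) {
    stop("internal geometry failure: realized contacts (",
         paste(got_contacts, collapse = ","), ") != planted (",
         paste(spec$planted_contacts, collapse = ","), ")")
  }
  ## no peptide-receptor pair may sit near the contact boundary
  rec <- which(at$chain %in% c("A", "B"))
  pep <- which(at$chain == "C" & at$resno %in% core_res)
  for (p in pep) for (q in rec) {
    d <- vnorm(co[p, ] - co[q, ])
    if (abs(d - 4.0) < CONTACT_MARGIN) {
      stop("internal geometry failure: pair at ", round(d, 3),
           " A is too close to the 4.0 A cutoff to survive jitter")
    }
  }
  ## brute-force hydrogen-bond check: peptide amide donors vs receptor O
  crit <- hbond_criteria()
  got_hb <- integer(9)
  acc <- which(at$chain %in% c("A", "B") & at$elesy == "O")
  for (i in 1:9) {
    r <- core_res[i]
    if (r < 2 || seq1[r] == "P") next
    bb <- toy_backbone(r)
    h <- bb["N", ] + toy_h_direction(r)
    for (q in acc) {
      if (hbond_pair_ok(bb["N", ], h, co[q, ], NULL, crit)) {
        got_hb[i] <- got_hb[i] + 1L
      }
    }
  }
  if (!identical(got_hb, spec$planted_hbonds)) {
    stop("internal geometry failure: realized hydrogen bonds (",
         paste(got_hb, collapse = ","), ") != planted (",
         paste(spec$planted_hbonds, collapse = ","), ")")
  }

  ## --- frames: jitter (norm-clamped) + energies ---
  set.seed(spec$seed)
  n_at <- nrow(at)
  xyz <- matrix(NA_real_, nrow = spec$n_frames, ncol = 3 * n_at)
  for (f in seq_len(spec$n_frames)) {
    if (spec$jitter_sd > 0) {
      disp <- matrix(rnorm(3 * n_at, sd = spec$jitter_sd), ncol = 3)
      nrm <- sqrt(rowSums(disp^2))
      over <- nrm > JITTER_CLAMP
      disp[over, ] <- disp[over, ] * (JITTER_CLAMP / nrm[over])
      xyz[f, ] <- as.vector(t(co + disp))
    } else {
      xyz[f, ] <- as.vector(t(co))
    }
  }
  energies <- rnorm(spec$n_frames)
  ens <- ensemble_complex(at, xyz, "C", c("A", "B"), spec$core_start, energies)
  list(ensemble = ens,
       truth = list(contacts = spec$planted_contacts,
                    hbonds = spec$planted_hbonds))
}

#' A planted 9 x 20 scoring matrix
#'
#' Per position, the 20 amino acids receive a random permutation of 20
#' linearly spaced frequency weights with a 6-fold spread (0.5 to 3.0),
#' normalized and log-transformed so the result is a legal scoring-energy
#' grid (`sum_j exp(-E_ij) = 1`).
#'
#' @param seed RNG seed.
#' @return 9 x 20 numeric matrix (positions x [aa_alphabet()]).
#' @export
default_planted_matrix <- function(seed = 1) {
  set.seed(seed)
  E <- matrix(0, 9, 20, dimnames = list(1:9, aa_alphabet()))
  w <- seq(0.5, 3.0, length.out = 20)
  for (i in 1:9) {
    p <- sample(w)
    E[i, ] <- -log(p / sum(p))
  }
  E
}

#' Specification of a planted peptide cohort
#'
#' @param n_peptides cohort size.
#' @param planted_E 9 x 20 scoring-energy grid (default
#'   [default_planted_matrix()] under `seed`).
#' @param activity_noise_sd lognormal activity noise, in log-nM units.
#' @param slope_scale multiplier on the calibrated activity slope `b`
#'   (default 1; 0 makes activities independent of sequence, the null
#'   model).
#' @param seed RNG seed.
#' @return List of class `PlantedCohortSpec`.
#' @export
planted_cohort_spec <- function(n_peptides = 500, planted_E = NULL,
                                activity_noise_sd = 0, slope_scale = 1,
                                seed = 1) {
  planted_E <- planted_E %||% default_planted_matrix(seed)
  if (!is.matrix(planted_E) || any(dim(planted_E) != c(9, 20))) {
    stop("planted_E must be a 9 x 20 matrix")
  }
  norm <- rowSums(exp(-planted_E))
  if (any(abs(norm - 1) > 1e-6)) {
    stop("planted_E rows must satisfy sum_j exp(-E_ij) = 1")
  }
  if (n_peptides < 1) stop("n_peptides must be positive")
  if (activity_noise_sd < 0) stop("activity_noise_sd must be non-negative")
  structure(list(n_peptides = as.integer(n_peptides), planted_E = planted_E,
                 activity_noise_sd = activity_noise_sd,
                 slope_scale = slope_scale, seed = as.integer(seed)),
            class = "PlantedCohortSpec")
}

## activity calibration: activities span 1..10,000 nM over the achievable
## score range of the planted matrix
activity_calibration <- function(planted_E) {
  s_min <- sum(apply(planted_E, 1, min))
  s_max <- sum(apply(planted_E, 1, max))
  b <- log(1e4) / (s_max - s_min)
  list(a = -b * s_min, b = b)
}

#' Generate a peptide cohort from a planted scoring matrix
#'
#' Peptide cores are drawn per position from the planted frequencies
#' `exp(-E)`; the activity of a peptide with total score
#' `S = sum_i E[i, aa_i]` is `exp(a + b*S + eps)`,
#' `eps ~ N(0, activity_noise_sd)`, with `a`, `b` fixed so noise-free
#' activities span 1 to 10,000 nM. Lower activity = stronger binder, so at
#' zero noise the sign of any single-substitution activity difference
#' equals the sign of the planted E difference by construction.
#'
#' @param spec a `PlantedCohortSpec`.
#' @return List with `peptides` (data.frame: `sequence`, `core_start`,
#'   `activity_nM`, `score`) and `planted` (list: `E`, `a`, `b`,
#'   `activity_noise_sd`).
#' @export
make_planted_cohort <- function(spec) {
  stopifnot(inherits(spec, "PlantedCohortSpec"))
  set.seed(spec$seed)
  E <- spec$planted_E
  aa <- colnames(E)
  cal <- activity_calibration(E)
  n <- spec$n_peptides
  idx <- matrix(0L, nrow = n, ncol = 9)
  for (i in 1:9) {
    idx[, i] <- sample.int(20, n, replace = TRUE, prob = exp(-E[i, ]))
  }
  seqs <- apply(idx, 1, function(r) paste(aa[r], collapse = ""))
  scores <- vapply(seq_len(n), function(k) sum(E[cbind(1:9, idx[k, ])]),
                   numeric(1))
  eps <- if (spec$activity_noise_sd > 0) rnorm(n, 0, spec$activity_noise_sd) else 0
  act <- exp(cal$a + spec$slope_scale * cal$b * scores + eps)
  list(peptides = data.frame(sequence = seqs, core_start = 0L,
                             activity_nM = act, score = scores,
                             stringsAsFactors = FALSE),
       planted = list(E = E, a = cal$a, b = spec$slope_scale * cal$b,
                      activity_noise_sd = spec$activity_noise_sd))
}

#' Planted contact counts for one core under the observable coupling
#'
#' Ties the toy-ensemble observables to the same planted matrix that
#' produced the activities: the contact count of amino acid `j` at
#' position `i` is `1 + round(gain * p_ij / max_j p_ij)` with
#' `p = exp(-E)`, a monotone function of the planted frequency. `gain`
#' controls how strongly the structural signal tracks the planted matrix
#' (`gain = 0` removes the coupling; counts become constant).
#'
#' @param planted_E 9 x 20 scoring-energy grid.
#' @param core 9-letter core sequence.
#' @param gain non-negative coupling strength (default 9; counts then span
#'   1..10, within the generator's capacity).
#' @return Integer vector of length 9.
#' @export
planted_counts <- function(planted_E, core, gain = 9) {
  aa <- check_sequence(core)
  p <- exp(-planted_E)
  j <- match(aa, colnames(planted_E))
  as.integer(1 + round(gain * p[cbind(1:9, j)] / apply(p, 1, max)))
}

#' Toy ensembles for a whole cohort
#'
#' One toy complex per peptide, with planted contact counts coupled to the
#' cohort's planted matrix via [planted_counts()].
#'
#' @param cohort result of [make_planted_cohort()].
#' @param gain coupling strength passed to [planted_counts()].
#' @param n_frames frames per ensemble.
#' @param jitter_sd frame jitter in Angstrom.
#' @param seed base seed; ensemble `k` uses `seed + k`.
#' @return List of `EnsembleComplex` objects, one per peptide.
#' @export
make_cohort_ensembles <- function(cohort, gain = 9, n_frames = 1,
                                  jitter_sd = 0, seed = 1) {
  peps <- cohort$peptides
  lapply(seq_len(nrow(peps)), function(k) {
    core <- peps$sequence[k]
    spec <- toy_complex_spec(
      n_frames = n_frames, peptide_length = nchar(core),
      core_start = peps$core_start[k],
      planted_contacts = planted_counts(cohort$planted$E, core, gain),
      planted_hbonds = rep(0L, 9), jitter_sd = jitter_sd,
      peptide_sequence = core, seed = seed + k)
    make_toy_complex(spec)$ensemble
  })
}

#' Generate single-substitution mutation pairs from a planted matrix
#'
#' Base cores are drawn from the planted frequencies; one position is
#' mutated to a random different amino acid; activities follow the same
#' planted model as [make_planted_cohort()], with lognormal noise. Pair
#' roles follow the package convention (wild type = stronger binder).
#'
#' @param planted_E 9 x 20 scoring-energy grid.
#' @param n_pairs number of pairs.
#' @param activity_noise_sd lognormal activity noise (log-nM units).
#' @param slope_scale multiplier on the calibrated activity slope (0 =
#'   null model: activities independent of the planted matrix).
#' @param seed RNG seed.
#' @return data.frame in the [make_pairs()] layout.
#' @export
make_mutation_pairs <- function(planted_E, n_pairs = 100,
                                activity_noise_sd = 0, slope_scale = 1,
                                seed = 1) {
  set.seed(seed)
  aa <- colnames(planted_E)
  cal <- activity_calibration(planted_E)
  j <- matrix(0L, nrow = n_pairs, ncol = 9)
  for (i in 1:9) {
    j[, i] <- sample.int(20, n_pairs, replace = TRUE, prob = exp(-planted_E[i, ]))
  }
  pos <- sample.int(9, n_pairs, replace = TRUE)
  ## mutant amino acid: uniform over the 19 alternatives
  m <- sample.int(19, n_pairs, replace = TRUE)
  jwt <- j[cbind(seq_len(n_pairs), pos)]
  jmut <- m + (m >= jwt)
  j2 <- j
  j2[cbind(seq_len(n_pairs), pos)] <- jmut
  score_of <- function(jm) {
    s <- numeric(n_pairs)
    for (i in 1:9) s <- s + planted_E[i, jm[, i]]
    s
  }
  s1 <- score_of(j)
  s2 <- score_of(j2)
  eps <- if (activity_noise_sd > 0) {
    matrix(rnorm(2 * n_pairs, 0, activity_noise_sd), ncol = 2)
  } else matrix(0, n_pairs, 2)
  a1 <- exp(cal$a + slope_scale * cal$b * s1 + eps[, 1])
  a2 <- exp(cal$a + slope_scale * cal$b * s2 + eps[, 2])
  seq1 <- apply(j, 1, function(r) paste(aa[r], collapse = ""))
  seq2 <- apply(j2, 1, function(r) paste(aa[r], collapse = ""))
  swap <- a2 < a1                     # wild type = stronger binder
  wt_seq <- ifelse(swap, seq2, seq1)
  mut_seq <- ifelse(swap, seq1, seq2)
  data.frame(
    pair_id = sprintf("pair%04d", seq_len(n_pairs)),
    wt_sequence = wt_seq, mut_sequence = mut_seq, core_position = pos,
    wt_aa = substr(wt_seq, pos, pos), mut_aa = substr(mut_seq, pos, pos),
    activity_wt = pmin(a1, a2), activity_mut = pmax(a1, a2),
    stringsAsFactors = FALSE)
}

#' Synthetic score tables for the multi-function consensus
#'
#' Each scoring function's mean-score difference carries the experimental
#' sign of each pair independently with its stated accuracy; per-frame
#' scores add small Gaussian noise around the means (small enough that the
#' sign of the frame-mean difference is effectively never flipped, so the
#' planted accuracies are exact).
#'
#' @param pairs data.frame in the [make_pairs()] layout.
#' @param per_function_accuracy numeric vector of per-function sign
#'   accuracies in `[0, 1]` (its length sets the number of functions;
#'   default six at 0.7).
#' @param frames_per_peptide frames scored per peptide role (default 10).
#' @param frame_noise_sd per-frame score noise (default 0.05).
#' @param seed RNG seed.
#' @return data.frame with columns `pair_id`, `role`, `function_name`,
#'   `frame`, `score` (all functions lower-is-better).
#' @export
make_score_tables <- function(pairs, per_function_accuracy = rep(0.7, 6),
                              frames_per_peptide = 10, frame_noise_sd = 0.05,
                              seed = 1) {
  if (any(per_function_accuracy < 0 | per_function_accuracy > 1)) {
    stop("accuracies must lie in [0, 1]")
  }
  set.seed(seed)
  n_fn <- length(per_function_accuracy)
  n_pr <- nrow(pairs)
  fn_names <- sprintf("fn%d", seq_len(n_fn))
  es <- experimental_sign(pairs$activity_wt, pairs$activity_mut)
  ## one Bernoulli draw per (pair, function), pair-major order
  correct <- runif(n_pr * n_fn) < rep(per_function_accuracy, times = n_pr)
  s <- rep(es, each = n_fn) * ifelse(correct, 1, -1)
  rows_per_fn <- 2L * frames_per_peptide
  n_rows <- n_pr * n_fn * rows_per_fn
  mean_score <- rep(ifelse(rep(rep(c(FALSE, TRUE), each = frames_per_peptide),
                               times = n_pr * n_fn),
                           rep(s, each = rows_per_fn), 0), 1)
  data.frame(
    pair_id = rep(pairs$pair_id, each = n_fn * rows_per_fn),
    role = rep(rep(c("wt", "mut"), each = frames_per_peptide),
               times = n_pr * n_fn),
    function_name = rep(rep(fn_names, each = rows_per_fn), times = n_pr),
    frame = rep(rep(seq_len(frames_per_peptide) - 1L, 2), times = n_pr * n_fn),
    score = mean_score + rnorm(n_rows, 0, frame_noise_sd),
    stringsAsFactors = FALSE)
}
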