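## Independent brute-force oracles and fixture builders used across the
## suite. The oracles are deliberately written as plain double loops,
## separate from the package's vectorized implementations.

## all-pairs contact count per core position
oracle_contact_counts <- function(ens, frame, cutoff = 4.0,
                                  include_hydrogens = FALSE) {
  at <- ens$atoms
  co <- frame_coords(ens, frame)
  heavy <- include_hydrogens | at$elesy != "H"
  rec <- which(at$chain %in% ens$receptor_chains & heavy)
  counts <- integer(9)
  for (i in 1:9) {
    pep <- which(at$chain == ens$peptide_chain &
                 at$resno == ens$core$core_resno[i] & heavy)
    for (p in pep) {
      for (q in rec) {
        if (sqrt(sum((co[p, ] - co[q, ])^2)) <= cutoff) {
          counts[i] <- counts[i] + 1L
        }
      }
    }
  }
  counts
}

## independently coded amide-H construction (the specified geometric rule)
oracle_place_h <- function(n, ca, c_prev) {
  u1 <- (c_prev - n) / sqrt(sum((c_prev - n)^2))
  u2 <- (ca - n) / sqrt(sum((ca - n)^2))
  b <- u1 + u2
  n - b / sqrt(sum(b^2))
}

## main-chain H-bond count per core position for fixtures whose receptor
## side carries acceptors only (no receptor donors): enumerates every
## (peptide amide donor, receptor O / His-N acceptor) pair and applies the
## three geometric criteria independently.
oracle_hbond_counts <- function(ens, frame, d_a_max = 3.9, h_a_max = 2.5,
                                theta_min = 90) {
  at <- ens$atoms
  co <- frame_coords(ens, frame)
  acc <- which(at$chain %in% ens$receptor_chains &
               (at$elesy == "O" |
                (at$resid == "HIS" & at$elety %in% c("ND1", "NE2"))))
  pep_rows <- which(at$chain == ens$peptide_chain)
  resnos <- unique(at$resno[pep_rows])
  counts <- integer(9)
  for (i in 1:9) {
    rn <- ens$core$core_resno[i]
    k <- match(rn, resnos)
    if (k <= 1) next
    rr <- pep_rows[at$resno[pep_rows] == rn]
    if (toupper(at$resid[rr][1]) == "PRO") next
    get1 <- function(rows, name) {
      j <- rows[at$elety[rows] == name]
      if (length(j) == 0) return(NULL)
      co[j[1], ]
    }
    n_pos <- get1(rr, "N")
    ca_pos <- get1(rr, "CA")
    prev_rr <- pep_rows[at$resno[pep_rows] == resnos[k - 1]]
    cprev <- get1(prev_rr, "C")
    if (is.null(n_pos) || is.null(ca_pos) || is.null(cprev)) next
    h <- oracle_place_h(n_pos, ca_pos, cprev)
    for (q in acc) {
      a <- co[q, ]
      da <- sqrt(sum((n_pos - a)^2))
      ha <- sqrt(sum((h - a)^2))
      v1 <- n_pos - h
      v2 <- a - h
      ang <- acos(max(-1, min(1, sum(v1 * v2) /
                     (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))))) * 180 / pi
      if (da <= d_a_max && ha <= h_a_max && ang >= theta_min) {
        counts[i] <- counts[i] + 1L
      }
    }
  }
  counts
}

## random two-chain frame: a 9-residue peptide and a cloud of receptor
## atoms, coordinates uniform in a box sized so some pairs fall under 4 A
random_box_ensemble <- function(seed, n_receptor = 80, n_frames = 1) {
  set.seed(seed)
  atoms <- data.frame(
    chain = c(rep("P", 36), rep("R", n_receptor)),
    resno = c(rep(1:9, each = 4), 100 + seq_len(n_receptor)),
    resid = c(rep("ALA", 36), rep("GLY", n_receptor)),
    elety = c(rep(c("N", "CA", "C", "O"), 9), rep("CA", n_receptor)),
    elesy = c(rep(c("N", "C", "C", "O"), 9), rep("C", n_receptor)),
    stringsAsFactors = FALSE)
  xyz <- matrix(runif(n_frames * 3 * nrow(atoms), 0, 18), nrow = n_frames)
  ensemble_complex(atoms, xyz, "P", "R", core_start = 0)
}

## peptide backbone plus receptor oxygens scattered at 2-6 A from the
## amide region of random core residues: a stochastic H-bond scene
random_hbond_ensemble <- function(seed, n_acceptors = 30) {
  set.seed(seed)
  base <- make_toy_complex(toy_complex_spec(
    n_frames = 1, peptide_length = 11, core_start = 1,
    planted_contacts = rep(0L, 9), planted_hbonds = rep(0L, 9),
    jitter_sd = 0, seed = seed))$ensemble
  at <- base$atoms
  co <- frame_coords(base, 0)
  n_rows <- which(at$chain == "C" & at$elety == "N" &
                  at$resno %in% base$core$core_resno)
  extra <- lapply(seq_len(n_acceptors), function(k) {
    anchor <- co[sample(n_rows, 1), ]
    dir <- rnorm(3)
    dir <- dir / sqrt(sum(dir^2))
    pos <- anchor + runif(1, 2, 6) * dir
    list(atom = data.frame(chain = "B", resno = 500 + k, resid = "GLY",
                           elety = "O1", elesy = "O", stringsAsFactors = FALSE),
         pos = pos)
  })
  atoms <- rbind(at, do.call(rbind, lapply(extra, `[[`, "atom")))
  all_co <- rbind(co, do.call(rbind, lapply(extra, `[[`, "pos")))
  xyz <- matrix(as.vector(t(all_co)), nrow = 1)
  ensemble_complex(atoms, xyz, "C", c("A", "B"), core_start = 1)
}

## rigid-body motion applied to every frame of an ensemble
rigid_transform <- function(ens, axis = c(1, 2, 3), angle = 35,
                            shift = c(5, -3, 2)) {
  k <- axis / sqrt(sum(axis^2))
  th <- angle * pi / 180
  rot1 <- function(v) {
    cr <- c(k[2] * v[3] - k[3] * v[2],
            k[3] * v[1] - k[1] * v[3],
            k[1] * v[2] - k[2] * v[1])
    v * cos(th) + cr * sin(th) + k * sum(k * v) * (1 - cos(th))
  }
  xyz <- ens$xyz
  for (f in seq_len(nrow(xyz))) {
    m <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
    m2 <- t(apply(m, 1, rot1)) + matrix(shift, nrow(m), 3, byrow = TRUE)
    xyz[f, ] <- as.vector(t(m2))
  }
  ens$xyz <- xyz
  ens
}

## spearman rank correlation (wrapper kept for readability in tests)
spearman <- function(x, y) cor(x, y, method = "spearman")
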