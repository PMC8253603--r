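## Structural observables measured per frame: non-bonded peptide--receptor
## contacts and main-chain hydrogen bonds, attributed to the 9 core
## positions. Frames are small (a peptide plus the receptor groove), so all
## detection is done with exact vectorized distance computations; the test
## suite holds an independently written double-loop oracle to the same
## geometric rules.

#' Count non-bonded peptide--receptor contacts in one frame
#'
#' A contact is a (peptide atom, receptor atom) pair at Euclidean distance
#' less than or equal to `cutoff` (inclusive boundary). Only atoms of the
#' peptide's 9-mer core are attributed; hydrogens are excluded by default
#' because crystal-derived frames rarely carry them, keeping counts
#' comparable across inputs.
#'
#' @param ensemble An `EnsembleComplex`.
#' @param frame 0-based frame identifier.
#' @param cutoff contact distance threshold in Angstrom (default 4.0).
#' @param include_hydrogens count hydrogen atoms too (default `FALSE`).
#' @return List with `per_position` (named integer vector, core positions
#'   1..9) and `total` (their sum).
#' @export
count_contacts <- function(ensemble, frame = 0, cutoff = 4.0,
                           include_hydrogens = FALSE) {
  if (cutoff <= 0) stop("cutoff must be positive")
  at <- ensemble$atoms
  co <- frame_coords(ensemble, frame)
  heavy <- include_hydrogens | at$elesy != "H"
  rec <- which(at$chain %in% ensemble$receptor_chains & heavy)
  counts <- integer(9)
  if (length(rec) > 0) {
    rc <- co[rec, , drop = FALSE]
    for (i in 1:9) {
      resno_i <- ensemble$core$core_resno[i]
      pep <- which(at$chain == ensemble$peptide_chain & at$resno == resno_i & heavy)
      if (length(pep) == 0) next
      pc <- co[pep, , drop = FALSE]
      ## squared distances peptide-atoms x receptor-atoms
      d2 <- outer(rowSums(pc^2), rowSums(rc^2), "+") - 2 * pc %*% t(rc)
      counts[i] <- sum(d2 <= cutoff^2 + 1e-12)
    }
  }
  names(counts) <- as.character(1:9)
  list(per_position = counts, total = sum(counts))
}

#' Geometric hydrogen-bond criteria
#'
#' HBPLUS-style geometric definitions: donor--acceptor and
#' hydrogen--acceptor distance caps plus a donor-H-acceptor angle floor.
#' The two auxiliary angle criteria involving the acceptor antecedent
#' (H-A-AA and D-A-AA floors) are available but disabled (`NULL`) by
#' default.
#'
#' @param d_a_max maximum donor--acceptor distance in Angstrom.
#' @param h_a_max maximum hydrogen--acceptor distance in Angstrom.
#' @param theta_min minimum donor-H-acceptor angle in degrees.
#' @param h_a_aa_min optional minimum H-acceptor-antecedent angle (degrees).
#' @param d_a_aa_min optional minimum donor-acceptor-antecedent angle
#'   (degrees).
#' @return List of class `HBondCriteria`.
#' @export
hbond_criteria <- function(d_a_max = 3.9, h_a_max = 2.5, theta_min = 90,
                           h_a_aa_min = NULL, d_a_aa_min = NULL) {
  if (d_a_max <= 0 || h_a_max <= 0) stop("distance caps must be positive")
  structure(list(d_a_max = d_a_max, h_a_max = h_a_max, theta_min = theta_min,
                 h_a_aa_min = h_a_aa_min, d_a_aa_min = d_a_aa_min),
            class = "HBondCriteria")
}

hbond_pair_ok <- function(d_pos, h_pos, a_pos, aa_pos, criteria) {
  if (vnorm(d_pos - a_pos) > criteria$d_a_max) return(FALSE)
  if (vnorm(h_pos - a_pos) > criteria$h_a_max) return(FALSE)
  if (vec_angle(d_pos, h_pos, a_pos) < criteria$theta_min) return(FALSE)
  if (!is.null(criteria$h_a_aa_min) && !is.null(aa_pos)) {
    if (vec_angle(h_pos, a_pos, aa_pos) < criteria$h_a_aa_min) return(FALSE)
  }
  if (!is.null(criteria$d_a_aa_min) && !is.null(aa_pos)) {
    if (vec_angle(d_pos, a_pos, aa_pos) < criteria$d_a_aa_min) return(FALSE)
  }
  TRUE
}

#' Place the backbone amide hydrogen geometrically
#'
#' Crystal-derived frames usually lack hydrogens, so the amide H of a
#' chain-interior, non-proline residue is reconstructed 1.00 Angstrom from
#' N, in the C(i-1)-N-CA plane, opposing the bisector of the C(i-1)-N and
#' CA-N bonds.
#'
#' @param n,ca numeric 3-vectors: backbone N and CA of the residue.
#' @param c_prev numeric 3-vector: carbonyl C of the preceding residue.
#' @return Numeric 3-vector, the hydrogen position.
#' @export
place_amide_hydrogen <- function(n, ca, c_prev) {
  u1 <- unit_vec(c_prev - n)
  u2 <- unit_vec(ca - n)
  b <- u1 + u2
  if (vnorm(b) < 1e-8) stop("degenerate backbone geometry: colinear C(i-1), N, CA")
  n - unit_vec(b)
}

## Enumerate donor and acceptor atoms of an ensemble frame for H-bond
## detection. Returns lists of candidates; each donor carries its hydrogen
## position (explicit from the file, or placed geometrically for backbone
## amides), each acceptor its antecedent when known.
hbond_candidates <- function(at, co, chains, resno_filter = NULL) {
  sel <- at$chain %in% chains
  donors <- list()
  acceptors <- list()
  ## explicit hydrogens: attach to nearest N/O within 1.2 A on same chain
  hyd <- which(sel & at$elesy == "H")
  heavy_no <- which(sel & at$elesy %in% c("N", "O"))
  explicit_h <- rep(FALSE, nrow(at))
  for (h in hyd) {
    if (length(heavy_no) == 0) next
    d <- sqrt(colSums((t(co[heavy_no, , drop = FALSE]) - co[h, ])^2))
    j <- heavy_no[which.min(d)]
    if (min(d) <= 1.2) {
      if (is.null(resno_filter) || at$resno[j] %in% resno_filter) {
        donors[[length(donors) + 1]] <-
          list(d_idx = j, d_pos = co[j, ], h_pos = co[h, ],
               chain = at$chain[j], resno = at$resno[j], elety = at$elety[j])
        explicit_h[j] <- TRUE
      }
    }
  }
  for (ch in chains) {
    rows <- which(at$chain == ch)
    resnos <- unique(at$resno[rows])
    for (k in seq_along(resnos)) {
      rn <- resnos[k]
      if (!is.null(resno_filter) && !(rn %in% resno_filter)) next
      rr <- rows[at$resno[rows] == rn]
      resid <- at$resid[rr][1]
      get_atom <- function(name) {
        i <- rr[at$elety[rr] == name]
        if (length(i) == 0) NULL else co[i[1], ]
      }
      n_pos <- get_atom("N")
      o_pos <- get_atom("O")
      c_pos <- get_atom("C")
      ## backbone amide donor: needs preceding residue's C, not proline
      ni <- rr[at$elety[rr] == "N"]
      if (!is.null(n_pos) && toupper(resid) != "PRO" && k > 1 &&
          !(length(ni) == 1 && explicit_h[ni])) {
        prev_rr <- rows[at$resno[rows] == resnos[k - 1]]
        cp <- prev_rr[at$elety[prev_rr] == "C"]
        ca <- rr[at$elety[rr] == "CA"]
        if (length(cp) > 0 && length(ca) > 0) {
          h_pos <- tryCatch(
            place_amide_hydrogen(n_pos, co[ca[1], ], co[cp[1], ]),
            error = function(e) NULL)
          if (!is.null(h_pos)) {
            donors[[length(donors) + 1]] <-
              list(d_idx = ni[1], d_pos = n_pos, h_pos = h_pos,
                   chain = ch, resno = rn, elety = "N")
          }
        }
      }
      ## acceptors: every O atom (antecedent = carbonyl C for backbone O),
      ## plus histidine ring nitrogens
      for (i in rr[at$elesy[rr] == "O"]) {
        ante <- if (at$elety[i] == "O" && !is.null(c_pos)) c_pos else NULL
        acceptors[[length(acceptors) + 1]] <-
          list(a_idx = i, a_pos = co[i, ], aa_pos = ante,
               chain = ch, resno = rn, elety = at$elety[i])
      }
      if (toupper(resid) == "HIS") {
        for (i in rr[at$elety[rr] %in% c("ND1", "NE2")]) {
          acceptors[[length(acceptors) + 1]] <-
            list(a_idx = i, a_pos = co[i, ], aa_pos = NULL,
                 chain = ch, resno = rn, elety = at$elety[i])
        }
      }
    }
  }
  list(donors = donors, acceptors = acceptors)
}

#' Count main-chain hydrogen bonds of the peptide core in one frame
#'
#' Counts hydrogen bonds whose peptide-side partner is a main-chain atom of
#' a core residue: the amide nitrogen donating to any receptor acceptor, or
#' the carbonyl oxygen accepting from any receptor donor. Receptor
#' acceptors are all oxygen atoms plus histidine ring nitrogens; receptor
#' donors are backbone amides (hydrogens placed geometrically when absent)
#' and any N/O with an explicit hydrogen in the file. A bond passes when
#' donor--acceptor distance, hydrogen--acceptor distance and the
#' donor-H-acceptor angle all satisfy `criteria`. Core residues lacking
#' backbone atoms are skipped with a warning.
#'
#' @inheritParams count_contacts
#' @param criteria an [hbond_criteria()] object.
#' @return List with `per_position` (named integer vector, positions 1..9),
#'   `total`, and `bonds` (data.frame describing each bond found).
#' @export
count_backbone_hbonds <- function(ensemble, frame = 0,
                                  criteria = hbond_criteria()) {
  at <- ensemble$atoms
  co <- frame_coords(ensemble, frame)
  core_resno <- ensemble$core$core_resno
  pep <- hbond_candidates(at, co, ensemble$peptide_chain,
                          resno_filter = core_resno)
  rec <- hbond_candidates(at, co, ensemble$receptor_chains)

  counts <- integer(9)
  names(counts) <- as.character(1:9)
  bonds <- list()
  pep_rows <- which(at$chain == ensemble$peptide_chain)
  for (i in 1:9) {
    rn <- core_resno[i]
    rr <- pep_rows[at$resno[pep_rows] == rn]
    if (!all(c("N", "CA", "C", "O") %in% at$elety[rr])) {
      warning("core position ", i, " (residue ", rn,
              ") lacks backbone atoms; skipped")
      next
    }
    ## peptide N donating to receptor acceptors
    for (d in pep$donors) {
      if (d$resno != rn || d$elety != "N") next
      for (a in rec$acceptors) {
        if (hbond_pair_ok(d$d_pos, d$h_pos, a$a_pos, a$aa_pos, criteria)) {
          counts[i] <- counts[i] + 1L
          bonds[[length(bonds) + 1]] <- data.frame(
            core_position = i, peptide_atom = "N", partner_chain = a$chain,
            partner_resno = a$resno, partner_atom = a$elety,
            role = "donor", stringsAsFactors = FALSE)
        }
      }
    }
    ## peptide O accepting from receptor donors
    oi <- rr[at$elety[rr] == "O"]
    ci <- rr[at$elety[rr] == "C"]
    if (length(oi) == 1) {
      a_pos <- co[oi, ]
      aa_pos <- if (length(ci) == 1) co[ci, ] else NULL
      for (d in rec$donors) {
        if (hbond_pair_ok(d$d_pos, d$h_pos, a_pos, aa_pos, criteria)) {
          counts[i] <- counts[i] + 1L
          bonds[[length(bonds) + 1]] <- data.frame(
            core_position = i, peptide_atom = "O", partner_chain = d$chain,
            partner_resno = d$resno, partner_atom = d$elety,
            role = "acceptor", stringsAsFactors = FALSE)
        }
      }
    }
  }
  bonds <- if (length(bonds) > 0) do.call(rbind, bonds) else
    data.frame(core_position = integer(), peptide_atom = character(),
               partner_chain = character(), partner_resno = integer(),
               partner_atom = character(), role = character(),
               stringsAsFactors = FALSE)
  list(per_position = counts, total = sum(counts), bonds = bonds)
}

#' Per-frame, per-core-position observable table
#'
#' Runs [count_backbone_hbonds()] and [count_contacts()] over the selected
#' frames of an ensemble and returns the long table that feeds
#' [accumulate_observables()]: one row per (frame, core position).
#'
#' @inheritParams count_contacts
#' @param frames 0-based frame identifiers (default: all frames).
#' @param run_id identifier of the simulation run this ensemble represents.
#' @param criteria an [hbond_criteria()] object.
#' @return data.frame with columns `run_id`, `frame`, `core_position`,
#'   `amino_acid`, `hbonds`, `contacts`; attributes `n_frames` (number of
#'   frames measured) and `core` (the ensemble's core assignment).
#' @export
observable_table <- function(ensemble, frames = NULL, run_id = "run1",
                             cutoff = 4.0, criteria = hbond_criteria(),
                             include_hydrogens = FALSE) {
  frames <- frames %||% (seq_len(n_frames(ensemble)) - 1L)
  core_aa <- check_sequence(ensemble$core$core_sequence)
  rows <- vector("list", length(frames))
  for (k in seq_along(frames)) {
    f <- frames[k]
    hb <- count_backbone_hbonds(ensemble, f, criteria)
    ct <- count_contacts(ensemble, f, cutoff, include_hydrogens)
    rows[[k]] <- data.frame(run_id = run_id, frame = f, core_position = 1:9,
                            amino_acid = core_aa,
                            hbonds = as.integer(hb$per_position),
                            contacts = as.integer(ct$per_position),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "n_frames") <- length(frames)
  attr(out, "core") <- ensemble$core
  out
}

#' Summarize an ensemble's observable table
#'
#' Mean and population standard deviation, across frames, of the per-frame
#' core-region totals of contacts and main-chain hydrogen bonds -- the
#' per-structure summary used to benchmark sampling methods.
#'
#' @param table an [observable_table()] result (>= 2 frames for a
#'   standard deviation).
#' @return One-row data.frame with `mean_contacts`, `sd_contacts`,
#'   `mean_hbonds`, `sd_hbonds`.
#' @export
summarize_ensemble <- function(table) {
  if (is.null(table) || nrow(table) == 0) stop("empty observable table")
  tot_c <- tapply(table$contacts, table$frame, sum)
  tot_h <- tapply(table$hbonds, table$frame, sum)
  data.frame(mean_contacts = mean(tot_c), sd_contacts = pop_sd(tot_c),
             mean_hbonds = mean(tot_h), sd_hbonds = pop_sd(tot_h))
}

#' Grand average over per-ensemble summaries
#'
#' Arithmetic mean over ensembles of per-ensemble means (column means of a
#' stack of [summarize_ensemble()] rows, or any numeric summary table),
#' rounded to 1 decimal for reporting.
#'
#' @param summaries data.frame of per-ensemble numeric summaries.
#' @return Named numeric vector of column means, rounded to 1 decimal.
#' @export
grand_average <- function(summaries) {
  if (is.null(summaries) || nrow(summaries) == 0) stop("no summaries supplied")
  num <- vapply(summaries, is.numeric, logical(1))
  round(colMeans(summaries[, num, drop = FALSE]), 1)
}
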