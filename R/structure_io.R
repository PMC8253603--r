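## Multi-model PDB ensembles of a peptide bound to a two-chain receptor.
##
## An EnsembleComplex stores one topology (atom table) plus an n_frames x
## 3*n_atoms coordinate matrix in bio3d xyz convention, optional per-frame
## energies, the chain annotation and the 9-mer core assignment. Frame
## identifiers are 0-based everywhere they appear in tables and files.

#' Construct an ensemble of a peptide--receptor complex
#'
#' Low-level constructor; most users will call [read_ensemble()] or
#' [make_toy_complex()] instead.
#'
#' @param atoms data.frame with columns `chain`, `resno`, `resid`
#'   (3-letter residue name), `elety` (atom name) and `elesy`
#'   (element symbol); one row per atom, identical across frames.
#' @param xyz numeric matrix, one row per frame, `3 * nrow(atoms)` columns
#'   (x1, y1, z1, x2, ...).
#' @param peptide_chain single chain identifier of the peptide.
#' @param receptor_chains character vector of receptor chain identifiers
#'   (disjoint from `peptide_chain`).
#' @param core_start 0-based offset of the 9-mer core within the peptide
#'   sequence.
#' @param energies optional numeric vector of per-frame energy scores
#'   (arbitrary units, lower is better).
#' @return An object of class `EnsembleComplex` with elements `atoms`,
#'   `xyz`, `energies`, `peptide_chain`, `receptor_chains` and `core`
#'   (a list with `peptide_sequence`, `core_start`, `core_sequence` and
#'   `core_resno`, the author residue numbers of the core).
#' @export
ensemble_complex <- function(atoms, xyz, peptide_chain, receptor_chains,
                             core_start, energies = NULL) {
  stopifnot(is.data.frame(atoms))
  need <- c("chain", "resno", "resid", "elety", "elesy")
  miss <- setdiff(need, names(atoms))
  if (length(miss) > 0) stop("atoms table lacks column(s): ", paste(miss, collapse = ", "))
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  if (nrow(xyz) < 1) stop("ensemble must contain at least one frame")
  if (ncol(xyz) != 3 * nrow(atoms)) {
    stop("topology mismatch: ", ncol(xyz) / 3, " coordinates per frame for ",
         nrow(atoms), " atoms")
  }
  if (!all(is.finite(xyz))) stop("non-finite coordinates in ensemble")
  if (length(peptide_chain) != 1) stop("exactly one peptide chain required")
  if (peptide_chain %in% receptor_chains) {
    stop("peptide chain '", peptide_chain, "' also listed as receptor chain")
  }
  for (ch in c(peptide_chain, receptor_chains)) {
    if (!any(atoms$chain == ch)) stop("chain '", ch, "' not present in structure")
  }
  key <- paste(atoms$chain, atoms$resno, atoms$elety)
  if (anyDuplicated(key)) {
    stop("duplicate (chain, residue, atom) record: ", key[duplicated(key)][1])
  }
  if (!is.null(energies)) {
    if (length(energies) != nrow(xyz)) {
      stop("got ", length(energies), " energies for ", nrow(xyz), " frames")
    }
    energies <- as.numeric(energies)
  }

  pep <- atoms[atoms$chain == peptide_chain, , drop = FALSE]
  resnos <- unique(pep$resno)          # file order defines peptide sequence order
  resid1 <- aa_one(pep$resid[match(resnos, pep$resno)])
  pep_seq <- paste(resid1, collapse = "")
  if (core_start < 0 || core_start + 9 > length(resnos)) {
    stop("core window out of range: start ", core_start, " + 9 exceeds peptide length ",
         length(resnos))
  }
  core_idx <- seq(core_start + 1, core_start + 9)
  core <- list(
    peptide_sequence = pep_seq,
    core_start = as.integer(core_start),
    core_sequence = substr(pep_seq, core_start + 1, core_start + 9),
    core_resno = resnos[core_idx]
  )
  structure(list(atoms = atoms, xyz = xyz, energies = energies,
                 peptide_chain = peptide_chain,
                 receptor_chains = receptor_chains, core = core),
            class = "EnsembleComplex")
}

#' @export
print.EnsembleComplex <- function(x, ...) {
  cat("EnsembleComplex:", n_frames(x), "frame(s),", nrow(x$atoms), "atoms\n")
  cat("  peptide chain", x$peptide_chain, ":", x$core$peptide_sequence,
      " core:", x$core$core_sequence,
      sprintf("(offset %d)\n", x$core$core_start))
  cat("  receptor chains:", paste(x$receptor_chains, collapse = ", "), "\n")
  cat("  per-frame energies:", if (is.null(x$energies)) "absent" else "present", "\n")
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ensemble An `EnsembleComplex`.
#' @return Integer frame count.
#' @export
n_frames <- function(ensemble) nrow(ensemble$xyz)

#' Coordinates of one frame
#'
#' @param ensemble An `EnsembleComplex`.
#' @param frame 0-based frame identifier.
#' @return `n_atoms` x 3 numeric matrix.
#' @export
frame_coords <- function(ensemble, frame = 0) {
  if (frame < 0 || frame >= n_frames(ensemble)) {
    stop("frame ", frame, " out of range 0..", n_frames(ensemble) - 1)
  }
  matrix(ensemble$xyz[frame + 1, ], ncol = 3, byrow = TRUE)
}

#' Read a (multi-model) PDB file into an ensemble
#'
#' One frame is created per MODEL record, in file order (single-model files
#' yield one frame). Waters and HETATM records are dropped by default, and
#' for alternate locations the highest-occupancy altloc is kept (ties broken
#' alphabetically). Per-frame energies may be supplied as a sidecar TSV with
#' header `frame<TAB>energy` and 0-based frame identifiers.
#'
#' @param path PDB file path.
#' @inheritParams ensemble_complex
#' @param energies optional path to the sidecar energy table.
#' @param keep_hetero keep HETATM records (default `FALSE`).
#' @return An `EnsembleComplex`.
#' @export
read_ensemble <- function(path, peptide_chain, receptor_chains, core_start,
                          energies = NULL, keep_hetero = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  keep <- rep(TRUE, nrow(at))
  if (!keep_hetero) keep <- at$type == "ATOM" & at$resid != "HOH"
  ## altloc: prefer highest occupancy, then alphabetical altloc letter
  alt <- at$alt
  alt[is.na(alt)] <- ""
  occ <- at$o
  occ[is.na(occ)] <- 1
  ord <- order(at$chain, at$resno, at$elety, -occ, alt)
  key <- paste(at$chain, at$resno, at$elety)
  dup <- duplicated(key[ord])
  drop_idx <- ord[dup]
  keep[drop_idx] <- FALSE
  at$chain[is.na(at$chain)] <- " "

  idx <- which(keep)
  atoms <- data.frame(chain = at$chain[idx], resno = at$resno[idx],
                      resid = at$resid[idx], elety = at$elety[idx],
                      elesy = guess_element(at$elesy[idx], at$elety[idx]),
                      stringsAsFactors = FALSE)
  xyz_cols <- as.vector(rbind(3 * idx - 2, 3 * idx - 1, 3 * idx))
  xyz <- pdb$xyz[, xyz_cols, drop = FALSE]
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)

  en <- NULL
  if (!is.null(energies)) en <- read_energy_table(energies, nrow(xyz))
  ensemble_complex(atoms, xyz, peptide_chain, receptor_chains, core_start,
                   energies = en)
}

guess_element <- function(elesy, elety) {
  elesy <- toupper(trimws(ifelse(is.na(elesy), "", elesy)))
  miss <- elesy == ""
  if (any(miss)) {
    ## fall back to first letter of the atom name, skipping digits
    nm <- gsub("[0-9']", "", toupper(elety[miss]))
    elesy[miss] <- substr(nm, 1, 1)
  }
  elesy
}

read_energy_table <- function(path, nf) {
  if (!file.exists(path)) stop("no such energy table: ", path)
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("frame", "energy") %in% names(tab))) {
    stop("energy sidecar must have header 'frame<TAB>energy'")
  }
  en <- rep(NA_real_, nf)
  ok <- tab$frame >= 0 & tab$frame < nf
  if (!all(ok)) stop("energy table frame id out of range 0..", nf - 1)
  en[tab$frame + 1] <- tab$energy
  if (anyNA(en)) stop("energy table covers ", sum(!is.na(en)), " of ", nf, " frames")
  en
}

#' Write an ensemble as a multi-model PDB file
#'
#' Round-trips through [read_ensemble()] preserving chain identifiers,
#' residue numbering, atom names and coordinates to PDB precision (3
#' decimals). Per-frame energies, when present, are written to
#' `<path>.energies.tsv` in the sidecar format read back by
#' [read_ensemble()].
#'
#' @param ensemble An `EnsembleComplex`.
#' @param path output file path.
#' @param energies_path optional explicit path for the energy sidecar;
#'   defaults to `<path>.energies.tsv` when the ensemble has energies.
#' @return Invisibly, `path`.
#' @export
write_ensemble <- function(ensemble, path, energies_path = NULL) {
  stopifnot(inherits(ensemble, "EnsembleComplex"))
  at <- ensemble$atoms
  if (any(nchar(at$elety) > 4)) {
    stop("atom name(s) longer than 4 characters cannot be encoded in PDB")
  }
  bio3d::write.pdb(pdb = NULL, file = path, xyz = ensemble$xyz,
                   type = rep("ATOM", nrow(at)),
                   resno = at$resno, resid = at$resid,
                   eleno = seq_len(nrow(at)), elety = at$elety,
                   chain = at$chain, elesy = at$elesy)
  if (!is.null(ensemble$energies)) {
    ep <- energies_path %||% paste0(path, ".energies.tsv")
    write.table(data.frame(frame = seq_len(n_frames(ensemble)) - 1L,
                           energy = ensemble$energies),
                ep, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
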