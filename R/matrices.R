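## Construction of the structural scoring matrices: frame selection,
## observable accumulation over runs (the 9 x 20 average observable O),
## and the -ln position-normalized scoring energy E.

FRAME_STRATEGIES <- c("all", "last_half", "best_energy_half", "best_energy_one")

#' Select frames of an ensemble under a sampling strategy
#'
#' Strategies mirror the four ways of extracting information from a
#' trajectory of `Nf` frames: every frame (`all`), the last `ceil(Nf/2)`
#' frames in trajectory order (`last_half`), the `ceil(Nf/2)` frames with
#' the lowest energy scores (`best_energy_half`), or the single
#' lowest-energy frame (`best_energy_one`). Energy ties are broken stably
#' in favour of the earlier frame.
#'
#' @param ensemble An `EnsembleComplex`; energy-based strategies require
#'   per-frame energies.
#' @param strategy one of `"all"`, `"last_half"`, `"best_energy_half"`,
#'   `"best_energy_one"`.
#' @return List of class `FrameSelection` with `strategy` and
#'   `selected_frames` (0-based identifiers, ascending).
#' @export
select_frames <- function(ensemble, strategy = FRAME_STRATEGIES) {
  strategy <- match.arg(strategy, FRAME_STRATEGIES)
  nf <- n_frames(ensemble)
  half <- ceiling(nf / 2)
  if (strategy %in% c("best_energy_half", "best_energy_one") &&
      is.null(ensemble$energies)) {
    stop("strategy '", strategy, "' requires per-frame energies")
  }
  ids <- select_frame_ids(seq_len(nf) - 1L, strategy, ensemble$energies)
  structure(list(strategy = strategy, selected_frames = ids),
            class = "FrameSelection")
}

## strategy selection over bare frame-id vectors (ids assumed in
## trajectory order); used by select_frames() and the CLI `build` path
select_frame_ids <- function(ids, strategy, energies = NULL) {
  nf <- length(ids)
  half <- ceiling(nf / 2)
  if (strategy %in% c("best_energy_half", "best_energy_one")) {
    if (is.null(energies)) stop("strategy '", strategy, "' requires per-frame energies")
    if (length(energies) != nf) stop("got ", length(energies), " energies for ", nf, " frames")
  }
  idx <- switch(strategy,
    all = seq_len(nf),
    last_half = seq(nf - half + 1, nf),
    best_energy_half = sort(order(energies)[seq_len(half)]),
    best_energy_one = order(energies)[1]
  )
  ids[idx]
}

#' Accumulate observables over runs into the 9 x 20 average O
#'
#' Computes `O_ij = (1/Nf) * sum_alpha sum_{f in selection} o_ijaf`, where
#' `o_ijaf` is the observable for amino acid `j` at core position `i` in
#' frame `f` of run `alpha`. `Nf` is by default the per-run selected-frame
#' count, which must be identical across runs; with
#' `nf_convention = "global"` the grand total of selected frames is used
#' instead (the two differ only by a per-position constant, which the
#' normalization in [build_matrix()] cancels). Cells for (position, amino
#' acid) combinations absent from every run are zero, so the natural
#' amino-acid frequencies of the cohort weight the matrix implicitly.
#'
#' @param tables list of [observable_table()] results, one per run.
#' @param observable `"hbonds"` or `"contacts"`.
#' @param selections optional list of [select_frames()] results (or 0-based
#'   frame-id vectors), one per run; default: all frames of each table.
#' @param nf_convention `"run"` (default) or `"global"`.
#' @return 9 x 20 numeric matrix with positions as rows and the
#'   [aa_alphabet()] as columns.
#' @export
accumulate_observables <- function(tables, observable = c("hbonds", "contacts"),
                                   selections = NULL,
                                   nf_convention = c("run", "global")) {
  observable <- match.arg(observable)
  nf_convention <- match.arg(nf_convention)
  if (!is.list(tables) || length(tables) == 0) stop("no observable tables supplied")
  if (is.data.frame(tables)) tables <- list(tables)
  aa <- aa_alphabet()
  O <- matrix(0, nrow = 9, ncol = 20, dimnames = list(1:9, aa))
  nfs <- integer(length(tables))
  for (k in seq_along(tables)) {
    tab <- tables[[k]]
    sel <- if (is.null(selections)) unique(tab$frame) else {
      s <- selections[[k]]
      if (inherits(s, "FrameSelection")) s$selected_frames else s
    }
    sub <- tab[tab$frame %in% sel, , drop = FALSE]
    got <- sort(unique(sub$frame))
    if (!identical(got, sort(unique(as.integer(sel))))) {
      stop("run ", k, ": selection requests frames absent from its table")
    }
    nfs[k] <- length(got)
    agg <- tapply(sub[[observable]],
                  list(factor(sub$core_position, levels = 1:9),
                       factor(sub$amino_acid, levels = aa)),
                  sum)
    agg[is.na(agg)] <- 0
    O <- O + agg
  }
  if (length(unique(nfs)) != 1) {
    stop("normalization failure: runs have differing selected-frame counts (",
         paste(unique(nfs), collapse = ", "), ")")
  }
  nf <- if (nf_convention == "run") nfs[1] else sum(nfs)
  O / nf
}

#' Build a structural scoring matrix from the average observable O
#'
#' Adds a pseudocount to every cell (keeping the scoring energy finite
#' where an amino acid was never observed at a position) and applies the
#' position-normalized log transform
#' `E_ij = -ln((O_ij + pc_i) / sum_j (O_ij + pc_i))`, so that
#' `sum_j exp(-E_ij) = 1` at every position.
#'
#' @param O non-negative numeric matrix (positions x amino acids); each
#'   position must have at least one positive cell unless a positive
#'   pseudocount is supplied.
#' @param pseudocount positive scalar added to every cell, or `NULL`
#'   (default) for `1e-6 * max(O[i, ])` per position.
#' @param observable label: `"hbonds"`, `"contacts"` or other.
#' @param strategy frame-selection label stored as metadata.
#' @return Object of class `StructMatrix` with elements `O`, `E`,
#'   `pseudocount` (per-position vector), `observable`, `strategy`.
#' @export
build_matrix <- function(O, pseudocount = NULL, observable = NA_character_,
                         strategy = NA_character_) {
  if (!is.matrix(O) || any(O < 0) || !all(is.finite(O))) {
    stop("O must be a finite non-negative matrix")
  }
  row_max <- apply(O, 1, max)
  if (is.null(pseudocount)) {
    if (any(row_max <= 0)) {
      stop("position(s) ", paste(which(row_max <= 0), collapse = ", "),
           " have no observations; supply an explicit pseudocount")
    }
    pc <- 1e-6 * row_max
  } else {
    if (pseudocount < 0) stop("pseudocount must be non-negative")
    if (pseudocount == 0 && any(row_max <= 0)) {
      stop("all-zero position with zero pseudocount: normalization undefined")
    }
    pc <- rep(pseudocount, nrow(O))
  }
  Op <- O + pc
  E <- -log(Op / rowSums(Op))
  structure(list(O = O, E = E, pseudocount = pc,
                 observable = observable, strategy = strategy),
            class = "StructMatrix")
}

#' @export
print.StructMatrix <- function(x, ...) {
  cat("StructMatrix (", nrow(x$E), "x", ncol(x$E), "): observable =",
      x$observable, ", strategy =", x$strategy, "\n")
  cat("E range: [", round(min(x$E), 3), ",", round(max(x$E), 3), "]\n")
  invisible(x)
}

#' Score a 9-mer core under a structural scoring matrix
#'
#' Additive score `sum_i E[i, core[i]]`; lower values predict better
#' binders (E is a negative log-probability).
#'
#' @param matrix a `StructMatrix` (9 x 20).
#' @param core 9-letter core sequence over the standard alphabet.
#' @return Scalar score.
#' @export
score_core <- function(matrix, core) {
  stopifnot(inherits(matrix, "StructMatrix"))
  aa <- check_sequence(core)
  if (length(aa) != nrow(matrix$E)) {
    stop("core length ", length(aa), " does not match matrix with ",
         nrow(matrix$E), " positions")
  }
  sum(matrix$E[cbind(seq_along(aa), match(aa, colnames(matrix$E)))])
}

#' Export a column-normalized frequency table for logo rendering
#'
#' For a `StructMatrix` the per-position frequencies are `exp(-E)` (the
#' exact inverse of the matrix transform, so rebuilding a matrix from the
#' exported frequencies reproduces E). For a set of aligned peptides the
#' per-position amino-acid frequencies are tabulated. Every position
#' (row) sums to one.
#'
#' @param x a `StructMatrix` or a character vector of equal-length aligned
#'   sequences.
#' @return Numeric matrix, positions x 20 amino acids, rows summing to 1.
#' @export
export_frequency_logo <- function(x) {
  if (inherits(x, "StructMatrix")) return(exp(-x$E))
  if (is.character(x)) {
    lens <- unique(nchar(x))
    if (length(lens) != 1) stop("sequences must be aligned (equal length)")
    aa <- aa_alphabet()
    mat <- t(vapply(seq_len(lens), function(i) {
      letters_i <- factor(substr(x, i, i), levels = aa)
      as.numeric(table(letters_i)) / length(x)
    }, numeric(20)))
    dimnames(mat) <- list(seq_len(lens), aa)
    return(mat)
  }
  stop("x must be a StructMatrix or a character vector of sequences")
}

#' Write / read a structural scoring matrix
#'
#' Serializes the O and E grids as labeled TSV files (`<prefix>_O.tsv`,
#' `<prefix>_E.tsv`) plus a JSON metadata bundle (`<prefix>_meta.json`)
#' recording the observable, strategy and pseudocounts.
#'
#' @param matrix a `StructMatrix`.
#' @param prefix output path prefix.
#' @return `write_struct_matrix`: invisibly, the three file paths.
#' @export
write_struct_matrix <- function(matrix, prefix) {
  stopifnot(inherits(matrix, "StructMatrix"))
  paths <- paste0(prefix, c("_O.tsv", "_E.tsv", "_meta.json"))
  write_grid <- function(m, path) {
    df <- data.frame(position = rownames(m), m, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_grid(matrix$O, paths[1])
  write_grid(matrix$E, paths[2])
  jsonlite::write_json(
    list(observable = matrix$observable, strategy = matrix$strategy,
         pseudocount = matrix$pseudocount,
         n_positions = nrow(matrix$E), alphabet = colnames(matrix$E)),
    paths[3], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' @rdname write_struct_matrix
#' @return `read_struct_matrix`: the deserialized `StructMatrix`.
#' @export
read_struct_matrix <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"), simplifyVector = TRUE)
  read_grid <- function(path) {
    df <- read.delim(path, check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    m
  }
  O <- read_grid(paste0(prefix, "_O.tsv"))
  E <- read_grid(paste0(prefix, "_E.tsv"))
  structure(list(O = O, E = E, pseudocount = meta$pseudocount,
                 observable = meta$observable, strategy = meta$strategy),
            class = "StructMatrix")
}
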