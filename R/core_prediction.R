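## Sequence-side machinery used to assemble the peptide dataset: sliding
## 9-mer core prediction under a published sequence PSSM, the two-method
## core consensus, and the flank-extension filter against the modelling
## template.

#' Read a 9 x 20 sequence PSSM from TSV
#'
#' Layout matches [write_struct_matrix()] grids: a `position` column
#' followed by 20 amino-acid columns; higher scores mean more probable.
#'
#' @param path TSV file path.
#' @param source_label free-text provenance label.
#' @return Object of class `SequencePSSM`: list with `scores` (9 x 20
#'   matrix) and `source_label`.
#' @export
read_pssm <- function(path, source_label = basename(path)) {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  sequence_pssm(m, source_label)
}

#' @rdname read_pssm
#' @param scores 9 x 20 numeric matrix (positions x amino acids).
#' @export
sequence_pssm <- function(scores, source_label = "pssm") {
  if (!is.matrix(scores) || nrow(scores) != 9) stop("PSSM must have 9 rows")
  miss <- setdiff(aa_alphabet(), colnames(scores))
  if (length(miss) > 0) {
    stop("PSSM lacks amino-acid column(s): ", paste(miss, collapse = ", "))
  }
  scores <- scores[, aa_alphabet(), drop = FALSE]
  structure(list(scores = scores, source_label = source_label),
            class = "SequencePSSM")
}

#' Rank candidate 9-mer cores of a peptide under a sequence PSSM
#'
#' Every 9-residue window of the peptide is scored additively under the
#' PSSM and the windows are ranked by descending score, ties broken in
#' favour of the smaller window start.
#'
#' @param pssm a `SequencePSSM`.
#' @param sequence peptide sequence (length >= 9, standard alphabet).
#' @return data.frame with columns `window_start` (0-based), `window`
#'   (9-mer) and `score`, best first.
#' @export
predict_core <- function(pssm, sequence) {
  stopifnot(inherits(pssm, "SequencePSSM"))
  aa <- check_sequence(sequence)
  L <- length(aa)
  if (L < 9) stop("sequence shorter than 9 residues")
  starts <- 0:(L - 9)
  scores <- vapply(starts, function(s) {
    idx <- match(aa[(s + 1):(s + 9)], colnames(pssm$scores))
    sum(pssm$scores[cbind(1:9, idx)])
  }, numeric(1))
  out <- data.frame(window_start = starts,
                    window = vapply(starts, function(s)
                      paste(aa[(s + 1):(s + 9)], collapse = ""), character(1)),
                    score = scores, stringsAsFactors = FALSE)
  out[order(-out$score, out$window_start), , drop = FALSE]
}

#' Two-method core consensus
#'
#' A peptide is accepted when both methods' top-ranked 9-mer windows are
#' identical (same start offset, hence same sequence).
#'
#' @param pred_a,pred_b ranked window tables from [predict_core()] (or any
#'   data.frame with `window_start` and `window`, best first) for the same
#'   sequence.
#' @return List with `accept` (logical), `core_start`, `core` (on
#'   acceptance) and `reason` (on rejection).
#' @export
consensus_core <- function(pred_a, pred_b) {
  a <- pred_a[1, ]
  b <- pred_b[1, ]
  if (a$window_start == b$window_start && a$window == b$window) {
    list(accept = TRUE, core_start = a$window_start, core = a$window,
         reason = NA_character_)
  } else {
    list(accept = FALSE, core_start = NA_integer_, core = NA_character_,
         reason = sprintf("top windows disagree: start %d ('%s') vs %d ('%s')",
                          a$window_start, a$window, b$window_start, b$window))
  }
}

#' Flank-extension filter against the modelling template
#'
#' With the query core aligned onto the template core, computes how many
#' residues would have to be appended to the template at each terminus to
#' host the query's flanking regions, and rejects the peptide when either
#' terminus needs more than `max_added` (default 2) added residues.
#'
#' @param core_start 0-based core offset of the query peptide.
#' @param peptide_length query peptide length.
#' @param template_core_start 0-based core offset of the template peptide.
#' @param template_length template peptide length.
#' @param max_added maximum residues that may be added per terminus.
#' @return List with `accept`, `added_n`, `added_c`.
#' @export
flank_filter <- function(core_start, peptide_length,
                         template_core_start, template_length,
                         max_added = 2) {
  if (peptide_length < 0 || template_length < 0 ||
      core_start < 0 || template_core_start < 0) {
    stop("lengths and offsets must be non-negative")
  }
  if (core_start + 9 > peptide_length || template_core_start + 9 > template_length) {
    stop("core window exceeds peptide length")
  }
  added_n <- max(0, core_start - template_core_start)
  added_c <- max(0, (peptide_length - core_start - 9) -
                    (template_length - template_core_start - 9))
  list(accept = added_n <= max_added && added_c <= max_added,
       added_n = added_n, added_c = added_c)
}

#' Read a peptide dataset
#'
#' TSV datasets need columns `sequence` and `activity_nM` (lower activity =
#' stronger binder); FASTA files (read via the seqinr package) yield
#' sequences with `NA` activities.
#'
#' @param path TSV or FASTA file path.
#' @param format `"auto"` (by extension), `"tsv"` or `"fasta"`.
#' @return data.frame with columns `sequence`, `activity_nM`.
#' @export
read_peptides <- function(path, format = c("auto", "tsv", "fasta")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("fa", "fasta", "faa")) "fasta" else "tsv"
  }
  if (format == "fasta") {
    if (!requireNamespace("seqinr", quietly = TRUE)) {
      stop("reading FASTA requires the seqinr package")
    }
    seqs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE)
    df <- data.frame(sequence = toupper(unlist(seqs)),
                     activity_nM = NA_real_, stringsAsFactors = FALSE)
    rownames(df) <- NULL
  } else {
    df <- read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("sequence", "activity_nM") %in% names(df))) {
      stop("peptide TSV needs columns 'sequence' and 'activity_nM'")
    }
  }
  invisible(lapply(df$sequence, check_sequence))
  df
}
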