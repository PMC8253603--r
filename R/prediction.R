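## Sign prediction of single-point-mutation activity differences and its
## evaluation: pair assembly, matrix-based signs, the >=3-of-6 scoring-
## function consensus, the conditional-"or" combination, and bootstrap
## resampling of match rates.
##
## Sign convention throughout: activities are nM-like (lower = stronger
## binder), so a positive experimental difference (mut - wt) means the
## mutation weakened binding; the matrix side uses E differences in the
## same orientation (E is a -ln probability, larger = less favourable).

#' Sign of the experimental activity difference of a mutation pair
#'
#' @param activity_wt,activity_mut positive binding activities in nM
#'   (vectorized).
#' @return Integer vector in \{-1, 0, +1\}: `+1` means the mutation
#'   weakens binding, `0` only on exact equality (such pairs are unusable
#'   for sign matching).
#' @export
experimental_sign <- function(activity_wt, activity_mut) {
  if (any(activity_wt <= 0) || any(activity_mut <= 0)) {
    stop("activities must be positive (nM)")
  }
  as.integer(sign(activity_mut - activity_wt))
}

#' Matrix-predicted sign for a single-point core mutation
#'
#' `sign(E[pos, mut] - E[pos, wt])`: positive predicts weakened binding.
#' A degenerate pair (`wt_aa == mut_aa`) returns 0 with a warning.
#'
#' @param matrix a `StructMatrix`.
#' @param core_position core position 1..9 of the substitution.
#' @param wt_aa,mut_aa 1-letter amino-acid codes.
#' @return Integer in \{-1, 0, +1\}.
#' @export
matrix_sign <- function(matrix, core_position, wt_aa, mut_aa) {
  stopifnot(inherits(matrix, "StructMatrix"))
  if (any(core_position < 1 | core_position > nrow(matrix$E))) {
    stop("core position out of range 1..", nrow(matrix$E))
  }
  jw <- match(wt_aa, colnames(matrix$E))
  jm <- match(mut_aa, colnames(matrix$E))
  if (anyNA(jw) || anyNA(jm)) stop("amino acid outside the standard alphabet")
  if (any(wt_aa == mut_aa)) warning("degenerate pair: wt_aa equals mut_aa")
  as.integer(sign(matrix$E[cbind(core_position, jm)] -
                  matrix$E[cbind(core_position, jw)]))
}

#' Predict signs for a table of mutation pairs
#'
#' @param matrix a `StructMatrix`.
#' @param pairs data.frame from [make_pairs()] (needs `core_position`,
#'   `wt_aa`, `mut_aa`).
#' @return Integer vector of predicted signs, one per pair.
#' @export
predict_pair_signs <- function(matrix, pairs) {
  matrix_sign(matrix, pairs$core_position, pairs$wt_aa, pairs$mut_aa)
}

#' Assemble single-point mutation pairs from a peptide dataset
#'
#' Emits every unordered pair of peptides whose full sequences differ at
#' exactly one residue, with that residue inside the 9-mer core. By
#' convention the stronger binder (lower nM) is the wild type of the pair.
#'
#' @param peptides data.frame with columns `sequence`, `activity_nM` and
#'   `core_start` (single value recycled, or one per peptide; pairs are
#'   only formed between peptides with equal `core_start` and length).
#' @return data.frame with columns `pair_id`, `wt_sequence`,
#'   `mut_sequence`, `core_position` (1..9), `wt_aa`, `mut_aa`,
#'   `activity_wt`, `activity_mut`.
#' @export
make_pairs <- function(peptides) {
  need <- c("sequence", "activity_nM", "core_start")
  miss <- setdiff(need, names(peptides))
  if (length(miss) > 0) stop("peptide table lacks column(s): ", paste(miss, collapse = ", "))
  n <- nrow(peptides)
  out <- list()
  if (n >= 2) {
    seqs <- peptides$sequence
    lens <- nchar(seqs)
    cs <- rep(peptides$core_start, length.out = n)
    ## split into groups of identical (length, core_start)
    for (grp in split(seq_len(n), paste(lens, cs))) {
      if (length(grp) < 2) next
      L <- lens[grp[1]]
      cstart <- cs[grp[1]]
      chars <- do.call(rbind, strsplit(seqs[grp], ""))
      for (a in seq_len(length(grp) - 1)) {
        diffs <- chars[rep(a, length(grp) - a), , drop = FALSE] !=
                 chars[(a + 1):length(grp), , drop = FALSE]
        nd <- rowSums(diffs)
        for (bb in which(nd == 1)) {
          b <- a + bb
          pos0 <- which(diffs[bb, ])          # 1-based position in sequence
          core_pos <- pos0 - cstart           # 1..9 if inside core
          if (core_pos < 1 || core_pos > 9) next
          ia <- grp[a]; ib <- grp[b]
          if (peptides$activity_nM[ib] < peptides$activity_nM[ia]) {
            tmp <- ia; ia <- ib; ib <- tmp
          }
          out[[length(out) + 1]] <- data.frame(
            wt_sequence = seqs[ia], mut_sequence = seqs[ib],
            core_position = core_pos,
            wt_aa = substr(seqs[ia], pos0, pos0),
            mut_aa = substr(seqs[ib], pos0, pos0),
            activity_wt = peptides$activity_nM[ia],
            activity_mut = peptides$activity_nM[ib],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(pair_id = character(), wt_sequence = character(),
                      mut_sequence = character(), core_position = integer(),
                      wt_aa = character(), mut_aa = character(),
                      activity_wt = numeric(), activity_mut = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, out)
  cbind(data.frame(pair_id = sprintf("pair%03d", seq_len(nrow(out)))), out)
}

#' Consensus matching of external scoring functions
#'
#' For each pair and scoring function, the mean score over frames is
#' computed for wild type and mutant; the function's predicted sign is
#' `sign(mean_mut - mean_wt)` under its orientation (flipped for
#' higher-is-better functions). A pair is a match when at least
#' `min_agree` functions' signs equal the experimental sign.
#'
#' @param scores data.frame with columns `pair_id`, `role` (`"wt"` /
#'   `"mut"`), `function_name`, `frame`, `score`.
#' @param pairs data.frame with `pair_id`, `activity_wt`, `activity_mut`.
#' @param min_agree minimum number of agreeing functions (default 3).
#' @param orientation named logical vector, `TRUE` (default for
#'   unlisted functions) when lower scores mean better binding.
#' @return data.frame with `pair_id`, `experimental_sign`, `n_agree`,
#'   `match` (logical).
#' @export
consensus_sign <- function(scores, pairs, min_agree = 3,
                           orientation = NULL) {
  need <- c("pair_id", "role", "function_name", "frame", "score")
  miss <- setdiff(need, names(scores))
  if (length(miss) > 0) stop("score table lacks column(s): ", paste(miss, collapse = ", "))
  if (!all(scores$role %in% c("wt", "mut"))) stop("role must be 'wt' or 'mut'")
  exp_sign <- setNames(experimental_sign(pairs$activity_wt, pairs$activity_mut),
                       pairs$pair_id)
  ## mean score per (pair, function, role); \r is safe as a field separator
  key <- paste(scores$pair_id, scores$function_name, scores$role, sep = "\r")
  mean_scores <- tapply(scores$score, key, mean)
  parts <- strsplit(names(mean_scores), "\r", fixed = TRUE)
  ms <- data.frame(pair_id = vapply(parts, `[`, "", 1),
                   fn = vapply(parts, `[`, "", 2),
                   role = vapply(parts, `[`, "", 3),
                   mean = as.numeric(mean_scores), stringsAsFactors = FALSE)
  wide_wt <- ms[ms$role == "wt", ]
  wide_mut <- ms[ms$role == "mut", ]
  m <- merge(wide_wt, wide_mut, by = c("pair_id", "fn"),
             suffixes = c("_wt", "_mut"), all = TRUE)
  if (anyNA(m$mean_wt) || anyNA(m$mean_mut)) {
    bad <- m$pair_id[is.na(m$mean_wt) | is.na(m$mean_mut)][1]
    stop("incomplete pair: missing wt or mut scores for ", bad)
  }
  lower_better <- rep(TRUE, nrow(m))
  if (!is.null(orientation)) {
    known <- m$fn %in% names(orientation)
    lower_better[known] <- orientation[m$fn[known]]
  }
  pred <- as.integer(sign(m$mean_mut - m$mean_wt)) * ifelse(lower_better, 1L, -1L)
  if (!all(m$pair_id %in% names(exp_sign))) {
    stop("score table contains pair(s) absent from the pair table")
  }
  agree <- pred == exp_sign[m$pair_id]
  n_agree <- tapply(agree, m$pair_id, sum)
  ids <- names(n_agree)
  data.frame(pair_id = ids,
             experimental_sign = as.integer(exp_sign[ids]),
             n_agree = as.integer(n_agree),
             match = as.integer(n_agree) >= min_agree,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Conditional-"or" combination of two methods' matches
#'
#' A pair counts as matched when either method matched it (elementwise OR);
#' the combined match count can never fall below either component's.
#'
#' @param matches_a,matches_b logical vectors over the same ordered pair
#'   set (names, when present, must agree).
#' @return Logical vector.
#' @export
combine_or <- function(matches_a, matches_b) {
  if (length(matches_a) != length(matches_b)) {
    stop("mismatched pair sets: ", length(matches_a), " vs ", length(matches_b))
  }
  if (!is.null(names(matches_a)) && !is.null(names(matches_b)) &&
      !identical(names(matches_a), names(matches_b))) {
    stop("mismatched pair sets: names disagree")
  }
  matches_a | matches_b
}

#' Point-estimate evaluation of per-pair matches
#'
#' @param matches logical vector of per-pair match indicators.
#' @param usable optional logical vector; pairs flagged `FALSE` (e.g.
#'   experimental ties) are excluded from the denominator.
#' @return List of class `EvaluationResult` with `n_pairs`, `n_matched`,
#'   `match_fraction`.
#' @export
evaluate_matches <- function(matches, usable = NULL) {
  if (length(matches) == 0) stop("no pairs to evaluate")
  if (!is.null(usable)) matches <- matches[usable]
  if (length(matches) == 0) stop("no usable pairs to evaluate")
  structure(list(n_pairs = length(matches), n_matched = sum(matches),
                 match_fraction = sum(matches) / length(matches)),
            class = "EvaluationResult")
}

#' @export
print.EvaluationResult <- function(x, ...) {
  cat(sprintf("matched %d of %d pairs: %.3f", x$n_matched, x$n_pairs,
              x$match_fraction))
  if (!is.null(x$bootstrap_mean)) {
    cat(sprintf("  (bootstrap %.3f +/- %.3f, %d replicas)",
                x$bootstrap_mean, x$bootstrap_sd, x$n_replicas))
  }
  cat("\n")
  invisible(x)
}

#' Bootstrap the match fraction
#'
#' Each replica resamples the pairs with replacement and recomputes the
#' match fraction; reproducible under `seed`.
#'
#' @param matches logical vector of per-pair match indicators (>= 2 pairs).
#' @param n_replicas number of bootstrap replicas (default 50).
#' @param seed RNG seed.
#' @return `EvaluationResult` augmented with `bootstrap_mean`,
#'   `bootstrap_sd` (sd over replicas), `n_replicas`, `seed`.
#' @export
bootstrap_matches <- function(matches, n_replicas = 50, seed = 1) {
  if (length(matches) < 2) stop("bootstrap needs at least 2 pairs")
  if (n_replicas < 2) stop("n_replicas must be at least 2")
  base <- evaluate_matches(matches)
  set.seed(seed)
  n <- length(matches)
  reps <- vapply(seq_len(n_replicas), function(r) {
    mean(matches[sample.int(n, n, replace = TRUE)])
  }, numeric(1))
  base$bootstrap_mean <- mean(reps)
  base$bootstrap_sd <- sd(reps)
  base$n_replicas <- n_replicas
  base$seed <- seed
  base
}
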