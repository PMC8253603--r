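## TSV dialects for the tabular interchange formats: per-frame observable
## tables, mutation-pair tables and external score tables (with the
## `#orientation` header line carrying each function's score direction).

#' Write / read a per-frame observable table
#'
#' Columns: `run_id`, `frame` (0-based), `core_position`, `amino_acid`,
#' `hbonds`, `contacts`.
#'
#' @param table an [observable_table()] result.
#' @param path TSV file path.
#' @return `write_observable_table`: invisibly, `path`.
#' @export
write_observable_table <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_observable_table
#' @return `read_observable_table`: the table, with its `n_frames`
#'   attribute restored.
#' @export
read_observable_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("run_id", "frame", "core_position", "amino_acid", "hbonds", "contacts")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) stop("observable table lacks column(s): ",
                             paste(miss, collapse = ", "))
  attr(tab, "n_frames") <- length(unique(tab$frame))
  tab
}

#' Write / read a mutation-pair table
#'
#' Columns as produced by [make_pairs()].
#'
#' @param pairs pair data.frame.
#' @param path TSV file path.
#' @return `write_pairs`: invisibly, `path`.
#' @export
write_pairs <- function(pairs, path) {
  write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pairs
#' @return `read_pairs`: the pair data.frame.
#' @export
read_pairs <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("pair_id", "wt_sequence", "mut_sequence", "core_position",
            "activity_wt", "activity_mut")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) stop("pair table lacks column(s): ",
                             paste(miss, collapse = ", "))
  if (!all(c("wt_aa", "mut_aa") %in% names(tab))) {
    tab$wt_aa <- substr(tab$wt_sequence, tab$core_position, tab$core_position)
    tab$mut_aa <- substr(tab$mut_sequence, tab$core_position, tab$core_position)
  }
  tab
}

#' Write / read an external score table
#'
#' Long TSV with columns `pair_id`, `role`, `function_name`, `frame`,
#' `score`. An optional comment line of the form
#' `#orientation fn1=asc fn2=desc ...` declares each function's score
#' direction (`asc` = lower is better, the default; `desc` = higher is
#' better) and is returned as the `orientation` attribute: a named logical
#' vector, `TRUE` for lower-is-better.
#'
#' @param scores score data.frame.
#' @param path TSV file path.
#' @param orientation optional named logical vector (lower-is-better flag
#'   per function) written as the `#orientation` header.
#' @return `write_score_table`: invisibly, `path`.
#' @export
write_score_table <- function(scores, path, orientation = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(orientation)) {
    writeLines(paste0("#orientation ",
                      paste0(names(orientation), "=",
                             ifelse(orientation, "asc", "desc"),
                             collapse = " ")), con)
  }
  write.table(scores, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_score_table
#' @return `read_score_table`: the score data.frame, with an `orientation`
#'   attribute when the header line is present.
#' @export
read_score_table <- function(path) {
  first <- readLines(path, n = 1)
  orientation <- NULL
  if (startsWith(first, "#orientation")) {
    fields <- strsplit(trimws(sub("^#orientation", "", first)), "\\s+")[[1]]
    kv <- strsplit(fields, "=", fixed = TRUE)
    orientation <- setNames(vapply(kv, `[`, "", 2) == "asc",
                            vapply(kv, `[`, "", 1))
  }
  tab <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("pair_id", "role", "function_name", "frame", "score")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) stop("score table lacks column(s): ",
                             paste(miss, collapse = ", "))
  attr(tab, "orientation") <- orientation
  tab
}
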