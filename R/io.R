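# CSV readers/writers for the package's tables.  Doubles are written
# with 17 significant digits so that a write/read round trip preserves
# every value bit-exactly.

write_precise_csv <- function(df, path) {
  out <- df
  for (nm in names(out)) {
    if (is.double(out[[nm]])) out[[nm]] <- sprintf("%.17g", out[[nm]])
  }
  write.table(out, path, sep = ",", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read and write package tables as CSV
#'
#' Plain-text CSV interfaces for the package's tables: simulated
#' populations (`id,sex,body_length,claw_size,claw_strength,
#' trait_score,trait_rank,true_dominance,true_rank`), contest records
#' (`round,winner_id,loser_id`), raw trait measurements (see
#' [generate_empirical_fixture()] for the column layout) and
#' long-format selection curves
#' (`replicate,sex,scenario,round,alpha,min_selected`).  Numeric
#' columns survive a write/read round trip bit-exactly.
#'
#' @param x Table to write.
#' @param path File path.
#' @return Readers return a `data.frame`; writers return `path`
#'   invisibly.
#' @name contestselect-io
NULL

#' @rdname contestselect-io
#' @export
write_population <- function(x, path) write_precise_csv(x, path)

#' @rdname contestselect-io
#' @export
read_population <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("population_table", "data.frame")
  out
}

#' @rdname contestselect-io
#' @export
write_contests <- function(x, path) {
  write_precise_csv(x[, c("round", "winner_id", "loser_id")], path)
}

#' @rdname contestselect-io
#' @export
read_contests <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("round", "winner_id", "loser_id") %in% names(out))) {
    stop("contest CSV must have columns round, winner_id, loser_id",
         call. = FALSE)
  }
  if (any(out$winner_id == out$loser_id)) {
    stop("contest CSV contains a self-contest", call. = FALSE)
  }
  out
}

#' @rdname contestselect-io
#' @export
write_traits <- function(x, path) write_precise_csv(x, path)

#' @rdname contestselect-io
#' @export
read_traits <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  meas <- out[, setdiff(names(out), c("id", "sex"))]
  if (any(vapply(meas, function(col) any(col <= 0), TRUE))) {
    stop("all raw measurements must be positive", call. = FALSE)
  }
  out
}

#' @rdname contestselect-io
#' @export
write_selection_curve <- function(x, path) write_precise_csv(x, path)

#' @rdname contestselect-io
#' @export
read_selection_curve <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname contestselect-io
#' @export
write_abilities <- function(x, path) {
  write_precise_csv(x[, c("round", "id", "ability", "contest_rank",
                          "n_contests")], path)
}
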