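#' Construct a scan path
#'
#' A scan path is the temporally ordered sequence of fixated areas of
#' interest (AOIs), stored as an integer vector over the alphabet
#' `{1, ..., A}`. The alphabet size is fixed explicitly (default 8, the
#' usual AOI layout for driving scenes) so that out-of-alphabet symbols
#' are caught as errors rather than silently widening the alphabet.
#'
#' @param symbols Integer vector of AOI labels in `1..A`.
#' @param A Alphabet size (number of AOIs).
#' @param back_index Integer vector mapping each symbol to the row of the
#'   source fixation table it came from (1-based). Defaults to
#'   `seq_along(symbols)`.
#' @return An object of class `"scanpath"`: an integer vector with
#'   attributes `A` and `back_index`.
#' @examples
#' p <- scanpath(c(1, 2, 1, 2), A = 2)
#' length(p)
#' @export
scanpath <- function(symbols, A = 8, back_index = seq_along(symbols)) {
  symbols <- as.integer(symbols)
  A <- as.integer(A)
  if (length(symbols) < 1L) {
    stop("a scan path must contain at least one fixation", call. = FALSE)
  }
  if (anyNA(symbols)) stop("scan path symbols must not be NA", call. = FALSE)
  if (A < 2L) stop("alphabet size `A` must be at least 2", call. = FALSE)
  bad <- which(symbols < 1L | symbols > A)
  if (length(bad)) {
    stop(sprintf(
      "symbols outside the alphabet 1..%d at positions: %s", A,
      paste(utils::head(bad, 10L), collapse = ", ")
    ), call. = FALSE)
  }
  if (length(back_index) != length(symbols)) {
    stop("`back_index` must have one entry per symbol", call. = FALSE)
  }
  structure(symbols, A = A, back_index = as.integer(back_index),
            class = "scanpath")
}

#' Coerce to a scan path
#'
#' @param x A `scanpath` or an integer-like vector of AOI labels.
#' @param A Alphabet size used when `x` is a bare vector.
#' @return A `scanpath`.
#' @export
as_scanpath <- function(x, A = 8) {
  if (inherits(x, "scanpath")) return(x)
  scanpath(x, A = A)
}

#' @export
print.scanpath <- function(x, ...) {
  cat(sprintf("<scanpath> %d fixations over alphabet 1..%d\n",
              length(x), attr(x, "A")))
  cat(" ", paste(utils::head(unclass(x), 20L), collapse = " "),
      if (length(x) > 20L) "...\n" else "\n")
  invisible(x)
}

#' Alphabet size of a scan path
#' @param path A `scanpath`.
#' @return Integer alphabet size.
#' @export
alphabet_size <- function(path) {
  attr(as_scanpath(path), "A")
}

#' Encode a labeled fixation table as a scan path
#'
#' Extracts the AOI-label sequence of a single recording in temporal
#' order, keeping an index that maps each symbol back to its source row
#' so per-fixation (local) measures can be re-attached to the table.
#' Rows removed by quality filtering simply do not appear; the back-index
#' is then non-contiguous.
#'
#' @param table Fixation table (one row per fixation) with an `aoi`
#'   column; rows must belong to a single `(participant, session)`.
#' @param A Alphabet size.
#' @return A `scanpath` whose `back_index` attribute holds the (1-based)
#'   row positions in `table`.
#' @export
encode_scanpath <- function(table, A = 8) {
  if (!is.data.frame(table) || nrow(table) == 0L) {
    stop("`table` must be a nonempty fixation table", call. = FALSE)
  }
  if (!"aoi" %in% names(table)) stop("column `aoi` is required", call. = FALSE)
  key <- character(nrow(table))
  if ("participant" %in% names(table)) key <- paste0(key, table$participant)
  if ("session" %in% names(table)) key <- paste0(key, "\r", table$session)
  if (length(unique(key)) > 1L) {
    stop("`table` spans multiple (participant, session) recordings; ",
         "split it before encoding", call. = FALSE)
  }
  scanpath(table$aoi, A = A, back_index = seq_len(nrow(table)))
}
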