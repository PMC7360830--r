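#' Circular genome intervals
#'
#' A `plastome_interval` is a 0-based, half-open `[start, end)` interval on a
#' circular axis of length `genome_length`.  When `start > end` the interval
#' wraps the origin (`wrap = TRUE`).  A full-circle interval is written
#' `[x, x)` with `wrap = TRUE` only through [interval()] with
#' `full_circle = TRUE`; the degenerate `[x, x)` with `wrap = FALSE` (length
#' zero) is disallowed.
#'
#' @param start,end 0-based half-open coordinates, already reduced modulo
#'   `genome_length` (values outside `[0, genome_length)` are reduced).
#' @param genome_length length of the circular axis in bp.
#' @param full_circle if `TRUE`, return the interval covering the whole
#'   circle starting at `start`.
#' @return an object of class `plastome_interval` with fields `start`, `end`,
#'   `wrap`, `genome_length`.
#' @examples
#' iv <- interval(4, 2, genome_length = 6)  # wraps: covers 4,5,0,1
#' interval_length(iv)                      # 4
#' @export
interval <- function(start, end, genome_length, full_circle = FALSE) {
  stopifnot(is.numeric(start), is.numeric(end), genome_length >= 1)
  if (!full_circle && end != start &&
      (end - start) %% genome_length == 0) full_circle <- TRUE
  start <- as.integer(start %% genome_length)
  end <- as.integer(end %% genome_length)
  if (full_circle) {
    end <- start
  } else if (start == end) {
    stop("zero-length interval [", start, ", ", end, ") is not representable; ",
         "use full_circle = TRUE for the whole circle")
  }
  structure(
    list(start = start, end = end,
         wrap = (start > end) || full_circle,
         genome_length = as.integer(genome_length)),
    class = "plastome_interval"
  )
}

#' @rdname interval
#' @param x a `plastome_interval`.
#' @export
interval_length <- function(x) {
  stopifnot(inherits(x, "plastome_interval"))
  len <- (x$end - x$start) %% x$genome_length
  if (len == 0L) x$genome_length else len
}

#' @export
print.plastome_interval <- function(x, ...) {
  cat(sprintf("<interval [%d, %d) on circle of %d bp, length %d%s>\n",
              x$start, x$end, x$genome_length, interval_length(x),
              if (x$wrap) ", wraps origin" else ""))
  invisible(x)
}

# Positions (0-based) covered by an interval, in order.
interval_positions <- function(x) {
  n <- interval_length(x)
  (seq.int(x$start, length.out = n)) %% x$genome_length
}

# Membership test for 0-based position(s) `pos`.
interval_contains <- function(x, pos) {
  pos <- pos %% x$genome_length
  if (!x$wrap) pos >= x$start & pos < x$end
  else pos >= x$start | pos < x$end
}

# Overlap length (bp) of two intervals on the same circle.
interval_overlap <- function(a, b) {
  stopifnot(a$genome_length == b$genome_length)
  sum(interval_contains(a, interval_positions(b)))
}
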