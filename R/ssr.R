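#' Find simple sequence repeats (microsatellites)
#'
#' Reports all maximal perfect tandem runs of a primitive 1-6 bp unit whose
#' copy number meets the class threshold.  Defaults follow the common
#' plastome survey settings: at least 10 copies for mononucleotide motifs,
#' 5 for di-, 4 for tri- and 3 for tetra-, penta- and hexanucleotide motifs.
#' Runs containing `N` are split at the `N`.  A run is reported at its
#' smallest primitive unit only (an `AT` run is a dinucleotide SSR, never a
#' tetranucleotide `ATAT` one).  The search is on the forward strand; motifs
#' are reported as they occur from the run's first base, with no
#' reverse-complement canonicalization.
#'
#' @param p a [plastome()] (or plain sequence string).
#' @param thresholds named/indexed integer vector: minimum copies per unit
#'   length 1..6.
#' @return data.frame of class `ssr_table`: motif, unit_len, copies, start,
#'   end (0-based half-open), length, region (if partitioned, else NA).
#' @export
find_ssrs <- function(p, thresholds = c(10L, 5L, 4L, 3L, 3L, 3L)) {
  seq <- if (inherits(p, "plastome")) p$seq else normalize_seq(p)
  circular <- if (inherits(p, "plastome")) p$circular else FALSE
  part <- if (inherits(p, "plastome")) p$partition else NULL
  stopifnot(length(thresholds) == 6L)
  n <- nchar(seq)
  # circular scan: runs crossing the origin are found on the doubled
  # sequence and reported once, with start reduced modulo n
  scan_seq <- if (circular) paste0(seq, seq) else seq
  s <- strsplit(scan_seq, "", fixed = TRUE)[[1L]]
  ns <- length(s)
  out <- list()
  for (u in 1:6) {
    if (n < u * thresholds[u]) next
    # positions where the base u ahead matches (and neither is N)
    idx <- seq_len(ns - u)
    m <- s[idx] == s[idx + u] & s[idx] != "N" & s[idx + u] != "N"
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      run_len <- min(r$lengths[j], n - u)  # cap fully periodic circles
      total <- run_len + u                 # array span: run + one period
      copies <- total %/% u
      if (copies < thresholds[u]) next
      a <- starts[j]                       # 1-based start of the array
      if (circular && a > n) next          # duplicate of the copy at a - n
      if (circular && a == 1L && m[n])
        next                               # left-truncated tail of a wrap run
      motif <- substr(scan_seq, a, a + u - 1L)
      if (!is_primitive(motif)) next       # reported at the smaller unit
      out[[length(out) + 1L]] <- data.frame(
        motif = motif, unit_len = u, copies = copies,
        start = a - 1L, end = a - 1L + copies * u,
        length = copies * u, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    res <- data.frame(motif = character(), unit_len = integer(),
                      copies = integer(), start = integer(), end = integer(),
                      length = integer(), region = character(),
                      stringsAsFactors = FALSE)
    class(res) <- c("ssr_table", "data.frame")
    return(res)
  }
  res <- do.call(rbind, out)
  res$region <- if (!is.null(part)) {
    vapply(seq_len(nrow(res)), function(i)
      region_of(part, interval(res$start[i], res$end[i], n)), "")
  } else NA_character_
  res <- res[order(res$start, res$unit_len), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("ssr_table", "data.frame")
  res
}

# A string is primitive when it is not a whole-number power of a shorter
# string (checked over the divisors of its length).
is_primitive <- function(motif) {
  u <- nchar(motif)
  if (u == 1L) return(TRUE)
  for (v in seq_len(u - 1L)) {
    if (u %% v != 0L) next
    if (strrep(substr(motif, 1L, v), u %/% v) == motif) return(FALSE)
  }
  TRUE
}
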