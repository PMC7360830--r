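#' Find tandem repeat arrays
#'
#' A deliberately transparent tandem-repeat finder in the spirit of Tandem
#' Repeats Finder's reporting contract, without its wraparound dynamic
#' programming or statistical filters.  For every candidate period `P` up to
#' `max_period`, maximal arrays of approximate `P`-periodicity are located
#' from runs of the lag-`P` self-match (short interruptions from point
#' substitutions are bridged); each array is tiled into consecutive
#' `P`-length copies, a majority-rule consensus is formed over the complete
#' copies, and the array is scored against the tiled consensus: `+match`
#' per agreeing position, `-mismatch` per disagreeing position.  The
#' alignment of array to consensus is gapless, so the `indel` penalty
#' participates only through the interface (kept for compatibility with the
#' conventional parameter set 2/7/7).  Trailing partial-copy bases are
#' included only while they extend the score (each agreeing base adds
#' `+match`).  Arrays with score at least `min_score` and at least two
#' copies are reported; reports of the same array at multiples of its
#' period are collapsed to the highest-scoring (then shortest) period.
#'
#' @param p a [plastome()] or sequence string.
#' @param match,mismatch,indel alignment scores (mismatch/indel given as
#'   positive penalties).
#' @param min_score minimum reported alignment score.
#' @param max_period maximum period size (bp).
#' @return data.frame of class `tandem_table`: start, end (0-based
#'   half-open), period, copies (fractional), consensus, score, mismatches.
#' @export
find_tandem_repeats <- function(p, match = 2L, mismatch = 7L, indel = 7L,
                                min_score = 80L, max_period = 500L) {
  seq <- if (inherits(p, "plastome")) p$seq else normalize_seq(p)
  n <- nchar(seq)
  s <- strsplit(seq, "", fixed = TRUE)[[1L]]
  notN <- s != "N"
  # smallest array that can reach min_score is all-match:
  min_array <- ceiling(min_score / match)
  recs <- list()
  for (P in seq_len(min(max_period, n %/% 2L))) {
    idx <- seq_len(n - P)
    m <- s[idx] == s[idx + P] & notN[idx] & notN[idx + P]
    r0 <- rle(m)
    # candidate arrays must carry an exact lag-P stretch of >= 10 bp (the
    # "recurring k-mer" seed); chance matches rarely do
    ends0 <- cumsum(r0$lengths)
    seed_runs <- which(r0$values & r0$lengths >= 10L)
    if (!length(seed_runs)) next
    seed_pos <- ends0[seed_runs] - r0$lengths[seed_runs] + 1L
    # bridge interruptions caused by isolated substitutions: a substituted
    # base breaks the lag-P match at up to two positions
    r <- r0
    if (length(r$lengths) > 1L) {
      gap <- !r$values & r$lengths <= 3L
      gap[c(1L, length(gap))] <- FALSE
      r$values[gap] <- TRUE
      r <- rle(inverse.rle(r))
    }
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      total <- r$lengths[j] + P          # array span in bp
      if (total < max(min_array, 2L * P)) next
      a <- starts[j]
      if (!any(seed_pos >= a & seed_pos <= ends[j])) next
      rec <- score_tandem(s, a, total, P, match, mismatch)
      if (is.null(rec) || rec$score < min_score) next
      recs[[length(recs) + 1L]] <- rec
    }
  }
  cols <- c("start", "end", "period", "copies", "consensus", "score",
            "mismatches")
  if (!length(recs)) {
    res <- data.frame(start = integer(), end = integer(), period = integer(),
                      copies = numeric(), consensus = character(),
                      score = integer(), mismatches = integer(),
                      stringsAsFactors = FALSE)
    class(res) <- c("tandem_table", "data.frame")
    return(res)
  }
  res <- do.call(rbind, lapply(recs, as.data.frame))[, cols]
  res <- collapse_period_multiples(res)
  res <- res[order(res$start, res$period), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("tandem_table", "data.frame")
  res
}

# Score the array starting at 1-based `a`, spanning `total` bp, period P.
# The candidate run can be padded with non-repetitive flanks (bridged
# interruptions), so the reported array is refined: the start phase
# (0..P-1) and the contiguous window of complete copies maximizing the
# score are chosen, then the consensus is recomputed on that window.
score_tandem <- function(s, a, total, P, match, mismatch) {
  if (total %/% P < 2L) return(NULL)
  best <- NULL
  for (off in 0:(P - 1L)) {
    ncopy <- (total - off) %/% P
    if (ncopy < 2L) break
    a0 <- a + off
    tiles <- matrix(s[a0:(a0 + ncopy * P - 1L)], nrow = P)
    cons <- apply(tiles, 1L, majority_base)
    agree <- tiles == cons
    copy_score <- match * colSums(agree) - mismatch * colSums(!agree)
    w <- best_copy_window(copy_score)
    if (is.null(w)) next
    sc <- sum(copy_score[w[1L]:w[2L]])
    if (is.null(best) || sc > best$sc)
      best <- list(sc = sc, off = off, w = w)
  }
  if (is.null(best)) return(NULL)
  # recompute the consensus on the chosen copies and rescore
  a1 <- a + best$off + (best$w[1L] - 1L) * P
  ncopy <- best$w[2L] - best$w[1L] + 1L
  tiles <- matrix(s[a1:(a1 + ncopy * P - 1L)], nrow = P)
  consensus <- apply(tiles, 1L, majority_base)
  agree <- tiles == consensus
  score <- match * sum(agree) - mismatch * sum(!agree)
  mism <- sum(!agree)
  # greedy trailing partial copy: extend while bases match the consensus
  end <- a1 + ncopy * P - 1L
  t <- 0L
  while (end < length(s) && t < P - 1L &&
         s[end + 1L] == consensus[t + 1L]) {
    end <- end + 1L; t <- t + 1L; score <- score + match
  }
  list(start = a1 - 1L, end = end, period = P,
       copies = round((end - a1 + 1L) / P, 2),
       consensus = paste(consensus, collapse = ""),
       score = score, mismatches = mism)
}

majority_base <- function(col) {
  tb <- table(col[col != "N"])
  if (!length(tb)) "N" else names(tb)[which.max(tb)]
}

# Contiguous window of >= 2 copies maximizing the summed copy scores
# (O(k^2) over the copy count, which is small).
best_copy_window <- function(copy_score) {
  k <- length(copy_score)
  if (k < 2L) return(NULL)
  cs <- c(0, cumsum(copy_score))
  best <- NULL; bestv <- -Inf
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    v <- cs[j + 1L] - cs[i]
    if (v > bestv) { bestv <- v; best <- c(i, j) }
  }
  best
}

# Collapse overlapping reports of the same array at period multiples,
# keeping the highest-scoring (ties: smallest period).
collapse_period_multiples <- function(res) {
  res <- res[order(-res$score, res$period, res$start), , drop = FALSE]
  keep <- rep(TRUE, nrow(res))
  for (i in seq_len(nrow(res))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(res))) {
      if (j == i || !keep[j]) next
      multiple <- res$period[j] %% res$period[i] == 0L ||
        res$period[i] %% res$period[j] == 0L
      overlap <- res$start[j] < res$end[i] & res$end[j] > res$start[i]
      if (multiple && overlap) keep[j] <- FALSE
    }
  }
  res[keep, , drop = FALSE]
}
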