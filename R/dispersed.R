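#' Find dispersed and palindromic repeat pairs
#'
#' Maximal repeat pairs under the four REPuter-style transforms:
#' * forward: second copy equals the first;
#' * reverse: second copy is the reverse of the first;
#' * complement: second copy is the base-complement (no reversal);
#' * palindromic: second copy is the reverse complement.
#'
#' A pair is reported when the copies have Hamming distance at most
#' `max_mismatch`, length at least `min_len`, begins and ends on a matching
#' position, and cannot be extended to any larger match-bounded window
#' without exceeding the mismatch budget.  Self-overlapping pairs are
#' excluded.  When a quadripartite
#' partition is attached, the palindromic hit produced by the two whole-IR
#' copies is flagged `is_ir`.  Output is truncated to the `max_out` longest
#' records across categories (ties broken by coordinates).
#'
#' Candidate diagonals are located with exact 7 bp seeds (pigeonhole bound
#' for 30 bp with 3 mismatches) and then scanned exhaustively, so results
#' match the definitional brute force.
#'
#' @param p a [plastome()] or sequence string.  The scan is on the linear
#'   input orientation; origin-wrapping pairs are not searched.
#' @param min_len minimum repeat length (bp).
#' @param max_mismatch Hamming-distance budget per pair.
#' @param max_out retain this many longest records (Inf for all).
#' @return data.frame of class `repeat_table`: category, start1, end1,
#'   start2, end2 (0-based half-open), length, mismatches, is_ir.
#' @export
find_dispersed_repeats <- function(p, min_len = 30L, max_mismatch = 3L,
                                   max_out = 100L) {
  seq <- if (inherits(p, "plastome")) p$seq else normalize_seq(p)
  part <- if (inherits(p, "plastome")) p$partition else NULL
  n <- nchar(seq)
  s <- strsplit(seq, "", fixed = TRUE)[[1L]]
  notN <- s != "N"
  comp <- chartr("ACGTN", "TGCAN", s)
  # pigeonhole: any window of min_len with <= max_mismatch mismatches
  # contains an exact run of at least (min_len - mm) / (mm + 1) bases
  seed_k <- max(2L, min(7L, (min_len - max_mismatch) %/% (max_mismatch + 1L)))

  recs <- list()
  add <- function(category, a1, b1, a2, b2, mism) {
    recs[[length(recs) + 1L]] <<- list(
      category = rep(category, length(a1)), start1 = a1 - 1L, end1 = b1,
      start2 = a2 - 1L, end2 = b2, length = b1 - a1 + 1L,
      mismatches = mism)
  }

  # Every reportable window (>= min_len, <= max_mismatch mismatches)
  # contains an exact seed in each of its 31-base stretches (pigeonhole),
  # so scanning seed neighborhoods of +/- pad positions on each seeded
  # (anti)diagonal is exhaustive.
  pad <- 4L * (seed_k + max_mismatch) + min_len

  # ---- diagonal families (forward, complement): compare x with x + d ----
  for (category in c("forward", "complement")) {
    target <- if (category == "forward") s else comp
    seeds <- candidate_diagonals(seq, category, seed_k, n)
    for (dch in names(seeds)) {
      d <- as.integer(dch)
      lo_all <- 1L; hi_all <- n - d
      if (hi_all < lo_all) next
      for (w in merge_windows(seeds[[dch]], pad, lo_all, hi_all)) {
        xs <- w[1L]:w[2L]
        m <- s[xs] == target[xs + d] & notN[xs] & notN[xs + d]
        runs <- match_bounded_runs(m, max_mismatch)
        keep <- runs$len >= min_len & runs$len <= d
        if (!any(keep)) next
        a <- w[1L] + runs$start[keep] - 1L
        b <- a + runs$len[keep] - 1L
        add(category, a, b, a + d, b + d, runs$mism[keep])
      }
    }
  }

  # ---- anti-diagonal families (reverse, palindromic): x with c - x ----
  for (category in c("reverse", "palindromic")) {
    target <- if (category == "reverse") s else comp
    seeds <- candidate_antidiagonals(seq, category, seed_k, n)
    for (cch in names(seeds)) {
      cc <- as.integer(cch)
      # paired 1-based positions x and y satisfy x + y = cc; scan x < y.
      hi_all <- as.integer(floor((cc - 1L) / 2L))
      lo_all <- max(1L, cc - n)
      if (hi_all < lo_all) next
      for (w in merge_windows(seeds[[cch]], pad, lo_all, hi_all)) {
        xs <- w[1L]:w[2L]
        m <- s[xs] == target[cc - xs] & notN[xs] & notN[cc - xs]
        runs <- match_bounded_runs(m, max_mismatch)
        keep <- runs$len >= min_len
        if (!any(keep)) next
        a <- w[1L] + runs$start[keep] - 1L
        b <- a + runs$len[keep] - 1L
        add(category, a, b, cc - b, cc - a, runs$mism[keep])
      }
    }
  }

  if (!length(recs)) {
    res <- data.frame(category = character(), start1 = integer(),
                      end1 = integer(), start2 = integer(), end2 = integer(),
                      length = integer(), mismatches = integer(),
                      is_ir = logical(), stringsAsFactors = FALSE)
    class(res) <- c("repeat_table", "data.frame")
    return(res)
  }
  res <- data.frame(
    category = unlist(lapply(recs, `[[`, "category")),
    start1 = unlist(lapply(recs, `[[`, "start1")),
    end1 = unlist(lapply(recs, `[[`, "end1")),
    start2 = unlist(lapply(recs, `[[`, "start2")),
    end2 = unlist(lapply(recs, `[[`, "end2")),
    length = unlist(lapply(recs, `[[`, "length")),
    mismatches = unlist(lapply(recs, `[[`, "mismatches")),
    stringsAsFactors = FALSE)
  res$is_ir <- flag_ir_hit(res, part, n)
  res <- res[order(-res$length, res$start1, res$start2,
                   res$category), , drop = FALSE]
  if (is.finite(max_out) && nrow(res) > max_out)
    res <- res[seq_len(max_out), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("repeat_table", "data.frame")
  res
}

# Maximal match-bounded windows with at most `budget` mismatches: each
# window starts and ends on a TRUE position and is contained in no larger
# such window within budget.  Returns list(start, len, mism) of equal
# integer vectors, 1-based starts relative to `m`.
match_bounded_runs <- function(m, budget) {
  empty <- list(start = integer(), len = integer(), mism = integer())
  n <- length(m)
  if (!n) return(empty)
  ms <- which(m)
  if (!length(ms)) return(empty)
  M <- cumsum(!m)
  M0 <- c(0L, M[-n])
  bmax <- findInterval(M0[ms] + budget, M)   # furthest end within budget
  # trim each window end to the last matching position
  bstar <- ms[findInterval(bmax, ms)]
  keep <- c(TRUE, bstar[-1L] > bstar[-length(bstar)])
  a <- ms[keep]; b <- bstar[keep]
  list(start = a, len = b - a + 1L, mism = M[b] - M0[a])
}

# Exact seed matching: for each diagonal d (offset) carrying at least one
# exact seed_k-mer pair under the category's transform, the seed start
# positions on that diagonal.  Any reportable window must contain an exact
# 7-mer (pigeonhole for 30 bp / 3 mismatches), so seeded diagonals plus
# seed neighborhoods are exhaustive.
candidate_diagonals <- function(seq, category, seed_k, n) {
  if (n <= seed_k) return(list())
  starts <- seq_len(n - seed_k + 1L)
  kmers <- substring(seq, starts, starts + seed_k - 1L)
  tgt <- if (category == "forward") kmers else
    substring(complement(seq), starts, starts + seed_k - 1L)
  grp <- split(starts, kmers)
  tgt_grp <- split(starts, tgt)
  common <- intersect(names(grp), names(tgt_grp))
  common <- setdiff(common, grep("N", common, value = TRUE, fixed = TRUE))
  acc <- lapply(common, function(k) {
    a <- grp[[k]]; b <- tgt_grp[[k]]
    # seed at a (in s) aligns with transformed seed at b: offset d = b - a
    d <- rep(b, each = length(a)) - rep(a, times = length(b))
    x <- rep(a, times = length(b))
    keep <- d > 0L
    list(x = x[keep], d = d[keep])
  })
  pos <- unlist(lapply(acc, `[[`, "x"), use.names = FALSE)
  dd <- unlist(lapply(acc, `[[`, "d"), use.names = FALSE)
  if (!length(pos)) return(list())
  split(pos, dd)
}

candidate_antidiagonals <- function(seq, category, seed_k, n) {
  if (n <= seed_k) return(list())
  starts <- seq_len(n - seed_k + 1L)
  kmers <- substring(seq, starts, starts + seed_k - 1L)
  rev1 <- vapply(strsplit(kmers, "", fixed = TRUE),
                 function(ch) paste(rev(ch), collapse = ""), "")
  tgt <- if (category == "reverse") rev1 else
    chartr("ACGTN", "TGCAN", rev1)
  # seed pair: s[a..a+k-1] matches transform of s[b..b+k-1]; paired
  # positions satisfy x + y = a + b + k - 1.
  grp <- split(starts, kmers)
  tgt_grp <- split(starts, tgt)
  common <- intersect(names(grp), names(tgt_grp))
  common <- setdiff(common, grep("N", common, value = TRUE, fixed = TRUE))
  acc <- lapply(common, function(k) {
    a <- grp[[k]]; b <- tgt_grp[[k]]
    list(x = rep(a, times = length(b)),
         cc = rep(b, each = length(a)) + rep(a, times = length(b)) +
           seed_k - 1L)
  })
  pos <- unlist(lapply(acc, `[[`, "x"), use.names = FALSE)
  cs <- unlist(lapply(acc, `[[`, "cc"), use.names = FALSE)
  if (!length(pos)) return(list())
  split(pos, cs)
}

# Merge seed positions into padded scan windows clipped to [lo, hi].
merge_windows <- function(positions, pad, lo, hi) {
  positions <- sort.int(positions, method = "radix")
  a <- pmax(positions - pad, lo)
  b <- pmin(positions + pad, hi)
  keep <- a <= b
  a <- a[keep]; b <- b[keep]
  if (!length(a)) return(list())
  out <- list(); cur <- c(a[1L], b[1L])
  for (i in seq_along(a)[-1L]) {
    if (a[i] <= cur[2L] + 1L) cur[2L] <- max(cur[2L], b[i])
    else { out[[length(out) + 1L]] <- cur; cur <- c(a[i], b[i]) }
  }
  out[[length(out) + 1L]] <- cur
  out
}

# Flag palindromic records representing the whole-IR pair: both copies
# must cover at least 90% of their respective IR interval.
flag_ir_hit <- function(res, part, n) {
  if (is.null(part)) return(rep(FALSE, nrow(res)))
  irb <- part$irb; ira <- part$ira
  ir_len <- interval_length(irb)
  vapply(seq_len(nrow(res)), function(i) {
    if (res$category[i] != "palindromic") return(FALSE)
    iv1 <- interval(res$start1[i], res$end1[i], n)
    iv2 <- interval(res$start2[i], res$end2[i], n)
    (interval_overlap(iv1, irb) >= 0.9 * ir_len &&
       interval_overlap(iv2, ira) >= 0.9 * ir_len) ||
      (interval_overlap(iv1, ira) >= 0.9 * ir_len &&
         interval_overlap(iv2, irb) >= 0.9 * ir_len)
  }, TRUE)
}
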