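# Fixtures and independent oracles shared across the test files.

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# ---------------------------------------------------------------------------
# Brute-force dispersed-repeat oracle: every diagonal / anti-diagonal of the
# full comparison matrix is enumerated (no seeding); each candidate window
# is then verified against the definition (Hamming budget, match-bounded
# ends, inextensibility) by direct substring comparison.
oracle_dispersed <- function(seq, min_len = 30L, max_mismatch = 3L) {
  s <- strsplit(seq, "", fixed = TRUE)[[1L]]
  comp <- chartr("ACGTN", "TGCAN", s)
  n <- length(s)
  rows <- list()
  push <- function(category, a, b, a2, b2, mism) {
    rows[[length(rows) + 1L]] <<- data.frame(
      category = category, start1 = a - 1L, end1 = b, start2 = a2 - 1L,
      end2 = b2, length = b - a + 1L, mismatches = mism,
      stringsAsFactors = FALSE)
  }
  windows_of <- function(m, budget) {
    # enumeration without seeding: for every match start, the furthest
    # match-bounded end within budget (prefix-sum arithmetic); windows
    # contained in another window are dropped.  Reported windows are
    # re-verified definitionally by the caller.
    ms <- which(m)
    if (!length(ms)) return(NULL)
    nm <- length(m)
    M <- cumsum(!m)
    M0 <- c(0L, M[-nm])
    bmax <- findInterval(M0[ms] + budget, M)
    bstar <- ms[findInterval(bmax, ms)]
    keep <- !duplicated(bstar)
    list(start = ms[keep], end = bstar[keep],
         mism = M[bstar[keep]] - M0[ms[keep]])
  }
  for (category in c("forward", "complement")) {
    tgt <- if (category == "forward") s else comp
    for (d in seq_len(n - 1L)) {
      if (n - d < min_len) break
      idx <- seq_len(n - d)
      m <- s[idx] == tgt[idx + d] & s[idx] != "N" & tgt[idx + d] != "N"
      w <- windows_of(m, max_mismatch)
      if (is.null(w)) next
      for (q in seq_along(w$start)) {
        len <- w$end[q] - w$start[q] + 1L
        if (len < min_len || len > d) next
        push(category, w$start[q], w$end[q],
             w$start[q] + d, w$end[q] + d, w$mism[q])
      }
    }
  }
  for (category in c("reverse", "palindromic")) {
    tgt <- if (category == "reverse") s else comp
    for (cc in 3:(2L * n - 1L)) {
      hi <- floor((cc - 1L) / 2L); lo <- max(1L, cc - n)
      if (hi - lo + 1L < min_len) next
      xs <- lo:hi
      m <- s[xs] == tgt[cc - xs] & s[xs] != "N" & tgt[cc - xs] != "N"
      w <- windows_of(m, max_mismatch)
      if (is.null(w)) next
      for (q in seq_along(w$start)) {
        len <- w$end[q] - w$start[q] + 1L
        if (len < min_len) next
        a <- lo + w$start[q] - 1L; b <- lo + w$end[q] - 1L
        push(category, a, b, cc - b, cc - a, w$mism[q])
      }
    }
  }
  if (!length(rows))
    return(data.frame(category = character(), start1 = integer(),
                      end1 = integer(), start2 = integer(),
                      end2 = integer(), length = integer(),
                      mismatches = integer(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

sort_repeats <- function(df) {
  df <- df[, c("category", "start1", "end1", "start2", "end2", "length",
               "mismatches")]
  df <- df[order(df$category, df$start1, df$start2), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- "data.frame"
  df
}

# Definitional verification of one dispersed-repeat record: re-extract the
# two copies and check the category relation, the mismatch budget and
# match-bounded ends.
verify_repeat_record <- function(seq, rec, max_mismatch = 3L) {
  s1 <- substr(seq, rec$start1 + 1L, rec$end1)
  s2 <- substr(seq, rec$start2 + 1L, rec$end2)
  t1 <- switch(rec$category,
               forward = s1,
               reverse = paste(rev(strsplit(s1, "")[[1L]]), collapse = ""),
               complement = chartr("ACGTN", "TGCAN", s1),
               palindromic = plastomics::revcomp(s1))
  a <- strsplit(t1, "")[[1L]]; b <- strsplit(s2, "")[[1L]]
  length(a) == length(b) && sum(a != b) <= max_mismatch &&
    sum(a != b) == rec$mismatches &&
    a[1L] == b[1L] && a[length(a)] == b[length(b)]
}

# ---------------------------------------------------------------------------
# Independent NG86 oracle built on Biostrings' genetic code.
oracle_translate <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  unname(gc[codon])
}

oracle_site_counts <- function(codon) {
  stops <- c("TAA", "TAG", "TGA")
  aa0 <- oracle_translate(codon)
  s <- 0
  for (pos in 1:3) {
    syn <- 0L; ok <- 0L
    for (b in c("A", "C", "G", "T")) {
      if (b == substr(codon, pos, pos)) next
      mut <- codon
      substr(mut, pos, pos) <- b
      if (mut %in% stops) next
      ok <- ok + 1L
      if (oracle_translate(mut) == aa0) syn <- syn + 1L
    }
    if (ok > 0L) s <- s + syn / ok
  }
  c(n = 3 - s, s = s)
}

# pathway enumeration oracle: average syn/nonsyn steps over all orderings
# of the differing positions, excluding paths through stop codons
oracle_diff_counts <- function(c1, c2) {
  stops <- c("TAA", "TAG", "TGA")
  pos <- which(strsplit(c1, "")[[1L]] != strsplit(c2, "")[[1L]])
  if (!length(pos)) return(c(nd = 0, sd = 0))
  perm_list <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perm_list(v[-i]))
        out[[length(out) + 1L]] <- c(v[i], rest)
    out
  }
  tot_n <- 0; tot_s <- 0; paths <- 0L
  for (ord in perm_list(pos)) {
    cur <- c1; ns <- 0L; nn <- 0L; valid <- TRUE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (nxt %in% stops) { valid <- FALSE; break }
      if (oracle_translate(nxt) == oracle_translate(cur)) ns <- ns + 1L
      else nn <- nn + 1L
      cur <- nxt
    }
    if (valid) { tot_n <- tot_n + nn; tot_s <- tot_s + ns; paths <- paths + 1L }
  }
  if (!paths) return(c(nd = length(pos), sd = 0))
  c(nd = tot_n / paths, sd = tot_s / paths)
}

all_sense_codons <- function() {
  bases <- c("A", "C", "G", "T")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  setdiff(codons, c("TAA", "TAG", "TGA"))
}

# ---------------------------------------------------------------------------
# quick fixture: a tiny annotated circular genome with two genes and a
# wrap-around spacer
toy_two_gene_plastome <- function(id = "toy", seed = 1) {
  set.seed(seed)
  n <- 600L
  seq <- random_dna(n)
  fa <- gene_feature("geneA", "CDS", interval(50, 230, n), "+")
  fb <- gene_feature("geneB", "CDS", interval(300, 480, n), "-")
  plastome(id, seq, features = list(fa, fb))
}
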