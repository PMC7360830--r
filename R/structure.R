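#' Detect the inverted repeat and partition a plastome
#'
#' Finds the maximal-length pair of disjoint segments `X`, `Y` on the circle
#' with `Y = revcomp(X)` within `max_mismatch` substitutions, both at least
#' `min_ir_len` bp, extended maximally on both flanks.  The two single-copy
#' segments between the IR copies are labeled LSC (the longer) and SSC (the
#' shorter); IRb is the IR copy immediately downstream of the LSC in input
#' orientation, so the circle reads LSC, IRb, SSC, IRa.
#'
#' The default `max_mismatch = 0` reflects the empirical identity of the two
#' IR copies in conserved plastomes; junctions are then bit-exact: each
#' junction position is the first coordinate after the last matching base.
#' Ties between candidate pairs are broken by total IR length after flank
#' extension, then by smaller start coordinate.
#'
#' @param p a [plastome()].
#' @param min_ir_len minimum acceptable IR copy length (bp).
#' @param max_mismatch substitution tolerance between the two copies.
#' @return a `quadripartite_partition`: list with intervals `lsc`, `irb`,
#'   `ssc`, `ira` and `genome_length`.
#' @seealso [partition_plastome()] to attach the result to the plastome.
#' @export
detect_ir <- function(p, min_ir_len = 1000L, max_mismatch = 0L) {
  stopifnot(inherits(p, "plastome"))
  n <- nchar(p$seq)
  if (n < 2L * min_ir_len + 2L)
    stop(partition_error(p$id, "sequence shorter than two IR copies"))
  s <- strsplit(p$seq, "", fixed = TRUE)[[1L]]
  comp <- chartr("ACGTN", "TGCAN", s)

  k <- as.integer(min(20L, min_ir_len))
  # Vectorized circular k-mers of the sequence and of its reverse
  # complement; kmer(y) == revcomp(kmer(x)) is looked up by index algebra.
  fwd2 <- paste0(p$seq, substr(p$seq, 1L, k))
  kmers <- substring(fwd2, seq_len(n), seq_len(n) + k - 1L)
  rc_full <- paste(rev(comp), collapse = "")
  rc2 <- paste0(rc_full, substr(rc_full, 1L, k))
  rc_at <- substring(rc2, seq_len(n), seq_len(n) + k - 1L)
  # revcomp of the k-mer starting at 0-based i is the k-mer of revcomp(S)
  # starting at 0-based (n - i - k) mod n.
  rc_kmers <- rc_at[((n - (seq_len(n) - 1L) - k) %% n) + 1L]
  hit <- match(rc_kmers, kmers)  # y = hit[x]: kmer(y) == revcomp(kmer(x))
  cand <- which(!is.na(hit) & !grepl("N", kmers, fixed = TRUE))
  if (!length(cand)) stop(partition_error(p$id, "no inverted seed found"))
  # Anti-diagonal invariant: when segment2 = revcomp(segment1), paired
  # 0-based positions satisfy x + y = c (mod n).  The first base of the
  # k-mer at x pairs with the last base of the partner k-mer at y.
  cs <- unique((cand - 1L + hit[cand] - 1L + k - 1L) %% n)

  best <- NULL
  consider <- function(seg1, seg2, best) {
    len <- interval_length(seg1)
    if (len < min_ir_len || interval_length(seg2) != len) return(best)
    if (interval_overlap(seg1, seg2) > 0L) return(best)
    h <- hamming(circular_slice(p$seq, seg2), revcomp(circular_slice(p$seq, seg1)))
    if (h > max_mismatch) return(best)
    if (is.null(best) || len > best$len ||
        (len == best$len && min(seg1$start, seg2$start) <
           min(best$seg1$start, best$seg2$start)))
      return(list(seg1 = seg1, seg2 = seg2, len = len))
    best
  }
  for (cc in cs) {
    # match vector over x = 0..n-1: s[x] complementary to s[(cc - x) mod n].
    # A pair mismatch shows up at both x and its mirror, so the run budget
    # is doubled; extracted segments are re-verified below.
    x <- 0:(n - 1L)
    partner <- (cc - x) %% n
    m <- s[x + 1L] == comp[partner + 1L] & s[x + 1L] != "N"
    runs <- budget_runs(c(m, m), 2L * max_mismatch)
    if (!nrow(runs)) next
    runs$len <- pmin(runs$len, n)
    runs <- runs[runs$start <= n, , drop = FALSE]
    for (r in seq_len(nrow(runs))) {
      a0 <- runs$start[r] - 1L                  # 0-based, may exceed n
      len <- runs$len[r]
      mir <- (cc - (a0 + len - 1L)) %% n        # mirror run start
      if (mir == a0 %% n) {
        # self-symmetric run: the two copies are adjacent within one run
        len1 <- len %/% 2L
        if (len1 < min_ir_len) next
        seg1 <- interval(a0 %% n, (a0 + len1) %% n, n)
        seg2 <- interval((a0 + len - len1) %% n, (a0 + len) %% n, n)
      } else {
        if (((a0 %% n) > mir)) next             # canonical order: process once
        seg1 <- interval(a0 %% n, (a0 + len) %% n, n)
        seg2 <- interval(mir, (mir + len) %% n, n)
      }
      best <- consider(seg1, seg2, best)
    }
  }
  if (is.null(best))
    stop(partition_error(p$id, sprintf(
      "no inverted duplication of >= %d bp found", min_ir_len)))
  build_partition(p, best$seg1, best$seg2)
}

# Assemble the quadripartite partition given the two IR copies (intervals).
build_partition <- function(p, seg1, seg2) {
  n <- nchar(p$seq)
  gap_a <- interval(seg1$end, seg2$start, n)   # between copy1 end, copy2 start
  gap_b <- interval(seg2$end, seg1$start, n)
  if (interval_length(gap_a) + interval_length(gap_b) +
      interval_length(seg1) + interval_length(seg2) != n)
    stop(partition_error(p$id, "IR copies overlap"))
  if (interval_length(gap_a) >= interval_length(gap_b)) {
    lsc <- gap_a; ssc <- gap_b; irb <- seg2; ira <- seg1
  } else {
    lsc <- gap_b; ssc <- gap_a; irb <- seg1; ira <- seg2
  }
  part <- structure(
    list(lsc = lsc, irb = irb, ssc = ssc, ira = ira,
         genome_length = n),
    class = "quadripartite_partition")
  validate_partition(p, part)
  part
}

validate_partition <- function(p, part) {
  lens <- vapply(part[c("lsc", "irb", "ssc", "ira")], interval_length, 0L)
  if (sum(lens) != part$genome_length)
    stop(partition_error(p$id, "partition does not tile the circle"))
  invisible(part)
}

partition_error <- function(id, msg) {
  errorCondition(
    sprintf("genome %s is not quadripartite: %s", id, msg),
    class = c("plastomics_partition_error", "error"))
}

#' @export
print.quadripartite_partition <- function(x, ...) {
  lens <- vapply(x[c("lsc", "irb", "ssc", "ira")], interval_length, 0L)
  cat(sprintf("<quadripartite partition of %d bp: LSC %d | IRb %d | SSC %d | IRa %d>\n",
              x$genome_length, lens[1], lens[2], lens[3], lens[4]))
  invisible(x)
}

#' @rdname detect_ir
#' @export
partition_plastome <- function(p, min_ir_len = 1000L, max_mismatch = 0L) {
  p$partition <- detect_ir(p, min_ir_len, max_mismatch)
  p
}

# Hamming distance between two equal-length strings.
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(strsplit(a, "", fixed = TRUE)[[1L]] !=
        strsplit(b, "", fixed = TRUE)[[1L]])
}

# Maximal runs with at most `budget` mismatches in logical vector m
# (TRUE = match).  Returns data.frame(start, len, mism), 1-based starts.
# A run is maximal when it cannot be extended one step either way.
budget_runs <- function(m, budget) {
  n <- length(m)
  empty <- data.frame(start = integer(), len = integer(), mism = integer())
  if (!n) return(empty)
  M <- cumsum(!m)                      # mismatch prefix counts
  M0 <- c(0L, M[-n])                   # mismatches strictly before position a
  b <- findInterval(M0 + budget, M)    # furthest end within budget, per start
  len <- b - seq_len(n) + 1L
  left_max <- c(TRUE, b[-n] < b[-1])   # window [a-1, b(a)] would blow budget
  keep <- which(left_max & len >= 1L)
  if (!length(keep)) return(empty)
  data.frame(start = keep, len = len[keep],
             mism = M[b[keep]] - M0[keep])
}

#' GC content as a percentage
#'
#' `100 * (G + C) / (A + C + G + T)`; `N` is excluded from both numerator
#' and denominator.
#'
#' @param x a sequence string or a [plastome()].
#' @param iv optional [interval()] restricting the computation.
#' @return percent (full precision); `NA` with a warning for an all-N input.
#' @examples
#' gc_content("ATGC")  # 50
#' @export
gc_content <- function(x, iv = NULL) {
  seq <- if (inherits(x, "plastome")) x$seq else x
  if (!is.null(iv)) seq <- circular_slice(seq, iv)
  counts <- table(strsplit(seq, "", fixed = TRUE)[[1L]])
  acgt <- sum(counts[intersect(names(counts), c("A", "C", "G", "T"))])
  if (acgt == 0L) {
    warning("GC content undefined: no unambiguous bases")
    return(NA_real_)
  }
  gc <- sum(counts[intersect(names(counts), c("G", "C"))])
  100 * gc / acgt
}

#' Per-region GC content of a partitioned plastome
#'
#' @param p a partitioned [plastome()].
#' @return named numeric: whole, lsc, irb, ssc, ira (percent).
#' @export
gc_by_region <- function(p) {
  stopifnot(inherits(p, "plastome"), !is.null(p$partition))
  pt <- p$partition
  c(whole = gc_content(p),
    lsc = gc_content(p, pt$lsc), irb = gc_content(p, pt$irb),
    ssc = gc_content(p, pt$ssc), ira = gc_content(p, pt$ira))
}

#' Which quadripartite region holds a position or interval
#'
#' Intervals straddling a junction are attributed to the region holding the
#' majority of their length.
#'
#' @param part a `quadripartite_partition`.
#' @param iv an [interval()] (or a single 0-based position).
#' @return one of "LSC", "IRb", "SSC", "IRa".
#' @export
region_of <- function(part, iv) {
  stopifnot(inherits(part, "quadripartite_partition"))
  if (!inherits(iv, "plastome_interval"))
    iv <- interval(iv, iv + 1L, part$genome_length)
  ov <- vapply(part[c("lsc", "irb", "ssc", "ira")],
               function(r) interval_overlap(r, iv), 0)
  c("LSC", "IRb", "SSC", "IRa")[which.max(ov)]
}

#' Junction gene contexts
#'
#' For each of the four junctions (LSC/IRb, IRb/SSC, SSC/IRa, IRa/LSC),
#' reports the genes whose span straddles the junction (with bp on each
#' side) and the nearest gene on either side with its distance in bp.
#' The junction position is the first coordinate of the downstream region.
#'
#' @param p a partitioned [plastome()].
#' @return data.frame with one row per (junction, gene-context) pair:
#'   columns junction, junction_pos, gene, kind, role
#'   (overlapping/nearest_left/nearest_right), bp_left, bp_right, distance.
#' @export
junction_report <- function(p) {
  stopifnot(inherits(p, "plastome"), !is.null(p$partition))
  pt <- p$partition
  n <- pt$genome_length
  juncs <- data.frame(
    junction = c("LSC/IRb", "IRb/SSC", "SSC/IRa", "IRa/LSC"),
    pos = c(pt$irb$start, pt$ssc$start, pt$ira$start, pt$lsc$start))
  rows <- list()
  for (j in seq_len(nrow(juncs))) {
    pos <- juncs$pos[j]
    left_best <- NULL; right_best <- NULL
    for (f in p$features) {
      sp <- feature_span(f)
      if (interval_contains(sp, pos) && interval_contains(sp, (pos - 1L) %% n)) {
        bp_right <- ((sp$end - pos) %% n)
        bp_left <- interval_length(sp) - bp_right
        if (bp_left > 0 && bp_right > 0) {
          rows[[length(rows) + 1L]] <- data.frame(
            junction = juncs$junction[j], junction_pos = pos, gene = f$name,
            kind = f$kind, role = "overlapping",
            bp_left = bp_left, bp_right = bp_right, distance = 0L)
          next
        }
      }
      d_left <- (pos - sp$end) %% n        # gap from gene end to junction
      d_right <- (sp$start - pos) %% n     # gap from junction to gene start
      if (d_left <= d_right) {
        if (is.null(left_best) || d_left < left_best$d)
          left_best <- list(f = f, d = d_left)
      } else {
        if (is.null(right_best) || d_right < right_best$d)
          right_best <- list(f = f, d = d_right)
      }
    }
    for (side in list(c("nearest_left", "left"), c("nearest_right", "right"))) {
      b <- if (side[2] == "left") left_best else right_best
      if (!is.null(b))
        rows[[length(rows) + 1L]] <- data.frame(
          junction = juncs$junction[j], junction_pos = juncs$pos[j],
          gene = b$f$name, kind = b$f$kind, role = side[1],
          bp_left = NA_integer_, bp_right = NA_integer_, distance = b$d)
    }
  }
  if (!length(rows))
    return(data.frame(junction = character(), junction_pos = integer(),
                      gene = character(), kind = character(),
                      role = character(), bp_left = integer(),
                      bp_right = integer(), distance = integer()))
  do.call(rbind, rows)
}

#' Gene inventory of a partitioned plastome
#'
#' Unique gene names are counted once; a gene is IR-duplicated when two
#' same-name features lie (by majority of their length) in IRa and IRb
#' respectively.  Intron count is `exons - 1` per cis-spliced gene;
#' trans-spliced genes (rps12 convention: one feature per location block)
#' are counted once with introns summed over blocks.
#'
#' @param p a partitioned [plastome()].
#' @return list of class `gene_inventory`.
#' @export
gene_inventory <- function(p) {
  stopifnot(inherits(p, "plastome"), !is.null(p$partition))
  feats <- p$features
  nm <- vapply(feats, function(f) f$name, "")
  kind <- vapply(feats, function(f) f$kind, "")
  reg <- vapply(feats, function(f) region_of(p$partition, feature_span(f)), "")

  un <- !duplicated(nm)
  dup_class <- function(kk) {
    names_k <- unique(nm[kind == kk])
    sum(vapply(names_k, function(g) {
      rs <- reg[nm == g]
      any(rs == "IRa") && any(rs == "IRb")
    }, TRUE))
  }
  # same-name features that are NOT an IRa/IRb pair get a warning
  for (g in unique(nm[duplicated(nm)])) {
    rs <- sort(reg[nm == g])
    ts <- any(vapply(feats[nm == g], function(f) f$trans_spliced, TRUE))
    if (!(any(rs == "IRa") && any(rs == "IRb")) && !ts)
      warning("gene '", g, "' has multiple features outside an IR pair (",
              paste(rs, collapse = ","), "); counted once, not IR-duplicated")
  }

  introns <- integer(0); intron_names <- character(0)
  for (g in unique(nm)) {
    fg <- feats[nm == g]
    ts <- any(vapply(fg, function(f) f$trans_spliced, TRUE))
    ic <- if (ts) sum(vapply(fg, function(f) length(f$exons) - 1L, 0L))
          else length(fg[[1L]]$exons) - 1L
    if (ic > 0L) { introns <- c(introns, ic); intron_names <- c(intron_names, g) }
  }
  names(introns) <- intron_names

  structure(list(
    n_genes_unique = sum(un),
    n_protein_coding = length(unique(nm[kind == "CDS"])),
    n_trna = length(unique(nm[kind == "tRNA"])),
    n_rrna = length(unique(nm[kind == "rRNA"])),
    n_other = length(unique(nm[kind == "other"])),
    n_ir_duplicated = sum(vapply(c("CDS", "tRNA", "rRNA", "other"),
                                 dup_class, 0L)),
    ir_duplicated_by_class = vapply(c(CDS = "CDS", tRNA = "tRNA",
                                      rRNA = "rRNA", other = "other"),
                                    dup_class, 0L),
    genes_with_introns = introns), class = "gene_inventory")
}

#' @export
print.gene_inventory <- function(x, ...) {
  cat(sprintf(
    "<gene inventory: %d unique (%d CDS, %d tRNA, %d rRNA, %d other), %d IR-duplicated, %d intron-containing>\n",
    x$n_genes_unique, x$n_protein_coding, x$n_trna, x$n_rrna, x$n_other,
    x$n_ir_duplicated, length(x$genes_with_introns)))
  invisible(x)
}
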