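#' Construct a plastome object
#'
#' The central data container: a circular (or linear) nucleotide sequence
#' plus an ordered list of gene features and, optionally, a quadripartite
#' partition (see [detect_ir()]).  All coordinates held by a plastome and its
#' features are 0-based half-open on the circular axis; GenBank I/O converts
#' to/from 1-based inclusive at the boundary.
#'
#' @param id accession-like identifier.
#' @param seq nucleotide string; uppercased on ingest, `U` mapped to `T`,
#'   IUPAC ambiguity codes other than `N` mapped to `N` with a warning.
#' @param features list of [gene_feature()] objects; re-sorted by smallest
#'   start coordinate.
#' @param circular logical; plastomes are circular molecules.
#' @param partition optional `quadripartite_partition`.
#' @return object of class `plastome`.
#' @examples
#' p <- plastome("toy", "ACGTACGTAA")
#' nchar(p$seq)
#' @export
plastome <- function(id, seq, features = list(), circular = TRUE,
                     partition = NULL) {
  seq <- normalize_seq(seq)
  n <- nchar(seq)
  if (n == 0L) stop("plastome sequence must be non-empty")
  stopifnot(is.list(features))
  for (f in features) {
    stopifnot(inherits(f, "gene_feature"))
    for (e in f$exons) {
      if (e$genome_length != n)
        stop("feature '", f$name, "' exon coordinates are on a circle of ",
             e$genome_length, " bp, but the sequence has ", n, " bp")
    }
  }
  if (length(features))
    features <- features[order(vapply(features, feature_start, 0L),
                               vapply(features, function(f) f$name, ""))]
  structure(
    list(id = as.character(id), seq = seq, circular = isTRUE(circular),
         features = features, partition = partition),
    class = "plastome"
  )
}

#' Gene feature on a plastome
#'
#' @param name gene symbol, e.g. `"rps19"` or `"trnH-GUG"`.
#' @param kind one of `"CDS"`, `"tRNA"`, `"rRNA"`, `"other"`.
#' @param exons list of `plastome_interval`s, ordered in transcription
#'   order; cis-spliced genes have `exons - 1` introns.
#' @param strand `"+"` or `"-"`.
#' @param trans_spliced logical; trans-spliced genes (rps12) are deposited
#'   as one feature per location block linked by shared name, and intron
#'   accounting treats the gene once.
#' @return object of class `gene_feature`.
#' @export
gene_feature <- function(name, kind = c("CDS", "tRNA", "rRNA", "other"),
                         exons, strand = c("+", "-"), trans_spliced = FALSE) {
  kind <- match.arg(kind)
  strand <- match.arg(strand)
  if (inherits(exons, "plastome_interval")) exons <- list(exons)
  stopifnot(length(exons) >= 1)
  for (e in exons) stopifnot(inherits(e, "plastome_interval"))
  structure(
    list(name = as.character(name), kind = kind, exons = exons,
         strand = strand, trans_spliced = isTRUE(trans_spliced)),
    class = "gene_feature"
  )
}

# Smallest start coordinate among a feature's exons (sort key).
feature_start <- function(f) min(vapply(f$exons, function(e) e$start, 0L))

# Total exonic length of a feature.
feature_length <- function(f) sum(vapply(f$exons, interval_length, 0L))

# Genomic span of a single-exon-equivalent footprint: the interval from the
# first exon's start to the last exon's end (used for junction overlap).
feature_span <- function(f) {
  first <- f$exons[[1L]]
  last <- f$exons[[length(f$exons)]]
  if (length(f$exons) == 1L) return(first)
  interval(first$start, last$end, first$genome_length)
}

#' @export
print.plastome <- function(x, ...) {
  cat(sprintf("<plastome %s: %s bp, %d features%s%s>\n", x$id,
              format(nchar(x$seq), big.mark = ","), length(x$features),
              if (x$circular) ", circular" else ", linear",
              if (!is.null(x$partition)) ", partitioned" else ""))
  invisible(x)
}

#' @export
print.gene_feature <- function(x, ...) {
  cat(sprintf("<gene %s (%s, %s) %d exon(s), %d bp>\n", x$name, x$kind,
              x$strand, length(x$exons), feature_length(x)))
  invisible(x)
}

# Uppercase, U->T, map ambiguity codes other than N to N (warn).
normalize_seq <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  s <- chartr("u", "t", toupper(seq))
  s <- chartr("U", "T", s)
  bad <- gsub("[ACGTN]", "", s)
  if (nchar(bad) > 0L) {
    warning(nchar(bad), " non-ACGTN character(s) (e.g. '",
            substr(bad, 1, 1), "') mapped to N")
    chars <- strsplit(s, "", fixed = TRUE)[[1L]]
    chars[!chars %in% c("A", "C", "G", "T", "N")] <- "N"
    s <- paste(chars, collapse = "")
  }
  s
}

#' Reverse complement
#'
#' @param seq nucleotide string over `{A,C,G,T,N}` (lowercase accepted).
#' @return the reverse complement, same case-normalized alphabet.
#' @examples
#' revcomp("AAAC")  # "GTTT"
#' @export
revcomp <- function(seq) {
  s <- chartr("ACGTUacgtu", "TGCAATGCAA", seq)
  vapply(strsplit(s, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), "")
}

# Complement without reversal (dispersed-repeat "complement" category).
complement <- function(seq) chartr("ACGTUacgtu", "TGCAATGCAA", seq)

#' Extract a (possibly origin-wrapping) slice of a circular genome
#'
#' @param x a [plastome()] or a plain sequence string.
#' @param iv a [interval()] on the same circle.
#' @return contiguous sequence string of length `interval_length(iv)`.
#' @examples
#' circular_slice(plastome("t", "ABCDEF"), interval(4, 2, 6))
#' @export
circular_slice <- function(x, iv) {
  seq <- if (inherits(x, "plastome")) x$seq else x
  stopifnot(inherits(iv, "plastome_interval"),
            nchar(seq) == iv$genome_length)
  n <- iv$genome_length
  if (!iv$wrap) return(substr(seq, iv$start + 1L, iv$end))
  paste0(substr(seq, iv$start + 1L, n), substr(seq, 1L, iv$end))
}

# Extract a feature's spliced (exon-concatenated) sequence in coding
# orientation: exons concatenated in stored order, reverse-complemented
# for minus-strand genes.
feature_seq <- function(p, f) {
  parts <- vapply(f$exons, function(e) circular_slice(p, e), "")
  s <- paste(parts, collapse = "")
  if (f$strand == "-") revcomp(s) else s
}
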