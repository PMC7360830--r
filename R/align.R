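#' Multiple alignment of a homologous region
#'
#' Progressive global alignment: sequences are merged greedily in an order
#' determined by pairwise k-mer similarity (most similar first), aligning
#' count-based profiles with affine gap penalties (Gotoh).  Deterministic
#' for fixed inputs; ties in guide order are broken by input order.  This
#' stands in for an external aligner; a pre-computed aligned FASTA can be
#' supplied instead through [import_alignment()].
#'
#' @param seqs named character vector (>= 2 sequences) or a
#'   `shared_regions` element.
#' @param name region identifier.
#' @param rtype "coding" or "noncoding".
#' @param match,mismatch,gap_open,gap_extend alignment scores.
#' @return object of class `region_alignment`: fields `name`, `rtype`,
#'   `taxa`, `rows` (equal-length gapped sequences).
#' @export
align_region <- function(seqs, name = "region", rtype = "noncoding",
                         match = 1, mismatch = -1, gap_open = -4,
                         gap_extend = -1) {
  if (is.list(seqs) && !is.null(seqs$seqs)) {
    name <- seqs$name; rtype <- seqs$rtype; seqs <- seqs$seqs
  }
  stopifnot(length(seqs) >= 2L, !is.null(names(seqs)))
  if (any(nchar(seqs) == 0L))
    stop("empty sequence among inputs for region '", name, "'")
  seqs <- vapply(seqs, normalize_seq, "")

  k <- length(seqs)
  sim <- kmer_similarity_matrix(seqs)
  # guide order: start from the closest pair, then repeatedly add the
  # sequence with the highest mean similarity to the aligned set
  pair <- which(sim == max(sim[upper.tri(sim)]), arr.ind = TRUE)
  pair <- pair[order(pair[, 1L], pair[, 2L]), , drop = FALSE]
  pair <- pair[pair[, 1L] < pair[, 2L], , drop = FALSE][1L, ]
  in_set <- c(pair[[1L]], pair[[2L]])
  while (length(in_set) < k) {
    rest <- setdiff(seq_len(k), in_set)
    mean_sim <- vapply(rest, function(i) mean(sim[i, in_set]), 0)
    in_set <- c(in_set, rest[which.max(mean_sim)])
  }

  # aligned rows kept as a character matrix during the merges
  mat <- matrix(strsplit(seqs[[in_set[1L]]], "", fixed = TRUE)[[1L]],
                nrow = 1L)
  rownames(mat) <- names(seqs)[in_set[1L]]
  for (i in in_set[-1L]) {
    new <- matrix(strsplit(seqs[[i]], "", fixed = TRUE)[[1L]], nrow = 1L)
    rownames(new) <- names(seqs)[i]
    res <- profile_align_cpp(profile_counts_mat(mat),
                             profile_counts_mat(new),
                             match, mismatch, gap_open, gap_extend)
    mat <- rbind(apply_trace_mat(mat, res$a), apply_trace_mat(new, res$b))
  }
  mat <- mat[names(seqs), , drop = FALSE]   # restore input taxon order
  rows <- apply(mat, 1L, paste, collapse = "")
  region_alignment(name, rtype, rows)
}

#' @rdname align_region
#' @param rows named character vector of equal-length gapped sequences.
#' @export
region_alignment <- function(name, rtype, rows) {
  stopifnot(length(rows) >= 2L, !is.null(names(rows)))
  L <- unique(nchar(rows))
  if (length(L) != 1L)
    stop("alignment rows have unequal lengths: ",
         paste(unique(nchar(rows)), collapse = ","))
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  allgap <- colSums(mat == "-") == nrow(mat)
  if (any(allgap)) {
    mat <- mat[, !allgap, drop = FALSE]
    rows <- apply(mat, 1L, paste, collapse = "")
  }
  structure(list(name = name, rtype = rtype, taxa = names(rows),
                 rows = rows),
            class = "region_alignment")
}

#' @export
print.region_alignment <- function(x, ...) {
  cat(sprintf("<alignment '%s' (%s): %d taxa x %d columns>\n",
              x$name, x$rtype, length(x$rows), nchar(x$rows[[1L]])))
  invisible(x)
}

#' @rdname align_region
#' @param path aligned FASTA file accepted verbatim (row lengths must
#'   match).
#' @export
import_alignment <- function(path, name = sub("\\.[^.]*$", "", basename(path)),
                             rtype = "noncoding") {
  set <- Biostrings::readBStringSet(path)
  rows <- toupper(as.character(set))
  rows <- chartr("U", "T", rows)
  names(rows) <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1L)
  region_alignment(name, rtype, rows)
}

# 5 x L count profile (rows A,C,G,T,gap) of an aligned character matrix.
# N contributes to no row (treated as missing).
profile_counts_mat <- function(mat) {
  out <- matrix(0, nrow = 5L, ncol = ncol(mat))
  lets <- c("A", "C", "G", "T", "-")
  for (b in seq_along(lets)) out[b, ] <- colSums(mat == lets[b])
  out
}

# Insert gap columns into an aligned character matrix according to a
# traceback index vector (0 = gap column).
apply_trace_mat <- function(mat, idx) {
  out <- matrix("-", nrow = nrow(mat), ncol = length(idx),
                dimnames = list(rownames(mat), NULL))
  out[, idx > 0L] <- mat[, idx[idx > 0L], drop = FALSE]
  out
}

# Shared-kmer similarity (Jaccard on 5-mer sets; sequences shorter than 5
# fall back to 2-mers).
kmer_similarity_matrix <- function(seqs) {
  k <- if (min(nchar(seqs)) >= 5L) 5L else 2L
  sets <- lapply(seqs, function(s) {
    if (nchar(s) < k) return(s)
    unique(substring(s, seq_len(nchar(s) - k + 1L),
                     seq_len(nchar(s) - k + 1L) + k - 1L))
  })
  n <- length(seqs)
  sim <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    sim[i, j] <- sim[j, i] <-
      length(intersect(sets[[i]], sets[[j]])) /
      max(1L, length(union(sets[[i]], sets[[j]])))
  }
  diag(sim) <- 1
  sim
}
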