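#' Percentage of variable sites in a region alignment
#'
#' The hotspot statistic:
#' `percent = 100 * (S + I) / (L_aln - L_indel + I)`
#' where `S` is the number of substitution columns, `I` the number of indel
#' events, `L_aln` the aligned length and `L_indel` the number of gap
#' columns.  Conventions (documented because the formula is stated for a
#' generic alignment):
#' * a gap column is any column in which at least one row has `-`;
#' * one indel event per maximal run of gap columns, however many rows gap;
#' * a substitution column is a non-gap column with two or more distinct
#'   bases among non-`N` residues (site-based, not pairwise; `N` missing);
#' * a column with both gaps and substitutions counts only as gap.
#'
#' @param aln a `region_alignment`.
#' @return list of class `variability_result`: name, rtype, S, I, L_aln,
#'   L_indel, percent, degenerate flag (TRUE when the denominator is 0 and
#'   percent is defined as 0).
#' @export
variability_percent <- function(aln) {
  stopifnot(inherits(aln, "region_alignment"))
  mat <- do.call(rbind, strsplit(aln$rows, "", fixed = TRUE))
  L <- ncol(mat)
  gap_col <- colSums(mat == "-") > 0L
  L_indel <- sum(gap_col)
  I <- if (L_indel) sum(rle(gap_col)$values) else 0L
  S <- sum(vapply(which(!gap_col), function(j) {
    b <- mat[, j]
    length(unique(b[b != "N"])) >= 2L
  }, TRUE))
  denom <- L - L_indel + I
  degenerate <- denom <= 0
  percent <- if (degenerate) 0 else 100 * (S + I) / denom
  structure(list(name = aln$name, rtype = aln$rtype, S = S, I = I,
                 L_aln = L, L_indel = L_indel, percent = percent,
                 degenerate = degenerate),
            class = "variability_result")
}

#' @export
print.variability_result <- function(x, ...) {
  cat(sprintf("<variability '%s': S=%d I=%d L=%d L_indel=%d -> %.4f%%%s>\n",
              x$name, x$S, x$I, x$L_aln, x$L_indel, x$percent,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Collect variability results into a table
#'
#' @param results list of `variability_result` (or `region_alignment`,
#'   which are computed on the fly).
#' @return data.frame: name, rtype, S, I, L_aln, L_indel, percent.
#' @export
variability_table <- function(results) {
  results <- lapply(results, function(r) {
    if (inherits(r, "region_alignment")) variability_percent(r) else r
  })
  do.call(rbind, lapply(results, function(r)
    data.frame(name = r$name, rtype = r$rtype, S = r$S, I = r$I,
               L_aln = r$L_aln, L_indel = r$L_indel, percent = r$percent,
               stringsAsFactors = FALSE)))
}

#' Rank mutational hotspots
#'
#' Orders regions by decreasing variability percentage (ties broken by
#' larger aligned length, then by name) and returns the top `k`, each
#' flagged when its percent exceeds `threshold`.  The default thresholds in
#' published use are 0.5 (within-genus comparisons) and 6.0 (across-genera
#' comparisons).
#'
#' @param results list of `variability_result`s or a [variability_table()]
#'   data.frame.
#' @param k number of hotspots to return.
#' @param threshold percent flag threshold.
#' @return data.frame with rank column and `above_threshold` flag.
#' @export
rank_hotspots <- function(results, k = 7L, threshold = 0.5) {
  tab <- if (is.data.frame(results)) results else variability_table(results)
  stopifnot(nrow(tab) >= 1L)
  ord <- order(-tab$percent, -tab$L_aln, tab$name)
  tab <- tab[ord, , drop = FALSE]
  tab <- tab[seq_len(min(k, nrow(tab))), , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  tab$above_threshold <- tab$percent > threshold
  rownames(tab) <- NULL
  tab
}

#' Combine genus- and family-level hotspot sets
#'
#' @param genus_topk,family_topk character vectors of region names (or
#'   data.frames from [rank_hotspots()], whose `name` column is used).
#' @return list with `intersection`, `union`, `n_intersection`, `n_union`.
#' @export
combine_hotspot_sets <- function(genus_topk, family_topk) {
  nm <- function(x) if (is.data.frame(x)) x$name else as.character(x)
  g <- unique(nm(genus_topk)); f <- unique(nm(family_topk))
  inter <- intersect(g, f); un <- union(g, f)
  list(intersection = sort(inter), union = sort(un),
       n_intersection = length(inter), n_union = length(un))
}
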