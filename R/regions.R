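#' Extract homologous coding and intergenic regions shared by all genomes
#'
#' Coding regions are the exon-concatenated sequences of each gene name
#' shared by every genome, strand-normalized to coding orientation.
#' Noncoding regions are the intergenic spacers between consecutive
#' features in genome order (circularly, so the last-to-first spacer is
#' included), named `"geneA-geneB"` by their ordered flanking pair; a
#' spacer is returned only when the same ordered flanking pair exists in
#' every genome with positive length.  For IR-duplicated genes one coding
#' region is extracted from the IRb copy and flagged; for genes deposited
#' as several same-name blocks (trans-spliced rps12 convention) the
#' lowest-coordinate block is used.
#'
#' @param plastomes list of two or more annotated [plastome()]s (partition
#'   needed only for the IRb-copy preference; without it the first copy by
#'   coordinate is used).
#' @return list of class `shared_regions`; each element has `name`, `rtype`
#'   ("coding"/"noncoding"), `duplicated_in_ir` flag and `seqs` (named
#'   character vector, one sequence per genome).  Dropped regions are
#'   reported via messages.
#' @export
extract_shared_regions <- function(plastomes) {
  if (length(plastomes) < 2L)
    stop("need at least 2 annotated genomes, got ", length(plastomes))
  for (p in plastomes) stopifnot(inherits(p, "plastome"))
  ids <- vapply(plastomes, function(p) p$id, "")
  if (anyDuplicated(ids)) stop("duplicate plastome ids")

  per_genome <- lapply(plastomes, genome_region_table)
  shared_names <- Reduce(intersect, lapply(per_genome, function(t) t$name))
  dropped <- setdiff(unique(unlist(lapply(per_genome, function(t) t$name))),
                     shared_names)
  if (length(dropped))
    message("dropping ", length(dropped),
            " region(s) absent from some genome: ",
            paste(utils::head(dropped, 8L), collapse = ", "),
            if (length(dropped) > 8L) ", ..." else "")

  out <- list()
  for (nmr in shared_names) {
    rows <- lapply(per_genome, function(t) t[t$name == nmr, , drop = FALSE])
    seqs <- vapply(seq_along(plastomes), function(i) rows[[i]]$seq[1L], "")
    if (any(nchar(seqs) == 0L)) {
      message("dropping region '", nmr, "': zero length in some genome")
      next
    }
    names(seqs) <- ids
    out[[nmr]] <- list(name = nmr, rtype = rows[[1L]]$rtype[1L],
                       duplicated_in_ir = rows[[1L]]$dup[1L], seqs = seqs)
  }
  structure(out, class = "shared_regions")
}

# Per-genome table of region name -> sequence (coding + spacers).
genome_region_table <- function(p) {
  feats <- p$features
  if (!length(feats)) return(data.frame(name = character(),
                                        rtype = character(),
                                        dup = logical(), seq = character(),
                                        stringsAsFactors = FALSE))
  n <- nchar(p$seq)
  nm <- vapply(feats, function(f) f$name, "")
  rows <- list()

  # coding regions: one per unique gene name
  for (g in unique(nm)) {
    fg <- feats[nm == g]
    dup <- FALSE
    pick <- fg[[1L]]
    if (length(fg) > 1L) {
      regs <- if (!is.null(p$partition))
        vapply(fg, function(f) region_of(p$partition, feature_span(f)), "")
      else rep("", length(fg))
      if (any(regs == "IRb")) { pick <- fg[[which(regs == "IRb")[1L]]]; dup <- TRUE }
      else if (any(regs == "IRa")) { pick <- fg[[which(regs == "IRa")[1L]]]; dup <- TRUE }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      name = g, rtype = "coding", dup = dup, seq = feature_seq(p, pick),
      stringsAsFactors = FALSE)
  }

  # intergenic spacers between consecutive feature spans (circular)
  ord <- order(vapply(feats, feature_start, 0L))
  feats_o <- feats[ord]
  k <- length(feats_o)
  for (i in seq_len(k)) {
    f1 <- feats_o[[i]]
    f2 <- feats_o[[if (i == k) 1L else i + 1L]]
    sp1 <- feature_span(f1); sp2 <- feature_span(f2)
    gap_len <- (sp2$start - sp1$end) %% n
    spacer_name <- paste0(f1$name, "-", f2$name)
    if (gap_len == 0L || gap_len >= n - feature_length(f2)) next
    if (interval_contains(sp2, sp1$end)) next   # overlapping features
    rows[[length(rows) + 1L]] <- data.frame(
      name = spacer_name, rtype = "noncoding", dup = FALSE,
      seq = circular_slice(p, interval(sp1$end, sp2$start, n)),
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  tab[!duplicated(tab$name), , drop = FALSE]
}
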