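# Standard bacterial/plastid genetic code (translation table 11): same
# codon assignments as the universal code; stops TAA, TAG, TGA.
GENETIC_CODE_11 <- c(
  TTT="F",TTC="F",TTA="L",TTG="L",CTT="L",CTC="L",CTA="L",CTG="L",
  ATT="I",ATC="I",ATA="I",ATG="M",GTT="V",GTC="V",GTA="V",GTG="V",
  TCT="S",TCC="S",TCA="S",TCG="S",CCT="P",CCC="P",CCA="P",CCG="P",
  ACT="T",ACC="T",ACA="T",ACG="T",GCT="A",GCC="A",GCA="A",GCG="A",
  TAT="Y",TAC="Y",TAA="*",TAG="*",CAT="H",CAC="H",CAA="Q",CAG="Q",
  AAT="N",AAC="N",AAA="K",AAG="K",GAT="D",GAC="D",GAA="E",GAG="E",
  TGT="C",TGC="C",TGA="*",TGG="W",CGT="R",CGC="R",CGA="R",CGG="R",
  AGT="S",AGC="S",AGA="R",AGG="R",GGT="G",GGC="G",GGA="G",GGG="G")

STOP_CODONS <- c("TAA", "TAG", "TGA")

translate_codon <- function(codon) {
  aa <- GENETIC_CODE_11[codon]
  ifelse(is.na(aa), "X", aa)
}

#' Split a CDS into codons
#'
#' A terminal stop codon is trimmed; an internal stop or a length not
#' divisible by 3 is an error.
#'
#' @param cds_seq in-frame coding sequence.
#' @return character vector of codons.
#' @examples
#' codon_partition("ATGAAATAA")  # "ATG" "AAA"
#' @export
codon_partition <- function(cds_seq) {
  s <- normalize_seq(cds_seq)
  n <- nchar(s)
  if (n %% 3L != 0L)
    stop("CDS length ", n, " is not divisible by 3")
  codons <- substring(s, seq(1L, n, 3L), seq(3L, n, 3L))
  if (length(codons) && codons[length(codons)] %in% STOP_CODONS)
    codons <- codons[-length(codons)]
  internal <- which(codons %in% STOP_CODONS)
  if (length(internal))
    stop("internal stop codon at codon position ", internal[1L])
  codons
}

#' Nei-Gojobori (1986) synonymous/nonsynonymous site counts of one codon
#'
#' For each codon position, the fraction of the single-nucleotide changes
#' that are synonymous contributes to the synonymous site count; changes to
#' stop codons are excluded from the denominator.
#'
#' @param codon 3-letter codon over `{A,C,G,T}`, not a stop.
#' @return c(n_sites, s_sites); sums to at most 3 (less when stop-bound
#'   changes are excluded).
#' @export
ng86_site_counts <- function(codon) {
  stopifnot(nchar(codon) == 3L, !codon %in% STOP_CODONS)
  if (grepl("[^ACGT]", codon)) stop("codon must be over {A,C,G,T}: ", codon)
  aa0 <- translate_codon(codon)
  bases <- c("A", "C", "G", "T")
  s_sites <- 0; n_sites <- 0
  for (pos in 1:3) {
    alts <- setdiff(bases, substr(codon, pos, pos))
    muts <- vapply(alts, function(b) {
      x <- codon; substr(x, pos, pos) <- b; x
    }, "")
    ok <- !muts %in% STOP_CODONS
    if (!any(ok)) next
    syn <- translate_codon(muts[ok]) == aa0
    s_sites <- s_sites + sum(syn) / sum(ok)
    n_sites <- n_sites + sum(!syn) / sum(ok)
  }
  c(n_sites = n_sites, s_sites = s_sites)
}

# Pathway-averaged synonymous/nonsynonymous difference counts between two
# codons: all orderings of the differing positions are enumerated, paths
# passing through a stop codon are excluded, and the per-step syn/nonsyn
# classifications are averaged over the surviving paths.
ng86_diff_counts <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1L]] != strsplit(c2, "")[[1L]])
  nd <- length(pos)
  if (nd == 0L) return(c(nd = 0, sd = 0))
  perms <- permutations(pos)
  tot_s <- 0; tot_n <- 0; n_paths <- 0L
  for (pi in seq_len(nrow(perms))) {
    cur <- c1
    s_acc <- 0L; n_acc <- 0L; valid <- TRUE
    for (p in perms[pi, ]) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (nxt %in% STOP_CODONS) { valid <- FALSE; break }
      if (translate_codon(nxt) == translate_codon(cur)) s_acc <- s_acc + 1L
      else n_acc <- n_acc + 1L
      cur <- nxt
    }
    if (valid) {
      tot_s <- tot_s + s_acc; tot_n <- tot_n + n_acc
      n_paths <- n_paths + 1L
    }
  }
  if (n_paths == 0L) {
    # all paths pass through stops: fall back to equal weighting of the
    # raw differences as nonsynonymous (cannot classify)
    return(c(nd = nd, sd = 0))
  }
  c(nd = tot_n / n_paths, sd = tot_s / n_paths)
}

permutations <- function(v) {
  if (length(v) == 1L) return(matrix(v, 1L))
  out <- NULL
  for (i in seq_along(v))
    out <- rbind(out, cbind(v[i], permutations(v[-i])))
  out
}

#' Pairwise NG86 dN/dS
#'
#' Codon-wise comparison of two aligned CDSs with Nei-Gojobori counting
#' and Jukes-Cantor correction `d = -(3/4) ln(1 - (4/3) p)`.  Codons
#' containing gaps or `N` in either sequence are skipped.  A proportion at
#' or beyond 3/4 is flagged saturated with the corresponding rate
#' undefined.
#'
#' @param cds1,cds2 equal-length in-frame sequences (gaps `-` allowed).
#' @param gene label carried into the result.
#' @return list of class `dnds_result`: gene, n_codons, n_sites, s_sites,
#'   nd, sd, pN, pS, dN, dS, omega (NA when dS is 0 or undefined),
#'   saturated.
#' @export
ng86_pairwise <- function(cds1, cds2, gene = "gene") {
  s1 <- chartr("u", "t", toupper(cds1)); s2 <- chartr("u", "t", toupper(cds2))
  if (nchar(s1) != nchar(s2))
    stop("sequences must be aligned to equal length")
  if (nchar(s1) %% 3L != 0L)
    stop("aligned length ", nchar(s1), " is not divisible by 3")
  starts <- seq(1L, nchar(s1), 3L)
  cod1 <- substring(s1, starts, starts + 2L)
  cod2 <- substring(s2, starts, starts + 2L)
  usable <- !grepl("[^ACGT]", cod1) & !grepl("[^ACGT]", cod2) &
    !cod1 %in% STOP_CODONS & !cod2 %in% STOP_CODONS
  cod1 <- cod1[usable]; cod2 <- cod2[usable]
  if (!length(cod1))
    stop("zero comparable codons between sequences for '", gene, "'")

  sites1 <- vapply(cod1, ng86_site_counts, c(n_sites = 0, s_sites = 0))
  sites2 <- vapply(cod2, ng86_site_counts, c(n_sites = 0, s_sites = 0))
  n_sites <- (sum(sites1[1, ]) + sum(sites2[1, ])) / 2
  s_sites <- (sum(sites1[2, ]) + sum(sites2[2, ])) / 2
  diffs <- mapply(function(a, b) ng86_diff_counts(a, b), cod1, cod2)
  nd <- sum(diffs[1, ]); sd <- sum(diffs[2, ])

  pN <- if (n_sites > 0) nd / n_sites else 0
  pS <- if (s_sites > 0) sd / s_sites else 0
  jc <- function(p) if (p >= 3 / 4) NA_real_ else -3 / 4 * log(1 - 4 * p / 3)
  dN <- jc(pN); dS <- jc(pS)
  saturated <- is.na(dN) || is.na(dS)
  omega <- if (!saturated && !is.na(dS) && dS > 0) dN / dS else NA_real_
  structure(list(gene = gene, n_codons = length(cod1), n_sites = n_sites,
                 s_sites = s_sites, nd = nd, sd = sd, pN = pN, pS = pS,
                 dN = dN, dS = dS, omega = omega, saturated = saturated),
            class = "dnds_result")
}

#' @export
print.dnds_result <- function(x, ...) {
  cat(sprintf("<dN/dS '%s': dN=%.4f dS=%.4f omega=%s%s>\n", x$gene,
              ifelse(is.na(x$dN), NaN, x$dN), ifelse(is.na(x$dS), NaN, x$dS),
              ifelse(is.na(x$omega), "undefined", sprintf("%.3f", x$omega)),
              if (x$saturated) " (saturated)" else ""))
  invisible(x)
}

#' Screen shared protein-coding genes for elevated omega
#'
#' For each gene alignment, averages NG86 dN and dS over all taxon pairs
#' and flags genes whose mean omega exceeds 1 as candidate positive
#' selection.  This desk-scale screen does not attempt to reproduce
#' codon-site-model (Codeml) results.  Genes whose sequences fail codon
#' checks (internal stops after alignment, zero comparable codons) are
#' skipped with a warning.
#'
#' @param gene_alignments named list of `region_alignment`s (coding).
#' @return data.frame sorted by omega descending: gene, n_taxa, mean dN,
#'   dS, omega, positive flag, n_saturated_pairs.
#' @export
selection_screen <- function(gene_alignments) {
  rows <- list()
  for (g in names(gene_alignments)) {
    aln <- gene_alignments[[g]]
    taxa <- aln$taxa
    if (length(taxa) < 2L) next
    dns <- c(); dss <- c(); sat <- 0L
    ok <- TRUE
    for (i in seq_len(length(taxa) - 1L)) for (j in (i + 1L):length(taxa)) {
      r <- tryCatch(ng86_pairwise(aln$rows[[i]], aln$rows[[j]], gene = g),
                    error = function(e) e)
      if (inherits(r, "error")) {
        warning("skipping gene '", g, "': ", conditionMessage(r))
        ok <- FALSE; break
      }
      if (r$saturated) { sat <- sat + 1L; next }
      dns <- c(dns, r$dN); dss <- c(dss, r$dS)
    }
    if (!ok || !length(dns)) next
    mdN <- mean(dns); mdS <- mean(dss)
    omega <- if (mdS > 0) mdN / mdS else NA_real_
    rows[[length(rows) + 1L]] <- data.frame(
      gene = g, n_taxa = length(taxa), dN = mdN, dS = mdS, omega = omega,
      positive = !is.na(omega) && omega > 1, n_saturated_pairs = sat,
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(gene = character(), n_taxa = integer(), dN = numeric(),
                      dS = numeric(), omega = numeric(), positive = logical(),
                      n_saturated_pairs = integer(), stringsAsFactors = FALSE))
  res <- do.call(rbind, rows)
  res <- res[order(-ifelse(is.na(res$omega), -Inf, res$omega), res$gene), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}
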