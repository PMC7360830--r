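#' Simulation configuration for synthetic plastomes
#'
#' The generator builds a circular quadripartite genome (LSC + IRb + SSC +
#' IRa = revcomp(IRb)) with annotated genes (including IR-duplicated,
#' intron-containing and junction-straddling genes), planted SSR /
#' dispersed / palindromic / tandem repeats at recorded coordinates, and
#' evolves it along a phylogeny with region-specific substitution and
#' indel rates.  Every region (gene or intergenic spacer) receives its own
#' rate multiplier: a deterministic log-spaced gradient from
#' `gradient_range[1]` to `gradient_range[2]` in genome order, with the
#' designated hotspot spacers overridden to `hotspot_multiplier`.  The
#' gradient makes the planted rate order recoverable as a rank order of
#' variability, which is how the generator is validated.
#'
#' Branch lengths are expected substitutions per site at multiplier 1.
#' Indel events are Poisson with rate `indel_rate` per site per unit
#' branch length (scaled by the region multiplier); lengths are geometric
#' (`indel_geom_p`) capped at `indel_max`; indels are restricted to
#' single-copy intergenic spacers and never touch gene boundaries, so
#' homologous region extraction stays well defined.  Mutations are sampled
#' on LSC/IRb/SSC and the IRb changes are mirrored into IRa, preserving
#' the empirical identity of the IR copies.
#'
#' @param preset "test" (20 kb genome, 3 kb IR; fast) or "full" (156 kb,
#'   25.65 kb IR).
#' @param genome_length,ir_length,ssc_length sizes in bp (defaults from
#'   the preset).
#' @param gc background GC fraction (default 0.363, the plastome regime).
#' @param hotspots spacer names planted at `hotspot_multiplier`.
#' @param hotspot_multiplier rate multiplier of hotspot spacers.
#' @param gradient_range range of the per-region multiplier gradient.
#' @param indel_rate indel events per site per unit branch length.
#' @param indel_geom_p,indel_max indel length distribution parameters.
#' @param tree newick string with branch lengths; leaves are individuals.
#' @param species_map named character vector individual -> species.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(preset = c("test", "full"),
                       genome_length = NULL, ir_length = NULL,
                       ssc_length = NULL, gc = 0.363,
                       hotspots = c("rpoB-trnC-GCA", "trnT-GGU-psbD",
                                    "psbK-psbI"),
                       hotspot_multiplier = 10,
                       gradient_range = c(0.7, 3),
                       indel_rate = 0.05, indel_geom_p = 0.5,
                       indel_max = 10L,
                       tree = default_tree_newick(),
                       species_map = default_species_map()) {
  preset <- match.arg(preset)
  if (is.null(genome_length))
    genome_length <- if (preset == "test") 20000L else 156000L
  if (is.null(ir_length))
    ir_length <- if (preset == "test") 3000L else 25650L
  if (is.null(ssc_length))
    ssc_length <- if (preset == "test") 2500L else 18000L
  lsc_length <- genome_length - 2L * ir_length - ssc_length
  if (lsc_length <= ssc_length)
    stop("infeasible sizes: LSC (", lsc_length, ") must exceed SSC (",
         ssc_length, ")")
  structure(list(
    preset = preset, genome_length = as.integer(genome_length),
    ir_length = as.integer(ir_length), ssc_length = as.integer(ssc_length),
    lsc_length = as.integer(lsc_length), gc = gc,
    layout = default_gene_layout(), hotspots = hotspots,
    hotspot_multiplier = hotspot_multiplier,
    gradient_range = gradient_range, indel_rate = indel_rate,
    indel_geom_p = indel_geom_p, indel_max = as.integer(indel_max),
    tree = tree, species_map = species_map), class = "sim_config")
}

# Gene layout: name, kind, region, exon lengths (genomic order), intron
# lengths, strand.  Scaled for the 20 kb test preset; the same inventory
# is used (sparser) on the full preset.  rps19 is handled specially: it
# straddles the LSC/IRb junction.
default_gene_layout <- function() {
  g <- function(name, kind, region, exons, strand, introns = NULL) {
    if (is.null(introns) && length(exons) > 1L)
      introns <- rep(60L, length(exons) - 1L)
    list(name = name, kind = kind, region = region,
         exons = as.integer(exons),
         introns = as.integer(introns %||% integer()), strand = strand)
  }
  list(
    g("psbA", "CDS", "LSC", 300, "-"),
    g("trnH-GUG", "tRNA", "LSC", 75, "-"),
    g("matK", "CDS", "LSC", 300, "+"),
    g("rps16", "CDS", "LSC", c(120, 120), "-"),
    g("psbK", "CDS", "LSC", 90, "+"),
    g("psbI", "CDS", "LSC", 75, "+"),
    g("atpA", "CDS", "LSC", 300, "-"),
    g("rpoB", "CDS", "LSC", 390, "-"),
    g("trnC-GCA", "tRNA", "LSC", 72, "+"),
    g("trnT-GGU", "tRNA", "LSC", 72, "+"),
    g("psbD", "CDS", "LSC", 300, "+"),
    g("ycf3", "CDS", "LSC", c(90, 90, 90), "-"),
    g("rbcL", "CDS", "LSC", 300, "+"),
    g("petB", "CDS", "LSC", c(90, 150), "+"),
    g("clpP", "CDS", "LSC", c(69, 90, 90), "-"),
    g("rpl2", "CDS", "IRb", c(120, 120), "-"),
    g("trnI-GAU", "tRNA", "IRb", 72, "+"),
    g("rrn16", "rRNA", "IRb", 600, "+"),
    g("ndhF", "CDS", "SSC", 390, "-"),
    g("ccsA", "CDS", "SSC", 240, "+"),
    g("ndhA", "CDS", "SSC", c(120, 120), "-"),
    g("ycf1", "CDS", "SSC", 450, "+"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname sim_config
#' @export
default_tree_newick <- function() {
  paste0(
    "((MBD01:0.002,MGD09:0.002,SDS11:0.002,XSJD10:0.002):0.018,",
    "(PYD03:0.002,Q09:0.002):0.018,((De07:0.002,De19:0.002):0.012,",
    "((GMD13:0.002,LAD10:0.002,MK05:0.002,ZXD12:0.002):0.008,",
    "Q05:0.01):0.004):0.008);")
}

#' @rdname sim_config
#' @export
default_species_map <- function() {
  c(De07 = "D_elliptica", De19 = "D_elliptica",
    GMD13 = "D_orientalis", LAD10 = "D_orientalis",
    MK05 = "D_orientalis", ZXD12 = "D_orientalis",
    MBD01 = "D_longifolia", MGD09 = "D_longifolia",
    SDS11 = "D_longifolia", XSJD10 = "D_longifolia",
    PYD03 = "D_saeneb", Q09 = "D_saeneb", Q05 = "D_squamata")
}

bg_probs <- function(gc) {
  c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
}

random_bases <- function(n, gc) {
  pr <- bg_probs(gc)
  sample(names(pr), n, replace = TRUE, prob = pr)
}

# Random ORF of `len` bases (multiple of 3): ATG, non-stop interior codons
# drawn from the background base composition, terminal TAA.
random_orf <- function(len, gc) {
  stopifnot(len %% 3L == 0L, len >= 9L)
  ncod <- len %/% 3L - 2L
  cod <- character(ncod)
  i <- 1L
  while (i <= ncod) {
    c3 <- paste(random_bases(3L, gc), collapse = "")
    if (!c3 %in% STOP_CODONS) { cod[i] <- c3; i <- i + 1L }
  }
  paste0("ATG", paste(cod, collapse = ""), "TAA")
}

#' Build the synthetic ancestor plastome
#'
#' @param config a [sim_config()].
#' @param seed integer seed (full determinism under (config, seed)).
#' @return list with `plastome` (a [plastome()], partition attached),
#'   `state` (internal evolution state) and `truth` (planted coordinates,
#'   per-region multipliers, tree, species map).
#' @export
build_ancestor <- function(config, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(as.integer(seed))
  L <- config$genome_length
  b1 <- config$lsc_length                  # LSC/IRb junction
  b2 <- b1 + config$ir_length              # IRb/SSC
  b3 <- b2 + config$ssc_length             # SSC/IRa
  s <- random_bases(L, config$gc)

  feats <- list()
  place_region <- function(genes, region_start, region_len, head_margin) {
    footprint <- sum(vapply(genes, function(g)
      sum(g$exons) + sum(g$introns), 0L))
    free <- region_len - footprint - head_margin
    ngap <- length(genes) + 1L
    if (free < ngap) stop("infeasible packing: planted genes exceed region")
    gap <- free %/% ngap
    cursor <- region_start + head_margin + gap
    for (g in genes) {
      total <- sum(g$exons)
      content <- if (g$kind == "CDS") random_orf(total, config$gc) else
        paste(random_bases(total, config$gc), collapse = "")
      genomic <- if (g$strand == "-") revcomp(content) else content
      exmat <- matrix(0L, nrow = length(g$exons), ncol = 2L)
      off <- 0L
      for (e in seq_along(g$exons)) {
        a <- cursor; b <- cursor + g$exons[e]
        s[(a + 1L):b] <<- strsplit(substr(genomic, off + 1L,
                                          off + g$exons[e]), "")[[1L]]
        exmat[e, ] <- c(a, b)
        off <- off + g$exons[e]
        cursor <- b + if (e < length(g$exons)) g$introns[e] else 0L
      }
      feats[[length(feats) + 1L]] <<- list(
        name = g$name, kind = g$kind, strand = g$strand, exons = exmat,
        trans = FALSE)
      cursor <- cursor + gap
    }
  }
  lay <- config$layout
  regions <- vapply(lay, function(g) g$region, "")
  place_region(lay[regions == "LSC"], 0L, b1 - 160L, 0L)
  place_region(lay[regions == "IRb"], b1, config$ir_length - 160L, 160L)
  place_region(lay[regions == "SSC"], b2, config$ssc_length, 0L)

  # rps19 straddles the LSC/IRb junction: 120 bp in LSC, 120 bp in IRb
  orf <- random_orf(240L, config$gc)
  s[(b1 - 120L + 1L):(b1 + 120L)] <- strsplit(orf, "")[[1L]]
  feats[[length(feats) + 1L]] <- list(
    name = "rps19", kind = "CDS", strand = "+",
    exons = matrix(c(b1 - 120L, b1 + 120L), 1L), trans = FALSE)

  # plant repeats in LSC spacers (recorded truth), then mirror the IR
  planted <- plant_repeats(environment())
  s <- planted$s; truth_records <- planted$records

  # IRa = revcomp(IRb); mirror IRb gene annotations into IRa
  s[(b3 + 1L):L] <- rev(chartr("ACGTN", "TGCAN", s[(b1 + 1L):b2]))
  for (f in feats[vapply(feats, function(f)
    all(f$exons[, 1L] >= b1 & f$exons[, 2L] <= b2), TRUE)]) {
    ex <- f$exons
    mex <- cbind(b3 + (b2 - ex[, 2L]), b3 + (b2 - ex[, 1L]))
    mex <- mex[rev(seq_len(nrow(mex))), , drop = FALSE]
    feats[[length(feats) + 1L]] <- list(
      name = f$name, kind = f$kind,
      strand = if (f$strand == "+") "-" else "+",
      exons = mex, trans = FALSE)
  }

  # junction guards: stop chance flank extension of the IR pair so the
  # detected partition equals the planted one exactly
  if (s[b1] == chartr("ACGT", "TGCA", s[1L])) s[1L] <- s[b1]
  if (s[b2 + 1L] == chartr("ACGT", "TGCA", s[b3])) s[b2 + 1L] <- s[b3]

  state <- list(s = s, feats = feats, b1 = b1, b2 = b2, b3 = b3, L = L)
  mult <- region_multipliers(state, config)
  truth <- list(tree = config$tree, species_map = config$species_map,
                multipliers = mult, planted = truth_records,
                genome_length = L,
                partition = c(lsc = b1, irb = config$ir_length,
                              ssc = config$ssc_length,
                              ira = config$ir_length))
  list(plastome = state_to_plastome(state, "ancestor"), state = state,
       truth = truth)
}

# Plant SSRs, a forward pair, a palindromic pair and a tandem array into
# LSC spacers; returns modified sequence and truth records.  Guard bases
# around each plant make the planted record maximal for its detector.
plant_repeats <- function(env) {
  s <- env$s
  records <- list()
  spacers <- lsc_spacers(env$feats, env$b1)
  spacers <- spacers[(spacers[, 2L] - spacers[, 1L]) >= 150L, , drop = FALSE]
  if (nrow(spacers) < 8L) stop("infeasible packing: too few free spacers")
  add <- function(type, start, len, detail) {
    records[[length(records) + 1L]] <<- data.frame(
      type = type, start = start, end = start + len, detail = detail,
      stringsAsFactors = FALSE)
  }
  put <- function(sp_i, offset, content) {
    a <- spacers[sp_i, 1L] + offset        # 0-based insertion point
    ch <- strsplit(content, "", fixed = TRUE)[[1L]]
    s[(a + 1L):(a + length(ch))] <<- ch
    a
  }
  guard_ssr <- function(a, len, motif) {
    u <- nchar(motif)
    before <- substr(motif, u, u); after <- substr(motif, 1L, 1L)
    s[a] <<- setdiff(c("A", "C", "G", "T"), before)[1L]          # pos a-1
    s[a + len + 1L] <<- setdiff(c("A", "C", "G", "T"),
                                c(after, substr(motif, (len %% u) + 1L,
                                                (len %% u) + 1L)))[1L]
  }
  ssrs <- list(c("A", 12L), c("AT", 6L), c("AAG", 5L), c("ACAT", 4L),
               c("AGATC", 3L), c("AATGCC", 3L))
  for (i in seq_along(ssrs)) {
    motif <- ssrs[[i]][1L]; copies <- as.integer(ssrs[[i]][2L])
    len <- nchar(motif) * copies
    a <- put(i, 30L, strrep(motif, copies))
    guard_ssr(a, len, motif)
    add("ssr", a, len, paste0(motif, "x", copies))
  }
  # forward pair: one exact 35-bp segment at two loci, 4-mismatch guards
  seg <- paste(random_bases(35L, 0.5), collapse = "")
  a1 <- put(7L, 20L, paste0("AAAA", seg, "AAAA")) + 4L
  a2 <- put(8L, 20L, paste0("CCCC", seg, "CCCC")) + 4L
  add("forward", a1, 35L, "pair1"); add("forward", a2, 35L, "pair1")
  # palindromic pair: segment and its revcomp; guards are self-identical
  # bases (x never pairs with comp(x))
  pseg <- paste(random_bases(40L, 0.5), collapse = "")
  a3 <- put(7L, 90L, paste0("GGGG", pseg, "GGGG")) + 4L
  a4 <- put(8L, 90L, paste0("GGGG", revcomp(pseg), "GGGG")) + 4L
  add("palindromic", a3, 40L, "pal1"); add("palindromic", a4, 40L, "pal1")
  # tandem array: 12-bp motif x 5 (gapless score 120)
  motif <- paste(random_bases(12L, 0.5), collapse = "")
  a5 <- put(6L, 60L, strrep(motif, 5L))
  s[a5] <- setdiff(c("A", "C", "G", "T"), substr(motif, 12L, 12L))[1L]
  s[a5 + 61L] <- setdiff(c("A", "C", "G", "T"), substr(motif, 1L, 1L))[1L]
  add("tandem", a5, 60L, paste0(motif, "x5"))
  env$s <- s
  list(s = s, records = do.call(rbind, records))
}

# Free intervals (0-based half-open) between consecutive features in the
# LSC, with a 6 bp margin on each side.
lsc_spacers <- function(feats, b1) {
  spans <- do.call(rbind, lapply(feats, function(f)
    c(min(f$exons[, 1L]), max(f$exons[, 2L]))))
  spans <- spans[spans[, 1L] < b1, , drop = FALSE]
  spans <- spans[order(spans[, 1L]), , drop = FALSE]
  gaps <- cbind(c(0L, spans[, 2L]), c(spans[, 1L], b1))
  gaps <- gaps[gaps[, 2L] - gaps[, 1L] > 12L, , drop = FALSE]
  cbind(gaps[, 1L] + 6L, gaps[, 2L] - 6L)
}

# Per-region rate multipliers: log-spaced gradient over all regions in
# genome order; hotspot spacers overridden.  Returns a named vector.
region_multipliers <- function(state, config) {
  regs <- state_regions(state)
  nm <- regs$name
  k <- length(nm)
  lo <- log(config$gradient_range[1L]); hi <- log(config$gradient_range[2L])
  mult <- exp(seq(lo, hi, length.out = max(k, 2L)))[seq_len(k)]
  names(mult) <- nm
  mult[names(mult) %in% config$hotspots] <- config$hotspot_multiplier
  mult
}

# Ordered regions of the evolution state: gene spans and intergenic
# spacers (by flanking pair), restricted to LSC + IRb + SSC.
state_regions <- function(state) {
  spans <- do.call(rbind, lapply(state$feats, function(f)
    c(min(f$exons[, 1L]), max(f$exons[, 2L]))))
  ord <- order(spans[, 1L])
  feats <- state$feats[ord]; spans <- spans[ord, , drop = FALSE]
  keep <- spans[, 1L] < state$b3           # exclude IRa copies
  feats <- feats[keep]; spans <- spans[keep, , drop = FALSE]
  n <- length(feats)
  name <- character(); start <- integer(); end <- integer()
  type <- character()
  for (i in seq_len(n)) {
    name <- c(name, feats[[i]]$name)
    start <- c(start, spans[i, 1L]); end <- c(end, spans[i, 2L])
    type <- c(type, "gene")
    j <- if (i == n) NA_integer_ else i + 1L
    if (!is.na(j) && spans[j, 1L] > spans[i, 2L]) {
      name <- c(name, paste0(feats[[i]]$name, "-", feats[[j]]$name))
      start <- c(start, spans[i, 2L]); end <- c(end, spans[j, 1L])
      type <- c(type, "spacer")
    }
  }
  data.frame(name = name, start = start, end = end, type = type,
             stringsAsFactors = FALSE)
}

# Convert the internal evolution state into a plastome object.
state_to_plastome <- function(state, id) {
  L <- state$L
  gf <- lapply(state$feats, function(f) {
    exons <- lapply(seq_len(nrow(f$exons)), function(i)
      interval(f$exons[i, 1L], f$exons[i, 2L], L))
    gene_feature(f$name, f$kind, exons, f$strand, f$trans)
  })
  part <- structure(list(
    lsc = interval(0L, state$b1, L),
    irb = interval(state$b1, state$b2, L),
    ssc = interval(state$b2, state$b3, L),
    ira = interval(state$b3, 0L, L),
    genome_length = L), class = "quadripartite_partition")
  plastome(id, paste(state$s, collapse = ""), features = gf,
           partition = part)
}

#' Evolve the ancestor along a tree
#'
#' Walks the configured newick tree from the root, applying independent
#' site substitutions at rate `multiplier(region) * branch_length` (new
#' base uniform among the three alternatives; substitutions that would
#' create an internal stop codon in a CDS are reverted), Poisson indel
#' events in single-copy spacers, and IRb-to-IRa mirroring.  Annotations
#' and planted-truth coordinates are lifted through indels.
#'
#' @param anc result of [build_ancestor()].
#' @param config the same [sim_config()].
#' @param seed integer seed.
#' @return list with `plastomes` (named list of leaf [plastome()]s) and
#'   `truth` (ancestor truth plus per-leaf planted coordinates).
#' @export
evolve_along_tree <- function(anc, config, seed = 1L) {
  set.seed(as.integer(seed))
  tr <- ape::read.tree(text = config$tree)
  if (is.null(tr$edge.length)) stop("tree must have branch lengths")
  ntip <- length(tr$tip.label)
  root <- ntip + 1L
  states <- list(); states[[root]] <- list(state = anc$state,
                                           planted = anc$truth$planted)
  out <- list(); leaf_truth <- list()
  tro <- ape::reorder.phylo(tr, "cladewise")
  edges <- tro$edge
  elens <- tro$edge.length
  for (e in seq_len(nrow(edges))) {
    par <- edges[e, 1L]; ch <- edges[e, 2L]
    res <- evolve_branch(states[[par]]$state, states[[par]]$planted,
                         elens[e], config)
    states[[ch]] <- res
    if (ch <= ntip) {
      id <- tr$tip.label[ch]
      out[[id]] <- state_to_plastome(res$state, id)
      leaf_truth[[id]] <- res$planted
    }
  }
  truth <- anc$truth
  truth$leaf_planted <- leaf_truth
  list(plastomes = out, truth = truth)
}

# One branch of evolution: substitutions, CDS stop repair, IR mirroring,
# spacer indels.
evolve_branch <- function(state, planted, t, config) {
  if (t <= 0) return(list(state = state, planted = planted))
  s <- state$s
  L <- state$L
  mult <- position_multipliers(state, config)
  mask <- rep(TRUE, L)
  mask[(state$b3 + 1L):L] <- FALSE        # IRa mirrored, not mutated
  p <- 1 - exp(-mult * t)
  hit <- which(runif(L) < p & mask)
  if (length(hit)) {
    old <- s[hit]
    s[hit] <- vapply(old, function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
    # repair internal stops created in CDSs
    for (f in state$feats) {
      if (f$kind != "CDS") next
      pos <- unlist(lapply(seq_len(nrow(f$exons)), function(i)
        (f$exons[i, 1L] + 1L):f$exons[i, 2L]))
      if (f$strand == "-") pos <- rev(pos)
      bases <- if (f$strand == "-")
        chartr("ACGTN", "TGCAN", s[pos]) else s[pos]
      ncod <- length(pos) %/% 3L
      for (ci in seq_len(ncod - 1L)) {
        idx <- (3L * ci - 2L):(3L * ci)
        if (paste(bases[idx], collapse = "") %in% STOP_CODONS)
          s[pos[idx]] <- state$s[pos[idx]]
      }
    }
  }
  # mirror IRb into IRa
  s[(state$b3 + 1L):L] <- rev(chartr("ACGTN", "TGCAN",
                                     s[(state$b1 + 1L):state$b2]))
  st <- state; st$s <- s
  # indels in single-copy spacers
  res <- apply_indels(st, planted, t, config)
  res
}

# Per-position rate multipliers from the named region multipliers.
position_multipliers <- function(state, config) {
  regs <- state_regions(state)
  named <- region_multipliers(state, config)
  mult <- rep(1, state$L)
  for (i in seq_len(nrow(regs))) {
    m <- named[[regs$name[i]]]
    if (!is.null(m) && !is.na(m))
      mult[(regs$start[i] + 1L):regs$end[i]] <- m
  }
  mult
}

apply_indels <- function(state, planted, t, config) {
  regs <- state_regions(state)
  named <- region_multipliers(state, config)
  spacers <- regs[regs$type == "spacer" &
                    (regs$end <= state$b1 |
                       (regs$start >= state$b2 & regs$end <= state$b3)), ,
                  drop = FALSE]
  events <- list()
  for (i in seq_len(nrow(spacers))) {
    a <- spacers$start[i] + 2L; b <- spacers$end[i] - 2L  # boundary guard
    if (b - a < 4L) next
    lam <- config$indel_rate * (b - a) * t * named[[spacers$name[i]]]
    nev <- stats::rpois(1L, lam)
    for (k in seq_len(nev)) {
      pos <- a + sample.int(b - a - 2L, 1L)       # 0-based interior point
      len <- min(stats::rgeom(1L, config$indel_geom_p) + 1L,
                 config$indel_max)
      ins <- stats::runif(1L) < 0.5
      if (!ins) len <- min(len, b - pos)          # deletion stays in spacer
      if (len < 1L) next
      events[[length(events) + 1L]] <- list(pos = pos, len = len, ins = ins)
    }
  }
  if (!length(events)) return(list(state = state, planted = planted))
  ord <- order(-vapply(events, function(e) e$pos, 0))
  s <- state$s
  shift_tab <- function(coords, pos, delta)
    ifelse(coords > pos, coords + delta, coords)
  for (e in events[ord]) {
    if (e$ins) {
      s <- append(s, random_bases(e$len, config$gc), after = e$pos)
      delta <- e$len
    } else {
      s <- s[-((e$pos + 1L):(e$pos + e$len))]
      delta <- -e$len
    }
    state$feats <- lapply(state$feats, function(f) {
      f$exons[] <- shift_tab(as.vector(f$exons), e$pos, delta)
      f
    })
    for (nmb in c("b1", "b2", "b3"))
      state[[nmb]] <- shift_tab(state[[nmb]], e$pos, delta)
    state$L <- state$L + delta
    if (!is.null(planted)) {
      planted$start <- shift_tab(planted$start, e$pos, delta)
      planted$end <- shift_tab(planted$end, e$pos, delta)
    }
  }
  state$s <- s
  list(state = state, planted = planted)
}

#' Rotate a plastome (move the origin)
#'
#' Utility for rotation-invariance checks: the sequence is rotated so that
#' former position `r` becomes position 0; features and partition shift
#' accordingly.
#'
#' @param p a [plastome()].
#' @param r rotation offset (0-based).
#' @return rotated [plastome()].
#' @export
rotate_plastome <- function(p, r) {
  n <- nchar(p$seq)
  r <- as.integer(r %% n)
  if (r == 0L) return(p)
  seq2 <- paste0(substr(p$seq, r + 1L, n), substr(p$seq, 1L, r))
  shift_iv <- function(iv) interval((iv$start - r) %% n, (iv$end - r) %% n, n)
  feats <- lapply(p$features, function(f) {
    gene_feature(f$name, f$kind, lapply(f$exons, shift_iv), f$strand,
                 f$trans_spliced)
  })
  part <- p$partition
  if (!is.null(part)) {
    part$lsc <- shift_iv(part$lsc); part$irb <- shift_iv(part$irb)
    part$ssc <- shift_iv(part$ssc); part$ira <- shift_iv(part$ira)
  }
  plastome(p$id, seq2, features = feats, circular = p$circular,
           partition = part)
}
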