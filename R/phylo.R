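#' Pairwise p-distance matrix from concatenated region alignments
#'
#' Regions are concatenated in name order; for each taxon pair, columns
#' containing a gap or `N` in either row are deleted pairwise and the
#' distance is mismatches / compared sites.
#'
#' @param alignments list of `region_alignment`s sharing the same taxa.
#' @param model `"p"` (default) or `"JC69"` for the Jukes-Cantor transform
#'   `-(3/4) log(1 - (4/3) p)`.
#' @return object of class `dist_matrix`: list(taxa, d) with a symmetric
#'   zero-diagonal matrix.
#' @export
p_distance_matrix <- function(alignments, model = c("p", "JC69")) {
  model <- match.arg(model)
  if (inherits(alignments, "region_alignment"))
    alignments <- list(alignments)
  stopifnot(length(alignments) >= 1L)
  taxa <- sort(alignments[[1L]]$taxa)
  for (a in alignments)
    if (!setequal(a$taxa, taxa))
      stop("alignments do not share the same taxa (region '", a$name, "')")
  nms <- vapply(alignments, function(a) a$name, "")
  alignments <- alignments[order(nms)]
  rows <- vapply(taxa, function(t)
    paste(vapply(alignments, function(a) a$rows[[match(t, a$taxa)]], ""),
          collapse = ""), "")
  mats <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  n <- length(taxa)
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    a <- mats[i, ]; b <- mats[j, ]
    ok <- a != "-" & b != "-" & a != "N" & b != "N"
    if (!any(ok))
      stop("zero comparable sites between '", taxa[i], "' and '", taxa[j], "'")
    p <- sum(a[ok] != b[ok]) / sum(ok)
    if (model == "JC69") {
      if (p >= 3 / 4) stop("JC69 distance undefined (p >= 3/4) between '",
                           taxa[i], "' and '", taxa[j], "'")
      p <- -3 / 4 * log(1 - 4 * p / 3)
    }
    d[i, j] <- d[j, i] <- p
  }
  structure(list(taxa = taxa, d = d), class = "dist_matrix")
}

#' Neighbor-joining tree
#'
#' Saitou & Nei (1987) agglomeration with deterministic tie-breaking: when
#' several pairs minimize the Q criterion (within 1e-12), the pair whose
#' (alphabetically sorted) cluster labels are smallest is joined.  Negative
#' branch lengths are clamped to zero.  Exact on additive matrices.
#'
#' @param dm a `dist_matrix` (or a plain symmetric matrix with dimnames).
#' @return an unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(dm) {
  if (inherits(dm, "dist_matrix")) { d <- dm$d } else { d <- as.matrix(dm) }
  n <- nrow(d)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa, got ", n)
  labs <- rownames(d)
  stopifnot(!is.null(labs), all(labs == colnames(d)))
  # cluster representations: newick fragments + smallest member label
  frag <- labs
  rep_lab <- labs
  repeat {
    n <- nrow(d)
    if (n == 2L) break
    rs <- rowSums(d)
    Q <- (n - 2) * d - outer(rs, rs, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    key <- apply(cand, 1L, function(ij) {
      pr <- sort(c(rep_lab[ij[1L]], rep_lab[ij[2L]]))
      paste(pr, collapse = "\r")
    })
    pick <- cand[order(key)[1L], ]
    i <- pick[[1L]]; j <- pick[[2L]]
    vi <- d[i, j] / 2 + (rs[i] - rs[j]) / (2 * (n - 2))
    vj <- d[i, j] - vi
    vi <- max(vi, 0); vj <- max(vj, 0)
    newfrag <- sprintf("(%s:%.10g,%s:%.10g)", frag[i], vi, frag[j], vj)
    newlab <- min(rep_lab[i], rep_lab[j])
    dnew <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    frag <- c(frag[keep], newfrag)
    rep_lab <- c(rep_lab[keep], newlab)
    rownames(d2) <- colnames(d2) <- c(rownames(d)[keep], newlab)
    d <- d2
  }
  bl <- max(d[1L, 2L], 0)
  if (!startsWith(frag[2L], "(") && startsWith(frag[1L], "("))
    frag <- rev(frag)                       # splice into the compound side
  nwk <- if (startsWith(frag[2L], "(")) {
    # attach the final edge inside the other cluster: unrooted trifurcation
    sub("^\\(", sprintf("(%s:%.10g,", frag[1L], bl), frag[2L])
  } else sprintf("(%s:%.10g,%s:0)", frag[1L], bl, frag[2L])
  nwk <- paste0(nwk, ";")
  tr <- ape::read.tree(text = nwk)
  ape::unroot(tr)
}

#' Robinson-Foulds distance
#'
#' Counts the non-trivial bipartitions present in exactly one of two
#' unrooted trees over the same leaf set.
#'
#' @param t1,t2 `ape::phylo` trees with identical leaf label sets.
#' @return integer RF distance.
#' @export
rf_distance <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees have different leaf sets")
  b1 <- tree_bipartitions(t1)
  b2 <- tree_bipartitions(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

# Canonical non-trivial bipartitions of an unrooted tree as strings: the
# side not containing the alphabetically first taxon, members sorted.
tree_bipartitions <- function(tr) {
  tr <- ape::unroot(tr)
  tips <- tr$tip.label
  ref <- sort(tips)[1L]
  n <- length(tips)
  splits <- character()
  desc <- descendant_tips(tr)
  for (node in unique(tr$edge[, 2L])) {
    if (node <= n) next                     # trivial leaf split
    side <- desc[[node]]
    if (ref %in% side) side <- setdiff(tips, side)
    if (length(side) <= 1L || length(side) >= n - 1L) next
    splits <- c(splits, paste(sort(side), collapse = "\r"))
  }
  unique(splits)
}

# tip labels under each internal node (post-order accumulation)
descendant_tips <- function(tr) {
  n <- length(tr$tip.label)
  total <- n + tr$Nnode
  out <- vector("list", total)
  for (i in seq_len(n)) out[[i]] <- tr$tip.label[i]
  ord <- ape::reorder.phylo(tr, "postorder")
  for (e in seq_len(nrow(ord$edge))) {
    par <- ord$edge[e, 1L]; ch <- ord$edge[e, 2L]
    out[[par]] <- c(out[[par]], out[[ch]])
  }
  out
}

#' Species-cluster exclusivity (marker discrimination) check
#'
#' A marker set discriminates the sampled species when every species with
#' two or more individuals forms an exclusive cluster in the tree, i.e.
#' the bipartition separating exactly its individuals exists.  Species
#' with a single individual are vacuously compatible and reported
#' untestable.
#'
#' @param tree `ape::phylo` whose tips are individuals.
#' @param species_map named character vector: individual id -> species.
#' @return list: `discriminates` (logical), `per_species` data.frame with
#'   columns species, n_individuals, exclusive, testable.
#' @export
marker_discrimination <- function(tree, species_map) {
  tips <- tree$tip.label
  if (!all(tips %in% names(species_map)))
    stop("species_map is missing: ",
         paste(setdiff(tips, names(species_map)), collapse = ", "))
  splits <- tree_bipartitions(tree)
  ref <- sort(tips)[1L]
  n <- length(tips)
  species <- unique(unname(species_map[tips]))
  rows <- lapply(species, function(sp) {
    members <- tips[species_map[tips] == sp]
    testable <- length(members) >= 2L
    exclusive <- TRUE
    if (testable && length(members) < n) {
      side <- members
      if (ref %in% side) side <- setdiff(tips, side)
      want <- paste(sort(side), collapse = "\r")
      # a clade of n-1 tips is a trivial split in an unrooted tree: always
      # present
      exclusive <- length(side) >= n - 1L || want %in% splits
    }
    data.frame(species = sp, n_individuals = length(members),
               exclusive = exclusive, testable = testable,
               stringsAsFactors = FALSE)
  })
  per_species <- do.call(rbind, rows)
  list(discriminates = all(per_species$exclusive[per_species$testable]),
       per_species = per_species)
}
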