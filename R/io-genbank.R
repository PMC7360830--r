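#' Read a GenBank flat file into a plastome
#'
#' A purpose-built reader for organelle-genome GenBank records: LOCUS,
#' FEATURES (`gene`, `CDS`, `tRNA`, `rRNA` keys; `join`/`complement`
#' location algebra) and ORIGIN are consumed; other feature keys are
#' ignored.  GenBank 1-based inclusive coordinates become 0-based half-open
#' internal coordinates; a `join` whose ranges abut across the origin of a
#' circular record is merged into one origin-wrapping exon.  `gene` features
#' that duplicate a parsed CDS/tRNA/rRNA of the same name are dropped;
#' orphan `gene` features are kept with kind `"other"`.  Duplicate gene
#' names (IR copies) are preserved as distinct features.
#'
#' @param path GenBank flat file.
#' @return a [plastome()].
#' @export
read_genbank <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  locus_i <- grep("^LOCUS", lines)
  if (length(locus_i) == 0L)
    stop("GenBank format error at line 1: no LOCUS line in '", path, "'")
  locus <- strsplit(trimws(lines[locus_i[1L]]), "\\s+")[[1L]]
  id <- locus[2L]
  circular <- any(grepl("^circular$", locus, ignore.case = TRUE))

  feat_i <- grep("^FEATURES", lines)
  orig_i <- grep("^ORIGIN", lines)
  if (length(orig_i) == 0L)
    stop("GenBank content error: record '", id, "' has no ORIGIN sequence")
  orig_i <- orig_i[1L]

  end_i <- grep("^//", lines)
  end_i <- if (length(end_i)) end_i[1L] else length(lines) + 1L
  seq_lines <- if (end_i - orig_i >= 2L)
    lines[seq.int(orig_i + 1L, end_i - 1L)] else character()
  seq <- gsub("[^A-Za-z]", "", paste(seq_lines, collapse = ""))
  if (nchar(seq) == 0L)
    stop("GenBank content error: record '", id, "' has an empty sequence")
  seq <- normalize_seq(seq)
  n <- nchar(seq)

  feats <- list()
  if (length(feat_i)) {
    fl <- lines[seq.int(feat_i[1L] + 1L, orig_i - 1L)]
    feats <- parse_genbank_features(fl, n, path, offset = feat_i[1L])
  }
  plastome(id, seq, features = feats, circular = circular)
}

# Parse the FEATURES block: returns a list of gene_feature.
parse_genbank_features <- function(fl, genome_length, path, offset = 0L) {
  key_re <- "^ {5}(\\S+) +(\\S.*)$"
  entries <- list()
  cur <- NULL
  for (k in seq_along(fl)) {
    line <- fl[k]
    if (grepl(key_re, line)) {
      if (!is.null(cur)) entries[[length(entries) + 1L]] <- cur
      cur <- list(key = sub(key_re, "\\1", line),
                  loc = sub(key_re, "\\2", line),
                  quals = character(), line = k + offset)
    } else if (!is.null(cur)) {
      txt <- trimws(line)
      if (startsWith(txt, "/")) cur$quals <- c(cur$quals, txt)
      else if (nzchar(txt) && !length(cur$quals)) # location continuation
        cur$loc <- paste0(cur$loc, txt)
      else if (nzchar(txt) && length(cur$quals))  # qualifier continuation
        cur$quals[length(cur$quals)] <-
          paste0(cur$quals[length(cur$quals)], txt)
    }
  }
  if (!is.null(cur)) entries[[length(entries) + 1L]] <- cur

  wanted <- c(gene = "other", CDS = "CDS", tRNA = "tRNA", rRNA = "rRNA")
  out <- list()
  for (e in entries) {
    if (!e$key %in% names(wanted)) next
    loc <- tryCatch(parse_location(e$loc, genome_length),
                    error = function(err)
                      stop("GenBank format error at line ", e$line, " of '",
                           path, "': ", conditionMessage(err)))
    nm <- qual_value(e$quals, "gene")
    if (is.na(nm)) nm <- qual_value(e$quals, "product")
    if (is.na(nm)) nm <- paste0(e$key, "_", e$line)
    ts <- any(grepl("^/trans_splicing", e$quals)) || loc$trans
    out[[length(out) + 1L]] <-
      list(key = e$key, feat = gene_feature(nm, wanted[[e$key]], loc$exons,
                                            loc$strand, trans_spliced = ts))
  }

  # Drop `gene` umbrellas that duplicate a typed feature of the same name
  # over the same span.
  typed <- out[vapply(out, function(x) x$key != "gene", TRUE)]
  genes <- out[vapply(out, function(x) x$key == "gene", TRUE)]
  span_sig <- function(x) {
    sp <- feature_span(x$feat)
    paste(x$feat$name, sp$start, sp$end)
  }
  typed_sigs <- vapply(typed, span_sig, "")
  keep_genes <- genes[!vapply(genes, span_sig, "") %in% typed_sigs &
                        !vapply(genes, function(g)
                          g$feat$name %in%
                            vapply(typed, function(t) t$feat$name, ""), TRUE)]
  lapply(c(typed, keep_genes), function(x) {
    k <- x$feat
    if (x$key != "gene") return(k)
    gene_feature(k$name, "other", k$exons, k$strand, k$trans_spliced)
  })
}

qual_value <- function(quals, name) {
  hit <- grep(paste0("^/", name, "="), quals, value = TRUE)
  if (!length(hit)) return(NA_character_)
  gsub("^\"|\"$", "", sub(paste0("^/", name, "="), "", hit[1L]))
}

# GenBank location algebra: ranges `a..b`, single bases `a`, `join(...)`,
# `order(...)` (treated as trans-spliced join) and `complement(...)`.
# Returns exons (0-based half-open intervals), strand, and a trans flag.
parse_location <- function(loc, genome_length) {
  loc <- gsub("[<> ]", "", loc)
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  trans <- grepl("^order\\(", loc)
  if (grepl("^(join|order)\\(", loc))
    loc <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
  if (grepl("[()]", loc))
    stop("unsupported location nesting: '", loc, "'")
  parts <- strsplit(loc, ",", fixed = TRUE)[[1L]]
  if (!length(parts)) stop("empty location")
  ranges <- lapply(parts, function(p) {
    if (grepl("^[0-9]+\\.\\.[0-9]+$", p)) {
      ab <- as.integer(strsplit(p, "..", fixed = TRUE)[[1L]])
    } else if (grepl("^[0-9]+$", p)) {
      ab <- rep(as.integer(p), 2L)
    } else stop("cannot parse location component '", p, "'")
    if (ab[1L] > ab[2L] || ab[2L] > genome_length)
      stop("location range out of order or beyond sequence: '", p, "'")
    ab
  })
  # Merge ranges that abut across the origin of the circle into one
  # wrapping exon.
  exons <- list()
  i <- 1L
  while (i <= length(ranges)) {
    ab <- ranges[[i]]
    if (ab[2L] == genome_length && i < length(ranges) &&
        ranges[[i + 1L]][1L] == 1L) {
      exons[[length(exons) + 1L]] <-
        interval(ab[1L] - 1L, ranges[[i + 1L]][2L], genome_length)
      i <- i + 2L
    } else {
      exons[[length(exons) + 1L]] <-
        interval(ab[1L] - 1L, ab[2L], genome_length)
      i <- i + 1L
    }
  }
  list(exons = exons, strand = strand, trans = trans)
}

#' Write a plastome as a GenBank flat file
#'
#' Inverse of [read_genbank()]: emits LOCUS, a FEATURES table with one typed
#' line per feature (`CDS`/`tRNA`/`rRNA`; kind `"other"` is written with the
#' `gene` key) and the ORIGIN sequence.  Internal 0-based half-open
#' coordinates become 1-based inclusive; origin-wrapping exons become a
#' two-range `join`.
#'
#' @param p a [plastome()].
#' @param path output path.
#' @export
write_genbank <- function(p, path) {
  stopifnot(inherits(p, "plastome"))
  n <- nchar(p$seq)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %s %d bp    DNA     %s PLN %s",
                     p$id, n, if (p$circular) "circular" else "linear",
                     format(Sys.Date(), "%d-%b-%Y")), con)
  writeLines(sprintf("DEFINITION  %s plastome.", p$id), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", n), con)
  for (f in p$features) {
    key <- if (f$kind == "other") "gene" else f$kind
    writeLines(sprintf("     %-15s %s", key, format_location(f, n)), con)
    writeLines(sprintf("                     /gene=\"%s\"", f$name), con)
    if (f$trans_spliced)
      writeLines("                     /trans_splicing", con)
  }
  writeLines("ORIGIN", con)
  starts <- seq.int(1L, n, by = 60L)
  for (s in starts) {
    chunk <- substr(p$seq, s, min(s + 59L, n))
    tens <- seq.int(1L, nchar(chunk), by = 10L)
    groups <- substring(chunk, tens, pmin(tens + 9L, nchar(chunk)))
    writeLines(sprintf("%9d %s", s, tolower(paste(groups, collapse = " "))),
               con)
  }
  writeLines("//", con)
  invisible(path)
}

format_location <- function(f, n) {
  fmt1 <- function(e) {
    if (!e$wrap) sprintf("%d..%d", e$start + 1L, e$end)
    else sprintf("%d..%d,1..%d", e$start + 1L, n, e$end)
  }
  ranges <- vapply(f$exons, fmt1, "")
  body <- paste(ranges, collapse = ",")
  njoin <- length(f$exons) + sum(grepl(",", ranges, fixed = TRUE))
  if (njoin > 1L)
    body <- sprintf("%s(%s)", if (f$trans_spliced) "order" else "join", body)
  if (f$strand == "-") body <- sprintf("complement(%s)", body)
  body
}
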