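test_that("extract_shared_regions returns genes and spacers incl. the wrap", {
  mk <- function(id, seed) {
    set.seed(seed)
    n <- 600L
    feats <- list(
      gene_feature("A", "CDS", interval(50, 230, n), "+"),
      gene_feature("B", "CDS", interval(300, 480, n), "-"),
      gene_feature("C", "tRNA", interval(520, 580, n), "+"))
    plastome(id, random_dna(n), features = feats)
  }
  regs <- extract_shared_regions(list(mk("g1", 1), mk("g2", 2)))
  expect_setequal(names(regs), c("A", "B", "C", "A-B", "B-C", "C-A"))
  expect_equal(regs[["A"]]$rtype, "coding")
  expect_equal(regs[["C-A"]]$rtype, "noncoding")
  # the wrap-around spacer has the right length: 600 - 580 + 50
  expect_equal(unname(nchar(regs[["C-A"]]$seqs)), c(70L, 70L))
  # coding region of a minus gene is strand-normalized
  g1 <- mk("g1", 1)
  expect_identical(unname(regs[["B"]]$seqs["g1"]),
                   revcomp(substr(g1$seq, 301, 480)))
})

test_that("regions missing from one genome are dropped with a message", {
  mk <- function(id, seed, extra = FALSE) {
    set.seed(seed)
    n <- 600L
    feats <- list(
      gene_feature("A", "CDS", interval(50, 230, n), "+"),
      gene_feature("B", "CDS", interval(300, 480, n), "-"))
    if (extra)
      feats <- c(feats, list(gene_feature("D", "CDS",
                                          interval(500, 560, n), "+")))
    plastome(id, random_dna(n), features = feats)
  }
  expect_message(
    regs <- extract_shared_regions(list(mk("g1", 1, TRUE), mk("g2", 2))),
    "dropping")
  expect_false("D" %in% names(regs))
  expect_false(any(grepl("D", names(regs))))
  expect_error(extract_shared_regions(list(mk("g1", 1))), "at least 2")
})

test_that("IR-duplicated genes are extracted once, from the IRb copy", {
  cfg <- sim_config("test")
  anc <- build_ancestor(cfg, seed = 31)
  sim <- evolve_along_tree(anc, cfg, seed = 32)
  two <- sim$plastomes[1:2]
  regs <- suppressMessages(extract_shared_regions(two))
  expect_true(regs[["rpl2"]]$duplicated_in_ir)
  expect_false(regs[["rbcL"]]$duplicated_in_ir)
  expect_equal(sum(names(regs) == "rpl2"), 1L)
})

test_that("align_region handles identity, a 1-bp gap, and import", {
  a1 <- align_region(c(x = "ACGTACGT", y = "ACGTACGT"))
  expect_false(any(grepl("-", a1$rows, fixed = TRUE)))
  a2 <- align_region(c(x = "ACGT", y = "AGT"))
  expect_equal(nchar(a2$rows[["x"]]), 4L)
  expect_equal(sum(strsplit(a2$rows[["y"]], "")[[1L]] == "-"), 1L)
  expect_identical(a2$rows[["x"]], "ACGT")
  expect_error(align_region(c(x = "ACGT", y = "")), "empty sequence")

  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">t1", "AC-GT", ">t2", "ACCGT"), f)
  imp <- import_alignment(f, name = "reg1")
  expect_s3_class(imp, "region_alignment")
  expect_identical(imp$rows[["t1"]], "AC-GT")
  writeLines(c(">t1", "AC-GT", ">t2", "ACCGTT"), f)
  expect_error(import_alignment(f), "unequal")
})

test_that("variability_percent implements the printed formula", {
  # identical rows, no gaps
  v0 <- variability_percent(region_alignment("r0", "noncoding",
                                             c(a = strrep("ACGTA", 100),
                                               b = strrep("ACGTA", 100))))
  expect_equal(v0$percent, 0)
  expect_equal(v0$L_aln, 500L)
  # the worked example: S=1, I=1, L=12, L_indel=2
  v1 <- variability_percent(region_alignment("r1", "noncoding",
                                             c(a = "ACGTACGTACGT",
                                               b = "ACCTAC--ACGT")))
  expect_equal(v1$S, 1L)
  expect_equal(v1$I, 1L)
  expect_equal(v1$L_aln, 12L)
  expect_equal(v1$L_indel, 2L)
  expect_equal(v1$percent, 100 * 2 / 11)
  # all columns polymorphic, no gaps: 100%
  v2 <- variability_percent(region_alignment("r2", "noncoding",
                                             c(a = "ACGT", b = "CGTA")))
  expect_equal(v2$percent, 100)
})

test_that("variability_percent conventions: indel runs, N, mixed columns", {
  # two separate gap runs = two indel events
  v <- variability_percent(region_alignment("r", "noncoding",
                                            c(a = "AAAAAAAAAA",
                                              b = "AA--AA--AA")))
  expect_equal(v$I, 2L)
  expect_equal(v$L_indel, 4L)
  # N is missing: a column of A/N is not a substitution
  v2 <- variability_percent(region_alignment("r", "noncoding",
                                             c(a = "AAAA", b = "ANAA")))
  expect_equal(v2$S, 0L)
  # a column with both gap and substitution counts as gap only
  v3 <- variability_percent(region_alignment("r", "noncoding",
                                             c(a = "AACA", b = "A-GA",
                                               x = "AAGA")))
  expect_equal(v3$S, 1L)      # column 3 only
  expect_equal(v3$L_indel, 1L)
})

test_that("variability invariants hold on random alignments", {
  set.seed(44)
  for (rep in 1:20) {
    L <- sample(30:80, 1)
    base <- strsplit(random_dna(L), "")[[1L]]
    rows <- vapply(1:4, function(i) {
      r <- base
      nm <- sample(L, sample(0:5, 1))
      r[nm] <- sample(c("A", "C", "G", "T"), length(nm), TRUE)
      g <- sample(L, sample(0:2, 1))
      r[g] <- "-"
      paste(r, collapse = "")
    }, "")
    names(rows) <- paste0("t", 1:4)
    rows_ok <- tryCatch(region_alignment("r", "noncoding", rows),
                        error = function(e) NULL)
    if (is.null(rows_ok)) next
    v <- variability_percent(rows_ok)
    # permutation invariance
    vp <- variability_percent(region_alignment("r", "noncoding",
                                               rows[c(3, 1, 4, 2)]))
    expect_equal(vp$percent, v$percent)
    # appending a duplicate row changes nothing
    vd <- variability_percent(region_alignment("r", "noncoding",
                                               c(rows, t5 = rows[[1L]])))
    expect_equal(vd$percent, v$percent)
    # percent == 0 iff all rows identical (ignoring nothing; no Ns here)
    expect_equal(v$percent == 0, length(unique(rows)) == 1L)
    # appending an invariant gap-free column strictly decreases a
    # positive percent (denominator monotonicity)
    rows2 <- paste0(rows, "A")
    names(rows2) <- names(rows)
    v2 <- variability_percent(region_alignment("r", "noncoding", rows2))
    if (v$S + v$I > 0) expect_lt(v2$percent, v$percent)
  }
})

test_that("rank_hotspots orders, breaks ties and flags thresholds", {
  tab <- data.frame(
    name = c("a", "b", "c", "d"), rtype = "noncoding",
    S = 1L, I = 0L, L_aln = c(100L, 200L, 200L, 50L), L_indel = 0L,
    percent = c(5, 2, 2, 0.3))
  r <- rank_hotspots(tab, k = 7, threshold = 0.5)
  expect_equal(r$name, c("a", "b", "c", "d"))  # tie b/c by larger L, name
  expect_equal(r$above_threshold, c(TRUE, TRUE, TRUE, FALSE))
  r2 <- rank_hotspots(tab, k = 2)
  expect_equal(nrow(r2), 2L)
  tie <- data.frame(name = c("z", "y"), rtype = "noncoding", S = 1L, I = 0L,
                    L_aln = c(100L, 100L), L_indel = 0L, percent = c(1, 1))
  expect_equal(rank_hotspots(tie, k = 2)$name, c("y", "z"))
})

test_that("combine_hotspot_sets does the 7 + 7 set arithmetic", {
  g <- paste0("r", 1:7)
  expect_equal(combine_hotspot_sets(g, paste0("f", 1:7))$n_union, 14L)
  expect_equal(combine_hotspot_sets(g, g)$n_union, 7L)
  expect_equal(combine_hotspot_sets(g, g)$n_intersection, 7L)
  mixed <- combine_hotspot_sets(g, c(g[1:3], paste0("f", 1:4)))
  expect_equal(mixed$n_intersection, 3L)
  expect_equal(mixed$n_union, 11L)
})
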