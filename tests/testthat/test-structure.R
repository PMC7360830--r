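test_that("detect_ir recovers the planted partition exactly", {
  cfg <- sim_config("test")
  anc <- build_ancestor(cfg, seed = 5)
  p <- plastome("bare", anc$plastome$seq)   # no annotation used
  pt <- detect_ir(p)
  lens <- vapply(pt[c("lsc", "irb", "ssc", "ira")], interval_length, 0L)
  expect_equal(unname(lens),
               c(cfg$lsc_length, cfg$ir_length, cfg$ssc_length,
                 cfg$ir_length))
  # IR copies are exact reverse complements
  expect_identical(circular_slice(p$seq, pt$ira),
                   revcomp(circular_slice(p$seq, pt$irb)))
  # the four regions tile the circle
  expect_equal(sum(lens), nchar(p$seq))
})

test_that("detect_ir is rotation-invariant and orientation-covariant", {
  cfg <- sim_config("test")
  anc <- build_ancestor(cfg, seed = 6)
  p <- plastome("bare", anc$plastome$seq)
  base <- detect_ir(p)
  base_lens <- vapply(base[c("lsc", "irb", "ssc", "ira")],
                      interval_length, 0L)
  set.seed(1)
  for (r in sample(1:19999, 3)) {
    pr <- rotate_plastome(p, r)
    ptr <- detect_ir(pr)
    expect_equal(vapply(ptr[c("lsc", "irb", "ssc", "ira")],
                        interval_length, 0L), base_lens)
    # junctions shift with the rotation
    expect_equal(ptr$irb$start,
                 as.integer((base$irb$start - r) %% 20000))
  }
  # flipping the genome preserves all four lengths
  pf <- plastome("flip", revcomp(p$seq))
  ptf <- detect_ir(pf)
  expect_equal(unname(vapply(ptf[c("lsc", "irb", "ssc", "ira")],
                             interval_length, 0L)),
               unname(base_lens))
})

test_that("genomes without an inverted duplication raise PartitionError", {
  set.seed(3)
  p <- plastome("rand", random_dna(8000))
  err <- tryCatch(detect_ir(p), error = function(e) e)
  expect_s3_class(err, "plastomics_partition_error")
  expect_match(conditionMessage(err), "not quadripartite")
})

test_that("gc_content follows the N-excluding definition", {
  expect_equal(gc_content("ATGC"), 50)
  expect_equal(gc_content("GGCC"), 100)
  expect_equal(gc_content("GCNN"), 100)   # N excluded from both sides
  expect_warning(v <- gc_content("NNNN"), "undefined")
  expect_true(is.na(v))
})

test_that("whole-genome GC is the length-weighted mean of region GC", {
  for (seed in 1:5) {
    cfg <- sim_config("test", gc = runif(1, 0.3, 0.5))
    p <- build_ancestor(cfg, seed = seed)$plastome
    gcs <- gc_by_region(p)
    lens <- vapply(p$partition[c("lsc", "irb", "ssc", "ira")],
                   interval_length, 0L)
    weighted <- sum(gcs[c("lsc", "irb", "ssc", "ira")] * lens) / sum(lens)
    expect_equal(unname(gcs[["whole"]]), weighted, tolerance = 1e-10)
  }
})

test_that("junction_report finds straddling and nearest genes", {
  n <- 2000L
  # partition: LSC [0,1000), IRb [1000,1300), SSC [1300,1700), IRa [1700,2000)
  irb <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  set.seed(8)
  lsc <- random_dna(1000); ssc <- random_dna(400)
  seq <- paste0(lsc, irb, ssc, revcomp(irb))
  feats <- list(
    gene_feature("cross", "CDS", interval(880, 1159, n), "+"),  # 120 | 159
    gene_feature("inner", "CDS", interval(1400, 1663, n), "+")) # 37 from SSC/IRa
  p <- plastome("jx", seq, features = feats)
  p$partition <- structure(list(
    lsc = interval(0, 1000, n), irb = interval(1000, 1300, n),
    ssc = interval(1300, 1700, n), ira = interval(1700, 0, n),
    genome_length = n), class = "quadripartite_partition")
  jr <- junction_report(p)
  cross <- jr[jr$junction == "LSC/IRb" & jr$gene == "cross", ]
  expect_equal(cross$role, "overlapping")
  expect_equal(cross$bp_left, 120L)
  expect_equal(cross$bp_right, 159L)
  near <- jr[jr$junction == "SSC/IRa" & jr$gene == "inner", ]
  expect_equal(near$role, "nearest_left")
  expect_equal(near$distance, 37L)
})

test_that("a gene duplicated adjacent to both LSC junctions shows in both contexts", {
  # the trnH-GUG-in-both-IRs layout: copies near IRa/LSC and LSC/IRb
  n <- 2000L
  set.seed(10)
  irb <- random_dna(300)
  seq <- paste0(random_dna(1000), irb, random_dna(400), revcomp(irb))
  feats <- list(
    gene_feature("trnH-GUG", "tRNA", interval(1005, 1065, n), "+"),
    gene_feature("trnH-GUG", "tRNA", interval(1935, 1995, n), "-"))
  p <- plastome("ht", seq, features = feats)
  p$partition <- structure(list(
    lsc = interval(0, 1000, n), irb = interval(1000, 1300, n),
    ssc = interval(1300, 1700, n), ira = interval(1700, 0, n),
    genome_length = n), class = "quadripartite_partition")
  jr <- junction_report(p)
  ctx <- jr[jr$gene == "trnH-GUG", "junction"]
  expect_true("LSC/IRb" %in% ctx)
  expect_true("IRa/LSC" %in% ctx)
})

test_that("gene_inventory counts unique, duplicated and intron genes", {
  cfg <- sim_config("test")
  p <- build_ancestor(cfg, seed = 12)$plastome
  inv <- gene_inventory(p)
  lay <- plastomics:::default_gene_layout()
  expect_equal(inv$n_genes_unique, length(lay) + 1L)   # + rps19
  expect_equal(inv$n_ir_duplicated,
               sum(vapply(lay, function(g) g$region == "IRb", TRUE)))
  # class split
  kinds <- c(vapply(lay, function(g) g$kind, ""), "CDS")
  expect_equal(inv$n_protein_coding, sum(kinds == "CDS"))
  expect_equal(inv$n_trna, sum(kinds == "tRNA"))
  expect_equal(inv$n_rrna, sum(kinds == "rRNA"))
  expect_equal(inv$n_genes_unique,
               inv$n_protein_coding + inv$n_trna + inv$n_rrna + inv$n_other)
  # intron accounting: exons - 1
  expected_introns <- vapply(lay, function(g) length(g$exons) - 1L, 0L)
  names(expected_introns) <- vapply(lay, function(g) g$name, "")
  expected_introns <- expected_introns[expected_introns > 0L]
  expect_mapequal(as.list(inv$genes_with_introns),
                  as.list(expected_introns))
  expect_equal(inv$genes_with_introns[["clpP"]], 2L)
  expect_equal(inv$genes_with_introns[["ycf3"]], 2L)
})

test_that("same-name features outside an IR pair warn and count once", {
  n <- 2000L
  set.seed(13)
  irb <- random_dna(300)
  seq <- paste0(random_dna(1000), irb, random_dna(400), revcomp(irb))
  feats <- list(
    gene_feature("dup", "CDS", interval(100, 200, n), "+"),
    gene_feature("dup", "CDS", interval(400, 500, n), "+"))
  p <- plastome("w", seq, features = feats)
  p$partition <- structure(list(
    lsc = interval(0, 1000, n), irb = interval(1000, 1300, n),
    ssc = interval(1300, 1700, n), ira = interval(1700, 0, n),
    genome_length = n), class = "quadripartite_partition")
  expect_warning(inv <- gene_inventory(p), "outside an IR pair")
  expect_equal(inv$n_genes_unique, 1L)
  expect_equal(inv$n_ir_duplicated, 0L)
})
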