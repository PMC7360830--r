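test_that("build_ancestor is deterministic and respects its GC target", {
  cfg <- sim_config("test")
  a1 <- build_ancestor(cfg, seed = 70)
  a2 <- build_ancestor(cfg, seed = 70)
  expect_identical(a1$plastome$seq, a2$plastome$seq)
  a3 <- build_ancestor(cfg, seed = 71)
  expect_false(identical(a1$plastome$seq, a3$plastome$seq))

  cfg50 <- sim_config("test", gc = 0.5)
  g <- gc_content(build_ancestor(cfg50, seed = 72)$plastome)
  expect_lt(abs(g - 50), 1)       # binomial tolerance on 20 kb
  g2 <- gc_content(build_ancestor(sim_config("test"), seed = 72)$plastome)
  expect_lt(abs(g2 - 36.3), 1.5)  # ORF codons shift composition slightly
})

test_that("planted truth re-locates in the emitted ancestor", {
  cfg <- sim_config("test")
  anc <- build_ancestor(cfg, seed = 73)
  s <- anc$plastome$seq
  tr <- anc$truth$planted
  for (i in seq_len(nrow(tr))) {
    piece <- substr(s, tr$start[i] + 1L, tr$end[i])
    if (tr$type[i] == "ssr") {
      motif <- sub("x.*", "", tr$detail[i])
      copies <- as.integer(sub(".*x", "", tr$detail[i]))
      expect_identical(piece, strrep(motif, copies), info = tr$detail[i])
    }
    if (tr$type[i] == "tandem") {
      motif <- sub("x.*", "", tr$detail[i])
      expect_identical(piece, strrep(motif, 5L))
    }
  }
  fw <- tr[tr$type == "forward", ]
  expect_identical(substr(s, fw$start[1L] + 1L, fw$end[1L]),
                   substr(s, fw$start[2L] + 1L, fw$end[2L]))
  pal <- tr[tr$type == "palindromic", ]
  expect_identical(substr(s, pal$start[2L] + 1L, pal$end[2L]),
                   revcomp(substr(s, pal$start[1L] + 1L, pal$end[1L])))
  # IR mirror identity
  pt <- anc$plastome$partition
  expect_identical(circular_slice(s, pt$ira),
                   revcomp(circular_slice(s, pt$irb)))
})

test_that("infeasible packing raises a configuration error", {
  cfg <- sim_config("test", genome_length = 7600, ir_length = 1500,
                    ssc_length = 1500)
  expect_error(build_ancestor(cfg, seed = 1), "infeasible packing")
})

test_that("zero-length branches copy the ancestor unchanged", {
  cfg <- sim_config(
    "test",
    tree = "((A:0,B:0):0,C:0);",
    species_map = c(A = "sp1", B = "sp1", C = "sp2"))
  anc <- build_ancestor(cfg, seed = 74)
  sim <- evolve_along_tree(anc, cfg, seed = 75)
  for (p in sim$plastomes)
    expect_identical(p$seq, anc$plastome$seq)
})

test_that("evolution is deterministic and preserves IR mirroring", {
  cfg <- sim_config("test")
  anc <- build_ancestor(cfg, seed = 76)
  s1 <- evolve_along_tree(anc, cfg, seed = 77)
  s2 <- evolve_along_tree(anc, cfg, seed = 77)
  expect_identical(lapply(s1$plastomes, `[[`, "seq"),
                   lapply(s2$plastomes, `[[`, "seq"))
  s3 <- evolve_along_tree(anc, cfg, seed = 78)
  expect_false(identical(s1$plastomes[[1L]]$seq, s3$plastomes[[1L]]$seq))
  for (p in s1$plastomes) {
    pt <- p$partition
    expect_identical(circular_slice(p$seq, pt$ira),
                     revcomp(circular_slice(p$seq, pt$irb)))
    # annotations still in range and CDSs still stop-free inside
    for (f in p$features) {
      if (f$kind != "CDS" || f$name == "rps19") next
      expect_silent(codon_partition(plastomics:::feature_seq(p, f)))
    }
  }
})

test_that("substitution counts follow the configured rate", {
  # one branch of length 0.01 at multiplier 1: each site mutates with
  # probability 1 - exp(-0.01); pooled over seeds the count is binomial
  cfg <- sim_config("test", tree = "(X:0.01,Y:0.0001);",
                    species_map = c(X = "x", Y = "y"),
                    hotspots = character(0), gradient_range = c(1, 1),
                    indel_rate = 0)
  anc <- build_ancestor(cfg, seed = 80)
  region <- plastomics:::state_regions(anc$state)
  sp <- region[region$type == "spacer" & region$end < cfg$lsc_length, ]
  sp <- sp[(sp$end - sp$start) >= 300L, ][1:4, ]
  tot_sites <- 0L; tot_subs <- 0L
  for (seed in 1:8) {
    sim <- evolve_along_tree(anc, cfg, seed = seed)
    a <- strsplit(anc$plastome$seq, "")[[1L]]
    x <- strsplit(sim$plastomes[["X"]]$seq, "")[[1L]]
    for (i in seq_len(nrow(sp))) {
      idx <- (sp$start[i] + 1L):sp$end[i]
      tot_sites <- tot_sites + length(idx)
      tot_subs <- tot_subs + sum(a[idx] != x[idx])
    }
  }
  p <- 1 - exp(-0.01)
  expected <- tot_sites * p
  expect_lt(abs(tot_subs - expected), 4 * sqrt(expected))
})

test_that("hotspot spacers accumulate many-fold more substitutions", {
  cfg <- sim_config("test", tree = "(X:0.02,Y:0.0001);",
                    species_map = c(X = "x", Y = "y"),
                    gradient_range = c(1, 1), indel_rate = 0)
  anc <- build_ancestor(cfg, seed = 81)
  regs <- plastomics:::state_regions(anc$state)
  hot <- regs[regs$name %in% cfg$hotspots, ]
  base <- regs[regs$type == "spacer" & !regs$name %in% cfg$hotspots &
                 regs$end < cfg$lsc_length, ]
  hot_subs <- 0L; hot_sites <- 0L; base_subs <- 0L; base_sites <- 0L
  for (seed in 1:6) {
    sim <- evolve_along_tree(anc, cfg, seed = 100 + seed)
    a <- strsplit(anc$plastome$seq, "")[[1L]]
    x <- strsplit(sim$plastomes[["X"]]$seq, "")[[1L]]
    count <- function(rows) {
      subs <- 0L; sites <- 0L
      for (i in seq_len(nrow(rows))) {
        idx <- (rows$start[i] + 1L):rows$end[i]
        subs <- subs + sum(a[idx] != x[idx]); sites <- sites + length(idx)
      }
      c(subs, sites)
    }
    h <- count(hot); b <- count(base)
    hot_subs <- hot_subs + h[1L]; hot_sites <- hot_sites + h[2L]
    base_subs <- base_subs + b[1L]; base_sites <- base_sites + b[2L]
  }
  rate_ratio <- (hot_subs / hot_sites) / (base_subs / base_sites)
  expect_gte(rate_ratio, 5)
})

test_that("indels shift annotations consistently", {
  cfg <- sim_config("test", tree = "(X:0.05,Y:0.0001);",
                    species_map = c(X = "x", Y = "y"),
                    indel_rate = 0.2)
  anc <- build_ancestor(cfg, seed = 82)
  sim <- evolve_along_tree(anc, cfg, seed = 83)
  px <- sim$plastomes[["X"]]
  expect_false(nchar(px$seq) == nchar(anc$plastome$seq) &&
                 identical(px$seq, anc$plastome$seq))
  # every non-straddling CDS still translates cleanly after lifting
  for (f in px$features) {
    if (f$kind != "CDS" || f$name == "rps19") next
    expect_silent(codon_partition(plastomics:::feature_seq(px, f)))
  }
  # partition still tiles the genome
  lens <- vapply(px$partition[c("lsc", "irb", "ssc", "ira")],
                 interval_length, 0L)
  expect_equal(sum(lens), nchar(px$seq))
  expect_equal(lens[["irb"]], lens[["ira"]])
})
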