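test_that("SSR thresholds, primitivity and maximality", {
  # below the mononucleotide threshold of 10
  expect_equal(nrow(find_ssrs(paste0("GC", strrep("A", 9), "GC"))), 0L)
  # A x 12 is one mono record
  t1 <- find_ssrs(paste0("GC", strrep("A", 12), "GC"))
  expect_equal(nrow(t1), 1L)
  expect_equal(t1$motif, "A")
  expect_equal(t1$copies, 12L)
  expect_equal(t1$start, 2L)
  # AT x 6 is a single di record, never a tetra ATAT one
  t2 <- find_ssrs(paste0("GGG", strrep("AT", 6), "GGG"))
  expect_equal(nrow(t2), 1L)
  expect_equal(t2$motif, "AT")
  expect_equal(t2$unit_len, 2L)
  expect_equal(t2$copies, 6L)
  # runs containing N are split
  t3 <- find_ssrs(paste0(strrep("A", 6), "N", strrep("A", 6)))
  expect_equal(nrow(t3), 0L)
})

test_that("planted SSRs are recovered with correct class and coordinates", {
  cfg <- sim_config("test")
  anc <- build_ancestor(cfg, seed = 21)
  found <- find_ssrs(anc$plastome)
  planted <- anc$truth$planted
  planted <- planted[planted$type == "ssr", ]
  for (i in seq_len(nrow(planted))) {
    hit <- found[found$start == planted$start[i] &
                   found$end == planted$end[i], ]
    expect_equal(nrow(hit), 1L, info = planted$detail[i])
    expect_equal(hit$length, planted$end[i] - planted$start[i])
  }
})

test_that("SSR set is invariant under genome rotation", {
  cfg <- sim_config("test")
  p <- build_ancestor(cfg, seed = 22)$plastome
  n <- nchar(p$seq)
  base <- find_ssrs(p)
  key <- function(t, shift = 0L)
    sort(paste(t$motif, t$copies, (t$start + shift) %% n))
  for (r in c(17L, 4321L, base$start[1L] + 3L)) {
    rot <- find_ssrs(rotate_plastome(p, r))
    expect_identical(key(rot, r), key(base), info = paste("rotation", r))
  }
})

test_that("dispersed detector matches planted repeats", {
  cfg <- sim_config("test")
  anc <- build_ancestor(cfg, seed = 23)
  res <- find_dispersed_repeats(anc$plastome, max_out = Inf)
  planted <- anc$truth$planted
  fw <- planted[planted$type == "forward", ]
  hit <- res[res$category == "forward" & res$start1 == fw$start[1L] &
               res$start2 == fw$start[2L], ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$length, 35L)
  expect_equal(hit$mismatches, 0L)
  pal <- planted[planted$type == "palindromic", ]
  hit2 <- res[res$category == "palindromic" & res$start1 == pal$start[1L] &
                res$start2 == pal$start[2L], ]
  expect_equal(nrow(hit2), 1L)
  expect_equal(hit2$length, 40L)
  # the whole-IR pair is one flagged palindromic hit
  expect_equal(sum(res$is_ir), 1L)
  ir_hit <- res[res$is_ir, ]
  expect_gte(ir_hit$length, cfg$ir_length)
  # every record self-verifies against its defining relation
  for (i in seq_len(nrow(res)))
    expect_true(verify_repeat_record(anc$plastome$seq, res[i, ]))
})

test_that("a 30-bp copy with 4 substitutions is rejected", {
  set.seed(30)
  bg <- random_dna(400)
  seg <- random_dna(30)
  seg2 <- strsplit(seg, "")[[1L]]
  pos <- c(3, 10, 18, 26)
  for (q in pos)
    seg2[q] <- setdiff(c("A", "C", "G", "T"), seg2[q])[1L]
  seq <- paste0(substr(bg, 1, 100), seg, substr(bg, 101, 300),
                paste(seg2, collapse = ""), substr(bg, 301, 400))
  res <- find_dispersed_repeats(seq)
  expect_false(any(res$category == "forward" & res$start1 == 100L &
                     res$start2 == 330L))
})

test_that("dispersed detector equals the brute-force oracle on random inputs", {
  # the full 50 x 2 kb equivalence runs in the acceptance suite; this is a
  # fast spot check including an N-containing input
  set.seed(31)
  for (rep in 1:4) {
    n <- sample(300:700, 1)
    s <- random_dna(n, gc = runif(1, 0.3, 0.6))
    if (rep == 4) substr(s, 50, 60) <- strrep("N", 11)
    got <- sort_repeats(find_dispersed_repeats(s, min_len = 12L,
                                               max_mismatch = 2L,
                                               max_out = Inf))
    want <- sort_repeats(oracle_dispersed(s, min_len = 12L,
                                          max_mismatch = 2L))
    expect_equal(got, want, info = paste("rep", rep))
  }
})

test_that("palindromic set is invariant under whole-genome revcomp", {
  set.seed(32)
  s <- random_dna(1500)
  a <- find_dispersed_repeats(s, min_len = 10L, max_mismatch = 1L,
                              max_out = Inf)
  b <- find_dispersed_repeats(revcomp(s), min_len = 10L, max_mismatch = 1L,
                              max_out = Inf)
  n <- nchar(s)
  pal_a <- a[a$category == "palindromic", ]
  pal_b <- b[b$category == "palindromic", ]
  # revcomp maps [s, e) to [n - e, n - s); pair order swaps
  key_a <- sort(paste(pal_a$start1, pal_a$end1, pal_a$start2, pal_a$end2))
  key_b <- sort(paste(n - pal_b$end2, n - pal_b$start2,
                      n - pal_b$end1, n - pal_b$start1))
  expect_identical(key_b, key_a)
})

test_that("tandem scoring matches the hand-computed boundary cases", {
  # exact 10-bp motif x 4: score 40 * 2 = 80, reported
  s1 <- paste0(strrep("T", 25), strrep("ACGGTACGTC", 4), strrep("G", 25))
  t1 <- find_tandem_repeats(s1)
  expect_equal(nrow(t1), 1L)
  expect_equal(t1$score, 80L)
  expect_equal(t1$period, 10L)
  expect_equal(t1$start, 25L)
  # exact 8-bp motif x 4: score 64 < 80, absent
  s2 <- paste0(strrep("T", 25), strrep("ACGGTACC", 4), strrep("G", 25))
  expect_equal(nrow(find_tandem_repeats(s2)), 0L)
  # 20-bp motif x 5 with one substitution: 99 * 2 - 7 = 191
  motif <- "ACGGTACGTCAAGGCTTACG"
  arr <- strrep(motif, 5)
  substr(arr, 47, 47) <- "T"   # position inside copy 3 (was A)
  s3 <- paste0(strrep("T", 25), arr, strrep("G", 25))
  t3 <- find_tandem_repeats(s3)
  expect_equal(nrow(t3), 1L)
  expect_equal(t3$score, 191L)
  expect_equal(t3$copies, 5)
  expect_equal(t3$consensus, motif)
})

test_that("planted tandem array is recovered exactly", {
  cfg <- sim_config("test")
  anc <- build_ancestor(cfg, seed = 24)
  tr <- anc$truth$planted
  tr <- tr[tr$type == "tandem", ]
  tt <- find_tandem_repeats(anc$plastome)
  hit <- tt[tt$start == tr$start & tt$period == 12L, ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$score, 120L)
})

test_that("summarize_repeats adds up and handles empty input", {
  z <- summarize_repeats(id = "empty")
  expect_equal(z$counts$total, 0L)
  expect_equal(sum(z$ssr_by_unit$count), 0L)

  cfg <- sim_config("test")
  anc <- build_ancestor(cfg, seed = 25)
  ssr <- find_ssrs(anc$plastome)
  disp <- find_dispersed_repeats(anc$plastome, max_out = Inf)
  tand <- find_tandem_repeats(anc$plastome)
  sm <- summarize_repeats(ssr, disp, tand, id = "anc")$counts
  expect_equal(sm$total,
               sm$dispersed_subtotal + sm$palindromic + sm$tandem)
  expect_equal(sm$dispersed_subtotal, sm$forward + sm$reverse + sm$complement)
  expect_gte(sm$forward, 1L)      # planted pair
  expect_gte(sm$palindromic, 2L)  # planted pair + IR hit
  expect_equal(sm$palindromic_excl_ir, sm$palindromic - 1L)
  expect_gte(sm$tandem, 1L)
  expect_equal(sm$n_ssr, nrow(ssr))
})
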