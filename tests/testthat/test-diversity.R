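test_that("site classification follows the SVS/PIP definitions", {
  inv <- classify_site(c("A", "A", "A", "A"))
  expect_identical(inv$status, "invariant")
  expect_identical(inv$n_diff_pairs, 0)

  sing <- classify_site(c("A", "A", "T", "-"))
  expect_identical(sing$status, "singleton")
  expect_identical(sing$n_valid, 3L)
  expect_identical(sing$n_pairs, 3)
  expect_identical(sing$n_diff_pairs, 2)

  pis <- classify_site(c("A", "A", "T", "T"))
  expect_identical(pis$status, "parsimony_informative")

  # gaps are never a fifth state: A,A,-,- is invariant, not informative
  expect_identical(classify_site(c("A", "A", "-", "-"))$status, "invariant")
  expect_identical(classify_site(c("A", "-", "-", "-"))$status, "invalid")
  # N behaves like a gap
  expect_identical(classify_site(c("A", "A", "T", "N"))$status, "singleton")
})

test_that("window pi is the ratio of sums, gap-aware", {
  aln <- alignment_matrix(c(s1 = "ACGT", s2 = "AC-T", s3 = "ATGA"))
  wp <- window_pi(aln, 0, 4)
  expect_equal(wp$pi, 0.4) # sum(diff pairs) 4 / sum(pairs) 10
  expect_equal(wp$pi, oracle_pi(c("ACGT", "AC-T", "ATGA")))

  ident <- alignment_matrix(c(a = "ACGTACGT", b = "ACGTACGT"))
  expect_equal(window_pi(ident, 0, 8)$pi, 0)

  nopairs <- alignment_matrix(c(a = "AAAA", b = "----"))
  expect_true(is.na(window_pi(nopairs, 0, 4)$pi))

  expect_error(window_pi(aln, 2, 2), "interval")
})

test_that("pi matches the brute-force pairwise oracle on random gapped alignments", {
  for (seed in 1:25) {
    set.seed(seed)
    nr <- sample(3:10, 1)
    nc <- sample(20:200, 1)
    rows <- vapply(seq_len(nr), function(i)
      paste(sample(c("A", "C", "G", "T", "-", "N"), nc, replace = TRUE,
                   prob = c(.22, .22, .22, .22, .08, .04)), collapse = ""),
      character(1))
    aln <- alignment_matrix(setNames(rows, paste0("s", seq_len(nr))))
    got <- window_pi(aln, 0, nc)$pi
    want <- oracle_pi(rows)
    if (is.na(want)) expect_true(is.na(got)) else
      expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("sliding windows advance by the step and cover the tail", {
  aln <- alignment_matrix(setNames(
    rep(paste(rep("A", 1000), collapse = ""), 3), paste0("s", 1:3)))
  w <- sliding_windows(aln, 600, 200)
  expect_identical(w$start, seq(0L, 800L, by = 200L))
  expect_identical(w$end, pmin(w$start + 600L, 1000L))
  expect_true(all(w$pi == 0))
  expect_true(all(w$n_pis == 0L))
  expect_equal(w$midpoint, (w$start + w$end) / 2)
  expect_warning(sliding_windows(aln, 100, 200), "win_len < step")
})

test_that("the max-pi window overlaps a planted hotspot", {
  sim <- simulate_alignment(list(
    n_samples = 12, n_columns = 8000, p_background = 0.001,
    p_hotspot = 0.06, hotspots = list(c(3100, 3800)), p_gap = 0.01,
    seed = 17))
  w <- sliding_windows(sim$aln)
  top <- w[which.max(w$pi), ]
  expect_lt(top$start, 3800)
  expect_gt(top$end, 3100)
})

test_that("qualifying windows merge by consecutive window index", {
  # synthetic window table: indices 11..13 qualify (win 600 / step 200)
  aln <- alignment_matrix(setNames(
    rep(paste(rep("A", 4000), collapse = ""), 4), paste0("s", 1:4)))
  w <- sliding_windows(aln, 600, 200)
  w$pi <- 0; w$n_pis <- 0L
  w$pi[11:13] <- 0.02; w$n_pis[11:13] <- 30L
  reg <- merge_hotspots(w, aln)
  expect_identical(nrow(reg), 1L)
  expect_identical(reg$start, 2000L) # window index 11 starts at 10 * 200
  expect_identical(reg$end, 3000L)   # window index 13 spans [2400, 3000)
  expect_identical(reg$length, 1000L)

  # strict thresholds: boundary-equal windows do not qualify
  w$pi[11:13] <- 0.01
  expect_identical(nrow(merge_hotspots(w, aln)), 0L)
  w$pi[11:13] <- 0.02; w$n_pis[11:13] <- 25L
  expect_identical(nrow(merge_hotspots(w, aln)), 0L)
})

test_that("region statistics are recomputed on the merged span, not averaged", {
  sim <- simulate_alignment(list(
    n_samples = 10, n_columns = 6000, p_background = 0.002,
    p_hotspot = 0.08, hotspots = list(c(2000, 3200)), p_gap = 0.02,
    seed = 23))
  w <- sliding_windows(sim$aln)
  reg <- merge_hotspots(w, sim$aln)
  expect_gte(nrow(reg), 1L)
  r <- reg[which.max(reg$length), ]
  direct <- window_pi(sim$aln, r$start, r$end)
  expect_equal(r$pi, direct$pi)
  expect_identical(r$n_pip, direct$n_pis)
  expect_identical(r$n_svs, direct$n_singleton)
  # ratio of sums, not mean of window pis
  covered <- w[w$start >= r$start & w$end <= r$end, ]
  expect_false(isTRUE(all.equal(r$pi, mean(covered$pi))))
})

test_that("the estimator ignores all-gap rows and row order", {
  rows <- c(a = "ACGTTGCA-A", b = "ACTTTGCAGA", c = "AAGT-GCAGT")
  aln <- alignment_matrix(rows)
  base <- window_pi(aln, 0, 10)
  plus_gap <- alignment_matrix(c(rows, d = "----------"))
  expect_equal(window_pi(plus_gap, 0, 10)$pi, base$pi)
  perm <- alignment_matrix(rows[c(3, 1, 2)])
  expect_equal(window_pi(perm, 0, 10), base)
})

test_that("pi concatenates through the ratio-of-sums identity", {
  sim <- simulate_alignment(list(
    n_samples = 8, n_columns = 900, p_background = 0.02, p_hotspot = 0.02,
    hotspots = list(), p_gap = 0.05, seed = 5))
  st <- site_stats(sim$aln)
  seg <- function(a, b) c(sum(st$n_diff_pairs[(a + 1):b]),
                          sum(st$n_pairs[(a + 1):b]))
  ab <- seg(0, 300); bc <- seg(300, 900)
  expect_equal(window_pi(sim$aln, 0, 900)$pi,
               (ab[1] + bc[1]) / (ab[2] + bc[2]))
})

test_that("raising the hotspot rate never loses qualifying windows", {
  n_qual <- vapply(c(0.02, 0.04, 0.08, 0.12), function(p) {
    sim <- simulate_alignment(list(
      n_samples = 12, n_columns = 5000, p_background = 0.001,
      p_hotspot = p, hotspots = list(c(1500, 2600)), p_gap = 0.01,
      seed = 99))
    w <- sliding_windows(sim$aln)
    sum(!is.na(w$pi) & w$pi > 0.01 & w$n_pis > 25)
  }, numeric(1))
  expect_true(all(diff(n_qual) >= 0))
})

test_that("regions are labelled by flanking genes via reference projection", {
  # reference row with 5 leading gap columns, genes gA [0,40) and gB [100,140)
  ref <- paste0(strrep("-", 5), random_seq(200, 7))
  other <- random_seq(205, 8)
  aln <- alignment_matrix(c(REF = ref, OTH = other))
  genome <- annotated_genome("REF", substr(ref, 6, 205), features = data.frame(
    name = c("gA", "gB"), kind = "gene", strand = "+",
    start = c(0L, 100L), end = c(40L, 140L), stringsAsFactors = FALSE))

  # column 0 maps to reference 0 only after the 5 gap columns
  expect_identical(project_to_reference(aln, "REF", 0, 6), c(0L, 1L))
  expect_identical(project_to_reference(aln, "REF", 5, 6), c(0L, 1L))

  # a region inside the intergenic spacer gets "gA-gB"
  reg <- list(start = 50 + 5, end = 90 + 5)
  expect_identical(name_region(reg, genome, aln, "REF"), "gA-gB")
  # a region inside a gene gets the gene name
  expect_identical(name_region(list(start = 10 + 5, end = 30 + 5),
                               genome, aln, "REF"), "gA")
  # region fully inside a reference gap is unplaced
  expect_identical(name_region(list(start = 0, end = 5), genome, aln, "REF"),
                   "unplaced")
})
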