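embed_in_random <- function(parts, seed, pad = 60L) {
  # paste parts with random padding between them, returning the sequence and
  # the 0-based start of each part; the pad base touching a part is chosen to
  # differ from both part ends so a planted run cannot extend by chance
  set.seed(seed)
  pads <- replicate(length(parts) + 1L,
                    random_seq(pad, sample.int(1e6, 1)))
  guard <- function(part) {
    b <- c(substr(part, 1, 1), substr(part, nchar(part), nchar(part)))
    setdiff(c("A", "C", "G", "T"), b)[1]
  }
  seq <- pads[1]
  starts <- integer(length(parts))
  for (i in seq_along(parts)) {
    g <- guard(parts[i])
    substr(seq, nchar(seq), nchar(seq)) <- g
    starts[i] <- nchar(seq)
    seq <- paste0(seq, parts[i], pads[i + 1L])
    substr(seq, starts[i] + nchar(parts[i]) + 1L,
           starts[i] + nchar(parts[i]) + 1L) <- g
  }
  list(seq = seq, starts = starts)
}

test_that("SSR copy-number thresholds are enforced exactly", {
  # A x 10 is below the mononucleotide threshold, A x 11 meets it
  e10 <- embed_in_random(strrep("A", 10), seed = 1)
  e11 <- embed_in_random(strrep("A", 11), seed = 1)
  s10 <- find_ssrs(e10$seq)
  s11 <- find_ssrs(e11$seq)
  expect_false(any(s10$motif == "A" & s10$copies >= 10))
  hit <- s11[s11$start == e11$starts[1], ]
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$ssr_type, "p1")
  expect_identical(hit$copies, 11L)

  # (AT) x 6 at the dinucleotide boundary
  e <- embed_in_random(strrep("AT", 6), seed = 2)
  s <- find_ssrs(e$seq)
  hit <- s[s$start == e$starts[1], ]
  expect_identical(hit$ssr_type, "p2")
  expect_identical(hit$copies, 6L)
  expect_identical(hit$end - hit$start, 12L)
})

test_that("runs are assigned to the smallest generating unit and N breaks runs", {
  e <- embed_in_random(strrep("A", 12), seed = 3)
  s <- find_ssrs(e$seq)
  expect_false(any(s$motif == "AA")) # poly-A is mono, never di
  expect_true(any(s$start == e$starts[1] & s$unit_len == 1))

  withN <- paste0(strrep("A", 6), "N", strrep("A", 6))
  e2 <- embed_in_random(withN, seed = 4)
  s2 <- find_ssrs(e2$seq)
  expect_false(any(s2$unit_len == 1 & s2$copies >= 11))
})

test_that("nearby SSRs merge into one compound record", {
  block <- paste0(strrep("AT", 6), random_seq(40, 9), strrep("A", 11))
  e <- embed_in_random(block, seed = 5, pad = 200L)
  merged <- find_ssrs(e$seq, compound_max_gap = 100L, compound = TRUE)
  split <- find_ssrs(e$seq, compound = FALSE)
  in_block <- function(tab) tab[tab$start >= e$starts[1] &
                                  tab$end <= e$starts[1] + nchar(block), ]
  expect_identical(nrow(in_block(merged)), 1L)
  expect_identical(in_block(merged)$ssr_type, "compound")
  expect_gte(nrow(in_block(split)), 2L)
  # far-apart SSRs stay separate
  far <- find_ssrs(e$seq, compound_max_gap = 10L)
  expect_gte(nrow(in_block(far)), 2L)
})

test_that("SSR scanner agrees with the brute-force definition on random sequences", {
  for (seed in 1:6) {
    seq <- paste0(random_seq(600, seed, gc = 0.25),
                  strrep("A", 11), random_seq(50, seed + 50),
                  strrep("GAT", 5), random_seq(50, seed + 100),
                  strrep("TA", 7))
    got <- find_ssrs(seq, compound = FALSE)
    want <- oracle_ssrs(seq)
    key <- function(d) sort(paste(d$motif, d$start, d$end, d$copies))
    expect_identical(key(got), key(want))
  }
})

test_that("no SSR can be extended by one unit in either direction", {
  seq <- paste0(random_seq(800, 77, gc = 0.2), strrep("TA", 8),
                random_seq(100, 78))
  tab <- find_ssrs(seq, compound = FALSE)
  ch <- strsplit(seq, "")[[1]]
  for (i in seq_len(nrow(tab))) {
    u <- tab$unit_len[i]; s <- tab$start[i]; e <- tab$end[i]
    motif <- tab$motif[i]
    if (s - u >= 0)
      expect_false(paste(ch[(s - u + 1):s], collapse = "") == motif)
    if (e + u <= nchar(seq))
      expect_false(paste(ch[(e + 1):(e + u)], collapse = "") ==
                     substr(seq, s + 1, s + u))
  }
})

test_that("planted long repeats of each class are found at exact truth coordinates", {
  for (cl in c("forward", "reverse", "complement", "palindromic")) {
    sim <- simulate_plastome(list(
      lsc_len = 2500L, ssc_len = 700L, ir_len = 1000L,
      seed = 60L + match(cl, c("forward", "reverse", "complement",
                               "palindromic")),
      planted_repeats = list(list(class = cl, length = 40,
                                  regions = c("LSC", "SSC")))))
    part <- detect_inverted_repeats(sim$genome, 900L)
    tab <- find_long_repeats(sim$genome, min_len = 30L, classes = cl,
                             part = part)
    tr <- sim$truth$repeats
    expect_identical(nrow(tab), 1L)
    expect_identical(tab$length, 40L)
    expect_identical(tab$pos1, tr$pos1)
    expect_identical(tab$pos2, tr$pos2)
    expect_identical(tab$class, cl)
  }
})

test_that("a seeded random sequence with no planted repeat yields nothing", {
  seq <- random_seq(5000, 123)
  tab <- find_long_repeats(seq, min_len = 30L)
  expect_identical(nrow(tab), 0L)
})

test_that("long-repeat scanner matches the quadratic oracle", {
  for (seed in 1:3) {
    base <- random_seq(500, 900 + seed)
    block <- random_seq(25, 950 + seed)
    seq <- paste0(base, block, random_seq(80, 980 + seed), block,
                  random_seq(60, 990 + seed), revcomp(block))
    for (cl in c("forward", "reverse", "complement", "palindromic")) {
      got <- find_long_repeats(seq, min_len = 14L, classes = cl)
      want <- oracle_long_repeats(seq, 14L, cl)
      key <- function(d) if (is.null(d) || !nrow(d)) character(0) else
        sort(paste(d$length, d$pos1, d$pos2))
      expect_identical(key(got), key(want),
                       label = paste("class", cl, "seed", seed))
    }
  }
})

test_that("repeat classes are symmetric under reverse complement", {
  sim <- simulate_plastome(list(
    lsc_len = 3000L, ssc_len = 800L, ir_len = 1000L, seed = 31L,
    planted_repeats = list(
      list(class = "forward", length = 45, regions = c("LSC", "SSC")),
      list(class = "reverse", length = 38, regions = c("LSC", "LSC")),
      list(class = "palindromic", length = 36, regions = c("SSC", "SSC")),
      list(class = "complement", length = 33, regions = c("LSC", "SSC")))))
  # scan plain sequences (no partition) so the genome-scale IR pair is the
  # same object in both orientations
  fwd <- find_long_repeats(sim$genome$seq, min_len = 30L)
  rc <- find_long_repeats(revcomp(sim$genome$seq), min_len = 30L)
  key <- function(d) sort(paste(d$class, d$length))
  expect_identical(key(fwd), key(rc))
})

test_that("region assignment covers LSC, IRb and SSC and skips the IRa copy", {
  sim <- simulate_plastome(list(
    lsc_len = 3000L, ssc_len = 800L, ir_len = 1000L, seed = 41L,
    planted_ssrs = list(list(motif = "AAG", copies = 6, region = "IRb")),
    planted_repeats = list(
      list(class = "forward", length = 40, regions = c("LSC", "SSC")))))
  part <- detect_inverted_repeats(sim$genome, 900L)
  ssrs <- find_ssrs(sim$genome, part = part)
  tr <- sim$truth$ssrs
  hit <- ssrs[ssrs$start == tr$start, ]
  expect_identical(hit$region, "IRb")
  # the IRa mirror of an IRb SSR appears as its own record in IRa
  expect_true(any(ssrs$region == "IRa" & ssrs$unit_len == 3))
  reps <- find_long_repeats(sim$genome, min_len = 30L, part = part)
  prt <- sim$truth$repeats
  got <- reps[reps$class == "forward" & reps$length == 40, ]
  expect_identical(got$pos1, prt$pos1)
  expect_identical(got$pos2, prt$pos2)
  expect_identical(c(got$region1, got$region2), c("LSC", "SSC"))
})
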