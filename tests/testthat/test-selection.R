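test_that("back-translation expands codons, gaps and strips terminal stops", {
  ca <- back_translate(c(s1 = "MA"), c(s1 = "ATGGCT"))
  expect_identical(ca$codons[1, ], c("ATG", "GCT"))

  ca2 <- back_translate(c(s1 = "M-A", s2 = "MKA"),
                        c(s1 = "ATGGCT", s2 = "ATGAAAGCATAA"))
  expect_identical(ca2$codons[1, ], c("ATG", "---", "GCT"))
  expect_identical(ca2$codons[2, ], c("ATG", "AAA", "GCA")) # TAA stripped

  expect_error(back_translate(c(s1 = "MV"), c(s1 = "ATGGCA")),
               "mismatch for 's1' at position 2")
  expect_error(back_translate(c(s1 = "MA"), c(s1 = "ATGGC")),
               "divisible by 3")
  expect_error(codon_alignment(matrix("TAA", 1, 1,
                                      dimnames = list("x", NULL))),
               "stop codon")
})

test_that("F3x4 frequencies are a renormalised positional product", {
  u <- uniform_codon_freqs()
  expect_identical(length(u), 61L)
  expect_equal(sum(u), 1)
  expect_equal(unname(u), rep(1 / 61, 61))

  sk <- skewed_codon_freqs()
  expect_equal(sum(sk), 1)
  expect_true(all(sk > 0))
  # frequencies estimated from a simulated alignment converge on the truth
  tr <- ape::read.tree(text = "(A:0.05,B:0.05);")
  caln <- simulate_codon_alignment(tr, 2, 0.5, sk, 20000, seed = 2)
  est <- f3x4_frequencies(caln)
  expect_lt(max(abs(est - sk)), 0.01)
})

test_that("the GY94 generator is reversible, scaled, and omega-sensitive", {
  fr <- skewed_codon_freqs()
  Q <- gy94_rates(kappa = 2.5, omega = 0.4, freqs = fr)
  expect_equal(unname(rowSums(Q)), rep(0, 61), tolerance = 1e-12)
  # detailed balance pi_i q_ij = pi_j q_ji
  A <- unname(fr * Q)
  expect_equal(A, t(A), tolerance = 1e-12)
  # unit expected substitution rate
  expect_equal(-sum(fr * diag(Q)), 1, tolerance = 1e-12)
  # omega = 0 silences all nonsynonymous moves
  Q0 <- gy94_rates(2.5, 0, fr)
  p <- plastome:::.codon_env$pairs
  ns <- p[!p$syn, ]
  expect_true(all(Q0[cbind(ns$i, ns$j)] == 0))
  expect_error(gy94_rates(2, 0.5, rep(0, 61)), "degenerate")
})

test_that("pruning equals exhaustive ancestral summation on small trees", {
  fr <- skewed_codon_freqs()
  trees <- c("(A:0.15,B:0.05);",
             "(A:0.1,B:0.2,C:0.05);",
             "((A:0.1,B:0.15):0.07,C:0.2,D:0.05);")
  for (tt in trees) {
    tr <- ape::read.tree(text = tt)
    caln <- simulate_codon_alignment(tr, 2, 0.6, fr, 5, seed = 11)
    # plant a gap codon to exercise missing data
    caln$codons[1, 2] <- "---"
    for (om in c(0.1, 1.3)) {
      got <- log_likelihood(caln, tr, kappa = 2.2, omega_map = om,
                            freqs = fr)
      want <- oracle_codon_lnl(caln, tr, 2.2, om, fr)
      expect_equal(got, want, tolerance = 1e-10)
    }
  }
})

test_that("identical sequences on a zero-length tree give the closed form", {
  fr <- uniform_codon_freqs()
  tr <- ape::read.tree(text = "(A:0,B:0,C:0);")
  cods <- sense_codons()[c(1, 5, 61, 30)]
  m <- matrix(rep(cods, each = 3), nrow = 3,
              dimnames = list(c("A", "B", "C"), NULL))
  caln <- codon_alignment(m)
  expect_equal(log_likelihood(caln, tr, 2, 0.5, fr),
               sum(log(fr[cods])))
})

test_that("the likelihood is invariant to rerooting (pulley principle)", {
  fr <- skewed_codon_freqs()
  tr <- ape::read.tree(text = "((A:0.1,B:0.15):0.07,(C:0.2,D:0.05):0.03,E:0.1);")
  caln <- simulate_codon_alignment(tr, 2, 0.4, fr, 40, seed = 3)
  base <- log_likelihood(caln, tr, 2, 0.4, fr)
  for (out in c("A", "C", "E")) {
    re <- ape::unroot(ape::root(tr, outgroup = out, resolve.root = TRUE))
    expect_equal(log_likelihood(caln, re, 2, 0.4, fr), base,
                 tolerance = 1e-8)
  }
})

test_that("foreground clade edges include the stem branch", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1,E:1);")
  fe <- foreground_edges(tr, c("A", "B"))
  expect_identical(length(fe), 3L) # A, B and the stem of (A,B)
  tips <- tr$edge[fe, 2]
  expect_true(all(match(c("A", "B"), tr$tip.label) %in% tips))
  expect_identical(length(foreground_edges(tr, "E")), 1L)
})

test_that("branch-model fits recover simulation parameters", {
  fr <- skewed_codon_freqs()
  tr <- ape::read.tree(
    text = "((A:0.08,B:0.08):0.04,(C:0.08,D:0.08):0.04,E:0.1);")
  caln <- simulate_codon_alignment(tr, kappa = 2, omega = 0.2, freqs = fr,
                                   n_codons = 800, seed = 7)
  fit <- fit_branch_model(caln, tr, "one_ratio", freqs = fr, seed = 1)
  expect_gt(fit$omega[["all"]], 0.13)
  expect_lt(fit$omega[["all"]], 0.27)
  expect_gt(fit$kappa, 1.3)
  expect_lt(fit$kappa, 3)

  # nesting: the alternative can never fit worse than the null
  alt <- fit_branch_model(caln, tr, "two_ratio", foreground = c("A", "B"),
                          freqs = fr, seed = 1)
  expect_gte(alt$lnL, fit$lnL - 1e-6)
})

test_that("the LRT uses the chi-square tail and the verdict rules", {
  mkfit <- function(model, lnL, omega) {
    structure(list(model = model, lnL = lnL, kappa = 2, omega = omega,
                   branch_lengths = numeric(0), foreground = integer(0)),
              class = "branch_model_fit")
  }
  null <- mkfit("one_ratio", -1000, c(all = 0.3))

  same <- lrt(null, mkfit("two_ratio", -1000,
                          c(background = 0.3, foreground = 0.3)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)

  # 3.841459 is the 95% point of chi-square with 1 df
  crit <- lrt(null, mkfit("two_ratio", -1000 + 3.841459 / 2,
                          c(background = 0.3, foreground = 0.9)))
  expect_equal(crit$p, 0.05, tolerance = 1e-6)

  pos <- lrt(null, mkfit("two_ratio", -996,
                         c(background = 0.3, foreground = 1.4)))
  expect_true(pos$significant)
  expect_true(pos$positive_selection)
  expect_false(pos$fast_evolving)

  fast <- lrt(null, mkfit("two_ratio", -996,
                          c(background = 0.3, foreground = 0.8)))
  expect_true(fast$fast_evolving)
  expect_false(fast$positive_selection)

  ns <- lrt(null, mkfit("two_ratio", -999.5,
                        c(background = 0.3, foreground = 1.4)))
  expect_false(ns$significant)
  expect_false(ns$positive_selection)
})
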