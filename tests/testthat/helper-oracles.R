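# Independent brute-force oracles used to check the fast implementations.

# --- nucleotide diversity: explicit loop over all row pairs and columns -----
oracle_pi <- function(rows) {
  # rows: character vector of equal-length aligned sequences
  m <- do.call(rbind, strsplit(toupper(rows), ""))
  valid <- matrix(m %in% c("A", "C", "G", "T"), nrow = nrow(m))
  D <- 0; C <- 0
  n <- nrow(m)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- valid[i, ] & valid[j, ]
    C <- C + sum(ok)
    D <- D + sum(ok & m[i, ] != m[j, ])
  }
  if (C == 0) NA_real_ else D / C
}

# --- SSRs: direct definition, substring comparisons only --------------------
oracle_ssrs <- function(seq, thresholds = c(`1` = 11L, `2` = 6L, `3` = 5L,
                                            `4` = 4L, `5` = 3L, `6` = 3L)) {
  seq <- toupper(seq)
  n <- nchar(seq)
  ch <- strsplit(seq, "")[[1]]
  valid <- ch %in% c("A", "C", "G", "T")
  out <- NULL
  for (u in 1:6) {
    thr <- thresholds[[as.character(u)]]
    for (i in seq_len(n)) {
      if (i + u * thr - 1L > n) break
      motif <- substr(seq, i, i + u - 1L)
      if (!all(valid[i:(i + u - 1L)])) next
      # smallest generating unit
      per <- FALSE
      for (d in seq_len(u - 1L)) if (u %% d == 0L &&
          strrep(substr(motif, 1, d), u / d) == motif) per <- TRUE
      if (per) next
      # left-maximality: the periodic run must not extend one position left
      if (i > 1L && valid[i - 1L] && ch[i - 1L] == ch[i - 1L + u]) next
      copies <- 1L
      while (i + (copies + 1L) * u - 1L <= n &&
             substr(seq, i + copies * u, i + (copies + 1L) * u - 1L) == motif &&
             all(valid[(i + copies * u):(i + (copies + 1L) * u - 1L)]))
        copies <- copies + 1L
      if (copies < thr) next
      out <- rbind(out, data.frame(motif = motif, unit_len = u,
                                   copies = copies, start = i - 1L,
                                   end = i - 1L + copies * u,
                                   stringsAsFactors = FALSE))
    }
  }
  out
}

# --- long repeats: quadratic common-extension matrix ------------------------
oracle_long_repeats <- function(seq, min_len, class) {
  a <- strsplit(toupper(seq), "")[[1]]
  n <- length(a)
  b <- switch(class,
              forward = a,
              reverse = rev(a),
              complement = unname(c(A = "T", C = "G", G = "C", T = "A",
                                    N = "N")[a]),
              palindromic = rev(unname(c(A = "T", C = "G", G = "C", T = "A",
                                         N = "N")[a])))
  oka <- a %in% c("A", "C", "G", "T")
  okb <- b %in% c("A", "C", "G", "T")
  # M[i, j] = length of the exact common run of a starting i, b starting j
  M <- matrix(0L, n + 1L, n + 1L)
  for (i in n:1) {
    hit <- (a[i] == b) & oka[i] & okb
    M[i, 1:n] <- ifelse(hit, M[i + 1L, 2:(n + 1L)] + 1L, 0L)
  }
  res <- NULL
  for (i in 1:n) for (j in 1:n) {
    L <- M[i, j]
    if (L < min_len) next
    if (i > 1L && j > 1L && M[i - 1L, j - 1L] > 0L) next # not maximal
    # map b-start to forward-strand coordinates of the second copy
    j2 <- switch(class,
                 forward = j,
                 complement = j,
                 reverse = n - j - L + 2L,
                 palindromic = n - j - L + 2L)
    p1 <- min(i, j2) - 1L
    p2 <- max(i, j2) - 1L
    if (p1 == p2) next # self pair
    res <- rbind(res, data.frame(class = class, length = L,
                                 pos1 = p1, pos2 = p2,
                                 stringsAsFactors = FALSE))
  }
  if (is.null(res)) return(res)
  res <- unique(res)
  if (class %in% c("forward", "complement")) {
    # each unordered pair appears at (i,j) and (j,i)
    res <- unique(res)
  }
  res[order(res$pos1, res$pos2), , drop = FALSE]
}

# --- codon pruning: exhaustive summation over internal node states ----------
oracle_codon_lnl <- function(caln, tree, kappa, omega, freqs) {
  tr <- ape::reorder.phylo(tree, "postorder")
  Q <- gy94_rates(kappa, omega, freqs)
  P <- lapply(seq_len(nrow(tr$edge)),
              function(e) ape::matexpo(Q * tr$edge.length[e]))
  ntip <- length(tr$tip.label)
  internal <- sort(unique(tr$edge[, 1]))
  states <- matrix(plastome:::codon_states(caln$codons),
                   nrow = length(caln$ids))
  states <- states[match(tr$tip.label, caln$ids), , drop = FALSE]
  pi <- freqs / sum(freqs)
  root <- tr$edge[nrow(tr$edge), 1]
  grid <- as.matrix(expand.grid(rep(list(1:61), length(internal))))
  total <- 0
  for (site in seq_len(ncol(states))) {
    lik <- pi[grid[, match(root, internal)]]
    for (e in seq_len(nrow(tr$edge))) {
      par <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
      ps <- grid[, match(par, internal)]
      if (ch <= ntip) {
        st <- states[ch, site]
        if (st == 0L) next # missing tip: sums to 1
        lik <- lik * P[[e]][cbind(ps, st)]
      } else {
        cs <- grid[, match(ch, internal)]
        lik <- lik * P[[e]][cbind(ps, cs)]
      }
    }
    total <- total + log(sum(lik))
  }
  total
}

# --- misc helpers -----------------------------------------------------------
random_seq <- function(n, seed, gc = 0.4) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

uniform_codon_freqs <- function() {
  f3x4_frequencies(pos_freqs = matrix(0.25, 3, 4,
                                      dimnames = list(NULL,
                                                      c("T", "C", "A", "G"))))
}

skewed_codon_freqs <- function() {
  f3x4_frequencies(pos_freqs = matrix(
    c(0.30, 0.20, 0.30, 0.20,
      0.25, 0.25, 0.25, 0.25,
      0.20, 0.30, 0.20, 0.30), 3, 4, byrow = TRUE,
    dimnames = list(NULL, c("T", "C", "A", "G"))))
}
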