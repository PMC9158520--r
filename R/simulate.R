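# Seed-deterministic generators emulating the pipeline's inputs:
# quadripartite plastomes with planted SSRs/repeats/genes, alignments with
# planted diversity hotspots, and codon alignments evolved under GY94.

random_dna <- function(n, gc = 0.36) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p)
}

other_base <- function(forbidden) {
  # first base (alphabetical) not in `forbidden`
  setdiff(c("A", "C", "G", "T"), forbidden)[1]
}

comp1 <- function(b) c(A = "T", C = "G", G = "C", T = "A", N = "N")[b]

#' Simulate a quadripartite plastome
#'
#' Generates a circular genome with LSC, IRb, SSC and IRa regions (IRa is the
#' exact reverse complement of IRb), plants SSRs, dispersed repeats and gene
#' features at recorded coordinates, and returns the genome together with a
#' ground-truth table for oracle tests. Flanking bases around planted
#' elements are adjusted so that the planted repeat cannot be extended, which
#' keeps the truth coordinates exact. Fully reproducible from `spec$seed`.
#'
#' @param spec list with fields `lsc_len`, `ssc_len`, `ir_len` (bp;
#'   `lsc_len > ssc_len`), `gc` (target fraction, default 0.36), `seed`, and
#'   optionally `planted_ssrs` (list of `list(motif=, copies=, region=)`),
#'   `planted_repeats` (list of `list(class=, length=, regions=c(r1, r2))`),
#'   `planted_genes` (list of `list(name=, region=, offset=, length=,
#'   strand=)`). Regions are `"LSC"`, `"IRb"`, `"SSC"`.
#' @return list with `genome` (an [annotated_genome()]), `truth` (list of
#'   data frames `ssrs`, `repeats`, `genes`) and `region_lengths`.
#' @export
simulate_plastome <- function(spec) {
  stopifnot(spec$lsc_len > spec$ssc_len, spec$ssc_len > 0, spec$ir_len > 0)
  gc <- if (is.null(spec$gc)) 0.36 else spec$gc
  set.seed(spec$seed)
  L <- as.integer(spec$lsc_len); I <- as.integer(spec$ir_len)
  S <- as.integer(spec$ssc_len)
  n <- L + 2L * I + S
  reg_off <- c(LSC = 0L, IRb = L, SSC = L + I)
  reg_len <- c(LSC = L, IRb = I, SSC = S)
  chars <- random_dna(L + I + S, gc) # LSC + IRb + SSC; IRa appended later

  cursor <- c(LSC = max(10L, L %/% 10L), IRb = max(10L, I %/% 10L),
              SSC = max(10L, S %/% 10L))
  place <- function(region, len) {
    if (!region %in% names(reg_off)) stop("unknown region: ", region)
    at <- cursor[[region]]
    if (at + len + 2L > reg_len[[region]])
      stop("planted elements overlap or do not fit in ", region)
    cursor[[region]] <<- at + len + 150L
    reg_off[[region]] + at # 0-based start within the concatenated sequence
  }

  ssr_truth <- rep_truth <- gene_truth <- NULL
  for (ps in spec$planted_ssrs) {
    u <- nchar(ps$motif)
    len <- as.integer(u * ps$copies)
    s0 <- place(ps$region, len)
    chars[(s0 + 1L):(s0 + len)] <- strsplit(strrep(toupper(ps$motif),
                                                   ps$copies), "")[[1]]
    # break periodic extension on both flanks
    chars[s0] <- other_base(chars[s0 + u])
    chars[s0 + len + 1L] <- other_base(chars[s0 + len + 1L - u])
    ssr_truth <- rbind(ssr_truth, data.frame(
      motif = toupper(ps$motif), unit_len = as.integer(u),
      copies = as.integer(ps$copies),
      start = as.integer(s0), end = as.integer(s0 + len),
      region = ps$region, stringsAsFactors = FALSE))
  }
  for (pr in spec$planted_repeats) {
    cl <- match.arg(pr$class, c("forward", "reverse", "complement",
                                "palindromic"))
    len <- as.integer(pr$length)
    block <- random_dna(len, gc)
    copy2 <- switch(cl,
                    forward = block,
                    reverse = rev(block),
                    complement = unname(comp1(block)),
                    palindromic = unname(comp1(rev(block))))
    s1 <- place(pr$regions[1], len)
    s2 <- place(pr$regions[2], len)
    chars[(s1 + 1L):(s1 + len)] <- block
    chars[(s2 + 1L):(s2 + len)] <- copy2
    # break extension: each end of copy1 pairs with a specific end of copy2
    lf1 <- s1; rf1 <- s1 + len + 1L         # 1-based flank positions
    lf2 <- s2; rf2 <- s2 + len + 1L
    if (cl == "forward") {
      chars[lf2] <- other_base(chars[lf1])
      chars[rf2] <- other_base(chars[rf1])
    } else if (cl == "complement") {
      chars[lf2] <- other_base(comp1(chars[lf1]))
      chars[rf2] <- other_base(comp1(chars[rf1]))
    } else if (cl == "reverse") {
      chars[rf2] <- other_base(chars[lf1])
      chars[lf2] <- other_base(chars[rf1])
    } else {
      chars[rf2] <- other_base(comp1(chars[lf1]))
      chars[lf2] <- other_base(comp1(chars[rf1]))
    }
    rep_truth <- rbind(rep_truth, data.frame(
      class = cl, length = len,
      pos1 = as.integer(min(s1, s2)), pos2 = as.integer(max(s1, s2)),
      region1 = pr$regions[1], region2 = pr$regions[2],
      stringsAsFactors = FALSE))
  }
  for (pg in spec$planted_genes) {
    s0 <- reg_off[[pg$region]] + pg$offset
    glen <- pg$length
    # genes may run past their region boundary (junction-straddling genes)
    stopifnot(pg$offset >= 0, s0 + glen <= n)
    gene_truth <- rbind(gene_truth, data.frame(
      name = pg$name, kind = "gene",
      strand = if (is.null(pg$strand)) "+" else pg$strand,
      start = as.integer(s0), end = as.integer(s0 + glen),
      stringsAsFactors = FALSE))
  }

  # pin the IR boundaries: the maximal inverted repeat must be exactly the
  # planted IR, so the bases flanking it must not pair under the
  # reverse-complement relation (left of IRb wraps onto the LSC start)
  chars[L] <- other_base(comp1(chars[1]))
  chars[L + I + 1L] <- other_base(comp1(chars[L + I + S]))

  body <- paste(chars, collapse = "")
  irb <- substr(body, L + 1L, L + I)
  seq <- paste0(body, revcomp_cpp(irb))
  feats <- if (is.null(gene_truth)) empty_features() else gene_truth
  # mirror IRb genes into IRa
  if (!is.null(gene_truth)) {
    in_irb <- gene_truth$start >= L & gene_truth$end <= L + I
    if (any(in_irb)) {
      mir <- gene_truth[in_irb, , drop = FALSE]
      s <- mir$start; e <- mir$end
      mir$start <- n - e
      mir$end <- n - s
      mir$strand <- ifelse(mir$strand == "+", "-", "+")
      feats <- rbind(feats, mir)
    }
  }
  genome <- annotated_genome(
    id = sprintf("SIM%06d", spec$seed %% 1000000L),
    seq = seq, circular = TRUE, features = feats)
  list(genome = genome,
       truth = list(ssrs = ssr_truth, repeats = rep_truth,
                    genes = gene_truth),
       region_lengths = c(lsc = L, irb = I, ssc = S, ira = I))
}

#' Simulate an alignment with planted diversity hotspots
#'
#' Draws an ancestral row, then mutates every sample independently
#' per-column (star-tree-like, sufficient for a tree-free diversity
#' estimator): the substitution probability is `p_background` outside and
#' `p_hotspot` inside the hotspot intervals, the substituted base is uniform
#' over the three alternatives, and gaps are inserted i.i.d. with `p_gap`.
#'
#' @param spec list with `n_samples`, `n_columns`, `p_background`,
#'   `p_hotspot`, `hotspots` (list of `c(start, end)` 0-based half-open
#'   column intervals), `p_gap`, `seed`.
#' @return list with `aln` (an [alignment_matrix()]) and `truth` (data frame
#'   of hotspot intervals).
#' @export
simulate_alignment <- function(spec) {
  stopifnot(spec$n_samples >= 2, spec$n_columns >= 1)
  set.seed(spec$seed)
  m <- spec$n_columns
  p <- rep(spec$p_background, m)
  hs <- spec$hotspots
  if (length(hs)) for (h in hs) {
    stopifnot(h[1] >= 0, h[2] <= m, h[1] < h[2])
    p[(h[1] + 1L):h[2]] <- spec$p_hotspot
  }
  p_gap <- if (is.null(spec$p_gap)) 0 else spec$p_gap
  anc <- sample.int(4L, m, replace = TRUE)
  x <- matrix(0L, nrow = spec$n_samples, ncol = m)
  for (i in seq_len(spec$n_samples)) {
    # fixed-size draws per sample: runs with the same seed but different
    # mutation rates share random numbers (monotone coupling)
    row <- anc
    u_mut <- runif(m)
    shift <- sample.int(3L, m, replace = TRUE)
    u_gap <- runif(m)
    mut <- u_mut < p
    row[mut] <- ((row[mut] - 1L + shift[mut]) %% 4L) + 1L
    if (p_gap > 0) row[u_gap < p_gap] <- 0L
    x[i, ] <- row
  }
  rownames(x) <- sprintf("sample%02d", seq_len(spec$n_samples))
  truth <- if (length(hs))
    data.frame(start = vapply(hs, `[`, numeric(1), 1),
               end = vapply(hs, `[`, numeric(1), 2))
  else data.frame(start = numeric(0), end = numeric(0))
  list(aln = alignment_matrix(x), truth = truth)
}

#' Simulate a codon alignment under GY94 branch models
#'
#' Draws root codons from the equilibrium frequencies and evolves them along
#' the tree with per-branch transition matrices `exp(Q t)`, where each
#' branch's generator uses its omega class.
#'
#' @param tree `phylo` with branch lengths (expected substitutions/codon).
#' @param kappa transition/transversion ratio.
#' @param omega single dN/dS value, or `c(background=, foreground=)`
#'   together with `foreground`.
#' @param freqs codon equilibrium frequencies (61 sense codons).
#' @param n_codons number of codon sites.
#' @param seed integer seed.
#' @param foreground foreground edge indices or tip labels (for two-ratio
#'   simulation).
#' @return a [codon_alignment()] over the tree's tips.
#' @export
simulate_codon_alignment <- function(tree, kappa, omega, freqs, n_codons,
                                     seed, foreground = NULL) {
  codon_setup()
  set.seed(seed)
  tr <- ape::reorder.phylo(tree, "cladewise")
  nedge <- nrow(tr$edge)
  if (length(omega) == 1L) {
    cls <- rep(1L, nedge)
    om <- unname(omega)
  } else {
    stopifnot(!is.null(foreground),
              all(c("background", "foreground") %in% names(omega)))
    if (is.character(foreground)) foreground <- foreground_edges(tr, foreground)
    cls <- rep(1L, nedge); cls[foreground] <- 2L
    om <- unname(omega[c("background", "foreground")])
  }
  pirf <- freqs / sum(freqs)
  eig <- lapply(om, function(w) gy94_eigen(kappa, w, freqs))
  ntip <- length(tr$tip.label)
  root <- ntip + 1L
  states <- matrix(0L, nrow = max(tr$edge), ncol = n_codons)
  states[root, ] <- sample.int(61L, n_codons, replace = TRUE, prob = pirf)
  for (e in seq_len(nedge)) {
    P <- gy94_pmatrix(eig[[cls[e]]], tr$edge.length[e])
    par <- states[tr$edge[e, 1], ]
    ch <- integer(n_codons)
    for (s in unique(par)) {
      ix <- which(par == s)
      ch[ix] <- sample.int(61L, length(ix), replace = TRUE, prob = P[s, ])
    }
    states[tr$edge[e, 2], ] <- ch
  }
  cods <- .codon_env$codons
  m <- matrix(cods[states[seq_len(ntip), , drop = FALSE]], nrow = ntip)
  rownames(m) <- tr$tip.label
  codon_alignment(m)
}
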