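# GY94 codon substitution model, Felsenstein pruning likelihood, branch-model
# (one-ratio vs two-ratio dN/dS) fits and likelihood-ratio tests.

#' GY94 generator matrix
#'
#' Goldman-Yang codon rate matrix: `q_ij = 0` when codons `i` and `j` differ
#' at more than one nucleotide, otherwise `pi_j * kappa^[transition] *
#' omega^[nonsynonymous]`. The diagonal makes rows sum to zero and the matrix
#' is rescaled so that `-sum_i pi_i q_ii = 1`, i.e. branch lengths are
#' expected substitutions per codon.
#'
#' @param kappa transition/transversion rate ratio (>= 0).
#' @param omega nonsynonymous/synonymous rate ratio dN/dS (>= 0).
#' @param freqs equilibrium frequencies over the 61 sense codons, e.g. from
#'   [f3x4_frequencies()].
#' @return 61 x 61 generator matrix with codon dimnames.
#' @export
gy94_rates <- function(kappa, omega, freqs) {
  codon_setup()
  stopifnot(kappa >= 0, omega >= 0, length(freqs) == 61L)
  if (any(freqs <= 0)) stop("degenerate codon frequencies (some pi_j == 0)")
  freqs <- freqs / sum(freqs)
  p <- .codon_env$pairs
  rate <- freqs[p$j] * ifelse(p$ts, kappa, 1) * ifelse(p$syn, 1, omega)
  Q <- matrix(0, 61L, 61L, dimnames = list(.codon_env$codons,
                                           .codon_env$codons))
  Q[cbind(p$i, p$j)] <- rate
  # reversibility: q_ji = pi_i * kappa^ts * omega^ns
  Q[cbind(p$j, p$i)] <- freqs[p$i] * ifelse(p$ts, kappa, 1) *
    ifelse(p$syn, 1, omega)
  diag(Q) <- -rowSums(Q)
  scale <- -sum(freqs * diag(Q))
  if (scale <= 0) stop("degenerate generator (zero total rate)")
  Q / scale
}

# symmetric eigendecomposition of a reversible generator:
# P(t) = U diag(exp(lam t)) W with U = V / sqrt(pi), W = t(V * sqrt(pi))
gy94_eigen <- function(kappa, omega, freqs) {
  Q <- gy94_rates(kappa, omega, freqs)
  sp <- sqrt(freqs / sum(freqs))
  S <- Q * (sp %o% (1 / sp))
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  list(U = e$vectors / sp, lam = e$values, W = t(e$vectors * sp))
}

# transition probability matrix for one branch
gy94_pmatrix <- function(eig, t) {
  P <- gy94_pmat_cpp(eig$U, eig$lam, eig$W, t)
  P / rowSums(P)
}

# tree bookkeeping: postorder edge arrays + tip state patterns
tree_data <- function(caln, tree) {
  stopifnot(inherits(caln, "codon_alignment"), inherits(tree, "phylo"))
  if (!setequal(tree$tip.label, caln$ids))
    stop("tree tip labels do not match alignment ids")
  tr <- ape::reorder.phylo(tree, "postorder")
  states <- matrix(codon_states(caln$codons), nrow = length(caln$ids))
  states <- states[match(tr$tip.label, caln$ids), , drop = FALSE]
  key <- apply(states, 2L, paste, collapse = ".")
  first <- !duplicated(key)
  w <- as.numeric(table(factor(key, levels = key[first])))
  list(tree = tr, states = states[, first, drop = FALSE], weights = w,
       n_sites = ncol(states))
}

#' Log-likelihood of a codon alignment under GY94 branch models
#'
#' Felsenstein pruning over codon sites with per-branch transition matrices
#' `exp(Q_branch t)`; gap or ambiguous codons are treated as fully missing
#' data (partial likelihood one over all 61 states).
#'
#' @param caln a [codon_alignment()].
#' @param tree `phylo` tree whose tip labels equal the alignment ids; edge
#'   lengths are expected substitutions per codon.
#' @param kappa transition/transversion ratio.
#' @param omega_map numeric vector of dN/dS values, one per edge of `tree`
#'   (in `tree$edge` order), or a single value for all edges.
#' @param freqs codon frequencies (default [f3x4_frequencies()] of `caln`).
#' @return log-likelihood (numeric scalar).
#' @export
log_likelihood <- function(caln, tree, kappa, omega_map,
                           freqs = f3x4_frequencies(caln)) {
  td <- tree_data(caln, tree)
  tr <- td$tree
  nedge <- nrow(tr$edge)
  if (length(omega_map) == 1L) omega_map <- rep(omega_map, nedge)
  stopifnot(length(omega_map) == nedge)
  om <- sort(unique(omega_map))
  cls <- match(omega_map, om)
  eig <- lapply(om, function(w) gy94_eigen(kappa, w, freqs))
  el <- tr$edge.length
  if (is.null(el)) stop("tree has no branch lengths")
  lnl <- pruning_lnl_cpp(eig, tr$edge[, 1], tr$edge[, 2], el, cls,
                         td$states, td$weights, freqs / sum(freqs),
                         max(tr$edge))
  if (!is.finite(lnl)) stop("non-finite likelihood")
  lnl
}

#' Edges of a foreground clade
#'
#' Returns the indices (rows of `tree$edge`) of all branches inside the
#' smallest clade containing `tips`, including the clade's stem branch.
#'
#' @param tree a `phylo` object.
#' @param tips tip labels spanning the foreground clade.
#' @return integer vector of edge indices.
#' @export
foreground_edges <- function(tree, tips) {
  stopifnot(all(tips %in% tree$tip.label))
  if (length(tips) == 1L)
    return(which(tree$edge[, 2] == match(tips, tree$tip.label)))
  node <- ape::getMRCA(tree, tips)
  desc <- node
  repeat {
    more <- tree$edge[tree$edge[, 1] %in% desc, 2]
    new <- setdiff(more, desc)
    if (!length(new)) break
    desc <- c(desc, new)
  }
  which(tree$edge[, 2] %in% desc)
}

#' Fit a GY94 branch model by maximum likelihood
#'
#' Maximises the pruning log-likelihood over kappa, the omega parameter(s)
#' and all branch lengths with bounded quasi-Newton optimisation
#' ([stats::nlminb()] on log-transformed parameters). The `one_ratio` model
#' shares a single omega across the tree; the `two_ratio` model gives the
#' `foreground` branches their own omega. Several omega starting values are
#' tried and the best fit kept; start jitter is deterministic given `seed`.
#'
#' @param caln a [codon_alignment()].
#' @param tree `phylo` with branch lengths (used as starting values and
#'   re-optimised, per gene, as in CODEML's default).
#' @param model `"one_ratio"` or `"two_ratio"`.
#' @param foreground foreground edge indices (see [foreground_edges()]) or
#'   tip labels; required for the two-ratio model.
#' @param freqs codon frequencies (default F3x4 from the alignment).
#' @param starts omega starting values.
#' @param extra_starts optional list of full warm starts, each
#'   `list(kappa=, omega=, bl=)` (omega length 1 or 2).
#' @param seed integer seed controlling start jitter.
#' @return object of class `branch_model_fit`: `model`, `lnL`, `kappa`,
#'   `omega` (named `all` or `background`/`foreground`), `branch_lengths`,
#'   `foreground`, `convergence`.
#' @export
fit_branch_model <- function(caln, tree,
                             model = c("one_ratio", "two_ratio"),
                             foreground = NULL,
                             freqs = f3x4_frequencies(caln),
                             starts = c(0.1, 0.5, 1.5),
                             extra_starts = NULL, seed = 1L) {
  model <- match.arg(model)
  td <- tree_data(caln, tree)
  tr <- td$tree
  nedge <- nrow(tr$edge)
  if (model == "two_ratio") {
    if (is.null(foreground)) stop("two_ratio model needs foreground branches")
    if (is.character(foreground)) foreground <- foreground_edges(tr, foreground)
    stopifnot(all(foreground %in% seq_len(nedge)))
    cls <- rep(1L, nedge); cls[foreground] <- 2L
    if (!any(cls == 1L)) stop("no background branches left")
    nomega <- 2L
  } else {
    cls <- rep(1L, nedge)
    nomega <- 1L
  }
  pirf <- freqs / sum(freqs)
  bl0 <- tr$edge.length
  if (is.null(bl0)) bl0 <- rep(0.1, nedge)
  bl0 <- pmax(bl0, 1e-4)

  eig_cache <- new.env(parent = emptyenv())
  negll <- function(par) {
    kappa <- exp(par[1])
    om <- exp(par[2:(1 + nomega)])
    el <- exp(par[-(1:(1 + nomega))])
    # branch-length moves reuse the same (kappa, omega) decompositions
    eig <- lapply(om, function(w) {
      key <- sprintf("%.17g_%.17g", kappa, w)
      e <- eig_cache[[key]]
      if (is.null(e)) {
        e <- gy94_eigen(kappa, w, freqs)
        assign(key, e, envir = eig_cache)
      }
      e
    })
    v <- tryCatch(
      pruning_lnl_cpp(eig, tr$edge[, 1], tr$edge[, 2], el, cls,
                      td$states, td$weights, pirf, max(tr$edge)),
      error = function(e) -Inf)
    if (!is.finite(v)) 1e10 else -v
  }
  lower <- c(log(0.05), rep(log(1e-4), nomega), rep(log(1e-7), nedge))
  upper <- c(log(500), rep(log(99), nomega), rep(log(10), nedge))

  start_list <- lapply(seq_along(starts), function(k) {
    list(kappa = 2, omega = rep(starts[k], nomega), bl = bl0, jit = k)
  })
  if (!is.null(extra_starts)) {
    extra_starts <- lapply(extra_starts, function(s) {
      s$omega <- rep(s$omega, length.out = nomega); s$jit <- 0L; s
    })
    start_list <- c(extra_starts, start_list)
  }

  best <- NULL
  for (k in seq_along(start_list)) {
    st <- start_list[[k]]
    set.seed(as.integer(seed) + st$jit)
    jit <- if (st$jit > 1L) runif(nedge, -0.05, 0.05) else 0
    par0 <- c(log(st$kappa), log(st$omega), log(st$bl) + jit)
    par0 <- pmin(pmax(par0, lower), upper)
    fit <- tryCatch(
      nlminb(par0, negll, lower = lower, upper = upper,
             control = list(iter.max = 500, eval.max = 2000,
                            rel.tol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  if (is.null(best) || !is.finite(best$objective) || best$objective >= 1e10)
    stop("branch-model optimisation failed to produce a finite likelihood")
  par <- best$par
  omega <- exp(par[2:(1 + nomega)])
  names(omega) <- if (nomega == 2L) c("background", "foreground") else "all"
  structure(list(
    model = model, lnL = -best$objective, kappa = exp(par[1]),
    omega = omega, branch_lengths = exp(par[-(1:(1 + nomega))]),
    foreground = if (model == "two_ratio") foreground else integer(0),
    tree = tr, convergence = best$convergence),
    class = "branch_model_fit")
}

#' @export
print.branch_model_fit <- function(x, ...) {
  cat(sprintf("<branch_model_fit> %s: lnL %.4f, kappa %.3f, omega %s\n",
              x$model, x$lnL, x$kappa,
              paste(sprintf("%s=%.4f", names(x$omega), x$omega),
                    collapse = ", ")))
  invisible(x)
}

#' Likelihood-ratio test between nested branch models
#'
#' `2 (lnL_alt - lnL_null)` referred to the chi-square distribution with one
#' degree of freedom (clipped at zero against optimizer noise). Verdicts
#' follow the standard classification: positive selection when the test is
#' significant and the foreground omega exceeds 1; fast-evolving when
#' significant with foreground omega above background but at most 1.
#'
#' @param null one-ratio `branch_model_fit`.
#' @param alt two-ratio `branch_model_fit`.
#' @param alpha significance level (default 0.05).
#' @return object of class `lrt_result`: `statistic`, `df`, `p`,
#'   `significant`, `positive_selection`, `fast_evolving`, plus the omega
#'   estimates.
#' @export
lrt <- function(null, alt, alpha = 0.05) {
  stopifnot(inherits(null, "branch_model_fit"),
            inherits(alt, "branch_model_fit"))
  stat <- max(0, 2 * (alt$lnL - null$lnL))
  p <- pchisq(stat, df = 1, lower.tail = FALSE)
  wf <- unname(alt$omega["foreground"])
  wb <- unname(alt$omega["background"])
  sig <- is.finite(p) && p < alpha
  structure(list(
    statistic = stat, df = 1L, p = p,
    omega_null = unname(null$omega["all"]),
    omega_background = wb, omega_foreground = wf,
    significant = sig,
    positive_selection = sig && !is.na(wf) && wf > 1,
    fast_evolving = sig && !is.na(wf) && !is.na(wb) && wf > wb && wf <= 1),
    class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf(paste0("<lrt_result> 2dlnL %.4f (df 1), p %.4g; ",
                     "omega0 %.4f, wb %.4f, wf %.4f%s\n"),
              x$statistic, x$p, x$omega_null, x$omega_background,
              x$omega_foreground,
              if (x$positive_selection) " [positive selection]"
              else if (x$fast_evolving) " [fast-evolving]" else ""))
  invisible(x)
}

#' One-ratio vs two-ratio branch test for one gene
#'
#' Fits the one-ratio null and the two-ratio alternative (warm-started from
#' the null fit) and returns both fits with the likelihood-ratio test.
#'
#' @inheritParams fit_branch_model
#' @param alpha significance level for the verdict flags.
#' @param ... passed to [fit_branch_model()].
#' @return list with `null`, `alt`, `lrt`.
#' @export
branch_model_lrt <- function(caln, tree, foreground, alpha = 0.05, ...) {
  null <- fit_branch_model(caln, tree, model = "one_ratio", ...)
  warm <- list(list(kappa = null$kappa, omega = unname(null$omega["all"]),
                    bl = null$branch_lengths))
  alt <- fit_branch_model(caln, tree, model = "two_ratio",
                          foreground = foreground, extra_starts = warm, ...)
  list(null = null, alt = alt, lrt = lrt(null, alt, alpha = alpha))
}
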