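# Codon machinery: genetic code, codon alignments, PAL2NAL-style
# back-translation, F3x4 equilibrium frequencies.

.codon_env <- new.env(parent = emptyenv())

codon_setup <- function() {
  if (!is.null(.codon_env$codons)) return(invisible())
  nts <- c("T", "C", "A", "G")
  all64 <- as.vector(outer(outer(nts, nts, function(a, b) paste0(a, b)),
                           nts, function(ab, c) paste0(ab, c)))
  # translation table 11 (bacterial/plastid) has the same codon -> amino acid
  # map as the standard code; they differ only in permitted start codons
  aa <- Biostrings::GENETIC_CODE[all64]
  stops <- all64[aa == "*"]
  codons <- all64[aa != "*"]
  .codon_env$codons <- codons
  .codon_env$stops <- stops
  .codon_env$aa <- aa[aa != "*"]
  nt_of <- function(k, pos) substr(k, pos, pos)
  ncod <- length(codons)
  # single-nucleotide neighbour pairs with transition / synonymy flags
  ii <- integer(0); jj <- integer(0); ts <- logical(0); syn <- logical(0)
  for (i in seq_len(ncod - 1L)) for (j in (i + 1L):ncod) {
    d <- which(vapply(1:3, function(p)
      nt_of(codons[i], p) != nt_of(codons[j], p), logical(1)))
    if (length(d) != 1L) next
    a <- nt_of(codons[i], d); b <- nt_of(codons[j], d)
    ii <- c(ii, i); jj <- c(jj, j)
    ts <- c(ts, paste0(sort(c(a, b)), collapse = "") %in% c("AG", "CT"))
    syn <- c(syn, .codon_env$aa[i] == .codon_env$aa[j])
  }
  .codon_env$pairs <- data.frame(i = ii, j = jj, ts = ts, syn = syn)
  invisible()
}

#' Sense codons of the plastid genetic code
#' @return character vector of the 61 sense codons.
#' @export
sense_codons <- function() {
  codon_setup()
  .codon_env$codons
}

codon_states <- function(codons) {
  # codon strings -> 1..61, 0 for gap/ambiguous codons (missing data)
  codon_setup()
  st <- match(codons, .codon_env$codons)
  st[is.na(st)] <- 0L
  st
}

translate_codons <- function(codons) {
  codon_setup()
  aa <- setNames(.codon_env$aa, .codon_env$codons)
  out <- unname(aa[codons])
  out[codons %in% .codon_env$stops] <- "*"
  out
}

#' Construct a codon alignment
#'
#' @param codon_mat character matrix (rows = sequences, named) of 3-letter
#'   codons; `---` marks an alignment gap. Codons containing gap characters
#'   or ambiguity codes are kept and treated as missing data by the
#'   likelihood. Stop codons inside the alignment are rejected.
#' @return object of class `codon_alignment`: list with `ids`, `codons`
#'   (matrix), `n_codons`.
#' @export
codon_alignment <- function(codon_mat) {
  codon_setup()
  stopifnot(is.matrix(codon_mat), !is.null(rownames(codon_mat)))
  if (any(codon_mat %in% .codon_env$stops))
    stop("stop codon inside codon alignment")
  structure(list(ids = rownames(codon_mat), codons = codon_mat,
                 n_codons = ncol(codon_mat)),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("<codon_alignment> %d sequence(s) x %d codon(s)\n",
              length(x$ids), x$n_codons))
  invisible(x)
}

#' Codon alignment from aligned nucleotide sequences
#'
#' Splits an in-frame gapped nucleotide alignment into codon columns.
#'
#' @param seqs named character vector of aligned sequences, lengths divisible
#'   by 3.
#' @param strip_terminal_stop drop a final codon column in which every
#'   non-gap codon is a stop.
#' @return a [codon_alignment()].
#' @export
codon_alignment_from_dna <- function(seqs, strip_terminal_stop = TRUE) {
  codon_setup()
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  w <- unique(nchar(seqs))
  if (length(w) != 1L || w %% 3L != 0L)
    stop("aligned sequences must share a length divisible by 3")
  nc <- w %/% 3L
  m <- t(vapply(toupper(seqs), function(s)
    substring(s, 3L * (seq_len(nc) - 1L) + 1L, 3L * seq_len(nc)),
    character(nc)))
  rownames(m) <- names(seqs)
  if (strip_terminal_stop && nc > 0L) {
    last <- m[, nc]
    nong <- last != "---"
    if (any(nong) && all(last[nong] %in% .codon_env$stops))
      m <- m[, -nc, drop = FALSE]
  }
  codon_alignment(m)
}

#' Back-translate a protein alignment to a codon alignment
#'
#' PAL2NAL-style: each aligned amino acid is replaced by its source codon
#' from the unaligned CDS, each protein gap becomes `---`, and a terminal
#' stop codon on the CDS is stripped. The translation of each CDS (table 11)
#' must reproduce the ungapped protein row exactly.
#'
#' @param prot_aln named character vector of aligned protein sequences
#'   (gaps `-`), all of equal length.
#' @param cds named character vector of unaligned coding sequences, names
#'   matching `prot_aln`.
#' @return a [codon_alignment()].
#' @export
back_translate <- function(prot_aln, cds) {
  codon_setup()
  stopifnot(is.character(prot_aln), !is.null(names(prot_aln)))
  if (length(unique(nchar(prot_aln))) != 1L)
    stop("protein alignment rows have unequal lengths")
  miss <- setdiff(names(prot_aln), names(cds))
  if (length(miss)) stop("no CDS for: ", paste(miss, collapse = ", "))
  ncol_aln <- nchar(prot_aln[[1]])
  rows <- lapply(names(prot_aln), function(id) {
    p <- toupper(prot_aln[[id]])
    d <- toupper(cds[[id]])
    if (nchar(d) %% 3L != 0L)
      stop("CDS length of '", id, "' is not divisible by 3")
    ncod <- nchar(d) %/% 3L
    codons <- substring(d, 3L * (seq_len(ncod) - 1L) + 1L, 3L * seq_len(ncod))
    if (ncod > 0L && codons[ncod] %in% .codon_env$stops)
      codons <- codons[-ncod]
    pa <- strsplit(p, "")[[1]]
    res <- rep("---", ncol_aln)
    k <- 0L
    for (col in seq_len(ncol_aln)) {
      if (pa[col] == "-") next
      k <- k + 1L
      if (k > length(codons))
        stop("translation mismatch for '", id, "': protein longer than CDS")
      aa <- translate_codons(codons[k])
      if (!identical(aa, pa[col]))
        stop("translation mismatch for '", id, "' at position ", k,
             ": codon ", codons[k], " (", aa, ") vs amino acid ", pa[col])
      res[col] <- codons[k]
    }
    if (k != length(codons))
      stop("translation mismatch for '", id, "': CDS longer than protein")
    res
  })
  m <- do.call(rbind, rows)
  rownames(m) <- names(prot_aln)
  codon_alignment(m)
}

#' F3x4 codon equilibrium frequencies
#'
#' Position-specific nucleotide frequencies are estimated from the non-gap
#' codons of the alignment; codon frequencies are their product with stop
#' codons removed and the rest renormalised (the CODEML `CodonFreq = 2`
#' default).
#'
#' @param caln a [codon_alignment()], or `NULL` with `pos_freqs` supplied.
#' @param pos_freqs optional 3 x 4 matrix of positional nucleotide
#'   frequencies (columns `T,C,A,G` order is irrelevant as long as the
#'   matrix has `dimnames` with nucleotides).
#' @return named numeric vector over the 61 sense codons, summing to 1.
#' @export
f3x4_frequencies <- function(caln = NULL, pos_freqs = NULL) {
  codon_setup()
  nts <- c("T", "C", "A", "G")
  if (is.null(pos_freqs)) {
    stopifnot(inherits(caln, "codon_alignment"))
    cod <- as.vector(caln$codons)
    cod <- cod[cod %in% .codon_env$codons]
    pos_freqs <- t(vapply(1:3, function(p) {
      tab <- table(factor(substr(cod, p, p), levels = nts))
      as.numeric(tab) / sum(tab)
    }, numeric(4)))
    colnames(pos_freqs) <- nts
  }
  stopifnot(nrow(pos_freqs) == 3L, all(nts %in% colnames(pos_freqs)))
  cods <- .codon_env$codons
  pi <- vapply(cods, function(k)
    pos_freqs[1, substr(k, 1, 1)] * pos_freqs[2, substr(k, 2, 2)] *
    pos_freqs[3, substr(k, 3, 3)], numeric(1))
  if (any(pi <= 0))
    stop("degenerate codon frequencies: a positional nucleotide frequency ",
         "is zero")
  pi / sum(pi)
}
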