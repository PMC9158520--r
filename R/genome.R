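#' Construct an annotated genome
#'
#' The basic substrate of the structure and repeat scans: a single (usually
#' circular) DNA sequence with an optional feature table.
#'
#' @param id accession or sample identifier.
#' @param seq DNA string; coerced to upper case. Characters outside
#'   `{A,C,G,T,N}` (IUPAC ambiguity codes etc.) are mapped to `N` with a
#'   warning.
#' @param circular logical; plastomes are circular molecules.
#' @param features a data frame as returned by [empty_features()]: columns
#'   `name`, `kind` (one of gene, tRNA, rRNA, CDS, pseudogene), `strand`
#'   (`+`/`-`), `start`, `end` (0-based half-open, on the given orientation).
#' @return An object of class `annotated_genome`: a list with elements `id`,
#'   `seq`, `circular`, `features`.
#' @export
annotated_genome <- function(id, seq, circular = TRUE,
                             features = empty_features()) {
  stopifnot(is.character(seq), length(seq) == 1L, nchar(seq) > 0L)
  seq <- toupper(seq)
  bad <- gsub("[ACGTN]", "", seq)
  if (nchar(bad) > 0L) {
    warning(sprintf("%d non-ACGTN character(s) mapped to N in '%s'",
                    nchar(bad), id))
    seq <- gsub("[^ACGTN]", "N", seq)
  }
  features <- validate_features(features, nchar(seq))
  structure(list(id = as.character(id), seq = seq,
                 circular = isTRUE(circular), features = features),
            class = "annotated_genome")
}

#' Empty feature table
#' @return zero-row data frame with the feature columns.
#' @export
empty_features <- function() {
  data.frame(name = character(), kind = character(), strand = character(),
             start = integer(), end = integer(), stringsAsFactors = FALSE)
}

validate_features <- function(features, n) {
  stopifnot(is.data.frame(features),
            all(c("name", "kind", "strand", "start", "end") %in%
                  names(features)))
  if (nrow(features)) {
    stopifnot(all(features$start >= 0L), all(features$end > features$start),
              all(features$start < n))
    # features may run past the origin on circular molecules (end > n,
    # "unwrapped" coordinates); they must not exceed one full turn
    stopifnot(all(features$end - features$start <= n))
  }
  features
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf("<annotated_genome> %s: %s bp, %s, %d feature(s)\n", x$id,
              format(nchar(x$seq), big.mark = ","),
              if (x$circular) "circular" else "linear", nrow(x$features)))
  invisible(x)
}

#' Sequence length of a genome
#' @param genome an `annotated_genome`.
#' @export
genome_length <- function(genome) nchar(genome$seq)

#' Reverse complement / complement / reverse of a DNA string
#'
#' Characters outside `{A,C,G,T}` become `N`.
#' @param x DNA string.
#' @return transformed string.
#' @export
revcomp <- function(x) revcomp_cpp(toupper(x))

#' @rdname revcomp
#' @export
complement <- function(x) comp_cpp(toupper(x))

#' @rdname revcomp
#' @export
rev_seq <- function(x) rev_cpp(x)

#' Rotate a circular genome
#'
#' Moves position `offset` (0-based) to position 0. Feature coordinates are
#' shifted modulo the genome length; features that then span the origin keep
#' "unwrapped" coordinates (`end` may exceed the genome length).
#'
#' @param genome an `annotated_genome` with `circular = TRUE`.
#' @param offset 0-based position that becomes the new origin.
#' @return the rotated `annotated_genome`.
#' @export
rotate_genome <- function(genome, offset) {
  n <- genome_length(genome)
  offset <- as.integer(offset %% n)
  if (offset == 0L) return(genome)
  if (!genome$circular) stop("cannot rotate a linear genome")
  seq <- paste0(substr(genome$seq, offset + 1L, n),
                substr(genome$seq, 1L, offset))
  f <- genome$features
  if (nrow(f)) {
    len <- f$end - f$start
    f$start <- (f$start - offset) %% n
    f$end <- f$start + len
  }
  out <- genome
  out$seq <- seq
  out$features <- f
  out
}

substr_circular <- function(seq, start, end) {
  # 0-based half-open; end may exceed nchar(seq) on circular molecules
  n <- nchar(seq)
  if (end <= n) return(substr(seq, start + 1L, end))
  paste0(substr(seq, start + 1L, n), substr(seq, 1L, end - n))
}

#' Extract a feature's sequence
#'
#' Returns `seq[start, end)`, reverse-complemented for minus-strand features.
#' @param genome an `annotated_genome`.
#' @param feature one row of the feature table (list or 1-row data frame).
#' @export
feature_seq <- function(genome, feature) {
  s <- substr_circular(genome$seq, feature$start, feature$end)
  if (identical(feature$strand, "-")) s <- revcomp(s) else s
}
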