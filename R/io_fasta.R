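#' Read and write FASTA
#'
#' Thin wrappers around Biostrings that return plain named character vectors,
#' the representation used throughout the package.
#'
#' @param path file path.
#' @return `read_fasta`: named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  setNames(toupper(as.character(x)), names(x))
}

#' @rdname read_fasta
#' @param seqs named character vector.
#' @param width line width for wrapping.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

# byte -> code lookup: '-'=0, A=1, C=2, G=3, T=4, N(and everything else)=5
aln_code_table <- local({
  tab <- rep(5L, 256L)
  tab[utf8ToInt("-") + 1L] <- 0L
  tab[utf8ToInt(".") + 1L] <- 0L
  tab[utf8ToInt("A") + 1L] <- 1L
  tab[utf8ToInt("C") + 1L] <- 2L
  tab[utf8ToInt("G") + 1L] <- 3L
  tab[utf8ToInt("T") + 1L] <- 4L
  tab
})

#' Construct an alignment matrix
#'
#' Stores a multiple sequence alignment as an integer matrix with codes
#' `-`/`.` = 0, `A`=1, `C`=2, `G`=3, `T`=4 and `N` (or any other character)
#' = 5. Codes 0 and 5 are "invalid" for the diversity estimator; only code 0
#' is a gap for coordinate projection.
#'
#' @param seqs named character vector of aligned sequences (equal lengths),
#'   or an integer matrix already coded as above (rows named by sample).
#' @return object of class `alignment_matrix`: list with `ids`, `x`
#'   (n_samples x n_columns integer matrix), `n_col`.
#' @export
alignment_matrix <- function(seqs) {
  if (is.matrix(seqs)) {
    stopifnot(is.numeric(seqs), !is.null(rownames(seqs)))
    x <- seqs
    storage.mode(x) <- "integer"
    ids <- rownames(x)
  } else {
    stopifnot(is.character(seqs), !is.null(names(seqs)))
    widths <- nchar(seqs)
    if (length(unique(widths)) != 1L)
      stop("alignment error: rows have unequal lengths (",
           paste(range(widths), collapse = "-"), ")")
    ids <- names(seqs)
    up <- toupper(seqs)
    v <- vapply(up, function(s)
      aln_code_table[as.integer(charToRaw(s)) + 1L],
      integer(widths[1]))
    x <- if (is.matrix(v)) t(v) else matrix(v, ncol = 1L)
    rownames(x) <- ids
  }
  if (anyDuplicated(ids)) stop("alignment error: duplicate sequence ids")
  structure(list(ids = ids, x = x, n_col = ncol(x)),
            class = "alignment_matrix")
}

#' Read an aligned multi-FASTA
#'
#' Rows are upper-cased, `.` is treated as `-`, ragged rows and duplicated
#' ids are rejected.
#'
#' @param path aligned multi-FASTA file.
#' @return an [alignment_matrix()].
#' @export
read_alignment <- function(path) {
  alignment_matrix(read_fasta(path))
}

#' @export
print.alignment_matrix <- function(x, ...) {
  cat(sprintf("<alignment_matrix> %d sequence(s) x %s column(s)\n",
              length(x$ids), format(x$n_col, big.mark = ",")))
  invisible(x)
}

#' Decode alignment rows back to character strings
#' @param aln an `alignment_matrix`.
#' @return named character vector.
#' @export
alignment_strings <- function(aln) {
  chars <- c("-", "A", "C", "G", "T", "N")
  apply(aln$x, 1L, function(r) paste(chars[r + 1L], collapse = ""))
}

#' Write hypervariable regions
#'
#' `tsv` reproduces the marker-table layout (columns Start, End, Length,
#' #SVS, #PIP, Pi, Gene name; 0-based starts, half-open ends). `bed` emits
#' BED6 with the Pi value (x 1e5, capped at 1000) as score.
#'
#' @param regions data frame with columns `start`, `end`, `length`, `n_svs`,
#'   `n_pip`, `pi`, `name`, sorted by `start` and pairwise disjoint.
#' @param path output file.
#' @param dialect `"tsv"` or `"bed"`.
#' @param chrom chromosome/alignment label used in the BED dialect.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path, dialect = c("tsv", "bed"),
                          chrom = "alignment") {
  dialect <- match.arg(dialect)
  req <- c("start", "end", "length", "n_svs", "n_pip", "pi", "name")
  stopifnot(all(req %in% names(regions)))
  if (nrow(regions) > 1L) {
    if (is.unsorted(regions$start, strictly = FALSE))
      stop("regions must be sorted by start")
    if (any(regions$start[-1L] < regions$end[-nrow(regions)]))
      stop("regions overlap; merge step guarantees disjointness")
  }
  if (dialect == "tsv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(c("Start", "End", "Length", "#SVS", "#PIP", "Pi",
                       "Gene name"), collapse = "\t"), con)
    if (nrow(regions))
      writeLines(paste(regions$start, regions$end, regions$length,
                       regions$n_svs, regions$n_pip,
                       format(regions$pi, scientific = FALSE, trim = TRUE,
                              digits = 15),
                       ifelse(is.na(regions$name), "unplaced", regions$name),
                       sep = "\t"), con)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    if (nrow(regions))
      writeLines(paste(chrom, regions$start, regions$end,
                       ifelse(is.na(regions$name), "unplaced", regions$name),
                       pmin(1000L, as.integer(round(regions$pi * 1e5))),
                       ".", sep = "\t"), con)
  }
  invisible(path)
}

#' Read a newick tree
#'
#' @param path newick file.
#' @return an `ape` `phylo` object.
#' @export
read_tree <- function(path) ape::read.tree(path)
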