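# Quadripartite architecture: IR detection, per-region GC, junction offsets.

#' Detect the quadripartite plastome structure
#'
#' Finds the maximal pair of exact inverted repeats (sequence vs its reverse
#' complement, seeded k-mer matching with mismatch-free extension over the
#' doubled circular sequence), labels the longer inter-repeat segment LSC and
#' the shorter SSC, and reports coordinates on the canonical rotation
#' LSC -> IRb -> SSC -> IRa with LSC starting at 0.
#'
#' @param genome an [annotated_genome()] (circular).
#' @param min_ir_len minimum acceptable IR length in bp. The 1 kb default
#'   rejects tRNA-scale false pairs while accepting any true plastome IR.
#' @return object of class `quadripartite_partition`: list with 0-based
#'   half-open intervals `lsc`, `irb`, `ssc`, `ira` (canonical coordinates),
#'   `n` (genome length), `ir_len`, and `offset` - the 0-based position of the
#'   input sequence that becomes canonical position 0 (see
#'   [canonicalize_genome()]).
#' @export
detect_inverted_repeats <- function(genome, min_ir_len = 1000L) {
  stopifnot(inherits(genome, "annotated_genome"))
  s <- genome$seq
  n <- nchar(s)
  if (!genome$circular) stop("quadripartite detection expects a circular genome")
  s2 <- paste0(s, s)
  m <- max_matches_cpp(s2, revcomp_cpp(s2), as.integer(min_ir_len),
                       self_pairs = TRUE, cap_len = n)
  if (!nrow(m)) stop("no quadripartite structure: no inverted repeat >= ",
                     min_ir_len, " bp in ", genome$id)
  a <- m$start_a %% n
  b <- (2L * n - m$start_b - m$len) %% n
  L <- pmin(m$len, n)
  # drop self-pairs and circularly overlapping copies
  ident <- a == b
  ov <- ((b - a) %% n) < L | ((a - b) %% n) < L
  keep <- !ident & !ov & L >= min_ir_len
  if (!any(keep)) stop("no quadripartite structure: no inverted repeat >= ",
                       min_ir_len, " bp in ", genome$id)
  lo <- pmin(a, b)[keep]; hi <- pmax(a, b)[keep]; L <- L[keep]
  key <- !duplicated(paste(lo, hi, L))
  lo <- lo[key]; hi <- hi[key]; L <- L[key]
  best <- L == max(L)
  if (sum(best) > 1L)
    warning("tie between ", sum(best), " equal-length inverted-repeat pairs;",
            " keeping the one with the smallest start after rotation")
  ord <- order(!best, lo, hi)
  a <- lo[ord[1]]; b <- hi[ord[1]]; irl <- L[ord[1]]

  g1 <- (b - a - irl) %% n   # segment following copy at a
  g2 <- (a - b - irl) %% n   # segment following copy at b
  if (g1 >= g2) {
    lsc_len <- g1; ssc_len <- g2; offset <- (a + irl) %% n
  } else {
    lsc_len <- g2; ssc_len <- g1; offset <- (b + irl) %% n
  }
  part <- structure(list(
    lsc = c(0L, lsc_len),
    irb = c(lsc_len, lsc_len + irl),
    ssc = c(lsc_len + irl, lsc_len + irl + ssc_len),
    ira = c(lsc_len + irl + ssc_len, n),
    n = n, ir_len = irl, offset = as.integer(offset)),
    class = "quadripartite_partition")
  # mirror identity must hold byte-wise on the canonical rotation
  cs <- canonical_seq(genome, part)
  stopifnot(identical(revcomp_cpp(substr(cs, part$irb[1] + 1L, part$irb[2])),
                      substr(cs, part$ira[1] + 1L, part$ira[2])))
  part
}

#' @export
print.quadripartite_partition <- function(x, ...) {
  cat(sprintf(paste0("<quadripartite_partition> %s bp: LSC %s | IRb %s | ",
                     "SSC %s | IRa %s (offset %d)\n"),
              format(x$n, big.mark = ","),
              format(diff(x$lsc), big.mark = ","),
              format(diff(x$irb), big.mark = ","),
              format(diff(x$ssc), big.mark = ","),
              format(diff(x$ira), big.mark = ","), x$offset))
  invisible(x)
}

canonical_seq <- function(genome, part) {
  if (part$offset == 0L) genome$seq
  else paste0(substr(genome$seq, part$offset + 1L, part$n),
              substr(genome$seq, 1L, part$offset))
}

#' Rotate a genome onto the canonical quadripartite orientation
#'
#' Applies the rotation recorded in a partition so that LSC starts at
#' position 0; feature coordinates are shifted accordingly. The returned
#' partition has `offset = 0`.
#'
#' @param genome an `annotated_genome`.
#' @param part partition from [detect_inverted_repeats()]; detected if `NULL`.
#' @param ... passed to [detect_inverted_repeats()].
#' @return list with elements `genome` (rotated) and `partition`.
#' @export
canonicalize_genome <- function(genome, part = NULL, ...) {
  if (is.null(part)) part <- detect_inverted_repeats(genome, ...)
  g <- rotate_genome(genome, part$offset)
  part$offset <- 0L
  list(genome = g, partition = part)
}

count_acgt <- function(seq) {
  r <- charToRaw(seq)
  c(A = sum(r == as.raw(65L)), C = sum(r == as.raw(67L)),
    G = sum(r == as.raw(71L)), T = sum(r == as.raw(84L)))
}

gc_pct <- function(seq) {
  cnt <- count_acgt(seq)
  tot <- sum(cnt)
  if (tot == 0L) return(NA_real_)
  100 * (cnt[["G"]] + cnt[["C"]]) / tot
}

#' GC content by plastome region
#'
#' GC% is `100 * (G + C) / (A + C + G + T)`; `N` is excluded from the
#' denominator. The two IR copies are pooled. A region with no valid base is
#' reported `NA`.
#'
#' @param genome an `annotated_genome`.
#' @param part a `quadripartite_partition` for that genome.
#' @return list of class `gc_report` with elements `total`, `lsc`, `ssc`,
#'   `ir` (percent, full precision; round for display).
#' @export
region_gc <- function(genome, part) {
  s <- canonical_seq(genome, part)
  reg <- function(iv) substr(s, iv[1] + 1L, iv[2])
  structure(list(
    total = gc_pct(s),
    lsc = gc_pct(reg(part$lsc)),
    ssc = gc_pct(reg(part$ssc)),
    ir = gc_pct(paste0(reg(part$irb), reg(part$ira)))),
    class = "gc_report")
}

#' @export
print.gc_report <- function(x, ...) {
  cat(sprintf("GC%% total %.2f (LSC %.2f / SSC %.2f / IR %.2f)\n",
              x$total, x$lsc, x$ssc, x$ir))
  invisible(x)
}

#' Junction-gene offsets (IRscope-style report)
#'
#' For each of the four junctions JLB (LSC|IRb), JSB (IRb|SSC), JSA (SSC|IRa)
#' and JLA (IRa|LSC), reports the nearest tracked gene and its signed offset:
#' positive offsets are the gap in bp between the junction and the gene's
#' nearest edge; a gene straddling the junction gets a negative offset equal
#' to the number of its bases lying inside the IR.
#'
#' @param part a `quadripartite_partition` (canonical coordinates).
#' @param features feature table in canonical coordinates (e.g. from
#'   [canonicalize_genome()]).
#' @param tracked gene names to consider; a feature matches a tracked name
#'   `g` when its name is `g` or starts with `g-` (anticodon suffixes).
#' @return data frame with one row per junction: `junction`, `position`,
#'   `gene`, `offset` (`NA` gene when no tracked feature exists).
#' @export
junction_report <- function(part, features,
                            tracked = c("rps19", "rpl2", "trnH", "ycf1",
                                        "trnN", "ndhF")) {
  n <- part$n
  juncs <- data.frame(
    junction = c("JLB", "JSB", "JSA", "JLA"),
    position = c(part$irb[1], part$ssc[1], part$ira[1], n),
    ir_side = c("right", "left", "right", "left"),
    stringsAsFactors = FALSE)
  base <- sub("-.*$", "", features$name)
  rows <- lapply(seq_len(nrow(juncs)), function(k) {
    J <- juncs$position[k]
    best <- list(gene = NA_character_, offset = NA_integer_)
    for (g in tracked) {
      f <- features[!is.na(base) & base == g, , drop = FALSE]
      if (!nrow(f)) next
      offs <- vapply(seq_len(nrow(f)), function(i) {
        s <- f$start[i]; e <- f$end[i]
        if (s < J && e > J) {
          inside <- if (juncs$ir_side[k] == "right") e - J else J - s
          -as.integer(inside)
        } else {
          as.integer(min((J - e) %% n, (s - J) %% n))
        }
      }, integer(1))
      o <- offs[which.min(abs(offs))]
      if (is.na(best$offset) || abs(o) < abs(best$offset))
        best <- list(gene = g, offset = o)
    }
    data.frame(junction = juncs$junction[k],
               position = J %% n, gene = best$gene, offset = best$offset,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' One-row structural summary of a genome
#'
#' @param genome an `annotated_genome`.
#' @param min_ir_len passed to [detect_inverted_repeats()].
#' @return data frame with accession, total/region lengths and GC columns.
#' @export
structure_report <- function(genome, min_ir_len = 1000L) {
  part <- detect_inverted_repeats(genome, min_ir_len)
  gc <- region_gc(genome, part)
  data.frame(accession = genome$id,
             total = part$n,
             lsc = diff(part$lsc), ssc = diff(part$ssc),
             ir = part$ir_len,
             gc_total = round(gc$total, 2), gc_lsc = round(gc$lsc, 2),
             gc_ssc = round(gc$ssc, 2), gc_ir = round(gc$ir, 2),
             stringsAsFactors = FALSE)
}
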