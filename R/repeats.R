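# Microsatellite (SSR) and dispersed long-repeat scanning.

seq_codes <- function(seq) {
  tab <- rep(0L, 256L)
  tab[utf8ToInt("A") + 1L] <- 1L
  tab[utf8ToInt("C") + 1L] <- 2L
  tab[utf8ToInt("G") + 1L] <- 3L
  tab[utf8ToInt("T") + 1L] <- 4L
  tab[as.integer(charToRaw(seq)) + 1L]
}

region_of <- function(pos, part) {
  if (is.null(part)) return(rep(NA_character_, length(pos)))
  vapply(pos, function(p) {
    if (p < part$lsc[2]) "LSC"
    else if (p < part$irb[2]) "IRb"
    else if (p < part$ssc[2]) "SSC"
    else "IRa"
  }, character(1))
}

is_periodic_motif <- function(motif) {
  u <- nchar(motif)
  if (u == 1L) return(FALSE)
  for (d in seq_len(u - 1L)) {
    if (u %% d != 0L) next
    if (strrep(substr(motif, 1L, d), u %/% d) == motif) return(TRUE)
  }
  FALSE
}

#' Scan simple sequence repeats (microsatellites)
#'
#' Finds maximal perfect tandem repeats of 1-6 bp units meeting per-unit
#' minimum copy numbers (MISA-style thresholds: 11/6/5/4/3/3 for mono- to
#' hexanucleotides). A run is assigned to the smallest unit that generates it
#' (a poly-A run is mono, never "AA" di). Only complete units are counted, so
#' `end - start == unit_len * copies`. `N` breaks runs. SSRs separated by at
#' most `compound_max_gap` bp are merged into one `compound` record.
#'
#' @param genome an [annotated_genome()] or plain DNA string.
#' @param thresholds named integer vector: minimum copies per unit length
#'   `"1"`..`"6"`.
#' @param compound_max_gap maximum interruption between SSRs merged as one
#'   compound (MISA default 100 bp).
#' @param compound merge nearby SSRs into compound records (`TRUE`) or report
#'   every simple SSR separately (`FALSE`).
#' @param part optional `quadripartite_partition` used to label each record's
#'   `region`; the genome must then be in canonical orientation.
#' @return data frame of class `ssr_table`: `motif`, `unit_len`, `copies`,
#'   `start`, `end` (0-based half-open), `ssr_type` (`p1`..`p6`, `compound`),
#'   `region`.
#' @export
find_ssrs <- function(genome,
                      thresholds = c(`1` = 11L, `2` = 6L, `3` = 5L,
                                     `4` = 4L, `5` = 3L, `6` = 3L),
                      compound_max_gap = 100L, compound = TRUE,
                      part = NULL) {
  seq <- if (inherits(genome, "annotated_genome")) genome$seq else toupper(genome)
  s <- seq_codes(seq)
  n <- length(s)
  recs <- list()
  for (u in 1:6) {
    thr <- thresholds[[as.character(u)]]
    if (is.null(thr) || n <= u) next
    eq <- s[seq_len(n - u)] == s[(u + 1L):n] &
      s[seq_len(n - u)] > 0L & s[(u + 1L):n] > 0L
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      stretch <- r$lengths[k] + u          # bp length of the periodic run
      copies <- stretch %/% u
      if (copies < thr) next
      i0 <- starts[k] - 1L                 # 0-based start of the run
      motif <- substr(seq, i0 + 1L, i0 + u)
      if (is_periodic_motif(motif)) next   # generated by a smaller unit
      recs[[length(recs) + 1L]] <- data.frame(
        motif = motif, unit_len = u, copies = copies,
        start = i0, end = i0 + copies * u,
        ssr_type = paste0("p", u), stringsAsFactors = FALSE)
    }
  }
  if (!length(recs)) {
    out <- data.frame(motif = character(), unit_len = integer(),
                      copies = integer(), start = integer(), end = integer(),
                      ssr_type = character(), region = character(),
                      stringsAsFactors = FALSE)
    class(out) <- c("ssr_table", class(out))
    return(out)
  }
  out <- do.call(rbind, recs)
  out <- out[order(out$start, out$end), , drop = FALSE]
  if (compound && nrow(out) > 1L) {
    grp <- cumsum(c(1L, as.integer(out$start[-1L] - out$end[-nrow(out)] >
                                     compound_max_gap)))
    merged <- lapply(split(seq_len(nrow(out)), grp), function(ix) {
      if (length(ix) == 1L) return(out[ix, , drop = FALSE])
      data.frame(motif = paste(out$motif[ix], collapse = "/"),
                 unit_len = NA_integer_, copies = NA_integer_,
                 start = min(out$start[ix]), end = max(out$end[ix]),
                 ssr_type = "compound", stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, merged)
    out <- out[order(out$start), , drop = FALSE]
  }
  out$region <- region_of(out$start, part)
  rownames(out) <- NULL
  class(out) <- c("ssr_table", class(out))
  out
}

#' Scan dispersed long repeats in four orientation classes
#'
#' Reports all maximal exact repeat pairs of length >= `min_len` where the
#' second copy is the identity (`forward`), reversal (`reverse`), complement
#' (`complement`) or reverse complement (`palindromic`) of the first. When a
#' partition is supplied the scan runs on the LSC+IRb+SSC portion of the
#' canonical sequence (the IRa copy is dropped), so the genome-scale IRa/IRb
#' pair itself is never reported; records are labelled with the regions of
#' both copies. Matches are mismatch-free; pairs contained in a longer pair
#' of the same class are suppressed.
#'
#' @param genome an [annotated_genome()] (canonical orientation when `part`
#'   is given) or plain DNA string.
#' @param min_len minimum repeat length in bp (>= semantics; default 30).
#' @param classes subset of the four repeat classes to scan.
#' @param part optional `quadripartite_partition`; restricts the scan to
#'   LSC/IRb/SSC and enables region labels.
#' @return data frame of class `repeat_table`: `class`, `length`, `pos1`,
#'   `pos2` (0-based starts, `pos1 <= pos2`), `region1`, `region2`.
#' @export
find_long_repeats <- function(genome, min_len = 30L,
                              classes = c("forward", "reverse", "complement",
                                          "palindromic"),
                              part = NULL) {
  classes <- match.arg(classes, several.ok = TRUE)
  seq <- if (inherits(genome, "annotated_genome")) {
    if (!is.null(part)) {
      cs <- canonical_seq(genome, part)
      substr(cs, 1L, part$ira[1])
    } else genome$seq
  } else toupper(genome)
  bn <- nchar(seq)
  res <- list()
  for (cl in classes) {
    if (cl == "forward") {
      m <- max_matches_cpp(seq, seq, as.integer(min_len), self_pairs = FALSE)
      if (nrow(m)) {
        p1 <- m$start_b; p2 <- m$start_a; L <- m$len
      } else p1 <- p2 <- L <- integer(0)
    } else if (cl == "complement") {
      m <- max_matches_cpp(seq, comp_cpp(seq), as.integer(min_len),
                           self_pairs = FALSE)
      if (nrow(m)) {
        p1 <- m$start_b; p2 <- m$start_a; L <- m$len
      } else p1 <- p2 <- L <- integer(0)
    } else {
      b <- if (cl == "reverse") rev_cpp(seq) else revcomp_cpp(seq)
      m <- max_matches_cpp(seq, b, as.integer(min_len), self_pairs = TRUE)
      if (nrow(m)) {
        i <- m$start_a
        j <- bn - m$start_b - m$len   # second copy start on the forward strand
        L <- m$len
        p1 <- pmin(i, j); p2 <- pmax(i, j)
        keep <- !duplicated(paste(p1, p2, L)) & !(i == j)
        p1 <- p1[keep]; p2 <- p2[keep]; L <- L[keep]
      } else p1 <- p2 <- L <- integer(0)
    }
    if (length(L))
      res[[length(res) + 1L]] <- data.frame(
        class = cl, length = L, pos1 = p1, pos2 = p2,
        stringsAsFactors = FALSE)
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(class = character(), length = integer(), pos1 = integer(),
               pos2 = integer(), stringsAsFactors = FALSE)
  out <- out[order(out$class, out$pos1, out$pos2), , drop = FALSE]
  out$region1 <- region_of(out$pos1, part)
  out$region2 <- region_of(out$pos2, part)
  rownames(out) <- NULL
  class(out) <- c("repeat_table", class(out))
  out
}
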