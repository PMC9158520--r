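# Gap-aware nucleotide diversity (ratio-of-sums, pixy-style), site
# classification, sliding windows and hypervariable-region merging.

#' Per-column alignment statistics
#'
#' For every column: the number of valid characters (`A,C,G,T`; gaps and `N`
#' are invalid), the number of differing pairs among valid characters, the
#' number of comparable pairs `n_valid * (n_valid - 1) / 2`, and a status:
#' `invalid` (fewer than 2 valid characters), `invariant`,
#' `parsimony_informative` (>= 2 distinct bases each in >= 2 sequences) or
#' `singleton` (variable but not parsimony-informative).
#'
#' @param aln an [alignment_matrix()].
#' @return data frame with one row per column: `col` (0-based), `n_valid`,
#'   `n_pairs`, `n_diff_pairs`, `status`.
#' @export
site_stats <- function(aln) {
  x <- aln$x
  cnt <- vapply(1:4, function(b) .colSums(x == b, nrow(x), ncol(x)),
                numeric(ncol(x)))
  if (is.null(dim(cnt))) cnt <- matrix(cnt, nrow = 1L) # single-column case
  n_valid <- rowSums(cnt)
  n_pairs <- n_valid * (n_valid - 1) / 2
  n_same <- rowSums(cnt * (cnt - 1) / 2)
  n_diff <- n_pairs - n_same
  n_distinct <- rowSums(cnt > 0)
  n_ge2 <- rowSums(cnt >= 2)
  status <- ifelse(n_valid < 2, "invalid",
            ifelse(n_distinct == 1, "invariant",
            ifelse(n_distinct >= 2 & n_ge2 >= 2, "parsimony_informative",
                   "singleton")))
  data.frame(col = seq_len(ncol(x)) - 1L,
             n_valid = as.integer(n_valid),
             n_pairs = n_pairs, n_diff_pairs = n_diff,
             status = status, stringsAsFactors = FALSE)
}

#' Classify one alignment column
#'
#' @param column character vector of single characters drawn from one column.
#' @return one-row data frame as in [site_stats()] (without `col`).
#' @export
classify_site <- function(column) {
  aln <- alignment_matrix(setNames(column, paste0("s", seq_along(column))))
  st <- site_stats(aln)
  st[, setdiff(names(st), "col")]
}

#' Nucleotide diversity over a column interval
#'
#' The gap-aware ratio-of-sums estimator: the sum over columns of differing
#' pairs divided by the sum over columns of comparable pairs. Columns with
#' fewer than two valid characters contribute zero to both sums; if no
#' comparable pair exists in the interval the estimate is `NA`. This is the
#' "unbiased in the presence of gaps" construction popularised by pixy, and
#' deliberately not the mean of per-column (or per-window) pi values.
#'
#' @param aln an [alignment_matrix()].
#' @param start,end 0-based half-open column interval.
#' @param stats optional precomputed [site_stats()] for `aln`.
#' @return list with `pi`, `n_pis` (parsimony-informative columns),
#'   `n_singleton`.
#' @export
window_pi <- function(aln, start, end, stats = NULL) {
  if (!(start >= 0 && end <= aln$n_col && start < end))
    stop("empty or out-of-range interval [", start, ",", end, ")")
  if (is.null(stats)) stats <- site_stats(aln)
  ix <- (start + 1L):end
  D <- sum(stats$n_diff_pairs[ix])
  C <- sum(stats$n_pairs[ix])
  list(pi = if (C > 0) D / C else NA_real_,
       n_pis = sum(stats$status[ix] == "parsimony_informative"),
       n_singleton = sum(stats$status[ix] == "singleton"))
}

#' Sliding-window diversity scan
#'
#' Windows start at 0, `step`, `2*step`, ... while the start lies inside the
#' alignment; each spans `min(win_len, remainder)` columns. The reported
#' midpoint is the plotting convention for diversity profiles.
#'
#' @param aln an [alignment_matrix()].
#' @param win_len window length in alignment columns (default 600).
#' @param step step size in columns (default 200).
#' @return data frame of class `window_stats`: `start`, `end`, `midpoint`,
#'   `pi`, `n_pis`, `n_singleton`.
#' @export
sliding_windows <- function(aln, win_len = 600L, step = 200L) {
  stopifnot(aln$n_col >= 1L, win_len >= 1L, step >= 1L)
  if (win_len < step)
    warning("win_len < step leaves uncovered columns between windows")
  stats <- site_stats(aln)
  cd <- cumsum(stats$n_diff_pairs)
  cc <- cumsum(stats$n_pairs)
  cp <- cumsum(stats$status == "parsimony_informative")
  cs <- cumsum(stats$status == "singleton")
  at <- function(v, i) if (i == 0L) 0 else v[i] # prefix sum lookup
  starts <- seq(0L, aln$n_col - 1L, by = as.integer(step))
  ends <- pmin(starts + as.integer(win_len), aln$n_col)
  D <- vapply(seq_along(starts),
              function(k) at(cd, ends[k]) - at(cd, starts[k]), numeric(1))
  C <- vapply(seq_along(starts),
              function(k) at(cc, ends[k]) - at(cc, starts[k]), numeric(1))
  out <- data.frame(
    start = starts, end = ends, midpoint = (starts + ends) / 2,
    pi = ifelse(C > 0, D / C, NA_real_),
    n_pis = vapply(seq_along(starts), function(k)
      as.integer(at(cp, ends[k]) - at(cp, starts[k])), integer(1)),
    n_singleton = vapply(seq_along(starts), function(k)
      as.integer(at(cs, ends[k]) - at(cs, starts[k])), integer(1)))
  class(out) <- c("window_stats", class(out))
  out
}

#' Merge qualifying windows into hypervariable regions
#'
#' A window qualifies when `pi > pi_min` and `n_pis > pis_min` (strict
#' inequalities). Maximal runs of consecutive windows in the sliding series
#' are merged; each region spans from the first qualifying window's start to
#' the last one's end, and its statistics (length, singleton and
#' parsimony-informative counts, pi) are recomputed over the merged column
#' span - not aggregated from the window values.
#'
#' @param windows result of [sliding_windows()].
#' @param aln the alignment the windows were computed on.
#' @param pi_min,pis_min qualification thresholds (defaults 0.01 and 25).
#' @return data frame of class `hypervariable_regions`: `start`, `end`,
#'   `length`, `n_svs`, `n_pip`, `pi`, `name` (NA until [name_region()]).
#' @export
merge_hotspots <- function(windows, aln, pi_min = 0.01, pis_min = 25L) {
  qual <- !is.na(windows$pi) & windows$pi > pi_min & windows$n_pis > pis_min
  empty <- data.frame(start = integer(), end = integer(), length = integer(),
                      n_svs = integer(), n_pip = integer(), pi = numeric(),
                      name = character(), stringsAsFactors = FALSE)
  class(empty) <- c("hypervariable_regions", class(empty))
  if (!any(qual)) return(empty)
  stats <- site_stats(aln)
  idx <- which(qual)
  runs <- split(idx, cumsum(c(1L, diff(idx) != 1L)))
  rows <- lapply(runs, function(ix) {
    s <- as.integer(windows$start[ix[1]])
    e <- as.integer(windows$end[ix[length(ix)]])
    wp <- window_pi(aln, s, e, stats = stats)
    data.frame(start = s, end = e, length = e - s,
               n_svs = wp$n_singleton, n_pip = wp$n_pis, pi = wp$pi,
               name = NA_character_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("hypervariable_regions", class(out))
  out
}

#' Project alignment columns onto a reference sequence
#'
#' Maps a 0-based half-open alignment-column interval to reference
#' coordinates by skipping the reference row's gap columns.
#'
#' @param aln an [alignment_matrix()] containing `ref_id`.
#' @param ref_id id of the reference row.
#' @param start,end alignment-column interval.
#' @return `c(start, end)` on the reference (0-based half-open), or `NULL`
#'   when the interval maps entirely into a reference gap.
#' @export
project_to_reference <- function(aln, ref_id, start, end) {
  stopifnot(ref_id %in% aln$ids)
  row <- aln$x[match(ref_id, aln$ids), ]
  nongap <- row != 0L
  ix <- (start + 1L):end
  hit <- which(nongap[ix])
  if (!length(hit)) return(NULL)
  before <- cumsum(nongap) # ref positions consumed up to each column
  rs <- before[ix[hit[1]]] - 1L        # 0-based ref coord of first non-gap col
  re <- before[ix[hit[length(hit)]]]   # half-open end
  c(rs, re)
}

#' Label a region by its flanking genes
#'
#' Projects the region onto an annotated reference genome and names it after
#' the genes flanking (or containing) it, `"geneL-geneR"`, the intergenic
#' spacer naming convention of plastid marker tables.
#'
#' @param region list or one-row data frame with `start`, `end` (alignment
#'   columns).
#' @param ref_genome an [annotated_genome()] whose coordinates match the
#'   reference row of the alignment.
#' @param aln the alignment.
#' @param ref_id id of the reference row in `aln`.
#' @return a label string, or `"unplaced"` when the region maps into a
#'   reference gap.
#' @export
name_region <- function(region, ref_genome, aln, ref_id) {
  pr <- project_to_reference(aln, ref_id, region$start, region$end)
  if (is.null(pr)) return("unplaced")
  f <- ref_genome$features
  f <- f[f$kind %in% c("gene", "tRNA", "rRNA", "CDS", "pseudogene"), ,
         drop = FALSE]
  f <- f[!is.na(f$name), , drop = FALSE]
  if (!nrow(f)) return("unplaced")
  f <- f[order(f$start), , drop = FALSE]
  rs <- pr[1]; re <- pr[2]
  inside <- f$start <= rs & f$end >= re
  if (any(inside)) return(f$name[which(inside)[1]])
  left <- f[f$start <= rs, , drop = FALSE]
  right <- f[f$end >= re, , drop = FALSE]
  gl <- if (nrow(left)) left$name[which.max(left$end)] else
    f$name[which.max(f$end)] # wrap around the origin
  gr <- if (nrow(right)) right$name[which.min(right$start)] else f$name[1]
  if (identical(gl, gr)) gl else paste0(gl, "-", gr)
}
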