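# Minimal GenBank flat-file reader for organellar records: LOCUS topology,
# gene/tRNA/rRNA/CDS features with join/complement locations, /pseudo flag,
# ORIGIN sequence. Coordinates converted from 1-based inclusive to 0-based
# half-open on read.

#' Read a GenBank flat file
#'
#' Parses a single-record GenBank flat file into an [annotated_genome()].
#' Features of kind gene/tRNA/rRNA/CDS are retained, one row per location
#' interval (exons of `join(...)` locations keep their order). Features
#' carrying a `/pseudo` or `/pseudogene` qualifier get kind `pseudogene`.
#' A two-interval join that runs through the origin of a circular record
#' (`join(a..N, 1..b)`) is merged into one origin-spanning interval with
#' unwrapped coordinates.
#'
#' @param path path to the GenBank file.
#' @return an `annotated_genome`.
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  id <- NA_character_
  circular <- FALSE
  if (length(locus)) {
    toks <- strsplit(trimws(sub("^LOCUS", "", locus[1])), "\\s+")[[1]]
    id <- toks[1]
    circular <- any(tolower(toks) == "circular")
  }
  acc <- grep("^VERSION\\s+", lines, value = TRUE)
  if (length(acc)) {
    v <- strsplit(trimws(sub("^VERSION", "", acc[1])), "\\s+")[[1]]
    if (length(v) && nzchar(v[1])) id <- v[1]
  }

  ori <- grep("^ORIGIN", lines)
  if (!length(ori)) stop("GenBank format error: no ORIGIN sequence in ", path)
  endrec <- grep("^//", lines)
  endrec <- if (length(endrec)) endrec[endrec > ori[1]][1] else length(lines) + 1L
  seq_lines <- lines[(ori[1] + 1L):(endrec - 1L)]
  seq <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nchar(seq)) stop("GenBank format error: empty sequence in ", path)

  featstart <- grep("^FEATURES", lines)
  feats <- empty_features()
  if (length(featstart)) {
    block <- lines[(featstart[1] + 1L):(ori[1] - 1L)]
    # group: a new feature begins when cols 6-20 hold a key
    keyline <- grepl("^ {5}\\S", block)
    grp <- cumsum(keyline)
    keep <- grp > 0L
    block <- block[keep]; grp <- grp[keep]; keyline <- keyline[keep]
    rows <- list()
    for (g in unique(grp)) {
      gl <- block[grp == g]
      key <- sub("^\\s*(\\S+).*$", "\\1", gl[1])
      if (!key %in% c("gene", "tRNA", "rRNA", "CDS")) next
      # location may continue over lines until the first qualifier
      body <- sub("^\\s*\\S+\\s*", "", gl[1])
      i <- 2L
      while (i <= length(gl) && !grepl("^\\s*/", gl[i])) {
        body <- paste0(body, trimws(gl[i])); i <- i + 1L
      }
      quals <- gl[grepl("^\\s*/", gl)]
      name <- NA_character_
      m <- grep("^\\s*/gene=", quals, value = TRUE)
      if (!length(m)) m <- grep("^\\s*/locus_tag=", quals, value = TRUE)
      if (length(m)) name <- gsub("\"", "", sub("^[^=]*=", "", m[1]))
      pseudo <- any(grepl("^\\s*/pseudo(gene)?\\b", quals))
      loc <- tryCatch(parse_gb_location(body),
                      error = function(e) NULL)
      if (is.null(loc)) {
        warning(sprintf("skipping feature '%s' (%s): unparseable location '%s'",
                        name, key, body))
        next
      }
      kind <- if (pseudo) "pseudogene" else key
      rows[[length(rows) + 1L]] <- data.frame(
        name = name, kind = kind, strand = loc$strand,
        start = loc$start, end = loc$end, stringsAsFactors = FALSE)
    }
    if (length(rows)) feats <- do.call(rbind, rows)
  }

  n <- nchar(seq)
  feats <- normalize_origin_spans(feats, n, circular)
  annotated_genome(id = id, seq = seq, circular = circular, features = feats)
}

# "complement(join(123..456,600..700))" -> data.frame(start, end, strand),
# 0-based half-open. "<" / ">" partial markers are stripped.
parse_gb_location <- function(x) {
  x <- gsub("\\s", "", x)
  strand <- "+"
  while (grepl("^complement\\(", x)) {
    strand <- if (strand == "+") "-" else "+"
    x <- sub("^complement\\((.*)\\)$", "\\1", x)
  }
  x <- sub("^(join|order)\\((.*)\\)$", "\\2", x)
  parts <- strsplit(x, ",")[[1]]
  parts <- gsub("[<>]", "", parts)
  starts <- integer(0); ends <- integer(0)
  for (p in parts) {
    pp <- sub("^complement\\((.*)\\)$", "\\1", p) # per-exon complement
    if (grepl("^[0-9]+\\.\\.[0-9]+$", pp)) {
      ab <- as.integer(strsplit(pp, "\\.\\.")[[1]])
    } else if (grepl("^[0-9]+$", pp)) {
      ab <- c(as.integer(pp), as.integer(pp))
    } else stop("bad location part: ", p)
    if (ab[1] > ab[2]) stop("bad interval: ", p)
    starts <- c(starts, ab[1] - 1L) # 1-based inclusive -> 0-based half-open
    ends <- c(ends, ab[2])
  }
  data.frame(start = starts, end = ends, strand = strand,
             stringsAsFactors = FALSE)
}

# merge join(a..n, 1..b) pairs on circular records into one unwrapped interval
normalize_origin_spans <- function(feats, n, circular) {
  if (!circular || nrow(feats) < 2L) return(feats)
  out <- feats[0, ]
  i <- 1L
  while (i <= nrow(feats)) {
    if (i < nrow(feats) &&
        (isTRUE(feats$name[i] == feats$name[i + 1L]) ||
           (is.na(feats$name[i]) && is.na(feats$name[i + 1L]))) &&
        feats$kind[i] == feats$kind[i + 1L] &&
        feats$strand[i] == feats$strand[i + 1L] &&
        feats$end[i] == n && feats$start[i + 1L] == 0L) {
      row <- feats[i, ]
      row$end <- n + feats$end[i + 1L]
      out <- rbind(out, row)
      i <- i + 2L
    } else {
      out <- rbind(out, feats[i, ])
      i <- i + 1L
    }
  }
  rownames(out) <- NULL
  out
}
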