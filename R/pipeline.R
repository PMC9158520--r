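# End-to-end comparison over a directory of genomes, emitting the report
# tables (structure / junctions / SSRs / repeats / hotspots / per-gene LRTs).

#' Default run configuration
#'
#' @return list of all tunable parameters with their defaults; see
#'   [run_comparison()].
#' @export
default_run_config <- function() {
  list(genomes = character(), alignment = NULL,
       ref_genbank = NULL, ref_id = NULL,
       codon_alignments = NULL, tree = NULL, foreground = NULL,
       out_dir = ".",
       min_ir_len = 1000L,
       ssr_thresholds = c(`1` = 11L, `2` = 6L, `3` = 5L, `4` = 4L,
                          `5` = 3L, `6` = 3L),
       compound_max_gap = 100L,
       repeat_min_len = 30L,
       win_len = 600L, step = 200L,
       pi_min = 0.01, pis_min = 25L,
       alpha = 0.05,
       tracked_genes = c("rps19", "rpl2", "trnH", "ycf1", "trnN", "ndhF"),
       seed = 1L)
}

read_any_genome <- function(path) {
  if (grepl("\\.(gb|gbk|gbff|genbank)$", path, ignore.case = TRUE)) {
    read_genbank(path)
  } else {
    x <- read_fasta(path)
    annotated_genome(id = names(x)[1], seq = x[[1]])
  }
}

#' Run the full comparative pipeline
#'
#' For every genome: quadripartite structure + GC (one row of the structure
#' table), junction offsets, SSR and long-repeat tables. If an alignment is
#' configured: sliding-window diversity and merged hypervariable regions
#' (named against the reference annotation when one is given). If codon
#' alignments plus a tree are configured: a per-gene one-ratio vs two-ratio
#' LRT table. Any stage failure is logged into the manifest and isolated;
#' remaining stages still run. All tables are written as TSV into
#' `config$out_dir` along with a `manifest.yaml` recording the configuration,
#' package version and seed, so a rerun with the same config reproduces the
#' tables.
#'
#' @param config a list (see [default_run_config()]) or the path of a YAML
#'   file holding one. `genomes` may be file paths or a directory.
#' @return invisible list of the tables
#'   (`structure`, `junctions`, `ssrs`, `repeats`, `windows`, `hotspots`,
#'   `lrt`) plus the `manifest`.
#' @export
run_comparison <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_run_config(), config)
  if (length(cfg$genomes) == 1L && dir.exists(cfg$genomes[1]))
    cfg$genomes <- list.files(cfg$genomes, full.names = TRUE,
                              pattern = "\\.(gb|gbk|gbff|genbank|fa|fasta)$",
                              ignore.case = TRUE)
  if (!length(cfg$genomes)) stop("no readable genome configured")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  issues <- character()
  note <- function(msg) {
    issues <<- c(issues, msg)
    message(msg)
  }

  structure_tab <- junction_tab <- ssr_tab <- rep_tab <- NULL
  for (path in cfg$genomes) {
    res <- tryCatch({
      g <- read_any_genome(path)
      part <- detect_inverted_repeats(g, cfg$min_ir_len)
      can <- canonicalize_genome(g, part)
      gc <- region_gc(g, part)
      srow <- data.frame(accession = g$id, total = part$n,
                         lsc = diff(part$lsc), ssc = diff(part$ssc),
                         ir = part$ir_len,
                         gc_total = round(gc$total, 2),
                         gc_lsc = round(gc$lsc, 2),
                         gc_ssc = round(gc$ssc, 2),
                         gc_ir = round(gc$ir, 2),
                         stringsAsFactors = FALSE)
      jrow <- if (nrow(can$genome$features)) {
        cbind(accession = g$id,
              junction_report(can$partition, can$genome$features,
                              cfg$tracked_genes))
      } else NULL
      ssr <- find_ssrs(can$genome, thresholds = cfg$ssr_thresholds,
                       compound_max_gap = cfg$compound_max_gap,
                       part = can$partition)
      lrep <- find_long_repeats(can$genome, min_len = cfg$repeat_min_len,
                                part = can$partition)
      list(srow = srow, jrow = jrow,
           ssr = if (nrow(ssr)) cbind(accession = g$id, ssr) else NULL,
           lrep = if (nrow(lrep)) cbind(accession = g$id, lrep) else NULL)
    }, error = function(e) {
      note(sprintf("genome stage failed for %s: %s", path,
                   conditionMessage(e)))
      NULL
    })
    if (is.null(res)) next
    structure_tab <- rbind(structure_tab, res$srow)
    junction_tab <- rbind(junction_tab, res$jrow)
    ssr_tab <- rbind(ssr_tab, res$ssr)
    rep_tab <- rbind(rep_tab, res$lrep)
  }

  windows <- hotspots <- NULL
  if (!is.null(cfg$alignment)) {
    ok <- tryCatch({
      aln <- read_alignment(cfg$alignment)
      windows <- sliding_windows(aln, cfg$win_len, cfg$step)
      hotspots <- merge_hotspots(windows, aln, cfg$pi_min, cfg$pis_min)
      if (!is.null(cfg$ref_genbank) && !is.null(cfg$ref_id) &&
          nrow(hotspots)) {
        ref <- read_genbank(cfg$ref_genbank)
        hotspots$name <- vapply(seq_len(nrow(hotspots)), function(i)
          name_region(hotspots[i, ], ref, aln, cfg$ref_id), character(1))
      }
      TRUE
    }, error = function(e) {
      note(sprintf("diversity stage failed: %s", conditionMessage(e)))
      FALSE
    })
    if (!ok) windows <- hotspots <- NULL
  } else {
    note("diversity stage skipped: no alignment configured")
  }

  lrt_tab <- NULL
  if (!is.null(cfg$codon_alignments) && !is.null(cfg$tree) &&
      !is.null(cfg$foreground)) {
    tree <- tryCatch(read_tree(cfg$tree), error = function(e) {
      note(sprintf("selection stage failed: %s", conditionMessage(e)))
      NULL
    })
    if (!is.null(tree)) for (gene in names(cfg$codon_alignments)) {
      row <- tryCatch({
        caln <- codon_alignment_from_dna(
          read_fasta(cfg$codon_alignments[[gene]]))
        keep <- ape::keep.tip(tree, intersect(tree$tip.label, caln$ids))
        fits <- branch_model_lrt(caln, keep, foreground = cfg$foreground,
                                 alpha = cfg$alpha, seed = cfg$seed)
        data.frame(gene = gene,
                   lnL0 = fits$null$lnL, lnL1 = fits$alt$lnL,
                   omega0 = fits$lrt$omega_null,
                   omega_b = fits$lrt$omega_background,
                   omega_f = fits$lrt$omega_foreground,
                   stat = fits$lrt$statistic, p = fits$lrt$p,
                   verdict = if (fits$lrt$positive_selection)
                     "positive_selection"
                   else if (fits$lrt$fast_evolving) "fast_evolving"
                   else if (fits$lrt$significant) "significant"
                   else "ns",
                   stringsAsFactors = FALSE)
      }, error = function(e) {
        note(sprintf("selection stage failed for %s: %s", gene,
                     conditionMessage(e)))
        NULL
      })
      lrt_tab <- rbind(lrt_tab, row)
    }
  } else {
    note("selection stage skipped: codon alignments / tree / foreground not configured")
  }

  wtsv <- function(tab, name) {
    if (is.null(tab)) return(invisible())
    write.table(tab, file.path(cfg$out_dir, name), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  wtsv(structure_tab, "structure.tsv")
  wtsv(junction_tab, "junctions.tsv")
  wtsv(ssr_tab, "ssrs.tsv")
  wtsv(rep_tab, "repeats.tsv")
  wtsv(windows, "windows.tsv")
  if (!is.null(hotspots))
    write_regions(hotspots, file.path(cfg$out_dir, "hotspots.tsv"), "tsv")
  wtsv(lrt_tab, "lrt.tsv")

  manifest <- list(
    package = "plastome",
    version = as.character(packageVersion("plastome")),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "ssr_thresholds")],
    ssr_thresholds = as.list(cfg$ssr_thresholds),
    n_genomes = if (is.null(structure_tab)) 0L else nrow(structure_tab),
    issues = as.list(issues))
  yaml::write_yaml(manifest, file.path(cfg$out_dir, "manifest.yaml"))

  invisible(list(structure = structure_tab, junctions = junction_tab,
                 ssrs = ssr_tab, repeats = rep_tab, windows = windows,
                 hotspots = hotspots, lrt = lrt_tab, manifest = manifest))
}
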