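# Synthetic GenBank record written at test time (no stored binary fixtures).

gb_feature_line <- function(key, loc) {
  sprintf("     %-16s%s", key, loc)
}

gb_qualifier_line <- function(q) {
  paste0(strrep(" ", 21), q)
}

write_toy_genbank <- function(path, n = 120L, seed = 42L) {
  set.seed(seed)
  seq <- paste(sample(c("a", "c", "g", "t"), n, replace = TRUE),
               collapse = "")
  lines <- c(
    sprintf("LOCUS       SYNTH01 %d bp    DNA     circular PLN 01-JAN-2024",
            n),
    "DEFINITION  synthetic toy plastome fragment for parser tests.",
    "VERSION     SYNTH01.1",
    "FEATURES             Location/Qualifiers",
    gb_feature_line("source", sprintf("1..%d", n)),
    gb_qualifier_line("/organism=\"synthetic construct\""),
    gb_feature_line("gene", "1..6"),
    gb_qualifier_line("/gene=\"psbA\""),
    gb_feature_line("CDS", "join(10..21,30..38)"),
    gb_qualifier_line("/gene=\"ycf3\""),
    gb_feature_line("gene", "complement(40..60)"),
    gb_qualifier_line("/gene=\"matK\""),
    gb_qualifier_line("/pseudo"),
    gb_feature_line("tRNA", "complement(70..80)"),
    gb_qualifier_line("/gene=\"trnH-GUG\""),
    # origin-spanning gene on a circular record
    gb_feature_line("gene", sprintf("complement(join(%d..%d,1..8))",
                                    n - 9L, n)),
    gb_qualifier_line("/gene=\"rps19\""),
    "ORIGIN",
    paste0("        1 ", substr(seq, 1, min(60, n))),
    if (n > 60) paste0("       61 ", substr(seq, 61, n)),
    "//")
  writeLines(lines, path)
  toupper(seq)
}
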