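# Minimal GenBank flat-file support for the polyadenylation-signal census.
#
# Only the slice of the format the census needs is handled: LOCUS names,
# the FEATURES table (keys, simple or complement() spans, quoted
# qualifiers), and the ORIGIN sequence block. No installed R package parses
# GenBank feature tables, so this focused reader/writer lives here; it is
# exercised head-to-head against the GFF3 route on identical corpora.

format_genbank_origin <- function(seq) {
  n <- nchar(seq)
  starts <- seq(1L, n, by = 60L)
  vapply(starts, function(s) {
    chunk <- substr(seq, s, min(s + 59L, n))
    blocks <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    sprintf("%9d %s", s, paste(tolower(blocks), collapse = " "))
  }, character(1))
}

write_corpus_genbank <- function(path, res, truth, seqs, pad, legacy_dialect) {
  by_tx <- split(seq_len(nrow(truth)), truth$transcript_id)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(res$tid)) {
    id <- res$tid[i]
    span <- sprintf("%d..%d", pad + 1L, pad + res$tlen[i])
    if (res$strand[i] == "-") span <- sprintf("complement(%s)", span)
    lines <- c(
      sprintf("LOCUS       %-16s %d bp    DNA     linear   SYN 01-JAN-2026",
              id, res$clen[i]),
      "DEFINITION  synthetic transcript corpus record.",
      sprintf("ACCESSION   %s", id),
      "FEATURES             Location/Qualifiers",
      sprintf("     source          1..%d", res$clen[i]),
      sprintf("     mRNA            %s", span),
      sprintf("                     /transcript_id=\"%s\"", id))
    for (j in by_tx[[id]]) {
      fspan <- sprintf("%d..%d", truth$start[j], truth$end[j])
      if (truth$strand[j] == "-") fspan <- sprintf("complement(%s)", fspan)
      if (legacy_dialect) {
        lines <- c(lines,
                   sprintf("     polyA_signal    %s", fspan),
                   sprintf("                     /transcript_id=\"%s\"", id))
      } else {
        lines <- c(lines,
                   sprintf("     regulatory      %s", fspan),
                   "                     /regulatory_class=\"polyA_signal_sequence\"",
                   sprintf("                     /transcript_id=\"%s\"", id))
      }
    }
    lines <- c(lines, "ORIGIN", format_genbank_origin(seqs[i]), "//")
    writeLines(lines, con)
  }
  invisible(path)
}

# Parse a (multi-record) GenBank flat file into feature and sequence tables.
# Returns list(features = data.frame(chrom, key, start, end, strand,
# qualifiers...), sequences = named character).
read_genbank <- function(path) {
  lines <- readLines(path)
  rec_id <- cumsum(c(TRUE, utils::head(lines, -1) == "//"))
  locus_idx <- grep("^LOCUS ", lines)
  locus_name <- sub("^LOCUS +(\\S+).*$", "\\1", lines[locus_idx])
  chrom_of_line <- locus_name[findInterval(seq_along(lines), locus_idx)]

  in_origin <- {
    o <- grepl("^ORIGIN", lines)
    e <- lines == "//"
    cumsum(o) - cumsum(e)
  } > 0
  seq_lines <- in_origin & grepl("^\\s*\\d", lines)
  seq_txt <- toupper(gsub("[^A-Za-z]", "", lines[seq_lines]))
  sequences <- vapply(split(seq_txt, chrom_of_line[seq_lines]),
                      paste, character(1), collapse = "")
  sequences <- sequences[unique(locus_name)]

  # feature lines: key starts in column 6; qualifier/continuation lines are
  # indented to column 22
  feat_idx <- grep("^ {5}\\S", lines)
  feat_idx <- feat_idx[!in_origin[feat_idx]]
  keys <- sub("^ {5}(\\S+).*$", "\\1", lines[feat_idx])
  locs <- sub("^ {5}\\S+\\s+(\\S+)\\s*$", "\\1", lines[feat_idx])
  strand <- ifelse(grepl("^complement\\(", locs), "-", "+")
  spans <- gsub("complement\\(|\\)", "", locs)
  start <- suppressWarnings(as.integer(sub("\\.\\..*$", "", spans)))
  end <- suppressWarnings(as.integer(sub("^.*\\.\\.", "", spans)))

  qual_idx <- grep("^ {21}/", lines)
  qual_owner <- findInterval(qual_idx, feat_idx)
  qtxt <- sub("^ {21}/", "", lines[qual_idx])
  qname <- sub("=.*$", "", qtxt)
  qval <- ifelse(grepl("=", qtxt),
                 gsub("^\"|\"$", "", sub("^[^=]*=", "", qtxt)), "")
  get_qual <- function(nm) {
    out <- rep(NA_character_, length(feat_idx))
    sel <- qname == nm & qual_owner >= 1
    out[qual_owner[sel]] <- qval[sel]
    out
  }
  features <- data.frame(chrom = chrom_of_line[feat_idx], key = keys,
                         start = start, end = end, strand = strand,
                         regulatory_class = get_qual("regulatory_class"),
                         transcript_id = get_qual("transcript_id"),
                         stringsAsFactors = FALSE)
  list(features = features, sequences = sequences)
}
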