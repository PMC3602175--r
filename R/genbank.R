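# Minimal GenBank flat-file reader/writer.
#
# Covers the subset used for annotated viral genomes: LOCUS / DEFINITION /
# FEATURES (source + CDS with simple or complement() spans) / ORIGIN. Multiple
# records per file become multiple contigs. join() locations (spliced CDS) are
# rejected with a clear error; chlorovirus CDSs are unspliced.

parse_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !any(startsWith(lines, "LOCUS")))
    stop("format error: '", path, "' is not a GenBank flat file")
  rec_starts <- which(startsWith(lines, "LOCUS"))
  rec_ends <- which(trimws(lines) == "//")
  if (length(rec_ends) < length(rec_starts))
    rec_ends <- c(rec_ends, length(lines))
  contigs <- character(0)
  genes <- list()
  first_locus <- NULL
  for (r in seq_along(rec_starts)) {
    block <- lines[rec_starts[r]:rec_ends[r]]
    locus <- strsplit(trimws(block[1]), "\\s+")[[1]][2]
    if (is.null(first_locus)) first_locus <- locus
    ori <- which(startsWith(block, "ORIGIN"))
    if (!length(ori)) stop("format error: record '", locus, "' has no ORIGIN")
    seq_lines <- block[(ori + 1L):length(block)]
    seq_lines <- seq_lines[trimws(seq_lines) != "//"]
    seq <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
    contigs[locus] <- seq

    feat <- which(startsWith(block, "FEATURES"))
    if (length(feat)) {
      fblock <- block[(feat + 1L):(ori - 1L)]
      starts <- grep("^ {5}\\S", fblock)
      bounds <- c(starts, length(fblock) + 1L)
      for (i in seq_along(starts)) {
        fl <- fblock[starts[i]:(bounds[i + 1L] - 1L)]
        key <- sub("^ {5}(\\S+).*$", "\\1", fl[1])
        if (key != "CDS") next
        txt <- paste(sub("^ +", "", fl), collapse = " ")
        loc <- sub("^CDS +", "", sub(" +/.*$", "", txt))
        loc <- gsub(" ", "", loc)
        if (grepl("join", loc, fixed = TRUE))
          stop("coordinate error: join() locations are not supported (", loc, ")")
        strand <- "+"
        if (grepl("^complement\\(", loc)) {
          strand <- "-"
          loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
        }
        loc <- gsub("[<>]", "", loc)
        m <- regmatches(loc, regexec("^(\\d+)\\.\\.(\\d+)$", loc))[[1]]
        if (length(m) != 3L)
          stop("format error: cannot parse CDS location '", loc, "'")
        start1 <- as.integer(m[2]); end1 <- as.integer(m[3])
        qual <- function(name) {
          hit <- regmatches(txt, regexec(sprintf('/%s="([^"]*)"', name), txt))[[1]]
          if (length(hit) == 2L) hit[2] else {
            hit <- regmatches(txt, regexec(sprintf("/%s=([^ ]+)", name), txt))[[1]]
            if (length(hit) == 2L) hit[2] else NA_character_
          }
        }
        gid <- qual("locus_tag")
        if (is.na(gid)) gid <- qual("protein_id")
        if (is.na(gid)) gid <- qual("gene")
        if (is.na(gid))
          stop("format error: CDS at ", loc, " in '", locus,
               "' carries no identifier (locus_tag/protein_id/gene)")
        if (end1 > nchar(seq))
          stop("coordinate error: CDS '", gid, "' extends past contig end")
        ann <- qual("product")
        genes[[length(genes) + 1L]] <- data.frame(
          gene_id = gid, contig_id = locus,
          start = start1 - 1L, end = end1, strand = strand,
          annotation = if (is.na(ann)) "" else ann,
          stringsAsFactors = FALSE)
      }
    }
  }
  genes <- if (length(genes)) do.call(rbind, genes) else
    data.frame(gene_id = character(0), contig_id = character(0),
               start = integer(0), end = integer(0), strand = character(0),
               annotation = character(0), stringsAsFactors = FALSE)
  list(locus = first_locus, contigs = contigs, genes = genes)
}

write_genbank <- function(genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cid in names(genome$contigs)) {
    seq <- genome$contigs[[cid]]
    writeLines(sprintf("LOCUS       %s %d bp    DNA     linear   VRL",
                       cid, nchar(seq)), con)
    writeLines(sprintf("DEFINITION  %s contig %s.", genome$genome_id, cid), con)
    writeLines("FEATURES             Location/Qualifiers", con)
    writeLines(sprintf("     source          1..%d", nchar(seq)), con)
    g <- genome$genes[genome$genes$contig_id == cid, , drop = FALSE]
    for (i in seq_len(nrow(g))) {
      loc <- sprintf("%d..%d", g$start[i] + 1L, g$end[i])
      if (g$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
      writeLines(sprintf("     CDS             %s", loc), con)
      writeLines(sprintf('                     /locus_tag="%s"', g$gene_id[i]), con)
      if (nzchar(g$annotation[i]))
        writeLines(sprintf('                     /product="%s"',
                           gsub('"', "'", g$annotation[i])), con)
    }
    writeLines("ORIGIN", con)
    pos <- seq(1L, nchar(seq), by = 60L)
    for (p in pos) {
      chunk <- substr(seq, p, min(p + 59L, nchar(seq)))
      parts <- substring(chunk, seq(1L, nchar(chunk), 10L),
                         pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
      writeLines(sprintf("%9d %s", p, tolower(paste(parts, collapse = " "))), con)
    }
    writeLines("//", con)
  }
  invisible(path)
}
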