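#' Construct an annotated genome
#'
#' The central container of the package: an ordered set of contigs plus an
#' ordered table of protein-coding gene records for a single virus isolate,
#' tagged with the algal host group it infects (chloroviruses are grouped by
#' host as NC64A, Pbi or SAG viruses).
#'
#' Coordinates are stored 0-based half-open; file formats (GenBank, GFF3) use
#' 1-based inclusive coordinates and are converted at the I/O boundary.
#'
#' @param genome_id single string naming the genome.
#' @param contigs named character vector of contig nucleotide sequences, in
#'   the order given by the source file.
#' @param genes data.frame with columns `gene_id`, `contig_id`, `start`,
#'   `end` (0-based half-open), `strand` (`"+"`/`"-"`) and optionally
#'   `annotation`. Columns `cds` (strand-resolved coding sequence, 5'->3')
#'   and `protein` are computed from the contigs when absent.
#' @param host_group host-group label, one of `"NC64A"`, `"Pbi"`, `"SAG"` or
#'   `"other"`.
#' @return an object of class `annotated_genome`.
#' @export
annotated_genome <- function(genome_id, contigs, genes, host_group = "other") {
  stopifnot(is.character(genome_id), length(genome_id) == 1L)
  if (is.null(names(contigs)) || anyNA(names(contigs)) || any(names(contigs) == ""))
    stop("contigs must be a named character vector")
  contigs <- stats::setNames(toupper(as.character(contigs)), names(contigs))
  if (sum(nchar(contigs)) == 0L) stop("genome length must be > 0")
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  required <- c("gene_id", "contig_id", "start", "end", "strand")
  miss <- setdiff(required, names(genes))
  if (length(miss)) stop("genes is missing column(s): ", paste(miss, collapse = ", "))
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  if (!"annotation" %in% names(genes)) genes$annotation <- rep("", nrow(genes))
  if (nrow(genes)) {
    if (anyDuplicated(genes$gene_id)) stop("duplicate gene_id in genes")
    bad <- !(genes$contig_id %in% names(contigs))
    if (any(bad)) stop("gene(s) on unknown contig: ",
                       paste(genes$gene_id[bad], collapse = ", "))
    if (any(genes$end - genes$start <= 0L)) stop("gene with non-positive length")
    clen <- nchar(contigs)[genes$contig_id]
    over <- genes$start < 0L | genes$end > clen
    if (any(over)) stop("coordinate error: feature(s) extend past contig end: ",
                        paste(genes$gene_id[over], collapse = ", "))
    if (!all(genes$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
    if (!"cds" %in% names(genes)) {
      fwd <- substr(rep(contigs[genes$contig_id], 1L),
                    genes$start + 1L, genes$end)
      genes$cds <- ifelse(genes$strand == "+", fwd, revcomp(fwd))
    }
    if (!"protein" %in% names(genes)) {
      genes$protein <- translate_cds(genes$cds, genes$gene_id)
    }
    ord <- order(match(genes$contig_id, names(contigs)), genes$start)
    genes <- genes[ord, , drop = FALSE]
    rownames(genes) <- NULL
  } else {
    genes$cds <- character(0)
    genes$protein <- character(0)
  }
  structure(list(genome_id = genome_id,
                 host_group = host_group,
                 contigs = contigs,
                 genes = genes),
            class = "annotated_genome")
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf("annotated_genome '%s' (host group %s): %d contig(s), %s bp, %d gene(s)\n",
              x$genome_id, x$host_group, length(x$contigs),
              format(genome_length(x), big.mark = ","), nrow(x$genes)))
  invisible(x)
}

#' Total genome length (sum of contig lengths)
#' @param genome an `annotated_genome`.
#' @return integer number of nucleotides.
#' @export
genome_length <- function(genome) sum(nchar(genome$contigs))

#' Read an annotated genome from file
#'
#' Supports GenBank flat files and FASTA + GFF3 pairs. CDS features become
#' gene records; minus-strand coding sequences are reverse-complemented; the
#' file's 1-based inclusive coordinates are converted to the internal 0-based
#' half-open convention.
#'
#' @param path GenBank file, or FASTA file when `format = "fasta+gff"`.
#' @param format `"genbank"` or `"fasta+gff"`.
#' @param gff GFF3 annotation path (required for `"fasta+gff"`).
#' @param genome_id genome identifier; defaults to the file base name.
#' @param host_group host-group label (see [annotated_genome()]); host
#'   assignments come from experimental metadata, never from sequence.
#' @return an `annotated_genome`.
#' @export
read_genome <- function(path, format = c("genbank", "fasta+gff"), gff = NULL,
                        genome_id = NULL, host_group = "other") {
  format <- match.arg(format)
  if (format == "genbank") {
    parsed <- parse_genbank(path)
    contigs <- parsed$contigs
    genes <- parsed$genes
    genome_id <- genome_id %||% parsed$locus %||%
      sub("\\.[^.]*$", "", basename(path))
  } else {
    if (is.null(gff)) stop("format 'fasta+gff' requires a gff path")
    contigs <- as.character(Biostrings::readDNAStringSet(path))
    names(contigs) <- sub("\\s.*$", "", names(contigs))
    gr <- tryCatch(rtracklayer::import(gff, format = "gff3"),
                   error = function(e) stop("format error: cannot parse GFF3 '",
                                            gff, "': ", conditionMessage(e)))
    gr <- gr[S4Vectors::mcols(gr)$type == "CDS"]
    md <- S4Vectors::mcols(gr)
    ids <- as.character(md$ID %||% md$Name %||% md$locus_tag)
    if (is.null(ids) || anyNA(ids))
      stop("format error: CDS features must carry ID/Name/locus_tag identifiers")
    ann <- if ("product" %in% names(md)) as.character(md$product) else ""
    ann[is.na(ann)] <- ""
    genes <- data.frame(gene_id = ids,
                        contig_id = as.character(GenomicRanges::seqnames(gr)),
                        start = GenomicRanges::start(gr) - 1L,
                        end = GenomicRanges::end(gr),
                        strand = as.character(GenomicRanges::strand(gr)),
                        annotation = ann,
                        stringsAsFactors = FALSE)
    genes$strand[!genes$strand %in% c("+", "-")] <- "+"
    genome_id <- genome_id %||% sub("\\.[^.]*$", "", basename(path))
  }
  annotated_genome(genome_id, contigs, genes, host_group = host_group)
}

#' Write an annotated genome to file
#'
#' @param genome an `annotated_genome`.
#' @param path output GenBank file, or FASTA path for `"fasta+gff"`.
#' @param format `"genbank"` or `"fasta+gff"`.
#' @param gff GFF3 output path (required for `"fasta+gff"`).
#' @return invisibly, the path(s) written.
#' @export
write_genome <- function(genome, path, format = c("genbank", "fasta+gff"),
                         gff = NULL) {
  format <- match.arg(format)
  if (format == "genbank") {
    write_genbank(genome, path)
    return(invisible(path))
  }
  if (is.null(gff)) stop("format 'fasta+gff' requires a gff path")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome$contigs), path)
  g <- genome$genes
  attr_col <- sprintf("ID=%s%s", g$gene_id,
                      ifelse(nzchar(g$annotation),
                             paste0(";product=", gsub("[;=\t\n]", " ", g$annotation)),
                             ""))
  lines <- c("##gff-version 3",
             if (nrow(g)) sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t0\t%s",
                                  g$contig_id, "chlorocomp", "CDS",
                                  g$start + 1L, g$end, g$strand, attr_col))
  writeLines(lines, gff)
  invisible(c(path, gff))
}

#' G+C content of a genome
#'
#' Fraction of G+C over all contigs; ambiguity codes are excluded from both
#' numerator and denominator.
#'
#' @param genome an `annotated_genome`, or a character vector of sequences.
#' @return fraction in \[0, 1\].
#' @export
gc_content <- function(genome) {
  seqs <- if (inherits(genome, "annotated_genome")) genome$contigs else toupper(genome)
  s <- Biostrings::DNAStringSet(seqs)
  af <- Biostrings::letterFrequency(s, letters = c("A", "C", "G", "T"))
  gc <- sum(af[, c("C", "G")])
  tot <- sum(af)
  if (tot == 0L) stop("undefined value: no unambiguous bases")
  gc / tot
}

#' Per-host-group summary of genome %GC
#'
#' Median (standard order-statistic) and standard deviation of percent GC per
#' host group. Chlorovirus host groups have characteristic compositions:
#' NC64A, Pbi and SAG viruses centre near 40, 45 and 49% GC.
#'
#' @param x either a list of `annotated_genome` objects, or a data.frame with
#'   columns `host_group` and `gc` (percent GC, as printed in genome reports).
#' @return data.frame with columns `host_group`, `n`, `median_gc`, `sd_gc`
#'   (percent units).
#' @export
group_gc_summary <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("host_group", "gc") %in% names(x)))
    df <- data.frame(host_group = as.character(x$host_group),
                     gc = as.numeric(x$gc), stringsAsFactors = FALSE)
  } else {
    df <- data.frame(host_group = vapply(x, function(g) g$host_group, ""),
                     gc = vapply(x, function(g) 100 * gc_content(g), 0),
                     stringsAsFactors = FALSE)
  }
  keep <- !is.na(df$host_group) & nzchar(df$host_group)
  if (!all(keep)) {
    warning("omitting ", sum(!keep), " genome(s) without a host group")
    df <- df[keep, , drop = FALSE]
  }
  groups <- unique(df$host_group)
  out <- do.call(rbind, lapply(groups, function(g) {
    v <- df$gc[df$host_group == g]
    data.frame(host_group = g, n = length(v),
               median_gc = stats::median(v),
               sd_gc = if (length(v) > 1L) stats::sd(v) else 0,
               stringsAsFactors = FALSE)
  }))
  out[order(out$host_group), , drop = FALSE]
}

#' Read a genome/host metadata table
#'
#' Tab-separated table with columns `genome_id` and `host_group` (extra
#' columns are preserved).
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_host_metadata <- function(path) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("genome_id", "host_group") %in% names(md)))
    stop("metadata must have columns genome_id and host_group")
  md
}

#' Published chlorovirus genome features
#'
#' The summary table of the 35 newly sequenced chlorovirus isolates (host
#' group, contig count, genome size, sequencing coverage, percent GC, gene
#' and protein-family counts, GenBank accession), shipped with the package
#' as a plain-text snapshot of the published report.
#'
#' @return data.frame, one row per isolate.
#' @export
chlorovirus_genome_features <- function() {
  path <- system.file("extdata", "chlorovirus_genome_features.tsv",
                      package = "chlorocomp", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
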