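#' Build a family-by-genome count matrix
#'
#' @param families a `family_set` from [build_families()] (its `membership`
#'   table is used), or a membership data.frame with columns `protein_id`,
#'   `genome_id`, `family_id`.
#' @param genome_meta data.frame with columns `genome_id`, `host_group`;
#'   defines the full genome set (genomes without members get zero columns).
#' @return a `family_matrix`: list with `counts` (families x genomes integer
#'   matrix) and `groups` (named character: genome -> host group).
#' @export
build_matrix <- function(families, genome_meta) {
  mem <- if (inherits(families, "family_set")) families$membership else families
  stopifnot(all(c("protein_id", "genome_id", "family_id") %in% names(mem)))
  genome_meta <- as.data.frame(genome_meta, stringsAsFactors = FALSE)
  stopifnot(all(c("genome_id", "host_group") %in% names(genome_meta)))
  unknown <- setdiff(unique(mem$genome_id), genome_meta$genome_id)
  if (length(unknown))
    stop("data error: protein(s) mapped to unknown genome(s): ",
         paste(unknown, collapse = ", "))
  fams <- sort(unique(mem$family_id))
  gens <- genome_meta$genome_id
  counts <- matrix(0L, length(fams), length(gens),
                   dimnames = list(fams, gens))
  tab <- table(mem$family_id, mem$genome_id)
  counts[rownames(tab), colnames(tab)] <- tab
  structure(list(counts = counts,
                 groups = stats::setNames(genome_meta$host_group, gens)),
            class = "family_matrix")
}

#' @export
print.family_matrix <- function(x, ...) {
  cat(sprintf("family_matrix: %d families x %d genomes (%d host groups)%s\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$groups)),
              if (!is.null(x$category)) ", classified" else ""))
  invisible(x)
}

#' Classify families into conservation categories
#'
#' Categories, applied in order of precedence:
#' * `core` — present in every genome;
#' * `host_specific:<g>` — present in every genome of group g, absent from
#'   all other genomes;
#' * `opposite:<g>` — absent from every genome of group g, present in every
#'   other genome;
#' * `singleton` — exactly one member overall;
#' * `scattered` — everything else.
#'
#' @param fm a `family_matrix`.
#' @return the `family_matrix` with a `category` vector (named by family).
#' @export
classify_families <- function(fm) {
  stopifnot(inherits(fm, "family_matrix"))
  groups <- unique(fm$groups)
  if (length(groups) < 2L) stop("classification requires >= 2 host groups")
  present <- fm$counts > 0L
  category <- rep("scattered", nrow(fm$counts))
  names(category) <- rownames(fm$counts)
  grp_all <- matrix(unlist(lapply(groups, function(g)
    rowSums(!present[, fm$groups == g, drop = FALSE]) == 0L)),
    nrow = nrow(present), dimnames = list(NULL, groups))
  grp_none <- matrix(unlist(lapply(groups, function(g)
    rowSums(present[, fm$groups == g, drop = FALSE]) == 0L)),
    nrow = nrow(present), dimnames = list(NULL, groups))
  is_core <- rowSums(!present) == 0L
  category[is_core] <- "core"
  # precedence: core > host_specific > opposite > singleton > scattered
  for (g in groups) {
    hs <- category == "scattered" & grp_all[, g] &
      rowSums(present[, fm$groups != g, drop = FALSE]) == 0L
    category[hs] <- paste0("host_specific:", g)
  }
  for (g in groups) {
    opp <- category == "scattered" & grp_none[, g] &
      rowSums(!present[, fm$groups != g, drop = FALSE]) == 0L
    category[opp] <- paste0("opposite:", g)
  }
  singles <- category == "scattered" & rowSums(fm$counts) == 1L
  category[singles] <- "singleton"
  fm$category <- category
  fm
}

#' Flag families inherited from the last common ancestor
#'
#' Parsimony rule on the two sides of the root of the virus phylogeny: a
#' family is ancestral iff it has at least one member in a genome of the
#' left clade (NC64A viruses) and at least one member in a genome of one of
#' the right clades (Pbi or SAG viruses). Families in `extra_evidence`
#' (e.g. families that are a sister group to homologs in other
#' nucleocytoplasmic large DNA viruses, identified from externally supplied
#' trees) are additionally flagged.
#'
#' @param fm a `family_matrix`.
#' @param extra_evidence character vector of family ids to force-flag.
#' @param left_group host group on one side of the root (default `"NC64A"`).
#' @param right_groups host groups on the other side (default
#'   `c("Pbi", "SAG")`).
#' @return the `family_matrix` with a logical `ancestral` vector.
#' @export
ancestral_families <- function(fm, extra_evidence = character(0),
                               left_group = "NC64A",
                               right_groups = c("Pbi", "SAG")) {
  stopifnot(inherits(fm, "family_matrix"))
  have <- unique(fm$groups)
  missing <- setdiff(c(left_group, right_groups), have)
  if (length(missing) == length(c(left_group, right_groups)))
    stop("configuration error: none of the root-defining host groups (",
         paste(c(left_group, right_groups), collapse = ", "), ") are present")
  if (length(missing))
    warning("host group(s) absent from the matrix: ",
            paste(missing, collapse = ", "))
  present <- fm$counts > 0L
  left <- rowSums(present[, fm$groups %in% left_group, drop = FALSE]) > 0L
  right <- rowSums(present[, fm$groups %in% right_groups, drop = FALSE]) > 0L
  anc <- left & right
  anc[rownames(fm$counts) %in% extra_evidence] <- TRUE
  fm$ancestral <- anc
  fm
}

#' Select single-copy core families (phylogenetic markers)
#'
#' Families with exactly one member in every focal genome (and in every
#' outgroup genome when supplied) — the input for concatenated-alignment
#' phylogeny.
#'
#' @param fm a `family_matrix` (built over focal plus outgroup genomes when
#'   outgroups are used).
#' @param outgroup character vector of outgroup genome ids; these genomes
#'   must also carry exactly one member.
#' @return character vector of family ids.
#' @export
select_single_copy_core <- function(fm, outgroup = character(0)) {
  stopifnot(inherits(fm, "family_matrix"))
  keep <- c(setdiff(colnames(fm$counts), outgroup),
            intersect(outgroup, colnames(fm$counts)))
  ok <- rowSums(fm$counts[, keep, drop = FALSE] != 1L) == 0L
  rownames(fm$counts)[ok]
}

# Scan one strand of a sequence (3 frames) for ATG-initiated, stop-terminated
# ORFs spanning more than min_len_bp (ATG through stop codon inclusive).
# Every qualifying ATG is counted, so nested starts count separately.
count_orfs_one_strand <- function(seq, min_len_bp) {
  n <- nchar(seq)
  total <- 0L
  for (off in 0:2) {
    ncod <- (n - off) %/% 3L
    if (ncod < 2L) next
    codons <- substring(seq, off + seq(1L, by = 3L, length.out = ncod),
                        off + seq(3L, by = 3L, length.out = ncod))
    stops <- which(codons %in% c("TAA", "TAG", "TGA"))
    atgs <- which(codons == "ATG")
    if (!length(stops) || !length(atgs)) next
    nxt <- stops[findInterval(atgs, stops) + 1L]
    len_bp <- 3L * (nxt - atgs + 1L)
    total <- total + sum(!is.na(len_bp) & len_bp > min_len_bp)
  }
  total
}

#' Chance-ORF null for ORFan genes
#'
#' Estimates how many ORFs longer than `min_len_bp` arise by chance in
#' sequence with the genome's composition: per replicate, the concatenated
#' coding sequence of the non-ORFan genes is shuffled (preserving
#' mononucleotide composition) and all six reading frames are scanned for
#' ATG-initiated, stop-terminated ORFs longer than the threshold. Counting
#' conventions (ATG start required, nested starts counted, ORF length
#' includes the stop codon) are returned in the result because the published
#' procedure is underspecified.
#'
#' @param genome an [annotated_genome()].
#' @param orfan logical vector (parallel to `genome$genes`) or character
#'   vector of gene ids flagging ORFan genes (an input annotation; it is
#'   never computed here). Default: none.
#' @param min_len_bp minimum ORF span in bp (default 300).
#' @param replicates number of shuffles (>= 1).
#' @param seed optional integer seed.
#' @return list with `mean`, `sd`, per-replicate `counts`, and `assumptions`.
#' @export
orfan_chance_null <- function(genome, orfan = character(0), min_len_bp = 300L,
                              replicates = 10L, seed = NULL) {
  stopifnot(inherits(genome, "annotated_genome"))
  if (replicates < 1L) stop("parameter error: replicates must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  is_orfan <- if (is.logical(orfan)) orfan else genome$genes$gene_id %in% orfan
  cds <- genome$genes$cds[!is_orfan]
  if (!length(cds)) stop("no non-ORFan coding sequence to shuffle")
  pool <- strsplit(paste(cds, collapse = ""), "")[[1]]
  pool <- pool[pool %in% NUC]
  counts <- integer(replicates)
  for (r in seq_len(replicates)) {
    s <- paste(pool[sample.int(length(pool))], collapse = "")
    counts[r] <- count_orfs_one_strand(s, min_len_bp) +
      count_orfs_one_strand(revcomp(s), min_len_bp)
  }
  list(mean = mean(counts), sd = stats::sd(counts), counts = counts,
       assumptions = c(shuffle_unit = "concatenated non-ORFan CDS, mononucleotide shuffle",
                       start_codon = "ATG required",
                       nested_starts = "counted separately",
                       length = "ATG through stop codon inclusive, > min_len_bp"))
}

#' Relative genomic location of non-ancestral families
#'
#' For each non-ancestral family, the mean over member genes of
#' (gene midpoint / genome length), with contigs concatenated in file order.
#'
#' @param fm a `family_matrix` carrying an `ancestral` flag (see
#'   [ancestral_families()]).
#' @param genomes list of [annotated_genome()] objects covering the matrix
#'   columns.
#' @param membership membership data.frame (`protein_id`, `genome_id`,
#'   `family_id`) linking genes to families.
#' @return data.frame with `family_id`, `mean_rel_pos` in \[0, 1\], and
#'   `n_members`.
#' @export
nonancestral_location_distribution <- function(fm, genomes, membership) {
  stopifnot(inherits(fm, "family_matrix"), !is.null(fm$ancestral))
  genomes <- stats::setNames(genomes,
                             vapply(genomes, function(g) g$genome_id, ""))
  pos <- lapply(genomes, function(g) {
    offs <- cumsum(c(0, nchar(g$contigs)))[seq_along(g$contigs)]
    names(offs) <- names(g$contigs)
    stats::setNames((offs[g$genes$contig_id] + (g$genes$start + g$genes$end) / 2) /
                      genome_length(g), g$genes$gene_id)
  })
  relpos <- unlist(unname(pos))
  nonanc <- rownames(fm$counts)[!fm$ancestral]
  mem <- membership[membership$family_id %in% nonanc, , drop = FALSE]
  out <- do.call(rbind, lapply(split(mem$protein_id, mem$family_id), function(p) {
    v <- relpos[p]
    data.frame(mean_rel_pos = mean(v, na.rm = TRUE), n_members = sum(!is.na(v)))
  }))
  data.frame(family_id = rownames(out), out, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Published full-scale benchmark targets
#'
#' Family-level statistics reported for the full 41-genome chlorovirus set.
#' Recomputing them requires the deposited GenBank records and a full
#' similarity search, so they are tracked as benchmark targets with a
#' +/-5 percent tolerance rather than asserted as unit tests.
#'
#' @return data.frame with `statistic`, `expected`, `rel_tol`.
#' @export
benchmark_targets <- function() {
  data.frame(
    statistic = c("multi_member_clusters", "core_families",
                  "rule_ancestral_families", "most_divergent_dnapol_identity"),
    expected = c(531, 155, 290, 64),
    rel_tol = 0.05,
    stringsAsFactors = FALSE)
}

#' Compare observed statistics against the benchmark targets
#'
#' @param observed named numeric vector (names matching
#'   [benchmark_targets()]`$statistic`).
#' @return the target table with `observed` and logical `pass` columns
#'   (`NA` where the statistic was not supplied).
#' @export
check_benchmarks <- function(observed) {
  bt <- benchmark_targets()
  bt$observed <- unname(observed[bt$statistic])
  bt$pass <- abs(bt$observed - bt$expected) <= bt$rel_tol * bt$expected
  bt
}
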