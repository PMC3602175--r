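#' Design for a synthetic chlorovirus-like genome set
#'
#' Describes a set of genomes organised into host groups with group-specific
#' GC composition, protein families with designed presence/absence patterns
#' (core, host-specific, opposite-pattern, scattered, singleton), conserved
#' gene order within groups and shuffled order between groups, and an optional
#' fraction of "alien" genes whose nucleotide sequence is emitted from a
#' compositionally offset codon model — the ground truth for compositional
#' HGT detection.
#'
#' Defaults mirror the study system: three host groups (NC64A-, Pbi- and
#' SAG-infecting viruses) with target GC of 40, 45 and 49%.
#'
#' @param host_groups data.frame with columns `group`, `n_genomes`, `gc`
#'   (target GC fraction of each group's genomes).
#' @param n_core,n_opposite,n_scattered,n_singleton counts of families per
#'   category. `n_opposite` families are absent from one group (cycled) and
#'   present everywhere else; singletons occur in exactly one genome.
#' @param n_group_specific named integer vector: families present in every
#'   genome of that group and absent elsewhere.
#' @param n_inparalog number of core families that carry a recent
#'   within-genome duplicate in one genome.
#' @param alien_fraction fraction of each genome's genes re-emitted from the
#'   alien composition model.
#' @param alien_gc_offset GC offset (fraction, e.g. 0.10 = 10 points) of the
#'   alien model relative to the genome's group target.
#' @param mean_len_codons,sdlog_len log-normal gene length parameters
#'   (codons), truncated to `len_range`.
#' @param len_range minimum/maximum gene length in codons (the study's ORF
#'   floor is 60 codons).
#' @param sub_rate_between,sub_rate_within per-site amino-acid substitution
#'   probabilities applied from the family ancestor to each group, and from
#'   the group sequence to each genome.
#' @param n_inversions number of random segment inversions applied to each
#'   genome's gene order (within-group order is otherwise conserved; order
#'   between groups is independently permuted).
#' @param spacer_range intergenic spacer length range (bp), drawn uniformly
#'   and filled with group-composition background.
#' @param seed integer; the single source of randomness for the whole set.
#' @return an object of class `synthetic_design`.
#' @export
synthetic_design <- function(host_groups = data.frame(
                               group = c("NC64A", "Pbi", "SAG"),
                               n_genomes = c(4L, 4L, 4L),
                               gc = c(0.40, 0.45, 0.49)),
                             n_core = 25L,
                             n_group_specific = c(NC64A = 3L, Pbi = 3L, SAG = 3L),
                             n_opposite = 2L,
                             n_scattered = 10L,
                             n_singleton = 4L,
                             n_inparalog = 0L,
                             alien_fraction = 0,
                             alien_gc_offset = 0.10,
                             mean_len_codons = 250,
                             sdlog_len = 0.4,
                             len_range = c(60L, 2000L),
                             sub_rate_between = 0.15,
                             sub_rate_within = 0.03,
                             n_inversions = 1L,
                             spacer_range = c(20L, 200L),
                             seed = 1L) {
  host_groups <- as.data.frame(host_groups, stringsAsFactors = FALSE)
  stopifnot(all(c("group", "n_genomes", "gc") %in% names(host_groups)),
            all(host_groups$gc > 0 & host_groups$gc < 1),
            all(host_groups$n_genomes >= 0))
  if (length(n_group_specific)) {
    bad <- setdiff(names(n_group_specific), host_groups$group)
    if (length(bad)) stop("design error: group_specific families for unknown group(s): ",
                          paste(bad, collapse = ", "))
    empty <- names(n_group_specific)[n_group_specific > 0 &
      host_groups$n_genomes[match(names(n_group_specific), host_groups$group)] == 0]
    if (length(empty)) stop("design error: group_specific families in empty group(s): ",
                            paste(empty, collapse = ", "))
  }
  stopifnot(alien_fraction >= 0, alien_fraction < 1,
            len_range[1] >= 2, len_range[2] >= len_range[1])
  structure(list(host_groups = host_groups, n_core = as.integer(n_core),
                 n_group_specific = n_group_specific,
                 n_opposite = as.integer(n_opposite),
                 n_scattered = as.integer(n_scattered),
                 n_singleton = as.integer(n_singleton),
                 n_inparalog = as.integer(n_inparalog),
                 alien_fraction = alien_fraction,
                 alien_gc_offset = alien_gc_offset,
                 mean_len_codons = mean_len_codons, sdlog_len = sdlog_len,
                 len_range = as.integer(len_range),
                 sub_rate_between = sub_rate_between,
                 sub_rate_within = sub_rate_within,
                 n_inversions = as.integer(n_inversions),
                 spacer_range = as.integer(spacer_range),
                 seed = as.integer(seed)),
            class = "synthetic_design")
}

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))  # amino acid (and "*") -> codons
}

codon_gc_count <- function(codons) {
  vapply(strsplit(codons, ""), function(v) sum(v %in% c("G", "C")), 0L)
}

# Expected coding GC fraction under exponential GC tilt exp(theta * #GC(codon))
# within each synonymous codon set, for a pool of residues `aa` (a character
# vector that may include "*" for the terminal stop).
expected_coding_gc <- function(theta, aa_counts, ctab) {
  egc <- vapply(names(aa_counts), function(a) {
    cods <- ctab[[a]]
    g <- codon_gc_count(cods)
    w <- exp(theta * g)
    sum(w * g) / sum(w)
  }, 0)
  sum(egc * aa_counts) / (3 * sum(aa_counts))
}

solve_gc_tilt <- function(target_gc, aa_counts, ctab) {
  f <- function(th) expected_coding_gc(th, aa_counts, ctab) - target_gc
  lo <- f(-30); hi <- f(30)
  if (lo > 0 || hi < 0)
    stop(sprintf("design error: coding GC target %.2f is infeasible for this protein set (achievable %.3f..%.3f)",
                 target_gc, expected_coding_gc(-30, aa_counts, ctab),
                 expected_coding_gc(30, aa_counts, ctab)))
  stats::uniroot(f, c(-30, 30), tol = 1e-9)$root
}

# Per-amino-acid codon sampling probabilities at tilt theta.
codon_probs <- function(theta, ctab) {
  lapply(ctab, function(cods) {
    w <- exp(theta * codon_gc_count(cods))
    stats::setNames(w / sum(w), cods)
  })
}

back_translate <- function(protein, cp) {
  aa <- c(strsplit(protein, "")[[1]], "*")
  out <- character(length(aa))
  for (a in unique(aa)) {
    idx <- which(aa == a)
    p <- cp[[a]]
    out[idx] <- names(p)[sample.int(length(p), length(idx), replace = TRUE, prob = p)]
  }
  paste(out, collapse = "")
}

mutate_protein <- function(protein, rate) {
  if (rate <= 0) return(protein)
  v <- strsplit(protein, "")[[1]]
  hit <- which(stats::runif(length(v)) < rate)
  hit <- hit[hit > 1L]  # keep the start methionine
  if (length(hit)) {
    repl <- AA20[sample.int(20L, length(hit), replace = TRUE)]
    same <- repl == v[hit]
    while (any(same)) {
      repl[same] <- AA20[sample.int(20L, sum(same), replace = TRUE)]
      same <- repl == v[hit]
    }
    v[hit] <- repl
  }
  paste(v, collapse = "")
}

random_protein <- function(len_codons) {
  paste(c("M", AA20[sample.int(20L, len_codons - 1L, replace = TRUE)]),
        collapse = "")
}

random_background <- function(n, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(NUC[sample.int(4L, n, replace = TRUE, prob = p)], collapse = "")
}

#' Generate a synthetic genome set with ground truth
#'
#' Every family starts from one ancestor protein; group and genome copies are
#' derived by per-site amino-acid substitution so that reciprocal-best-hit
#' clustering can recover the designed partition. Nucleotide sequences are
#' back-translated through a codon model tilted to the group's GC target;
#' alien genes are back-translated through a model offset by
#' `alien_gc_offset`. The same seed yields byte-identical output.
#'
#' @param design a [synthetic_design()].
#' @return list with `genomes` (list of [annotated_genome()]) and `truth`
#'   (list of data.frames: `genes` with per-gene family and alien flags,
#'   `families` with designed categories, `groups` with emission parameters).
#' @export
generate_genome_set <- function(design) {
  stopifnot(inherits(design, "synthetic_design"))
  ctab <- codon_table()
  hg <- design$host_groups
  groups <- hg$group
  genome_ids <- unlist(lapply(seq_len(nrow(hg)), function(i)
    sprintf("%s_v%02d", hg$group[i], seq_len(hg$n_genomes[i]))), use.names = FALSE)
  genome_group <- rep(hg$group, hg$n_genomes)
  n_genomes <- length(genome_ids)
  if (n_genomes == 0L) stop("design error: no genomes")

  set.seed(design$seed)

  ## --- family plan -----------------------------------------------------
  fam_cat <- c(rep("core", design$n_core),
               unlist(lapply(names(design$n_group_specific), function(g)
                 rep(paste0("group_specific:", g), design$n_group_specific[[g]])),
                 use.names = FALSE),
               if (design$n_opposite > 0)
                 paste0("opposite:", groups[((seq_len(design$n_opposite) - 1L) %% length(groups)) + 1L]),
               rep("scattered", design$n_scattered),
               rep("singleton", design$n_singleton))
  n_fam <- length(fam_cat)
  if (n_fam == 0L) stop("design error: empty family plan")
  if (design$n_scattered > 0L && n_genomes < 3L)
    stop("design error: scattered families need >= 3 genomes")
  fam_id <- sprintf("FAM%04d", seq_len(n_fam))

  presence <- matrix(FALSE, n_fam, n_genomes,
                     dimnames = list(fam_id, genome_ids))
  for (i in seq_len(n_fam)) {
    cat_i <- fam_cat[i]
    if (cat_i == "core") presence[i, ] <- TRUE
    else if (startsWith(cat_i, "group_specific:"))
      presence[i, ] <- genome_group == sub("^group_specific:", "", cat_i)
    else if (startsWith(cat_i, "opposite:"))
      presence[i, ] <- genome_group != sub("^opposite:", "", cat_i)
    else if (cat_i == "singleton")
      presence[i, sample.int(n_genomes, 1L)] <- TRUE
    else {  # scattered: any pattern not matching a named category
      repeat {
        k <- sample(2:(n_genomes - 1L), 1L)
        s <- sort(sample.int(n_genomes, k))
        pat <- logical(n_genomes); pat[s] <- TRUE
        grp_all <- vapply(groups, function(g) all(pat[genome_group == g]), TRUE)
        grp_none <- vapply(groups, function(g) !any(pat[genome_group == g]), TRUE)
        special <- all(pat) ||
          any(grp_all & vapply(groups, function(g) !any(pat[genome_group != g]), TRUE)) ||
          any(grp_none & vapply(groups, function(g) all(pat[genome_group != g]), TRUE))
        if (!special) { presence[i, ] <- pat; break }
      }
    }
  }

  lens <- pmin(pmax(round(stats::rlnorm(n_fam, log(design$mean_len_codons),
                                        design$sdlog_len)),
                    design$len_range[1]), design$len_range[2])
  anc_prot <- vapply(lens, random_protein, "")
  fam_strand <- sample(c("+", "-"), n_fam, replace = TRUE)

  group_prot <- sapply(groups, function(g)
    vapply(anc_prot, mutate_protein, "", rate = design$sub_rate_between))
  dim(group_prot) <- c(n_fam, length(groups))
  dimnames(group_prot) <- list(fam_id, groups)

  # gene-order rank of each family within each group (shuffled between groups)
  group_rank <- sapply(groups, function(g) sample.int(n_fam))
  dim(group_rank) <- c(n_fam, length(groups))
  dimnames(group_rank) <- list(fam_id, groups)

  # in-paralog plan: core family index -> genome carrying the duplicate
  dup_fams <- integer(0)
  if (design$n_inparalog > 0) {
    dup_fams <- utils::head(which(fam_cat == "core"), design$n_inparalog)
    dup_genome <- genome_ids[((seq_along(dup_fams) - 1L) %% n_genomes) + 1L]
  }

  genome_seeds <- sample.int(.Machine$integer.max - 1L, n_genomes)

  ## --- per-genome emission ---------------------------------------------
  genomes <- vector("list", n_genomes)
  truth_genes <- vector("list", n_genomes)
  for (gi in seq_len(n_genomes)) {
    set.seed(genome_seeds[gi])
    gid <- genome_ids[gi]
    grp <- genome_group[gi]
    fams <- which(presence[, gi])
    prot <- vapply(group_prot[fams, grp], mutate_protein, "",
                   rate = design$sub_rate_within)
    fam_of_gene <- fam_id[fams]
    strand <- fam_strand[fams]
    # within-genome duplicates
    if (length(dup_fams)) {
      for (d in seq_along(dup_fams)) {
        if (dup_genome[d] == gid && dup_fams[d] %in% fams) {
          j <- match(dup_fams[d], fams)
          prot <- c(prot, mutate_protein(prot[j], design$sub_rate_within / 2))
          fam_of_gene <- c(fam_of_gene, fam_id[dup_fams[d]])
          strand <- c(strand, strand[j])
        }
      }
    }
    n_genes <- length(prot)
    # order: group rank of the family; duplicates sit next to their parent
    rank <- group_rank[match(fam_of_gene, fam_id), grp] +
      0.5 * (duplicated(fam_of_gene))
    ord <- order(rank)
    prot <- prot[ord]; fam_of_gene <- fam_of_gene[ord]; strand <- strand[ord]
    # inversions: reverse a random segment of the gene order, flipping strands
    if (design$n_inversions > 0 && n_genes >= 2) {
      for (k in seq_len(design$n_inversions)) {
        ab <- sort(sample.int(n_genes, 2L))
        seg <- ab[1]:ab[2]
        prot[seg] <- rev(prot[seg])
        fam_of_gene[seg] <- rev(fam_of_gene[seg])
        strand[seg] <- rev(ifelse(strand[seg] == "+", "-", "+"))
      }
    }
    # alien selection and codon models
    n_alien <- round(design$alien_fraction * n_genes)
    alien <- logical(n_genes)
    if (n_alien > 0) alien[sample.int(n_genes, n_alien)] <- TRUE
    aa_pool <- function(p) {
      tab <- table(c(unlist(strsplit(p, ""), use.names = FALSE),
                     rep("*", length(p))))
      stats::setNames(as.numeric(tab), names(tab))
    }
    gc_native <- hg$gc[hg$group == grp]
    native_pool <- if (any(!alien)) prot[!alien] else prot
    cp_native <- codon_probs(solve_gc_tilt(gc_native, aa_pool(native_pool), ctab), ctab)
    cp_alien <- if (n_alien > 0)
      codon_probs(solve_gc_tilt(gc_native + design$alien_gc_offset,
                                aa_pool(prot[alien]), ctab), ctab)
    cds <- character(n_genes)
    for (j in seq_len(n_genes))
      cds[j] <- back_translate(prot[j], if (alien[j]) cp_alien else cp_native)
    # assemble one contig with intergenic spacers
    spacers <- vapply(sample(design$spacer_range[1]:design$spacer_range[2],
                             n_genes + 1L, replace = TRUE),
                      random_background, "", gc = gc_native)
    pieces <- character(2L * n_genes + 1L)
    pieces[seq(1L, by = 2L, length.out = n_genes + 1L)] <- spacers
    starts <- integer(n_genes); ends <- integer(n_genes)
    pos <- nchar(spacers[1])
    for (j in seq_len(n_genes)) {
      piece <- if (strand[j] == "+") cds[j] else revcomp(cds[j])
      pieces[2L * j] <- piece
      starts[j] <- pos
      pos <- pos + nchar(piece)
      ends[j] <- pos
      pos <- pos + nchar(spacers[j + 1L])
    }
    contig_id <- paste0(gid, "_c1")
    contig <- paste(pieces, collapse = "")
    gene_id <- sprintf("%s_%03d", gid, seq_len(n_genes))
    genes <- data.frame(gene_id = gene_id, contig_id = contig_id,
                        start = starts, end = ends, strand = strand,
                        annotation = "", cds = cds,
                        stringsAsFactors = FALSE)
    genes$protein <- prot
    genomes[[gi]] <- annotated_genome(gid, stats::setNames(contig, contig_id),
                                      genes, host_group = grp)
    truth_genes[[gi]] <- data.frame(gene_id = gene_id, genome_id = gid,
                                    family_id = fam_of_gene, alien = alien,
                                    length_nt = nchar(cds) + 3L,
                                    stringsAsFactors = FALSE)
  }

  truth <- list(
    genes = do.call(rbind, truth_genes),
    families = data.frame(family_id = fam_id, category = fam_cat,
                          stringsAsFactors = FALSE),
    groups = data.frame(group = hg$group, n_genomes = hg$n_genomes,
                        gc = hg$gc, alien_gc = hg$gc + design$alien_gc_offset,
                        stringsAsFactors = FALSE))
  list(genomes = genomes, truth = truth)
}

#' Write a generated genome set to disk
#'
#' Emits one FASTA + GFF3 (or GenBank) file pair per genome plus the host
#' metadata table and the ground-truth tables.
#'
#' @param genomes,truth output of [generate_genome_set()].
#' @param outdir output directory (created if needed).
#' @param format `"fasta+gff"` or `"genbank"`.
#' @return invisibly, the output directory.
#' @export
emit_files <- function(genomes, truth, outdir, format = c("fasta+gff", "genbank")) {
  format <- match.arg(format)
  ok <- dir.exists(outdir) || dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(outdir, 2L) != 0L)
    stop("I/O error: cannot write to directory '", outdir, "'")
  for (g in genomes) {
    if (format == "fasta+gff") {
      write_genome(g, file.path(outdir, paste0(g$genome_id, ".fasta")),
                   format = "fasta+gff",
                   gff = file.path(outdir, paste0(g$genome_id, ".gff3")))
    } else {
      write_genome(g, file.path(outdir, paste0(g$genome_id, ".gbk")),
                   format = "genbank")
    }
  }
  meta <- data.frame(genome_id = vapply(genomes, function(g) g$genome_id, ""),
                     host_group = vapply(genomes, function(g) g$host_group, ""))
  utils::write.table(meta, file.path(outdir, "metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(truth$genes, file.path(outdir, "truth_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(truth$families, file.path(outdir, "truth_families.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(outdir)
}
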