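# Independent brute-force oracles and small fixture builders used across the
# suite. These deliberately avoid the code paths they check.

# --- Smith-Waterman (Gotoh) with affine gaps: cost(open, ext) for a gap of
# length L is open + L*ext (the convention of the internal engine).
sw_oracle <- function(a, b, mat, open = 11, ext = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)  # gap in A (move along B)
  F <- matrix(-Inf, n + 1, m + 1)  # gap in B
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - (open + ext), E[i, j - 1] - ext)
      F[i, j] <- max(H[i - 1, j] - (open + ext), F[i - 1, j] - ext)
      H[i, j] <- max(0, H[i - 1, j - 1] + mat[A[i - 1], B[j - 1]],
                     E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# --- RBH by literal double loop over the hit table.
rbh_oracle <- function(hits) {
  h <- hits[hits$query_genome != hits$subject_genome, , drop = FALSE]
  best_of <- function(q, tg) {
    cand <- h[h$query_id == q & h$subject_genome == tg, , drop = FALSE]
    if (!nrow(cand)) return(NA_character_)
    cand <- cand[order(-cand$score, cand$evalue, -cand$aln_len,
                       cand$subject_id), , drop = FALSE]
    cand$subject_id[1]
  }
  out <- character(0)
  for (q in unique(h$query_id)) {
    for (tg in unique(h$subject_genome[h$query_id == q])) {
      b <- best_of(q, tg)
      qg <- h$query_genome[h$query_id == q][1]
      if (!is.na(b) && identical(best_of(b, qg), q) && q < b)
        out <- c(out, paste(q, b, sep = "|"))
    }
  }
  sort(out)
}

# --- connected components by union-find.
uf_components <- function(pairs) {
  nodes <- sort(unique(c(pairs$protein_a, pairs$protein_b)))
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (i in seq_len(nrow(pairs))) {
    ra <- find(pairs$protein_a[i]); rb <- find(pairs$protein_b[i])
    if (ra != rb) parent[[ra]] <- rb
  }
  roots <- vapply(nodes, find, "")
  comps <- split(nodes, roots)
  comps <- lapply(comps, sort)
  unname(comps[order(vapply(comps, `[`, "", 1L))])
}

# --- in-paralog rule, evaluated literally.
inparalog_oracle <- function(clusters, hits, unassigned) {
  h <- hits[hits$query_id != hits$subject_id, , drop = FALSE]
  sc <- function(a, b) {
    v <- h$score[(h$query_id == a & h$subject_id == b) |
                 (h$query_id == b & h$subject_id == a)]
    if (length(v)) max(v) else -Inf
  }
  out <- stats::setNames(rep(NA_character_, length(unassigned)), unassigned)
  for (p in unassigned) {
    best_margin <- -Inf; best_cl <- NA_character_
    for (cn in names(clusters)) {
      members <- clusters[[cn]]
      margin <- -Inf
      for (m in members) {
        spm <- sc(p, m)
        if (spm == -Inf) next
        others <- setdiff(members, m)
        mmax <- if (length(others)) max(vapply(others, sc, 0, a = m)) else -Inf
        if (spm > mmax) margin <- max(margin, spm - mmax)
      }
      if (margin > best_margin) { best_margin <- margin; best_cl <- cn }
    }
    if (best_margin > -Inf) out[p] <- best_cl
  }
  out
}

# --- family category rules, evaluated literally row by row.
classify_oracle <- function(counts, groups) {
  out <- character(nrow(counts))
  for (i in seq_len(nrow(counts))) {
    v <- counts[i, ]
    cat_i <- "scattered"
    if (all(v > 0)) cat_i <- "core"
    else {
      for (g in unique(groups)) {
        if (all(v[groups == g] > 0) && all(v[groups != g] == 0)) {
          cat_i <- paste0("host_specific:", g); break
        }
      }
      if (cat_i == "scattered") {
        for (g in unique(groups)) {
          if (all(v[groups == g] == 0) && all(v[groups != g] > 0)) {
            cat_i <- paste0("opposite:", g); break
          }
        }
      }
      if (cat_i == "scattered" && sum(v) == 1) cat_i <- "singleton"
    }
    out[i] <- cat_i
  }
  stats::setNames(out, rownames(counts))
}

# --- longest colinear chain by exhaustive top-down memoized recursion over
# successors (both directions), independent of the package's bottom-up DP.
longest_block_oracle <- function(ra, rb, max_gap) {
  n <- length(ra)
  if (n < 2) return(0L)
  best <- 0L
  for (dir in c(1L, -1L)) {
    memo <- rep(NA_integer_, n)
    longest_from <- function(i) {
      if (!is.na(memo[i])) return(memo[i])
      res <- 1L
      for (j in seq_len(n)) {
        da <- ra[j] - ra[i]; db <- dir * (rb[j] - rb[i])
        if (da > 0 && db > 0 && da - 1 <= max_gap && db - 1 <= max_gap)
          res <- max(res, 1L + longest_from(j))
      }
      memo[i] <<- res
      res
    }
    for (i in seq_len(n)) best <- max(best, longest_from(i))
  }
  if (best < 2L) 0L else best
}

# --- shred a single-contig genome into n shuffled contigs cut at intergenic
# points, reverse-complementing the flagged ones; gene ids get a prefix.
shred_genome <- function(ref, flip, prefix = "asm_") {
  n_ctg <- length(flip)
  g <- ref$genes
  cuts <- sort(sample(2:nrow(g), n_ctg - 1L))
  bounds <- c(0L, g$start[cuts] - 1L, genome_length(ref))
  pieces <- substring(ref$contigs[[1]], bounds[-length(bounds)] + 1L, bounds[-1])
  names(pieces) <- paste0("ctg", seq_along(pieces))
  genes2 <- g
  genes2$contig_id <- paste0("ctg", findInterval(g$start, bounds))
  off <- stats::setNames(bounds[-length(bounds)], names(pieces))
  genes2$start <- g$start - off[genes2$contig_id]
  genes2$end <- g$end - off[genes2$contig_id]
  pieces2 <- pieces[sample(n_ctg)]
  for (i in which(flip)) {
    cid <- names(pieces2)[i]
    L <- nchar(pieces2[i])
    pieces2[i] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(pieces2[[i]])))
    sel <- genes2$contig_id == cid
    s <- genes2$start[sel]; e <- genes2$end[sel]
    genes2$start[sel] <- L - e
    genes2$end[sel] <- L - s
    genes2$strand[sel] <- ifelse(genes2$strand[sel] == "+", "-", "+")
  }
  genes2$gene_id <- paste0(prefix, genes2$gene_id)
  annotated_genome(paste0(prefix, ref$genome_id), pieces2,
                   genes2[, c("gene_id", "contig_id", "start", "end",
                              "strand", "annotation")],
                   host_group = ref$host_group)
}

# Random in-paralog assignment instance: frozen clusters, extra unassigned
# proteins, sparse symmetric within-genome scores.
random_inparalog_instance <- function() {
  n_cl <- sample(1:3, 1)
  sizes <- sample(1:3, n_cl, replace = TRUE)
  clusters <- list()
  pid <- 0L
  for (ci in seq_len(n_cl)) {
    clusters[[sprintf("CL%04d", ci)]] <- sprintf("m%d", pid + seq_len(sizes[ci]))
    pid <- pid + sizes[ci]
  }
  unassigned <- sprintf("p%d", seq_len(sample(1:3, 1)))
  all_ids <- c(unlist(clusters, use.names = FALSE), unassigned)
  prs <- t(utils::combn(all_ids, 2))
  keep <- stats::runif(nrow(prs)) < 0.6
  if (!any(keep)) keep[1L] <- TRUE
  prs <- prs[keep, , drop = FALSE]
  hits <- data.frame(query_id = prs[, 1], subject_id = prs[, 2],
                     query_genome = "A", subject_genome = "A",
                     identity = 90, aln_len = 100, evalue = 1e-30,
                     score = sample(10:100, nrow(prs), replace = TRUE),
                     stringsAsFactors = FALSE)
  list(clusters = clusters, hits = hits, unassigned = unassigned,
       all_ids = all_ids)
}

# --- sliding-window tuple counter on a character string (codon frames).
tuple_count_oracle <- function(orf, k) {
  orf <- substr(orf, 1, (nchar(orf) %/% 3) * 3)
  n <- nchar(orf)
  kmers <- apply(expand.grid(rep(list(c("A", "C", "G", "T")), k))[, k:1, drop = FALSE],
                 1, paste, collapse = "")
  Nji <- lapply(1:3, function(f)
    matrix(0, 4^k, 4, dimnames = list(kmers, c("A", "C", "G", "T"))))
  for (t in seq_len(n - k)) {
    j <- substr(orf, t, t + k - 1)
    i <- substr(orf, t + k, t + k)
    f <- (t - 1) %% 3 + 1
    if (grepl("^[ACGT]+$", j) && i %in% c("A", "C", "G", "T"))
      Nji[[f]][j, i] <- Nji[[f]][j, i] + 1
  }
  Nji
}

# AUROC of "lower score = positive" via the rank-sum formula.
auc_lower <- function(score, positive) {
  r <- rank(score)
  n1 <- sum(positive); n0 <- sum(!positive)
  (sum(r[!positive]) - n0 * (n0 + 1) / 2) / (n0 * n1)
}

# Random cross-genome hit table over n_genomes with n_prot proteins each.
random_hit_table <- function(n_genomes, n_prot, density = 0.5) {
  ids <- unlist(lapply(seq_len(n_genomes), function(g)
    sprintf("g%d_p%d", g, seq_len(n_prot))))
  genome <- rep(sprintf("g%d", seq_len(n_genomes)), each = n_prot)
  names(genome) <- ids
  pairs <- expand.grid(q = ids, s = ids, stringsAsFactors = FALSE)
  pairs <- pairs[genome[pairs$q] != genome[pairs$s], ]
  keep <- runif(nrow(pairs)) < density
  pairs <- pairs[keep, , drop = FALSE]
  data.frame(query_id = pairs$q, subject_id = pairs$s,
             query_genome = unname(genome[pairs$q]),
             subject_genome = unname(genome[pairs$s]),
             identity = runif(nrow(pairs), 30, 100),
             aln_len = sample(50:500, nrow(pairs), replace = TRUE),
             evalue = 10^runif(nrow(pairs), -50, -6),
             score = round(runif(nrow(pairs), 20, 500), 1),
             stringsAsFactors = FALSE)
}

# Small genome-set design used by several files.
small_design <- function(...) {
  synthetic_design(host_groups = data.frame(group = c("NC64A", "Pbi", "SAG"),
                                            n_genomes = c(2L, 2L, 2L),
                                            gc = c(0.40, 0.45, 0.49)),
                   n_core = 8L,
                   n_group_specific = c(NC64A = 1L, Pbi = 1L, SAG = 1L),
                   n_opposite = 1L, n_scattered = 3L, n_singleton = 2L,
                   mean_len_codons = 100, seed = 7L, ...)
}

genome_meta <- function(genomes) {
  data.frame(genome_id = vapply(genomes, function(g) g$genome_id, ""),
             host_group = vapply(genomes, function(g) g$host_group, ""),
             stringsAsFactors = FALSE)
}
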