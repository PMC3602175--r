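#' Gene-order matches between two genomes
#'
#' One match per hit below the e-value threshold between genes of the two
#' genomes, on gene-rank axes (order index within each genome, 0-based).
#' Orientation is the product of the two genes' strands; mutual best hits
#' (by score) are flagged, mirroring the convention of published dot-plots
#' (same orientation black, reverse grey, best matches larger).
#'
#' @param genome_a,genome_b [annotated_genome()] objects.
#' @param hits hit table covering the pair (see [pairwise_scores()]).
#' @param evalue_max e-value threshold (default 1e-5).
#' @return data.frame of class `gene_matches` with columns `gene_a`,
#'   `gene_b`, `rank_a`, `rank_b`, `orientation` (`"same"`/`"reverse"`),
#'   `score`, `is_best`.
#' @export
dotplot_matches <- function(genome_a, genome_b, hits, evalue_max = 1e-5) {
  ga <- genome_a$genes; gb <- genome_b$genes
  rank_a <- stats::setNames(seq_len(nrow(ga)) - 1L, ga$gene_id)
  rank_b <- stats::setNames(seq_len(nrow(gb)) - 1L, gb$gene_id)
  h <- hits[hits$query_id %in% ga$gene_id & hits$subject_id %in% gb$gene_id &
              hits$evalue < evalue_max, , drop = FALSE]
  # collapse duplicate pairs to the best-scoring record
  key <- paste(h$query_id, h$subject_id, sep = "\r")
  ord <- order(key, -h$score)
  h <- h[ord, , drop = FALSE][!duplicated(key[ord]), , drop = FALSE]
  sa <- stats::setNames(ga$strand, ga$gene_id)[h$query_id]
  sb <- stats::setNames(gb$strand, gb$gene_id)[h$subject_id]
  # mutual best: best partner of each gene on both axes
  best_ab <- tapply(seq_len(nrow(h)), h$query_id, function(ii)
    h$subject_id[ii[order(-h$score[ii], h$subject_id[ii])][1L]])
  best_ba <- tapply(seq_len(nrow(h)), h$subject_id, function(ii)
    h$query_id[ii[order(-h$score[ii], h$query_id[ii])][1L]])
  is_best <- unname(best_ab[h$query_id] == h$subject_id &
                    best_ba[h$subject_id] == h$query_id)
  out <- data.frame(gene_a = h$query_id, gene_b = h$subject_id,
                    rank_a = unname(rank_a[h$query_id]),
                    rank_b = unname(rank_b[h$subject_id]),
                    orientation = ifelse(sa == sb, "same", "reverse"),
                    score = h$score, is_best = is_best,
                    stringsAsFactors = FALSE)
  out <- out[order(out$rank_a, out$rank_b), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gene_matches", "data.frame")
  out
}

# All longest monotone chains under a rank-gap constraint, by quadratic
# dynamic programming plus backtracking; dir = +1 (ascending in rank_b) or
# -1 (descending). Returns a list of index vectors into the match table.
# Enumeration is capped; the cap only affects which of several equal-length
# blocks is reported first.
best_chains <- function(ra, rb, max_gap, dir, cap = 5000L) {
  n <- length(ra)
  if (!n) return(list())
  ord <- order(ra, dir * rb)
  sra <- ra[ord]; srb <- rb[ord]
  L <- rep(1L, n)
  preds <- vector("list", n)
  for (jj in seq_len(n)) {
    for (ii in seq_len(jj - 1L)) {
      da <- sra[jj] - sra[ii]
      db <- dir * (srb[jj] - srb[ii])
      if (da > 0L && db > 0L && da - 1L <= max_gap && db - 1L <= max_gap) {
        if (L[ii] + 1L > L[jj]) {
          L[jj] <- L[ii] + 1L
          preds[[jj]] <- ii
        } else if (L[ii] + 1L == L[jj]) {
          preds[[jj]] <- c(preds[[jj]], ii)
        }
      }
    }
  }
  lmax <- max(L)
  chains <- list()
  walk <- function(node, tail) {
    if (length(chains) >= cap) return()
    ps <- preds[[node]]
    ps <- ps[L[ps] == L[node] - 1L]
    if (L[node] == 1L || !length(ps)) {
      chains[[length(chains) + 1L]] <<- c(node, tail)
      return()
    }
    for (p in ps) walk(p, c(node, tail))
  }
  for (end in which(L == lmax)) walk(end, integer(0))
  lapply(chains, function(ch) ord[ch])
}

#' Colinear blocks from gene matches
#'
#' Maximal runs of matches whose ranks are strictly monotone on both axes
#' (ascending = same-direction block; descending on one axis = inverted
#' block) with at most `max_gap` intervening unmatched genes between
#' consecutive matches. Found by repeated longest-chain extraction; blocks
#' are reported longest-first and have length >= 2.
#'
#' @param matches a `gene_matches` table (deduplicate to best hits first for
#'   a clean plot; any match table works).
#' @param max_gap maximum intervening unmatched genes (default 3).
#' @return list of class `colinear_blocks`; each element is the block's
#'   match data.frame with attribute `direction` (`"ascending"` /
#'   `"descending"`).
#' @export
colinear_blocks <- function(matches, max_gap = 3L) {
  m <- as.data.frame(matches)
  # tie-break on the sorted unordered gene-pair keys: invariant under
  # swapping the two genomes, which keeps block extraction symmetric
  chain_key <- function(chain) {
    paste(sort(paste(pmin(m$gene_a[chain], m$gene_b[chain]),
                     pmax(m$gene_a[chain], m$gene_b[chain]), sep = "\r")),
          collapse = "\n")
  }
  blocks <- list()
  repeat {
    if (nrow(m) < 2L) break
    up <- best_chains(m$rank_a, m$rank_b, max_gap, +1L)
    dn <- best_chains(m$rank_a, m$rank_b, max_gap, -1L)
    lu <- if (length(up)) length(up[[1L]]) else 0L
    ld <- if (length(dn)) length(dn[[1L]]) else 0L
    if (max(lu, ld) < 2L) break
    cand <- c(if (lu >= ld) up, if (ld >= lu) dn)
    dirs <- c(if (lu >= ld) rep("ascending", length(up)),
              if (ld >= lu) rep("descending", length(dn)))
    keys <- vapply(cand, chain_key, "")
    pick <- order(keys)[1L]
    chain <- cand[[pick]]
    blk <- m[chain, , drop = FALSE]
    blk <- blk[order(blk$rank_a), , drop = FALSE]
    rownames(blk) <- NULL
    attr(blk, "direction") <- dirs[pick]
    blocks[[length(blocks) + 1L]] <- blk
    m <- m[-chain, , drop = FALSE]
  }
  blocks <- blocks[order(-vapply(blocks, nrow, 0L))]
  structure(blocks, class = "colinear_blocks")
}

#' @export
print.colinear_blocks <- function(x, ...) {
  cat(sprintf("colinear_blocks: %d block(s)%s\n", length(x),
              if (length(x)) sprintf(", longest = %d genes", nrow(x[[1L]])) else ""))
  invisible(x)
}

#' Order assembly contigs against a reference genome
#'
#' Each contig is anchored by its genes' best hits into the reference: the
#' contig is placed at the median reference rank of its anchors, oriented by
#' majority strand agreement, and contigs are sorted by that median
#' (ties broken by contig length, longer first, then id). Contigs without
#' anchors are appended last and flagged; if no contig has an anchor the
#' assembly is returned unchanged with a warning.
#'
#' @param assembly an [annotated_genome()] with one or more contigs.
#' @param reference an annotated reference genome.
#' @param hits hit table covering assembly-vs-reference gene pairs.
#' @param evalue_max e-value threshold for anchoring hits.
#' @return list with `genome` (reordered/reoriented `annotated_genome`) and
#'   `report` (per-contig placement data.frame).
#' @export
order_contigs <- function(assembly, reference, hits, evalue_max = 1e-5) {
  ref_rank <- stats::setNames(seq_len(nrow(reference$genes)) - 1L,
                              reference$genes$gene_id)
  ref_strand <- stats::setNames(reference$genes$strand,
                                reference$genes$gene_id)
  h <- hits[hits$query_id %in% assembly$genes$gene_id &
              hits$subject_id %in% reference$genes$gene_id &
              hits$evalue < evalue_max, , drop = FALSE]
  # best reference partner per assembly gene
  ord <- order(h$query_id, -h$score, h$evalue, h$subject_id)
  h <- h[ord, , drop = FALSE][!duplicated(h$query_id[ord]), , drop = FALSE]
  anchors <- stats::setNames(h$subject_id, h$query_id)
  g <- assembly$genes
  report <- do.call(rbind, lapply(names(assembly$contigs), function(cid) {
    gids <- g$gene_id[g$contig_id == cid]
    anc <- anchors[intersect(gids, names(anchors))]
    if (!length(anc))
      return(data.frame(contig_id = cid, n_anchors = 0L,
                        median_ref_rank = NA_real_, flip = FALSE,
                        anchored = FALSE, stringsAsFactors = FALSE))
    agree <- stats::setNames(g$strand, g$gene_id)[names(anc)] == ref_strand[anc]
    data.frame(contig_id = cid, n_anchors = length(anc),
               median_ref_rank = stats::median(ref_rank[anc]),
               flip = mean(agree) < 0.5, anchored = TRUE,
               stringsAsFactors = FALSE)
  }))
  if (!any(report$anchored)) {
    warning("no anchors between assembly and reference; contig order unchanged")
    return(list(genome = assembly, report = report))
  }
  clen <- nchar(assembly$contigs)[report$contig_id]
  ord <- order(!report$anchored, report$median_ref_rank, -clen,
               report$contig_id)
  report <- report[ord, , drop = FALSE]
  rownames(report) <- NULL
  contigs <- assembly$contigs[report$contig_id]
  genes <- g
  for (cid in report$contig_id[report$flip]) {
    len <- nchar(contigs[[cid]])
    contigs[[cid]] <- revcomp(contigs[[cid]])
    sel <- genes$contig_id == cid
    s0 <- genes$start[sel]; e0 <- genes$end[sel]
    genes$start[sel] <- len - e0
    genes$end[sel] <- len - s0
    genes$strand[sel] <- ifelse(genes$strand[sel] == "+", "-", "+")
  }
  placed <- annotated_genome(assembly$genome_id, contigs,
                             genes[, c("gene_id", "contig_id", "start", "end",
                                       "strand", "annotation")],
                             host_group = assembly$host_group)
  list(genome = placed, report = report)
}

#' Render a gene-order dot-plot to SVG
#'
#' Scatter of gene ranks: same-orientation matches black, reverse-orientation
#' grey, mutual best matches drawn larger. The SVG is written directly as
#' markup, so output is deterministic for a fixed match table.
#'
#' @param matches a non-empty `gene_matches` table.
#' @param path output SVG path.
#' @param width,height canvas size in pixels.
#' @return invisibly, the path.
#' @export
render_dotplot <- function(matches, path, width = 480, height = 480) {
  m <- as.data.frame(matches)
  if (!nrow(m)) stop("no matches to plot")
  pad <- 30
  amax <- max(m$rank_a, 1L); bmax <- max(m$rank_b, 1L)
  sx <- function(r) pad + (width - 2 * pad) * r / amax
  sy <- function(r) height - pad - (height - 2 * pad) * r / bmax
  circles <- sprintf(
    '<circle cx="%.2f" cy="%.2f" r="%s" fill="%s" class="%s"/>',
    sx(m$rank_a), sy(m$rank_b),
    ifelse(m$is_best, "3", "1.5"),
    ifelse(m$orientation == "same", "black", "grey"),
    ifelse(m$orientation == "same", "same", "reverse"))
  svg <- c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">',
                   width, height),
           sprintf('<rect x="%d" y="%d" width="%d" height="%d" fill="none" stroke="black"/>',
                   pad, pad, width - 2 * pad, height - 2 * pad),
           circles, "</svg>")
  ok <- tryCatch({ writeLines(svg, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("I/O error: cannot write '", path, "'")
  invisible(path)
}
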