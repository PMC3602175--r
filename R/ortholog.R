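#' Pairwise protein similarity scores
#'
#' The internal engine computes Smith–Waterman local alignments (BLOSUM62,
#' affine gaps, opening 11 / extension 1) for all protein pairs and attaches a
#' Karlin–Altschul-style expectation value `E = K m n exp(-lambda S)` with the
#' standard gapped BLOSUM62 parameters (lambda = 0.267, K = 0.041). Hits with
#' e-value at or above `evalue_max` are discarded. Alternatively, a
#' 12-column tabular hit file from an external aligner can be imported and
#' filtered by the same threshold.
#'
#' @param proteomes named list (genome_id -> named character vector of protein
#'   sequences). Protein identifiers must be globally unique.
#' @param engine `"internal"` or `"imported"`.
#' @param hits_file path to a 12-column tabular hit file (required when
#'   `engine = "imported"`).
#' @param evalue_max expectation-value cutoff (hits with `evalue >= evalue_max`
#'   are dropped).
#' @param prefilter internal engine only: skip pairs sharing no 4-mer (a
#'   cheap seed filter; any pair passing the e-value cutoff shares one).
#' @param self_hits include within-genome (and self) alignments, needed for
#'   in-paralog assignment.
#' @return a hit table: data.frame with columns `query_id`, `subject_id`,
#'   `query_genome`, `subject_genome`, `identity` (percent), `aln_len`,
#'   `evalue`, `score`.
#' @export
pairwise_scores <- function(proteomes, engine = c("internal", "imported"),
                            hits_file = NULL, evalue_max = 1e-5,
                            prefilter = TRUE, self_hits = TRUE) {
  engine <- match.arg(engine)
  empty <- vapply(proteomes, length, 0L) == 0L
  if (any(empty)) {
    warning("excluding empty proteome(s): ",
            paste(names(proteomes)[empty], collapse = ", "))
    proteomes <- proteomes[!empty]
  }
  if (!length(proteomes)) stop("no non-empty proteomes")
  ids <- unlist(lapply(proteomes, names), use.names = FALSE)
  if (is.null(ids) || anyDuplicated(ids))
    stop("protein identifiers must be present and globally unique")
  gene2genome <- stats::setNames(rep(names(proteomes),
                                     vapply(proteomes, length, 0L)), ids)
  if (engine == "imported") {
    if (is.null(hits_file)) stop("engine 'imported' requires hits_file")
    ht <- read_hit_table(hits_file, gene2genome)
    return(ht[ht$evalue < evalue_max, , drop = FALSE])
  }
  seqs <- unlist(proteomes, use.names = FALSE)
  names(seqs) <- ids
  n <- length(seqs)
  aa <- Biostrings::AAStringSet(seqs)
  data_env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = data_env)
  mat <- get("BLOSUM62", envir = data_env)
  lambda <- 0.267; K <- 0.041
  kmers <- if (prefilter)
    lapply(seqs, function(s) unique(substring(s, 1:max(1L, nchar(s) - 3L),
                                              4:max(4L, nchar(s))))) else NULL
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    js <- if (i < n) (i + 1L):n else integer(0)
    if (self_hits) js <- c(i, js)
    if (prefilter && length(js)) {
      keep <- vapply(js, function(j) j == i || any(kmers[[i]] %in% kmers[[j]]), TRUE)
      js <- js[keep]
    }
    if (!length(js)) next
    aln <- Biostrings::pairwiseAlignment(aa[js], aa[[i]], type = "local",
                                         substitutionMatrix = mat,
                                         gapOpening = 11, gapExtension = 1)
    score <- Biostrings::score(aln)
    alen <- Biostrings::nchar(aln)
    pid <- Biostrings::pid(aln)
    ev <- K * nchar(seqs[js]) * nchar(seqs[i]) * exp(-lambda * score)
    keep <- ev < evalue_max
    if (!any(keep)) next
    rows[[i]] <- data.frame(query_id = names(seqs)[js][keep],
                            subject_id = names(seqs)[i],
                            identity = pid[keep], aln_len = alen[keep],
                            evalue = ev[keep], score = score[keep],
                            stringsAsFactors = FALSE)
  }
  ht <- do.call(rbind, rows)
  if (is.null(ht)) ht <- data.frame(query_id = character(0), subject_id = character(0),
                                    identity = numeric(0), aln_len = integer(0),
                                    evalue = numeric(0), score = numeric(0),
                                    stringsAsFactors = FALSE)
  # alignment is symmetric: emit both directions
  rev_ht <- ht[ht$query_id != ht$subject_id, , drop = FALSE]
  if (nrow(rev_ht)) {
    tmp <- rev_ht$query_id; rev_ht$query_id <- rev_ht$subject_id
    rev_ht$subject_id <- tmp
    ht <- rbind(ht, rev_ht)
  }
  ht$query_genome <- unname(gene2genome[ht$query_id])
  ht$subject_genome <- unname(gene2genome[ht$subject_id])
  rownames(ht) <- NULL
  ht[, c("query_id", "subject_id", "query_genome", "subject_genome",
         "identity", "aln_len", "evalue", "score")]
}

#' Import a 12-column tabular hit file
#'
#' Standard tabular output of protein aligners (query, subject, percent
#' identity, alignment length, mismatches, gap opens, query start/end,
#' subject start/end, e-value, bit score). Multiple HSPs per pair are
#' collapsed to the best-scoring one.
#'
#' @param path tabular file.
#' @param gene2genome named character vector mapping protein id -> genome id.
#' @return hit table (see [pairwise_scores()]); `score` is the bit score.
#' @export
read_hit_table <- function(path, gene2genome) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 12L)
  if (length(bad)) stop("parse error: line ", bad[1], " has ",
                        lengths(parts)[bad[1]], " columns (12 expected)")
  m <- do.call(rbind, parts)
  ht <- data.frame(query_id = m[, 1], subject_id = m[, 2],
                   identity = as.numeric(m[, 3]), aln_len = as.integer(m[, 4]),
                   evalue = as.numeric(m[, 11]), score = as.numeric(m[, 12]),
                   stringsAsFactors = FALSE)
  unknown <- setdiff(unique(c(ht$query_id, ht$subject_id)), names(gene2genome))
  if (length(unknown)) stop("data error: protein(s) with unknown genome: ",
                            paste(utils::head(unknown, 5), collapse = ", "))
  ht$query_genome <- unname(gene2genome[ht$query_id])
  ht$subject_genome <- unname(gene2genome[ht$subject_id])
  # collapse HSPs to the max-scoring one per (query, subject)
  key <- paste(ht$query_id, ht$subject_id, sep = "\r")
  ord <- order(key, -ht$score, ht$evalue)
  ht <- ht[ord, , drop = FALSE]
  ht <- ht[!duplicated(key[ord]), , drop = FALSE]
  rownames(ht) <- NULL
  ht[, c("query_id", "subject_id", "query_genome", "subject_genome",
         "identity", "aln_len", "evalue", "score")]
}

#' Reciprocal best hits
#'
#' A cross-genome pair (a, b) is an RBH iff b is a's best-scoring hit in b's
#' genome and a is b's best-scoring hit in a's genome. Ties are broken by
#' higher score, lower e-value, longer alignment, then lexicographic subject
#' id.
#'
#' @param hits hit table (see [pairwise_scores()]).
#' @return data.frame of unordered pairs (`protein_a` < `protein_b`).
#' @export
reciprocal_best_hits <- function(hits) {
  h <- hits[hits$query_genome != hits$subject_genome, , drop = FALSE]
  if (!nrow(h)) return(data.frame(protein_a = character(0),
                                  protein_b = character(0),
                                  stringsAsFactors = FALSE))
  key <- paste(h$query_id, h$subject_genome, sep = "\r")
  ord <- order(key, -h$score, h$evalue, -h$aln_len, h$subject_id)
  h <- h[ord, , drop = FALSE]
  best <- h[!duplicated(key[ord]), , drop = FALSE]
  fwd <- paste(best$query_id, best$subject_id, sep = "\r")
  rev <- paste(best$subject_id, best$query_id, sep = "\r")
  mutual <- best[fwd %in% rev, , drop = FALSE]
  a <- pmin(mutual$query_id, mutual$subject_id)
  b <- pmax(mutual$query_id, mutual$subject_id)
  pairs <- unique(data.frame(protein_a = a, protein_b = b,
                             stringsAsFactors = FALSE))
  pairs <- pairs[order(pairs$protein_a, pairs$protein_b), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

#' Single-linkage clusters from RBH pairs
#'
#' Clusters are the connected components of the RBH graph; only components of
#' two or more proteins are families at this stage.
#'
#' @param pairs data.frame from [reciprocal_best_hits()].
#' @return a `family_set`: list with `clusters` (named list of member id
#'   vectors), `singletons` (empty here), and `provenance`.
#' @export
single_linkage_clusters <- function(pairs) {
  if (!nrow(pairs)) {
    return(structure(list(clusters = stats::setNames(list(), character(0)),
                          singletons = character(0),
                          provenance = list(rbh_pairs = pairs,
                                            inparalogs = character(0))),
                     class = "family_set"))
  }
  g <- igraph::graph_from_data_frame(pairs, directed = FALSE)
  comp <- igraph::components(g)
  members <- split(names(comp$membership), comp$membership)
  members <- lapply(members, function(v) sort(unname(v)))
  members <- members[order(vapply(members, `[`, "", 1L))]
  names(members) <- sprintf("CL%04d", seq_along(members))
  structure(list(clusters = members, singletons = character(0),
                 provenance = list(rbh_pairs = pairs,
                                   inparalogs = character(0))),
            class = "family_set")
}

#' @export
print.family_set <- function(x, ...) {
  cat(sprintf("family_set: %d cluster(s) of >=2 proteins (%d proteins), %d singleton(s)\n",
              length(x$clusters), sum(lengths(x$clusters)), length(x$singletons)))
  invisible(x)
}

#' Assign in-paralogs to existing clusters
#'
#' An unassigned protein p joins a cluster if its alignment score with some
#' member m exceeds every alignment score between m and the other cluster
#' members (for single-member clusters that maximum is vacuous, so any scored
#' hit qualifies). When several clusters qualify, p joins the one with the
#' largest margin; remaining unassigned proteins become singletons.
#'
#' @param families a `family_set` from [single_linkage_clusters()].
#' @param hits hit table including within-genome records.
#' @param all_proteins character vector of every protein id in the focal
#'   proteomes (defines who can become a singleton).
#' @return the updated `family_set` with `singletons` filled in.
#' @export
assign_inparalogs <- function(families, hits, all_proteins) {
  assigned <- unlist(families$clusters, use.names = FALSE)
  unassigned <- setdiff(all_proteins, assigned)
  # symmetric score lookup keyed "a\rb" (covers one-directional hit tables)
  h <- hits[hits$query_id != hits$subject_id, , drop = FALSE]
  skey <- c(paste(h$query_id, h$subject_id, sep = "\r"),
            paste(h$subject_id, h$query_id, sep = "\r"))
  smax <- tapply(c(h$score, h$score), skey, max)
  score_of <- function(a, b) {
    v <- smax[paste(a, b, sep = "\r")]
    ifelse(is.na(v), -Inf, v)
  }
  # every candidate is evaluated against the original clusters (single pass),
  # so the result does not depend on the order of the unassigned proteins
  joins <- character(0)
  cl <- families$clusters
  dest <- character(0)
  for (p in unassigned) {
    best_margin <- -Inf; best_cl <- NA_character_
    for (cn in names(cl)) {
      members <- cl[[cn]]
      sp <- score_of(p, members)
      if (all(sp == -Inf)) next
      # max score between m and the *other* members (vacuous -> -Inf)
      margin <- -Inf
      for (mi in seq_along(members)) {
        if (sp[mi] == -Inf) next
        others <- members[-mi]
        mmax <- if (length(others)) max(score_of(members[mi], others)) else -Inf
        if (sp[mi] > mmax) margin <- max(margin, sp[mi] - mmax)
      }
      if (margin > best_margin) { best_margin <- margin; best_cl <- cn }
    }
    if (!is.na(best_cl) && best_margin > -Inf) {
      dest[p] <- best_cl
      joins <- c(joins, p)
    }
  }
  for (p in names(dest)) cl[[dest[p]]] <- sort(c(cl[[dest[p]]], p))
  families$clusters <- cl
  families$singletons <- sort(setdiff(all_proteins,
                                      unlist(cl, use.names = FALSE)))
  families$provenance$inparalogs <- joins
  families
}

#' Build orthologous protein families end to end
#'
#' Runs [pairwise_scores()] (unless a hit table is supplied),
#' [reciprocal_best_hits()], [single_linkage_clusters()] and
#' [assign_inparalogs()]. Proteins of outgroup genomes participate in
#' clustering but never become singletons of the focal set.
#'
#' @inheritParams pairwise_scores
#' @param hits optional precomputed hit table.
#' @param outgroup character vector of genome ids to treat as outgroups.
#' @return a `family_set` with a `membership` data.frame attached
#'   (`protein_id`, `genome_id`, `family_id`, `membership_type`).
#' @export
build_families <- function(proteomes, hits = NULL, evalue_max = 1e-5,
                           outgroup = character(0), prefilter = TRUE) {
  if (is.null(hits))
    hits <- pairwise_scores(proteomes, engine = "internal",
                            evalue_max = evalue_max, prefilter = prefilter)
  gene2genome <- stats::setNames(
    rep(names(proteomes), vapply(proteomes, length, 0L)),
    unlist(lapply(proteomes, names), use.names = FALSE))
  focal <- names(gene2genome)[!(gene2genome %in% outgroup)]
  fams <- single_linkage_clusters(reciprocal_best_hits(hits))
  fams <- assign_inparalogs(fams, hits, focal)
  ortho <- unlist(lapply(fams$clusters, function(v)
    setdiff(v, fams$provenance$inparalogs)), use.names = FALSE)
  mem <- data.frame(
    protein_id = c(unlist(fams$clusters, use.names = FALSE), fams$singletons),
    family_id = c(rep(names(fams$clusters), lengths(fams$clusters)),
                  if (length(fams$singletons))
                    sprintf("SGL%04d", seq_along(fams$singletons))),
    stringsAsFactors = FALSE)
  mem$genome_id <- unname(gene2genome[mem$protein_id])
  mem$membership_type <- ifelse(mem$protein_id %in% fams$singletons, "singleton",
                         ifelse(mem$protein_id %in% fams$provenance$inparalogs,
                                "inparalog", "ortholog"))
  fams$membership <- mem[order(mem$family_id, mem$protein_id), ]
  rownames(fams$membership) <- NULL
  fams$outgroup <- outgroup
  fams
}

#' Extract per-genome proteomes from annotated genomes
#'
#' @param genomes list of [annotated_genome()] objects.
#' @return named list genome_id -> named character vector of proteins.
#' @export
proteomes <- function(genomes) {
  out <- lapply(genomes, function(g) stats::setNames(g$genes$protein,
                                                     g$genes$gene_id))
  stats::setNames(out, vapply(genomes, function(g) g$genome_id, ""))
}
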