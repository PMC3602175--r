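# Compositional deviation index (CDI).
#
# A non-homogeneous Markov model of order k describes ancestral coding
# sequence: an initial probability vector P0 over k-nucleotide tuples opening
# an ORF (codon position 1), and three transition matrices P1, P2, P3 giving
# the probability of the next nucleotide conditional on the preceding k-tuple,
# indexed by the codon position (1/2/3) of the tuple's first nucleotide. The
# CDI of an ORF standardizes its log-likelihood under the model against
# model-emitted random sequences of the same length: native-like composition
# scores near 0, compositionally deviant (candidate horizontally transferred)
# ORFs score far from 0, typically below.
#
# All likelihood arithmetic is in log space: raw ORF probabilities underflow
# for any realistic gene length, and standardization of log-likelihoods
# preserves the expectation CDI = 0 for model-emitted sequences.

# Tuple index of the k-mer starting at each position of an integer-coded
# sequence (1-based indices into 1..4^k; NA where the window touches an
# ambiguity code). First nucleotide is the most significant digit.
tuple_indices <- function(codes, k) {
  n <- length(codes)
  m <- n - k + 1L
  if (m < 1L) return(integer(0))
  idx <- rep(1, m)
  for (u in 0:(k - 1L)) idx <- idx + codes[(1L + u):(m + u)] * 4^(k - 1L - u)
  idx
}

#' Train a codon-position-specific Markov model
#'
#' Parameters are tuple counts from the training ORFs: `P0` is the frequency
#' of each ORF's opening k-tuple, and `P^f(i | j) = (N^f_(j,i) + a) /
#' (N^f_j + 4a)` where `N^f_(j,i)` counts occurrences of tuple j at codon
#' position f followed by nucleotide i, and `a` is the pseudocount. Windows
#' containing ambiguity codes are skipped; trailing partial codons are
#' trimmed.
#'
#' @param orfs character vector of in-frame coding sequences (each starting
#'   at codon position 1).
#' @param k Markov order (tuple length), default 5.
#' @param alpha pseudocount per (tuple, nucleotide) cell, default 0.5.
#' @return an object of class `codon_markov_model`.
#' @export
train_codon_model <- function(orfs, k = 5L, alpha = 0.5) {
  if (k < 1L) stop("parameter error: k must be >= 1")
  orfs <- toupper(orfs)
  orfs <- orfs[nchar(orfs) > 0L]
  if (!length(orfs)) stop("training error: empty training set")
  nt4k <- as.integer(4^k)
  p0_counts <- numeric(nt4k)
  trans_counts <- lapply(1:3, function(f) matrix(0, nt4k, 4L))
  total_nt <- 0L
  n_init <- 0L
  for (orf in orfs) {
    orf <- substr(orf, 1L, (nchar(orf) %/% 3L) * 3L)
    codes <- seq_to_codes(orf)
    total_nt <- total_nt + length(codes)
    if (length(codes) < k) next
    idx <- tuple_indices(codes, k)
    j1 <- idx[1L]
    if (!is.na(j1)) {
      p0_counts[j1] <- p0_counts[j1] + 1
      n_init <- n_init + 1L
    }
    m <- length(codes) - k
    if (m < 1L) next
    t_pos <- seq_len(m)
    j <- idx[t_pos]
    i <- codes[t_pos + k] + 1L
    f <- (t_pos - 1L) %% 3L + 1L
    ok <- !is.na(j) & !is.na(i)
    if (!any(ok)) next
    comb <- (f[ok] - 1L) * (nt4k * 4L) + (i[ok] - 1L) * nt4k + j[ok]
    tab <- tabulate(comb, nbins = 3L * nt4k * 4L)
    for (ff in 1:3) {
      block <- tab[((ff - 1L) * nt4k * 4L + 1L):(ff * nt4k * 4L)]
      trans_counts[[ff]] <- trans_counts[[ff]] + matrix(block, nt4k, 4L)
    }
  }
  if (total_nt < 10 * 4^(k + 1))
    warning(sprintf("training set has %d nt; >= %d recommended for k = %d",
                    total_nt, 10 * 4^(k + 1), k))
  p0 <- (p0_counts + alpha) / (n_init + nt4k * alpha)
  trans <- lapply(trans_counts, function(N) {
    (N + alpha) / (rowSums(N) + 4 * alpha)
  })
  structure(list(k = as.integer(k), alpha = alpha,
                 p0 = p0, trans = trans,
                 log_p0 = log(p0), log_trans = lapply(trans, log),
                 p0_counts = p0_counts, trans_counts = trans_counts,
                 training_nt = total_nt, n_training_orfs = length(orfs)),
            class = "codon_markov_model")
}

#' @export
print.codon_markov_model <- function(x, ...) {
  cat(sprintf("codon_markov_model: order k = %d, alpha = %g, trained on %d ORFs (%s nt)\n",
              x$k, x$alpha, x$n_training_orfs,
              format(x$training_nt, big.mark = ",")))
  invisible(x)
}

#' Log-likelihood of an ORF under a codon Markov model
#'
#' `log P(ORF | model) = log P0(j_1) + sum over t of log P^f(i_(t+k) | j_t)`
#' with the codon position f cycling 1, 2, 3 along the sequence. Windows
#' containing ambiguity codes contribute 0 to the sum. ORFs shorter than
#' k + 1 usable nucleotides have no defined score and return `NA`.
#'
#' @param orf coding sequence (assumed to start at codon position 1).
#' @param model a `codon_markov_model`.
#' @return log-probability (natural log), or `NA_real_` if undefined.
#' @export
orf_log_likelihood <- function(orf, model) {
  k <- model$k
  codes <- seq_to_codes(toupper(orf))
  if (length(codes) < k + 1L) return(NA_real_)
  idx <- tuple_indices(codes, k)
  ll <- if (is.na(idx[1L])) 0 else model$log_p0[idx[1L]]
  m <- length(codes) - k
  t_pos <- seq_len(m)
  j <- idx[t_pos]
  i <- codes[t_pos + k] + 1L
  f <- (t_pos - 1L) %% 3L + 1L
  ok <- !is.na(j) & !is.na(i)
  for (ff in 1:3) {
    sel <- ok & f == ff
    if (any(sel))
      ll <- ll + sum(model$log_trans[[ff]][cbind(j[sel], i[sel])])
  }
  ll
}

# Simulate n chains of a given length from the model, returning accumulated
# log-likelihoods (and optionally the integer-coded sequences). Vectorized
# across chains; this is what makes CDI with n_rand randomizations tractable.
sample_chains <- function(model, length_nt, n, keep_codes = FALSE) {
  k <- model$k
  nt4k <- length(model$p0)
  if (length_nt < k + 1L) stop("parameter error: length must be >= k + 1")
  cum0 <- cumsum(model$p0)
  cumt <- lapply(model$trans, function(P) {
    cbind(P[, 1L], P[, 1L] + P[, 2L], P[, 1L] + P[, 2L] + P[, 3L])
  })
  j <- findInterval(stats::runif(n), cum0) + 1L
  j[j > nt4k] <- nt4k
  ll <- model$log_p0[j]
  codes <- NULL
  if (keep_codes) {
    codes <- matrix(0L, n, length_nt)
    jj <- j - 1L
    for (u in k:1) { codes[, u] <- jj %% 4L; jj <- jj %/% 4L }
  }
  drop_base <- as.integer(4^(k - 1L))
  for (t in seq_len(length_nt - k)) {
    f <- (t - 1L) %% 3L + 1L
    cm <- cumt[[f]]
    u <- stats::runif(n)
    i <- 1L + (u > cm[j, 1L]) + (u > cm[j, 2L]) + (u > cm[j, 3L])
    ll <- ll + model$log_trans[[f]][j + (i - 1L) * nt4k]
    if (keep_codes) codes[, t + k] <- i - 1L
    j <- ((j - 1L) %% drop_base) * 4L + i
  }
  list(ll = ll, codes = codes)
}

#' Emit a random coding sequence from the model
#'
#' The opening k-tuple is drawn from `P0`, subsequent nucleotides from the
#' position-appropriate transition matrix.
#'
#' @param model a `codon_markov_model`.
#' @param length_nt sequence length (>= k + 1).
#' @param seed optional integer seed; a fixed seed gives an identical
#'   sequence.
#' @return a nucleotide string of the requested length.
#' @export
sample_orf <- function(model, length_nt, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sim <- sample_chains(model, length_nt, 1L, keep_codes = TRUE)
  codes_to_seq(as.integer(sim$codes[1L, ]))
}

#' Compositional deviation index
#'
#' For each ORF, `n_rand` random coding sequences of the same length are
#' emitted from the model; the CDI is the ORF's log-likelihood standardized
#' by the mean and standard deviation of the random sequences'
#' log-likelihoods. Model-like ORFs score near 0; compositionally deviant
#' ORFs (recent horizontal acquisitions among them) deviate, typically
#' downwards.
#'
#' @param orfs character vector of coding sequences (optionally named; names
#'   become `orf_id`).
#' @param model a `codon_markov_model`.
#' @param n_rand randomizations per ORF (default 100).
#' @param seed optional integer seed for the randomizations.
#' @return data.frame with `orf_id`, `length_nt`, `logL`, `null_mean`,
#'   `null_sd`, `cdi` and `flag` (`"ok"`, `"short"` for unscorable ORFs,
#'   `"degenerate"` when the null SD is 0).
#' @export
compute_cdi <- function(orfs, model, n_rand = 100L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_rand < 2L) stop("parameter error: n_rand must be >= 2")
  ids <- names(orfs) %||% sprintf("orf%04d", seq_along(orfs))
  lens <- nchar(orfs)
  logL <- vapply(orfs, orf_log_likelihood, 0, model = model, USE.NAMES = FALSE)
  null_mean <- rep(NA_real_, length(orfs))
  null_sd <- rep(NA_real_, length(orfs))
  scorable <- which(!is.na(logL))
  # chains are simulated in batches grouped by ORF length
  max_chains <- 65536L
  for (l in sort(unique(lens[scorable]))) {
    members <- scorable[lens[scorable] == l]
    for (chunk in split(members, ceiling(seq_along(members) /
                                         max(1L, max_chains %/% n_rand)))) {
      sim <- sample_chains(model, l, length(chunk) * n_rand)
      mat <- matrix(sim$ll, nrow = n_rand)
      null_mean[chunk] <- colMeans(mat)
      null_sd[chunk] <- apply(mat, 2L, stats::sd)
    }
  }
  cdi <- (logL - null_mean) / null_sd
  flag <- ifelse(is.na(logL), "short",
                 ifelse(!is.na(null_sd) & null_sd == 0, "degenerate", "ok"))
  cdi[flag != "ok"] <- NA_real_
  data.frame(orf_id = ids, length_nt = lens, logL = logL,
             null_mean = null_mean, null_sd = null_sd, cdi = cdi,
             flag = flag, stringsAsFactors = FALSE, row.names = NULL)
}

#' Compare CDI distributions between gene categories
#'
#' Kruskal–Wallis omnibus test of CDI by category, all pairwise two-sided
#' Wilcoxon rank-sum tests with family-wise (Holm) correction, and — when
#' ORFan flags are supplied — the named contrast of long (> 300 bp) versus
#' short (< 300 bp) ORFan genes.
#'
#' @param cdi numeric CDI values.
#' @param labels category label per value.
#' @param orfan optional logical ORFan flag per value.
#' @param length_nt optional ORF length per value (required for the ORFan
#'   contrast).
#' @param long_cutoff_bp boundary for the long/short ORFan contrast.
#' @return list of class `cdi_comparison` with `omnibus`, `pairwise` and
#'   optionally `orfan_long_short`.
#' @export
cdi_group_comparison <- function(cdi, labels, orfan = NULL, length_nt = NULL,
                                 long_cutoff_bp = 300L) {
  ok <- !is.na(cdi) & !is.na(labels)
  cdi <- cdi[ok]; labels <- as.character(labels)[ok]
  if (!is.null(orfan)) orfan <- orfan[ok]
  if (!is.null(length_nt)) length_nt <- length_nt[ok]
  sizes <- table(labels)
  small <- names(sizes)[sizes < 2L]
  if (length(small)) {
    warning("excluding group(s) with < 2 observations: ",
            paste(small, collapse = ", "))
    keep <- !(labels %in% small)
    cdi <- cdi[keep]; labels <- labels[keep]
    if (!is.null(orfan)) orfan <- orfan[keep]
    if (!is.null(length_nt)) length_nt <- length_nt[keep]
  }
  if (length(unique(labels)) < 2L) stop("need >= 2 groups with >= 2 observations")
  omnibus <- stats::kruskal.test(cdi, factor(labels))
  pairwise <- stats::pairwise.wilcox.test(cdi, factor(labels),
                                          p.adjust.method = "holm",
                                          exact = FALSE)
  out <- list(omnibus = omnibus, pairwise = pairwise)
  if (!is.null(orfan) && !is.null(length_nt)) {
    long <- cdi[orfan & length_nt > long_cutoff_bp]
    short <- cdi[orfan & length_nt < long_cutoff_bp]
    if (length(long) >= 2L && length(short) >= 2L)
      out$orfan_long_short <- stats::wilcox.test(long, short, exact = FALSE)
  }
  class(out) <- "cdi_comparison"
  out
}

#' @export
print.cdi_comparison <- function(x, ...) {
  cat(sprintf("CDI group comparison: Kruskal-Wallis chi^2 = %.3f, p = %.3g\n",
              unname(x$omnibus$statistic), x$omnibus$p.value))
  cat("Pairwise Wilcoxon (Holm-adjusted) p-values:\n")
  print(signif(x$pairwise$p.value, 3))
  if (!is.null(x$orfan_long_short))
    cat(sprintf("Long vs short ORFan contrast: p = %.3g\n",
                x$orfan_long_short$p.value))
  invisible(x)
}

#' Serialize a codon Markov model to JSON
#'
#' Writes a documented JSON object (`k`, `alpha`, `p0`, the three transition
#' matrices row-major, and training metadata) readable by
#' [read_codon_model()].
#'
#' @param model a `codon_markov_model`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_codon_model <- function(model, path) {
  obj <- list(format = "chlorocomp codon_markov_model",
              version = 1L, k = model$k, alpha = model$alpha,
              p0 = model$p0,
              trans = lapply(model$trans, function(m) as.vector(t(m))),
              training_nt = model$training_nt,
              n_training_orfs = model$n_training_orfs)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a codon Markov model from JSON
#'
#' @param path a file written by [write_codon_model()].
#' @return a `codon_markov_model`.
#' @export
read_codon_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "chlorocomp codon_markov_model"))
    stop("format error: not a codon model file")
  nt4k <- as.integer(4^obj$k)
  if (is.matrix(obj$trans))  # equal-length arrays simplify to a matrix
    obj$trans <- lapply(seq_len(nrow(obj$trans)), function(r) obj$trans[r, ])
  trans <- lapply(obj$trans, function(v) matrix(v, nt4k, 4L, byrow = TRUE))
  structure(list(k = as.integer(obj$k), alpha = obj$alpha,
                 p0 = obj$p0, trans = trans,
                 log_p0 = log(obj$p0), log_trans = lapply(trans, log),
                 p0_counts = NULL, trans_counts = NULL,
                 training_nt = obj$training_nt,
                 n_training_orfs = obj$n_training_orfs),
            class = "codon_markov_model")
}
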