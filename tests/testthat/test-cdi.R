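# Hand-constructable model helper: uniform or explicit probability tables.
manual_model <- function(k, p0, trans) {
  structure(list(k = as.integer(k), alpha = 0, p0 = p0, trans = trans,
                 log_p0 = log(p0), log_trans = lapply(trans, log),
                 p0_counts = NULL, trans_counts = NULL,
                 training_nt = NA_integer_, n_training_orfs = NA_integer_),
            class = "codon_markov_model")
}

uniform_model <- function(k) {
  manual_model(k, rep(1 / 4^k, 4^k),
               lapply(1:3, function(f) matrix(0.25, 4^k, 4)))
}

test_that("training counts equal a sliding-window tuple counter", {
  set.seed(61)
  k <- 3L
  orf <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
  mod <- suppressWarnings(train_codon_model(orf, k = k, alpha = 0.5))
  oracle <- tuple_count_oracle(orf, k)
  for (f in 1:3) {
    expect_equal(unname(mod$trans_counts[[f]]), unname(oracle[[f]]),
                 ignore_attr = TRUE)
  }
  # initial-tuple count: one ORF, its opening k-mer
  open <- substr(orf, 1, k)
  idx <- chlorocomp:::tuple_indices(chlorocomp:::seq_to_codes(open), k)
  expect_equal(sum(mod$p0_counts), 1)
  expect_equal(mod$p0_counts[idx], 1)
})

test_that("trained probabilities are normalized for any input", {
  set.seed(62)
  for (rep in 1:5) {
    orfs <- vapply(1:8, function(i)
      paste(sample(c("A", "C", "G", "T", "N"), 3 * sample(25:80, 1),
                   replace = TRUE, prob = c(0.24, 0.24, 0.24, 0.24, 0.04)),
            collapse = ""), "")
    mod <- suppressWarnings(train_codon_model(orfs, k = 2, alpha = 0.5))
    expect_equal(sum(mod$p0), 1)
    for (f in 1:3) expect_equal(unname(rowSums(mod$trans[[f]])), rep(1, 16))
    expect_true(all(mod$p0 > 0))
    expect_true(all(vapply(mod$trans, function(m) all(m > 0), TRUE)))
  }
})

test_that("poly-A training drives P(A | AAAAA) to 1 as the pseudocount vanishes", {
  orfs <- rep(paste(rep("A", 120), collapse = ""), 5)
  mod <- suppressWarnings(train_codon_model(orfs, k = 5, alpha = 1e-9))
  jA <- chlorocomp:::tuple_indices(rep(0L, 5L), 5L)
  for (f in 1:3) expect_gt(mod$trans[[f]][jA, 1], 1 - 1e-6)
})

test_that("under a uniform model every ORF scores -l log 4", {
  mod <- uniform_model(3L)
  set.seed(63)
  for (l in c(4L, 30L, 99L)) {
    orf <- paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
    expect_equal(orf_log_likelihood(orf, mod), -l * log(4))
  }
})

test_that("a k=1 toy model reproduces a pencil-and-paper likelihood", {
  # rows/cols in A, C, G, T order
  t1 <- matrix(c(0.7, 0.1, 0.1, 0.1,
                 0.25, 0.25, 0.25, 0.25,
                 0.1, 0.2, 0.3, 0.4,
                 0.4, 0.3, 0.2, 0.1), 4, 4, byrow = TRUE)
  t2 <- matrix(0.25, 4, 4); t2[2, ] <- c(0.1, 0.6, 0.2, 0.1)
  t3 <- matrix(0.25, 4, 4); t3[4, ] <- c(0.05, 0.05, 0.4, 0.5)
  p0 <- c(0.4, 0.3, 0.2, 0.1)
  mod <- manual_model(1L, p0, list(t1, t2, t3))
  orf <- "ACGTACGTA"  # 9 nt: initial A + 8 transitions with f cycling 1,2,3
  nuc <- c(A = 1, C = 2, G = 3, T = 4)
  v <- nuc[strsplit(orf, "")[[1]]]
  tr <- list(t1, t2, t3)
  by_hand <- log(p0[v[1]])
  for (t in 1:8) {
    f <- (t - 1) %% 3 + 1
    by_hand <- by_hand + log(tr[[f]][v[t], v[t + 1]])
  }
  expect_equal(orf_log_likelihood(orf, mod), by_hand)
  # likelihood strictly decreases as the ORF is extended
  lls <- vapply(3:9, function(l) orf_log_likelihood(substr(orf, 1, l), mod), 0)
  expect_true(all(diff(lls) < 0))
  # too-short input is an explicit NA, not an exception or a zero
  expect_true(is.na(orf_log_likelihood("A", mod)))
})

test_that("ambiguity codes contribute nothing to the log-likelihood", {
  mod <- uniform_model(2L)
  expect_equal(orf_log_likelihood("ACGNACG", mod),
               # initial AC + transitions whose 3-windows avoid the N
               log(1 / 16) + 2 * log(0.25))
})

test_that("sampled ORFs have the requested length and obey the seed", {
  orfs <- rep(paste(rep(c("ATG", "GCA", "TTC"), 40), collapse = ""), 30)
  mod <- train_codon_model(orfs, k = 2)
  s1 <- sample_orf(mod, 200L, seed = 5L)
  s2 <- sample_orf(mod, 200L, seed = 5L)
  expect_equal(nchar(s1), 200L)
  expect_identical(s1, s2)
  expect_false(identical(sample_orf(mod, 200L, seed = 6L), s1))
  expect_error(sample_orf(mod, 2L, seed = 1L), "parameter error")
})

test_that("emitted transition frequencies match the model (chi-square)", {
  set.seed(64)
  k <- 1L
  orfs <- vapply(1:20, function(i)
    paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE,
                 prob = c(0.35, 0.15, 0.2, 0.3)), collapse = ""), "")
  mod <- train_codon_model(orfs, k = k)
  sim <- chlorocomp:::sample_chains(mod, 1000L, 1000L, keep_codes = TRUE)
  codes <- sim$codes  # 1000 chains x 1000 nt, ~1e6 transitions
  stat <- 0; df <- 0
  for (f in 1:3) {
    t_pos <- seq(f, 1000L - k, by = 3L)
    j <- codes[, t_pos] + 1L
    i <- codes[, t_pos + k] + 1L
    obs <- table(factor(j, 1:4), factor(i, 1:4))
    expct <- rowSums(obs) * mod$trans[[f]]
    keep <- expct >= 5
    stat <- stat + sum((obs[keep] - expct[keep])^2 / expct[keep])
    df <- df + sum(keep) - 4L
  }
  expect_gt(stats::pchisq(stat, df, lower.tail = FALSE), 0.01)
})

test_that("CDI nulls converge to the exhaustive enumeration at k=1, l=6", {
  set.seed(65)
  orfs <- vapply(1:20, function(i)
    paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE,
                 prob = c(0.4, 0.1, 0.2, 0.3)), collapse = ""), "")
  mod <- train_codon_model(orfs, k = 1)
  # enumerate all 4^6 sequences: exact E[logP] and SD[logP] under the model
  grid <- as.matrix(expand.grid(rep(list(0:3), 6)))
  ll <- apply(grid, 1, function(v)
    orf_log_likelihood(paste(c("A", "C", "G", "T")[v + 1], collapse = ""), mod))
  w <- exp(ll)
  expect_equal(sum(w), 1, tolerance = 1e-10)  # enumeration is complete
  exact_mean <- sum(w * ll)
  exact_sd <- sqrt(sum(w * (ll - exact_mean)^2))
  res <- compute_cdi(c(x = "ACGTAC"), mod, n_rand = 4000L, seed = 66L)
  expect_equal(res$null_mean, exact_mean, tolerance = 4 * exact_sd / sqrt(4000))
  expect_equal(res$null_sd, exact_sd, tolerance = 0.05 * exact_sd)
  # the CDI itself uses the same standardization
  expect_equal(res$cdi, (res$logL - res$null_mean) / res$null_sd)
})

test_that("model-emitted ORFs have CDI centred at zero", {
  set.seed(67)
  orfs <- vapply(1:50, function(i)
    paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE,
                 prob = c(0.3, 0.2, 0.2, 0.3)), collapse = ""), "")
  mod <- train_codon_model(orfs, k = 2)
  emitted <- vapply(1:100, function(i) sample_orf(mod, 300L), "")
  res <- compute_cdi(emitted, mod, n_rand = 100L, seed = 68L)
  expect_lt(abs(mean(res$cdi)), 0.3)
  expect_true(all(res$flag == "ok"))
})

test_that("degenerate and too-short cases are flagged, not faked", {
  # deterministic model: every emission identical -> null SD 0
  t_det <- matrix(c(1, 0, 0, 0), 4, 4, byrow = FALSE)
  mod <- manual_model(1L, c(1, 0, 0, 0) + 1e-300,
                      lapply(1:3, function(f) t_det + 1e-300))
  res <- compute_cdi(c(a = "AAAAAA"), mod, n_rand = 50L, seed = 1L)
  expect_equal(res$flag, "degenerate")
  expect_true(is.na(res$cdi))
  res2 <- compute_cdi(c(b = "AC"),
                      suppressWarnings(train_codon_model("ACGTACGTACGT", k = 3)),
                      n_rand = 10L, seed = 1L)
  expect_equal(res2$flag, "short")
  expect_true(is.na(res2$cdi))
})

test_that("CDI calibration holds across length strata", {
  set.seed(69)
  d <- synthetic_design(host_groups = data.frame(group = "NC64A", n_genomes = 1L,
                                                 gc = 0.40),
                        n_core = 150L, n_group_specific = NULL, n_opposite = 0L,
                        n_scattered = 0L, n_singleton = 0L,
                        mean_len_codons = 250, seed = 70L)
  mod <- train_codon_model(generate_genome_set(d)$genomes[[1]]$genes$cds, k = 5)
  for (l in c(150L, 600L, 1500L)) {
    emitted <- vapply(1:100, function(i) sample_orf(mod, l), "")
    res <- compute_cdi(emitted, mod, n_rand = 100L, seed = l)
    expect_lt(abs(mean(res$cdi)), 0.3)
  }
})

test_that("group comparisons behave on identical, shifted and permuted data", {
  set.seed(71)
  x <- rnorm(100)
  # identical groups: omnibus statistic is 0, p = 1
  cmp <- cdi_group_comparison(c(x, x), rep(c("a", "b"), each = 100))
  expect_gt(cmp$omnibus$p.value, 0.99)
  # two groups shifted by 3 SD: decisive rejection
  cmp2 <- cdi_group_comparison(c(x, x + 3), rep(c("a", "b"), each = 100))
  expect_lt(cmp2$omnibus$p.value, 0.001)
  expect_lt(cmp2$pairwise$p.value["b", "a"], 0.001)
  # long/short ORFan contrast is wired through (identical samples -> p ~ 1)
  orfan <- rep(TRUE, 200)
  lens <- rep(c(150L, 600L), each = 100)
  cmp3 <- cdi_group_comparison(c(x, x), rep(c("a", "b"), each = 100),
                               orfan = orfan, length_nt = lens)
  expect_gt(cmp3$orfan_long_short$p.value, 0.9)
  # tiny groups are excluded with a warning
  expect_warning(cdi_group_comparison(c(x, x, 1),
                                      c(rep(c("a", "b"), each = 100), "tiny")),
                 "excluding")
  # under label permutation the omnibus p-values are uniform
  pv <- vapply(1:200, function(i)
    stats::kruskal.test(x, factor(sample(rep(c("a", "b"), 50))))$p.value, 0)
  # rank-based p-values can tie; the KS uniformity check is still informative
  expect_gt(suppressWarnings(stats::ks.test(pv, "punif"))$p.value, 0.01)
})

test_that("model JSON serialization round-trips scores exactly", {
  set.seed(72)
  orfs <- vapply(1:10, function(i)
    paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = ""), "")
  mod <- train_codon_model(orfs, k = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_codon_model(mod, path)
  mod2 <- read_codon_model(path)
  probe <- paste(sample(c("A", "C", "G", "T"), 90, replace = TRUE), collapse = "")
  expect_equal(orf_log_likelihood(probe, mod2), orf_log_likelihood(probe, mod))
  expect_equal(mod2$k, mod$k)
})

test_that("training on an empty set or invalid order fails loudly", {
  expect_error(train_codon_model(character(0), k = 2), "training error")
  expect_error(train_codon_model("ACGT", k = 0), "parameter error")
})
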