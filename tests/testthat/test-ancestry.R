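make_fm <- function(counts, groups) {
  mem <- do.call(rbind, lapply(seq_len(nrow(counts)), function(i) {
    reps <- rep(colnames(counts), counts[i, ])
    if (!length(reps)) return(NULL)
    data.frame(protein_id = sprintf("f%d_%s_%d", i, reps, seq_along(reps)),
               genome_id = reps, family_id = rownames(counts)[i],
               stringsAsFactors = FALSE)
  }))
  build_matrix(mem, data.frame(genome_id = colnames(counts),
                               host_group = groups,
                               stringsAsFactors = FALSE))
}

test_that("build_matrix counts members per genome, in-paralogs included", {
  counts <- matrix(c(1L, 1L), 1, 2, dimnames = list("F1", c("gA", "gB")))
  fm <- make_fm(counts, c("X", "Y"))
  expect_equal(unname(fm$counts["F1", ]), c(1L, 1L))
  counts2 <- matrix(c(2L, 1L), 1, 2, dimnames = list("F1", c("gA", "gB")))
  fm2 <- make_fm(counts2, c("X", "Y"))
  expect_equal(fm2$counts["F1", "gA"], 2L)
  # unknown genome is a data error
  mem <- data.frame(protein_id = "p", genome_id = "nope", family_id = "F1")
  expect_error(build_matrix(mem, data.frame(genome_id = "gA", host_group = "X")),
               "data error")
})

test_that("row sums equal cluster sizes on a generated family set", {
  gs <- generate_genome_set(small_design())
  fams <- build_families(proteomes(gs$genomes))
  fm <- build_matrix(fams, genome_meta(gs$genomes))
  sizes <- c(lengths(fams$clusters),
             stats::setNames(rep(1L, length(fams$singletons)),
                             sprintf("SGL%04d", seq_along(fams$singletons))))
  expect_equal(rowSums(fm$counts)[names(sizes)], as.numeric(sizes),
               ignore_attr = TRUE)
})

test_that("family categories follow the five rules with correct precedence", {
  groups <- c("NC64A", "NC64A", "Pbi", "Pbi", "SAG")
  counts <- rbind(F1 = c(1L, 2L, 1L, 1L, 1L),  # core (in-paralog irrelevant)
                  F2 = c(1L, 1L, 0L, 0L, 0L),  # host_specific:NC64A
                  F3 = c(0L, 0L, 1L, 1L, 1L),  # opposite:NC64A
                  F4 = c(0L, 1L, 0L, 0L, 0L),  # singleton
                  F5 = c(1L, 0L, 1L, 0L, 0L))  # scattered
  colnames(counts) <- sprintf("g%d", 1:5)
  fm <- classify_families(make_fm(counts, groups))
  expect_equal(unname(fm$category),
               c("core", "host_specific:NC64A", "opposite:NC64A",
                 "singleton", "scattered"))
  # with two groups, host-specific takes precedence over the opposite pattern
  fm2 <- classify_families(make_fm(counts[2, , drop = FALSE][, 1:4, drop = FALSE],
                                   groups[1:4]))
  expect_equal(unname(fm2$category), "host_specific:NC64A")
})

test_that("random matrices classify identically to the literal rule oracle", {
  set.seed(21)
  for (rep in 1:40) {
    ng <- sample(3:7, 1)
    groups <- sample(c("NC64A", "Pbi", "SAG"), ng, replace = TRUE)
    while (length(unique(groups)) < 2) groups <- sample(c("NC64A", "Pbi", "SAG"),
                                                        ng, replace = TRUE)
    counts <- matrix(rpois(ng * 12, 0.8), 12, ng,
                     dimnames = list(sprintf("F%02d", 1:12), sprintf("g%d", 1:ng)))
    counts <- counts[rowSums(counts) > 0, , drop = FALSE]
    if (!nrow(counts)) next
    fm <- classify_families(make_fm(counts, groups))
    expect_equal(fm$category, classify_oracle(fm$counts, fm$groups))
  }
})

test_that("category counts sum to the family total and reproduce a design", {
  gs <- generate_genome_set(small_design())
  fams <- build_families(proteomes(gs$genomes))
  fm <- classify_families(build_matrix(fams, genome_meta(gs$genomes)))
  expect_equal(sum(table(fm$category)), nrow(fm$counts))
  got <- sub(":.*", "", fm$category)
  truth <- gs$truth$families
  expect_equal(unname(table(got)[c("core", "host_specific", "opposite")]),
               unname(table(sub(":.*", "", sub("group_specific", "host_specific",
                                               truth$category)))[
                 c("core", "host_specific", "opposite")]))
})

test_that("the two-clade parsimony rule flags ancestral families", {
  groups <- c("NC64A", "Pbi", "SAG")
  counts <- rbind(F1 = c(1L, 0L, 1L),  # NC64A + SAG -> ancestral
                  F2 = c(0L, 2L, 0L),  # Pbi only -> non-ancestral
                  F3 = c(0L, 1L, 1L),  # right side only -> non-ancestral
                  F4 = c(1L, 1L, 1L))  # core -> ancestral
  colnames(counts) <- c("gN", "gP", "gS")
  fm <- ancestral_families(make_fm(counts, groups))
  expect_equal(unname(fm$ancestral), c(TRUE, FALSE, FALSE, TRUE))
  # externally supplied evidence (e.g. NCLDV-sister trees) force-flags
  fm2 <- ancestral_families(make_fm(counts, groups), extra_evidence = "F2")
  expect_true(fm2$ancestral["F2"])
  expect_error(ancestral_families(make_fm(counts, c("X", "Y", "Z"))),
               "configuration error")
})

test_that("ancestral flag is monotone in membership and contains the core", {
  set.seed(33)
  groups <- c("NC64A", "NC64A", "Pbi", "SAG")
  for (rep in 1:30) {
    counts <- matrix(rpois(4 * 8, 0.7), 8, 4,
                     dimnames = list(sprintf("F%d", 1:8), sprintf("g%d", 1:4)))
    counts <- counts[rowSums(counts) > 0, , drop = FALSE]
    if (!nrow(counts)) next
    fm <- ancestral_families(classify_families(make_fm(counts, groups)))
    expect_true(all(fm$ancestral[fm$category == "core"]))  # core subset ancestral
    # adding one member anywhere never flips ancestral -> non-ancestral
    i <- sample(nrow(counts), 1); j <- sample(4, 1)
    counts2 <- counts; counts2[i, j] <- counts2[i, j] + 1L
    fm2 <- ancestral_families(make_fm(counts2, groups))
    expect_true(all(fm2$ancestral[fm$ancestral]))
  }
})

test_that("single-copy core selection demands exactly one member everywhere", {
  counts <- rbind(F1 = c(1L, 1L, 1L), F2 = c(1L, 2L, 1L), F3 = c(1L, 1L, 0L))
  colnames(counts) <- c("g1", "g2", "og1")
  fm <- make_fm(counts, c("NC64A", "Pbi", "outgroup"))
  # all-ones row selected; a 2 anywhere excluded; a supplied outgroup genome
  # must also carry exactly one member
  expect_equal(select_single_copy_core(fm, outgroup = "og1"), "F1")
  # on a designed genome set the single-copy core is exactly the core set
  gs <- generate_genome_set(small_design())
  fams <- build_families(proteomes(gs$genomes))
  fm2 <- classify_families(build_matrix(fams, genome_meta(gs$genomes)))
  expect_setequal(select_single_copy_core(fm2),
                  names(fm2$category)[fm2$category == "core"])
})

test_that("chance-ORF scan finds nothing in tandem stop codons", {
  s <- paste(rep("TAA", 200), collapse = "")
  expect_equal(chlorocomp:::count_orfs_one_strand(s, 300L), 0L)
  # and exactly one ORF when a long ATG-opened frame is present
  s2 <- paste0(paste(rep("TAA", 5), collapse = ""),
               "ATG", paste(rep("AAA", 110), collapse = ""), "TGA",
               paste(rep("TAA", 5), collapse = ""))
  expect_equal(chlorocomp:::count_orfs_one_strand(s2, 300L), 1L)
})

test_that("chance-ORF null matches the geometric closed form on iid sequence", {
  set.seed(44)
  # iid uniform coding pool, one synthetic gene
  L <- 60000L
  cds <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  g <- suppressWarnings(  # a random 60-kb "gene" necessarily has internal stops
    annotated_genome("iid", c(c1 = cds),
                     data.frame(gene_id = "g1", contig_id = "c1",
                                start = 0L, end = L, strand = "+")))
  res <- orfan_chance_null(g, replicates = 40L, seed = 7L)
  # analytic expectation for one strand frame of n codons, composition p:
  # each ATG counts if some in-frame stop follows with total span > 300 bp
  p <- table(factor(strsplit(cds, "")[[1]], levels = c("A", "C", "G", "T"))) / L
  p_atg <- p["A"] * p["T"] * p["G"]
  p_stop <- p["T"] * p["A"] * p["A"] + p["T"] * p["A"] * p["G"] +
    p["T"] * p["G"] * p["A"]
  min_cod <- ceiling((300 + 1) / 3)  # codons ATG..stop needed to exceed 300 bp
  exp_frame <- function(ncod) {
    if (ncod < min_cod) return(0)
    t <- seq_len(ncod - min_cod + 1L)  # ATG positions with room for a stop
    sum(p_atg * (1 - p_stop)^(min_cod - 2) *
          (1 - (1 - p_stop)^(ncod - t - min_cod + 2)))
  }
  expected <- sum(vapply(0:2, function(off) exp_frame((L - off) %/% 3L), 0)) * 2
  expect_lt(abs(res$mean - expected), 2 * max(res$sd, 1))
  # determinism under a fixed seed
  res2 <- orfan_chance_null(g, replicates = 5L, seed = 123L)
  res3 <- orfan_chance_null(g, replicates = 5L, seed = 123L)
  expect_identical(res2$counts, res3$counts)
  expect_error(orfan_chance_null(g, replicates = 0L), "parameter error")
})

test_that("relative genomic positions average gene midpoints over length", {
  mkg <- function(id, start, end, glen) {
    annotated_genome(id, c(c1 = paste(rep("ACGT", glen / 4), collapse = "")),
                     data.frame(gene_id = paste0(id, "_g"), contig_id = "c1",
                                start = start, end = end, strand = "+"))
  }
  g1 <- mkg("v1", 4998L, 5004L, 10000L)   # centered gene
  g2 <- mkg("v2", 0L, 6L, 10000L)         # gene at the origin
  fm <- make_fm(matrix(c(1L, 1L), 2, 1,
                       dimnames = list(c("F1", "F2"), "x")), "NC64A")
  fm$ancestral <- c(F1 = FALSE, F2 = FALSE)
  mem <- data.frame(protein_id = c("v1_g", "v2_g"), genome_id = c("v1", "v2"),
                    family_id = c("F1", "F2"), stringsAsFactors = FALSE)
  out <- nonancestral_location_distribution(fm, list(g1, g2), mem)
  expect_equal(out$mean_rel_pos[out$family_id == "F1"], 0.5001, tolerance = 1e-6)
  expect_lt(out$mean_rel_pos[out$family_id == "F2"], 0.001)
})

test_that("uniformly placed families pass a KS test against uniform", {
  set.seed(55)
  n <- 200L
  glen <- 100000L
  starts <- sort(sample.int(glen - 10L, n))
  g <- annotated_genome("u", c(c1 = paste(rep("ACGT", glen / 4), collapse = "")),
                        data.frame(gene_id = sprintf("u_g%03d", seq_len(n)),
                                   contig_id = "c1", start = starts,
                                   end = starts + 6L, strand = "+"))
  fam <- sprintf("F%03d", seq_len(n))
  fm <- make_fm(matrix(1L, n, 1, dimnames = list(fam, "u")), "NC64A")
  fm$ancestral <- stats::setNames(rep(FALSE, n), fam)
  mem <- data.frame(protein_id = g$genes$gene_id, genome_id = "u",
                    family_id = fam, stringsAsFactors = FALSE)
  out <- nonancestral_location_distribution(fm, list(g), mem)
  expect_gt(stats::ks.test(out$mean_rel_pos, "punif")$p.value, 0.01)
})

test_that("benchmark registry tracks the full-scale targets with 5% slack", {
  bt <- benchmark_targets()
  expect_setequal(bt$statistic,
                  c("multi_member_clusters", "core_families",
                    "rule_ancestral_families", "most_divergent_dnapol_identity"))
  chk <- check_benchmarks(c(multi_member_clusters = 540, core_families = 155,
                            rule_ancestral_families = 270,
                            most_divergent_dnapol_identity = 64))
  expect_true(chk$pass[chk$statistic == "multi_member_clusters"])   # within 5%
  expect_false(chk$pass[chk$statistic == "rule_ancestral_families"]) # off by 7%
  expect_true(is.na(check_benchmarks(c(core_families = 155))$pass[1]))
})
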