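small_locus <- function() {
  set.seed(123)
  locus_spec("toy", random_coding_seq(30), copies_per_individual = 1L)
}

test_that("locus_spec validates its invariants", {
  expect_error(locus_spec("x", "ACGTA"), "multiple of 3")
  expect_error(locus_spec("x", "ACGTNN"), "only A/C/G/T")
  expect_error(locus_spec("x", "ACGACG", copies_per_individual = 0),
               ">= 1")
  loc <- small_locus()
  expect_equal(loc$amplicon_length, 90)
})

test_that("sim_config validates rates, depth and positions", {
  expect_error(sim_config(migration_rate = 1.5), "rates")
  expect_error(sim_config(depth_per_individual = 0), "depth")
  expect_error(sim_config(coastline_positions = c(0, 100)), "one coastline")
  expect_error(sim_config(n_populations = 3,
                          coastline_positions = c(0, 100, 50)),
               "strictly increasing")
})

test_that("theta = 0 yields a pool identical to the reference", {
  loc <- small_locus()
  pool <- generate_allele_pool(loc, 12, theta = 0, seed = 1)
  expect_equal(pool$n_distinct, 1)
  expect_true(all(pool$sequences == loc$reference_sequence))
})

test_that("dN/dS of 0 forces purely synonymous divergence", {
  loc <- small_locus()
  pool <- generate_allele_pool(loc, 10, theta = 12, dnds_target = 0, seed = 2)
  kk <- pool_kaks(pool)
  expect_gt(pool$n_distinct, 1)
  expect_equal(kk$Ka, 0)
  expect_gt(kk$Ks, 0)
  # translated protein identical to the reference everywhere
  ref_aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(loc$reference_sequence)))
  for (s in unique(pool$sequences)) {
    expect_identical(as.character(Biostrings::translate(
      Biostrings::DNAString(s))), ref_aa)
  }
})

test_that("no stop codons ever arise in pool sequences", {
  loc <- small_locus()
  pool <- generate_allele_pool(loc, 15, theta = 20, dnds_target = 3, seed = 3)
  for (s in unique(pool$sequences)) {
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(s)))
    expect_false(grepl("\\*", aa))
  }
})

test_that("realized pool dN/dS lands near the target and responds to the dial", {
  set.seed(77)
  loc <- locus_spec("toy", random_coding_seq(60))
  # single pool at the target used in the acceptance surface
  pool <- generate_allele_pool(loc, 20, theta = 10, dnds_target = 1, seed = 11)
  kk <- pool_kaks(pool)
  expect_true(abs(kk$omega - 1) <= 0.5)
  # monotone nondecreasing mean omega over targets {0.2, 1, 3}, >= 10 seeds
  mean_omega <- vapply(c(0.2, 1, 3), function(target) {
    oms <- vapply(1:10, function(s) {
      p <- generate_allele_pool(loc, 12, theta = 10, dnds_target = target,
                                seed = 1000 + s)
      o <- pool_kaks(p)$omega
      if (is.na(o)) NA_real_ else o
    }, numeric(1))
    mean(oms, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(mean_omega) > 0))
})

test_that("genotype truth frequencies sum to one and match the tallies", {
  loc <- small_locus()
  pool <- generate_allele_pool(loc, 20, theta = 8, seed = 4)
  cfg <- sim_config(n_populations = 3, individuals_per_population = 8,
                    coastline_positions = c(0, 300, 700), seed = 4)
  g <- assign_genotypes(pool, cfg, seed = 4)
  freqs <- attr(g, "frequencies")
  for (bc in unique(g$barcode)) {
    f <- freqs[freqs$barcode == bc, ]
    expect_equal(sum(f$freq), 1, tolerance = 1e-12)
    tallies <- table(g$allele_id[g$barcode == bc])
    expect_equal(sort(f$freq),
                 sort(as.numeric(tallies) / sum(tallies)),
                 tolerance = 1e-12)
  }
  # diploid single-copy locus: at most 2 distinct alleles per individual
  per_ind <- tapply(g$allele_id, paste(g$barcode, g$individual),
                    function(x) length(unique(x)))
  expect_true(all(per_ind <= 2))
})

test_that("panmictic partition deals every lineage out once", {
  loc <- small_locus()
  cfg <- sim_config(n_populations = 2, individuals_per_population = 5,
                    coastline_positions = c(0, 100), migration_rate = 0.5,
                    assignment = "partition", seed = 6)
  pool <- generate_allele_pool(loc, 20, theta = 5, seed = 6)  # 20 = slots
  g <- assign_genotypes(pool, cfg, seed = 6)
  expect_equal(sort(g$allele_id), sort(names(pool$sequences)))
  # partition refuses structured settings
  cfg_low <- sim_config(n_populations = 2, individuals_per_population = 5,
                        coastline_positions = c(0, 100),
                        migration_rate = 0.01, assignment = "partition")
  expect_error(assign_genotypes(pool, cfg_low, seed = 1), "panmixia")
})

test_that("noiseless reads reproduce their source alleles exactly", {
  loc <- small_locus()
  pool <- generate_allele_pool(loc, 15, theta = 6, seed = 8)
  cfg <- sim_config(n_populations = 2, individuals_per_population = 4,
                    coastline_positions = c(0, 200),
                    depth_per_individual = 6,
                    substitution_error_rate = 0, homopolymer_indel_rate = 0,
                    chimera_rate = 0, degraded_read_rate = 0, seed = 8)
  g <- assign_genotypes(pool, cfg, seed = 8)
  sim <- simulate_reads(g, pool, cfg, seed = 8)
  src <- attr(g, "alleles")[sim$provenance$source_allele]
  expect_identical(sim$reads$bases, unname(src))
  expect_equal(sum(sim$provenance$n_subst_errors), 0)
  # fixed depth split evenly over slots makes read tallies match truth
  freqs <- attr(g, "frequencies")
  for (bc in unique(sim$reads$barcode)) {
    pr <- sim$provenance[sim$provenance$barcode == bc, ]
    tt <- table(pr$source_allele)
    f <- freqs[freqs$barcode == bc, ]
    expect_equal(sort(as.numeric(tt) / sum(tt)), sort(f$freq),
                 tolerance = 1e-12)
  }
})

test_that("forced chimerism produces recombinants matching neither parent", {
  loc <- locus_spec("toy", paste(rep(c("AAA", "CCC"), 15), collapse = ""))
  # two handcrafted parents differing at both ends
  p1 <- loc$reference_sequence
  p2 <- paste0("GGG", substr(p1, 4, nchar(p1) - 3), "TTT")
  pool <- generate_allele_pool(loc, 2, theta = 0, seed = 9)
  pool$sequences <- stats::setNames(c(p1, p2), names(pool$sequences))
  pool$n_distinct <- 2L
  cfg <- sim_config(n_populations = 1, individuals_per_population = 2,
                    coastline_positions = 0, depth_per_individual = 10,
                    chimera_rate = 1, substitution_error_rate = 0,
                    homopolymer_indel_rate = 0, degraded_read_rate = 0,
                    migration_rate = 0.5, seed = 9)
  g <- assign_genotypes(pool, cfg, seed = 9)
  # force heterozygous genotypes so both parents are present
  g$allele_id <- rep(names(pool$sequences), length.out = nrow(g))
  attr(g, "frequencies") <- data.frame(
    barcode = "BC1", locus = "toy", allele_id = names(pool$sequences),
    freq = c(0.5, 0.5), stringsAsFactors = FALSE)
  sim <- simulate_reads(g, pool, cfg, seed = 9)
  cross <- !is.na(sim$provenance$chimera_parent) &
    sim$provenance$chimera_parent != sim$provenance$source_allele
  expect_true(all(!is.na(sim$provenance$chimera_parent)))
  # crossed chimeras equal neither parent
  expect_true(any(cross))
  expect_true(all(!(sim$reads$bases[cross] %in% c(p1, p2))))
})

test_that("substitution errors occur at the configured binomial rate", {
  loc <- small_locus()   # 90 bp
  pool <- generate_allele_pool(loc, 5, theta = 3, seed = 10)
  cfg <- sim_config(n_populations = 1, individuals_per_population = 30,
                    coastline_positions = 0, depth_per_individual = 20,
                    substitution_error_rate = 0.01,
                    homopolymer_indel_rate = 0, chimera_rate = 0,
                    degraded_read_rate = 0, migration_rate = 0.5, seed = 10)
  g <- assign_genotypes(pool, cfg, seed = 10)
  sim <- simulate_reads(g, pool, cfg, seed = 10)
  n_reads <- nrow(sim$provenance)
  expect_equal(n_reads, 600)
  mean_err <- mean(sim$provenance$n_subst_errors)
  # expectation 0.9 errors per 90-bp read; binomial SE ~ 0.04
  expect_lt(abs(mean_err - 0.9), 0.12)
})

test_that("identical config and seed give byte-identical FASTQ output", {
  cfg <- sim_config(n_populations = 2, individuals_per_population = 4,
                    coastline_positions = c(0, 600),
                    depth_per_individual = 5, seed = 33)
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  write_simulation(simulate_dataset(cfg), d1)
  write_simulation(simulate_dataset(cfg), d2)
  for (f in list.files(d1, pattern = "fastq$")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # manifest and truth tables also reproduce
  expect_identical(readLines(file.path(d1, "truth_genotypes.tsv")),
                   readLines(file.path(d2, "truth_genotypes.tsv")))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("quality strings reflect the realized error structure", {
  loc <- small_locus()
  pool <- generate_allele_pool(loc, 4, theta = 2, seed = 12)
  cfg <- sim_config(n_populations = 1, individuals_per_population = 10,
                    coastline_positions = 0, depth_per_individual = 10,
                    substitution_error_rate = 0.02,
                    homopolymer_indel_rate = 0, chimera_rate = 0,
                    degraded_read_rate = 0, migration_rate = 0.5, seed = 12)
  g <- assign_genotypes(pool, cfg, seed = 12)
  sim <- simulate_reads(g, pool, cfg, seed = 12)
  # every substituted base carries a low quality score
  pr <- sim$provenance[sim$provenance$n_subst_errors > 0, ]
  expect_gt(nrow(pr), 0)
  for (i in seq_len(min(nrow(pr), 20))) {
    pos <- as.integer(strsplit(pr$error_positions[i], ",")[[1]])
    q <- phred_scores(sim$reads$quality[sim$reads$id == pr$read_id[i]])[[1]]
    expect_true(all(q[pos] < 20))
  }
})
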