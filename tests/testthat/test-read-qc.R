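# small helpers to build read tables in code
mk_reads <- function(bases, barcode = "b1", phred = 40L) {
  data.frame(
    id = sprintf("%s_r%03d", barcode, seq_along(bases)),
    barcode = barcode,
    bases = bases,
    quality = vapply(nchar(bases), function(n) phred_encode(rep(phred, n)), ""),
    stringsAsFactors = FALSE)
}

toy_refs <- function() {
  set.seed(2023)
  c(L1 = random_coding_seq(80),   # 240 bp
    L2 = random_coding_seq(84))   # 252 bp
}

test_that("length filter removes strictly-under-threshold reads", {
  lens <- seq(150, 330, by = 20)
  reads <- mk_reads(vapply(lens, function(n) strrep("A", n), ""))
  kept <- filter_length(reads, 180L)
  expect_equal(nrow(kept), 8)          # lengths 190..330 and none at 150/170
  expect_equal(nrow(filter_length(mk_reads(strrep("A", 179)))), 0)
  expect_equal(nrow(filter_length(mk_reads(strrep("A", 180)))), 1)
})

test_that("locus assignment uses free-end-gap identity with a 70% floor", {
  refs <- toy_refs()
  # identical to L2: assigned with identity 1
  al <- assign_locus(refs[["L2"]], refs)
  expect_equal(al$locus, "L2")
  expect_equal(al$identity, 1.0)
  # random 261-bp read: identity far below 0.70, unassigned
  set.seed(1)
  rnd <- paste(sample(c("A", "C", "G", "T"), 261, replace = TRUE),
               collapse = "")
  al <- assign_locus(rnd, refs)
  expect_true(is.na(al$locus))
  expect_lt(al$identity, 0.7)
  # 25% of positions substituted: identity ~0.75, assigned
  set.seed(2)
  chars <- strsplit(refs[["L1"]], "")[[1]]
  pos <- sample(length(chars), length(chars) %/% 4)
  for (p in pos) chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  mut <- paste(chars, collapse = "")
  al <- assign_locus(mut, refs)
  expect_equal(al$locus, "L1")
  expect_gte(al$identity, 0.70)
  expect_lt(al$identity, 0.85)
  expect_error(assign_locus("", refs), "empty")
})

test_that("alignment score agrees with an exhaustive free-end-gap DP oracle", {
  set.seed(7)
  params <- qc_params()
  for (rep in 1:12) {
    a <- paste(sample(c("A", "C", "G", "T"), sample(20:40, 1), replace = TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(20:40, 1), replace = TRUE),
               collapse = "")
    al <- poolMHC:::align_to_reference(a, b, params)
    expect_equal(al$score, oracle_overlap_score(a, b), tolerance = 1e-9)
  }
})

test_that("reverse-complement reads are detected and normalized", {
  refs <- toy_refs()
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(refs[["L1"]])))
  al <- assign_locus(rc, refs)
  expect_equal(al$locus, "L1")
  expect_equal(al$identity, 1.0)
  expect_true(al$reverse_complemented)
  expect_identical(al$bases, refs[["L1"]])
})

test_that("dereplication counts by exact sequence and orders deterministically", {
  reads <- rbind(
    mk_reads(rep("AAACCC", 6), barcode = "b1"),
    mk_reads(rep("GGGTTT", 3), barcode = "b1"),
    mk_reads("CCCAAA", barcode = "b1"))
  reads$locus <- "L1"
  v <- dereplicate(reads)
  expect_equal(v$total_count, c(6L, 3L, 1L))
  expect_equal(v$sequence, c("AAACCC", "GGGTTT", "CCCAAA"))
  # quality strings do not split variants
  reads2 <- mk_reads(rep("AAACCC", 2), phred = 40L)
  reads2$quality[2] <- phred_encode(rep(10L, 6))
  reads2$locus <- "L1"
  expect_equal(nrow(dereplicate(reads2)), 1)
  # ties broken lexicographically by sequence
  tie <- mk_reads(c("TTTT", "AAAA"))
  tie$locus <- "L1"
  expect_equal(dereplicate(tie)$sequence, c("AAAA", "TTTT"))
})

test_that("singleton removal is scoped per barcode", {
  reads <- rbind(
    mk_reads("AAAA", barcode = "b1"),                  # singleton everywhere
    mk_reads(c("CCCC", rep("GGGG", 2)), barcode = "b1"),
    mk_reads(rep("CCCC", 5), barcode = "b2"))
  reads$locus <- "L1"
  v <- dereplicate(reads)
  out <- drop_singletons(v)
  # AAAA: counts {b1:1} -> removed everywhere
  expect_false("AAAA" %in% out$sequence)
  # CCCC: counts {b1:1, b2:5} -> removed from b1, kept in b2
  cc <- out[out$sequence == "CCCC", ]
  expect_equal(cc$b1, 0L)
  expect_equal(cc$b2, 5L)
  expect_equal(cc$total_count, 5L)
  # GGGG: count 2 in b1 survives
  expect_true("GGGG" %in% out$sequence)
  # derived fixture: counts {3,2,1,1,2} in one barcode -> 3 survive
  seqs <- c("AAAA", "CCCC", "GGGG", "TTTT", "ACGT")
  reads <- mk_reads(rep(seqs, c(3, 2, 1, 1, 2)), barcode = "b9")
  reads$locus <- "L1"
  expect_equal(nrow(drop_singletons(dereplicate(reads))), 3)
  # global scope keeps cross-barcode singletons
  v2 <- dereplicate(rbind(
    within(mk_reads("AAAA", barcode = "b1"), locus <- "L1"),
    within(mk_reads("AAAA", barcode = "b2"), locus <- "L1")))
  expect_equal(nrow(drop_singletons(v2, scope = "global")), 1)
  expect_equal(nrow(drop_singletons(v2, scope = "barcode")), 0)
})

test_that("quality filter keeps reads at or above the 80% HQ boundary", {
  # all Phred 40: retained
  expect_equal(nrow(filter_quality(mk_reads(strrep("A", 100)))), 1)
  # 261 bp with 60 bases at Phred 10: fraction 201/261 = 0.770 < 0.80
  q <- c(rep(10L, 60), rep(40L, 201))
  r <- mk_reads(strrep("A", 261))
  r$quality <- phred_encode(q)
  expect_equal(nrow(filter_quality(r)), 0)
  # exactly 208 of 260 HQ = 0.80: retained
  r <- mk_reads(strrep("A", 260))
  r$quality <- phred_encode(c(rep(40L, 208), rep(10L, 52)))
  expect_equal(nrow(filter_quality(r)), 1)
  # missing qualities pass with a warning
  r$quality <- NA_character_
  expect_warning(out <- filter_quality(r), "without qualities")
  expect_equal(nrow(out), 1)
})

test_that("frameshift filter removes net indels not divisible by three", {
  refs <- toy_refs()
  ref <- refs[["L1"]]
  del1 <- paste0(substr(ref, 1, 99), substr(ref, 101, nchar(ref)))
  del3 <- paste0(substr(ref, 1, 99), substr(ref, 103, nchar(ref)))
  ins2 <- paste0(substr(ref, 1, 99), "TT", substr(ref, 100, nchar(ref)))
  reads <- mk_reads(c(rep(ref, 2), rep(del1, 2), rep(del3, 2), rep(ins2, 2)))
  reads$locus <- "L1"
  v <- dereplicate(reads)
  out <- filter_frameshift(v, refs)
  expect_true(ref %in% out$sequence)      # zero indels retained
  expect_true(del3 %in% out$sequence)     # in-frame deletion retained
  expect_false(del1 %in% out$sequence)    # 1-bp deletion removed
  expect_false(ins2 %in% out$sequence)    # 2-bp insertion removed too
})

test_that("filters are idempotent and order-invariant over reads", {
  set.seed(21)
  refs <- toy_refs()
  cfg <- sim_config(n_populations = 2, individuals_per_population = 4,
                    coastline_positions = c(0, 500),
                    depth_per_individual = 6, seed = 21)
  sim <- simulate_dataset(cfg)
  reads <- sim$reads
  # idempotence of read-level filters
  once <- filter_length(reads)
  expect_identical(filter_length(once), once)
  q1 <- filter_quality(reads)
  expect_identical(filter_quality(q1), q1)
  # idempotence of variant-level filters
  reads$locus <- "L"
  v <- dereplicate(reads)
  s1 <- drop_singletons(v)
  expect_identical(drop_singletons(s1)$sequence, s1$sequence)
  # permutation invariance of the retained variant set
  refs2 <- vapply(sim$loci, `[[`, "", "reference_sequence")
  manifest <- simulated_manifest(cfg)
  qc1 <- suppressWarnings(run_qc_pipeline(sim$reads, refs2, manifest))
  shuffled <- sim$reads[sample(nrow(sim$reads)), ]
  qc2 <- suppressWarnings(run_qc_pipeline(shuffled, refs2, manifest))
  expect_identical(qc1$variants$sequence, qc2$variants$sequence)
  expect_identical(qc1$variants$total_count, qc2$variants$total_count)
})

test_that("noiseless simulated reads recover the exact true allele sets", {
  cfg <- sim_config(n_populations = 3, individuals_per_population = 6,
                    coastline_positions = c(0, 400, 900),
                    depth_per_individual = 8,
                    substitution_error_rate = 0, homopolymer_indel_rate = 0,
                    chimera_rate = 0, degraded_read_rate = 0, seed = 5)
  sim <- simulate_dataset(cfg)
  refs <- vapply(sim$loci, `[[`, "", "reference_sequence")
  qc <- run_qc_pipeline(sim$reads, refs, simulated_manifest(cfg))
  for (bc in unique(sim$reads$barcode)) {
    for (locus in names(sim$loci)) {
      truth <- sort(true_allele_set(sim, bc, locus))
      v <- qc$variants[qc$variants$locus == locus, ]
      got <- sort(v$sequence[v[[bc]] > 0])
      # depth/slot >= 2 guarantees no true allele is lost as a singleton
      expect_identical(got, truth)
    }
  }
  # filter report: no losses after the input stage
  rep <- qc$report
  input <- rep$n_reads[rep$stage == "input"]
  final <- rep$n_reads[rep$stage == "frameshift"]
  expect_identical(final, input)
})

test_that("monotone attrition holds per barcode through the cascade", {
  cfg <- sim_config(n_populations = 2, individuals_per_population = 6,
                    coastline_positions = c(0, 800),
                    depth_per_individual = 10, seed = 99,
                    degraded_read_rate = 0.1)
  sim <- simulate_dataset(cfg)
  refs <- vapply(sim$loci, `[[`, "", "reference_sequence")
  qc <- suppressWarnings(run_qc_pipeline(sim$reads, refs,
                                         simulated_manifest(cfg)))
  stages <- unique(qc$report$stage)
  for (bc in unique(qc$report$barcode)) {
    counts <- vapply(stages, function(s) {
      n <- qc$report$n_reads[qc$report$stage == s & qc$report$barcode == bc]
      if (length(n) == 0) 0L else n
    }, integer(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("unknown barcodes in the read set are a hard error", {
  cfg <- sim_config(n_populations = 2, individuals_per_population = 3,
                    coastline_positions = c(0, 100),
                    depth_per_individual = 4, seed = 1)
  sim <- simulate_dataset(cfg)
  refs <- vapply(sim$loci, `[[`, "", "reference_sequence")
  manifest <- simulated_manifest(cfg)
  manifest <- manifest[manifest$barcode != "BC2", ]
  expect_error(run_qc_pipeline(sim$reads, refs, manifest),
               "absent from manifest")
})
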