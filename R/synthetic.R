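#' Locus specification for the simulator
#'
#' @param name Locus label, e.g. `"MHC1ex3"` or `"MHC2ex2"`.
#' @param reference_sequence In-frame nucleotide reference (A/C/G/T, length
#'   a multiple of 3, no stop codons).
#' @param copies_per_individual Number of gene copies per diploid genome
#'   (>= 1): multi-copy for MHC class I, single-copy for class II.
#' @return An object of class `locus_spec`.
#' @export
locus_spec <- function(name, reference_sequence, copies_per_individual = 1L) {
  reference_sequence <- toupper(reference_sequence)
  L <- nchar(reference_sequence)
  if (L %% 3 != 0) stop("amplicon length must be a multiple of 3")
  if (grepl("[^ACGT]", reference_sequence))
    stop("reference must contain only A/C/G/T")
  if (copies_per_individual < 1) stop("copies_per_individual must be >= 1")
  structure(list(name = name, amplicon_length = L,
                 copies_per_individual = as.integer(copies_per_individual),
                 reference_sequence = reference_sequence),
            class = "locus_spec")
}

#' Default locus pair emulating the two MHC amplicons
#'
#' A 261-bp class I exon 3 amplicon carried at two locus copies per
#' individual and a 270-bp class II exon 2 amplicon at one copy, with
#' synthetic reference sequences shipped with the package (real exon
#' references can be dropped in via [locus_spec()]).
#'
#' @return Named list of two [locus_spec()] objects.
#' @export
default_loci <- function() {
  fa <- read_fasta(system.file("extdata", "references_synthetic.fasta",
                               package = "poolMHC", mustWork = TRUE))
  list(
    MHC1ex3 = locus_spec("MHC1ex3", fa[["MHC1ex3_synthetic"]],
                         copies_per_individual = 2L),
    MHC2ex2 = locus_spec("MHC2ex2", fa[["MHC2ex2_synthetic"]],
                         copies_per_individual = 1L)
  )
}

#' Simulation configuration
#'
#' Defaults emulate the pooled-colony study design this package targets:
#' seven barcodes of 25 pooled individuals along a ~5000-km coastline, with
#' 454-style error rates.
#'
#' @param n_populations Number of colonies/barcodes.
#' @param individuals_per_population Pooled individuals per barcode.
#' @param coastline_positions Strictly increasing positions (km) along a 1-D
#'   habitat, one per population.
#' @param migration_rate Per-generation fraction exchanged with adjacent
#'   demes in the stepping-stone model (0-1; >= 0.5 is treated as panmixia).
#' @param theta Scaled mutation parameter of the allele-pool coalescent
#'   (expected pairwise differences between pool lineages).
#' @param dnds_target Target dN/dS ratio biasing allele-pool mutations.
#' @param depth_per_individual Reads per individual per locus.
#' @param substitution_error_rate Per-base substitution error probability.
#' @param homopolymer_indel_rate Per-homopolymer-run probability of gaining
#'   or losing one base (runs of length >= 2).
#' @param chimera_rate Per-read probability of a two-parent chimera.
#' @param degraded_read_rate Fraction of reads with pervasive low-confidence
#'   bases (exercises the 80%-quality filter).
#' @param n_generations Wright-Fisher generations for the stepping-stone
#'   frequency model.
#' @param assignment `"auto"`, `"partition"` (pool lineages dealt out
#'   without replacement; exact coalescent sample, panmixia only) or
#'   `"frequency"` (stepping-stone drift model).
#' @param poisson_depth Draw per-individual depth as Poisson instead of
#'   fixed (default fixed, which keeps truth frequencies exact).
#' @param seed Integer RNG seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_populations = 7L,
                       individuals_per_population = 25L,
                       coastline_positions = c(0, 1287, 1678, 2012, 3074,
                                               4325, 4980),
                       migration_rate = 0.05,
                       theta = 8,
                       dnds_target = 1,
                       depth_per_individual = 20L,
                       substitution_error_rate = 5e-4,
                       homopolymer_indel_rate = 0.02,
                       chimera_rate = 0.02,
                       degraded_read_rate = 0.02,
                       n_generations = 50L,
                       assignment = c("auto", "partition", "frequency"),
                       poisson_depth = FALSE,
                       seed = 1L) {
  assignment <- match.arg(assignment)
  rates <- c(migration_rate, substitution_error_rate, homopolymer_indel_rate,
             chimera_rate, degraded_read_rate)
  if (any(rates < 0 | rates > 1)) stop("all rates must be in [0, 1]")
  if (depth_per_individual < 1) stop("depth must be >= 1")
  if (length(coastline_positions) != n_populations)
    stop("need one coastline position per population")
  if (any(diff(coastline_positions) <= 0))
    stop("coastline positions must be strictly increasing")
  if (theta < 0) stop("theta must be >= 0")
  if (dnds_target < 0) stop("dnds_target must be >= 0")
  structure(list(
    n_populations = as.integer(n_populations),
    individuals_per_population = as.integer(individuals_per_population),
    coastline_positions = coastline_positions,
    migration_rate = migration_rate, theta = theta,
    dnds_target = dnds_target,
    depth_per_individual = as.integer(depth_per_individual),
    substitution_error_rate = substitution_error_rate,
    homopolymer_indel_rate = homopolymer_indel_rate,
    chimera_rate = chimera_rate, degraded_read_rate = degraded_read_rate,
    n_generations = as.integer(n_generations), assignment = assignment,
    poisson_depth = poisson_depth, seed = as.integer(seed)
  ), class = "sim_config")
}

# Codon-aware single substitution biased toward the target dN/dS.
# Proposals uniform over position x alternative base; stop-creating
# proposals rejected and resampled; nonsynonymous proposals accepted with
# probability min(1, omega), synonymous with min(1, 1/omega).
mutate_codon_aware <- function(chars, omega, max_tries = 10000L) {
  L <- length(chars)
  for (try in seq_len(max_tries)) {
    pos <- sample.int(L, 1L)
    nb <- sample(setdiff(ng_bases, chars[pos]), 1L)
    ci <- (pos - 1L) %/% 3L
    idx <- ci * 3L + 1:3
    cod <- chars[idx]
    new_cod <- cod
    new_cod[pos - ci * 3L] <- nb
    aa_old <- codon_aa(paste(cod, collapse = ""))
    aa_new <- codon_aa(paste(new_cod, collapse = ""))
    if (aa_new == "*") next
    syn <- aa_new == aa_old
    accept_p <- if (syn) min(1, 1 / max(omega, 1e-12)) else min(1, omega)
    if (stats::runif(1) < accept_p) {
      chars[pos] <- nb
      return(chars)
    }
  }
  stop("could not place a mutation compatible with dnds_target; ",
       "the target may be impossible for this reference (e.g. 0 with no ",
       "synonymous changes available)")
}

# Kingman coalescent tree over n tips: edge list with branch lengths in
# coalescent units, root node id, node count.
kingman_tree <- function(n) {
  if (n == 1L) return(list(edges = data.frame(parent = integer(),
    child = integer(), length = numeric()), root = 1L, n_nodes = 1L))
  active <- seq_len(n)
  heights <- rep(0, n)
  next_id <- n + 1L
  edges <- vector("list", n - 1L)
  t <- 0
  for (k in seq(n, 2L)) {
    t <- t + stats::rexp(1, rate = k * (k - 1) / 2)
    pick <- sample(seq_along(active), 2L)
    c1 <- active[pick[1]]; c2 <- active[pick[2]]
    heights[next_id] <- t
    edges[[n - k + 1L]] <- data.frame(
      parent = c(next_id, next_id), child = c(c1, c2),
      length = c(t - heights[c1], t - heights[c2]))
    active <- c(active[-pick], next_id)
    next_id <- next_id + 1L
  }
  list(edges = do.call(rbind, edges), root = next_id - 1L,
       n_nodes = next_id - 1L)
}

#' Generate an allele pool by coalescent simulation with codon-aware mutation
#'
#' Simulates a Kingman coalescent genealogy over `n_alleles` lineages with
#' the reference sequence at the root; each branch receives
#' `Poisson(theta/2 * length)` substitutions proposed uniformly over sites
#' and accepted with probabilities that bias the realized pool dN/dS toward
#' `dnds_target`. Mutations creating stop codons are rejected and resampled,
#' so all pool sequences stay in frame and stop-free.
#'
#' @param locus A [locus_spec()].
#' @param n_alleles Number of pool lineages (tips) to simulate.
#' @param theta Scaled mutation parameter (expected pairwise differences).
#' @param dnds_target Target dN/dS ratio (>= 0).
#' @param seed Optional RNG seed.
#' @return Object of class `allele_pool`: `sequences` (named character,
#'   one per lineage; duplicates collapse into shared alleles downstream),
#'   `genealogy` (edge list), `locus`, plus the generating parameters.
#' @export
generate_allele_pool <- function(locus, n_alleles, theta, dnds_target = 1,
                                 seed = NULL) {
  stopifnot(inherits(locus, "locus_spec"), n_alleles >= 1)
  if (!is.null(seed)) set.seed(seed)
  ref_chars <- strsplit(locus$reference_sequence, "")[[1]]
  if (dnds_target == 0 && theta > 0) {
    total_syn <- sum(vapply(seq_len(locus$amplicon_length / 3), function(ci) {
      codon_syn_sites_memo(paste(ref_chars[(ci - 1) * 3 + 1:3], collapse = ""))
    }, numeric(1)))
    if (total_syn == 0)
      stop("dnds_target = 0 impossible: reference has no synonymous sites")
  }
  tree <- kingman_tree(n_alleles)
  node_seq <- vector("list", tree$n_nodes)
  node_seq[[tree$root]] <- ref_chars
  if (nrow(tree$edges) > 0) {
    # process edges parent-first (edges were created child-before-parent)
    ord <- order(tree$edges$parent, decreasing = TRUE)
    for (e in ord) {
      p <- tree$edges$parent[e]; ch <- tree$edges$child[e]
      s <- node_seq[[p]]
      n_mut <- stats::rpois(1, theta / 2 * tree$edges$length[e])
      if (theta > 0) {
        for (m in seq_len(n_mut)) s <- mutate_codon_aware(s, dnds_target)
      }
      node_seq[[ch]] <- s
    }
  }
  sequences <- vapply(seq_len(n_alleles), function(i)
    paste(node_seq[[i]], collapse = ""), character(1))
  names(sequences) <- sprintf("%s_A%03d", locus$name, seq_len(n_alleles))
  structure(list(sequences = sequences, genealogy = tree$edges,
                 locus = locus, theta = theta, dnds_target = dnds_target,
                 n_distinct = length(unique(sequences))),
            class = "allele_pool")
}

#' @export
print.allele_pool <- function(x, ...) {
  cat("allele_pool:", x$locus$name, "-", length(x$sequences), "lineages,",
      x$n_distinct, "distinct sequences, theta =", x$theta,
      ", dN/dS target =", x$dnds_target, "\n")
  invisible(x)
}

#' Realized dN/dS of an allele pool
#'
#' Nei-Gojobori Ka/Ks over the pool's distinct sequences — the independent
#' check of the simulator's dN/dS dial.
#'
#' @param pool An [generate_allele_pool()] result.
#' @return List as returned by [ka_ks()].
#' @export
pool_kaks <- function(pool) {
  seqs <- unique(pool$sequences)
  if (length(seqs) < 2) return(list(Ka = 0, Ks = 0, omega = NA_real_,
                                    omega_defined = FALSE))
  panel <- barcode_panel(seqs, rep(1L, length(seqs)), barcode = "pool",
                         locus = pool$locus$name)
  ka_ks(panel)
}

barcode_labels <- function(config) sprintf("BC%d", seq_len(config$n_populations))

#' Assign pooled-individual genotypes under a 1-D stepping-stone model
#'
#' Each individual carries `2 * copies_per_individual` allele slots per
#' locus. Two regimes: `"partition"` (panmixia; the pool's coalescent
#' lineages are dealt out without replacement, so every barcode is an exact
#' coalescent subsample — requires the pool to have at least as many
#' lineages as there are slots) and `"frequency"` (per-deme allele counts
#' evolve by Wright-Fisher drift with nearest-neighbour migration for
#' `n_generations`, with recurrent codon-aware mutation at the per-copy
#' rate implied by `theta` so the metapopulation sits at mutation-drift
#' balance instead of drifting to fixation; the final-generation counts
#' are dealt to individuals, so truth frequencies are exact).
#' Allele-frequency divergence grows with coastline distance when
#' migration is weak. `"auto"` picks partition when
#' `migration_rate >= 0.5` and the pool is large enough.
#'
#' @param pool An [generate_allele_pool()] result.
#' @param config A [sim_config()].
#' @param seed Optional RNG seed (defaults to the config seed stream if
#'   already set by the caller; pass explicitly for standalone use).
#' @return Data frame (`population`, `barcode`, `individual`, `slot`,
#'   `allele_id`) with attribute `frequencies` (true per-barcode allele
#'   frequencies; sums to 1 per barcode).
#' @export
assign_genotypes <- function(pool, config, seed = NULL) {
  stopifnot(inherits(pool, "allele_pool"), inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  P <- config$n_populations
  I <- config$individuals_per_population
  slots_per_ind <- 2L * pool$locus$copies_per_individual
  slots_per_pop <- I * slots_per_ind
  total_slots <- P * slots_per_pop
  n_lineages <- length(pool$sequences)
  mode <- config$assignment
  if (mode == "auto") {
    mode <- if (config$migration_rate >= 0.5 && n_lineages >= total_slots)
      "partition" else "frequency"
  }
  allele_ids <- names(pool$sequences)
  if (mode == "partition") {
    if (n_lineages < total_slots)
      stop("partition assignment needs >= ", total_slots, " pool lineages")
    if (config$migration_rate < 0.5)
      stop("partition assignment models panmixia (migration_rate >= 0.5)")
    dealt <- sample(allele_ids, total_slots)
    assignment <- dealt
  } else {
    # collapse lineages to distinct alleles; initial frequency = lineage
    # multiplicity (the neutral sample frequency spectrum)
    tab <- table(pool$sequences)
    seqs <- names(tab)
    ids <- allele_ids[match(seqs, pool$sequences)]
    freq0 <- as.numeric(tab) / n_lineages
    counts <- vapply(seq_len(P), function(p)
      stats::rmultinom(1, slots_per_pop, freq0)[, 1], integer(length(freq0)))
    counts <- t(matrix(counts, ncol = P))     # demes x alleles
    m <- config$migration_rate
    # per-copy mutation probability at mutation-drift balance with the
    # pool's theta: theta = 2 * N_total * mu over the metapopulation
    mu <- config$theta / (2 * P * slots_per_pop)
    n_new <- 0L
    for (g in seq_len(config$n_generations)) {
      freqs <- counts / slots_per_pop
      if (P > 1 && m > 0) {
        mixed <- freqs
        for (p in seq_len(P)) {
          nb <- c(if (p > 1) p - 1L, if (p < P) p + 1L)
          mixed[p, ] <- (1 - m) * freqs[p, ] +
            m * colMeans(freqs[nb, , drop = FALSE])
        }
        freqs <- mixed
      }
      for (p in seq_len(P)) {
        counts[p, ] <- stats::rmultinom(1, slots_per_pop, freqs[p, ])[, 1]
      }
      if (mu > 0) {
        for (p in seq_len(P)) {
          n_mut <- stats::rbinom(1, slots_per_pop, mu)
          for (mm in seq_len(n_mut)) {
            j <- sample.int(ncol(counts), 1, prob = counts[p, ])
            new_seq <- paste(mutate_codon_aware(
              strsplit(seqs[j], "")[[1]], config$dnds_target), collapse = "")
            hit <- match(new_seq, seqs)
            if (is.na(hit)) {
              n_new <- n_new + 1L
              seqs <- c(seqs, new_seq)
              ids <- c(ids, sprintf("%s_M%04d", pool$locus$name, n_new))
              counts <- cbind(counts, 0L)
              hit <- length(seqs)
            }
            counts[p, j] <- counts[p, j] - 1L
            counts[p, hit] <- counts[p, hit] + 1L
          }
        }
      }
    }
    assignment <- unlist(lapply(seq_len(P), function(p) {
      sample(rep(ids, counts[p, ]))
    }))
  }
  allele_map <- if (mode == "partition") pool$sequences
                else stats::setNames(seqs, ids)
  bl <- barcode_labels(config)
  geno <- data.frame(
    population = rep(seq_len(P), each = slots_per_pop),
    barcode = rep(bl, each = slots_per_pop),
    individual = rep(rep(seq_len(I), each = slots_per_ind), times = P),
    slot = rep(seq_len(slots_per_ind), times = P * I),
    allele_id = assignment,
    locus = pool$locus$name,
    stringsAsFactors = FALSE
  )
  attr(geno, "alleles") <- allele_map
  tallies <- do.call(rbind, lapply(split(geno, geno$barcode), function(g) {
    tt <- table(g$allele_id)
    data.frame(barcode = g$barcode[1], locus = pool$locus$name,
               allele_id = names(tt),
               freq = as.numeric(tt) / sum(tt), stringsAsFactors = FALSE)
  }))
  rownames(tallies) <- NULL
  attr(geno, "frequencies") <- tallies
  geno
}

# One homopolymer-indel + substitution error channel pass over a sequence,
# returning the mutated characters, a parallel per-base quality vector and
# error bookkeeping.
apply_454_errors <- function(chars, config, degraded) {
  q_normal <- if (config$substitution_error_rate > 0)
    min(40L, as.integer(round(-10 * log10(config$substitution_error_rate))))
  else 40L
  q_low <- 10L
  qual <- rep(q_normal, length(chars))
  n_homo <- 0L
  if (config$homopolymer_indel_rate > 0) {
    r <- rle(chars)
    runs <- which(r$lengths >= 2L)
    hit <- runs[stats::runif(length(runs)) < config$homopolymer_indel_rate]
    if (length(hit)) {
      ends <- cumsum(r$lengths)
      # process right-to-left so positions stay valid
      for (ri in rev(hit)) {
        pos <- ends[ri]
        if (stats::runif(1) < 0.5) {            # gain one base
          chars <- append(chars, chars[pos], after = pos)
          qual <- append(qual, q_low, after = pos)
        } else {                                 # lose one base
          chars <- chars[-pos]
          qual <- qual[-pos]
        }
        n_homo <- n_homo + 1L
      }
    }
  }
  L <- length(chars)
  sub_pos <- integer()
  if (degraded) {
    lowmask <- which(stats::runif(L) < 0.30)
    qual[lowmask] <- q_low
    flip <- lowmask[stats::runif(length(lowmask)) < 0.25]
    sub_pos <- flip
  }
  if (config$substitution_error_rate > 0) {
    sub_pos <- union(sub_pos,
                     which(stats::runif(L) < config$substitution_error_rate))
  }
  for (pos in sub_pos) {
    chars[pos] <- sample(setdiff(ng_bases, chars[pos]), 1L)
    qual[pos] <- q_low
  }
  list(chars = chars, qual = qual, n_subst = length(sub_pos),
       n_homopolymer = n_homo, error_positions = sort(sub_pos))
}

#' Simulate 454-style barcoded reads from assigned genotypes
#'
#' Emits `depth_per_individual` reads per individual for one locus. Depth is
#' split as evenly as possible across an individual's allele slots (exact
#' truth frequencies when depth is divisible by the slot count). Each read
#' may become a chimera of its source allele and a second barcode-local
#' parent (uniform breakpoint), then passes through the error channel:
#' per-homopolymer-run single-base gains/losses, i.i.d. substitution
#' errors, and (for a `degraded_read_rate` fraction of reads) pervasive
#' low-confidence bases. Phred qualities encode the per-base confidence
#' after errors: untouched bases carry `round(-10*log10(substitution rate))`
#' and error/low-confidence bases carry Q10.
#'
#' @param genotypes Genotype table from [assign_genotypes()] (one locus).
#' @param pool The matching [generate_allele_pool()] result.
#' @param config A [sim_config()].
#' @param seed Optional RNG seed.
#' @return List with `reads` (read table as in [read_fastq()], plus the true
#'   `locus`) and `provenance` (per-read truth: source allele, chimera
#'   parent and breakpoint, error counts and positions).
#' @export
simulate_reads <- function(genotypes, pool, config, seed = NULL) {
  stopifnot(inherits(pool, "allele_pool"), inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  if (pool$locus$amplicon_length == 0) stop("zero-length amplicon")
  seqs <- attr(genotypes, "alleles") %||% pool$sequences
  freqs <- attr(genotypes, "frequencies")
  locus <- pool$locus$name
  per_ind <- split(genotypes,
                   paste(genotypes$barcode, genotypes$individual, sep = "|"))
  reads <- vector("list", length(per_ind))
  prov <- vector("list", length(per_ind))
  counter <- 0L
  for (gi in seq_along(per_ind)) {
    g <- per_ind[[gi]]
    bc <- g$barcode[1]
    depth <- if (config$poisson_depth)
      stats::rpois(1, config$depth_per_individual)
    else config$depth_per_individual
    if (depth == 0L) next
    slots <- g$allele_id
    ns <- length(slots)
    base_n <- depth %/% ns
    extra <- depth %% ns
    slot_reads <- c(rep(slots, base_n),
                    if (extra > 0) sample(slots, extra) else character())
    bc_freq <- freqs[freqs$barcode == bc, ]
    r_rows <- vector("list", length(slot_reads))
    p_rows <- vector("list", length(slot_reads))
    for (ri in seq_along(slot_reads)) {
      counter <- counter + 1L
      src <- slot_reads[ri]
      s <- seqs[[src]]
      chim_parent <- NA_character_; breakpoint <- NA_integer_
      if (stats::runif(1) < config$chimera_rate) {
        chim_parent <- sample(bc_freq$allele_id, 1L, prob = bc_freq$freq)
        L <- nchar(s)
        breakpoint <- sample.int(L - 1L, 1L)
        s <- paste0(substr(s, 1L, breakpoint),
                    substr(seqs[[chim_parent]], breakpoint + 1L, L))
      }
      degraded <- stats::runif(1) < config$degraded_read_rate
      err <- apply_454_errors(strsplit(s, "")[[1]], config, degraded)
      id <- sprintf("%s_%s_r%06d", bc, locus, counter)
      r_rows[[ri]] <- data.frame(
        id = id, barcode = bc, bases = paste(err$chars, collapse = ""),
        quality = phred_encode(err$qual), locus = locus,
        stringsAsFactors = FALSE)
      p_rows[[ri]] <- data.frame(
        read_id = id, barcode = bc, locus = locus, source_allele = src,
        chimera_parent = chim_parent, breakpoint = breakpoint,
        n_subst_errors = err$n_subst,
        n_homopolymer_indels = err$n_homopolymer,
        degraded = degraded,
        error_positions = paste(err$error_positions, collapse = ","),
        stringsAsFactors = FALSE)
    }
    reads[[gi]] <- do.call(rbind, r_rows)
    prov[[gi]] <- do.call(rbind, p_rows)
  }
  list(reads = do.call(rbind, reads), provenance = do.call(rbind, prov))
}

#' Run the full simulator for a set of loci
#'
#' Chains [generate_allele_pool()], [assign_genotypes()] and
#' [simulate_reads()] for every locus under one seed, returning reads plus
#' a complete truth table.
#'
#' @param config A [sim_config()].
#' @param loci Named list of [locus_spec()] (default [default_loci()]).
#' @param n_alleles Named or scalar number of pool lineages per locus
#'   (default: 60 for multi-copy loci, 40 for single-copy).
#' @return Object of class `mhc_simulation`: `reads` (all loci), `truth`
#'   (list with `genotypes`, `frequencies`, `provenance`, `pools`),
#'   `config`, `loci`.
#' @export
simulate_dataset <- function(config = sim_config(), loci = default_loci(),
                             n_alleles = NULL) {
  set.seed(config$seed)
  reads <- list(); genos <- list(); freqs <- list(); prov <- list()
  pools <- list(); alleles <- list()
  for (ln in names(loci)) {
    locus <- loci[[ln]]
    na <- if (is.null(n_alleles)) {
      if (locus$copies_per_individual > 1L) 60L else 40L
    } else if (length(n_alleles) > 1L) n_alleles[[ln]] else n_alleles
    pool <- generate_allele_pool(locus, na, config$theta, config$dnds_target)
    g <- assign_genotypes(pool, config)
    sim <- simulate_reads(g, pool, config)
    pools[[ln]] <- pool
    alleles[[ln]] <- attr(g, "alleles")
    genos[[ln]] <- g
    freqs[[ln]] <- attr(g, "frequencies")
    reads[[ln]] <- sim$reads
    prov[[ln]] <- sim$provenance
  }
  structure(list(
    reads = do.call(rbind, reads),
    truth = list(genotypes = do.call(rbind, genos),
                 frequencies = do.call(rbind, freqs),
                 provenance = do.call(rbind, prov),
                 alleles = alleles,
                 pools = pools),
    config = config, loci = loci
  ), class = "mhc_simulation")
}

#' Simulated colony manifest
#'
#' Synthetic localities placed along the configured coastline (km positions
#' mapped to latitude on a fixed meridian). With seven populations the
#' species split mirrors a 4 + 3 two-species design; otherwise all
#' populations are one species.
#'
#' @param config A [sim_config()].
#' @return Manifest data frame in the standard column layout.
#' @export
simulated_manifest <- function(config) {
  P <- config$n_populations
  species <- if (P == 7L) rep(c("SpeciesA", "SpeciesB"), c(4L, 3L))
             else rep("SpeciesA", P)
  data.frame(
    barcode = barcode_labels(config),
    locality = sprintf("Locality_%d", seq_len(P)),
    latitude = -15 - config$coastline_positions / 111,
    longitude = rep(-72, P),
    country = "synthetic",
    species = species,
    n_individuals = config$individuals_per_population,
    stringsAsFactors = FALSE
  )
}

#' Write a simulation to disk
#'
#' One FASTQ per barcode (both loci pooled, as in a demultiplexed 454 run),
#' plus the manifest, truth tables, reference FASTA and the serialized
#' configuration.
#'
#' @param sim A [simulate_dataset()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "mhc_simulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (bc in unique(sim$reads$barcode)) {
    write_fastq(sim$reads[sim$reads$barcode == bc, ],
                file.path(dir, paste0(bc, ".fastq")))
  }
  write_tsv(simulated_manifest(sim$config), file.path(dir, "manifest.tsv"))
  write_tsv(sim$truth$genotypes, file.path(dir, "truth_genotypes.tsv"))
  write_tsv(sim$truth$frequencies, file.path(dir, "truth_frequencies.tsv"))
  write_tsv(sim$truth$provenance, file.path(dir, "truth_provenance.tsv"))
  refs <- vapply(sim$loci, `[[`, "", "reference_sequence")
  write_fasta(refs, file.path(dir, "references.fasta"))
  cfg <- sim$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' True allele set of a barcode at one locus
#'
#' Distinct sequences present in the barcode's genotype slots — the ground
#' truth the cleaning cascade should recover.
#'
#' @param sim A [simulate_dataset()] result.
#' @param barcode Barcode label.
#' @param locus Locus name.
#' @return Character vector of distinct true allele sequences.
#' @export
true_allele_set <- function(sim, barcode, locus) {
  g <- sim$truth$genotypes
  ids <- unique(g$allele_id[g$barcode == barcode & g$locus == locus])
  amap <- sim$truth$alleles[[locus]] %||% sim$truth$pools[[locus]]$sequences
  unique(unname(amap[ids]))
}
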