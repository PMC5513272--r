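#' Construct a per-barcode panel of retained variants
#'
#' A panel is the unit on which the per-colony summary statistics are
#' computed: the distinct retained sequences ("alleles") observed in one
#' barcode at one locus, together with their read counts. All sequences must
#' be aligned to a common length; amplicons of a fixed-length exon satisfy
#' this directly, and in-frame indel variants must be gap-padded first.
#'
#' @param sequences Character vector of aligned variant sequences (common
#'   length; `-` and `N` allowed and ignored in comparisons).
#' @param counts Integer vector of read counts, one per sequence.
#' @param barcode,locus Labels.
#' @param n_individuals Number of pooled individuals behind the barcode.
#' @return An object of class `barcode_panel`.
#' @export
barcode_panel <- function(sequences, counts, barcode = "bc", locus = "locus",
                          n_individuals = NA_integer_) {
  sequences <- toupper(as.character(sequences))
  counts <- as.integer(counts)
  if (length(sequences) == 0L) stop("empty panel")
  if (length(sequences) != length(counts)) stop("sequences/counts length mismatch")
  if (length(unique(nchar(sequences))) != 1L)
    stop("panel sequences must be aligned to a common length")
  if (anyDuplicated(sequences)) stop("panel sequences must be distinct")
  if (any(counts < 1L)) stop("counts must be >= 1")
  structure(list(sequences = sequences, counts = counts, barcode = barcode,
                 locus = locus, n_individuals = as.integer(n_individuals)),
            class = "barcode_panel")
}

#' @export
print.barcode_panel <- function(x, ...) {
  cat("barcode_panel:", x$barcode, "/", x$locus, "-", length(x$sequences),
      "variants,", sum(x$counts), "reads, L =", nchar(x$sequences[1]), "bp\n")
  invisible(x)
}

seq_matrix <- function(sequences) {
  do.call(rbind, strsplit(sequences, "", fixed = TRUE))
}

#' Pairwise nucleotide difference matrix between variants
#'
#' Counts, for every pair of variant sequences, the number of positions at
#' which both carry an unambiguous base (A/C/G/T) and the bases differ.
#'
#' @param sequences Character vector of aligned sequences.
#' @return Symmetric integer matrix of pairwise difference counts.
#' @export
pairwise_differences <- function(sequences) {
  m <- seq_matrix(sequences)
  k <- nrow(m)
  ok <- matrix(m %in% c("A", "C", "G", "T"), nrow = k)
  d <- matrix(0L, k, k)
  if (k >= 2) {
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        use <- ok[i, ] & ok[j, ]
        d[i, j] <- d[j, i] <- sum(m[i, use] != m[j, use])
      }
    }
  }
  d
}

#' Number of segregating (polymorphic) sites
#'
#' A site segregates when at least two distinct unambiguous bases are
#' observed among the panel's variant sequences. Presence-based: read counts
#' do not weight the column scan.
#'
#' @param panel A [barcode_panel()], or a character vector of aligned sequences.
#' @return Integer count S.
#' @export
segregating_sites <- function(panel) {
  sequences <- if (inherits(panel, "barcode_panel")) panel$sequences else panel
  if (length(sequences) == 0L) stop("empty panel")
  m <- seq_matrix(sequences)
  sum(apply(m, 2, function(col) {
    length(unique(col[col %in% c("A", "C", "G", "T")])) >= 2
  }))
}

#' Allelic (haplotype) diversity Hd
#'
#' `Hd = n/(n-1) * (1 - sum(p_i^2))` with `p_i` the read frequency of
#' variant i — the small-sample-corrected probability that two randomly
#' drawn reads carry different alleles.
#'
#' @param counts Integer vector of per-variant read counts (or a
#'   [barcode_panel()]).
#' @return Hd in \[0, 1\].
#' @export
allelic_diversity <- function(counts) {
  if (inherits(counts, "barcode_panel")) counts <- counts$counts
  n <- sum(counts)
  if (n < 2) stop("allelic diversity needs at least 2 reads")
  p <- counts / n
  (n / (n - 1)) * (1 - sum(p^2))
}

#' Mean number of pairwise differences (theta-pi, per locus)
#'
#' Average nucleotide difference count over all unordered pairs of reads,
#' computed from variant counts: `khat = sum_{i<j} c_i c_j d_ij / C(n,2)`
#' (within-variant pairs contribute zero differences).
#'
#' @param panel A [barcode_panel()].
#' @param weighted If `FALSE`, each distinct variant counts once (allele
#'   mode) instead of read-count weighting.
#' @return Mean pairwise difference count (per locus, not per site).
#' @export
mean_pairwise_differences <- function(panel, weighted = TRUE) {
  counts <- if (weighted) panel$counts else rep(1L, length(panel$sequences))
  n <- sum(counts)
  if (n < 2) stop("needs at least 2 reads")
  d <- pairwise_differences(panel$sequences)
  tot <- 0
  k <- length(counts)
  if (k >= 2) {
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) tot <- tot + counts[i] * counts[j] * d[i, j]
    }
  }
  tot / (n * (n - 1) / 2)
}

#' Nucleotide diversity (pi)
#'
#' Mean pairwise nucleotide differences per site over reads:
#' `pi = khat / L`.
#'
#' @inheritParams mean_pairwise_differences
#' @return pi (per-site).
#' @export
nucleotide_diversity <- function(panel, weighted = TRUE) {
  mean_pairwise_differences(panel, weighted = weighted) / nchar(panel$sequences[1])
}

#' Tajima's standard-constant set
#'
#' The a1, a2, b1, b2, c1, c2, e1, e2 constants as functions of the sample
#' size n.
#'
#' @param n Sample size (number of sequences).
#' @return Named list of constants.
#' @export
tajima_constants <- function(n) {
  if (n < 2) stop("n must be >= 2")
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2, e1 = e1, e2 = e2)
}

#' Tajima's D
#'
#' `D = (khat - S/a1) / sqrt(e1*S + e2*S*(S-1))`, the normalized difference
#' between the pairwise-difference and segregating-sites estimators of the
#' scaled mutation rate. Zero is the neutral-equilibrium expectation. Sample
#' size n is the read count by default (allele mode available).
#'
#' @inheritParams mean_pairwise_differences
#' @return D, or `NA` when S = 0 (undefined, reported as missing).
#' @export
tajimas_d <- function(panel, weighted = TRUE) {
  S <- segregating_sites(panel)
  if (S == 0) return(NA_real_)
  counts <- if (weighted) panel$counts else rep(1L, length(panel$sequences))
  n <- sum(counts)
  if (n < 4) stop("Tajima's D needs n >= 4")
  k <- tajima_constants(n)
  khat <- mean_pairwise_differences(panel, weighted = weighted)
  (khat - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
}

#' Log unsigned Stirling numbers of the first kind, row n
#'
#' Returns `log(|s(n, k)|)` for k = 1..n via the recurrence
#' `|s(n+1,k)| = n*|s(n,k)| + |s(n,k-1)|`, carried in log space so rows up
#' to n in the thousands are exact to double precision.
#'
#' @param n Row index (sample size).
#' @return Numeric vector of length n: `log|s(n,k)|` for k = 1..n.
#' @export
log_stirling_first <- function(n) {
  stopifnot(n >= 1)
  row <- 0  # log|s(1,1)| = log 1
  if (n == 1) return(row)
  for (m in 1:(n - 1)) {
    # row holds log|s(m, 1..m)|; build row m+1
    prev <- c(row, -Inf)           # |s(m, k)| for k = 1..m+1
    shifted <- c(-Inf, row)        # |s(m, k-1)|
    a <- log(m) + prev
    row <- pmax(a, shifted) + log1p(exp(-abs(a - shifted)))
    row[is.nan(row)] <- -Inf
  }
  row
}

#' Ewens distribution of the number of distinct alleles
#'
#' `Pr(K = k | theta, n) = |s(n,k)| theta^k / prod_{i=0}^{n-1} (theta + i)`,
#' computed in log space.
#'
#' @param n Sample size.
#' @param theta Scaled mutation rate (> 0).
#' @return Numeric vector of probabilities for k = 1..n.
#' @export
ewens_k_distribution <- function(n, theta) {
  stopifnot(n >= 1, theta > 0)
  ls <- log_stirling_first(n)
  k <- seq_len(n)
  logp <- ls + k * log(theta) - sum(log(theta + 0:(n - 1)))
  exp(logp - max(logp)) / sum(exp(logp - max(logp)))
}

#' Fu's Fs
#'
#' With `theta = khat` (the mean pairwise difference count), computes the
#' Ewens-model tail probability `S' = Pr(K >= k_obs | theta, n)` of seeing
#' at least the observed number of distinct alleles, and returns
#' `Fs = ln(S'/(1 - S'))`. Strongly negative Fs indicates an excess of
#' alleles (recent expansion / many rare variants); positive Fs an allele
#' deficiency consistent with balancing-type patterns. When `S' = 1`
#' (e.g. a single observed allele) the `-Inf` sentinel is returned.
#'
#' @inheritParams mean_pairwise_differences
#' @return Fs (possibly `-Inf`/`Inf` sentinels), or `NA` when khat = 0.
#' @export
fus_fs <- function(panel, weighted = TRUE) {
  counts <- if (weighted) panel$counts else rep(1L, length(panel$sequences))
  n <- sum(counts)
  if (n < 2) stop("Fu's Fs needs n >= 2")
  theta <- mean_pairwise_differences(panel, weighted = weighted)
  if (theta <= 0) return(NA_real_)
  k_obs <- length(panel$sequences)
  ls <- log_stirling_first(n)
  k <- seq_len(n)
  logp <- ls + k * log(theta) - sum(log(theta + 0:(n - 1)))
  logsum <- function(v) {
    if (all(v == -Inf)) return(-Inf)
    m <- max(v); m + log(sum(exp(v - m)))
  }
  log_tail <- logsum(logp[k >= k_obs])     # log S'
  log_head <- logsum(logp[k < k_obs])      # log (1 - S')
  if (log_head == -Inf) return(-Inf)
  if (log_tail == -Inf) return(Inf)
  log_tail - log_head
}

# --- Nei-Gojobori (1986) machinery ------------------------------------------

ng_bases <- c("A", "C", "G", "T")

codon_aa <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  unname(gc[codon])
}

#' Synonymous site count of a single codon
#'
#' For each codon position, the fraction of possible single-base changes
#' that are synonymous, among changes that do not create a stop codon
#' (stop-creating changes are excluded from the denominator, so synonymous
#' plus nonsynonymous fractions always sum to 1 per position and to 3 per
#' codon).
#'
#' @param codon 3-character string (A/C/G/T only).
#' @return Number of synonymous sites in \[0, 3\], or `NA` for a stop codon
#'   or a codon containing an ambiguous base.
#' @export
codon_syn_sites <- function(codon) {
  b <- strsplit(codon, "")[[1]]
  if (length(b) != 3L || !all(b %in% ng_bases)) return(NA_real_)
  aa <- codon_aa(codon)
  if (is.na(aa) || aa == "*") return(NA_real_)
  s <- 0
  for (pos in 1:3) {
    alt_syn <- 0L; alt_valid <- 0L
    for (nb in setdiff(ng_bases, b[pos])) {
      mb <- b; mb[pos] <- nb
      maa <- codon_aa(paste(mb, collapse = ""))
      if (maa == "*") next
      alt_valid <- alt_valid + 1L
      if (maa == aa) alt_syn <- alt_syn + 1L
    }
    if (alt_valid > 0L) s <- s + alt_syn / alt_valid
  }
  s
}

# All orderings of positions 1..k (k <= 3), as a list of integer vectors.
all_orderings <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_orderings(v[-i])) out <- c(out, list(c(v[i], rest)))
  }
  out
}

#' Synonymous/nonsynonymous differences between two codons
#'
#' Equal-weight enumeration of all shortest mutational pathways between two
#' codons; each pathway step is classified synonymous or nonsynonymous and
#' averaged over pathways. Pathways passing through a stop codon are
#' excluded; if every pathway is blocked, all pathways are used with
#' stop-entering steps counted as nonsynonymous.
#'
#' @param c1,c2 Codon strings.
#' @return `c(syn, nonsyn)` difference counts (sum = number of differing
#'   positions), or `NA` for codons with ambiguous bases or stop codons.
#' @export
codon_path_differences <- function(c1, c2) {
  b1 <- strsplit(c1, "")[[1]]; b2 <- strsplit(c2, "")[[1]]
  if (!all(c(b1, b2) %in% ng_bases)) return(c(NA_real_, NA_real_))
  if (codon_aa(c1) == "*" || codon_aa(c2) == "*") return(c(NA_real_, NA_real_))
  diff_pos <- which(b1 != b2)
  if (length(diff_pos) == 0L) return(c(0, 0))
  paths <- all_orderings(diff_pos)
  score_path <- function(order, allow_stop) {
    cur <- b1; sd <- 0; nd <- 0
    for (pos in order) {
      nxt <- cur; nxt[pos] <- b2[pos]
      aa_cur <- codon_aa(paste(cur, collapse = ""))
      aa_nxt <- codon_aa(paste(nxt, collapse = ""))
      if (aa_nxt == "*" && !allow_stop) return(NULL)
      if (aa_nxt == aa_cur) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd)
  }
  scored <- Filter(Negate(is.null), lapply(paths, score_path, allow_stop = FALSE))
  if (length(scored) == 0L) {
    scored <- lapply(paths, score_path, allow_stop = TRUE)
  }
  colMeans(do.call(rbind, scored))
}

.ng_cache <- new.env(parent = emptyenv())

codon_syn_sites_memo <- function(codon) {
  v <- .ng_cache[[paste0("s:", codon)]]
  if (is.null(v)) {
    v <- codon_syn_sites(codon)
    .ng_cache[[paste0("s:", codon)]] <- v
  }
  v
}

codon_path_differences_memo <- function(c1, c2) {
  key <- paste0("p:", c1, c2)
  v <- .ng_cache[[key]]
  if (is.null(v)) {
    v <- codon_path_differences(c1, c2)
    .ng_cache[[key]] <- v
  }
  v
}

ng_pair <- function(s1, s2) {
  L <- nchar(s1)
  stopifnot(nchar(s2) == L, L %% 3 == 0)
  n_codons <- L / 3
  S_sites <- 0; sd <- 0; nd <- 0; used <- 0L
  for (ci in seq_len(n_codons)) {
    from <- (ci - 1) * 3 + 1
    c1 <- substr(s1, from, from + 2)
    c2 <- substr(s2, from, from + 2)
    ss1 <- codon_syn_sites_memo(c1); ss2 <- codon_syn_sites_memo(c2)
    pd <- codon_path_differences_memo(c1, c2)
    if (is.na(ss1) || is.na(ss2) || anyNA(pd)) next  # gap/N/stop codon: skip
    used <- used + 1L
    S_sites <- S_sites + (ss1 + ss2) / 2
    sd <- sd + pd[1]; nd <- nd + pd[2]
  }
  N_sites <- 3 * used - S_sites
  list(S_sites = S_sites, N_sites = N_sites, sd = sd, nd = nd,
       codons_used = used)
}

jukes_cantor <- function(p) {
  ifelse(p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
}

#' Nei-Gojobori Ka, Ks and their ratio
#'
#' For every unordered pair of distinct variants, counts synonymous and
#' nonsynonymous sites (averaged between the two sequences) and differences
#' (equal-weight enumeration of shortest mutational pathways), applies the
#' Jukes-Cantor correction `d = -3/4 ln(1 - 4/3 p)` to the per-pair
#' proportions, and averages the corrected dN and dS over pairs. Pair
#' averaging is unweighted over distinct variants by default (the usual way
#' haplotype-level data are fed to this estimator); set `weighted = TRUE`
#' to weight pairs by read-count products.
#'
#' Codons containing a gap, an ambiguous base, or a stop codon are skipped
#' pair-wise (with a warning for stops).
#'
#' @param panel A [barcode_panel()] (aligned length divisible by 3, reading
#'   frame at position 1).
#' @param weighted Weight pairs by read counts (default `FALSE`).
#' @return List with `Ka`, `Ks`, `omega` (`NA` with `omega_defined = FALSE`
#'   when Ks = 0 or any component is undefined).
#' @export
ka_ks <- function(panel, weighted = FALSE) {
  seqs <- panel$sequences
  L <- nchar(seqs[1])
  if (L %% 3 != 0) stop("aligned length must be a multiple of 3")
  has_stop <- vapply(seqs, function(s) {
    cods <- substring(s, seq(1, L - 2, 3), seq(3, L, 3))
    any(!is.na(codon_aa(cods)) & codon_aa(cods) == "*")
  }, logical(1))
  if (any(has_stop)) warning(sum(has_stop), " variant(s) contain stop codons; ",
                             "those codons are excluded pair-wise")
  k <- length(seqs)
  if (k < 2) return(list(Ka = 0, Ks = 0, omega = NA_real_, omega_defined = FALSE))
  wsum <- 0; dN_acc <- 0; dS_acc <- 0; any_na <- FALSE
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      pr <- ng_pair(seqs[i], seqs[j])
      if (pr$codons_used == 0L) { any_na <- TRUE; next }
      pS <- if (pr$S_sites > 0) pr$sd / pr$S_sites else 0
      pN <- if (pr$N_sites > 0) pr$nd / pr$N_sites else 0
      dS <- jukes_cantor(pS); dN <- jukes_cantor(pN)
      if (is.na(dS) || is.na(dN)) { any_na <- TRUE; next }
      w <- if (weighted) panel$counts[i] * panel$counts[j] else 1
      dN_acc <- dN_acc + w * dN
      dS_acc <- dS_acc + w * dS
      wsum <- wsum + w
    }
  }
  if (wsum == 0) return(list(Ka = NA_real_, Ks = NA_real_, omega = NA_real_,
                             omega_defined = FALSE))
  Ka <- dN_acc / wsum
  Ks <- dS_acc / wsum
  defined <- Ks > 0
  list(Ka = Ka, Ks = Ks, omega = if (defined) Ka / Ks else NA_real_,
       omega_defined = defined)
}

#' Average number of alleles per pooled individual
#'
#' @param n_alleles Number of distinct retained alleles in the barcode.
#' @param n_individuals Number of pooled individuals.
#' @return `n_alleles / n_individuals`.
#' @export
alleles_per_individual <- function(n_alleles, n_individuals) {
  if (n_individuals < 1) stop("n_individuals must be >= 1")
  n_alleles / n_individuals
}

#' Mean-centered allelic diversity and its correlation with population size
#'
#' Drift check: each population's allele count is divided by the mean allele
#' count over populations; under drift, centered diversity is expected to
#' correlate positively with population size.
#'
#' @param allele_counts Numeric vector of per-population allele counts.
#' @param population_sizes Numeric vector of population size estimates
#'   (same order); optional.
#' @param n_perm Permutations for the correlation p-value.
#' @param seed Optional RNG seed for the permutation p-value.
#' @return List with `centered`, and when sizes are supplied `r` (Pearson)
#'   and permutation `p` (`NA` with zero variance).
#' @export
mean_centered_diversity <- function(allele_counts, population_sizes = NULL,
                                    n_perm = 9999, seed = NULL) {
  if (length(allele_counts) < 2) stop("need >= 2 populations")
  mu <- mean(allele_counts)
  if (mu == 0) stop("zero mean allele count")
  centered <- allele_counts / mu
  out <- list(centered = centered)
  if (!is.null(population_sizes)) {
    stopifnot(length(population_sizes) == length(allele_counts))
    if (stats::sd(centered) == 0 || stats::sd(population_sizes) == 0) {
      out$r <- NA_real_; out$p <- NA_real_
    } else {
      if (!is.null(seed)) set.seed(seed)
      r_obs <- stats::cor(centered, population_sizes)
      perm_r <- replicate(n_perm,
        stats::cor(centered, sample(population_sizes)))
      out$r <- r_obs
      out$p <- (1 + sum(perm_r >= r_obs)) / (n_perm + 1)
    }
  }
  out
}

#' Per-barcode summary table of diversity and neutrality statistics
#'
#' One row per panel with the read count, segregating sites S, allele count
#' A, alleles per individual A/N, allelic diversity Hd, nucleotide diversity
#' pi, Tajima's D, Fu's Fs, and Nei-Gojobori Ka, Ks and Ka/Ks.
#'
#' @param panels List of [barcode_panel()] objects.
#' @param weighted Read-count weighting for Hd/pi/D/Fs (default `TRUE`).
#' @return A `data.frame`, one row per barcode x locus.
#' @export
diversity_table <- function(panels, weighted = TRUE) {
  rows <- lapply(panels, function(p) {
    n_reads <- sum(p$counts)
    A <- length(p$sequences)
    S <- segregating_sites(p)
    kk <- ka_ks(p)
    data.frame(
      barcode = p$barcode,
      locus = p$locus,
      N = p$n_individuals,
      reads = n_reads,
      S = S,
      n_alleles = A,
      alleles_per_ind = if (is.na(p$n_individuals)) NA_real_ else
        alleles_per_individual(A, p$n_individuals),
      Hd = if (n_reads >= 2) allelic_diversity(if (weighted) p$counts else
        rep(1L, A)) else NA_real_,
      pi = if (n_reads >= 2) nucleotide_diversity(p, weighted) else NA_real_,
      tajima_D = if (S >= 1 && (if (weighted) n_reads else A) >= 4)
        tajimas_d(p, weighted) else NA_real_,
      fu_Fs = if ((if (weighted) n_reads else A) >= 2)
        fus_fs(p, weighted) else NA_real_,
      Ka = kk$Ka, Ks = kk$Ks,
      Ka_Ks = kk$omega,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
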