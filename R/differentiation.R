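#' Pairwise FST between two barcode panels
#'
#' Default mode `"phi"` is the AMOVA-style haplotype estimator built from
#' pairwise nucleotide differences:
#' `Phi_ST = (pi_total - pi_within) / pi_total`, where `pi_within` is the
#' sample-size-weighted mean of the two within-population expected pairwise
#' difference counts and `pi_total` the expected pairwise difference count
#' of the pooled sample, both computed on variant frequencies (so identical
#' frequency distributions give exactly zero). Mode `"freq"` is Hudson's
#' frequency-based estimator on variant identity: `1 - Hw/Hb`, with `Hw`
#' the unweighted mean within-population haplotype heterozygosity and `Hb`
#' the probability that reads drawn from the two populations differ.
#'
#' Negative estimates are reported as computed; set `clamp = TRUE` to floor
#' at zero for display.
#'
#' @param panelA,panelB [barcode_panel()] objects at the same locus with the
#'   same alignment length.
#' @param mode `"phi"` (default) or `"freq"`.
#' @param clamp Floor negative estimates at zero (default `FALSE`).
#' @return FST estimate, or `NA` when total diversity is zero (undefined).
#' @export
pairwise_fst <- function(panelA, panelB, mode = c("phi", "freq"),
                         clamp = FALSE) {
  mode <- match.arg(mode)
  if (panelA$locus != panelB$locus)
    stop("panels must be at the same locus")
  if (nchar(panelA$sequences[1]) != nchar(panelB$sequences[1]))
    stop("panels must share an alignment length")
  nA <- sum(panelA$counts); nB <- sum(panelB$counts)
  if (nA < 2 || nB < 2) stop("each panel needs >= 2 reads")
  est <- if (mode == "phi") {
    phi_st(panelA$sequences, panelA$counts, panelB$sequences, panelB$counts)
  } else {
    hudson_fst(panelA$sequences, panelA$counts, panelB$sequences, panelB$counts)
  }
  if (clamp && !is.na(est)) est <- max(0, est)
  est
}

# Expected nucleotide difference between two reads drawn (with replacement)
# from a frequency vector over variant sequences.
expected_pairwise_diff <- function(sequences, freqs) {
  d <- pairwise_differences(sequences)
  as.numeric(t(freqs) %*% d %*% freqs)
}

pool_variants <- function(seqsA, countsA, seqsB, countsB) {
  seqs <- c(seqsA, seqsB)
  counts <- c(countsA, countsB)
  agg <- tapply(counts, seqs, sum)
  list(sequences = names(agg), counts = as.integer(agg))
}

# Phi_ST from the pi decomposition on variant frequencies. Frequency (with-
# replacement) forms are used for both terms so that identical frequency
# distributions give exactly zero.
phi_st <- function(seqsA, countsA, seqsB, countsB) {
  nA <- sum(countsA); nB <- sum(countsB)
  piA <- expected_pairwise_diff(seqsA, countsA / nA)
  piB <- expected_pairwise_diff(seqsB, countsB / nB)
  pooled <- pool_variants(seqsA, countsA, seqsB, countsB)
  pi_total <- expected_pairwise_diff(pooled$sequences,
                                     pooled$counts / (nA + nB))
  if (pi_total == 0) return(NA_real_)
  pi_within <- (nA * piA + nB * piB) / (nA + nB)
  (pi_total - pi_within) / pi_total
}

hudson_fst <- function(seqsA, countsA, seqsB, countsB) {
  nA <- sum(countsA); nB <- sum(countsB)
  pA <- countsA / nA; pB <- countsB / nB
  Hw <- ((1 - sum(pA^2)) + (1 - sum(pB^2))) / 2
  shared <- intersect(seqsA, seqsB)
  match_prob <- sum(pA[match(shared, seqsA)] * pB[match(shared, seqsB)])
  Hb <- 1 - match_prob
  if (Hb == 0) return(NA_real_)
  1 - Hw / Hb
}

#' Permutation p-value for a pairwise FST
#'
#' Reads are pooled and randomly reassigned to the two populations at their
#' original sample sizes; `p = (1 + #\{FST_perm >= FST_obs\}) / (n_perm + 1)`.
#'
#' @inheritParams pairwise_fst
#' @param n_perm Number of permutations (>= 1).
#' @param seed Optional RNG seed.
#' @return One-tailed permutation p-value.
#' @export
fst_permutation_p <- function(panelA, panelB, n_perm = 999, seed = NULL,
                              mode = c("phi", "freq")) {
  mode <- match.arg(mode)
  stopifnot(n_perm >= 1)
  if (!is.null(seed)) set.seed(seed)
  obs <- pairwise_fst(panelA, panelB, mode = mode)
  if (is.na(obs)) return(NA_real_)
  pooled_seq <- c(rep(panelA$sequences, panelA$counts),
                  rep(panelB$sequences, panelB$counts))
  nA <- sum(panelA$counts)
  n <- length(pooled_seq)
  fst_fun <- if (mode == "phi") phi_st else hudson_fst
  hits <- 0L
  for (b in seq_len(n_perm)) {
    idx <- sample.int(n, nA)
    ta <- table(pooled_seq[idx]); tb <- table(pooled_seq[-idx])
    est <- fst_fun(names(ta), as.integer(ta), names(tb), as.integer(tb))
    if (!is.na(est) && est >= obs) hits <- hits + 1L
  }
  (1 + hits) / (n_perm + 1)
}

#' Great-circle distance in kilometers
#'
#' Haversine formula with Earth radius 6371.0 km.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in signed decimal degrees
#'   (south/west negative). Vectorized.
#' @return Distance(s) in km.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90) || any(abs(c(lon1, lon2)) > 180))
    stop("coordinates out of range")
  r <- 6371.0
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

#' Great-circle distance matrix for a manifest
#'
#' @param manifest Manifest data frame (see [read_manifest()]).
#' @return Symmetric km matrix with locality labels.
#' @export
distance_matrix_km <- function(manifest) {
  k <- nrow(manifest)
  m <- matrix(0, k, k, dimnames = list(manifest$locality, manifest$locality))
  for (i in seq_len(k)) {
    m[i, ] <- haversine_km(manifest$latitude[i], manifest$longitude[i],
                           manifest$latitude, manifest$longitude)
  }
  m
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- vector("list", factorial(n))
  pos <- 1L
  for (i in seq_len(n)) {
    for (rest in all_permutations(n - 1L)) {
      rem <- seq_len(n)[-i]
      out[[pos]] <- c(i, rem[rest])
      pos <- pos + 1L
    }
  }
  out
}

#' Mantel test between two labeled distance matrices
#'
#' Computes the cross-product statistic `Z = sum_{i<j} A_ij B_ij`, the
#' Pearson correlation `r` over the k(k-1)/2 off-diagonal pairs, and a
#' one-tailed permutation p-value for positive association. For small
#' matrices (`k < exhaustive_below`) all k! simultaneous row/column
#' permutations are enumerated and p is exact (the fraction of permutations
#' with `r >= observed`, observed included); otherwise `n_perm` random
#' permutations are drawn and `p = (1 + #\{r_perm >= r_obs\}) / (n_perm + 1)`.
#'
#' @param matA,matB Symmetric numeric matrices with matching dimnames (or
#'   unlabeled but equal size).
#' @param n_perm Random permutations when not exhaustive (default 10000).
#' @param seed Optional RNG seed for the sampled branch.
#' @param exhaustive_below Enumerate all k! permutations when k is below
#'   this (default 8, i.e. up to 5040 permutations).
#' @return List of class `mantel_result`: `Z`, `r`, `p`, `n_permutations`
#'   (`"exhaustive"` or the count).
#' @export
mantel <- function(matA, matB, n_perm = 10000, seed = NULL,
                   exhaustive_below = 8) {
  matA <- as.matrix(matA); matB <- as.matrix(matB)
  k <- nrow(matA)
  if (k < 3) stop("Mantel test needs matrices of size >= 3")
  if (!all(dim(matA) == dim(matB))) stop("matrix size mismatch")
  if (!is.null(rownames(matA)) && !is.null(rownames(matB))) {
    if (!identical(rownames(matA), rownames(matB)))
      stop("matrix labels do not match")
  }
  lt <- lower.tri(matA)
  a <- matA[lt]
  if (anyNA(a) || anyNA(matB[lt]))
    stop("matrix contains undefined (NA) distances")
  if (stats::sd(a) == 0 || stats::sd(matB[lt]) == 0)
    stop("constant matrix: Mantel r undefined")
  r_for <- function(perm) stats::cor(a, matB[perm, perm][lt])
  r_obs <- r_for(seq_len(k))
  Z <- sum(a * matB[lt])
  if (k < exhaustive_below) {
    perms <- all_permutations(k)
    rs <- vapply(perms, r_for, numeric(1))
    p <- mean(rs >= r_obs - 1e-12)
    n_permutations <- "exhaustive"
  } else {
    if (!is.null(seed)) set.seed(seed)
    hits <- 0L
    for (b in seq_len(n_perm)) {
      if (r_for(sample.int(k)) >= r_obs - 1e-12) hits <- hits + 1L
    }
    p <- (1 + hits) / (n_perm + 1)
    n_permutations <- n_perm
  }
  structure(list(Z = Z, r = r_obs, p = p, n_permutations = n_permutations),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test: Z = %.4g, r = %.4f, p = %.4g (%s permutations)\n",
              x$Z, x$r, x$p,
              if (identical(x$n_permutations, "exhaustive")) "exhaustive"
              else format(x$n_permutations)))
  invisible(x)
}

#' FST matrix over a set of panels
#'
#' @param panels List of [barcode_panel()] objects at one locus, one per
#'   locality.
#' @param labels Locality labels (default barcode labels).
#' @inheritParams pairwise_fst
#' @return Symmetric FST matrix.
#' @export
fst_matrix <- function(panels, labels = NULL, mode = c("phi", "freq")) {
  mode <- match.arg(mode)
  k <- length(panels)
  if (is.null(labels)) labels <- vapply(panels, `[[`, "", "barcode")
  m <- matrix(0, k, k, dimnames = list(labels, labels))
  if (k >= 2) {
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        m[i, j] <- m[j, i] <- pairwise_fst(panels[[i]], panels[[j]],
                                           mode = mode)
      }
    }
  }
  m
}

#' Isolation-by-distance report (Mantel per species x locus)
#'
#' Runs the Mantel test of each FST matrix against great-circle distances
#' between the corresponding localities, one row per species x locus.
#'
#' @param fst_matrices Named list: `fst_matrices[[species]][[locus]]` is a
#'   labeled FST matrix whose labels are localities present in `manifest`.
#' @param manifest Manifest data frame with `locality`, `latitude`,
#'   `longitude`.
#' @param n_perm,seed,exhaustive_below Passed to [mantel()].
#' @param alpha Significance level for the flag column (default 0.05).
#' @return Data frame with `species`, `locus`, `Z`, `r`, `p`, `significant`.
#' @export
ibd_report <- function(fst_matrices, manifest, n_perm = 10000, seed = NULL,
                       exhaustive_below = 8, alpha = 0.05) {
  rows <- list()
  for (species in names(fst_matrices)) {
    for (locus in names(fst_matrices[[species]])) {
      fm <- fst_matrices[[species]][[locus]]
      if (nrow(fm) < 3) stop("Mantel needs >= 3 localities (", species, ")")
      sub <- manifest[match(rownames(fm), manifest$locality), ]
      if (anyNA(sub$locality)) stop("FST labels missing from manifest")
      dm <- distance_matrix_km(sub)
      lt <- lower.tri(fm)
      undefined <- anyNA(fm[lt]) || stats::sd(fm[lt]) == 0
      rows[[length(rows) + 1L]] <- if (undefined) {
        data.frame(species = species, locus = locus, Z = NA_real_,
                   r = NA_real_, p = NA_real_, significant = NA,
                   stringsAsFactors = FALSE)
      } else {
        mt <- mantel(fm, dm, n_perm = n_perm, seed = seed,
                     exhaustive_below = exhaustive_below)
        data.frame(species = species, locus = locus, Z = mt$Z, r = mt$r,
                   p = mt$p, significant = mt$p < alpha,
                   stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
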