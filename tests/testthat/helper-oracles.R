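# Independent brute-force oracles. Everything here works on an expanded
# per-read representation and naive pair loops, deliberately sharing no code
# with the package implementations it checks.

expand_reads <- function(sequences, counts) rep(sequences, counts)

hamming <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  ok <- ca %in% c("A", "C", "G", "T") & cb %in% c("A", "C", "G", "T")
  sum(ca[ok] != cb[ok])
}

# probability two random reads carry different sequences (with the n/(n-1)
# small-sample factor folded in as a pair ratio)
oracle_hd <- function(sequences, counts) {
  reads <- expand_reads(sequences, counts)
  n <- length(reads)
  pairs_diff <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (reads[i] != reads[j]) pairs_diff <- pairs_diff + 1
  }
  pairs_diff / (n * (n - 1) / 2)
}

oracle_khat <- function(sequences, counts) {
  reads <- expand_reads(sequences, counts)
  n <- length(reads)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tot <- tot + hamming(reads[i], reads[j])
  }
  tot / (n * (n - 1) / 2)
}

oracle_pi <- function(sequences, counts) {
  oracle_khat(sequences, counts) / nchar(sequences[1])
}

oracle_S <- function(sequences) {
  m <- do.call(rbind, strsplit(sequences, ""))
  sum(apply(m, 2, function(col) {
    length(unique(col[col %in% c("A", "C", "G", "T")])) >= 2
  }))
}

oracle_tajima_d <- function(sequences, counts) {
  reads <- expand_reads(sequences, counts)
  n <- length(reads)
  S <- oracle_S(sequences)
  if (S == 0) return(NA_real_)
  khat <- oracle_khat(sequences, counts)
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (khat - S / a1) /
    sqrt((c1 / a1) * S + (c2 / (a1^2 + a2)) * S * (S - 1))
}

# unsigned Stirling numbers of the first kind via the coefficients of the
# rising factorial x(x+1)...(x+n-1); exact in doubles for n <= 20 within
# the tolerances used
stirling_row <- function(n) {
  coefs <- 1                            # polynomial "1"
  for (m in 0:(n - 1)) {
    # multiply by (x + m): coefs are c0 + c1 x + ...
    coefs <- c(0, coefs) + m * c(coefs, 0)
  }
  coefs[2:(n + 1)]                      # |s(n,k)| for k = 1..n
}

oracle_fs <- function(sequences, counts) {
  reads <- expand_reads(sequences, counts)
  n <- length(reads)
  theta <- oracle_khat(sequences, counts)
  if (theta <= 0) return(NA_real_)
  k_obs <- length(unique(reads))
  s <- stirling_row(n)
  pk <- s * theta^seq_len(n) / prod(theta + 0:(n - 1))
  Sp <- sum(pk[seq_len(n) >= k_obs])
  if (Sp >= 1) return(-Inf)
  log(Sp / (1 - Sp))
}

# --- Nei-Gojobori oracle (independent code path via Biostrings::translate)
aa_of <- function(codon) {
  as.character(Biostrings::translate(Biostrings::DNAString(codon),
                                     no.init.codon = TRUE))
}

oracle_syn_sites <- function(codon) {
  if (aa_of(codon) == "*") return(NA_real_)
  b <- strsplit(codon, "")[[1]]
  total <- 0
  for (pos in 1:3) {
    syn <- 0; valid <- 0
    for (alt in setdiff(c("A", "C", "G", "T"), b[pos])) {
      m <- b; m[pos] <- alt
      maa <- aa_of(paste(m, collapse = ""))
      if (maa == "*") next
      valid <- valid + 1
      if (maa == aa_of(codon)) syn <- syn + 1
    }
    if (valid > 0) total <- total + syn / valid
  }
  total
}

# enumerate shortest pathways with utils::combn-free recursion
oracle_pathways <- function(c1, c2) {
  b1 <- strsplit(c1, "")[[1]]; b2 <- strsplit(c2, "")[[1]]
  pos <- which(b1 != b2)
  if (length(pos) == 0) return(list(syn = 0, nonsyn = 0))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    unlist(lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(r) c(v[i], r))), recursive = FALSE)
  }
  walk <- function(order, allow_stop) {
    cur <- b1; syn <- 0; nonsyn <- 0
    for (p in order) {
      nxt <- cur; nxt[p] <- b2[p]
      if (aa_of(paste(nxt, collapse = "")) == "*" && !allow_stop) return(NULL)
      if (aa_of(paste(nxt, collapse = "")) ==
          aa_of(paste(cur, collapse = ""))) syn <- syn + 1
      else nonsyn <- nonsyn + 1
      cur <- nxt
    }
    list(syn = syn, nonsyn = nonsyn)
  }
  res <- Filter(Negate(is.null), lapply(perms(pos), walk, allow_stop = FALSE))
  if (length(res) == 0) res <- lapply(perms(pos), walk, allow_stop = TRUE)
  list(syn = mean(vapply(res, `[[`, 0, "syn")),
       nonsyn = mean(vapply(res, `[[`, 0, "nonsyn")))
}

oracle_kaks_pair <- function(s1, s2) {
  L <- nchar(s1)
  Ssites <- 0; Nsites <- 0; sd <- 0; nd <- 0
  for (ci in seq_len(L / 3)) {
    from <- (ci - 1) * 3 + 1
    c1 <- substr(s1, from, from + 2); c2 <- substr(s2, from, from + 2)
    ss1 <- oracle_syn_sites(c1); ss2 <- oracle_syn_sites(c2)
    if (is.na(ss1) || is.na(ss2)) next
    pw <- oracle_pathways(c1, c2)
    Ssites <- Ssites + (ss1 + ss2) / 2
    Nsites <- Nsites + 3 - (ss1 + ss2) / 2
    sd <- sd + pw$syn; nd <- nd + pw$nonsyn
  }
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(dN = jc(if (Nsites > 0) nd / Nsites else 0),
       dS = jc(if (Ssites > 0) sd / Ssites else 0),
       S_sites = Ssites, N_sites = Nsites, sd = sd, nd = nd)
}

oracle_kaks <- function(sequences) {
  k <- length(sequences)
  dNs <- c(); dSs <- c()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    pr <- oracle_kaks_pair(sequences[i], sequences[j])
    if (is.na(pr$dN) || is.na(pr$dS)) next
    dNs <- c(dNs, pr$dN); dSs <- c(dSs, pr$dS)
  }
  list(Ka = mean(dNs), Ks = mean(dSs))
}

# Needleman-Wunsch with free end gaps; returns the optimal score under
# match/mismatch/gap scoring
oracle_overlap_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  M <- matrix(0, n + 1, m + 1)          # free leading end gaps
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      sc <- if (ca[i] == cb[j]) match else mismatch
      M[i + 1, j + 1] <- max(M[i, j] + sc, M[i, j + 1] + gap,
                             M[i + 1, j] + gap)
    }
  }
  max(M[n + 1, ], M[, m + 1])           # free trailing end gaps
}

# random in-frame stop-free coding sequences for statistic fixtures
random_coding_seq <- function(n_codons) {
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)[gc != "*"]
  paste(sample(codons, n_codons, replace = TRUE), collapse = "")
}

# a random aligned panel: base sequence plus point mutations
random_panel <- function(n_variants, L, max_count = 6, coding = FALSE) {
  stopifnot(L %% 3 == 0)
  base <- if (coding) random_coding_seq(L / 3) else
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  seqs <- base
  while (length(unique(seqs)) < n_variants) {
    s <- strsplit(base, "")[[1]]
    nmut <- sample(1:max(1, L %/% 10), 1)
    pos <- sample(L, nmut)
    for (p in pos) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1)
    seqs <- unique(c(seqs, paste(s, collapse = "")))
  }
  seqs <- seqs[seq_len(n_variants)]
  counts <- sample(seq_len(max_count), n_variants, replace = TRUE)
  barcode_panel(seqs, counts, barcode = "toy", locus = "toy")
}
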