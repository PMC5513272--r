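#' Default QC parameters
#'
#' The six-rule cleaning cascade's thresholds: minimum read length 180 bp,
#' minimum 70% alignment identity to a reference, 80% of bases at Phred >=
#' 20, and frameshift (net indel not a multiple of 3) removal. "Under 180
#' bp" and "under 80% quality" are strict-less-than removals: boundary
#' values are retained.
#'
#' @param min_length Minimum read length in bases.
#' @param min_identity Minimum alignment identity (matches over alignment
#'   columns, gaps included) to the best reference.
#' @param min_fraction_hq Minimum fraction of high-quality bases.
#' @param hq_phred Phred score at or above which a base counts as
#'   high-quality.
#' @param match,mismatch,gap Alignment scores (global with free end gaps).
#' @param singleton_scope `"barcode"` (a count-1 occurrence is removed from
#'   that barcode) or `"global"` (variants with total count 1 removed).
#' @param quality_first Apply the quality filter before dereplication
#'   instead of after (default `FALSE`, following the narrative stage
#'   order).
#' @return A named list of parameters.
#' @export
qc_params <- function(min_length = 180L, min_identity = 0.70,
                      min_fraction_hq = 0.80, hq_phred = 20L,
                      match = 1, mismatch = -1, gap = 2,
                      singleton_scope = c("barcode", "global"),
                      quality_first = FALSE) {
  singleton_scope <- match.arg(singleton_scope)
  stopifnot(min_length >= 0, min_identity >= 0, min_identity <= 1,
            min_fraction_hq >= 0, min_fraction_hq <= 1, hq_phred >= 0)
  list(min_length = as.integer(min_length), min_identity = min_identity,
       min_fraction_hq = min_fraction_hq, hq_phred = as.integer(hq_phred),
       match = match, mismatch = mismatch, gap = gap,
       singleton_scope = singleton_scope, quality_first = quality_first)
}

#' Length filter
#'
#' Removes reads under `min_length` bases; reads exactly at the boundary
#' are retained.
#'
#' @param reads Read table (see [read_fastq()]).
#' @param min_length Minimum retained length (default 180).
#' @return Filtered read table.
#' @export
filter_length <- function(reads, min_length = 180L) {
  reads[nchar(reads$bases) >= min_length, , drop = FALSE]
}

#' Quality filter
#'
#' Retains reads whose fraction of bases at Phred >= `hq_phred` is at least
#' `min_fraction_hq`; the boundary is retained. Reads without qualities
#' (FASTA input) pass through with a warning when `missing_ok = TRUE`.
#'
#' @param reads Read table.
#' @param min_fraction_hq Minimum high-quality fraction (default 0.80).
#' @param hq_phred High-quality Phred threshold (default 20).
#' @param missing_ok Pass reads with missing qualities (default `TRUE`,
#'   with a warning).
#' @return Filtered read table.
#' @export
filter_quality <- function(reads, min_fraction_hq = 0.80, hq_phred = 20L,
                           missing_ok = TRUE) {
  if (nrow(reads) == 0L) return(reads)
  missing <- is.na(reads$quality) | reads$quality == ""
  if (any(missing)) {
    if (!missing_ok) stop("reads without quality strings")
    warning(sum(missing), " read(s) without qualities pass the quality ",
            "filter unchecked")
  }
  frac <- vapply(seq_len(nrow(reads)), function(i) {
    if (missing[i]) return(1)
    q <- utf8ToInt(reads$quality[i]) - 33L
    mean(q >= hq_phred)
  }, numeric(1))
  reads[frac >= min_fraction_hq, , drop = FALSE]
}

align_to_reference <- function(seqs, reference, params, type = "overlap") {
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = params$match, mismatch = params$mismatch, baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(seqs),
    subject = Biostrings::DNAString(reference),
    type = type, substitutionMatrix = mat,
    gapOpening = 0, gapExtension = params$gap)
  aln_len <- Biostrings::nchar(pa)
  # gaps in the aligned subject = insertions in the read; gaps in the
  # aligned pattern = deletions. For global alignments the gap characters
  # of the aligned strings are counted so terminal indels are included
  # (indel() skips end gaps); the overlap path uses the cheap indel()
  # slots, since its end gaps are free by construction.
  if (type == "global") {
    subj_aln <- as.character(Biostrings::alignedSubject(pa))
    patt_aln <- as.character(Biostrings::alignedPattern(pa))
    ins <- nchar(gsub("[^-]", "", subj_aln))
    del <- nchar(gsub("[^-]", "", patt_aln))
  } else {
    ins <- vapply(as.list(Biostrings::indel(pa)@insertion), function(x)
      sum(IRanges::width(x)), numeric(1))
    del <- vapply(as.list(Biostrings::indel(pa)@deletion), function(x)
      sum(IRanges::width(x)), numeric(1))
  }
  list(identity = Biostrings::nmatch(pa) / aln_len,
       score = BiocGenerics::score(pa),
       net_indel = as.integer(round(ins - del)),
       start = BiocGenerics::start(Biostrings::subject(pa)) - 1L,
       end = BiocGenerics::end(Biostrings::subject(pa)))
}

#' Assign reads to a locus by reference alignment
#'
#' Aligns each sequence to every reference (global alignment with free end
#' gaps; match +1, mismatch -1, gap -2 by default) in both orientations,
#' and assigns the best reference when its identity (matches over alignment
#' columns, gap columns included) reaches `min_identity`; otherwise the
#' locus is `NA`. Reverse-complement hits are normalized to reference
#' orientation.
#'
#' @param reads Read table, or a character vector of sequences.
#' @param references Named character vector of reference sequences (one per
#'   locus), or a path to a FASTA file.
#' @param params [qc_params()] list (supplies `min_identity` and alignment
#'   scores).
#' @return Data frame with one row per input read: `locus` (NA if
#'   unassigned), `identity`, `net_indel`, `aligned_start`, `aligned_end`
#'   (0-based half-open reference coordinates), `reverse_complemented`, and
#'   `bases` (orientation-normalized sequence).
#' @export
assign_locus <- function(reads, references, params = qc_params()) {
  if (is.character(references) && length(references) == 1L &&
      file.exists(references)) {
    references <- read_fasta(references)
  }
  if (is.null(names(references)) || any(names(references) == ""))
    stop("references must be named (one name per locus)")
  seqs <- if (is.data.frame(reads)) reads$bases else as.character(reads)
  if (length(seqs) == 0L) {
    return(data.frame(locus = character(), identity = numeric(),
                      net_indel = integer(), aligned_start = integer(),
                      aligned_end = integer(),
                      reverse_complemented = logical(),
                      bases = character(), stringsAsFactors = FALSE))
  }
  if (any(nchar(seqs) == 0L)) stop("empty read sequence")
  # align unique sequences once, in both orientations, against each reference
  useqs <- unique(seqs)
  rcseqs <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(useqs)))
  n <- length(useqs)
  best <- data.frame(locus = rep(NA_character_, n), identity = 0,
                     net_indel = NA_integer_, aligned_start = NA_integer_,
                     aligned_end = NA_integer_,
                     reverse_complemented = FALSE, score = -Inf,
                     stringsAsFactors = FALSE)
  for (locus in names(references)) {
    for (rc in c(FALSE, TRUE)) {
      al <- align_to_reference(if (rc) rcseqs else useqs,
                               references[[locus]], params)
      better <- al$score > best$score
      if (any(better)) {
        best$locus[better] <- locus
        best$identity[better] <- al$identity[better]
        best$net_indel[better] <- al$net_indel[better]
        best$aligned_start[better] <- al$start[better]
        best$aligned_end[better] <- al$end[better]
        best$reverse_complemented[better] <- rc
        best$score[better] <- al$score[better]
      }
    }
  }
  unassigned <- best$identity < params$min_identity
  best$locus[unassigned] <- NA_character_
  best$bases <- ifelse(best$reverse_complemented, rcseqs, useqs)
  idx <- match(seqs, useqs)
  out <- best[idx, c("locus", "identity", "net_indel", "aligned_start",
                     "aligned_end", "reverse_complemented", "bases")]
  rownames(out) <- NULL
  out
}

#' Dereplicate locus-assigned reads into a variant table
#'
#' Groups reads by exact (100%) sequence identity within each locus; one
#' variant per distinct sequence, with per-barcode read counts. Variant
#' order is deterministic: descending total count, ties broken
#' lexicographically by sequence.
#'
#' @param reads Read table with `bases`, `barcode` and `locus` columns.
#' @return Variant table: `variant_id`, `locus`, `sequence`, one count
#'   column per barcode, `total_count`.
#' @export
dereplicate <- function(reads) {
  stopifnot(all(c("bases", "barcode", "locus") %in% names(reads)))
  reads <- reads[!is.na(reads$locus), , drop = FALSE]
  barcodes <- sort(unique(reads$barcode))
  if (nrow(reads) == 0L) {
    out <- data.frame(variant_id = character(), locus = character(),
                      sequence = character(), total_count = integer(),
                      stringsAsFactors = FALSE)
    return(out)
  }
  tab <- table(paste(reads$locus, reads$bases, sep = "\r"), reads$barcode)
  key <- rownames(tab)
  locus <- sub("\r.*$", "", key)
  sequence <- sub("^[^\r]*\r", "", key)
  counts <- matrix(as.integer(tab), nrow = nrow(tab),
                   dimnames = list(NULL, colnames(tab)))
  total <- rowSums(counts)
  ord <- order(locus, -total, sequence)
  out <- data.frame(locus = locus[ord], sequence = sequence[ord],
                    stringsAsFactors = FALSE)
  cm <- counts[ord, , drop = FALSE]
  for (bc in barcodes) out[[bc]] <- cm[, bc]
  out$total_count <- total[ord]
  out <- cbind(data.frame(variant_id = variant_ids(out$locus),
                          stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  out
}

variant_ids <- function(locus) {
  idx <- stats::ave(seq_along(locus), locus, FUN = seq_along)
  sprintf("%s_v%04d", locus, idx)
}

barcode_columns <- function(variants) {
  setdiff(names(variants), c("variant_id", "locus", "sequence", "total_count"))
}

#' Remove singleton variant occurrences
#'
#' With `scope = "barcode"` (default), any per-barcode count of exactly 1
#' is zeroed: the variant disappears from that barcode but survives in
#' barcodes where it was seen more than once. A variant is removed entirely
#' only when all its per-barcode counts were 1 (or 0). With
#' `scope = "global"`, only variants whose total count is 1 are removed.
#'
#' @param variants Variant table from [dereplicate()].
#' @param scope `"barcode"` or `"global"`.
#' @return Filtered variant table with recomputed totals.
#' @export
drop_singletons <- function(variants, scope = c("barcode", "global")) {
  scope <- match.arg(scope)
  bcs <- barcode_columns(variants)
  if (nrow(variants) == 0L) return(variants)
  if (scope == "barcode") {
    for (bc in bcs) {
      variants[[bc]][variants[[bc]] == 1L] <- 0L
    }
  } else {
    variants[rowSums(as.matrix(variants[bcs])) == 1L, bcs] <- 0L
  }
  variants$total_count <- as.integer(rowSums(as.matrix(variants[bcs])))
  out <- variants[variants$total_count > 0L, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove frameshifted variants
#'
#' Drops variants whose alignment to their locus reference carries a net
#' indel length that is not a multiple of three (a reading-frame shift);
#' in-frame (multiple-of-3) indels are retained. Deletions and insertions
#' are treated alike. The net indel is measured by end-to-end (global)
#' alignment: variants at this stage represent complete amplicons, so a
#' single-base gain or loss at the amplicon end — where a free-end-gap
#' alignment would silently clip it — still shifts the frame and is
#' removed.
#'
#' @param variants Variant table.
#' @param references Named reference vector or FASTA path.
#' @param params [qc_params()].
#' @return Filtered variant table.
#' @export
filter_frameshift <- function(variants, references, params = qc_params()) {
  if (nrow(variants) == 0L) return(variants)
  if (is.character(references) && length(references) == 1L &&
      file.exists(references)) {
    references <- read_fasta(references)
  }
  keep <- rep(FALSE, nrow(variants))
  for (locus in unique(variants$locus)) {
    idx <- which(variants$locus == locus)
    al <- align_to_reference(variants$sequence[idx], references[[locus]],
                             params, type = "global")
    keep[idx] <- !is.na(al$net_indel) & al$net_indel %% 3L == 0L
  }
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

stage_counts <- function(reads, stage) {
  if (nrow(reads) == 0L) {
    return(data.frame(stage = stage, barcode = character(),
                      n_reads = integer(), stringsAsFactors = FALSE))
  }
  tt <- table(reads$barcode)
  data.frame(stage = stage, barcode = names(tt), n_reads = as.integer(tt),
             stringsAsFactors = FALSE)
}

#' Run the full six-rule cleaning cascade
#'
#' Applies, in order: length filter, reference-alignment locus assignment,
#' exact dereplication, per-barcode singleton removal, quality filter (on
#' the reads backing each surviving variant; a variant occurrence is
#' dropped when all its backing reads fail), and frameshift removal. The
#' filter report records per-barcode read counts after every stage.
#'
#' @param reads Read table (all barcodes together), as from [read_fastq()]
#'   rows bound together, or a named character vector of FASTQ paths.
#' @param references Named reference vector or FASTA path.
#' @param manifest Manifest data frame; every read barcode must appear in
#'   it (hard error otherwise).
#' @param params [qc_params()].
#' @return List of class `qc_result`: `variants` (final variant table),
#'   `reads` (retained reads with locus), `report` (stage x barcode read
#'   counts), `variant_stage_counts` (variants per stage).
#' @export
run_qc_pipeline <- function(reads, references, manifest = NULL,
                            params = qc_params()) {
  if (is.character(reads)) {
    paths <- reads
    reads <- do.call(rbind, lapply(seq_along(paths), function(i) {
      read_fastq(paths[i], barcode = names(paths)[i] %||% NULL)
    }))
  }
  if (nrow(reads) == 0L) stop("no reads supplied")
  if (!is.null(manifest)) {
    unknown <- setdiff(unique(reads$barcode), manifest$barcode)
    if (length(unknown))
      stop("barcode(s) absent from manifest: ", paste(unknown, collapse = ", "))
  }
  report <- list(stage_counts(reads, "input"))
  vcounts <- list()

  if (params$quality_first) {
    reads <- filter_quality(reads, params$min_fraction_hq, params$hq_phred)
    report <- c(report, list(stage_counts(reads, "quality")))
  }
  reads <- filter_length(reads, params$min_length)
  report <- c(report, list(stage_counts(reads, "length")))

  al <- assign_locus(reads, references, params)
  reads$locus <- al$locus
  reads$bases <- al$bases        # orientation-normalized
  reads$net_indel <- al$net_indel
  reads <- reads[!is.na(reads$locus), , drop = FALSE]
  report <- c(report, list(stage_counts(reads, "locus")))

  variants <- dereplicate(reads)
  vcounts$dereplicate <- nrow(variants)

  variants <- drop_singletons(variants, params$singleton_scope)
  vcounts$singleton <- nrow(variants)
  reads <- backing_reads(reads, variants)
  report <- c(report, list(stage_counts(reads, "singleton")))

  if (!params$quality_first) {
    reads <- filter_quality(reads, params$min_fraction_hq, params$hq_phred)
    variants <- recount_variants(variants, reads)
    vcounts$quality <- nrow(variants)
    report <- c(report, list(stage_counts(reads, "quality")))
  }

  variants <- filter_frameshift(variants, references, params)
  vcounts$frameshift <- nrow(variants)
  reads <- backing_reads(reads, variants)
  report <- c(report, list(stage_counts(reads, "frameshift")))

  report <- do.call(rbind, report)
  structure(list(variants = variants, reads = reads, report = report,
                 variant_stage_counts = unlist(vcounts)),
            class = "qc_result")
}

# keep only reads that back a surviving (variant, barcode) occurrence
backing_reads <- function(reads, variants) {
  if (nrow(reads) == 0L || nrow(variants) == 0L)
    return(reads[integer(), , drop = FALSE])
  bcs <- barcode_columns(variants)
  keys <- unlist(lapply(bcs, function(bc) {
    live <- variants[[bc]] > 0L
    paste(variants$locus[live], variants$sequence[live], bc, sep = "\r")
  }))
  rk <- paste(reads$locus, reads$bases, reads$barcode, sep = "\r")
  reads[rk %in% keys, , drop = FALSE]
}

# recompute per-barcode counts from surviving reads, dropping emptied cells
recount_variants <- function(variants, reads) {
  if (nrow(variants) == 0L) return(variants)
  bcs <- barcode_columns(variants)
  key <- paste(variants$locus, variants$sequence, sep = "\r")
  rkey <- paste(reads$locus, reads$bases, sep = "\r")
  for (bc in bcs) {
    sub <- rkey[reads$barcode == bc]
    tt <- table(sub)
    variants[[bc]] <- as.integer(tt[key])
    variants[[bc]][is.na(variants[[bc]])] <- 0L
  }
  variants$total_count <- as.integer(rowSums(as.matrix(variants[bcs])))
  out <- variants[variants$total_count > 0L, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.qc_result <- function(x, ...) {
  cat("qc_result:", nrow(x$variants), "retained variants,",
      nrow(x$reads), "retained reads\n")
  invisible(x)
}

#' Extract per-barcode panels from a QC result
#'
#' @param qc A [run_qc_pipeline()] result (or a variant table).
#' @param manifest Optional manifest supplying `n_individuals`.
#' @return List of [barcode_panel()] objects, one per barcode x locus with
#'   at least one variant.
#' @export
qc_panels <- function(qc, manifest = NULL) {
  variants <- if (inherits(qc, "qc_result")) qc$variants else qc
  bcs <- barcode_columns(variants)
  panels <- list()
  for (locus in unique(variants$locus)) {
    v <- variants[variants$locus == locus, , drop = FALSE]
    for (bc in bcs) {
      live <- v[[bc]] > 0L
      if (!any(live)) next
      ni <- if (!is.null(manifest)) {
        manifest$n_individuals[match(bc, manifest$barcode)]
      } else NA_integer_
      panels[[paste(bc, locus, sep = ".")]] <-
        barcode_panel(v$sequence[live], v[[bc]][live], barcode = bc,
                      locus = locus, n_individuals = ni)
    }
  }
  panels
}
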