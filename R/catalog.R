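#' Build a cross-barcode allele catalog
#'
#' Allele identity across barcodes is exact full-length sequence equality
#' (consistent with 100%-identity dereplication). Species presence is
#' derived from the manifest, never stored independently.
#'
#' @param variants Variant table from [run_qc_pipeline()]/[dereplicate()].
#' @param manifest Manifest data frame mapping barcodes to localities and
#'   species.
#' @return Object of class `allele_catalog` wrapping the variant table and
#'   manifest.
#' @export
allele_catalog <- function(variants, manifest) {
  bcs <- barcode_columns(variants)
  missing <- setdiff(bcs, manifest$barcode)
  if (length(missing))
    stop("barcode(s) absent from manifest: ", paste(missing, collapse = ", "))
  structure(list(variants = variants, manifest = manifest,
                 barcodes = bcs), class = "allele_catalog")
}

#' @export
print.allele_catalog <- function(x, ...) {
  cat("allele_catalog:", nrow(x$variants), "alleles across",
      length(x$barcodes), "barcodes\n")
  invisible(x)
}

catalog_units <- function(catalog, level) {
  if (level == "locality") {
    stats::setNames(catalog$barcodes, catalog$barcodes)
  } else {
    stats::setNames(
      catalog$manifest$species[match(catalog$barcodes,
                                     catalog$manifest$barcode)],
      catalog$barcodes)
  }
}

#' Shared-allele summary
#'
#' For every allele, the set of units (localities/barcodes or species) it
#' occurs in, and headline counts of private (single-unit) versus mixed
#' (multi-unit) alleles per locus.
#'
#' @param catalog An [allele_catalog()].
#' @param level `"locality"` (barcode) or `"species"`.
#' @return List with `membership` (data frame: `variant_id`, `locus`,
#'   `n_units`, `units` comma-joined) and `summary` (per locus: total,
#'   private, mixed allele counts).
#' @export
shared_alleles <- function(catalog, level = c("locality", "species")) {
  level <- match.arg(level)
  units <- catalog_units(catalog, level)
  if (length(unique(units)) < 2L)
    stop("need >= 2 units at level '", level, "'")
  v <- catalog$variants
  mem <- lapply(seq_len(nrow(v)), function(i) {
    present <- catalog$barcodes[vapply(catalog$barcodes,
                                       function(bc) v[[bc]][i] > 0L,
                                       logical(1))]
    sort(unique(unname(units[present])))
  })
  membership <- data.frame(
    variant_id = v$variant_id, locus = v$locus,
    n_units = vapply(mem, length, integer(1)),
    units = vapply(mem, paste, "", collapse = ","),
    stringsAsFactors = FALSE)
  summary <- do.call(rbind, lapply(split(membership, membership$locus),
    function(m) data.frame(locus = m$locus[1], total = nrow(m),
                           private = sum(m$n_units == 1L),
                           mixed = sum(m$n_units > 1L),
                           stringsAsFactors = FALSE)))
  rownames(summary) <- NULL
  list(membership = membership, summary = summary)
}

#' Frequency of the dominant allele in a panel
#'
#' @param panel A [barcode_panel()].
#' @return List with `frequency` (max count / total reads) and `alleles`
#'   (sequences of all tied top alleles).
#' @export
dominant_allele_frequency <- function(panel) {
  total <- sum(panel$counts)
  top <- max(panel$counts)
  list(frequency = top / total,
       alleles = panel$sequences[panel$counts == top])
}

#' Private-allele summary per barcode
#'
#' For each barcode: the number of alleles found only there, and the summed
#' within-barcode read frequency those private alleles carry.
#'
#' @param catalog An [allele_catalog()].
#' @return Data frame: `barcode`, `locus`, `n_private`, `private_frequency`.
#' @export
private_allele_summary <- function(catalog) {
  v <- catalog$variants
  bcs <- catalog$barcodes
  pres <- sapply(bcs, function(bc) v[[bc]] > 0L)
  if (is.null(dim(pres))) pres <- matrix(pres, nrow = 1,
                                         dimnames = list(NULL, bcs))
  n_units <- rowSums(pres)
  rows <- list()
  for (locus in unique(v$locus)) {
    in_locus <- v$locus == locus
    for (bc in bcs) {
      here <- in_locus & pres[, bc]
      total_reads <- sum(v[[bc]][here])
      priv <- here & n_units == 1L
      rows[[length(rows) + 1L]] <- data.frame(
        barcode = bc, locus = locus, n_private = sum(priv),
        private_frequency = if (total_reads > 0)
          sum(v[[bc]][priv]) / total_reads else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Figure-ready catalog tables
#'
#' Emits the per-barcode allele-count table (alleles per locality, per
#' locus) and per-barcode allele-frequency vectors with stable shared-
#' allele keys (shared alleles keep one key everywhere; private alleles
#' are keyed per barcode).
#'
#' @param catalog An [allele_catalog()].
#' @return List with `allele_counts` (barcode x locus counts) and
#'   `frequencies` (long data frame: `barcode`, `locus`, `variant_id`,
#'   `frequency`, `shared`).
#' @export
catalog_report <- function(catalog) {
  v <- catalog$variants
  bcs <- catalog$barcodes
  counts <- do.call(rbind, lapply(unique(v$locus), function(locus) {
    in_locus <- v$locus == locus
    data.frame(locus = locus, barcode = bcs,
               n_alleles = vapply(bcs, function(bc)
                 sum(v[[bc]][in_locus] > 0L), integer(1)),
               stringsAsFactors = FALSE)
  }))
  rownames(counts) <- NULL
  n_units <- rowSums(sapply(bcs, function(bc) v[[bc]] > 0L))
  freq_rows <- list()
  for (bc in bcs) {
    live <- v[[bc]] > 0L
    if (!any(live)) next
    total <- sum(v[[bc]][live])
    freq_rows[[bc]] <- data.frame(
      barcode = bc, locus = v$locus[live], variant_id = v$variant_id[live],
      frequency = v[[bc]][live] / total_by_locus(v, bc, live),
      shared = n_units[live] > 1L, stringsAsFactors = FALSE)
  }
  list(allele_counts = counts, frequencies = do.call(rbind, freq_rows))
}

total_by_locus <- function(v, bc, live) {
  tot <- tapply(v[[bc]][live], v$locus[live], sum)
  as.numeric(tot[v$locus[live]])
}

#' Headline catalog counts as JSON-ready list
#'
#' @param catalog An [allele_catalog()].
#' @return List: per locus, total alleles, mixed-locality alleles, and
#'   trans-species alleles (identical sequence in >= 1 barcode of each
#'   species).
#' @export
catalog_summary <- function(catalog) {
  by_loc <- shared_alleles(catalog, "locality")$summary
  out <- list()
  n_species <- length(unique(catalog$manifest$species))
  by_sp <- if (n_species >= 2L) shared_alleles(catalog, "species") else NULL
  for (i in seq_len(nrow(by_loc))) {
    locus <- by_loc$locus[i]
    entry <- list(total_alleles = by_loc$total[i],
                  mixed_locality = by_loc$mixed[i],
                  private_locality = by_loc$private[i])
    if (!is.null(by_sp)) {
      m <- by_sp$membership
      entry$trans_species <- sum(m$locus == locus & m$n_units > 1L)
    }
    out[[locus]] <- entry
  }
  out
}
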