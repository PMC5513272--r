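#' Read a FASTQ file of amplicon reads
#'
#' Parses a standard 4-line FASTQ file (Sanger Phred+33 qualities) into the
#' read table used throughout the pipeline. One FASTQ file corresponds to one
#' barcode (one pooled colony), mirroring how pooled 454 runs are demultiplexed.
#'
#' @param path Path to a FASTQ file.
#' @param barcode Barcode label to attach to every read. Defaults to the file
#'   name without extension.
#' @return A `data.frame` with columns `id`, `barcode`, `bases`, `quality`
#'   (Phred+33 encoded string, same length as `bases`).
#' @export
read_fastq <- function(path, barcode = NULL) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  if (is.null(barcode)) {
    barcode <- sub("\\.(fastq|fq)(\\.gz)?$", "", basename(path))
  }
  n_lines <- length(readLines(path, n = 8L, warn = FALSE))
  if (n_lines == 0L) {
    warning("empty FASTQ file: ", path)
    return(empty_reads())
  }
  seqs <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  quals <- S4Vectors::mcols(seqs)$qualities
  data.frame(
    id = names(seqs),
    barcode = barcode,
    bases = as.character(seqs),
    quality = as.character(quals),
    stringsAsFactors = FALSE
  )
}

empty_reads <- function() {
  data.frame(id = character(), barcode = character(), bases = character(),
             quality = character(), stringsAsFactors = FALSE)
}

#' Write reads to FASTQ (Phred+33)
#'
#' @param reads Read table (`id`, `bases`, `quality`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "bases", "quality") %in% names(reads)))
  stopifnot(all(nchar(reads$bases) == nchar(reads$quality)))
  x <- Biostrings::DNAStringSet(reads$bases)
  names(x) <- reads$id
  q <- Biostrings::BStringSet(reads$quality)
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path Path to FASTA.
#' @return Named character vector of sequences (uppercase).
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to FASTA, wrapped at 80 columns
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(unname(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' Convert Phred+33 quality strings to integer scores
#'
#' @param quality Character vector of Phred+33 strings.
#' @return List of integer vectors.
#' @export
phred_scores <- function(quality) {
  lapply(quality, function(q) as.integer(utf8ToInt(q)) - 33L)
}

#' Encode integer Phred scores as a Phred+33 string
#' @param scores Integer vector of Phred scores.
#' @return Single character string.
#' @export
phred_encode <- function(scores) {
  scores <- pmin(pmax(as.integer(scores), 0L), 93L)
  intToUtf8(scores + 33L)
}

#' Parse a degrees-minutes coordinate to signed decimal degrees
#'
#' Accepts plain decimal values and strings like `"15°22′ S"`,
#' `"75°12' W"` or `"15 22 S"`. South and West map to negative decimal
#' degrees.
#'
#' @param x Character or numeric vector.
#' @param hemisphere Optional vector of `"N"/"S"/"E"/"W"` overriding a
#'   hemisphere letter embedded in `x`.
#' @return Numeric vector of signed decimal degrees.
#' @export
parse_coordinate <- function(x, hemisphere = NULL) {
  if (is.numeric(x)) return(as.numeric(x))
  vapply(seq_along(x), function(i) {
    s <- trimws(x[i])
    hem <- if (is.null(hemisphere)) NA_character_ else toupper(hemisphere[i])
    hm <- regmatches(toupper(s), regexpr("[NSEW](?=[^0-9]*$)", toupper(s),
                                         perl = TRUE))
    if (is.na(hem) && length(hm) == 1L) hem <- hm
    num <- suppressWarnings(as.numeric(s))
    if (!is.na(num)) return(num)
    parts <- as.numeric(regmatches(s, gregexpr("[0-9]+(\\.[0-9]+)?", s))[[1]])
    if (length(parts) < 1L || anyNA(parts)) stop("cannot parse coordinate: ", s)
    dd <- parts[1] + (if (length(parts) >= 2) parts[2] / 60 else 0) +
      (if (length(parts) >= 3) parts[3] / 3600 else 0)
    if (!is.na(hem) && hem %in% c("S", "W")) dd <- -dd
    dd
  }, numeric(1))
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

#' Read a barcode manifest
#'
#' The manifest is a TSV with one row per barcode/colony and columns
#' `barcode`, `locality`, `latitude`, `longitude`, `country`, `species`,
#' `n_individuals`. Coordinates may be decimal degrees or degree-minute
#' strings such as `"15°22′ S"`; they are converted to signed
#' decimal degrees (south/west negative).
#'
#' @param path Path to the manifest TSV.
#' @return A `data.frame` with `latitude`/`longitude` as numeric decimal
#'   degrees and integer `n_individuals`.
#' @export
read_manifest <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character")
  required <- c("barcode", "locality", "latitude", "longitude", "species",
                "n_individuals")
  missing <- setdiff(required, names(m))
  if (length(missing)) stop("manifest missing column(s): ",
                            paste(missing, collapse = ", "))
  if (anyDuplicated(m$barcode)) stop("duplicate barcodes in manifest")
  m$latitude <- parse_coordinate(m$latitude)
  m$longitude <- parse_coordinate(m$longitude)
  m$n_individuals <- as.integer(m$n_individuals)
  if (any(is.na(m$n_individuals)) || any(m$n_individuals < 1L))
    stop("n_individuals must be integers >= 1")
  if (any(abs(m$latitude) > 90) || any(abs(m$longitude) > 180))
    stop("coordinates out of range")
  m
}

#' Write a data frame as TSV
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path Path to TSV file.
#' @return Data frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
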