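#' Run configuration for the pipeline
#'
#' Bundles every threshold and mode switch; serialized as JSON next to
#' every output directory for provenance.
#'
#' @param qc [qc_params()] list.
#' @param weighting `"reads"` (count-weighted statistics, default) or
#'   `"alleles"`.
#' @param fst_mode `"phi"` or `"freq"`.
#' @param mantel_permutations Random permutations for large Mantel tests.
#' @param seed Integer seed.
#' @param output_dir Output directory for pipeline artifacts.
#' @return Named list of class `run_config`.
#' @export
run_config <- function(qc = qc_params(), weighting = c("reads", "alleles"),
                       fst_mode = c("phi", "freq"),
                       mantel_permutations = 10000L, seed = 1L,
                       output_dir = "poolmhc_out") {
  weighting <- match.arg(weighting)
  fst_mode <- match.arg(fst_mode)
  structure(list(qc = qc, weighting = weighting, fst_mode = fst_mode,
                 mantel_permutations = as.integer(mantel_permutations),
                 seed = as.integer(seed), output_dir = output_dir),
            class = "run_config")
}

write_run_config <- function(config, dir) {
  cfg <- config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA)
}

#' Run QC + statistics + differentiation + catalog on a set of FASTQ files
#'
#' The `all` pipeline: cleans the reads, writes the variant tables and
#' filter report, computes the per-barcode diversity table, the per-species
#' FST matrices with the isolation-by-distance Mantel report, and the
#' allele catalog. All artifacts are TSV/FASTA/JSON in `config$output_dir`.
#'
#' @param fastq_paths Named character vector of per-barcode FASTQ paths
#'   (names = barcodes; unnamed paths use the file stem).
#' @param references Named reference vector or FASTA path.
#' @param manifest_path Path to the manifest TSV.
#' @param config A [run_config()].
#' @return Invisible list with `qc`, `diversity`, `fst`, `ibd`, `catalog`.
#' @export
run_pipeline <- function(fastq_paths, references, manifest_path,
                         config = run_config()) {
  manifest <- read_manifest(manifest_path)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  write_run_config(config, config$output_dir)
  set.seed(config$seed)

  qc <- run_qc_pipeline(fastq_paths, references, manifest, config$qc)
  write_tsv(qc$variants, file.path(config$output_dir, "variants.tsv"))
  write_tsv(qc$report, file.path(config$output_dir, "filter_report.tsv"))
  if (nrow(qc$variants) > 0) {
    alleles <- stats::setNames(qc$variants$sequence, qc$variants$variant_id)
    write_fasta(alleles, file.path(config$output_dir, "alleles.fasta"))
  }

  panels <- qc_panels(qc, manifest)
  div <- diversity_table(panels, weighted = config$weighting == "reads")
  write_tsv(div, file.path(config$output_dir, "diversity_table.tsv"))

  fst <- list(); ibd <- NULL
  species_of <- manifest$species[match(vapply(panels, `[[`, "", "barcode"),
                                       manifest$barcode)]
  loci <- unique(vapply(panels, `[[`, "", "locus"))
  fst_matrices <- list()
  for (sp in unique(manifest$species)) {
    for (locus in loci) {
      sel <- panels[species_of == sp &
                    vapply(panels, `[[`, "", "locus") == locus]
      if (length(sel) < 2) next
      labels <- manifest$locality[match(vapply(sel, `[[`, "", "barcode"),
                                        manifest$barcode)]
      fm <- fst_matrix(sel, labels = labels, mode = config$fst_mode)
      fst[[paste(sp, locus, sep = ".")]] <- fm
      write_tsv(cbind(data.frame(locality = rownames(fm)), as.data.frame(fm)),
                file.path(config$output_dir,
                          paste0("fst_", sp, "_", locus, ".tsv")))
      if (nrow(fm) >= 3) fst_matrices[[sp]][[locus]] <- fm
    }
  }
  if (length(fst_matrices)) {
    ibd <- ibd_report(fst_matrices, manifest,
                      n_perm = config$mantel_permutations,
                      seed = config$seed)
    write_tsv(ibd, file.path(config$output_dir, "ibd_report.tsv"))
  }

  catalog <- allele_catalog(qc$variants, manifest)
  rep <- catalog_report(catalog)
  write_tsv(rep$allele_counts, file.path(config$output_dir,
                                         "allele_counts.tsv"))
  write_tsv(rep$frequencies, file.path(config$output_dir,
                                       "allele_frequencies.tsv"))
  jsonlite::write_json(catalog_summary(catalog),
                       file.path(config$output_dir, "catalog_summary.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(qc = qc, diversity = div, fst = fst, ibd = ibd,
                 catalog = catalog))
}

#' Read a variant table written by the pipeline
#'
#' @param path Path to a `variants.tsv`.
#' @return Variant table data frame.
#' @export
read_variants <- function(path) {
  v <- read_tsv(path)
  required <- c("variant_id", "locus", "sequence", "total_count")
  if (!all(required %in% names(v)))
    stop("not a variant table: ", path)
  for (bc in setdiff(names(v), c("variant_id", "locus", "sequence"))) {
    v[[bc]] <- as.integer(v[[bc]])
  }
  v
}

cli_usage <- function() {
  paste(
    "usage: poolmhc <simulate|qc|stats|diff|catalog|all> [options]",
    "  simulate --out DIR [--seed N] [--populations N] [--individuals N]",
    "           [--depth N] [--migration X] [--theta X] [--dnds X]",
    "  qc       --out DIR --manifest TSV --references FASTA FASTQ [FASTQ ...]",
    "  stats    --out DIR --manifest TSV --variants TSV",
    "  diff     --out DIR --manifest TSV --variants TSV [--seed N]",
    "  catalog  --out DIR --manifest TSV --variants TSV",
    "  all      --out DIR --manifest TSV --references FASTA FASTQ [FASTQ ...]",
    sep = "\n")
}

parse_cli_options <- function(args) {
  opts <- list(positional = character())
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- substring(a, 3)
      if (i == length(args) || startsWith(args[i + 1L], "--"))
        stop("missing value for --", key)
      opts[[key]] <- args[i + 1L]
      i <- i + 2L
    } else {
      opts$positional <- c(opts$positional, a)
      i <- i + 1L
    }
  }
  opts
}

#' Command-line entry point
#'
#' Dispatches the `simulate`, `qc` and `all` subcommands used by the
#' shipped `inst/scripts/poolmhc.R` wrapper. Every run writes its
#' serialized configuration into the output directory.
#'
#' @param args Character vector of command-line arguments (default:
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Exit status (0 on success), invisibly.
#' @export
pool_mhc_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) {
    message(cli_usage())
    return(invisible(1L))
  }
  sub <- args[1]
  opts <- parse_cli_options(args[-1])
  num <- function(x, default) if (is.null(x)) default else as.numeric(x)
  if (sub == "simulate") {
    if (is.null(opts$out)) stop("simulate needs --out")
    pos <- NULL
    np <- as.integer(num(opts$populations, 7))
    cfg_defaults <- sim_config()
    pos <- if (np == 7L) cfg_defaults$coastline_positions
           else seq(0, by = 500, length.out = np)
    cfg <- sim_config(
      n_populations = np,
      individuals_per_population = as.integer(num(opts$individuals, 25)),
      coastline_positions = pos,
      depth_per_individual = as.integer(num(opts$depth, 20)),
      migration_rate = num(opts$migration, 0.05),
      theta = num(opts$theta, 8),
      dnds_target = num(opts$dnds, 1),
      seed = as.integer(num(opts$seed, 1)))
    sim <- simulate_dataset(cfg)
    write_simulation(sim, opts$out)
    message("simulation written to ", opts$out)
    return(invisible(0L))
  }
  if (sub %in% c("qc", "all")) {
    if (is.null(opts$out) || is.null(opts$manifest) ||
        is.null(opts$references) || length(opts$positional) == 0L)
      stop("missing inputs; ", cli_usage())
    for (p in c(opts$manifest, opts$references, opts$positional)) {
      if (!file.exists(p)) stop("input not found: ", p)
    }
    fq <- opts$positional
    names(fq) <- sub("\\.(fastq|fq)(\\.gz)?$", "", basename(fq))
    cfg <- run_config(seed = as.integer(num(opts$seed, 1)),
                      output_dir = opts$out)
    if (sub == "qc") {
      manifest <- read_manifest(opts$manifest)
      dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
      write_run_config(cfg, cfg$output_dir)
      qc <- run_qc_pipeline(fq, opts$references, manifest, cfg$qc)
      write_tsv(qc$variants, file.path(cfg$output_dir, "variants.tsv"))
      write_tsv(qc$report, file.path(cfg$output_dir, "filter_report.tsv"))
    } else {
      run_pipeline(fq, opts$references, opts$manifest, cfg)
    }
    message("artifacts written to ", opts$out)
    return(invisible(0L))
  }
  if (sub %in% c("stats", "diff", "catalog")) {
    if (is.null(opts$out) || is.null(opts$manifest) || is.null(opts$variants))
      stop("missing inputs; ", cli_usage())
    for (p in c(opts$manifest, opts$variants)) {
      if (!file.exists(p)) stop("input not found: ", p)
    }
    manifest <- read_manifest(opts$manifest)
    variants <- read_variants(opts$variants)
    cfg <- run_config(seed = as.integer(num(opts$seed, 1)),
                      output_dir = opts$out)
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    write_run_config(cfg, cfg$output_dir)
    panels <- qc_panels(variants, manifest)
    if (sub == "stats") {
      div <- diversity_table(panels, weighted = cfg$weighting == "reads")
      write_tsv(div, file.path(cfg$output_dir, "diversity_table.tsv"))
    } else if (sub == "diff") {
      species_of <- manifest$species[match(vapply(panels, `[[`, "", "barcode"),
                                           manifest$barcode)]
      loci <- unique(vapply(panels, `[[`, "", "locus"))
      fst_matrices <- list()
      for (sp in unique(manifest$species)) {
        for (locus in loci) {
          sel <- panels[species_of == sp &
                        vapply(panels, `[[`, "", "locus") == locus]
          if (length(sel) < 3)
            stop("Mantel isolation-by-distance needs >= 3 localities per ",
                 "species (", sp, " has ", length(sel), " at ", locus, ")")
          labels <- manifest$locality[match(vapply(sel, `[[`, "", "barcode"),
                                            manifest$barcode)]
          fm <- fst_matrix(sel, labels = labels, mode = cfg$fst_mode)
          write_tsv(cbind(data.frame(locality = rownames(fm)),
                          as.data.frame(fm)),
                    file.path(cfg$output_dir,
                              paste0("fst_", sp, "_", locus, ".tsv")))
          fst_matrices[[sp]][[locus]] <- fm
        }
      }
      ibd <- ibd_report(fst_matrices, manifest,
                        n_perm = cfg$mantel_permutations, seed = cfg$seed)
      write_tsv(ibd, file.path(cfg$output_dir, "ibd_report.tsv"))
    } else {
      catalog <- allele_catalog(variants, manifest)
      rep <- catalog_report(catalog)
      write_tsv(rep$allele_counts,
                file.path(cfg$output_dir, "allele_counts.tsv"))
      write_tsv(rep$frequencies,
                file.path(cfg$output_dir, "allele_frequencies.tsv"))
      jsonlite::write_json(catalog_summary(catalog),
                           file.path(cfg$output_dir, "catalog_summary.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    message("artifacts written to ", opts$out)
    return(invisible(0L))
  }
  stop("unknown subcommand '", sub, "'\n", cli_usage())
}
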