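# Pipeline binding: configuration, file round-tripping, end-to-end runs.

#' Read / write FASTQ
#'
#' Thin wrappers around Biostrings' FASTQ support, exchanging the package's
#' read tables (`read_id`, `sequence`, `quality`; Phred+33).
#'
#' @param reads a read `data.table`.
#' @param path FASTQ path (gz-transparent on read).
#' @return `read_fastq()` returns a read `data.table`.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$read_id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$quality))
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.table::data.table(
    read_id = names(x),
    sequence = as.character(x),
    quality = as.character(S4Vectors::mcols(x)$qualities))
}

#' TSV round-trip helpers
#'
#' All pipeline tables are tab-separated text; unknown extra columns are
#' preserved on read.
#'
#' @param dt a data frame.
#' @param path file path.
#' @return `read_table_tsv()` returns a `data.table`.
#' @export
write_table_tsv <- function(dt, path) {
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path) {
  data.table::fread(path, sep = "\t")
}

#' Pipeline run configuration
#'
#' Collects every tunable of a pipeline run; the full configuration
#' (including the seed and all thresholds) is echoed to the output directory
#' so any figure-level number can be reproduced from the persisted
#' intermediates alone.
#'
#' @param substrate a [substrate_spec()] or path to a substrate JSON config.
#' @param mode `"simulate"`, `"analyze"`, `"quantify"`, or `"all"`.
#' @param outdir output directory (created if needed).
#' @param seed integer seed for all randomness.
#' @param kinetics a [kinetics_model()] (simulate).
#' @param n_molecules,harvest_time,oversampling_mean,error_rate library
#'   parameters (simulate).
#' @param barcode sample barcode (simulate); `barcode_table` named vector
#'   (analyze; defaults to `c(sample1 = barcode)`).
#' @param insertion_labels,window passed to [enumerate_expected_products()].
#' @param min_family_fraction,min_strand_fraction,n_input_templates filter
#'   parameters; `n_input_templates = NA` takes the simulated molecule count.
#' @param fastq input FASTQ (analyze without simulate).
#' @param sample,timepoint identifiers for the summary.
#' @param ct_csv,dpcr_csv quantification inputs (quantify).
#' @return an object of class `run_config`.
#' @export
run_config <- function(substrate, mode = c("all", "simulate", "analyze",
                                           "quantify"),
                       outdir, seed = 1L,
                       kinetics = kinetics_model(),
                       n_molecules = 1000L, harvest_time = 10,
                       oversampling_mean = 50, error_rate = 0.002,
                       barcode = "ACGTAC", barcode_table = NULL,
                       insertion_labels = character(), window = 40L,
                       min_family_fraction = 0.02, min_strand_fraction = 0.20,
                       n_input_templates = NA_integer_,
                       fastq = NULL, sample = "sample1", timepoint = NA_real_,
                       ct_csv = NULL, dpcr_csv = NULL) {
  mode <- match.arg(mode)
  if (is.character(substrate)) substrate <- read_substrate_config(substrate)
  stopifnot(inherits(substrate, "substrate_spec"))
  if (missing(outdir)) stop("outdir is required")
  if (is.null(barcode_table)) barcode_table <- c(sample1 = barcode)
  structure(list(substrate = substrate, mode = mode, outdir = outdir,
                 seed = as.integer(seed), kinetics = kinetics,
                 n_molecules = as.integer(n_molecules),
                 harvest_time = harvest_time,
                 oversampling_mean = oversampling_mean,
                 error_rate = error_rate, barcode = barcode,
                 barcode_table = barcode_table,
                 insertion_labels = insertion_labels, window = window,
                 min_family_fraction = min_family_fraction,
                 min_strand_fraction = min_strand_fraction,
                 n_input_templates = n_input_templates,
                 fastq = fastq, sample = sample, timepoint = timepoint,
                 ct_csv = ct_csv, dpcr_csv = dpcr_csv),
            class = "run_config")
}

config_echo <- function(config) {
  x <- unclass(config)
  x$substrate <- list(name = config$substrate$name)
  x$kinetics <- unclass(config$kinetics)
  x
}

summary_as_list <- function(s) {
  list(sample = s$sample, timepoint = s$timepoint,
       n_molecules = s$n_molecules,
       class_counts = as.list(s$class_counts),
       class_freq = as.list(s$class_freq),
       path_counts = as.list(s$path_counts),
       path_freq = as.list(s$path_freq),
       label_freq = lapply(s$label_freq, function(tb)
         as.list(stats::setNames(as.numeric(tb), names(tb)))))
}

#' Run the pipeline
#'
#' Executes the stages requested by the configuration's `mode`:
#' \describe{
#'   \item{simulate}{ground-truth kinetics simulation and read synthesis;
#'     writes `reads.fastq`, `truth.tsv`, `molecules.tsv`.}
#'   \item{analyze}{read annotation and duplex reconstruction; writes
#'     `annotated_reads.tsv`, `duplex_calls.tsv`, `summary.tsv`,
#'     `summary.json`.}
#'   \item{quantify}{Ct/droplet table processing; writes
#'     `fraction_rna.tsv` and/or `dpcr_concentration.tsv`.}
#' }
#' A `config.json` echo and a `run_log.json` with input counts, per-stage
#' drop counts, thresholds and the seed are always written. Reruns with the
#' same configuration and seed produce byte-identical outputs.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the key in-memory objects and the output
#'   directory.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  spec <- config$substrate
  products <- enumerate_expected_products(spec, config$insertion_labels,
                                          config$window)
  out <- list(outdir = config$outdir, products = products)
  log <- list(seed = config$seed, mode = config$mode,
              substrate = spec$name,
              package_version = as.character(utils::packageVersion("duplexrepair")))
  jsonlite::write_json(config_echo(config),
                       file.path(config$outdir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)

  do_sim <- config$mode %in% c("simulate", "all")
  do_ana <- config$mode %in% c("analyze", "all")
  do_qnt <- config$mode == "quantify"

  reads <- NULL
  if (do_sim) {
    states <- simulate_repair(spec, config$kinetics, config$n_molecules,
                              config$harvest_time)
    lib <- synthesize_reads(states, spec, products,
                            oversampling_mean = config$oversampling_mean,
                            error_rate = config$error_rate,
                            barcode = config$barcode)
    write_fastq(lib$reads, file.path(config$outdir, "reads.fastq"))
    write_table_tsv(lib$truth, file.path(config$outdir, "truth.tsv"))
    write_table_tsv(lib$molecules, file.path(config$outdir, "molecules.tsv"))
    log$n_molecules <- config$n_molecules
    log$n_reads_simulated <- nrow(lib$reads)
    out$states <- states
    out$library <- lib
    reads <- lib$reads
  }
  if (do_ana) {
    if (is.null(reads)) {
      fq <- config$fastq %||% file.path(config$outdir, "reads.fastq")
      if (!file.exists(fq)) stop("no FASTQ input: ", fq)
      reads <- read_fastq(fq)
    }
    if (nrow(reads) == 0L) stop("no reads")
    annotated <- annotate_reads(reads, spec, products,
                                barcode_table = config$barcode_table)
    write_table_tsv(annotated, file.path(config$outdir, "annotated_reads.tsv"))
    n_templates <- config$n_input_templates
    if (is.na(n_templates)) {
      if (!do_sim) stop("n_input_templates is required when analyzing ",
                        "external reads (measure it by digital PCR)")
      n_templates <- config$n_molecules
    }
    params <- filter_params(config$min_family_fraction,
                            config$min_strand_fraction, n_templates)
    recon <- reconstruct_duplexes(annotated, products, params,
                                  total_reads = nrow(reads))
    write_table_tsv(recon$calls, file.path(config$outdir, "duplex_calls.tsv"))
    summ <- summarize_repair(recon$calls, config$sample, config$timepoint)
    jsonlite::write_json(summary_as_list(summ),
                         file.path(config$outdir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    class_tab <- data.table::data.table(
      sample = config$sample, timepoint = config$timepoint,
      molecule_class = names(summ$class_counts),
      count = as.integer(summ$class_counts),
      freq = as.numeric(summ$class_freq))
    write_table_tsv(class_tab, file.path(config$outdir, "summary.tsv"))
    log <- c(log, attr(annotated, "run_log"), recon$log)
    out$annotated <- annotated
    out$calls <- recon$calls
    out$summary <- summ
  }
  if (do_qnt) {
    if (!is.null(config$ct_csv)) {
      ct <- read_ct_csv(config$ct_csv)
      wide <- data.table::dcast(
        ct[treatment %in% c("mock", "alkali")],
        sample + target + strand ~ treatment, value.var = "ct")
      if (!all(c("mock", "alkali") %in% names(wide)))
        stop("Ct table must contain mock and alkali treatments")
      wide[, fraction_rna := fraction_rna(mock, alkali)]
      write_table_tsv(wide, file.path(config$outdir, "fraction_rna.tsv"))
      out$fraction_rna <- wide
    }
    if (!is.null(config$dpcr_csv)) {
      dp <- read_dpcr_csv(config$dpcr_csv)
      dp[, lambda := -log(1 - positives / total)]
      write_table_tsv(dp, file.path(config$outdir, "dpcr_concentration.tsv"))
      out$dpcr <- dp
    }
    if (is.null(config$ct_csv) && is.null(config$dpcr_csv))
      stop("quantify mode needs ct_csv and/or dpcr_csv")
  }
  jsonlite::write_json(log, file.path(config$outdir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  out$log <- log
  invisible(out)
}
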