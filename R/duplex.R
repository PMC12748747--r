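# UMI-family grouping, the oversampling-ratio (2%) and minor-strand (20%)
# filters, per-molecule consensus and repair-path classification.

#' Filter parameters for duplex reconstruction
#'
#' @param min_family_fraction a UMI family is kept only if its read count is
#'   at least this fraction of the mean oversampling ratio
#'   (total reads / input template molecules); families strictly below the
#'   threshold are excluded. Default 0.02 (the "2% rule").
#' @param min_strand_fraction within a family, a strand is dropped if its
#'   read count is strictly less than this fraction of the family's total.
#'   Default 0.20 (the "20% rule").
#' @param n_input_templates number of input duplex molecules in the library,
#'   as measured by digital PCR (or taken from simulation truth). The 2%
#'   rule is undefined without it.
#' @return an object of class `filter_params`.
#' @export
filter_params <- function(min_family_fraction = 0.02,
                          min_strand_fraction = 0.20,
                          n_input_templates) {
  if (min_family_fraction <= 0 || min_family_fraction >= 1 ||
      min_strand_fraction <= 0 || min_strand_fraction >= 1)
    stop("filter fractions must be in (0, 1)")
  if (missing(n_input_templates) || n_input_templates < 1)
    stop("n_input_templates must be >= 1")
  structure(list(min_family_fraction = min_family_fraction,
                 min_strand_fraction = min_strand_fraction,
                 n_input_templates = as.integer(n_input_templates)),
            class = "filter_params")
}

#' Group annotated reads into UMI families
#'
#' UMIs are grouped by exact string match (no clustering); reads with an
#' undetermined strand are excluded first and counted in the log.
#'
#' @param annotated an [annotate_reads()] table.
#' @return an object of class `umi_families`: `reads` (the retained reads),
#'   `families` (`umi`, `n_top`, `n_bottom`, `n_total`), and `log`.
#' @export
group_by_umi <- function(annotated) {
  annotated <- data.table::as.data.table(annotated)
  n0 <- nrow(annotated)
  reads <- annotated[strand %in% c("top", "bottom") & !is.na(umi)]
  fam <- reads[, .(n_top = sum(strand == "top"),
                   n_bottom = sum(strand == "bottom")), by = "umi"]
  fam[, n_total := n_top + n_bottom]
  structure(list(reads = reads, families = fam,
                 log = list(n_reads_in = n0,
                            n_excluded_undetermined = n0 - nrow(reads),
                            n_families = nrow(fam))),
            class = "umi_families")
}

#' Apply the oversampling-ratio family filter (2% rule)
#'
#' The mean oversampling ratio is `total_reads / n_input_templates`; a family
#' is excluded iff its read count is strictly less than
#' `min_family_fraction` times that ratio.
#'
#' @param families a [group_by_umi()] object.
#' @param total_reads total reads in the library (before any exclusion).
#' @param params a [filter_params()].
#' @return the `umi_families` object with dropped families removed; the
#'   threshold and drop count are appended to its `log`.
#' @export
filter_families <- function(families, total_reads, params) {
  stopifnot(inherits(families, "umi_families"), inherits(params, "filter_params"))
  if (params$n_input_templates == 0L) stop("n_input_templates must be >= 1")
  if (total_reads < sum(families$families$n_total))
    stop("total_reads is smaller than the number of grouped reads")
  mean_oversampling <- total_reads / params$n_input_templates
  threshold <- params$min_family_fraction * mean_oversampling
  keep <- families$families$n_total >= threshold   # strictly-less excluded
  kept_umis <- families$families$umi[keep]
  families$families <- families$families[keep]
  families$reads <- families$reads[umi %in% kept_umis]
  families$log <- c(families$log,
                    list(mean_oversampling = mean_oversampling,
                         family_threshold = threshold,
                         n_families_dropped = sum(!keep)))
  families
}

#' Apply the minor-strand filter (20% rule)
#'
#' Within each family, a strand's reads are dropped iff that strand's count
#' is strictly less than `min_strand_fraction` of the family's read sum. The
#' larger strand always holds at least half the reads, so at most one strand
#' can be dropped.
#'
#' @param families a [group_by_umi()] (usually [filter_families()]) object.
#' @param params a [filter_params()].
#' @return the `umi_families` object with minor-strand reads removed and
#'   per-family counts updated.
#' @export
filter_strands <- function(families, params) {
  stopifnot(inherits(families, "umi_families"), inherits(params, "filter_params"))
  fam <- families$families
  frac <- params$min_strand_fraction
  drop_top <- fam$n_top > 0L & fam$n_top < frac * fam$n_total
  drop_bottom <- fam$n_bottom > 0L & fam$n_bottom < frac * fam$n_total
  drop <- data.table::data.table(
    umi = c(fam$umi[drop_top], fam$umi[drop_bottom]),
    strand = c(rep("top", sum(drop_top)), rep("bottom", sum(drop_bottom))))
  if (nrow(drop) > 0L) {
    families$reads <- families$reads[!drop, on = c("umi", "strand")]
    fam <- families$reads[, .(n_top = sum(strand == "top"),
                              n_bottom = sum(strand == "bottom")), by = "umi"]
    fam[, n_total := n_top + n_bottom]
    families$families <- fam[families$families$umi, on = "umi"]
    data.table::setnafill(families$families,
                          fill = 0L, cols = c("n_top", "n_bottom", "n_total"))
  }
  families$log <- c(families$log, list(n_strands_dropped = nrow(drop)))
  families
}

#' Call per-strand consensus junction labels
#'
#' For each family and strand with retained reads, the consensus is the
#' plurality junction label; a tie between labels gives `"ambiguous"`.
#'
#' @param families a filtered `umi_families` object.
#' @return `data.table` with `umi`, `n_top`, `n_bottom`, `consensus_top`,
#'   `consensus_bottom` (`NA` for strands without retained reads).
#' @export
call_consensus <- function(families) {
  stopifnot(inherits(families, "umi_families"))
  plurality <- function(labels) {
    labels <- labels[!is.na(labels)]
    if (length(labels) == 0L) return(NA_character_)
    tab <- sort(table(labels), decreasing = TRUE)
    if (length(tab) > 1L && tab[1L] == tab[2L]) "ambiguous" else names(tab)[1L]
  }
  cons <- families$reads[, .(
    consensus_top = plurality(label[strand == "top"]),
    consensus_bottom = plurality(label[strand == "bottom"])), by = "umi"]
  out <- cons[families$families, on = "umi"]
  data.table::setcolorder(out, c("umi", "n_top", "n_bottom",
                                 "consensus_top", "consensus_bottom"))
  out[, c("umi", "n_top", "n_bottom", "consensus_top", "consensus_bottom")]
}

# path possibilities for candidate label sets (after splitting joint labels)
possible_paths <- function(top_labels, bottom_labels) {
  m1 <- FALSE; m2 <- FALSE
  for (a in top_labels) for (b in bottom_labels) {
    if (a == "unclassified" || b == "unclassified") next
    if (is_autonomous_label(a) && is_autonomous_label(b)) m1 <- TRUE
    if (b == paste0("model2_copy_of_", a) ||
        a == paste0("model2_copy_of_", b)) m2 <- TRUE
  }
  c(model1 = m1, model2 = m2)
}

#' Classify molecules from consensus labels
#'
#' Each surviving UMI becomes one duplex call: `molecule_class` records which
#' strands have a non-ambiguous consensus (`both_joined`, `top_only`,
#' `bottom_only`, `ambiguous`), and for both-joined molecules `path` is
#' `model1` if the two labels are strand-autonomous products (direct or
#' ins:*), `model2` if one label is the semi-conservative copy of the other,
#' and `indeterminate` when the labels are degenerate between the two paths
#' or match neither pattern.
#'
#' @param consensus a [call_consensus()] table.
#' @param products an [enumerate_expected_products()] result.
#' @return `data.table`: `umi`, `top_label`, `bottom_label`,
#'   `molecule_class`, `path`.
#' @export
classify_molecules <- function(consensus, products) {
  top_ok <- !is.na(consensus$consensus_top) &
    consensus$consensus_top != "ambiguous"
  bot_ok <- !is.na(consensus$consensus_bottom) &
    consensus$consensus_bottom != "ambiguous"
  mol_class <- ifelse(top_ok & bot_ok, "both_joined",
                ifelse(top_ok, "top_only",
                 ifelse(bot_ok, "bottom_only", "ambiguous")))
  path <- rep("not_applicable", nrow(consensus))
  both <- which(mol_class == "both_joined")
  for (i in both) {
    pp <- possible_paths(split_label(consensus$consensus_top[i]),
                         split_label(consensus$consensus_bottom[i]))
    path[i] <- if (pp["model1"] && !pp["model2"]) "model1"
      else if (pp["model2"] && !pp["model1"]) "model2"
      else "indeterminate"
  }
  data.table::data.table(umi = consensus$umi,
                         top_label = consensus$consensus_top,
                         bottom_label = consensus$consensus_bottom,
                         molecule_class = mol_class,
                         path = path)
}

#' Reconstruct duplex molecules from annotated reads
#'
#' Convenience wrapper: [group_by_umi()] then [filter_families()],
#' [filter_strands()], [call_consensus()], [classify_molecules()].
#'
#' @param annotated an [annotate_reads()] table.
#' @param products an [enumerate_expected_products()] result.
#' @param params a [filter_params()].
#' @param total_reads total reads in the library; defaults to
#'   `nrow(annotated)`.
#' @return list with `calls` (the duplex-call table), `families` (the
#'   filtered `umi_families`), and `log`.
#' @export
reconstruct_duplexes <- function(annotated, products, params,
                                 total_reads = nrow(annotated)) {
  fams <- group_by_umi(annotated)
  fams <- filter_families(fams, total_reads, params)
  fams <- filter_strands(fams, params)
  cons <- call_consensus(fams)
  calls <- classify_molecules(cons, products)
  list(calls = calls, families = fams, log = fams$log)
}

#' Summarise duplex calls
#'
#' Frequency table over molecule classes, repair paths among both-joined
#' molecules, and per-strand product labels among joined strands.
#'
#' @param calls a [classify_molecules()] table.
#' @param sample,timepoint identifiers recorded in the summary.
#' @return an object of class `repair_summary`.
#' @export
summarize_repair <- function(calls, sample = "sample1", timepoint = NA_real_) {
  if (nrow(calls) == 0L) stop("no duplex calls to summarise")
  n <- nrow(calls)
  classes <- c("both_joined", "top_only", "bottom_only", "ambiguous")
  class_counts <- vapply(classes, function(cl) sum(calls$molecule_class == cl),
                         integer(1))
  both <- calls[calls$molecule_class == "both_joined"]
  paths <- c("model1", "model2", "indeterminate")
  path_counts <- vapply(paths, function(p) sum(both$path == p), integer(1))
  lab_freq <- function(strand) {
    keep <- calls$molecule_class %in%
      c("both_joined", paste0(strand, "_only"))
    labs <- calls[[paste0(strand, "_label")]][keep]
    labs <- labs[!is.na(labs)]
    if (length(labs) == 0L) return(table(character(0)))
    table(labs) / length(labs)
  }
  structure(list(sample = sample, timepoint = timepoint,
                 n_molecules = n,
                 class_counts = class_counts,
                 class_freq = class_counts / n,
                 path_counts = path_counts,
                 path_freq = if (sum(class_counts["both_joined"]) > 0)
                   path_counts / class_counts[["both_joined"]]
                 else path_counts * NA_real_,
                 label_freq = list(top = lab_freq("top"),
                                   bottom = lab_freq("bottom"))),
            class = "repair_summary")
}

#' @export
print.repair_summary <- function(x, ...) {
  cat(sprintf("<repair_summary> sample %s, t = %s min, %d molecules\n",
              x$sample, format(x$timepoint), x$n_molecules))
  cat("molecule classes:\n")
  print(round(x$class_freq, 4))
  cat("paths among both-joined:\n")
  print(round(x$path_freq, 4))
  invisible(x)
}

#' Model-1 : model-2 preference ratio
#'
#' Ratio of model-1 to model-2 frequencies among both-joined molecules (and
#' its inverse). Indeterminate-path molecules are excluded from numerator
#' and denominator and reported separately; a zero denominator is flagged,
#' not an error.
#'
#' @param summary a [summarize_repair()] object.
#' @return list with `model1_over_model2`, `model2_over_model1`, the counts,
#'   and `flag` (`"ok"`, `"no_model2"`, `"no_model1"`, or `"no_calls"`).
#' @export
preference_ratio <- function(summary) {
  stopifnot(inherits(summary, "repair_summary"))
  n1 <- summary$path_counts[["model1"]]
  n2 <- summary$path_counts[["model2"]]
  flag <- if (n1 + n2 == 0L) "no_calls"
    else if (n2 == 0L) "no_model2"
    else if (n1 == 0L) "no_model1"
    else "ok"
  list(model1_over_model2 = if (n2 > 0L) n1 / n2 else Inf,
       model2_over_model1 = if (n1 > 0L) n2 / n1 else Inf,
       n_model1 = n1, n_model2 = n2,
       n_indeterminate = summary$path_counts[["indeterminate"]],
       flag = flag)
}
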