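# Stochastic two-strand repair kinetics and synthetic duplex-sequencing reads.
#
# Joining of each strand break is modelled as a continuous-time exponential
# hazard. In parallel/independent mode ("model 1") the two strand breaks are
# joined independently; in ordered mode ("model 2") the second strand break's
# clock only starts once the first strand has joined, and its product is the
# semi-conservative copy of the first strand's product.

#' Kinetics model for two-strand repair
#'
#' @param mode `"parallel_independent"` (model 1) or `"ordered"` (model 2).
#' @param k_top,k_bottom joining hazards (per minute) of the top/bottom strand
#'   break. In ordered mode these are the candidate first-strand hazards.
#' @param k_second ordered mode only: hazard of the second strand break,
#'   active from the moment the first strand joins.
#' @param first_strand ordered mode: `"top"`, `"bottom"`, or `"either"`
#'   (competing `k_top` vs `k_bottom` per molecule).
#' @param insertion_probs named probabilities over first-strand product
#'   labels (`"direct"`, `"ins:C"`, ...); must sum to 1.
#' @param p_ribo probability that an inserted nucleotide is a ribonucleotide.
#' @param k_rer hazard (per minute) of ribonucleotide excision repair
#'   replacing an embedded ribonucleotide after joining.
#' @return an object of class `kinetics_model`.
#' @export
kinetics_model <- function(mode = c("parallel_independent", "ordered"),
                           k_top = 0.3, k_bottom = 0.3, k_second = 0.15,
                           first_strand = c("either", "top", "bottom"),
                           insertion_probs = c(direct = 1),
                           p_ribo = 0, k_rer = 0) {
  mode <- match.arg(mode)
  first_strand <- match.arg(first_strand)
  if (any(c(k_top, k_bottom, k_second, k_rer) < 0))
    stop("hazards must be >= 0")
  if (p_ribo < 0 || p_ribo > 1) stop("p_ribo must be in [0, 1]")
  if (is.null(names(insertion_probs)) || any(!nzchar(names(insertion_probs))))
    stop("insertion_probs must be a named vector of product labels")
  if (abs(sum(insertion_probs) - 1) > 1e-8)
    stop("insertion_probs must sum to 1")
  structure(list(mode = mode, k_top = k_top, k_bottom = k_bottom,
                 k_second = k_second, first_strand = first_strand,
                 insertion_probs = insertion_probs,
                 p_ribo = p_ribo, k_rer = k_rer),
            class = "kinetics_model")
}

rexp_or_inf <- function(n, rate) {
  if (rate <= 0) rep(Inf, n) else stats::rexp(n, rate)
}

#' Simulate ground-truth repair of duplex molecules
#'
#' Draws per-strand join times from the kinetics model, assigns product
#' labels, and applies ribonucleotide marking with subsequent excision-repair
#' decay: a ribonucleotide embedded at `join_time` is still present at
#' harvest with probability `exp(-k_rer * (harvest_time - join_time))`.
#'
#' @param spec a [substrate_spec()] (recorded for provenance).
#' @param kinetics a [kinetics_model()].
#' @param n_molecules number of duplex molecules.
#' @param harvest_time harvest time in minutes.
#' @param seed optional integer seed (`set.seed` if non-NULL).
#' @return a `data.table` with one row per molecule: `molecule_id`,
#'   and per strand `*_joined`, `*_label`, `*_ribo`, `*_time`.
#' @export
simulate_repair <- function(spec, kinetics, n_molecules, harvest_time,
                            seed = NULL) {
  stopifnot(inherits(kinetics, "kinetics_model"))
  if (n_molecules < 1L) stop("n_molecules must be >= 1")
  if (harvest_time < 0) stop("harvest_time must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_molecules)
  k <- kinetics
  labels <- names(k$insertion_probs)

  draw_labels <- function(n) {
    if (length(labels) == 1L) rep(labels, n)
    else sample(labels, n, replace = TRUE, prob = k$insertion_probs)
  }
  ribo_state <- function(lab, t_join) {
    # only inserted nucleotides can be ribonucleotides
    ribo <- startsWith(lab, "ins:") & stats::runif(length(lab)) < k$p_ribo
    keep <- stats::runif(length(lab)) <
      exp(-k$k_rer * pmax(harvest_time - t_join, 0))
    ribo & keep
  }

  if (k$mode == "parallel_independent") {
    t_top <- rexp_or_inf(n, k$k_top)
    t_bot <- rexp_or_inf(n, k$k_bottom)
    top_joined <- t_top <= harvest_time
    bot_joined <- t_bot <= harvest_time
    top_label <- ifelse(top_joined, draw_labels(n), NA_character_)
    bot_label <- ifelse(bot_joined, draw_labels(n), NA_character_)
    top_ribo <- top_joined & ribo_state(ifelse(top_joined, top_label, ""), t_top)
    bot_ribo <- bot_joined & ribo_state(ifelse(bot_joined, bot_label, ""), t_bot)
    out <- data.table::data.table(
      molecule_id = seq_len(n),
      top_joined = top_joined,
      top_label = top_label,
      top_ribo = top_ribo,
      top_time = ifelse(top_joined, t_top, NA_real_),
      bottom_joined = bot_joined,
      bottom_label = bot_label,
      bottom_ribo = bot_ribo,
      bottom_time = ifelse(bot_joined, t_bot, NA_real_))
  } else {
    first <- switch(k$first_strand,
      top = rep("top", n),
      bottom = rep("bottom", n),
      either = {
        tt <- rexp_or_inf(n, k$k_top); tb <- rexp_or_inf(n, k$k_bottom)
        ifelse(tt <= tb, "top", "bottom")
      })
    k1 <- ifelse(first == "top", k$k_top, k$k_bottom)
    t1 <- stats::rexp(n) / ifelse(k1 > 0, k1, NA_real_)
    t1[is.na(t1)] <- Inf
    t2 <- t1 + rexp_or_inf(n, k$k_second)
    j1 <- t1 <= harvest_time
    j2 <- t2 <= harvest_time           # implies j1
    lab1 <- ifelse(j1, draw_labels(n), NA_character_)
    lab2 <- ifelse(j2, paste0("model2_copy_of_", lab1), NA_character_)
    ribo1 <- j1 & ribo_state(ifelse(j1, lab1, ""), t1)
    is_top_first <- first == "top"
    out <- data.table::data.table(
      molecule_id = seq_len(n),
      top_joined = ifelse(is_top_first, j1, j2),
      top_label = ifelse(is_top_first, lab1, lab2),
      top_ribo = is_top_first & ribo1,
      top_time = ifelse(is_top_first, ifelse(j1, t1, NA_real_),
                        ifelse(j2, t2, NA_real_)),
      bottom_joined = ifelse(is_top_first, j2, j1),
      bottom_label = ifelse(is_top_first, lab2, lab1),
      bottom_ribo = (!is_top_first) & ribo1,
      bottom_time = ifelse(is_top_first, ifelse(j2, t2, NA_real_),
                           ifelse(j1, t1, NA_real_)))
    out$first_strand <- ifelse(j1, first, NA_character_)
  }
  data.table::setattr(out, "harvest_time", harvest_time)
  out[]
}

#' Repaired strand sequences of one molecule
#'
#' Only a ligated strand yields a junction-spanning amplicon: unjoined
#' strands are absent from the result.
#'
#' @param state one row of a [simulate_repair()] table (list or 1-row
#'   data.frame).
#' @param spec a [substrate_spec()].
#' @param products an [enumerate_expected_products()] result for `spec`.
#' @return named list mapping `"top"`/`"bottom"` to the full repaired-strand
#'   sequence.
#' @export
render_strand_sequences <- function(state, spec, products) {
  state <- as.list(state)
  out <- list()
  for (strand in c("top", "bottom")) {
    if (!isTRUE(state[[paste0(strand, "_joined")]])) next
    lab <- state[[paste0(strand, "_label")]]
    tab <- strand_products(products, strand)
    hit <- which(tab$label == lab)
    if (length(hit) != 1L)
      stop("product label '", lab, "' not enumerated for ", strand, " strand")
    out[[strand]] <- tab$full_seq[hit]
  }
  out
}

#' Adapter and read layout
#'
#' Synthetic reads are laid out as
#' `phasing (0-5 random nt) | barcode (6 nt) | UMI | adapter flank | insert`,
#' with the insert the full rendered repaired-strand sequence. The constant
#' adapter flank anchors UMI extraction; the random phasing bases shift the
#' barcode by 0-5 positions, as sequencing primers with phasing bases do.
#'
#' @param umi_length UMI length in nt (default 10).
#' @param flank constant adapter sequence between UMI and insert.
#' @param barcode_length sample barcode length (default 6).
#' @param phasing_max maximum number of random phasing bases (default 5).
#' @return a list of layout constants, class `adapter_layout`.
#' @export
adapter_layout <- function(umi_length = 10L, flank = "ACACGACGCTCT",
                           barcode_length = 6L, phasing_max = 5L) {
  stopifnot(is_dna(flank), nzchar(flank))
  structure(list(umi_length = as.integer(umi_length), flank = toupper(flank),
                 barcode_length = as.integer(barcode_length),
                 phasing_max = as.integer(phasing_max)),
            class = "adapter_layout")
}

#' Number of distinct UMIs of the adapter model
#'
#' @param umi_length UMI length in nt.
#' @return `4 ^ umi_length`.
#' @export
umi_space_size <- function(umi_length = 10L) 4^as.integer(umi_length)

#' Synthesize UMI-tagged amplicon reads
#'
#' One UMI is drawn uniformly per molecule (the double-stranded adapter) and
#' shared by the reads of both of its strands. Each joined strand receives a
#' Poisson(`oversampling_mean`) number of reads; substitution errors are
#' applied i.i.d. at `error_rate` over the entire read.
#'
#' @param states a [simulate_repair()] table.
#' @param spec a [substrate_spec()].
#' @param products an [enumerate_expected_products()] result for `spec`.
#' @param oversampling_mean expected reads per joined strand (> 0).
#' @param error_rate per-base substitution probability (in `[0, 0.5)`).
#' @param barcode 6-nt sample barcode.
#' @param layout an [adapter_layout()].
#' @param seed optional integer seed.
#' @param overdispersion optional negative-binomial size parameter for the
#'   per-strand read count (default `NULL`: Poisson).
#' @param exact_coverage if `TRUE`, every joined strand receives exactly
#'   `round(oversampling_mean)` reads instead of a Poisson draw (useful for
#'   deterministic fixtures).
#' @return list with elements `reads` (`data.table`: `read_id`, `sequence`,
#'   `quality`), `truth` (`read_id`, `molecule_id`, `strand`,
#'   `product_label`, `ribo_flag`, `umi`), and `molecules` (`molecule_id`,
#'   `umi`).
#' @export
synthesize_reads <- function(states, spec, products, oversampling_mean,
                             error_rate = 0, barcode = "ACGTAC",
                             layout = adapter_layout(), seed = NULL,
                             overdispersion = NULL, exact_coverage = FALSE) {
  if (oversampling_mean <= 0) stop("oversampling_mean must be > 0")
  if (error_rate < 0 || error_rate >= 0.5)
    stop("error_rate must be in [0, 0.5)")
  if (!is_dna(barcode) || nchar(barcode) != layout$barcode_length)
    stop("barcode must be a ", layout$barcode_length, "-nt A/C/G/T string")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(states)
  umis <- rand_dna(n, layout$umi_length)
  molecules <- data.table::data.table(molecule_id = states$molecule_id,
                                      umi = umis)

  seq_tab <- strand_products(products, "top")[, c("label", "full_seq")]
  seq_tab_b <- strand_products(products, "bottom")[, c("label", "full_seq")]

  strand_reads <- function(strand) {
    joined <- which(states[[paste0(strand, "_joined")]])
    if (length(joined) == 0L) return(NULL)
    lab <- states[[paste0(strand, "_label")]][joined]
    tab <- if (strand == "top") seq_tab else seq_tab_b
    idx <- match(lab, tab$label)
    if (anyNA(idx))
      stop("simulated label(s) missing from expected products: ",
           paste(unique(lab[is.na(idx)]), collapse = ", "))
    counts <- if (exact_coverage)
      rep(as.integer(round(oversampling_mean)), length(joined))
    else if (is.null(overdispersion))
      stats::rpois(length(joined), oversampling_mean)
    else
      stats::rnbinom(length(joined), size = overdispersion,
                     mu = oversampling_mean)
    rep_i <- rep(seq_along(joined), counts)
    if (length(rep_i) == 0L) return(NULL)
    data.table::data.table(
      molecule_id = states$molecule_id[joined][rep_i],
      strand = strand,
      product_label = lab[rep_i],
      ribo_flag = states[[paste0(strand, "_ribo")]][joined][rep_i],
      umi = umis[joined][rep_i],
      insert = tab$full_seq[idx][rep_i])
  }
  truth <- data.table::rbindlist(
    Filter(Negate(is.null), lapply(c("top", "bottom"), strand_reads)))
  if (nrow(truth) == 0L) {
    return(list(reads = data.table::data.table(read_id = character(0),
                                               sequence = character(0),
                                               quality = character(0)),
                truth = data.table::data.table(
                  read_id = character(0), molecule_id = integer(0),
                  strand = character(0), product_label = character(0),
                  ribo_flag = logical(0), umi = character(0)),
                molecules = molecules))
  }
  nr <- nrow(truth)
  phas_len <- sample.int(layout$phasing_max + 1L, nr, replace = TRUE) - 1L
  phas_full <- rand_dna(nr, layout$phasing_max)
  phas <- substr(phas_full, 1L, phas_len)
  raw <- paste0(phas, barcode, truth$umi, layout$flank, truth$insert)
  seqs <- mutate_seq_cpp(raw, error_rate)
  truth[, insert := NULL]
  truth[, read_id := sprintf("r%08d", seq_len(nr))]
  data.table::setcolorder(truth, c("read_id", "molecule_id", "strand",
                                   "product_label", "ribo_flag", "umi"))
  reads <- data.table::data.table(read_id = truth$read_id, sequence = seqs,
                                  quality = strrep("?", nchar(seqs)))
  list(reads = reads, truth = truth, molecules = molecules)
}

#' Split pre-merged reads into overlapping mates
#'
#' Utility to exercise the read merger: mate 1 is the first `mate_length`
#' bases of each read, mate 2 the reverse complement of the last
#' `mate_length` bases (inward orientation).
#'
#' @param reads a `reads` table from [synthesize_reads()].
#' @param mate_length mate length; must exceed half the read length for the
#'   mates to overlap.
#' @return list of two `data.table`s, `mate1` and `mate2`.
#' @export
split_into_pairs <- function(reads, mate_length) {
  L <- nchar(reads$sequence)
  if (any(mate_length >= L))
    stop("mate_length must be shorter than the reads")
  m1 <- substr(reads$sequence, 1L, mate_length)
  m2 <- revcomp(substr(reads$sequence, L - mate_length + 1L, L))
  q1 <- substr(reads$quality, 1L, mate_length)
  q2 <- vapply(substr(reads$quality, L - mate_length + 1L, L),
               function(q) paste(rev(strsplit(q, "")[[1]]), collapse = ""),
               character(1), USE.NAMES = FALSE)
  list(mate1 = data.table::data.table(read_id = reads$read_id, sequence = m1,
                                      quality = q1),
       mate2 = data.table::data.table(read_id = reads$read_id, sequence = m2,
                                      quality = q2))
}

#' Emulate the mock/alkali qPCR pair for a ribonucleotide fraction
#'
#' Alkali cleaves templates with embedded ribonucleotides, so only the
#' `1 - frac_ribo` DNA-only fraction amplifies:
#' `ct_alkali - ct_mock = -log2(1 - frac_ribo)` (plus optional Gaussian Ct
#' noise). The exact inverse of [fraction_rna()] at zero noise.
#'
#' @param n_templates template molecules in the mock reaction (sets the
#'   absolute mock Ct as `40 - log2(n_templates)`).
#' @param frac_ribo fraction of templates carrying a ribonucleotide, in
#'   `[0, 1)`; 1 is censored (alkali leaves no template) and raises an error.
#' @param noise_sd Gaussian Ct noise standard deviation (default 0).
#' @param seed optional integer seed.
#' @return list with `ct_mock` and `ct_alkali`.
#' @export
emulate_alkali_qpcr <- function(n_templates, frac_ribo, noise_sd = 0,
                                seed = NULL) {
  if (n_templates < 1L) stop("n_templates must be >= 1")
  if (frac_ribo < 0 || frac_ribo > 1) stop("frac_ribo must be in [0, 1]")
  if (frac_ribo == 1)
    stop("frac_ribo = 1 is censored: alkali leaves no amplifiable template")
  if (!is.null(seed)) set.seed(seed)
  ct_mock <- 40 - log2(n_templates) + stats::rnorm(1L, 0, noise_sd)
  ct_alkali <- ct_mock - log2(1 - frac_ribo) + stats::rnorm(1L, 0, noise_sd)
  list(ct_mock = ct_mock, ct_alkali = ct_alkali)
}
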