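# Bulk quantification arithmetic: spike-in normalised qPCR fold changes,
# droplet digital PCR Poisson occupancy, the alkali fraction-RNA formula,
# and time-course scaling. All functions are pure.

#' Spike-in normalised relative abundance (2^-ddCt)
#'
#' Each sample's target Ct is first normalised to its spike-in control
#' (electroporation/recovery normalisation), then compared with a reference
#' condition on the log2 scale before transformation to linear scale:
#' `2^-((ct - spike_ct) - (ref_ct - ref_spike_ct))`.
#'
#' @param ct,spike_ct sample target and spike-in Ct.
#' @param ref_ct,ref_spike_ct reference-condition target and spike-in Ct.
#' @param efficiency amplification factor per cycle (default 2).
#' @return fold change relative to the reference.
#' @export
relative_abundance <- function(ct, spike_ct, ref_ct, ref_spike_ct,
                               efficiency = 2) {
  stopifnot(all(is.finite(c(ct, spike_ct, ref_ct, ref_spike_ct))))
  efficiency^-((ct - spike_ct) - (ref_ct - ref_spike_ct))
}

#' Fraction of templates with embedded RNA (alkali sensitivity)
#'
#' `fraction RNA = 1 - 2^(Ct_mock - Ct_alkali)`: alkali cleavage removes
#' ribonucleotide-containing templates, raising the alkali Ct relative to
#' mock in proportion to the surviving DNA-only fraction. Negative values
#' (alkali Ct below mock, i.e. noise) are clamped to 0 with a warning by
#' default.
#'
#' @param ct_mock,ct_alkali threshold cycles of mock- and alkali-treated
#'   aliquots.
#' @param clamp clamp negative fractions to 0 (default TRUE).
#' @return fraction in `[0, 1]` (or possibly negative if `clamp = FALSE`).
#' @export
fraction_rna <- function(ct_mock, ct_alkali, clamp = TRUE) {
  stopifnot(all(is.finite(c(ct_mock, ct_alkali))))
  f <- 1 - 2^(ct_mock - ct_alkali)
  if (clamp && any(f < 0)) {
    warning("negative fraction RNA clamped to 0 (alkali Ct below mock)")
    f <- pmax(f, 0)
  }
  f
}

#' Droplet counts for digital PCR
#'
#' @param positives positive droplets.
#' @param total total accepted droplets.
#' @param droplet_volume droplet volume in microliters; default `0.85e-3`
#'   (0.85 nL, the droplet-reader standard).
#' @return an object of class `dpcr_counts`.
#' @export
dpcr_counts <- function(positives, total, droplet_volume = 0.85e-3) {
  if (total <= 0 || positives < 0 || positives > total)
    stop("need 0 <= positives <= total and total > 0")
  structure(list(positives = positives, total = total,
                 droplet_volume = droplet_volume),
            class = "dpcr_counts")
}

#' Poisson concentration estimate from droplet occupancy
#'
#' Inverts the droplet occupancy map `p = 1 - exp(-lambda)`:
#' `lambda = -ln(1 - positives/total)` copies per droplet, and
#' `lambda / droplet_volume` copies per microliter (`droplet_volume` in uL).
#'
#' @param counts a [dpcr_counts()].
#' @return list with `lambda` (copies/droplet), `copies_per_ul`, and
#'   `saturated` (TRUE when every droplet is positive, leaving no finite
#'   estimate).
#' @export
dpcr_concentration <- function(counts) {
  stopifnot(inherits(counts, "dpcr_counts"))
  if (counts$positives == counts$total)
    return(list(lambda = Inf, copies_per_ul = Inf, saturated = TRUE))
  lambda <- -log(1 - counts$positives / counts$total)
  list(lambda = lambda, copies_per_ul = lambda / counts$droplet_volume,
       saturated = FALSE)
}

#' Bottom:top strand ratio (fraction of both strands joined)
#'
#' The abundance of bottom strands carrying the sequence complementary to
#' the top-strand product, divided by the abundance of the top-strand
#' product itself - the digital-PCR readout of how many first-strand repair
#' events have completed second-strand repair. Accepts raw droplet counts
#' (converted via [dpcr_concentration()]; droplet volume cancels) or
#' pre-computed copy numbers.
#'
#' @param bottom,top [dpcr_counts()] objects or numeric copy numbers.
#' @return list with `ratio` and `flag` (`"ok"`, `"zero_top"`, or
#'   `"saturated"`).
#' @export
both_joined_fraction <- function(bottom, top) {
  val <- function(x) {
    if (inherits(x, "dpcr_counts")) dpcr_concentration(x)$lambda else x
  }
  b <- val(bottom); t <- val(top)
  if (is.infinite(b) || is.infinite(t))
    return(list(ratio = NA_real_, flag = "saturated"))
  if (t <= 0) return(list(ratio = NA_real_, flag = "zero_top"))
  list(ratio = b / t, flag = "ok")
}

#' Assemble a scaled time course
#'
#' Scales a tidy table of abundances/fractions against a named reference
#' condition (e.g. the most abundant product at 30 min): every value is
#' divided by the reference value, which maps to 1.
#'
#' @param records `data.frame` with columns `target`, `timepoint`, `value`
#'   (extra columns are preserved).
#' @param ref_target,ref_timepoint the reference condition; must be present
#'   exactly once.
#' @return `data.table` sorted by `target`, `timepoint`, with a
#'   `scaled_value` column.
#' @export
assemble_timecourse <- function(records, ref_target, ref_timepoint) {
  dt <- data.table::as.data.table(records)
  stopifnot(all(c("target", "timepoint", "value") %in% names(dt)))
  ref <- dt[target == ref_target & timepoint == ref_timepoint]
  if (nrow(ref) == 0L)
    stop("reference condition not present: ", ref_target, " at ",
         ref_timepoint, " min")
  if (nrow(ref) > 1L)
    stop("reference condition is not unique")
  out <- data.table::copy(dt)
  out[, scaled_value := value / ref$value]
  data.table::setorder(out, target, timepoint)
  out[]
}

#' Read a Ct record CSV
#'
#' Expected columns: `sample`, `target`, `strand`, `channel`, `treatment`,
#' `ct`, `spike_ct`. The channel must be consistent with the strand (top =
#' FAM, bottom = HEX probes).
#'
#' @param path CSV path.
#' @return `data.table` of validated records.
#' @export
read_ct_csv <- function(path) {
  dt <- data.table::fread(path)
  need <- c("sample", "target", "strand", "channel", "treatment", "ct",
            "spike_ct")
  miss <- setdiff(need, names(dt))
  if (length(miss) > 0L)
    stop("Ct table missing column(s): ", paste(miss, collapse = ", "))
  if (any(dt$ct <= 0)) stop("Ct values must be positive")
  bad <- (dt$strand == "top" & dt$channel != "FAM") |
    (dt$strand == "bottom" & dt$channel != "HEX")
  if (any(bad))
    stop("channel/strand mismatch at row(s) ",
         paste(which(bad), collapse = ", "),
         " (top = FAM, bottom = HEX)")
  dt
}

#' Read a droplet-count CSV
#'
#' Expected columns: `sample`, `target`, `positives`, `total` (optional
#' `droplet_volume` in uL).
#'
#' @param path CSV path.
#' @return `data.table`.
#' @export
read_dpcr_csv <- function(path) {
  dt <- data.table::fread(path)
  need <- c("sample", "target", "positives", "total")
  miss <- setdiff(need, names(dt))
  if (length(miss) > 0L)
    stop("droplet table missing column(s): ", paste(miss, collapse = ", "))
  if (any(dt$positives > dt$total) || any(dt$total <= 0))
    stop("need 0 <= positives <= total and total > 0")
  dt
}
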