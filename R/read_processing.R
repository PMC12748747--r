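# Per-read annotation: sample barcode, UMI, strand identity, junction call.

#' Demultiplex reads by sample barcode
#'
#' Each read is assigned to the unique barcode matching within
#' `max_mismatch` substitutions at some offset in the first
#' `barcode length + phasing_max` positions (phasing-tolerant scan).
#' Unassignable reads are labelled `"undetermined"`. The barcode table is
#' validated up front: all barcodes must have equal length and minimum
#' pairwise Hamming distance `> 2 * max_mismatch`, otherwise assignment
#' would be ambiguous and the call aborts.
#'
#' @param reads a `data.table`/`data.frame` with a `sequence` column (and
#'   usually `read_id`, `quality`).
#' @param barcode_table named character vector, sample label -> barcode.
#' @param max_mismatch maximum substitutions tolerated (default 1).
#' @param layout an [adapter_layout()] (supplies `phasing_max`).
#' @return the input with a `sample` column added.
#' @export
demultiplex <- function(reads, barcode_table, max_mismatch = 1L,
                        layout = adapter_layout()) {
  bl <- nchar(barcode_table)
  if (length(unique(bl)) != 1L)
    stop("all barcodes must have the same length")
  if (is.null(names(barcode_table)) || any(!nzchar(names(barcode_table))))
    stop("barcode_table must be named by sample label")
  if (!all(is_dna(barcode_table)))
    stop("barcodes must be A/C/G/T strings")
  if (length(barcode_table) > 1L) {
    for (a in seq_len(length(barcode_table) - 1L))
      for (b in seq(a + 1L, length(barcode_table)))
        if (hamming(barcode_table[[a]], barcode_table[[b]]) <= 2L * max_mismatch)
          stop("ambiguous barcode table: '", barcode_table[[a]], "' and '",
               barcode_table[[b]], "' are within Hamming distance ",
               2L * max_mismatch)
  }
  seqs <- reads$sequence
  n <- length(seqs)
  best_mm <- rep(Inf, n)
  best_lab <- rep(NA_character_, n)
  tie <- rep(FALSE, n)
  for (lab in names(barcode_table)) {
    bc <- barcode_table[[lab]]
    mm_lab <- rep(Inf, n)
    for (off in 0:layout$phasing_max) {
      mm <- mismatch_at_cpp(seqs, bc, rep(off, n))
      mm[is.na(mm)] <- Inf
      mm_lab <- pmin(mm_lab, mm)
    }
    better <- mm_lab < best_mm
    same <- mm_lab == best_mm & is.finite(mm_lab)
    tie[same] <- TRUE
    tie[better] <- FALSE
    best_lab[better] <- lab
    best_mm[better] <- mm_lab[better]
  }
  sample <- ifelse(best_mm <= max_mismatch & !tie, best_lab, "undetermined")
  out <- data.table::as.data.table(reads)
  out[, sample := sample]
  out[]
}

#' Merge an inward-oriented read pair
#'
#' Scans all overlap lengths `>= min_overlap` between the 3' end of mate 1
#' and the reverse complement of mate 2, picks the overlap with the fewest
#' mismatches (ties: longest overlap), and merges if the mismatch rate is
#' within `max_mismatch_rate`. Disagreeing overlap bases take the
#' higher-quality call.
#'
#' @param read1,read2 lists (or 1-row data.frames) with `sequence` and
#'   `quality`.
#' @param min_overlap minimum acceptable overlap (default 20).
#' @param max_mismatch_rate maximum mismatch fraction in the overlap.
#' @return on success, `list(merged = TRUE, sequence, quality, overlap,
#'   mismatches)`; on failure `list(merged = FALSE, reason)`.
#' @export
merge_pairs <- function(read1, read2, min_overlap = 20L,
                        max_mismatch_rate = 0.1) {
  s1 <- as.list(read1)$sequence; q1 <- as.list(read1)$quality
  s2 <- revcomp(as.list(read2)$sequence)
  q2 <- paste(rev(strsplit(as.list(read2)$quality, "")[[1]]), collapse = "")
  n1 <- nchar(s1); n2 <- nchar(s2)
  max_o <- min(n1, n2)
  if (max_o < min_overlap)
    return(list(merged = FALSE, reason = "reads shorter than min_overlap"))
  c1 <- strsplit(s1, "")[[1]]; c2 <- strsplit(s2, "")[[1]]
  best_o <- NA_integer_; best_mm <- Inf
  for (o in seq(min_overlap, max_o)) {
    mm <- sum(c1[(n1 - o + 1L):n1] != c2[seq_len(o)])
    if (mm < best_mm || (mm == best_mm && !is.na(best_o) && o > best_o)) {
      best_mm <- mm; best_o <- o
    }
  }
  if (best_mm / best_o > max_mismatch_rate)
    return(list(merged = FALSE, reason = "no acceptable overlap"))
  o <- best_o
  ov1 <- c1[(n1 - o + 1L):n1]; ov2 <- c2[seq_len(o)]
  qv1 <- strsplit(q1, "")[[1]][(n1 - o + 1L):n1]
  qv2 <- strsplit(q2, "")[[1]][seq_len(o)]
  take2 <- ov1 != ov2 & utf8ToInt_chr(qv2) > utf8ToInt_chr(qv1)
  ov <- ifelse(take2, ov2, ov1)
  qov <- ifelse(take2, qv2, pmax_chr(qv1, qv2, ov1 == ov2))
  seq <- paste0(substr(s1, 1L, n1 - o), paste0(ov, collapse = ""),
                substr(s2, o + 1L, n2))
  qual <- paste0(substr(q1, 1L, n1 - o), paste0(qov, collapse = ""),
                 substr(q2, o + 1L, n2))
  list(merged = TRUE, sequence = seq, quality = qual, overlap = o,
       mismatches = best_mm)
}

utf8ToInt_chr <- function(x) vapply(x, utf8ToInt, integer(1), USE.NAMES = FALSE)

# agreeing bases keep the better quality; disagreeing keep the winner's own
pmax_chr <- function(q1, q2, agree) {
  i1 <- utf8ToInt_chr(q1); i2 <- utf8ToInt_chr(q2)
  out <- q1
  out[agree & i2 > i1] <- q2[agree & i2 > i1]
  out
}

#' Extract the UMI and insert from a read
#'
#' Locates the constant adapter flank (up to `max_mismatch` substitutions);
#' the `umi_length` bases preceding it are the UMI and everything after it is
#' the insert. Reads without a locatable flank (or with the flank too close
#' to the read start to fit a UMI) are marked not-found.
#'
#' @param read a sequence string, or a list with a `sequence` element.
#' @param layout an [adapter_layout()].
#' @param max_mismatch flank mismatches tolerated (default 1).
#' @return `list(found = TRUE, umi, insert)` or
#'   `list(found = FALSE, reason = "adapter not found")`.
#' @export
extract_umi <- function(read, layout = adapter_layout(), max_mismatch = 1L) {
  seq <- if (is.character(read)) read else as.list(read)$sequence
  res <- extract_umi_batch(seq, layout, max_mismatch)
  if (is.na(res$umi[1L]))
    list(found = FALSE, reason = "adapter not found")
  else
    list(found = TRUE, umi = res$umi[1L], insert = res$insert[1L])
}

extract_umi_batch <- function(seqs, layout = adapter_layout(),
                              max_mismatch = 1L) {
  off <- locate_pattern_cpp(seqs, layout$flank, max_mismatch)
  ok <- off >= layout$umi_length
  umi <- rep(NA_character_, length(seqs))
  insert <- rep(NA_character_, length(seqs))
  umi[ok] <- substr(seqs[ok], off[ok] - layout$umi_length + 1L, off[ok])
  insert[ok] <- substr(seqs[ok], off[ok] + nchar(layout$flank) + 1L,
                       nchar(seqs[ok]))
  list(umi = umi, insert = insert)
}

# Constant flanks anchoring the strand-ID locus on each strand.
strand_id_anchors <- function(spec, flank_len = 8L) {
  s1 <- spec$strand_id$start + 1L
  bi <- strand_id_bottom_interval(spec)
  if (s1 <= flank_len || bi["lo"] <= flank_len)
    stop("strand-ID region too close to a strand end for an anchor flank")
  list(top = list(flank = substr(spec$top_seq, s1 - flank_len, s1 - 1L),
                  variant = spec$strand_id$top_variant),
       bottom = list(flank = substr(spec$bottom_seq, bi["lo"] - flank_len,
                                    bi["lo"] - 1L),
                     variant = spec$strand_id$bottom_variant))
}

#' Assign a read to the top or bottom strand
#'
#' Locates the strand-ID locus through its constant 5' flank for each
#' candidate strand and counts mismatches of the 5 observed bases against
#' that strand's variant. The read is assigned to the closer variant only if
#' its mismatch count is `<= max_best` and the margin to the other variant is
#' `>= min_margin`; otherwise `"undetermined"`. With fully mismatched 5-nt
#' variants a single sequencing error can never flip the assignment.
#'
#' @param insert insert sequence(s) (character vector).
#' @param spec a [substrate_spec()].
#' @param max_best maximum mismatches of the winning variant (default 1).
#' @param min_margin required mismatch margin between variants (default 2).
#' @param flank_mismatch mismatches tolerated when locating the anchor flank.
#' @return character vector: `"top"`, `"bottom"`, or `"undetermined"`.
#' @export
assign_strand <- function(insert, spec, max_best = 1L, min_margin = 2L,
                          flank_mismatch = 1L) {
  u <- unique(insert)
  if (length(u) < length(insert)) {
    return(assign_strand(u, spec, max_best, min_margin,
                         flank_mismatch)[match(insert, u)])
  }
  anchors <- strand_id_anchors(spec)
  mm <- sapply(c("top", "bottom"), function(strand) {
    a <- anchors[[strand]]
    off <- locate_pattern_cpp(insert, a$flank, flank_mismatch)
    voff <- ifelse(off < 0L, NA_integer_, off + nchar(a$flank))
    m <- mismatch_at_cpp(insert, a$variant, voff)
    ifelse(is.na(m), Inf, m)
  })
  mm <- matrix(mm, ncol = 2L)
  best <- pmin(mm[, 1L], mm[, 2L])
  margin <- ifelse(is.finite(mm[, 1L]) & is.finite(mm[, 2L]),
                   abs(mm[, 1L] - mm[, 2L]),
                   ifelse(is.finite(best), Inf, 0))
  ok <- is.finite(best) & best <= max_best & margin >= min_margin
  out <- rep("undetermined", length(insert))
  out[ok & mm[, 1L] < mm[, 2L]] <- "top"
  out[ok & mm[, 2L] < mm[, 1L]] <- "bottom"
  out
}

#' Classify a read's repair junction
#'
#' Finds the best edit-distance match of each reference junction window for
#' the read's strand within the insert. The label is the unique best match
#' with distance `<= max_edit`; ties between labels whose windows are
#' identical (declared degenerate) collapse to the canonical joint label
#' (members joined by `=`); any other tie, or best distance `> max_edit`,
#' yields `"unclassified"`.
#'
#' @param insert insert sequence (single string).
#' @param strand `"top"` or `"bottom"`.
#' @param products an [enumerate_expected_products()] result.
#' @param max_edit maximum edit distance (default 1).
#' @param use_offset if `TRUE`, restrict the search to each reference's
#'   expected position in the insert (fast path used by the pipeline);
#'   default `FALSE` searches the whole insert.
#' @return `list(label, edit_distance, matched_window)` where
#'   `matched_window` is the 1-based `c(start, end)` of the reference's
#'   expected window in the insert (`NA` when unclassified).
#' @export
call_junction <- function(insert, strand, products, max_edit = 1L,
                          use_offset = FALSE) {
  res <- call_junction_batch(insert, strand, products, max_edit, use_offset)
  list(label = res$label[1L], edit_distance = res$edit_distance[1L],
       matched_window = c(res$win_start[1L], res$win_end[1L]))
}

call_junction_batch <- function(inserts, strand, products, max_edit = 1L,
                                use_offset = FALSE, slack = 5L) {
  u <- unique(inserts)
  if (length(u) < length(inserts)) {
    res <- call_junction_batch(u, strand, products, max_edit, use_offset,
                               slack)
    return(res[match(inserts, u)])
  }
  tab <- strand_products(products, strand)
  refs <- tab$junction
  ref_off <- if (use_offset) tab$junction_offset else rep(-1L, length(refs))
  d <- junction_dist_cpp(inserts, refs, as.integer(ref_off), as.integer(slack),
                         as.integer(max_edit))
  keep_deg <- products$degenerate_pairs$strand == strand
  deg <- products$degenerate_pairs[keep_deg]
  n <- length(inserts)
  dmin <- d[, 1L]
  for (j in seq_len(ncol(d))[-1L]) dmin <- pmin(dmin, d[, j])
  n_win <- rowSums(d == dmin)
  label <- rep("unclassified", n)
  edit <- rep(NA_integer_, n)
  wstart <- rep(NA_integer_, n)
  wend <- rep(NA_integer_, n)
  wcol <- max.col(d == dmin, ties.method = "first")
  single <- dmin <= max_edit & n_win == 1L
  label[single] <- tab$label[wcol[single]]
  assigned <- single
  # ties: only callable if every pair of tying labels is declared degenerate
  for (i in which(dmin <= max_edit & n_win > 1L)) {
    labs <- tab$label[d[i, ] == dmin[i]]
    all_deg <- all(apply(utils::combn(labs, 2L), 2L, function(pr) {
      any((deg$label1 == pr[1L] & deg$label2 == pr[2L]) |
            (deg$label1 == pr[2L] & deg$label2 == pr[1L]))
    }))
    if (!all_deg) next  # ambiguous between distinguishable labels
    label[i] <- joint_label(labs)
    assigned[i] <- TRUE
  }
  edit[assigned] <- dmin[assigned]
  wstart[assigned] <- tab$junction_offset[wcol[assigned]] + 1L
  wend[assigned] <- tab$junction_offset[wcol[assigned]] +
    nchar(tab$junction[wcol[assigned]])
  data.table::data.table(label = label, edit_distance = edit,
                         win_start = wstart, win_end = wend)
}

#' Annotate a read table end to end
#'
#' Runs demultiplexing, UMI extraction, strand assignment, and junction
#' calling, producing one annotated record per read plus a run log of
#' per-stage drop counts. Reads failing a stage are retained in the table
#' with `NA`/`"undetermined"` markers, never silently removed.
#'
#' @param reads `data.table` with `read_id`, `sequence` (and `quality`).
#' @param spec a [substrate_spec()].
#' @param products an [enumerate_expected_products()] result.
#' @param barcode_table named character vector for [demultiplex()];
#'   `NULL` skips demultiplexing (single-sample library).
#' @param layout an [adapter_layout()].
#' @param max_edit junction-call edit-distance cap.
#' @param use_offset use the fast positional junction search (default TRUE;
#'   appropriate for substitution-dominated error profiles).
#' @return `data.table` with columns `read_id`, `sample`, `umi`, `strand`,
#'   `label`, `edit_distance`; attribute `"run_log"` holds the stage counts.
#' @export
annotate_reads <- function(reads, spec, products, barcode_table = NULL,
                           layout = adapter_layout(), max_edit = 1L,
                           use_offset = TRUE) {
  reads <- data.table::as.data.table(reads)
  n0 <- nrow(reads)
  if (!is.null(barcode_table)) {
    reads <- demultiplex(reads, barcode_table, layout = layout)
  } else {
    reads[, sample := "sample1"]
  }
  ex <- extract_umi_batch(reads$sequence, layout)
  out <- data.table::data.table(read_id = reads$read_id,
                                sample = reads$sample,
                                umi = ex$umi,
                                strand = "undetermined",
                                label = NA_character_,
                                edit_distance = NA_integer_)
  has_umi <- !is.na(ex$umi)
  out$strand[has_umi] <- assign_strand(ex$insert[has_umi], spec)
  for (strand in c("top", "bottom")) {
    idx <- which(out$strand == strand)
    if (length(idx) == 0L) next
    jc <- call_junction_batch(ex$insert[idx], strand, products,
                              max_edit = max_edit, use_offset = use_offset)
    out$label[idx] <- jc$label
    out$edit_distance[idx] <- jc$edit_distance
  }
  log <- list(
    n_input = n0,
    n_demux_undetermined = sum(out$sample == "undetermined"),
    n_adapter_not_found = sum(!has_umi),
    n_strand_undetermined = sum(has_umi & out$strand == "undetermined"),
    n_unclassified = sum(out$label == "unclassified", na.rm = TRUE))
  data.table::setattr(out, "run_log", log)
  out[]
}
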