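# Enumeration of expected repair-product junctions.
#
# All rendered product sequences share one linearisation of the repaired
# circle per strand: the strand is cut at a fixed interior phosphate (the
# "rotation cut"), so the head-to-tail junction sits mid-sequence. The cut on
# the bottom strand is the phosphate conjugate to the top-strand cut under
# the duplex pairing map, which makes a model-2 product literally the reverse
# complement of its template strand's rendering (up to the strand-ID region).

SID_FLANK_LEN <- 8L  # constant bases anchoring the strand-ID locus

# Rotation cut on the top strand (1-based: cut after position c). The cut
# must keep the junction window margins on both strands and must not split
# the strand-ID locus or its anchor flank on either strand; among admissible
# cuts the one closest to the middle of the top strand is used.
choose_cut <- function(spec, margin = 0L) {
  pm <- pairing_map(spec)
  Lt <- pm$Lt; Lb <- pm$Lb
  s1 <- spec$strand_id$start + 1L
  s5 <- spec$strand_id$end
  bi <- strand_id_bottom_interval(spec)
  cand <- seq(max(margin, 1L), Lt - max(margin, 1L))
  cb <- pm$j_of_i(cand + 1L)
  ok <- cand >= margin & (Lt - cand) >= margin &
    cb >= margin & (Lb - cb) >= margin &
    !(cand >= s1 - SID_FLANK_LEN & cand <= s5 - 1L) &
    !(cb >= bi["lo"] - SID_FLANK_LEN & cb <= bi["hi"] - 1L)
  if (!any(ok))
    stop("no admissible rotation cut: substrate too short for this window")
  cand <- cand[ok]
  cand[which.min(abs(cand - Lt %/% 2L))]
}

cut_bottom <- function(spec, c_top) {
  pm <- pairing_map(spec)
  pm$j_of_i(c_top + 1L) # cut after this bottom position = same phosphate
}

# Rotation of a strand's own sequence with `ins` placed at the junction.
render_autonomous <- function(seq, cut, ins) {
  L <- nchar(seq)
  list(seq = paste0(substr(seq, cut + 1L, L), ins, substr(seq, 1L, cut)),
       j0 = L - cut,            # 0-based offset where `ins` begins
       ins_len = nchar(ins))
}

# Strand-ID location (0-based start) inside a rendered sequence.
sid_offset_rendered <- function(s1, cut, L, j0, ins_len) {
  if (s1 > cut) s1 - cut - 1L else (L - cut) + ins_len + (s1 - 1L)
}

#' Enumerate expected repair products
#'
#' For each strand, builds the reference junction sequence of every repair
#' product: the direct-ligation junction (the strand's own terminal bases,
#' including any designed terminal mispair base, joined head to tail), one
#' junction per requested templated insertion, and one "model-2 copy" per
#' opposite-strand product - the sequence obtained by semi-conservative
#' synthesis across the opposite strand's sealed junction, i.e. its reverse
#' complement carrying this strand's own strand-ID variant. Label pairs whose
#' rendered products are identical (hence unresolvable from any read; e.g.
#' direct vs model-2-direct on a blunt complementary substrate, or a
#' self-complementary gap-filling insertion) are listed in
#' `degenerate_pairs`.
#'
#' @param spec a [substrate_spec()].
#' @param insertion_labels character vector of inserted sequences (e.g.
#'   `c("C", "TC", "CTC")`); the default, no insertions, suits substrates
#'   repaired by direct ligation.
#' @param window junction window size J: each reference junction comprises
#'   J/2 bases either side of the inserted bases (so windows are `J + insert
#'   length` nt). Must satisfy `J >= 2 * (max overhang + max insertion + 2)`.
#' @return an object of class `expected_products` with elements `products`
#'   (a `data.table` with one row per strand x label), `degenerate_pairs`,
#'   `window`, `spec`, and the rotation cuts used.
#' @export
enumerate_expected_products <- function(spec, insertion_labels = character(),
                                        window = 40L) {
  stopifnot(all(is_dna(insertion_labels)), all(nzchar(insertion_labels)) ||
              length(insertion_labels) == 0L)
  if (spec$head$polarity != spec$tail$polarity)
    stop("unjoinable end polarities: head is ", spec$head$polarity,
         ", tail is ", spec$tail$polarity)
  max_ov <- max(nchar(spec$head$overhang_seq), nchar(spec$tail$overhang_seq))
  max_ins <- if (length(insertion_labels)) max(nchar(insertion_labels)) else 0L
  if (window < 2L * (max_ov + max_ins + 2L))
    stop("window J = ", window, " too short to span the distinguishing ",
         "context; need >= ", 2L * (max_ov + max_ins + 2L))
  window <- as.integer(window)
  half <- window %/% 2L

  c_top <- choose_cut(spec, margin = half + max_ov)
  c_bot <- cut_bottom(spec, c_top)
  Lt <- nchar(spec$top_seq); Lb <- nchar(spec$bottom_seq)

  sid <- spec$strand_id
  s1_top <- sid$start + 1L
  bi <- strand_id_bottom_interval(spec)

  auto_labels <- c("direct", if (length(insertion_labels))
    paste0("ins:", insertion_labels))
  auto_ins <- c("", insertion_labels)

  render_strand <- function(strand) {
    seq <- if (strand == "top") spec$top_seq else spec$bottom_seq
    cut <- if (strand == "top") c_top else c_bot
    s1 <- if (strand == "top") s1_top else unname(bi["lo"])
    L <- nchar(seq)
    out <- vector("list", length(auto_labels))
    for (k in seq_along(auto_labels)) {
      r <- render_autonomous(seq, cut, auto_ins[k])
      r$label <- auto_labels[k]
      r$class <- "autonomous"
      r$opposite_label <- NA_character_
      r$sid_off <- sid_offset_rendered(s1, cut, L, r$j0, r$ins_len)
      out[[k]] <- r
    }
    out
  }

  auto <- list(top = render_strand("top"), bottom = render_strand("bottom"))

  # model-2 copies: reverse complement of the opposite autonomous product,
  # with this strand's own strand-ID variant substituted in.
  m2_of <- function(strand, opp) {
    own_variant <- if (strand == "top") sid$top_variant else sid$bottom_variant
    Lr <- nchar(opp$seq)
    seq <- revcomp(opp$seq)
    sid_off <- Lr - opp$sid_off - 5L
    substr(seq, sid_off + 1L, sid_off + 5L) <- own_variant
    list(seq = seq,
         j0 = Lr - opp$j0 - opp$ins_len,
         ins_len = opp$ins_len,
         label = paste0("model2_copy_of_", opp$label),
         class = "model2",
         opposite_label = opp$label,
         sid_off = sid_off)
  }
  prods <- list(
    top = c(auto$top, lapply(auto$bottom, m2_of, strand = "top")),
    bottom = c(auto$bottom, lapply(auto$top, m2_of, strand = "bottom"))
  )

  rows <- lapply(c("top", "bottom"), function(strand) {
    lapply(prods[[strand]], function(p) {
      win_start0 <- p$j0 - half
      win <- substr(p$seq, win_start0 + 1L, p$j0 + p$ins_len + half)
      data.table::data.table(
        strand = strand, label = p$label, class = p$class,
        opposite_label = p$opposite_label,
        insert = if (p$class == "autonomous" && p$ins_len > 0L)
          sub("^ins:", "", p$label) else "",
        ins_len = p$ins_len, junction = win,
        junction_offset = win_start0, full_seq = p$seq,
        sid_offset = p$sid_off)
    })
  })
  products <- data.table::rbindlist(unlist(rows, recursive = FALSE))

  deg <- products[, degenerate_pairs_strand(.SD), by = "strand"]

  structure(list(spec = spec, window = window,
                 cut_top = c_top, cut_bottom = c_bot,
                 products = products, degenerate_pairs = deg),
            class = "expected_products")
}

# All unordered label pairs of one strand whose products cannot be told
# apart by any read. Products of one strand differ only within their
# junction windows, so two labels are read-indistinguishable iff their full
# rendered sequences are identical - which also catches windows that are
# equal up to the nick-offset shift (e.g. a self-complementary gap-filling
# insertion, where the model-1 product and the model-2 copy are the same
# molecule with the ligation scar at a different phosphate).
degenerate_pairs_strand <- function(sd) {
  n <- nrow(sd)
  res <- list()
  if (n >= 2L) {
    for (a in seq_len(n - 1L)) for (b in seq((a + 1L), n)) {
      if (sd$full_seq[a] == sd$full_seq[b])
        res[[length(res) + 1L]] <- data.table::data.table(
          label1 = sd$label[a], label2 = sd$label[b])
    }
  }
  if (length(res) == 0L)
    return(data.table::data.table(label1 = character(0), label2 = character(0)))
  data.table::rbindlist(res)
}

#' @export
print.expected_products <- function(x, ...) {
  cat(sprintf("<expected_products> substrate %s, J = %d\n",
              x$spec$name, x$window))
  print(x$products[, c("strand", "label", "class", "ins_len", "junction")])
  if (nrow(x$degenerate_pairs) > 0L) {
    cat("degenerate pairs:\n")
    print(x$degenerate_pairs)
  }
  invisible(x)
}

# canonical joint label for a set of degenerate labels
joint_label <- function(labels) paste(sort(unique(labels)), collapse = "=")

# split a (possibly joint) label back into its members
split_label <- function(label) strsplit(label, "=", fixed = TRUE)[[1]]

is_autonomous_label <- function(label) !startsWith(label, "model2_copy_of_")

#' Reference junction table for one strand
#'
#' @param products an [enumerate_expected_products()] result.
#' @param strand `"top"` or `"bottom"`.
#' @return `data.table` of that strand's reference products.
#' @export
strand_products <- function(products, strand = c("top", "bottom")) {
  strand <- match.arg(strand)
  keep <- products$products$strand == strand
  products$products[keep]
}
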