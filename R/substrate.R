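#' End structure of a double-strand break substrate
#'
#' Describes one end ("head" = left/5' end of the top strand, "tail" =
#' right/3' end of the top strand) of a designed linear DSB substrate.
#'
#' @param polarity one of `"five_prime_overhang"`, `"three_prime_overhang"`,
#'   `"blunt"`.
#' @param overhang_seq DNA string, 5'->3' on the overhanging strand. Must be
#'   empty iff `polarity == "blunt"`; at most 10 nt.
#' @param label free-text label.
#' @return an object of class `end_structure`.
#' @export
end_structure <- function(polarity = c("five_prime_overhang",
                                       "three_prime_overhang", "blunt"),
                          overhang_seq = "", label = "") {
  polarity <- match.arg(polarity)
  stopifnot(is.character(overhang_seq), length(overhang_seq) == 1L)
  structure(list(polarity = polarity,
                 overhang_seq = toupper(overhang_seq),
                 label = label),
            class = "end_structure")
}

#' Strand-identification region
#'
#' The designed 5-nt mismatched duplex region that distinguishes top-strand
#' from bottom-strand reads. Coordinates are 0-based half-open on the top
#' strand; `bottom_variant` is given as read on the bottom strand, 5'->3'.
#'
#' @param start 0-based start of the region on the top strand.
#' @param top_variant 5-nt DNA string carried by the top strand.
#' @param bottom_variant 5-nt DNA string carried by the bottom strand (5'->3').
#' @return an object of class `strand_id_region`.
#' @export
strand_id_region <- function(start, top_variant, bottom_variant) {
  structure(list(start = as.integer(start),
                 end = as.integer(start) + 5L,   # half-open
                 top_variant = toupper(top_variant),
                 bottom_variant = toupper(bottom_variant)),
            class = "strand_id_region")
}

#' Designed DSB substrate
#'
#' Bundles the two strand sequences, both end structures, and the strand-ID
#' region. Use [validate_substrate()] to check the design invariants; the
#' constructor only checks types.
#'
#' @param name substrate name.
#' @param top_seq top strand, 5'->3'.
#' @param bottom_seq bottom strand, 5'->3'.
#' @param head,tail [end_structure()] objects.
#' @param strand_id a [strand_id_region()].
#' @return an object of class `substrate_spec`.
#' @export
substrate_spec <- function(name, top_seq, bottom_seq, head, tail, strand_id) {
  stopifnot(inherits(head, "end_structure"), inherits(tail, "end_structure"),
            inherits(strand_id, "strand_id_region"))
  structure(list(name = name,
                 top_seq = toupper(top_seq),
                 bottom_seq = toupper(bottom_seq),
                 head = head, tail = tail,
                 strand_id = strand_id),
            class = "substrate_spec")
}

#' @export
print.substrate_spec <- function(x, ...) {
  cat(sprintf("<substrate_spec> %s\n", x$name))
  cat(sprintf("  top    (%3d nt) %s\n", nchar(x$top_seq), x$top_seq))
  cat(sprintf("  bottom (%3d nt) %s\n", nchar(x$bottom_seq), x$bottom_seq))
  cat(sprintf("  head: %s '%s'  tail: %s '%s'\n",
              x$head$polarity, x$head$overhang_seq,
              x$tail$polarity, x$tail$overhang_seq))
  cat(sprintf("  strand ID: top[%d,%d) %s / %s (bottom 5'->3')\n",
              x$strand_id$start, x$strand_id$end,
              x$strand_id$top_variant, x$strand_id$bottom_variant))
  invisible(x)
}

# Pairing geometry of the linear duplex, 1-based coordinates.
# top[i] pairs bottom[j] with j = bottom_hi - (i - top_lo).
pairing_map <- function(spec) {
  h <- nchar(spec$head$overhang_seq)
  t <- nchar(spec$tail$overhang_seq)
  head5 <- spec$head$polarity == "five_prime_overhang"
  head3 <- spec$head$polarity == "three_prime_overhang"
  tail5 <- spec$tail$polarity == "five_prime_overhang"
  tail3 <- spec$tail$polarity == "three_prime_overhang"
  Lt <- nchar(spec$top_seq); Lb <- nchar(spec$bottom_seq)
  top_lo <- 1L + if (head5) h else 0L
  top_hi <- Lt - if (tail3) t else 0L
  bottom_lo <- 1L + if (tail5) t else 0L
  bottom_hi <- Lb - if (head3) h else 0L
  j_of_i <- function(i) bottom_hi - (i - top_lo)
  list(top_lo = top_lo, top_hi = top_hi,
       bottom_lo = bottom_lo, bottom_hi = bottom_hi,
       j_of_i = j_of_i, Lt = Lt, Lb = Lb)
}

# Bottom-strand 1-based interval [lo, hi] carrying the strand-ID variant.
strand_id_bottom_interval <- function(spec) {
  pm <- pairing_map(spec)
  s1 <- spec$strand_id$start + 1L
  s5 <- spec$strand_id$end
  c(lo = pm$j_of_i(s5), hi = pm$j_of_i(s1))
}

#' Validate a substrate design
#'
#' Checks every design invariant of a [substrate_spec()] and returns the
#' violations as data: an empty data frame means a valid design. Nothing is
#' thrown; malformed designs are reportable objects.
#'
#' @param spec a [substrate_spec()].
#' @param strict_strand_id if `TRUE` (the default, used for package-designed
#'   substrates) the 5 strand-ID positions must be mismatched at every
#'   position; if `FALSE` (user-supplied substrates) at least one mismatch
#'   suffices.
#' @param mispair_margin designed terminal mispairs are tolerated within this
#'   many paired positions of either strand's terminus (default 5).
#' @return a `data.frame` with columns `check`, `message`.
#' @export
validate_substrate <- function(spec, strict_strand_id = TRUE,
                               mispair_margin = 5L) {
  v <- list()
  bad <- function(check, message) {
    v[[length(v) + 1L]] <<- data.frame(check = check, message = message,
                                       stringsAsFactors = FALSE)
  }
  for (fld in c("top_seq", "bottom_seq")) {
    if (!is_dna(spec[[fld]]) || !nzchar(spec[[fld]]))
      bad("alphabet", sprintf("%s is not a non-empty A/C/G/T string", fld))
  }
  for (endn in c("head", "tail")) {
    e <- spec[[endn]]
    ov <- nchar(e$overhang_seq)
    if (!is_dna(e$overhang_seq))
      bad("alphabet", sprintf("%s overhang is not A/C/G/T", endn))
    if ((e$polarity == "blunt") != (ov == 0L))
      bad("overhang/polarity mismatch",
          sprintf("%s: polarity %s with %d-nt overhang", endn, e$polarity, ov))
    if (ov > 10L)
      bad("overhang length", sprintf("%s overhang longer than 10 nt", endn))
  }
  if (nrow_violations(v) > 0L) return(as_violation_df(v))

  pm <- pairing_map(spec)
  if ((pm$top_hi - pm$top_lo) != (pm$bottom_hi - pm$bottom_lo)) {
    bad("inconsistent end structure",
        sprintf("paired ranges differ in length (top %d, bottom %d)",
                pm$top_hi - pm$top_lo + 1L, pm$bottom_hi - pm$bottom_lo + 1L))
    return(as_violation_df(v))
  }

  # overhang sequences must match the terminal bases of the strands
  h <- nchar(spec$head$overhang_seq); t <- nchar(spec$tail$overhang_seq)
  if (spec$head$polarity == "five_prime_overhang" &&
      substr(spec$top_seq, 1L, h) != spec$head$overhang_seq)
    bad("overhang sequence", "head 5' overhang != top strand 5' terminus")
  if (spec$head$polarity == "three_prime_overhang" &&
      substr(spec$bottom_seq, pm$Lb - h + 1L, pm$Lb) != spec$head$overhang_seq)
    bad("overhang sequence", "head 3' overhang != bottom strand 3' terminus")
  if (spec$tail$polarity == "five_prime_overhang" &&
      substr(spec$bottom_seq, 1L, t) != spec$tail$overhang_seq)
    bad("overhang sequence", "tail 5' overhang != bottom strand 5' terminus")
  if (spec$tail$polarity == "three_prime_overhang" &&
      substr(spec$top_seq, pm$Lt - t + 1L, pm$Lt) != spec$tail$overhang_seq)
    bad("overhang sequence", "tail 3' overhang != top strand 3' terminus")

  # strand-ID region
  sid <- spec$strand_id
  s1 <- sid$start + 1L; s5 <- sid$end
  if (s5 - s1 + 1L != 5L)
    bad("strand-ID interval", "strand-ID interval is not 5 nt")
  if (nchar(sid$top_variant) != 5L || nchar(sid$bottom_variant) != 5L)
    bad("strand-ID variant length", "strand-ID variants must be 5 nt")
  if (s1 < pm$top_lo || s5 > pm$top_hi) {
    bad("strand-ID interval", "strand-ID region outside the paired duplex")
    return(as_violation_df(v))
  }
  if (substr(spec$top_seq, s1, s5) != sid$top_variant)
    bad("strand-ID variant",
        sprintf("top strand [%d,%d) does not carry top_variant", sid$start, sid$end))
  bi <- strand_id_bottom_interval(spec)
  if (substr(spec$bottom_seq, bi["lo"], bi["hi"]) != sid$bottom_variant)
    bad("strand-ID variant",
        sprintf("bottom strand [%d,%d] does not carry bottom_variant",
                bi["lo"], bi["hi"]))
  mism <- strsplit(sid$top_variant, "")[[1]] !=
    strsplit(revcomp(sid$bottom_variant), "")[[1]]
  if (strict_strand_id && !all(mism))
    bad("strand-ID region not mismatched",
        "strand-ID variants are complementary at >=1 of the 5 positions")
  if (!strict_strand_id && !any(mism))
    bad("strand-ID region not mismatched",
        "strand-ID variants are perfectly complementary")

  # complementarity outside strand-ID and terminal mispair margin
  topc <- strsplit(spec$top_seq, "")[[1]]
  botc <- strsplit(spec$bottom_seq, "")[[1]]
  is_paired <- seq(pm$top_lo, pm$top_hi)
  jj <- pm$j_of_i(is_paired)
  exempt <- (is_paired >= s1 & is_paired <= s5) |
    (is_paired - pm$top_lo < mispair_margin) |
    (pm$top_hi - is_paired < mispair_margin) |
    (jj - pm$bottom_lo < mispair_margin) |
    (pm$bottom_hi - jj < mispair_margin)
  mm <- botc[jj] != comp_base(topc[is_paired])
  offending <- which(mm & !exempt)
  if (length(offending) > 0L)
    bad("complementarity",
        sprintf("%d unpaired interior position(s), first at top position %d",
                length(offending), is_paired[offending[1L]]))
  as_violation_df(v)
}

nrow_violations <- function(v) length(v)
as_violation_df <- function(v) {
  if (length(v) == 0L)
    return(data.frame(check = character(0), message = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, v)
}

#' Construct a substrate from a top strand design
#'
#' Builds the bottom strand as the reverse complement of the paired region of
#' `top_seq`, installs the strand-ID variants on both strands, and attaches
#' the requested overhangs. This is the supported way to create well-formed
#' substrates; arbitrary strand pairs can be assembled with
#' [substrate_spec()] and checked with [validate_substrate()].
#'
#' @param name substrate name.
#' @param top_seq full top strand (5'->3'), including any overhang bases; the
#'   strand-ID positions are overwritten with `top_variant`.
#' @param head,tail [end_structure()] objects.
#' @param sid_start 0-based start of the 5-nt strand-ID region (top strand).
#' @param top_variant,bottom_variant 5-nt strand-ID variants.
#' @return a validated [substrate_spec()].
#' @export
design_substrate <- function(name, top_seq, head, tail, sid_start,
                             top_variant, bottom_variant) {
  top_seq <- toupper(top_seq)
  s1 <- sid_start + 1L
  substr(top_seq, s1, s1 + 4L) <- toupper(top_variant)
  tmp <- substrate_spec(name, top_seq, top_seq, head, tail,
                        strand_id_region(sid_start, top_variant, bottom_variant))
  pm <- pairing_map(tmp)
  paired_len <- pm$top_hi - pm$top_lo + 1L
  h <- nchar(head$overhang_seq); t <- nchar(tail$overhang_seq)
  Lb <- paired_len +
    (if (head$polarity == "three_prime_overhang") h else 0L) +
    (if (tail$polarity == "five_prime_overhang") t else 0L)
  bot <- character(Lb)
  topc <- strsplit(top_seq, "")[[1]]
  bottom_lo <- 1L + if (tail$polarity == "five_prime_overhang") t else 0L
  bottom_hi <- Lb - if (head$polarity == "three_prime_overhang") h else 0L
  if (tail$polarity == "five_prime_overhang")
    bot[seq_len(t)] <- strsplit(tail$overhang_seq, "")[[1]]
  if (head$polarity == "three_prime_overhang")
    bot[(bottom_hi + 1L):Lb] <- strsplit(head$overhang_seq, "")[[1]]
  jj <- seq(bottom_lo, bottom_hi)
  ii <- pm$top_lo + (bottom_hi - jj)
  bot[jj] <- comp_base(topc[ii])
  bottom_seq <- paste0(bot, collapse = "")
  spec <- substrate_spec(name, top_seq, bottom_seq, head, tail,
                         strand_id_region(sid_start, top_variant, bottom_variant))
  bi <- strand_id_bottom_interval(spec)
  substr(bottom_seq, bi["lo"], bi["hi"]) <- toupper(bottom_variant)
  spec$bottom_seq <- bottom_seq
  spec
}

# Fixed 76-nt duplex core shared by the bundled example substrates.
EXAMPLE_CORE <- "AAAACTCCATGTGTAACTCCGGAAGTAGAATCTTGCACTCGGCCTTTCCATATCTCGTGAACCCCCTGCACGCCCT"

#' Bundled example substrates
#'
#' Small, fully specified substrates mirroring the designed end chemistries
#' used in strand-resolved NHEJ assays:
#' \describe{
#'   \item{`gt5`}{symmetric 4-nt 5' overhangs `GCGT`; annealing head to tail
#'     leaves a terminal G:T mispair at each strand break, and both breaks can
#'     be sealed by direct ligation.}
#'   \item{`ct5`}{as `gt5` but the tail overhang is `CCGT`, replacing the
#'     bottom-strand G:T mispair with a harder-to-ligate C:T mispair.}
#'   \item{`gag3`}{symmetric non-complementary 3' overhangs `GAG`; ligation
#'     requires a templated +C (or +TC/+CTC) insertion first.}
#'   \item{`blunt`}{blunt, fully complementary ends; direct ligation products
#'     of the two paths are indistinguishable (degenerate).}
#' }
#'
#' @param name one of `"gt5"`, `"ct5"`, `"gag3"`, `"blunt"`.
#' @return a [substrate_spec()].
#' @export
example_substrate <- function(name = c("gt5", "ct5", "gag3", "blunt")) {
  name <- match.arg(name)
  tv <- "TCAGC"; bv <- "ATCAG"  # revcomp(bv) = CTGAT, mismatched to tv at all 5
  switch(name,
    gt5 = design_substrate(
      "gt5", paste0("GCGT", EXAMPLE_CORE),
      end_structure("five_prime_overhang", "GCGT", "head"),
      end_structure("five_prime_overhang", "GCGT", "tail"),
      sid_start = 44L, top_variant = tv, bottom_variant = bv),
    ct5 = design_substrate(
      "ct5", paste0("GCGT", EXAMPLE_CORE),
      end_structure("five_prime_overhang", "GCGT", "head"),
      end_structure("five_prime_overhang", "CCGT", "tail"),
      sid_start = 44L, top_variant = tv, bottom_variant = bv),
    gag3 = design_substrate(
      "gag3", paste0(EXAMPLE_CORE, "GAG"),
      end_structure("three_prime_overhang", "GAG", "head"),
      end_structure("three_prime_overhang", "GAG", "tail"),
      sid_start = 44L, top_variant = tv, bottom_variant = bv),
    blunt = design_substrate(
      "blunt", EXAMPLE_CORE,
      end_structure("blunt", "", "head"),
      end_structure("blunt", "", "tail"),
      sid_start = 44L, top_variant = tv, bottom_variant = bv)
  )
}

#' Read / write substrate configurations
#'
#' Substrates round-trip through a structured JSON file with keys `name`,
#' `top_seq`, `bottom_seq`, `head`, `tail`, `strand_id`.
#'
#' @param path file path.
#' @param spec a [substrate_spec()].
#' @param strict_strand_id passed to [validate_substrate()]; user-loaded
#'   substrates only need one mismatched strand-ID position.
#' @return `read_substrate_config()` returns a [substrate_spec()];
#'   `write_substrate_config()` returns `path` invisibly.
#' @export
read_substrate_config <- function(path, strict_strand_id = FALSE) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- substrate_spec(
    x$name, x$top_seq, x$bottom_seq,
    end_structure(x$head$polarity, x$head$overhang_seq %||% "",
                  x$head$label %||% "head"),
    end_structure(x$tail$polarity, x$tail$overhang_seq %||% "",
                  x$tail$label %||% "tail"),
    strand_id_region(x$strand_id$start, x$strand_id$top_variant,
                     x$strand_id$bottom_variant))
  rep <- validate_substrate(spec, strict_strand_id = strict_strand_id)
  if (nrow(rep) > 0L)
    stop("invalid substrate config '", path, "': ",
         paste(rep$message, collapse = "; "))
  spec
}

#' @rdname read_substrate_config
#' @export
write_substrate_config <- function(spec, path) {
  x <- list(name = spec$name, top_seq = spec$top_seq,
            bottom_seq = spec$bottom_seq,
            head = spec$head[c("polarity", "overhang_seq", "label")],
            tail = spec$tail[c("polarity", "overhang_seq", "label")],
            strand_id = spec$strand_id[c("start", "top_variant",
                                         "bottom_variant")])
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Export substrate strands as FASTA
#'
#' Writes two records, `<name>_top` and `<name>_bottom`.
#'
#' @param spec a [substrate_spec()].
#' @param path output FASTA path.
#' @export
write_substrate_fasta <- function(spec, path) {
  ss <- Biostrings::DNAStringSet(c(spec$top_seq, spec$bottom_seq))
  names(ss) <- paste0(spec$name, c("_top", "_bottom"))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
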