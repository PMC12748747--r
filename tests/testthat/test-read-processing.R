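spec <- example_substrate("gt5")
prod <- enumerate_expected_products(spec)

test_that("the infix edit-distance oracle itself is correct on known cases", {
  expect_identical(infix_edit_oracle("ACGT", "TTACGTTT"), 0L)
  expect_identical(infix_edit_oracle("ACGT", "TTACTTTT"), 1L)   # substitution
  expect_identical(infix_edit_oracle("ACGT", "TTAGTTTT"), 1L)   # deletion
  expect_identical(infix_edit_oracle("ACGT", "TTACCGTT"), 1L)   # insertion
  expect_identical(infix_edit_oracle("AAAA", "GGGGGGGG"), 4L)
  expect_identical(infix_edit_oracle("ACGT", ""), 4L)
  # matches the global edit distance when pattern length equals subject
  expect_identical(infix_edit_oracle("ACGT", "AGGT"),
                   as.integer(utils::adist("ACGT", "AGGT")))
})

test_that("demultiplexing assigns exact and phased, errored barcodes", {
  bcs <- c(s1 = "ACGTAC", s2 = "TTGGCC")
  mk <- function(seq) data.table::data.table(read_id = "r", sequence = seq)
  insert <- strrep("A", 30)
  expect_identical(demultiplex(mk(paste0("ACGTAC", insert)), bcs)$sample, "s1")
  # offset 3 (phasing) with 1 substitution
  expect_identical(
    demultiplex(mk(paste0("GGG", "ACGTAA", insert)), bcs)$sample, "s1")
  expect_identical(
    demultiplex(mk(paste0("CCCCCC", insert)), bcs)$sample, "undetermined")
  # 2 substitutions exceed max_mismatch = 1
  expect_identical(
    demultiplex(mk(paste0("ACGGGC", insert)), bcs)$sample, "undetermined")
})

test_that("ambiguous barcode tables are rejected up front", {
  near <- c(a = "ACGTAC", b = "ACGTAA")  # Hamming 1 <= 2 * max_mismatch
  reads <- data.table::data.table(read_id = "r", sequence = strrep("A", 40))
  expect_error(demultiplex(reads, near), "ambiguous")
  expect_error(demultiplex(reads, c(a = "ACGTAC", b = "ACGT")), "same length")
})

test_that("merge_pairs recovers the simulated insert from split mates", {
  st <- simulate_repair(spec, kinetics_model(), 30, 10, seed = 20)
  lib <- synthesize_reads(st, spec, prod, oversampling_mean = 2,
                          error_rate = 0, seed = 21)
  pairs <- split_into_pairs(lib$reads, mate_length = 70L)
  for (i in seq_len(min(nrow(lib$reads), 10L))) {
    m <- merge_pairs(pairs$mate1[i, ], pairs$mate2[i, ])
    expect_true(m$merged)
    expect_identical(m$sequence, lib$reads$sequence[i])
  }
})

test_that("merge_pairs picks the minimal-mismatch overlap and resolves
           disagreements by quality (exhaustive scoring oracle)", {
  core <- "CCATGAACGTTGACGGTTCAACGGATTACCAGGTT"
  r1 <- list(sequence = paste0("AAAAA", core), quality = strrep("I", 40))
  # mate 2 carries the core with one disagreeing base at a Q10-vs-Q40 position
  core2 <- core
  substr(core2, 10, 10) <- "A"  # disagree: r1 has G originally?
  r2seq <- revcomp(paste0(core2, "TTTTT"))
  q2 <- strrep("I", 40); substr(q2, 31, 31) <- "+"  # Q10 at the mismatch
  r2 <- list(sequence = r2seq, quality = q2)
  m <- merge_pairs(r1, r2, min_overlap = 20)
  expect_true(m$merged)
  # oracle: score all overlaps by direct character comparison
  s2 <- revcomp(r2$sequence)
  mm <- vapply(20:40, function(o) {
    a <- substring(r1$sequence, 41 - o, 40)
    b <- substring(s2, 1, o)
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, integer(1))
  expect_identical(m$mismatches, min(mm))
  expect_identical(m$overlap, (20:40)[max(which(mm == min(mm)))])
  # the high-quality (r1) call wins at the disagreement
  expect_identical(substr(m$sequence, 15, 15), substr(core, 10, 10))
  # non-overlapping random mates fail
  bad <- merge_pairs(list(sequence = strrep("ACGT", 10),
                          quality = strrep("I", 40)),
                     list(sequence = strrep("T", 40),
                          quality = strrep("I", 40)))
  expect_false(bad$merged)
})

test_that("UMI extraction finds the flank with up to one substitution", {
  layout <- adapter_layout()
  umi <- "ACGTACGTAC"
  read <- paste0("GG", "ACGTAC", umi, layout$flank, strrep("T", 30))
  expect_identical(extract_umi(read)$umi, umi)
  # one substitution inside the flank
  fl <- layout$flank
  substr(fl, 4, 4) <- setdiff(c("A", "C", "G", "T"), substr(fl, 4, 4))[1]
  read2 <- paste0("GG", "ACGTAC", umi, fl, strrep("T", 30))
  expect_identical(extract_umi(read2)$umi, umi)
  # missing flank
  expect_false(extract_umi(paste0(umi, strrep("T", 40)))$found)
})

test_that("strand assignment follows the margin rule", {
  tabs <- strand_products(prod, "top")
  ins_top <- tabs$full_seq[1]
  ins_bot <- strand_products(prod, "bottom")$full_seq[1]
  expect_identical(assign_strand(ins_top, spec), "top")
  expect_identical(assign_strand(ins_bot, spec), "bottom")
  # one error inside the bottom variant still assigns bottom
  anch <- duplexrepair:::strand_id_anchors(spec)
  pos <- regexpr(anch$bottom$flank, ins_bot, fixed = TRUE) + 8L
  errd <- ins_bot
  substr(errd, pos, pos) <- setdiff(c("A", "C", "G", "T"),
                                    substr(errd, pos, pos))[1]
  expect_identical(assign_strand(errd, spec), "bottom")
  # no strand-ID locus at all -> undetermined
  expect_identical(assign_strand(strrep("ACGT", 25), spec), "undetermined")
  # equidistant variants -> undetermined: plant 3 errors in the variant
  amb <- ins_top
  pos_t <- regexpr(anch$top$flank, amb, fixed = TRUE) + 8L
  obs <- anch$top$variant
  for (p in 1:3)
    substr(obs, p, p) <- setdiff(c("A", "C", "G", "T"), substr(obs, p, p))[1]
  substr(amb, pos_t, pos_t + 4L) <- obs
  expect_identical(assign_strand(amb, spec), "undetermined")
})

test_that("junction calls match references and reject random windows", {
  sg <- example_substrate("gag3")
  pg <- enumerate_expected_products(sg, c("C", "TC", "CTC"))
  top <- strand_products(pg, "top")
  direct_read <- top$full_seq[top$label == "direct"]
  jc <- call_junction(direct_read, "top", pg)
  expect_identical(jc$label, "direct")
  expect_identical(jc$edit_distance, 0L)
  plusC_read <- top$full_seq[top$label == "ins:C"]
  expect_identical(call_junction(plusC_read, "top", pg)$label, "ins:C")
  set.seed(30)
  rand <- rand_dna(20, 40)
  res <- duplexrepair:::call_junction_batch(rand, "top", pg)
  expect_true(all(res$label == "unclassified"))
})

test_that("call_junction agrees with the dynamic-programming oracle on
           random and lightly mutated inserts", {
  set.seed(31)
  pg <- enumerate_expected_products(example_substrate("gag3"), c("C", "TC"))
  top <- strand_products(pg, "top")
  inserts <- c(rand_dna(100, 80),
               vapply(sample(top$full_seq, 100, replace = TRUE),
                      function(s) random_edits(s, sample(0:2, 1)), "",
                      USE.NAMES = FALSE))
  got <- duplexrepair:::call_junction_batch(inserts, "top", pg,
                                            use_offset = FALSE)
  for (i in seq_along(inserts)) {
    want <- call_junction_oracle(inserts[i], "top", pg)
    expect_identical(got$label[i], want$label)
    expect_identical(got$edit_distance[i], want$edit_distance)
  }
})

test_that("error-free libraries annotate with perfect fidelity", {
  ml <- make_library("gt5", n = 200, oversampling = 10, error_rate = 0,
                     seed = 32)
  ann <- annotate_reads(ml$lib$reads, ml$spec, ml$prod)
  tr <- merge(ann, ml$lib$truth, by = "read_id")
  expect_identical(nrow(tr), nrow(ml$lib$reads))
  expect_true(all(tr$strand.x == tr$strand.y))
  expect_true(all(tr$label == tr$product_label))
  log <- attr(ann, "run_log")
  expect_identical(log$n_adapter_not_found, 0L)
  expect_identical(log$n_strand_undetermined, 0L)
})

test_that("per-read label accuracy beats the window-length error bound", {
  e <- 0.005
  ml <- make_library("gt5", n = 400, oversampling = 10, error_rate = e,
                     seed = 33)
  ann <- annotate_reads(ml$lib$reads, ml$spec, ml$prod)
  tr <- merge(ann, ml$lib$truth, by = "read_id")
  ok <- tr$strand.x == tr$strand.y & !is.na(tr$label) &
    tr$label == tr$product_label
  expect_gte(mean(ok), 1 - 40 * e)
})
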