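spec <- example_substrate("gt5")
prod <- enumerate_expected_products(spec)

ann_row <- function(umi, strand, label, id = NULL) {
  data.table::data.table(
    read_id = id %||% paste0("r", format(stats::runif(1), digits = 12)),
    sample = "s1", umi = umi, strand = strand, label = label,
    edit_distance = 0L)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("UMI grouping is exact-match and excludes undetermined strands", {
  ann <- rbind(ann_row("AAAAAAAAAA", "top", "direct", "r1"),
               ann_row("AAAAAAAAAA", "bottom", "direct", "r2"),
               ann_row("AAAAAAAAAT", "top", "direct", "r3"),
               ann_row("CCCCCCCCCC", "undetermined", NA_character_, "r4"))
  fam <- group_by_umi(ann)
  expect_identical(nrow(fam$families), 2L)
  f1 <- fam$families[fam$families$umi == "AAAAAAAAAA"]
  expect_identical(f1$n_top, 1L)
  expect_identical(f1$n_bottom, 1L)
  expect_identical(fam$log$n_excluded_undetermined, 1L)
})

test_that("grouping matches a hash-free nested-loop oracle on a library", {
  ml <- make_library("gt5", n = 100, oversampling = 10, error_rate = 0,
                     seed = 40)
  ann <- annotate_reads(ml$lib$reads, ml$spec, ml$prod)
  fam <- group_by_umi(ann)
  # oracle: loop over unique UMIs counting reads by identity comparison
  for (u in fam$families$umi) {
    rows <- which(ann$umi == u & ann$strand != "undetermined")
    expect_identical(fam$families[fam$families$umi == u]$n_total,
                     length(rows))
    expect_identical(fam$families[fam$families$umi == u]$n_top,
                     sum(ann$strand[rows] == "top"))
  }
})

test_that("the 2% family filter applies a strict less-than threshold", {
  # total 2000 reads, 10 templates -> mean oversampling 200, threshold 4
  sizes <- c(3L, 4L, 5L, 250L)
  umis <- c("AAAAAAAAAA", "CCCCCCCCCC", "GGGGGGGGGG", "TTTTTTTTTT")
  ann <- data.table::rbindlist(lapply(seq_along(sizes), function(i) {
    data.table::data.table(read_id = sprintf("u%d_%d", i, seq_len(sizes[i])),
                           sample = "s1", umi = umis[i],
                           strand = rep(c("top", "bottom"),
                                        length.out = sizes[i]),
                           label = "direct", edit_distance = 0L)
  }))
  fam <- group_by_umi(ann)
  params <- filter_params(n_input_templates = 10)
  kept <- filter_families(fam, total_reads = 2000L, params = params)
  expect_identical(kept$log$family_threshold, 4)
  expect_setequal(kept$families$umi, umis[sizes >= 4L])  # 3 dropped, 4 kept
  # shallow oversampling: threshold < 1 retains every non-empty family
  kept_all <- filter_families(fam, total_reads = 400L, params = params)
  expect_identical(nrow(kept_all$families), length(sizes))
  expect_error(filter_families(fam, total_reads = 10L, params = params),
               "smaller")
})

test_that("the 20% strand filter applies a strict less-than threshold", {
  mk_fam <- function(n_top, n_bottom, umi) {
    data.table::data.table(
      read_id = sprintf("%s_%d", umi, seq_len(n_top + n_bottom)),
      sample = "s1", umi = umi,
      strand = c(rep("top", n_top), rep("bottom", n_bottom)),
      label = "direct", edit_distance = 0L)
  }
  ann <- rbind(mk_fam(9L, 1L, "AAAAAAAAAA"),   # 1 < 2: bottom dropped
               mk_fam(8L, 2L, "CCCCCCCCCC"),   # 2 == 20% of 10: kept
               mk_fam(5L, 0L, "GGGGGGGGGG"))   # single strand: unchanged
  fam <- group_by_umi(ann)
  params <- filter_params(n_input_templates = 1)
  out <- filter_strands(fam, params)
  f <- function(u) out$families[out$families$umi == u]
  expect_identical(f("AAAAAAAAAA")$n_bottom, 0L)
  expect_identical(f("AAAAAAAAAA")$n_top, 9L)
  expect_identical(f("CCCCCCCCCC")$n_bottom, 2L)
  expect_identical(f("GGGGGGGGGG")$n_top, 5L)
  expect_identical(out$log$n_strands_dropped, 1L)
})

test_that("consensus is plurality with ties ambiguous", {
  mk <- function(labels, strand = "top", umi = "AAAAAAAAAA") {
    data.table::data.table(read_id = paste0(umi, seq_along(labels), strand),
                           sample = "s1", umi = umi, strand = strand,
                           label = labels, edit_distance = 0L)
  }
  cons <- call_consensus(group_by_umi(mk(rep("ins:C", 5))))
  expect_identical(cons$consensus_top, "ins:C")
  cons2 <- call_consensus(group_by_umi(mk(c("direct", "direct",
                                            "ins:C", "ins:C"))))
  expect_identical(cons2$consensus_top, "ambiguous")
  cons3 <- call_consensus(group_by_umi(
    mk(c("direct", "direct", "direct", "unclassified"))))
  expect_identical(cons3$consensus_top, "direct")
  # counting oracle: plurality equals the arg-max of table()
  labs <- c("direct", "ins:C", "direct", "unclassified", "direct")
  tab <- table(labs)
  expect_identical(call_consensus(group_by_umi(mk(labs)))$consensus_top,
                   names(tab)[which.max(tab)])
})

test_that("molecule classification separates the two repair paths", {
  mk_cons <- function(top, bottom) data.table::data.table(
    umi = "AAAAAAAAAA", n_top = 5L, n_bottom = 5L,
    consensus_top = top, consensus_bottom = bottom)
  cl <- classify_molecules(mk_cons("direct", "direct"), prod)
  expect_identical(cl$molecule_class, "both_joined")
  expect_identical(cl$path, "model1")

  sg <- example_substrate("gag3")
  pg <- enumerate_expected_products(sg, c("C"))
  cl2 <- classify_molecules(mk_cons("ins:C", "model2_copy_of_ins:C"), pg)
  expect_identical(cl2$path, "model2")
  cl2b <- classify_molecules(mk_cons("model2_copy_of_ins:C", "ins:C"), pg)
  expect_identical(cl2b$path, "model2")

  cl3 <- classify_molecules(mk_cons("direct", NA_character_), prod)
  expect_identical(cl3$molecule_class, "top_only")
  expect_identical(cl3$path, "not_applicable")

  cl4 <- classify_molecules(mk_cons(NA_character_, NA_character_), prod)
  expect_identical(cl4$molecule_class, "ambiguous")

  # degenerate joint labels (blunt substrate) are path-indeterminate
  pb <- enumerate_expected_products(example_substrate("blunt"))
  joint <- "direct=model2_copy_of_direct"
  cl5 <- classify_molecules(mk_cons(joint, joint), pb)
  expect_identical(cl5$molecule_class, "both_joined")
  expect_identical(cl5$path, "indeterminate")

  # unclassified consensus: joined but with unknown product
  cl6 <- classify_molecules(mk_cons("direct", "unclassified"), prod)
  expect_identical(cl6$molecule_class, "both_joined")
  expect_identical(cl6$path, "indeterminate")
})

test_that("summaries report exact frequencies (counting oracle)", {
  calls <- data.table::data.table(
    umi = sprintf("u%03d", 1:100),
    top_label = "direct", bottom_label = "direct",
    molecule_class = c(rep("both_joined", 72), rep("top_only", 20),
                       rep("bottom_only", 8)),
    path = c(rep("model1", 70), rep("model2", 2), rep("not_applicable", 28)))
  s <- summarize_repair(calls, "s1", 2)
  expect_identical(s$class_freq[["both_joined"]], 0.72)
  expect_equal(sum(s$class_freq), 1)
  expect_identical(s$path_counts[["model1"]], 70L)
  # random call set vs naive counting
  set.seed(41)
  calls2 <- data.table::data.table(
    umi = sprintf("u%03d", 1:200),
    top_label = "direct", bottom_label = "direct",
    molecule_class = sample(c("both_joined", "top_only", "bottom_only",
                              "ambiguous"), 200, replace = TRUE),
    path = "indeterminate")
  calls2$path[calls2$molecule_class != "both_joined"] <- "not_applicable"
  s2 <- summarize_repair(calls2)
  for (cl in names(s2$class_freq))
    expect_identical(s2$class_freq[[cl]],
                     sum(calls2$molecule_class == cl) / 200)
  expect_equal(sum(s2$class_freq), 1)
  expect_error(summarize_repair(calls[0, ]), "no duplex calls")
})

test_that("preference ratios follow the worked arithmetic", {
  calls <- data.table::data.table(
    umi = sprintf("u%03d", 1:200),
    top_label = "direct", bottom_label = "direct",
    molecule_class = "both_joined",
    path = c(rep("model1", 180), rep("model2", 9), rep("indeterminate", 11)))
  pr <- preference_ratio(summarize_repair(calls))
  expect_equal(pr$model1_over_model2, 20)   # 0.90 vs 0.045 of both-joined
  expect_identical(pr$n_indeterminate, 11L)
  calls$path <- c(rep("model1", 200))
  pr2 <- preference_ratio(summarize_repair(calls))
  expect_identical(pr2$flag, "no_model2")
  expect_identical(pr2$model1_over_model2, Inf)
  expect_identical(pr2$n_model1, 200L)
})

test_that("filters are deterministic and order-independent", {
  ml <- make_library("gt5", n = 150, oversampling = 8, error_rate = 0.002,
                     seed = 42)
  ann <- annotate_reads(ml$lib$reads, ml$spec, ml$prod)
  params <- filter_params(n_input_templates = 150)
  run <- function(a) {
    fams <- filter_strands(
      filter_families(group_by_umi(a), nrow(a), params), params)
    data.table::setorder(
      classify_molecules(call_consensus(fams), ml$prod), umi)[]
  }
  base <- run(ann)
  set.seed(43)
  shuffled <- run(ann[sample(nrow(ann)), ])
  expect_identical(base, shuffled)
})

test_that("pipeline molecule classes track simulation ground truth", {
  ml <- make_library("gt5", n = 400, oversampling = 50, error_rate = 0,
                     seed = 44)
  ann <- annotate_reads(ml$lib$reads, ml$spec, ml$prod)
  rec <- reconstruct_duplexes(ann, ml$prod,
                              filter_params(n_input_templates = 400))
  truth_class <- with(ml$states, ifelse(
    top_joined & bottom_joined, "both_joined",
    ifelse(top_joined, "top_only",
           ifelse(bottom_joined, "bottom_only", "none"))))
  truth_by_umi <- data.table::data.table(umi = ml$lib$molecules$umi,
                                         truth = truth_class)
  joined <- merge(rec$calls, truth_by_umi, by = "umi")
  collide <- sum(duplicated(ml$lib$molecules$umi))
  mismatches <- sum(joined$molecule_class != joined$truth)
  expect_lte(mismatches, collide + 3L)
})

test_that("ordered-mode libraries are called model-2 dominant", {
  kin <- kinetics_model("ordered", k_top = 0.5, k_second = 0.15,
                        first_strand = "top")
  ml <- make_library("ct5", kin, n = 400, harvest = 30, oversampling = 30,
                     error_rate = 0, seed = 45)
  ann <- annotate_reads(ml$lib$reads, ml$spec, ml$prod)
  rec <- reconstruct_duplexes(ann, ml$prod,
                              filter_params(n_input_templates = 400))
  s <- summarize_repair(rec$calls, "ordered", 30)
  pr <- preference_ratio(s)
  expect_gt(pr$model2_over_model1, 1)
  expect_gte(s$path_freq[["model2"]], 0.95)
})
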