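mk_truth_rec <- function(pos, ref, alt, gt = "0/1", af = NULL) {
  r <- variant_record("chr1", pos, ref, alt, gt = gt)
  r$af <- af
  r
}

test_that("identical callsets compare with no errors", {
  recs <- list(mk_truth_rec(100L, "A", "G"), mk_truth_rec(200L, "C", "T", "1/1"))
  truth <- callset(recs, samples = "S", source = "truth")
  cmp <- compare_to_truth(truth, truth, tiny_ref())
  expect_length(cmp$fp, 0L)
  expect_length(cmp$fn, 0L)
  expect_length(cmp$tp, 2L)
  m <- comparison_metrics(cmp)
  expect_equal(unname(m[c("precision", "recall", "f1")]), c(1, 1, 1))
})

test_that("metric identities hold on planted counts", {
  m <- comparison_metrics(c(tp = 9L, fp = 1L, fn = 1L))
  expect_equal(unname(m["precision"]), 0.9)
  expect_equal(unname(m["recall"]), 0.9)
  expect_equal(unname(m["f1"]), 0.9)
  # F1 lies between precision and recall
  m2 <- comparison_metrics(c(tp = 8L, fp = 4L, fn = 1L))
  expect_gte(m2[["f1"]], min(m2[["precision"]], m2[["recall"]]))
  expect_lte(m2[["f1"]], max(m2[["precision"]], m2[["recall"]]))
})

test_that("representation-shifted true calls are not penalized", {
  ref <- tiny_ref()
  # truth holds the left-aligned deletion, the caller right-shifted it
  truth <- callset(list(mk_truth_rec(12L, "AA", "A")), samples = "S",
                   source = "t")
  calls <- callset(list(mk_truth_rec(15L, "AA", "A")), samples = "S",
                   source = "c")
  cmp <- compare_to_truth(calls, truth, ref)
  expect_length(cmp$tp, 1L)
  expect_length(cmp$fp, 0L)
  expect_length(cmp$fn, 0L)
  # padded representation also matches
  calls2 <- callset(list(mk_truth_rec(12L, "AAA", "AA")), samples = "S",
                    source = "c2")
  cmp2 <- compare_to_truth(calls2, truth, ref)
  expect_length(cmp2$tp, 1L)
})

test_that("genotype mismatches count as a false positive and negative pair", {
  ref <- tiny_ref()
  truth <- callset(list(mk_truth_rec(4L, "A", "G", "1/1")), samples = "S",
                   source = "t")
  calls <- callset(list(mk_truth_rec(4L, "A", "G", "0/1")), samples = "S",
                   source = "c")
  cmp <- compare_to_truth(calls, truth, ref)
  expect_length(cmp$tp, 0L)
  expect_length(cmp$fp, 1L)
  expect_length(cmp$fn, 1L)
  # the truth partition invariant: |truth| = TP + FN
  expect_equal(cmp$truth_total, length(cmp$tp) + length(cmp$fn))
})

test_that("region restriction and planted confusion counts line up", {
  cfg <- sim_config(53L, genome_length = 20000L, n_samples = 40L)
  gr <- gen_reference(cfg)
  panel <- gen_panel(cfg, gr)
  tc <- gen_truth_and_calls(cfg, panel, gr$ref)
  cmp <- compare_to_truth(tc$calls_a, tc$truth, gr$ref)
  expect_equal(length(cmp$fp), unname(tc$ledger$n_fp["a"]))
  expect_equal(length(cmp$fn), unname(tc$ledger$n_fn["a"]))
  expect_equal(cmp$truth_total, tc$ledger$n_truth)
  # restricting to a half-genome region keeps only records inside it
  regions <- list(genomic_interval("chr1", 0L, 10000L))
  cmp_r <- compare_to_truth(tc$calls_a, tc$truth, gr$ref, regions)
  expect_true(cmp_r$truth_total <= cmp$truth_total)
  expect_true(all(vapply(c(cmp_r$fp, cmp_r$fn, cmp_r$tp), function(r)
    r$pos0 < 10000L, TRUE)))
})

test_that("commonness stratification partitions every error class", {
  comparison <- structure(list(
    tp = c(make_af_set(6, 0.2), make_af_set(3, 0.001),
           list({ r <- variant_record("chr1", 999L, "A", c("G", "C"))
                  r$af <- c(0.5, 0.001); r })),
    fp = c(make_af_set(2, 0.02), make_af_set(2, 0.01)),
    fn = make_af_set(1, 0.5),
    truth_total = 11L, call_total = 13L), class = "comparison")
  sm <- stratify_by_commonness(comparison, threshold = 0.01)
  tab <- sm$table
  # boundary semantics: AF 0.02 is common, AF 0.01 is rare
  expect_equal(tab[tab$stratum == "common" & tab$type == "snp", ]$fp, 2L)
  expect_equal(tab[tab$stratum == "rare" & tab$type == "snp", ]$fp, 2L)
  # mixed multi-allelic record excluded and counted
  expect_equal(unname(sm$excluded["tp"]), 1L)
  # partition identity: common + rare + excluded = total per class
  expect_equal(sum(tab$tp) + sm$excluded[["tp"]], length(comparison$tp))
  expect_equal(sum(tab$fp) + sm$excluded[["fp"]], length(comparison$fp))
  expect_equal(sum(tab$fn) + sm$excluded[["fn"]], length(comparison$fn))
  # missing AF directs the user to annotation
  bad <- structure(list(tp = list(variant_record("chr1", 5L, "A", "G")),
                        fp = list(), fn = list(), truth_total = 1L,
                        call_total = 1L), class = "comparison")
  expect_error(stratify_by_commonness(bad), "annotate_callset")
})

test_that("stratified counts match a brute-force partition on planted labels", {
  set.seed(61)
  afs <- c(0.001, 0.005, 0.01, 0.02, 0.2, 0.9)
  recs <- lapply(1:60, function(i) {
    r <- variant_record("chr1", i * 7L, "A", if (i %% 3 == 0) "AT" else "G")
    r$af <- sample(afs, 1)
    r
  })
  split3 <- split(recs, rep(c("tp", "fp", "fn"), each = 20))
  comparison <- structure(c(split3, list(truth_total = 40L, call_total = 40L)),
                          class = "comparison")
  sm <- stratify_by_commonness(comparison)
  for (cls in c("tp", "fp", "fn")) {
    for (st in c("common", "rare")) {
      for (ty in c("snp", "indel")) {
        want <- sum(vapply(split3[[cls]], function(r) {
          is_snp <- nchar(r$ref) == 1 && all(nchar(r$alt) == 1)
          side <- if (r$af > 0.01) "common" else "rare"
          side == st && is_snp == (ty == "snp")
        }, TRUE))
        got <- sm$table[sm$table$stratum == st & sm$table$type == ty, ][[cls]]
        expect_equal(got, want)
      }
    }
  }
})

test_that("zero-frequency recall is computed over the unseen-subset only", {
  cmp <- structure(list(tp = c(make_af_set(2, 0), make_af_set(5, 0.3)),
                        fp = list(), fn = make_af_set(2, 0),
                        truth_total = 9L, call_total = 7L),
                   class = "comparison")
  expect_equal(zero_frequency_recall(cmp), 0.5)
  # all truth in panel: undefined sentinel, not 1.0
  cmp2 <- structure(list(tp = make_af_set(3, 0.2), fp = list(),
                         fn = make_af_set(1, 0.2), truth_total = 4L,
                         call_total = 3L), class = "comparison")
  expect_true(is.na(zero_frequency_recall(cmp2)))
})

test_that("model-specific error sets equal brute-force set algebra", {
  cfg <- sim_config(67L, genome_length = 20000L, n_samples = 40L)
  gr <- gen_reference(cfg)
  panel <- gen_panel(cfg, gr)
  fpan <- compute_frequencies(panel$callset, list(ALL = panel$callset$samples))
  tc <- gen_truth_and_calls(cfg, panel, gr$ref)
  cmp_a <- compare_to_truth(tc$calls_a, tc$truth, gr$ref)
  cmp_b <- compare_to_truth(tc$calls_b, tc$truth, gr$ref)
  errs <- model_specific_errors(cmp_a, cmp_b, fpan, gr$ref)
  # brute force from the generator ledger
  expect_equal(length(errs$a_specific_fp),
               unname(tc$ledger$n_specific_fp["a"]))
  expect_equal(length(errs$b_specific_fp),
               unname(tc$ledger$n_specific_fp["b"]))
  expect_equal(length(errs$a_specific_fn),
               unname(tc$ledger$n_specific_fn["a"]))
  expect_equal(length(errs$b_specific_fn),
               unname(tc$ledger$n_specific_fn["b"]))
  key <- function(r) paste0(r$contig, ":", r$pos0, ":", r$ref, ">",
                            paste(r$alt, collapse = ","))
  led <- tc$ledger$fp
  expect_setequal(vapply(errs$a_specific_fp, key, ""),
                  led$variant_key[led$model == "a"])
  expect_setequal(vapply(errs$b_specific_fp, key, ""),
                  led$variant_key[led$model == "b"])
  # disjointness of the specific sets
  expect_length(intersect(vapply(errs$a_specific_fp, key, ""),
                          vapply(errs$b_specific_fp, key, "")), 0L)
  # every error carries an AF in [0,1]; FPs carry VAF from the source VCF
  for (set in errs) for (r in set) {
    expect_true(all(r$af >= 0 & r$af <= 1))
  }
  expect_true(all(vapply(errs$a_specific_fp, function(r)
    !is.null(r$vaf), TRUE)))
  # identical models have no specific errors
  none <- model_specific_errors(cmp_a, cmp_a, fpan, gr$ref)
  expect_true(all(vapply(none, length, 0L) == 0L))
})

test_that("rare and common fractions reproduce printed worked examples", {
  expect_equal(rare_fraction(c(make_af_set(1125, 0.001),
                               make_af_set(960, 0.3))), 54.0)
  expect_equal(rare_fraction(c(make_af_set(49, 0.001),
                               make_af_set(1903, 0.3))), 2.5)
  expect_equal(common_fraction(c(make_af_set(2207, 0.3),
                                 make_af_set(77, 0.001))), 96.6)
  expect_equal(common_fraction(c(make_af_set(588, 0.3),
                                 make_af_set(1364, 0.001))), 30.1)
  expect_equal(rare_fraction(make_af_set(10, 0.5)), 0)
  expect_true(is.na(rare_fraction(list())))
  # threshold boundary: AF exactly at the threshold is rare
  expect_equal(rare_fraction(make_af_set(4, 0.01)), 100)
})

test_that("error reduction reproduces printed worked examples", {
  expect_equal(error_reduction(431, 469), list(count = 38, percentage = 8.1))
  expect_equal(error_reduction(456, 487), list(count = 31, percentage = 6.4))
  expect_equal(error_reduction(10, 10), list(count = 0, percentage = 0))
  expect_true(is.na(error_reduction(5, 0)$percentage))
  # list inputs are measured by length
  expect_equal(error_reduction(make_af_set(3, 0), make_af_set(4, 0))$count, 1)
})
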