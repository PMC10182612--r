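# haplotype-identity comparison of two records: their alt alleles are
# spliced into the window covering both spans and compared as string sets;
# when both records carry a (single-sample) genotype, the genotype allele
# multisets are compared in haplotype space as well
records_equivalent <- function(a, b, reference, require_gt = TRUE) {
  if (a$contig != b$contig) return(FALSE)
  win <- genomic_interval(a$contig, min(a$pos0, b$pos0),
                          max(rec_end0(a), rec_end0(b)))
  haps_a <- sort(vapply(a$alt, function(al) build_haplotype(reference, win, a, al), ""))
  haps_b <- sort(vapply(b$alt, function(al) build_haplotype(reference, win, b, al), ""))
  gt_a <- if (!is.null(a$gt)) a$gt[1] else NULL
  gt_b <- if (!is.null(b$gt)) b$gt[1] else NULL
  if (require_gt && !is.null(gt_a) && !is.null(gt_b)) {
    hap_of <- function(rec, k) {
      if (is.na(k)) return(NA_character_)
      al <- if (k == 0L) rec$ref else rec$alt[k]
      build_haplotype(reference, win, rec, al)
    }
    ga <- sort(vapply(gt_matrix(gt_a)[1, ], function(k) hap_of(a, k), ""))
    gb <- sort(vapply(gt_matrix(gt_b)[1, ], function(k) hap_of(b, k), ""))
    return(identical(ga, gb))
  }
  identical(unname(haps_a), unname(haps_b))
}

# does a's alt-haplotype set equal b's, ignoring genotypes (site identity)
records_same_site <- function(a, b, reference) {
  records_equivalent(a, b, reference, require_gt = FALSE)
}

rec_overlaps_regions <- function(rec, regions) {
  for (iv in regions) {
    if (rec$contig == iv$contig && rec$pos0 < iv$end && rec_end0(rec) > iv$start)
      return(TRUE)
  }
  FALSE
}

#' Compare a callset against a truth set
#'
#' Records are matched by haplotype identity using the allele-matching
#' machinery: each record's alleles are spliced into the window covering
#' both spans and compared as raw strings, so representation differences
#' (shifted indels, padding bases) never create spurious errors. Calls
#' matching no truth record are false positives; truth records matching no
#' call are false negatives; a site matched with the wrong genotype counts
#' as both a false positive and a false negative.
#'
#' @param cs single-sample [callset()] of actual calls
#' @param truth single-sample truth [callset()] on the same reference
#' @param reference a [reference_sequence()]
#' @param regions optional list of [genomic_interval()]s restricting the
#'   comparison to high-confidence territory
#' @param slop maximum start-position distance (bp) at which two records are
#'   still tested for haplotype identity
#' @return object of class `comparison`: lists `tp` (matched truth records),
#'   `fp` (call records), `fn` (truth records)
#' @export
compare_to_truth <- function(cs, truth, reference, regions = NULL, slop = 50L) {
  stopifnot(inherits(cs, "callset"), inherits(truth, "callset"))
  call_contigs <- unique(cs$index$contig)
  truth_contigs <- unique(truth$index$contig)
  if (length(cs$records) && length(truth$records) &&
      !setequal(call_contigs, truth_contigs)) {
    warning("contig sets differ between calls and truth; using intersection")
    shared <- intersect(call_contigs, truth_contigs)
    cs <- callset(cs$records[cs$index$contig %in% shared], cs$samples, cs$source)
    truth <- callset(truth$records[truth$index$contig %in% shared],
                     truth$samples, truth$source)
  }
  calls <- cs$records
  truths <- truth$records
  if (!is.null(regions)) {
    calls <- Filter(function(r) rec_overlaps_regions(r, regions), calls)
    truths <- Filter(function(r) rec_overlaps_regions(r, regions), truths)
  }
  matched_truth <- rep(FALSE, length(truths))
  matched_call <- rep(FALSE, length(calls))
  gt_mismatch_call <- rep(FALSE, length(calls))
  gt_mismatch_truth <- rep(FALSE, length(truths))
  t_contig <- vapply(truths, `[[`, "", "contig")
  t_pos <- vapply(truths, `[[`, 0L, "pos0")
  for (i in seq_along(calls)) {
    cr <- calls[[i]]
    near <- which(!matched_truth & t_contig == cr$contig &
                    abs(t_pos - cr$pos0) <= slop)
    for (j in near) {
      if (!records_same_site(cr, truths[[j]], reference)) next
      if (records_equivalent(cr, truths[[j]], reference)) {
        matched_truth[j] <- TRUE
        matched_call[i] <- TRUE
      } else {  # same site, wrong genotype -> FP + FN pair
        matched_truth[j] <- TRUE
        gt_mismatch_truth[j] <- TRUE
        gt_mismatch_call[i] <- TRUE
      }
      break
    }
  }
  tp <- truths[matched_truth & !gt_mismatch_truth]
  fn <- c(truths[!matched_truth], truths[gt_mismatch_truth])
  fp <- calls[!matched_call]
  structure(list(tp = tp, fp = fp, fn = fn,
                 truth_total = length(truths), call_total = length(calls)),
            class = "comparison")
}

#' @export
print.comparison <- function(x, ...) {
  m <- comparison_metrics(x)
  cat(sprintf("<comparison> TP=%d FP=%d FN=%d  P=%.4f R=%.4f F1=%.4f\n",
              length(x$tp), length(x$fp), length(x$fn),
              m["precision"], m["recall"], m["f1"]))
  invisible(x)
}

#' Precision, recall and F1 of a comparison
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`, `F1 = 2PR/(P+R)`;
#' empty denominators yield `NA`.
#'
#' @param comparison a [compare_to_truth()] result, or a named vector/list
#'   with elements tp, fp, fn
#' @return named numeric: precision, recall, f1, tp, fp, fn
#' @export
comparison_metrics <- function(comparison) {
  if (inherits(comparison, "comparison")) {
    tp <- length(comparison$tp); fp <- length(comparison$fp)
    fn <- length(comparison$fn)
  } else {
    tp <- comparison[["tp"]]; fp <- comparison[["fp"]]; fn <- comparison[["fn"]]
  }
  p <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  r <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(p) && !is.na(r) && p + r > 0) 2 * p * r / (p + r) else NA_real_
  c(precision = p, recall = r, f1 = f1, tp = tp, fp = fp, fn = fn)
}

rec_is_snp <- function(r) nchar(r$ref) == 1L && all(nchar(r$alt) == 1L)

# stratum of an AF-annotated record: "common", "rare", or "excluded" for
# multi-allelic records with alleles on both sides of the threshold
rec_stratum <- function(r, threshold) {
  if (is.null(r$af)) stop("record lacks AF annotation; run annotate_callset() first")
  common <- r$af > threshold
  if (any(common) && any(!common)) return("excluded")
  if (all(common)) "common" else "rare"
}

#' Stratify benchmarking results by variant commonness
#'
#' Every TP/FP/FN record is assigned to the common stratum (panel allele
#' frequency `> threshold`) or the rare stratum (`<= threshold`), separately
#' for SNPs and indels, and precision/recall/F1 are computed per stratum.
#' Multi-allelic records with one common and one rare allele are excluded
#' and counted.
#'
#' @param comparison a [compare_to_truth()] result whose records carry AF
#'   annotations (see [annotate_callset()])
#' @param threshold commonness threshold on allele frequency (default 0.01:
#'   common means AF > 0.01, rare means AF <= 0.01)
#' @return object of class `stratified_metrics`: a data.table with one row
#'   per (stratum, type) holding counts and metrics, plus `excluded` counts
#' @export
stratify_by_commonness <- function(comparison, threshold = 0.01) {
  stopifnot(inherits(comparison, "comparison"))
  tally <- function(recs) {
    strat <- vapply(recs, rec_stratum, "", threshold = threshold)
    type <- ifelse(vapply(recs, rec_is_snp, TRUE), "snp", "indel")
    list(strat = strat, type = type)
  }
  sets <- list(tp = tally(comparison$tp), fp = tally(comparison$fp),
               fn = tally(comparison$fn))
  grid <- data.table::CJ(stratum = c("common", "rare"),
                         type = c("snp", "indel"))
  counts <- grid[, {
    n <- vapply(names(sets), function(s)
      sum(sets[[s]]$strat == stratum & sets[[s]]$type == type), 0L)
    as.list(n)
  }, by = .(stratum, type)]
  counts[, c("precision", "recall", "f1") :=
           as.list(comparison_metrics(c(tp = tp, fp = fp, fn = fn))[1:3]),
         by = .(stratum, type)]
  excluded <- vapply(names(sets), function(s)
    sum(sets[[s]]$strat == "excluded"), 0L)
  structure(list(table = counts[], excluded = excluded,
                 threshold = threshold), class = "stratified_metrics")
}

#' @export
print.stratified_metrics <- function(x, ...) {
  cat(sprintf("<stratified metrics> threshold AF > %g\n", x$threshold))
  print(x$table)
  cat("excluded mixed multi-allelic:",
      paste(names(x$excluded), x$excluded, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Recall restricted to truth variants absent from the panel
#'
#' Computes recall over the subset of truth records whose every alternate
#' allele has annotated frequency exactly zero (variants unseen in the
#' reference panel). An empty subset yields `NA`, never 1.
#'
#' @param comparison a [compare_to_truth()] result with AF-annotated truth
#'   records on both the TP and FN sides
#' @return recall in `[0,1]`, or `NA_real_` if no zero-frequency truth exists
#' @export
zero_frequency_recall <- function(comparison) {
  is_zero <- function(r) {
    if (is.null(r$af)) stop("truth record lacks AF annotation")
    all(r$af == 0)
  }
  tp0 <- sum(vapply(comparison$tp, is_zero, TRUE))
  fn0 <- sum(vapply(comparison$fn, is_zero, TRUE))
  if (tp0 + fn0 == 0L) return(NA_real_)
  tp0 / (tp0 + fn0)
}

# records of `xs` with no haplotype-identical counterpart in `ys`
setdiff_by_haplotype <- function(xs, ys, reference, slop = 50L) {
  if (!length(ys)) return(xs)
  y_contig <- vapply(ys, `[[`, "", "contig")
  y_pos <- vapply(ys, `[[`, 0L, "pos0")
  Filter(function(x) {
    near <- which(y_contig == x$contig & abs(y_pos - x$pos0) <= slop)
    !any(vapply(near, function(j) records_same_site(x, ys[[j]], reference), TRUE))
  }, xs)
}

#' Model-specific error analysis between two callers
#'
#' Given comparisons of two models A and B against the same truth set,
#' computes the errors specific to each model (haplotype-identity set
#' difference; errors common to both models are excluded) and annotates
#' every error with its panel allele frequency. Variant allele fractions
#' are carried through on false positives when present in the source VCFs.
#' When A is a baseline and B a frequency-aware model, A-specific errors
#' are the population-resolved ones and B-specific errors the
#' population-induced ones.
#'
#' @param comparison_a,comparison_b [compare_to_truth()] results against the
#'   same truth set
#' @param freq_panel a [compute_frequencies()] result
#' @param reference a [reference_sequence()]
#' @param grouping panel grouping used for the AF annotation
#' @return object of class `model_specific_errors` with AF-annotated sets
#'   `a_specific_fp`, `a_specific_fn`, `b_specific_fp`, `b_specific_fn`
#' @export
model_specific_errors <- function(comparison_a, comparison_b, freq_panel,
                                  reference, grouping = "ALL") {
  if (comparison_a$truth_total != comparison_b$truth_total ||
      length(comparison_a$tp) + length(comparison_a$fn) !=
      length(comparison_b$tp) + length(comparison_b$fn))
    stop("comparisons were made against differing truth sets")
  annotate_set <- function(recs) {
    lapply(recs, function(r) {
      r$af <- as.numeric(match_alleles(r, freq_panel, reference, grouping))
      r
    })
  }
  out <- list(
    a_specific_fp = annotate_set(setdiff_by_haplotype(comparison_a$fp,
                                                      comparison_b$fp, reference)),
    a_specific_fn = annotate_set(setdiff_by_haplotype(comparison_a$fn,
                                                      comparison_b$fn, reference)),
    b_specific_fp = annotate_set(setdiff_by_haplotype(comparison_b$fp,
                                                      comparison_a$fp, reference)),
    b_specific_fn = annotate_set(setdiff_by_haplotype(comparison_b$fn,
                                                      comparison_a$fn, reference)))
  structure(out, class = "model_specific_errors")
}

#' Fraction of an error set that is rare, as a printed percentage
#'
#' `100 * |{records with every alt AF <= threshold}| / |set|`, rounded half
#' away from zero to one decimal. An empty set yields `NA_real_`.
#'
#' @param error_set list of AF-annotated [variant_record()]s
#' @param threshold rarity threshold (default 0.01)
#' @return percentage to one decimal, or `NA_real_`
#' @export
rare_fraction <- function(error_set, threshold = 0.01) {
  if (!length(error_set)) return(NA_real_)
  rare <- vapply(error_set, function(r) {
    if (is.null(r$af)) stop("record lacks AF annotation")
    all(r$af <= threshold)
  }, TRUE)
  round_half_away(100 * sum(rare) / length(error_set), 1L)
}

#' Fraction of an error set that is common, as a printed percentage
#'
#' Complement of [rare_fraction()]: `100 * |{any alt AF > threshold}| / |set|`,
#' rounded half away from zero to one decimal.
#'
#' @inheritParams rare_fraction
#' @return percentage to one decimal, or `NA_real_`
#' @export
common_fraction <- function(error_set, threshold = 0.01) {
  if (!length(error_set)) return(NA_real_)
  common <- vapply(error_set, function(r) {
    if (is.null(r$af)) stop("record lacks AF annotation")
    any(r$af > threshold)
  }, TRUE)
  round_half_away(100 * sum(common) / length(error_set), 1L)
}

#' Error reduction of a candidate model relative to a baseline
#'
#' @param errors_candidate,errors_baseline total error counts (numbers) or
#'   error sets (lists, measured by length)
#' @return list with `count` (baseline - candidate) and `percentage`
#'   (100 * count / baseline, one decimal, rounded half away from zero);
#'   a zero baseline yields `NA` percentage
#' @export
error_reduction <- function(errors_candidate, errors_baseline) {
  nc <- if (is.list(errors_candidate)) length(errors_candidate) else errors_candidate
  nb <- if (is.list(errors_baseline)) length(errors_baseline) else errors_baseline
  count <- nb - nc
  pct <- if (nb > 0) round_half_away(100 * count / nb, 1L) else NA_real_
  list(count = count, percentage = pct)
}

#' Export model-specific error sets as a long TSV
#'
#' One row per error record with its set label, position, alleles, panel AF
#' and (for false positives) VAF — the layout needed for AF/VAF
#' scatterplots of caller-specific errors.
#'
#' @param errs a [model_specific_errors()] result
#' @param path output TSV
#' @return `path`, invisibly
#' @export
write_error_tsv <- function(errs, path) {
  rows <- list()
  for (set in names(errs)) {
    for (r in errs[[set]]) {
      rows[[length(rows) + 1L]] <- data.table::data.table(
        set = set, contig = r$contig, pos = r$pos0 + 1L, ref = r$ref,
        alt = paste(r$alt, collapse = ","),
        af = paste(signif(r$af, 6), collapse = ","),
        vaf = if (!is.null(r$vaf)) paste(signif(r$vaf, 6), collapse = ",") else NA)
    }
  }
  dt <- if (length(rows)) data.table::rbindlist(rows) else
    data.table::data.table(set = character(), contig = character(),
                           pos = integer(), ref = character(),
                           alt = character(), af = character(), vaf = character())
  utils::write.table(dt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
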