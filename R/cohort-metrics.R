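#' Assign each cohort alt allele to a call-frequency bin
#'
#' The call frequency of an alt allele is the number of cohort samples
#' carrying at least one copy of it (a sample-level count, not an allele
#' count): frequency 1 is a singleton. Alleles called in more than `K`
#' samples are excluded from the bins (`bin = NA`).
#'
#' @param cohort multi-sample [callset()] with genotypes
#' @param K number of bins (default 10: singleton up to a call in 10
#'   samples)
#' @return data.table with one row per (record `i`, alt index `j`):
#'   `n_samples_called`, `bin`
#' @export
call_frequency_bins <- function(cohort, K = 10L) {
  stopifnot(inherits(cohort, "callset"), length(cohort$samples) > 0L)
  rows <- lapply(seq_along(cohort$records), function(i) {
    r <- cohort$records[[i]]
    gm <- if (!is.null(r$gt)) gt_matrix(r$gt) else
      matrix(NA_integer_, length(cohort$samples), 2L)
    nsc <- vapply(seq_along(r$alt), function(j)
      sum(rowSums(gm == j, na.rm = TRUE) > 0L), 0L)
    data.table::data.table(i = i, j = seq_along(r$alt),
                           n_samples_called = nsc)
  })
  dt <- data.table::rbindlist(rows)
  dt[, bin := ifelse(n_samples_called >= 1L & n_samples_called <= K,
                     n_samples_called, NA_integer_)]
  dt[]
}

# per-sample hom/het carrier matrices for one record's alt j
gt_carriers <- function(r, j) {
  gm <- gt_matrix(r$gt)
  hits <- rowSums(gm == j, na.rm = TRUE)
  list(hom = hits == 2L, het = hits == 1L)
}

#' Per-sample homozygous call counts per frequency bin
#'
#' Counts, for every sample and every bin, the alt alleles for which the
#' sample is homozygous (both alleles equal to the binned alt).
#'
#' @param cohort multi-sample [callset()] with genotypes
#' @param bins result of [call_frequency_bins()]
#' @return data.table in long format: `bin`, `sample`, `count`
#' @export
homozygous_counts <- function(cohort, bins) {
  K_bins <- sort(unique(bins$bin[!is.na(bins$bin)]))
  out <- data.table::CJ(bin = K_bins, sample = cohort$samples)
  out[, count := 0L]
  binned <- bins[!is.na(bin)]
  for (k in seq_len(nrow(binned))) {
    r <- cohort$records[[binned$i[k]]]
    hom <- gt_carriers(r, binned$j[k])$hom
    if (any(hom))
      out[bin == binned$bin[k] & sample %in% cohort$samples[hom],
          count := count + 1L]
  }
  out[]
}

#' Per-sample flagged-call counts per frequency bin
#'
#' Counts calls that haplotype-match a site in an annotation callset (for
#' example pathogenic-flagged sites), per sample and per bin. A sample is
#' counted when it carries at least one copy of the flagged alt.
#'
#' @param cohort multi-sample [callset()] with genotypes
#' @param bins result of [call_frequency_bins()]
#' @param flag_sites [callset()] of flagged sites (any annotation source)
#' @param reference a [reference_sequence()] for haplotype-identity matching
#' @param slop maximum start distance for match candidates
#' @return data.table in long format: `bin`, `sample`, `count`
#' @export
flagged_counts <- function(cohort, bins, flag_sites, reference, slop = 50L) {
  K_bins <- sort(unique(bins$bin[!is.na(bins$bin)]))
  out <- data.table::CJ(bin = K_bins, sample = cohort$samples)
  out[, count := 0L]
  f_contig <- vapply(flag_sites$records, `[[`, "", "contig")
  f_pos <- vapply(flag_sites$records, `[[`, 0L, "pos0")
  binned <- bins[!is.na(bin)]
  for (k in seq_len(nrow(binned))) {
    r <- cohort$records[[binned$i[k]]]
    sub <- variant_record(r$contig, r$pos0, r$ref, r$alt[binned$j[k]])
    near <- which(f_contig == r$contig & abs(f_pos - r$pos0) <= slop)
    flagged <- any(vapply(near, function(q) {
      fr <- flag_sites$records[[q]]
      any(vapply(fr$alt, function(al) {
        one <- variant_record(fr$contig, fr$pos0, fr$ref, al)
        records_same_site(sub, one, reference)
      }, TRUE))
    }, TRUE))
    if (!flagged) next
    car <- gt_carriers(r, binned$j[k])
    carrier <- car$hom | car$het
    if (any(carrier))
      out[bin == binned$bin[k] & sample %in% cohort$samples[carrier],
          count := count + 1L]
  }
  out[]
}

TRANSITIONS <- c(A = "G", G = "A", C = "T", T = "C")

#' Transition:transversion ratio of a set of SNVs
#'
#' Transitions are A<->G and C<->T; every other base substitution is a
#' transversion. Non-SNV pairs are skipped with a log. Zero transversions
#' yield `NA_real_` (undefined), never infinity.
#'
#' @param ref,alt character vectors of reference and alternate alleles
#' @return ratio, or `NA_real_`
#' @export
titv_ratio <- function(ref, alt) {
  snv <- nchar(ref) == 1L & nchar(alt) == 1L
  if (any(!snv)) pa_log("titv_ratio: skipped %d non-SNV allele(s)", sum(!snv))
  ref <- ref[snv]; alt <- alt[snv]
  if (!length(ref)) return(NA_real_)
  ti <- sum(TRANSITIONS[ref] == alt, na.rm = TRUE)
  tv <- length(ref) - ti
  if (tv == 0L) return(NA_real_)
  ti / tv
}

#' Cohort Ti:Tv ratios per frequency bin, split by zygosity
#'
#' For every bin, collects the SNV alt alleles called in each sample at the
#' requested zygosity and computes the Ti:Tv ratio either per sample and
#' then averaged (`"per_sample_mean"`, the default) or pooled across the
#' cohort (`"pooled"`).
#'
#' @param cohort multi-sample [callset()] with genotypes
#' @param bins result of [call_frequency_bins()]
#' @param zygosity `"hom"` or `"het"`
#' @param average `"per_sample_mean"` or `"pooled"`
#' @return data.table: `bin`, `titv`
#' @export
cohort_titv <- function(cohort, bins, zygosity = c("hom", "het"),
                        average = c("per_sample_mean", "pooled")) {
  zygosity <- match.arg(zygosity)
  average <- match.arg(average)
  binned <- bins[!is.na(bin)]
  K_bins <- sort(unique(binned$bin))
  res <- lapply(K_bins, function(b) {
    sub <- binned[bin == b]
    per_sample <- lapply(seq_along(cohort$samples), function(s) {
      refs <- character(); alts <- character()
      for (k in seq_len(nrow(sub))) {
        r <- cohort$records[[sub$i[k]]]
        if (!rec_is_snp(variant_record(r$contig, r$pos0, r$ref,
                                       r$alt[sub$j[k]]))) next
        car <- gt_carriers(r, sub$j[k])
        hit <- if (zygosity == "hom") car$hom[s] else car$het[s]
        if (hit) { refs <- c(refs, r$ref); alts <- c(alts, r$alt[sub$j[k]]) }
      }
      list(ref = refs, alt = alts)
    })
    titv <- if (average == "pooled") {
      titv_ratio(unlist(lapply(per_sample, `[[`, "ref")),
                 unlist(lapply(per_sample, `[[`, "alt")))
    } else {
      vals <- vapply(per_sample, function(p) titv_ratio(p$ref, p$alt), 0.0)
      if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
    }
    data.table::data.table(bin = b, titv = titv)
  })
  data.table::rbindlist(res)
}

rec_alt_is_frameshift <- function(r, j) {
  d <- abs(nchar(r$ref) - nchar(r$alt[j]))
  d > 0L && d %% 3L != 0L
}

#' Count positions with frameshift indel calls inside regions
#'
#' An indel is a frameshift iff the ref/alt length difference is not a
#' multiple of 3. Positions are counted once regardless of how many samples
#' or alleles carry a frameshift; the homozygous subset counts positions
#' where at least one sample is homozygous for a frameshift allele. A
#' position counts when its record span intersects any region interval, so
#' adding intervals never decreases the counts.
#'
#' @param cohort multi-sample [callset()] with genotypes
#' @param regions non-empty list of [genomic_interval()]s (e.g. CDS regions)
#' @return list with `positions_with_frameshift` and `homozygous_positions`
#' @export
frameshift_counts <- function(cohort, regions) {
  if (!length(regions)) stop("regions must be non-empty")
  pos_any <- character(); pos_hom <- character()
  for (r in cohort$records) {
    if (!rec_overlaps_regions(r, regions)) next
    key <- paste0(r$contig, ":", r$pos0)
    for (j in seq_along(r$alt)) {
      if (!rec_alt_is_frameshift(r, j)) next
      car <- gt_carriers(r, j)
      if (any(car$hom | car$het)) pos_any <- c(pos_any, key)
      if (any(car$hom)) pos_hom <- c(pos_hom, key)
    }
  }
  list(positions_with_frameshift = length(unique(pos_any)),
       homozygous_positions = length(unique(pos_hom)))
}
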