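#' Extend a candidate window to cover all overlapping cohort variants
#'
#' Starting from the candidate's own reference span, the window is widened to
#' the smallest start and the largest end over the candidate plus the cohort
#' variants that overlap it. A single pass: the cohort set is not re-queried
#' after extension (see `requery` in [match_alleles()] for the fixed-point
#' variant).
#'
#' @param candidate a [variant_record()]
#' @param cohort_records list of cohort [variant_record()]s overlapping the
#'   candidate span (may be empty)
#' @return a [genomic_interval()] containing every span in the union set
#' @export
extend_window <- function(candidate, cohort_records) {
  starts <- c(candidate$pos0, vapply(cohort_records, `[[`, 0L, "pos0"))
  ends <- c(rec_end0(candidate), vapply(cohort_records, rec_end0, 0L))
  genomic_interval(candidate$contig, min(starts), max(ends))
}

#' Splice one allele of a variant into a reference window
#'
#' The local haplotype is
#' `ref[window.start, pos0) + allele + ref[pos0 + nchar(ref_allele), window.end)`.
#' Its length is the window length minus the ref-allele length plus the
#' spliced allele length.
#'
#' @param reference a [reference_sequence()]
#' @param window a [genomic_interval()] fully containing the variant span
#' @param variant a [variant_record()]
#' @param allele the reference allele or one of the variant's alt alleles
#' @return the haplotype string, with attributes `window`
#' @export
build_haplotype <- function(reference, window, variant, allele) {
  if (variant$contig != window$contig)
    stop("variant and window on different contigs")
  v_end <- rec_end0(variant)
  if (variant$pos0 < window$start || v_end > window$end)
    stop(sprintf(
      "variant span [%d,%d) exceeds window [%d,%d); extend the window first",
      variant$pos0, v_end, window$start, window$end))
  if (!(allele == variant$ref || allele %in% variant$alt))
    stop("allele '", allele, "' is neither ref nor an alt of the variant")
  left <- ref_fetch(reference, genomic_interval(window$contig, window$start,
                                                variant$pos0))
  right <- ref_fetch(reference, genomic_interval(window$contig, v_end,
                                                 window$end))
  structure(paste0(left, allele, right), window = window)
}

#' Match candidate alleles against a frequency panel by haplotype identity
#'
#' The core matching algorithm. Cohort variants overlapping the candidate's
#' reference span are queried; the window is extended to cover every span in
#' the union set; each candidate alt haplotype is compared by exact string
#' equality against every cohort alt haplotype spliced into the same
#' extended window. Because both representations are expanded into full
#' window sequences, differently represented but equivalent alleles (e.g. a
#' left-aligned versus right-aligned indel in a repeat run, or a padded
#' record) match exactly. Haplotypes are built one variant-allele at a time:
#' no combined multi-variant haplotypes are formed.
#'
#' When several cohort alleles match one candidate haplotype the maximum
#' frequency is kept and the collision logged (duplicate panel entries for
#' one physical haplotype are not double counted).
#'
#' @param candidate a [variant_record()]
#' @param freq_panel a [compute_frequencies()] result
#' @param reference a [reference_sequence()] covering the extended window
#' @param grouping grouping label whose frequencies are looked up
#' @param requery if `TRUE`, re-query the cohort after extending and iterate
#'   to a fixed point; the default single pass follows the algorithm as
#'   described
#' @return named numeric vector: candidate alt allele -> matched panel
#'   frequency, `0.0` for unmatched alleles. Attribute `window` holds the
#'   extended window used.
#' @export
match_alleles <- function(candidate, freq_panel, reference, grouping = "ALL",
                          requery = FALSE) {
  w0 <- genomic_interval(candidate$contig, candidate$pos0, rec_end0(candidate))
  cohort <- query_overlapping(freq_panel, w0)
  win <- extend_window(candidate, cohort)
  if (requery) {
    repeat {
      cohort2 <- query_overlapping(freq_panel, win)
      win2 <- extend_window(candidate, cohort2)
      if (win2$start == win$start && win2$end == win$end) {
        cohort <- cohort2
        break
      }
      win <- win2
      cohort <- cohort2
    }
  }
  idx <- attr(cohort, "idx")
  af <- setNames(numeric(length(candidate$alt)), candidate$alt)
  if (!length(cohort)) return(structure(af, window = win))
  cand_haps <- vapply(candidate$alt, function(a)
    build_haplotype(reference, win, candidate, a), "")
  n_coll <- 0L
  for (k in seq_along(cohort)) {
    u <- cohort[[k]]
    u_af <- panel_af(freq_panel, idx[k], grouping)
    for (j in seq_along(u$alt)) {
      hap_u <- build_haplotype(reference, win, u, u$alt[j])
      hit <- which(cand_haps == hap_u)
      for (h in hit) {
        if (af[h] > 0 && af[h] != u_af[j]) n_coll <- n_coll + 1L
        af[h] <- max(af[h], u_af[j])
      }
    }
  }
  if (n_coll > 0L)
    pa_log("%s:%d: %d duplicate cohort haplotype match(es); kept max frequency",
           candidate$contig, candidate$pos0 + 1L, n_coll)
  structure(af, window = win)
}

# per-reference-position expansion of an aligned read:
# a character vector indexed by reference offset, where matched/mismatched
# bases sit at their position, deletions contribute "" and insertion bases
# are appended to the preceding reference position's entry (the VCF anchor
# convention)
read_piece_map <- function(read) {
  ops <- cigar_ops(read$cigar)
  ref_len <- sum(ops$len[ops$op %in% c("M", "D", "=", "X")])
  pieces <- character(ref_len)
  rp <- 0L  # offset from read$start0
  qp <- 0L  # consumed query bases
  for (k in seq_along(ops$op)) {
    op <- ops$op[k]; len <- ops$len[k]
    if (op %in% c("M", "=", "X")) {
      pieces[(rp + 1L):(rp + len)] <-
        substring(read$bases, qp + (1:len), qp + (1:len))
      rp <- rp + len; qp <- qp + len
    } else if (op == "I") {
      ins <- substr(read$bases, qp + 1L, qp + len)
      if (rp >= 1L) pieces[rp] <- paste0(pieces[rp], ins)
      qp <- qp + len
    } else if (op == "D") {
      pieces[(rp + 1L):(rp + len)] <- ""
      rp <- rp + len
    } else if (op == "S") {
      qp <- qp + len
    } else stop("unsupported CIGAR op: ", op)
  }
  list(start0 = read$start0, pieces = pieces)
}

# the allele a read exhibits over the candidate's reference span, or NA if
# the read does not fully cover the span
read_observed_allele <- function(read, candidate) {
  if (read$contig != candidate$contig) return(NA_character_)
  pm <- read_piece_map(read)
  lo <- candidate$pos0 - pm$start0
  hi <- rec_end0(candidate) - pm$start0
  if (lo < 0L || hi > length(pm$pieces)) return(NA_character_)
  paste(pm$pieces[(lo + 1L):hi], collapse = "")
}

#' Assign each read the panel frequency of the allele it supports
#'
#' A read carrying a matched alt allele at the candidate site receives that
#' allele's dictionary frequency; a read matching the reference allele
#' receives `1 - sum(matched alt frequencies)` floored at zero; a read
#' carrying any other allele receives `0.0`. Reads that do not fully cover
#' the candidate span are skipped (`NA`, logged).
#'
#' @param reads list of [aligned_read()]s
#' @param candidate a [variant_record()]
#' @param af_dict named frequency vector from [match_alleles()]
#' @return numeric vector, one frequency per read (`NA` for skipped reads)
#' @export
annotate_reads <- function(reads, candidate, af_dict) {
  ref_freq <- max(0, 1 - sum(af_dict))
  out <- vapply(reads, function(rd) {
    obs <- read_observed_allele(rd, candidate)
    if (is.na(obs)) return(NA_real_)
    if (obs == candidate$ref) return(ref_freq)
    j <- match(obs, names(af_dict))
    if (!is.na(j)) unname(af_dict[j]) else 0.0
  }, 0.0)
  n_skip <- sum(is.na(out))
  if (n_skip > 0L)
    pa_log("%d read(s) not fully covering candidate span skipped", n_skip)
  out
}

#' Annotate every record of a callset with matched panel frequencies
#'
#' Runs [match_alleles()] per record and fills `per-alt` AF slots. A summary
#' of matched and zero-frequency records is logged and attached as the
#' `annotation_summary` attribute.
#'
#' @inheritParams match_alleles
#' @param cs a [callset()]
#' @return the callset with every record's `af` filled
#' @export
annotate_callset <- function(cs, freq_panel, reference, grouping = "ALL",
                             requery = FALSE) {
  stopifnot(inherits(cs, "callset"))
  n_zero <- 0L
  recs <- lapply(cs$records, function(r) {
    d <- match_alleles(r, freq_panel, reference, grouping, requery = requery)
    r$af <- as.numeric(d)
    if (all(r$af == 0)) n_zero <<- n_zero + 1L
    r
  })
  pa_log("annotated %d record(s): %d matched, %d all-zero frequency",
         length(recs), length(recs) - n_zero, n_zero)
  out <- callset(recs, samples = cs$samples, source = cs$source)
  attr(out, "annotation_summary") <-
    c(total = length(recs), matched = length(recs) - n_zero, zero = n_zero)
  out
}
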