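#' Genomic interval (0-based, half-open)
#'
#' All internal coordinates in popaf are 0-based half-open `[start, end)`,
#' the BED convention. Conversion to/from the 1-based VCF convention happens
#' only inside [read_vcf()] and [write_vcf()].
#'
#' @param contig contig name (non-empty string)
#' @param start 0-based inclusive start
#' @param end 0-based exclusive end; must satisfy `start <= end`
#' @return an object of class `genomic_interval`
#' @export
genomic_interval <- function(contig, start, end) {
  stopifnot(is.character(contig), length(contig) == 1L, nzchar(contig))
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || start > end)
    stop("invalid interval: need 0 <= start <= end, got [", start, ", ", end, ")")
  structure(list(contig = contig, start = start, end = end),
            class = "genomic_interval")
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("<interval> %s:[%d,%d)\n", x$contig, x$start, x$end))
  invisible(x)
}

#' A single variant record
#'
#' Represents one VCF-style record with 0-based start coordinate. The
#' reference span of the record is `[pos0, pos0 + nchar(ref))`; an insertion
#' therefore occupies the 1-base span of its anchor base.
#'
#' @param contig contig name
#' @param pos0 0-based start position
#' @param ref reference allele (uppercase DNA, non-empty)
#' @param alt character vector of alternate alleles (uppercase DNA); each must
#'   differ from `ref`
#' @param qual optional quality
#' @param af optional per-alt population allele frequencies in `[0,1]`
#'   (one per alt)
#' @param vaf optional per-alt variant allele fractions in `[0,1]` (fraction
#'   of reads supporting the alt in one sample)
#' @param gt optional per-sample diploid genotype strings such as `"0/1"`;
#'   phased separators are normalized to `/`, missing alleles written `.`
#' @return an object of class `variant_record`
#' @export
variant_record <- function(contig, pos0, ref, alt, qual = NA_real_,
                           af = NULL, vaf = NULL, gt = NULL) {
  ref <- toupper(ref); alt <- toupper(alt)
  stopifnot(is.character(contig), nzchar(contig), length(alt) >= 1L)
  pos0 <- as.integer(pos0)
  if (is.na(pos0) || pos0 < 0L) stop("pos0 must be a non-negative integer")
  if (!is_dna(ref)) stop("ref allele must be non-empty A/C/G/T/N: ", ref)
  if (!all(is_dna(alt))) stop("alt alleles must be non-empty A/C/G/T/N")
  if (any(alt == ref)) stop("alt allele equal to ref at ", contig, ":", pos0 + 1L)
  if (!is.null(af)) {
    if (length(af) != length(alt)) stop("af must have one entry per alt")
    if (any(!is.na(af) & (af < 0 | af > 1))) stop("af outside [0,1]")
  }
  if (!is.null(vaf) && length(vaf) != length(alt))
    stop("vaf must have one entry per alt")
  if (!is.null(gt)) gt <- gsub("|", "/", gt, fixed = TRUE)
  structure(list(contig = contig, pos0 = pos0, ref = ref, alt = alt,
                 qual = qual, af = af, vaf = vaf, gt = gt),
            class = "variant_record")
}

rec_end0 <- function(rec) rec$pos0 + nchar(rec$ref)
rec_span <- function(rec) genomic_interval(rec$contig, rec$pos0, rec_end0(rec))

#' @export
print.variant_record <- function(x, ...) {
  cat(sprintf("<variant> %s:%d %s>%s%s\n", x$contig, x$pos0 + 1L, x$ref,
              paste(x$alt, collapse = ","),
              if (!is.null(x$af)) paste0(" AF=", paste(signif(x$af, 4), collapse = ",")) else ""))
  invisible(x)
}

# parse a vector of genotype strings into an n x 2 integer matrix
# (NA for missing '.'); rejects non-diploid genotypes
gt_matrix <- function(gt) {
  gt <- gsub("|", "/", gt, fixed = TRUE)
  parts <- strsplit(gt, "/", fixed = TRUE)
  n_alleles <- lengths(parts)
  if (any(n_alleles != 2L))
    stop("non-diploid genotype encountered: ", gt[which(n_alleles != 2L)[1L]])
  m <- matrix(suppressWarnings(as.integer(unlist(parts))), ncol = 2L, byrow = TRUE)
  m
}

#' In-memory reference sequence
#'
#' A named set of uppercase contig sequences with an exact substring fetch.
#'
#' @param sequences named character vector, contig name -> DNA string
#' @return an object of class `ref_seq`
#' @export
reference_sequence <- function(sequences) {
  stopifnot(is.character(sequences), !is.null(names(sequences)),
            all(nzchar(names(sequences))))
  sequences <- toupper(sequences)
  structure(list(seq = sequences), class = "ref_seq")
}

#' Fetch a subsequence from a reference
#'
#' @param ref a [reference_sequence()]
#' @param interval a [genomic_interval()]; fetching outside the contig is an
#'   error, and the returned string always has length `end - start`
#' @return DNA string
#' @export
ref_fetch <- function(ref, interval) {
  s <- ref$seq[[interval$contig]]
  if (is.null(s)) stop("unknown contig in reference: ", interval$contig)
  if (interval$end > nchar(s))
    stop(sprintf("fetch [%d,%d) out of range for %s (length %d)",
                 interval$start, interval$end, interval$contig, nchar(s)))
  substr(s, interval$start + 1L, interval$end)
}

ref_contig_lengths <- function(ref) vapply(ref$seq, nchar, integer(1))

#' An aligned read
#'
#' Minimal read model sufficient for pileup rendering: an ungapped or
#' indel-containing local alignment described by a CIGAR string over
#' M/I/D/S operations.
#'
#' @param name read name
#' @param contig contig name
#' @param start0 0-based leftmost reference position of the alignment
#' @param cigar CIGAR string (M, I, D, S operations)
#' @param bases read bases
#' @param quals integer base qualities (one per base)
#' @param mapq mapping quality
#' @param strand `"+"` or `"-"`
#' @return an object of class `aligned_read`
#' @export
aligned_read <- function(name, contig, start0, cigar, bases, quals,
                         mapq = 60L, strand = "+") {
  bases <- toupper(bases)
  ops <- cigar_ops(cigar)
  qlen <- sum(ops$len[ops$op %in% c("M", "I", "S")])
  if (qlen != nchar(bases))
    stop("CIGAR consumes ", qlen, " query bases but read has ", nchar(bases))
  if (length(quals) != nchar(bases))
    stop("need one base quality per base")
  stopifnot(strand %in% c("+", "-"))
  structure(list(name = name, contig = contig, start0 = as.integer(start0),
                 cigar = cigar, bases = bases, quals = as.integer(quals),
                 mapq = as.integer(mapq), strand = strand),
            class = "aligned_read")
}

cigar_ops <- function(cigar) {
  m <- gregexpr("(\\d+)([MIDSHNP=X])", cigar)[[1]]
  if (m[1] == -1L || sum(attr(m, "match.length")) != nchar(cigar))
    stop("unparseable CIGAR: ", cigar)
  toks <- regmatches(cigar, gregexpr("\\d+[MIDSHNP=X]", cigar))[[1]]
  list(op = substr(toks, nchar(toks), nchar(toks)),
       len = as.integer(substr(toks, 1L, nchar(toks) - 1L)))
}

read_ref_end0 <- function(read) {
  ops <- cigar_ops(read$cigar)
  read$start0 + sum(ops$len[ops$op %in% c("M", "D", "N", "=", "X")])
}

#' A callset: an ordered, interval-queryable collection of variant records
#'
#' @param records list of [variant_record()]s (any order; sorted internally
#'   by contig then position)
#' @param samples character vector of sample names (required when records
#'   carry genotypes)
#' @param source free-text label of where the calls came from
#' @return an object of class `callset`
#' @export
callset <- function(records, samples = character(), source = "") {
  stopifnot(is.list(records))
  for (r in records) stopifnot(inherits(r, "variant_record"))
  if (length(samples)) {
    if (anyDuplicated(samples)) stop("duplicate sample ids")
    for (r in records)
      if (!is.null(r$gt) && length(r$gt) != length(samples))
        stop("record genotype count does not match sample count")
  }
  cs <- structure(list(source = source, samples = samples, records = records,
                       index = NULL), class = "callset")
  cs_reindex(cs)
}

cs_reindex <- function(cs) {
  if (!length(cs$records)) {
    cs$index <- data.table::data.table(contig = character(), pos0 = integer(),
                                       end0 = integer(), i = integer())
    return(cs)
  }
  idx <- data.table::data.table(
    contig = vapply(cs$records, `[[`, "", "contig"),
    pos0 = vapply(cs$records, `[[`, 0L, "pos0"),
    end0 = vapply(cs$records, rec_end0, 0L),
    i = seq_along(cs$records))
  data.table::setorderv(idx, c("contig", "pos0", "end0"))
  cs$records <- cs$records[idx$i]
  idx$i <- seq_along(cs$records)
  cs$index <- idx
  cs
}

#' @export
print.callset <- function(x, ...) {
  cat(sprintf("<callset '%s'> %d records, %d samples\n",
              x$source, length(x$records), length(x$samples)))
  invisible(x)
}

#' @export
length.callset <- function(x) length(x$records)

# indices of records whose reference span overlaps [start, end) on contig;
# half-open overlap: a < end && b > start
query_idx <- function(cs, contig, start, end) {
  idx <- cs$index
  idx$i[idx$contig == contig & idx$pos0 < end & idx$end0 > start]
}

#' Query records overlapping an interval
#'
#' Overlap uses half-open semantics: a record with span `[a,b)` overlaps the
#' query `[start,end)` iff `a < end` and `b > start`. Insertions occupy the
#' single-base span of their VCF anchor base. An unknown contig yields an
#' empty result (logged), not an error.
#'
#' @param x a [callset()] or [frequency_panel()]
#' @param interval a [genomic_interval()]
#' @param ... unused
#' @return list of matching [variant_record()]s, with the attribute `idx`
#'   giving their indices in the underlying callset
#' @export
query_overlapping <- function(x, interval, ...) UseMethod("query_overlapping")

#' @export
query_overlapping.callset <- function(x, interval, ...) {
  if (!interval$contig %in% x$index$contig) {
    pa_log("query on unknown contig '%s': empty result", interval$contig)
    return(structure(list(), idx = integer()))
  }
  i <- query_idx(x, interval$contig, interval$start, interval$end)
  structure(x$records[i], idx = i)
}
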