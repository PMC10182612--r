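#' Parameters of the logarithmic allele-frequency intensity transform
#'
#' @param af_floor frequencies at or below this value map to intensity 0;
#'   the default 1e-4 sits below one allele in a ~5,000-haplotype panel
#' @param max_intensity intensity of frequency 1 (default 254, the usual
#'   8-bit pileup ceiling)
#' @return an object of class `transform_params`
#' @export
transform_params <- function(af_floor = 1e-4, max_intensity = 254L) {
  stopifnot(af_floor > 0, af_floor < 1, max_intensity >= 1L)
  structure(list(af_floor = af_floor, max_intensity = as.integer(max_intensity)),
            class = "transform_params")
}

#' Log-transform an allele frequency into a pileup intensity
#'
#' `intensity = round(max_intensity * max(0, 1 - log10(af) / log10(af_floor)))`
#' for `af > af_floor`; frequencies of zero or at/below the floor map to 0.
#' The transform is monotone non-decreasing, maps the floor to 0 and
#' frequency 1 to `max_intensity` exactly, and concentrates resolution at
#' low frequencies where the biological signal of interest (rare variants)
#' lives.
#'
#' @param af numeric vector of frequencies in `[0, 1]`
#' @param params a [transform_params()]
#' @return integer intensities in `[0, max_intensity]`
#' @export
transform_af <- function(af, params = transform_params()) {
  if (any(is.na(af)) || any(af < 0 | af > 1))
    stop("allele frequencies must lie in [0,1]")
  out <- integer(length(af))
  pos <- af > params$af_floor
  if (any(pos)) {
    frac <- pmax(0, pmin(1, 1 - log10(af[pos]) / log10(params$af_floor)))
    out[pos] <- as.integer(round(params$max_intensity * frac))
  }
  out
}

reads_render_order <- function(reads) {
  order(vapply(reads, `[[`, 0L, "start0"), vapply(reads, `[[`, "", "name"))
}

#' Render the allele-frequency channel of a pileup image
#'
#' One row per read (sorted by alignment start, then name), one column per
#' window position. Each row is filled uniformly with the transformed
#' frequency of the allele the read supports at the candidate site
#' ([annotate_reads()]); columns outside the read's aligned reference span
#' are 0. The same read may receive different intensities in pileups of
#' different candidates, since the supported allele is candidate-specific.
#'
#' @param reads list of [aligned_read()]s overlapping the candidate
#' @param candidate a [variant_record()]
#' @param af_dict named frequencies from [match_alleles()]
#' @param params a [transform_params()]
#' @param window a [genomic_interval()] defining the columns
#' @return integer matrix reads x window-width (0 rows if no reads)
#' @export
render_af_channel <- function(reads, candidate, af_dict,
                              params = transform_params(), window) {
  width <- window$end - window$start
  if (!length(reads)) return(matrix(0L, nrow = 0L, ncol = width))
  reads <- reads[reads_render_order(reads)]
  freqs <- annotate_reads(reads, candidate, af_dict)
  m <- matrix(0L, nrow = length(reads), ncol = width)
  for (i in seq_along(reads)) {
    if (is.na(freqs[i])) next
    lo <- max(reads[[i]]$start0, window$start) - window$start
    hi <- min(read_ref_end0(reads[[i]]), window$end) - window$start
    if (hi > lo) m[i, (lo + 1L):hi] <- transform_af(freqs[i], params)
  }
  m
}

# linear channel scalings for the six stand-in base channels; documented,
# deliberately simple (exact production rendering is the upstream caller's)
base_intensity <- function(base, max_intensity) {
  v <- c(A = 0.25, C = 0.5, G = 0.75, T = 1)[base]
  v[is.na(v)] <- 0
  as.integer(round(max_intensity * v))
}

#' Render a full pileup tensor with the allele-frequency channel
#'
#' Produces a reads x positions x 7 integer array. Channels 1-6 are
#' simplified stand-ins for the conventional pileup channels: (1) base
#' identity (A/C/G/T -> 25/50/75/100% of max), (2) base quality (linear,
#' capped at Q60), (3) mapping quality (linear, capped at 60), (4) strand
#' (30% of max for `+`, max for `-`), (5) read supports an alt allele of the
#' candidate (max or 0, row-constant), (6) base differs from the local
#' reference (max or 0). Channel 7 is the allele-frequency channel and
#' equals [render_af_channel()] exactly.
#'
#' @inheritParams render_af_channel
#' @param reference a [reference_sequence()] covering the window
#' @return integer array with `dim = c(n_reads, window width, 7)`
#' @export
render_pileup <- function(reads, reference, candidate, window, af_dict,
                          params = transform_params()) {
  if (window$contig != candidate$contig ||
      candidate$pos0 < window$start || rec_end0(candidate) > window$end)
    stop("window must contain the candidate span on the same contig")
  width <- window$end - window$start
  ref_win <- strsplit(ref_fetch(reference, window), "")[[1]]
  reads <- reads[reads_render_order(reads)]
  tens <- array(0L, dim = c(length(reads), width, 7L))
  if (!length(reads)) return(tens)
  mx <- params$max_intensity
  freqs <- annotate_reads(reads, candidate, af_dict)
  for (i in seq_along(reads)) {
    rd <- reads[[i]]
    pm <- read_piece_map(rd)
    obs <- read_observed_allele(rd, candidate)
    supports <- !is.na(obs) && obs %in% candidate$alt
    qp <- 0L
    ops <- cigar_ops(rd$cigar)
    # per-reference-position base and quality (first base of each piece)
    for (off in seq_along(pm$pieces)) {
      col <- pm$start0 + off - window$start
      if (col < 1L || col > width) next
      piece <- pm$pieces[off]
      if (nchar(piece) == 0L) {  # deletion: differs from ref, no base
        tens[i, col, 6L] <- mx
        tens[i, col, 3L] <- as.integer(round(mx * min(rd$mapq, 60L) / 60))
        tens[i, col, 4L] <- if (rd$strand == "+") as.integer(round(mx * 0.3)) else mx
        if (supports) tens[i, col, 5L] <- mx
        next
      }
      b <- substr(piece, 1L, 1L)
      tens[i, col, 1L] <- base_intensity(b, mx)
      tens[i, col, 3L] <- as.integer(round(mx * min(rd$mapq, 60L) / 60))
      tens[i, col, 4L] <- if (rd$strand == "+") as.integer(round(mx * 0.3)) else mx
      if (supports) tens[i, col, 5L] <- mx
      if (nchar(piece) > 1L || b != ref_win[col]) tens[i, col, 6L] <- mx
    }
    # base qualities need query coordinates; walk the cigar once more
    rp <- rd$start0
    for (k in seq_along(ops$op)) {
      op <- ops$op[k]; len <- ops$len[k]
      if (op %in% c("M", "=", "X")) {
        for (u in seq_len(len)) {
          col <- rp + u - window$start
          if (col >= 1L && col <= width)
            tens[i, col, 2L] <- as.integer(round(mx * min(rd$quals[qp + u], 60L) / 60))
        }
        rp <- rp + len; qp <- qp + len
      } else if (op == "I") qp <- qp + len
      else if (op == "D") rp <- rp + len
      else if (op == "S") qp <- qp + len
    }
  }
  tens[, , 7L] <- render_af_channel(reads, candidate, af_dict, params, window)
  tens
}

#' Export a pileup tensor as one TSV per channel
#'
#' @param tensor array from [render_pileup()]
#' @param dir output directory; files `channel_1.tsv` ... `channel_7.tsv`
#' @return vector of file paths
#' @export
write_pileup_tsv <- function(tensor, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(dim(tensor)[3])
  for (ch in seq_len(dim(tensor)[3])) {
    p <- file.path(dir, sprintf("channel_%d.tsv", ch))
    utils::write.table(tensor[, , ch, drop = TRUE], p, sep = "\t",
                       row.names = FALSE, col.names = FALSE)
    paths[ch] <- p
  }
  paths
}
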