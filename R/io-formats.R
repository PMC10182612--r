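#' Read a VCF file into a callset
#'
#' Ingests VCF 4.2 via vcfR. The 1-based VCF POS becomes the 0-based `pos0`;
#' alleles are uppercased; phased genotype separators are normalized to `/`.
#' Records with symbolic or breakend ALT alleles (`<DEL>`, `]chr1:...]`, `*`)
#' are skipped with a logged count, because haplotype splicing needs literal
#' sequence. Multi-allelic records are preserved as single records. Per-alt
#' `AF` and `VAF` INFO fields (Number=A) are mapped onto the records when
#' present.
#'
#' @param path VCF file
#' @param region optional [genomic_interval()]; only overlapping records kept
#' @param source label stored on the callset (defaults to the file name)
#' @return a [callset()]
#' @export
read_vcf <- function(path, region = NULL, source = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("malformed VCF ", path, ": ",
                                         conditionMessage(e)))
  fix <- v@fix
  n_header <- length(v@meta) + 1L  # meta lines + #CHROM line
  samples <- character()
  gt_raw <- NULL
  if (ncol(v@gt) >= 2L) {
    samples <- colnames(v@gt)[-1L]
    gt_raw <- v@gt
  }
  records <- vector("list", nrow(fix))
  n_sym <- 0L
  keep <- logical(nrow(fix))
  for (k in seq_len(nrow(fix))) {
    alt <- strsplit(fix[k, "ALT"], ",", fixed = TRUE)[[1]]
    if (is.na(fix[k, "ALT"]) || any(!grepl("^[ACGTNacgtn]+$", alt))) {
      n_sym <- n_sym + 1L
      next
    }
    pos <- suppressWarnings(as.integer(unname(fix[k, "POS"])))
    ref <- unname(toupper(fix[k, "REF"]))
    if (is.na(pos) || !is_dna(ref))
      stop(sprintf("parse error in %s at line %d: bad POS/REF", path,
                   n_header + k))
    info <- unname(fix[k, "INFO"])
    af <- parse_info_numeric(info, "AF", length(alt))
    vaf <- parse_info_numeric(info, "VAF", length(alt))
    gt <- NULL
    if (!is.null(gt_raw)) {
      fmt <- strsplit(gt_raw[k, 1L], ":", fixed = TRUE)[[1]]
      gi <- match("GT", fmt)
      if (!is.na(gi)) {
        cells <- gt_raw[k, -1L]
        gt <- unname(vapply(strsplit(cells, ":", fixed = TRUE), function(x)
          if (length(x) >= gi) x[gi] else "./.", ""))
        gt[is.na(gt)] <- "./."
      }
    }
    qual <- suppressWarnings(as.numeric(unname(fix[k, "QUAL"])))
    rec <- tryCatch(
      variant_record(unname(fix[k, "CHROM"]), pos - 1L, ref, toupper(alt),
                     qual = qual, af = af, vaf = vaf, gt = gt),
      error = function(e) stop(sprintf("parse error in %s at line %d: %s",
                                       path, n_header + k,
                                       conditionMessage(e))))
    records[[k]] <- rec
    keep[k] <- TRUE
  }
  if (n_sym > 0L) pa_log("%s: skipped %d record(s) with symbolic ALTs",
                         path, n_sym)
  records <- records[keep]
  cs <- callset(records, samples = samples, source = source)
  attr(cs, "n_symbolic_skipped") <- n_sym
  if (!is.null(region)) {
    i <- query_idx(cs, region$contig, region$start, region$end)
    cs <- callset(cs$records[i], samples = samples, source = source)
  }
  cs
}

parse_info_numeric <- function(info, key, n_alt) {
  if (is.na(info)) return(NULL)
  m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]+"), info))
  if (!length(m)) return(NULL)
  vals <- suppressWarnings(as.numeric(strsplit(sub(paste0(".*", key, "="), "",
                                                   m), ",")[[1]]))
  if (length(vals) != n_alt) return(NULL)
  vals
}

#' Write a callset to a VCF 4.2 file
#'
#' Per-alt allele frequencies are written as the `AF` INFO key (Number=A,
#' Type=Float) and per-alt variant allele fractions as `VAF`; genotypes are
#' written as a `GT` FORMAT column per sample when present.
#'
#' @param cs a [callset()]
#' @param path output file
#' @param contig_lengths optional named integer vector; emitted as
#'   `##contig` header lines
#' @return `path`, invisibly
#' @export
write_vcf <- function(cs, path, contig_lengths = NULL) {
  stopifnot(inherits(cs, "callset"))
  hdr <- c("##fileformat=VCFv4.2",
           "##source=popaf",
           '##INFO=<ID=AF,Number=A,Type=Float,Description="Panel allele frequency per ALT allele">',
           '##INFO=<ID=VAF,Number=A,Type=Float,Description="Variant allele fraction per ALT allele">')
  if (!is.null(contig_lengths)) {
    if (anyDuplicated(names(contig_lengths))) stop("duplicate contig names")
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
                          as.integer(contig_lengths)))
  }
  has_gt <- length(cs$samples) > 0L
  if (has_gt)
    hdr <- c(hdr, '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (has_gt) cols <- c(cols, "FORMAT", cs$samples)
  hdr <- c(hdr, paste(cols, collapse = "\t"))
  fmt_num <- function(x) sub("\\.?0+$", "", sprintf("%.6f", x))
  lines <- vapply(cs$records, function(r) {
    info <- character()
    if (!is.null(r$af)) info <- c(info, paste0("AF=", paste(fmt_num(r$af), collapse = ",")))
    if (!is.null(r$vaf)) info <- c(info, paste0("VAF=", paste(fmt_num(r$vaf), collapse = ",")))
    fields <- c(r$contig, r$pos0 + 1L, ".", r$ref, paste(r$alt, collapse = ","),
                if (is.na(r$qual)) "." else fmt_num(r$qual), ".",
                if (length(info)) paste(info, collapse = ";") else ".")
    if (has_gt) {
      gt <- r$gt
      if (is.null(gt)) gt <- rep("./.", length(cs$samples))
      fields <- c(fields, "GT", gt)
    }
    paste(fields, collapse = "\t")
  }, "")
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read a BED3+ file
#'
#' BED is already 0-based half-open, matching popaf's internal convention,
#' so coordinates are passed through unchanged. Overlapping intervals are
#' not merged.
#'
#' @param path BED file with at least 3 columns
#' @return list of [genomic_interval()]s
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) return(list())
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 3L) stop("BED file needs at least 3 columns: ", path)
  lapply(seq_len(nrow(df)), function(i)
    genomic_interval(df[i, 1], df[i, 2], df[i, 3]))
}

#' Write intervals as BED3
#' @param intervals list of [genomic_interval()]s
#' @param path output file
#' @export
write_bed <- function(intervals, path) {
  lines <- vapply(intervals, function(iv)
    paste(iv$contig, iv$start, iv$end, sep = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTA reference
#' @param path FASTA file
#' @return a [reference_sequence()]
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(ss))
  reference_sequence(seqs)
}

#' Write a reference to FASTA (plus .fai index)
#' @param ref a [reference_sequence()]
#' @param path output FASTA path
#' @export
write_fasta <- function(ref, path) {
  ss <- Biostrings::DNAStringSet(ref$seq)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  tryCatch(Rsamtools::indexFa(path), error = function(e) NULL)
  invisible(path)
}

#' Read a sample-to-population map
#'
#' Tab-separated file with header columns `sample`, `population`,
#' `superpopulation`.
#'
#' @param path TSV file
#' @return data.table with those three columns; sample ids must be unique
#' @export
read_sample_map <- function(path) {
  df <- data.table::as.data.table(
    utils::read.table(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE))
  need <- c("sample", "population", "superpopulation")
  if (!all(need %in% names(df)))
    stop("sample map must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$sample)) stop("duplicate sample ids in sample map")
  df[, need, with = FALSE]
}

#' Write a sample map TSV
#' @param sample_map data.table/data.frame with sample, population,
#'   superpopulation columns
#' @param path output file
#' @export
write_sample_map <- function(sample_map, path) {
  utils::write.table(sample_map, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write reads to a SAM file
#' @param reads list of [aligned_read()]s
#' @param path output SAM path
#' @param contig_lengths named integer vector for the `@SQ` header lines
#' @export
write_sam <- function(reads, path, contig_lengths) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths),
                   as.integer(contig_lengths)))
  ord <- order(vapply(reads, `[[`, "", "contig"),
               vapply(reads, `[[`, 0L, "start0"),
               vapply(reads, `[[`, "", "name"))
  lines <- vapply(reads[ord], function(r) {
    flag <- if (r$strand == "-") 16L else 0L
    paste(r$name, flag, r$contig, r$start0 + 1L, r$mapq, r$cigar, "*", 0L, 0L,
          r$bases, rawToChar(as.raw(r$quals + 33L)), sep = "\t")
  }, "")
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read aligned reads from a SAM/BAM file
#'
#' SAM input is converted with Rsamtools and scanned back; hard-clipped or
#' unmapped records are dropped.
#'
#' @param path SAM or BAM file
#' @return list of [aligned_read()]s
#' @export
read_sam <- function(path) {
  bam <- path
  if (!grepl("\\.bam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- suppressMessages(Rsamtools::asBam(path, destination = dest,
                                             overwrite = TRUE,
                                             indexDestination = FALSE))
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "cigar", "seq", "qual", "mapq", "strand"))
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  keep <- !is.na(x$pos)
  lapply(which(keep), function(i) {
    aligned_read(name = x$qname[i], contig = as.character(x$rname[i]),
                 start0 = x$pos[i] - 1L, cigar = x$cigar[i],
                 bases = as.character(x$seq[i]),
                 quals = as.integer(charToRaw(as.character(x$qual[i]))) - 33L,
                 mapq = x$mapq[i], strand = as.character(x$strand[i]))
  })
}
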