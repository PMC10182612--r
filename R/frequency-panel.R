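#' Build population groupings from a sample map
#'
#' Always includes the `ALL` grouping (every panel sample); adds one grouping
#' per superpopulation label present in the map.
#'
#' @param sample_map data.table from [read_sample_map()]
#' @param samples panel sample ids (defaults to every sample in the map)
#' @return named list of character vectors of member sample ids
#' @export
population_groupings <- function(sample_map, samples = sample_map$sample) {
  g <- list(ALL = samples)
  sm <- sample_map[sample_map$sample %in% samples, ]
  for (sp in sort(unique(sm$superpopulation)))
    g[[sp]] <- sm$sample[sm$superpopulation == sp]
  g
}

#' Compute per-population allele frequencies from a panel callset
#'
#' For every record and every grouping, the frequency of each alternate
#' allele is its allele count among grouping members divided by
#' `ploidy * n_members`. Missing genotype alleles are counted as reference
#' (the missing-to-ref fill), so every site in a grouping shares the same
#' denominator. When a record also carries precomputed `AF` INFO values,
#' genotypes win and disagreements beyond 1e-6 are logged. Panels without
#' genotypes fall back to their `AF` tags under the single grouping `ALL`.
#'
#' @param panel_callset multi-sample [callset()] with genotypes
#' @param groupings named list of member sample-id vectors, e.g. from
#'   [population_groupings()]; defaults to `ALL` = every panel sample
#' @param ploidy fixed at 2; non-diploid genotypes are rejected
#' @return an object of class `frequency_panel`
#' @export
compute_frequencies <- function(panel_callset,
                                groupings = list(ALL = panel_callset$samples),
                                ploidy = 2L) {
  stopifnot(inherits(panel_callset, "callset"))
  if (ploidy != 2L) stop("only diploid panels are supported")
  has_gt <- length(panel_callset$samples) > 0L &&
    any(vapply(panel_callset$records, function(r) !is.null(r$gt), TRUE))
  if (!has_gt) {
    if (!all(vapply(panel_callset$records, function(r) !is.null(r$af), TRUE)))
      stop("panel has neither genotypes nor AF tags")
    counts <- list(ALL = lapply(panel_callset$records, function(r) NULL))
    fp <- structure(list(callset = panel_callset, groupings = list(ALL = character()),
                         counts = NULL, denom = c(ALL = NA_integer_),
                         af_only = TRUE, n_samples = 0L, ploidy = ploidy),
                    class = "frequency_panel")
    return(fp)
  }
  for (lab in names(groupings)) {
    missing_ids <- setdiff(groupings[[lab]], panel_callset$samples)
    if (length(missing_ids))
      stop("grouping '", lab, "' members absent from panel: ",
           paste(missing_ids, collapse = ", "))
    if (!length(groupings[[lab]])) stop("grouping '", lab, "' is empty")
  }
  member_idx <- lapply(groupings, match, panel_callset$samples)
  denom <- vapply(member_idx, function(ix) ploidy * length(ix), 0L)
  n_mismatch <- 0L
  counts <- lapply(names(groupings), function(lab) {
    ix <- member_idx[[lab]]
    lapply(panel_callset$records, function(r) {
      if (is.null(r$gt)) return(rep(0L, length(r$alt)))
      gm <- gt_matrix(r$gt[ix])
      alleles <- as.vector(gm)
      vapply(seq_along(r$alt), function(j)
        sum(alleles == j, na.rm = TRUE), 0L)  # NA (missing) counts as ref
    })
  })
  names(counts) <- names(groupings)
  if ("ALL" %in% names(groupings)) {
    for (k in seq_along(panel_callset$records)) {
      r <- panel_callset$records[[k]]
      if (!is.null(r$af)) {
        gt_af <- counts[["ALL"]][[k]] / denom[["ALL"]]
        if (any(abs(gt_af - r$af) > 1e-6, na.rm = TRUE)) n_mismatch <- n_mismatch + 1L
      }
    }
    if (n_mismatch > 0L)
      pa_log("genotype-derived AF disagrees with AF tag at %d site(s); genotypes win",
             n_mismatch)
  }
  structure(list(callset = panel_callset, groupings = groupings,
                 counts = counts, denom = denom, af_only = FALSE,
                 n_samples = length(panel_callset$samples), ploidy = ploidy),
            class = "frequency_panel")
}

#' @export
print.frequency_panel <- function(x, ...) {
  cat(sprintf("<frequency panel> %d sites, %d samples, groupings: %s\n",
              length(x$callset$records), x$n_samples,
              paste(names(x$groupings), collapse = ", ")))
  invisible(x)
}

#' Per-alt allele frequencies of one panel record
#'
#' @param panel a [compute_frequencies()] result
#' @param i record index in `panel$callset`
#' @param grouping grouping label
#' @return numeric vector, one frequency per alt allele
#' @export
panel_af <- function(panel, i, grouping = "ALL") {
  if (isTRUE(panel$af_only)) {
    if (grouping != "ALL") stop("AF-tag panel has only the ALL grouping")
    af <- panel$callset$records[[i]]$af
    if (is.null(af)) stop("record ", i, " has no AF tag")
    return(af)
  }
  if (!grouping %in% names(panel$counts)) stop("unknown grouping: ", grouping)
  panel$counts[[grouping]][[i]] / panel$denom[[grouping]]
}

# reference-allele frequency: (denom - sum alt counts) / denom
panel_ref_freq <- function(panel, i, grouping = "ALL") {
  if (isTRUE(panel$af_only)) return(1 - sum(panel$callset$records[[i]]$af))
  (panel$denom[[grouping]] - sum(panel$counts[[grouping]][[i]])) /
    panel$denom[[grouping]]
}

#' Remove samples from a panel callset
#'
#' @param panel_callset multi-sample [callset()]
#' @param samples sample ids to drop, or a population/superpopulation label
#'   resolved through `sample_map`
#' @param sample_map optional map used to resolve a label
#' @return the callset with those samples (and their genotype columns)
#'   removed; frequencies computed downstream shrink their denominators
#'   accordingly
#' @export
exclude_samples <- function(panel_callset, samples, sample_map = NULL) {
  stopifnot(inherits(panel_callset, "callset"))
  if (!is.null(sample_map) && length(samples) == 1L &&
      !samples %in% panel_callset$samples) {
    hit <- sample_map$sample[sample_map$population == samples |
                               sample_map$superpopulation == samples]
    if (!length(hit)) stop("label '", samples, "' matches no sample or population")
    samples <- hit
  }
  unknown <- setdiff(samples, panel_callset$samples)
  if (length(unknown))
    stop("samples not in panel: ", paste(unknown, collapse = ", "))
  keep <- !(panel_callset$samples %in% samples)
  if (!any(keep)) stop("cannot exclude every sample from the panel")
  recs <- lapply(panel_callset$records, function(r) {
    if (!is.null(r$gt)) r$gt <- r$gt[keep]
    r
  })
  callset(recs, samples = panel_callset$samples[keep],
          source = panel_callset$source)
}

#' @export
query_overlapping.frequency_panel <- function(x, interval, ...) {
  query_overlapping(x$callset, interval, ...)
}

#' Write one frequency VCF per grouping
#'
#' @param panel a `frequency_panel`
#' @param dir output directory; files are named `freq_<grouping>.vcf`
#' @param contig_lengths optional named lengths for the VCF header
#' @return named vector of file paths
#' @export
write_frequency_vcfs <- function(panel, dir, contig_lengths = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- character()
  for (lab in names(panel$groupings)) {
    recs <- lapply(seq_along(panel$callset$records), function(i) {
      r <- panel$callset$records[[i]]
      r$af <- panel_af(panel, i, lab)
      r$gt <- NULL
      r
    })
    path <- file.path(dir, paste0("freq_", lab, ".vcf"))
    write_vcf(callset(recs, source = paste0("freq:", lab)), path,
              contig_lengths = contig_lengths)
    out[lab] <- path
  }
  out
}
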