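#' Configuration of the synthetic cohort generator
#'
#' Defaults emulate a desk-scale slice of a 1000Genomes-style study: a
#' diploid panel of 100 samples drawn from the five continental
#' superpopulations at roughly their 1000Genomes proportions, a rare-skewed
#' Beta(0.3, 1.5) site-frequency spectrum, ~5 segregating sites per kb, 15%
#' indels, 30x read depth with 100 bp reads and a 1e-3 base error rate.
#' Planted homopolymer/tandem runs provide the repeat context needed for
#' representation-equivalence fixtures.
#'
#' @param seed integer seed; every generator output is byte-identical under
#'   a fixed seed and config
#' @param genome_length contig length in bp
#' @param n_contigs number of contigs
#' @param n_samples panel size
#' @param populations named superpopulation proportions (must sum to 1)
#' @param site_density_per_kb segregating sites per kb
#' @param af_beta shape parameters of the Beta site-frequency spectrum
#' @param pop_shift_sd sd of the per-population logit-normal frequency shift
#' @param indel_fraction fraction of sites that are indels
#' @param multiallelic_fraction fraction of SNP sites given a second alt
#' @param repeat_density_per_kb planted repeat runs per kb
#' @param missing_rate fraction of genotypes masked to `./.`
#' @param depth read depth at a simulated site
#' @param read_length read length in bp
#' @param error_rate per-base sequencing error rate
#' @return an object of class `sim_config`
#' @export
sim_config <- function(seed,
                       genome_length = 20000L,
                       n_contigs = 1L,
                       n_samples = 100L,
                       populations = c(AFR = 0.26, AMR = 0.14, EAS = 0.20,
                                       EUR = 0.20, SAS = 0.20),
                       site_density_per_kb = 5,
                       af_beta = c(0.3, 1.5),
                       pop_shift_sd = 0.8,
                       indel_fraction = 0.15,
                       multiallelic_fraction = 0.05,
                       repeat_density_per_kb = 1,
                       missing_rate = 0.02,
                       depth = 30L,
                       read_length = 100L,
                       error_rate = 0.001) {
  stopifnot(abs(sum(populations) - 1) < 1e-9,
            all(c(indel_fraction, multiallelic_fraction, missing_rate,
                  error_rate) >= 0),
            all(c(indel_fraction, multiallelic_fraction, missing_rate,
                  error_rate) <= 1),
            genome_length > 0, n_samples >= 1)
  structure(list(seed = as.integer(seed), genome_length = as.integer(genome_length),
                 n_contigs = as.integer(n_contigs), n_samples = as.integer(n_samples),
                 populations = populations,
                 site_density_per_kb = site_density_per_kb, af_beta = af_beta,
                 pop_shift_sd = pop_shift_sd, indel_fraction = indel_fraction,
                 multiallelic_fraction = multiallelic_fraction,
                 repeat_density_per_kb = repeat_density_per_kb,
                 missing_rate = missing_rate, depth = as.integer(depth),
                 read_length = as.integer(read_length), error_rate = error_rate,
                 ploidy = 2L),
            class = "sim_config")
}

#' Generate a random reference with planted repeat runs
#'
#' Homopolymer and short-tandem runs (unit length 1-3, run length 8-15 bp)
#' are planted at `repeat_density_per_kb`; the run ledger is returned so
#' downstream fixtures know where shiftable indel context exists.
#'
#' @param config a [sim_config()]
#' @return list with `ref` (a [reference_sequence()]) and `runs` (data.table:
#'   contig, start, end, unit)
#' @export
gen_reference <- function(config) {
  with_seed(config$seed + 101L, {
    seqs <- character(config$n_contigs)
    names(seqs) <- paste0("chr", seq_len(config$n_contigs))
    runs <- list()
    for (c_i in seq_len(config$n_contigs)) {
      L <- config$genome_length
      bases <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
      n_runs <- max(0L, round(config$repeat_density_per_kb * L / 1000))
      if (n_runs > 0L) {
        # evenly spaced slots keep runs non-overlapping
        slot <- floor(L / n_runs)
        for (k in seq_len(n_runs)) {
          unit <- paste(sample(c("A", "C", "G", "T"),
                               sample(1:3, 1), replace = TRUE), collapse = "")
          run_len <- sample(8:15, 1)
          lo <- (k - 1L) * slot + 1L
          hi <- k * slot - run_len - 1L
          if (hi <= lo) next
          s <- sample(lo:hi, 1)
          run_seq <- strsplit(strtrim(paste(rep(unit, ceiling(run_len / nchar(unit))),
                                            collapse = ""), run_len), "")[[1]]
          bases[s:(s + run_len - 1L)] <- run_seq
          runs[[length(runs) + 1L]] <- data.table::data.table(
            contig = names(seqs)[c_i], start = s - 1L, end = s + run_len - 1L,
            unit = unit)
        }
      }
      seqs[c_i] <- paste(bases, collapse = "")
    }
    run_dt <- if (length(runs)) data.table::rbindlist(runs) else
      data.table::data.table(contig = character(), start = integer(),
                             end = integer(), unit = character())
    list(ref = reference_sequence(seqs), runs = run_dt)
  })
}

sample_populations <- function(config) {
  n_per <- floor(config$n_samples * config$populations)
  rem <- config$n_samples - sum(n_per)
  if (rem > 0) n_per[seq_len(rem)] <- n_per[seq_len(rem)] + 1L
  rep(names(config$populations), n_per)
}

#' Generate a diploid panel with known per-population allele frequencies
#'
#' Sites are drawn at the configured density; each gets a target frequency
#' from the Beta spectrum, shifted per population on the logit scale;
#' genotypes are sampled per haplotype from the population-specific
#' frequency, then a configurable fraction is masked to missing. The ledger
#' reports, for the ALL grouping and each superpopulation, the alt-allele
#' count of the genotypes actually written with missing alleles counted as
#' reference — the exact quantity [compute_frequencies()] must recover.
#'
#' @param config a [sim_config()]
#' @param reference output of [gen_reference()] (the list, so run context is
#'   available), or a bare [reference_sequence()]
#' @return list with `callset` (multi-sample panel), `sample_map`
#'   (data.table), `ledger` (data.table: contig, pos0, ref, alt, alt_index,
#'   grouping, alt_count, denom)
#' @export
gen_panel <- function(config, reference) {
  runs <- NULL
  if (is.list(reference) && !inherits(reference, "ref_seq")) {
    runs <- reference$runs
    reference <- reference$ref
  }
  with_seed(config$seed + 202L, {
    pops <- sample_populations(config)
    samples <- sprintf("S%03d", seq_len(config$n_samples))
    sample_map <- data.table::data.table(
      sample = samples, population = paste0(pops, "_1"), superpopulation = pops)
    records <- list()
    for (contig in names(reference$seq)) {
      L <- nchar(reference$seq[[contig]])
      n_sites <- max(1L, round(config$site_density_per_kb * L / 1000))
      pos_pool <- 10:(L - 25L)
      # bias some sites into planted runs so shiftable indels exist
      run_pos <- integer()
      if (!is.null(runs) && nrow(runs[runs$contig == contig]) > 0) {
        rr <- runs[runs$contig == contig]
        run_pos <- unlist(lapply(seq_len(nrow(rr)), function(k)
          seq(rr$start[k], rr$end[k] - 4L)))
        run_pos <- run_pos[run_pos >= 10L & run_pos <= L - 25L]
      }
      n_run_sites <- min(length(run_pos), round(0.3 * n_sites))
      pos <- sort(unique(c(
        if (n_run_sites > 0) sample(run_pos, n_run_sites),
        sample(setdiff(pos_pool, run_pos), n_sites - n_run_sites))))
      for (p in pos) {
        anchor <- substr(reference$seq[[contig]], p + 1L, p + 1L)
        is_indel <- runif(1) < config$indel_fraction
        if (is_indel) {
          if (runif(1) < 0.5) {  # deletion
            dlen <- sample(1:3, 1)
            ref_al <- substr(reference$seq[[contig]], p + 1L, p + 1L + dlen)
            alt_al <- anchor
          } else {               # insertion
            ref_al <- anchor
            alt_al <- paste0(anchor, paste(sample(c("A", "C", "G", "T"),
                                                  sample(1:3, 1),
                                                  replace = TRUE), collapse = ""))
          }
          alts <- alt_al
        } else {
          alts <- sample(setdiff(c("A", "C", "G", "T"), anchor), 1)
          ref_al <- anchor
          if (runif(1) < config$multiallelic_fraction)
            alts <- c(alts, sample(setdiff(c("A", "C", "G", "T"),
                                           c(anchor, alts)), 1))
        }
        # per-population target frequency of the site (split over alts)
        base_p <- min(0.95, max(1 / (2 * config$n_samples),
                                rbeta(1, config$af_beta[1], config$af_beta[2])))
        w <- if (length(alts) > 1L) {
          x <- runif(length(alts)); x / sum(x)
        } else 1
        pop_p <- lapply(names(config$populations), function(sp) {
          shift <- rnorm(1, 0, config$pop_shift_sd)
          p_sp <- stats::plogis(stats::qlogis(base_p) + shift)
          p_sp * w
        })
        names(pop_p) <- names(config$populations)
        gt <- vapply(seq_len(config$n_samples), function(s) {
          pv <- pop_p[[pops[s]]]
          draw <- function() {
            u <- runif(1); cum <- cumsum(pv)
            j <- which(u < cum)
            if (length(j)) j[1] else 0L
          }
          a <- sort(c(draw(), draw()))
          paste(a, collapse = "/")
        }, "")
        gt[runif(config$n_samples) < config$missing_rate] <- "./."
        records[[length(records) + 1L]] <-
          variant_record(contig, p, ref_al, alts, gt = gt)
      }
    }
    cs <- callset(records, samples = samples, source = "synthetic_panel")
    groupings <- population_groupings(sample_map, samples)
    ledger <- data.table::rbindlist(lapply(cs$records, function(r) {
      gm <- gt_matrix(r$gt)
      data.table::rbindlist(lapply(names(groupings), function(lab) {
        ix <- match(groupings[[lab]], samples)
        al <- as.vector(gm[ix, , drop = FALSE])
        data.table::data.table(
          contig = r$contig, pos0 = r$pos0, ref = r$ref, alt = r$alt,
          alt_index = seq_along(r$alt), grouping = lab,
          alt_count = vapply(seq_along(r$alt), function(j)
            sum(al == j, na.rm = TRUE), 0L),
          denom = 2L * length(ix))
      }))
    }))
    list(callset = cs, sample_map = sample_map, ledger = ledger)
  })
}

#' Rewrite a variant into an equivalent representation
#'
#' Produces a literally different record whose spliced window haplotype is
#' identical to the input's — the class of rewrites a VCF normalizer or a
#' different caller might emit. Modes: `"shift"` moves an indel within its
#' repeat context, `"pad"` appends the shared next reference base to both
#' alleles, `"mnp_split"` reduces an MNP differing at exactly one base to
#' the equivalent SNP. Splice equality over the combined window is verified
#' internally before the record is returned; a variant not perturbable in
#' the requested mode yields `NULL` with a `reason` attribute.
#'
#' @param variant a biallelic [variant_record()]
#' @param reference a [reference_sequence()]
#' @param mode one of `"shift"`, `"pad"`, `"mnp_split"`
#' @return a [variant_record()], or `NULL` (no-op signal)
#' @export
perturb_representation <- function(variant, reference,
                                   mode = c("shift", "pad", "mnp_split")) {
  mode <- match.arg(mode)
  if (length(variant$alt) != 1L)
    { pa_log("not perturbable: %s", "multi-allelic"); return(NULL) }
  L <- nchar(reference$seq[[variant$contig]])
  rlen <- nchar(variant$ref); alen <- nchar(variant$alt)
  verify <- function(cand) {
    win <- genomic_interval(variant$contig,
                            max(0L, min(variant$pos0, cand$pos0) - 1L),
                            min(L, max(rec_end0(variant), rec_end0(cand)) + 1L))
    h1 <- build_haplotype(reference, win, variant, variant$alt)
    h2 <- build_haplotype(reference, win, cand, cand$alt)
    if (!identical(h1, h2))
      stop("internal error: perturbation changed the spliced haplotype")
    cand
  }
  if (mode == "pad") {
    if (rec_end0(variant) >= L) { pa_log("not perturbable: %s", "contig end"); return(NULL) }
    pad <- ref_fetch(reference, genomic_interval(variant$contig,
                                                 rec_end0(variant),
                                                 rec_end0(variant) + 1L))
    cand <- variant_record(variant$contig, variant$pos0,
                           paste0(variant$ref, pad), paste0(variant$alt, pad),
                           gt = variant$gt)
    return(verify(cand))
  }
  if (mode == "mnp_split") {
    if (rlen != alen || rlen < 2L)
      { pa_log("not perturbable: %s", "not an MNP"); return(NULL) }
    diff <- which(strsplit(variant$ref, "")[[1]] != strsplit(variant$alt, "")[[1]])
    if (length(diff) != 1L)
      { pa_log("not perturbable: %s", "MNP differs at multiple bases"); return(NULL) }
    cand <- variant_record(variant$contig, variant$pos0 + diff - 1L,
                           substr(variant$ref, diff, diff),
                           substr(variant$alt, diff, diff), gt = variant$gt)
    return(verify(cand))
  }
  # shift: same ref length, new start; the required alt allele is read off
  # the original haplotype, then splice equality decides admissibility.
  # Shifts are bounded to |d| < ref length so the rewritten span still
  # intersects the original: the windowed cohort query matches on span
  # overlap, and a representation whose span is disjoint from every
  # equivalent one is invisible to it (callers emitting left-aligned
  # records keep overlap for deletions and MNPs; see the methods vignette)
  if (rlen < 2L) { pa_log("not perturbable: span too short to shift"); return(NULL) }
  deltas <- seq_len(rlen - 1L)
  for (d in as.integer(rbind(-deltas, deltas))) {
    np <- variant$pos0 + d
    if (np < 1L || np + rlen > L - 1L) next
    win <- genomic_interval(variant$contig, min(variant$pos0, np) - 1L,
                            max(rec_end0(variant), np + rlen) + 1L)
    h <- build_haplotype(reference, win, variant, variant$alt)
    new_alt <- substr(h, np - win$start + 1L, np - win$start + alen)
    new_ref <- ref_fetch(reference, genomic_interval(variant$contig, np, np + rlen))
    if (!is_dna(new_alt) || new_alt == new_ref) next
    cand <- tryCatch(variant_record(variant$contig, np, new_ref, new_alt,
                                    gt = variant$gt),
                     error = function(e) NULL)
    if (is.null(cand)) next
    h2 <- tryCatch(build_haplotype(reference, win, cand, cand$alt),
                   error = function(e) "")
    if (identical(h, h2)) return(verify(cand))
  }
  pa_log("not perturbable: no equivalent shifted representation")
  NULL
}

#' Simulate reads over a site for a given genotype
#'
#' Draws `depth` reads covering the site; at a heterozygous site each read
#' carries the alternate allele with probability 1/2 (expected variant
#' allele fraction 0.5); base errors are injected at the configured rate.
#' Reads are locally aligned (M runs with a single I/D at the variant for
#' indel alleles).
#'
#' @param config a [sim_config()]
#' @param reference a [reference_sequence()]
#' @param genotype integer pair of allele indices, e.g. `c(0, 1)`
#' @param site a [variant_record()]
#' @param seed RNG seed for this pileup (defaults to `config$seed + pos0`)
#' @return list of [aligned_read()]s
#' @export
gen_reads <- function(config, reference, genotype, site,
                      seed = config$seed + site$pos0 + 303L) {
  stopifnot(length(genotype) == 2L, all(genotype >= 0L),
            all(genotype <= length(site$alt)))
  with_seed(seed, {
    L <- nchar(reference$seq[[site$contig]])
    rl <- config$read_length
    end0 <- rec_end0(site)
    lo <- max(0L, end0 - rl + 5L)
    hi <- max(lo, site$pos0 - 4L)
    reads <- vector("list", config$depth)
    for (i in seq_len(config$depth)) {
      allele_idx <- if (genotype[1] == genotype[2]) genotype[1] else
        genotype[1 + rbinom(1, 1, 0.5)]
      s <- if (hi > lo) sample(lo:hi, 1) else lo
      if (allele_idx == 0L) {
        hi_end <- min(L, s + rl)
        bases <- ref_fetch(reference, genomic_interval(site$contig, s, hi_end))
        cigar <- paste0(nchar(bases), "M")
      } else {
        al <- site$alt[allele_idx]
        left <- ref_fetch(reference, genomic_interval(site$contig, s, site$pos0))
        right_end <- min(L, end0 + rl)
        right <- ref_fetch(reference, genomic_interval(site$contig, end0, right_end))
        full <- paste0(left, al, right)
        bases <- strtrim(full, rl)
        rlen <- nchar(site$ref); alen <- nchar(al)
        n_left <- nchar(left)
        if (rlen == alen) {
          cigar <- paste0(nchar(bases), "M")
        } else if (alen > rlen) {  # insertion after the anchor
          n_right <- nchar(bases) - n_left - alen
          if (n_right > 0L) {
            cigar <- paste0(n_left + rlen, "M", alen - rlen, "I", n_right, "M")
          } else {
            bases <- strtrim(bases, n_left + alen)
            cigar <- paste0(n_left + rlen, "M", alen - rlen, "I")
          }
        } else {                   # deletion after the anchor
          n_right <- nchar(bases) - n_left - alen
          cigar <- paste0(n_left + alen, "M", rlen - alen, "D", n_right, "M")
        }
      }
      # inject base errors
      if (config$error_rate > 0) {
        bv <- strsplit(bases, "")[[1]]
        err <- which(runif(length(bv)) < config$error_rate)
        for (e in err) bv[e] <- sample(setdiff(c("A", "C", "G", "T"), bv[e]), 1)
        bases <- paste(bv, collapse = "")
      }
      reads[[i]] <- aligned_read(
        name = sprintf("r%d_%03d", site$pos0, i), contig = site$contig,
        start0 = s, cigar = cigar, bases = bases,
        quals = rep(30L, nchar(bases)), mapq = 60L,
        strand = if (rbinom(1, 1, 0.5) == 1L) "+" else "-")
    }
    reads
  })
}

#' Generate a truth set and two perturbed callsets with planted errors
#'
#' Samples one diploid individual from the panel frequencies (the truth
#' set), then derives two callsets by deleting planted false negatives and
#' inserting planted false positives. Common false positives are panel
#' sites (frequency above the threshold) where the individual is
#' homozygous reference; rare false positives are novel sites absent from
#' the panel (frequency zero). A configurable share of errors is planted in
#' both callsets, so model-specific set differences have known sizes. Every
#' call carries a simulated variant allele fraction. The ledger records the
#' planted composition exactly.
#'
#' @param config a [sim_config()]
#' @param panel output of [gen_panel()]
#' @param reference a [reference_sequence()]
#' @param n_fp,n_fn model-specific error counts per callset, named `a`/`b`
#' @param n_shared_fp,n_shared_fn errors planted identically in both
#' @param fp_rare_frac fraction of planted false positives that are rare
#' @param threshold commonness threshold used when planting
#' @return list: `truth`, `calls_a`, `calls_b` (single-sample callsets) and
#'   `ledger` (planted counts and per-record keys)
#' @export
gen_truth_and_calls <- function(config, panel, reference,
                                n_fp = c(a = 10L, b = 8L),
                                n_fn = c(a = 5L, b = 6L),
                                n_shared_fp = 3L, n_shared_fn = 2L,
                                fp_rare_frac = 0.5, threshold = 0.01) {
  with_seed(config$seed + 404L, {
    fpanel <- compute_frequencies(panel$callset,
                                  list(ALL = panel$callset$samples))
    recs <- panel$callset$records
    truth <- list(); homref_common <- list()
    for (i in seq_along(recs)) {
      r <- recs[[i]]
      af <- panel_af(fpanel, i, "ALL")
      draw <- function() {
        u <- runif(1); cum <- cumsum(af)
        j <- which(u < cum)
        if (length(j)) j[1] else 0L
      }
      g <- sort(c(draw(), draw()))
      if (any(g > 0L)) {
        truth[[length(truth) + 1L]] <-
          variant_record(r$contig, r$pos0, r$ref, r$alt,
                         gt = paste(g, collapse = "/"))
      } else if (any(af > threshold)) {
        homref_common[[length(homref_common) + 1L]] <- r
      }
    }
    L <- nchar(reference$seq[[1]])
    panel_pos <- vapply(recs, `[[`, 0L, "pos0")
    truth_pos <- vapply(truth, `[[`, 0L, "pos0")
    # planted FP pools
    total_fp <- sum(n_fp) + n_shared_fp
    n_rare <- round(fp_rare_frac * total_fp)
    novel_pos <- setdiff(20:(L - 25L), c(panel_pos, truth_pos,
                                         panel_pos + 1L, panel_pos - 1L))
    rare_fp <- lapply(sample(novel_pos, n_rare), function(p) {
      anchor <- substr(reference$seq[[1]], p + 1L, p + 1L)
      r <- variant_record(names(reference$seq)[1], p, anchor,
                          sample(setdiff(c("A", "C", "G", "T"), anchor), 1),
                          gt = "0/1")
      r$vaf <- rbinom(1, config$depth, 0.5) / config$depth
      r
    })
    n_common <- total_fp - n_rare
    if (length(homref_common) < n_common)
      stop("not enough common hom-ref panel sites to plant false positives; ",
           "increase panel size or density")
    common_fp <- lapply(sample(seq_along(homref_common), n_common), function(k) {
      r <- homref_common[[k]]
      out <- variant_record(r$contig, r$pos0, r$ref, r$alt[1], gt = "0/1")
      out$vaf <- rbinom(1, config$depth, 0.5) / config$depth
      out
    })
    fp_pool <- c(rare_fp, common_fp)
    fp_pool <- fp_pool[sample(length(fp_pool))]
    fp_shared <- fp_pool[seq_len(n_shared_fp)]
    fp_a <- fp_pool[n_shared_fp + seq_len(n_fp[["a"]])]
    fp_b <- fp_pool[n_shared_fp + n_fp[["a"]] + seq_len(n_fp[["b"]])]
    # planted FNs: drop truth records
    total_fn <- sum(n_fn) + n_shared_fn
    if (length(truth) <= total_fn)
      stop("not enough truth records to plant false negatives")
    fn_idx <- sample(seq_along(truth), total_fn)
    fn_shared <- fn_idx[seq_len(n_shared_fn)]
    fn_a <- fn_idx[n_shared_fn + seq_len(n_fn[["a"]])]
    fn_b <- fn_idx[n_shared_fn + n_fn[["a"]] + seq_len(n_fn[["b"]])]
    add_vaf <- function(r) {
      if (is.null(r$vaf)) {
        g <- gt_matrix(r$gt[1])[1, ]
        p <- if (g[1] == g[2]) 0.98 else 0.5
        r$vaf <- rep(rbinom(1, config$depth, p) / config$depth,
                     length(r$alt))
      }
      r
    }
    make_calls <- function(drop_idx, fps, label) {
      kept <- truth[setdiff(seq_along(truth), drop_idx)]
      callset(lapply(c(kept, fps), add_vaf), samples = "SAMPLE",
              source = label)
    }
    calls_a <- make_calls(c(fn_shared, fn_a), c(fp_shared, fp_a), "model_a")
    calls_b <- make_calls(c(fn_shared, fn_b), c(fp_shared, fp_b), "model_b")
    key <- function(r) paste0(r$contig, ":", r$pos0, ":", r$ref, ">",
                              paste(r$alt, collapse = ","))
    rare_keys <- vapply(rare_fp, key, "")
    fp_key_dt <- function(fps, model, shared) data.table::data.table(
      model = model, shared = shared,
      variant_key = vapply(fps, key, ""),
      rare = vapply(fps, key, "") %in% rare_keys)
    ledger <- list(
      n_truth = length(truth),
      fp = data.table::rbindlist(list(
        fp_key_dt(fp_shared, "both", TRUE),
        fp_key_dt(fp_a, "a", FALSE),
        fp_key_dt(fp_b, "b", FALSE))),
      fn = data.table::data.table(
        model = c(rep("both", n_shared_fn), rep("a", n_fn[["a"]]),
                  rep("b", n_fn[["b"]])),
        variant_key = vapply(truth[c(fn_shared, fn_a, fn_b)], key, "")),
      n_fp = c(a = n_fp[["a"]] + n_shared_fp, b = n_fp[["b"]] + n_shared_fp),
      n_fn = c(a = n_fn[["a"]] + n_shared_fn, b = n_fn[["b"]] + n_shared_fn),
      n_specific_fp = n_fp, n_specific_fn = n_fn)
    list(truth = callset(truth, samples = "SAMPLE", source = "truth"),
         calls_a = calls_a, calls_b = calls_b, ledger = ledger)
  })
}
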