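test_that("window extension spans the candidate and all cohort variants", {
  snp <- variant_record("chr1", 100L, "A", "G")
  w <- extend_window(snp, list())
  expect_equal(c(w$start, w$end), c(100L, 101L))

  del <- variant_record("chr1", 100L, "ACGT", "A")
  cohort <- list(variant_record("chr1", 98L, "T", "C"),
                 variant_record("chr1", 103L, "TGA", "T"))
  w2 <- extend_window(del, cohort)
  expect_equal(c(w2$start, w2$end), c(98L, 106L))

  # min/max oracle on random variant sets
  set.seed(9)
  for (rep in 1:50) {
    vs <- lapply(1:sample(1:6, 1), function(i)
      variant_record("chr1", sample(50:80, 1),
                     paste(rep("A", sample(1:5, 1)), collapse = ""), "T"))
    w <- extend_window(vs[[1]], vs[-1])
    starts <- vapply(vs, `[[`, 0L, "pos0")
    ends <- starts + vapply(vs, function(v) nchar(v$ref), 0L)
    expect_equal(w$start, min(starts))
    expect_equal(w$end, max(ends))
    expect_true(all(starts >= w$start & ends <= w$end))
  }
})

test_that("haplotype splicing handles substitution, deletion and insertion", {
  ref <- reference_sequence(c(chr1 = "ACGTA"))
  win <- genomic_interval("chr1", 0L, 5L)
  expect_equal(as.character(build_haplotype(
    ref, win, variant_record("chr1", 2L, "G", "T"), "T")), "ACTTA")
  expect_equal(as.character(build_haplotype(
    ref, win, variant_record("chr1", 2L, "GTA", "G"), "G")), "ACG")
  expect_equal(as.character(build_haplotype(
    ref, win, variant_record("chr1", 1L, "C", "CGG"), "CGG")), "ACGGGTA")
  # splicing the reference allele reproduces the window sequence
  expect_equal(as.character(build_haplotype(
    ref, win, variant_record("chr1", 2L, "G", "T"), "G")), "ACGTA")
  # length identity: window - ref + allele
  h <- build_haplotype(ref, win, variant_record("chr1", 1L, "C", "CGG"), "CGG")
  expect_equal(nchar(h), 5L - 1L + 3L)
  expect_error(build_haplotype(ref, genomic_interval("chr1", 0L, 3L),
                               variant_record("chr1", 2L, "GTA", "G"), "G"),
               "extend")
  expect_error(build_haplotype(ref, win,
                               variant_record("chr1", 2L, "G", "T"), "C"),
               "neither ref nor an alt")
})

test_that("identical representation matches and foreign alleles get zero", {
  ref <- tiny_ref()
  panel_rec <- variant_record("chr1", 4L, "A", "G", gt = c("0/1", "0/0"))
  fpan <- make_panel(list(panel_rec), c("S1", "S2"))
  hit <- match_alleles(variant_record("chr1", 4L, "A", "G"), fpan, ref)
  expect_equal(as.numeric(hit), 0.25)
  # same site, different alt: no match
  miss <- match_alleles(variant_record("chr1", 4L, "A", "T"), fpan, ref)
  expect_equal(as.numeric(miss), 0)
  # empty panel region
  far <- match_alleles(variant_record("chr1", 40L, "C", "T"), fpan, ref)
  expect_equal(as.numeric(far), 0)
})

test_that("shifted deletions in a homopolymer run match by haplotype", {
  # tiny_ref has A-run at 0-based [12, 20)
  ref <- tiny_ref()
  panel_rec <- variant_record("chr1", 12L, "AA", "A", gt = c("0/1", "0/1"))
  fpan <- make_panel(list(panel_rec), c("S1", "S2"))
  # right-shifted representation of the same 1 bp A deletion; the shifted
  # span must still overlap the panel record's span for the windowed
  # query to see it
  got <- match_alleles(variant_record("chr1", 13L, "AA", "A"), fpan, ref)
  expect_equal(as.numeric(got), 0.5)
  # a padded representation of the same deletion also matches
  got_pad <- match_alleles(variant_record("chr1", 12L, "AAA", "AA"), fpan, ref)
  expect_equal(as.numeric(got_pad), 0.5)
  # a 1 bp C deletion elsewhere must not match
  got2 <- match_alleles(variant_record("chr1", 9L, "GC", "G"), fpan, ref)
  expect_equal(as.numeric(got2), 0)
})

test_that("match_alleles agrees with the splice oracle on random pairs", {
  sim <- small_sim(17L)
  seq_str <- sim$ref$seq[["chr1"]]
  recs <- sim$fpan$callset$records
  afs <- lapply(seq_along(recs), function(i) panel_af(sim$fpan, i))
  set.seed(99)
  pos_pool <- vapply(recs, `[[`, 0L, "pos0")
  for (it in 1:300) {
    p <- max(2L, min(nchar(seq_str) - 10L,
                     sample(pos_pool, 1) + sample(-3:3, 1)))
    type <- sample(c("snp", "del", "ins"), 1)
    anchor <- substr(seq_str, p + 1L, p + 1L)
    cand <- switch(type,
      snp = variant_record("chr1", p, anchor,
                           sample(setdiff(c("A", "C", "G", "T"), anchor), 1)),
      del = variant_record("chr1", p,
                           substr(seq_str, p + 1L, p + 1L + sample(1:3, 1)),
                           anchor),
      ins = variant_record("chr1", p, anchor,
                           paste0(anchor, paste(sample(c("A", "C", "G", "T"),
                                                       sample(1:3, 1),
                                                       replace = TRUE),
                                                collapse = ""))))
    got <- match_alleles(cand, sim$fpan, sim$ref)
    want <- oracle_match(cand, recs, afs, seq_str)
    expect_equal(as.numeric(got), as.numeric(want), info = paste("iter", it))
  }
})

test_that("reads receive the frequency of the allele they support", {
  ref <- tiny_ref()
  cand <- variant_record("chr1", 4L, "A", "G")
  af_dict <- setNames(0.25, "G")
  mk_read <- function(name, base) {
    bases <- paste0(substr(ref$seq[["chr1"]], 1, 4), base,
                    substr(ref$seq[["chr1"]], 6, 10))
    aligned_read(name, "chr1", 0L, "10M", bases, rep(30L, 10))
  }
  reads <- list(mk_read("alt", "G"), mk_read("ref", "A"), mk_read("oth", "T"))
  f <- annotate_reads(reads, cand, af_dict)
  expect_equal(f, c(0.25, 0.75, 0))
  # non-covering read is skipped with NA
  short <- aligned_read("s", "chr1", 0L, "3M",
                        substr(ref$seq[["chr1"]], 1, 3), rep(30L, 3))
  expect_true(is.na(annotate_reads(list(short), cand, af_dict)))
  # ref frequency floors at zero when matched alts exceed 1
  f2 <- annotate_reads(reads[2], cand, setNames(1.0, "G"))
  expect_equal(f2, 0)
})

test_that("indel-carrying reads are scored through their alignment", {
  ref <- tiny_ref()
  seq_str <- ref$seq[["chr1"]]
  del <- variant_record("chr1", 12L, "AA", "A")
  af_dict <- setNames(0.4, "A")
  # read deleting one A of the run: 13M 1D 6M starting at 0
  bases_del <- paste0(substr(seq_str, 1, 13), substr(seq_str, 15, 20))
  rd_del <- aligned_read("d", "chr1", 0L, "13M1D6M", bases_del, rep(30L, 19))
  rd_ref <- aligned_read("r", "chr1", 0L, "20M", substr(seq_str, 1, 20),
                         rep(30L, 20))
  f <- annotate_reads(list(rd_del, rd_ref), del, af_dict)
  expect_equal(f, c(0.4, 0.6))
  # insertion-carrying read at an insertion candidate
  ins <- variant_record("chr1", 4L, "A", "AGG")
  bases_ins <- paste0(substr(seq_str, 1, 5), "GG", substr(seq_str, 6, 13))
  rd_ins <- aligned_read("i", "chr1", 0L, "5M2I8M", bases_ins, rep(30L, 15))
  f2 <- annotate_reads(list(rd_ins, rd_ref), ins, setNames(0.1, "AGG"))
  expect_equal(f2, c(0.1, 0.9))
})

test_that("annotating the panel against itself recovers panel frequencies", {
  sim <- small_sim(29L, n_samples = 20L, genome_length = 8000L)
  cs <- callset(lapply(sim$fpan$callset$records, strip_gt), source = "self")
  ann <- annotate_callset(cs, sim$fpan, sim$ref)
  for (i in seq_along(ann$records)) {
    r <- ann$records[[i]]
    j <- which(vapply(sim$fpan$callset$records, function(q)
      q$pos0 == r$pos0 && q$ref == r$ref, TRUE))[1]
    expect_equal(r$af, unname(panel_af(sim$fpan, j)))
  }
  s <- attr(ann, "annotation_summary")
  expect_equal(unname(s["total"]), length(ann$records))
  # empty panel: everything annotates to zero
  empty <- make_panel(list(variant_record("chr2", 5L, "A", "G", gt = "0/1")),
                      "S1")
  ann0 <- annotate_callset(callset(list(
    variant_record("chr1", 100L, "A", "G")), source = "x"), empty, sim$ref)
  expect_equal(ann0$records[[1]]$af, 0)
})

test_that("representation-perturbed records annotate identically", {
  sim <- small_sim(37L)
  n_checked <- 0L
  for (r in sim$fpan$callset$records) {
    if (length(r$alt) != 1L) next
    bare <- variant_record(r$contig, r$pos0, r$ref, r$alt)
    base_af <- as.numeric(match_alleles(bare, sim$fpan, sim$ref))
    for (mode in c("shift", "pad", "mnp_split")) {
      p <- perturb_representation(bare, sim$ref, mode)
      if (is.null(p)) next
      # the perturbed record is literally different
      expect_false(p$pos0 == bare$pos0 && p$ref == bare$ref &&
                     p$alt == bare$alt)
      expect_identical(as.numeric(match_alleles(p, sim$fpan, sim$ref)),
                       base_af)
      n_checked <- n_checked + 1L
    }
  }
  expect_gt(n_checked, 50L)
})

test_that("duplicate cohort matches keep the maximum frequency", {
  ref <- tiny_ref()
  # two panel records for the same physical deletion, different shifts
  r1 <- variant_record("chr1", 12L, "AA", "A", gt = c("0/1", "0/0"))
  r2 <- variant_record("chr1", 13L, "AA", "A", gt = c("1/1", "0/1"))
  fpan <- make_panel(list(r1, r2), c("S1", "S2"))
  got <- match_alleles(variant_record("chr1", 12L, "AA", "A"), fpan, ref)
  expect_equal(as.numeric(got), max(0.25, 0.75))
})
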