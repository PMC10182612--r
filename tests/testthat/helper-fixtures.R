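# fixtures built in code; nothing is read from disk except what a test writes

# a fixed reference with an A-homopolymer at [12,20) and an AC tandem run
# at [24,33), padded with a non-repetitive tail so positions up to ~500 are
# addressable
tiny_ref <- function() {
  reference_sequence(c(chr1 = paste0(
    "ACGTACGTGGCTAAAAAAAATCGACACACACACGGTTGACCTGATCGGATCCAGTTGCA",
    strrep("TTAGGCATCGGAACGATCCGTGCAT", 20))))
}

# single-record panel with explicit genotypes
make_panel <- function(records, samples) {
  compute_frequencies(callset(records, samples = samples, source = "fixture"),
                      list(ALL = samples))
}

# n minimal AF-annotated records for fraction arithmetic
make_af_set <- function(n, af) {
  lapply(seq_len(n), function(i) {
    r <- variant_record("chr1", i * 10L, "A", "G")
    r$af <- af
    r
  })
}

# brute-force splice oracle, independent of the package's haplotype code:
# works on the raw reference string with substr arithmetic only
oracle_match <- function(candidate, panel_records, panel_afs, seq_str) {
  c_end <- candidate$pos0 + nchar(candidate$ref)
  overl <- which(vapply(panel_records, function(u)
    u$contig == candidate$contig & u$pos0 < c_end &
      (u$pos0 + nchar(u$ref)) > candidate$pos0, TRUE))
  out <- setNames(numeric(length(candidate$alt)), candidate$alt)
  if (!length(overl)) return(out)
  starts <- c(candidate$pos0, vapply(panel_records[overl], `[[`, 0L, "pos0"))
  ends <- c(c_end, vapply(panel_records[overl], function(u)
    u$pos0 + nchar(u$ref), 0L))
  ws <- min(starts); we <- max(ends)
  splice <- function(pos0, ref, allele)
    paste0(substr(seq_str, ws + 1L, pos0),
           allele,
           substr(seq_str, pos0 + nchar(ref) + 1L, we))
  for (j in seq_along(candidate$alt)) {
    s_c <- splice(candidate$pos0, candidate$ref, candidate$alt[j])
    best <- 0
    for (k in overl) {
      u <- panel_records[[k]]
      for (m in seq_along(u$alt)) {
        if (splice(u$pos0, u$ref, u$alt[m]) == s_c)
          best <- max(best, panel_afs[[k]][m])
      }
    }
    out[j] <- best
  }
  out
}

# small seeded panel + reference for matching tests
small_sim <- function(seed = 11L, n_samples = 30L, genome_length = 15000L) {
  cfg <- sim_config(seed, genome_length = genome_length,
                    n_samples = n_samples)
  gr <- gen_reference(cfg)
  panel <- gen_panel(cfg, gr)
  fpan <- compute_frequencies(panel$callset,
                              population_groupings(panel$sample_map))
  list(cfg = cfg, ref = gr$ref, runs = gr$runs, panel = panel, fpan = fpan)
}

strip_gt <- function(r) { r$gt <- NULL; r }
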