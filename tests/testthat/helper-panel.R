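# shared small-panel fixtures, built once per test run
.fixtures <- new.env(parent = emptyenv())

small_config <- function(...) {
  panel_config(
    n_pairs_per_chrom = 150,
    doses = data.frame(radiation_type = "gamma", dose_Gy = 2000,
                       n_m1 = 8, sibs_per_m1 = 2),
    n_controls = 8, seed = 42, ...
  )
}

# a cached simulated mini-panel (map, lesions, genome counts, dosage profile)
small_panel <- function() {
  if (!is.null(.fixtures$panel)) return(.fixtures$panel)
  cfg <- small_config()
  pm <- make_pair_map(cfg)
  les <- simulate_lesions(cfg)
  cm <- simulate_counts(pm, les, noise_model("genome"), cfg)
  rpkm <- rpkm_normalize(cm)
  bl <- control_baseline(rpkm)
  prof <- dosage_profile(rpkm, bl, pm)
  .fixtures$panel <- list(cfg = cfg, pm = pm, les = les, cm = cm,
                          rpkm = rpkm, bl = bl, prof = prof)
  .fixtures$panel
}

# dosage profile with prescribed k values on a single synthetic chromosome
# pair (A chromosome "A1" / C chromosome "C1"), for direct caller tests
toy_profile <- function(k_A, k_C = rep(2, length(k_A)),
                        sample_id = "S1") {
  n <- length(k_A)
  tibble::tibble(
    sample_id = sample_id,
    pair_id = sprintf("p%03d", seq_len(n)),
    chrom_A = "A1", idx_A = seq_len(n) - 1L,
    chrom_C = "C1", idx_C = seq_len(n) - 1L,
    k_A = k_A, k_C = k_C, masked = FALSE,
    C = pmin(1, k_A / 4), M = pmin(1, k_C / 4), Y = 0, K = 0
  )
}

toy_pair_map <- function(n = 100) {
  tibble::tibble(
    pair_id = sprintf("p%03d", seq_len(n)),
    gene_A = sprintf("A1.g%03d", seq_len(n) - 1L),
    chrom_A = "A1", idx_A = seq_len(n) - 1L, len_A_bp = 1500L,
    gene_C = sprintf("C1.g%03d", seq_len(n) - 1L),
    chrom_C = "C1", idx_C = seq_len(n) - 1L, len_C_bp = 1500L
  )
}

# bare variant records in the layout read_vcf() produces
toy_records <- function(chrom, pos, ref = "A", alt = "T", qual = 50,
                        sample = "S1", vad = 5) {
  n <- max(lengths(list(chrom, pos, ref, alt, qual, sample, vad)))
  tibble::tibble(
    chrom = rep_len(chrom, n), pos = as.integer(rep_len(pos, n)),
    ref = rep_len(ref, n), alt = rep_len(alt, n),
    qual = rep_len(qual, n), sample = rep_len(sample, n),
    gt = "0/1", vad = as.integer(rep_len(vad, n)),
    filter = NA_character_, filter_history = ""
  ) |> dplyr::arrange(chrom, pos)
}
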