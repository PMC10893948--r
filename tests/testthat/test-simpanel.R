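test_that("pair map has the configured geometry and round-trips", {
  cfg <- panel_config(n_pairs_per_chrom = 100, seed = 5)
  pm <- make_pair_map(cfg)
  expect_equal(nrow(pm), 1000)
  expect_equal(unname(table(pm$chrom_A)), rep(100L, 10),
               ignore_attr = TRUE)
  for (ch in unique(pm$chrom_A)) {
    expect_equal(pm$idx_A[pm$chrom_A == ch], 0:99)
  }
  # C genome carries at least as many genes as A
  sz <- chrom_sizes(pm)
  expect_gte(sum(sz$n_genes[sz$subgenome == "C"]),
             sum(sz$n_genes[sz$subgenome == "A"]))

  # identical seed => identical map; TSV round-trip is lossless
  expect_identical(pm, make_pair_map(cfg))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pair_map(pm, path)
  expect_equal(as.data.frame(read_pair_map(path)), as.data.frame(pm))

  expect_error(panel_config(n_pairs_per_chrom = 0), "zero")
  expect_error(panel_config(doses = data.frame(
    radiation_type = "gamma", dose_Gy = -10, n_m1 = 1, sibs_per_m1 = 1)),
    "non-negative")
})

test_that("lesion draws are deterministic and vanish at zero rate", {
  cfg <- small_config(he_prob_control = 0)
  les1 <- simulate_lesions(cfg)
  les2 <- simulate_lesions(cfg)
  expect_identical(les1$events, les2$events)

  cfg0 <- panel_config(
    n_pairs_per_chrom = 50,
    doses = data.frame(radiation_type = "gamma", dose_Gy = 0,
                       n_m1 = 10, sibs_per_m1 = 2),
    n_controls = 4, he_prob_control = 0, seed = 9)
  expect_equal(nrow(simulate_lesions(cfg0)$events), 0)
})

test_that("per-plant lesion class means converge to rate x dose", {
  cfg <- panel_config(
    n_pairs_per_chrom = 50,
    doses = data.frame(radiation_type = "gamma", dose_Gy = 2000,
                       n_m1 = 2500, sibs_per_m1 = 2),
    n_controls = 3, he_prob_control = 0, seed = 31)
  les <- simulate_lesions(cfg)
  n <- sum(les$samples$role == "treated")
  rates <- default_rate_coefficients()$gamma
  for (spec in list(list("segmental_deletion", "A", rates$alpha_del_A),
                    list("segmental_deletion", "C", rates$alpha_del_C),
                    list("segmental_duplication", "A", rates$alpha_dup_A))) {
    target <- spec[[3]] * 2000
    m <- sum(les$events$event_class == spec[[1]] &
               les$events$subgenome == spec[[2]]) / n
    se <- sqrt(target / n)
    expect_lt(abs(m - target), 3 * se)
  }
})

test_that("M2 zygosity of carriers segregates 2 het : 1 hom", {
  cfg <- panel_config(
    n_pairs_per_chrom = 50,
    doses = data.frame(radiation_type = "gamma", dose_Gy = 2000,
                       n_m1 = 1500, sibs_per_m1 = 2),
    n_controls = 3, recip_prob = 0, he_prob_control = 0, seed = 13)
  ev <- simulate_lesions(cfg)$events
  seg <- ev[ev$event_class == "segmental_deletion", ]
  expect_gt(nrow(seg), 3000)
  tab <- table(factor(seg$zygosity, levels = c("het", "hom")))
  p <- stats::chisq.test(tab, p = c(2 / 3, 1 / 3))$p.value
  expect_gt(p, 0.001)
})

test_that("reciprocal inheritance pairs every het deletion with a sibling duplication", {
  cfg <- panel_config(
    n_pairs_per_chrom = 80,
    doses = data.frame(radiation_type = "gamma", dose_Gy = 2000,
                       n_m1 = 40, sibs_per_m1 = 2),
    n_controls = 3, recip_prob = 1, he_prob_control = 0, seed = 21)
  les <- simulate_lesions(cfg)
  ev <- les$events
  dels <- ev[ev$event_class == "segmental_deletion", ]
  expect_gt(nrow(dels), 0)
  expect_true(all(dels$zygosity == "het"))
  for (i in seq_len(nrow(dels))) {
    twin <- ev[ev$lesion_id == dels$lesion_id[i] &
                 ev$event_class == "segmental_duplication", ]
    expect_equal(nrow(twin), 1)
    expect_false(twin$sample_id == dels$sample_id[i])
    expect_equal(twin$start_idx, dels$start_idx[i])
    expect_equal(twin$end_idx, dels$end_idx[i])
    sib_fams <- les$samples$m1_family[
      les$samples$sample_id %in% c(twin$sample_id, dels$sample_id[i])]
    expect_equal(sib_fams[1], sib_fams[2])
  }
})

test_that("counts respond to copy number and transcriptome mode is noisier", {
  cfg <- panel_config(
    n_pairs_per_chrom = 300,
    doses = data.frame(radiation_type = "gamma", dose_Gy = 2000,
                       n_m1 = 1, sibs_per_m1 = 1),
    n_controls = 3, he_prob_control = 0, seed = 77)
  pm <- make_pair_map(cfg)
  # one hom deletion and one hom duplication, each 250 genes, injected
  ev <- tibble::tibble(
    sample_id = "G2000_1a", subgenome = c("A", "A"),
    chrom = c("A1", "A2"), start_idx = c(10L, 10L), end_idx = c(260L, 260L),
    event_class = c("segmental_deletion", "segmental_duplication"),
    copies = c(0L, 4L), zygosity = "hom",
    m1_family = "G2000_1", lesion_id = c("L1", "L2"))
  les <- simulate_lesions(cfg)
  les$events <- ev
  cm <- simulate_counts(pm, les, noise_model("genome"), cfg)
  genes <- cm$genes
  sel <- function(chrom) genes$subgenome == "A" & genes$chrom == chrom &
    genes$idx >= 10 & genes$idx < 260
  base <- function(chrom) genes$subgenome == "A" & genes$chrom == chrom &
    (genes$idx < 10 | genes$idx >= 260)
  x <- cm$counts[, "G2000_1a"]
  # hard deletion: essentially no reads
  expect_lt(mean(x[sel("A1")]), 0.05 * mean(x[base("A1")]))
  # 4 copies vs 2: mean ratio about 2 (>= 250 genes averaged)
  ratio <- mean(x[sel("A2")]) / mean(x[base("A2")])
  expect_lt(abs(ratio - 2), 0.2)

  # same events, transcriptome mode: per-gene dosage ratios strictly noisier
  cmt <- simulate_counts(pm, les, noise_model("transcriptome"), cfg)
  r_g <- rpkm_normalize(cm)
  r_t <- rpkm_normalize(cmt)
  ctrl <- les$samples$sample_id[les$samples$role == "control"]
  ratio_var <- function(r) {
    k <- 2 * r$counts[, "G2000_1a"] / rowMeans(r$counts[, ctrl])
    stats::var(k[base("A1")])
  }
  expect_gt(ratio_var(r_t), ratio_var(r_g))

  # events on unknown chromosomes are refused, naming the offender
  les$events$chrom[1] <- "A99"
  expect_error(simulate_counts(pm, les, noise_model("genome"), cfg),
               "G2000_1a.*A99")
})

test_that("variant truth tables follow the depth-stratified validity model", {
  cfg <- small_config(calls_eq2_per_line = 40, calls_gt2_per_line = 40)
  pv <- simulate_variants(cfg)
  ls <- pv$variants[pv$variants$category == "line_specific", ]
  frac2 <- mean(ls$is_true[ls$vad == 2])
  fracg <- mean(ls$is_true[ls$vad > 2])
  n2 <- sum(ls$vad == 2); ng <- sum(ls$vad > 2)
  expect_lt(abs(frac2 - 0.035), 3 * sqrt(0.035 * 0.965 / n2))
  expect_lt(abs(fracg - 0.38), 3 * sqrt(0.38 * 0.62 / ng))

  # all-valid configuration marks every line-specific call true
  cfg1 <- small_config(p_valid_gt2 = 1, p_valid_eq2 = 1)
  pv1 <- simulate_variants(cfg1)
  ls1 <- pv1$variants[pv1$variants$category == "line_specific", ]
  expect_true(all(ls1$is_true))

  # artifacts recur across samples including controls
  art <- pv$variants[pv$variants$category == "artifact", ]
  occ <- table(paste(art$chrom, art$pos))
  expect_gt(stats::median(occ), 8)
  expect_true(any(art$sample %in%
                    pv$samples$sample_id[pv$samples$role == "control"]))
})

test_that("emitted VCF is v4.2 and round-trips through the reader", {
  cfg <- small_config(calls_eq2_per_line = 5, calls_gt2_per_line = 5,
                      n_artifact_sites = 10)
  pv <- simulate_variants(cfg)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(pv$variants, path)
  expect_match(readLines(path, n = 1), "fileformat=VCFv4.2")
  back <- read_vcf(path)
  key <- function(d) sort(paste(d$chrom, d$pos, d$ref, d$alt, d$sample,
                                d$vad))
  expect_identical(key(back), key(pv$variants))
})

test_that("phenotype anchors, closed-form means and slope recovery hold", {
  wt <- tibble::tibble(sample_id = "wt", fae1_a8_copies = 2,
                       fae1_c3_copies = 2, fad2_a5_copies = 2)
  null_fad2 <- dplyr::mutate(wt, sample_id = "fad2_null",
                             fad2_a5_copies = 0)
  p0 <- trait_params(resid_sd = 0)
  ph_wt <- simulate_phenotypes(wt, p0)
  expect_equal(ph_wt$erucic, 46)
  expect_equal(ph_wt$linoleic, 15)
  ph_null <- simulate_phenotypes(null_fad2, p0)
  expect_equal(ph_null$erucic, 50)
  expect_equal(ph_null$linoleic, 8)
  expect_equal(ph_null$oleic, 19)

  # no functional elongase at either locus: intercept-only erucic level
  fae0 <- dplyr::mutate(wt, fae1_a8_copies = 0, fae1_c3_copies = 0)
  ph0 <- simulate_phenotypes(fae0, p0)
  expect_equal(ph0$erucic, 46 - 4 * p0$fae1_erucic_per_copy)
  expect_lt(ph0$erucic, ph_wt$erucic)

  # regression on 200 simulated plants recovers the configured slope
  withr::local_seed(99)
  prm <- trait_params()
  g <- tibble::tibble(
    sample_id = sprintf("s%03d", 1:200),
    fae1_a8_copies = sample(0:2, 200, replace = TRUE),
    fae1_c3_copies = sample(0:2, 200, replace = TRUE),
    fad2_a5_copies = 2)
  ph <- simulate_phenotypes(g, prm, seed = 8)
  fit <- stats::lm(ph$erucic ~ I(g$fae1_a8_copies + g$fae1_c3_copies))
  est <- summary(fit)$coefficients[2, ]
  expect_lt(abs(est["Estimate"] - prm$fae1_erucic_per_copy),
            2 * est["Std. Error"])

  expect_error(trait_params(resid_sd = -1), "resid_sd")
})
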