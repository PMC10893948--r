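test_that("running median matches a brute-force windowed median", {
  expect_equal(smooth_series(rep(2, 30), 9), rep(2, 30))
  x <- rep(2, 31)
  x[16] <- 8                      # lone outlier is erased
  expect_equal(smooth_series(x, 15), rep(2, 31))

  withr::local_seed(6)
  y <- rnorm(200)
  for (w in c(1, 5, 9, 15)) {
    brute <- sapply(seq_along(y), function(i) {
      median(y[max(1, i - (w - 1) / 2):min(length(y), i + (w - 1) / 2)])
    })
    expect_equal(smooth_series(y, w), brute)
  }
  expect_error(smooth_series(numeric(0), 5), "empty")
  expect_error(smooth_series(y, 4), "odd")
})

# independent enumeration of the caller's definition, for short chromosomes
oracle_segments <- function(k, params) {
  n <- length(k)
  h <- (params$w - 1) / 2
  sm <- sapply(seq_len(n), function(i) {
    median(k[max(1, i - h):min(n, i + h)])
  })
  st <- ifelse(sm < params$del_thresh, "del",
               ifelse(sm > params$dup_thresh, "dup", "base"))
  # maximal same-state runs by exhaustive scan
  runs <- list()
  i <- 1
  while (i <= n) {
    j <- i
    while (j < n && st[j + 1] == st[i]) j <- j + 1
    if (st[i] != "base") runs[[length(runs) + 1]] <-
      list(state = st[i], start = i, end = j)
    i <- j + 1
  }
  # bridge small baseline gaps between same-state runs
  merged <- list()
  for (r in runs) {
    m <- length(merged)
    if (m > 0 && merged[[m]]$state == r$state &&
        r$start - merged[[m]]$end - 1 < params$w / 2) {
      merged[[m]]$end <- r$end
    } else {
      merged[[length(merged) + 1]] <- r
    }
  }
  sigma <- stats::mad(k, center = 2)
  keep <- Filter(function(r) {
    len <- r$end - r$start + 1
    if (len < params$min_run) return(FALSE)
    rm <- median(k[r$start:r$end])
    need <- params$conf_z * 1.2533 * sigma / sqrt(len)
    if (r$state == "del") rm < params$del_thresh && (2 - rm) >= need
    else rm > params$dup_thresh && (rm - 2) >= need
  }, merged)
  tibble::tibble(
    state = vapply(keep, `[[`, character(1), "state"),
    start_idx = vapply(keep, function(r) as.integer(r$start - 1),
                       integer(1)),
    end_idx = vapply(keep, function(r) as.integer(r$end), integer(1)))
}

test_that("segment calls equal exhaustive run enumeration on short chromosomes", {
  params <- caller_params(w = 5, min_run = 4)
  withr::local_seed(17)
  for (rep in 1:25) {
    n <- sample(20:50, 1)
    k <- 2 + rnorm(n, 0, 0.15)
    # paint in a random lesion half the time
    if (rep %% 2 == 0) {
      len <- sample(4:15, 1)
      s <- sample(1:(n - len), 1)
      k[s:(s + len - 1)] <- sample(c(0, 1, 3, 4), 1) + rnorm(len, 0, 0.1)
    }
    calls <- call_segments(toy_profile(k), params)
    calls <- calls[calls$subgenome == "A", ]
    orc <- oracle_segments(k, params)
    expect_equal(nrow(calls), nrow(orc))
    if (nrow(orc) > 0) {
      expect_equal(calls$start_idx, orc$start_idx)
      expect_equal(calls$end_idx, orc$end_idx)
      expect_equal(
        calls$event_class %in% c("segmental_deletion", "chromosome_loss"),
        orc$state == "del")
    }
  }
})

test_that("balanced simulated controls yield almost no calls", {
  cfg <- panel_config(
    n_pairs_per_chrom = 150,
    doses = data.frame(radiation_type = "gamma", dose_Gy = 2000,
                       n_m1 = 1, sibs_per_m1 = 1),
    n_controls = 100, he_prob_control = 0, seed = 23)
  pm <- make_pair_map(cfg)
  les <- simulate_lesions(cfg)
  les$events <- les$events[0, ] # fully balanced panel
  cm <- simulate_counts(pm, les, noise_model("genome"), cfg)
  rpkm <- rpkm_normalize(cm)
  prof <- dosage_profile(rpkm, control_baseline(rpkm), pm)
  calls <- call_segments(prof)
  expect_lt(nrow(calls) / 101, 0.01)
})

test_that("injected lesions are recovered with the right class and zygosity", {
  cfg <- panel_config(
    n_pairs_per_chrom = 200,
    doses = data.frame(radiation_type = "gamma", dose_Gy = 2000,
                       n_m1 = 1, sibs_per_m1 = 1),
    n_controls = 6, he_prob_control = 0, seed = 29)
  pm <- make_pair_map(cfg)
  les <- simulate_lesions(cfg)
  les$events <- tibble::tibble(
    sample_id = "G2000_1a", subgenome = c("A", "A", "C"),
    chrom = c("A3", "A6", "C2"),
    start_idx = c(40L, 0L, 30L), end_idx = c(160L, 200L, 75L),
    event_class = c("segmental_deletion", "chromosome_loss",
                    "segmental_duplication"),
    copies = c(0L, 1L, 3L), zygosity = c("hom", "het", "het"),
    m1_family = "G2000_1", lesion_id = c("L1", "L2", "L3"))
  cm <- simulate_counts(pm, les, noise_model("genome"), cfg)
  rpkm <- rpkm_normalize(cm)
  prof <- dosage_profile(rpkm, control_baseline(rpkm), pm)
  calls <- call_segments(prof)
  calls <- calls[calls$sample_id == "G2000_1a", ]

  del <- calls[calls$event_class == "segmental_deletion", ]
  expect_equal(nrow(del), 1)
  expect_equal(del$copies, 0L)
  expect_gte(interval_jaccard <- radpanel:::interval_jaccard(
    del$start_idx, del$end_idx, 40, 160), 0.9)

  loss <- calls[calls$chrom == "A6", ]
  expect_equal(loss$event_class, "chromosome_loss")

  dup <- calls[calls$event_class == "segmental_duplication", ]
  expect_equal(dup$chrom, "C2")
  expect_equal(dup$zygosity, "het")
})

test_that("reciprocal dosage skews merge into homoeologous exchange calls", {
  # constructed calls: A2 duplication whose pairs coincide with a C deletion
  pm <- small_panel()$pm
  blk <- pm[pm$chrom_A == "A2" & pm$idx_A < 60, ]
  c_chrom <- names(sort(table(blk$chrom_C), decreasing = TRUE))[1]
  cblk <- blk[blk$chrom_C == c_chrom, ]
  ev <- tibble::tibble(
    sample_id = "S1", subgenome = c("A", "C"),
    chrom = c("A2", c_chrom),
    start_idx = c(0L, min(cblk$idx_C)),
    end_idx = c(60L, max(cblk$idx_C) + 1L),
    event_class = c("segmental_duplication", "segmental_deletion"),
    copies = c(4L, 0L), zygosity = "hom", mean_k = c(4, 0),
    n_genes = c(60L, nrow(cblk)))
  out <- detect_homoeologous_exchange(ev, pm)
  expect_equal(nrow(out), 1)
  expect_equal(out$event_class, "homoeologous_exchange")
  expect_equal(out$direction, "A->C")

  # isolated deletion: nothing to merge
  out2 <- detect_homoeologous_exchange(ev[2, ], pm)
  expect_equal(out2$event_class, "segmental_deletion")

  # overlap just below the threshold keeps both constituents
  ev3 <- ev
  ev3$end_idx[1] <- 100L # dup covers many pairs outside the deletion
  ev3$n_genes[1] <- 100L
  out3 <- detect_homoeologous_exchange(ev3, pm, he_overlap = 0.9)
  expect_equal(sort(out3$event_class),
               c("segmental_deletion", "segmental_duplication"))
})

test_that("an end-to-end simulated exchange is called with direction A->C", {
  cfg <- panel_config(
    n_pairs_per_chrom = 200,
    doses = data.frame(radiation_type = "gamma", dose_Gy = 2000,
                       n_m1 = 1, sibs_per_m1 = 1),
    n_controls = 6, he_prob_control = 0, seed = 37)
  pm <- make_pair_map(cfg)
  les <- simulate_lesions(cfg)
  les$events <- tibble::tibble(
    sample_id = "G2000_1a", subgenome = "A", chrom = "A4",
    start_idx = 20L, end_idx = 120L,
    event_class = "homoeologous_exchange", copies = 4L, zygosity = "hom",
    m1_family = "G2000_1", lesion_id = "HE1")
  cm <- simulate_counts(pm, les, noise_model("genome"), cfg)
  rpkm <- rpkm_normalize(cm)
  prof <- dosage_profile(rpkm, control_baseline(rpkm), pm)
  calls <- call_segments(prof)
  merged <- detect_homoeologous_exchange(
    calls[calls$sample_id == "G2000_1a", ], pm)
  he <- merged[merged$event_class == "homoeologous_exchange", ]
  expect_equal(nrow(he), 1)
  expect_equal(he$direction, "A->C")
})

test_that("single-gene scan flags the planted duplication and respects suppression", {
  cfg <- panel_config(
    n_pairs_per_chrom = 60,
    doses = data.frame(radiation_type = "gamma", dose_Gy = 2000,
                       n_m1 = 12, sibs_per_m1 = 1),
    n_controls = 12, he_prob_control = 0, seed = 41)
  pm <- make_pair_map(cfg)
  les <- simulate_lesions(cfg)
  # plant on a well-covered C3 gene (long genes give tight ratios)
  c3 <- pm[pm$chrom_C == "C3", ]
  target_idx <- c3$idx_C[which.max(c3$len_C_bp)]
  les$events <- tibble::tibble(
    sample_id = "G2000_5a", subgenome = "C", chrom = "C3",
    start_idx = target_idx, end_idx = target_idx + 1L,
    event_class = "segmental_duplication", copies = 4L, zygosity = "hom",
    m1_family = "G2000_5", lesion_id = "L1")
  cm <- simulate_counts(pm, les, noise_model("genome"), cfg)
  rpkm <- rpkm_normalize(cm)
  bl <- control_baseline(rpkm)
  cand <- scan_gene_level(rpkm, bl)
  target_gene <- pm$gene_C[pm$chrom_C == "C3" & pm$idx_C == target_idx]
  expect_gt(nrow(cand), 0)
  top_dup <- cand[cand$type == "duplication", ][1, ]
  expect_equal(top_dup$gene_id, target_gene)
  expect_equal(top_dup$sample_id, "G2000_5a")

  # inside a called segment the gene is not re-reported
  seg <- tibble::tibble(sample_id = "G2000_5a", subgenome = "C",
                        chrom = "C3", start_idx = 0L, end_idx = 66L,
                        event_class = "segmental_duplication", copies = 4L,
                        zygosity = "hom")
  cand2 <- scan_gene_level(rpkm, bl, events = seg)
  expect_false(any(cand2$gene_id == target_gene &
                     cand2$sample_id == "G2000_5a"))

  # an exactly balanced matrix yields nothing at the default thresholds
  flat <- matrix(50, nrow = 40, ncol = 24,
                 dimnames = list(sprintf("g%02d", 1:40),
                                 sprintf("s%02d", 1:24)))
  r0 <- rpkm_normalize(flat, gene_lengths = rep(1000, 40))
  bl0 <- tibble::tibble(gene_id = rownames(flat),
                        median_rpkm = r0$counts[, 1], usable = TRUE)
  expect_equal(nrow(scan_gene_level(r0, bl0)), 0)
})

test_that("sibling reciprocal events pair within families only, in either order", {
  samples <- tibble::tibble(
    sample_id = c("G2000_1a", "G2000_1b", "G2000_2a", "G2000_2b"),
    role = "treated", radiation_type = "gamma", dose_Gy = 2000,
    m1_family = c("G2000_1", "G2000_1", "G2000_2", "G2000_2"),
    sib_label = c("a", "b", "a", "b"))
  ev <- tibble::tibble(
    sample_id = c("G2000_1a", "G2000_1b", "G2000_2a"),
    subgenome = "A", chrom = "A5",
    start_idx = c(0L, 2L, 0L), end_idx = c(100L, 98L, 100L),
    event_class = c("segmental_deletion", "segmental_duplication",
                    "segmental_deletion"),
    copies = c(1L, 3L, 1L), zygosity = "het")
  pairs <- match_sibling_events(ev, samples)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$deleted_sample, "G2000_1a")
  expect_equal(pairs$duplicated_sample, "G2000_1b")
  expect_gte(pairs$jaccard, 0.9)

  # G2000_2a's matching interval sits in another family: not paired
  expect_false("G2000_2a" %in% pairs$deleted_sample)

  # invariant to event order
  pairs_rev <- match_sibling_events(ev[3:1, ], samples)
  expect_equal(pairs_rev$deleted_sample, pairs$deleted_sample)
  expect_equal(pairs_rev$duplicated_sample, pairs$duplicated_sample)

  # a deletion without a sibling duplication stays unpaired
  expect_equal(nrow(match_sibling_events(ev[c(1, 3), ], samples)), 0)
})

test_that("simulated reciprocal families are all found from truth events", {
  rates <- default_rate_coefficients()
  rates$gamma$alpha_chromloss <- 0
  rates$gamma$alpha_chromgain <- 0
  cfg <- panel_config(
    n_pairs_per_chrom = 100,
    doses = data.frame(radiation_type = "gamma", dose_Gy = 2000,
                       n_m1 = 30, sibs_per_m1 = 2),
    n_controls = 3, recip_prob = 1, he_prob_control = 0,
    rate_coefficients = rates, seed = 43)
  les <- simulate_lesions(cfg)
  dels <- les$events[les$events$event_class == "segmental_deletion", ]
  pairs <- match_sibling_events(les$events, les$samples)
  expect_equal(nrow(pairs), nrow(dels))
  expect_true(all(pairs$jaccard == 1))
})

test_that("dose-response tables divide class counts by plants and average the visible rates", {
  # 100 plants at one dose with exact class counts reproducing a printed row
  samples <- tibble::tibble(
    sample_id = sprintf("G2000_%d", 1:100), role = "treated",
    radiation_type = "gamma", dose_Gy = 2000,
    m1_family = sprintf("G2000_%d", 1:100), sib_label = "a")
  mk <- function(class, sg, n) {
    if (n == 0) return(NULL)
    tibble::tibble(sample_id = sample(samples$sample_id, n, replace = TRUE),
                   subgenome = sg, chrom = paste0(sg, "1"),
                   start_idx = 0L, end_idx = 10L, event_class = class,
                   copies = 1L, zygosity = "het")
  }
  withr::local_seed(3)
  ev <- dplyr::bind_rows(
    mk("segmental_deletion", "A", 150), mk("segmental_deletion", "C", 238),
    mk("segmental_duplication", "A", 63),
    mk("segmental_duplication", "C", 31),
    mk("chromosome_loss", "C", 6))
  tab <- summarize_dose_response(ev, samples)
  expect_equal(tab$del_A, 1.5)
  expect_equal(tab$del_C, 2.38)
  expect_equal(tab$dup_A, 0.63)
  expect_equal(tab$dup_C, 0.31)
  expect_equal(tab$chrom_loss_C, 0.06)
  expect_equal(tab$mean_del_dup, 1.21)

  # no events at all: an all-zero table
  tab0 <- summarize_dose_response(ev[0, ], samples)
  expect_true(all(tab0[, 4:12] == 0))

  # homoeologous exchanges never enter the dose-response accounting
  he <- mk("segmental_deletion", "A", 10)
  he$event_class <- "homoeologous_exchange"
  expect_equal(summarize_dose_response(he, samples)$del_A, 0)
})

test_that("per-plant event rates rise with dose in a linear-rate simulation", {
  cfg <- panel_config(
    n_pairs_per_chrom = 50,
    doses = data.frame(radiation_type = "gamma",
                       dose_Gy = c(750, 1500, 1750, 2000),
                       n_m1 = 500, sibs_per_m1 = 2),
    n_controls = 3, he_prob_control = 0, seed = 47)
  les <- simulate_lesions(cfg)
  tab <- summarize_dose_response(les$events, les$samples)
  expect_equal(tab$dose_Gy, c(750, 1500, 1750, 2000))
  expect_true(!is.unsorted(tab$mean_del_dup))
})

test_that("saturation sizing follows the fixed-point expectation", {
  expect_equal(saturation_size(2.5, 0.002), 1000L)
  expect_equal(saturation_size(2.5, 0.002, target_multiplicity = 0), 0L)
  expect_lte(saturation_size(3, 0.002), saturation_size(2.5, 0.002))
  expect_lte(saturation_size(2.5, 0.003), saturation_size(2.5, 0.002))
  expect_error(saturation_size(0, 0.002), "> 0")
})
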