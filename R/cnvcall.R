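#' Parameters for the segment caller
#'
#' Thresholds sit midway between integer copy states (deletion below 1.5,
#' duplication above 2.5), giving maximal margin under symmetric noise.
#' The minimum run length operationalizes "visible" lesions: shorter skews
#' are not reported.
#'
#' @param w Running-median smoothing window in genes (odd).
#' @param del_thresh,dup_thresh Copy-number thresholds for the deletion and
#'   duplication states.
#' @param min_run Minimum run length in genes for a reported segment.
#' @param whole_chrom_frac Fraction of a chromosome's genes a run must cover
#'   to be reclassified as whole-chromosome loss/gain.
#' @param he_overlap Reciprocal-overlap fraction for merging a duplication
#'   and a homoeologous deletion into one exchange call.
#' @param sib_jaccard Interval Jaccard index for pairing reciprocal sibling
#'   events.
#' @param zygosity_cuts Copy-number cut points mapping mean segment dosage
#'   to integer copies 0-4.
#' @param conf_z Confirmation stringency: a run's raw-median deviation from
#'   the balanced state must exceed `conf_z` times the standard error of a
#'   median at the series' robust noise level (MAD). Adapts the caller to
#'   the data's noise: ineffective for tight genome counts, it suppresses
#'   short marginal runs in noisier transcriptome dosage series.
#' @return A `caller_params` list.
#' @export
caller_params <- function(w = 9, del_thresh = 1.5, dup_thresh = 2.5,
                          min_run = 10, whole_chrom_frac = 0.95,
                          he_overlap = 0.7, sib_jaccard = 0.6,
                          zygosity_cuts = c(0.5, 1.5, 2.5, 3.5),
                          conf_z = 4) {
  if (w < 1 || w %% 2 == 0) stop_bad_arg("`w` must be odd and >= 1")
  if (!(del_thresh > 0 && del_thresh < 2 && dup_thresh > 2)) {
    stop_bad_arg("need 0 < del_thresh < 2 < dup_thresh")
  }
  for (f in c(whole_chrom_frac, he_overlap, sib_jaccard)) {
    if (f <= 0 || f > 1) stop_bad_arg("fractions must lie in (0, 1]")
  }
  if (length(zygosity_cuts) != 4 || is.unsorted(zygosity_cuts)) {
    stop_bad_arg("`zygosity_cuts` must be four increasing cut points")
  }
  structure(list(w = as.integer(w), del_thresh = del_thresh,
                 dup_thresh = dup_thresh, min_run = as.integer(min_run),
                 whole_chrom_frac = whole_chrom_frac,
                 he_overlap = he_overlap, sib_jaccard = sib_jaccard,
                 zygosity_cuts = zygosity_cuts, conf_z = conf_z),
            class = "caller_params")
}

#' Truncated-window running median
#'
#' Median over a centred window of `w` genes, truncated (not padded) at the
#' chromosome ends, so the output has the length of the input and endpoints
#' average over fewer genes.
#'
#' @param x Numeric series along one chromosome (gene order).
#' @param w Odd window width.
#' @return Smoothed series, same length as `x`.
#' @export
smooth_series <- function(x, w) {
  if (length(x) == 0) stop_bad_arg("empty series")
  if (w < 1 || w %% 2 == 0) stop_bad_arg("`w` must be odd and >= 1")
  n <- length(x)
  h <- (w - 1L) %/% 2L
  trunc_med <- function(i) {
    stats::median(x[max(1L, i - h):min(n, i + h)], na.rm = TRUE)
  }
  if (h == 0L) return(as.numeric(x))
  if (n <= w || anyNA(x)) {
    return(vapply(seq_len(n), trunc_med, numeric(1)))
  }
  out <- as.vector(stats::runmed(x, w, endrule = "keep"))
  edge <- c(seq_len(h), (n - h + 1L):n)
  out[edge] <- vapply(edge, trunc_med, numeric(1))
  out
}

copies_from_k <- function(k, cuts) {
  as.integer(cut(k, breaks = c(-Inf, cuts, Inf), labels = FALSE)) - 1L
}

# maximal runs of one state, with small baseline gaps bridged
state_runs <- function(state, gap_max) {
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(state = r$values, start = starts, end = ends)
  runs <- runs[runs$state != "base", , drop = FALSE]
  if (nrow(runs) <= 1) return(runs)
  merged <- runs[1, , drop = FALSE]
  for (i in 2:nrow(runs)) {
    last <- nrow(merged)
    if (runs$state[i] == merged$state[last] &&
        runs$start[i] - merged$end[last] - 1L < gap_max) {
      merged$end[last] <- runs$end[i]
    } else {
      merged <- rbind(merged, runs[i, ])
    }
  }
  merged
}

#' Call copy-number segments for one or more samples
#'
#' Automates the visual read-out of a dosage tile plot: per sample,
#' subgenome and chromosome, the copy-number series in gene order is
#' smoothed by a running median, maximal runs below `del_thresh` (or above
#' `dup_thresh`) of at least `min_run` genes become segmental deletion
#' (duplication) events, adjacent runs separated by fewer than `w/2`
#' baseline genes are bridged first, integer copies and zygosity come from
#' the mean smoothed dosage via the cut points, and runs covering at least
#' `whole_chrom_frac` of the chromosome are reclassified as
#' whole-chromosome loss or gain. Intervals are 0-based half-open
#' gene-order indices.
#'
#' @param profile A dosage profile tibble ([dosage_profile()]); may contain
#'   several samples.
#' @param params A [caller_params()].
#' @param sizes Chromosome sizes ([chrom_sizes()]); defaults to sizes
#'   implied by the profile itself.
#' @return Event tibble (`sample_id`, `subgenome`, `chrom`, `start_idx`,
#'   `end_idx`, `event_class`, `copies`, `zygosity`, `mean_k`, `n_genes`).
#' @export
call_segments <- function(profile, params = caller_params(), sizes = NULL) {
  stopifnot(inherits(params, "caller_params"))
  prof <- profile[!profile$masked, , drop = FALSE]
  out <- list()

  call_one_chrom <- function(sample_id, subgenome, chrom, idx, k, n_chrom) {
    o <- order(idx)
    idx <- idx[o]; k <- k[o]
    sm <- smooth_series(k, params$w)
    state <- ifelse(sm < params$del_thresh, "del",
                    ifelse(sm > params$dup_thresh, "dup", "base"))
    runs <- state_runs(state, gap_max = params$w / 2)
    if (nrow(runs) == 0) return(NULL)
    runs <- runs[runs$end - runs$start + 1L >= params$min_run, ,
                 drop = FALSE]
    if (nrow(runs) == 0) return(NULL)
    # confirm on the raw series: a handful of outlier genes can drag a
    # whole smoothing-window-length run over the threshold, but cannot
    # move the run's raw median; the required deviation scales with the
    # series' robust noise level so short marginal runs need strong support
    sigma <- stats::mad(k, center = 2)
    raw_ok <- vapply(seq_len(nrow(runs)), function(i) {
      n_run <- runs$end[i] - runs$start[i] + 1L
      raw_med <- stats::median(k[runs$start[i]:runs$end[i]])
      need <- params$conf_z * 1.2533 * sigma / sqrt(n_run)
      if (runs$state[i] == "del") {
        raw_med < params$del_thresh && (2 - raw_med) >= need
      } else {
        raw_med > params$dup_thresh && (raw_med - 2) >= need
      }
    }, logical(1))
    runs <- runs[raw_ok, , drop = FALSE]
    if (nrow(runs) == 0) return(NULL)
    lapply(seq_len(nrow(runs)), function(i) {
      span <- runs$start[i]:runs$end[i]
      mean_k <- mean(sm[span])
      copies <- copies_from_k(mean_k, params$zygosity_cuts)
      if (runs$state[i] == "del") copies <- min(copies, 1L)
      if (runs$state[i] == "dup") copies <- max(copies, 3L)
      frac <- length(span) / n_chrom
      class <- if (frac >= params$whole_chrom_frac) {
        if (runs$state[i] == "del") "chromosome_loss" else "chromosome_gain"
      } else {
        if (runs$state[i] == "del") "segmental_deletion"
        else "segmental_duplication"
      }
      list(sample_id = sample_id, subgenome = subgenome, chrom = chrom,
           start_idx = idx[runs$start[i]], end_idx = idx[runs$end[i]] + 1L,
           event_class = class, copies = copies,
           zygosity = if (copies %in% c(0L, 4L)) "hom" else "het",
           mean_k = mean_k, n_genes = length(span))
    })
  }

  for (sg in c("A", "C")) {
    chrom_col <- paste0("chrom_", sg)
    idx_col <- paste0("idx_", sg)
    k_col <- paste0("k_", sg)
    n_per_chrom <- tapply(profile[[idx_col]], profile[[chrom_col]],
                          function(v) length(unique(v)))
    split_keys <- interaction(prof$sample_id, prof[[chrom_col]], drop = TRUE)
    pieces <- split(seq_len(nrow(prof)), split_keys)
    for (rows in pieces) {
      res <- call_one_chrom(prof$sample_id[rows[1]], sg,
                            prof[[chrom_col]][rows[1]],
                            prof[[idx_col]][rows], prof[[k_col]][rows],
                            n_per_chrom[[prof[[chrom_col]][rows[1]]]])
      if (!is.null(res)) out <- c(out, res)
    }
  }

  if (length(out) == 0) {
    return(tibble::tibble(
      sample_id = character(), subgenome = character(), chrom = character(),
      start_idx = integer(), end_idx = integer(), event_class = character(),
      copies = integer(), zygosity = character(), mean_k = numeric(),
      n_genes = integer()))
  }
  dplyr::bind_rows(lapply(out, tibble::as_tibble)) |>
    dplyr::arrange(.data$sample_id, .data$subgenome, .data$chrom,
                   .data$start_idx)
}

# pair ids covered by an event interval
event_pairs <- function(event, pair_map) {
  if (event$subgenome == "A") {
    pair_map$pair_id[pair_map$chrom_A == event$chrom &
                       pair_map$idx_A >= event$start_idx &
                       pair_map$idx_A < event$end_idx]
  } else {
    pair_map$pair_id[pair_map$chrom_C == event$chrom &
                       pair_map$idx_C >= event$start_idx &
                       pair_map$idx_C < event$end_idx]
  }
}

#' Merge reciprocal duplication/deletion calls into homoeologous exchanges
#'
#' A duplication on one subgenome and a deletion covering the homoeologous
#' pairs on the other subgenome, with reciprocal overlap (in pair space) of
#' at least `he_overlap` in both directions, are merged into a single
#' homoeologous-exchange call whose subgenome records the gaining side;
#' the constituent events are consumed.
#'
#' @param events Segment calls for one sample ([call_segments()]).
#' @param pair_map The homoeologue pair map.
#' @param he_overlap Reciprocal-overlap threshold (default 0.7).
#' @return Event tibble with exchanges merged; exchange rows carry
#'   `event_class = "homoeologous_exchange"` and the direction in
#'   `direction` (e.g. `"A->C"`).
#' @export
detect_homoeologous_exchange <- function(events, pair_map, he_overlap = 0.7) {
  ev <- dplyr::mutate(events, direction = NA_character_)
  if (nrow(ev) == 0) return(ev)
  dup_i <- which(ev$event_class %in%
                   c("segmental_duplication", "chromosome_gain"))
  del_i <- which(ev$event_class %in%
                   c("segmental_deletion", "chromosome_loss"))
  consumed <- logical(nrow(ev))
  merged <- list()
  for (di in dup_i) {
    if (consumed[di]) next
    dup_pairs <- event_pairs(ev[di, ], pair_map)
    if (length(dup_pairs) == 0) next
    # the reciprocal loss may be split over several partner chromosomes
    # (synteny blocks); gather every deletion that the duplication explains
    partners <- integer(0)
    covered <- character(0)
    for (li in del_i) {
      if (consumed[li] || ev$sample_id[li] != ev$sample_id[di] ||
          ev$subgenome[li] == ev$subgenome[di]) next
      del_pairs <- event_pairs(ev[li, ], pair_map)
      if (length(del_pairs) == 0) next
      inter <- intersect(dup_pairs, del_pairs)
      if (length(inter) / length(del_pairs) >= he_overlap) {
        partners <- c(partners, li)
        covered <- union(covered, inter)
      }
    }
    if (length(partners) > 0 &&
        length(covered) / length(dup_pairs) >= he_overlap) {
      consumed[c(di, partners)] <- TRUE
      he <- ev[di, ]
      he$event_class <- "homoeologous_exchange"
      he$direction <- paste0(ev$subgenome[di], "->",
                             ev$subgenome[partners[1]])
      merged[[length(merged) + 1L]] <- he
    }
  }
  dplyr::bind_rows(ev[!consumed, , drop = FALSE], dplyr::bind_rows(merged))
}

#' Scan for single-gene copy-number candidates
#'
#' Population-normalized per-gene dosage: for each gene and sample,
#' `r = k / median across samples`; candidates are genes with `r >= 1.75`
#' (duplication) or `r <= 0.25` (homozygous deletion) that do not lie
#' inside an already-called segment, ranked by |log2 r|.
#'
#' @param rpkm An RPKM `count_matrix` (needs >= 20 samples).
#' @param baseline A [control_baseline()].
#' @param events Called segments used to suppress re-reporting (optional).
#' @param dup_ratio,del_ratio Candidate thresholds.
#' @return Tibble `gene_id`, `sample_id`, `ratio`, `k`, `type`, ordered by
#'   decreasing |log2 ratio|.
#' @export
scan_gene_level <- function(rpkm, baseline, events = NULL,
                            dup_ratio = 1.75, del_ratio = 0.25) {
  if (ncol(rpkm$counts) < 20) {
    stop_bad_arg("gene-level scan needs a population of >= 20 samples")
  }
  k <- estimate_copies(rpkm, baseline)
  med <- apply(k, 1, stats::median, na.rm = TRUE)
  degenerate <- !is.na(med) & med == 0
  if (any(degenerate)) {
    warning(sprintf("%d gene(s) with zero population median skipped",
                    sum(degenerate)))
  }
  ok <- !is.na(med) & med > 0
  r <- k[ok, , drop = FALSE] / med[ok]
  hits <- which(r >= dup_ratio | r <= del_ratio, arr.ind = TRUE)
  if (nrow(hits) == 0) {
    return(tibble::tibble(gene_id = character(), sample_id = character(),
                          ratio = numeric(), k = numeric(),
                          type = character()))
  }
  cand <- tibble::tibble(
    gene_id = rownames(r)[hits[, 1]],
    sample_id = colnames(r)[hits[, 2]],
    ratio = r[hits], k = k[ok, , drop = FALSE][hits],
    type = ifelse(r[hits] >= dup_ratio, "duplication", "deletion")
  )
  if (!is.null(events) && nrow(events) > 0 && !is.null(rpkm$genes)) {
    gmeta <- rpkm$genes
    inside <- rep(FALSE, nrow(cand))
    gi <- match(cand$gene_id, gmeta$gene_id)
    for (i in seq_len(nrow(events))) {
      hit <- cand$sample_id == events$sample_id[i] &
        gmeta$subgenome[gi] == events$subgenome[i] &
        gmeta$chrom[gi] == events$chrom[i] &
        gmeta$idx[gi] >= events$start_idx[i] &
        gmeta$idx[gi] < events$end_idx[i]
      inside <- inside | hit
    }
    cand <- cand[!inside, , drop = FALSE]
  }
  cand[order(-abs(log2(cand$ratio))), ]
}

#' Match reciprocal deletion/duplication events between siblings
#'
#' Within each M1 family, a deletion interval in one M2 sibling and a
#' duplication interval in a different sibling on the same subgenome and
#' chromosome with gene-index Jaccard at least `sib_jaccard` are reported
#' as one reciprocal pair (a lost segment inherited as extra copies by the
#' sibling). Invariant to sibling order.
#'
#' @param events Event tibble with `sample_id`.
#' @param samples Sample sheet with `m1_family`.
#' @param sib_jaccard Interval Jaccard threshold (default 0.6).
#' @return Tibble of pairs: family, chromosome, both sample ids, both
#'   intervals and their Jaccard index.
#' @export
match_sibling_events <- function(events, samples, sib_jaccard = 0.6) {
  ev <- events
  ev$m1_family <- NULL # the sample sheet is authoritative for kinship
  ev <- dplyr::left_join(ev, samples[, c("sample_id", "m1_family")],
                         by = "sample_id")
  ev <- ev[!is.na(ev$m1_family), , drop = FALSE]
  dels <- ev[ev$event_class %in% c("segmental_deletion", "chromosome_loss"), ]
  dups <- ev[ev$event_class %in% c("segmental_duplication",
                                   "chromosome_gain"), ]
  out <- list()
  for (i in seq_len(nrow(dels))) {
    cand <- dups[dups$m1_family == dels$m1_family[i] &
                   dups$sample_id != dels$sample_id[i] &
                   dups$subgenome == dels$subgenome[i] &
                   dups$chrom == dels$chrom[i], , drop = FALSE]
    if (nrow(cand) == 0) next
    jac <- interval_jaccard(dels$start_idx[i], dels$end_idx[i],
                            cand$start_idx, cand$end_idx)
    best <- which.max(jac)
    if (jac[best] >= sib_jaccard) {
      out[[length(out) + 1L]] <- tibble::tibble(
        m1_family = dels$m1_family[i], subgenome = dels$subgenome[i],
        chrom = dels$chrom[i],
        deleted_sample = dels$sample_id[i],
        duplicated_sample = cand$sample_id[best],
        del_start = dels$start_idx[i], del_end = dels$end_idx[i],
        dup_start = cand$start_idx[best], dup_end = cand$end_idx[best],
        jaccard = jac[best])
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(
      m1_family = character(), subgenome = character(), chrom = character(),
      deleted_sample = character(), duplicated_sample = character(),
      del_start = integer(), del_end = integer(), dup_start = integer(),
      dup_end = integer(), jaccard = numeric()))
  }
  dplyr::bind_rows(out)
}

#' Summarize called events into a dose-response table
#'
#' Per radiation type and dose: per-plant rates of A/C chromosome loss and
#' duplication and of A/C visible (segmental) deletions and duplications,
#' each the class count divided by the number of plants in the dose group,
#' rounded half-up to 2 decimals; the final column is the mean of the four
#' visible-event rates, again rounded half-up to 2 decimals.
#' Homoeologous exchanges are not dose-dependent and are excluded.
#'
#' @param events Event tibble (called or simulated truth).
#' @param samples Sample sheet with `radiation_type` and `dose_Gy`.
#' @return Tibble: `radiation_type`, `dose_Gy`, `n_plants`, the eight class
#'   rate columns, and `mean_del_dup`.
#' @export
summarize_dose_response <- function(events, samples) {
  treated <- samples[samples$role == "treated", , drop = FALSE]
  if (nrow(treated) == 0) stop_bad_arg("no treated plants in sample sheet")
  groups <- treated |>
    dplyr::count(.data$radiation_type, .data$dose_Gy, name = "n_plants")
  if (any(groups$n_plants == 0)) stop_bad_arg("dose group with zero plants")

  ev <- dplyr::inner_join(
    events, treated[, c("sample_id", "radiation_type", "dose_Gy")],
    by = "sample_id",
    suffix = c("_event", ""))
  ev <- ev[ev$event_class != "homoeologous_exchange", , drop = FALSE]

  class_cols <- c(chromosome_loss_A = "chrom_loss_A",
                  chromosome_loss_C = "chrom_loss_C",
                  chromosome_gain_A = "chrom_dup_A",
                  chromosome_gain_C = "chrom_dup_C",
                  segmental_deletion_A = "del_A",
                  segmental_deletion_C = "del_C",
                  segmental_duplication_A = "dup_A",
                  segmental_duplication_C = "dup_C")
  counts <- ev |>
    dplyr::count(.data$radiation_type, .data$dose_Gy,
                 key = paste(.data$event_class, .data$subgenome, sep = "_")) |>
    tidyr::pivot_wider(names_from = "key", values_from = "n",
                       values_fill = 0L)
  tab <- dplyr::left_join(groups, counts,
                          by = c("radiation_type", "dose_Gy"))
  for (nm in names(class_cols)) {
    val <- if (nm %in% names(tab)) tab[[nm]] else 0L
    val[is.na(val)] <- 0L
    tab[[class_cols[[nm]]]] <- round_half_up(val / tab$n_plants, 2)
    tab[[nm]] <- NULL
  }
  tab$mean_del_dup <- dose_response_mean(
    cbind(tab$del_A, tab$del_C, tab$dup_A, tab$dup_C))
  tab[order(tab$radiation_type, tab$dose_Gy),
      c("radiation_type", "dose_Gy", "n_plants", unname(class_cols),
        "mean_del_dup")]
}

#' Mean of the four visible deletion/duplication per-plant rates
#'
#' @param rates Length-4 vector (A deletion, C deletion, A duplication, C
#'   duplication per-plant rates) or a 4-column matrix of such rows.
#' @return Unweighted mean, rounded half-up to 2 decimals.
#' @export
dose_response_mean <- function(rates) {
  if (is.matrix(rates)) {
    stopifnot(ncol(rates) == 4)
    return(round_half_up(rowMeans(rates), 2))
  }
  stopifnot(length(rates) == 4)
  round_half_up(mean(rates), 2)
}

#' Population size to saturate a genome for deletions (or duplications)
#'
#' Expected hits of a fixed genome point after N lines is
#' `N * rate * frac`; the lines needed for an average of `target`
#' independent hits is `ceil(target / (rate * frac))`.
#'
#' @param mean_per_plant Mean events per plant.
#' @param mean_frac_genome Mean fraction of the genome covered by one event.
#' @param target_multiplicity Desired average hits per genome point
#'   (default 5).
#' @return Required number of lines (integer).
#' @export
saturation_size <- function(mean_per_plant, mean_frac_genome,
                            target_multiplicity = 5) {
  if (mean_per_plant <= 0 || mean_frac_genome <= 0) {
    stop_bad_arg("rates must be > 0")
  }
  if (target_multiplicity < 0) stop_bad_arg("target must be >= 0")
  as.integer(ceiling(target_multiplicity /
                       (mean_per_plant * mean_frac_genome)))
}
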