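# Chromosome sizes implied by a config alone (must agree with the pair map
# built from the same config; C indices are inflated by c_extra_frac).
config_chrom_sizes <- function(config) {
  n_per <- config$n_pairs_per_chrom
  a <- tibble::tibble(subgenome = "A", chrom = config$chrom_names_A,
                      n_genes = as.integer(n_per))
  n_pairs <- sum(n_per)
  n_c <- length(config$chrom_names_C)
  block_sizes <- as.integer(table(sort(rep_len(seq_len(n_c), n_pairs))))
  c_ <- tibble::tibble(
    subgenome = "C", chrom = config$chrom_names_C,
    n_genes = as.integer(floor((block_sizes - 1L) *
                                 (1 + config$c_extra_frac))) + 1L
  )
  dplyr::bind_rows(a, c_)
}

# log-uniform segment length in genes, between min_len and chrom length
draw_seg_len <- function(n, min_len, chrom_len) {
  lo <- log(pmin(min_len, chrom_len))
  hi <- log(chrom_len)
  pmax(1L, as.integer(round(exp(stats::runif(n, lo, hi)))))
}

# one segregation draw per sibling: 1 absent : 2 het : 1 hom
draw_mendelian <- function(k) {
  sample(c("absent", "het", "hom"), k, replace = TRUE,
         prob = c(0.25, 0.5, 0.25))
}

copies_for <- function(event_class, zygosity) {
  gain <- event_class %in% c("segmental_duplication", "chromosome_gain",
                             "homoeologous_exchange")
  ifelse(gain, ifelse(zygosity == "hom", 4L, 3L),
         ifelse(zygosity == "hom", 0L, 1L))
}

#' Simulate radiation-induced lesions for a panel
#'
#' Draws M1 lesion counts per family as Poisson with mean proportional to
#' dose, segregates each lesion 1:2:1 (absent : heterozygous : homozygous)
#' into the genotyped M2 siblings, and converts a configurable fraction of
#' deletions into sibling-reciprocal events (one sibling inherits the
#' deletion, another the corresponding duplication). M1 rates are inflated
#' so that the detectable per-M2-plant event mean of each calibrated class
#' equals `alpha_class * dose`. Every line additionally receives a
#' pre-existing homoeologous exchange with probability `he_prob_control`,
#' reflecting seed-lot heterogeneity; untreated controls carry only such
#' exchanges.
#'
#' @param config A [panel_config()].
#' @return A `panel_lesions` list with `$events` (tibble: `sample_id`,
#'   `subgenome`, `chrom`, `start_idx`, `end_idx` 0-based half-open
#'   gene-order interval, `event_class`, `copies`, `zygosity`,
#'   `m1_family`, `lesion_id`) and `$samples` (the sample sheet).
#' @export
simulate_lesions <- function(config) {
  stopifnot(inherits(config, "panel_config"))
  samples <- make_sample_sheet(config)
  sizes <- config_chrom_sizes(config)
  sizes_by <- stats::setNames(sizes$n_genes, paste(sizes$subgenome, sizes$chrom))

  events <- withr::with_seed(config$seed + 202L, {
    out <- list()
    lesion_no <- 0L

    # lesions of one family (or one control line) never overlap: at the
    # observed per-plant rates physical collisions are rare, and disjoint
    # placement keeps every truth interval individually detectable
    occupancy <- new.env(parent = emptyenv())
    occ_key <- function(owner, subgenome, chrom) {
      paste(owner, subgenome, chrom, sep = "\r")
    }
    occ_free <- function(owner, subgenome, chrom, start, end) {
      iv <- occupancy[[occ_key(owner, subgenome, chrom)]]
      is.null(iv) || all(end <= iv[, 1] | start >= iv[, 2])
    }
    occ_add <- function(owner, subgenome, chrom, start, end) {
      key <- occ_key(owner, subgenome, chrom)
      occupancy[[key]] <- rbind(occupancy[[key]], c(start, end))
    }

    new_segment <- function(subgenome, chrom, owner) {
      n_genes <- sizes_by[[paste(subgenome, chrom)]]
      for (try in 1:25) {
        len <- draw_seg_len(1, config$min_seg_genes, n_genes)
        start <- sample.int(n_genes - len + 1L, 1L) - 1L
        if (occ_free(owner, subgenome, chrom, start, start + len)) {
          occ_add(owner, subgenome, chrom, start, start + len)
          return(c(start = start, end = start + len))
        }
      }
      NULL # chromosome effectively saturated for this family
    }

    emit <- function(sample_id, subgenome, chrom, start, end, event_class,
                     zygosity, m1_family, lesion_id) {
      out[[length(out) + 1L]] <<- list(
        sample_id = sample_id, subgenome = subgenome, chrom = chrom,
        start_idx = as.integer(start), end_idx = as.integer(end),
        event_class = event_class,
        copies = copies_for(event_class, zygosity), zygosity = zygosity,
        m1_family = if (is.na(m1_family)) NA_character_ else m1_family,
        lesion_id = lesion_id)
    }

    # pre-existing homoeologous exchanges (A segment replacing its C partner)
    for (s in seq_len(nrow(samples))) {
      if (stats::runif(1) < config$he_prob_control) {
        chrom <- sample(config$chrom_names_A, 1L)
        owner <- if (is.na(samples$m1_family[s])) samples$sample_id[s]
                 else samples$m1_family[s]
        seg <- new_segment("A", chrom, owner)
        if (is.null(seg)) next
        lesion_no <- lesion_no + 1L
        emit(samples$sample_id[s], "A", chrom, seg["start"], seg["end"],
             "homoeologous_exchange", "hom", samples$m1_family[s],
             sprintf("HE%05d", lesion_no))
      }
    }

    seg_classes <- tibble::tibble(
      event_class = rep(c("segmental_deletion", "segmental_duplication"), 2),
      subgenome = rep(c("A", "C"), each = 2),
      rate_name = c("alpha_del_A", "alpha_dup_A", "alpha_del_C", "alpha_dup_C")
    )[c(1, 3, 2, 4), ] # deletions first so reciprocal budget is known

    fam_tbl <- samples |>
      dplyr::filter(.data$role == "treated") |>
      dplyr::group_by(.data$m1_family, .data$radiation_type, .data$dose_Gy) |>
      dplyr::summarise(sibs = list(.data$sample_id), .groups = "drop")

    for (f in seq_len(nrow(fam_tbl))) {
      sibs <- fam_tbl$sibs[[f]]
      k <- length(sibs)
      dose <- fam_tbl$dose_Gy[f]
      rates <- rates_for(config, fam_tbl$radiation_type[f])
      p_rec <- if (k >= 2) config$recip_prob else 0
      mend_frac <- 0.75

      # whole-chromosome events first (uniform over the 19 chromosomes),
      # so segmental placement avoids already-aneuploid chromosomes
      for (class in c("chromosome_loss", "chromosome_gain")) {
        rate <- if (class == "chromosome_loss") rates$alpha_chromloss
                else rates$alpha_chromgain
        n_les <- stats::rpois(1L, if (rate > 0) rate * dose / mend_frac else 0)
        if (n_les == 0) next
        rows <- sample.int(nrow(sizes), n_les, replace = TRUE)
        for (i in seq_len(n_les)) {
          sg_i <- sizes$subgenome[rows[i]]
          ch_i <- sizes$chrom[rows[i]]
          n_i <- sizes$n_genes[rows[i]]
          if (!occ_free(fam_tbl$m1_family[f], sg_i, ch_i, 0L, n_i)) next
          occ_add(fam_tbl$m1_family[f], sg_i, ch_i, 0L, n_i)
          lesion_no <- lesion_no + 1L
          gt <- draw_mendelian(k)
          for (j in which(gt != "absent")) {
            emit(sibs[j], sg_i, ch_i, 0L, n_i, class, gt[j],
                 fam_tbl$m1_family[f], sprintf("L%06d", lesion_no))
          }
        }
      }

      for (cl in seq_len(nrow(seg_classes))) {
        class <- seg_classes$event_class[cl]
        sg <- seg_classes$subgenome[cl]
        target <- rates[[seg_classes$rate_name[cl]]] * dose
        if (class == "segmental_deletion") {
          factor <- p_rec / k + (1 - p_rec) * mend_frac
          lam <- if (target > 0) target / factor else 0
        } else {
          # reciprocal captures of this subgenome's deletions already
          # contribute duplications; draw only the remainder independently
          del_target <- rates[[paste0("alpha_del_", sg)]] * dose
          del_lam <- if (del_target > 0) {
            del_target / (p_rec / k + (1 - p_rec) * mend_frac)
          } else 0
          contrib <- del_lam * p_rec / k
          lam <- max(0, target - contrib) / mend_frac
        }
        n_les <- stats::rpois(1L, lam)
        if (n_les == 0) next
        sg_chroms <- sizes$chrom[sizes$subgenome == sg]
        for (i in seq_len(n_les)) {
          # if the drawn chromosome cannot host the segment without
          # overlapping the family's earlier lesions, try another
          seg <- NULL
          for (attempt in seq_len(10L)) {
            chrom_i <- sample(sg_chroms, 1L)
            seg <- new_segment(sg, chrom_i, fam_tbl$m1_family[f])
            if (!is.null(seg)) break
          }
          if (is.null(seg)) next
          lesion_no <- lesion_no + 1L
          lid <- sprintf("L%06d", lesion_no)
          if (class == "segmental_deletion" && stats::runif(1) < p_rec) {
            # reciprocal inheritance: het deletion in one sibling, het
            # duplication of the same segment in another
            pick <- sample.int(k, 2L)
            emit(sibs[pick[1]], sg, chrom_i, seg["start"], seg["end"],
                 "segmental_deletion", "het", fam_tbl$m1_family[f], lid)
            emit(sibs[pick[2]], sg, chrom_i, seg["start"], seg["end"],
                 "segmental_duplication", "het", fam_tbl$m1_family[f], lid)
          } else {
            gt <- draw_mendelian(k)
            for (j in which(gt != "absent")) {
              emit(sibs[j], sg, chrom_i, seg["start"], seg["end"],
                   class, gt[j], fam_tbl$m1_family[f], lid)
            }
          }
        }
      }
    }

    tibble::tibble(
      sample_id = vapply(out, `[[`, character(1), "sample_id"),
      subgenome = vapply(out, `[[`, character(1), "subgenome"),
      chrom = vapply(out, `[[`, character(1), "chrom"),
      start_idx = vapply(out, `[[`, integer(1), "start_idx"),
      end_idx = vapply(out, `[[`, integer(1), "end_idx"),
      event_class = vapply(out, `[[`, character(1), "event_class"),
      copies = vapply(out, `[[`, integer(1), "copies"),
      zygosity = vapply(out, `[[`, character(1), "zygosity"),
      m1_family = vapply(out, `[[`, character(1), "m1_family"),
      lesion_id = vapply(out, `[[`, character(1), "lesion_id")
    )
  })

  structure(list(events = events, samples = samples, config = config),
            class = "panel_lesions")
}

#' @rdname simulate_lesions
#' @param events Event tibble (truth or called).
#' @param path File path for the tab-separated event table.
#' @export
write_events <- function(events, path) {
  readr::write_tsv(events, path)
  invisible(path)
}

#' @rdname simulate_lesions
#' @export
read_events <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
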