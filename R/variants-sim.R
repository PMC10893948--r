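#' Simulate small-variant calls with a depth-stratified false-positive model
#'
#' Emulates the raw SNV/InDel call set of a re-sequenced panel: each treated
#' line receives line-specific calls in two variant-allele read depth (VAD)
#' strata, true with probability `p_valid_gt2` (VAD > 2) or `p_valid_eq2`
#' (VAD = 2) — the validation rates observed by capillary re-sequencing.
#' Shared artifact positions recur across many lines including the untreated
#' controls, and controls additionally carry private false calls, so the
#' control-subtraction and recurrence filters have realistic targets.
#'
#' @param config A [panel_config()].
#' @return A `panel_variants` list: `$variants` tibble (`chrom`, `pos`,
#'   `ref`, `alt`, `qual`, `sample`, `gt`, `vad`, `is_true`, `category` in
#'   line_specific/artifact/control_private) and `$samples`.
#' @export
simulate_variants <- function(config) {
  stopifnot(inherits(config, "panel_config"))
  samples <- make_sample_sheet(config)
  sizes <- config_chrom_sizes(config)
  chrom_bp <- stats::setNames(sizes$n_genes * 5000, sizes$chrom)
  bases <- c("A", "C", "G", "T")

  variants <- withr::with_seed(config$seed + 404L, {
    rows <- list()
    draw_site <- function(n) {
      chrom <- sample(names(chrom_bp), n, replace = TRUE)
      pos <- floor(stats::runif(n, 1, chrom_bp[chrom])) + 0
      list(chrom = chrom, pos = as.integer(pos))
    }
    draw_alleles <- function(n) {
      ref <- sample(bases, n, replace = TRUE)
      alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1),
                    character(1))
      is_indel <- stats::runif(n) < 0.3
      for (i in which(is_indel)) {
        len <- sample(c(1:6, 9L, 12L, 21L), 1)
        ins <- paste(sample(bases, len, replace = TRUE), collapse = "")
        if (stats::runif(1) < 1 / 3) {
          alt[i] <- paste0(ref[i], ins)            # insertion
        } else {
          ref[i] <- paste0(ref[i], ins)            # deletion
          alt[i] <- substr(ref[i], 1, 1)
        }
      }
      list(ref = ref, alt = unname(alt))
    }

    # shared artifact sites, present in most lines including controls
    n_art <- config$n_artifact_sites
    art_site <- draw_site(n_art)
    art_allele <- draw_alleles(n_art)
    for (s in samples$sample_id) {
      present <- which(stats::runif(n_art) < 0.6)
      if (length(present) == 0) next
      rows[[length(rows) + 1L]] <- tibble::tibble(
        chrom = art_site$chrom[present], pos = art_site$pos[present],
        ref = art_allele$ref[present], alt = art_allele$alt[present],
        qual = stats::runif(length(present), 21, 60),
        sample = s, gt = "0/1",
        vad = pmax(2L, stats::rbinom(length(present), 12, 0.5)),
        is_true = FALSE, category = "artifact")
    }

    # private false calls in untreated controls
    for (s in samples$sample_id[samples$role == "control"]) {
      n <- stats::rpois(1, 5)
      if (n == 0) next
      site <- draw_site(n); al <- draw_alleles(n)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        chrom = site$chrom, pos = site$pos, ref = al$ref, alt = al$alt,
        qual = stats::runif(n, 5, 55), sample = s, gt = "0/1",
        vad = pmax(2L, stats::rbinom(n, 12, 0.4)),
        is_true = FALSE, category = "control_private")
    }

    # line-specific calls in treated lines, stratified by VAD
    for (s in samples$sample_id[samples$role == "treated"]) {
      n2 <- stats::rpois(1, config$calls_eq2_per_line)
      ng <- stats::rpois(1, config$calls_gt2_per_line)
      n <- n2 + ng
      if (n == 0) next
      site <- draw_site(n); al <- draw_alleles(n)
      vad <- c(rep(2L, n2), sample(3:8, ng, replace = TRUE))
      p <- ifelse(vad == 2, config$p_valid_eq2, config$p_valid_gt2)
      is_true <- stats::runif(n) < p
      rows[[length(rows) + 1L]] <- tibble::tibble(
        chrom = site$chrom, pos = site$pos, ref = al$ref, alt = al$alt,
        qual = ifelse(is_true, stats::runif(n, 25, 60),
                      stats::runif(n, 5, 55)),
        sample = s, gt = "0/1", vad = vad,
        is_true = is_true, category = "line_specific")
    }

    dplyr::bind_rows(rows) |>
      dplyr::arrange(.data$chrom, .data$pos, .data$sample)
  })

  structure(list(variants = variants, samples = samples, config = config),
            class = "panel_variants")
}
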