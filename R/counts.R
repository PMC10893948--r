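#' Gene table implied by a pair map
#'
#' Expands a homoeologue pair map into one row per gene (A genes then C
#' genes) with subgenome, chromosome, gene-order index, length and pair id.
#'
#' @param pair_map A pair map from [make_pair_map()].
#' @return Tibble with `gene_id`, `subgenome`, `chrom`, `idx`, `len_bp`,
#'   `pair_id`.
#' @export
panel_genes <- function(pair_map) {
  dplyr::bind_rows(
    pair_map |> dplyr::transmute(
      gene_id = .data$gene_A, subgenome = "A", chrom = .data$chrom_A,
      idx = .data$idx_A, len_bp = .data$len_A_bp, pair_id = .data$pair_id),
    pair_map |> dplyr::transmute(
      gene_id = .data$gene_C, subgenome = "C", chrom = .data$chrom_C,
      idx = .data$idx_C, len_bp = .data$len_C_bp, pair_id = .data$pair_id)
  )
}

# per-sample gene copy numbers (baseline 2) after overlaying events
overlay_copies <- function(genes, events, sample_id, pair_map) {
  copies <- rep(2L, nrow(genes))
  ev <- events[events$sample_id == sample_id, , drop = FALSE]
  if (nrow(ev) == 0) return(copies)
  known <- unique(paste(genes$subgenome, genes$chrom))
  for (i in seq_len(nrow(ev))) {
    key <- paste(ev$subgenome[i], ev$chrom[i])
    if (!key %in% known) {
      stop_bad_arg("sample %s: event on unknown chromosome %s (%s subgenome)",
                   sample_id, ev$chrom[i], ev$subgenome[i])
    }
    hit <- genes$subgenome == ev$subgenome[i] & genes$chrom == ev$chrom[i] &
      genes$idx >= ev$start_idx[i] & genes$idx < ev$end_idx[i]
    copies[hit] <- ev$copies[i]
    if (ev$event_class[i] == "homoeologous_exchange") {
      # reciprocal side: the partner subgenome loses what this one gains
      partner <- setdiff(c("A", "C"), ev$subgenome[i])
      pairs_hit <- unique(genes$pair_id[hit])
      phit <- genes$subgenome == partner & genes$pair_id %in% pairs_hit
      copies[phit] <- 4L - ev$copies[i]
    }
  }
  copies
}

#' Simulate gene-level read counts for a panel
#'
#' Raw counts per gene and sample are negative binomial with mean
#' proportional to gene length, sequencing depth and the gene's post-lesion
#' copy number (baseline 2). Transcriptome mode multiplies in a fixed
#' per-gene expression level and an extra per-gene, per-sample lognormal
#' factor of coefficient of variation `expression_cv`, making dosage ratios
#' noisier than in genome mode.
#'
#' @param pair_map A pair map from [make_pair_map()].
#' @param lesions A `panel_lesions` object from [simulate_lesions()], or an
#'   event tibble (then `samples` must be supplied).
#' @param noise A [noise_model()].
#' @param config The [panel_config()] (seeds the draw).
#' @param samples Sample sheet; defaults to the one in `lesions`.
#' @return A `count_matrix`: list with `$counts` (genes x samples integer
#'   matrix), `$genes`, `$samples`, `$totals` (per-sample mapped reads) and
#'   `$unit = "count"`.
#' @export
simulate_counts <- function(pair_map, lesions, noise = noise_model("genome"),
                            config, samples = NULL) {
  events <- if (inherits(lesions, "panel_lesions")) lesions$events else lesions
  samples <- samples %||%
    if (inherits(lesions, "panel_lesions")) lesions$samples else NULL
  if (is.null(samples)) stop_bad_arg("`samples` sheet required")
  stopifnot(inherits(noise, "noise_model"))

  genes <- panel_genes(pair_map)
  g <- nrow(genes)
  base_mu <- noise$mean_depth * genes$len_bp / 1000

  counts <- withr::with_seed(config$seed + 303L, {
    expr_level <- if (noise$mode == "transcriptome") {
      stats::rlnorm(g, meanlog = -0.8^2 / 2, sdlog = 0.8)
    } else {
      rep(1, g)
    }
    sd_j <- sqrt(log(1 + noise$expression_cv^2))
    m <- matrix(0L, nrow = g, ncol = nrow(samples),
                dimnames = list(genes$gene_id, samples$sample_id))
    for (s in seq_len(nrow(samples))) {
      cp <- overlay_copies(genes, events, samples$sample_id[s], pair_map)
      mu <- base_mu * expr_level * cp / 2
      if (sd_j > 0) {
        mu <- mu * stats::rlnorm(g, meanlog = -sd_j^2 / 2, sdlog = sd_j)
      }
      m[, s] <- as.integer(stats::rnbinom(g, mu = mu,
                                          size = 1 / noise$dispersion))
    }
    m
  })

  structure(list(counts = counts, genes = genes, samples = samples,
                 totals = colSums(counts), unit = "count"),
            class = "count_matrix")
}

#' Count-matrix input/output
#'
#' Counts are written as a TSV with the gene id in the first column and one
#' column per sample; the sample sheet is a companion TSV. Reading requires
#' the pair map to restore gene metadata.
#'
#' @param cm A `count_matrix`.
#' @param counts_path,samples_path Output TSV paths.
#' @export
write_count_matrix <- function(cm, counts_path, samples_path = NULL) {
  tb <- tibble::as_tibble(cm$counts)
  tb <- dplyr::bind_cols(tibble::tibble(gene_id = rownames(cm$counts)), tb)
  readr::write_tsv(tb, counts_path)
  if (!is.null(samples_path)) readr::write_tsv(cm$samples, samples_path)
  invisible(counts_path)
}

#' @rdname write_count_matrix
#' @param pair_map Pair map used to generate the counts.
#' @export
read_count_matrix <- function(counts_path, samples_path, pair_map) {
  tb <- readr::read_tsv(counts_path, show_col_types = FALSE)
  samples <- readr::read_tsv(samples_path, show_col_types = FALSE)
  genes <- panel_genes(pair_map)
  m <- as.matrix(tb[, -1, drop = FALSE])
  rownames(m) <- tb$gene_id
  m <- m[genes$gene_id, samples$sample_id, drop = FALSE]
  structure(list(counts = m, genes = genes,
                 samples = tibble::as_tibble(samples),
                 totals = colSums(m), unit = "count"),
            class = "count_matrix")
}
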