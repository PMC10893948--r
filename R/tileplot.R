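#' Plot specification for a dosage tile plot
#'
#' @param tile_px Tile edge length in pixels.
#' @param include_key Append the in-silico colour key below the samples.
#' @param format `"png"` or `"svg"`.
#' @param gap_colour RGB triple (0-1) used for masked pairs.
#' @param sep_colour RGB triple for chromosome separator columns.
#' @return A `plot_spec` list.
#' @export
plot_spec <- function(tile_px = 2, include_key = TRUE,
                      format = c("png", "svg"),
                      gap_colour = c(0.85, 0.85, 0.85),
                      sep_colour = c(0.2, 0.2, 0.2)) {
  format <- match.arg(format)
  if (tile_px < 1) stop_bad_arg("`tile_px` must be >= 1")
  structure(list(tile_px = as.integer(tile_px), include_key = include_key,
                 format = format, gap_colour = gap_colour,
                 sep_colour = sep_colour),
            class = "plot_spec")
}

# CMYK (Y=K=0) to RGB: R = 1-C, G = 1-M, B = 1
cmyk_to_rgb <- function(C, M) {
  cbind(1 - C, 1 - M, rep(1, length(C)))
}

# sample display order: controls first, then doses ascending
order_samples <- function(samples) {
  controls <- samples$sample_id[samples$role == "control"]
  treated <- samples[samples$role == "treated", , drop = FALSE]
  treated <- treated[order(treated$radiation_type, treated$dose_Gy,
                           treated$sample_id), , drop = FALSE]
  c(sort(controls), treated$sample_id)
}

# one RGB row (pairs in A-genome order + chromosome separators) per sample
gdtp_matrix <- function(profile, pair_map, sample_ids, spec) {
  pm <- pair_map[order(pair_map$chrom_A, pair_map$idx_A), , drop = FALSE]
  chrom_rle <- rle(pm$chrom_A)
  n_chrom <- length(chrom_rle$values)
  n_col <- nrow(pm) + n_chrom - 1L
  sep_after <- cumsum(chrom_rle$lengths)[-n_chrom] +
    seq_len(max(n_chrom - 1L, 0))
  col_of_pair <- seq_len(nrow(pm)) +
    findInterval(seq_len(nrow(pm)) - 1L, cumsum(chrom_rle$lengths)[-n_chrom])

  arr <- array(1, dim = c(length(sample_ids), n_col, 3))
  for (ch in 1:3) arr[, sep_after, ch] <- spec$sep_colour[ch]

  for (si in seq_along(sample_ids)) {
    p <- profile[profile$sample_id == sample_ids[si], , drop = FALSE]
    if (nrow(p) == 0) {
      stop_bad_arg("no dosage profile for sample %s", sample_ids[si])
    }
    p <- p[match(pm$pair_id, p$pair_id), , drop = FALSE]
    rgb <- cmyk_to_rgb(ifelse(p$masked, 0, p$C), ifelse(p$masked, 0, p$M))
    for (ch in 1:3) {
      v <- rgb[, ch]
      v[p$masked] <- spec$gap_colour[ch]
      arr[si, col_of_pair, ch] <- v
    }
  }
  list(arr = arr, col_of_pair = col_of_pair, pm = pm)
}

#' Render a genome/transcriptome display tile plot
#'
#' One coloured tile per homoeologue pair (cyan = A dosage, magenta = C
#' dosage), pairs in A-genome order with separator columns between
#' chromosomes, one row per sample with untreated controls first and dose
#' groups ascending, and optionally the in-silico colour key appended
#' below. Output bytes are deterministic for fixed inputs.
#'
#' @param profile Dosage profile ([dosage_profile()]) covering all plotted
#'   samples.
#' @param pair_map The homoeologue pair map (defines the plot axis; genes
#'   without a partner are not plotted).
#' @param samples Sample sheet (defines row order and grouping).
#' @param path Output file (`.png` or `.svg` according to the spec).
#' @param spec A [plot_spec()].
#' @return Invisibly, the RGB array that was rendered.
#' @export
render_gdtp <- function(profile, pair_map, samples, path,
                        spec = plot_spec()) {
  sample_ids <- order_samples(samples)
  g <- gdtp_matrix(profile, pair_map, sample_ids, spec)
  arr <- g$arr

  if (spec$include_key) {
    key <- colour_key()
    key_rgb <- cmyk_to_rgb(key$C, key$M)
    blank <- array(1, dim = c(1, ncol(arr), 3))
    key_rows <- array(1, dim = c(nrow(key), ncol(arr), 3))
    run <- max(1L, ncol(arr) %/% (2L * nrow(key)))
    for (i in seq_len(nrow(key))) {
      cols <- ((i - 1L) * run + 1L):min(i * run, ncol(arr))
      for (ch in 1:3) key_rows[i, cols, ch] <- key_rgb[i, ch]
    }
    arr2 <- array(1, dim = c(dim(arr)[1] + 1 + nrow(key), ncol(arr), 3))
    arr2[seq_len(dim(arr)[1]), , ] <- arr
    arr2[dim(arr)[1] + 1, , ] <- blank
    arr2[(dim(arr)[1] + 2):dim(arr2)[1], , ] <- key_rows
    arr <- arr2
  }

  # scale tiles
  t <- spec$tile_px
  big <- arr[rep(seq_len(dim(arr)[1]), each = t),
             rep(seq_len(dim(arr)[2]), each = t), , drop = FALSE]

  if (spec$format == "png") {
    png::writePNG(big, path)
  } else {
    write_svg_raster(big, path)
  }
  invisible(arr)
}

# plain SVG writer: one rect per run of identical colour per row
write_svg_raster <- function(arr, path) {
  h <- dim(arr)[1]; w <- dim(arr)[2]
  lines <- c(sprintf(
    paste0("<svg xmlns=\"http://www.w3.org/2000/svg\" width=\"%d\" ",
           "height=\"%d\" shape-rendering=\"crispEdges\">"), w, h))
  for (y in seq_len(h)) {
    hexrow <- grDevices::rgb(arr[y, , 1], arr[y, , 2], arr[y, , 3])
    r <- rle(hexrow)
    x <- c(0L, cumsum(r$lengths))
    lines <- c(lines, sprintf(
      "<rect x=\"%d\" y=\"%d\" width=\"%d\" height=\"1\" fill=\"%s\"/>",
      x[-length(x)], y - 1L, r$lengths, r$values))
  }
  writeLines(c(lines, "</svg>"), path)
  invisible(path)
}

#' Render a gene-resolution dosage track for one chromosome
#'
#' SVG line plot of the smoothed copy-number series along the gene order of
#' one chromosome of one sample, with called duplication intervals marked
#' in red and deletions in blue; marker extents equal the call intervals.
#'
#' @param profile Dosage profile rows for one sample.
#' @param subgenome `"A"` or `"C"`.
#' @param chrom Chromosome label.
#' @param calls Event tibble for this sample (intervals drawn as bars).
#' @param path Output `.svg` path.
#' @param w Smoothing window (odd; 1 = no smoothing).
#' @param height,px_per_gene Figure geometry.
#' @return Invisibly, the path.
#' @export
render_depth_track <- function(profile, subgenome, chrom, calls = NULL,
                               path, w = 9, height = 120, px_per_gene = 2) {
  idx_col <- paste0("idx_", subgenome)
  k_col <- paste0("k_", subgenome)
  chrom_col <- paste0("chrom_", subgenome)
  p <- profile[profile[[chrom_col]] == chrom & !profile$masked, ,
               drop = FALSE]
  if (nrow(p) == 0) stop_bad_arg("chromosome %s empty in profile", chrom)
  o <- order(p[[idx_col]])
  idx <- p[[idx_col]][o]
  k <- smooth_series(p[[k_col]][o], w)

  wpx <- (max(idx) + 1L) * px_per_gene
  ymax <- 4
  ypix <- function(kv) height - pmin(kv, ymax) / ymax * height
  pts <- paste(sprintf("%.1f,%.1f", idx * px_per_gene + px_per_gene / 2,
                       ypix(k)), collapse = " ")
  lines <- c(
    sprintf(paste0("<svg xmlns=\"http://www.w3.org/2000/svg\" ",
                   "width=\"%d\" height=\"%d\">"), wpx, height),
    sprintf(paste0("<line x1=\"0\" y1=\"%.1f\" x2=\"%d\" y2=\"%.1f\" ",
                   "stroke=\"#cccccc\"/>"), ypix(2), wpx, ypix(2)))
  if (!is.null(calls) && nrow(calls) > 0) {
    cc <- calls[calls$subgenome == subgenome & calls$chrom == chrom, ,
                drop = FALSE]
    for (i in seq_len(nrow(cc))) {
      fill <- if (cc$event_class[i] %in%
                    c("segmental_duplication", "chromosome_gain")) {
        "#d62728"
      } else {
        "#1f77b4"
      }
      lines <- c(lines, sprintf(
        paste0("<rect x=\"%d\" y=\"%d\" width=\"%d\" height=\"6\" ",
               "fill=\"%s\"/>"),
        cc$start_idx[i] * px_per_gene, height - 8L,
        (cc$end_idx[i] - cc$start_idx[i]) * px_per_gene, fill))
    }
  }
  lines <- c(lines, sprintf(
    "<polyline points=\"%s\" fill=\"none\" stroke=\"#333333\"/>", pts),
    "</svg>")
  writeLines(lines, path)
  invisible(path)
}
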