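#' Significance label from an adjusted p value
#'
#' @param p Adjusted p values.
#' @param thresholds Named numeric vector mapping labels to upper p
#'   thresholds, checked in increasing order of threshold; defaults to the
#'   two tiers used for the fatty-acid comparisons.
#' @return Character labels (`"ns"` where no threshold is met).
#' @export
significance_label <- function(p, thresholds = c("****" = 5e-5,
                                                 "**" = 5e-3)) {
  thresholds <- sort(thresholds)
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    hit <- which(pi < thresholds)
    if (length(hit) == 0) "ns" else names(thresholds)[hit[1]]
  }, character(1))
}

#' Compare phenotype groups with Welch t tests
#'
#' Welch (unequal-variance) two-sample t tests of each group against its
#' stated control group, with Benjamini-Hochberg adjustment across all the
#' comparisons of the analysis and significance labels from the adjusted p
#' values.
#'
#' @param table Phenotype tibble with `group` and one column per analyte
#'   (mol%).
#' @param analyte Column name to compare (e.g. `"erucic"`).
#' @param comparisons Two-column table (or list of length-2 vectors) of
#'   (group, control) pairs; defaults to every non-control group against
#'   `control_group`.
#' @param control_group Default control label (used when `comparisons` is
#'   `NULL`).
#' @param thresholds Passed to [significance_label()].
#' @return Tibble: `group`, `control`, group and control means, `mean_diff`,
#'   `t`, `df`, `p`, `p_adj`, `label`.
#' @export
compare_groups <- function(table, analyte, comparisons = NULL,
                           control_group = "wild_type",
                           thresholds = c("****" = 5e-5, "**" = 5e-3)) {
  if (!analyte %in% names(table)) {
    stop_bad_arg("analyte `%s` not found in phenotype table", analyte)
  }
  if (is.null(comparisons)) {
    others <- setdiff(unique(table$group), control_group)
    comparisons <- tibble::tibble(group = others, control = control_group)
  } else if (!is.data.frame(comparisons)) {
    comparisons <- tibble::tibble(
      group = vapply(comparisons, `[[`, character(1), 1),
      control = vapply(comparisons, `[[`, character(1), 2))
  }
  res <- lapply(seq_len(nrow(comparisons)), function(i) {
    g <- comparisons$group[i]
    ctl <- comparisons$control[i]
    x <- table[[analyte]][table$group == g]
    y <- table[[analyte]][table$group == ctl]
    for (nm in c(g, ctl)) {
      if (sum(table$group == nm) < 2) {
        stop_bad_arg("group `%s` has fewer than 2 observations", nm)
      }
    }
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      # degenerate: identical constant groups give t = 0, p = 1
      tt <- list(statistic = c(t = 0),
                 parameter = c(df = length(x) + length(y) - 2),
                 p.value = 1)
    } else {
      tt <- stats::t.test(x, y, var.equal = FALSE)
    }
    tibble::tibble(
      group = g, control = ctl,
      mean_group = mean(x), mean_control = mean(y),
      mean_diff = mean(x) - mean(y),
      t = unname(tt$statistic), df = unname(tt$parameter),
      p = tt$p.value)
  })
  out <- dplyr::bind_rows(res)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$label <- significance_label(out$p_adj, thresholds)
  out
}

#' Expected phenotype direction of a copy-number or knockout change
#'
#' Encodes the fatty-acid biosynthesis logic: the elongase (FAE1) converts
#' oleic to erucic acid, so losing copies lowers erucic and raises oleic
#' (and vice versa for gains); the A5 desaturase (FAD2) converts oleic to
#' linoleic acid, so losing it lowers linoleic and raises the
#' monounsaturates oleic and erucic.
#'
#' @param genotype_change One of `"FAE1_loss"`, `"FAE1_gain"`,
#'   `"FAD2.A5_loss"`.
#' @return Named numeric vector of expected signs per analyte (+1 up, -1
#'   down).
#' @export
predict_direction <- function(genotype_change) {
  switch(
    genotype_change,
    FAE1_loss = c(erucic = -1, oleic = +1),
    FAE1_gain = c(erucic = +1, oleic = -1),
    `FAD2.A5_loss` = c(linoleic = -1, oleic = +1, erucic = +1),
    stop_bad_arg("unknown genotype change `%s`", genotype_change)
  )
}
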