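#' Univariate F score of a feature
#'
#' `|mean(hotspots) - mean(non-hotspots)| / (sd(hotspots) +
#' sd(non-hotspots))`, with sample (n-1) standard deviations. A large
#' value means the feature separates the two classes well relative to
#' their spreads. Returns `NA` with a warning when both class standard
#' deviations are zero (constant feature).
#'
#' @param values_h,values_n Feature values for the hotspot and
#'   non-hotspot classes.
#' @return A single non-negative number (or `NA` for a constant
#'   feature).
#' @export
f_score <- function(values_h, values_n) {
  if (!length(values_h) || !length(values_n)) {
    stopf("both classes must be non-empty")
  }
  sh <- stats::sd(values_h)
  sn <- stats::sd(values_n)
  if (length(values_h) == 1L) sh <- 0
  if (length(values_n) == 1L) sn <- 0
  if ((sh + sn) == 0) {
    warnf("constant feature: F score undefined")
    return(NA_real_)
  }
  abs(mean(values_h) - mean(values_n)) / (sh + sn)
}

#' Jensen-Shannon divergence between two samples
#'
#' Histograms both samples on their shared range with `bins` equal-width
#' bins and computes the Jensen-Shannon divergence of the two empirical
#' distributions with base-2 logarithms (so the value lies in
#' `[0, 1]`), using the convention `0 * log(0) = 0`.
#'
#' @param values_h,values_n Samples from the two classes.
#' @param bins Number of shared histogram bins.
#' @return The divergence in `[0, 1]`.
#' @export
jsd <- function(values_h, values_n, bins = 20L) {
  if (!length(values_h) || !length(values_n)) {
    stopf("both classes must be non-empty")
  }
  rng <- range(c(values_h, values_n))
  if (rng[1] == rng[2]) {
    warnf("degenerate shared range: JSD = 0")
    return(0)
  }
  brk <- seq(rng[1], rng[2], length.out = bins + 1L)
  p <- tabulate(findInterval(values_h, brk, rightmost.closed = TRUE,
                             all.inside = TRUE), bins) / length(values_h)
  q <- tabulate(findInterval(values_n, brk, rightmost.closed = TRUE,
                             all.inside = TRUE), bins) / length(values_n)
  jsd_hist(p, q)
}

## JSD of two discrete distributions (base 2).
jsd_hist <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) {
    sel <- a > 0
    sum(a[sel] * log2(a[sel] / b[sel]))
  }
  (kl(p, m) + kl(q, m)) / 2
}

#' Rank all features of a labelled matrix by F score and JSD
#'
#' @param matrix A labelled feature matrix (27 registry columns plus
#'   `label`), e.g. from [assemble_feature_matrix()] or
#'   [generate_feature_matrix()].
#' @param bins Histogram bins for the JSD.
#' @return A list of class `importance_table`: `table` (one row per
#'   feature: class means/sds, `f_score`, `jsd`, `rank_f`, `rank_jsd`)
#'   sorted by descending F score, and `group_summary` (mean F score
#'   and JSD per feature class).
#' @export
rank_features <- function(matrix, bins = 20L) {
  validate_feature_matrix(matrix)
  if (is.null(matrix$label)) stopf("feature matrix carries no labels")
  lab <- matrix$label
  if (length(unique(lab)) < 2L) {
    stopf("both classes must be present in the labels")
  }
  reg <- feature_registry()
  rows <- lapply(reg$name, function(nm) {
    vh <- matrix[[nm]][lab == 1]
    vn <- matrix[[nm]][lab == 0]
    fs <- suppressWarnings(f_score(vh, vn))
    js <- suppressWarnings(jsd(vh, vn, bins = bins))
    data.frame(feature = nm, class = reg$class[reg$name == nm],
               mean_hotspot = mean(vh), mean_other = mean(vn),
               sd_hotspot = stats::sd(vh), sd_other = stats::sd(vn),
               f_score = fs, jsd = js, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$rank_f <- rank(-tab$f_score, ties.method = "first",
                     na.last = "keep")
  tab$rank_jsd <- rank(-tab$jsd, ties.method = "first", na.last = "keep")
  tab <- tab[order(tab$rank_f), ]
  rownames(tab) <- NULL
  grp <- stats::aggregate(tab[, c("f_score", "jsd")],
                          by = list(class = tab$class), FUN = mean,
                          na.rm = TRUE)
  structure(list(table = tab, group_summary = grp),
            class = "importance_table")
}

#' @rdname rank_features
#' @param importance An `importance_table`.
#' @param file Output TSV path.
#' @export
write_importance_tsv <- function(importance, file) {
  utils::write.table(importance$table, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
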