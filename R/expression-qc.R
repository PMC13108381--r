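## Normalization, MAD cell QC and the tau specificity index.

#' Counts-per-million normalization
#'
#' Scales each cell's counts to reads per million mapped reads. The
#' denominator is the per-cell total mapped reads: the column sum by
#' default, or an externally supplied totals vector (as produced by an
#' aligner summary) when the [CellCounts] object carries one.
#'
#' Cells with a zero total cannot be normalized; they are dropped with a
#' warning listing their identifiers.
#'
#' @param x a [CellCounts] object or a genes x cells count matrix.
#' @param total optional per-cell totals overriding the default.
#' @return genes x cells matrix of CPM values.
#' @examples
#' computeCPM(matrix(c(1, 3), ncol = 1))  # 250000, 750000
#' @export
computeCPM <- function(x, total = NULL) {
  if (is(x, "CellCounts")) {
    counts <- assay(x, "counts")
    if (is.null(total)) total <- cellTotals(x)
  } else counts <- as.matrix(x)
  if (is.null(total)) total <- colSums(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  bad <- !is.finite(total) | total <= 0
  if (any(bad)) {
    warning(sprintf("excluding %d cell(s) with zero/invalid totals: %s",
                    sum(bad),
                    paste(colnames(counts)[bad], collapse = ", ")))
    counts <- counts[, !bad, drop = FALSE]
    total <- total[!bad]
  }
  sweep(counts, 2, total, "/") * 1e6
}

#' log2(CPM + 1) transform
#'
#' @param cpm non-negative matrix (or vector) of CPM values.
#' @return values transformed as `log2(cpm + 1)`; zero stays zero.
#' @export
logNormalize <- function(cpm) {
  if (any(cpm < 0, na.rm = TRUE)) stop("CPM values must be non-negative")
  log2(cpm + 1)
}

#' Unscaled median absolute deviation
#'
#' Median of absolute deviations from the median, with no normality
#' scaling constant (contrast with [stats::mad], which multiplies by
#' 1.4826 by default).
#'
#' @param x numeric vector.
#' @return the unscaled MAD.
#' @export
madRaw <- function(x) stats::median(abs(x - stats::median(x)))

#' Reject low-quality cells by MAD thresholds
#'
#' For each of the two per-cell quality metrics -- genes detected (at
#' least one read) and total mapped reads -- computes the median and
#' unscaled MAD across all cells, and rejects any cell strictly below
#' `median - k * MAD` in either metric. With a degenerate MAD of zero
#' the threshold equals the median and only strictly-below cells are
#' rejected.
#'
#' @param x a [CellCounts] object.
#' @param k MAD multiplier (default 3).
#' @return list with `kept` (a [CellCounts] of the surviving cells),
#'   `rejected` (character vector of rejected cell ids) and `report`
#'   (data.frame of medians, MADs and thresholds for both metrics).
#' @export
qcFilterCells <- function(x, k = 3) {
  stopifnot(is(x, "CellCounts"), ncol(x) >= 1)
  metrics <- list(genesDetected = colData(x)$genesDetected,
                  mappedReads = cellTotals(x))
  report <- do.call(rbind, lapply(names(metrics), function(nm) {
    v <- metrics[[nm]]
    med <- stats::median(v); md <- madRaw(v)
    data.frame(metric = nm, median = med, mad = md,
               threshold = med - k * md)
  }))
  below <- mapply(function(v, thr) v < thr, metrics, report$threshold)
  if (is.null(dim(below))) below <- matrix(below, nrow = ncol(x))
  reject <- rowSums(below) > 0
  list(kept = x[, !reject], rejected = colnames(x)[reject], report = report)
}

#' Mean log2(CPM+1) expression per cell subclass
#'
#' @param norm genes x cells matrix of log2(CPM+1) values.
#' @param labels per-cell subclass labels.
#' @param trimmed if `TRUE`, use the 25--75% interquartile trimmed mean
#'   instead of the plain mean.
#' @return genes x subclasses matrix of mean expression; empty
#'   subclasses (no cells) are dropped with a warning.
#' @export
subclassMeans <- function(norm, labels, trimmed = FALSE) {
  norm <- as.matrix(norm)
  labels <- as.character(labels)
  if (length(labels) != ncol(norm))
    stop("'labels' must have one entry per cell")
  keep <- table(labels)
  subs <- names(keep)[keep >= 1]
  if (length(subs) < length(unique(labels)))
    warning("dropping empty subclasses")
  fun <- if (trimmed) interquartileMean else mean
  out <- vapply(subs, function(s) {
    apply(norm[, labels == s, drop = FALSE], 1, fun)
  }, numeric(nrow(norm)))
  out <- matrix(out, nrow = nrow(norm),
                dimnames = list(rownames(norm), subs))
  out
}

#' Tau expression-specificity index
#'
#' For a per-gene profile of mean expression \eqn{x_i} over \eqn{n}
#' subclasses, tau is \eqn{\sum_i (1 - y_i) / (n - 1)} with
#' \eqn{y_i = x_i / \max_i x_i}. Tau is 0 for a uniform profile and 1
#' when expression is confined to a single subclass. All-zero profiles
#' leave tau undefined (`NA`, flagged), since the formula divides by the
#' profile maximum.
#'
#' @param profile numeric vector (one gene) or genes x subclasses matrix
#'   of non-negative mean expression values.
#' @return data.frame with columns `tau` and `undefined`.
#' @examples
#' computeTau(c(4, 2, 2))$tau  # 0.5
#' @export
computeTau <- function(profile) {
  if (is.null(dim(profile))) profile <- matrix(profile, nrow = 1)
  profile <- as.matrix(profile)
  n <- ncol(profile)
  if (n < 2) stop("tau requires at least 2 subclasses")
  if (any(profile < 0, na.rm = TRUE))
    stop("expression profile must be non-negative")
  mx <- apply(profile, 1, max)
  undef <- mx <= 0
  tau <- rep(NA_real_, nrow(profile))
  if (any(!undef)) {
    y <- profile[!undef, , drop = FALSE] / mx[!undef]
    tau[!undef] <- rowSums(1 - y) / (n - 1)
  }
  data.frame(tau = tau, undefined = undef,
             row.names = rownames(profile))
}

#' Interquartile (25--75%) trimmed mean
#'
#' Mean of the values lying within the closed interquartile interval;
#' values tied with either quartile are included.
#'
#' @param values numeric vector.
#' @return the trimmed mean (`NaN` on empty input).
#' @export
interquartileMean <- function(values) {
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  mean(values[values >= q[1] & values <= q[2]])
}

#' Subclass expression gate
#'
#' A subclass passes for a gene when it contributes more than
#' `minCells` cells and the 25--75% trimmed mean of its per-cell
#' log2(CPM+1) values exceeds `threshold`. Both comparisons are strict.
#'
#' @param values per-cell log2(CPM+1) values of the gene within one
#'   subclass.
#' @param minCells minimum cell count (exclusive; default 100).
#' @param threshold expression threshold (exclusive; default 1).
#' @return logical scalar.
#' @export
trimmedMeanGate <- function(values, minCells = 100, threshold = 1) {
  length(values) > minCells && interquartileMean(values) > threshold
}

#' Cohort incidence rate
#'
#' Percentage of affected individuals in a cohort, e.g. hydrocephalus
#' cases among knock-in animals.
#'
#' @param affected number of affected individuals.
#' @param total cohort size (> 0).
#' @return incidence as a percentage.
#' @examples
#' incidenceRate(8, 1660)  # ~0.48%
#' @export
incidenceRate <- function(affected, total) {
  stopifnot(total > 0, affected >= 0, affected <= total)
  100 * affected / total
}
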