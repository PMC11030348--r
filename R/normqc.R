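## Segment QC, gene detection-rate filtering, the normalization suite, and
## the MA-correlation / Kolmogorov-Smirnov normalization-selection
## diagnostic.

#' GeoMx-style segment QC thresholds
#'
#' All thresholds are inclusive at the printed value (`>=` for minima, `<=`
#' for the NTC maximum).
#'
#' @param min_segment_reads minimum raw reads per segment.
#' @param min_pct_trimmed,min_pct_stitched,min_pct_aligned,min_pct_saturation
#'   minimum percentages (0-100).
#' @param min_negative_count minimum negative-probe count.
#' @param max_ntc_count maximum no-template-control count.
#' @param min_nuclei minimum nuclei per segment.
#' @param min_area minimum segment area.
#' @param min_gene_detection_rate minimum fraction of samples in which a gene
#'   must be detected (used by [detection_rate_filter()]).
#' @return object of class `segment_qc_thresholds`.
#' @export
segment_qc_thresholds <- function(min_segment_reads = 1000,
                                  min_pct_trimmed = 80,
                                  min_pct_stitched = 80,
                                  min_pct_aligned = 75,
                                  min_pct_saturation = 50,
                                  min_negative_count = 1,
                                  max_ntc_count = 10000,
                                  min_nuclei = 20,
                                  min_area = 1000,
                                  min_gene_detection_rate = 0.01) {
  thr <- list(min_segment_reads = min_segment_reads,
              min_pct_trimmed = min_pct_trimmed,
              min_pct_stitched = min_pct_stitched,
              min_pct_aligned = min_pct_aligned,
              min_pct_saturation = min_pct_saturation,
              min_negative_count = min_negative_count,
              max_ntc_count = max_ntc_count,
              min_nuclei = min_nuclei,
              min_area = min_area,
              min_gene_detection_rate = min_gene_detection_rate)
  stopifnot(all(unlist(thr) >= 0),
            all(unlist(thr[c("min_pct_trimmed", "min_pct_stitched",
                             "min_pct_aligned", "min_pct_saturation")]) <= 100),
            min_gene_detection_rate <= 1)
  structure(thr, class = "segment_qc_thresholds")
}

## rule -> (QC-table column, comparison)
qc_rule_columns <- function() {
  list(min_segment_reads  = list(col = "reads",          op = ">="),
       min_pct_trimmed    = list(col = "pct_trimmed",    op = ">="),
       min_pct_stitched   = list(col = "pct_stitched",   op = ">="),
       min_pct_aligned    = list(col = "pct_aligned",    op = ">="),
       min_pct_saturation = list(col = "pct_saturation", op = ">="),
       min_negative_count = list(col = "negative_count", op = ">="),
       max_ntc_count      = list(col = "ntc_count",      op = "<="),
       min_nuclei         = list(col = "nuclei",         op = ">="),
       min_area           = list(col = "area",           op = ">="))
}

#' Filter segments by QC thresholds
#'
#' A segment is retained iff every threshold is met; removed segments list
#' every violated rule. Output is independent of row order.
#'
#' @param table segment QC data.frame with columns `segment_id`, `reads`,
#'   `pct_trimmed`, `pct_stitched`, `pct_aligned`, `pct_saturation`,
#'   `negative_count`, `ntc_count`, `nuclei`, `area`.
#' @param thr a [segment_qc_thresholds()].
#' @return data.frame: `segment_id`, `retained`, `reasons` (comma-separated
#'   violated rule names, `""` when retained).
#' @export
qc_filter_segments <- function(table, thr = segment_qc_thresholds()) {
  stopifnot(inherits(thr, "segment_qc_thresholds"))
  rules <- qc_rule_columns()
  missing <- setdiff(c("segment_id", vapply(rules, `[[`, "", "col")),
                     names(table))
  if (length(missing))
    stop("segment QC table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)

  viol <- vapply(names(rules), function(rn) {
    r <- rules[[rn]]
    x <- table[[r$col]]
    if (r$op == ">=") !(x >= thr[[rn]]) else !(x <= thr[[rn]])
  }, logical(nrow(table)))
  viol <- matrix(viol, nrow = nrow(table),
                 dimnames = list(NULL, names(rules)))

  reasons <- apply(viol, 1, function(v) paste(names(rules)[v], collapse = ","))
  data.frame(segment_id = table$segment_id,
             retained = rowSums(viol) == 0,
             reasons = reasons,
             stringsAsFactors = FALSE)
}

#' Filter genes by detection rate
#'
#' A gene is retained iff the fraction of samples with a nonzero count is at
#' least `min_rate` (inclusive).
#'
#' @param mat counts, genes x samples.
#' @param min_rate minimum detection rate in `[0, 1]`.
#' @return character vector of retained gene names (row indices if unnamed).
#' @export
detection_rate_filter <- function(mat, min_rate = 0.01) {
  stopifnot(min_rate >= 0, min_rate <= 1)
  keep <- Matrix::rowMeans(mat > 0) >= min_rate
  if (is.null(rownames(mat))) which(keep) else rownames(mat)[keep]
}

## per-sample scaling applied to all rows
scale_columns <- function(mat, factors) {
  sweep(mat, 2, factors, `*`)
}

#' Normalize a counts matrix
#'
#' Methods (samples are columns, features rows):
#' \describe{
#'   \item{quantile}{each sample's sorted values are replaced by the
#'     across-sample mean of order statistics (ties receive adjacent
#'     reference values in stable row order); afterwards every column has
#'     the identical sorted vector.}
#'   \item{q3}{each sample scaled so the 75th percentile of its detected
#'     (nonzero) genes equals the geometric mean of per-sample 75th
#'     percentiles.}
#'   \item{background}{each sample divided by its mean negative-probe
#'     count.}
#'   \item{libsize}{each sample scaled so its total equals the mean total.}
#'   \item{median}{each sample scaled so its median over globally-detected
#'     genes (nonzero somewhere in the matrix) equals the cross-sample
#'     median of those medians. The definition of the reference scale is a
#'     package choice; see the methods vignette.}
#' }
#' Negative-probe rows, when flagged, are excluded from the statistics that
#' define scale factors (but are scaled along for `q3`, `libsize` and
#' `median`, and define the factor for `background`).
#'
#' @param mat nonnegative counts, features x samples.
#' @param method one of `"median"`, `"quantile"`, `"q3"`, `"background"`,
#'   `"libsize"`.
#' @param negative_probes optional logical vector flagging negative-probe
#'   rows (required for `background`).
#' @return normalized numeric matrix with the input's dimnames.
#' @export
normalize_counts <- function(mat,
                             method = c("median", "quantile", "q3",
                                        "background", "libsize"),
                             negative_probes = NULL) {
  method <- match.arg(method)
  mat <- as.matrix(mat)
  if (any(mat < 0)) stop("counts must be nonnegative", call. = FALSE)
  if (is.null(negative_probes)) negative_probes <- rep(FALSE, nrow(mat))
  stopifnot(length(negative_probes) == nrow(mat))
  genes <- mat[!negative_probes, , drop = FALSE]
  sample_names <- if (is.null(colnames(mat))) as.character(seq_len(ncol(mat)))
                  else colnames(mat)

  if (method == "quantile") {
    out <- mat
    out[!negative_probes, ] <- quantile_normalize(genes)
    return(out)
  }

  factors <- switch(method,
    libsize = {
      tot <- colSums(genes)
      if (any(tot == 0))
        stop("all-zero sample(s): ",
             paste(sample_names[tot == 0], collapse = ", "), call. = FALSE)
      mean(tot) / tot
    },
    q3 = {
      q3s <- vapply(seq_len(ncol(genes)), function(j) {
        v <- genes[, j]
        v <- v[v > 0]
        if (!length(v))
          stop("all-zero sample: ", sample_names[j], call. = FALSE)
        stats::quantile(v, 0.75, names = FALSE)
      }, numeric(1))
      exp(mean(log(q3s))) / q3s
    },
    background = {
      if (!any(negative_probes))
        stop("background normalization requires negative-probe rows",
             call. = FALSE)
      neg_mean <- colMeans(mat[negative_probes, , drop = FALSE])
      if (any(neg_mean == 0))
        stop("zero mean negative-probe count in sample(s): ",
             paste(sample_names[neg_mean == 0], collapse = ", "),
             call. = FALSE)
      1 / neg_mean
    },
    median = {
      detected <- rowSums(genes > 0) > 0
      meds <- apply(genes[detected, , drop = FALSE], 2, stats::median)
      if (any(meds == 0))
        stop("zero median over detected genes in sample(s): ",
             paste(sample_names[meds == 0], collapse = ", "), call. = FALSE)
      stats::median(meds) / meds
    })
  scale_columns(mat, factors)
}

## quantile normalization: each column's sorted values are replaced by the
## across-sample mean of order statistics, so every column's sorted vector
## equals the reference exactly. Ties are assigned adjacent reference values
## in stable row order (deterministic).
quantile_normalize <- function(mat) {
  n <- nrow(mat)
  if (n == 0 || ncol(mat) < 2) return(mat)
  ref <- rowMeans(apply(mat, 2, sort))
  out <- mat
  for (j in seq_len(ncol(mat))) {
    out[order(mat[, j]), j] <- ref
  }
  out
}

#' Normalization-selection diagnostic
#'
#' For each candidate method, normalizes the matrix and computes (a) the
#' per-sample Pearson correlation between M (log2 ratio of the sample to a
#' pseudo-reference, the gene-wise geometric mean with a +1 pseudocount) and
#' A (the mean of the two log2 values), summarized as the mean absolute
#' correlation, and (b) the fraction of samples whose normalized value
#' distribution differs from the pooled distribution by a two-sided
#' Kolmogorov-Smirnov test at p < 0.05. The chosen method is the
#' lexicographic minimum of (mean |r|, fraction significant), tie-broken by
#' mean KS statistic. Constant-M samples contribute a correlation of 0.
#'
#' @param mat counts, features x samples (at least 2 samples).
#' @param methods subset of the [normalize_counts()] methods to compare;
#'   `"background"` is skipped unless negative probes are flagged.
#' @param negative_probes optional logical row flags.
#' @param alpha KS significance level.
#' @return object of class `normalization_report`: a per-method data.frame
#'   (`method`, `mean_abs_ma_cor`, `frac_ks_significant`, `mean_ks_stat`)
#'   plus the `chosen` method.
#' @export
normalization_diagnostic <- function(mat,
                                     methods = c("median", "quantile", "q3",
                                                 "background", "libsize"),
                                     negative_probes = NULL,
                                     alpha = 0.05) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2)
    stop("the normalization diagnostic needs at least 2 samples",
         call. = FALSE)
  methods <- match.arg(methods, several.ok = TRUE)
  if (is.null(negative_probes)) methods <- setdiff(methods, "background")

  rows <- lapply(methods, function(m) {
    nm <- normalize_counts(mat, m, negative_probes = negative_probes)
    if (!is.null(negative_probes)) nm <- nm[!negative_probes, , drop = FALSE]
    ## pseudo-reference: gene-wise geometric mean of the +1-pseudocounted
    ## values, so identical samples give M identically 0
    ref <- exp(rowMeans(log(nm + 1)))
    cors <- ks_p <- ks_d <- numeric(ncol(nm))
    pooled <- as.vector(nm)
    for (j in seq_len(ncol(nm))) {
      M <- log2((nm[, j] + 1) / ref)
      A <- 0.5 * (log2(nm[, j] + 1) + log2(ref))
      ## constant M (up to floating noise from exact normalizations) has no
      ## defined correlation; report 0 by convention
      cors[j] <- if (stats::sd(M) <= 1e-10 || stats::sd(A) <= 1e-10) 0
                 else stats::cor(M, A)
      ks <- suppressWarnings(stats::ks.test(nm[, j], pooled))
      ks_p[j] <- ks$p.value
      ks_d[j] <- unname(ks$statistic)
    }
    data.frame(method = m,
               mean_abs_ma_cor = mean(abs(cors)),
               frac_ks_significant = mean(ks_p < alpha),
               mean_ks_stat = mean(ks_d),
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  ord <- order(report$mean_abs_ma_cor, report$frac_ks_significant,
               report$mean_ks_stat)
  structure(list(report = report, chosen = report$method[ord[1]],
                 alpha = alpha),
            class = "normalization_report")
}

#' @export
print.normalization_report <- function(x, ...) {
  cat("Normalization diagnostic (MA correlation / KS):\n")
  print(x$report, row.names = FALSE, digits = 4)
  cat("chosen method:", x$chosen, "\n")
  invisible(x)
}
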