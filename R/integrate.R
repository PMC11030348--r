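## Downstream analyses: PCA group structure on sample-region aggregates,
## activity-score normalization and group comparison, and mouse-to-human
## directional congruence.

#' PCA embedding of sample-region aggregate profiles
#'
#' Aggregates the (median-normalized) expression matrix to per-animal,
#' per-region mean profiles over selected discs, restricts to genes whose
#' expression is greater than zero in every included region, mean-centers
#' gene-wise, and returns the first two principal-component coordinates with
#' their explained-variance fractions. Deterministic up to component sign.
#'
#' @param mat normalized expression, genes x spots.
#' @param assignment a `region_assignment` from [select_discs()] carrying
#'   `animal_id` and `group`.
#' @param regions region labels to include (default the DA midbrain
#'   regions).
#' @param per_disc embed individual discs instead of per-animal aggregates.
#' @return data.frame with one row per aggregate: `aggregate`, `animal_id`,
#'   `group`, `region`, `PC1`, `PC2`; the explained-variance fractions are
#'   in `attr(, "var_explained")` and the retained gene count in
#'   `attr(, "n_genes")`.
#' @export
pca_embed <- function(mat, assignment, regions = c("SN", "VTA"),
                      per_disc = FALSE) {
  mat <- as.matrix(mat)
  sel <- assignment$selected & assignment$region_label %in% regions
  if (!any(sel)) stop("no selected discs in the requested regions",
                      call. = FALSE)
  a <- assignment[sel, ]
  idx <- match(a$barcode, colnames(mat))
  x <- mat[, idx, drop = FALSE]

  if (per_disc) {
    agg <- x
    info <- data.frame(aggregate = a$barcode, animal_id = a$animal_id,
                       group = a$group, region = a$region_label,
                       stringsAsFactors = FALSE)
  } else {
    f <- factor(paste(a$animal_id, a$region_label, sep = "."))
    agg <- sapply(levels(f), function(l) rowMeans(x[, f == l, drop = FALSE]))
    first <- match(levels(f), f)
    info <- data.frame(aggregate = levels(f),
                       animal_id = a$animal_id[first],
                       group = a$group[first],
                       region = a$region_label[first],
                       stringsAsFactors = FALSE)
  }
  if (ncol(agg) < 3)
    stop("need at least 3 aggregates for a 2-D embedding (got ",
         ncol(agg), ")", call. = FALSE)

  ## genes expressed (>0) in every included region
  keep <- rep(TRUE, nrow(agg))
  for (rg in unique(info$region)) {
    keep <- keep & rowMeans(agg[, info$region == rg, drop = FALSE]) > 0
  }
  if (sum(keep) < 2)
    stop("fewer than 2 genes expressed in all included regions",
         call. = FALSE)

  pc <- stats::prcomp(t(agg[keep, , drop = FALSE]), center = TRUE,
                      scale. = FALSE)
  out <- cbind(info, PC1 = pc$x[, 1],
               PC2 = if (ncol(pc$x) >= 2) pc$x[, 2] else 0)
  rownames(out) <- NULL
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  attr(out, "var_explained") <- ve[1:min(2, length(ve))]
  attr(out, "n_genes") <- sum(keep)
  out
}

#' Normalize activity scores by section mean
#'
#' Divides each spot's activity score by the mean score of the tissue
#' section it came from, so every section's mean normalized score is exactly
#' 1. Idempotent.
#'
#' @param table data.frame with columns `score` and `section_id`.
#' @return the input with a `normalized_score` column (replaced if present).
#' @export
normalize_activity <- function(table) {
  stopifnot(all(c("score", "section_id") %in% names(table)))
  means <- tapply(table$score, table$section_id, mean)
  if (any(means == 0))
    stop("zero mean activity score in section(s): ",
         paste(names(means)[means == 0], collapse = ", "), call. = FALSE)
  table$normalized_score <-
    as.numeric(table$score / means[as.character(table$section_id)])
  table
}

#' Compare two groups of activity scores (two-sample KS test)
#'
#' Two-sided two-sample Kolmogorov-Smirnov test on (normalized) activity
#' scores, with the asymptotic p-value (sample sizes in this design are in
#' the hundreds).
#'
#' @param case_scores,ctrl_scores numeric score vectors.
#' @return list with `statistic` (D) and `p_value`.
#' @export
compare_activity <- function(case_scores, ctrl_scores) {
  if (!length(case_scores) || !length(ctrl_scores))
    stop("both score samples must be nonempty", call. = FALSE)
  ks <- suppressWarnings(stats::ks.test(case_scores, ctrl_scores,
                                        alternative = "two.sided",
                                        exact = FALSE))
  list(statistic = unname(ks$statistic), p_value = ks$p.value)
}

#' Mouse-to-human directional congruence (chi-square test)
#'
#' Maps mouse genes to the human panel case-insensitively (an explicit
#' `mapping` table may override), drops unmapped genes and genes with zero
#' direction, builds the 2x2 mouse-direction x human-direction contingency
#' table, and applies Pearson's chi-square test of independence (continuity
#' correction off by default). With fewer than 2 mapped genes or a zero
#' table margin the result is flagged untestable rather than an error.
#'
#' @param mouse a `hit_set`, `de_comparison`, or any data.frame with `gene`
#'   and `direction` (+1/-1) columns.
#' @param human_directions data.frame with `symbol` and `direction`
#'   (`"up"`/`"down"` or +1/-1).
#' @param mapping optional data.frame with `mouse` and `human` symbol
#'   columns overriding the case-insensitive match.
#' @param correct apply Yates' continuity correction.
#' @return object of class `congruence_result`: the 2x2 `counts` table
#'   (rows: mouse up/down; columns: human up/down), `chi_square`, `p_value`,
#'   `n_mapped`, and `untestable`.
#' @export
congruence_test <- function(mouse, human_directions, mapping = NULL,
                            correct = FALSE) {
  stopifnot(all(c("gene", "direction") %in% names(mouse)),
            all(c("symbol", "direction") %in% names(human_directions)))
  m_dir <- sign(as.numeric(mouse$direction))
  keep <- m_dir != 0
  m_gene <- mouse$gene[keep]
  m_dir <- m_dir[keep]

  h_dir_raw <- human_directions$direction
  h_dir <- if (is.numeric(h_dir_raw)) sign(h_dir_raw)
           else ifelse(tolower(h_dir_raw) == "up", 1,
                       ifelse(tolower(h_dir_raw) == "down", -1, 0))
  h_sym <- human_directions$symbol

  if (!is.null(mapping)) {
    stopifnot(all(c("mouse", "human") %in% names(mapping)))
    mapped_sym <- mapping$human[match(toupper(m_gene), toupper(mapping$mouse))]
  } else {
    mapped_sym <- m_gene
  }
  j <- match(toupper(mapped_sym), toupper(h_sym))
  ok <- !is.na(j) & h_dir[ifelse(is.na(j), 1, j)] != 0
  mouse_d <- factor(ifelse(m_dir[ok] > 0, "up", "down"),
                    levels = c("up", "down"))
  human_d <- factor(ifelse(h_dir[j[ok]] > 0, "up", "down"),
                    levels = c("up", "down"))
  counts <- table(mouse = mouse_d, human = human_d)
  n_mapped <- sum(counts)

  untestable <- n_mapped < 2 || any(rowSums(counts) == 0) ||
    any(colSums(counts) == 0)
  if (untestable) {
    res <- list(counts = counts, chi_square = NA_real_, p_value = NA_real_,
                n_mapped = n_mapped, untestable = TRUE)
  } else {
    ct <- suppressWarnings(stats::chisq.test(counts, correct = correct))
    res <- list(counts = counts, chi_square = unname(ct$statistic),
                p_value = ct$p.value, n_mapped = n_mapped,
                untestable = FALSE)
  }
  class(res) <- "congruence_result"
  res
}

#' @export
print.congruence_result <- function(x, ...) {
  cat("Mouse-human directional congruence (", x$n_mapped, "mapped genes )\n")
  print(x$counts)
  if (x$untestable) {
    cat("untestable: fewer than 2 mapped genes or a zero margin\n")
  } else {
    cat(sprintf("chi-square = %.4g, p = %.4g\n", x$chi_square, x$p_value))
  }
  invisible(x)
}
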