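## Per-region differential expression with fold-change-score (FCS) and
## signal-to-noise-score (SNS) ranking and dual-control hit intersection.

#' Fold-change score
#'
#' `FCS = log2((mu_case + pseudocount) / (mu_ctrl + pseudocount)) *
#' (-log10(max(p, p_floor)))`: an effect-size-weighted significance rank.
#' Zero whenever `p = 1` or the (pseudocounted) means are equal.
#'
#' @param mu_case,mu_ctrl group mean expression.
#' @param p two-sided t-test p-value.
#' @param pseudocount added to both means before the ratio (guards log2 of
#'   zero means).
#' @param p_floor smallest p used inside `-log10` (guards underflow).
#' @return numeric vector of scores.
#' @export
fcs_score <- function(mu_case, mu_ctrl, p, pseudocount = 0.5,
                      p_floor = 1e-300) {
  log2((mu_case + pseudocount) / (mu_ctrl + pseudocount)) *
    (-log10(pmax(p, p_floor)))
}

#' Signal-to-noise score
#'
#' `SNS = (mu_case - mu_ctrl) / (sigma_case + sigma_ctrl + sd_floor) *
#' (-log10(max(p, p_floor)))`: a noise-penalized significance rank whose
#' sign equals the direction of change.
#'
#' @param mu_case,mu_ctrl group mean expression.
#' @param sigma_case,sigma_ctrl group standard deviations (sample, n-1).
#' @param p two-sided t-test p-value.
#' @param sd_floor added to the summed standard deviations (guards division
#'   by zero).
#' @param p_floor smallest p used inside `-log10`.
#' @return numeric vector of scores.
#' @export
sns_score <- function(mu_case, mu_ctrl, sigma_case, sigma_ctrl, p,
                      sd_floor = 1e-8, p_floor = 1e-300) {
  (mu_case - mu_ctrl) / (sigma_case + sigma_ctrl + sd_floor) *
    (-log10(pmax(p, p_floor)))
}

## vectorized two-sided t-test over matrix rows; Welch by default.
## Rows where both groups have zero variance: p = 1 if the means are equal
## (no evidence), p = 0 otherwise (infinite t).
row_t_test <- function(x_case, x_ctrl, var_equal = FALSE) {
  n1 <- ncol(x_case); n2 <- ncol(x_ctrl)
  m1 <- rowMeans(x_case); m2 <- rowMeans(x_ctrl)
  v1 <- rowSums((x_case - m1)^2) / (n1 - 1)
  v2 <- rowSums((x_ctrl - m2)^2) / (n2 - 1)
  if (var_equal) {
    sp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(m1))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t_stat <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(t_stat), df)
  degenerate <- se == 0
  p[degenerate] <- ifelse(m1[degenerate] == m2[degenerate], 1, 0)
  t_stat[degenerate & m1 == m2] <- 0
  list(mu_case = m1, mu_ctrl = m2,
       sigma_case = sqrt(v1), sigma_ctrl = sqrt(v2),
       t = t_stat, df = df, p = p, n_case = n1, n_ctrl = n2)
}

#' Per-gene group comparison with FCS/SNS ranking statistics
#'
#' For every gene, computes group means and standard deviations over the
#' selected discs of a region, a two-sided t-test (Welch by default), and
#' the [fcs_score()] and [sns_score()] ranking statistics. The unit of
#' replication defaults to the disc (pooled within group); `unit =
#' "animal"` first averages discs within each animal (see the methods
#' vignette for the pseudoreplication trade-off). A Benjamini-Hochberg
#' adjusted p-value column is emitted for transparency but plays no role in
#' hit calling.
#'
#' @param mat normalized expression, genes x spots (columns named by
#'   barcode).
#' @param assignment a `region_assignment` from [select_discs()] carrying
#'   `group` (and `animal_id` for `unit = "animal"`).
#' @param region region label to compare within.
#' @param case_group,ctrl_group group labels.
#' @param unit `"disc"` (default) or `"animal"`.
#' @param var_equal pooled-variance t-test instead of Welch.
#' @param pseudocount,sd_floor,p_floor see [fcs_score()] and [sns_score()].
#' @return a `de_comparison` data.frame, one row per gene: `gene`,
#'   `mu_case`, `mu_ctrl`, `sigma_case`, `sigma_ctrl`, `n_case`, `n_ctrl`,
#'   `p_value`, `p_adj`, `fcs`, `sns`, `direction`.
#' @export
compare_groups <- function(mat, assignment, region, case_group, ctrl_group,
                           unit = c("disc", "animal"), var_equal = FALSE,
                           pseudocount = 0.5, sd_floor = 1e-8,
                           p_floor = 1e-300) {
  unit <- match.arg(unit)
  mat <- as.matrix(mat)
  sel <- assignment$selected & assignment$region_label == region
  if (!any(sel))
    stop("no selected discs in region '", region, "'", call. = FALSE)
  sel_case <- sel & assignment$group == case_group
  sel_ctrl <- sel & assignment$group == ctrl_group

  get_cols <- function(keep) {
    bc <- assignment$barcode[keep]
    idx <- match(bc, colnames(mat))
    if (anyNA(idx))
      stop("barcodes missing from the expression matrix: ",
           paste(utils::head(bc[is.na(idx)], 5), collapse = ", "),
           call. = FALSE)
    mat[, idx, drop = FALSE]
  }
  x_case <- get_cols(sel_case)
  x_ctrl <- get_cols(sel_ctrl)

  if (unit == "animal") {
    avg_by_animal <- function(x, keep) {
      f <- factor(assignment$animal_id[keep])
      t(apply(x, 1, function(v) tapply(v, f, mean)))
    }
    x_case <- avg_by_animal(x_case, sel_case)
    x_ctrl <- avg_by_animal(x_ctrl, sel_ctrl)
  }
  if (ncol(x_case) < 2 || ncol(x_ctrl) < 2)
    stop("need at least 2 replicates per group in region '", region,
         "' (case: ", ncol(x_case), ", control: ", ncol(x_ctrl), ")",
         call. = FALSE)

  tt <- row_t_test(x_case, x_ctrl, var_equal = var_equal)
  out <- data.frame(
    gene = rownames(mat),
    mu_case = tt$mu_case, mu_ctrl = tt$mu_ctrl,
    sigma_case = tt$sigma_case, sigma_ctrl = tt$sigma_ctrl,
    n_case = tt$n_case, n_ctrl = tt$n_ctrl,
    p_value = tt$p,
    p_adj = stats::p.adjust(tt$p, method = "BH"),
    fcs = fcs_score(tt$mu_case, tt$mu_ctrl, tt$p, pseudocount, p_floor),
    sns = sns_score(tt$mu_case, tt$mu_ctrl, tt$sigma_case, tt$sigma_ctrl,
                    tt$p, sd_floor, p_floor),
    direction = sign(tt$mu_case - tt$mu_ctrl),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "region") <- region
  attr(out, "case_group") <- case_group
  attr(out, "ctrl_group") <- ctrl_group
  attr(out, "pseudocount") <- pseudocount
  class(out) <- c("de_comparison", "data.frame")
  out
}

#' Dual-control hit calling
#'
#' A gene is a hit iff its p-value is below `alpha` in \emph{both}
#' case-versus-control comparisons (e.g. GqCNO vs GqVeh \emph{and} GqCNO vs
#' CNO-alone). Hits are ranked by descending `|FCS|` and descending `|SNS|`
#' taken from the first (case vs vehicle) comparison, ties broken by gene
#' symbol.
#'
#' @param case_vs_veh,case_vs_alt `de_comparison` objects over the same gene
#'   universe and region.
#' @param alpha significance threshold on the raw p-values.
#' @return a `hit_set` data.frame: `gene`, `direction`, `fcs`, `sns`,
#'   `p_case_vs_veh`, `p_case_vs_alt`, `rank_by_fcs`, `rank_by_sns`.
#' @export
call_hits <- function(case_vs_veh, case_vs_alt, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  g1 <- case_vs_veh$gene
  g2 <- case_vs_alt$gene
  if (!setequal(g1, g2) || length(g1) != length(g2)) {
    diff <- c(setdiff(g1, g2), setdiff(g2, g1))
    stop("gene universes differ between the two comparisons: ",
         paste(utils::head(unique(diff), 10), collapse = ", "),
         call. = FALSE)
  }
  case_vs_alt <- case_vs_alt[match(g1, g2), ]
  hit <- case_vs_veh$p_value < alpha & case_vs_alt$p_value < alpha
  out <- data.frame(
    gene = g1[hit],
    direction = case_vs_veh$direction[hit],
    fcs = case_vs_veh$fcs[hit],
    sns = case_vs_veh$sns[hit],
    p_case_vs_veh = case_vs_veh$p_value[hit],
    p_case_vs_alt = case_vs_alt$p_value[hit],
    stringsAsFactors = FALSE)
  out$rank_by_fcs <- rank_desc_abs(out$fcs, out$gene)
  out$rank_by_sns <- rank_desc_abs(out$sns, out$gene)
  out <- out[order(out$rank_by_fcs), ]
  rownames(out) <- NULL
  attr(out, "region") <- attr(case_vs_veh, "region")
  attr(out, "alpha") <- alpha
  class(out) <- c("hit_set", "data.frame")
  out
}

## rank by descending |x|, stable tie-break on the gene symbol
rank_desc_abs <- function(x, gene) {
  ord <- order(-abs(x), gene)
  r <- integer(length(x))
  r[ord] <- seq_along(x)
  r
}

#' Export a comparison as a volcano-style table (and optional plot)
#'
#' Writes a TSV with columns `gene`, `log2fc`, `p`, `fcs`, `sns`,
#' `direction`, rows in gene-symbol order. If `plot_path` is given and
#' \pkg{ggplot2} is installed, also saves a volcano plot (log2 fold change
#' vs -log10 p).
#'
#' @param comparison a `de_comparison`.
#' @param path output TSV path.
#' @param plot_path optional plot file path (extension decides the device).
#' @param alpha significance line drawn on the plot.
#' @return invisibly, the exported data.frame.
#' @export
export_volcano <- function(comparison, path, plot_path = NULL, alpha = 0.05) {
  eps <- attr(comparison, "pseudocount")
  if (is.null(eps)) eps <- 0.5
  tab <- data.frame(
    gene = comparison$gene,
    log2fc = log2((comparison$mu_case + eps) / (comparison$mu_ctrl + eps)),
    p = comparison$p_value,
    fcs = comparison$fcs,
    sns = comparison$sns,
    direction = comparison$direction,
    stringsAsFactors = FALSE)
  tab <- tab[order(tab$gene), ]
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)

  if (!is.null(plot_path)) {
    if (!requireNamespace("ggplot2", quietly = TRUE)) {
      warning("ggplot2 not installed; skipping the volcano plot",
              call. = FALSE)
    } else {
      ptab <- tab
      ptab$neg_log10_p <- -log10(pmax(ptab$p, 1e-300))
      ptab$significant <- ptab$p < alpha
      gg <- ggplot2::ggplot(ptab,
              ggplot2::aes(x = log2fc, y = neg_log10_p,
                           colour = significant)) +
        ggplot2::geom_point(size = 0.8, alpha = 0.7) +
        ggplot2::geom_hline(yintercept = -log10(alpha), linetype = 2) +
        ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                                `TRUE` = "firebrick"),
                                     guide = "none") +
        ggplot2::labs(x = "log2 fold change", y = "-log10 p") +
        ggplot2::theme_minimal()
      ggplot2::ggsave(plot_path, gg, width = 5, height = 4)
    }
  }
  invisible(tab)
}
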