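test_that("quantile normalization equals the mean of order statistics", {
  m <- cbind(a = c(1, 2, 3), b = c(2, 4, 6))
  out <- normalize_counts(m, "quantile")
  expect_equal(unname(out), cbind(c(1.5, 3, 4.5), c(1.5, 3, 4.5)))
  ## tie-free random matrix: agrees with limma's implementation
  skip_if_not_installed("limma")
  set.seed(4)
  r <- matrix(runif(200, 0, 50), 40, 5)
  expect_equal(unname(normalize_counts(r, "quantile")),
               unname(limma::normalizeQuantiles(r)), tolerance = 1e-12)
})

test_that("quantile-normalized columns share the identical sorted vector", {
  set.seed(8)
  m <- matrix(rpois(600, 3), 100, 6)   # counts, plenty of ties
  out <- normalize_counts(m, "quantile")
  ref <- unname(sort(out[, 1]))
  for (j in 2:ncol(out)) expect_identical(unname(sort(out[, j])), ref)
})

test_that("q3, median and libsize satisfy their defining equalities", {
  set.seed(5)
  m <- matrix(rnbinom(100 * 8, mu = 10, size = 5), 100, 8,
              dimnames = list(NULL, paste0("s", 1:8)))
  q3 <- normalize_counts(m, "q3")
  q3s_in <- apply(m, 2, function(v) quantile(v[v > 0], 0.75, names = FALSE))
  q3s_out <- vapply(seq_len(ncol(q3)), function(j) {
    v <- q3[, j]
    quantile(v[v > 0], 0.75, names = FALSE)
  }, numeric(1))
  expect_lt(max(abs(q3s_out - exp(mean(log(q3s_in))))), 1e-10)

  med <- normalize_counts(m, "median")
  detected <- rowSums(m > 0) > 0
  meds_in <- apply(m[detected, ], 2, median)
  meds_out <- apply(med[detected, ], 2, median)
  expect_lt(max(abs(meds_out - median(meds_in))), 1e-10)

  ls <- normalize_counts(m, "libsize")
  expect_lt(max(abs(colSums(ls) - mean(colSums(m)))), 1e-10)
})

test_that("background normalization divides by the mean negative-probe count", {
  m <- rbind(gene1 = c(8, 10), np1 = c(1, 4), np2 = c(3, 6))
  negp <- c(FALSE, TRUE, TRUE)
  out <- normalize_counts(m, "background", negative_probes = negp)
  expect_equal(out["gene1", ], c(8 / 2, 10 / 5))
  expect_error(normalize_counts(m, "background"), "negative-probe")
})

test_that("identical samples are fixed points of every method (up to scale)", {
  v <- c(0, 1, 3, 7, 2, 5)
  m <- cbind(v, v, v)
  negp <- c(rep(FALSE, 5), TRUE)
  for (method in c("median", "quantile", "q3", "libsize", "background")) {
    out <- normalize_counts(m, method, negative_probes = negp)
    scale <- out[2, 1] / m[2, 1]
    expect_equal(unname(out), unname(m * scale), tolerance = 1e-12,
                 label = method)
  }
})

test_that("degenerate samples raise errors naming the sample", {
  m <- cbind(good = c(1, 2, 3), bad = c(0, 0, 0))
  expect_error(normalize_counts(m, "q3"), "bad")
  expect_error(normalize_counts(m, "libsize"), "bad")
  expect_error(normalize_counts(m, "median"), "bad")
  expect_error(normalize_counts(m - 1, "median"), "nonnegative")
})

test_that("all normalizations preserve zeros", {
  set.seed(6)
  m <- matrix(rnbinom(50 * 6, mu = 2, size = 2), 50, 6)
  m[m < 1] <- 0
  for (method in c("median", "q3", "libsize")) {
    out <- normalize_counts(m, method)
    expect_identical(out == 0, m == 0, label = method)
  }
})

test_that("segment QC retains iff every inclusive threshold is met", {
  thr <- segment_qc_thresholds()
  boundary <- data.frame(segment_id = "edge", reads = 1000, pct_trimmed = 80,
                         pct_stitched = 80, pct_aligned = 75,
                         pct_saturation = 50, negative_count = 1,
                         ntc_count = 10000, nuclei = 20, area = 1000)
  ## one violation per rule, everything else at the boundary
  viol <- list(min_segment_reads = c("reads", 999),
               min_pct_trimmed = c("pct_trimmed", 79.9),
               min_pct_stitched = c("pct_stitched", 79.9),
               min_pct_aligned = c("pct_aligned", 74.9),
               min_pct_saturation = c("pct_saturation", 49.9),
               min_negative_count = c("negative_count", 0),
               max_ntc_count = c("ntc_count", 10001),
               min_nuclei = c("nuclei", 19),
               min_area = c("area", 999))
  tab <- boundary
  for (rn in names(viol)) {
    row <- boundary
    row$segment_id <- rn
    row[[viol[[rn]][1]]] <- as.numeric(viol[[rn]][2])
    tab <- rbind(tab, row)
  }
  res <- qc_filter_segments(tab, thr)
  expect_identical(res$retained, c(TRUE, rep(FALSE, length(viol))))
  expect_identical(res$reasons, c("", names(viol)))
})

test_that("segment QC is row-order invariant and reports multiple reasons", {
  tab <- data.frame(segment_id = c("a", "b"), reads = c(500, 2000),
                    pct_trimmed = c(70, 90), pct_stitched = c(90, 90),
                    pct_aligned = c(90, 90), pct_saturation = c(60, 60),
                    negative_count = c(5, 5), ntc_count = c(10, 10),
                    nuclei = c(50, 50), area = c(5000, 5000))
  r1 <- qc_filter_segments(tab)
  r2 <- qc_filter_segments(tab[2:1, ])
  expect_equal(r1$reasons[r1$segment_id == "a"], "min_segment_reads,min_pct_trimmed")
  expect_identical(r1[order(r1$segment_id), ],
                   r2[order(r2$segment_id), ], ignore_attr = TRUE)
  expect_error(qc_filter_segments(tab[, -2]), "reads")
})

test_that("detection-rate filtering is inclusive at the boundary", {
  m <- matrix(0, 3, 100, dimnames = list(c("zero", "one", "all"), NULL))
  m["one", 1] <- 5
  m["all", ] <- 1
  kept <- detection_rate_filter(m, 0.01)
  expect_setequal(kept, c("one", "all"))
  expect_setequal(detection_rate_filter(m, 0), rownames(m))
  expect_setequal(detection_rate_filter(m, 0.02), "all")
})

test_that("the normalization diagnostic behaves on degenerate designs", {
  ## exact scalar multiples: library-size normalization gives constant M,
  ## reported as correlation 0; KS fraction 0
  v <- c(1, 4, 2, 8, 5, 3, 9, 7, 6, 10)
  m <- cbind(v, 2 * v, 4 * v)
  rep_ls <- normalization_diagnostic(m, methods = "libsize")
  expect_equal(rep_ls$report$mean_abs_ma_cor, 0)
  expect_equal(rep_ls$report$frac_ks_significant, 0)
  ## identical samples: every method has KS statistic 0 everywhere
  ident <- cbind(v, v, v)
  rep_all <- normalization_diagnostic(ident,
                                      methods = c("median", "quantile",
                                                  "q3", "libsize"))
  expect_lt(max(rep_all$report$mean_ks_stat), 1e-12)
  expect_true(all(rep_all$report$frac_ks_significant == 0))
  expect_error(normalization_diagnostic(m[, 1, drop = FALSE]), "2 samples")
})

test_that("quantile ranks at or below raw counts under library-size artifacts", {
  set.seed(12)
  base <- rnbinom(400, mu = 20, size = 3)
  m <- sapply(c(0.2, 0.6, 1, 1.8, 3, 5),
              function(f) rpois(400, pmax(base * f, 0.1)))
  rep <- normalization_diagnostic(m, methods = c("quantile", "libsize", "q3"))
  qrow <- rep$report[rep$report$method == "quantile", ]
  ## raw-count baseline under the same MA / KS definitions
  ref <- exp(rowMeans(log(m + 1)))
  raw_cor <- mean(abs(apply(m, 2, function(x) {
    M <- log2((x + 1) / ref)
    A <- 0.5 * (log2(x + 1) + log2(ref))
    if (sd(M) == 0) 0 else cor(M, A)
  })))
  raw_ks <- mean(apply(m, 2, function(x)
    suppressWarnings(ks.test(x, as.vector(m))$p.value)) < 0.05)
  expect_lte(qrow$mean_abs_ma_cor, raw_cor)
  expect_lte(qrow$frac_ks_significant, raw_ks)
  ## quantile forces identical sample distributions: no KS rejections
  expect_equal(qrow$frac_ks_significant, 0)
})
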