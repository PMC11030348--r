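## Shared study designs for the test suite. The midbrain design mirrors the
## study's per-section disc counts (SN 6, VTA 30, thalamus 20 capture areas);
## the DE bench design uses a single DA region sized so the smallest group
## has exactly 40 discs (20 discs/section x 2 CNO-alone animals).

midbrain_design <- function(n_genes = 60, seed = 1, ...) {
  sim_design(
    n_genes = n_genes,
    n_negative_probes = 10L,
    region_layout = list(SN = list(rows = 3:4, cols = 3:5),
                         VTA = list(rows = 8:12, cols = 3:8),
                         thalamus = list(rows = 16:19, cols = 3:7)),
    marker_panel = default_marker_panel()[c("SN", "VTA", "thalamus")],
    seed = seed, ...)
}

small_midbrain_design <- function(n_genes = 60, seed = 1,
                                  n_negative_probes = 10L, ...) {
  sim_design(
    n_genes = n_genes,
    n_negative_probes = n_negative_probes,
    lattice_rows = 16, lattice_cols = 16,
    region_layout = list(SN = list(rows = 2:3, cols = 2:4),
                         VTA = list(rows = 6:9, cols = 2:6),
                         thalamus = list(rows = 12:14, cols = 2:5)),
    marker_panel = default_marker_panel()[c("SN", "VTA", "thalamus")],
    seed = seed, ...)
}

de_bench_design <- function(n_genes = 2000, planted_effects = NULL, seed = 1,
                            ...) {
  sim_design(
    n_genes = n_genes,
    n_negative_probes = 20L,
    lattice_rows = 12, lattice_cols = 12,
    region_layout = list(VTA = list(rows = 2:5, cols = 2:6)),
    marker_panel = list(VTA = c("Th", "Slc6a3", "Slc18a2")),
    glial_spot_fraction = 0,
    planted_effects = planted_effects,
    seed = seed, ...)
}

normalized_expression <- function(sim, method = "median") {
  counts <- SummarizedExperiment::assay(sim$se, "counts")
  negp <- SummarizedExperiment::rowData(sim$se)$is_negative_probe
  normalize_counts(counts, method, negative_probes = negp)[!negp, ,
                                                           drop = FALSE]
}

## staggered-lattice positions table (1 section) in array coordinates
staggered_positions <- function(nrow, ncol, section = "s1") {
  r <- rep(seq_len(nrow), times = ncol) - 1L
  cc <- rep(seq_len(ncol), each = nrow) - 1L
  data.frame(barcode = sprintf("%s_R%02dC%02d", section, r, cc),
             array_row = r,
             array_col = 2L * cc + r %% 2L,
             section_id = section,
             stringsAsFactors = FALSE)
}

## brute-force hex neighbor oracle: spots at Euclidean distance exactly 2 in
## the plane embedding x = array_col, y = array_row * sqrt(3)
oracle_neighbors <- function(positions, spot) {
  i <- match(spot, positions$barcode)
  x <- positions$array_col
  y <- positions$array_row * sqrt(3)
  d2 <- (x - x[i])^2 + (y - y[i])^2
  same <- if (is.null(positions$section_id)) TRUE
          else positions$section_id == positions$section_id[i]
  positions$barcode[same & d2 > 0 & abs(d2 - 4) < 1e-9]
}

## reference two-sample KS: ECDF max difference + asymptotic p
reference_ks <- function(x, y) {
  n <- length(x); m <- length(y)
  v <- sort(unique(c(x, y)))
  d <- max(abs(ecdf(x)(v) - ecdf(y)(v)))
  lambda <- sqrt(n * m / (n + m)) * d
  k <- 1:1000
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  list(statistic = d, p_value = max(0, min(1, p)))
}
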