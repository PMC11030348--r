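## Synthetic data generator: negative-binomial counts on a staggered
## (Visium-style) hexagonal lattice, with region marker structure, planted
## group effects, glial-contaminated spots, negative probes, activity scores
## and a human ortholog direction panel.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's `.Random.seed` afterwards, so generator calls do not
#' perturb user RNG state.
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## deterministic sub-stream seeds derived from the design seed
substream_seed <- function(seed, k) {
  as.integer((as.double(seed) %% 65011 * 32749 + k * 10007 + 1) %% 2147483629)
}

## gene universe: region markers and glial markers first, then filler genes
build_gene_universe <- function(design) {
  special <- unique(c(unlist(design$marker_panel, use.names = FALSE),
                      glial_markers()))
  if (length(special) > design$n_genes)
    stop("n_genes smaller than the marker panel", call. = FALSE)
  n_fill <- design$n_genes - length(special)
  fillers <- if (n_fill > 0) sprintf("Gene%04d", seq_len(n_fill)) else character()
  symbols <- c(special, fillers)
  data.frame(
    gene_id = sprintf("SIMG%05d", seq_along(symbols)),
    symbol = symbols,
    feature_type = "Gene Expression",
    is_negative_probe = FALSE,
    stringsAsFactors = FALSE)
}

negative_probe_features <- function(n) {
  if (n == 0)
    return(data.frame(gene_id = character(), symbol = character(),
                      feature_type = character(), is_negative_probe = logical(),
                      stringsAsFactors = FALSE))
  data.frame(
    gene_id = sprintf("SIMN%05d", seq_len(n)),
    symbol = sprintf("NegProbe-%03d", seq_len(n)),
    feature_type = "Negative Probe",
    is_negative_probe = TRUE,
    stringsAsFactors = FALSE)
}

## per-spot region label for one section (lattice in 1-based row/col)
region_label_matrix <- function(design) {
  lab <- matrix("unassigned", design$lattice_rows, design$lattice_cols)
  for (nm in names(design$region_layout)) {
    blk <- design$region_layout[[nm]]
    lab[blk$rows, blk$cols] <- nm
  }
  lab
}

#' Generate human ortholog direction labels for a set of mouse genes
#'
#' Each mouse gene is mapped into the human panel with probability
#' `mapping_rate` (human symbols are upper-cased); a mapped gene's direction
#' agrees with the mouse sign with probability `agreement`, otherwise it is
#' flipped.
#'
#' @param directions named numeric vector of mouse directions (+1 / -1),
#'   names are mouse gene symbols.
#' @param agreement probability of sign agreement, in `[0, 1]`.
#' @param mapping_rate probability a gene is present in the human panel.
#' @param seed integer seed.
#' @return list with `table` (data.frame `symbol`, `direction` with values
#'   `"up"`/`"down"`) and `truth` (data.frame `gene`, `mouse_direction`,
#'   `human_direction`, `mapped`).
#' @export
simulate_human_directions <- function(directions, agreement = 0.8,
                                      mapping_rate = 1, seed = 1L) {
  stopifnot(is.numeric(directions), !is.null(names(directions)),
            all(directions %in% c(-1, 1)),
            agreement >= 0, agreement <= 1,
            mapping_rate >= 0, mapping_rate <= 1)
  with_seed(seed, {
    mapped <- stats::runif(length(directions)) < mapping_rate
    agree <- stats::runif(length(directions)) < agreement
    human_dir <- ifelse(agree, directions, -directions)
    truth <- data.frame(
      gene = names(directions),
      mouse_direction = as.numeric(directions),
      human_direction = as.numeric(human_dir),
      mapped = mapped,
      stringsAsFactors = FALSE)
    tab <- data.frame(
      symbol = toupper(names(directions))[mapped],
      direction = ifelse(human_dir[mapped] > 0, "up", "down"),
      stringsAsFactors = FALSE)
    list(table = tab, truth = truth)
  })
}

## synthetic GeoMx-style segment QC table; a `fail_fraction` of segments get
## exactly one randomly chosen violated rule
simulate_segment_qc <- function(n_segments, fail_fraction, seed) {
  with_seed(seed, {
    tab <- data.frame(
      segment_id = sprintf("SEG%03d", seq_len(n_segments)),
      group = rep(c("control", "ePD"), length.out = n_segments),
      reads = round(stats::rlnorm(n_segments, log(5e4), 0.3)),
      pct_trimmed = stats::runif(n_segments, 90, 100),
      pct_stitched = stats::runif(n_segments, 90, 100),
      pct_aligned = stats::runif(n_segments, 85, 100),
      pct_saturation = stats::runif(n_segments, 60, 95),
      negative_count = round(stats::runif(n_segments, 2, 30)),
      ntc_count = round(stats::runif(n_segments, 0, 2000)),
      nuclei = round(stats::runif(n_segments, 40, 400)),
      area = round(stats::runif(n_segments, 2500, 30000)),
      stringsAsFactors = FALSE)
    n_fail <- round(fail_fraction * n_segments)
    if (n_fail > 0) {
      idx <- sample.int(n_segments, n_fail)
      rule <- sample(c("reads", "pct_aligned", "nuclei", "area", "ntc_count"),
                     n_fail, replace = TRUE)
      for (i in seq_len(n_fail)) {
        tab[idx[i], rule[i]] <- switch(rule[i],
          reads = 500, pct_aligned = 50, nuclei = 5, area = 400,
          ntc_count = 20000)
      }
    }
    tab
  })
}

#' Simulate a full synthetic spatial-transcriptomics dataset
#'
#' Draws counts gene-wise from a negative-binomial model on a staggered
#' hexagonal lattice according to a [sim_design()]: region markers are
#' up-weighted in their home regions, planted effects are applied
#' multiplicatively to the stated group/region, glial-contaminated spots
#' receive elevated astrocyte/microglia markers (which have zero baseline
#' elsewhere), and negative probes are drawn from a low-mean background
#' identical across groups. Also generates per-spot activity scores (with an
#' additive `GqCNO` shift), a human ortholog direction panel tied to the
#' planted effect signs, and a GeoMx-style segment QC table. Fully
#' reproducible for a fixed `design$seed`.
#'
#' @param design a [sim_design()] object.
#' @return object of class `spothits_sim`: a list with elements
#' \describe{
#'   \item{se}{[SummarizedExperiment::SummarizedExperiment] of integer counts
#'     (features x spots) with spot metadata in `colData` (barcode, animal,
#'     group, section, lattice position, region label, soma flag) and feature
#'     metadata in `rowData` (negative-probe flags).}
#'   \item{truth}{ground truth: per-spot `spots` data.frame (true region,
#'     glial flag), planted `deg` table with signed effects, the activity
#'     shift, and the human sign truth.}
#'   \item{activity}{per-spot activity score table (`barcode`, `section_id`,
#'     `group`, `score`).}
#'   \item{human}{human direction table (`symbol`, `direction`).}
#'   \item{segment_qc}{synthetic GeoMx-style segment QC table.}
#' }
#' @examples
#' d <- sim_design(n_genes = 50, lattice_rows = 14, lattice_cols = 14,
#'                 region_layout = list(SN = list(rows = 2:3, cols = 2:4)),
#'                 marker_panel = list(SN = c("Th", "Slc6a3", "Slc18a2")),
#'                 seed = 7)
#' sim <- simulate_dataset(d)
#' dim(sim$se)
#' @export
simulate_dataset <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  features <- rbind(build_gene_universe(design),
                    negative_probe_features(design$n_negative_probes))
  gene_rows <- which(!features$is_negative_probe)
  symbols <- features$symbol[gene_rows]

  if (!is.null(design$planted_effects)) {
    missing_genes <- setdiff(design$planted_effects$gene, symbols)
    if (length(missing_genes))
      stop("planted effect on gene(s) absent from the panel: ",
           paste(missing_genes, collapse = ", "), call. = FALSE)
  }

  ## gene-level baseline means: log-normal around nb_mean; glial markers have
  ## zero ambient baseline (cell-type specific by construction)
  base_mu <- with_seed(substream_seed(design$seed, 0), {
    mu <- stats::rlnorm(design$n_genes, meanlog = log(design$nb_mean),
                        sdlog = design$nb_meanlog_sd)
    names(mu) <- symbols
    mu[intersect(glial_markers(), symbols)] <- 0
    mu
  })

  lab <- region_label_matrix(design)
  nr <- design$lattice_rows; nc <- design$lattice_cols
  n_spots_section <- nr * nc
  grid_row <- rep(seq_len(nr), times = nc)
  grid_col <- rep(seq_len(nc), each = nr)
  region_vec <- lab[cbind(grid_row, grid_col)]
  da_regions <- intersect(c("SN", "VTA"), names(design$region_layout))

  ## DA neighborhood (DA-region spots plus their hex ring): the spots whose
  ## activity scores carry the GqCNO shift. Elevated activity is a property
  ## of the scored DA neighborhoods, not of the whole section, so it must
  ## survive section-mean normalization.
  arr_row <- grid_row - 1L
  arr_col <- 2L * (grid_col - 1L) + (grid_row - 1L) %% 2L
  key <- paste(arr_row, arr_col)
  da_mask <- region_vec %in% da_regions
  offsets <- cbind(dr = c(0, 0, -1, -1, 1, 1), dc = c(-2, 2, -1, 1, -1, 1))
  nb_keys <- unlist(lapply(seq_len(nrow(offsets)), function(k)
    paste(arr_row[da_mask] + offsets[k, "dr"],
          arr_col[da_mask] + offsets[k, "dc"])))
  da_neighborhood <- da_mask | key %in% nb_keys

  animals <- data.frame(
    animal_id = sprintf("%s_m%d", rep(names(design$n_per_group), design$n_per_group),
                        unlist(lapply(design$n_per_group, seq_len))),
    group = rep(names(design$n_per_group), design$n_per_group),
    stringsAsFactors = FALSE)

  sections <- list()
  k <- 0L
  for (a in seq_len(nrow(animals))) {
    for (s in seq_len(design$sections_per_animal)) {
      k <- k + 1L
      sections[[k]] <- list(
        section_id = sprintf("%s_s%d", animals$animal_id[a], s),
        animal_id = animals$animal_id[a],
        group = animals$group[a],
        index = k)
    }
  }

  n_feat <- nrow(features)
  counts_list <- vector("list", length(sections))
  coldata_list <- vector("list", length(sections))
  activity_list <- vector("list", length(sections))
  glial_barcodes <- character()

  for (sec in sections) {
    sec_seed <- substream_seed(design$seed, sec$index)
    res <- with_seed(sec_seed, {
      barcodes <- sprintf("%s_R%02dC%02d", sec$section_id, grid_row, grid_col)
      glial <- stats::runif(n_spots_section) < design$glial_spot_fraction

      ## expected counts: features x spots
      mu <- matrix(0, n_feat, n_spots_section)
      mu[gene_rows, ] <- base_mu
      if (design$n_negative_probes > 0)
        mu[features$is_negative_probe, ] <- design$negative_probe_mean

      for (nm in names(design$marker_panel)) {
        in_region <- region_vec == nm
        if (!any(in_region)) next
        mk <- match(design$marker_panel[[nm]], features$symbol)
        if (anyNA(mk))
          stop("marker panel gene missing from features for region ", nm,
               call. = FALSE)
        mu[mk, in_region] <- mu[mk, in_region] * design$marker_boost
      }
      if (!is.null(design$planted_effects)) {
        pe <- design$planted_effects[design$planted_effects$group == sec$group, ,
                                     drop = FALSE]
        if (nrow(pe)) {
          for (i in seq_len(nrow(pe))) {
            gi <- match(pe$gene[i], features$symbol)
            in_region <- region_vec == pe$region[i]
            mu[gi, in_region] <- mu[gi, in_region] * 2^pe$log2fc[i]
          }
        }
      }
      if (any(glial)) {
        gm <- match(intersect(glial_markers(), features$symbol), features$symbol)
        mu[gm, glial] <- design$glial_boost
      }

      counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                      size = design$nb_dispersion),
                       n_feat, n_spots_section)
      storage.mode(counts) <- "integer"
      colnames(counts) <- barcodes
      rownames(counts) <- features$symbol

      score <- stats::rnorm(n_spots_section, design$activity_mean,
                            design$activity_sd)
      if (sec$group == "GqCNO")
        score[da_neighborhood] <- score[da_neighborhood] + design$activity_effect
      score <- pmin(pmax(score, 1e-3), 1)

      list(counts = counts, glial = glial, barcodes = barcodes, score = score)
    })

    counts_list[[sec$index]] <- res$counts
    glial_barcodes <- c(glial_barcodes, res$barcodes[res$glial])
    coldata_list[[sec$index]] <- data.frame(
      barcode = res$barcodes,
      animal_id = sec$animal_id,
      group = sec$group,
      section_id = sec$section_id,
      array_row = grid_row - 1L,
      array_col = 2L * (grid_col - 1L) + (grid_row - 1L) %% 2L,
      px_x = 2 * (grid_col - 1) + (grid_row - 1) %% 2,
      px_y = (grid_row - 1) * sqrt(3),
      region_label = region_vec,
      has_soma = region_vec %in% da_regions,
      stringsAsFactors = FALSE)
    activity_list[[sec$index]] <- data.frame(
      barcode = res$barcodes,
      section_id = sec$section_id,
      group = sec$group,
      score = res$score,
      stringsAsFactors = FALSE)
  }

  counts <- do.call(cbind, counts_list)
  coldata <- do.call(rbind, coldata_list)
  activity <- do.call(rbind, activity_list)
  rownames(coldata) <- coldata$barcode
  rownames(activity) <- NULL

  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(features, row.names = features$symbol),
    colData = S4Vectors::DataFrame(coldata, row.names = coldata$barcode))

  ## human panel tied to planted effect signs (deduplicated per gene)
  if (!is.null(design$planted_effects) && nrow(design$planted_effects)) {
    pe <- design$planted_effects
    dirs <- tapply(sign(pe$log2fc), pe$gene, function(s) s[1])
    dirs <- stats::setNames(as.numeric(dirs), names(dirs))
    hu <- simulate_human_directions(dirs,
                                    agreement = design$human_sign_agreement,
                                    mapping_rate = design$human_mapping_rate,
                                    seed = substream_seed(design$seed, 999998L))
  } else {
    hu <- list(table = data.frame(symbol = character(), direction = character(),
                                  stringsAsFactors = FALSE),
               truth = NULL)
  }

  truth <- list(
    spots = data.frame(
      barcode = coldata$barcode,
      section_id = coldata$section_id,
      region = coldata$region_label,
      glial = coldata$barcode %in% glial_barcodes,
      stringsAsFactors = FALSE),
    deg = design$planted_effects,
    activity_shift = design$activity_effect,
    human_signs = hu$truth)

  out <- list(
    se = se,
    truth = truth,
    activity = activity,
    human = hu$table,
    segment_qc = simulate_segment_qc(design$n_segments, design$qc_fail_fraction,
                                     substream_seed(design$seed, 999999L)),
    design = design)
  class(out) <- "spothits_sim"
  out
}

#' @export
print.spothits_sim <- function(x, ...) {
  cat("Synthetic spatial dataset:", nrow(x$se), "features x", ncol(x$se),
      "spots\n")
  cat("  sections:", length(unique(x$se$section_id)),
      " groups:", paste(unique(x$se$group), collapse = ", "), "\n")
  cat("  glial spots:", sum(x$truth$spots$glial),
      " planted effects:", if (is.null(x$truth$deg)) 0 else nrow(x$truth$deg),
      "\n")
  invisible(x)
}
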