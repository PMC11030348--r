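## Disc (capture-area) selection: marker rules for DA regions, region-marker
## rules for control regions, glial-contamination exclusion, soma flag, and
## hexagonal lattice neighborhoods for region expansion.

#' Disc selection rule
#'
#' A dopaminergic-region (SN/VTA) spot is selected iff at least
#' `min_markers_detected` of the `da_markers` reach `marker_threshold`
#' counts, no `exclusion_markers` gene exceeds its per-section
#' `exclusion_quantile` across all spots of the section, and (when
#' `require_soma_flag`) the spot's `has_soma` flag is true. Spots of other
#' labelled regions are selected when any of that region's markers reaches
#' `marker_threshold`.
#'
#' @param da_markers characteristic DA gene symbols.
#' @param min_markers_detected how many DA markers must be detected.
#' @param marker_threshold detection threshold in counts (inclusive).
#' @param exclusion_markers astrocyte/microglia contamination markers.
#' @param exclusion_quantile per-section, per-gene quantile above which a
#'   spot is excluded as glial-contaminated (strictly above).
#' @param region_marker_map named list mapping region to marker symbols for
#'   non-DA regions.
#' @param da_regions region labels treated as dopaminergic.
#' @param require_soma_flag require the per-spot `has_soma` flag for DA
#'   regions.
#' @return object of class `selection_rule`.
#' @export
selection_rule <- function(da_markers = c("Th", "Slc6a3", "Slc18a2"),
                           min_markers_detected = 2L,
                           marker_threshold = 1,
                           exclusion_markers = glial_markers(),
                           exclusion_quantile = 0.90,
                           region_marker_map = default_marker_panel(),
                           da_regions = c("SN", "VTA"),
                           require_soma_flag = TRUE) {
  stopifnot(min_markers_detected <= length(da_markers),
            min_markers_detected >= 1,
            exclusion_quantile > 0, exclusion_quantile < 1,
            marker_threshold >= 0)
  structure(list(da_markers = da_markers,
                 min_markers_detected = as.integer(min_markers_detected),
                 marker_threshold = marker_threshold,
                 exclusion_markers = exclusion_markers,
                 exclusion_quantile = exclusion_quantile,
                 region_marker_map = region_marker_map,
                 da_regions = da_regions,
                 require_soma_flag = isTRUE(require_soma_flag)),
            class = "selection_rule")
}

## extract a counts matrix + spot metadata from an SE or matrix+meta pair
spot_inputs <- function(x, meta = NULL) {
  if (methods::is(x, "SummarizedExperiment")) {
    list(counts = SummarizedExperiment::assay(x, 1),
         meta = as.data.frame(SummarizedExperiment::colData(x)))
  } else {
    stopifnot(is.matrix(x) || methods::is(x, "Matrix"), !is.null(meta))
    list(counts = x, meta = as.data.frame(meta))
  }
}

#' Select analysis discs per region
#'
#' Applies the marker, glial-exclusion and soma rules of a
#' [selection_rule()] to every spot. Region labels are an input (anatomical
#' assignment is done upstream); the rule filters within labels. The
#' exclusion threshold for each glial marker is its `exclusion_quantile`
#' quantile across all spots of the same section.
#'
#' @param x `SummarizedExperiment` of counts (features x spots) or a counts
#'   matrix (with `meta`).
#' @param regions optional per-spot region labels; defaults to the
#'   `region_label` metadata column.
#' @param rule a [selection_rule()].
#' @param meta spot metadata data.frame when `x` is a bare matrix; must carry
#'   `barcode`, `section_id` and (for soma checking) `has_soma`, plus any
#'   columns to carry through (`group`, `animal_id`, `array_row`,
#'   `array_col`).
#' @return a `region_assignment` data.frame, one row per spot: `barcode`,
#'   `region_label`, `selected`, `exclusion_reason` (one of `none`,
#'   `too_few_markers`, `glial_high`, `no_soma`) plus carried-through
#'   metadata columns. Selected spots always have reason `none`.
#' @export
select_discs <- function(x, regions = NULL, rule = selection_rule(),
                         meta = NULL) {
  inp <- spot_inputs(x, meta)
  counts <- inp$counts
  meta <- inp$meta
  if (is.null(regions)) {
    if (is.null(meta$region_label))
      stop("no `regions` given and no `region_label` metadata column",
           call. = FALSE)
    regions <- meta$region_label
  }
  stopifnot(length(regions) == ncol(counts))

  needed <- unique(c(rule$da_markers, rule$exclusion_markers,
                     unlist(rule$region_marker_map[
                       setdiff(intersect(regions, names(rule$region_marker_map)),
                               rule$da_regions)])))
  missing <- setdiff(needed, rownames(counts))
  if (length(missing))
    stop("marker gene(s) missing from the count matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)

  n <- ncol(counts)
  selected <- logical(n)
  reason <- rep("none", n)
  section <- meta$section_id
  if (is.null(section)) section <- rep("section1", n)

  ## DA marker detection
  da_counts <- counts[rule$da_markers, , drop = FALSE]
  n_detected <- Matrix::colSums(da_counts >= rule$marker_threshold)

  ## per-section, per-gene glial exclusion thresholds (strictly above)
  excl <- counts[rule$exclusion_markers, , drop = FALSE]
  glial_high <- logical(n)
  for (s in unique(section)) {
    in_s <- section == s
    thr <- apply(excl[, in_s, drop = FALSE], 1, stats::quantile,
                 probs = rule$exclusion_quantile, names = FALSE)
    glial_high[in_s] <- Matrix::colSums(excl[, in_s, drop = FALSE] > thr) > 0
  }

  is_da <- regions %in% rule$da_regions
  if (any(is_da)) {
    few <- is_da & n_detected < rule$min_markers_detected
    reason[few] <- "too_few_markers"
    gl <- is_da & !few & glial_high
    reason[gl] <- "glial_high"
    if (rule$require_soma_flag) {
      if (is.null(meta$has_soma))
        stop("rule requires a soma flag but metadata has no `has_soma` column",
             call. = FALSE)
      ns <- is_da & !few & !gl & !meta$has_soma
      reason[ns] <- "no_soma"
      selected[is_da & !few & !gl & !ns] <- TRUE
    } else {
      selected[is_da & !few & !gl] <- TRUE
    }
  }

  ## non-DA labelled regions: selected by their own region marker(s)
  other_regions <- setdiff(intersect(unique(regions),
                                     names(rule$region_marker_map)),
                           rule$da_regions)
  for (rg in other_regions) {
    in_r <- regions == rg
    mk <- rule$region_marker_map[[rg]]
    det <- Matrix::colSums(counts[mk, in_r, drop = FALSE] >=
                             rule$marker_threshold) > 0
    selected[in_r] <- det
    reason[in_r][!det] <- "too_few_markers"
  }

  labelled <- regions != "unassigned" & !is.na(regions)
  for (rg in setdiff(unique(regions[labelled]),
                     c(rule$da_regions, other_regions))) {
    warning("region '", rg, "' has no marker rule; zero spots selected",
            call. = FALSE)
  }
  if (any(labelled) && !any(selected))
    warning("no spots selected in any region", call. = FALSE)

  out <- data.frame(barcode = if (!is.null(meta$barcode)) meta$barcode
                              else colnames(counts),
                    region_label = regions,
                    selected = selected,
                    exclusion_reason = reason,
                    stringsAsFactors = FALSE)
  for (cc in intersect(c("section_id", "animal_id", "group", "array_row",
                         "array_col", "has_soma"), names(meta)))
    out[[cc]] <- meta[[cc]]
  class(out) <- c("region_assignment", "data.frame")
  out
}

#' Hexagonal lattice neighbors of a spot
#'
#' On the staggered (Visium-style) lattice, where `array_col` steps by 2
#' within a row and adjacent rows are offset by one column, the at-most six
#' neighbors of `(r, c)` are `(r, c±2)` and `(r±1, c±1)`, restricted to the
#' same section. The relation is symmetric.
#'
#' @param positions data.frame with `barcode`, `array_row`, `array_col` and
#'   (optionally) `section_id`.
#' @param spot barcode of the query spot.
#' @return character vector of neighbor barcodes (possibly empty).
#' @export
hex_neighbors <- function(positions, spot) {
  i <- match(spot, positions$barcode)
  if (is.na(i))
    stop("spot '", spot, "' not found in positions", call. = FALSE)
  idx <- hex_neighbor_indices(positions, i)
  positions$barcode[idx]
}

## indices of lattice-adjacent spots of positions[i, ], same section only
hex_neighbor_indices <- function(positions, i) {
  r <- positions$array_row[i]
  co <- positions$array_col[i]
  dr <- positions$array_row - r
  dc <- positions$array_col - co
  adj <- (dr == 0 & abs(dc) == 2) | (abs(dr) == 1 & abs(dc) == 1)
  if (!is.null(positions$section_id))
    adj <- adj & positions$section_id == positions$section_id[i]
  which(adj)
}

#' Expand a region by its outer ring of hex neighbors
#'
#' Returns the region's spots together with every spot lattice-adjacent to
#' any of them (the "inner + outer" neighborhood), computed section-wise.
#'
#' @param assignment a `region_assignment` from [select_discs()] (or any
#'   data.frame with `barcode`, `region_label`, `array_row`, `array_col`,
#'   `section_id`).
#' @param region region label to expand.
#' @param selected_only expand only selected region spots (default `FALSE`:
#'   all spots carrying the label).
#' @return character vector of barcodes (region spots plus outer ring).
#' @export
expand_region <- function(assignment, region, selected_only = FALSE) {
  stopifnot(all(c("barcode", "region_label", "array_row", "array_col") %in%
                  names(assignment)))
  in_region <- assignment$region_label == region
  if (selected_only) in_region <- in_region & assignment$selected
  if (!any(in_region)) return(character())

  section <- assignment$section_id
  if (is.null(section)) section <- rep("section1", nrow(assignment))
  key <- paste(section, assignment$array_row, assignment$array_col, sep = "\r")
  offsets <- cbind(dr = c(0, 0, -1, -1, 1, 1), dc = c(-2, 2, -1, 1, -1, 1))

  ridx <- which(in_region)
  nb_keys <- unlist(lapply(seq_len(nrow(offsets)), function(k) {
    paste(section[ridx],
          assignment$array_row[ridx] + offsets[k, "dr"],
          assignment$array_col[ridx] + offsets[k, "dc"], sep = "\r")
  }))
  hit <- key %in% nb_keys
  assignment$barcode[in_region | hit]
}
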