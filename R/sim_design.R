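#' Default region layout on the spot lattice
#'
#' Disjoint rectangular blocks of lattice rows/columns, one per anatomical
#' region. Block sizes are chosen so the number of capture areas per region
#' falls inside the ranges typical of targeted midbrain/striatal Visium
#' sections: SN 6 discs, VTA 30, thalamus 20, CP 400, LSX 40, white matter 48.
#'
#' @param lattice_rows,lattice_cols lattice dimensions the layout must fit in.
#' @return named list; each element has integer vectors `rows` and `cols`.
#' @export
default_region_layout <- function(lattice_rows = 40L, lattice_cols = 40L) {
  layout <- list(
    SN           = list(rows = 3:4,   cols = 3:5),
    VTA          = list(rows = 8:12,  cols = 3:8),
    thalamus     = list(rows = 16:19, cols = 3:7),
    CP           = list(rows = 3:22,  cols = 15:34),
    LSX          = list(rows = 26:30, cols = 3:10),
    white_matter = list(rows = 26:31, cols = 15:22)
  )
  for (nm in names(layout)) {
    blk <- layout[[nm]]
    if (max(blk$rows) > lattice_rows || max(blk$cols) > lattice_cols)
      stop("default region layout does not fit a ", lattice_rows, "x",
           lattice_cols, " lattice; supply `region_layout` explicitly",
           call. = FALSE)
  }
  layout
}

#' Default region marker panel
#'
#' Dopaminergic midbrain regions (SN, VTA) share the three characteristic
#' DA genes Th, Slc6a3 (DAT) and Slc18a2 (VMAT2); thalamus is marked by
#' Prkcd, Ptpn3 and Synpo2; CP by Ppp1r1b (DARPP-32); LSX by Prkcd; white
#' matter by Mbp.
#'
#' @return named list of character vectors, one per region.
#' @export
default_marker_panel <- function() {
  list(
    SN           = c("Th", "Slc6a3", "Slc18a2"),
    VTA          = c("Th", "Slc6a3", "Slc18a2"),
    thalamus     = c("Prkcd", "Ptpn3", "Synpo2"),
    CP           = "Ppp1r1b",
    LSX          = "Prkcd",
    white_matter = "Mbp"
  )
}

#' Glial contamination markers
#'
#' Astrocyte (Gfap, Aldh1l1) and microglia (Aif1, P2ry12) markers used both
#' by the generator (elevated in glial-contaminated spots) and by the disc
#' selection exclusion rule.
#'
#' @return character vector of gene symbols.
#' @export
glial_markers <- function() c("Gfap", "Aldh1l1", "Aif1", "P2ry12")

#' Describe a synthetic chemogenetic spatial-transcriptomics study
#'
#' Defines the full design of a synthetic dataset: the three treatment
#' groups (DREADD + agonist `GqCNO`, DREADD + vehicle `GqVeh`, agonist-only
#' `CNOalone`), the per-section hexagonal spot lattice with its region
#' blocks, the gene panel with region markers and negative probes, the
#' negative-binomial count model, planted group effects, glial-contaminated
#' spots, per-spot activity scores and the human ortholog direction panel.
#'
#' Counts are drawn gene-wise from a negative binomial with gene-level
#' baseline means drawn log-normally around `nb_mean` and common size
#' (inverse-dispersion) parameter `nb_dispersion`. Region markers are
#' up-weighted by `marker_boost` in their home region. Glial markers have
#' zero baseline outside glial-contaminated spots, where they are drawn with
#' mean `glial_boost`; contaminated spots are placed uniformly over the
#' lattice, including inside DA regions, so that exclusion rules are
#' exercised. Negative probes are drawn from a low-mean background
#' distribution identical across groups.
#'
#' @param n_per_group named integer vector of animals per treatment group.
#' @param sections_per_animal sections generated per animal.
#' @param lattice_rows,lattice_cols spot lattice dimensions per section.
#' @param region_layout named list of `list(rows=, cols=)` lattice blocks;
#'   blocks must be disjoint and fit the lattice.
#' @param n_genes number of genes (excluding negative probes).
#' @param n_negative_probes number of negative-probe features.
#' @param marker_panel named list mapping region to marker gene symbols.
#' @param nb_mean baseline negative-binomial mean; gene-level means are drawn
#'   log-normally with median `nb_mean` and log-sd `nb_meanlog_sd`.
#' @param nb_meanlog_sd log-scale standard deviation of gene baseline means.
#' @param nb_dispersion negative-binomial size parameter (larger = closer to
#'   Poisson).
#' @param marker_boost multiplicative enrichment of region markers in their
#'   home region.
#' @param glial_boost negative-binomial mean of glial markers in
#'   glial-contaminated spots (baseline elsewhere is zero).
#' @param planted_effects `NULL` or a data.frame with columns
#'   `gene`, `region`, `group`, `log2fc`; each row multiplies the NB mean of
#'   `gene` by `2^log2fc` in spots of `region` for animals of `group`.
#' @param glial_spot_fraction fraction of spots that are glial-contaminated.
#' @param activity_mean,activity_sd location and scale of per-spot activity
#'   scores (truncated to (0, 1]).
#' @param activity_effect additive shift of activity scores for `GqCNO`
#'   animals over the DA regions and their hexagonal outer ring (the scored
#'   neighborhood); the default is 0.3 standard deviations. The shift is
#'   local so that it survives section-mean score normalization, as a
#'   neighborhood-restricted activity increase does in real sections.
#' @param human_sign_agreement probability that a mapped human gene's
#'   direction agrees with the planted mouse direction.
#' @param human_mapping_rate probability that a planted mouse gene is present
#'   in the human panel at all.
#' @param negative_probe_mean NB mean of negative probes.
#' @param n_segments rows of the synthetic GeoMx-style segment QC table.
#' @param qc_fail_fraction fraction of synthetic segments given one randomly
#'   chosen QC violation.
#' @param seed integer seed; the single RNG stream of the dataset. Section
#'   sub-streams are derived deterministically from it.
#' @return object of class `sim_design`.
#' @seealso [simulate_dataset()]
#' @export
sim_design <- function(n_per_group = c(GqCNO = 3L, GqVeh = 3L, CNOalone = 2L),
                       sections_per_animal = 1L,
                       lattice_rows = 40L,
                       lattice_cols = 40L,
                       region_layout = default_region_layout(lattice_rows, lattice_cols),
                       n_genes = 2000L,
                       n_negative_probes = 50L,
                       marker_panel = default_marker_panel(),
                       nb_mean = 5,
                       nb_meanlog_sd = 0.4,
                       nb_dispersion = 20,
                       marker_boost = 20,
                       glial_boost = 40,
                       planted_effects = NULL,
                       glial_spot_fraction = 0.05,
                       activity_mean = 0.5,
                       activity_sd = 0.1,
                       activity_effect = 0.3 * activity_sd,
                       human_sign_agreement = 0.8,
                       human_mapping_rate = 51 / 59,
                       negative_probe_mean = 0.5,
                       n_segments = 20L,
                       qc_fail_fraction = 0.1,
                       seed = 1L) {
  stopifnot(length(n_per_group) >= 1, !is.null(names(n_per_group)),
            all(n_per_group >= 1), sections_per_animal >= 1,
            lattice_rows >= 1, lattice_cols >= 1,
            n_genes >= 1, n_negative_probes >= 0,
            nb_mean > 0, nb_dispersion > 0, marker_boost > 0, glial_boost > 0,
            glial_spot_fraction >= 0, glial_spot_fraction <= 1,
            human_sign_agreement >= 0, human_sign_agreement <= 1,
            human_mapping_rate >= 0, human_mapping_rate <= 1,
            negative_probe_mean >= 0,
            qc_fail_fraction >= 0, qc_fail_fraction <= 1)
  seed <- as.integer(seed)

  ## region blocks must fit the lattice and be pairwise disjoint
  occupied <- matrix(FALSE, lattice_rows, lattice_cols)
  for (nm in names(region_layout)) {
    blk <- region_layout[[nm]]
    if (min(blk$rows) < 1 || min(blk$cols) < 1 ||
        max(blk$rows) > lattice_rows || max(blk$cols) > lattice_cols)
      stop("region '", nm, "' does not fit the ",
           lattice_rows, "x", lattice_cols, " lattice", call. = FALSE)
    if (any(occupied[blk$rows, blk$cols]))
      stop("region blocks overlap at region '", nm, "'", call. = FALSE)
    occupied[blk$rows, blk$cols] <- TRUE
  }

  ## marker panel regions must exist in the layout (extra layout regions
  ## without markers are not allowed either: selection needs a marker rule)
  unmarked <- setdiff(names(region_layout), names(marker_panel))
  if (length(unmarked))
    stop("no markers defined for region(s): ",
         paste(unmarked, collapse = ", "), call. = FALSE)

  if (!is.null(planted_effects)) {
    need <- c("gene", "region", "group", "log2fc")
    if (!all(need %in% names(planted_effects)))
      stop("planted_effects needs columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    bad_region <- setdiff(planted_effects$region, names(region_layout))
    if (length(bad_region))
      stop("planted effect in unknown region(s): ",
           paste(bad_region, collapse = ", "), call. = FALSE)
    bad_group <- setdiff(planted_effects$group, names(n_per_group))
    if (length(bad_group))
      stop("planted effect for unknown group(s): ",
           paste(bad_group, collapse = ", "), call. = FALSE)
    if (anyDuplicated(planted_effects[c("gene", "region", "group")]))
      stop("duplicated planted effect (gene, region, group)", call. = FALSE)
  }

  design <- list(
    n_per_group = n_per_group, sections_per_animal = as.integer(sections_per_animal),
    lattice_rows = as.integer(lattice_rows), lattice_cols = as.integer(lattice_cols),
    region_layout = region_layout, n_genes = as.integer(n_genes),
    n_negative_probes = as.integer(n_negative_probes),
    marker_panel = marker_panel, nb_mean = nb_mean,
    nb_meanlog_sd = nb_meanlog_sd, nb_dispersion = nb_dispersion,
    marker_boost = marker_boost, glial_boost = glial_boost,
    planted_effects = planted_effects,
    glial_spot_fraction = glial_spot_fraction,
    activity_mean = activity_mean, activity_sd = activity_sd,
    activity_effect = activity_effect,
    human_sign_agreement = human_sign_agreement,
    human_mapping_rate = human_mapping_rate,
    negative_probe_mean = negative_probe_mean,
    n_segments = as.integer(n_segments), qc_fail_fraction = qc_fail_fraction,
    seed = seed)
  class(design) <- "sim_design"
  design
}

#' @export
print.sim_design <- function(x, ...) {
  groups <- paste(sprintf("%s (n=%d)", names(x$n_per_group), x$n_per_group),
                  collapse = ", ")
  cat("Synthetic spatial study design\n")
  cat("  groups:            ", groups, "\n")
  cat("  sections/animal:   ", x$sections_per_animal, "\n")
  cat("  lattice:           ", x$lattice_rows, "x", x$lattice_cols,
      "spots/section\n")
  cat("  regions:           ", paste(names(x$region_layout), collapse = ", "),
      "\n")
  cat("  genes:             ", x$n_genes, "(+", x$n_negative_probes,
      "negative probes )\n")
  cat("  planted effects:   ",
      if (is.null(x$planted_effects)) 0 else nrow(x$planted_effects), "\n")
  cat("  glial fraction:    ", x$glial_spot_fraction, "\n")
  cat("  seed:              ", x$seed, "\n")
  invisible(x)
}
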