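test_that("hex neighbors match the Euclidean-distance oracle, incl. edges", {
  for (dims in list(c(1, 1), c(2, 3), c(5, 4), c(7, 7))) {
    pos <- staggered_positions(dims[1], dims[2])
    for (bc in pos$barcode) {
      expect_setequal(hex_neighbors(pos, bc), oracle_neighbors(pos, bc))
    }
  }
  ## interior spot: exactly 6 neighbors
  pos <- staggered_positions(7, 7)
  interior <- pos$barcode[pos$array_row == 3 &
                            pos$array_col %in% c(6, 7)][1]
  expect_length(hex_neighbors(pos, interior), 6)
  ## corners: 2 or 3 depending on row parity/stagger
  corner_counts <- vapply(
    pos$barcode[(pos$array_row %in% c(0, 6)) &
                  (pos$array_col %in% range(pos$array_col))],
    function(b) length(hex_neighbors(pos, b)), integer(1))
  expect_true(all(corner_counts %in% 2:3))
  ## single-spot section: no neighbors
  expect_length(hex_neighbors(staggered_positions(1, 1), "s1_R00C00"), 0)
})

test_that("hex adjacency is symmetric and section-local", {
  pos <- rbind(staggered_positions(4, 4, "a"), staggered_positions(4, 4, "b"))
  for (bc in sample(pos$barcode, 8)) {
    for (nb in hex_neighbors(pos, bc)) {
      expect_true(bc %in% hex_neighbors(pos, nb))
      expect_equal(pos$section_id[pos$barcode == nb],
                   pos$section_id[pos$barcode == bc])
    }
  }
  expect_error(hex_neighbors(pos, "nope"), "not found")
})

test_that("region expansion adds exactly the brute-forced outer ring", {
  pos <- staggered_positions(8, 8)
  make_assignment <- function(region_barcodes) {
    a <- pos
    a$region_label <- ifelse(a$barcode %in% region_barcodes, "SN",
                             "unassigned")
    a$selected <- a$region_label == "SN"
    a
  }
  ## single interior spot: itself + its 6 neighbors
  center <- pos$barcode[pos$array_row == 4 & pos$array_col == 8]
  a <- make_assignment(center)
  expect_setequal(expand_region(a, "SN"),
                  c(center, oracle_neighbors(pos, center)))
  expect_length(expand_region(a, "SN"), 7)
  ## two adjacent region spots: 2 + union of their outer neighbors
  nb1 <- oracle_neighbors(pos, center)[1]
  a2 <- make_assignment(c(center, nb1))
  want <- union(c(center, nb1),
                setdiff(union(oracle_neighbors(pos, center),
                              oracle_neighbors(pos, nb1)),
                        c(center, nb1)))
  expect_setequal(expand_region(a2, "SN"), want)
  ## region = whole section: expansion is closed
  a3 <- make_assignment(pos$barcode)
  expect_setequal(expand_region(a3, "SN"), pos$barcode)
  ## absent region: empty set
  expect_length(expand_region(a, "CP"), 0)
})

## tiny hand-built section: 12 spots, 8 genes
toy_section <- function() {
  pos <- staggered_positions(3, 4)
  genes <- c("Th", "Slc6a3", "Slc18a2", glial_markers(), "Prkcd")
  counts <- matrix(0L, length(genes), nrow(pos),
                   dimnames = list(genes, pos$barcode))
  meta <- data.frame(barcode = pos$barcode, section_id = pos$section_id,
                     array_row = pos$array_row, array_col = pos$array_col,
                     has_soma = TRUE, stringsAsFactors = FALSE)
  regions <- rep("SN", nrow(pos))
  list(counts = counts, meta = meta, regions = regions)
}

test_that("the DA marker rule selects and excludes per the stated boundaries", {
  toy <- toy_section()
  ## spot 1: two of three DA markers detected, clean -> selected
  toy$counts[c("Th", "Slc6a3"), 1] <- c(3L, 2L)
  ## spot 2: only Th -> too few markers
  toy$counts["Th", 2] <- 5L
  ## spot 3: all three markers but Gfap above the section 90th pct
  toy$counts[c("Th", "Slc6a3", "Slc18a2"), 3] <- 2L
  toy$counts["Gfap", 3] <- 50L
  ## spot 4: markers fine but no soma
  toy$counts[c("Th", "Slc18a2"), 4] <- 1L
  toy$meta$has_soma[4] <- FALSE

  a <- select_discs(toy$counts, toy$regions, meta = toy$meta)
  expect_true(a$selected[1])
  expect_equal(a$exclusion_reason[1], "none")
  expect_false(a$selected[2])
  expect_equal(a$exclusion_reason[2], "too_few_markers")
  expect_false(a$selected[3])
  expect_equal(a$exclusion_reason[3], "glial_high")
  expect_false(a$selected[4])
  expect_equal(a$exclusion_reason[4], "no_soma")
  ## selected spots always carry reason "none"
  expect_true(all(a$exclusion_reason[a$selected] == "none"))
})

test_that("marker-threshold detection is inclusive and configurable", {
  toy <- toy_section()
  toy$counts[c("Th", "Slc6a3"), 1] <- 1L   # exactly at threshold
  a <- select_discs(toy$counts, toy$regions, meta = toy$meta)
  expect_true(a$selected[1])
  rule2 <- selection_rule(marker_threshold = 2, min_markers_detected = 2)
  a2 <- suppressWarnings(
    select_discs(toy$counts, toy$regions, rule = rule2, meta = toy$meta))
  expect_false(a2$selected[1])
})

test_that("non-DA regions are selected by their region marker; unknowns warn", {
  toy <- toy_section()
  toy$regions[] <- "thalamus"
  toy$counts["Prkcd", 1:3] <- 2L
  ## thalamus markers Prkcd/Ptpn3/Synpo2: only Prkcd present in the toy panel
  rule <- selection_rule(region_marker_map = list(thalamus = "Prkcd"))
  a <- select_discs(toy$counts, toy$regions, rule = rule, meta = toy$meta)
  expect_equal(sum(a$selected), 3)
  expect_true(all(a$exclusion_reason[!a$selected] == "too_few_markers"))
  ## a labelled region with no marker rule yields a warning, not an error
  toy$regions[1] <- "mystery"
  expect_warning(select_discs(toy$counts, toy$regions, rule = rule,
                              meta = toy$meta), "no marker rule")
})

test_that("selection requires marker genes to exist and a soma flag if asked", {
  toy <- toy_section()
  counts2 <- toy$counts[setdiff(rownames(toy$counts), "Slc18a2"), ]
  expect_error(select_discs(counts2, toy$regions, meta = toy$meta),
               "Slc18a2")
  meta2 <- toy$meta
  meta2$has_soma <- NULL
  expect_error(suppressWarnings(
    select_discs(toy$counts, toy$regions, meta = meta2)), "has_soma")
  a <- suppressWarnings(
    select_discs(toy$counts, toy$regions,
                 rule = selection_rule(require_soma_flag = FALSE),
                 meta = meta2))
  expect_s3_class(a, "region_assignment")
})

test_that("selection is invariant to gene order and spot order", {
  sim <- simulate_dataset(small_midbrain_design(n_genes = 30, seed = 21))
  counts <- as.matrix(SummarizedExperiment::assay(sim$se, "counts"))
  meta <- as.data.frame(SummarizedExperiment::colData(sim$se))
  a0 <- select_discs(counts, meta$region_label, meta = meta)
  set.seed(1)
  gperm <- sample(nrow(counts))
  sperm <- sample(ncol(counts))
  a1 <- select_discs(counts[gperm, sperm], meta$region_label[sperm],
                     meta = meta[sperm, ])
  a1 <- a1[match(a0$barcode, a1$barcode), ]
  expect_equal(a0$selected, a1$selected)
  expect_equal(a0$exclusion_reason, a1$exclusion_reason)
})

test_that("selection agrees exactly with generator truth on DA regions", {
  sim <- simulate_dataset(small_midbrain_design(n_genes = 30, seed = 9))
  counts <- SummarizedExperiment::assay(sim$se, "counts")
  meta <- as.data.frame(SummarizedExperiment::colData(sim$se))
  a <- select_discs(sim$se)
  rule <- selection_rule()
  is_da <- meta$region_label %in% c("SN", "VTA")
  meets_markers <- colSums(counts[rule$da_markers, , drop = FALSE] >= 1) >= 2
  glial <- sim$truth$spots$glial
  expected <- unname(is_da & meets_markers & !glial)
  got <- a$selected & is_da
  expect_identical(got, expected)
  expect_true(all(!a$selected[is_da & glial]))
})
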