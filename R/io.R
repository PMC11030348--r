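## On-disk fixture formats: 10x-style triplet bundle (matrix.mtx +
## barcodes.tsv + features.tsv) plus positions and metadata CSVs, and the
## auxiliary activity / human-direction / segment-QC tables.

## MatrixMarket coordinate writer with an integer header (as emitted by 10x
## pipelines; Matrix::writeMM only writes `real`, hence a local writer).
write_mtx_integer <- function(counts, path) {
  m <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                               "generalMatrix"), "TsparseMatrix")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "%",
               paste(nrow(m), ncol(m), length(m@x))), con)
  if (length(m@x))
    writeLines(paste(m@i + 1L, m@j + 1L, as.integer(m@x)), con)
  invisible(path)
}

## Matrix::readMM wrapped so malformed triplets raise an error naming the
## file and the offending line.
read_mtx <- function(path) {
  out <- tryCatch(Matrix::readMM(path), error = function(e) e)
  if (!inherits(out, "error")) return(out)
  lines <- readLines(path, warn = FALSE)
  body <- which(!startsWith(lines, "%"))
  bad <- NA_integer_
  for (i in body) {
    fields <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    vals <- suppressWarnings(as.numeric(fields))
    if (length(fields) < 2 || length(fields) > 3 || anyNA(vals)) {
      bad <- i
      break
    }
  }
  stop("malformed MatrixMarket triplet in '", path, "'",
       if (!is.na(bad)) paste0(" at line ", bad),
       ": ", conditionMessage(out), call. = FALSE)
}

#' Write a spot count matrix (and companions) as a 10x-style fixture bundle
#'
#' Emits `matrix.mtx` (1-based MatrixMarket integer coordinate),
#' `barcodes.tsv`, `features.tsv` (gene id, symbol, feature type; negative
#' probes flagged by type), `positions.csv`
#' (`barcode,array_row,array_col,px_x,px_y,section_id`) and `metadata.csv`
#' (`barcode,animal_id,group,region_label` plus the optional `has_soma`
#' flag). Given a full [simulate_dataset()] result, also writes
#' `activity.csv`, `human_directions.csv` and `segment_qc.csv`.
#' [read_fixture_bundle()] is its exact inverse on integer counts.
#'
#' @param x a `SummarizedExperiment` of counts with the generator's
#'   `colData`/`rowData` layout, or a `spothits_sim` object.
#' @param dir_path writable directory (created if absent).
#' @return invisibly, a manifest data.frame (file, rows, md5).
#' @export
write_fixture_bundle <- function(x, dir_path) {
  sim <- NULL
  if (inherits(x, "spothits_sim")) {
    sim <- x
    x <- x$se
  }
  stopifnot(methods::is(x, "SummarizedExperiment"))
  dir.create(dir_path, showWarnings = FALSE, recursive = TRUE)

  cd <- as.data.frame(SummarizedExperiment::colData(x))
  rd <- as.data.frame(SummarizedExperiment::rowData(x))
  counts <- SummarizedExperiment::assay(x, "counts")

  write_mtx_integer(counts, file.path(dir_path, "matrix.mtx"))
  writeLines(cd$barcode, file.path(dir_path, "barcodes.tsv"))
  utils::write.table(rd[, c("gene_id", "symbol", "feature_type")],
                     file.path(dir_path, "features.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  utils::write.csv(cd[, c("barcode", "array_row", "array_col",
                          "px_x", "px_y", "section_id")],
                   file.path(dir_path, "positions.csv"), row.names = FALSE,
                   quote = FALSE)
  meta_cols <- c("barcode", "animal_id", "group", "region_label",
                 intersect("has_soma", names(cd)))
  utils::write.csv(cd[, meta_cols], file.path(dir_path, "metadata.csv"),
                   row.names = FALSE, quote = FALSE)

  if (!is.null(sim)) {
    utils::write.csv(sim$activity, file.path(dir_path, "activity.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(sim$human, file.path(dir_path, "human_directions.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(sim$segment_qc, file.path(dir_path, "segment_qc.csv"),
                     row.names = FALSE, quote = FALSE)
  }

  files <- list.files(dir_path)
  manifest <- data.frame(
    file = files,
    bytes = file.size(file.path(dir_path, files)),
    md5 = unname(tools::md5sum(file.path(dir_path, files))),
    stringsAsFactors = FALSE)
  invisible(manifest)
}

#' Read a fixture bundle written by [write_fixture_bundle()]
#'
#' @param dir_path bundle directory.
#' @return a `SummarizedExperiment` with integer counts and the bundle's
#'   spot/feature metadata; auxiliary tables present in the directory
#'   (`activity.csv`, `human_directions.csv`, `segment_qc.csv`) are attached
#'   in `metadata()`.
#' @export
read_fixture_bundle <- function(dir_path) {
  need <- c("matrix.mtx", "barcodes.tsv", "features.tsv", "positions.csv",
            "metadata.csv")
  missing <- need[!file.exists(file.path(dir_path, need))]
  if (length(missing))
    stop("fixture bundle is missing: ", paste(missing, collapse = ", "),
         call. = FALSE)

  counts <- as.matrix(read_mtx(file.path(dir_path, "matrix.mtx")))
  storage.mode(counts) <- "integer"
  barcodes <- readLines(file.path(dir_path, "barcodes.tsv"))
  feats <- utils::read.delim(file.path(dir_path, "features.tsv"),
                             header = FALSE,
                             col.names = c("gene_id", "symbol", "feature_type"),
                             stringsAsFactors = FALSE)
  feats$is_negative_probe <- feats$feature_type == "Negative Probe"
  if (nrow(feats) != nrow(counts) || length(barcodes) != ncol(counts))
    stop("fixture bundle dimensions disagree: matrix is ",
         nrow(counts), "x", ncol(counts), " but features/barcodes give ",
         nrow(feats), "/", length(barcodes), call. = FALSE)
  dimnames(counts) <- list(feats$symbol, barcodes)

  pos <- utils::read.csv(file.path(dir_path, "positions.csv"),
                         stringsAsFactors = FALSE)
  meta <- utils::read.csv(file.path(dir_path, "metadata.csv"),
                          stringsAsFactors = FALSE)
  cd <- merge(meta, pos, by = "barcode", sort = FALSE)
  cd <- cd[match(barcodes, cd$barcode), ]
  rownames(cd) <- cd$barcode

  extras <- list()
  for (f in c("activity", "human_directions", "segment_qc")) {
    p <- file.path(dir_path, paste0(f, ".csv"))
    if (file.exists(p)) extras[[f]] <- utils::read.csv(p, stringsAsFactors = FALSE)
  }

  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(feats, row.names = feats$symbol),
    colData = S4Vectors::DataFrame(cd, row.names = cd$barcode),
    metadata = extras)
}
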