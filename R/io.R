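#' Read a 10x-style count matrix directory
#'
#' Parses `matrix.mtx`, `barcodes.tsv` and `features.tsv` (gzipped or
#' plain). Orientation is normalized to genes x cells; if the MTX is
#' transposed relative to the annotation files it is flipped. Duplicate
#' gene names are made unique deterministically with [make.unique()].
#'
#' @param dir directory containing the triple.
#' @return a `dgCMatrix`, genes x cells, with gene/cell dimnames.
#' @export
read_counts_10x <- function(dir) {
  find <- function(base) {
    for (f in c(file.path(dir, base), file.path(dir, paste0(base, ".gz"))))
      if (file.exists(f)) return(f)
    stop(sprintf("missing %s(.gz) in %s", base, dir), call. = FALSE)
  }
  mtx_f <- find("matrix.mtx")
  open_maybe_gz <- function(f) if (grepl("\\.gz$", f)) gzfile(f) else file(f)
  m <- Matrix::readMM(open_maybe_gz(mtx_f))
  read_tsv1 <- function(f)
    utils::read.table(open_maybe_gz(f), sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE, quote = "", comment.char = "")
  bc <- read_tsv1(find("barcodes.tsv"))[[1]]
  ft <- read_tsv1(find("features.tsv"))
  gene_names <- if (ncol(ft) >= 2) ft[[2]] else ft[[1]]
  if (nrow(m) == length(gene_names) && ncol(m) == length(bc)) {
    # genes x cells already
  } else if (nrow(m) == length(bc) && ncol(m) == length(gene_names)) {
    m <- Matrix::t(m)
  } else {
    stop(sprintf("MTX dims %dx%d match neither %d features x %d barcodes nor its transpose",
                 nrow(m), ncol(m), length(gene_names), length(bc)), call. = FALSE)
  }
  dimnames(m) <- list(make.unique(gene_names), bc)
  methods::as(m, "CsparseMatrix")
}

#' Write a count matrix as a 10x-style directory
#'
#' @param counts genes x cells matrix with dimnames.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_counts_10x <- function(counts, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(methods::as(Matrix::Matrix(counts, sparse = TRUE), "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  utils::write.table(data.frame(id = rownames(counts), name = rownames(counts),
                                type = "Gene Expression"),
                     file.path(dir, "features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' Read ROI traces from CSV
#'
#' Expected layout: first column `time_s`, one column per ROI.
#' @param path CSV file.
#' @return data.frame with `time_s` first.
#' @export
read_traces_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "time_s") stop("first column must be time_s", call. = FALSE)
  df
}

#' Write ROI traces to CSV
#' @param traces data.frame, `time_s` first column.
#' @param path output CSV.
#' @export
write_traces_csv <- function(traces, path) {
  stopifnot(names(traces)[1] == "time_s")
  utils::write.csv(traces, path, row.names = FALSE)
  invisible(path)
}

#' Read a 3D scene from JSON
#'
#' Schema: object with `cells` (array of records: id, type, cx, cy, cz,
#' ax, ay, az — center and semi-axes in um), `varicosities` (array of
#' records: id, fiber_class, x, y, z) and optional `voxel_size_um`.
#'
#' @param path JSON file.
#' @return an `ens_scene` list.
#' @export
read_scene_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  stopifnot(is.data.frame(obj$cells), is.data.frame(obj$varicosities))
  scene <- list(cells = obj$cells, varicosities = obj$varicosities,
                voxel_size_um = obj$voxel_size_um %||% NA_real_)
  class(scene) <- "ens_scene"
  scene
}

#' Write a 3D scene to JSON
#' @param scene an `ens_scene`.
#' @param path output JSON file.
#' @export
write_scene_json <- function(scene, path) {
  stopifnot(inherits(scene, "ens_scene"))
  jsonlite::write_json(list(cells = scene$cells,
                            varicosities = scene$varicosities,
                            voxel_size_um = scene$voxel_size_um),
                       path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}
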