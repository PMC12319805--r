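# NIfTI / TSV / JSON interchange. NIfTI handling goes through RNifti; only
# thin wrappers that attach this pipeline's metadata live here.

#' Write and read volumes as NIfTI-1
#'
#' Volumes are written in RAS+ orientation with the geometry's voxel sizes.
#'
#' @param vol 3D or 4D numeric array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxel_size Voxel sizes in mm (length 3), e.g.
#'   `geometry$voxel_size`.
#' @param tr Repetition time in seconds for 4D volumes (optional).
#' @return `write_volume` returns `path` invisibly; `read_volume` returns
#'   a plain numeric array with a `voxel_size` attribute.
#' @export
write_volume <- function(vol, path, voxel_size = c(1, 1, 1), tr = NULL) {
  img <- RNifti::asNifti(vol * 1)
  nd <- length(dim(vol))
  pix <- c(voxel_size, if (nd == 4) (tr %||% 1))[seq_len(nd)]
  RNifti::pixdim(img) <- pix
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  attr(arr, "voxel_size") <- RNifti::pixdim(img)[seq_len(min(3, length(dim(arr))))]
  arr
}

#' Level-map I/O as integer-coded NIfTI plus JSON sidecar
#'
#' Binary level maps are stored as one multi-label volume with integer codes
#' 1..7 for L1..S2 and a JSON sidecar naming the codes.
#'
#' @param map A binary `level_map`.
#' @param path Output NIfTI path; the sidecar replaces the extension with
#'   `.json`.
#' @return `write_level_map` returns `path` invisibly; `read_level_map`
#'   returns a binary `level_map`.
#' @export
write_level_map <- function(map, path) {
  stopifnot(inherits(map, "level_map"))
  if (map$kind != "binary") stopf("only binary level maps are written as labels")
  lab <- array(0L, map$grid_shape)
  for (i in seq_along(map$levels)) lab[map$levels[[i]]] <- i
  write_volume(lab, path, voxel_size = map$voxel_size %||% c(1, 1, 1))
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(
    list(codes = stats::setNames(as.list(seq_along(map$levels)), names(map$levels))),
    sidecar, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_level_map
#' @export
read_level_map <- function(path) {
  lab <- read_volume(path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  codes <- if (file.exists(sidecar))
    unlist(jsonlite::fromJSON(sidecar)$codes) else
    stats::setNames(seq_along(LEVEL_NAMES), LEVEL_NAMES)
  levels <- lapply(codes, function(code) {
    m <- lab == code
    dim(m) <- dim(lab)[seq_len(3)]
    m
  })
  names(levels) <- names(codes)
  new_level_map(levels, kind = "binary", grid_shape = dim(lab)[seq_len(3)],
                voxel_size = attr(lab, "voxel_size"))
}

#' Motion-parameter trace I/O (6-column TSV)
#'
#' @param motion n_volumes x 6 matrix (tx ty tz mm, rx ry rz deg).
#' @param path TSV path.
#' @return `write_motion_tsv` returns `path` invisibly; `read_motion_tsv`
#'   the matrix.
#' @export
write_motion_tsv <- function(motion, path) {
  utils::write.table(motion, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_motion_tsv
#' @export
read_motion_tsv <- function(path) {
  as.matrix(utils::read.delim(path))
}

#' Root-entry-zone annotation I/O (JSON)
#'
#' @param rez Named numeric vector over [root_names()], or the list form
#'   accepted by [levels_from_rez()].
#' @param path JSON path.
#' @return `write_rez_json` returns `path` invisibly; `read_rez_json` the
#'   list form (`entries`, `unit`, optional `slice_thickness_mm`).
#' @export
write_rez_json <- function(rez, path) {
  if (!is.list(rez) || is.null(rez$entries))
    rez <- list(entries = as.list(rez), unit = "mm")
  jsonlite::write_json(rez, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_rez_json
#' @export
read_rez_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  obj$entries <- unlist(obj$entries)
  obj
}

#' Write a QC report as JSON
#'
#' @param report A `qc_report`.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_qc_json <- function(report, path) {
  stopifnot(inherits(report, "qc_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' Write a projectome as CSV
#'
#' @param projectome A `projectome` data.frame.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_projectome_csv <- function(projectome, path) {
  utils::write.csv(projectome, path, row.names = FALSE)
  invisible(path)
}
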