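# Minimal NIfTI-1 (.nii, single file, little-endian) I/O: enough to
# exchange 3D masks and 4D float time series with standard neuroimaging
# tools. Data are written as float32 with no scaling.

#' Write a 3D/4D array as an uncompressed NIfTI-1 file
#'
#' @param arr numeric array, 3 or 4 dimensions.
#' @param path output path (`.nii`).
#' @param pixdim voxel size in mm, length 3 (default 2 mm isotropic).
#' @param tr repetition time in s for the 4th dimension (default 2).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(arr, path, pixdim = c(2, 2, 2), tr = 2) {
  nd <- length(dim(arr))
  stopifnot(nd %in% c(3L, 4L))
  dims <- dim(arr)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wi(348L, 4)                                   # sizeof_hdr
  writeBin(raw(36), con)                        # data_type..dim_info (unused)
  wi(c(nd, dims, rep(1L, 7 - nd)), 2)           # dim[8]
  writeBin(raw(14), con)                        # intent_p1..intent_code
  wi(16L, 2)                                    # datatype: float32
  wi(32L, 2)                                    # bitpix
  wi(0L, 2)                                     # slice_start
  wf(c(1, pixdim, tr, 0, 0, 0))                 # pixdim[8] (qfac 1)
  wf(352)                                       # vox_offset
  wf(1); wf(0)                                  # scl_slope, scl_inter
  writeBin(raw(3), con)                         # slice_end, slice_code, xyzt_units
  writeBin(as.raw(c(0x0aL)), con)               # xyzt_units: mm|s -> 0x0a
  wf(0); wf(0)                                  # cal_max, cal_min
  wf(0); wf(0)                                  # slice_duration, toffset
  wi(0L, 4); wi(0L, 4)                          # glmax, glmin
  writeBin(raw(80 + 24), con)                   # descrip, aux_file
  wi(0L, 2); wi(0L, 2)                          # qform_code, sform_code
  writeBin(raw(18 * 4), con)                    # quatern/qoffset/srow
  writeBin(raw(16), con)                        # intent_name (bytes 328-343)
  writeBin(c(charToRaw("n+1"), as.raw(0)), con) # magic at byte 344
  writeBin(raw(4), con)                         # extension flag
  writeBin(as.numeric(arr), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read an uncompressed NIfTI-1 file
#'
#' Supports the common data types (uint8, int16, int32, float32, float64),
#' applying `scl_slope`/`scl_inter` when set.
#'
#' @param path `.nii` file.
#' @return numeric array with the file's dimensions.
#' @export
read_nifti <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_size <- readBin(con, "integer", 1, 4, endian = "little")
  if (hdr_size != 348L) stop("read_nifti: not a little-endian NIfTI-1 file")
  seek(con, 40)
  dims <- readBin(con, "integer", 8, 2, endian = "little")
  nd <- dims[1]
  seek(con, 70)
  datatype <- readBin(con, "integer", 1, 2, endian = "little")
  seek(con, 108)
  vox_offset <- readBin(con, "numeric", 1, 4, endian = "little")
  scl_slope <- readBin(con, "numeric", 1, 4, endian = "little")
  scl_inter <- readBin(con, "numeric", 1, 4, endian = "little")
  n <- prod(dims[2:(nd + 1)])
  seek(con, vox_offset)
  x <- switch(as.character(datatype),
    "2"  = readBin(con, "integer", n, 1, signed = FALSE, endian = "little"),
    "4"  = readBin(con, "integer", n, 2, endian = "little"),
    "8"  = readBin(con, "integer", n, 4, endian = "little"),
    "16" = readBin(con, "numeric", n, 4, endian = "little"),
    "64" = readBin(con, "numeric", n, 8, endian = "little"),
    stop("read_nifti: unsupported datatype ", datatype))
  x <- as.numeric(x)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    x <- x * scl_slope + scl_inter
  array(x, dim = dims[2:(nd + 1)])
}

#' Export a simulated dataset as NIfTI + events CSV
#'
#' Voxels have no real geometry; each ROI is laid out as a slab along the
#' z axis (x = voxel index within ROI), which keeps ROIs disjoint in the
#' exported mask. Writes `bold.nii` (4D), `roi_mask.nii` (3D integer
#' codes), `events.csv`, and `motion.txt`.
#'
#' @param dataset a `roi_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "roi_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rois <- unique(dataset$roi)
  nmax <- max(table(dataset$roi))
  TT <- ncol(dataset$data)
  vol4 <- array(0, dim = c(nmax, 1, length(rois), TT))
  mask <- array(0, dim = c(nmax, 1, length(rois)))
  for (zi in seq_along(rois)) {
    vv <- which(dataset$roi == rois[zi])
    vol4[seq_along(vv), 1, zi, ] <- dataset$data[vv, ]
    mask[seq_along(vv), 1, zi] <- zi
  }
  write_nifti(vol4, file.path(dir, "bold.nii"))
  write_nifti(mask, file.path(dir, "roi_mask.nii"))
  ev <- if (dataset$type == "block") dataset$design$blocks else dataset$design$events
  write.csv(ev, file.path(dir, "events.csv"), row.names = FALSE)
  utils::write.table(dataset$motion, file.path(dir, "motion.txt"),
                     row.names = FALSE, col.names = FALSE)
  invisible(dir)
}
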