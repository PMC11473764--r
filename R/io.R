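#' Read a CT volume from disk
#'
#' Reads either a NIfTI-1 file or a directory containing one uncompressed
#' DICOM series. DICOM pixel values are rescaled to HU as
#' `raw * RescaleSlope + RescaleIntercept` (tags (0028,1053) and
#' (0028,1052)); NIfTI volumes are assumed to already store HU. Slices of a
#' DICOM series are sorted along z and must be uniformly spaced; a directory
#' mixing several SeriesInstanceUIDs is rejected with the conflicting UIDs
#' named.
#'
#' @param path a NIfTI file or a DICOM directory.
#' @param format `"auto"`, `"nifti"` or `"dicom"`.
#' @param hu_limits representable HU range stored on the volume.
#' @param spacing_tol relative tolerance on slice-spacing uniformity.
#' @return A [ct_volume].
#' @export
read_ct_volume <- function(path, format = c("auto", "nifti", "dicom"),
                           hu_limits = c(-1024, 3071), spacing_tol = 1e-3) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (dir.exists(path)) "dicom" else "nifti"
  if (format == "nifti") read_nifti_volume(path, hu_limits)
  else read_dicom_series(path, hu_limits, spacing_tol)
}

read_nifti_volume <- function(path, hu_limits = c(-1024, 3071)) {
  img <- RNifti::readNifti(path)
  vals <- array(as.numeric(img), dim = dim(img))
  if (length(dim(vals)) == 2L) dim(vals) <- c(dim(vals), 1L)
  if (length(dim(vals)) != 3L) stop("expected a 3-D NIfTI volume")
  pd <- RNifti::pixdim(img)
  hdr <- RNifti::niftiHeader(img)
  # qoffset stores the world position of the first voxel centre
  origin <- c(hdr$qoffset_x, hdr$qoffset_y, hdr$qoffset_z)
  grid <- voxel_grid(pd[1:3], dim(vals), origin)
  ct_volume(vals, grid, hu_limits, metadata = list(source = path))
}

#' Write a volume or mask to NIfTI-1
#'
#' The voxel grid is stored in pixdim and the qform offset, so a write/read
#' round trip through [read_ct_volume] reproduces values and geometry.
#'
#' @param volume a [ct_volume], [voi_mask], or map list with `values`+`grid`.
#' @param path output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_nifti_volume <- function(volume, path) {
  vals <- if (inherits(volume, "voi_mask")) volume$included * 1L else volume$values
  g <- volume$grid
  img <- RNifti::asNifti(array(as.numeric(vals), dim = g$shape))
  img <- RNifti::`pixdim<-`(img, g$spacing_mm)
  hdr <- list(qoffset_x = g$origin_mm[1], qoffset_y = g$origin_mm[2],
              qoffset_z = g$origin_mm[3], qform_code = 1L)
  img <- RNifti::asNifti(img, hdr)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read a VOI mask from a NIfTI label image
#'
#' Nonzero voxels are included. If `grid` is supplied the mask geometry is
#' checked against it.
#'
#' @param path NIfTI file.
#' @param grid optional [voxel_grid] the mask must match.
#' @return A [voi_mask].
#' @export
read_voi_mask <- function(path, grid = NULL) {
  vol <- read_nifti_volume(path, hu_limits = c(-1e12, 1e12))
  m <- voi_mask(vol$values != 0, vol$grid)
  if (!is.null(grid)) stop_if_grid_mismatch(m$grid, grid, "mask and target volume")
  m
}

## ---- minimal DICOM series reader -------------------------------------------
## Part-10 files, explicit or implicit VR little endian, uncompressed
## 16-bit integer pixel data. Only the tags needed for CT geometry and HU
## rescaling are interpreted.

read_uint <- function(raw, little = TRUE) {
  sum(as.numeric(raw) * 256^(if (little) seq_along(raw) - 1 else rev(seq_along(raw) - 1)))
}

dicom_read_file <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  bytes <- readBin(con, "raw", n = file.size(path))
  if (length(bytes) < 132 || rawToChar(bytes[129:132]) != "DICM")
    stop("not a part-10 DICOM file: ", path)
  pos <- 133L
  explicit <- TRUE
  elems <- list()
  n <- length(bytes)
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (pos + 7L <= n) {
    group <- read_uint(bytes[pos:(pos + 1L)]); elem <- read_uint(bytes[(pos + 2L):(pos + 3L)])
    pos <- pos + 4L
    vr <- rawToChar(bytes[pos:(pos + 1L)])
    if (explicit && grepl("^[A-Z]{2}$", vr)) {
      if (vr %in% long_vrs) {
        len <- read_uint(bytes[(pos + 4L):(pos + 7L)]); pos <- pos + 8L
      } else {
        len <- read_uint(bytes[(pos + 2L):(pos + 3L)]); pos <- pos + 4L
      }
    } else {
      vr <- NA_character_
      len <- read_uint(bytes[pos:(pos + 3L)]); pos <- pos + 4L
      explicit <- FALSE
    }
    if (group == 0x0002 && elem == 0x0010) {
      ts <- sub("\\s+$", "", rawToChar(bytes[pos:(pos + len - 1L)]))
      ts <- gsub("\\0", "", ts)
      explicit <- !identical(ts, "1.2.840.10008.1.2")
      if (grepl("1.2.840.10008.1.2.4|1.2.840.10008.1.2.5|1.2.840.10008.1.2.1.99", ts, fixed = FALSE))
        stop("compressed DICOM transfer syntax not supported: ", ts)
    }
    if (len == 0xFFFFFFFF) stop("undefined-length DICOM elements not supported")
    key <- sprintf("%04x,%04x", group, elem)
    elems[[key]] <- list(vr = vr, raw = if (len > 0) bytes[pos:(pos + len - 1L)] else raw(0))
    pos <- pos + len
    if (group == 0x7FE0 && elem == 0x0010) break
  }
  elems
}

dicom_str <- function(elems, key, default = NULL) {
  e <- elems[[key]]
  if (is.null(e)) return(default)
  gsub("\\0", "", sub("\\s+$", "", rawToChar(e$raw)))
}

dicom_num <- function(elems, key, default = NULL) {
  s <- dicom_str(elems, key)
  if (is.null(s) || !nzchar(s)) return(default)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

dicom_us <- function(elems, key, default = NULL) {
  e <- elems[[key]]
  if (is.null(e)) return(default)
  read_uint(e$raw[1:2])
}

read_dicom_series <- function(dir, hu_limits = c(-1024, 3071), spacing_tol = 1e-3) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0L) stop("no files in DICOM directory: ", dir)
  slices <- lapply(files, dicom_read_file)
  uids <- vapply(slices, dicom_str, "", key = "0020,000e", default = "")
  if (length(unique(uids)) > 1L)
    stop("directory mixes DICOM series; SeriesInstanceUIDs found: ",
         paste(unique(uids), collapse = ", "))
  modality <- dicom_str(slices[[1]], "0008,0060", "")
  if (!identical(modality, "CT"))
    warning("DICOM Modality is '", modality, "', not CT")
  rows <- dicom_us(slices[[1]], "0028,0010")
  cols <- dicom_us(slices[[1]], "0028,0011")
  bits <- dicom_us(slices[[1]], "0028,0100", 16)
  signed <- identical(dicom_us(slices[[1]], "0028,0103", 0), 1)
  if (bits != 16) stop("only 16-bit DICOM pixel data supported")
  ps <- dicom_num(slices[[1]], "0028,0030")
  thick <- dicom_num(slices[[1]], "0018,0050", NA_real_)
  zpos <- vapply(slices, function(e) {
    ipp <- dicom_num(e, "0020,0032")
    if (is.null(ipp)) dicom_num(e, "0020,1041", 0)[1] else ipp[3]
  }, 0)
  ord <- order(zpos)
  slices <- slices[ord]; zpos <- zpos[ord]
  nz <- length(slices)
  dz <- if (nz > 1L) diff(zpos) else thick
  if (nz > 1L && (max(dz) - min(dz)) > spacing_tol * max(abs(dz)))
    stop("non-uniform DICOM slice spacing: ", paste(signif(unique(dz), 6), collapse = ", "))
  dzv <- if (nz > 1L) mean(dz) else if (is.finite(thick)) thick else 1
  ipp1 <- dicom_num(slices[[1]], "0020,0032", c(0, 0, zpos[1]))
  vals <- array(0, c(cols, rows, nz))
  for (k in seq_len(nz)) {
    e <- slices[[k]]
    slope <- dicom_num(e, "0028,1053", 1)[1]
    inter <- dicom_num(e, "0028,1052", 0)[1]
    px <- readBin(e[["7fe0,0010"]]$raw, "integer", n = rows * cols, size = 2,
                  signed = signed, endian = "little")
    if (!signed) px <- as.numeric(px)
    # DICOM stores row-major (x fastest within a row? columns vary fastest)
    m <- matrix(px, nrow = cols, ncol = rows)  # column index = image row
    vals[, , k] <- m * slope + inter
  }
  grid <- voxel_grid(c(ps[2], ps[1], dzv), c(cols, rows, nz), c(ipp1[1], ipp1[2], zpos[1]))
  md <- list(source = dir, modality = modality,
             slice_thickness_mm = if (is.finite(thick)) thick else dzv,
             series_uid = uids[1])
  kvp <- dicom_num(slices[[1]], "0018,0060")
  if (!is.null(kvp)) md$kvp <- kvp[1]
  kern <- dicom_str(slices[[1]], "0018,1210")
  if (!is.null(kern)) md$kernel <- kern
  scanner <- dicom_str(slices[[1]], "0008,1090")
  if (!is.null(scanner)) md$scanner <- scanner
  ct_volume(vals, grid, hu_limits, md)
}
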