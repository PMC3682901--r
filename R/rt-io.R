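# DICOM-RT input/output on top of the minimal codec in dicom-core.R.
# Geometry convention throughout: LPS patient coordinates in mm, voxel array
# stored (x, y, z) with x fastest, origin at the center of voxel (0,0,0).

#' Read an axial CT series from a directory
#'
#' Reads every DICOM file in `directory`, checks that they form one coherent
#' axial series (single frame of reference, uniform inter-slice gap), sorts
#' slices by spatial position along the slice normal, and applies the HU
#' rescale (slope/intercept).
#'
#' @param directory directory containing one CT series.
#' @return An [image_volume()] in Hounsfield units.
#' @export
read_ct_series <- function(directory) {
  files <- list.files(directory, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0L) stop("no files in CT series directory: ", directory)
  slices <- lapply(files, dcm_read_file)
  modal <- vapply(slices, function(ds) dcm_get(ds, "0008,0060", ""), "")
  slices <- slices[modal == "CT"]
  if (length(slices) == 0L) stop("no CT instances in ", directory)
  frames <- vapply(slices, function(ds) dcm_get(ds, "0020,0052", ""), "")
  if (length(unique(frames)) != 1L)
    stop("mixed frames of reference in CT series: ",
         paste(unique(frames), collapse = ", "))
  iop <- dcm_require(slices[[1L]], "0020,0037", "ImageOrientationPatient")
  row_dir <- iop[1:3]; col_dir <- iop[4:6]
  normal <- c(row_dir[2L] * col_dir[3L] - row_dir[3L] * col_dir[2L],
              row_dir[3L] * col_dir[1L] - row_dir[1L] * col_dir[3L],
              row_dir[1L] * col_dir[2L] - row_dir[2L] * col_dir[1L])
  ipp <- t(vapply(slices, function(ds)
    dcm_require(ds, "0020,0032", "ImagePositionPatient"), numeric(3)))
  pos <- as.numeric(ipp %*% normal)
  ord <- order(pos)
  slices <- slices[ord]; ipp <- ipp[ord, , drop = FALSE]; pos <- pos[ord]
  nz <- length(slices)
  if (nz > 1L) {
    gaps <- diff(pos)
    if (any(gaps <= 0))
      stop("duplicate or non-advancing slice positions in CT series")
    if (diff(range(gaps)) > 1e-3)
      stop(sprintf(paste0("irregular slice spacing in CT series: gaps range ",
                          "from %.4f to %.4f mm"), min(gaps), max(gaps)))
    dz <- mean(gaps)
  } else {
    dz <- dcm_get(slices[[1L]], "0018,0050", 1)
  }
  ps <- dcm_require(slices[[1L]], "0028,0030", "PixelSpacing")
  rows <- dcm_require(slices[[1L]], "0028,0010", "Rows")
  cols <- dcm_require(slices[[1L]], "0028,0011", "Columns")
  vox <- array(0, dim = c(cols, rows, nz))
  for (k in seq_len(nz)) {
    ds <- slices[[k]]
    signed <- isTRUE(dcm_get(ds, "0028,0103", 0L) == 1L)
    px <- dcm_decode_pixels16(dcm_require(ds, "7FE0,0010", "PixelData"),
                              signed = signed)
    slope <- dcm_get(ds, "0028,1053", 1)
    intercept <- dcm_get(ds, "0028,1052", 0)
    vox[, , k] <- matrix(px * slope + intercept, nrow = cols, ncol = rows)
  }
  image_volume(vox,
               origin = ipp[1L, ],
               spacing = c(ps[2L], ps[1L], dz), # PixelSpacing is (row, col)
               orientation = cbind(row_dir, col_dir, normal),
               frame_of_reference = frames[1L])
}

#' Write an [image_volume()] as a DICOM CT series
#'
#' One file per axial slice, explicit VR little endian, signed 16-bit pixels
#' with identity rescale (HU values are rounded to the nearest integer, as CT
#' scanners emit them).
#'
#' @param vol an `ImageVolume` in HU.
#' @param directory output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_ct_series <- function(vol, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  d <- dim(vol$voxels)
  frame_uid <- if (nzchar(vol$frame_of_reference)) vol$frame_of_reference
               else dcm_new_uid()
  study_uid <- dcm_new_uid(); series_uid <- dcm_new_uid()
  iop <- c(vol$orientation[, 1L], vol$orientation[, 2L])
  paths <- character(d[3L])
  for (k in seq_len(d[3L])) {
    ipp <- index_to_phys(vol, c(0, 0, k - 1))[1L, ]
    sop_uid <- dcm_new_uid()
    els <- list(
      dcm_element(0x0008L, 0x0016L, "UI", DCM_SOP_CT),
      dcm_element(0x0008L, 0x0018L, "UI", sop_uid),
      dcm_element(0x0008L, 0x0060L, "CS", "CT"),
      dcm_element(0x0018L, 0x0050L, "DS", fmt_ds(vol$spacing[3L])),
      dcm_element(0x0020L, 0x000DL, "UI", study_uid),
      dcm_element(0x0020L, 0x000EL, "UI", series_uid),
      dcm_element(0x0020L, 0x0013L, "IS", as.character(k)),
      dcm_element(0x0020L, 0x0032L, "DS", fmt_ds(ipp)),
      dcm_element(0x0020L, 0x0037L, "DS", fmt_ds(iop)),
      dcm_element(0x0020L, 0x0052L, "UI", frame_uid),
      dcm_element(0x0028L, 0x0002L, "US", 1L),
      dcm_element(0x0028L, 0x0004L, "CS", "MONOCHROME2"),
      dcm_element(0x0028L, 0x0010L, "US", d[2L]), # Rows = ny
      dcm_element(0x0028L, 0x0011L, "US", d[1L]), # Columns = nx
      dcm_element(0x0028L, 0x0030L, "DS",
                  fmt_ds(c(vol$spacing[2L], vol$spacing[1L]))),
      dcm_element(0x0028L, 0x0100L, "US", 16L),
      dcm_element(0x0028L, 0x0101L, "US", 16L),
      dcm_element(0x0028L, 0x0102L, "US", 15L),
      dcm_element(0x0028L, 0x0103L, "US", 1L),
      dcm_element(0x0028L, 0x1052L, "DS", "0"),
      dcm_element(0x0028L, 0x1053L, "DS", "1"),
      dcm_element(0x7FE0L, 0x0010L, "OW",
                  dcm_encode_pixels16(vol$voxels[, , k], signed = TRUE))
    )
    paths[k] <- file.path(directory, sprintf("ct_%03d.dcm", k))
    dcm_write_file(paths[k], els, DCM_SOP_CT, sop_uid)
  }
  invisible(paths)
}

# decimal-string formatting: DICOM DS is limited to 16 bytes per value
fmt_ds <- function(x) {
  s <- formatC(x, format = "fg", digits = 10, width = 1)
  trimws(s)
}

#' Read an RT Structure Set into a list of [roi()] objects
#'
#' Vertex coordinates are kept in physical mm exactly as stored. When the
#' structure set references a different frame of reference than
#' `frame_of_reference`, each ROI is flagged `"frame_mismatch"` and a warning
#' is raised (never a silent pass).
#'
#' @param file RTSTRUCT DICOM file.
#' @param frame_of_reference expected frame identifier; `NULL` to skip the
#'   check.
#' @return named list of `ROI` objects.
#' @export
read_rtstruct <- function(file, frame_of_reference = NULL) {
  ds <- dcm_read_file(file)
  if (!identical(dcm_get(ds, "0008,0060", ""), "RTSTRUCT"))
    stop("not an RT Structure Set: ", file)
  ref_seq <- dcm_get(ds, "3006,0010", list())
  frame <- if (length(ref_seq)) dcm_get(ref_seq[[1L]], "0020,0052", "") else ""
  mismatch <- !is.null(frame_of_reference) &&
    !identical(frame, frame_of_reference)
  if (mismatch)
    warning("structure set frame of reference '", frame,
            "' does not match expected '", frame_of_reference, "'")
  roi_defs <- dcm_get(ds, "3006,0020", list())
  contour_sets <- dcm_get(ds, "3006,0039", list())
  by_number <- list()
  for (item in contour_sets) {
    num <- dcm_get(item, "3006,0084", NA_integer_)
    by_number[[as.character(num)]] <- dcm_get(item, "3006,0040", list())
  }
  out <- list()
  for (def in roi_defs) {
    num <- dcm_get(def, "3006,0022", NA_integer_)
    name <- dcm_get(def, "3006,0026", paste0("ROI_", num))
    cts <- by_number[[as.character(num)]]
    contours <- list()
    for (ct in cts) {
      data <- dcm_get(ct, "3006,0050", numeric(0))
      if (length(data) >= 9L)
        contours[[length(contours) + 1L]] <- matrix(data, ncol = 3L,
                                                    byrow = TRUE)
    }
    r <- roi(name, contours, frame_of_reference = frame)
    if (mismatch) r$flags <- union(r$flags, "frame_mismatch")
    out[[name]] <- r
  }
  out
}

#' Write ROIs as an RT Structure Set
#'
#' @param rois list of [roi()] objects.
#' @param path output file.
#' @param frame_of_reference frame identifier to reference; defaults to the
#'   first ROI's frame.
#' @export
write_rtstruct <- function(rois, path, frame_of_reference = NULL) {
  if (is.null(frame_of_reference)) {
    frame_of_reference <- ""
    for (r in rois) if (nzchar(r$frame_of_reference)) {
      frame_of_reference <- r$frame_of_reference; break
    }
    if (!nzchar(frame_of_reference)) frame_of_reference <- dcm_new_uid()
  }
  sop_uid <- dcm_new_uid()
  roi_defs <- list(); contour_sets <- list()
  for (i in seq_along(rois)) {
    r <- rois[[i]]
    roi_defs[[i]] <- list(
      dcm_element(0x3006L, 0x0022L, "IS", as.character(i)),
      dcm_element(0x3006L, 0x0024L, "UI", frame_of_reference),
      dcm_element(0x3006L, 0x0026L, "LO", r$name)
    )
    cts <- lapply(r$contours, function(ct) {
      list(
        dcm_element(0x3006L, 0x0042L, "CS", "CLOSED_PLANAR"),
        dcm_element(0x3006L, 0x0046L, "IS", as.character(nrow(ct))),
        dcm_element(0x3006L, 0x0050L, "DS", fmt_ds(as.numeric(t(ct))))
      )
    })
    contour_sets[[i]] <- list(
      dcm_element(0x3006L, 0x0040L, "SQ", cts),
      dcm_element(0x3006L, 0x0084L, "IS", as.character(i))
    )
  }
  els <- list(
    dcm_element(0x0008L, 0x0016L, "UI", DCM_SOP_RTSTRUCT),
    dcm_element(0x0008L, 0x0018L, "UI", sop_uid),
    dcm_element(0x0008L, 0x0060L, "CS", "RTSTRUCT"),
    dcm_element(0x0020L, 0x000DL, "UI", dcm_new_uid()),
    dcm_element(0x0020L, 0x000EL, "UI", dcm_new_uid()),
    dcm_element(0x3006L, 0x0010L, "SQ", list(list(
      dcm_element(0x0020L, 0x0052L, "UI", frame_of_reference)))),
    dcm_element(0x3006L, 0x0020L, "SQ", roi_defs),
    dcm_element(0x3006L, 0x0039L, "SQ", contour_sets)
  )
  dcm_write_file(path, els, DCM_SOP_RTSTRUCT, sop_uid)
  invisible(path)
}

#' Read an RT Dose grid
#'
#' Voxel values are converted to absolute Gy (stored value times
#' DoseGridScaling). A dose whose summation type indicates a composite/sum
#' plan (anything other than `PLAN` or `FRACTION`) is flagged
#' `"sum_plan"` -- per-plan analysis of such a grid is not possible and the
#' pipeline skips it rather than mis-reporting.
#'
#' @param file RTDOSE DICOM file.
#' @return An `ImageVolume` in Gy with extra fields `summation_type` and
#'   `flags`.
#' @export
read_rtdose <- function(file) {
  ds <- dcm_read_file(file)
  if (!identical(dcm_get(ds, "0008,0060", ""), "RTDOSE"))
    stop("not an RT Dose object: ", file)
  scaling <- dcm_get(ds, "3004,000E", NULL)
  if (is.null(scaling)) stop("RT Dose missing DoseGridScaling: ", file)
  rows <- dcm_require(ds, "0028,0010", "Rows")
  cols <- dcm_require(ds, "0028,0011", "Columns")
  nframes <- dcm_get(ds, "0028,0008", 1L)
  offsets <- dcm_get(ds, "3004,000C", seq_len(nframes) - 1)
  if (nframes > 1L) {
    gaps <- diff(offsets)
    if (diff(range(gaps)) > 1e-3)
      stop("non-uniform GridFrameOffsetVector in RT Dose")
    dz <- mean(gaps)
  } else dz <- 1
  ps <- dcm_require(ds, "0028,0030", "PixelSpacing")
  iop <- dcm_get(ds, "0020,0037", c(1, 0, 0, 0, 1, 0))
  row_dir <- iop[1:3]; col_dir <- iop[4:6]
  normal <- c(row_dir[2L] * col_dir[3L] - row_dir[3L] * col_dir[2L],
              row_dir[3L] * col_dir[1L] - row_dir[1L] * col_dir[3L],
              row_dir[1L] * col_dir[2L] - row_dir[2L] * col_dir[1L])
  signed <- isTRUE(dcm_get(ds, "0028,0103", 0L) == 1L)
  px <- dcm_decode_pixels16(dcm_require(ds, "7FE0,0010", "PixelData"), signed)
  vox <- array(px * scaling, dim = c(cols, rows, nframes))
  summation <- dcm_get(ds, "3004,000A", "PLAN")
  vol <- image_volume(vox,
                      origin = dcm_require(ds, "0020,0032",
                                           "ImagePositionPatient"),
                      spacing = c(ps[2L], ps[1L], dz),
                      orientation = cbind(row_dir, col_dir, normal),
                      frame_of_reference = dcm_get(ds, "0020,0052", ""))
  vol$summation_type <- summation
  vol$flags <- if (summation %in% c("PLAN", "FRACTION")) character(0)
               else "sum_plan"
  vol
}

#' Write an [image_volume()] of dose (Gy) as an RT Dose file
#'
#' Stored as unsigned 16-bit with a DoseGridScaling chosen so the maximum
#' dose maps near the top of the range (quantization below 0.001 Gy at
#' clinical dose levels).
#'
#' @param vol `ImageVolume` in Gy; values must be non-negative.
#' @param path output file.
#' @param summation_type `"PLAN"` for a per-plan grid; `"MULTI_PLAN"` marks a
#'   composite sum plan.
#' @export
write_rtdose <- function(vol, path, summation_type = "PLAN") {
  if (min(vol$voxels) < 0) stop("negative dose values")
  d <- dim(vol$voxels)
  mx <- max(vol$voxels)
  scaling <- if (mx > 0) mx / 60000 else 1e-6
  stored <- round(vol$voxels / scaling)
  sop_uid <- dcm_new_uid()
  frame_uid <- if (nzchar(vol$frame_of_reference)) vol$frame_of_reference
               else dcm_new_uid()
  iop <- c(vol$orientation[, 1L], vol$orientation[, 2L])
  els <- list(
    dcm_element(0x0008L, 0x0016L, "UI", DCM_SOP_RTDOSE),
    dcm_element(0x0008L, 0x0018L, "UI", sop_uid),
    dcm_element(0x0008L, 0x0060L, "CS", "RTDOSE"),
    dcm_element(0x0020L, 0x000DL, "UI", dcm_new_uid()),
    dcm_element(0x0020L, 0x000EL, "UI", dcm_new_uid()),
    dcm_element(0x0020L, 0x0032L, "DS",
                fmt_ds(index_to_phys(vol, c(0, 0, 0))[1L, ])),
    dcm_element(0x0020L, 0x0037L, "DS", fmt_ds(iop)),
    dcm_element(0x0020L, 0x0052L, "UI", frame_uid),
    dcm_element(0x0028L, 0x0002L, "US", 1L),
    dcm_element(0x0028L, 0x0004L, "CS", "MONOCHROME2"),
    dcm_element(0x0028L, 0x0008L, "IS", as.character(d[3L])),
    dcm_element(0x0028L, 0x0010L, "US", d[2L]),
    dcm_element(0x0028L, 0x0011L, "US", d[1L]),
    dcm_element(0x0028L, 0x0030L, "DS",
                fmt_ds(c(vol$spacing[2L], vol$spacing[1L]))),
    dcm_element(0x0028L, 0x0100L, "US", 16L),
    dcm_element(0x0028L, 0x0101L, "US", 16L),
    dcm_element(0x0028L, 0x0102L, "US", 15L),
    dcm_element(0x0028L, 0x0103L, "US", 0L),
    dcm_element(0x3004L, 0x0002L, "CS", "GY"),
    dcm_element(0x3004L, 0x0004L, "CS", "PHYSICAL"),
    dcm_element(0x3004L, 0x000AL, "CS", summation_type),
    dcm_element(0x3004L, 0x000CL, "DS",
                fmt_ds((seq_len(d[3L]) - 1) * vol$spacing[3L])),
    dcm_element(0x3004L, 0x000EL, "DS",
                formatC(scaling, format = "e", digits = 9)),
    dcm_element(0x7FE0L, 0x0010L, "OW",
                dcm_encode_pixels16(stored, signed = FALSE))
  )
  dcm_write_file(path, els, DCM_SOP_RTDOSE, sop_uid)
  invisible(path)
}
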