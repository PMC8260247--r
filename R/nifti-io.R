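#' Export a subject as NIfTI volumes
#'
#' Writes one 4-D NIfTI per run (unsimulated grid voxels are zero), a
#' 3-D integer-label NIfTI mask (regions numbered in layout order, the
#' non-gray block and any unlabelled gray voxels with the two labels
#' after the last region), and a JSON sidecar holding the exact layout
#' (per-region linear indices), design events, motion series and TR —
#' the sidecar is authoritative for reconstruction, since region labels
#' cannot encode overlapping regions.
#'
#' @param subject a \linkS4class{SubjectDataset}.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
writeSubjectNifti <- function(subject, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  layout <- subject@layout
  dims <- gridDims(layout)
  tr <- subject@trSeconds
  files <- character()

  for (r in seq_len(nRuns(subject))) {
    y <- subject@runs[[r]]
    vol <- array(0, c(dims, nrow(y)))
    flat <- matrix(vol, prod(dims), nrow(y))
    flat[subject@voxels, ] <- t(y)
    vol <- array(flat, c(dims, nrow(y)))
    f <- file.path(dir, sprintf("run%02d.nii.gz", r))
    RNifti::writeNifti(RNifti::asNifti(vol, pixdim = c(1, 1, 1, tr)), f)
    files <- c(files, f)
  }

  lab <- array(0L, dims)
  nm <- regionNames(layout)
  lab[grayVoxels(layout)] <- length(nm) + 2L
  for (i in seq_along(nm)) lab[regionVoxels(layout, nm[i])] <- i
  lab[whiteVoxels(layout)] <- length(nm) + 1L
  fmask <- file.path(dir, "mask.nii.gz")
  RNifti::writeNifti(lab, fmask)

  side <- list(
    trSeconds = tr,
    gridDims = dims,
    nVolumes = subject@design@nVolumes,
    conditions = subject@design@conditions,
    regions = lapply(nm, function(r) list(
      name = r, role = regionRole(layout, r),
      category = regionCategory(layout, r),
      voxels = regionVoxels(layout, r))),
    gray = grayVoxels(layout),
    white = whiteVoxels(layout),
    voxels = subject@voxels,
    design = subject@design@runs,
    motion = lapply(subject@motion, function(m) unname(as.matrix(m)))
  )
  fside <- file.path(dir, "subject.json")
  jsonlite::write_json(side, fside, digits = NA, auto_unbox = TRUE)
  invisible(c(files, fmask, fside))
}

#' Read a subject exported with \code{\link{writeSubjectNifti}}
#'
#' @param dir directory written by \code{\link{writeSubjectNifti}}.
#' @return a \linkS4class{SubjectDataset} (with an empty truth record).
#' @export
readSubjectNifti <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "subject.json"),
                              simplifyVector = TRUE)
  dims <- as.integer(side$gridDims)
  regions <- list(); roles <- character(); cats <- character()
  for (i in seq_len(nrow(side$regions))) {
    nm <- side$regions$name[i]
    regions[[nm]] <- gridCoords(side$regions$voxels[[i]], dims)
    roles[nm] <- side$regions$role[i]
    cats[nm] <- side$regions$category[i]
  }
  layout <- new("RegionLayout", gridDims = dims, regions = regions,
                roles = roles, categories = cats,
                gray = gridCoords(as.integer(side$gray), dims),
                white = gridCoords(as.integer(side$white), dims))
  design <- new("DesignSpec", trSeconds = side$trSeconds,
                nVolumes = as.integer(side$nVolumes),
                runs = lapply(side$design, as.data.frame),
                conditions = side$conditions)
  voxels <- as.integer(side$voxels)
  runFiles <- sort(list.files(dir, pattern = "^run[0-9]+\\.nii",
                              full.names = TRUE))
  runs <- lapply(runFiles, function(f) {
    vol <- RNifti::readNifti(f)
    d <- dim(vol)
    flat <- matrix(vol, prod(d[1:3]), d[4])
    t(flat[voxels, , drop = FALSE])
  })
  mraw <- side$motion
  motion <- if (is.array(mraw) && length(dim(mraw)) == 3L)
    lapply(seq_len(dim(mraw)[1]), function(i) mraw[i, , ])
  else lapply(mraw, function(m) {
    if (is.matrix(m)) m else matrix(unlist(m), ncol = 6L, byrow = TRUE)
  })
  new("SubjectDataset", runs = runs, voxels = voxels,
      trSeconds = side$trSeconds, layout = layout, design = design,
      motion = motion, truth = list())
}

#' Write a voxel map as a 3-D NIfTI volume
#'
#' @param values numeric values per voxel.
#' @param maskIdx linear grid indices of the voxels.
#' @param dims integer(3) grid dimensions.
#' @param file output path.
#' @param background fill value outside the mask (default 0).
#' @return invisibly, the file path.
#' @export
writeMapNifti <- function(values, maskIdx, dims, file, background = 0) {
  vol <- array(background, dims)
  vol[maskIdx] <- values
  RNifti::writeNifti(vol, file)
  invisible(file)
}
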