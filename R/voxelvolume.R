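#' Voxel volume container
#'
#' A 3D scalar lattice with per-axis voxel spacing (mm) and an origin given
#' as the centre of voxel index (1,1,1).  `value_kind` documents the physical
#' meaning of the stored values: activity concentration (MBq/mL), linear
#' attenuation (1/cm), projection counts, compartment labels, or an
#' HU-like CT value.
#'
#' @param values numeric or integer 3D array.
#' @param voxel_size_mm length-3 (or scalar) positive voxel spacing in mm.
#' @param origin_mm length-3 position (mm) of the centre of voxel (1,1,1).
#' @param value_kind one of `"activity"`, `"attenuation"`, `"counts"`,
#'   `"label"`, `"hu"`.
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(values, voxel_size_mm, origin_mm = c(0, 0, 0),
                         value_kind = c("activity", "attenuation", "counts",
                                        "label", "hu")) {
  value_kind <- match.arg(value_kind)
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  voxel_size_mm <- rep_len(as.numeric(voxel_size_mm), 3L)
  if (any(!is.finite(voxel_size_mm)) || any(voxel_size_mm <= 0))
    stop("voxel sizes must be strictly positive")
  if (anyNA(values) || any(!is.finite(values)))
    stop("all voxel values must be finite")
  structure(list(values = values,
                 voxel_size_mm = voxel_size_mm,
                 origin_mm = rep_len(as.numeric(origin_mm), 3L),
                 value_kind = value_kind),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<voxel_volume> %d x %d x %d, voxel %s mm, kind '%s'\n",
              d[1], d[2], d[3],
              paste(signif(x$voxel_size_mm, 4), collapse = " x "),
              x$value_kind))
  cat(sprintf("  range [%.4g, %.4g], origin (%s) mm\n",
              min(x$values), max(x$values),
              paste(signif(x$origin_mm, 4), collapse = ", ")))
  invisible(x)
}

#' Voxel volume element in mL
#' @param vv a `voxel_volume`.
#' @return Scalar voxel volume in mL.
#' @export
voxel_mL <- function(vv) prod(vv$voxel_size_mm) / 1000

#' Physical voxel-centre coordinates along one axis
#' @param vv a `voxel_volume`.
#' @param axis 1, 2 or 3.
#' @return Numeric vector of centre coordinates in mm.
#' @export
voxel_coords <- function(vv, axis) {
  n <- dim(vv$values)[axis]
  vv$origin_mm[axis] + (seq_len(n) - 1) * vv$voxel_size_mm[axis]
}

#' Write a volume as MetaImage (.mha, local binary data)
#'
#' MetaImage is a simple, widely supported 3D research format (ITK/ImageJ);
#' spacing and offset are preserved so round-trips keep geometry.
#'
#' @param vv a `voxel_volume`.
#' @param path output file path (`.mha`).
#' @return `path`, invisibly.
#' @export
write_mha <- function(vv, path) {
  d <- dim(vv$values)
  hdr <- c("ObjectType = Image",
           "NDims = 3",
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           sprintf("DimSize = %d %d %d", d[1], d[2], d[3]),
           sprintf("ElementSpacing = %.9g %.9g %.9g",
                   vv$voxel_size_mm[1], vv$voxel_size_mm[2], vv$voxel_size_mm[3]),
           sprintf("Offset = %.9g %.9g %.9g",
                   vv$origin_mm[1], vv$origin_mm[2], vv$origin_mm[3]),
           sprintf("ValueKind = %s", vv$value_kind),
           "ElementType = MET_DOUBLE",
           "ElementDataFile = LOCAL")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  writeBin(as.numeric(vv$values), con, size = 8, endian = "little")
  invisible(path)
}

#' Read a MetaImage volume written by [write_mha()]
#' @param path `.mha` file path.
#' @return A `voxel_volume`.
#' @export
read_mha <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L)
    kv <- strsplit(line, " = ", fixed = TRUE)[[1]]
    hdr[[kv[1]]] <- kv[2]
    if (kv[1] == "ElementDataFile") break
  }
  if (!identical(hdr[["ElementDataFile"]], "LOCAL"))
    stop("only LOCAL-data MetaImage files are supported")
  if (!identical(hdr[["ElementType"]], "MET_DOUBLE"))
    stop("only MET_DOUBLE MetaImage files are supported")
  d <- as.integer(strsplit(hdr[["DimSize"]], " ")[[1]])
  vals <- readBin(con, "double", n = prod(d), size = 8, endian = "little")
  kind <- hdr[["ValueKind"]]
  if (is.null(kind)) kind <- "activity"
  voxel_volume(array(vals, dim = d),
               as.numeric(strsplit(hdr[["ElementSpacing"]], " ")[[1]]),
               as.numeric(strsplit(hdr[["Offset"]], " ")[[1]]),
               kind)
}

# Downsample (bin-average) a volume onto a coarser grid that spans `dims_out`
# voxels of size `voxel_out` with origin `origin_out`.  Values are treated as
# densities: each fine voxel deposits value * v_fine / v_coarse into the
# coarse voxel containing its centre, so totals (value x volume) are
# conserved for sources fully inside the output grid.
bin_average <- function(vv, voxel_out, dims_out, origin_out) {
  d <- dim(vv$values)
  cx <- voxel_coords(vv, 1); cy <- voxel_coords(vv, 2); cz <- voxel_coords(vv, 3)
  ix <- floor((cx - origin_out[1]) / voxel_out[1] + 0.5) + 1L
  iy <- floor((cy - origin_out[2]) / voxel_out[2] + 0.5) + 1L
  iz <- floor((cz - origin_out[3]) / voxel_out[3] + 0.5) + 1L
  okx <- ix >= 1L & ix <= dims_out[1]
  oky <- iy >= 1L & iy <= dims_out[2]
  okz <- iz >= 1L & iz <= dims_out[3]
  out <- array(0, dim = dims_out)
  ratio <- prod(vv$voxel_size_mm) / prod(voxel_out)
  # linear index of the target coarse voxel for every fine voxel
  tgt <- array(0L, dim = d)
  tgt <- outer(outer(ix, (iy - 1L) * dims_out[1], "+"),
               (iz - 1L) * dims_out[1] * dims_out[2], "+")
  ok <- outer(outer(okx, oky, "&"), okz, "&")
  vals <- vv$values[ok] * ratio
  idx <- tgt[ok]
  acc <- rowsum(vals, idx)
  out[as.integer(rownames(acc))] <- acc[, 1]
  out
}
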