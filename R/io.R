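# File formats: a minimal NIfTI-1 reader/writer (single-file .nii, float32),
# BIDS-style physio TSV + JSON sidecar, events TSV, and feature-series TSV.
# The NIfTI code covers exactly what the pipeline emits (4D magnitude data
# on a regular grid); it is not a general NIfTI implementation.

#' Write a 3D/4D array as a NIfTI-1 file
#'
#' Emits a single-file uncompressed (or gzipped, by extension) NIfTI-1
#' image, float32, identity orientation, with voxel dimensions `pixdim_mm`
#' and repetition time `tr_s` stored in pixdim[5].
#'
#' @param arr Numeric array, 3 or 4 dimensions.
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @param pixdim_mm Voxel edge lengths in mm (length 3).
#' @param tr_s Repetition time in seconds (stored for 4D images).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(arr, path, pixdim_mm = c(3, 3, 3), tr_s = 1) {
  nd <- length(dim(arr))
  if (!nd %in% c(3L, 4L)) stop("`arr` must be a 3D or 4D array")
  dims <- c(nd, dim(arr), rep(1L, 7 - nd))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeBin(348L, con, size = 4)                     # sizeof_hdr
  writeBin(raw(36), con)                            # unused
  writeBin(as.integer(dims), con, size = 2)         # dim[8]
  writeBin(raw(14), con)                            # intent params etc.
  writeBin(16L, con, size = 2)                      # datatype = float32
  writeBin(32L, con, size = 2)                      # bitpix
  writeBin(0L, con, size = 2)                       # slice_start
  writeBin(c(0, pixdim_mm, tr_s, 0, 0, 0), con, size = 4)  # pixdim[8]
  writeBin(352, con, size = 4)                      # vox_offset (float)
  writeBin(c(1, 0), con, size = 4)                  # scl_slope, scl_inter
  writeBin(raw(4), con)                             # slice_end, slice_code, xyzt_units
  writeBin(c(0, 0), con, size = 4)                  # cal_max, cal_min
  writeBin(c(0, 0), con, size = 4)                  # slice_duration, toffset
  writeBin(c(0L, 0L), con, size = 4)                # glmax, glmin
  writeBin(charToRaw(sprintf("%-80s", "generated")), con)   # descrip
  writeBin(raw(24), con)                            # aux_file
  writeBin(c(0L, 1L), con, size = 2)                # qform, sform codes
  writeBin(rep(0, 6), con, size = 4)                # quatern b,c,d, qoffset
  srow <- rbind(c(pixdim_mm[1], 0, 0, 0), c(0, pixdim_mm[2], 0, 0),
                c(0, 0, pixdim_mm[3], 0))
  writeBin(as.numeric(t(srow)), con, size = 4)      # srow_x/y/z
  writeBin(charToRaw(sprintf("%-16s", "")), con)    # intent_name
  writeBin(charToRaw("n+1"), con); writeBin(raw(1), con)  # magic
  writeBin(raw(4), con)                             # extension flag
  writeBin(as.numeric(arr), con, size = 4)
  invisible(path)
}

#' Read a NIfTI-1 file written by this package
#'
#' Supports single-file little-endian NIfTI-1 with float32/float64/int16
#' data and no extensions beyond the 352-byte offset.
#'
#' @param path `.nii` or `.nii.gz` path.
#' @return List with `data` (array), `pixdim_mm`, `tr_s`.
#' @export
read_nifti <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr_sz <- readBin(con, "integer", 1, size = 4)
  if (hdr_sz != 348L) stop("not a little-endian NIfTI-1 file: ", path)
  invisible(readBin(con, "raw", 36))
  dims <- readBin(con, "integer", 8, size = 2)
  invisible(readBin(con, "raw", 14))
  datatype <- readBin(con, "integer", 1, size = 2)
  invisible(readBin(con, "integer", 1, size = 2))   # bitpix
  invisible(readBin(con, "integer", 1, size = 2))   # slice_start
  pixdim <- readBin(con, "numeric", 8, size = 4)
  vox_offset <- readBin(con, "numeric", 1, size = 4)
  # 112 header bytes consumed so far; skip the rest up to vox_offset
  invisible(readBin(con, "raw", vox_offset - 112))
  nd <- dims[1]
  shape <- dims[2:(1 + nd)]
  n <- prod(shape)
  data <- switch(as.character(datatype),
    "16" = readBin(con, "numeric", n, size = 4),
    "64" = readBin(con, "numeric", n, size = 8),
    "4"  = readBin(con, "integer", n, size = 2),
    stop("unsupported NIfTI datatype: ", datatype))
  list(data = array(data, dim = shape),
       pixdim_mm = pixdim[2:4], tr_s = pixdim[5])
}

#' Write a physiological recording as BIDS-style physio TSV + JSON sidecar
#'
#' The TSV is headerless and gzipped (`_physio.tsv.gz`); column names,
#' sampling frequency and start time go to the JSON sidecar, following the
#' BIDS physiological-recording convention.
#'
#' @param signals Named list or data.frame of equal-length numeric columns.
#' @param prefix Output path prefix; writes `<prefix>.tsv.gz` and
#'   `<prefix>.json`.
#' @param fs_hz Sampling frequency (Hz).
#' @param start_time_s Recording onset relative to the first fMRI volume.
#' @return The TSV path, invisibly.
#' @export
write_physio_bids <- function(signals, prefix, fs_hz, start_time_s = 0) {
  df <- as.data.frame(signals)
  tsv <- paste0(prefix, ".tsv.gz")
  data.table::fwrite(df, tsv, sep = "\t", col.names = FALSE, compress = "gzip")
  meta <- list(SamplingFrequency = fs_hz, StartTime = start_time_s,
               Columns = names(df))
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(tsv)
}

#' Read a BIDS-style physio TSV + JSON sidecar
#' @param prefix Path prefix used by [write_physio_bids()].
#' @return List with `signals` (data.frame), `fs_hz`, `start_time_s`.
#' @export
read_physio_bids <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  df <- utils::read.table(gzfile(paste0(prefix, ".tsv.gz")), sep = "\t",
                          header = FALSE, col.names = meta$Columns)
  list(signals = as.data.frame(df), fs_hz = meta$SamplingFrequency,
       start_time_s = meta$StartTime)
}

#' Write an events table as BIDS-style events TSV
#' @param events Data frame with at least `onset` and `duration` columns.
#' @param path Output `.tsv` path.
#' @export
write_events_tsv <- function(events, path) {
  data.table::fwrite(as.data.frame(events), path, sep = "\t")
  invisible(path)
}

#' Read a BIDS-style events TSV
#' @param path `.tsv` path.
#' @return data.frame.
#' @export
read_events_tsv <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t"))
}

#' Serialize a feature series as TSV with metadata header lines
#'
#' Metadata (`name`, `units`, `tr_s`) is written as `# key=value` comment
#' lines before a single `value` column.
#'
#' @param feat A `feature_series` object.
#' @param path Output path.
#' @export
write_feature_tsv <- function(feat, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# name=%s", feat$name),
               sprintf("# units=%s", feat$units),
               sprintf("# tr_s=%.10g", feat$tr_s), "value"), con)
  writeLines(sprintf("%.12g", feat$values), con)
  invisible(path)
}

#' Read a feature series TSV written by [write_feature_tsv()]
#' @param path Input path.
#' @return A `feature_series` object.
#' @export
read_feature_tsv <- function(path) {
  lines <- readLines(path)
  meta <- grep("^# ", lines, value = TRUE)
  kv <- strsplit(sub("^# ", "", meta), "=", fixed = TRUE)
  kv <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  vals <- as.numeric(lines[-seq_len(length(meta) + 1)])
  feature_series(vals, tr_s = as.numeric(kv[["tr_s"]]), name = kv[["name"]],
                 units = kv[["units"]])
}
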