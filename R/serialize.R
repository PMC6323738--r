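# ROI and result serialization.
#
# Native format: a zip archive (stored, uncompressed) holding manifest.json
# (image metadata, config, threshold, correction log, roi index) plus one
# roi_<id>.json per fiber. Written with a minimal built-in zip writer so
# archives are byte-reproducible; read back with utils::unzip. The ImageJ
# binary ROI format (.roi records, .zip archives of them) is supported on
# the read side for interoperability with the visual-checking workflow.

# ---- CRC-32 (needed by the zip writer) ------------------------------------

# 32-bit values are carried as doubles; xor via 16-bit halves
.xor32 <- function(a, b) {
  lo <- bitwXor(a %% 65536, b %% 65536)
  hi <- bitwXor(a %/% 65536, b %/% 65536)
  hi * 65536 + lo
}

.crc32_table <- local({
  tab <- numeric(256)
  poly <- 3988292384  # 0xEDB88320
  for (n in 0:255) {
    c <- n
    for (k in 1:8) {
      c <- if (c %% 2 == 1) .xor32(floor(c / 2), poly) else floor(c / 2)
    }
    tab[n + 1] <- c
  }
  tab
})

.crc32 <- function(bytes) {
  crc <- 4294967295  # 0xFFFFFFFF
  v <- as.integer(bytes)
  for (b in v) {
    idx <- bitwXor(crc %% 256, b)
    crc <- .xor32(.crc32_table[idx + 1], floor(crc / 256))
  }
  .xor32(crc, 4294967295)
}

# ---- minimal stored-zip writer --------------------------------------------

.u16 <- function(x) as.raw(c(x %% 256, (x %/% 256) %% 256))
.u32 <- function(x) as.raw(c(x %% 256, (x %/% 256) %% 256,
                             (x %/% 65536) %% 256,
                             (x %/% 16777216) %% 256))

# files: named list of raw vectors; writes a stored (method 0) zip
.write_zip <- function(files, path) {
  out <- raw(0)
  central <- raw(0)
  nfiles <- length(files)
  names_raw <- lapply(names(files), charToRaw)
  # fixed DOS timestamp for byte-reproducible archives
  dos_time <- 0; dos_date <- 33            # 1980-01-01
  for (i in seq_len(nfiles)) {
    data <- files[[i]]
    nm <- names_raw[[i]]
    crc <- .crc32(data)
    offset <- length(out)
    local_hdr <- c(.u32(67324752),         # PK\3\4
                   .u16(20), .u16(0), .u16(0),
                   .u16(dos_time), .u16(dos_date),
                   .u32(crc), .u32(length(data)), .u32(length(data)),
                   .u16(length(nm)), .u16(0))
    out <- c(out, local_hdr, nm, data)
    central <- c(central,
                 .u32(33639248),           # PK\1\2
                 .u16(20), .u16(20), .u16(0), .u16(0),
                 .u16(dos_time), .u16(dos_date),
                 .u32(crc), .u32(length(data)), .u32(length(data)),
                 .u16(length(nm)), .u16(0), .u16(0), .u16(0), .u16(0),
                 .u32(0), .u32(offset), nm)
  }
  eocd <- c(.u32(101010256),               # PK\5\6
            .u16(0), .u16(0), .u16(nfiles), .u16(nfiles),
            .u32(length(central)), .u32(length(out)), .u16(0))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(out, central, eocd), con)
  invisible(path)
}

# ---- native export / import -----------------------------------------------

.roi_to_list <- function(roi) {
  list(fiber_id = roi$fiber_id,
       origin = roi$origin,
       polygon_x = roi$polygon[, 1],
       polygon_y = roi$polygon[, 2],
       area_um2 = roi$area_um2,
       perimeter_um = roi$perimeter_um,
       circularity = roi$circularity,
       centroid = roi$centroid,
       touches_edge = roi$touches_edge,
       tile_id = roi$tile_id)
}

.roi_from_list <- function(x) {
  .fiber_roi(fiber_id = x$fiber_id,
             polygon = cbind(x = as.numeric(x$polygon_x),
                             y = as.numeric(x$polygon_y)),
             origin = x$origin,
             area_um2 = x$area_um2,
             perimeter_um = x$perimeter_um,
             circularity = if (is.null(x$circularity)) NA_real_ else
               x$circularity,
             centroid = as.numeric(x$centroid),
             touches_edge = isTRUE(x$touches_edge),
             tile_id = if (is.null(x$tile_id)) NA_integer_ else x$tile_id)
}

.log_to_list <- function(log) {
  lapply(log, function(ev) {
    if (ev$op == "add") {
      list(op = "add", id = ev$id,
           polygon_x = ev$polygon[, 1], polygon_y = ev$polygon[, 2],
           pixel_size_um = ev$pixel_size_um)
    } else {
      list(op = "delete", ids = ev$ids)
    }
  })
}

.log_from_list <- function(x) {
  lapply(x, function(ev) {
    if (ev$op == "add") {
      list(op = "add", id = as.integer(ev$id),
           polygon = cbind(x = as.numeric(ev$polygon_x),
                           y = as.numeric(ev$polygon_y)),
           pixel_size_um = as.numeric(ev$pixel_size_um))
    } else {
      list(op = "delete", ids = as.integer(unlist(ev$ids)))
    }
  })
}

#' Export a segmentation result to a ROI archive
#'
#' Writes a zip archive with a JSON manifest (image metadata, configuration,
#' threshold, correction log) and one JSON record per fiber ROI. The
#' export/import round trip preserves every polygon vertex, fiber id and
#' origin exactly, and archives are byte-reproducible.
#'
#' @param result a `segmentation_result`.
#' @param path output path (conventionally `.zip`).
#' @return `path`, invisibly.
#' @seealso [import_rois()]
#' @export
export_rois <- function(result, path) {
  stopifnot(inherits(result, "segmentation_result"))
  to_json <- function(x) {
    # I(17) significant digits: doubles survive the round trip bit-exactly
    charToRaw(jsonlite::toJSON(x, digits = I(17), auto_unbox = TRUE,
                               null = "null", na = "null", pretty = FALSE))
  }
  files <- list()
  manifest <- list(
    format = "fibercsa-roi-archive",
    format_version = 1L,
    image_name = result$image_name,
    image_size = result$image_size,
    pixel_size_um = result$pixel_size_um,
    threshold_used = result$threshold_used,
    config = unclass(result$config),
    correction_log = .log_to_list(result$correction_log),
    roi_files = if (length(result$rois))
      sprintf("roi_%06d.json",
              vapply(result$rois, `[[`, integer(1), "fiber_id"))
    else character(0))
  files[["manifest.json"]] <- to_json(manifest)
  for (roi in result$rois) {
    files[[sprintf("roi_%06d.json", roi$fiber_id)]] <-
      to_json(.roi_to_list(roi))
  }
  .write_zip(files, path)
  invisible(path)
}

#' Import a ROI archive
#'
#' Reads either a native archive written by [export_rois()], an ImageJ ROI
#' zip of polygon records, or a single ImageJ `.roi` file. ImageJ polygon
#' ROIs are imported with `origin = "manual"`, their CSA computed from the
#' polygon geometry and the supplied calibration.
#'
#' @param path archive or `.roi` file.
#' @param pixel_size_um calibration used for ImageJ imports (native
#'   archives carry their own); default 1.
#' @param image_size `c(width, height)` frame for ImageJ imports; inferred
#'   from the polygon extent when `NULL`.
#' @return A `segmentation_result`.
#' @export
import_rois <- function(path, pixel_size_um = 1, image_size = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  head4 <- readBin(path, "raw", n = 4)
  if (length(head4) >= 4 && rawToChar(head4) == "Iout") {
    roi <- .read_imagej_roi(path)
    return(.result_from_imagej(list(roi), pixel_size_um, image_size,
                               basename(path)))
  }
  if (length(head4) < 2 || head4[1] != as.raw(0x50) ||
      head4[2] != as.raw(0x4b)) {
    stop("malformed ROI file: unrecognized magic at byte offset 0")
  }
  exdir <- tempfile("roiarchive")
  dir.create(exdir)
  on.exit(unlink(exdir, recursive = TRUE))
  listing <- utils::unzip(path, exdir = exdir)
  names_in <- basename(listing)
  if ("manifest.json" %in% names_in) {
    man <- jsonlite::fromJSON(file.path(exdir, "manifest.json"),
                              simplifyVector = TRUE,
                              simplifyDataFrame = FALSE,
                              simplifyMatrix = FALSE)
    rois <- lapply(unlist(man$roi_files), function(f) {
      .roi_from_list(jsonlite::fromJSON(file.path(exdir, f),
                                        simplifyVector = TRUE,
                                        simplifyDataFrame = FALSE,
                                        simplifyMatrix = FALSE))
    })
    cfg <- do.call(pipeline_config, man$config)
    return(.segmentation_result(
      rois = rois, image_name = man$image_name,
      image_size = as.integer(unlist(man$image_size)),
      pixel_size_um = man$pixel_size_um,
      config = cfg,
      threshold_used = man$threshold_used,
      correction_log = .log_from_list(man$correction_log)))
  }
  roi_files <- listing[grepl("\\.roi$", listing, ignore.case = TRUE)]
  if (!length(roi_files)) {
    stop("malformed archive: neither a manifest.json nor .roi records found")
  }
  rois <- lapply(sort(roi_files), .read_imagej_roi)
  .result_from_imagej(rois, pixel_size_um, image_size, basename(path))
}

# assemble an imported set of ImageJ polygons into a segmentation_result
.result_from_imagej <- function(polys, pixel_size_um, image_size, name) {
  if (is.null(image_size)) {
    mx <- max(c(1, vapply(polys, function(p) max(p[, 1]), numeric(1))))
    my <- max(c(1, vapply(polys, function(p) max(p[, 2]), numeric(1))))
    image_size <- c(ceiling(mx), ceiling(my))
  }
  rois <- lapply(seq_along(polys), function(i) {
    p <- polys[[i]]
    .fiber_roi(fiber_id = i, polygon = p, origin = "manual",
               area_um2 = abs(.shoelace_signed(p)) * pixel_size_um^2,
               perimeter_um = .polygon_perimeter(p) * pixel_size_um,
               circularity = NA_real_,
               centroid = .polygon_centroid(p))
  })
  .segmentation_result(rois = rois, image_name = name,
                       image_size = image_size,
                       pixel_size_um = pixel_size_um,
                       config = NULL, threshold_used = NA_integer_)
}

# parse one ImageJ .roi record (polygon-family types); big-endian layout:
# 0-3 magic "Iout", 4-5 version, 6 type, 8/10/12/14 top/left/bottom/right
# (int16), 16 point count (uint16), coordinates from byte 64 as int16 x
# offsets (relative to left) then int16 y offsets (relative to top).
.read_imagej_roi <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 64 || rawToChar(raw[1:4]) != "Iout") {
    stop("malformed ImageJ ROI '", basename(path),
         "': bad magic at byte offset 0")
  }
  rd_i16 <- function(off, n = 1, signed = TRUE) {
    readBin(raw[(off + 1):(off + 2 * n)], "integer", n = n, size = 2,
            endian = "big", signed = signed)
  }
  type <- as.integer(raw[7])
  # 0 polygon, 7 freehand, 8 traced
  if (!type %in% c(0L, 7L, 8L)) {
    stop("unsupported ImageJ ROI type ", type, " at byte offset 6 (only ",
         "polygon-family ROIs can become fibers)")
  }
  top <- rd_i16(8); left <- rd_i16(10)
  n <- rd_i16(16, signed = FALSE)
  if (n < 3) {
    stop("malformed ImageJ ROI: fewer than 3 points (count at byte offset 16)")
  }
  need <- 64 + 4 * n
  if (length(raw) < need) {
    stop("malformed ImageJ ROI: truncated at byte offset ", length(raw),
         " (need ", need, ")")
  }
  xs <- rd_i16(64, n)
  ys <- rd_i16(64 + 2 * n, n)
  cbind(x = as.numeric(left + xs), y = as.numeric(top + ys))
}

#' Write per-fiber results as CSV
#'
#' @param result a `segmentation_result`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(result, path) {
  df <- as.data.frame(result)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
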