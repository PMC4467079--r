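#' Read and write raster grids
#'
#' Two plain-text raster formats are supported:
#'
#' * `"asc"` — ESRI ASCII grid: the standard six-line header (`ncols`,
#'   `nrows`, `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`)
#'   followed by rows of values, top row first.  `cellsize` carries the
#'   pixel size, so round trips preserve it exactly.
#' * `"csv"` — headerless comma-separated matrix, one raster row per
#'   line.  The pixel size is not stored in the file; supply it via
#'   `pixel_size` when reading (default 4 m).
#'
#' When `format` is omitted it is inferred from the file extension.
#'
#' @param path File path.
#' @param format `"asc"` or `"csv"`.
#' @param pixel_size Pixel size in m, used for CSV input.
#' @param units Units tag attached to the grid on reading.
#' @return `read_raster` returns a `raster_grid`; `write_raster` returns
#'   the path invisibly.
#' @examples
#' f <- tempfile(fileext = ".asc")
#' write_raster(raster_grid(matrix(1:12 / 10, 3, 4)), f)
#' read_raster(f)
#' @export
read_raster <- function(path, format = NULL, pixel_size = 4,
                        units = "NDVI") {
  format <- infer_format(path, format)
  if (format == "asc") {
    lines <- readLines(path)
    hdr <- list()
    i <- 1L
    while (i <= length(lines) &&
           grepl("^\\s*[A-Za-z_]+\\s", lines[i])) {
      kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
      i <- i + 1L
    }
    need <- c("ncols", "nrows", "cellsize")
    if (!all(need %in% names(hdr))) {
      stop("ESRI ASCII header is missing: ",
           paste(setdiff(need, names(hdr)), collapse = ", "))
    }
    vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
                 quiet = TRUE)
    if (length(vals) != hdr$nrows * hdr$ncols) {
      stop("ESRI ASCII body does not match the declared dimensions")
    }
    m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
    if (!is.null(hdr$nodata_value) &&
        any(m == hdr$nodata_value)) {
      stop("raster contains NODATA cells, which are not supported")
    }
    raster_grid(m, pixel_size = hdr$cellsize, units = units)
  } else {
    rows <- strsplit(readLines(path), ",")
    if (!length(rows)) stop("empty CSV raster: ", path)
    widths <- lengths(rows)
    if (length(unique(widths)) != 1L) {
      stop("ragged CSV: rows have differing numbers of values")
    }
    m <- suppressWarnings(do.call(rbind, lapply(rows, as.numeric)))
    if (any(is.na(m))) stop("non-numeric values in CSV raster")
    raster_grid(m, pixel_size = pixel_size, units = units)
  }
}

#' @rdname read_raster
#' @param grid A `raster_grid` (or plain matrix for CSV).
#' @export
write_raster <- function(grid, path, format = NULL) {
  format <- infer_format(path, format)
  if (format == "asc") {
    stopifnot(inherits(grid, "raster_grid"))
    px <- pixel_size(grid)
    hdr <- c(sprintf("ncols %d", ncol(grid)),
             sprintf("nrows %d", nrow(grid)),
             "xllcorner 0", "yllcorner 0",
             sprintf("cellsize %.17g", px),
             "NODATA_value -9999")
    body <- apply(unclass(grid), 1L, function(r) {
      paste(formatC(r, format = "g", digits = 17), collapse = " ")
    })
    writeLines(c(hdr, body), path)
  } else {
    body <- apply(as.matrix(grid), 1L, function(r) {
      paste(formatC(r, format = "g", digits = 17), collapse = ",")
    })
    writeLines(body, path)
  }
  invisible(path)
}

infer_format <- function(path, format) {
  if (is.null(format)) {
    format <- tolower(tools::file_ext(path))
    if (format == "") stop("cannot infer raster format from path: ", path)
  }
  format <- tolower(format)
  if (!format %in% c("asc", "csv")) {
    stop(sprintf("unknown raster format '%s' (supported: asc, csv)", format))
  }
  format
}

#' Write an edge mask as a 0/1 raster
#'
#' @param mask An `edge_mask`.
#' @param pixel_size Pixel size recorded in the output, m.
#' @inheritParams write_raster
#' @export
write_mask <- function(mask, path, format = NULL, pixel_size = 4) {
  g <- raster_grid(matrix(as.numeric(mask), nrow(mask), ncol(mask)),
                   pixel_size = pixel_size, units = "edge")
  write_raster(g, path, format)
}
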