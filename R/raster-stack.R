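# Minimal monthly raster container: a (time, row, col) array plus the month
# axis. IO goes through float TIFF (one band per file) or plain CSV matrices;
# there is no reprojection or resampling — all layers must share one grid.

#' Construct a monthly raster stack
#'
#' @param data 3-D numeric array indexed (time, row, col). \code{NA} marks
#'   nodata; nodata pixels are excluded from all statistics.
#' @param start integer \code{c(year, month)} of the first layer.
#' @param units,name metadata.
#' @return an object of class \code{raster_stack}.
#' @export
raster_stack <- function(data, start = c(2001L, 1L), units = "", name = "") {
  if (length(dim(data)) != 3L) stop("data must be a (time, row, col) array")
  structure(list(data = data, start = as.integer(start),
                 units = units, name = name),
            class = "raster_stack")
}

#' @export
print.raster_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<raster_stack '%s'> %d months x %d x %d, %d nodata cells\n",
              x$name, d[1L], d[2L], d[3L], sum(is.na(x$data))))
  invisible(x)
}

n_months_of <- function(stack) dim(stack$data)[1L]

stack_month_of <- function(stack) {
  lin <- ym_to_linear(stack$start[1L], stack$start[2L]) + seq_len(n_months_of(stack)) - 1L
  as.integer(lin %% 12L + 1L)
}

stack_year_of <- function(stack) {
  lin <- ym_to_linear(stack$start[1L], stack$start[2L]) + seq_len(n_months_of(stack)) - 1L
  as.integer(lin %/% 12L)
}

#' Extract one pixel's series from a stack
#' @param stack a \code{raster_stack}.
#' @param row,col pixel indices (1-based).
#' @return a \code{monthly_ts}.
#' @export
pixel_series <- function(stack, row, col) {
  monthly_ts(stack$data[, row, col], stack$start, units = stack$units,
             name = sprintf("%s[%d,%d]", stack$name, row, col))
}

# ---- IO ---------------------------------------------------------------------

read_layer <- function(path) {
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    m <- tiff::readTIFF(path)
    if (length(dim(m)) == 3L) m <- m[, , 1L]
    sidecar <- paste0(path, ".json")
    if (file.exists(sidecar)) {
      meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
      m <- meta$vmin + m * (meta$vmax - meta$vmin)
      if (length(meta$na_cells)) m[meta$na_cells] <- NA_real_
    }
    m
  } else {
    as.matrix(utils::read.csv(path, header = FALSE))
  }
}

#' Assemble a raster stack from per-month layer files
#'
#' Layers are read in the order given (assumed chronological). TIFF layers are
#' read with the \pkg{tiff} package; \code{.csv} layers are headerless numeric
#' matrices. All layers must share one shape.
#'
#' @param paths character vector of layer file paths, in time order.
#' @param start \code{c(year, month)} of the first layer.
#' @param units,name metadata.
#' @return a \code{raster_stack}.
#' @export
read_raster_stack <- function(paths, start = c(2001L, 1L), units = "", name = "") {
  layers <- lapply(paths, read_layer)
  shapes <- vapply(layers, function(m) paste(dim(m), collapse = "x"), "")
  if (length(unique(shapes)) != 1L)
    stop("layer shape mismatch: ", paste(unique(shapes), collapse = " vs "))
  d <- dim(layers[[1L]])
  a <- array(NA_real_, c(length(layers), d[1L], d[2L]))
  for (i in seq_along(layers)) a[i, , ] <- layers[[i]]
  raster_stack(a, start = start, units = units, name = name)
}

#' Write a single 2-D map to disk
#'
#' \code{.tif}/\code{.tiff} paths are written as 32-bit TIFF holding the map
#' linearly scaled to [0,1], with a JSON sidecar (\code{<path>.json}) storing
#' the value range and nodata cells; round trips preserve values to better
#' than float32 precision of the map's range. \code{.csv} paths are written as
#' a headerless numeric matrix (exact decimal round trip).
#'
#' @param map numeric matrix.
#' @param path output path.
#' @export
write_raster <- function(map, path) {
  map <- as.matrix(map)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    na_cells <- which(is.na(map))
    vmin <- suppressWarnings(min(map, na.rm = TRUE))
    vmax <- suppressWarnings(max(map, na.rm = TRUE))
    if (!is.finite(vmin)) { vmin <- 0; vmax <- 1 }
    scaled <- if (vmax > vmin) (map - vmin) / (vmax - vmin) else map * 0
    scaled[is.na(scaled)] <- 0
    tiff::writeTIFF(scaled, path, bits.per.sample = 32L,
                    compression = "none", reduce = FALSE)
    jsonlite::write_json(list(vmin = vmin, vmax = vmax,
                              na_cells = as.integer(na_cells)),
                         paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.table(map, path, sep = ",", row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Write every layer of a stack
#' @param stack a \code{raster_stack}.
#' @param dir output directory.
#' @param prefix file-name prefix; layer files are \code{<prefix>_<YYYY-MM>.<ext>}.
#' @param format "tif" or "csv".
#' @return the written paths, in time order.
#' @export
write_raster_stack <- function(stack, dir, prefix = "layer", format = c("tif", "csv")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lin <- ym_to_linear(stack$start[1L], stack$start[2L]) + seq_len(n_months_of(stack)) - 1L
  labs <- sprintf("%04d-%02d", lin %/% 12L, lin %% 12L + 1L)
  paths <- file.path(dir, sprintf("%s_%s.%s", prefix, labs, format))
  for (i in seq_len(n_months_of(stack))) write_raster(stack$data[i, , ], paths[i])
  invisible(paths)
}
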