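#' Write a surface cloud as a PLY file
#'
#' Emits per-vertex properties `x,y,z` (float64), `vessel` (uchar code:
#' 0 = LM, 1 = LAD, 2 = LCX, 3 = JUNCTION), `station` (int32), `angle`
#' (float64, radians) and, when supplied, a `tawss` float64 property.
#' Binary little-endian by default; ASCII for diffable output.
#'
#' @param cloud a `surface_cloud`.
#' @param path output path.
#' @param tawss optional per-point TAWSS vector to append.
#' @param format `"binary_little_endian"` or `"ascii"`.
#' @return `path`, invisibly.
#' @export
write_ply <- function(cloud, path, tawss = NULL,
                      format = c("binary_little_endian", "ascii")) {
  format <- match.arg(format)
  n <- nrow(cloud$coords)
  codes <- c(LM = 0L, LAD = 1L, LCX = 2L, JUNCTION = 3L)
  vessel <- codes[cloud$vessel_label]
  if (!is.null(tawss) && length(tawss) != n) {
    stop("tawss length does not match the cloud", call. = FALSE)
  }
  header <- c("ply",
              paste("format", format, "1.0"),
              "comment idealized coronary bifurcation surface cloud",
              paste("element vertex", n),
              "property double x", "property double y", "property double z",
              "property uchar vessel", "property int station",
              "property double angle",
              if (!is.null(tawss)) "property double tawss",
              "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  if (format == "ascii") {
    df <- data.frame(cloud$coords[, 1], cloud$coords[, 2], cloud$coords[, 3],
                     vessel, cloud$station_index, cloud$circ_angle)
    if (!is.null(tawss)) df$tawss <- tawss
    txt <- do.call(paste, lapply(df, base::format, digits = 17, trim = TRUE,
                                 scientific = FALSE))
    writeLines(txt, con, sep = "\n")
  } else {
    for (i in seq_len(n)) {
      writeBin(as.numeric(cloud$coords[i, ]), con, size = 8,
               endian = "little")
      writeBin(as.raw(vessel[i]), con)
      writeBin(as.integer(cloud$station_index[i]), con, size = 4,
               endian = "little")
      vals <- c(cloud$circ_angle[i], if (!is.null(tawss)) tawss[i])
      writeBin(as.numeric(vals), con, size = 8, endian = "little")
    }
  }
  invisible(path)
}

#' Read a PLY file written by [write_ply()]
#'
#' Supports the vertex schema emitted by this package (ascii or binary
#' little-endian).
#'
#' @param path file path.
#' @return List with `cloud` (a partial `surface_cloud`: coords, labels,
#'   stations, angles) and `tawss` (vector or `NULL`).
#' @export
read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character(0)
  repeat {
    line <- readLines(con, n = 1L)
    header <- c(header, line)
    if (identical(line, "end_header")) break
    if (length(header) > 100L) stop("malformed PLY header", call. = FALSE)
  }
  fmt <- sub("^format ([a-z_]+) .*$", "\\1", grep("^format", header,
                                                  value = TRUE))
  n <- as.integer(sub("^element vertex ", "",
                      grep("^element vertex", header, value = TRUE)))
  props <- sub("^property ([a-z0-9]+) ([a-z]+)$", "\\1 \\2",
               grep("^property", header, value = TRUE))
  types <- vapply(strsplit(props, " "), `[`, "", 1L)
  nms <- vapply(strsplit(props, " "), `[`, "", 2L)
  vals <- matrix(NA_real_, n, length(nms), dimnames = list(NULL, nms))
  if (fmt == "ascii") {
    txt <- readLines(con, n = n)
    sp <- strsplit(trimws(txt), "[[:space:]]+")
    vals[] <- t(vapply(sp, as.numeric, numeric(length(nms))))
  } else {
    for (i in seq_len(n)) {
      for (j in seq_along(nms)) {
        vals[i, j] <- switch(types[j],
          double = readBin(con, "numeric", 1L, size = 8, endian = "little"),
          float = readBin(con, "numeric", 1L, size = 4, endian = "little"),
          int = readBin(con, "integer", 1L, size = 4, endian = "little"),
          uchar = as.integer(readBin(con, "raw", 1L)),
          stop("unsupported PLY property type: ", types[j], call. = FALSE))
      }
    }
  }
  codes <- c("LM", "LAD", "LCX", "JUNCTION")
  nc <- sqrt(n)
  cloud <- structure(list(
    coords = vals[, c("x", "y", "z"), drop = FALSE],
    vessel_label = codes[vals[, "vessel"] + 1L],
    station_index = as.integer(vals[, "station"]),
    circ_angle = vals[, "angle"],
    grid_rows = if (nc == round(nc)) as.integer(nc) else NA_integer_,
    grid_cols = if (nc == round(nc)) as.integer(nc) else NA_integer_,
    model_id = NA_character_), class = "surface_cloud")
  list(cloud = cloud,
       tawss = if ("tawss" %in% nms) vals[, "tawss"] else NULL)
}

#' @rdname write_ply
#' @export
write_cloud_csv <- function(cloud, path, tawss = NULL) {
  df <- data.frame(x = cloud$coords[, 1], y = cloud$coords[, 2],
                   z = cloud$coords[, 3], vessel = cloud$vessel_label,
                   station = cloud$station_index, angle = cloud$circ_angle)
  if (!is.null(tawss)) df$tawss <- tawss
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_ply
#' @export
read_cloud_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  n <- nrow(df); nc <- sqrt(n)
  cloud <- structure(list(
    coords = as.matrix(df[, c("x", "y", "z")]),
    vessel_label = df$vessel, station_index = df$station,
    circ_angle = df$angle,
    grid_rows = if (nc == round(nc)) as.integer(nc) else NA_integer_,
    grid_cols = if (nc == round(nc)) as.integer(nc) else NA_integer_,
    model_id = NA_character_), class = "surface_cloud")
  list(cloud = cloud, tawss = df$tawss)
}
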