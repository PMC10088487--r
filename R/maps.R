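#' Frequency map of significant responses
#'
#' A channels x points matrix of values in `[0, 1]`: the fraction of
#' pairs/trials/subjects with a significant response at each (channel, point).
#' Points are either times after phoneme onset or cross-correlation lags, in
#' milliseconds on the EEG sampling grid. The chance level is the expected
#' fraction of significant cells under the null (about `0.05 / n_points` per
#' channel for BH-FDR at alpha = 0.05, i.e. ~0.0004 for 125 points).
#'
#' @param values channels x points numeric matrix in `[0, 1]`.
#' @param points_ms numeric vector of point positions in ms.
#' @param channels channel labels.
#' @param axis `"time"` (post-onset) or `"lag"`.
#' @param level aggregation level: `"pair"`, `"trial"`, `"subject"`, `"group"`.
#' @param chance_level expected null fraction of significant cells.
#' @param n_s,n_v number of subjects / visits entering the map (group level).
#' @return object of class `frequency_map` (a matrix with attributes).
#' @export
frequency_map <- function(values, points_ms, channels = rownames(values),
                          axis = c("time", "lag"),
                          level = c("pair", "trial", "subject", "group"),
                          chance_level = 0.05 / ncol(values),
                          n_s = NA_integer_, n_v = NA_integer_) {
  axis <- match.arg(axis); level <- match.arg(level)
  values <- as.matrix(values)
  if (is.null(channels)) channels <- paste0("ch", seq_len(nrow(values)))
  if (length(points_ms) != ncol(values))
    stop("points_ms length does not match map width")
  if (any(values < -1e-12 | values > 1 + 1e-12, na.rm = TRUE))
    stop("frequency map values must lie in [0, 1]")
  rownames(values) <- channels
  colnames(values) <- sprintf("%g", points_ms)
  structure(values, points_ms = as.numeric(points_ms), axis = axis,
            level = level, chance_level = chance_level,
            n_s = as.integer(n_s), n_v = as.integer(n_v),
            class = c("frequency_map", "matrix", "array"))
}

#' @export
print.frequency_map <- function(x, ...) {
  cat(sprintf("<frequency_map level=%s axis=%s> %d channels x %d points, chance %.2g\n",
              attr(x, "level"), attr(x, "axis"), nrow(x), ncol(x),
              attr(x, "chance_level")))
  cat(sprintf("  value range [%.4g, %.4g], mean %.4g\n",
              min(x), max(x), mean(x)))
  invisible(x)
}

#' Write / read a frequency map
#'
#' Lossless round trip through a tab-separated table with `#`-prefixed
#' metadata header lines (axis, level, chance level, subject/visit counts)
#' followed by a channels x points matrix at full double precision.
#'
#' @param map a [frequency_map].
#' @param path file path.
#' @return `write_map`: `path`, invisibly; `read_map`: a [frequency_map].
#' @export
write_map <- function(map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# axis: %s", attr(map, "axis")),
               sprintf("# level: %s", attr(map, "level")),
               sprintf("# chance_level: %.17g", attr(map, "chance_level")),
               sprintf("# n_s: %d", attr(map, "n_s")),
               sprintf("# n_v: %d", attr(map, "n_v")),
               paste0("# channels: ", paste(rownames(map), collapse = "\t")),
               paste0("# points_ms: ",
                      paste(sprintf("%.10g", attr(map, "points_ms")), collapse = "\t"))),
             con)
  utils::write.table(format(unclass(map), digits = 17, trim = TRUE, scientific = TRUE),
                     con, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    m <- grep(paste0("^#\\s*", key, ":"), hdr, value = TRUE)
    if (!length(m)) stop("map file lacks '", key, "' header: ", path)
    sub(paste0("^#\\s*", key, ":\\s*"), "", m[1])
  }
  channels <- strsplit(get("channels"), "\t", fixed = TRUE)[[1]]
  points_ms <- as.numeric(strsplit(get("points_ms"), "\t", fixed = TRUE)[[1]])
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != length(channels))
    stop("declared channel count (", length(channels),
         ") does not match data rows (", length(body), ")")
  values <- do.call(rbind, lapply(body, function(l)
    as.numeric(strsplit(trimws(l), "[\t ]+")[[1]])))
  if (ncol(values) != length(points_ms))
    stop("declared point count does not match data columns")
  ns <- suppressWarnings(as.integer(get("n_s")))
  nv <- suppressWarnings(as.integer(get("n_v")))
  frequency_map(values, points_ms, channels, axis = get("axis"),
                level = get("level"),
                chance_level = as.numeric(get("chance_level")),
                n_s = ns, n_v = nv)
}
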