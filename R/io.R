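#' Plain-text I/O for feature tables and parameter maps
#'
#' The usual neuroimaging containers (NIfTI) have no reader in this
#' package's dependency set, so on-disk exchange uses plain text: feature
#' tables as CSV and parameter-map sets as long-format TSV with a header
#' line carrying grid dimensions and voxel size. Round-trips are exact to
#' the printed precision (full double precision is written).
#'
#' @param tab a feature table ([build_feature_table()]).
#' @param path output file.
#' @name text_io
NULL

#' @rdname text_io
#' @export
write_feature_csv <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname text_io
#' @export
read_feature_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path, check.names = FALSE)
  need <- c("id", "label")
  miss <- setdiff(need, colnames(tab))
  if (length(miss)) stop("feature CSV missing column(s): ",
                         paste(miss, collapse = ", "))
  tab
}

#' @rdname text_io
#' @param map_set a [param_map_set].
#' @export
write_param_maps <- function(map_set, path) {
  stopifnot(inherits(map_set, "param_map_set"))
  d <- dim(map_set$maps[[1L]])
  hdr <- sprintf("#dims %d %d %d voxel %.17g %.17g %.17g",
                 d[1L], d[2L], d[3L],
                 map_set$voxel_size[1L], map_set$voxel_size[2L],
                 map_set$voxel_size[3L])
  any_fin <- Reduce(`|`, lapply(map_set$maps, is.finite))
  idx <- which(any_fin)
  co <- arrayInd(idx, d)
  df <- data.frame(x = co[, 1L], y = co[, 2L], z = co[, 3L])
  for (nm in names(map_set$maps)) df[[nm]] <- map_set$maps[[nm]][idx]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = TRUE),
                     con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname text_io
#' @export
read_param_maps <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  hdr <- readLines(path, n = 1L)
  if (!startsWith(hdr, "#dims")) stop("not a parameter-map TSV: ", path)
  tok <- strsplit(trimws(hdr), "\\s+")[[1L]]
  d <- as.integer(tok[2:4]); vs <- as.numeric(tok[6:8])
  df <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1L,
                          check.names = FALSE)
  idx <- df$x + (df$y - 1L) * d[1L] + (df$z - 1L) * d[1L] * d[2L]
  map_names <- setdiff(colnames(df), c("x", "y", "z"))
  maps <- lapply(map_names, function(nm) {
    a <- array(NA_real_, d)
    a[idx] <- as.numeric(df[[nm]])
    a
  })
  names(maps) <- map_names
  param_map_set(maps, voxel_size = vs,
                require_full = setequal(map_names, metric_catalog()$map))
}
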