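#' Construct a peak table
#'
#' A peak table holds a chromatographic fingerprint as a peaks-by-observations
#' matrix of peak areas, optionally accompanied by a matching matrix of
#' standard deviations (for group-mean tables) and per-peak metadata
#' (retention time in minutes, compound name, source herb, detection
#' wavelength in nm).
#'
#' @param areas numeric matrix, peaks in rows, observations (samples or
#'   groups) in columns.  Row names are the peak ids, column names the
#'   observation labels.  All areas must be non-negative.
#' @param area_sd optional non-negative matrix of the same shape, holding the
#'   standard deviation of each group mean.
#' @param meta optional data frame of per-peak metadata with a `peak_id`
#'   column; typical columns are `rt`, `compound`, `herb` and `wavelength`.
#' @return an object of class `peak_table`.
#' @export
peak_table <- function(areas, area_sd = NULL, meta = NULL) {
  areas <- as.matrix(areas)
  if (is.null(rownames(areas)))
    rownames(areas) <- paste0("P", seq_len(nrow(areas)))
  if (is.null(colnames(areas)))
    colnames(areas) <- paste0("obs", seq_len(ncol(areas)))
  if (anyDuplicated(rownames(areas)))
    stop("duplicate peak ids: ",
         paste(unique(rownames(areas)[duplicated(rownames(areas))]),
               collapse = ", "))
  if (anyNA(areas))
    stop("missing values are not allowed in peak areas")
  if (!is.numeric(areas))
    stop("peak areas must be numeric")
  if (any(areas < 0))
    stop("negative peak areas are not allowed")
  if (!is.null(area_sd)) {
    area_sd <- as.matrix(area_sd)
    if (!identical(dim(area_sd), dim(areas)))
      stop("area_sd must have the same shape as areas")
    if (anyNA(area_sd) || any(area_sd < 0))
      stop("area_sd must be non-negative and complete")
    dimnames(area_sd) <- dimnames(areas)
  }
  if (!is.null(meta)) {
    meta <- as.data.frame(meta)
    if (!"peak_id" %in% names(meta))
      stop("meta must have a peak_id column")
    if (!setequal(meta$peak_id, rownames(areas)))
      stop("meta peak ids do not match the area matrix")
    meta <- meta[match(rownames(areas), meta$peak_id), , drop = FALSE]
    rownames(meta) <- NULL
  }
  structure(list(areas = areas, area_sd = area_sd, meta = meta),
            class = "peak_table")
}

#' @export
print.peak_table <- function(x, ...) {
  cat(sprintf("<peak_table> %d peaks x %d observations%s\n",
              nrow(x$areas), ncol(x$areas),
              if (!is.null(x$area_sd)) " (group means +/- sd)" else ""))
  cat("peaks:        ", paste(utils::head(rownames(x$areas), 6L),
                              collapse = ", "),
      if (nrow(x$areas) > 6L) ", ..." else "", "\n", sep = "")
  cat("observations: ", paste(colnames(x$areas), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' @export
dim.peak_table <- function(x) dim(x$areas)

peak_ids <- function(x) rownames(x$areas)

#' Read a peak table from CSV/TSV
#'
#' Two dialects are supported.  `samples`: plain numeric cells, one column
#' per sample.  `group_means`: each cell encodes a group mean and standard
#' deviation, either as a single `"mean +/- sd"` string (the characters
#' `±`, `+-` and `+/-` are all accepted as the separator) or as paired
#' `<group>_mean` / `<group>_sd` columns.
#'
#' @param path file path; the delimiter is inferred from the extension
#'   (`.tsv`/`.txt` are tab-separated, everything else comma-separated).
#' @param dialect `"samples"` or `"group_means"`.
#' @return a [peak_table()].  Metadata columns (`rt`, `compound`, `herb`,
#'   `wavelength`) are picked up when present.
#' @export
load_peak_table <- function(path, dialect = c("samples", "group_means")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read_delim_auto(path)
  if (!nrow(df)) stop("empty peak table: ", path)
  id_col <- names(df)[1L]
  ids <- as.character(df[[id_col]])
  if (anyDuplicated(ids))
    stop("duplicate peak ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  meta_cols <- intersect(c("rt", "compound", "herb", "wavelength"), names(df))
  val_cols <- setdiff(names(df), c(id_col, meta_cols))
  if (!length(val_cols)) stop("no observation columns in ", path)

  if (dialect == "samples") {
    areas <- as.matrix(df[val_cols])
    if (!is.numeric(areas))
      stop("non-numeric area cells in ", path)
    storage.mode(areas) <- "double"
    area_sd <- NULL
    colnames(areas) <- val_cols
  } else {
    sd_cols <- grep("_sd$", val_cols, value = TRUE)
    mean_cols <- grep("_mean$", val_cols, value = TRUE)
    if (length(mean_cols) && setequal(sub("_mean$", "", mean_cols),
                                      sub("_sd$", "", sd_cols))) {
      groups <- sub("_mean$", "", mean_cols)
      areas <- as.matrix(df[mean_cols])
      area_sd <- as.matrix(df[paste0(groups, "_sd")])
      storage.mode(areas) <- "double"
      storage.mode(area_sd) <- "double"
      colnames(areas) <- colnames(area_sd) <- groups
    } else {
      # "mean +/- sd" encoded cells
      parse_pm <- function(v) {
        v <- gsub(",", "", as.character(v))
        parts <- strsplit(v, "±|\\+/-|\\+-")
        mean <- vapply(parts, function(p) as.numeric(trimws(p[1L])), 0)
        sd <- vapply(parts, function(p)
          if (length(p) > 1L) as.numeric(trimws(p[2L])) else 0, 0)
        list(mean = mean, sd = sd)
      }
      parsed <- lapply(df[val_cols], parse_pm)
      areas <- vapply(parsed, `[[`, numeric(nrow(df)), "mean")
      area_sd <- vapply(parsed, `[[`, numeric(nrow(df)), "sd")
      areas <- matrix(areas, nrow = nrow(df),
                      dimnames = list(NULL, val_cols))
      area_sd <- matrix(area_sd, nrow = nrow(df),
                        dimnames = list(NULL, val_cols))
      if (anyNA(areas))
        stop("unparseable mean ± sd cells in ", path)
    }
  }
  rownames(areas) <- ids
  if (!is.null(area_sd)) rownames(area_sd) <- ids
  meta <- if (length(meta_cols))
    cbind(data.frame(peak_id = ids, stringsAsFactors = FALSE), df[meta_cols])
  peak_table(areas, area_sd = area_sd, meta = meta)
}

#' Write a peak table to CSV
#'
#' Values are written at full double precision (15 significant digits) so a
#' write/read round trip reproduces the table to at least 12 significant
#' digits.  Group-mean tables are written with paired `_mean`/`_sd` columns.
#'
#' @param x a [peak_table()].
#' @param path output file path.
#' @export
write_peak_table <- function(x, path) {
  stopifnot(inherits(x, "peak_table"))
  fmt <- function(m) apply(m, 2L, function(col) sprintf("%.15g", col))
  df <- data.frame(peak_id = rownames(x$areas), stringsAsFactors = FALSE)
  if (!is.null(x$meta))
    df <- cbind(df, x$meta[setdiff(names(x$meta), "peak_id")])
  if (is.null(x$area_sd)) {
    df <- cbind(df, as.data.frame(fmt(x$areas)))
  } else {
    groups <- colnames(x$areas)
    vals <- fmt(x$areas); sds <- fmt(x$area_sd)
    for (g in seq_along(groups)) {
      df[[paste0(groups[g], "_mean")]] <- vals[, g]
      df[[paste0(groups[g], "_sd")]] <- sds[, g]
    }
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Standardize peak rows to z-scores
#'
#' Each peak row is centred and scaled to zero mean and unit sample standard
#' deviation (n-1 denominator, the SPSS "save standardized values"
#' convention).  Constant rows cannot be scaled; they are mapped to all-zero
#' with a warning.
#'
#' @param x a [peak_table()].
#' @return a `peak_table` of standardized areas (the `area_sd` slot is
#'   dropped; z-scores may be negative, so validation is relaxed).
#' @export
standardize_peaks <- function(x) {
  stopifnot(inherits(x, "peak_table"))
  if (ncol(x$areas) < 2L)
    stop("at least 2 observations per peak are required (sd undefined)")
  m <- rowMeans(x$areas)
  s <- apply(x$areas, 1L, stats::sd)
  const <- s < .Machine$double.eps * 100 * pmax(abs(m), 1)
  if (any(const))
    warning("constant peak rows mapped to zero: ",
            paste(rownames(x$areas)[const], collapse = ", "))
  z <- (x$areas - m) / ifelse(const, 1, s)
  z[const, ] <- 0
  out <- x
  out$areas <- z
  out$area_sd <- NULL
  attr(out, "standardized") <- TRUE
  out
}
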