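#' Construct an efficacy panel
#'
#' A groups-by-indicators matrix of pharmacodynamic outcomes, with an
#' orientation flag per indicator (`TRUE` = higher is better, the state of
#' every indicator after positive transformation).
#'
#' @param values numeric matrix, groups in rows, indicators in columns.
#' @param orientation logical vector, one flag per indicator; recycled from
#'   a single value.  Defaults to all `TRUE`.
#' @return an object of class `efficacy_panel`.
#' @export
efficacy_panel <- function(values, orientation = TRUE) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("efficacy values must be numeric")
  if (anyNA(values)) stop("missing values are not allowed in efficacy panels")
  if (is.null(rownames(values)))
    rownames(values) <- paste0("G", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("ind", seq_len(ncol(values)))
  if (anyDuplicated(colnames(values)))
    stop("duplicate indicator ids")
  orientation <- rep_len(as.logical(orientation), ncol(values))
  names(orientation) <- colnames(values)
  structure(list(values = values, orientation = orientation),
            class = "efficacy_panel")
}

#' @export
print.efficacy_panel <- function(x, ...) {
  cat(sprintf("<efficacy_panel> %d groups x %d indicators\n",
              nrow(x$values), ncol(x$values)))
  print(round(x$values, 3))
  invisible(x)
}

#' @export
dim.efficacy_panel <- function(x) dim(x$values)

#' Subset the indicators of an efficacy panel
#'
#' @param x an [efficacy_panel()].
#' @param indicators character vector of indicator ids to keep, in order.
#' @return an `efficacy_panel` restricted to those indicators.
#' @export
panel_indicators <- function(x, indicators) {
  stopifnot(inherits(x, "efficacy_panel"))
  missing <- setdiff(indicators, colnames(x$values))
  if (length(missing))
    stop("unknown indicators: ", paste(missing, collapse = ", "))
  efficacy_panel(x$values[, indicators, drop = FALSE],
                 x$orientation[indicators])
}

#' Read an efficacy panel from CSV/TSV
#'
#' @param path file path; first column = group labels, remaining columns =
#'   indicators.
#' @param orientation per-indicator higher-is-better flags (default all
#'   `TRUE`, the convention for positively transformed panels).
#' @return an [efficacy_panel()].
#' @export
load_efficacy_panel <- function(path, orientation = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read_delim_auto(path)
  vals <- as.matrix(df[-1L])
  storage.mode(vals) <- "double"
  rownames(vals) <- as.character(df[[1L]])
  efficacy_panel(vals, orientation)
}

#' Write an efficacy panel to CSV
#'
#' @param x an [efficacy_panel()].
#' @param path output file path.
#' @export
write_efficacy_panel <- function(x, path) {
  stopifnot(inherits(x, "efficacy_panel"))
  df <- data.frame(group = rownames(x$values), stringsAsFactors = FALSE,
                   check.names = FALSE)
  for (j in colnames(x$values)) df[[j]] <- sprintf("%.15g", x$values[, j])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# shared reader: delimiter by extension, no name mangling
read_delim_auto <- function(path) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  n_fields <- utils::count.fields(path, sep = sep, quote = "\"",
                                  comment.char = "")
  if (length(unique(n_fields)) > 1L)
    stop("ragged rows in ", path)
  utils::read.table(path, header = TRUE, sep = sep,
                    check.names = FALSE, stringsAsFactors = FALSE,
                    quote = "\"", comment.char = "")
}
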