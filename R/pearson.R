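#' Pearson correlation screening of peaks against an indicator
#'
#' Computes the Pearson coefficient of every peak row against one
#' pharmacodynamic indicator, with a two-sided p-value from the t transform
#' \eqn{t = r\sqrt{(n-2)/(1-r^2)}} on n-2 degrees of freedom, and returns
#' the peaks ranked for screening.  Ranking is by absolute coefficient by
#' default (strongly negatively correlated peaks are candidate actives
#' too); `rank_by = "signed"` ranks by the signed coefficient.  Ties are
#' broken by peak id order.  Constant peak rows have no defined coefficient
#' and are skipped with a warning.
#'
#' @param peaks a [peak_table()] (typically standardized) or a numeric
#'   matrix with peaks in rows.
#' @param efficacy numeric vector of the indicator over the same
#'   observations (length = number of columns).
#' @param k top-k peaks to report (default 5).
#' @param rank_by `"abs"` (default) or `"signed"`.
#' @return an object of class `correlation_result`: a list with `table`
#'   (data frame peak, r, p, rank ordered by rank), `top` (the top-k peak
#'   ids), `n`, `rank_by`.
#' @export
pearson_screen <- function(peaks, efficacy, k = 5,
                           rank_by = c("abs", "signed")) {
  rank_by <- match.arg(rank_by)
  x <- if (inherits(peaks, "peak_table")) peaks$areas else as.matrix(peaks)
  if (is.null(rownames(x))) rownames(x) <- paste0("P", seq_len(nrow(x)))
  n <- ncol(x)
  if (length(efficacy) != n)
    stop("efficacy length does not match the number of observations")
  if (n < 3L) stop("at least 3 paired observations are required")
  if (stats::sd(efficacy) == 0)
    stop("the indicator is constant; correlation undefined")

  sds <- apply(x, 1L, stats::sd)
  const <- sds == 0
  if (all(const)) {
    warning("all peaks constant; empty ranking")
    return(structure(list(table = data.frame(peak = character(),
                                             r = numeric(), p = numeric(),
                                             rank = integer()),
                          top = character(), n = n, rank_by = rank_by),
                     class = "correlation_result"))
  }
  if (any(const))
    warning("constant peaks skipped: ",
            paste(rownames(x)[const], collapse = ", "))
  x <- x[!const, , drop = FALSE]
  r <- as.numeric(stats::cor(t(x), efficacy))
  # two-sided p from the exact t reference; |r| = 1 gives p = 0
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1] <- 0
  key <- if (rank_by == "abs") -abs(r) else -r
  ord <- order(key, rownames(x))
  tab <- data.frame(peak = rownames(x)[ord], r = r[ord], p = p[ord],
                    rank = seq_along(ord), stringsAsFactors = FALSE)
  structure(list(table = tab, top = utils::head(tab$peak, k), n = n,
                 rank_by = rank_by),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> n = %d, ranked by %s r\n", x$n,
              if (x$rank_by == "abs") "|r|" else "signed"))
  print(utils::head(x$table, 10L), row.names = FALSE)
  invisible(x)
}
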