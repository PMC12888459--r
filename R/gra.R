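#' Grey relational analysis
#'
#' Deng's grey relational analysis of a set of peak subsequences against a
#' pharmacodynamic parent sequence.  With
#' \eqn{\Delta_{oi}(k) = |x_0(k) - x_i(k)|} and the global extremes
#' \eqn{\Delta_{min}, \Delta_{max}} taken over all subsequences and
#' positions, the relational coefficient is
#' \deqn{\varepsilon_i(k) = \frac{\Delta_{min} + \rho\,\Delta_{max}}
#'       {\Delta_{oi}(k) + \rho\,\Delta_{max}}}
#' and the grey relational degree of subsequence i is the mean coefficient
#' \eqn{r_i = \frac{1}{N}\sum_k \varepsilon_i(k)}.
#'
#' Sequences are compared exactly as supplied; standardize peaks and parent
#' to a common scale first (see [standardize_peaks()]).  Classical
#' initial-value or mean-image pre-normalisation is available through
#' `normalize` for raw positive sequences.
#'
#' @param parent numeric parent (reference) sequence of length N >= 2.
#' @param subsequences numeric matrix, one subsequence per row, N columns;
#'   a vector is treated as a single subsequence.
#' @param rho distinguishing coefficient in (0, 1]; conventionally 0.5.
#' @param normalize `"none"` (default), `"initial"` (divide each sequence
#'   by its first value) or `"mean"` (divide by its mean), applied to
#'   parent and subsequences alike.
#' @return an object of class `gra_result` with fields `rho`,
#'   `coefficients` (subsequences x N), `grd` (named per subsequence),
#'   `delta_min`, `delta_max` and `ranking` (subsequence ids by descending
#'   GRD, ties broken by id order).
#' @export
gray_relational <- function(parent, subsequences, rho = 0.5,
                            normalize = c("none", "initial", "mean")) {
  normalize <- match.arg(normalize)
  if (is.null(dim(subsequences)))
    subsequences <- matrix(subsequences, nrow = 1L)
  subsequences <- as.matrix(subsequences)
  if (is.null(rownames(subsequences)))
    rownames(subsequences) <- paste0("S", seq_len(nrow(subsequences)))
  N <- length(parent)
  if (N < 2L) stop("sequences must have length >= 2")
  if (ncol(subsequences) != N)
    stop("subsequence length does not match the parent sequence")
  if (rho <= 0 || rho > 1) stop("rho must be in (0, 1]")
  norm_fun <- switch(normalize,
                     none = identity,
                     initial = function(v) v / v[1L],
                     mean = function(v) v / mean(v))
  parent <- norm_fun(as.numeric(parent))
  if (normalize != "none")
    subsequences <- t(apply(subsequences, 1L, norm_fun))

  delta <- abs(sweep(subsequences, 2L, parent))
  d_min <- min(delta)
  d_max <- max(delta)
  eps <- if (d_max == 0) {
    # every subsequence identical to the parent
    matrix(1, nrow(delta), ncol(delta), dimnames = dimnames(delta))
  } else {
    (d_min + rho * d_max) / (delta + rho * d_max)
  }
  grd <- rowMeans(eps)
  ord <- order(-grd, rownames(subsequences))
  structure(list(rho = rho,
                 coefficients = eps,
                 grd = grd,
                 delta_min = d_min,
                 delta_max = d_max,
                 ranking = rownames(subsequences)[ord]),
            class = "gra_result")
}

#' @export
print.gra_result <- function(x, ...) {
  cat(sprintf("<gra_result> %d subsequences, N = %d, rho = %g\n",
              length(x$grd), ncol(x$coefficients), x$rho))
  top <- x$grd[x$ranking][seq_len(min(10L, length(x$grd)))]
  print(round(top, 4))
  invisible(x)
}

#' Screen peaks by grey relational degree
#'
#' Keeps subsequences with GRD strictly above `threshold`, ordered by
#' descending GRD (ties broken by id order), truncated to the top `k`.
#'
#' @param result a [gray_relational()] result.
#' @param threshold GRD cutoff (default 0.8).
#' @param k maximum number of peaks returned (default 5).
#' @return character vector of surviving peak ids (possibly empty).
#' @export
grd_screen <- function(result, threshold = 0.8, k = 5) {
  stopifnot(inherits(result, "gra_result"))
  keep <- result$ranking[result$grd[result$ranking] > threshold]
  utils::head(keep, k)
}

#' Export grey relational degrees as a long-format table
#'
#' @param result a [gray_relational()] result.
#' @param indicator label of the parent sequence.
#' @return data frame with columns indicator, peak, grd, rank.
#' @export
gra_table <- function(result, indicator = "indicator") {
  stopifnot(inherits(result, "gra_result"))
  data.frame(indicator = indicator,
             peak = result$ranking,
             grd = as.numeric(result$grd[result$ranking]),
             rank = seq_along(result$ranking),
             stringsAsFactors = FALSE)
}
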