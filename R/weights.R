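#' Construct a weight scheme
#'
#' A named, normalised set of per-indicator weights together with its
#' provenance (`"AHP"`, `"EWM"`, `"combined"` or `"supplied"`).
#'
#' @param indicators character vector of indicator ids.
#' @param weights non-negative weights, one per indicator; normalised to
#'   sum 1.
#' @param provenance how the weights were obtained.
#' @return an object of class `weight_scheme`.
#' @export
weight_scheme <- function(indicators,
                          weights,
                          provenance = c("supplied", "AHP", "EWM",
                                         "combined")) {
  provenance <- match.arg(provenance)
  indicators <- as.character(indicators)
  if (length(indicators) != length(weights))
    stop("one weight per indicator is required")
  if (anyDuplicated(indicators)) stop("duplicate indicator ids")
  if (anyNA(weights) || any(weights < 0))
    stop("weights must be non-negative")
  s <- sum(weights)
  if (s <= 0) stop("weights must not all be zero")
  w <- as.numeric(weights) / s
  names(w) <- indicators
  structure(list(weights = w, provenance = provenance),
            class = "weight_scheme")
}

#' @export
print.weight_scheme <- function(x, ...) {
  cat(sprintf("<weight_scheme> (%s)\n", x$provenance))
  print(round(x$weights, 4))
  invisible(x)
}

# Saaty random consistency indices, n = 1..9
saaty_ri <- c(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45)

#' Analytic hierarchy process weights
#'
#' Derives priority weights from an n-by-n positive reciprocal pairwise
#' comparison matrix as the normalised principal right eigenvector (power
#' iteration), and reports Saaty's consistency ratio
#' \eqn{CR = [(\lambda_{max} - n)/(n - 1)] / RI(n)}.  A warning is issued
#' when CR >= 0.1, the conventional acceptability bound.
#'
#' @param matrix square positive reciprocal matrix (`a_ij = 1/a_ji`,
#'   unit diagonal), n in 2..9.
#' @param tol convergence tolerance of the power iteration.
#' @param max_iter iteration cap.
#' @param method `"eigenvector"` (default) or `"geometric_mean"` (row
#'   geometric means, normalised); the two agree on consistent matrices.
#' @return a list with `weights` (a [weight_scheme()]), `cr`, `lambda_max`.
#' @export
ahp_weights <- function(matrix, tol = 1e-12, max_iter = 1e4,
                        method = c("eigenvector", "geometric_mean")) {
  method <- match.arg(method)
  m <- as.matrix(matrix)
  n <- nrow(m)
  if (n != ncol(m) || n < 2L) stop("a square matrix with n >= 2 is required")
  if (any(m <= 0)) stop("comparison matrix must be positive")
  if (max(abs(m * t(m) - 1)) > 1e-6)
    stop("comparison matrix must be reciprocal (a_ij = 1/a_ji)")
  ids <- rownames(m)
  if (is.null(ids)) ids <- paste0("C", seq_len(n))

  if (method == "geometric_mean") {
    v <- exp(rowMeans(log(m)))
    v <- v / sum(v)
    lambda <- mean((m %*% v) / v)
  } else {
    v <- rep(1 / n, n)
    for (i in seq_len(max_iter)) {
      v_new <- as.numeric(m %*% v)
      v_new <- v_new / sum(v_new)
      if (max(abs(v_new - v)) < tol) { v <- v_new; break }
      v <- v_new
    }
    lambda <- mean((m %*% v) / v)
  }
  ri <- if (n <= length(saaty_ri)) saaty_ri[n] else 1.49
  ci <- (lambda - n) / (n - 1)
  cr <- if (ri == 0) 0 else ci / ri
  if (cr >= 0.1)
    warning(sprintf("consistency ratio %.3f >= 0.1; judgements inconsistent",
                    cr))
  list(weights = weight_scheme(ids, v, provenance = "AHP"),
       cr = cr, lambda_max = lambda)
}

#' Entropy weight method
#'
#' Objective weighting of a positively oriented panel: each indicator is
#' min-max normalised across groups, turned into a share distribution
#' \eqn{p_{ij}}, and scored by its information entropy
#' \eqn{e_j = -\frac{1}{\ln n}\sum_i p_{ij}\ln p_{ij}} (with
#' \eqn{0\ln 0 := 0}).  The divergence \eqn{d_j = 1 - e_j} becomes the
#' weight after normalisation: indicators that differentiate the groups
#' more receive more weight; constant indicators receive weight 0.
#'
#' @param panel an [efficacy_panel()] with at least 2 groups, all
#'   indicators higher-is-better.
#' @return a [weight_scheme()] with provenance `"EWM"`.
#' @export
ewm_weights <- function(panel) {
  stopifnot(inherits(panel, "efficacy_panel"))
  x <- panel$values
  n <- nrow(x)
  if (n < 2L) stop("at least 2 groups are required")
  if (!all(panel$orientation))
    stop("EWM requires a positively oriented panel")
  d <- apply(x, 2L, function(col) {
    rng <- max(col) - min(col)
    if (rng == 0) return(0)            # constant indicator: no information
    xp <- (col - min(col)) / rng
    p <- xp / sum(xp)
    e <- -sum(ifelse(p > 0, p * log(p), 0)) / log(n)
    1 - e
  })
  if (all(d == 0))
    stop("all indicators constant across groups; weights undefined")
  weight_scheme(colnames(x), d, provenance = "EWM")
}

#' Combine subjective and objective weight schemes
#'
#' @param w_ahp,w_ewm two [weight_scheme()]s over the same indicators.
#' @param method `"multiplicative"` (default):
#'   \eqn{w_j = a_j b_j / \sum_k a_k b_k}; or `"arithmetic_mean"`:
#'   \eqn{w_j = (a_j + b_j)/2}.
#' @return a normalised [weight_scheme()] with provenance `"combined"`.
#' @export
combine_weights <- function(w_ahp, w_ewm,
                            method = c("multiplicative",
                                       "arithmetic_mean")) {
  method <- match.arg(method)
  stopifnot(inherits(w_ahp, "weight_scheme"),
            inherits(w_ewm, "weight_scheme"))
  if (!setequal(names(w_ahp$weights), names(w_ewm$weights)))
    stop("indicator sets differ between the two schemes")
  a <- w_ahp$weights
  b <- w_ewm$weights[names(a)]
  w <- switch(method,
              multiplicative = a * b,
              arithmetic_mean = (a + b) / 2)
  weight_scheme(names(a), w, provenance = "combined")
}

#' Composite efficacy score
#'
#' The weighted sum \eqn{\mathrm{score}_g = \sum_j w_j v_{gj}} of a
#' positively oriented panel, with no further rescaling, plus the
#' descending rank order of the groups.
#'
#' @param panel an [efficacy_panel()]; its indicator set must match the
#'   weight scheme.
#' @param w a [weight_scheme()].
#' @return a list with `scores` (named by group) and `ranking` (group ids,
#'   best first).
#' @export
composite_score <- function(panel, w) {
  stopifnot(inherits(panel, "efficacy_panel"), inherits(w, "weight_scheme"))
  if (!setequal(colnames(panel$values), names(w$weights)))
    stop("panel indicators do not match the weight scheme")
  if (!all(panel$orientation))
    stop("composite scoring requires a positively oriented panel")
  v <- panel$values[, names(w$weights), drop = FALSE]
  scores <- as.numeric(v %*% w$weights)
  names(scores) <- rownames(v)
  list(scores = scores,
       ranking = names(sort(scores, decreasing = TRUE)))
}

#' Read/write weight schemes as two-column CSV
#'
#' @param path CSV path with columns `indicator`, `weight`.
#' @param provenance provenance tag for the loaded scheme.
#' @return a [weight_scheme()].
#' @export
load_weights <- function(path, provenance = "supplied") {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  weight_scheme(df[[1L]], df[[2L]], provenance = provenance)
}

#' @rdname load_weights
#' @param w a [weight_scheme()] to write.
#' @export
write_weights <- function(w, path) {
  stopifnot(inherits(w, "weight_scheme"))
  utils::write.csv(data.frame(indicator = names(w$weights),
                              weight = sprintf("%.15g", w$weights)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
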