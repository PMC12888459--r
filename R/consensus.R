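#' Construct a consensus table
#'
#' A named list mapping each efficacy indicator (and, typically, the
#' composite "Overall rating") to the set of peak ids surviving the
#' three-method consensus screen.
#'
#' @param sets named list of character vectors (peak ids per indicator).
#' @return an object of class `consensus_table`.
#' @export
consensus_table <- function(sets) {
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("every set must be named by its indicator")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  structure(list(sets = sets), class = "consensus_table")
}

#' @export
print.consensus_table <- function(x, ...) {
  cat(sprintf("<consensus_table> %d indicators, %d distinct peaks\n",
              length(x$sets), length(union_dedup(x)$peaks)))
  for (ind in names(x$sets))
    cat(sprintf("  %-22s %s\n", ind,
                if (length(x$sets[[ind]]))
                  paste(sort(x$sets[[ind]]), collapse = ", ")
                else "(empty)"))
  invisible(x)
}

#' Per-method screened peak sets
#'
#' Applies the three screening rules to the per-indicator results of the
#' three correlation engines: Pearson keeps the top `pearson_k` peaks by
#' ranking, grey relational analysis keeps peaks with GRD above
#' `grd_threshold` truncated to `grd_k`, and OPLS keeps peaks with
#' VIP >= `vip_threshold` (inclusive).
#'
#' @param pearson a [pearson_screen()] result for one indicator.
#' @param gra a [gray_relational()] result for the same indicator.
#' @param vip_values named per-peak VIP vector from [vip()].
#' @param pearson_k,grd_threshold,grd_k,vip_threshold the rule settings
#'   (defaults 5, 0.8, 10, 1).
#' @return named list with `pearson`, `gra`, `opls` character sets.
#' @export
method_sets <- function(pearson, gra, vip_values,
                        pearson_k = 5, grd_threshold = 0.8, grd_k = 10,
                        vip_threshold = 1) {
  if (missing(pearson) || missing(gra) || missing(vip_values))
    stop("all three method results are required")
  stopifnot(inherits(pearson, "correlation_result"),
            inherits(gra, "gra_result"))
  list(pearson = utils::head(pearson$table$peak, pearson_k),
       gra = grd_screen(gra, threshold = grd_threshold, k = grd_k),
       opls = names(vip_values)[vip_values >= vip_threshold])
}

#' Intersect the three method sets per indicator
#'
#' @param sets_by_indicator named list; each element a list with
#'   components `pearson`, `gra`, `opls` (see [method_sets()]).
#' @return a [consensus_table()]; each indicator maps to the three-way
#'   intersection, ordered by peak id.
#' @export
intersect_sets <- function(sets_by_indicator) {
  sets <- lapply(sets_by_indicator, function(ms) {
    if (!all(c("pearson", "gra", "opls") %in% names(ms)))
      stop("each indicator needs pearson, gra and opls sets")
    sort(Reduce(intersect, ms[c("pearson", "gra", "opls")]))
  })
  consensus_table(sets)
}

#' Deduplicated union of the consensus sets
#'
#' @param table a [consensus_table()].
#' @return a list with `peaks` (distinct peak ids over all indicators,
#'   sorted) and `multiplicity` (named count of indicator memberships per
#'   peak).
#' @export
union_dedup <- function(table) {
  stopifnot(inherits(table, "consensus_table"))
  all <- unlist(table$sets, use.names = FALSE)
  if (!length(all))
    return(list(peaks = character(), multiplicity = integer()))
  mult <- table(all)
  peaks <- sort(names(mult))
  list(peaks = peaks,
       multiplicity = stats::setNames(as.integer(mult[peaks]), peaks))
}
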