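#' Histology-based lung injury score
#'
#' Each high-power field is graded 0-2 on five features: A neutrophils in
#' the alveolar space, B neutrophils in the interstitial space, C hyaline
#' membranes, D proteinaceous debris filling the airspaces, E alveolar
#' septal thickening.  The per-animal score is
#' \deqn{\mathrm{score} = \frac{\sum_{fields} 20A + 14B + 7C + 7D + 2E}
#'       {100 \times \mathrm{fields}}}
#' and ranges from 0 (normal) to 1 (maximal injury in every field).
#'
#' @param fields a data frame or matrix with columns `A`, `B`, `C`, `D`,
#'   `E`; one row per scored field, each grade an integer in 0-2.
#' @return the dimensionless injury score.
#' @export
lung_injury_score <- function(fields) {
  fields <- as.data.frame(fields)
  need <- c("A", "B", "C", "D", "E")
  if (!all(need %in% names(fields)))
    stop("fields must have columns A, B, C, D, E")
  if (!nrow(fields)) stop("at least one field is required")
  g <- as.matrix(fields[need])
  if (anyNA(g) || any(g != round(g)) || any(g < 0) || any(g > 2))
    stop("grades must be integers in {0, 1, 2}")
  weights <- c(A = 20, B = 14, C = 7, D = 7, E = 2)
  sum(g %*% weights) / (nrow(g) * 100)
}

#' Inhibition rate of a pharmacodynamic indicator
#'
#' \deqn{\mathrm{rate} = \frac{\mathrm{model} - \mathrm{treatment}}
#'       {\mathrm{model}} \times 100}
#' Positive values mean the treatment lowered the indicator relative to the
#' untreated model group; worsening yields a negative rate.
#'
#' @param model_value indicator level in the model (untreated disease)
#'   group; must be non-zero.
#' @param treatment_value indicator level in the treatment group.
#' @return the inhibition rate in percent (vectorised).
#' @export
inhibition_rate <- function(model_value, treatment_value) {
  if (any(model_value == 0))
    stop("model group value must be non-zero")
  (model_value - treatment_value) / model_value * 100
}

#' Positive transformation of an efficacy panel
#'
#' Replaces every indicator by its inhibition rate against the model group,
#' so that all indicators become higher-is-better, and removes the model
#' group row.  By default the transformation is applied uniformly to all
#' indicators; `skip` names indicators to pass through unchanged.
#'
#' @param raw an [efficacy_panel()] of raw indicator levels.
#' @param model_group row label of the untreated model group.
#' @param skip optional character vector of indicators to leave untouched
#'   (they are still flagged higher-is-better on output).
#' @return an [efficacy_panel()] of inhibition rates, model row removed,
#'   all orientations `TRUE`.
#' @export
positive_transform <- function(raw, model_group, skip = character()) {
  stopifnot(inherits(raw, "efficacy_panel"))
  if (!model_group %in% rownames(raw$values))
    stop("model group '", model_group, "' not present in panel")
  model <- raw$values[model_group, ]
  keep <- setdiff(rownames(raw$values), model_group)
  transform_cols <- setdiff(colnames(raw$values), skip)
  if (any(model[transform_cols] == 0))
    stop("model group has zero values; inhibition rate undefined")
  out <- raw$values[keep, , drop = FALSE]
  for (j in transform_cols)
    out[, j] <- inhibition_rate(model[[j]], out[, j])
  efficacy_panel(out, orientation = TRUE)
}

#' Relative standard deviation of replicate measurements
#'
#' Sample (n-1) standard deviation divided by the mean, in percent; the
#' routine quality-control statistic for precision, repeatability and
#' stability of characteristic peak areas.
#'
#' @param values numeric vector of at least 2 replicate measurements with
#'   non-zero mean.
#' @return the RSD in percent.
#' @export
rsd <- function(values) {
  if (length(values) < 2L) stop("at least 2 replicates are required")
  m <- mean(values)
  if (m == 0) stop("mean is zero; RSD undefined")
  stats::sd(values) / m * 100
}
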