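#' Load a packaged reference table
#'
#' The package ships the published reference tables of the two-herb lung
#' decoction study as plain-CSV fixtures:
#' \describe{
#'   \item{`table3`}{57 characteristic fingerprint peaks (A1-A40 at 254 nm,
#'     B1-B17 at 440 nm) with group-mean areas and standard deviations for
#'     the four formulation groups PW1-PW4; returned as a [peak_table()].}
#'   \item{`table6`}{the positively transformed pharmacodynamic panel:
#'     4 groups x 7 indicators plus the published composite "Overall
#'     rating" column; returned as an [efficacy_panel()] (all indicators
#'     higher-is-better).}
#'   \item{`table8`}{the per-indicator three-method consensus peak sets;
#'     returned as a [consensus_table()].}
#'   \item{`table9`}{the published compound centrality table (betweenness,
#'     closeness, degree, source herb, median-filter flag); returned as a
#'     data frame.}
#'   \item{`herb_map`}{peak id to source herb assignment for all 57 peaks
#'     (`herb` = fingerprint table source column, `herb_alt` = the variant
#'     printed with the centrality table); returned as a data frame.}
#'   \item{`weights`}{the published seven AHP-EWM indicator weights;
#'     returned as a [weight_scheme()].}
#' }
#'
#' @param name one of `"table3"`, `"table6"`, `"table8"`, `"table9"`,
#'   `"herb_map"`, `"weights"`.
#' @return the typed table described above.
#' @export
load_fixture <- function(name) {
  known <- c("table3", "table6", "table8", "table9", "herb_map", "weights")
  if (length(name) != 1L || !name %in% known)
    stop("unknown fixture '", name, "'; available: ",
         paste(known, collapse = ", "))
  path <- function(f) system.file("extdata", f, package = "specscreen",
                                  mustWork = TRUE)
  switch(name,
    table3 = load_peak_table(path("table3.csv"), dialect = "group_means"),
    table6 = load_efficacy_panel(path("table6.csv")),
    table8 = {
      df <- utils::read.csv(path("table8.csv"), check.names = FALSE,
                            stringsAsFactors = FALSE)
      sets <- lapply(strsplit(df$peaks, ";"), trimws)
      names(sets) <- df$indicator
      consensus_table(sets)
    },
    table9 = utils::read.csv(path("table9.csv"), check.names = FALSE,
                             stringsAsFactors = FALSE),
    herb_map = utils::read.csv(path("herb_map.csv"), check.names = FALSE,
                               stringsAsFactors = FALSE),
    weights = {
      df <- utils::read.csv(path("ahp_ewm_weights.csv"), check.names = FALSE,
                            stringsAsFactors = FALSE)
      weight_scheme(df$indicator, df$weight, provenance = "supplied")
    })
}
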