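#' Three-method spectrum-effect consensus screen
#'
#' Runs the full screening cascade in memory: peak standardization, then,
#' per efficacy indicator, Pearson correlation screening, grey relational
#' analysis and an OPLS fit with VIP, followed by the three-way
#' intersection, the deduplicated union, network construction and the
#' centrality median filter.
#'
#' Observations may be per-sample or per-group.  When the peak table's
#' column names follow the `<group>_r<replicate>` convention and the
#' efficacy panel is per-group, each group's indicator values are expanded
#' across its replicates; otherwise the peak observations must match the
#' panel's groups one to one.  For grey relational analysis the indicator
#' (parent) sequence is z-scored so that parent and standardized peak
#' subsequences share a scale.
#'
#' @param peaks a [peak_table()] (raw areas; standardized internally).
#' @param efficacy an [efficacy_panel()], positively oriented.
#' @param weights optional [weight_scheme()]; when supplied, a composite
#'   "Overall rating" indicator is computed from the weighted panel and
#'   screened alongside the individual indicators.
#' @param herb_map optional data frame (`peak_id`, `herb`) enabling the
#'   network stage.
#' @param pearson_k,grd_threshold,grd_k,vip_threshold screening rules
#'   (defaults 5, 0.8, 10, 1; see [method_sets()]).
#' @param rho grey relational distinguishing coefficient (default 0.5).
#' @param n_orth orthogonal components of the OPLS fits (default 1).
#' @param k_of_3 median-filter rule (default 2).
#' @param include_overall include the composite indicator as a network
#'   node (default `TRUE`).
#' @return an object of class `spectrum_screen`: per-indicator method
#'   sets, the consensus table, the union with multiplicities, composite
#'   scores (when weighted), the network and flagged compounds (when a
#'   herb map is given), and the per-indicator engine results.
#' @export
spectrum_effect_screen <- function(peaks, efficacy, weights = NULL,
                                   herb_map = NULL,
                                   pearson_k = 5, grd_threshold = 0.8,
                                   grd_k = 10, vip_threshold = 1,
                                   rho = 0.5, n_orth = 1, k_of_3 = 2,
                                   include_overall = TRUE) {
  stopifnot(inherits(peaks, "peak_table"),
            inherits(efficacy, "efficacy_panel"))
  obs <- colnames(peaks$areas)
  groups <- rownames(efficacy$values)
  if (all(obs %in% groups)) {
    group_of <- obs
  } else {
    cand <- sub("_r\\d+$", "", obs)
    if (!all(cand %in% groups))
      stop("peak observations cannot be matched to efficacy groups")
    group_of <- cand
  }
  eff <- efficacy$values[group_of, , drop = FALSE]

  scores <- NULL
  if (!is.null(weights)) {
    cs <- composite_score(
      panel_indicators(efficacy, names(weights$weights)), weights)
    scores <- cs$scores
    eff <- cbind(eff, `Overall rating` = cs$scores[group_of])
  }

  z <- standardize_peaks(peaks)
  engines <- list()
  sets <- list()
  for (ind in colnames(eff)) {
    y <- eff[, ind]
    pe <- pearson_screen(z, y, k = pearson_k)
    gr <- gray_relational(as.numeric(scale(y)), z$areas, rho = rho)
    op <- opls(t(z$areas), y, n_orth = n_orth, scale = FALSE)
    vi <- vip(op)
    engines[[ind]] <- list(pearson = pe, gra = gr, opls = op, vip = vi)
    sets[[ind]] <- method_sets(pe, gr, vi, pearson_k = pearson_k,
                               grd_threshold = grd_threshold,
                               grd_k = grd_k,
                               vip_threshold = vip_threshold)
  }
  consensus <- intersect_sets(sets)
  un <- union_dedup(consensus)

  network <- flagged <- NULL
  if (!is.null(herb_map) && length(un$peaks)) {
    network <- build_network(consensus, herb_map,
                             include_overall = include_overall)
    flagged <- median_filter(network$centrality, k_of_3 = k_of_3)
  }
  structure(list(method_sets = sets, consensus = consensus, union = un,
                 composite_scores = scores, network = network,
                 flagged = flagged, engines = engines,
                 rules = list(pearson_k = pearson_k,
                              grd_threshold = grd_threshold,
                              grd_k = grd_k,
                              vip_threshold = vip_threshold, rho = rho,
                              n_orth = n_orth, k_of_3 = k_of_3)),
            class = "spectrum_screen")
}

#' @export
print.spectrum_screen <- function(x, ...) {
  cat("<spectrum_screen>\n")
  if (!is.null(x$composite_scores)) {
    cat("composite scores:\n")
    print(round(x$composite_scores, 2))
  }
  print(x$consensus)
  cat(sprintf("union: %d compounds\n", length(x$union$peaks)))
  if (!is.null(x$flagged))
    cat("median-filter flagged:", paste(x$flagged, collapse = ", "), "\n")
  invisible(x)
}

#' Run the full screening pipeline with file artifacts
#'
#' Orchestrates the whole analysis from a configuration list or YAML file:
#' input loading (file paths or packaged fixture names), optional positive
#' transformation against a model group, composite scoring, the
#' three-method screen, consensus, network and median filter, writing CSV
#' /JSON/GraphML artifacts plus a JSON run manifest.  Any stage error
#' aborts with a stage-tagged message and leaves a `manifest.json.partial`
#' marker in the output directory.
#'
#' @param config a named list or the path of a YAML file.  Recognised
#'   entries: `peaks`, `efficacy`, `weights`, `herb_map` (each a file
#'   path, a fixture name understood by [load_fixture()], or an in-memory
#'   object), `model_group` (triggers [positive_transform()]),
#'   `drop_indicators` (columns removed from the panel before screening,
#'   e.g. a pre-computed composite column), the rule settings of
#'   [spectrum_effect_screen()], `truth` (a `sim_truth` from
#'   [simulate_dataset()]; adds a recovery report to the manifest),
#'   `seed` (default 0) and `out_dir`.
#' @return the manifest, invisibly; artifacts under `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  cfg <- utils::modifyList(
    list(pearson_k = 5, grd_threshold = 0.8, grd_k = 10,
         vip_threshold = 1, rho = 0.5, n_orth = 1, k_of_3 = 2,
         include_overall = TRUE, seed = 0,
         out_dir = file.path(tempdir(), "specscreen_run")),
    config)
  set.seed(cfg$seed)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  partial <- file.path(cfg$out_dir, "manifest.json.partial")
  file.create(partial)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }

  peaks <- stage("load_peaks", resolve_input(cfg$peaks, "peaks"))
  efficacy <- stage("load_efficacy", resolve_input(cfg$efficacy, "efficacy"))
  weights <- if (!is.null(cfg$weights))
    stage("load_weights", resolve_input(cfg$weights, "weights"))
  herb_map <- if (!is.null(cfg$herb_map))
    stage("load_herb_map", resolve_input(cfg$herb_map, "herb_map"))

  if (!is.null(cfg$model_group))
    efficacy <- stage("positive_transform",
                      positive_transform(efficacy, cfg$model_group))
  if (!is.null(cfg$drop_indicators))
    efficacy <- stage("drop_indicators", panel_indicators(
      efficacy, setdiff(colnames(efficacy$values), cfg$drop_indicators)))

  screen <- stage("screen", spectrum_effect_screen(
    peaks, efficacy, weights = weights, herb_map = herb_map,
    pearson_k = cfg$pearson_k, grd_threshold = cfg$grd_threshold,
    grd_k = cfg$grd_k, vip_threshold = cfg$vip_threshold, rho = cfg$rho,
    n_orth = cfg$n_orth, k_of_3 = cfg$k_of_3,
    include_overall = cfg$include_overall))

  stage("artifacts", {
    out <- function(f) file.path(cfg$out_dir, f)
    if (!is.null(screen$composite_scores))
      utils::write.csv(data.frame(group = names(screen$composite_scores),
                                  score = screen$composite_scores),
                       out("composite_scores.csv"), row.names = FALSE)
    long <- do.call(rbind, lapply(names(screen$engines), function(ind) {
      e <- screen$engines[[ind]]
      data.frame(indicator = ind, peak = e$pearson$table$peak,
                 r = e$pearson$table$r, p = e$pearson$table$p,
                 grd = as.numeric(e$gra$grd[e$pearson$table$peak]),
                 vip = as.numeric(e$vip[e$pearson$table$peak]))
    }))
    utils::write.csv(long, out("screen_long.csv"), row.names = FALSE)
    utils::write.csv(
      data.frame(indicator = rep(names(screen$consensus$sets),
                                 lengths(screen$consensus$sets)),
                 peak = unlist(screen$consensus$sets, use.names = FALSE)),
      out("consensus.csv"), row.names = FALSE)
    if (!is.null(screen$network)) {
      write_network_graphml(screen$network, out("network.graphml"))
      write_network_sif(screen$network, out("network.sif"))
      centrality_table(screen$network, out("centrality.csv"))
    }
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("specscreen")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed,
    config = Filter(function(v) is.character(v) || is.numeric(v) ||
                      is.logical(v),
                    cfg[setdiff(names(cfg), "out_dir")]),
    counts = list(
      peaks = nrow(peaks$areas),
      observations = ncol(peaks$areas),
      indicators = ncol(efficacy$values),
      consensus_union = length(screen$union$peaks),
      flagged = length(screen$flagged)),
    composite_scores = as.list(screen$composite_scores),
    union = screen$union$peaks,
    flagged = screen$flagged)
  if (!is.null(cfg$truth)) {
    rec <- stage("recovery", recovery_report(cfg$truth, screen$union$peaks))
    manifest$recovery <- rec[c("sensitivity", "precision")]
  }
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  file.remove(partial)
  invisible(c(manifest, list(screen = screen)))
}

# resolve a config entry: in-memory object, fixture name, or file path
resolve_input <- function(x, kind) {
  if (is.null(x)) stop("missing input: ", kind)
  if (!is.character(x)) return(x)
  fixtures <- c(peaks = "table3", efficacy = "table6",
                weights = "weights", herb_map = "herb_map")
  if (x %in% c("table3", "table6", "table8", "table9", "herb_map",
               "weights"))
    return(load_fixture(x))
  if (!file.exists(x)) stop("input path not found: ", x)
  switch(kind,
         peaks = load_peak_table(x, dialect = "samples"),
         efficacy = load_efficacy_panel(x),
         weights = load_weights(x),
         herb_map = utils::read.csv(x, stringsAsFactors = FALSE))
}
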