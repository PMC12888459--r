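#' Configuration of the synthetic fingerprint-efficacy generator
#'
#' Collects and validates the generator settings.  Defaults emulate a
#' multi-formulation fingerprint study large enough for stable screening:
#' log-normal peak abundances (strictly positive, right-skewed, like real
#' chromatographic areas), replicate noise at a 10% coefficient of
#' variation, and efficacy indicators built as noisy linear combinations
#' of a planted subset of "active" peaks on the standardized scale.
#'
#' @param n_groups number of formulation groups (default 12).
#' @param n_replicates replicate injections per group (default 6).
#' @param n_peaks number of fingerprint peaks (default 50).
#' @param n_active number of planted active peaks (default 5).
#' @param beta effect size per active peak on the standardized scale,
#'   recycled to `n_active` (default 1; magnitudes of 1 give each active
#'   an equal share of the signal).
#' @param cv replicate coefficient of variation around the group mean
#'   (default 0.1).
#' @param noise_sd standard deviation of the Gaussian indicator noise on
#'   the standardized scale (default 0.25).
#' @param log_mean,log_sd baseline log-mean and log-sd of the group-level
#'   peak abundances (defaults log(5e4) and 0.5).
#' @param n_indicators number of efficacy indicators (default 7).
#' @param seed RNG seed recorded in all outputs (default 0).
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_groups = 12, n_replicates = 6, n_peaks = 50,
                       n_active = 5, beta = 1, cv = 0.1, noise_sd = 0.25,
                       log_mean = log(5e4), log_sd = 0.5,
                       n_indicators = 7, seed = 0) {
  if (n_active > n_peaks) stop("n_active must not exceed n_peaks")
  if (cv < 0) stop("cv must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (n_groups < 2 || n_replicates < 1 || n_peaks < 1 || n_indicators < 1)
    stop("invalid dimensions")
  beta <- rep_len(beta, max(n_active, 1L))
  structure(list(n_groups = n_groups, n_replicates = n_replicates,
                 n_peaks = n_peaks, n_active = n_active, beta = beta,
                 cv = cv, noise_sd = noise_sd, log_mean = log_mean,
                 log_sd = log_sd, n_indicators = n_indicators,
                 seed = seed),
            class = "sim_config")
}

#' Simulate a fingerprint-efficacy dataset with known ground truth
#'
#' Group-level peak abundances are drawn i.i.d. log-normal
#' (`log_mean`, `log_sd`); replicate observations are log-normal around
#' their group mean with coefficient of variation `cv`.  Each efficacy
#' indicator is the linear combination \eqn{\sum_j \beta_j z_{gj}} of the
#' standardized (z-scored across groups) abundances of the planted active
#' peaks plus Gaussian noise, mapped onto a positive inhibition-rate-like
#' scale (`50 + 10 x`, an affine map that leaves every correlation
#' untouched).  Identical seeds give bit-identical outputs.
#'
#' @param cfg a [sim_config()].
#' @return a list with `peaks` (a per-sample [peak_table()]; sample names
#'   `<group>_r<replicate>`), `efficacy` (group-level [efficacy_panel()]),
#'   and `truth` (class `sim_truth`: active peak ids, `beta`, realized
#'   group-level means, noiseless efficacy, the per-sample group factor, a
#'   synthetic two-herb `herb_map`, and the seed).
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(cfg$seed)

  peak_id <- sprintf("P%02d", seq_len(cfg$n_peaks))
  group_id <- sprintf("G%02d", seq_len(cfg$n_groups))
  gm <- matrix(stats::rlnorm(cfg$n_peaks * cfg$n_groups,
                             meanlog = cfg$log_mean, sdlog = cfg$log_sd),
               nrow = cfg$n_peaks, dimnames = list(peak_id, group_id))

  sdlog_w <- sqrt(log(1 + cfg$cv^2))
  sample_id <- as.vector(t(outer(group_id, seq_len(cfg$n_replicates),
                                 function(g, r) paste0(g, "_r", r))))
  group_of <- sub("_r\\d+$", "", sample_id)
  areas <- matrix(0, cfg$n_peaks, length(sample_id),
                  dimnames = list(peak_id, sample_id))
  for (s in seq_along(sample_id))
    areas[, s] <- gm[, group_of[s]] *
      stats::rlnorm(cfg$n_peaks, meanlog = -sdlog_w^2 / 2, sdlog = sdlog_w)

  active <- sort(sample(peak_id, cfg$n_active))
  z <- t(scale(t(gm)))                    # peaks x groups, z across groups
  signal <- if (cfg$n_active > 0)
    as.numeric(crossprod(z[active, , drop = FALSE], cfg$beta))
  else rep(0, cfg$n_groups)
  indicator_id <- sprintf("I%d", seq_len(cfg$n_indicators))
  noiseless <- matrix(50 + 10 * signal, cfg$n_groups, cfg$n_indicators,
                      dimnames = list(group_id, indicator_id))
  eff <- noiseless + 10 * matrix(stats::rnorm(length(noiseless),
                                              sd = cfg$noise_sd),
                                 nrow = cfg$n_groups)

  herb_map <- data.frame(peak_id = peak_id,
                         herb = rep_len(c("H1", "H2"), cfg$n_peaks),
                         stringsAsFactors = FALSE)
  truth <- structure(list(active = active, beta = cfg$beta,
                          group_means = gm, noiseless = noiseless,
                          group = stats::setNames(group_of, sample_id),
                          herb_map = herb_map, seed = cfg$seed),
                     class = "sim_truth")
  list(peaks = peak_table(areas),
       efficacy = efficacy_panel(eff, orientation = TRUE),
       truth = truth)
}

#' Recovery of planted actives by a screen
#'
#' @param truth the `sim_truth` from [simulate_dataset()].
#' @param screened character vector of screened peak ids.
#' @return a list with `sensitivity` (= recovered/actives), `precision`
#'   (= recovered/screened), and the recovered ids.  An empty screened set
#'   against an empty active set scores 1/1; otherwise a zero denominator
#'   yields `NA` (undefined).
#' @export
recovery_report <- function(truth, screened) {
  stopifnot(inherits(truth, "sim_truth"))
  screened <- unique(as.character(screened))
  hit <- intersect(screened, truth$active)
  n_active <- length(truth$active)
  sens <- if (n_active == 0) {
    if (length(screened) == 0) 1 else NA_real_
  } else length(hit) / n_active
  prec <- if (length(screened) == 0) {
    if (n_active == 0) 1 else NA_real_
  } else length(hit) / length(screened)
  list(sensitivity = sens, precision = prec, recovered = sort(hit))
}
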