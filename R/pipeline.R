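#' End-to-end profiling pipeline
#'
#' Runs the full analysis — CDDS scoring, optional interview-timing
#' correction, age-window filter, univariate screening, polling, the
#' propensity/matching stage, impact profiling and the need-versus-impact
#' comparison — and writes every table, figure-data file and a
#' machine-readable manifest into a run directory.  Stages never mutate
#' their inputs; every output is reproducible from the manifest (config +
#' seed) alone.
#'
#' @param config A named list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{`input`, `codebook`}{CSV / codebook paths, or `simulate =
#'       TRUE` to use the synthetic generator.}
#'     \item{`simulate`}{logical; generate data instead of loading.}
#'     \item{`sim_config`}{optional [synthetic_config()] when simulating.}
#'     \item{`out_dir`}{output directory (created if absent).}
#'     \item{`k`}{profile size, default 5.}
#'     \item{`top_k_screen`}{variables kept by screening, default 10.}
#'     \item{`alpha_grid`}{default `seq(0, 1, 0.1)`.}
#'     \item{`bandwidth`}{kernel bandwidth, default 0.06.}
#'     \item{`min_treated`}{minimum treated per significant profile,
#'       default 100.}
#'     \item{`t_threshold`}{one-sided t cutoff, default 1.645.}
#'     \item{`min_treated_att`}{minimum treated before a profile ATT is
#'       attempted, default 10.}
#'     \item{`age_window`}{default `c(6, 25)`.}
#'     \item{`detrend`}{`"none"` or `"day-regression"`, default
#'       `"none"`.}
#'     \item{`seed`}{default 20151104.}
#'   }
#' @return The run directory path, invisibly; side effect: CSV/JSON
#'   outputs including `manifest.json`, `screen.csv`,
#'   `polling_metrics.csv`, `polling_winners.csv`,
#'   `propensity_marginal_effects.csv`, `att_global.csv`, `balance.csv`,
#'   `impact_metrics.csv`, `impact_winners.csv`, `characteristics.csv`,
#'   `fig2_density.csv`, `fig3_curve.csv`, `fig4_distributions.csv`,
#'   `fig5_scatter.csv`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(list(
    simulate = FALSE, input = NULL, codebook = NULL, sim_config = NULL,
    out_dir = tempfile("pollmatch_run_"), k = 5L, top_k_screen = 10L,
    alpha_grid = seq(0, 1, by = 0.1), bandwidth = 0.06,
    min_treated = 100L, t_threshold = 1.645, min_treated_att = 10L,
    age_window = c(6L, 25L), detrend = "none", seed = 20151104L),
    config)

  if (!cfg$simulate && (is.null(cfg$input) || !file.exists(cfg$input)))
    stop("input path missing or not found (set simulate = TRUE to generate)")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "load"
  manifest <- list(package = "pollmatch",
                   version = as.character(utils::packageVersion("pollmatch")),
                   seed = cfg$seed, started = format(Sys.time()),
                   config = cfg[setdiff(names(cfg), "sim_config")])
  emit <- function(name, df) {
    utils::write.csv(df, file.path(cfg$out_dir, name), row.names = FALSE)
  }
  fail <- function(e) {
    manifest$failed_stage <- stage
    manifest$error <- conditionMessage(e)
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  }

  tryCatch({
    tab <- if (cfg$simulate) {
      sc <- cfg$sim_config
      if (is.null(sc)) sc <- synthetic_config(seed = cfg$seed)
      generate_households(sc)
    } else {
      load_households(cfg$input, read_codebook(cfg$codebook))
    }

    stage <- "cdds"
    mapping <- cdds_mapping()
    if (all(names(mapping) %in% names(tab))) tab <- score_cdds(tab, mapping)
    if (is.null(tab$diet_class))
      stop("no diet_class column and no item flags to score")
    if (cfg$detrend != "none")
      tab <- detrend_interview_timing(tab, method = cfg$detrend)

    stage <- "age-filter"
    if (!is.null(tab$child_age_months))
      tab <- filter_age_window(tab, cfg$age_window[1L], cfg$age_window[2L])
    manifest$n_records <- nrow(tab)
    manifest$treated_share <- mean(tab$diet_class)

    stage <- "screening"
    cb <- attr(tab, "codebook")
    candidates <- codebook_vars(cb, "covariate")
    scr <- univariate_screen(tab, candidates, outcome = "adequate",
                             k = min(cfg$top_k_screen, length(candidates)))
    emit("screen.csv", as.data.frame(scr))
    vars <- scr$variable

    stage <- "polling"
    pm <- polling_analysis(tab, vars, k = min(cfg$k, length(vars)))
    emit("polling_metrics.csv", pm)
    emit("polling_winners.csv", winning_profiles(pm, cfg$alpha_grid))

    stage <- "matching"
    ps <- fit_propensity(tab, vars)
    emit("propensity_marginal_effects.csv", ps$marginal_effects)
    sup <- common_support(ps$scores, tab$diet_class)
    att <- kernel_att(tab, ps$scores, sup, bandwidth = cfg$bandwidth)
    emit("att_global.csv", data.frame(
      row = c("Unmatched", "ATT"),
      treated = c(NA, att$mean_treated),
      comparison = c(NA, att$mean_matched_comparison),
      difference = c(att$unmatched_diff, att$att),
      se = c(att$unmatched_se, att$se),
      t = c(att$unmatched_t, att$t)))
    bal <- balance_report(ps, tab, att)
    emit("balance.csv", bal$balance)
    emit("fig2_density.csv", bal$density_data)
    emit("fig3_curve.csv", tryCatch(
      att_by_pscore_curve(att),
      error = function(e) data.frame(score = numeric(0),
                                     local_att = numeric(0))))
    manifest$share_treated_off_support <- sup$share_treated_off

    stage <- "impact"
    im <- impact_analysis(tab, vars, k = min(cfg$k, length(vars)), ps,
                          bandwidth = cfg$bandwidth,
                          min_treated = cfg$min_treated_att)
    im <- impact_coverage(im, tab, overlap_adjust = TRUE)
    emit("impact_metrics.csv", im)
    emit("impact_winners.csv", winning_impact_profiles(
      im, cfg$alpha_grid, min_members = cfg$min_treated))
    dist <- att_distribution_by_min_n(im)
    emit("fig4_distributions.csv", dist)
    emit("characteristics.csv",
         profile_characteristics(im, cb, t_min = cfg$t_threshold,
                                 min_treated = cfg$min_treated))

    stage <- "need-vs-impact"
    nvi <- need_vs_impact(pm, im, t_min = cfg$t_threshold,
                          min_treated = cfg$min_treated)
    emit("fig5_scatter.csv", nvi$data)
    manifest$need_impact_correlation <- nvi$correlation
    manifest$n_significant_profiles <- nvi$n_profiles
    manifest$global_att <- att$att
    manifest$finished <- format(Sys.time())
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }, error = fail)
  invisible(cfg$out_dir)
}
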