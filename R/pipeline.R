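# Study orchestration: simulate a cohort per group, run every requested
# quantification stage, aggregate mean +/- SEM, classify severity, and
# feed each endpoint through the statistics engine.

#' Read a study configuration from YAML
#'
#' See [run_study()] for the configuration structure; parameters are
#' validated against module-level constraints at load.
#'
#' @param path YAML file.
#' @return validated config list.
#' @export
read_study_config <- function(path) {
  validate_study_config(yaml::read_yaml(path))
}

validate_study_config <- function(config) {
  stopifnot(is.list(config), !is.null(config$groups), length(config$groups) >= 1)
  config$seed <- config$seed %||% 1
  config$images_per_mouse <- config$images_per_mouse %||% 3
  config$severity_threshold <- config$severity_threshold %||% 1320
  config$doppler <- config$doppler %||% list()
  d <- config$doppler
  config$doppler <- list(
    heart_rate = d$heart_rate %||% 465,
    ejection_fraction_of_cycle = d$ejection_fraction_of_cycle %||% 0.35,
    n_cycles = d$n_cycles %||% 10,
    noise_frac = d$noise_frac %||% 0.05,
    sampling_rate = d$sampling_rate %||% 2000)
  stopifnot(config$images_per_mouse >= 1, config$severity_threshold > 0)
  for (g in config$groups) {
    stopifnot(!is.null(g$name), !is.null(g$n), g$n >= 2,
              !is.null(g$peak_velocity), g$peak_velocity > 0,
              (g$peak_velocity_sd %||% 0) >= 0)
    if (!is.null(g$trichrome))
      stopifnot(abs(sum(unlist(g$trichrome$class_fractions)) - 1) < 1e-9)
    if (!is.null(g$fluorescence))
      stopifnot((g$fluorescence$n_nuclei %||% 40) >= 1)
  }
  config
}

#' Run a full synthetic phenotyping study
#'
#' For each group, simulates `n` mice. Every mouse gets
#' `images_per_mouse` Doppler clips (mouse-level true peak velocity drawn
#' from Normal(`peak_velocity`, `peak_velocity_sd`), envelope noise
#' `noise_frac` of the true peak); optional per-group `trichrome` and
#' `fluorescence` blocks add one section/field per mouse, and a `qpcr`
#' block adds one Cq table per study. All per-mouse endpoints are then
#' aggregated as mean +/- SEM, classified for hemodynamic severity, and
#' compared across groups through the test-selection engine.
#'
#' Config structure (YAML or list):
#' \preformatted{
#' seed: 1
#' images_per_mouse: 3
#' severity_threshold: 1320
#' doppler: {heart_rate: 465, ejection_fraction_of_cycle: 0.35,
#'           n_cycles: 10, noise_frac: 0.05, sampling_rate: 2000}
#' groups:
#'   - name: control
#'     n: 8
#'     peak_velocity: 1500       # mm/s, group mean
#'     peak_velocity_sd: 150     # mm/s, between-mouse SD
#'     trichrome: {class_fractions: {collagen: 0.35, cytoplasm: 0.65}}
#'     fluorescence: {n_nuclei: 40, n_touching_pairs: 4,
#'                    positive_fraction: 0.55}
#'     qpcr: {mean_cq: {Acta2: 25, Gapdh: 20, Actb: 22}, sd: 0.3}
#' }
#'
#' All randomness is derived from the single root seed.
#'
#' @param config config list or path to a YAML file.
#' @param out_dir optional output directory; when given, per-mouse
#'   metrics, group summaries, the severity table and the statistics
#'   report are written as CSV plus a combined JSON report.
#' @param seed optional override of `config$seed`.
#' @return list of class `study_report`: `mice` (per-mouse endpoint data
#'   frame), `group_summary` (mean/SEM per endpoint), `severity`
#'   (per-group counts above threshold), `stats` (tidy test table),
#'   `results` (named `test_result` list), `config`.
#' @export
run_study <- function(config, out_dir = NULL, seed = NULL) {
  if (is.character(config)) config <- read_study_config(config)
  config <- validate_study_config(config)
  if (!is.null(seed)) config$seed <- seed
  seeds <- derive_seeds(config$seed, 4)

  mice <- run_doppler_stage(config, seeds[1])
  mice <- run_trichrome_stage(config, mice, seeds[2])
  mice <- run_fluorescence_stage(config, mice, seeds[3])

  endpoints <- setdiff(names(mice), c("mouse", "group"))
  group_summary <- do.call(rbind, lapply(endpoints, function(ep) {
    agg_m <- tapply(mice[[ep]], mice$group, mean)
    agg_s <- tapply(mice[[ep]], mice$group, sem)
    data.frame(endpoint = ep, group = names(agg_m),
               mean = as.numeric(agg_m), sem = as.numeric(agg_s),
               row.names = NULL)
  }))

  severe <- classify_severe(mice$peak_velocity, config$severity_threshold)
  severity <- do.call(rbind, lapply(split(severe, mice$group), function(s)
    data.frame(n = length(s), n_severe = sum(s), fraction = mean(s))))
  severity <- cbind(group = rownames(severity), severity)
  rownames(severity) <- NULL

  results <- list()
  if (length(unique(mice$group)) >= 2) {
    for (ep in endpoints)
      results[[ep]] <- compare_groups(split(mice[[ep]], mice$group))
  }
  qp <- run_qpcr_stage(config, seeds[4])
  results <- c(results, qp$results)

  rep_tab <- report(results)
  out <- structure(list(mice = mice, group_summary = group_summary,
                        severity = severity, stats = rep_tab,
                        results = results, qpcr = qp$expression,
                        config = config),
                   class = "study_report")
  if (!is.null(out_dir)) write_study_report(out, out_dir)
  out
}

run_doppler_stage <- function(config, seed) {
  d <- config$doppler
  mouse_seeds <- derive_seeds(seed, sum(vapply(config$groups, `[[`, 0, "n")))
  rows <- list(); k <- 0
  for (g in config$groups) {
    for (i in seq_len(g$n)) {
      k <- k + 1
      sub <- derive_seeds(mouse_seeds[k], config$images_per_mouse + 1)
      set.seed(sub[1])
      pv_true <- max(100, stats::rnorm(1, g$peak_velocity,
                                       g$peak_velocity_sd %||% 0))
      images <- lapply(seq_len(config$images_per_mouse), function(im) {
        tr <- simulate_doppler(
          peak_velocity = pv_true, heart_rate = d$heart_rate,
          ejection_fraction_of_cycle = d$ejection_fraction_of_cycle,
          n_cycles = d$n_cycles, noise_sd = d$noise_frac * pv_true,
          seed = sub[im + 1], sampling_rate = d$sampling_rate)
        summarize_image(analyze_trace(tr))
      })
      ms <- summarize_mouse(images)
      rows[[k]] <- data.frame(mouse = sprintf("%s_m%02d", g$name, i),
                              group = g$name,
                              peak_velocity = ms$peak_velocity,
                              mean_gradient = ms$mean_gradient)
    }
  }
  do.call(rbind, rows)
}

run_trichrome_stage <- function(config, mice, seed) {
  if (!any(vapply(config$groups, function(g) !is.null(g$trichrome), TRUE)))
    return(mice)
  mouse_seeds <- derive_seeds(seed, nrow(mice))
  mice$collagen_fraction <- NA_real_
  mice$leaflet_thickness <- NA_real_
  k <- 0
  for (g in config$groups) {
    for (i in seq_len(g$n)) {
      k <- k + 1
      tcfg <- g$trichrome
      if (is.null(tcfg)) next
      sim <- simulate_trichrome(
        class_fractions = unlist(tcfg$class_fractions),
        background_fraction = tcfg$background_fraction %||% 0.05,
        dim = unlist(tcfg$dim %||% c(160, 160)), seed = mouse_seeds[k])
      comp <- quantify_trichrome(sim$image, sim$roi, thickness = TRUE)
      mice$collagen_fraction[k] <- comp$fractions[["collagen"]]
      mice$leaflet_thickness[k] <- comp$thickness$thickness
    }
  }
  if (all(is.na(mice$collagen_fraction)))
    mice$collagen_fraction <- mice$leaflet_thickness <- NULL
  mice
}

run_fluorescence_stage <- function(config, mice, seed) {
  if (!any(vapply(config$groups, function(g) !is.null(g$fluorescence), TRUE)))
    return(mice)
  mouse_seeds <- derive_seeds(seed, nrow(mice))
  mice$runx2_positive_fraction <- NA_real_
  k <- 0
  for (g in config$groups) {
    for (i in seq_len(g$n)) {
      k <- k + 1
      fcfg <- g$fluorescence
      if (is.null(fcfg)) next
      n_nuc <- fcfg$n_nuclei %||% 40
      pos_frac <- fcfg$positive_fraction %||% 0.5
      n_pos <- round(pos_frac * n_nuc)
      set.seed(mouse_seeds[k])
      cov <- sample(c(stats::runif(n_pos, 0.65, 0.9),
                      stats::runif(n_nuc - n_pos, 0.1, 0.35)))
      sim <- simulate_fluorescence(
        n_nuclei = n_nuc,
        n_touching_pairs = fcfg$n_touching_pairs %||% round(n_nuc / 10),
        marker_coverage = cov,
        dim = unlist(fcfg$dim %||% c(320, 320)),
        seed = mouse_seeds[k])
      lab <- segment_nuclei(sim$dapi, sim$roi)
      thr <- marker_threshold(sim$marker, sim$roi)
      mq <- runx2_positivity(lab, sim$marker, thr)
      mice$runx2_positive_fraction[k] <- mq$positive_fraction
    }
  }
  if (all(is.na(mice$runx2_positive_fraction)))
    mice$runx2_positive_fraction <- NULL
  mice
}

run_qpcr_stage <- function(config, seed) {
  has_q <- vapply(config$groups, function(g) !is.null(g$qpcr), TRUE)
  if (!any(has_q)) return(list(results = list(), expression = NULL))
  gdefs <- lapply(config$groups[has_q], function(g)
    list(name = g$name, n = g$n,
         mean_cq = unlist(g$qpcr$mean_cq), sd = g$qpcr$sd %||% 0.3))
  tab <- simulate_ct_table(gdefs, seed = seed)
  dct <- delta_ct(tab)
  expr <- relative_expression(dct, reference = gdefs[[1]]$name)
  results <- list()
  if (length(gdefs) >= 2) {
    for (tg in unique(dct$target))
      results[[paste0("delta_ct_", tg)]] <-
        compare_groups(stats_input(dct, tg))
  }
  list(results = results, expression = expr)
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>", nrow(x$mice), "mice,",
      length(unique(x$mice$group)), "groups\n")
  print(x$group_summary, row.names = FALSE)
  cat("severity (threshold", x$config$severity_threshold, "mm/s):\n")
  print(x$severity, row.names = FALSE)
  if (nrow(x$stats)) print(x$stats, row.names = FALSE)
  invisible(x)
}

write_study_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$mice, file.path(out_dir, "mice.csv"),
                   row.names = FALSE)
  utils::write.csv(report$group_summary,
                   file.path(out_dir, "group_summary.csv"), row.names = FALSE)
  utils::write.csv(report$severity, file.path(out_dir, "severity.csv"),
                   row.names = FALSE)
  utils::write.csv(report$stats, file.path(out_dir, "stats.csv"),
                   row.names = FALSE)
  if (!is.null(report$qpcr))
    utils::write.csv(report$qpcr, file.path(out_dir, "qpcr_expression.csv"),
                     row.names = FALSE)
  jsonlite::write_json(
    list(group_summary = report$group_summary, severity = report$severity,
         stats = report$stats),
    file.path(out_dir, "report.json"), dataframe = "rows", digits = NA)
  invisible(out_dir)
}
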