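#' Read and validate a pipeline run configuration
#'
#' Configurations are YAML (or an equivalent R list) with blocks `seed`
#' (mandatory), `out_dir`, `layout`, `groups` (label -> either
#' `preset: <name>` or explicit [larva_params()] fields), `protocol`
#' (`type: spontaneous` with `duration_h`, `frame_rate_hz`, `zt_start_h`,
#' or `type: startle` with the [startle_protocol()] fields), `thresholds`
#' (`movement_mm`, `latency_mm`) and `render` (`enabled`, `noise_sd`,
#' `background`).
#'
#' @param config Path to a YAML file, or a list.
#' @return Validated configuration list of class `run_config`.
#' @export
read_run_config <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (is.null(cfg$seed)) stop("config must set a seed", call. = FALSE)
  defaults <- list(
    out_dir = "larvatrack_run",
    layout = list(),
    groups = list(wildtype = list(preset = "wildtype"),
                  gr_mutant = list(preset = "gr_mutant")),
    protocol = list(type = "spontaneous"),
    thresholds = list(movement_mm = 0.3, latency_mm = 0.3),
    render = list(enabled = FALSE, noise_sd = 2, background = 200)
  )
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
    else if (is.list(defaults[[nm]]) && nm != "groups")
      cfg[[nm]] <- utils::modifyList(defaults[[nm]], cfg[[nm]])
  }
  if (is.null(cfg$protocol$type) ||
      !cfg$protocol$type %in% c("spontaneous", "startle"))
    stop("protocol type must be 'spontaneous' or 'startle'", call. = FALSE)
  proto_defaults <- if (cfg$protocol$type == "spontaneous") {
    list(duration_h = 24, frame_rate_hz = 0.5, zt_start_h = 20)
  } else {
    list(trials_per_block = 5, n_blocks = 5, inter_trial_s = 2,
         inter_block_min = 30, post_stim_window_s = 1, frame_rate_hz = 100)
  }
  cfg$protocol <- utils::modifyList(proto_defaults, cfg$protocol)
  if (any(unlist(cfg$thresholds) <= 0))
    stop("thresholds must be positive", call. = FALSE)
  structure(cfg, class = c("run_config", "list"))
}

.cfg_layout <- function(cfg) do.call(plate_layout, cfg$layout)

.cfg_groups <- function(cfg) {
  lapply(cfg$groups, function(g) {
    if (!is.null(g$preset)) {
      p <- preset_params(g$preset)
      extra <- g[setdiff(names(g), "preset")]
      if (length(extra)) p <- do.call(larva_params,
                                      utils::modifyList(unclass(p), extra))
      p
    } else {
      do.call(larva_params, g)
    }
  })
}

.cfg_protocol <- function(cfg) {
  p <- cfg$protocol
  do.call(startle_protocol,
          p[intersect(names(p), names(formals(startle_protocol)))])
}

# out_dir is implicit in the run directory; keeping it out of the persisted
# config makes the config hash location-independent
.write_cfg <- function(cfg, path) {
  cfg <- unclass(cfg)
  cfg$out_dir <- NULL
  yaml::write_yaml(cfg, path)
  invisible(path)
}

.dep <- function(path, stage, needed_by) {
  if (!file.exists(path))
    stop(sprintf("stage '%s' requires output of stage '%s' (%s not found)",
                 needed_by, stage, basename(path)), call. = FALSE)
  path
}

#' Run the analysis pipeline
#'
#' Orchestrates simulate -> (track) -> metrics -> stats -> report as a
#' reproducible, file-based run: every stage communicates only through CSV,
#' TIFF and JSON files in `out_dir`, and a manifest records the config
#' hash, seed and the MD5 of every output, so reruns with an identical
#' configuration are bit-identical.
#'
#' The `track` stage re-tracks rendered video and is only available when
#' `render$enabled` is true in the config (rendering whole 24 h recordings
#' is deliberately not attempted; tracking accuracy is validated on short
#' stacks).
#'
#' @param config Path to a YAML config or a list ([read_run_config()]).
#' @param stages Character subset of
#'   `c("simulate", "track", "metrics", "stats", "report")`, in pipeline
#'   order.
#' @param out_dir Optional override of the config's output directory.
#' @return The manifest (list), invisibly; all outputs land in `out_dir`.
#' @examples
#' \donttest{
#' cfg <- list(seed = 7, protocol = list(type = "spontaneous",
#'                                       duration_h = 1),
#'             out_dir = tempfile())
#' man <- run_pipeline(cfg)
#' names(man$stages)
#' }
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "metrics", "stats",
                                    "report"),
                         out_dir = NULL) {
  cfg <- read_run_config(config)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  stages <- match.arg(stages, c("simulate", "track", "metrics", "stats",
                                "report"), several.ok = TRUE)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(...) file.path(cfg$out_dir, ...)
  .write_cfg(cfg, pth("config_used.yaml"))
  cfg_hash <- unname(tools::md5sum(pth("config_used.yaml")))

  manifest <- list(config_hash = cfg_hash, seed = cfg$seed,
                   package_version = as.character(
                     utils::packageVersion("larvatrack")),
                   stages = list())
  done <- function(stage, files, records = NA) {
    files <- files[file.exists(files)]
    manifest$stages[[stage]] <<- list(
      outputs = as.list(stats::setNames(unname(tools::md5sum(files)),
                                        basename(files))),
      records = records)
  }
  log_stage <- function(stage, t0, n) {
    message(sprintf("[larvatrack] %-8s %6.2f s, %d record(s)", stage,
                    as.numeric(Sys.time()) - t0, n))
  }

  spont <- cfg$protocol$type == "spontaneous"

  for (stage in stages) {
    t0 <- as.numeric(Sys.time())
    n_rec <- 0L
    if (stage == "simulate") {
      layout <- .cfg_layout(cfg)
      ga <- group_assignment(layout, .cfg_groups(cfg))
      write.csv(as.data.frame(ga)[c("well_id", "group_label")],
                pth("groups.csv"), row.names = FALSE, quote = FALSE)
      if (spont) {
        pt <- simulate_plate(ga,
                             duration_s = cfg$protocol$duration_h * 3600,
                             frame_rate_hz = cfg$protocol$frame_rate_hz,
                             zt_start_h = cfg$protocol$zt_start_h,
                             well_radius_mm = layout$well_diameter_mm / 2,
                             seed = cfg$seed)
        write_trajectories(pt, pth("trajectories.csv"))
        n_rec <- sum(vapply(pt, nrow, integer(1)))
        if (isTRUE(cfg$render$enabled)) {
          rf <- render_frames(pt, layout, noise_sd = cfg$render$noise_sd,
                              background = cfg$render$background,
                              seed = cfg$seed + 1)
          write_frame_stack(rf$stack, pth("frames.tif"))
          write_reference(rf$reference, pth("reference.tif"))
        }
        done("simulate", pth(c("groups.csv", "trajectories.csv",
                               "frames.tif", "reference.tif")), n_rec)
      } else {
        proto <- .cfg_protocol(cfg)
        ses <- simulate_startle_session(
          ga, proto, well_radius_mm = layout$well_diameter_mm / 2,
          seed = cfg$seed)
        write.csv(ses$traces, pth("traces.csv"), row.names = FALSE,
                  quote = FALSE)
        write_stim_events(ses$events, pth("stim_events.csv"))
        write.csv(ses$truth, pth("truth.csv"), row.names = FALSE,
                  quote = FALSE)
        n_rec <- nrow(ses$traces)
        done("simulate", pth(c("groups.csv", "traces.csv",
                               "stim_events.csv", "truth.csv")), n_rec)
      }
    } else if (stage == "track") {
      .dep(pth("frames.tif"), "simulate", "track")
      .dep(pth("reference.tif"), "simulate", "track")
      layout <- .cfg_layout(cfg)
      stk <- read_frame_stack(pth("frames.tif"),
                              frame_rate_hz = cfg$protocol$frame_rate_hz,
                              t0_zt_h = cfg$protocol$zt_start_h)
      tk <- track(stk, read_reference(pth("reference.tif")), layout)
      write_trajectories(tk, pth("tracked.csv"))
      n_rec <- sum(vapply(tk, nrow, integer(1)))
      done("track", pth("tracked.csv"), n_rec)
    } else if (stage == "metrics") {
      groups <- read.csv(.dep(pth("groups.csv"), "simulate", "metrics"),
                         stringsAsFactors = FALSE)
      if (spont) {
        src <- if (file.exists(pth("tracked.csv"))) pth("tracked.csv") else
          .dep(pth("trajectories.csv"), "simulate", "metrics")
        trs <- read_trajectories(src,
                                 frame_rate_hz = cfg$protocol$frame_rate_hz)
        profs <- lapply(trs, activity_profile,
                        displacement_threshold_mm =
                          cfg$thresholds$movement_mm)
        act <- do.call(rbind, lapply(profs, function(p) data.frame(
          well_id = p$well_id, overall_pct = p$overall_pct)))
        act$group_label <- groups$group_label[match(act$well_id,
                                                    groups$well_id)]
        write.csv(act, pth("metrics_activity.csv"), row.names = FALSE,
                  quote = FALSE)
        hourly <- do.call(rbind, lapply(profs, function(p)
          data.frame(well_id = p$well_id, bin_index = seq_len(nrow(p$hourly)),
                     p$hourly)))
        hourly$group_label <- groups$group_label[match(hourly$well_id,
                                                       groups$well_id)]
        write.csv(hourly, pth("metrics_hourly.csv"), row.names = FALSE,
                  quote = FALSE)
        n_rec <- nrow(act)
        done("metrics", pth(c("metrics_activity.csv",
                              "metrics_hourly.csv")), n_rec)
      } else {
        traces <- read.csv(.dep(pth("traces.csv"), "simulate", "metrics"),
                           stringsAsFactors = FALSE)
        events <- read_stim_events(.dep(pth("stim_events.csv"), "simulate",
                                        "metrics"))
        proto <- .cfg_protocol(cfg)
        res <- startle_session_measures(
          traces, events, proto, groups = groups,
          latency_threshold_mm = cfg$thresholds$latency_mm)
        kept <- inclusion_filter(res)
        res$retained <- res$well_id %in% kept
        write.csv(res, pth("metrics_trials.csv"), row.names = FALSE,
                  quote = FALSE)
        kept_res <- res[res$retained, ]
        if (nrow(kept_res)) {
          rr <- response_rate(kept_res)
          write.csv(rr$grand, pth("metrics_response_rate.csv"),
                    row.names = FALSE, quote = FALSE)
          hab <- do.call(rbind, lapply(
            split(kept_res, kept_res$group_label), function(d) {
              h <- habituation_slopes(trial_means(d), proto,
                                      group_label = d$group_label[1])
              data.frame(group_label = h$group_label,
                         block = c(seq_along(h$per_block_slope), NA),
                         slope = c(h$per_block_slope, h$overall_slope),
                         stringsAsFactors = FALSE)
            }))
          write.csv(hab, pth("metrics_habituation.csv"),
                    row.names = FALSE, quote = FALSE)
        }
        n_rec <- nrow(res)
        done("metrics", pth(c("metrics_trials.csv",
                              "metrics_response_rate.csv",
                              "metrics_habituation.csv")), n_rec)
      }
    } else if (stage == "stats") {
      stats_out <- .stage_stats(cfg, pth, spont)
      jsonlite::write_json(stats_out, pth("stats.json"), auto_unbox = TRUE,
                           digits = 10, pretty = TRUE)
      writeLines(unlist(lapply(stats_out$tests, function(s) s$report)),
                 pth("stats.txt"))
      n_rec <- length(stats_out$tests)
      done("stats", pth(c("stats.json", "stats.txt")), n_rec)
    } else if (stage == "report") {
      rep_txt <- make_report(cfg$out_dir)
      n_rec <- length(rep_txt)
      done("report", pth("report.txt"), n_rec)
    }
    log_stage(stage, t0, n_rec)
  }
  jsonlite::write_json(manifest, pth("run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

# Statistics stage: group comparisons in the style of the results the
# pipeline is meant to reproduce.
.stage_stats <- function(cfg, pth, spont) {
  tests <- list()
  # a statistic that cannot be computed on this run (e.g. too few retained
  # larvae in a group) is skipped with a message, not fatal
  add <- function(name, expr) {
    sr <- tryCatch(expr, error = function(e) {
      message(sprintf("[larvatrack] stats: skipping %s (%s)", name,
                      conditionMessage(e)))
      NULL
    })
    if (is.null(sr)) return(invisible(NULL))
    tests[[name]] <<- list(statistic = sr$statistic_name, value = sr$value,
                           df1 = sr$df1, df2 = sr$df2, p = sr$p,
                           effect = sr$effect_size,
                           report = paste0(name, ": ", report_round(sr)))
  }
  if (spont) {
    act <- read.csv(.dep(pth("metrics_activity.csv"), "metrics", "stats"),
                    stringsAsFactors = FALSE)
    gs <- lapply(split(act$overall_pct, act$group_label), function(v)
      group_summary(mean(v), sd(v), length(v)))
    labs <- names(gs)
    if (length(labs) >= 2) {
      for (i in seq_len(length(labs) - 1)) for (j in (i + 1):length(labs)) {
        nm <- paste0("activity_t_", labs[i], "_vs_", labs[j])
        add(nm, pooled_t_test(gs[[i]], gs[[j]]))
      }
    }
    hourly <- read.csv(pth("metrics_hourly.csv"), stringsAsFactors = FALSE)
    # one full circadian cycle per larva for the time x group ANOVA
    hourly <- hourly[hourly$bin_index <= 24, ]
    n_bins <- stats::aggregate(bin_index ~ well_id, hourly, length)
    if (nrow(hourly) && all(n_bins$bin_index == 24) && length(labs) >= 2) {
      fit <- tryCatch(mixed_rm_anova(hourly, subject = "well_id",
                                     group = "group_label",
                                     within = "zt_hour", value = "pct"),
                      error = function(e) NULL)
      if (!is.null(fit)) {
        add("circadian_anova_time", anova_effect(fit, "within"))
        add("circadian_anova_genotype", anova_effect(fit, "between"))
        add("circadian_anova_interaction",
            anova_effect(fit, "within:between"))
      }
    }
  } else {
    res <- read.csv(.dep(pth("metrics_trials.csv"), "metrics", "stats"),
                    stringsAsFactors = FALSE)
    res <- res[res$retained, ]
    if (nrow(res)) {
      rr <- response_rate(res)
      labs <- rr$grand$group_label
      if (length(labs) >= 2) {
        for (i in seq_len(length(labs) - 1)) for (j in (i + 1):length(labs)) {
          g1 <- rr$per_trial[rr$per_trial$group_label == labs[i], ]
          g2 <- rr$per_trial[rr$per_trial$group_label == labs[j], ]
          nm <- paste0("response_rate_t_", labs[i], "_vs_", labs[j])
          add(nm, pooled_t_test(
            group_summary(mean(g1$pct), sd(g1$pct), nrow(g1)),
            group_summary(mean(g2$pct), sd(g2$pct), nrow(g2))))
        }
        fit_t <- tryCatch(mixed_rm_anova(res, subject = "well_id",
                                         group = "group_label",
                                         within = "trial_in_block",
                                         value = "distance_mm"),
                          error = function(e) NULL)
        if (!is.null(fit_t)) {
          add("startle_anova_trial", anova_effect(fit_t, "within"))
          add("startle_anova_genotype", anova_effect(fit_t, "between"))
        }
        fit_b <- tryCatch(mixed_rm_anova(res, subject = "well_id",
                                         group = "group_label",
                                         within = "block",
                                         value = "distance_mm"),
                          error = function(e) NULL)
        if (!is.null(fit_b))
          add("startle_anova_block", anova_effect(fit_b, "within"))
      }
    }
  }
  list(thresholds = cfg$thresholds, seed = cfg$seed, tests = tests)
}

#' Assemble the run report
#'
#' Collects the metric and statistics outputs of a completed (or partial)
#' run directory into a human-readable text report with a provenance
#' header. Missing sections are reported as "no data" with a warning.
#'
#' @param run_dir Output directory of [run_pipeline()].
#' @return Character vector of report lines (also written to
#'   `report.txt` in `run_dir`), invisibly.
#' @export
make_report <- function(run_dir) {
  pth <- function(...) file.path(run_dir, ...)
  if (!file.exists(pth("config_used.yaml")))
    stop("not a pipeline run directory (config_used.yaml missing)",
         call. = FALSE)
  cfg <- read_run_config(pth("config_used.yaml"))
  lines <- c("larvatrack run report",
             "=====================",
             sprintf("config hash: %s",
                     unname(tools::md5sum(pth("config_used.yaml")))),
             sprintf("seed: %s", cfg$seed),
             sprintf("protocol: %s", cfg$protocol$type),
             sprintf("thresholds: movement %g mm, latency %g mm",
                     cfg$thresholds$movement_mm, cfg$thresholds$latency_mm),
             "")
  section <- function(title, body) c(sprintf("-- %s --", title), body, "")
  partial <- FALSE

  if (file.exists(pth("metrics_activity.csv"))) {
    act <- read.csv(pth("metrics_activity.csv"), stringsAsFactors = FALSE)
    tab <- vapply(split(act$overall_pct, act$group_label), function(v)
      sprintf("%.2f +/- %.2f %% (n = %d)", mean(v), sd(v), length(v)),
      character(1))
    lines <- c(lines, section("spontaneous activity (percent time in motion)",
                              sprintf("  %s: %s", names(tab), tab)))
  }
  if (file.exists(pth("metrics_response_rate.csv"))) {
    rr <- read.csv(pth("metrics_response_rate.csv"),
                   stringsAsFactors = FALSE)
    lines <- c(lines, section("startle response rate (grand mean over trials)",
      sprintf("  %s: %.1f +/- %.1f %%", rr$group_label, rr$mean_pct,
              rr$sd_pct)))
  }
  if (file.exists(pth("metrics_trials.csv"))) {
    res <- read.csv(pth("metrics_trials.csv"), stringsAsFactors = FALSE)
    kept <- res[res$retained, ]
    tab <- vapply(split(kept$distance_mm, kept$group_label), function(v)
      sprintf("%.2f +/- %.2f mm", mean(v), sd(v)), character(1))
    lines <- c(lines, section("startle distance (1 s post-stimulus, retained larvae)",
                              sprintf("  %s: %s", names(tab), tab)))
  }
  if (file.exists(pth("metrics_habituation.csv"))) {
    hab <- read.csv(pth("metrics_habituation.csv"),
                    stringsAsFactors = FALSE)
    ov <- hab[is.na(hab$block), ]
    lines <- c(lines, section("habituation (overall slope, mm/trial)",
      sprintf("  %s: %.3f", ov$group_label, ov$slope)))
  }
  if (!any(file.exists(pth(c("metrics_activity.csv",
                             "metrics_trials.csv"))))) {
    lines <- c(lines, section("metrics", "  no data"))
    partial <- TRUE
  }
  if (file.exists(pth("stats.txt"))) {
    lines <- c(lines, section("statistics",
                              paste0("  ", readLines(pth("stats.txt")))))
  } else {
    lines <- c(lines, section("statistics", "  no data"))
    partial <- TRUE
  }
  if (partial) warning("incomplete run: report contains 'no data' sections")
  writeLines(lines, pth("report.txt"))
  invisible(lines)
}
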