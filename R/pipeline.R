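#' Default pipeline configuration
#'
#' Assembles the run configuration for the full three-tier analysis:
#' analysis thresholds (contact 2.5 A, salt-bridge 4.0 A, open-state
#' boundary 110 degrees, hotspot 0.10, coupling-ratio threshold 1.5,
#' recoupling dead-bands), the synthetic study conditions for each tier
#' (trajectory-metric distributions per troponin x ligand condition,
#' motility EC50 pairs, myocyte dobutamine effects), and the seed.
#' Condition parameters are the package's reference study set; every
#' entry can be overridden or replaced, and the config round-trips
#' through YAML via [read_config()] / [write_config()].
#'
#' @param seed Integer seed for all generators.
#' @param n_frames,n_runs Trajectory sampling per condition.
#' @param n_cells Myocyte cells per condition.
#' @param out_dir Optional output directory for [run_pipeline()].
#' @return A `tn_config` list.
#' @export
default_config <- function(seed = 1L, n_frames = 3750L, n_runs = 5L,
                           n_cells = 20L, out_dir = NULL) {
  g <- function(mean, sd) list(weights = 1, means = mean, sds = sd)
  md <- list(
    list(condition = "WT apo", variant = "WT", ligand = NULL,
         ab = list(uP = g(101.81, 9.15), P = g(96.16, 5.73)),
         hinge = list(uP = g(121.61, 7.24), P = g(123.26, 5.95)),
         distance = list(uP = list(mean = 30.18, sd = 1.34),
                         P = list(mean = 29.9, sd = 0.9)),
         saltbridge = list(uP = 0, P = 0)),
    list(condition = "G159D apo", variant = "G159D", ligand = NULL,
         ab = list(uP = g(97.06, 5.48), P = g(98.97, 6.73)),
         hinge = list(uP = g(121.51, 4.82), P = g(116.2, 6.04)),
         distance = list(uP = list(mean = 29.22, sd = 0.98),
                         P = list(mean = 29.59, sd = 1.18)),
         saltbridge = list(uP = 0.801, P = 0.761)),
    list(condition = "G159D EGCG", variant = "G159D",
         ligand = list(label = "EGC", bound = list(uP = 0.93, P = 0.88)),
         ab = list(uP = g(102.25, 6.07), P = g(89.0, 18.07)),
         hinge = list(uP = g(114.62, 9.18), P = g(107.59, 14.53)),
         distance = list(uP = list(mean = 31.17, sd = 1.48),
                         P = list(mean = 31.98, sd = 1.59)),
         saltbridge = list(uP = 0.222, P = 0.530)),
    list(condition = "G159D RVL", variant = "G159D",
         ligand = list(label = "RVL", bound = list(uP = 0.49, P = 0.33)),
         ab = list(uP = g(105.48, 9.16), P = g(94.34, 8.72)),
         hinge = list(uP = g(112.61, 7.64), P = g(121.89, 6.99)),
         distance = list(uP = list(mean = 32.13, sd = 1.69),
                         P = list(mean = 31.39, sd = 1.51)),
         saltbridge = list(uP = 0.505, P = 0.460)),
    list(condition = "G159D SilybinA", variant = "G159D",
         ligand = list(label = "SLA", bound = list(uP = 0.95, P = 0.82)),
         ab = list(uP = g(98.55, 10.98), P = g(103.43, 10.94)),
         hinge = list(uP = g(126.65, 5.77), P = g(120.3, 8.47)),
         distance = list(uP = list(mean = 30.09, sd = 1.5),
                         P = list(mean = 30.84, sd = 1.04)),
         saltbridge = list(uP = 0.083, P = 0.403)),
    list(condition = "G159D SilybinB", variant = "G159D",
         ligand = list(label = "SLB", bound = list(uP = 0.95, P = 0.88)),
         ab = list(uP = g(103.61, 5.81), P = g(100.52, 7.45)),
         hinge = list(uP = g(117.74, 5.6), P = g(121.32, 4.98)),
         distance = list(uP = list(mean = 31.83, sd = 1.83),
                         P = list(mean = 30.72, sd = 1.13)),
         saltbridge = list(uP = 0.175, P = 0.227)),
    list(condition = "G159D ECG", variant = "G159D",
         ligand = list(label = "ECG", bound = list(uP = 0.92, P = 0.92)),
         ab = list(uP = g(98.1, 6.4), P = g(97.9, 6.9)),
         hinge = list(uP = g(118.9, 9.0), P = g(110.6, 9.0)),
         distance = list(uP = list(mean = 30.2, sd = 1.2),
                         P = list(mean = 30.2, sd = 1.4)),
         saltbridge = list(uP = 0.820, P = 0.86))
  )
  motility <- list(
    list(condition = "Native", ec50_unp = 0.059, ratio = 2.24, n = 6),
    list(condition = "Native EGCG", ec50_unp = 0.15, ratio = 1.73, n = 6),
    list(condition = "E180G", ec50_unp = 0.0363, ratio = 0.95, n = 9),
    list(condition = "G159D", ec50_unp = 0.095, ratio = 0.97, n = 5),
    list(condition = "G159D EGCG", ec50_unp = 0.088, ratio = 2.25, n = 5),
    list(condition = "G159D SilybinA", ec50_unp = 0.136, ratio = 1.0,
         n = 1),
    list(condition = "G159D SilybinB", ec50_unp = 0.053, ratio = 2.3,
         n = 1),
    list(condition = "R92Q", ec50_unp = 0.060, ratio = 1.2, n = 1),
    list(condition = "R92Q EGCG", ec50_unp = 0.045, ratio = 3.1, n = 1)
  )
  # 1 Hz pacing bounds contraction + relaxation below the period, so the
  # planted kinetics use mouse-like times that keep every dobutamine
  # condition realisable
  myo <- function(condition, ttp90, ttb90, amp_f, ttb_f) {
    list(condition = condition, l0 = 120, amplitude_pct = 8,
         ttp90 = ttp90, ttb90 = ttb90, amplitude_factor = amp_f,
         ttp90_factor = 0.97, ttb90_factor = ttb_f)
  }
  myocyte <- list(
    myo("NTG", 0.12, 0.31, 1.47, 0.79),
    myo("E99K", 0.12, 0.45, 1.00, 1.12),
    myo("E99K SilybinA", 0.12, 0.45, 1.00, 1.04),
    myo("E99K SilybinB", 0.12, 0.45, 1.05, 0.75),
    myo("E99K RVL", 0.12, 0.45, 1.05, 0.59),
    myo("E99K EGCG", 0.12, 0.45, 1.05, 0.78)
  )
  structure(
    list(
      seed = as.integer(seed),
      n_frames = as.integer(n_frames),
      n_runs = as.integer(n_runs),
      n_cells = as.integer(n_cells),
      frame_interval_ns = 0.4,
      cutoffs = list(contact = 2.5, saltbridge = 4.0, open_state = 110,
                     hotspot = 0.10, coupling_ratio = 1.5,
                     dead_band_angle = 0.5, dead_band_distance = 0.25,
                     dead_band_pct = 1),
      chain_map = list(tnc = "C", tni = "I", ligand = "L"),
      md_conditions = md,
      motility_conditions = motility,
      myocyte_conditions = myocyte,
      mmpbsa_csv = NULL,
      out_dir = out_dir
    ),
    class = "tn_config"
  )
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return [read_config()] returns a `tn_config`; [write_config()]
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (any(unlist(cfg$cutoffs) <= 0)) abort("All cutoffs must be positive.")
  structure(cfg, class = "tn_config")
}

#' @rdname read_config
#' @param config A `tn_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Hash of the analysis-relevant configuration
#'
#' Stable hash over every parameter that affects results (output paths
#' excluded), recorded in reports for provenance.
#'
#' @param config A `tn_config`.
#' @return Character hash.
#' @export
config_hash <- function(config) {
  x <- unclass(config)
  x$out_dir <- NULL
  rlang::hash(x)
}

simulate_md_condition <- function(cond, phospho, n_frames, n_runs,
                                  frame_interval_ns, seed) {
  lig <- NULL
  if (!is.null(cond$ligand)) {
    lig <- list(label = cond$ligand$label,
                bound_fraction = cond$ligand$bound[[phospho]],
                targets = 20L, mean_bound_episode = 25)
  }
  spec <- trajectory_spec(
    n_frames = n_frames, n_runs = n_runs,
    frame_interval_ns = frame_interval_ns,
    ab_angle = cond$ab[[phospho]], hinge = cond$hinge[[phospho]],
    distance = cond$distance[[phospho]], variant = cond$variant,
    saltbridge_occupancy = cond$saltbridge[[phospho]], ligand = lig,
    condition = paste(cond$condition, phospho)
  )
  simulate_trajectory(spec, seed = seed, verify = FALSE)
}

#' Run the full three-tier coupling analysis
#'
#' Executes the stages present in the config — trajectory metrics,
#' motility coupling, myocyte transients — on synthetic data generated
#' from the configured study conditions, and assembles the report
#' tables: helix A/B angle, hinge angle, interdomain distance plus
#' salt-bridge occupancy, ligand attachment, EC50 coupling and
#' myocyte/lusitropy tables. Deterministic given config (the seed is
#' part of the config).
#'
#' @param config A [default_config()]-style `tn_config`.
#' @param stages Character subset of `c("md", "motility", "myocyte")`.
#' @return A `tn_study_report` list of tibbles: `ab_table`,
#'   `hinge_table`, `distance_table`, `saltbridge_table`,
#'   `attachment_table`, `metrics_long`, `per_run`, `motility_table`,
#'   `myocyte_table`, plus `config_hash` and `version`. When
#'   `config$out_dir` is set, each table is written as CSV plus a JSON
#'   summary, and the used thresholds are logged to `thresholds.json`.
#' @export
run_pipeline <- function(config,
                         stages = c("md", "motility", "myocyte")) {
  stopifnot(inherits(config, "tn_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  set.seed(config$seed)
  stage_seeds <- setNames(sample.int(1e9, 3),
                          c("md", "motility", "myocyte"))
  report <- list(config_hash = config_hash(config),
                 version = as.character(utils::packageVersion("tncoupling")))
  regions <- default_regions()
  cut <- config$cutoffs
  if ("md" %in% stages && length(config$md_conditions)) {
    long <- list()
    sb_rows <- list()
    att_rows <- list()
    set.seed(stage_seeds[["md"]])
    cond_seeds <- sample.int(1e9, 2L * length(config$md_conditions))
    k <- 0
    for (cond in config$md_conditions) {
      for (ph in c("uP", "P")) {
        k <- k + 1
        sim <- tryCatch(
          simulate_md_condition(cond, ph, config$n_frames, config$n_runs,
                                config$frame_interval_ns, cond_seeds[k]),
          error = function(e) {
            abort(paste0("Stage 'md' failed for condition '",
                         cond$condition, "' (", ph, "): ",
                         conditionMessage(e)))
          }
        )
        for (traj in sim$runs) {
          long[[length(long) + 1]] <- bind_rows(
            ab_angle_series(traj, regions$helix_a, regions$helix_b),
            hinge_angle_series(traj, regions$domain_n, regions$domain_itc,
                               regions$pivot),
            interdomain_distance_series(traj, regions$domain_n,
                                        regions$domain_itc)
          ) |>
            mutate(condition = cond$condition, phospho = ph)
        }
        sb <- lapply(sim$runs, function(traj) {
          pair_bond_occupancy(traj, regions$d159, regions$r83,
                              cutoff = cut$saltbridge)$series
        })
        sb_rows[[length(sb_rows) + 1]] <- tibble(
          condition = cond$condition, phospho = ph,
          occupancy = mean(bind_rows(sb)$bound)
        )
        if (!is.null(cond$ligand)) {
          att <- vapply(sim$runs, function(traj) {
            ligand_attachment(traj, regions$ligand, regions$protein,
                              cutoff = cut$contact)$fraction_attached
          }, numeric(1))
          att_rows[[length(att_rows) + 1]] <- tibble(
            condition = cond$condition, ligand = cond$ligand$label,
            phospho = ph, fraction_attached = mean(att)
          )
        }
      }
    }
    metrics_long <- bind_rows(long)
    md_tab <- function(metric_name, threshold, dead_band) {
      metrics_long |>
        filter(.data$metric == metric_name) |>
        metric_table(threshold = threshold, wt = "WT apo",
                     dead_band = dead_band)
    }
    report$metrics_long <- metrics_long
    report$ab_table <- md_tab("AB_helix", cut$open_state,
                              cut$dead_band_angle)
    report$hinge_table <- md_tab("hinge", NA, cut$dead_band_angle)
    report$distance_table <- md_tab("interdomain_distance", NA,
                                    cut$dead_band_distance)
    report$per_run <- metrics_long |>
      group_by(.data$condition, .data$phospho, .data$metric,
               .data$run_id) |>
      summarise(mean = mean(.data$value), sd = sd(.data$value),
                .groups = "drop")
    report$saltbridge_table <- bind_rows(sb_rows) |>
      tidyr::pivot_wider(names_from = "phospho", values_from = "occupancy",
                         names_prefix = "occupancy_")
    report$attachment_table <- if (length(att_rows)) {
      tab <- bind_rows(att_rows) |>
        tidyr::pivot_wider(names_from = "phospho",
                           values_from = "fraction_attached",
                           names_prefix = "attached_")
      if (!is.null(config$mmpbsa_csv)) {
        # externally supplied binding free energies: echoed, never computed
        dg <- as_tibble(utils::read.csv(config$mmpbsa_csv))
        tab <- left_join(tab, dg, by = "condition")
      }
      tab
    } else {
      tibble()
    }
  }
  if ("motility" %in% stages && length(config$motility_conditions)) {
    set.seed(stage_seeds[["motility"]])
    mot_seeds <- sample.int(1e9, length(config$motility_conditions))
    rows <- purrr::imap(config$motility_conditions, function(mc, i) {
      curves <- simulate_activation_curves(
        ec50_unp = mc$ec50_unp, ratio = mc$ratio,
        n_replicates = mc$n %||% 1L, noise_sd = mc$noise_sd %||% 0.02,
        condition = mc$condition, seed = mot_seeds[i]
      )
      fits <- curves |>
        group_by(.data$replicate_id, .data$phospho) |>
        dplyr::group_modify(~ glance(fit_hill(.x))) |>
        ungroup() |>
        tidyr::pivot_wider(names_from = "phospho", values_from = "ec50",
                           id_cols = "replicate_id") |>
        dplyr::rename(ec50_p = "P", ec50_unp = "uP")
      call <- coupling_call(fits, threshold = cut$coupling_ratio)
      mutate(call, condition = mc$condition,
             ec50_p_mean = mean(fits$ec50_p),
             ec50_unp_mean = mean(fits$ec50_unp), .before = 1)
    })
    report$motility_table <- bind_rows(rows)
  }
  if ("myocyte" %in% stages && length(config$myocyte_conditions)) {
    set.seed(stage_seeds[["myocyte"]])
    myo_seeds <- sample.int(1e9, length(config$myocyte_conditions))
    rows <- purrr::imap(config$myocyte_conditions, function(mc, i) {
      traces <- simulate_dobutamine_pair(
        l0 = mc$l0, amplitude_pct = mc$amplitude_pct, ttp90 = mc$ttp90,
        ttb90 = mc$ttb90, amplitude_factor = mc$amplitude_factor,
        ttp90_factor = mc$ttp90_factor, ttb90_factor = mc$ttb90_factor,
        n_cells = config$n_cells, seed = myo_seeds[i]
      )
      feats <- traces |>
        group_by(.data$cell_id, .data$treatment) |>
        dplyr::group_modify(~ transient_features(.x)) |>
        ungroup()
      paired_response(feats) |>
        mutate(condition = mc$condition, .before = 1)
    })
    report$myocyte_table <- bind_rows(rows)
  }
  class(report) <- "tn_study_report"
  if (!is.null(config$out_dir)) write_report(report, config)
  report
}

write_report <- function(report, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- Filter(is.data.frame, report)
  for (nm in names(tabs)) {
    utils::write.csv(tabs[[nm]], file.path(config$out_dir,
                                           paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  jsonlite::write_json(
    c(list(config_hash = report$config_hash, version = report$version),
      lapply(tabs, identity)),
    file.path(config$out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, na = "null"
  )
  jsonlite::write_json(config$cutoffs,
                       file.path(config$out_dir, "thresholds.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(config$out_dir)
}

#' @export
print.tn_study_report <- function(x, ...) {
  cat("<study report> tables:",
      paste(names(Filter(is.data.frame, x)), collapse = ", "), "\n")
  invisible(x)
}

#' Cross-level consistency of recoupling calls
#'
#' Lines up, per ligand, the restored/not-restored calls from each
#' analysis level present in the report — helix A/B angle delta, hinge
#' angle delta, motility coupling, myocyte lusitropy — and scores their
#' agreement (fraction of levels agreeing with the majority call).
#'
#' @param report A [run_pipeline()] result with at least two levels.
#' @param lusitropy_threshold Minimum group-mean lusitropy (with
#'   p < 0.05) counting as a restored myocyte response.
#' @return Tibble: `ligand`, one logical column per level, `n_levels`,
#'   `agreement`, `consistent`.
#' @export
cross_level_summary <- function(report, lusitropy_threshold = 0.1) {
  ligands <- c("EGCG", "RVL", "SilybinA", "SilybinB", "ECG")
  levels <- list()
  pick <- function(tab, lig) {
    r <- tab[grepl(paste0(" ", lig, "$"), tab$condition), ]
    pref <- r[grepl("^G159D", r$condition), ]  # prefer the MD mutant
    if (nrow(pref)) pref else r
  }
  if (!is.null(report$ab_table)) {
    levels$md_ab <- function(lig) {
      r <- pick(report$ab_table, lig)
      if (nrow(r)) r$restored else NA
    }
  }
  if (!is.null(report$hinge_table)) {
    levels$md_hinge <- function(lig) {
      r <- pick(report$hinge_table, lig)
      if (nrow(r)) r$restored else NA
    }
  }
  if (!is.null(report$motility_table)) {
    levels$motility <- function(lig) {
      r <- pick(report$motility_table, lig)
      if (nrow(r)) r$coupled else NA
    }
  }
  if (!is.null(report$myocyte_table)) {
    levels$myocyte <- function(lig) {
      r <- pick(report$myocyte_table, lig)
      r <- r[r$measure == "lusitropy", ]
      if (nrow(r)) r$mean > lusitropy_threshold & r$p_value < 0.05 else NA
    }
  }
  if (length(levels) < 2L) {
    abort("Cross-level summary needs at least two analysis levels.")
  }
  rows <- purrr::map(ligands, function(lig) {
    calls <- purrr::map_lgl(levels, function(f) {
      v <- f(lig)
      if (length(v) == 0) NA else as.logical(v[1])
    })
    known <- calls[!is.na(calls)]
    if (length(known) == 0) return(NULL)
    majority <- mean(known) >= 0.5
    tibble(ligand = lig, !!!as.list(calls),
           n_levels = length(known),
           agreement = mean(known == majority),
           consistent = all(known == known[1]))
  })
  bind_rows(rows)
}

#' Density plot of a metric by condition and phosphorylation state
#'
#' @param data Long metric tibble (`condition`, `phospho`, `value`), e.g.
#'   `report$metrics_long` filtered to one metric.
#' @param threshold Optional vertical reference (e.g. the 110-degree
#'   open-state boundary).
#' @return A ggplot object.
#' @export
plot_metric_distribution <- function(data, threshold = NULL) {
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$value,
                                          colour = .data$phospho)) +
    ggplot2::geom_density() +
    ggplot2::facet_wrap(~condition, scales = "free_y") +
    ggplot2::labs(x = "Metric value", y = "Density",
                  colour = "Phospho") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_vline(xintercept = threshold, linetype = 2,
                                 colour = "grey50")
  }
  p
}
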