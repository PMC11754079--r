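#' Default configuration for a synthetic two-genotype study
#'
#' Defines the study conditions for an end-to-end synthetic run: two genotype
#' profiles sampled at ZT 0/6/12/18 (E/I) or ZT 0/12 (minis, charge), cell and
#' animal counts per group, and the per-phase true values each generator
#' receives. The default mutant profile (`"flat"`) removes the E/I
#' oscillation; `"reversed"` swaps the dark/light values.
#'
#' @param seed Master seed; every stage derives its own stream from it.
#' @param mutant_profile `"flat"` or `"reversed"`.
#' @param n_cells_ei,n_cells_mini,n_cells_charge,n_mice_sleep,n_mice_imaging
#'   Group sizes.
#' @param stages Which stages [run_study()] executes.
#' @return Configuration list.
#' @export
study_config <- function(seed = 1, mutant_profile = c("flat", "reversed"),
                         n_cells_ei = 12, n_cells_mini = 6, n_cells_charge = 8,
                         n_mice_sleep = 5, n_mice_imaging = 5,
                         stages = c("ei", "minis", "charge", "sleep", "imaging")) {
  mutant_profile <- match.arg(mutant_profile)
  mut_ei <- switch(mutant_profile,
                   flat = c(dark = 0.42, light = 0.42),
                   reversed = c(dark = 0.35, light = 0.50))
  mut_mepsc <- switch(mutant_profile,
                      flat = c(ZT0 = 3.0, ZT12 = 3.0),
                      reversed = c(ZT0 = 2.4, ZT12 = 3.6))
  list(
    seed = as.integer(seed),
    stages = stages,
    mutant_profile = mutant_profile,
    cell_sd = 0.15,           # between-cell log-scale SD of E/I and rates
    genotypes = list(
      WT = list(ei = c(dark = 0.50, light = 0.35),
                mepsc_rate = c(ZT0 = 3.6, ZT12 = 2.4),
                charge_scale = c(vehicle.ZT0 = 1.0, WIN.ZT0 = 1.0,
                                 vehicle.ZT12 = 1.0, WIN.ZT12 = 0.5),
                odi = 0.33),
      MUT = list(ei = mut_ei,
                 mepsc_rate = mut_mepsc,
                 charge_scale = c(vehicle.ZT0 = 1.0, WIN.ZT0 = 0.6,
                                  vehicle.ZT12 = 1.0, WIN.ZT12 = 0.6),
                 odi = 0.30)),
    n_cells_ei = n_cells_ei, n_cells_mini = n_cells_mini,
    n_cells_charge = n_cells_charge, n_mice_sleep = n_mice_sleep,
    n_mice_imaging = n_mice_imaging
  )
}

#' Run the full synthetic study
#'
#' Executes the requested stages in dependency order on synthetic data
#' generated from the configuration, quantifies each modality with the
#' package's analysis operations, and applies the statistical battery,
#' producing per-figure-style tables plus a statistics log. Identical
#' configuration and seed give identical output.
#'
#' @param config From [study_config()].
#' @param out_dir Optional directory; when given, every table is written as
#'   CSV.
#' @return List of tables: `ei`, `ei_stats`, `mini`, `mini_stats`, `charge`,
#'   `charge_stats`, `sleep`, `sleep_stats`, `odi`, `odi_stats`, `log`.
#' @export
run_study <- function(config = study_config(), out_dir = NULL) {
  res <- list(log = data.frame())
  log_line <- function(stage, note) {
    res$log <<- rbind(res$log, data.frame(stage = stage, note = note))
  }

  if ("ei" %in% config$stages) {
    tab <- list(); k <- 0
    for (g in names(config$genotypes)) {
      prof <- config$genotypes[[g]]$ei
      for (zt in c(0, 6, 12, 18)) {
        phase <- zt_to_phase(zt)
        for (cell in seq_len(config$n_cells_ei)) {
          sd_ <- child_seed(config$seed, paste("ei", g, zt, cell))
          set.seed(sd_)
          cell_ratio <- prof[[phase]] * exp(stats::rnorm(1, 0, config$cell_sd))
          ser <- gen_evoked_series(e_max = 400 * cell_ratio, i_max = 400,
                                   noise_rms = 5, seed = child_seed(sd_, "trace"))
          cer <- cell_ei_ratio(compute_ratio_curve(ser$pairs), zeitgeber_time = zt)
          k <- k + 1
          tab[[k]] <- data.frame(cell_id = sprintf("%s_ZT%d_c%02d", g, zt, cell),
                                 genotype = g, zt = zt, phase = phase,
                                 circuit = "L2/3-2/3",
                                 ei_ratio = cer$value,
                                 n_intensities = cer$n_intensities_used)
        }
      }
    }
    res$ei <- do.call(rbind, tab)
    an <- anova_two_way(res$ei$ei_ratio, res$ei$genotype, res$ei$phase)
    res$ei_stats <- an$effects
    res$ei_posthoc <- an$posthoc
    log_line("ei", sprintf("genotype x phase interaction F(%g, %g) = %.3f, p = %.4g",
                           an$df[1], an$df[2], an$statistic_value, an$p_value))
  }

  if ("minis" %in% config$stages) {
    tab <- list(); k <- 0
    for (g in names(config$genotypes)) {
      rates <- config$genotypes[[g]]$mepsc_rate
      for (zt in c(0, 12)) {
        for (cell in seq_len(config$n_cells_mini)) {
          sd_ <- child_seed(config$seed, paste("mini", g, zt, cell))
          set.seed(sd_)
          rate <- rates[[paste0("ZT", zt)]] * exp(stats::rnorm(1, 0, config$cell_sd))
          gm <- gen_mini_sweep(rate = rate, duration = 60,
                               seed = child_seed(sd_, "trace"))
          cs <- analyze_mini_cell(gm$sweep, "mEPSC")
          k <- k + 1
          tab[[k]] <- data.frame(cell_id = sprintf("%s_ZT%d_m%02d", g, zt, cell),
                                 genotype = g, zt = zt,
                                 frequency = cs$frequency,
                                 amplitude = cs$mean_amplitude,
                                 rms = cs$rms_noise, n = cs$n_events_used,
                                 qc = cs$qc_pass)
        }
      }
    }
    res$mini <- do.call(rbind, tab)
    an <- anova_two_way(res$mini$frequency, res$mini$genotype,
                        factor(res$mini$zt))
    res$mini_stats <- an$effects
    log_line("minis", sprintf("mEPSC frequency genotype x ZT interaction p = %.4g",
                              an$p_value))
  }

  if ("charge" %in% config$stages) {
    tab <- list(); k <- 0
    for (g in names(config$genotypes)) {
      scl <- config$genotypes[[g]]$charge_scale
      for (cond in c("vehicle", "WIN")) for (zt in c(0, 12)) {
        for (cell in seq_len(config$n_cells_charge)) {
          sd_ <- child_seed(config$seed, paste("chg", g, cond, zt, cell))
          set.seed(sd_)
          amp <- 0.1 * scl[[paste0(cond, ".ZT", zt)]] *
            exp(stats::rnorm(1, 0, config$cell_sd))
          gs <- gen_sipsc_sweep(amp_mean = amp, duration = 200,
                                seed = child_seed(sd_, "trace"),
                                meta = list(drug = cond, zeitgeber_time = zt,
                                            genotype = g))
          uc <- unit_charge(gs$sweep)
          k <- k + 1
          tab[[k]] <- data.frame(cell_id = sprintf("%s_%s_ZT%d_s%02d", g, cond, zt, cell),
                                 genotype = g, condition = cond, zt = zt,
                                 unit_charge = uc$unit_charge,
                                 duration = uc$duration_used)
        }
      }
    }
    res$charge <- do.call(rbind, tab)
    stats_tab <- list()
    for (g in names(config$genotypes)) {
      sub <- res$charge[res$charge$genotype == g, ]
      kw <- condition_contrast(sub$unit_charge, sub$condition, sub$zt)
      stats_tab[[g]] <- data.frame(genotype = g, H = kw$statistic_value,
                                   df = kw$df, p = kw$p_value)
      log_line("charge", sprintf("%s Kruskal-Wallis H = %.2f, p = %.4g",
                                 g, kw$statistic_value, kw$p_value))
    }
    res$charge_stats <- do.call(rbind, stats_tab)
  }

  if ("sleep" %in% config$stages) {
    tab <- list(); k <- 0
    for (g in names(config$genotypes)) {
      for (m in seq_len(config$n_mice_sleep)) {
        days <- lapply(1:3, function(d) {
          truth <- gen_sleep_truth(hours = 24,
                                   seed = child_seed(config$seed,
                                                     paste("sleep", g, m, d)))
          architecture(hypnogram(truth$state_sequence), bin = "12h")
        })
        avg <- average_days(days, n_days = 3)
        for (b in seq_len(nrow(avg$percent_time))) {
          k <- k + 1
          tab[[k]] <- cbind(data.frame(genotype = g, animal = sprintf("%s_m%d", g, m),
                                       phase = ifelse(avg$percent_time$zt_start[b] < 12,
                                                      "light", "dark")),
                            avg$percent_time[b, SLEEP_STATES])
        }
      }
    }
    res$sleep <- do.call(rbind, tab)
    an <- anova_two_way(res$sleep$WAKE, res$sleep$genotype, res$sleep$phase,
                        subject = res$sleep$animal)
    res$sleep_stats <- an$effects
    log_line("sleep", sprintf("wake %% genotype x phase RM interaction p = %.4g",
                              an$p_value))
  }

  if ("imaging" %in% config$stages) {
    tab <- list(); k <- 0
    for (g in names(config$genotypes)) {
      odi_target <- config$genotypes[[g]]$odi
      for (m in seq_len(config$n_mice_imaging)) {
        sd_ <- child_seed(config$seed, paste("img", g, m))
        set.seed(sd_)
        # per-animal ODI scatter around the genotype profile, then the
        # contra/ipsi peak ratio tuned so the true ODI matches it
        odi_animal <- min(0.95, max(-0.95, odi_target + stats::rnorm(1, 0, 0.04)))
        ratio <- (1 + odi_animal) / (1 - odi_animal)
        truth <- gen_imaging_truth(contra_peak = 1.5 * ratio, ipsi_peak = 1.5,
                                   contra_base = 0.2 * ratio, ipsi_base = 0.2)
        stacks <- gen_imaging_stack(truth, seed = sd_)
        odi <- analyze_ocular_dominance(stacks$contra, stacks$ipsi)
        k <- k + 1
        tab[[k]] <- data.frame(genotype = g, animal = sprintf("%s_i%d", g, m),
                               odi = odi$odi, true_odi = truth$true_odi,
                               n_roi_pixels = odi$responsive_pixel_count)
      }
    }
    res$odi <- do.call(rbind, tab)
    gs <- split(res$odi$odi, res$odi$genotype)
    tt <- t_test_unpaired(gs[[1]], gs[[2]])
    res$odi_stats <- data.frame(t = tt$statistic_value, df = tt$df, p = tt$p_value)
    log_line("imaging", sprintf("ODI genotype t(%g) = %.3f, p = %.4g",
                                tt$df, tt$statistic_value, tt$p_value))
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(res)) {
      if (is.data.frame(res[[nm]])) {
        utils::write.csv(res[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                         row.names = FALSE)
      }
    }
  }
  res
}

#' Generate a small on-disk fixture bundle
#'
#' Writes a deterministic miniature dataset through every writer in the
#' package — a sweep container (minis, one evoked pair, one short sIPSC-style
#' trace), an EDF polysomnography file, a hypnogram TSV, contra/ipsi TIFF
#' stacks — plus a ground-truth JSON, for use by tests and demonstrations.
#'
#' @param seed Integer seed.
#' @param dir Output directory (created if needed).
#' @return Named list of file paths, invisibly.
#' @export
make_fixtures <- function(seed = 1, dir = tempfile("fixtures")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  minis <- lapply(1:3, function(i) {
    gm <- gen_mini_sweep(rate = 2, duration = 15,
                         seed = child_seed(seed, paste("fixmini", i)),
                         meta = list(cell_id = sprintf("mini%02d", i),
                                     zeitgeber_time = c(0, 6, 12)[i]))
    gm$sweep
  })
  paths$sweeps <- file.path(dir, "sweeps.h5")
  write_sweeps(minis, paths$sweeps)

  truth <- gen_sleep_truth(hours = 1, seed = child_seed(seed, "fixsleep"))
  ps <- gen_polysomnography(truth, seed = child_seed(seed, "fixpsg"))
  paths$edf <- file.path(dir, "psg.edf")
  write_polysomnography(ps$psg, paths$edf)
  paths$hypnogram <- file.path(dir, "hypnogram.tsv")
  write_hypnogram(ps$hypnogram, paths$hypnogram)

  itruth <- gen_imaging_truth(height = 24, width = 24)
  stacks <- gen_imaging_stack(itruth, n_cycles = 3,
                              seed = child_seed(seed, "fiximg"))
  paths$contra <- file.path(dir, "contra.tif")
  paths$ipsi <- file.path(dir, "ipsi.tif")
  write_image_stack(stacks$contra, paths$contra)
  write_image_stack(stacks$ipsi, paths$ipsi)

  paths$truth <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(list(
    mini_rate_hz = 2,
    sleep_states = as.list(table(truth$state_sequence)),
    true_odi = itruth$true_odi
  ), paths$truth, auto_unbox = TRUE, digits = NA)

  invisible(paths)
}
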