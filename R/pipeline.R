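## End-to-end study orchestration.
##
## A study config enables any subset of the six stages (spectra ->
## colorspace -> kinetics -> morpho -> physio -> raman) and supplies, for
## each enabled stage, either a data path or a synthetic scenario.  One
## global seed expands deterministically into per-stage seeds, so the
## report is a pure function of (config, seed, input files).

stage_names <- c("spectra", "kinetics", "morpho", "physio", "raman")

stage_seed <- function(seed, stage) {
  (as.integer(seed) + 1000L * match(stage, stage_names)) %% .Machine$integer.max
}

#' Default all-synthetic study configuration
#'
#' Every stage enabled and driven by its default synthetic scenario: ten
#' rearing backgrounds (seven greys plus red, green, blue) with five
#' tadpoles each and three replicate readings; pooled light-to-dark and
#' dark-to-light luma series (three individuals per direction); five dark
#' and five light landmark configurations; six individuals per group in
#' the antioxidant panel; three eumelanin-profile and three baseline-only
#' Raman spectra.
#'
#' @param seed Global integer seed.
#' @return A config list accepted by [run_study()].
#' @export
default_study_config <- function(seed = 1L) {
  list(
    seed = seed,
    spectra = list(enabled = TRUE, scenario = list(
      grey = list(background_kind = "grey",
                  background_brightness = c(2, 12, 25, 45, 65, 80, 92)),
      colour = list(background_kind = "colour",
                    background_brightness = c(35, 35, 35),
                    hue_peak = c(460, 540, 640)))),
    kinetics = list(enabled = TRUE, scenario = list(
      light_to_dark = list(a = 0.451, b = -0.057, xs = 12.673),
      dark_to_light = list(a = 0.137, b = 0.007, xs = 79.741)),
      n_individuals = 3),
    morpho = list(enabled = TRUE, scenario = list(), n_perm = 1000),
    physio = list(enabled = TRUE, scenario = list()),
    raman = list(enabled = TRUE, scenario = list(), n_per_group = 3)
  )
}

validate_config <- function(config) {
  if (is.null(config$seed)) stop("config needs a `seed`", call. = FALSE)
  for (st in stage_names) {
    block <- config[[st]]
    if (is.null(block) || !isTRUE(block$enabled)) next
    if (is.null(block$scenario) && is.null(block$path))
      stop(sprintf("stage '%s' is enabled but has neither a scenario nor a path",
                   st), call. = FALSE)
  }
  invisible(config)
}

#' Run the full analysis pipeline from a config
#'
#' Executes the enabled stages in order and collects a structured report
#' with a named slot for each headline statistic (`pc1_variance`,
#' `mismatch_table`, `plateau_fit_light_to_dark`, `anova_F`,
#' `enzyme_pc1_variance`, `pigment_calls`, ...).  Identical config + seed
#' give an identical report.
#'
#' @param config Config list (see [default_study_config()]) or path to a
#'   JSON file with the same structure.
#' @param outdir Optional output directory; when given, the report is
#'   written as `report.json` plus CSV tables.
#' @return The report, a nested list of class `"study_report"`.
#' @export
run_study <- function(config = default_study_config(), outdir = NULL) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  validate_config(config)
  seed <- config$seed
  report <- list(config_seed = seed, stages = character(0))

  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  if (isTRUE(config$spectra$enabled)) {
    report$stages <- c(report$stages, "spectra")
    report$spectra <- run_stage("spectra", function() {
      spectra <- if (!is.null(config$spectra$path))
        read_spectra(config$spectra$path)
      else {
        sc <- config$spectra$scenario
        parts <- lapply(seq_along(sc), function(i) {
          args <- sc[[i]]
          args$seed <- stage_seed(seed, "spectra") + i
          df <- gen_spectra(do.call(spectra_scenario, args))
          df$specimen_id <- paste0(names(sc)[i], "_", df$specimen_id)
          df$background_id <- paste0(names(sc)[i], "_", df$background_id)
          df
        })
        do.call(rbind, parts)
      }
      raw <- mismatch_analysis(spectra, normalized = FALSE)
      norm <- mismatch_analysis(spectra, normalized = TRUE)
      # per-treatment index regressions on specimen means
      reps <- split_spectra(spectra)
      idx <- lapply(reps, function(s) {
        ci <- color_indices(process_spectrum(s))
        data.frame(specimen_id = s$specimen_id[1], role = s$role[1],
                   background_id = s$background_id[1], B2 = ci$B2,
                   H1 = ci$H1, S8 = ci$S8)
      })
      idx <- do.call(rbind, idx)
      agg <- stats::aggregate(idx[, c("B2", "H1", "S8")],
                              by = list(background_id = idx$background_id,
                                        role = idx$role), FUN = mean)
      tad <- agg[agg$role == "tadpole", ]
      bg <- agg[agg$role == "background", ]
      m <- match(tad$background_id, bg$background_id)
      regs <- lapply(c("B2", "H1", "S8"), function(v)
        regress_index(bg[[v]][m], tad[[v]]))
      names(regs) <- c("B2", "H1", "S8")
      list(pc1_variance = raw$model$variance_explained[1],
           pc2_variance = raw$model$variance_explained[2],
           pc1_variance_normalized = norm$model$variance_explained[1],
           mismatch_table = raw$mismatch,
           mismatch_table_normalized = norm$mismatch,
           index_regressions = regs)
    })
  }

  if (isTRUE(config$kinetics$enabled)) {
    report$stages <- c(report$stages, "kinetics")
    report$kinetics <- run_stage("kinetics", function() {
      out <- list()
      if (!is.null(config$kinetics$path)) {
        lum <- read_luma_csv(config$kinetics$path)
        fit <- fit_quadratic_plateau(lum)
        out$plateau_fit <- unclass(fit)
      } else {
        nind <- config$kinetics$n_individuals %||% 3
        for (dir_name in names(config$kinetics$scenario)) {
          args <- config$kinetics$scenario[[dir_name]]
          series <- do.call(rbind, lapply(seq_len(nind), function(j) {
            args$seed <- stage_seed(seed, "kinetics") +
              100L * match(dir_name, names(config$kinetics$scenario)) + j
            gen_luma_series(do.call(kinetics_scenario, args),
                            individual_id = sprintf("%s_%d", dir_name, j))
          }))
          out[[paste0("plateau_fit_", dir_name)]] <-
            unclass(fit_quadratic_plateau(series))
        }
      }
      out
    })
  }

  if (isTRUE(config$morpho$enabled)) {
    report$stages <- c(report$stages, "morpho")
    report$morpho <- run_stage("morpho", function() {
      configs <- if (!is.null(config$morpho$path)) {
        read_tps(config$morpho$path)
      } else {
        args <- config$morpho$scenario
        args$seed <- stage_seed(seed, "morpho")
        gen_landmarks(do.call(shape_scenario, args))
      }
      groups <- vapply(configs, function(cf)
        cf$group %||% "unknown", character(1))
      fit <- gpa(configs, slide = !is.null(configs[[1]]$semi_idx))
      pca <- shape_pca(fit)
      an <- procrustes_anova(fit, groups,
                             n_perm = config$morpho$n_perm %||% 1000,
                             seed = stage_seed(seed, "morpho"))
      list(pc1_variance = pca$variance_explained[1],
           anova_F = an$F, anova_Z = an$Z, anova_p = an$p,
           anova_df = as.integer(an$df))
    })
  }

  if (isTRUE(config$physio$enabled)) {
    report$stages <- c(report$stages, "physio")
    report$physio <- run_stage("physio", function() {
      panel <- if (!is.null(config$physio$path))
        utils::read.csv(config$physio$path, stringsAsFactors = FALSE)
      else {
        args <- config$physio$scenario
        args$seed <- stage_seed(seed, "physio")
        gen_panel(do.call(panel_scenario, args))
      }
      res <- analyze_panel(panel)
      list(enzyme_pc1_variance = res$enzyme_pca$variance_explained[1],
           pc1_test = res$pc1_test, mda_test = res$mda_test,
           ratio_test = res$ratio_test)
    })
  }

  if (isTRUE(config$raman$enabled)) {
    report$stages <- c(report$stages, "raman")
    report$raman <- run_stage("raman", function() {
      spectra <- if (!is.null(config$raman$path)) {
        df <- read_raman(config$raman$path)
        split(df, df$specimen_id)
      } else {
        np <- config$raman$n_per_group %||% 3
        c(lapply(seq_len(np), function(j) {
          args <- config$raman$scenario
          args$seed <- stage_seed(seed, "raman") + j
          gen_raman(do.call(raman_scenario, args),
                    specimen_id = sprintf("dark%02d", j))
        }),
        lapply(seq_len(np), function(j) {
          args <- config$raman$scenario
          args$band_centers <- numeric(0)
          args$band_amplitudes <- numeric(0)
          args$band_widths <- numeric(0)
          args$seed <- stage_seed(seed, "raman") + 100L + j
          gen_raman(do.call(raman_scenario, args),
                    specimen_id = sprintf("light%02d", j))
        }))
      }
      calls <- lapply(spectra, function(s) {
        pk <- detect_peaks(baseline_correct(s))
        cl <- classify_pigment(pk)
        list(specimen_id = s$specimen_id[1], eumelanin = cl$eumelanin,
             pheomelanin = cl$pheomelanin)
      })
      list(pigment_calls = do.call(rbind, lapply(calls, as.data.frame)))
    })
  }

  class(report) <- "study_report"
  if (!is.null(outdir)) write_report(report, outdir)
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(unclass(report), file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  if (!is.null(report$spectra$mismatch_table))
    utils::write.csv(report$spectra$mismatch_table,
                     file.path(outdir, "mismatch.csv"), row.names = FALSE)
  if (!is.null(report$raman$pigment_calls))
    utils::write.csv(report$raman$pigment_calls,
                     file.path(outdir, "pigment_calls.csv"),
                     row.names = FALSE)
  invisible(outdir)
}
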