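#' Default study configuration
#'
#' The four parametric studies and their default settings: bulk shear rate
#' sweep (gamma0 = 150...3000 1/s at S = 80%, alpha = 85 deg, Newtonian
#' blood), stenosis-level sweep (S = 30...95% at gamma0 = 1000 1/s),
#' contraction-angle sweep (alpha = 30...85 deg at gamma0 = 1000 1/s), and
#' the fluid-medium benchmark (water vs Newtonian blood vs GPL blood at
#' S = 80%, alpha = 85 deg).
#'
#' @param grid `c(nx, ny)` cells used for every member run.
#' @return Named list of study settings.
#' @export
study_defaults <- function(grid = c(192, 48)) {
  list(
    gamma0_sweep = list(gamma0 = c(150, 600, 1000, 1500, 2000, 2500, 3000),
                        S = 0.8, alpha = 85, fluid = "blood_newtonian",
                        placements = c("eccentric", "concentric"), grid = grid),
    S_sweep = list(S = c(0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 0.95),
                   gamma0 = 1000, alpha = 85, fluid = "blood_newtonian",
                   placements = c("eccentric", "concentric"), grid = grid),
    alpha_sweep = list(alpha = c(30, 45, 60, 75, 85),
                       gamma0 = 1000, S = 0.8, fluid = "blood_newtonian",
                       placements = c("eccentric", "concentric"), grid = grid),
    medium_benchmark = list(fluid = c("water", "blood_newtonian", "blood_gpl"),
                            gamma0 = 1000, S = 0.8, alpha = 85,
                            placements = c("eccentric", "concentric"), grid = grid)
  )
}

fluid_by_name <- function(name) {
  switch(name,
         water = water(),
         blood_newtonian = blood_newtonian(),
         blood_gpl = blood_gpl(),
         stop("unknown fluid name: ", name))
}

#' Run one parametric study
#'
#' Executes the geometry -> solve -> post pipeline for each value of the
#' swept variable (and each placement), collecting the peak records into a
#' tidy table. Fold-changes are reported relative to the smallest swept
#' value; for the bulk-shear-rate sweep a linear fit of peak shear rate
#' versus gamma0 is attached.
#'
#' @param study one of `"gamma0_sweep"`, `"S_sweep"`, `"alpha_sweep"`,
#'   `"medium_benchmark"`.
#' @param config settings list as produced by [study_defaults()] (that
#'   study's element), or `NULL` for the defaults.
#' @param grid optional `c(nx, ny)` override.
#' @return An object of class `sweep_result`: `table` (one row per run),
#'   `study`, `variable` and, for linear sweeps, `fit` statistics.
#' @export
run_study <- function(study = c("gamma0_sweep", "S_sweep", "alpha_sweep",
                                "medium_benchmark"),
                      config = NULL, grid = NULL) {
  study <- match.arg(study)
  cfg <- study_defaults()[[study]]
  if (!is.null(config)) cfg <- utils::modifyList(cfg, config)
  if (!is.null(grid)) cfg$grid <- grid
  variable <- switch(study, gamma0_sweep = "gamma0", S_sweep = "S",
                     alpha_sweep = "alpha", medium_benchmark = "fluid")
  values <- cfg[[variable]]
  rows <- list()
  for (pl in cfg$placements) {
    for (val in values) {
      S <- if (variable == "S") val else cfg$S
      alpha <- if (variable == "alpha") val else cfg$alpha
      gamma0 <- if (variable == "gamma0") val else cfg$gamma0
      fl_name <- if (variable == "fluid") val else cfg$fluid
      rec <- tryCatch({
        geom <- stenosis_geometry(S = S, alpha = alpha, placement = pl)
        gr <- generate_grid(geom, cfg$grid[1], cfg$grid[2])
        fl <- solve_flow(geom, fluid_by_name(fl_name), gamma0, gr)
        map <- shear_rate_field(fl)
        pr <- platelet_trajectory_profile(fl, map)
        cbind(data.frame(study = study, placement = pl,
                         S = S, alpha = alpha, gamma0 = gamma0,
                         fluid = fl_name, value = if (is.numeric(val)) val else NA,
                         Re = fl$op$Re, Q_uL_min = fl$op$Q_uL_min),
              peak_summary(pr, map))
      }, error = function(e) {
        stop(sprintf("sweep member failed at %s = %s (%s): %s",
                     variable, format(val), pl, conditionMessage(e)),
             call. = FALSE)
      })
      rows[[length(rows) + 1L]] <- rec
    }
  }
  tab <- do.call(rbind, rows)
  # fold-changes relative to the first swept value within each placement
  tab$fold_gamma_max <- NA_real_
  tab$fold_tau_max <- NA_real_
  for (pl in unique(tab$placement)) {
    selp <- tab$placement == pl
    base <- which(selp)[1]
    tab$fold_gamma_max[selp] <- tab$gamma_max_s_inv[selp] / tab$gamma_max_s_inv[base]
    tab$fold_tau_max[selp] <- tab$tau_max_Pa[selp] / tab$tau_max_Pa[base]
  }
  fit <- NULL
  if (study == "gamma0_sweep") {
    fit <- lapply(split(tab, tab$placement), function(d) {
      m <- stats::lm(gamma_max_s_inv ~ gamma0, data = d)
      list(slope = unname(stats::coef(m)[2]),
           intercept = unname(stats::coef(m)[1]),
           r_squared = summary(m)$r.squared)
    })
  }
  structure(list(study = study, variable = variable, table = tab,
                 config = cfg, fit = fit),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("<sweep_result> ", x$study, " (", nrow(x$table), " runs)\n", sep = "")
  print(x$table[, c("placement", x$variable, "gamma_max_s_inv",
                    "gamma_prime_max_um_inv_s_inv", "tau_max_Pa",
                    "fold_gamma_max")], row.names = FALSE)
  if (!is.null(x$fit)) {
    for (pl in names(x$fit))
      cat(sprintf("  %s: gamma_max ~ gamma0 slope %.3f, R^2 %.6f\n",
                  pl, x$fit[[pl]]$slope, x$fit[[pl]]$r_squared))
  }
  invisible(x)
}

#' Write the report artifacts of a sweep
#'
#' Emits a tidy CSV (one row per run), a JSON summary, and a peak-vs-variable
#' PNG figure per placement. Re-running on the same result overwrites with
#' byte-identical content.
#'
#' @param result a [run_study()] result.
#' @param outdir output directory (created if missing).
#' @param figures whether to write PNG figures.
#' @return Invisibly, the paths written.
#' @export
study_report <- function(result, outdir, figures = TRUE) {
  stopifnot(inherits(result, "sweep_result"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  base <- file.path(outdir, result$study)
  csv <- paste0(base, ".csv")
  utils::write.csv(result$table, csv, row.names = FALSE)
  js <- paste0(base, ".json")
  summary <- list(study = result$study, variable = result$variable,
                  n_runs = nrow(result$table),
                  fold_range = range(result$table$fold_gamma_max),
                  fit = result$fit)
  jsonlite::write_json(summary, js, auto_unbox = TRUE, digits = NA)
  paths <- c(csv, js)
  if (figures && result$variable != "fluid") {
    png_path <- paste0(base, ".png")
    grDevices::png(png_path, width = 900, height = 600, res = 120)
    on.exit(grDevices::dev.off(), add = TRUE)
    tab <- result$table
    xvar <- tab[[result$variable]]
    plot(range(xvar), range(tab$gamma_max_s_inv), type = "n",
         xlab = result$variable, ylab = "peak shear rate (1/s)",
         main = result$study)
    cols <- c(eccentric = "firebrick", concentric = "navy")
    for (pl in unique(tab$placement)) {
      d <- tab[tab$placement == pl, ]
      graphics::lines(d[[result$variable]], d$gamma_max_s_inv,
                      type = "b", col = cols[[pl]], pch = 16)
    }
    graphics::legend("topleft", legend = unique(tab$placement),
                     col = cols[unique(tab$placement)], lty = 1, pch = 16, bty = "n")
    paths <- c(paths, png_path)
  }
  invisible(paths)
}
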