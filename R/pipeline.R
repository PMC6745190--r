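# Cheap stable checksum of a config for the provenance manifest.
config_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(deparse(x), collapse = "")))
  sprintf("%08x", sum(bytes * (seq_along(bytes) %% 97L + 1L)) %% .Machine$integer.max)
}

stage_log <- function(fmt, ...) {
  message(sprintf(paste0("[landesv] ", fmt), ...))
}

#' Run the projection half of the pipeline
#'
#' Config-driven CA-Markov projection: estimate the transition matrix from
#' the last two input epochs, derive Markov target areas for each horizon
#' year, allocate them in space with the CA rule, and (when three or more
#' input epochs are supplied) hindcast the last observed epoch from the two
#' before it and score the simulation with Cohen's kappa.
#'
#' @param config List with fields:
#'   * `epochs`: list of `lulc_raster` objects or `.asc` file paths (>= 2);
#'   * `years`: strictly increasing epoch years (equal spacing = one Markov
#'     step);
#'   * `horizon`: future years, each a whole number of intervals after the
#'     last epoch;
#'   * `legend`, `cell_area_ha`: used when `epochs` are paths;
#'   * `window` (default 5), `max_iter` (default 10), `seed` (default 1);
#'   * `hindcast` (default `TRUE` when >= 3 epochs);
#'   * `out_dir`: optional directory for rasters (`.asc`), the area table
#'     (CSV), the transition matrix (CSV), the kappa result (JSON) and a
#'     provenance manifest (YAML).
#' @return List with `simulated` (rasters by horizon year), `areas` (long
#'   data.frame over all epochs and horizons), `transition`
#'   (`transition_matrix`), `kappa` (`kappa_result` or `NULL`), `manifest`.
#' @export
run_projection <- function(config) {
  cfg <- utils::modifyList(
    list(window = 5L, max_iter = 10L, seed = 1L, hindcast = NULL,
         legend = identity_legend(), cell_area_ha = 9, out_dir = NULL),
    config
  )
  if (is.null(cfg$epochs) || length(cfg$epochs) < 2L) {
    stop("config$epochs: need at least 2 input epochs for projection")
  }
  if (is.null(cfg$years) || length(cfg$years) != length(cfg$epochs)) {
    stop("config$years: need one year per epoch")
  }
  if (is.unsorted(cfg$years, strictly = TRUE)) {
    stop("config$years: must be strictly increasing")
  }
  interval <- diff(cfg$years)
  if (length(unique(interval)) != 1L) {
    stop("config$years: epochs must be equally spaced")
  }
  interval <- interval[1]
  if (!is.null(cfg$horizon)) {
    off <- cfg$horizon - cfg$years[length(cfg$years)]
    if (any(off <= 0) || any(off %% interval != 0)) {
      stop("config$horizon: each horizon year must be a positive whole ",
           "number of ", interval, "-year intervals after ",
           cfg$years[length(cfg$years)])
    }
  }
  rasters <- lapply(seq_along(cfg$epochs), function(k) {
    e <- cfg$epochs[[k]]
    if (inherits(e, "lulc_raster")) {
      e$year <- cfg$years[k]
      e
    } else {
      if (!file.exists(e)) stop("config$epochs: file not found: ", e)
      load_raster(e, legend = cfg$legend, cell_area_ha = cfg$cell_area_ha,
                  year = cfg$years[k])
    }
  })
  rasters <- harmonize_masks(rasters)
  ne <- length(rasters)
  stage_log("loaded %d epochs of %d x %d cells", ne,
            nrow(rasters[[1]]$grid), ncol(rasters[[1]]$grid))

  kappa <- NULL
  do_hindcast <- if (is.null(cfg$hindcast)) ne >= 3L else isTRUE(cfg$hindcast)
  if (do_hindcast && ne >= 3L) {
    Ah <- estimate_transition(rasters[[ne - 2L]], rasters[[ne - 1L]])
    tg <- target_areas(tabulate_areas(rasters[[ne - 1L]]), Ah, 1L)
    sim <- allocate(rasters[[ne - 1L]], tg, trans = Ah, window = cfg$window,
                    max_iter = cfg$max_iter, seed = cfg$seed)
    kappa <- cohens_kappa(rasters[[ne]], sim)
    stage_log("hindcast of %s: kappa = %.4f (p0 = %.4f, pc = %.4f)",
              cfg$years[ne], kappa$kappa, kappa$p0, kappa$pc)
  }

  A <- estimate_transition(rasters[[ne - 1L]], rasters[[ne]])
  simulated <- list()
  areas <- lapply(rasters, tabulate_areas)
  names(areas) <- cfg$years
  if (!is.null(cfg$horizon)) {
    prev <- rasters[[ne]]
    prev_year <- cfg$years[ne]
    for (y in sort(cfg$horizon)) {
      steps <- (y - prev_year) %/% interval
      tg <- target_areas(tabulate_areas(prev), A, steps)
      sim <- allocate(prev, tg, trans = A, window = cfg$window,
                      max_iter = cfg$max_iter, seed = cfg$seed + y)
      sim$year <- y
      res <- attr(sim, "residual_cells")
      stage_log("allocated %s: residual %d cells", y, sum(abs(res)))
      simulated[[as.character(y)]] <- sim
      areas[[as.character(y)]] <- tabulate_areas(sim)
      prev <- sim
      prev_year <- y
    }
  }
  area_tab <- do.call(rbind, lapply(names(areas), function(y) {
    data.frame(year = as.integer(y), class = lulc_classes(),
               area_ha = as.numeric(areas[[y]]), row.names = NULL)
  }))
  manifest <- list(stage = "projection", config_hash = config_hash(cfg),
                   seed = cfg$seed, window = cfg$window,
                   max_iter = cfg$max_iter, years = cfg$years,
                   horizon = cfg$horizon,
                   kappa = if (!is.null(kappa)) kappa$kappa else NA,
                   package_version = as.character(utils::packageVersion("landesv")))
  out <- list(simulated = simulated, areas = area_tab, transition = A,
              kappa = kappa, manifest = manifest)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    for (y in names(simulated)) {
      write_asc(simulated[[y]], file.path(cfg$out_dir,
                                          paste0("simulated_", y, ".asc")))
    }
    utils::write.csv(area_tab, file.path(cfg$out_dir, "areas.csv"),
                     row.names = FALSE)
    write_transition_csv(A, file.path(cfg$out_dir, "transition.csv"))
    if (!is.null(kappa)) {
      write_kappa_json(kappa, file.path(cfg$out_dir, "kappa.json"))
    }
    yaml::write_yaml(manifest, file.path(cfg$out_dir, "manifest.yaml"))
  }
  out
}

#' Run the valuation half of the pipeline
#'
#' Values a multi-year area table with a benefit-transfer coefficient matrix:
#' per-class and per-function values, totals, change rates for every year
#' pair, and the coefficient-of-sensitivity table.
#'
#' @param config List with fields:
#'   * `areas`: long data.frame (`year`, `class`, `area_1e4_ha` or `area_ha`)
#'     or a CSV path; defaults to the packaged study table;
#'   * `vc`: coefficient matrix or CSV path; defaults to the packaged matrix;
#'   * `delta`: sensitivity adjustment (default 0.5);
#'   * `out_dir`: optional directory for CSV/JSON reports and a manifest.
#' @return List with `report` (see [esv_report()]), `sensitivity` (see
#'   [sensitivity_table()]), `manifest`.
#' @export
run_valuation <- function(config = list()) {
  cfg <- utils::modifyList(
    list(areas = NULL, vc = NULL, delta = 0.5, out_dir = NULL),
    config
  )
  areas <- cfg$areas
  if (is.null(areas)) areas <- central_asia_areas()
  if (is.character(areas)) areas <- utils::read.csv(areas)
  vc <- cfg$vc
  if (is.null(vc)) vc <- value_coefficients()
  if (is.character(vc)) vc <- value_coefficients(vc)
  report <- esv_report(areas, vc)
  sens <- sensitivity_table(areas, vc, cfg$delta)
  stage_log("valued %d years; total ESV %s billion US$",
            length(report$years),
            paste(sprintf("%.2f", report$total), collapse = ", "))
  manifest <- list(stage = "valuation", config_hash = config_hash(cfg),
                   delta = cfg$delta, years = report$years,
                   package_version = as.character(utils::packageVersion("landesv")))
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(round(report$by_class, 2),
                     file.path(cfg$out_dir, "esv_by_class.csv"))
    utils::write.csv(round(report$by_function, 2),
                     file.path(cfg$out_dir, "esv_by_function.csv"))
    utils::write.csv(data.frame(year = report$years,
                                esv_billion_usd = round(report$total, 2)),
                     file.path(cfg$out_dir, "esv_total.csv"),
                     row.names = FALSE)
    if (!is.null(report$class_change_pct)) {
      utils::write.csv(round(report$class_change_pct, 2),
                       file.path(cfg$out_dir, "esv_change_pct.csv"))
    }
    sens_out <- sens
    sens_out$pct_change <- round(sens_out$pct_change, 2)
    sens_out$cs <- round(sens_out$cs, 2)
    utils::write.csv(sens_out, file.path(cfg$out_dir, "sensitivity.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(total_billion_usd = stats::setNames(as.list(report$total),
                                               report$years),
           total_change_pct = as.list(report$total_change_pct)),
      file.path(cfg$out_dir, "summary.json"), auto_unbox = TRUE, digits = NA
    )
    yaml::write_yaml(manifest, file.path(cfg$out_dir, "manifest.yaml"))
  }
  list(report = report, sensitivity = sens, manifest = manifest)
}

#' Write a transition matrix as CSV
#'
#' Row and column headers are the class names, the layout of published
#' transition-probability tables.
#'
#' @param x A `transition_matrix`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_transition_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x$A), path, row.names = TRUE)
  invisible(path)
}

#' Read a transition matrix from CSV
#'
#' @param path CSV written by [write_transition_csv()].
#' @return A `transition_matrix`.
#' @export
read_transition_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1)
  transition_matrix(as.matrix(df))
}
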