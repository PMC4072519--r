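#' Validate a pipeline run configuration
#'
#' A run configuration is a plain named list (usually read from YAML):
#'
#' ```yaml
#' input:
#'   spectra: spectra.csv      # or simulate: paper_scale_two_class
#'   metadata: meta.csv
#' binning: {ppm_min: 0, ppm_max: 9.6, bin_width: 0.32}
#' mode: unsupervised          # supervised | unsupervised | pca
#' label_map: {PF: 0, DGF: 1, AR: 1}
#' loocv: true
#' grid: {profile: 101, committor: 201}
#' seed: 1
#' output_dir: runs/demo
#' ```
#'
#' @param config Named list or path to a YAML file.
#' @return The validated config list (with defaults filled in).
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) abort(paste("config file not found:", config))
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  config$mode <- config$mode %||% "unsupervised"
  if (!config$mode %in% c("supervised", "unsupervised", "pca")) {
    abort("mode must be supervised, unsupervised or pca")
  }
  config$binning <- config$binning %||% list()
  config$label_map <- config$label_map %||% list(PF = 0, DGF = 1, AR = 1)
  config$loocv <- isTRUE(config$loocv %||% TRUE)
  config$grid <- config$grid %||% list(profile = 25, committor = 201)
  config$seed <- as.integer(config$seed %||% 1L)
  if (is.null(config$output_dir)) abort("config needs `output_dir`")

  inp <- config$input %||% list()
  if (is.null(inp$simulate)) {
    for (f in c("spectra", "metadata")) {
      if (is.null(inp[[f]])) {
        abort(sprintf("config input needs `%s` (or `simulate: <scenario>`)",
                      f))
      }
      if (!file.exists(inp[[f]])) {
        abort(sprintf("input file not found: %s", inp[[f]]))
      }
    }
  }
  if (config$mode == "supervised" && is.null(config$label_map)) {
    abort("supervised mode needs a label_map")
  }
  config$input <- inp
  config
}

#' Run the full biomarker pipeline
#'
#' Orchestrates preprocess -> fit -> project -> profiles -> landscape ->
#' outcome probabilities and writes all artifacts (model JSON, TSV tables,
#' a markdown report, a log) under `config$output_dir`. Deterministic
#' given the config and seed; each artifact records the config hash and
#' package version.
#'
#' @param config Named list or YAML path; see [validate_config()].
#' @return Invisibly, a list with every intermediate result and the
#'   artifact paths.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  set.seed(config$seed)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- rlang::hash(config)
  version <- as.character(utils::packageVersion("cfep"))
  log_path <- file.path(config$output_dir, "run.log")
  log_line <- function(...) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"),
                sprintf(...)), file = log_path, append = TRUE)
  }
  log_line("run start: config %s, cfep %s, seed %d", hash, version,
           config$seed)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      log_line("stage %s FAILED: %s", name, conditionMessage(e))
      abort(sprintf("pipeline stage `%s` failed: %s", name,
                    conditionMessage(e)))
    })
  }

  # -- input ---------------------------------------------------------------
  dat <- stage("input", {
    if (!is.null(config$input$simulate)) {
      sim <- generate_cohort(config$input$simulate, seed = config$seed)
      list(spectra = sim$spectra, metadata = sim$metadata)
    } else {
      list(spectra = read_spectra(config$input$spectra),
           metadata = read_metadata(config$input$metadata))
    }
  })

  # -- preprocess ----------------------------------------------------------
  scheme <- do.call(binning_scheme, config$binning)
  cohort <- stage("preprocess",
                  build_trajectories(dat$spectra, dat$metadata, scheme))
  log_line("preprocess: %d patients, %d features",
           dplyr::n_distinct(cohort$patient_id),
           length(feature_cols(cohort)))

  # -- fit + project -------------------------------------------------------
  label_map <- unlist(config$label_map)
  model <- stage("fit", fit_coordinate(cohort, mode = config$mode,
                                       label_map = label_map))
  proj <- stage("project", project_coordinate(cohort, model))

  cv <- NULL
  if (config$loocv) {
    cv <- stage("loocv", loocv(cohort, mode = config$mode,
                               label_map = label_map))
    log_line("loocv: median |cor| %.3f -> %s", cv$median_abs_cor,
             cv$verdict)
  }

  # -- profiles + landscape ------------------------------------------------
  prof <- stage("profile",
                cut_profile(proj, n_grid = config$grid$profile %||% 25))
  prof <- estimate_diffusion(prof)
  prof <- net_flux(prof)
  land <- stage("landscape", {
    l <- reconstruct_landscape(prof)
    rescale_unit_diffusion(l)
  })
  comm <- stage("committor",
                committor_from_profile(
                  land, n_grid = config$grid$committor %||% 201))

  split_point <- land$basins$barrier
  if (!is.finite(split_point)) split_point <- stats::median(proj$x)
  outcome <- stage("outcome",
                   empirical_outcome_probability(proj, split_point))

  # -- artifacts -----------------------------------------------------------
  out_tsv <- function(d, name) {
    p <- file.path(config$output_dir, name)
    utils::write.table(d, p, sep = "\t", row.names = FALSE, quote = FALSE)
    p
  }
  paths <- list(
    model = file.path(config$output_dir, "model.json"),
    projections = out_tsv(proj, "projections.tsv"),
    profiles = out_tsv(tibble::as_tibble(prof), "profiles.tsv"),
    landscape = out_tsv(land$table, "landscape.tsv"),
    committor = out_tsv(comm, "committor.tsv"),
    outcome = out_tsv(outcome, "outcome.tsv"),
    report = file.path(config$output_dir, "report.md"),
    log = log_path)
  if (!is.null(cv)) paths$loocv <- out_tsv(tidy(cv), "loocv.tsv")

  jsonlite::write_json(
    list(package_version = version, config_hash = hash,
         mode = model$mode, seed = config$seed,
         bin_edges = model$bin_edges,
         weights = as.list(model$weights), const = model$const,
         affine = as.list(model$affine),
         eigenvalues = model$eigen$values,
         basins = land$basins),
    paths$model, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  writeLines(c(
    "# cfep pipeline report",
    "",
    sprintf("- package version: %s", version),
    sprintf("- config hash: %s", hash),
    sprintf("- seed: %d", config$seed),
    sprintf("- mode: %s", model$mode),
    sprintf("- patients: %d", dplyr::n_distinct(cohort$patient_id)),
    sprintf("- features: %d", length(model$weights)),
    if (!is.null(cv)) {
      sprintf("- LOOCV: median |cor| = %.3f, verdict **%s**",
              cv$median_abs_cor, cv$verdict)
    },
    sprintf("- basins: %.3g / %.3g, barrier height %.3g kT",
            land$basins$left, land$basins$right,
            land$basins$barrier_height),
    "",
    "Artifacts: projections.tsv, profiles.tsv, landscape.tsv,",
    "committor.tsv, outcome.tsv, model.json",
    if (!is.null(cv)) "loocv.tsv"
  ), paths$report)
  log_line("run complete")

  invisible(list(config = config, cohort = cohort, model = model,
                 projections = proj, loocv = cv, profile = prof,
                 landscape = land, committor = comm, outcome = outcome,
                 paths = paths, config_hash = hash))
}
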