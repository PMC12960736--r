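#' Validate a pipeline configuration
#'
#' A configuration drives one end-to-end run. Exactly one input mode is
#' active: `preset` (simulate a synthetic cohort) or `paths` (read
#' respondent-level CSVs plus a margin table). All seeds are recorded in
#' the output manifest so a run is reproducible from the manifest alone.
#'
#' @param preset simulation preset name (see [ising_preset()]), or `NULL`.
#' @param paths list with `responses`, `demographics`, `margins` file
#'   paths, or `NULL`.
#' @param n cohort size for simulation mode.
#' @param seed master seed.
#' @param level confidence level used throughout.
#' @param K CV folds for the network stage.
#' @param rake_by stratum column raked within (`"country"` by default;
#'   `NULL` pools).
#' @param out_dir output directory.
#' @return Validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(preset = NULL, paths = NULL, n = 5000,
                            seed = 1L, level = 0.99, K = 10,
                            rake_by = "country", out_dir = "coendorse-out") {
  if (is.null(preset) == is.null(paths))
    stop("exactly one of 'preset' or 'paths' must be given", call. = FALSE)
  if (!is.null(paths)) {
    need <- c("responses", "demographics", "margins")
    if (!all(need %in% names(paths)))
      stop("paths must name: ", paste(need, collapse = ", "), call. = FALSE)
    for (f in unlist(paths[need]))
      if (!file.exists(f)) stop("input file not found: ", f, call. = FALSE)
  }
  structure(list(preset = preset, paths = paths, n = as.integer(n),
                 seed = as.integer(seed), level = level, K = as.integer(K),
                 rake_by = rake_by, out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a respondent-level cohort from CSV files
#'
#' Validates ids (unique), item columns (0/1), and applies a
#' complete-case filter on the demographic columns with a logged count of
#' dropped rows.
#'
#' @param responses_path CSV with an `id` column plus the 0/1 item columns.
#' @param demographics_path CSV with `id` and the demographic variables.
#' @return List: `items` (0/1 matrix), `demographics` (data frame),
#'   `n_dropped` (incomplete demographic rows removed).
#' @export
read_cohort <- function(responses_path, demographics_path) {
  resp <- read.csv(responses_path, check.names = FALSE)
  demo <- read.csv(demographics_path, check.names = FALSE)
  for (d in list(resp, demo)) {
    if (!"id" %in% names(d)) stop("missing 'id' column", call. = FALSE)
    if (anyDuplicated(d$id)) stop("duplicate respondent ids", call. = FALSE)
  }
  if (!setequal(resp$id, demo$id))
    stop("responses and demographics cover different ids", call. = FALSE)
  demo <- demo[match(resp$id, demo$id), , drop = FALSE]
  keep <- complete.cases(demo)
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message(n_dropped, " respondent(s) dropped for missing demographic data")
  resp <- resp[keep, , drop = FALSE]
  demo <- demo[keep, , drop = FALSE]
  item_cols <- setdiff(names(resp), "id")
  items <- as.matrix(resp[item_cols])
  for (j in item_cols) check_binary(items[, j], j)
  storage.mode(items) <- "integer"
  list(items = items, demographics = demo, n_dropped = n_dropped)
}

#' Read a margin table from CSV or JSON
#'
#' @param path file with columns/fields `variable`, `level`, `target`.
#' @return Validated margin data frame.
#' @export
read_margins <- function(path) {
  m <- if (grepl("\\.json$", path, ignore.case = TRUE))
    as.data.frame(jsonlite::fromJSON(path)) else read.csv(path)
  validate_margins(m)
}

#' Run the full co-endorsement analysis pipeline
#'
#' Stages: simulate (optional) -> rake -> prevalence (pooled, by country,
#' by age band) -> demographic correlates -> co-endorsement overlap ->
#' Ising network. Writes tidy CSVs per stage, a JSON manifest (config,
#' seeds, package version, per-stage status) and returns the result
#' bundle invisibly. A stage failure stops the run with the stage name;
#' outputs of completed stages are retained and flagged in the manifest.
#'
#' @param config a [pipeline_config()].
#' @return List with elements `design`, `prevalence`, `by_country`,
#'   `by_age`, `rao_scott`, `correlates`, `overlap`, `network`, `manifest`
#'   (invisible).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = unclass(config),
                   package_version = as.character(
                     utils::packageVersion("coendorse")),
                   stages = list())
  results <- list()
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      jsonlite::write_json(manifest,
                           file.path(config$out_dir, "manifest.json"),
                           digits = NA, pretty = TRUE, auto_unbox = TRUE,
                           force = TRUE)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- list(status = "ok")
    res
  }

  ## --- input -------------------------------------------------------
  truth <- NULL
  if (!is.null(config$preset)) {
    dat <- stage("simulate", {
      truth <- ising_preset(config$preset)
      spec <- cohort_spec(config$n, seed = config$seed,
                         selection_bias = c(age = -0.6, university = 0.5))
      cohort <- generate_cohort(spec, truth)
      write_cohort(cohort, file.path(config$out_dir, "cohort"))
      list(items = cohort$responses, demographics = cohort$demographics,
           margins = cohort$population_margins)
    })
  } else {
    dat <- stage("read", {
      cohort <- read_cohort(config$paths$responses,
                            config$paths$demographics)
      cohort$margins <- read_margins(config$paths$margins)
      cohort
    })
  }
  items <- dat$items
  demo <- dat$demographics

  ## --- weighting ---------------------------------------------------
  design <- stage("rake", {
    by <- config$rake_by
    if (!is.null(by) && !by %in% names(demo)) by <- NULL
    d <- rake(demo, dat$margins, by = by)
    write.csv(data.frame(id = demo$id, weight = d$weights),
              file.path(config$out_dir, "weights.csv"), row.names = FALSE)
    write.csv(margin_report(d, demo, dat$margins),
              file.path(config$out_dir, "margin_report.csv"),
              row.names = FALSE)
    d
  })

  ## --- prevalence --------------------------------------------------
  results$prevalence <- stage("prevalence", {
    pooled <- weighted_prevalence(items, design, level = config$level)
    out <- pooled
    if ("country" %in% names(demo)) {
      byc <- weighted_prevalence(items, design, level = config$level,
                                 by = demo$country)
      rs <- lapply(colnames(items), function(it)
        rao_scott_test(items[, it], demo$country, design))
      byc$F_stat <- rep(vapply(rs, `[[`, numeric(1), "F_stat"),
                        each = length(unique(demo$country)))
      byc$p_value_F <- rep(vapply(rs, `[[`, numeric(1), "p_value"),
                           each = length(unique(demo$country)))
      out <- rbind(cbind(pooled, F_stat = NA, p_value_F = NA), byc)
      results$rao_scott <- rs
    }
    if ("age" %in% names(demo)) {
      bya <- weighted_prevalence(items, design, level = config$level,
                                 by = demo$age)
      write.csv(bya, file.path(config$out_dir, "prevalence_by_age.csv"),
                row.names = FALSE)
      results$by_age <- bya
    }
    write.csv(out, file.path(config$out_dir, "prevalence.csv"),
              row.names = FALSE)
    out
  })

  ## --- correlates --------------------------------------------------
  results$correlates <- stage("correlates", {
    preds <- intersect(c("high_income", "partnered", "employed",
                         "university", "child_household", "works_children"),
                       names(demo))
    if (!length(preds)) return(NULL)
    grid <- correlate_grid(items, demo[preds], design,
                           level = config$level)
    write.csv(grid, file.path(config$out_dir, "correlates.csv"),
              row.names = FALSE)
    grid
  })

  ## --- overlap -----------------------------------------------------
  results$overlap <- stage("overlap", {
    ct <- coendorsement_table(items, design)
    write.csv(as.data.frame(ct), file.path(config$out_dir, "overlap.csv"),
              row.names = FALSE)
    ct
  })

  ## --- network -----------------------------------------------------
  results$network <- stage("network", {
    net <- estimate_network(items, design, K = config$K,
                            seed = derive_seed(config$seed, 99),
                            level = config$level)
    write_network(net, file.path(config$out_dir, "network"))
    net
  })

  if (!is.null(truth)) {
    rec <- edge_recovery(results$network, truth)
    manifest$edge_recovery <- rec
  }
  manifest$seeds <- list(master = config$seed,
                         network = derive_seed(config$seed, 99))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       digits = NA, pretty = TRUE, auto_unbox = TRUE,
                       force = TRUE)
  results$design <- design
  results$manifest <- manifest
  invisible(results)
}
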