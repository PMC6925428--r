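#' Deterministic per-stage child seed
#'
#' All randomness flows from one run seed; each pipeline stage (or stratum
#' fit) derives its own substream seed from the run seed and its name, so
#' any stage can be re-run in isolation and reproduce its output.
#'
#' @param seed integer run seed.
#' @param stage character stage name.
#' @return integer seed below 2^31.
#' @export
stage_seed <- function(seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 1000003
  as.integer((as.numeric(seed) * 1009 + h) %% 2147483629L)
}

#' Pipeline run configuration
#'
#' @param seed integer run seed (mandatory; every stage derives from it).
#' @param out_dir output directory.
#' @param counts,indicators,adjacency optional input paths; when `NULL` a
#'   synthetic city is simulated first and written alongside the results.
#' @param periods named list mapping period labels to calendar-year
#'   vectors; periods must not overlap.
#' @param n_rows,n_cols lattice size for the simulated city.
#' @param strata data.frame `age_group, nationality` of strata to smooth
#'   (default: the 15-49 group for both nationality groups).
#' @param mcmc an [mcmc_control()]; its seed field is ignored in favour of
#'   stage-derived seeds.
#' @param priors a [bym_priors()].
#' @param percentiles exposure-contrast percentile pair (default 5 and 95).
#' @return list of class `run_config`.
#' @export
run_config <- function(seed, out_dir,
                       counts = NULL, indicators = NULL, adjacency = NULL,
                       periods = list(P1 = 1999:2003, P2 = 2004:2008,
                                      P3 = 2009:2013),
                       n_rows = 10, n_cols = 10,
                       strata = data.frame(
                         age_group = "15-49",
                         nationality = c("Spanish", "LIC")),
                       mcmc = mcmc_control(),
                       priors = bym_priors(),
                       percentiles = c(5, 95)) {
  if (missing(seed)) stop("a run seed is mandatory")
  yrs <- unlist(periods)
  if (anyDuplicated(yrs)) stop("periods overlap: year(s) ",
                               paste(unique(yrs[duplicated(yrs)]), collapse = ", "))
  if (length(percentiles) != 2L || percentiles[1L] >= percentiles[2L])
    stop("percentiles must be an increasing pair")
  structure(list(seed = as.integer(seed), out_dir = out_dir, counts = counts,
                 indicators = indicators, adjacency = adjacency,
                 periods = periods, n_rows = n_rows, n_cols = n_cols,
                 strata = strata, mcmc = mcmc, priors = priors,
                 percentiles = percentiles),
            class = "run_config")
}

#' Write a choropleth GeoJSON
#'
#' One feature per tract, with properties `tract_id`, `value` and `class`
#' (septile label under `classing = "septile"`, the value itself under
#' `"continuous"`), in deterministic tract order.
#'
#' @param values named numeric vector of per-tract values (names = tract
#'   ids) or unnamed vector in polygon order.
#' @param polygons named list of closed coordinate rings (see
#'   [lattice_polygons()]); must cover every tract in `values`.
#' @param classing `"septile"` or `"continuous"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_choropleth <- function(values, polygons, classing = c("septile", "continuous"),
                             path) {
  classing <- match.arg(classing)
  if (is.null(names(values))) {
    if (length(values) != length(polygons))
      stop("unnamed values must match the polygon list in length")
    names(values) <- names(polygons)
  }
  missing_poly <- setdiff(names(values), names(polygons))
  if (length(missing_poly))
    stop("no polygon for tract(s): ", paste(missing_poly, collapse = ", "))
  cls <- switch(classing,
                septile = assign_septiles(unname(values)),
                continuous = unname(values))
  feats <- lapply(seq_along(values), function(i) {
    ring <- polygons[[names(values)[i]]]
    list(type = "Feature",
         properties = list(tract_id = names(values)[i],
                           value = unname(values[i]), class = cls[i]),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(k) ring[k, ]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a choropleth GeoJSON back
#'
#' @param path a file written by [write_choropleth()].
#' @return data.frame `tract_id, value, class`.
#' @export
read_choropleth <- function(path) {
  gj <- jsonlite::read_json(path)
  props <- lapply(gj$features, `[[`, "properties")
  data.frame(tract_id = vapply(props, `[[`, "", "tract_id"),
             value = vapply(props, function(p) as.numeric(p$value), 0),
             class = vapply(props, function(p) as.numeric(p$class), 0),
             stringsAsFactors = FALSE)
}

#' Read a stratified counts CSV
#'
#' @param path CSV with columns `tract_id, period, age_group, nationality,
#'   births, women`.
#' @return validated data.frame.
#' @export
read_counts <- function(path) {
  cc <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(tract_id = "character"))
  need <- c("tract_id", "period", "age_group", "nationality", "births", "women")
  miss <- setdiff(need, names(cc))
  if (length(miss)) stop("counts CSV lacks column(s): ", paste(miss, collapse = ", "))
  if (any(cc$births < 0) || any(cc$women < 0)) stop("counts must be non-negative")
  cc
}

#' Read an indicators CSV
#'
#' @param path CSV with `tract_id` plus the five indicator columns.
#' @return numeric matrix with tract ids as rownames.
#' @export
read_indicators <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(tract_id = "character"))
  if (!"tract_id" %in% names(df)) stop("indicators CSV needs a tract_id column")
  m <- as.matrix(df[, setdiff(names(df), "tract_id"), drop = FALSE])
  rownames(m) <- df$tract_id
  m
}

#' Run the full pipeline
#'
#' Orchestrates simulate (when no inputs are given) -> deprivation index ->
#' crude rates -> BYM smoothing per configured stratum and period ->
#' three-period ecological regression per stratum, writing every product
#' under `out_dir` and a `manifest.json` recording input hashes, the seed,
#' package version, the files written, and convergence summaries (a run
#' with any split R-hat above 1.1 is marked `"unconverged"`). Identical
#' configurations reproduce identical outputs.
#'
#' @param config a [run_config()].
#' @return the manifest, invisibly (a list).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  rhat_all <- c()

  if (is.null(config$counts)) {
    city <- simulate_city(n_rows = config$n_rows, n_cols = config$n_cols,
                          seed = stage_seed(config$seed, "simulate"),
                          n_periods = length(config$periods))
    city$counts$period <- names(config$periods)[
      match(city$counts$period, paste0("P", seq_along(config$periods)))]
    paths <- write_city(city, config$out_dir)
    files <- c(files, unname(paths))
    counts <- city$counts
    indicators <- city$indicators
    graph <- city$graph
  } else {
    counts <- read_counts(config$counts)
    indicators <- read_indicators(config$indicators)
    graph <- read_gal(config$adjacency)
  }

  # exposure
  index <- compute_index(indicators)
  idx_path <- file.path(config$out_dir, "deprivation_index.csv")
  utils::write.csv(data.frame(tract_id = names(index$x), x = index$x,
                              septile = index$septile, row.names = NULL),
                   idx_path, row.names = FALSE)
  files <- c(files, idx_path)

  # crude rates table
  rates_path <- file.path(config$out_dir, "crude_rates.csv")
  utils::write.csv(rates_table(counts), rates_path, row.names = FALSE)
  files <- c(files, rates_path)

  # BYM smoothing per stratum x period
  periods <- sort(unique(counts$period))
  for (k in seq_len(nrow(config$strata))) {
    a <- config$strata$age_group[k]; g <- config$strata$nationality[k]
    for (p in periods) {
      cc <- counts[counts$age_group == a & counts$nationality == g &
                     counts$period == p, , drop = FALSE]
      if (!nrow(cc)) next
      cc <- cc[match(graph$tract_id, cc$tract_id), , drop = FALSE]
      m <- config$mcmc
      m$seed <- stage_seed(config$seed, paste("smooth", a, g, p))
      fit <- suppressWarnings(
        fit_bym(bym_model(cc$births, cc$women, graph, config$priors), m))
      rhat_all <- c(rhat_all, stats::setNames(
        max(fit$rhat), paste("smooth", a, g, p)))
      sm <- smoothed_rates(fit)
      sm_path <- file.path(config$out_dir,
                           sprintf("smoothed_%s_%s_%s.csv", gsub("-", "", a), g, p))
      utils::write.csv(sm, sm_path, row.names = FALSE)
      files <- c(files, sm_path)
    }
  }

  # ecological regression per stratum
  m <- config$mcmc
  m$seed <- config$seed
  rr <- suppressWarnings(
    run_stratified_analysis(
      counts[counts$age_group %in% config$strata$age_group &
               counts$nationality %in% config$strata$nationality, , drop = FALSE],
      index, graph, mcmc = m, priors = config$priors))
  rr_path <- file.path(config$out_dir, "relative_risks.csv")
  utils::write.csv(rr, rr_path, row.names = FALSE)
  files <- c(files, rr_path)
  rhat_all <- c(rhat_all, stats::setNames(
    rr$max_rhat[!duplicated(paste(rr$age_group, rr$nationality))],
    paste("regress", unique(paste(rr$age_group, rr$nationality)))))

  input_files <- files[basename(files) %in%
                         c("counts.csv", "indicators.csv", "adjacency.gal")]
  manifest <- list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("fertimap")),
    files = basename(files),
    input_md5 = as.list(stats::setNames(
      vapply(input_files, function(f) unname(tools::md5sum(f)), ""),
      basename(input_files))),
    rhat = as.list(round(rhat_all, 4)),
    status = if (length(rhat_all) && max(rhat_all) > 1.1) "unconverged" else "converged"
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
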