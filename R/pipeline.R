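#' Run the full measurement pipeline from one configuration
#'
#' Executes the whole chain — indicator weights, min-max normalization and
#' composite scores, regional means, year-by-year Theil decomposition,
#' global Moran's I per year, LISA cluster typing and the two-timepoint
#' quadrant classification — and writes every stage's table plus a JSON run
#' manifest to `out_dir`. Outputs are deterministic under a fixed seed:
#' rerunning the same configuration yields byte-identical files.
#'
#' The configuration is a named list (or path to a YAML file) with:
#' \describe{
#'   \item{panel, meta}{paths to the panel and metadata CSVs, or omit both
#'     and supply `synthetic:` (a list of [synthetic_config()] arguments)
#'     to generate the inputs.}
#'   \item{partition}{path to a unit,group CSV (defaults to the generated
#'     partition for synthetic runs).}
#'   \item{weights}{`"reference"` (the packaged nine-indicator tree,
#'     default for panels using its indicator names), `"equal"`, or a list
#'     with `secondary` and `tertiary` (named list) judgment-matrix CSV
#'     paths.}
#'   \item{spatial_weights}{path to a GAL or edge-list file, with optional
#'     `spatial_format`; defaults to the generated adjacency for synthetic
#'     runs.}
#'   \item{scope}{normalization scope, `"pooled"` (default) or
#'     `"per_year"`.}
#'   \item{permutations, alpha, seed}{inference settings (defaults 999,
#'     0.05; seed is required).}
#'   \item{quadrant_years}{two years for the quadrant stage (default
#'     first and last panel year); LISA runs on these same years.}
#'   \item{epsilon_shift}{see [theil_timeseries()] (default FALSE).}
#' }
#'
#' @param config named list or path to a YAML config file.
#' @param out_dir output directory; overrides `config$out_dir`.
#' @return Invisibly, a list with all stage results and the manifest.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  .assert(is.list(config), "config must be a list or a YAML file path")
  out_dir <- out_dir %||% config$out_dir
  .assert(!is.null(out_dir), "an output directory is required")
  seed <- config$seed
  .assert(!is.null(seed), "config must set a seed")
  seed <- as.integer(seed)
  perms <- as.integer(config$permutations %||% 999)
  alpha <- as.numeric(config$alpha %||% 0.05)
  scope <- config$scope %||% "pooled"
  # the hash identifies the analysis configuration, not where it is written
  hash <- config_hash(config[setdiff(names(config), "out_dir")])
  warnings_log <- character(0)
  note <- function(...) {
    warnings_log <<- c(warnings_log, sprintf(...))
  }
  stage <- function(name, expr) {
    tryCatch(
      withCallingHandlers(expr, message = function(m) {
        note("[%s] %s", name, trimws(conditionMessage(m)))
        invokeRestart("muffleMessage")
      }),
      error = function(e) {
        stop(sprintf("pipeline stage '%s' failed: %s", name,
                     conditionMessage(e)), call. = FALSE)
      }
    )
  }

  # ---- inputs ---------------------------------------------------------------
  inputs <- stage("inputs", {
    if (!is.null(config$synthetic)) {
      sc <- do.call(synthetic_config,
                    c(config$synthetic,
                      if (is.null(config$synthetic$seed)) list(seed = seed)))
      gen <- generate_panel(sc)
      list(panel = gen$panel, partition = gen$partition, sw = gen$weights,
           synthetic = TRUE)
    } else {
      .assert(!is.null(config$panel) && !is.null(config$meta),
              "config needs panel and meta paths (or a synthetic block)")
      panel <- read_panel(config$panel, config$meta)
      .assert(!is.null(config$partition), "config needs a partition path")
      part <- read_partition(config$partition, units = panel$units)
      .assert(!is.null(config$spatial_weights),
              "config needs a spatial_weights path")
      sw <- read_spatial_weights(config$spatial_weights,
                                 format = config$spatial_format %||%
                                   "edge_list",
                                 units = panel$units)
      list(panel = panel, partition = part, sw = sw, synthetic = FALSE)
    }
  })
  panel <- inputs$panel
  partition <- inputs$partition
  sw <- inputs$sw

  # ---- weights --------------------------------------------------------------
  tree <- stage("weights", {
    wspec <- config$weights %||%
      (if (setequal(panel$indicators,
                    names(reference_weight_tree()$global)))
        "reference" else "equal")
    if (identical(wspec, "reference")) {
      reference_weight_tree()
    } else if (identical(wspec, "equal")) {
      groups <- unique(panel$meta$group)
      sec <- setNames(rep(1 / length(groups), length(groups)), groups)
      local <- lapply(setNames(groups, groups), function(g) {
        ind <- panel$meta$indicator[panel$meta$group == g]
        setNames(rep(1 / length(ind), length(ind)), ind)
      })
      weight_tree(sec, local)
    } else {
      .assert(is.list(wspec) && !is.null(wspec$secondary) &&
                !is.null(wspec$tertiary),
              "weights must be 'reference', 'equal', or a list with secondary and tertiary matrix paths")
      sec_m <- read_judgment_matrix(wspec$secondary)
      ter <- lapply(wspec$tertiary, read_judgment_matrix)
      build_weight_tree(sec_m, ter)
    }
  })
  weights_tab <- data.frame(
    indicator = names(tree$global),
    group = unname(tree$groups[names(tree$global)]),
    local_weight = unname(unlist(tree$local)[vapply(
      names(tree$global),
      function(i) paste0(tree$groups[[i]], ".", i), character(1))]),
    global_weight = unname(tree$global),
    stringsAsFactors = FALSE
  )

  # ---- scores ---------------------------------------------------------------
  scores <- stage("scores", {
    composite_score(normalize_panel(panel, scope = scope), tree)
  })
  region_means <- stage("region_means",
                        summarize_by_region(scores, partition))

  # ---- inequality -----------------------------------------------------------
  theil <- stage("theil", {
    theil_timeseries(scores, partition,
                     epsilon_shift = isTRUE(config$epsilon_shift))
  })

  # ---- spatial --------------------------------------------------------------
  years <- sort(unique(scores$year))
  qyears <- as.integer(config$quadrant_years %||%
                         c(min(years), max(years)))
  .assert(length(qyears) == 2 && all(qyears %in% years),
          "quadrant_years must be two years present in the panel")
  moran_tab <- stage("moran", {
    do.call(rbind, lapply(seq_along(years), function(k) {
      y <- years[k]
      v <- setNames(scores$Z[scores$year == y],
                    scores$unit[scores$year == y])
      r <- moran_global(v, sw, n_permutations = perms, seed = seed + k)
      data.frame(year = y, I = r$I, expected_I = r$expected_I,
                 variance_randomization = r$variance_randomization,
                 variance_normality = r$variance_normality,
                 z = r$z, p_analytic = r$p_analytic,
                 pseudo_p = r$pseudo_p)
    }))
  })
  lisa_tabs <- stage("lisa", {
    do.call(rbind, lapply(seq_along(qyears), function(k) {
      y <- qyears[k]
      v <- setNames(scores$Z[scores$year == y],
                    scores$unit[scores$year == y])
      l <- moran_local(v, sw, n_permutations = perms,
                       seed = seed + 1000L + k, alpha = alpha)
      cbind(year = y, as.data.frame(l))
    }))
  })

  # ---- quadrant -------------------------------------------------------------
  quad <- stage("quadrant", {
    classify_quadrants(scores, qyears[1], qyears[2], partition = partition)
  })
  quad_tab <- as.data.frame(quad)
  quad_counts <- attr(quad, "region_counts")

  tables <- list(
    weights = weights_tab,
    scores = as.data.frame(scores),
    region_means = region_means$region_year,
    theil = theil$table,
    theil_contrib = theil$contrib,
    moran_global = moran_tab,
    lisa = lisa_tabs,
    quadrant = quad_tab,
    quadrant_counts = quad_counts
  )
  paths <- write_results(tables, out_dir, seed = seed, config_hash = hash)

  manifest <- list(
    package = "hralloc",
    version = as.character(packageVersion("hralloc")),
    seed = seed,
    config_hash = hash,
    config = config[setdiff(names(config), "out_dir")],
    stages = lapply(tables, nrow),
    quadrant_origin = as.list(attr(quad, "origin")),
    warnings = warnings_log
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(panel = panel, partition = partition, weights = tree,
                 scores = scores, region_means = region_means,
                 theil = theil, moran = moran_tab, lisa = lisa_tabs,
                 quadrant = quad, tables = tables, manifest = manifest,
                 paths = c(paths, manifest_path)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
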