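#' Min-max normalization of an indicator panel
#'
#' Maps each raw indicator value onto `[0, 1]` relative to the indicator's
#' extrema: positive-orientation indicators use
#' `d = (x - min) / (max - min)`, negative-orientation indicators the
#' reflected map `d = (max - x) / (max - min)`, so that larger `d` always
#' means better provision. Extrema are taken either over the whole panel
#' (`scope = "pooled"`, the default, which keeps scores comparable across
#' years) or within each year (`scope = "per_year"`).
#'
#' @param panel a complete [indicator_panel()].
#' @param scope `"pooled"` or `"per_year"`.
#' @return An object of class `normalized_panel`: a list with `data`
#'   (unit, year, indicator, d), `meta`, `scope` and the `extrema` used.
#' @export
normalize_panel <- function(panel, scope = c("pooled", "per_year")) {
  .assert(inherits(panel, "indicator_panel"), "panel must be indicator_panel")
  scope <- match.arg(scope)
  .assert(panel$complete,
          "scoring requires a rectangular panel; %d combinations are missing",
          nrow(panel$completeness))
  df <- panel$data
  orient <- setNames(panel$meta$orientation, panel$meta$indicator)
  keyf <- if (scope == "pooled") df$indicator else
    paste(df$indicator, df$year, sep = "\r")
  mins <- tapply(df$value, keyf, min)
  maxs <- tapply(df$value, keyf, max)
  flat <- names(mins)[maxs == mins]
  .assert(length(flat) == 0L,
          "constant indicator within normalization scope (max = min): %s",
          paste(gsub("\r", " @ ", flat), collapse = ", "))
  lo <- mins[keyf]; hi <- maxs[keyf]
  d <- ifelse(orient[df$indicator] == "positive",
              (df$value - lo) / (hi - lo),
              (hi - df$value) / (hi - lo))
  out <- data.frame(unit = df$unit, year = df$year, indicator = df$indicator,
                    d = as.numeric(d), stringsAsFactors = FALSE)
  extrema <- data.frame(key = names(mins), min = as.numeric(mins),
                        max = as.numeric(maxs), stringsAsFactors = FALSE)
  structure(list(data = out, meta = panel$meta, units = panel$units,
                 years = panel$years, indicators = panel$indicators,
                 scope = scope, extrema = extrema),
            class = "normalized_panel")
}

#' Composite score and secondary sub-scores
#'
#' Aggregates normalized indicator values with the global tertiary weights
#' of a [weight_tree()]: the sub-score of group `g` for a unit-year is
#' `sum over indicators i in g of w_i * d_i`, and the composite score `Z`
#' is the sum of the sub-scores (equivalently `sum w_i d_i` over all nine
#' indicators). Each sub-score lies in `[0, secondary weight of g]` and
#' `Z` in `[0, 1]`.
#'
#' @param np a [normalize_panel()] result.
#' @param weights a [weight_tree()] whose indicators exactly match the
#'   panel's.
#' @return An object of class `score_panel`: data.frame with columns
#'   `unit`, `year`, `Z`, and one `Z_<group>` column per secondary group;
#'   attributes `groups`, `scope`.
#' @export
composite_score <- function(np, weights) {
  .assert(inherits(np, "normalized_panel"),
          "np must come from normalize_panel()")
  .assert(inherits(weights, "weight_tree"), "weights must be a weight_tree")
  panel_ind <- np$indicators
  tree_ind <- names(weights$global)
  extra_w <- setdiff(tree_ind, panel_ind)
  extra_p <- setdiff(panel_ind, tree_ind)
  .assert(length(extra_w) == 0L, "weight(s) without panel indicator: %s",
          paste(extra_w, collapse = ", "))
  .assert(length(extra_p) == 0L, "panel indicator(s) without weight: %s",
          paste(extra_p, collapse = ", "))

  df <- np$data
  df$w <- weights$global[df$indicator]
  df$g <- weights$groups[df$indicator]
  df$wd <- df$w * df$d
  groups <- names(weights$secondary)
  uy <- unique(df[, c("unit", "year")])
  uy <- uy[order(uy$unit, uy$year), , drop = FALSE]
  key <- paste(df$unit, df$year, sep = "\r")
  ukey <- paste(uy$unit, uy$year, sep = "\r")
  out <- data.frame(unit = uy$unit, year = uy$year, stringsAsFactors = FALSE)
  sub <- matrix(0, nrow(uy), length(groups),
                dimnames = list(NULL, paste0("Z_", groups)))
  for (g in groups) {
    sel <- df$g == g
    s <- tapply(df$wd[sel], key[sel], sum)
    sub[, paste0("Z_", g)] <- as.numeric(s[ukey])
  }
  out$Z <- rowSums(sub)
  out <- cbind(out, as.data.frame(sub))
  rownames(out) <- NULL
  structure(out, class = c("score_panel", "data.frame"),
            groups = groups, scope = np$scope)
}

#' Regional mean scores per year
#'
#' Unweighted arithmetic means of unit composite scores per region-year,
#' plus two whole-sample summaries per year: the mean of the region means
#' (the "average score of the regions") and the plain mean over all units.
#' Both summaries are reported because they differ whenever region sizes
#' differ.
#'
#' @param scores a [composite_score()] result.
#' @param partition a [region_partition()] covering all scored units.
#' @return list with `region_year` (region x year means, long) and
#'   `year_summary` (year, mean_of_region_means, unit_mean).
#' @export
summarize_by_region <- function(scores, partition) {
  .assert(inherits(scores, "score_panel"), "scores must be a score_panel")
  .assert(inherits(partition, "region_partition"),
          "partition must be a region_partition")
  un <- setdiff(unique(scores$unit), names(partition$assignment))
  .assert(length(un) == 0L, "unit(s) not assigned to any region: %s",
          paste(un, collapse = ", "))
  reg <- partition$assignment[scores$unit]
  agg <- aggregate(list(mean_Z = scores$Z),
                   by = list(region = reg, year = scores$year), FUN = mean)
  agg$region <- factor(agg$region, levels = partition$groups)
  agg <- agg[order(agg$year, agg$region), c("year", "region", "mean_Z")]
  agg$region <- as.character(agg$region)
  rownames(agg) <- NULL
  ys <- aggregate(list(mean_of_region_means = agg$mean_Z),
                  by = list(year = agg$year), FUN = mean)
  um <- aggregate(list(unit_mean = scores$Z),
                  by = list(year = scores$year), FUN = mean)
  list(region_year = agg, year_summary = merge(ys, um, by = "year"))
}
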