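#' Two-timepoint quadrant classification of composite scores
#'
#' Places every unit in a plane whose axes are its composite score at two
#' timepoints and whose origin is the pair of cross-unit mean scores:
#' quadrant I is above average at both timepoints, II below at `year0` but
#' above at `year1`, III below at both, IV above at `year0` but below at
#' `year1`. Units landing exactly on a mean count as above average (the
#' `>=` convention) and are flagged as ties so the convention is visible
#' in output.
#'
#' @param scores a [composite_score()] result containing both years.
#' @param year0,year1 the two timepoints.
#' @param partition optional [region_partition()]; adds per-region counts.
#' @return An object of class `quadrant_result`: data.frame with columns
#'   `unit`, `score_t0`, `score_t1`, `quadrant`, `tie`; attributes
#'   `origin` (mean_t0, mean_t1), `counts` (per quadrant) and
#'   `region_counts` (region x quadrant, when a partition is given).
#' @export
classify_quadrants <- function(scores, year0, year1, partition = NULL) {
  .assert(inherits(scores, "score_panel"), "scores must be a score_panel")
  for (y in c(year0, year1)) {
    .assert(y %in% scores$year, "year %d not present in the score panel", y)
  }
  s0 <- scores[scores$year == year0, c("unit", "Z")]
  s1 <- scores[scores$year == year1, c("unit", "Z")]
  .assert(setequal(s0$unit, s1$unit),
          "the two years cover different unit sets")
  s1 <- s1[match(s0$unit, s1$unit), ]
  m0 <- mean(s0$Z)
  m1 <- mean(s1$Z)
  hi0 <- s0$Z >= m0
  hi1 <- s1$Z >= m1
  quadrant <- ifelse(hi0 & hi1, "I",
                     ifelse(!hi0 & hi1, "II",
                            ifelse(!hi0 & !hi1, "III", "IV")))
  tie <- s0$Z == m0 | s1$Z == m1
  if (any(tie)) {
    message("unit(s) exactly on a mean, counted as above-average: ",
            paste(s0$unit[tie], collapse = ", "))
  }
  out <- data.frame(unit = s0$unit, score_t0 = s0$Z, score_t1 = s1$Z,
                    quadrant = quadrant, tie = tie, stringsAsFactors = FALSE)
  counts <- table(factor(quadrant, levels = c("I", "II", "III", "IV")))
  region_counts <- NULL
  if (!is.null(partition)) {
    .assert(inherits(partition, "region_partition"),
            "partition must be a region_partition")
    reg <- partition$assignment[out$unit]
    region_counts <- as.data.frame.matrix(
      table(factor(reg, levels = partition$groups),
            factor(quadrant, levels = c("I", "II", "III", "IV"))))
    region_counts <- cbind(region = rownames(region_counts), region_counts,
                           stringsAsFactors = FALSE)
    rownames(region_counts) <- NULL
  }
  structure(out, class = c("quadrant_result", "data.frame"),
            origin = c(mean_t0 = m0, mean_t1 = m1),
            counts = counts, region_counts = region_counts,
            years = c(year0, year1))
}

#' @export
print.quadrant_result <- function(x, ...) {
  yrs <- attr(x, "years")
  o <- attr(x, "origin")
  cat(sprintf("quadrant_result: %d units, %d vs %d, origin (%.4f, %.4f)\n",
              nrow(x), yrs[1], yrs[2], o[1], o[2]))
  print(attr(x, "counts"))
  invisible(x)
}
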