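#' Generalized-entropy inequality index
#'
#' The GE family over positive values `y` with unit weights `p` (default
#' equal, `1/n`):
#' \itemize{
#'   \item `c = 1` (Theil T): `sum p_i (y_i/mu) ln(y_i/mu)`;
#'   \item `c = 0` (Theil L / mean log deviation): `sum p_i ln(mu/y_i)`;
#'   \item otherwise: `1/(c(c-1)) sum p_i ((y_i/mu)^c - 1)`,
#' }
#' with `mu` the (weighted) mean. For `c = 1` the equivalent income-share
#' form `sum s_i ln(s_i/p_i)` (equal weights: `sum s_i ln(n s_i)`) is also
#' available and is used as a cross-check; the two coincide to machine
#' precision. GE is nonnegative, zero iff all values are equal, scale
#' invariant and replication invariant.
#'
#' @param values positive numeric vector.
#' @param c sensitivity parameter (default 1, the Theil index).
#' @param weights optional unit weights summing to 1; default equal.
#' @param form `"mean_ratio"` (default) or `"share"` (c = 1 only).
#' @return The index value (nonnegative scalar).
#' @examples
#' ge_index(c(1, 1, 1, 9))          # 0.25*log(1/3) + 0.75*log(3)
#' ge_index(c(5, 5, 5))             # 0
#' @export
ge_index <- function(values, c = 1, weights = NULL,
                     form = c("mean_ratio", "share")) {
  form <- match.arg(form)
  values <- as.numeric(values)
  .assert(length(values) >= 1 && all(is.finite(values)),
          "values must be finite numbers")
  .assert(all(values > 0),
          "generalized-entropy index needs strictly positive values (logarithm undefined at <= 0)")
  n <- length(values)
  if (is.null(weights)) weights <- rep(1 / n, n)
  .assert(length(weights) == n && all(weights > 0) &&
            abs(sum(weights) - 1) < 1e-9,
          "weights must be positive and sum to 1")
  mu <- sum(weights * values)
  if (form == "share") {
    .assert(c == 1, "the share form is defined for c = 1 only")
    s <- weights * values / mu
    return(sum(s * log(s / weights)))
  }
  r <- values / mu
  if (c == 1) {
    sum(weights * r * log(r))
  } else if (c == 0) {
    sum(weights * log(1 / r))
  } else {
    sum(weights * (r^c - 1)) / (c * (c - 1))
  }
}

#' Theil decomposition into within- and between-region components
#'
#' Decomposes the Theil index (GE at `c = 1`, equal unit weights) of unit
#' values exactly into a within-region and a between-region part:
#' `T = TWR + TBR` with
#' `TWR = sum_g S_g T_g` and `TBR = sum_g S_g ln(S_g / (n_g/n))`,
#' where `S_g` is region g's share of the total value, `T_g` its internal
#' Theil index and `n_g` its unit count. The reported per-region within
#' component is `S_g T_g`. Contribution rates express each component as a
#' percent of `T` and sum to 100 (undefined when `T = 0`).
#'
#' @param values positive numeric vector named by unit (or unnamed, in
#'   partition order).
#' @param partition a [region_partition()] covering the units.
#' @param year optional year tag carried through to the result.
#' @return An object of class `theil_result`: list with `year`, `T`, `TWR`,
#'   `TBR`, `within` (named per-region components `S_g T_g`), `shares`
#'   (`S_g`), `contrib` (percent: per region, `TWR`, `TBR`), `n`.
#' @export
theil_decompose <- function(values, partition, year = NA_integer_) {
  .assert(inherits(partition, "region_partition"),
          "partition must be a region_partition")
  if (is.null(names(values))) {
    .assert(length(values) == length(partition$assignment),
            "unnamed values must match the partition's unit count")
    names(values) <- names(partition$assignment)
  }
  un <- setdiff(names(values), names(partition$assignment))
  .assert(length(un) == 0L, "unit(s) not in partition: %s",
          paste(un, collapse = ", "))
  nm <- names(values)
  values <- as.numeric(values)
  names(values) <- nm
  .assert(all(values > 0),
          "Theil decomposition needs strictly positive values")
  n <- length(values)
  total <- sum(values)
  groups <- partition$groups
  reg <- partition$assignment[names(values)]
  within <- setNames(numeric(length(groups)), groups)
  shares <- setNames(numeric(length(groups)), groups)
  TBR <- 0
  for (g in groups) {
    yg <- values[reg == g]
    ng <- length(yg)
    Sg <- sum(yg) / total
    Tg <- if (ng > 1) ge_index(yg, c = 1) else 0
    within[g] <- Sg * Tg
    shares[g] <- Sg
    TBR <- TBR + Sg * log(Sg / (ng / n))
  }
  TWR <- sum(within)
  Ttot <- ge_index(values, c = 1)
  contrib <- if (Ttot > 0) {
    c(setNames(100 * within / Ttot, groups),
      TWR = 100 * TWR / Ttot, TBR = 100 * TBR / Ttot)
  } else {
    c(setNames(rep(NA_real_, length(groups)), groups),
      TWR = NA_real_, TBR = NA_real_)
  }
  structure(list(year = year, T = Ttot, TWR = TWR, TBR = TBR,
                 within = within, shares = shares, contrib = contrib, n = n),
            class = "theil_result")
}

#' @export
print.theil_result <- function(x, ...) {
  hdr <- if (is.na(x$year)) "theil_result" else
    sprintf("theil_result (%d)", x$year)
  cat(sprintf("%s: T = %.4f = TWR %.4f + TBR %.4f\n",
              hdr, x$T, x$TWR, x$TBR))
  cat("  within components:",
      paste(sprintf("%s=%.4f", names(x$within), x$within), collapse = ", "),
      "\n")
  invisible(x)
}

#' Year-by-year Theil decomposition of composite scores
#'
#' Runs [theil_decompose()] on the composite score of every year in a
#' [composite_score()] panel and tabulates the components, the contribution
#' rates and first-to-last-year percent changes (computed from unrounded
#' values). Composite scores of exactly zero (a unit at the pooled minimum
#' on every indicator) make the logarithm undefined; by default this is an
#' error, or set `epsilon_shift = TRUE` to add `1e-6 * mean` to all values
#' of the affected year — the shift is reported, never silent.
#'
#' @param scores a [composite_score()] result.
#' @param partition a [region_partition()].
#' @param epsilon_shift shift nonpositive score cross-sections by
#'   `1e-6 * mean(values)` instead of erroring (default FALSE).
#' @return An object of class `theil_series`: list with `by_year` (list of
#'   [theil_decompose()] results), `table` (one row per year: T, TWR, TBR,
#'   per-region components), `contrib` (long: year, component, percent),
#'   `change` (percent change first to last year per component),
#'   `shifted_years`.
#' @export
theil_timeseries <- function(scores, partition, epsilon_shift = FALSE) {
  .assert(inherits(scores, "score_panel"), "scores must be a score_panel")
  years <- sort(unique(scores$year))
  groups <- partition$groups
  by_year <- list()
  shifted <- integer(0)
  for (y in years) {
    sel <- scores$year == y
    v <- setNames(scores$Z[sel], scores$unit[sel])
    .assert(!anyDuplicated(names(v)), "duplicate unit in year %d", y)
    if (any(v <= 0)) {
      if (!epsilon_shift) {
        stop(sprintf(
          "nonpositive composite score(s) in year %d (%s); rescale or set epsilon_shift = TRUE",
          y, paste(names(v)[v <= 0], collapse = ", ")), call. = FALSE)
      }
      v <- v + 1e-6 * mean(v)
      .assert(all(v > 0), "epsilon shift did not make year %d positive", y)
      shifted <- c(shifted, y)
    }
    by_year[[as.character(y)]] <- theil_decompose(v, partition, year = y)
  }
  if (length(shifted)) {
    message("epsilon-shifted nonpositive scores in year(s): ",
            paste(shifted, collapse = ", "))
  }
  tab <- do.call(rbind, lapply(by_year, function(r) {
    data.frame(year = r$year, t(r$within), TWR = r$TWR, TBR = r$TBR,
               T = r$T, check.names = FALSE)
  }))
  rownames(tab) <- NULL
  contrib <- do.call(rbind, lapply(by_year, function(r) {
    data.frame(year = r$year, component = names(r$contrib),
               percent = as.numeric(r$contrib), stringsAsFactors = FALSE)
  }))
  rownames(contrib) <- NULL
  first <- by_year[[1L]]; last <- by_year[[length(by_year)]]
  comp_first <- c(first$within, TWR = first$TWR, TBR = first$TBR, T = first$T)
  comp_last <- c(last$within, TWR = last$TWR, TBR = last$TBR, T = last$T)
  change <- 100 * (comp_last - comp_first) / comp_first
  structure(list(by_year = by_year, table = tab, contrib = contrib,
                 change = change, shifted_years = shifted),
            class = "theil_series")
}

#' @export
print.theil_series <- function(x, ...) {
  cat(sprintf("theil_series: %d years\n", nrow(x$table)))
  print(cbind(year = x$table$year,
              round(x$table[, -1, drop = FALSE], 4)), row.names = FALSE)
  invisible(x)
}
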