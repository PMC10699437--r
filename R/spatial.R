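# Cliff-Ord moments of Moran's I. W need not be symmetric (row-standardized
# matrices are not); S1/S2 use the standard symmetrized sums.
.moran_moments <- function(w, z, assumption) {
  n <- length(z)
  S0 <- sum(w)
  S1 <- 0.5 * sum((w + t(w))^2)
  S2 <- sum((rowSums(w) + colSums(w))^2)
  EI <- -1 / (n - 1)
  if (assumption == "normality") {
    v <- (n^2 * S1 - n * S2 + 3 * S0^2) / (S0^2 * (n^2 - 1)) - EI^2
  } else {
    b2 <- n * sum(z^4) / (sum(z^2)^2)
    num <- n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * S0^2) -
      b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * S0^2)
    v <- num / ((n - 1) * (n - 2) * (n - 3) * S0^2) - EI^2
  }
  list(S0 = S0, S1 = S1, S2 = S2, EI = EI, variance = v)
}

.moran_stat <- function(zmat, w, S0) {
  # zmat: n x k matrix of centered value columns; returns I per column
  n <- nrow(zmat)
  num <- colSums((w %*% zmat) * zmat)
  den <- colSums(zmat^2)
  (n / S0) * num / den
}

.align_values <- function(values, sw) {
  units <- sw$units
  if (!is.null(names(values))) {
    .assert(setequal(names(values), units),
            "value names do not match the spatial weights' units")
    values <- values[units]
  } else {
    .assert(length(values) == length(units),
            "unnamed values must match the number of spatial units")
    names(values) <- units
  }
  setNames(as.numeric(values), units)
}

#' Global Moran's I with analytic and permutation inference
#'
#' Computes `I = (n/S0) * sum_ij w_ij z_i z_j / sum_i z_i^2` for centered
#' values `z_i = x_i - xbar`, its exact null expectation `E(I) = -1/(n-1)`,
#' the closed-form variance under the chosen assumption (randomization,
#' i.e. permutation moments accounting for kurtosis, or normality), the
#' z-statistic with a two-sided normal p-value, and a permutation pseudo
#' p-value: values are randomly reassigned to units, the directional count
#' `(1 + #{permuted I at least as extreme as observed, in the observed
#' direction}) / (n_permutations + 1)` is formed, and reported two-sided
#' (doubled, capped at 1).
#'
#' @param values numeric vector, named by unit or in the weights' order.
#' @param sw a [spatial_weights()] object.
#' @param n_permutations number of random permutations (0 disables the
#'   permutation test).
#' @param seed integer seed; required when permutations are requested.
#' @param assumption `"randomization"` (default) or `"normality"` for the
#'   analytic variance; both are reported.
#' @return An object of class `moran_global_result`: list with `I`,
#'   `expected_I`, `variance` (chosen assumption), `variance_randomization`,
#'   `variance_normality`, `z`, `p_analytic`, `pseudo_p` (two-sided),
#'   `pseudo_p_directional`, `n_permutations`, `seed`, `assumption`, `n`.
#' @export
moran_global <- function(values, sw, n_permutations = 999, seed = NULL,
                         assumption = c("randomization", "normality")) {
  .assert(inherits(sw, "spatial_weights"), "sw must be spatial_weights")
  assumption <- match.arg(assumption)
  x <- .align_values(values, sw)
  n <- length(x)
  .assert(n >= 3, "global Moran's I needs at least 3 units")
  z <- x - mean(x)
  .assert(sum(z^2) > 0, "constant values: Moran's I undefined (zero variance)")
  w <- sw$w
  S0 <- sw$S0
  I <- .moran_stat(matrix(z, ncol = 1), w, S0)
  mom_r <- .moran_moments(w, z, "randomization")
  mom_n <- .moran_moments(w, z, "normality")
  EI <- mom_r$EI
  variance <- if (assumption == "randomization") mom_r$variance else
    mom_n$variance
  zstat <- (I - EI) / sqrt(variance)
  p_analytic <- 2 * pnorm(-abs(zstat))

  pseudo_dir <- NA_real_
  pseudo <- NA_real_
  if (n_permutations > 0) {
    .assert(!is.null(seed),
            "a seed is required when permutations are requested")
    perm_I <- with_preserved_rng(seed, {
      zm <- replicate(n_permutations, sample(z))
      .moran_stat(zm, w, S0)
    })
    if (I >= EI) {
      pseudo_dir <- (1 + sum(perm_I >= I)) / (n_permutations + 1)
    } else {
      pseudo_dir <- (1 + sum(perm_I <= I)) / (n_permutations + 1)
    }
    pseudo <- min(1, 2 * pseudo_dir)
  }
  structure(
    list(I = unname(I), expected_I = EI, variance = variance,
         variance_randomization = mom_r$variance,
         variance_normality = mom_n$variance,
         z = unname(zstat), p_analytic = unname(p_analytic),
         pseudo_p = pseudo, pseudo_p_directional = pseudo_dir,
         n_permutations = n_permutations,
         seed = if (is.null(seed)) NA_integer_ else seed,
         assumption = assumption, n = n),
    class = "moran_global_result"
  )
}

#' @export
print.moran_global_result <- function(x, ...) {
  cat(sprintf("moran_global_result: I = %.4f (E[I] = %.4f, n = %d)\n",
              x$I, x$expected_I, x$n))
  cat(sprintf("  z = %.4f (%s variance %.6f), analytic p = %.4g\n",
              x$z, x$assumption, x$variance, x$p_analytic))
  if (!is.na(x$pseudo_p)) {
    cat(sprintf("  pseudo p = %.4g (%d permutations, seed %d)\n",
                x$pseudo_p, x$n_permutations, x$seed))
  }
  invisible(x)
}

#' Local Moran's I and LISA cluster typing
#'
#' For each unit, `I_i = z_i * sum_j w_ij z_j` with `z` standardized to
#' unit variance using the n-divisor (so that with row-standardized
#' weights `sum_i I_i = n * I`). Significance is assessed by conditional
#' permutation: holding unit i's value fixed, the remaining values are
#' randomly placed on its neighbor positions and the directional pseudo
#' p-value `(1 + #{as extreme}) / (n_permutations + 1)` is formed. Units
#' whose pseudo p is at most `alpha` are typed by the sign pattern of
#' `(z_i, spatial lag of z at i)`: HH (high among high neighbors), HL, LH,
#' LL; others are NS. Isolated units have no spatial lag and are labeled
#' `undefined`.
#'
#' @param values numeric vector, named by unit or in the weights' order.
#' @param sw a [spatial_weights()] object.
#' @param n_permutations permutations per unit.
#' @param seed integer seed; required when permutations are requested.
#' @param alpha significance level gating the cluster labels.
#' @param fdr apply a Benjamini-Hochberg correction across units before
#'   gating (off by default; the conventional LISA map is uncorrected).
#' @return An object of class `lisa_result`: data.frame with columns
#'   `unit`, `local_I`, `lag`, `pseudo_p`, `mean_comparison`,
#'   `lag_comparison`, `label`; attributes `alpha`, `n_permutations`,
#'   `seed`, `global_mean`.
#' @export
moran_local <- function(values, sw, n_permutations = 999, seed = NULL,
                        alpha = 0.05, fdr = FALSE) {
  .assert(inherits(sw, "spatial_weights"), "sw must be spatial_weights")
  x <- .align_values(values, sw)
  n <- length(x)
  .assert(n >= 3, "local Moran's I needs at least 3 units")
  sdev <- sqrt(mean((x - mean(x))^2))
  .assert(sdev > 0, "constant values: local Moran's I undefined")
  z <- (x - mean(x)) / sdev
  w <- sw$w
  lag <- as.vector(w %*% z)
  Ii <- z * lag
  deg <- rowSums(w != 0)
  isolated <- deg == 0

  pseudo <- rep(NA_real_, n)
  if (n_permutations > 0) {
    .assert(!is.null(seed),
            "a seed is required when permutations are requested")
    pseudo <- with_preserved_rng(seed, {
      p <- rep(NA_real_, n)
      for (i in seq_len(n)) {
        if (isolated[i]) next
        nb <- which(w[i, ] != 0)
        wts <- w[i, nb]
        zo <- z[-i]
        k <- length(nb)
        sims <- vapply(seq_len(n_permutations), function(s) {
          sum(sample(zo, k) * wts)
        }, numeric(1))
        sims <- z[i] * sims
        # ties count as extreme in both directions (discrete null support)
        upper <- sum(sims >= Ii[i])
        lower <- sum(sims <= Ii[i])
        p[i] <- (min(upper, lower) + 1) / (n_permutations + 1)
      }
      p
    })
  }
  gate <- pseudo
  if (fdr) gate <- p.adjust(pseudo, method = "BH")
  mean_cmp <- ifelse(z >= 0, "high", "low")
  lag_cmp <- ifelse(lag >= 0, "high", "low")
  label <- rep("NS", n)
  sig <- !is.na(gate) & gate <= alpha & !isolated
  label[sig] <- paste0(toupper(substr(mean_cmp[sig], 1, 1)),
                       toupper(substr(lag_cmp[sig], 1, 1)))
  label[sig] <- c(HH = "HH", HL = "HL", LH = "LH", LL = "LL")[label[sig]]
  label[isolated] <- "undefined"
  Ii[isolated] <- NA_real_
  if (any(isolated)) {
    message("isolated unit(s) with undefined local statistics: ",
            paste(sw$units[isolated], collapse = ", "))
  }
  out <- data.frame(unit = sw$units, local_I = Ii, lag = lag,
                    pseudo_p = pseudo, mean_comparison = mean_cmp,
                    lag_comparison = lag_cmp, label = label,
                    stringsAsFactors = FALSE)
  structure(out, class = c("lisa_result", "data.frame"),
            alpha = alpha, n_permutations = n_permutations,
            seed = if (is.null(seed)) NA_integer_ else seed,
            global_mean = mean(x))
}

#' Tabulate significant LISA cluster memberships by region
#'
#' Counts the units carrying each significant cluster label (HH, HL, LH,
#' LL) within each region, the layout used for reporting which provinces
#' form high-high and low-low clusters.
#'
#' @param lisa a [moran_local()] result.
#' @param partition a [region_partition()] covering the units.
#' @return data.frame with one row per region and columns `HH`, `HL`,
#'   `LH`, `LL`, plus a `total` row; attribute `members` lists the units
#'   per label.
#' @export
lisa_summary <- function(lisa, partition) {
  .assert(inherits(lisa, "lisa_result"), "lisa must come from moran_local()")
  .assert(inherits(partition, "region_partition"),
          "partition must be a region_partition")
  labels <- c("HH", "HL", "LH", "LL")
  un <- setdiff(lisa$unit, names(partition$assignment))
  .assert(length(un) == 0L, "unit(s) not in partition: %s",
          paste(un, collapse = ", "))
  reg <- partition$assignment[lisa$unit]
  counts <- matrix(0L, nrow = length(partition$groups), ncol = length(labels),
                   dimnames = list(partition$groups, labels))
  for (lab in labels) {
    sel <- lisa$label == lab
    if (any(sel)) {
      tb <- table(factor(reg[sel], levels = partition$groups))
      counts[, lab] <- as.integer(tb)
    }
  }
  out <- data.frame(region = rownames(counts), counts,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- rbind(out, data.frame(region = "total",
                               t(colSums(counts)),
                               stringsAsFactors = FALSE))
  members <- lapply(setNames(labels, labels),
                    function(lab) lisa$unit[lisa$label == lab])
  structure(out, members = members)
}
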