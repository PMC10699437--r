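#' Pairwise-comparison judgment matrix
#'
#' A judgment matrix records pairwise importance ratios on Saaty's 1-9
#' scale: entry (i, j) says how much more important element i is than
#' element j. The diagonal is exactly 1 and the matrix is (approximately)
#' reciprocal, `x[i,j] * x[j,i] = 1`. Matrices transcribed from published
#' tables are typically rounded to 4 decimal places, so reciprocity is only
#' enforced up to `reciprocity_tol` (relative); the default admits
#' 4-d.p. rounding while rejecting genuinely non-reciprocal input.
#'
#' @param x square numeric matrix of positive ratios.
#' @param labels element names; defaults to rownames or `e1..en`.
#' @param reciprocity_tol relative tolerance on `x[i,j] * x[j,i] - 1`.
#' @return An object of class `judgment_matrix`.
#' @examples
#' judgment_matrix(matrix(c(1, 2, 1/2, 1), 2, 2, byrow = TRUE),
#'                 labels = c("beds", "staff"))
#' @export
judgment_matrix <- function(x, labels = NULL, reciprocity_tol = 1e-3) {
  .assert(is.matrix(x) && nrow(x) == ncol(x) && nrow(x) >= 2,
          "judgment matrix must be square with n >= 2")
  .assert(is.numeric(x) && all(is.finite(x)) && all(x > 0),
          "judgment matrix entries must be positive finite numbers")
  n <- nrow(x)
  .assert(all(diag(x) == 1), "judgment matrix diagonal must be exactly 1")
  scale_eps <- 1e-6
  .assert(all(x > 1 / 9 - scale_eps & x < 9 + scale_eps),
          "judgment matrix entries must lie on the 1/9..9 scale")
  recip <- x * t(x)
  .assert(max(abs(recip - 1)) <= reciprocity_tol,
          "judgment matrix is not reciprocal within tolerance %g (max dev %g)",
          reciprocity_tol, max(abs(recip - 1)))
  if (is.null(labels)) labels <- rownames(x)
  if (is.null(labels)) labels <- paste0("e", seq_len(n))
  .assert(length(labels) == n && !anyDuplicated(labels),
          "labels must be %d distinct names", n)
  dimnames(x) <- list(labels, labels)
  structure(list(labels = labels, x = x, n = n), class = "judgment_matrix")
}

#' @export
print.judgment_matrix <- function(x, ...) {
  cat(sprintf("judgment_matrix: %d x %d\n", x$n, x$n))
  print(round(x$x, 4))
  invisible(x)
}

#' Read a judgment matrix from a labeled CSV
#'
#' Square CSV whose header row and first column carry the element labels.
#'
#' @param path CSV path.
#' @param ... passed to [judgment_matrix()].
#' @return A [judgment_matrix()].
#' @export
read_judgment_matrix <- function(path, ...) {
  df <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                 check.names = FALSE)
  labels <- .trim(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  judgment_matrix(m, labels = labels, ...)
}

# Saaty's random consistency index, orders 1..10.
saaty_ri <- c(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45, 1.49)

#' Derive priority weights from a judgment matrix
#'
#' The default `sum_product` method normalizes each column to sum one,
#' averages across rows, and renormalizes; the principal eigenvalue
#' `lambda_max` is then estimated as the mean of the componentwise Rayleigh
#' ratios `(X w)_i / w_i`. The `power_iteration` method computes the
#' dominant eigenpair directly (to 1e-12) and serves as an independent
#' cross-check; for near-consistent matrices the two agree closely.
#'
#' @param m a [judgment_matrix()].
#' @param method `"sum_product"` (default) or `"power_iteration"`.
#' @return An object of class `ahp_result`: list with `weights` (named,
#'   summing to 1), `lambda_max`, `CI`, `RI`, `CR`, `consistent`
#'   (CR < 0.1), `n`, `method`.
#' @examples
#' m <- judgment_matrix(matrix(c(1, 1, 1, 1, 1, 1, 1, 1, 1), 3, 3))
#' derive_weights(m)$weights     # 1/3 each
#' @export
derive_weights <- function(m, method = c("sum_product", "power_iteration")) {
  .assert(inherits(m, "judgment_matrix"),
          "m must be a judgment_matrix (see judgment_matrix())")
  method <- match.arg(method)
  x <- m$x
  n <- m$n
  if (method == "sum_product") {
    colnorm <- sweep(x, 2, colSums(x), "/")
    w <- rowMeans(colnorm)
    w <- w / sum(w)
    lambda_max <- mean((x %*% w) / w)
  } else {
    w <- rep(1 / n, n)
    for (iter in seq_len(10000L)) {
      v <- as.vector(x %*% w)
      v <- v / sum(v)
      if (max(abs(v - w)) < 1e-14) { w <- v; break }
      w <- v
    }
    lambda_max <- mean((x %*% w) / w)
  }
  cons <- consistency_check(lambda_max, n)
  structure(
    list(weights = setNames(as.vector(w), m$labels),
         lambda_max = lambda_max, CI = cons$CI, RI = cons$RI, CR = cons$CR,
         consistent = cons$consistent, n = n, method = method),
    class = "ahp_result"
  )
}

#' @export
print.ahp_result <- function(x, ...) {
  cat(sprintf("ahp_result (%s): n = %d\n", x$method, x$n))
  print(round(x$weights, 4))
  cat(sprintf("lambda_max = %.6f, CI = %.6f, CR = %.6f -> %s\n",
              x$lambda_max, x$CI, x$CR,
              if (x$consistent) "consistent (CR < 0.1)" else
                "NOT consistent (CR >= 0.1)"))
  invisible(x)
}

#' Consistency test for a judgment matrix
#'
#' Computes `CI = (lambda_max - n) / (n - 1)` and `CR = CI / RI` against
#' Saaty's random index; a matrix is accepted when `CR < 0.1`. Orders 1 and
#' 2 are always consistent (RI = 0), so CI and CR are defined as 0 there.
#'
#' @param lambda_max principal eigenvalue estimate, or an `ahp_result`.
#' @param n matrix order (taken from the `ahp_result` if one is given).
#' @param ri optional random-index value overriding the packaged table
#'   (required for n > 10).
#' @return list with `CI`, `RI`, `CR`, `consistent`.
#' @export
consistency_check <- function(lambda_max, n = NULL, ri = NULL) {
  if (inherits(lambda_max, "ahp_result")) {
    n <- lambda_max$n
    lambda_max <- lambda_max$lambda_max
  }
  .assert(is.numeric(n) && n >= 2, "n must be an integer >= 2")
  n <- as.integer(n)
  if (n <= 2L) {
    return(list(CI = 0, RI = 0, CR = 0, consistent = TRUE))
  }
  if (is.null(ri)) {
    .assert(n <= length(saaty_ri),
            paste("no packaged random index for n = %d;",
                  "supply ri= for orders above 10"), n)
    ri <- saaty_ri[n]
  }
  CI <- (lambda_max - n) / (n - 1)
  CR <- CI / ri
  list(CI = CI, RI = ri, CR = CR, consistent = CR < 0.1)
}

#' Hierarchical weight tree
#'
#' Combines secondary-level weights (one per indicator group) with local
#' tertiary weights (per indicator, within its group) into global tertiary
#' weights `global = secondary x local`. By construction the global weights
#' of a group sum to that group's secondary weight, and all global weights
#' sum to one.
#'
#' @param secondary named numeric vector of group weights summing to 1.
#' @param local named list (one element per group, same names) of named
#'   numeric vectors each summing to 1.
#' @return An object of class `weight_tree` with elements `secondary`,
#'   `local`, `global` (named by indicator), `groups` (named character
#'   vector indicator -> group).
#' @export
weight_tree <- function(secondary, local) {
  .assert(is.numeric(secondary) && !is.null(names(secondary)),
          "secondary must be a named numeric vector")
  .assert(abs(sum(secondary) - 1) < 1e-9, "secondary weights must sum to 1")
  .assert(all(secondary > 0), "secondary weights must be positive")
  .assert(is.list(local) && setequal(names(local), names(secondary)),
          "local must be a list with one element per secondary group")
  global <- numeric(0)
  groups <- character(0)
  for (g in names(secondary)) {
    lw <- local[[g]]
    .assert(is.numeric(lw) && !is.null(names(lw)) && all(lw > 0),
            "local weights for group %s must be a named positive vector", g)
    .assert(abs(sum(lw) - 1) < 1e-9,
            "local weights for group %s must sum to 1", g)
    global <- c(global, secondary[[g]] * lw)
    groups <- c(groups, setNames(rep(g, length(lw)), names(lw)))
  }
  .assert(!anyDuplicated(names(global)),
          "an indicator appears in more than one group")
  .assert(abs(sum(global) - 1) < 1e-9, "global weights must sum to 1")
  structure(list(secondary = secondary, local = local, global = global,
                 groups = groups),
            class = "weight_tree")
}

#' @export
print.weight_tree <- function(x, ...) {
  cat(sprintf("weight_tree: %d groups, %d indicators\n",
              length(x$secondary), length(x$global)))
  for (g in names(x$secondary)) {
    cat(sprintf("  %s (%.4f):\n", g, x$secondary[[g]]))
    idx <- names(x$groups)[x$groups == g]
    for (i in idx) cat(sprintf("    %-40s %.4f\n", i, x$global[[i]]))
  }
  invisible(x)
}

#' Build a weight tree from judgment matrices at both levels
#'
#' Derives secondary weights from `secondary_m` and local tertiary weights
#' from one judgment matrix per group, refusing if any matrix fails the
#' CR < 0.1 consistency test (the matrix must then be adjusted by the
#' analyst, not patched by software).
#'
#' @param secondary_m [judgment_matrix()] over the groups.
#' @param tertiary_ms named list of [judgment_matrix()], names matching the
#'   labels of `secondary_m`; each matrix's labels are the indicator ids of
#'   that group.
#' @param method weight-derivation method, see [derive_weights()].
#' @return A [weight_tree()].
#' @export
build_weight_tree <- function(secondary_m, tertiary_ms,
                              method = c("sum_product", "power_iteration")) {
  method <- match.arg(method)
  .assert(inherits(secondary_m, "judgment_matrix"),
          "secondary_m must be a judgment_matrix")
  .assert(is.list(tertiary_ms) &&
            setequal(names(tertiary_ms), secondary_m$labels),
          "tertiary_ms must be a named list covering exactly the groups: %s",
          paste(secondary_m$labels, collapse = ", "))
  sec <- derive_weights(secondary_m, method = method)
  .assert(sec$consistent,
          "secondary judgment matrix fails consistency: CR = %.4f >= 0.1 (adjust the matrix)",
          sec$CR)
  local <- list()
  for (g in secondary_m$labels) {
    tm <- tertiary_ms[[g]]
    .assert(inherits(tm, "judgment_matrix"),
            "tertiary_ms[['%s']] must be a judgment_matrix", g)
    res <- derive_weights(tm, method = method)
    .assert(res$consistent,
            "tertiary judgment matrix for group '%s' fails consistency: CR = %.4f >= 0.1 (adjust the matrix)",
            g, res$CR)
    local[[g]] <- res$weights
  }
  weight_tree(sec$weights, local)
}
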