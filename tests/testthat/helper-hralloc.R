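# shared builders for tiny in-code fixtures

# complete unit x year x indicator panel from a value function
tiny_panel <- function(units = c("a", "b", "c"), years = 2010:2011,
                       indicators = c("i1", "i2"),
                       orientation = rep("positive", length(indicators)),
                       groups = rep("G", length(indicators)),
                       value_fn = function(u, y, i) {
                         match(u, units) + 0.1 * match(i, indicators)
                       }) {
  grid <- expand.grid(unit = units, year = years, indicator = indicators,
                      stringsAsFactors = FALSE)
  grid$value <- mapply(value_fn, grid$unit, grid$year, grid$indicator)
  meta <- data.frame(indicator = indicators, orientation = orientation,
                     group = groups, stringsAsFactors = FALSE)
  indicator_panel(grid, meta)
}

# fully consistent judgment matrix built from a priority vector
consistent_matrix <- function(v, labels = NULL) {
  judgment_matrix(outer(v, v, "/"), labels = labels)
}

# random near-consistent judgment matrix: ratio structure times small
# multiplicative perturbations on the upper triangle
random_near_consistent <- function(n, jitter = 0.05) {
  v <- exp(runif(n, -0.5, 0.5))
  x <- outer(v, v, "/")
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      f <- exp(rnorm(1, 0, jitter))
      x[i, j] <- x[i, j] * f
      x[j, i] <- 1 / x[i, j]
    }
  }
  judgment_matrix(pmin(pmax(x, 1 / 9 + 1e-6), 9 - 1e-6), reciprocity_tol = 1)
}

# random connected binary weights via a spanning path plus random extra edges
random_connected_weights <- function(n, extra = n) {
  w <- matrix(0, n, n)
  ord <- sample(n)
  for (k in seq_len(n - 1)) {
    w[ord[k], ord[k + 1]] <- 1
    w[ord[k + 1], ord[k]] <- 1
  }
  for (k in seq_len(extra)) {
    ij <- sample(n, 2)
    w[ij[1], ij[2]] <- 1
    w[ij[2], ij[1]] <- 1
  }
  diag(w) <- 0
  spatial_weights(w, sprintf("u%02d", seq_len(n)), mode = "binary")
}

# equal-weight tree over a panel's metadata
equal_tree <- function(panel) {
  groups <- unique(panel$meta$group)
  sec <- stats::setNames(rep(1 / length(groups), length(groups)), groups)
  local <- lapply(stats::setNames(groups, groups), function(g) {
    ind <- panel$meta$indicator[panel$meta$group == g]
    stats::setNames(rep(1 / length(ind), length(ind)), ind)
  })
  weight_tree(sec, local)
}
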