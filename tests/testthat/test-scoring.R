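test_that("min-max normalization maps endpoints and flips negatives", {
  p <- tiny_panel(units = c("a", "b", "c"), years = 2010L,
                  indicators = c("pos", "neg"),
                  orientation = c("positive", "negative"),
                  value_fn = function(u, y, i) c(a = 2, b = 4, c = 6)[u])
  np <- normalize_panel(p)
  d <- np$data
  expect_equal(d$d[d$indicator == "pos"][order(d$unit[d$indicator == "pos"])],
               c(0, 0.5, 1))
  expect_equal(d$d[d$indicator == "neg"][order(d$unit[d$indicator == "neg"])],
               c(1, 0.5, 0))
})

test_that("constant indicators and incomplete panels are rejected", {
  p <- tiny_panel(value_fn = function(u, y, i)
    if (i == "i1") 5 else match(u, c("a", "b", "c")))
  expect_error(normalize_panel(p), "i1")
  p2 <- tiny_panel()
  p2inc <- indicator_panel(p2$data[-1, ], p2$meta)
  expect_error(normalize_panel(p2inc), "rectangular")
})

test_that("per-year scope uses within-year extrema", {
  p <- tiny_panel(units = c("a", "b"), years = 2010:2011,
                  indicators = "i1",
                  value_fn = function(u, y, i) {
                    (if (u == "a") 1 else 2) * (if (y == 2010) 1 else 10)
                  })
  np <- normalize_panel(p, scope = "per_year")
  expect_equal(sort(unique(np$data$d)), c(0, 1))
  pooled <- normalize_panel(p, scope = "pooled")
  # pooled extrema are 1..20, so the 2010 values stay near the bottom
  expect_true(all(pooled$data$d[pooled$data$year == 2010] < 0.1))
})

test_that("composite scores aggregate weighted normalized values", {
  tr <- reference_weight_tree()
  ind <- names(tr$global)
  # two units: one at every pooled max, one at every pooled min
  p <- tiny_panel(units = c("lo", "hi"), years = 2021L, indicators = ind,
                  groups = unname(tr$groups[ind]),
                  value_fn = function(u, y, i) if (u == "hi") 10 else 0)
  sc <- composite_score(normalize_panel(p), tr)
  hi <- sc[sc$unit == "hi", ]
  lo <- sc[sc$unit == "lo", ]
  expect_equal(hi$Z, 1)
  expect_equal(lo$Z, 0)
  expect_equal(unname(unlist(hi[paste0("Z_", c("HF", "HP", "HB"))])),
               c(0.3324, 0.3596, 0.3080))
  # Z always equals the sum of the sub-scores
  expect_equal(sc$Z, unname(rowSums(sc[grep("^Z_", names(sc))])))
})

test_that("two-indicator hand example gives Z = 0.4", {
  tr <- weight_tree(c(G1 = 0.6, G2 = 0.4),
                    list(G1 = c(x = 1), G2 = c(y = 1)))
  # three units spread so that unit b has d = (0.5, 0.25)
  p <- tiny_panel(units = c("a", "b", "c"), years = 2020L,
                  indicators = c("x", "y"), groups = c("G1", "G2"),
                  value_fn = function(u, y, i) {
                    v <- list(a = c(x = 0, y = 0), b = c(x = 2, y = 1),
                              c = c(x = 4, y = 4))
                    v[[u]][[i]]
                  })
  sc <- composite_score(normalize_panel(p), tr)
  expect_equal(sc$Z[sc$unit == "b"], 0.6 * 0.5 + 0.4 * 0.25)
})

test_that("weight/indicator mismatches are errors", {
  p <- tiny_panel()
  tr <- weight_tree(c(G = 1), list(G = c(i1 = 0.5, i3 = 0.5)))
  expect_error(composite_score(normalize_panel(p), tr), "i3")
})

test_that("raising a positive indicator never lowers Z (monotonicity)", {
  set.seed(21)
  p <- tiny_panel(units = letters[1:5], years = 2010L,
                  indicators = c("i1", "i2"),
                  value_fn = function(u, y, i) runif(1, 1, 9))
  tr <- equal_tree(p)
  base <- composite_score(normalize_panel(p), tr)
  d2 <- p$data
  # move one interior value up without touching the extrema
  sel <- which(d2$indicator == "i1")
  mid <- sel[which(rank(d2$value[sel]) == 3)]
  d2$value[mid] <- d2$value[mid] + 0.5 * (max(d2$value[sel]) - d2$value[mid])
  bumped <- composite_score(normalize_panel(indicator_panel(d2, p$meta)), tr)
  u <- d2$unit[mid]
  expect_gte(bumped$Z[bumped$unit == u], base$Z[base$unit == u])
  others <- setdiff(letters[1:5], u)
  expect_equal(bumped$Z[bumped$unit %in% others],
               base$Z[base$unit %in% others])
})

test_that("Z is invariant to constant shifts of an indicator and to unit order", {
  set.seed(22)
  p <- tiny_panel(units = letters[1:4], years = 2010:2012,
                  value_fn = function(u, y, i) runif(1, 1, 9))
  tr <- equal_tree(p)
  base <- composite_score(normalize_panel(p), tr)
  shifted <- p$data
  shifted$value[shifted$indicator == "i1"] <-
    shifted$value[shifted$indicator == "i1"] + 100
  sc2 <- composite_score(normalize_panel(indicator_panel(shifted, p$meta)),
                         tr)
  expect_equal(sc2$Z, base$Z, tolerance = 1e-12)

  perm <- p$data[sample(nrow(p$data)), ]
  sc3 <- composite_score(normalize_panel(indicator_panel(perm, p$meta)), tr)
  expect_equal(sc3, base)
})

test_that("regional means average units and recover planted effects", {
  part <- region_partition(c(a = "g1", b = "g2", c = "g2"))
  p <- tiny_panel(units = c("a", "b", "c"), years = 2010L,
                  value_fn = function(u, y, i) match(u, c("a", "b", "c")))
  sc <- composite_score(normalize_panel(p), equal_tree(p))
  sm <- summarize_by_region(sc, part)
  expect_equal(sm$region_year$mean_Z[sm$region_year$region == "g1"],
               sc$Z[sc$unit == "a"])
  expect_equal(sm$region_year$mean_Z[sm$region_year$region == "g2"],
               mean(sc$Z[sc$unit %in% c("b", "c")]))
  expect_equal(sm$year_summary$mean_of_region_means,
               mean(sm$region_year$mean_Z))

  # a planted region effect shows up in the regional mean gap
  cfg <- synthetic_config(
    n_units = 20, group_sizes = c(hi = 10, lo = 10),
    region_effects = c(hi = 0.5, lo = 0), trend = 0, rho = 0,
    noise_sd = 0.02, n_indicators = 3, n_years = 2, seed = 99)
  gen <- generate_panel(cfg)
  sc2 <- composite_score(normalize_panel(gen$panel), equal_tree(gen$panel))
  sm2 <- summarize_by_region(sc2, gen$partition)
  gap <- with(sm2$region_year,
              mean(mean_Z[region == "hi"]) - mean(mean_Z[region == "lo"]))
  expect_gt(gap, 0.5)  # on the normalized scale the planted gap dominates
})
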