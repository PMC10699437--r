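#' Indicator panel: unit x year x indicator observations with metadata
#'
#' An `indicator_panel` holds a tidy long panel of raw indicator values plus
#' per-indicator metadata: the orientation (`"positive"` means larger is
#' better, `"negative"` means smaller is better) and the secondary-indicator
#' group the indicator belongs to. Scoring requires a rectangular panel
#' (every unit x year x indicator combination present); completeness is
#' checked at construction and reported in the `completeness` element.
#'
#' @param data data.frame with columns `unit`, `year`, `indicator`, `value`.
#' @param meta data.frame with columns `indicator`, `orientation`
#'   (`"positive"` or `"negative"`), `group`.
#' @return An object of class `indicator_panel`: a list with elements
#'   `data` (the validated observations), `meta`, `units`, `years`,
#'   `indicators`, `complete` (logical) and `completeness` (a data.frame of
#'   missing combinations, zero rows when complete).
#' @examples
#' obs <- expand.grid(unit = c("a", "b"), year = 2010:2011,
#'                    indicator = "beds", stringsAsFactors = FALSE)
#' obs$value <- 1:4
#' meta <- data.frame(indicator = "beds", orientation = "positive",
#'                    group = "HB")
#' p <- indicator_panel(obs, meta)
#' p$complete
#' @export
indicator_panel <- function(data, meta) {
  need <- c("unit", "year", "indicator", "value")
  .assert(is.data.frame(data) && all(need %in% names(data)),
          "panel data must have columns %s", paste(need, collapse = ", "))
  need_m <- c("indicator", "orientation", "group")
  .assert(is.data.frame(meta) && all(need_m %in% names(meta)),
          "indicator metadata must have columns %s",
          paste(need_m, collapse = ", "))

  data <- data.frame(
    unit = .trim(data$unit),
    year = as.integer(data$year),
    indicator = .trim(data$indicator),
    value = as.numeric(data$value),
    stringsAsFactors = FALSE
  )
  .assert(!anyNA(data$year), "panel contains non-integer year values")
  .assert(!anyNA(data$value), "panel contains missing or non-numeric values")

  key <- paste(data$unit, data$year, data$indicator, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    first <- data[which(dup)[1L], ]
    stop(sprintf("duplicate (unit, year, indicator) key: (%s, %d, %s)",
                 first$unit, first$year, first$indicator), call. = FALSE)
  }

  meta <- data.frame(
    indicator = .trim(meta$indicator),
    orientation = .trim(meta$orientation),
    group = .trim(meta$group),
    stringsAsFactors = FALSE
  )
  bad <- setdiff(unique(meta$orientation), c("positive", "negative"))
  .assert(length(bad) == 0L,
          "unknown orientation token(s): %s (use 'positive' or 'negative')",
          paste(bad, collapse = ", "))
  .assert(!anyDuplicated(meta$indicator),
          "duplicated indicator in metadata: %s",
          paste(meta$indicator[duplicated(meta$indicator)], collapse = ", "))

  indicators <- sort(unique(data$indicator))
  missing_meta <- setdiff(indicators, meta$indicator)
  .assert(length(missing_meta) == 0L,
          "indicator(s) without metadata: %s",
          paste(missing_meta, collapse = ", "))
  meta <- meta[match(indicators, meta$indicator), , drop = FALSE]
  rownames(meta) <- NULL

  units <- sort(unique(data$unit))
  years <- sort(unique(data$year))
  grid <- expand.grid(unit = units, year = years, indicator = indicators,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  gkey <- paste(grid$unit, grid$year, grid$indicator, sep = "\r")
  missing <- grid[!gkey %in% key, , drop = FALSE]
  rownames(missing) <- NULL

  structure(
    list(data = data, meta = meta, units = units, years = years,
         indicators = indicators, complete = nrow(missing) == 0L,
         completeness = missing),
    class = "indicator_panel"
  )
}

#' @export
print.indicator_panel <- function(x, ...) {
  cat(sprintf(
    "indicator_panel: %d units x %d years x %d indicators (%d observations)\n",
    length(x$units), length(x$years), length(x$indicators), nrow(x$data)))
  cat(sprintf("  complete: %s", if (x$complete) "yes" else
    sprintf("no (%d missing combinations)", nrow(x$completeness))), "\n")
  invisible(x)
}

#' Read a tidy indicator panel from CSV
#'
#' The panel file must be long-format CSV with columns
#' `unit,year,indicator,value` (UTF-8, '.' decimal); wide layouts are
#' rejected. The metadata file has columns `indicator,orientation,group`.
#'
#' @param path path to the panel CSV.
#' @param meta_path path to the indicator metadata CSV.
#' @return An [indicator_panel()].
#' @export
read_panel <- function(path, meta_path) {
  data <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  meta <- read.csv(meta_path, stringsAsFactors = FALSE, comment.char = "#")
  indicator_panel(data, meta)
}

# region partition ------------------------------------------------------------

#' Region partition: assignment of units to regions
#'
#' @param assignment named character vector mapping `unit -> group`, or a
#'   data.frame with columns `unit`, `group`.
#' @param group_order optional stable ordering of group ids; defaults to
#'   first-appearance order.
#' @return An object of class `region_partition` with elements `assignment`
#'   (named character vector), `groups` (ordered group ids) and `sizes`.
#' @examples
#' region_partition(c(a = "north", b = "north", c = "south"))
#' @export
region_partition <- function(assignment, group_order = NULL) {
  if (is.data.frame(assignment)) {
    .assert(all(c("unit", "group") %in% names(assignment)),
            "partition data.frame needs columns unit, group")
    assignment <- setNames(.trim(assignment$group), .trim(assignment$unit))
  }
  .assert(is.character(assignment) && !is.null(names(assignment)),
          "assignment must be a named character vector or data.frame")
  dup <- names(assignment)[duplicated(names(assignment))]
  .assert(length(dup) == 0L, "unit assigned more than once: %s",
          paste(unique(dup), collapse = ", "))
  groups <- if (is.null(group_order)) unique(unname(assignment)) else
    .trim(group_order)
  .assert(setequal(groups, unique(assignment)),
          "group_order does not match the groups present in the assignment")
  sizes <- vapply(groups, function(g) sum(assignment == g), integer(1))
  .assert(all(sizes > 0L), "empty group(s): %s",
          paste(groups[sizes == 0L], collapse = ", "))
  structure(list(assignment = assignment, groups = groups, sizes = sizes),
            class = "region_partition")
}

#' @export
print.region_partition <- function(x, ...) {
  cat(sprintf("region_partition: %d units in %d groups (%s)\n",
              length(x$assignment), length(x$groups),
              paste(sprintf("%s=%d", x$groups, x$sizes), collapse = ", ")))
  invisible(x)
}

#' Read a unit-to-region partition from CSV
#'
#' @param path CSV with columns `unit,group`.
#' @param units optional character vector of units that must all be covered
#'   (e.g. the panel's units); an unassigned unit is an error.
#' @return A [region_partition()].
#' @export
read_partition <- function(path, units = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  part <- region_partition(df)
  if (!is.null(units)) {
    missing <- setdiff(.trim(units), names(part$assignment))
    .assert(length(missing) == 0L, "unit(s) not assigned to any region: %s",
            paste(missing, collapse = ", "))
  }
  part
}

# spatial weights -------------------------------------------------------------

#' Spatial weights matrix
#'
#' Wraps a nonnegative square weights matrix over an ordered unit list.
#' Binary-mode matrices must be symmetric with zero diagonal; in
#' row-standardized mode every row with at least one neighbor sums to one.
#' Units with no neighbors (islands) are allowed and flagged: their local
#' statistics are undefined rather than silently zero.
#'
#' @param w square numeric matrix.
#' @param units character vector of unit ids, one per row/column.
#' @param mode `"binary"` or `"row_standardized"`.
#' @return An object of class `spatial_weights` with elements `units`, `w`,
#'   `mode`, `S0` (sum of all weights) and `islands` (units with no
#'   neighbors).
#' @export
spatial_weights <- function(w, units, mode = c("binary", "row_standardized")) {
  mode <- match.arg(mode)
  units <- .trim(units)
  .assert(is.matrix(w) && nrow(w) == ncol(w), "w must be a square matrix")
  .assert(length(units) == nrow(w), "units must match the matrix dimension")
  .assert(!anyDuplicated(units), "duplicated unit ids in spatial weights")
  .assert(all(w >= 0), "spatial weights must be nonnegative")
  .assert(all(diag(w) == 0), "spatial weights must have a zero diagonal")
  if (mode == "binary") {
    .assert(isTRUE(all.equal(w, t(w), tolerance = 1e-12)),
            "binary spatial weights must be symmetric")
  } else {
    rs <- rowSums(w)
    live <- rs > 0
    .assert(all(abs(rs[live] - 1) < 1e-9),
            "row_standardized weights: rows with neighbors must sum to 1")
  }
  S0 <- sum(w)
  .assert(S0 > 0, "all-zero spatial weights matrix (S0 = 0)")
  islands <- units[rowSums(w) == 0 & colSums(w) == 0]
  dimnames(w) <- list(units, units)
  structure(list(units = units, w = w, mode = mode, S0 = S0,
                 islands = islands),
            class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat(sprintf("spatial_weights: %d units, mode %s, S0 = %g",
              length(x$units), x$mode, x$S0))
  if (length(x$islands)) cat(sprintf(", %d island(s)", length(x$islands)))
  cat("\n")
  invisible(x)
}

#' Row-standardize a spatial weights matrix
#'
#' Divides each row with at least one neighbor by its row sum; the
#' zero/nonzero pattern is preserved and islands stay all-zero.
#'
#' @param sw a [spatial_weights()] object.
#' @return A `spatial_weights` object in `row_standardized` mode.
#' @export
row_standardize <- function(sw) {
  .assert(inherits(sw, "spatial_weights"), "sw must be spatial_weights")
  w <- sw$w
  rs <- rowSums(w)
  live <- rs > 0
  w[live, ] <- w[live, , drop = FALSE] / rs[live]
  spatial_weights(w, sw$units, mode = "row_standardized")
}

#' Read spatial weights from a GAL file or an edge-list CSV
#'
#' GAL is GeoDa's plain-text adjacency list: a header line whose last-but-two
#' token is the number of units, then for each unit a line `id k` followed by
#' a line with its `k` neighbor ids. The edge-list CSV has columns
#' `unit_a,unit_b` and an optional `weight`. Both encode an undirected graph;
#' the binary matrix is symmetrized from the listed links.
#'
#' @param path input file.
#' @param format `"gal"` or `"edge_list"`.
#' @param mode `"binary"` (default) or `"row_standardized"`.
#' @param units optional master unit list: link units outside it are an
#'   error, and the matrix is ordered (and padded with islands) to match.
#' @return A [spatial_weights()] object.
#' @export
read_spatial_weights <- function(path, format = c("gal", "edge_list"),
                                 mode = c("binary", "row_standardized"),
                                 units = NULL) {
  format <- match.arg(format)
  mode <- match.arg(mode)
  if (format == "gal") {
    built <- .parse_gal(path)
  } else {
    df <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
    .assert(ncol(df) >= 2, "edge list needs columns unit_a, unit_b[, weight]")
    built <- list(
      edges = data.frame(a = .trim(df[[1]]), b = .trim(df[[2]]),
                         weight = if (ncol(df) >= 3) as.numeric(df[[3]]) else 1,
                         stringsAsFactors = FALSE),
      units = NULL
    )
  }
  edges <- built$edges
  .assert(all(edges$a != edges$b), "self-loop in spatial links: %s",
          paste(unique(edges$a[edges$a == edges$b]), collapse = ", "))
  link_units <- unique(c(edges$a, edges$b))
  if (is.null(units)) {
    units <- if (!is.null(built$units)) built$units else sort(link_units)
  } else {
    units <- .trim(units)
    unknown <- setdiff(link_units, units)
    .assert(length(unknown) == 0L,
            "spatial link names unit(s) absent from the unit list: %s",
            paste(unknown, collapse = ", "))
  }
  n <- length(units)
  w <- matrix(0, n, n, dimnames = list(units, units))
  ia <- match(edges$a, units)
  ib <- match(edges$b, units)
  w[cbind(ia, ib)] <- edges$weight
  w[cbind(ib, ia)] <- edges$weight
  sw <- spatial_weights(w, units, mode = "binary")
  if (length(sw$islands)) {
    message("isolated unit(s) with no neighbors: ",
            paste(sw$islands, collapse = ", "))
  }
  if (mode == "row_standardized") sw <- row_standardize(sw) else sw
}

.parse_gal <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  .assert(length(lines) >= 1, "empty GAL file")
  head_tok <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  # header is either "n" or "0 n shapefile var"; n is the count of units
  n <- if (length(head_tok) == 1) as.integer(head_tok) else
    as.integer(head_tok[2])
  .assert(!is.na(n) && n > 0, "cannot parse GAL header: %s", lines[1])
  units <- character(n)
  edges_a <- character(0); edges_b <- character(0)
  i <- 2L
  for (k in seq_len(n)) {
    .assert(i <= length(lines), "truncated GAL file at record %d", k)
    rec <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    .assert(length(rec) == 2, "malformed GAL record line: %s", lines[i])
    id <- rec[1]
    deg <- as.integer(rec[2])
    units[k] <- id
    i <- i + 1L
    if (deg > 0) {
      .assert(i <= length(lines), "truncated GAL neighbors for unit %s", id)
      nb <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      .assert(length(nb) == deg,
              "GAL unit %s declares %d neighbors but lists %d",
              id, deg, length(nb))
      edges_a <- c(edges_a, rep(id, deg))
      edges_b <- c(edges_b, nb)
      i <- i + 1L
    }
  }
  # keep each undirected link once; symmetry restored when the matrix is built
  key <- ifelse(edges_a < edges_b, paste(edges_a, edges_b),
                paste(edges_b, edges_a))
  keep <- !duplicated(key)
  list(edges = data.frame(a = edges_a[keep], b = edges_b[keep], weight = 1,
                          stringsAsFactors = FALSE),
       units = units)
}

# results writing -------------------------------------------------------------

#' Write result tables as CSV with a run-metadata header
#'
#' Each table is written as `<name>.csv` in `out_dir`, preceded by `#`
#' comment lines recording the seed and a config hash so a results directory
#' is self-describing. Column order is preserved as given.
#'
#' @param tables named list of data.frames.
#' @param out_dir output directory (created if needed).
#' @param seed integer seed recorded in the header (NA if none used).
#' @param config_hash short string identifying the run configuration.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(tables, out_dir, seed = NA_integer_,
                          config_hash = "") {
  .assert(is.list(tables) && length(names(tables)) == length(tables),
          "tables must be a named list of data.frames")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tables)) {
    df <- as.data.frame(tables[[nm]])
    path <- file.path(out_dir, paste0(nm, ".csv"))
    con <- file(path, open = "wt")
    writeLines(c(sprintf("# hralloc results: %s", nm),
                 sprintf("# seed: %s", seed),
                 sprintf("# config_hash: %s", config_hash)), con)
    write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
    close(con)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read back a results CSV written by [write_results()]
#'
#' @param path CSV path; `#` header lines are skipped.
#' @return data.frame.
#' @export
read_results <- function(path) {
  read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
}

# Polynomial rolling hash over the serialized config; stable across runs.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
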