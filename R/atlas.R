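#' midgutclones: clonal lineage simulation and compartment statistics for the
#' Drosophila midgut
#'
#' The adult Drosophila midgut is an ordered series of subregions
#' (A1--A3, Cu, LFC, Fe, P1--P4) maintained by intestinal stem cells (ISCs).
#' This package provides (i) a region atlas mapping anterior--posterior lattice
#' positions to subregions and zones, (ii) a stochastic simulator of marked ISC
#' clones on a cylindrical epithelial lattice with per-boundary crossing
#' permissions, (iii) boundary-clone scoring and compartmentalization
#' statistics (crossing fractions, a binomial all-fail null, expected-crossing
#' chi-square tests), (iv) division-rate estimation from clone-size time
#' courses, and (v) a regional fold-change enrichment screen for fpkm
#' expression matrices, together with synthetic-data generators and a packaged
#' clonal-analysis count table.
#'
#' @useDynLib midgutclones, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm rpois runif rbinom sd cor pchisq setNames
#' @importFrom utils read.delim write.table
#' @keywords internal
"_PACKAGE"

# Canonical subregion order and zone membership: anterior = A1-A3,
# middle = Cu/LFC/Fe, posterior = P1-P4.
MIDGUT_REGIONS <- c("A1", "A2", "A3", "Cu", "LFC", "Fe", "P1", "P2", "P3", "P4")
MIDGUT_ZONES <- c(
  A1 = "anterior", A2 = "anterior", A3 = "anterior",
  Cu = "middle", LFC = "middle", Fe = "middle",
  P1 = "posterior", P2 = "posterior", P3 = "posterior", P4 = "posterior"
)

#' Build a midgut region atlas
#'
#' Assembles an ordered anterior-to-posterior atlas of midgut subregions.
#' Each region occupies a half-open, 0-based interval of lattice rows along
#' the a/p axis, derived by cumulative sum of the region lengths (in
#' enterocyte cell diameters). Adjacent regions are separated by an internal
#' boundary carrying directional crossing permissions; by default every
#' boundary is blocked except LFC/Fe, which is open in both directions.
#'
#' @param regions data frame with columns `name`, `length_cells`, and
#'   optionally `zone` (`anterior`/`middle`/`posterior`; inferred for the
#'   canonical names), `division_rate` (ISC divisions per day),
#'   `ee_per_isc` and `ec_per_isc` (cell-type composition ratios).
#'   Missing rates/ratios default to 0 with a warning.
#' @param boundaries optional data frame of boundary overrides with columns
#'   `upstream`, `downstream`, `open_up_to_down`, `open_down_to_up`.
#' @return An object of class `region_atlas`: a list with elements
#'   `regions` (data frame with derived `start`/`end` row intervals),
#'   `boundaries` (one row per adjacent pair) and `n_rows`.
#' @examples
#' atlas <- build_atlas(data.frame(
#'   name = c("LFC", "Fe"), length_cells = c(5, 7),
#'   division_rate = c(0.3, 0.35), ee_per_isc = 0.5, ec_per_isc = 4.5
#' ))
#' locate(atlas, c(0, 4, 5, 11))
#' @export
build_atlas <- function(regions, boundaries = NULL) {
  regions <- as.data.frame(regions, stringsAsFactors = FALSE)
  if (nrow(regions) < 1L) stop("atlas needs at least one region")
  if (!all(c("name", "length_cells") %in% names(regions))) {
    stop("regions must have 'name' and 'length_cells' columns")
  }
  regions$name <- as.character(regions$name)
  if (anyDuplicated(regions$name)) {
    stop("duplicate region name: ",
         paste(unique(regions$name[duplicated(regions$name)]), collapse = ", "))
  }
  len <- regions$length_cells
  if (any(!is.finite(len)) || any(len < 1) || any(len != floor(len))) {
    stop("region lengths must be positive integers (cell diameters)")
  }
  if (is.null(regions$zone)) {
    zone <- unname(MIDGUT_ZONES[regions$name])
    if (anyNA(zone)) {
      stop("zone missing for region(s) with non-canonical names: ",
           paste(regions$name[is.na(zone)], collapse = ", "))
    }
    regions$zone <- zone
  }
  if (!all(regions$zone %in% c("anterior", "middle", "posterior"))) {
    stop("unknown zone label: ",
         paste(setdiff(regions$zone, c("anterior", "middle", "posterior")),
               collapse = ", "))
  }
  rate_cols <- c("division_rate", "ee_per_isc", "ec_per_isc")
  absent <- rate_cols[vapply(rate_cols, function(col)
    is.null(regions[[col]]), logical(1))]
  if (length(absent)) {
    warning("unspecified, defaulting to 0 for all regions: ",
            paste(absent, collapse = ", "))
    for (col in absent) regions[[col]] <- 0
  }
  for (col in rate_cols) {
    bad <- !is.finite(regions[[col]]) | regions[[col]] < 0
    if (any(bad)) stop("'", col, "' must be finite and >= 0")
  }
  regions$end <- cumsum(regions$length_cells)
  regions$start <- regions$end - regions$length_cells

  n <- nrow(regions)
  if (n > 1L) {
    b <- data.frame(
      upstream = regions$name[-n],
      downstream = regions$name[-1L],
      open_up_to_down = FALSE,
      open_down_to_up = FALSE,
      stringsAsFactors = FALSE
    )
    # Empirical default: only the LFC/Fe border permits cross-regional
    # differentiation, in both directions.
    lf <- b$upstream == "LFC" & b$downstream == "Fe"
    b$open_up_to_down[lf] <- TRUE
    b$open_down_to_up[lf] <- TRUE
    if (!is.null(boundaries)) {
      boundaries <- as.data.frame(boundaries, stringsAsFactors = FALSE)
      for (i in seq_len(nrow(boundaries))) {
        j <- which(b$upstream == boundaries$upstream[i] &
                     b$downstream == boundaries$downstream[i])
        if (length(j) != 1L) {
          stop("boundary override names non-adjacent regions: ",
               boundaries$upstream[i], "/", boundaries$downstream[i])
        }
        if (!is.null(boundaries$open_up_to_down)) {
          b$open_up_to_down[j] <- isTRUE(boundaries$open_up_to_down[i])
        }
        if (!is.null(boundaries$open_down_to_up)) {
          b$open_down_to_up[j] <- isTRUE(boundaries$open_down_to_up[i])
        }
      }
    }
  } else {
    b <- data.frame(
      upstream = character(), downstream = character(),
      open_up_to_down = logical(), open_down_to_up = logical(),
      stringsAsFactors = FALSE
    )
  }
  structure(
    list(regions = regions, boundaries = b, n_rows = sum(regions$length_cells)),
    class = "region_atlas"
  )
}

#' Default ten-region midgut atlas
#'
#' The canonical A1...P4 atlas. Region lengths, division rates and cell-type
#' ratios are reported in the source study only graphically, so the values
#' here are documented placeholders chosen to match the qualitative pattern:
#' posterior ISCs divide about once per day, anterior ISCs slightly less
#' often, and middle-region ISCs much more slowly (copper-region ISCs about
#' every 4-5 days). Only the LFC/Fe boundary is open.
#'
#' @return A `region_atlas` with 10 regions and 9 internal boundaries.
#' @export
default_atlas <- function() {
  build_atlas(data.frame(
    name = MIDGUT_REGIONS,
    length_cells = c(30L, 30L, 20L, 20L, 10L, 12L, 25L, 20L, 20L, 25L),
    division_rate = c(0.6, 0.7, 0.6, 0.22, 0.3, 0.35, 1.0, 1.0, 1.0, 0.7),
    ee_per_isc = c(0.3, 0.4, 0.4, 0.5, 0.4, 0.4, 0.3, 0.3, 0.4, 0.4),
    ec_per_isc = c(5, 4, 4, 5, 5, 5, 4, 4, 4, 5),
    stringsAsFactors = FALSE
  ))
}

#' Read an atlas configuration from a YAML (or JSON-dialect) file
#'
#' The file must contain a `regions` list of maps with keys `name`,
#' `length_cells` and optionally `zone`, `division_rate`, `ee_per_isc`,
#' `ec_per_isc`, plus an optional `boundaries` list of maps with keys
#' `upstream`, `downstream`, `open_up_to_down`, `open_down_to_up`.
#'
#' @param path file path.
#' @return A `region_atlas`.
#' @export
read_atlas <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$regions)) stop("atlas config has no 'regions' entry")
  regions <- do.call(rbind, lapply(cfg$regions, function(r) {
    data.frame(
      name = r$name,
      length_cells = r$length_cells,
      zone = if (is.null(r$zone)) NA_character_ else r$zone,
      division_rate = if (is.null(r$division_rate)) 0 else r$division_rate,
      ee_per_isc = if (is.null(r$ee_per_isc)) 0 else r$ee_per_isc,
      ec_per_isc = if (is.null(r$ec_per_isc)) 0 else r$ec_per_isc,
      stringsAsFactors = FALSE
    )
  }))
  if (all(is.na(regions$zone))) regions$zone <- NULL
  boundaries <- NULL
  if (!is.null(cfg$boundaries)) {
    boundaries <- do.call(rbind, lapply(cfg$boundaries, function(b) {
      data.frame(
        upstream = b$upstream, downstream = b$downstream,
        open_up_to_down = isTRUE(b$open_up_to_down),
        open_down_to_up = isTRUE(b$open_down_to_up),
        stringsAsFactors = FALSE
      )
    }))
  }
  build_atlas(regions, boundaries)
}

#' Map lattice rows to region names
#'
#' Rows index the a/p axis, 0-based; each region occupies a half-open
#' interval, so the first row of a region belongs to it and the row just past
#' its last row belongs to the next region.
#'
#' @param atlas a `region_atlas`.
#' @param row integer vector of 0-based a/p positions.
#' @return Character vector of region names.
#' @export
locate <- function(atlas, row) {
  stopifnot(inherits(atlas, "region_atlas"))
  if (any(!is.finite(row)) || any(row < 0) || any(row >= atlas$n_rows)) {
    stop("row out of range [0, ", atlas$n_rows, ")")
  }
  idx <- findInterval(row, atlas$regions$start)
  atlas$regions$name[idx]
}

# Integer region index (1-based) per lattice row; internal.
region_index_of_rows <- function(atlas) {
  rep.int(seq_len(nrow(atlas$regions)), atlas$regions$length_cells)
}

# Validate that two region names form an adjacent pair; returns the boundary
# row index (first row of the downstream region) and the ordered pair.
boundary_cut <- function(atlas, boundary) {
  stopifnot(length(boundary) == 2L)
  rn <- atlas$regions$name
  i <- match(boundary[1L], rn)
  j <- match(boundary[2L], rn)
  if (is.na(i) || is.na(j)) stop("unknown region in boundary: ",
                                 paste(boundary, collapse = "/"))
  if (abs(i - j) != 1L) stop("regions are not adjacent: ",
                             paste(boundary, collapse = "/"))
  up <- min(i, j)
  list(upstream = rn[up], downstream = rn[up + 1L],
       cut_row = atlas$regions$end[up])
}

#' @export
print.region_atlas <- function(x, ...) {
  cat("Midgut region atlas:", nrow(x$regions), "regions,",
      nrow(x$boundaries), "internal boundaries,", x$n_rows, "rows (a/p)\n")
  r <- x$regions
  cat(sprintf("  %-4s %-9s [%3d,%3d)  rate %.2f/day  ee:ISC %.2f  EC:ISC %.2f\n",
              r$name, r$zone, r$start, r$end, r$division_rate,
              r$ee_per_isc, r$ec_per_isc), sep = "")
  open <- x$boundaries$open_up_to_down | x$boundaries$open_down_to_up
  if (any(open)) {
    cat("  open boundaries:",
        paste(x$boundaries$upstream[open], x$boundaries$downstream[open],
              sep = "/", collapse = ", "), "\n")
  }
  invisible(x)
}
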