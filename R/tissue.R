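# Cell-type codes shared with the compiled event loop.
CELL_TYPES <- c("ISC", "EC", "ee")

# Deterministic, evenly spaced picks of n_pick indices out of n_total
# (1-based). Used to spread ISCs (and ee's) over a region's sites so that
# stem cells are quasi-regularly distributed rather than clumped.
spread_indices <- function(n_pick, n_total) {
  if (n_pick <= 0L) return(integer())
  floor((seq_len(n_pick) - 0.5) * n_total / n_pick) + 1L
}

# Staggered near-square grid of ISC positions within a region of `len` rows
# by `circ` columns (1-based local site indices, row-major). Equal row and
# column spacings with alternate rows offset by half a column spacing, so
# ISCs are neither clumped nor vertically aligned (vertical alignment would
# wall off all axial daughter placement).
isc_grid <- function(n_isc, len, circ) {
  if (n_isc <= 0L) return(integer())
  g_r <- max(1L, min(len, as.integer(round(sqrt(n_isc * len / circ)))))
  g_c <- ceiling(n_isc / g_r)
  if (g_c > circ) {
    g_c <- circ
    g_r <- min(len, ceiling(n_isc / g_c))
  }
  rows <- spread_indices(g_r, len) - 1L
  cols <- spread_indices(g_c, circ) - 1L
  shift <- max(1L, (circ %/% g_c) %/% 2L)
  pos <- unlist(lapply(seq_along(rows), function(i) {
    rows[i] * circ + (cols + (i %% 2L) * shift) %% circ
  }))
  sort(pos[seq_len(n_isc)]) + 1L
}

# Largest-remainder apportionment of n sites among ISC/ee/EC given the
# per-ISC composition ratios.
apportion_cells <- function(n, ee_per_isc, ec_per_isc) {
  w <- c(ISC = 1, ee = ee_per_isc, EC = ec_per_isc)
  quota <- n * w / sum(w)
  counts <- floor(quota)
  short <- n - sum(counts)
  if (short > 0L) {
    take <- order(quota - counts, decreasing = TRUE)[seq_len(short)]
    counts[take] <- counts[take] + 1L
  }
  counts
}

#' Initialize a cylindrical midgut epithelium
#'
#' Fills every lattice site of a cylinder (`n_rows(atlas)` rows along the a/p
#' axis times `circumference` columns) with a typed cell. Within each region
#' the counts of ISCs, enteroendocrine cells and enterocytes satisfy the
#' configured `ee_per_isc` and `ec_per_isc` ratios under deterministic
#' largest-remainder rounding; ISCs (and ee's) are spread evenly over the
#' region's sites, so initialization is fully deterministic.
#'
#' @param atlas a `region_atlas` whose regions carry composition ratios.
#' @param circumference positive integer number of columns (>= 3).
#' @return An object of class `midgut_tissue`: lattice vectors `type`
#'   (1 = ISC, 2 = EC, 3 = ee), `lineage` (per-ISC progeny label), `clone`
#'   (0 = unlabeled), `birth` (days), laid out row-major (site = row *
#'   circumference + col, rows/cols 0-based), plus the atlas, dimensions,
#'   a founder table and the current `time`.
#' @export
initialize_epithelium <- function(atlas, circumference) {
  stopifnot(inherits(atlas, "region_atlas"))
  circumference <- as.integer(circumference)
  if (circumference < 3L) stop("circumference must be >= 3")
  n_rows <- atlas$n_rows
  n_sites <- n_rows * circumference
  type <- integer(n_sites)
  next_lineage <- 1L
  lineage <- integer(n_sites)
  for (i in seq_len(nrow(atlas$regions))) {
    r <- atlas$regions[i, ]
    n <- r$length_cells * circumference
    if (n == 0L) next
    counts <- apportion_cells(n, r$ee_per_isc, r$ec_per_isc)
    if (r$division_rate > 0 && counts[["ISC"]] == 0L) {
      stop("region ", r$name, ": composition ratios leave no room for an ISC ",
           "in ", n, " sites")
    }
    offset <- r$start * circumference
    local <- rep.int(2L, n)                       # EC background
    isc_at <- isc_grid(counts[["ISC"]], r$length_cells, circumference)
    local[isc_at] <- 1L
    free <- which(local == 2L)
    ee_at <- free[spread_indices(counts[["ee"]], length(free))]
    local[ee_at] <- 3L
    type[offset + seq_len(n)] <- local
    k <- counts[["ISC"]]
    if (k > 0L) {
      lineage[offset + isc_at] <- seq.int(next_lineage, length.out = k)
      next_lineage <- next_lineage + k
    }
  }
  structure(
    list(
      atlas = atlas, n_rows = n_rows, circumference = circumference,
      type = type, lineage = lineage, clone = integer(n_sites),
      birth = numeric(n_sites), time = 0,
      founders = data.frame(
        clone_id = integer(), founder_row = integer(), founder_col = integer(),
        founder_region = character(), induction_time = numeric(),
        stringsAsFactors = FALSE
      )
    ),
    class = "midgut_tissue"
  )
}

#' Induce marked clones in stem cells
#'
#' Labels each currently unlabeled ISC independently with a fresh clone id
#' with probability `frequency`, emulating sparse heat-shock lineage marking.
#' Non-ISC cells are never labeled at induction. The founder's row (hence
#' region) and the induction time are recorded.
#'
#' @param tissue a `midgut_tissue`.
#' @param frequency per-ISC labeling probability in \[0, 1\].
#' @param seed optional integer seed for reproducibility.
#' @return The tissue with clone labels and an updated founder table.
#' @export
induce_clones <- function(tissue, frequency, seed = NULL) {
  stopifnot(inherits(tissue, "midgut_tissue"))
  if (!is.finite(frequency) || frequency < 0 || frequency > 1) {
    stop("frequency must be in [0, 1]")
  }
  if (!is.null(seed)) set.seed(seed)
  isc <- which(tissue$type == 1L & tissue$clone == 0L)
  hit <- isc[runif(length(isc)) < frequency]
  if (length(hit)) {
    first <- if (nrow(tissue$founders)) max(tissue$founders$clone_id) + 1L else 1L
    ids <- seq.int(first, length.out = length(hit))
    tissue$clone[hit] <- ids
    row0 <- (hit - 1L) %/% tissue$circumference
    col0 <- (hit - 1L) %% tissue$circumference
    tissue$founders <- rbind(tissue$founders, data.frame(
      clone_id = ids, founder_row = row0, founder_col = col0,
      founder_region = locate(tissue$atlas, row0),
      induction_time = tissue$time, stringsAsFactors = FALSE
    ))
  }
  tissue
}

# Resolve per-boundary crossing permissions for a simulation mode.
boundary_permissions <- function(atlas, mode = c("atlas", "blocked", "permissive")) {
  mode <- match.arg(mode)
  b <- atlas$boundaries
  switch(mode,
    atlas = list(fwd = b$open_up_to_down, bwd = b$open_down_to_up),
    blocked = list(fwd = rep(FALSE, nrow(b)), bwd = rep(FALSE, nrow(b))),
    permissive = list(fwd = rep(TRUE, nrow(b)), bwd = rep(TRUE, nrow(b)))
  )
}

#' Simulate ISC divisions on the lattice
#'
#' Division events are drawn as independent Poisson processes, one per ISC at
#' its region's `division_rate`, scheduled exactly (Gillespie-style
#' exponential waiting times over the constant total rate). At each division
#' the ISC persists and commits one daughter to the enteroendocrine fate
#' (with the per-region probability `ee/(ee + ec)` unless overridden by
#' `fate_rule`) or to the enterocyte fate. The daughter is inserted in the
#' neighboring site along a direction drawn with circumferential bias
#' `anisotropy`; the ISC's own contiguous run of progeny along that direction
#' is pushed one site outward and the first non-progeny cell at the end of
#' the run dies, so total cell count is conserved and each division adds one
#' cell to the clone. A push never displaces an ISC and never moves a cell
#' across a blocked boundary; blocked directions fall back deterministically
#' to circumferential +1, then -1, then the away-from-boundary row.
#'
#' @param tissue a `midgut_tissue` (clones induced or not).
#' @param days non-negative simulation duration in days.
#' @param mode `"atlas"` (use the atlas' per-boundary permissions),
#'   `"blocked"` (all boundaries closed) or `"permissive"` (all open).
#' @param anisotropy probability that a daughter is placed circumferentially
#'   rather than axially, in \[0, 1\]; values near 1 reproduce clone
#'   elongation perpendicular to the a/p axis.
#' @param fate_rule optional global override for P(daughter is ee).
#' @param seed optional integer seed.
#' @return The advanced tissue; `attr(, "n_events")` and `attr(, "n_skipped")`
#'   record the division and fully-blocked event counts of this call.
#' @export
simulate_tissue <- function(tissue, days, mode = c("atlas", "blocked", "permissive"),
                            anisotropy = 0.7, fate_rule = NULL, seed = NULL) {
  stopifnot(inherits(tissue, "midgut_tissue"))
  if (!is.finite(days) || days < 0) stop("days must be >= 0")
  if (anisotropy < 0 || anisotropy > 1) stop("anisotropy must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  atlas <- tissue$atlas
  perm <- boundary_permissions(atlas, match.arg(mode))
  pee <- if (is.null(fate_rule)) {
    denom <- atlas$regions$ee_per_isc + atlas$regions$ec_per_isc
    ifelse(denom > 0, atlas$regions$ee_per_isc / denom, 0)
  } else {
    if (fate_rule < 0 || fate_rule > 1) stop("fate_rule must be in [0, 1]")
    rep(fate_rule, nrow(atlas$regions))
  }
  out <- sim_core(
    tissue$type, tissue$lineage, tissue$clone, tissue$birth,
    region_index_of_rows(atlas), atlas$regions$start, atlas$regions$end,
    atlas$regions$division_rate, pee, perm$fwd, perm$bwd,
    tissue$n_rows, tissue$circumference,
    tissue$time, tissue$time + days, anisotropy
  )
  tissue$type <- out$type
  tissue$lineage <- out$lineage
  tissue$clone <- out$clone
  tissue$birth <- out$birth
  tissue$time <- tissue$time + days
  attr(tissue, "n_events") <- out$n_events
  attr(tissue, "n_skipped") <- out$n_skipped
  tissue
}

#' All lattice cells as a data frame
#'
#' @param tissue a `midgut_tissue`.
#' @return Data frame with one row per lattice site: `cell_row`, `cell_col`
#'   (0-based), `cell_type`, `clone_id` (0 = unlabeled), `birth_time` and the
#'   derived `region`.
#' @export
tissue_cells <- function(tissue) {
  stopifnot(inherits(tissue, "midgut_tissue"))
  n <- tissue$n_rows * tissue$circumference
  row0 <- (seq_len(n) - 1L) %/% tissue$circumference
  data.frame(
    cell_row = row0,
    cell_col = (seq_len(n) - 1L) %% tissue$circumference,
    cell_type = CELL_TYPES[tissue$type],
    clone_id = tissue$clone,
    birth_time = tissue$birth,
    region = locate(tissue$atlas, row0),
    stringsAsFactors = FALSE
  )
}

#' Extract marked clones from a tissue
#'
#' Groups labeled cells into clones; the founder region is the region of the
#' founding ISC's row at induction, not the cells' current positions.
#'
#' @param tissue a `midgut_tissue`.
#' @return Data frame with one row per labeled cell: `clone_id`,
#'   `founder_region`, `induction_time`, `cell_row`, `cell_col`, `cell_type`,
#'   `birth_time`, ordered by clone then row then column.
#' @export
extract_clones <- function(tissue) {
  stopifnot(inherits(tissue, "midgut_tissue"))
  lab <- which(tissue$clone > 0L)
  founders <- tissue$founders
  df <- data.frame(
    clone_id = tissue$clone[lab],
    cell_row = (lab - 1L) %/% tissue$circumference,
    cell_col = (lab - 1L) %% tissue$circumference,
    cell_type = CELL_TYPES[tissue$type[lab]],
    birth_time = tissue$birth[lab],
    stringsAsFactors = FALSE
  )
  m <- match(df$clone_id, founders$clone_id)
  df$founder_region <- founders$founder_region[m]
  df$induction_time <- founders$induction_time[m]
  df <- df[order(df$clone_id, df$cell_row, df$cell_col),
           c("clone_id", "founder_region", "induction_time",
             "cell_row", "cell_col", "cell_type", "birth_time")]
  rownames(df) <- NULL
  df
}

#' Per-clone cell counts at the current time
#'
#' @param tissue a `midgut_tissue`.
#' @return Data frame `clone_id`, `founder_region`, `n_cells`, one row per
#'   induced clone. Sizes are always >= 1: the founding ISC is never
#'   displaced, so a clone cannot vanish.
#' @export
clone_sizes <- function(tissue) {
  stopifnot(inherits(tissue, "midgut_tissue"))
  f <- tissue$founders
  counts <- tabulate(tissue$clone, nbins = if (nrow(f)) max(f$clone_id) else 0L)
  data.frame(
    clone_id = f$clone_id,
    founder_region = f$founder_region,
    n_cells = counts[f$clone_id],
    stringsAsFactors = FALSE
  )
}

#' @export
print.midgut_tissue <- function(x, ...) {
  cat("Midgut tissue:", x$n_rows, "rows x", x$circumference, "cols,",
      sum(x$type == 1L), "ISCs,", nrow(x$founders), "marked clones, t =",
      x$time, "days\n")
  invisible(x)
}
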