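# Shared fixtures: small atlases and an independent brute-force scorer used
# as the oracle for the vectorized tabulation.

two_region_atlas <- function(len1 = 12L, len2 = 15L, open = TRUE) {
  build_atlas(
    data.frame(
      name = c("LFC", "Fe"), length_cells = c(len1, len2),
      division_rate = c(0.3, 0.35), ee_per_isc = 0.4, ec_per_isc = 4.6,
      stringsAsFactors = FALSE
    ),
    boundaries = data.frame(
      upstream = "LFC", downstream = "Fe",
      open_up_to_down = open, open_down_to_up = open,
      stringsAsFactors = FALSE
    )
  )
}

three_region_atlas <- function() {
  build_atlas(data.frame(
    name = c("Cu", "LFC", "Fe"), length_cells = c(8L, 8L, 8L),
    division_rate = c(0.4, 0.4, 0.4), ee_per_isc = 0.5, ec_per_isc = 4.5,
    stringsAsFactors = FALSE
  ))
}

# Brute-force recount of the boundary-clone table: enumerates every cell and
# every lattice neighbor, classifying regions through locate() only. Slow,
# simple, and independent of the row-arithmetic implementation.
oracle_tabulate <- function(clones, atlas, circumference) {
  reg_names <- atlas$regions$name
  b <- atlas$boundaries
  pairs <- list()
  for (i in seq_len(nrow(b))) {
    pairs[[length(pairs) + 1L]] <- c(b$upstream[i], b$downstream[i])
    pairs[[length(pairs) + 1L]] <- c(b$downstream[i], b$upstream[i])
  }
  by_clone <- if (nrow(clones)) split(clones, clones$clone_id) else list()
  out <- data.frame(
    region1 = vapply(pairs, `[`, "", 1L),
    region2 = vapply(pairs, `[`, "", 2L),
    clones = 0L, boundary_clones = 0L, crossed_clones = 0L,
    total_cells = 0L, boundary_cells = 0L, crossed_cells = 0L,
    p_annotation = "", stringsAsFactors = FALSE
  )
  n_rows <- atlas$n_rows
  for (d in by_clone) {
    founder <- d$founder_region[1L]
    for (k in seq_along(pairs)) {
      p <- pairs[[k]]
      if (p[1L] != founder) next
      # boundary cells: any lattice neighbor on the opposite side of this pair
      nb <- 0L
      for (i in seq_len(nrow(d))) {
        r <- d$cell_row[i]; cc <- d$cell_col[i]
        here <- locate(atlas, r)
        touches <- FALSE
        for (delta in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
          rr <- r + delta[1L]
          if (rr < 0L || rr >= n_rows) next
          there <- locate(atlas, rr)
          if (here != there && setequal(c(here, there), p)) touches <- TRUE
        }
        if (touches) nb <- nb + 1L
      }
      # crossed cells: located in any region on the far side of the pair
      i1 <- match(p[1L], reg_names); i2 <- match(p[2L], reg_names)
      cell_idx <- match(locate(atlas, d$cell_row), reg_names)
      ncr <- if (i2 > i1) sum(cell_idx >= i2) else sum(cell_idx <= i2)
      # minimal covering arc via a doubled occupancy scan
      occ <- rep(FALSE, circumference)
      occ[d$cell_col %% circumference + 1L] <- TRUE
      runs <- rle(c(!occ, !occ))
      gap <- max(c(0L, runs$lengths[runs$values]))
      span <- circumference - min(gap, circumference - 1L)
      eligible <- sum(d$cell_type == "ISC") == 1L && nrow(d) >= 4L &&
        span <= circumference / 2 && nb >= 1L
      out$clones[k] <- out$clones[k] + 1L
      if (eligible) {
        out$boundary_clones[k] <- out$boundary_clones[k] + 1L
        out$crossed_clones[k] <- out$crossed_clones[k] + (ncr >= 1L)
        out$total_cells[k] <- out$total_cells[k] + nrow(d)
        out$boundary_cells[k] <- out$boundary_cells[k] + nb
        out$crossed_cells[k] <- out$crossed_cells[k] + ncr
      }
    }
  }
  out
}

# One simulated clone dataset (induced, grown) plus its tabulations.
simulate_and_tabulate <- function(atlas, seed, mode, days = 15,
                                  circumference = 36, frequency = 0.4) {
  set.seed(seed)
  ti <- initialize_epithelium(atlas, circumference)
  ti <- induce_clones(ti, frequency)
  ti <- simulate_tissue(ti, days, mode = mode)
  clones <- extract_clones(ti)
  list(
    clones = clones,
    table = tabulate_boundary_clones(clones, atlas, circumference),
    oracle = oracle_tabulate(clones, atlas, circumference)
  )
}
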