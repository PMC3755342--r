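test_that("initialization fills the lattice at the configured ratios", {
  atlas <- build_atlas(data.frame(name = c("LFC", "Fe"),
                                  length_cells = c(10L, 5L),
                                  division_rate = 0.3,
                                  ee_per_isc = c(1, 0.5),
                                  ec_per_isc = c(4, 4.5)))
  ti <- initialize_epithelium(atlas, 6L)
  cells <- tissue_cells(ti)
  # exact ratios: 60 sites in LFC at 1:1:4 -> 10 ISC, 10 ee, 40 EC
  lfc <- cells[cells$region == "LFC", ]
  expect_equal(sum(lfc$cell_type == "ISC"), 10L)
  expect_equal(sum(lfc$cell_type == "ee"), 10L)
  expect_equal(sum(lfc$cell_type == "EC"), 40L)
  # total cell count equals rows x circumference, every site filled
  expect_equal(nrow(cells), 15L * 6L)
  expect_false(anyNA(cells$cell_type))
  # initialization is deterministic
  expect_identical(ti$type, initialize_epithelium(atlas, 6L)$type)
})

test_that("induction labels only ISCs at the requested frequency", {
  atlas <- calibration_atlas("Cu", division_rate = 0.22, length_cells = 100L,
                             ee_per_isc = 1, ec_per_isc = 4)
  ti <- initialize_epithelium(atlas, 60L)
  expect_equal(sum(ti$type == 1L), 1000L)

  expect_equal(nrow(induce_clones(ti, 0)$founders), 0L)
  full <- induce_clones(ti, 1)
  expect_equal(nrow(full$founders), 1000L)
  expect_true(all(full$type[full$clone > 0L] == 1L))

  # frequency 0.05 over 1000 ISCs: central 99% binomial interval
  lo <- qbinom(0.005, 1000, 0.05)
  hi <- qbinom(0.995, 1000, 0.05)
  n <- nrow(induce_clones(ti, 0.05, seed = 11)$founders)
  expect_gte(n, lo)
  expect_lte(n, hi)
  expect_error(induce_clones(ti, 1.2), "frequency")
})

test_that("simulation conserves cell count and is reproducible under seed", {
  atlas <- three_region_atlas()
  run <- function(seed) {
    set.seed(seed)
    ti <- initialize_epithelium(atlas, 24L)
    ti <- induce_clones(ti, 0.3)
    ti <- simulate_tissue(ti, 12)
    ti
  }
  a <- run(5); b <- run(5); c <- run(6)
  expect_equal(length(a$type), 24L * atlas$n_rows)
  expect_true(all(a$type %in% 1:3))                 # every site occupied
  expect_equal(sum(a$type == 1L), sum(b$type == 1L))
  expect_identical(extract_clones(a), extract_clones(b))
  expect_false(identical(extract_clones(a), extract_clones(c)))
  # zero division rate leaves the tissue unchanged
  still <- build_atlas(data.frame(name = c("LFC", "Fe"),
                                  length_cells = c(5L, 5L),
                                  division_rate = 0,
                                  ee_per_isc = 0.5, ec_per_isc = 4.5))
  t0 <- initialize_epithelium(still, 12L)
  t1 <- simulate_tissue(t0, 30, seed = 1)
  expect_identical(t1$type, t0$type)
  expect_error(simulate_tissue(t0, -1), "days")
})

test_that("extracted clones partition the labeled cells", {
  atlas <- three_region_atlas()
  set.seed(9)
  ti <- initialize_epithelium(atlas, 24L)
  ti <- induce_clones(ti, 0.3)
  # immediately after induction every clone is its single founding ISC
  cl0 <- extract_clones(ti)
  expect_equal(nrow(cl0), nrow(ti$founders))
  expect_true(all(cl0$cell_type == "ISC"))
  ti <- simulate_tissue(ti, 12)
  cl <- extract_clones(ti)
  expect_equal(nrow(cl), sum(ti$clone > 0L))        # sizes sum to labeled cells
  expect_equal(anyDuplicated(cl[, c("cell_row", "cell_col")]), 0L)
  expect_setequal(unique(cl$clone_id), ti$founders$clone_id)
  expect_equal(sort(unique(cl$founder_region)),
               sort(unique(ti$founders$founder_region)))
  # each clone retains exactly one ISC (its founder)
  isc_per_clone <- tapply(cl$cell_type == "ISC", cl$clone_id, sum)
  expect_true(all(isc_per_clone == 1L))
})

test_that("mean clone size follows the linear growth law 1 + lambda t", {
  atlas <- calibration_atlas("P1", division_rate = 1, length_cells = 200L,
                             ee_per_isc = 2, ec_per_isc = 197)
  set.seed(21)
  ti <- initialize_epithelium(atlas, 200L)
  ti <- induce_clones(ti, 1)
  ti <- simulate_tissue(ti, 10)
  sz <- clone_sizes(ti)$n_cells
  expect_gte(length(sz), 200L)
  se <- sd(sz) / sqrt(length(sz))
  expect_lt(abs(mean(sz) - 11), 3 * se)
})

test_that("blocked boundaries are never crossed; open ones are, increasingly", {
  blocked <- two_region_atlas(open = FALSE)
  for (seed in 1:4) {
    res <- simulate_and_tabulate(blocked, seed, mode = "atlas")
    expect_equal(sum(res$table$crossed_cells), 0L)
  }
  open <- two_region_atlas(open = TRUE)
  frac_at <- function(days) {
    tabs <- lapply(1:6, function(s) {
      set.seed(s)
      ti <- initialize_epithelium(open, 200L)
      ti <- induce_clones(ti, 0.5)
      ti <- simulate_tissue(ti, days)
      tabulate_boundary_clones(extract_clones(ti), open, 200L)
    })
    crossed <- sum(vapply(tabs, function(t) sum(t$crossed_clones), 0L))
    nb <- sum(vapply(tabs, function(t) sum(t$boundary_clones), 0L))
    crossed / nb
  }
  early <- frac_at(6); late <- frac_at(24)
  expect_gt(late, 0)
  expect_gt(late, early)   # crossing accumulates with duration
})

test_that("strong anisotropy elongates clones perpendicular to the a/p axis", {
  atlas <- two_region_atlas(open = FALSE)
  set.seed(3)
  ti <- initialize_epithelium(atlas, 60L)
  ti <- induce_clones(ti, 0.3)
  ti <- simulate_tissue(ti, 20, anisotropy = 0.95)
  cl <- extract_clones(ti)
  boxes <- do.call(rbind, lapply(split(cl, cl$clone_id), function(d) {
    if (nrow(d) < 4L) return(NULL)
    width <- length(unique(d$cell_col))
    height <- diff(range(d$cell_row)) + 1L
    c(width = width, height = height)
  }))
  expect_gt(mean(boxes[, "width"]), mean(boxes[, "height"]))
})
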