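toy_atlas <- function() {
  build_atlas(data.frame(name = c("LFC", "Fe"), length_cells = c(5L, 5L),
                         division_rate = 0.3, ee_per_isc = 0.5,
                         ec_per_isc = 4.5))
}

test_that("clone scoring applies the eligibility and counting rules", {
  atlas <- toy_atlas()
  # five-cell clone straddling the cut at row 5: founder at row 4
  cells <- data.frame(
    cell_row = c(3L, 4L, 4L, 5L, 5L),
    cell_col = c(0L, 0L, 1L, 0L, 1L),
    cell_type = c("EC", "ISC", "EC", "EC", "ee"),
    stringsAsFactors = FALSE
  )
  s <- score_clone(cells, "LFC", atlas, c("LFC", "Fe"), circumference = 12)
  expect_true(s$eligible)
  expect_equal(s$n_cells, 5L)
  expect_equal(s$n_crossed_cells, 2L)   # the two cells at row 5
  expect_true(s$crossed)
  # cross-check boundary/crossed counts against the exhaustive oracle
  clone_df <- cbind(clone_id = 1L, founder_region = "LFC",
                    induction_time = 0, cells, birth_time = 0)
  orc <- oracle_tabulate(clone_df, atlas, 12L)
  lfc_fe <- orc[orc$region1 == "LFC" & orc$region2 == "Fe", ]
  expect_equal(s$n_boundary_cells, lfc_fe$boundary_cells)
  expect_equal(s$n_crossed_cells, lfc_fe$crossed_cells)
  expect_equal(s$n_boundary_cells, 4L)  # rows 4 and 5 flank the cut

  # three-cell clone touching the boundary: too small
  small <- score_clone(cells[2:4, ], "LFC", atlas, c("LFC", "Fe"), 12)
  expect_false(small$eligible)
  expect_match(small$reason, "four cells")

  # six-cell clone interior to its region: no boundary cell
  interior <- data.frame(
    cell_row = c(1L, 1L, 2L, 2L, 3L, 3L), cell_col = rep(0:1, 3),
    cell_type = c("ISC", rep("EC", 5)), stringsAsFactors = FALSE
  )
  si <- score_clone(interior, "LFC", atlas, c("LFC", "Fe"), 12)
  expect_false(si$eligible)
  expect_equal(si$n_boundary_cells, 0L)

  # two ISCs, or a wrap around most of the circumference, disqualify
  twins <- cells; twins$cell_type[1] <- "ISC"
  expect_false(score_clone(twins, "LFC", atlas, c("LFC", "Fe"), 12)$eligible)
  wrap <- data.frame(cell_row = 4L, cell_col = 0:7,
                     cell_type = c("ISC", rep("EC", 7)),
                     stringsAsFactors = FALSE)
  sw <- score_clone(wrap, "LFC", atlas, c("LFC", "Fe"), 12)
  expect_false(sw$eligible)
  expect_match(sw$reason, "wraps")

  expect_error(score_clone(cells[0, ], "LFC", atlas, c("LFC", "Fe")),
               "empty clone")
})

test_that("binomial all-fail null matches its closed form and conventions", {
  expect_equal(binomial_null(0.88, 3), 0.001728)
  expect_equal(round(binomial_null(15 / 17, 3), 4), 0.0017)  # rounds to 0.88
  expect_equal(binomial_null(0.7, 0), 1)
  expect_equal(binomial_null(0.5, 2), 0.25)
  # without the two-decimal convention the raw fraction is used
  expect_equal(binomial_null(15 / 17, 3, round_digits = NULL), (2 / 17)^3)
  # non-increasing in both arguments
  r <- seq(0, 1, by = 0.1)
  expect_true(all(diff(binomial_null(r, 3)) <= 0))
  expect_true(all(diff(vapply(0:10, binomial_null, 0, r_ref = 0.3)) <= 0))
})

test_that("expected-crossing chi-square follows the single-term Pearson form", {
  t1 <- expected_crossing_test(0, 10, 0.63)
  expect_equal(t1$chi2, 6.3)
  expect_equal(t1$expected, 6.3)
  expect_equal(t1$p, pchisq(6.3, 1, lower.tail = FALSE))
  expect_equal(expected_crossing_test(0, 21, 0.63)$chi2, 13.23)
  same <- expected_crossing_test(6.3, 10, 0.63)
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)
  # alternative constructions exist but are non-default
  expect_gt(expected_crossing_test(0, 10, 0.63, method = "two_cell")$chi2,
            t1$chi2)
  expect_error(expected_crossing_test(0, 10, 0.63, method = "prop"), "n_ref")
})

test_that("tabulation matches the brute-force recount on simulated data", {
  atlas <- three_region_atlas()
  for (mode in c("blocked", "permissive")) {
    res <- simulate_and_tabulate(atlas, seed = 17, mode = mode)
    expect_equal(as.data.frame(res$table), res$oracle,
                 ignore_attr = TRUE)
  }
  # empty clone set gives the all-zero table
  empty <- tabulate_boundary_clones(
    extract_clones(initialize_epithelium(atlas, 24L)), atlas, 24L)
  expect_true(all(empty$clones == 0L))
  expect_true(all(empty$crossed_cells == 0L))
})

test_that("crossing fraction and cell ratio sum both directions of a boundary", {
  tab <- table1_fixture()
  expect_equal(crossing_fraction(tab, c("LFC", "Fe")), 15 / 17)
  expect_equal(crossing_fraction(tab, c("Fe", "LFC")), 15 / 17)  # orderless
  expect_equal(crossing_fraction(tab, c("A1", "A2")), 0)
  expect_equal(crossed_per_boundary_cell(tab, c("LFC", "Fe")), 48 / 73)
  expect_error(crossing_fraction(tab, c("A1", "P4")), "not in table")
  # a boundary without any boundary clones (or cells) has no defined ratio
  none <- tab
  none[none$region1 %in% c("Cu", "A3") & none$region2 %in% c("Cu", "A3"),
       c("boundary_clones", "crossed_clones", "boundary_cells",
         "crossed_cells")] <- 0L
  expect_error(crossing_fraction(none, c("A3", "Cu")), "no boundary clones")
  expect_error(crossed_per_boundary_cell(none, c("A3", "Cu")),
               "no boundary cells")
})

test_that("summary reports per-boundary nulls and keeps reference k at zero", {
  tab <- table1_fixture()
  s <- summarize_crossing(tab, reference = c("LFC", "Fe"))
  expect_equal(s$total_boundary_clones, 49L)
  b <- s$boundaries
  ref <- b[b$boundary == "LFC/Fe", ]
  expect_equal(ref$p_binomial, 1)            # its own null uses k = 0
  a3cu <- b[b$boundary == "A3/Cu", ]
  expect_equal(round(a3cu$p_binomial, 4), 0.0017)  # three non-crossing clones
  expect_equal(b$r_clone[b$boundary %in%
    c("A1/A2", "A3/Cu", "Cu/LFC", "Fe/P1", "P1/P2")], rep(0, 5))
  expect_output(print(s), "total boundary clones: 49")
})

test_that("boundary table round-trips byte-identically through TSV", {
  tab <- table1_fixture()
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_boundary_table(tab, p1)
  back <- read_boundary_table(p1)
  write_boundary_table(back, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_equal(as.data.frame(back), as.data.frame(tab), ignore_attr = TRUE)
  # malformed input names the problem
  writeLines(c("region1\tregion2\tclones", "A1\tA2\t5"), p2)
  expect_error(read_boundary_table(p2), "missing column")
})
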