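toy_matrix <- function(rows, sets = c("A1", "Cu"), reps = 3) {
  values <- do.call(rbind, rows)
  fpkm_matrix(values, rep(sets, each = reps))
}

test_that("replicate QC removes high-dispersion and all-zero genes", {
  m <- toy_matrix(list(
    steady = c(10, 10, 10, 10, 10, 10),
    noisy  = c(0, 0, 30, 5, 5, 5),     # SD/mean = 1.73 in A1
    zero   = c(0, 0, 0, 0, 0, 0)
  ))
  filtered <- qc_filter(m)
  expect_equal(rownames(filtered$values), "steady")
  removed <- attr(filtered, "removed")
  expect_equal(removed$reason[removed$gene == "noisy"], "SD/mean > 1")
  expect_equal(removed$reason[removed$gene == "zero"],
               "zero in all region sets")
  # the worked ratio: sample SD of (0, 0, 30) over its mean
  expect_equal(sd(c(0, 0, 30)) / mean(c(0, 0, 30)), sqrt(3), tolerance = 1e-12)
  # idempotent
  expect_identical(qc_filter(filtered)$values, filtered$values)
  single <- fpkm_matrix(matrix(1:4, 2), c("A1", "Cu"))
  expect_error(qc_filter(single), "single replicate")
})

test_that("replicate concordance is 1 for identical and ~0 for permuted", {
  set.seed(2)
  base <- 10^rnorm(1500, 1.5, 1)
  ident <- fpkm_matrix(cbind(base, base), c("A1", "A1"))
  expect_equal(replicate_concordance(ident)$r_squared, 1)
  perm <- fpkm_matrix(cbind(base, sample(base)), c("A1", "A1"))
  expect_lt(replicate_concordance(perm)$r_squared, 0.1)
  const <- fpkm_matrix(cbind(base, rep(2, 1500)), c("A1", "A1"))
  expect_warning(r2 <- replicate_concordance(const)$r_squared, "constant")
  expect_true(is.na(r2))
})

test_that("subregion enrichment applies the strict 10x rule with pseudocount", {
  m <- toy_matrix(list(
    planted = c(100, 100, 100, 5, 5, 5),
    border  = c(100, 100, 100, 10.1, 10.1, 10.1),
    uniform = c(50, 50, 50, 50, 50, 50)
  ))
  calls <- region_enrichment(m, fold = 10)
  expect_equal(calls$gene, "planted")
  expect_equal(calls$target, "A1")
  expect_gte(calls$fold_vs_best_other, 19)
  expect_equal(calls$category, "subregion-10x")
  # 100.1 is not strictly greater than 10 * 10.2: no call for the border gene
  expect_false("border" %in% calls$gene)
})

test_that("zone enrichment uses >= 5x against each of the other two zones", {
  values <- rbind(
    ant  = c(50, 50, 50, 5, 5, 5, 8, 8, 8),
    weak = c(50, 50, 50, 5, 5, 5, 20, 20, 20),
    flat = rep(30, 9)
  )
  m <- fpkm_matrix(values, rep(c("anterior", "middle", "posterior"), each = 3))
  calls <- zone_enrichment(m, fold = 5)
  expect_equal(calls$gene, "ant")
  expect_equal(calls$target, "anterior")
  expect_equal(calls$category, "zone-5x")
  # 50.1 / 20.1 = 2.5x misses the threshold against the posterior zone
  expect_false("weak" %in% calls$gene)
  two <- fpkm_matrix(values[, 1:6], rep(c("anterior", "middle"), each = 3))
  expect_error(zone_enrichment(two), "three zones")
})

test_that("fold versus best other region follows the pseudocount identity", {
  m <- toy_matrix(list(
    lab  = c(4000, 4000, 4000, 60, 60, 60),
    tied = c(7, 7, 7, 7, 7, 7),
    off  = c(0, 0, 0, 0, 0, 0)
  ))
  lab_fold <- fold_vs_best_other(m, "lab", "A1")
  expect_equal(lab_fold, 4000.1 / 60.1)
  expect_gt(lab_fold, 40); expect_lt(lab_fold, 100)
  expect_equal(fold_vs_best_other(m, "tied", "A1"), 1)
  expect_equal(fold_vs_best_other(m, "off", "A1"), 1)  # 0.1/0.1
  expect_error(fold_vs_best_other(m, "nope", "A1"), "unknown gene")
  expect_error(fold_vs_best_other(m, "lab", "XX"), "unknown region set")
})

test_that("calls are stable under gene reordering and global rescaling", {
  spec <- fpkm_spec(n_genes = 400, region_sets = c(A1 = 3, Cu = 3, Fe = 3),
                    planted_per_set = 10, planted_fold = 50,
                    noise_sd = 0, seed = 4)
  m <- generate_fpkm(spec)
  calls <- region_enrichment(m)
  reordered <- fpkm_matrix(m$values[rev(seq_len(nrow(m$values))), ],
                           m$samples$region_set)
  calls_r <- region_enrichment(reordered)
  expect_setequal(paste(calls$gene, calls$target),
                  paste(calls_r$gene, calls_r$target))
  for (scale in c(0.5, 2, 10)) {
    scaled <- fpkm_matrix(m$values * scale, m$samples$region_set)
    calls_s <- region_enrichment(scaled)
    expect_setequal(paste(calls$gene, calls$target),
                    paste(calls_s$gene, calls_s$target))
  }
})

test_that("fpkm matrices round-trip through TSV", {
  spec <- fpkm_spec(n_genes = 50, region_sets = c(A1 = 2, Cu = 2),
                    planted_per_set = 5, seed = 3)
  m <- generate_fpkm(spec)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fpkm(m, path)
  back <- read_fpkm(path)
  expect_equal(back$values, m$values, tolerance = 1e-12)
  expect_equal(back$samples$region_set, m$samples$region_set)
  writeLines(c("gene\tA1.1", "g1\tnot_a_number"), path)
  expect_error(read_fpkm(path), "non-numeric")
})
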