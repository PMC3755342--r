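# Regional enrichment screen for fpkm expression matrices.
#
# Screening rules: replicate QC removes genes whose within-replicate
# SD/mean exceeds 1 in any sample set; region enrichment calls a gene for a
# subregion when its mean is more than `fold` (default 10) times the best
# other subregion mean; zone enrichment uses `fold` = 5 with ">=" against
# each of the other two zones. A pseudocount of 0.1 (the fpkm floor of the
# assay) is added to every mean before forming ratios.

#' Construct an fpkm expression matrix
#'
#' @param values numeric matrix, genes x samples, fpkm (finite, >= 0); row
#'   names identify genes.
#' @param region_set character vector, one label per column (sample).
#' @param replicate optional replicate ids per column; defaults to running
#'   numbers within each region set.
#' @return An object of class `fpkm_matrix`: list with `values` and a
#'   `samples` data frame (`region_set`, `replicate`).
#' @export
fpkm_matrix <- function(values, region_set, replicate = NULL) {
  values <- as.matrix(values)
  if (length(region_set) != ncol(values)) {
    stop("one region_set label per sample column required")
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("fpkm values must be finite and non-negative")
  }
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("gene", seq_len(nrow(values)))
  }
  if (is.null(replicate)) {
    replicate <- stats::ave(seq_along(region_set), region_set,
                            FUN = seq_along)
  }
  colnames(values) <- paste(region_set, replicate, sep = ".")
  structure(
    list(values = values,
         samples = data.frame(region_set = as.character(region_set),
                              replicate = replicate,
                              stringsAsFactors = FALSE)),
    class = "fpkm_matrix"
  )
}

#' @export
print.fpkm_matrix <- function(x, ...) {
  sets <- table(x$samples$region_set)
  cat("fpkm matrix:", nrow(x$values), "genes x", ncol(x$values), "samples (",
      paste(names(sets), sets, sep = " x ", collapse = ", "), ")\n")
  invisible(x)
}

set_means <- function(mat) summarize_sets(mat, "mean")

#' Replicate quality-control filter
#'
#' Removes genes whose within-replicate sample SD divided by the replicate
#' mean exceeds 1 in any region set (divergence of this size usually
#' reflects inconsistent read alignment rather than expression), and genes
#' whose replicate mean is 0 in every region set. The filter is idempotent.
#'
#' @param mat an `fpkm_matrix` with >= 2 replicates per region set.
#' @return The filtered `fpkm_matrix`; removed genes and their reasons are
#'   recorded in `attr(, "removed")`.
#' @export
qc_filter <- function(mat) {
  stopifnot(inherits(mat, "fpkm_matrix"))
  sets <- unique(mat$samples$region_set)
  for (s in sets) {
    if (sum(mat$samples$region_set == s) < 2L) {
      stop("region set '", s, "' has a single replicate; QC needs >= 2")
    }
  }
  cv_bad <- rep(FALSE, nrow(mat$values))
  for (s in sets) {
    v <- mat$values[, mat$samples$region_set == s, drop = FALSE]
    sds <- apply(v, 1L, sd)
    mns <- rowMeans(v)
    # sd > 0 implies mean > 0 for non-negative data; sd == 0 passes.
    cv_bad <- cv_bad | (sds > 0 & sds / mns > 1)
  }
  all_zero <- rowSums(set_means(mat)) == 0
  drop <- cv_bad | all_zero
  removed <- data.frame(
    gene = rownames(mat$values)[drop],
    reason = ifelse(cv_bad[drop], "SD/mean > 1", "zero in all region sets"),
    stringsAsFactors = FALSE
  )
  mat$values <- mat$values[!drop, , drop = FALSE]
  attr(mat, "removed") <- removed
  mat
}

#' Replicate concordance (R-squared)
#'
#' Squared Pearson correlation of log10(fpkm + pseudocount) for every
#' within-region-set replicate pair.
#'
#' @param mat an `fpkm_matrix`.
#' @param pseudocount added before the log transform (default 0.1, the
#'   fpkm floor).
#' @return Data frame `region_set`, `replicate_1`, `replicate_2`,
#'   `r_squared` (NA with a warning for constant replicate vectors).
#' @export
replicate_concordance <- function(mat, pseudocount = 0.1) {
  stopifnot(inherits(mat, "fpkm_matrix"))
  lv <- log10(mat$values + pseudocount)
  out <- list()
  for (s in unique(mat$samples$region_set)) {
    idx <- which(mat$samples$region_set == s)
    if (length(idx) < 2L) stop("region set '", s, "' has a single replicate")
    for (i in seq_along(idx)[-length(idx)]) {
      for (j in seq.int(i + 1L, length(idx))) {
        a <- lv[, idx[i]]; b <- lv[, idx[j]]
        r2 <- if (sd(a) == 0 || sd(b) == 0) {
          warning("constant replicate vector in region set '", s,
                  "'; R-squared undefined")
          NA_real_
        } else cor(a, b)^2
        out[[length(out) + 1L]] <- data.frame(
          region_set = s,
          replicate_1 = mat$samples$replicate[idx[i]],
          replicate_2 = mat$samples$replicate[idx[j]],
          r_squared = r2, stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, out)
}

#' Subregion enrichment calls
#'
#' Calls a gene for a subregion when its replicate mean exceeds `fold`
#' times the best mean among the other subregions (strict inequality), with
#' the pseudocount added to all means. Calls do not depend on gene order;
#' because the pseudocount is an absolute fpkm floor, rescaling all samples
#' changes calls only for genes whose means are comparable to it.
#'
#' @param mat an `fpkm_matrix` (QC-filtered) with >= 2 region sets.
#' @param fold fold-change threshold (default 10).
#' @param pseudocount added to every mean (default 0.1).
#' @param stat `"mean"` (default) or `"median"` across replicates.
#' @return Data frame of enrichment calls: `gene`, `target`,
#'   `fold_vs_best_other`, `category` (`"subregion-<fold>x"`).
#' @export
region_enrichment <- function(mat, fold = 10, pseudocount = 0.1,
                              stat = c("mean", "median")) {
  stopifnot(inherits(mat, "fpkm_matrix"))
  stat <- match.arg(stat)
  sets <- unique(mat$samples$region_set)
  if (length(sets) < 2L) stop("need >= 2 region sets")
  m <- summarize_sets(mat, stat) + pseudocount
  calls <- list()
  for (s in sets) {
    best_other <- apply(m[, colnames(m) != s, drop = FALSE], 1L, max)
    ratio <- m[, s] / best_other
    hit <- m[, s] > fold * best_other
    if (any(hit)) {
      calls[[length(calls) + 1L]] <- data.frame(
        gene = rownames(mat$values)[hit], target = s,
        fold_vs_best_other = ratio[hit],
        category = paste0("subregion-", fold, "x"),
        stringsAsFactors = FALSE
      )
    }
  }
  res <- if (length(calls)) do.call(rbind, calls) else data.frame(
    gene = character(), target = character(),
    fold_vs_best_other = numeric(), category = character(),
    stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  res
}

summarize_sets <- function(mat, stat = "mean") {
  sets <- unique(mat$samples$region_set)
  f <- if (stat == "mean") rowMeans else function(v) apply(v, 1L, stats::median)
  out <- vapply(sets, function(s) {
    f(mat$values[, mat$samples$region_set == s, drop = FALSE])
  }, numeric(nrow(mat$values)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1,
                                       dimnames = list(rownames(mat$values),
                                                       sets))
  out
}

#' Zone enrichment calls
#'
#' Calls a gene for a zone (anterior, middle, posterior) when its mean is at
#' least `fold` times the mean of *each* of the other two zones
#' (inequality is `>=`, reading "at least"), with the pseudocount added to
#' all means.
#'
#' @param mat an `fpkm_matrix` whose region sets map onto the three zones.
#' @param fold fold-change threshold (default 5).
#' @param zones named character vector mapping region-set labels to zones;
#'   by default labels that already are zone names map to themselves and
#'   canonical subregion names map via the atlas zones.
#' @param pseudocount added to every mean (default 0.1).
#' @param stat `"mean"` (default) or `"median"`.
#' @return Data frame of calls: `gene`, `target` (zone),
#'   `fold_vs_best_other`, `category` (`"zone-<fold>x"`).
#' @export
zone_enrichment <- function(mat, fold = 5, zones = NULL, pseudocount = 0.1,
                            stat = c("mean", "median")) {
  stopifnot(inherits(mat, "fpkm_matrix"))
  stat <- match.arg(stat)
  sets <- unique(mat$samples$region_set)
  if (is.null(zones)) {
    zones <- ifelse(sets %in% c("anterior", "middle", "posterior"), sets,
                    unname(MIDGUT_ZONES[sets]))
    names(zones) <- sets
    if (anyNA(zones)) {
      stop("cannot infer a zone for region set(s): ",
           paste(sets[is.na(zones)], collapse = ", "))
    }
  }
  zone_of <- zones[mat$samples$region_set]
  present <- unique(zone_of)
  if (length(present) < 3L) {
    stop("zone enrichment needs all three zones; present: ",
         paste(present, collapse = ", "))
  }
  zmat <- fpkm_matrix(mat$values, region_set = zone_of,
                      replicate = seq_along(zone_of))
  m <- summarize_sets(zmat, stat) + pseudocount
  calls <- list()
  for (z in c("anterior", "middle", "posterior")) {
    others <- m[, colnames(m) != z, drop = FALSE]
    hit <- m[, z] >= fold * apply(others, 1L, max)
    if (any(hit)) {
      calls[[length(calls) + 1L]] <- data.frame(
        gene = rownames(mat$values)[hit], target = z,
        fold_vs_best_other = (m[, z] / apply(others, 1L, max))[hit],
        category = paste0("zone-", fold, "x"),
        stringsAsFactors = FALSE
      )
    }
  }
  res <- if (length(calls)) do.call(rbind, calls) else data.frame(
    gene = character(), target = character(),
    fold_vs_best_other = numeric(), category = character(),
    stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  res
}

#' Fold change of a gene versus the best other region set
#'
#' `(mean(target) + pseudocount) / (best other mean + pseudocount)`.
#'
#' @param mat an `fpkm_matrix`.
#' @param gene gene identifier (row name).
#' @param target region-set label.
#' @param pseudocount added to both means (default 0.1).
#' @return The fold-change ratio (> 0).
#' @export
fold_vs_best_other <- function(mat, gene, target, pseudocount = 0.1) {
  stopifnot(inherits(mat, "fpkm_matrix"))
  if (!gene %in% rownames(mat$values)) stop("unknown gene: ", gene)
  if (!target %in% mat$samples$region_set) stop("unknown region set: ", target)
  m <- set_means(mat)[gene, , drop = TRUE]
  best_other <- max(m[names(m) != target])
  (m[[target]] + pseudocount) / (best_other + pseudocount)
}

#' Read / write an fpkm matrix (TSV)
#'
#' Genes as rows, samples as columns, header `gene<TAB><set>.<rep>...`.
#'
#' @param path file path.
#' @rdname fpkm_io
#' @return `read_fpkm`: an `fpkm_matrix`.
#' @export
read_fpkm <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (names(df)[1L] != "gene") {
    stop("malformed fpkm matrix ", path, ": first column must be 'gene'")
  }
  values <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(storage.mode(values) <- "numeric")
  if (any(is.na(values))) {
    bad <- which(rowSums(is.na(values)) > 0)[1L]
    stop("malformed fpkm matrix ", path, ": non-numeric value at line ",
         bad + 1L)
  }
  rownames(values) <- df$gene
  parts <- strsplit(colnames(values), ".", fixed = TRUE)
  if (any(lengths(parts) < 2L)) {
    stop("malformed fpkm matrix ", path,
         ": sample columns must be named <set>.<replicate>")
  }
  region_set <- vapply(parts, function(p)
    paste(p[-length(p)], collapse = "."), character(1))
  replicate <- vapply(parts, function(p) p[length(p)], character(1))
  fpkm_matrix(values, region_set, replicate)
}

#' @param mat an `fpkm_matrix`.
#' @rdname fpkm_io
#' @export
write_fpkm <- function(mat, path) {
  stopifnot(inherits(mat, "fpkm_matrix"))
  df <- data.frame(gene = rownames(mat$values), mat$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
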