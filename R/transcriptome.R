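#' CPM filtering of a count matrix
#'
#' Computes counts-per-million against raw library sizes (column sums of the
#' unfiltered matrix) and retains genes with `CPM >= min_cpm` in at least
#' `min_samples` samples. All samples are kept. The alternative literal
#' reading of the rule — discard genes whose CPM falls below the threshold
#' in `min_samples` or more samples — is available via `rule`.
#'
#' @param cm a `counts_matrix`.
#' @param min_cpm CPM threshold (default 5).
#' @param min_samples sample count threshold (default 2).
#' @param rule `"retain"` (default) or `"discard_literal"`.
#' @return filtered `counts_matrix` (truth subset accordingly).
#' @export
cpm_filter <- function(cm, min_cpm = 5, min_samples = 2,
                       rule = c("retain", "discard_literal")) {
  rule <- match.arg(rule)
  stopifnot(inherits(cm, "counts_matrix"))
  lib <- colSums(cm$counts)
  if (any(lib <= 0)) stopf("library sizes must be positive")
  cpm <- edgeR::cpm(cm$counts, lib.size = lib)
  n_pass <- rowSums(cpm >= min_cpm)
  keep <- if (rule == "retain") n_pass >= min_samples
  else rowSums(cpm < min_cpm) < min_samples
  if (!any(keep))
    stopf("CPM filter removed every gene (min_cpm=%g, min_samples=%d)",
          min_cpm, min_samples)
  structure(list(counts = cm$counts[keep, , drop = FALSE],
                 gene_ids = cm$gene_ids[keep],
                 sample_groups = cm$sample_groups,
                 truth_fc = cm$truth_fc[keep]),
            class = "counts_matrix")
}

#' log2-CPM with a 0.5-count offset
#' @param cm a `counts_matrix`.
#' @export
log_cpm <- function(cm) {
  lib <- colSums(cm$counts)
  log2(sweep(cm$counts + 0.5, 2, lib + 1, "/") * 1e6)
}

#' Hierarchical clustering of samples on expression profiles
#'
#' Agglomerative clustering (average linkage by default) of samples on the
#' Euclidean distance between log2-CPM profiles, as used to show that
#' tract-associated biopsies separate from tumor bulk and normal tissue.
#' @param cm a `counts_matrix` (or a numeric gene-by-sample matrix of
#'   log-expression).
#' @param k optional number of flat clusters to cut.
#' @param method linkage method.
#' @return list with `hclust` and (when `k` given) integer `labels`.
#' @export
hier_cluster <- function(cm, k = NULL, method = "average") {
  m <- if (inherits(cm, "counts_matrix")) log_cpm(cm) else cm
  if (ncol(m) < 3) stopf("need >= 3 samples")
  hc <- stats::hclust(stats::dist(t(m)), method = method)
  out <- list(hclust = hc)
  if (!is.null(k)) out$labels <- stats::cutree(hc, k = k)
  out
}

#' voom differential expression for the tract contrast
#'
#' Precision-weighted linear modeling of log2-CPM: the mean-variance trend
#' of the standardized counts maps to per-observation weights, a linear
#' model is fitted per gene for the tract-vs-rest contrast (tumor and
#' normal pooled; `contrast = "three_group"` keeps them separate and tests
#' tract vs their average), and empirical-Bayes moderation yields the
#' moderated t and its p-value. Benjamini-Hochberg adjustment controls FDR.
#'
#' @param cm a filtered `counts_matrix` with a `"tract"` group.
#' @param contrast `"tract_vs_rest"` or `"three_group"`.
#' @return `de_table` data.frame: `gene_id`, `log2fc` (tract vs rest),
#'   `ave_log_cpm`, `t`, `p_value`, `q_value`.
#' @export
voom_de <- function(cm, contrast = c("tract_vs_rest", "three_group")) {
  contrast <- match.arg(contrast)
  stopifnot(inherits(cm, "counts_matrix"))
  grp <- cm$sample_groups
  if (!"tract" %in% levels(grp)) stopf("no 'tract' group present")
  if (sum(grp == "tract") < 2 || sum(grp != "tract") < 2)
    stopf("each side of the contrast needs >= 2 samples")
  if (contrast == "tract_vs_rest") {
    tract <- as.numeric(grp == "tract")
    design <- cbind(Intercept = 1, tract = tract)
    v <- limma::voom(cm$counts, design)
    fit <- limma::eBayes(limma::lmFit(v, design))
    tt <- limma::topTable(fit, coef = "tract", number = Inf,
                          sort.by = "none")
  } else {
    g <- droplevels(grp)
    design <- stats::model.matrix(~ 0 + g)
    colnames(design) <- levels(g)
    v <- limma::voom(cm$counts, design)
    fit <- limma::lmFit(v, design)
    others <- setdiff(levels(g), "tract")
    ctr <- limma::makeContrasts(
      contrasts = paste0("tract-(", paste(others, collapse = "+"), ")/",
                         length(others)),
      levels = design)
    fit <- limma::eBayes(limma::contrasts.fit(fit, ctr))
    tt <- limma::topTable(fit, coef = 1, number = Inf, sort.by = "none")
  }
  out <- data.frame(gene_id = cm$gene_ids,
                    log2fc = tt$logFC,
                    ave_log_cpm = tt$AveExpr,
                    t = tt$t,
                    p_value = tt$P.Value,
                    q_value = bh_adjust(tt$P.Value),
                    stringsAsFactors = FALSE)
  class(out) <- c("de_table", "data.frame")
  out
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' @param p numeric p-values in `[0, 1]`.
#' @return adjusted q-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Differential-expression call with fold-change and FDR thresholds
#'
#' Genes with `|log2FC| >= log2(fc_threshold)` and `q < q_threshold`; a
#' 2-fold minimum difference is the default call criterion.
#' @param table a `de_table`.
#' @param fc_threshold linear fold-change threshold (>= 1).
#' @param q_threshold FDR threshold.
#' @return data.frame with `gene_id`, `direction` ("up"/"down"), `log2fc`,
#'   `q_value`.
#' @export
de_call <- function(table, fc_threshold = 2, q_threshold = 0.05) {
  stopifnot(fc_threshold >= 1)
  sel <- abs(table$log2fc) >= log2(fc_threshold) &
    table$q_value < q_threshold
  out <- table[sel, c("gene_id", "log2fc", "q_value")]
  out$direction <- ifelse(out$log2fc > 0, "up", "down")
  rownames(out) <- NULL
  out[, c("gene_id", "direction", "log2fc", "q_value")]
}

#' Exact over-representation test of a gene set in a DE list
#'
#' One-sided hypergeometric tail probability of observing at least the seen
#' overlap between the DE set and an annotated set within the filtered
#' universe, plus the sample odds ratio of the 2x2 table. Stands in for a
#' full GO enrichment: same question, user-supplied gene sets.
#'
#' @param de_set character gene ids (subset of universe).
#' @param annotation_set character gene ids (subset of universe).
#' @param universe character gene ids.
#' @return `enrichment_result`: list with `overlap`, `set_size`,
#'   `de_count`, `universe_size`, `odds_ratio`, `p_value`.
#' @export
ora_fisher <- function(de_set, annotation_set, universe) {
  if (!length(universe)) stopf("empty universe")
  universe <- unique(universe)
  de_set <- unique(de_set); annotation_set <- unique(annotation_set)
  if (!all(de_set %in% universe) || !all(annotation_set %in% universe))
    stopf("de_set and annotation_set must be subsets of the universe")
  n_u <- length(universe)
  n_a <- length(annotation_set)
  n_d <- length(de_set)
  k <- length(intersect(de_set, annotation_set))
  p <- stats::phyper(k - 1, n_a, n_u - n_a, n_d, lower.tail = FALSE)
  tab <- c(k, n_d - k, n_a - k, n_u - n_a - n_d + k)
  or <- (tab[1] * tab[4]) / (tab[2] * tab[3])
  structure(list(overlap = k, set_size = n_a, de_count = n_d,
                 universe_size = n_u, odds_ratio = or, p_value = p),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "enrichment: %d/%d DE genes in set of %d (universe %d); OR %.2f, p = %.3g\n",
    x$overlap, x$de_count, x$set_size, x$universe_size, x$odds_ratio,
    x$p_value))
  invisible(x)
}

#' Read / write GMT gene-set files
#'
#' Tab-separated lines: set name, description, then member gene ids.
#' @param path GMT path.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  sets <- lapply(strsplit(lines, "\t"), function(f) f[-(1:2)])
  names(sets) <- vapply(strsplit(lines, "\t"), `[`, character(1), 1)
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, nm, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}
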