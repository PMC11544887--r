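#' Simulate an RNA-seq count matrix with a tract-group signal
#'
#' Negative-binomial counts with log-normal baseline expression and
#' log-normal library-size factors. A fraction of genes is up-regulated by
#' `fold_change` in the "tract" group, mimicking a motility-expression
#' signal in tract-associated biopsies; the true per-gene fold change is
#' recorded. The default group sizes reproduce a 13-sample biopsy design
#' (6 tract-associated, 5 tumor, 2 normal).
#'
#' @param n_genes number of genes.
#' @param samples_per_group named integer vector; names become group labels.
#' @param de_fraction fraction of genes differentially expressed in the
#'   "tract" group.
#' @param fold_change multiplicative effect (>= 1) for DE genes.
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2);
#'   values below 1e-8 fall back to Poisson.
#' @param seed RNG seed.
#' @return `counts_matrix`: list with integer `counts` (genes x samples),
#'   `gene_ids`, `sample_groups` (factor) and `truth_fc`.
#' @export
simulate_counts <- function(n_genes = 2000,
                            samples_per_group = c(tract = 6, tumor = 5,
                                                  normal = 2),
                            de_fraction = 0.1, fold_change = 2,
                            dispersion = 0.1, seed = 0) {
  stopifnot(n_genes >= 1, fold_change >= 1, dispersion >= 0)
  if (length(samples_per_group) < 2 || any(samples_per_group < 1))
    stopf("need >= 1 sample in each of >= 2 groups")
  n_de <- round(de_fraction * n_genes)
  if (de_fraction > 0 && n_de < 1)
    stopf("de_fraction * n_genes < 1: no DE gene can be simulated")
  groups <- factor(rep(names(samples_per_group), samples_per_group),
                   levels = names(samples_per_group))
  ns <- length(groups)
  with_seed(seed, {
    base_mean <- exp(stats::rnorm(n_genes, mean = log(200), sd = 1.2))
    lib_factor <- exp(stats::rnorm(ns, mean = 0, sd = 0.25))
    truth_fc <- rep(1, n_genes)
    if (n_de > 0) truth_fc[sample.int(n_genes, n_de)] <- fold_change
    mu <- outer(base_mean, lib_factor)
    if ("tract" %in% levels(groups))
      mu[, groups == "tract"] <- mu[, groups == "tract"] * truth_fc
    counts <- if (dispersion < 1e-8) {
      matrix(stats::rpois(n_genes * ns, lambda = mu), n_genes, ns)
    } else {
      matrix(stats::rnbinom(n_genes * ns, size = 1 / dispersion, mu = mu),
             n_genes, ns)
    }
    storage.mode(counts) <- "integer"
    gene_ids <- sprintf("gene%05d", seq_len(n_genes))
    rownames(counts) <- gene_ids
    colnames(counts) <- sprintf("%s_%d", groups, stats::ave(
      seq_len(ns), groups, FUN = seq_along))
    structure(list(counts = counts, gene_ids = gene_ids,
                   sample_groups = groups, truth_fc = truth_fc),
              class = "counts_matrix")
  })
}

#' @export
print.counts_matrix <- function(x, ...) {
  cat(sprintf("counts_matrix: %d genes x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s:%d", levels(x$sample_groups),
                            table(x$sample_groups)), collapse = ", ")))
  invisible(x)
}

#' Write / read counts and group labels
#'
#' Counts go to a TSV (genes x samples, first column `gene_id`); groups to a
#' two-column CSV (`sample_id,group`).
#' @param cm a `counts_matrix`.
#' @param counts_path,groups_path output paths.
#' @export
write_counts <- function(cm, counts_path, groups_path) {
  df <- data.frame(gene_id = cm$gene_ids, cm$counts, check.names = FALSE)
  utils::write.table(df, counts_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.csv(data.frame(sample_id = colnames(cm$counts),
                              group = as.character(cm$sample_groups)),
                   groups_path, row.names = FALSE)
  invisible(counts_path)
}

#' @rdname write_counts
#' @export
read_counts <- function(counts_path, groups_path) {
  df <- utils::read.delim(counts_path, check.names = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df$gene_id
  grp <- utils::read.csv(groups_path, stringsAsFactors = FALSE)
  stopifnot(identical(grp$sample_id, colnames(counts)))
  structure(list(counts = counts, gene_ids = df$gene_id,
                 sample_groups = factor(grp$group, levels = unique(grp$group)),
                 truth_fc = NULL),
            class = "counts_matrix")
}
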