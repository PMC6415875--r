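#' Upper-quartile normalization factors
#'
#' Per-sample scale factor equal to the 75th percentile of that sample's
#' nonzero counts (linear-interpolation quantile), rescaled so the factors
#' have geometric mean 1. Used to make expression levels comparable across
#' libraries before logCPM conversion.
#'
#' @param counts integer matrix, genes x samples (each sample needs at least
#'   one nonzero count).
#' @return Named numeric vector of scale factors (geometric mean 1), with
#'   attribute `raw_uq` (the unscaled upper quartiles).
#' @export
upper_quartile_normalize <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  uq <- apply(counts, 2, function(x) {
    nz <- x[x > 0]
    if (!length(nz)) {
      stop("a sample has all-zero counts; cannot normalize", call. = FALSE)
    }
    quantile(nz, 0.75, names = FALSE)  # type 7, linear interpolation
  })
  factors <- uq / exp(mean(log(uq)))
  names(factors) <- colnames(counts)
  structure(factors, raw_uq = uq)
}

#' Convert counts to log2 counts-per-million
#'
#' `log2((count + 0.5) / (factor * library_size + 1) * 1e6)`, where the
#' library size is the sample's total count and `factor` its upper-quartile
#' scale factor. The half-count offset keeps zeros finite.
#'
#' @param counts genes x samples count matrix.
#' @param factors per-sample scale factors from [upper_quartile_normalize()].
#' @return Matrix of logCPM values, same dimensions as `counts`.
#' @export
log_cpm <- function(counts, factors = upper_quartile_normalize(counts)) {
  counts <- as.matrix(counts)
  lib <- colSums(counts)
  eff <- factors * lib + 1
  log2(sweep(counts + 0.5, 2, eff, "/") * 1e6)
}

#' Standardize genes to unit variance
#'
#' Scales every gene (row) to variance 1 across samples so that each gene
#' contributes comparably to multivariate distances. Zero-variance genes are
#' dropped with a warning.
#'
#' @param mat numeric matrix, genes x samples (>= 2 samples).
#' @return The scaled matrix (possibly with fewer rows).
#' @export
standardize_genes <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2L) stop("standardization needs >= 2 samples", call. = FALSE)
  s <- apply(mat, 1, sd)
  zero <- s == 0 | !is.finite(s)
  if (all(zero)) stop("all genes have zero variance", call. = FALSE)
  if (any(zero)) {
    warning(sum(zero), " zero-variance gene(s) dropped", call. = FALSE)
    mat <- mat[!zero, , drop = FALSE]
    s <- s[!zero]
  }
  mat / s
}

# within-group mean pairwise distances from a full distance matrix
.delta_from_dist <- function(D, idx_by_group, N) {
  delta <- 0
  for (idx in idx_by_group) {
    n <- length(idx)
    xi <- sum(D[idx, idx]) / (n * (n - 1))  # mean over ordered pairs = mean pairwise
    delta <- delta + n / N * xi
  }
  delta
}

#' MRPP test statistic
#'
#' The multiresponse permutation procedure statistic for two (or more)
#' groups of samples in the subspace of one pathway's genes:
#' `delta = sum_g (n_g / N) * xi_g`, where `xi_g` is the mean pairwise
#' Euclidean distance between the samples of group g (classical MRPP group
#' weights n_g/N). Small delta indicates within-group cohesion, i.e. group
#' separation.
#'
#' @param mat numeric matrix, genes x samples, restricted to the pathway's
#'   genes (>= 1 row).
#' @param labels group label per sample; every group needs >= 2 samples.
#' @return The observed delta (>= 0).
#' @export
mrpp_statistic <- function(mat, labels) {
  mat <- if (is.null(dim(mat))) rbind(mat) else as.matrix(mat)
  labels <- as.character(labels)
  if (ncol(mat) != length(labels)) {
    stop("one label per sample required", call. = FALSE)
  }
  sizes <- table(labels)
  if (any(sizes < 2L)) {
    stop("every group needs at least 2 samples", call. = FALSE)
  }
  D <- as.matrix(dist(t(mat)))
  .delta_from_dist(D, split(seq_along(labels), labels), length(labels))
}

#' Permutation p-value for an observed MRPP statistic
#'
#' Permutes the group labels across samples and reports
#' `p = (1 + #\{delta_perm <= delta_obs\}) / (1 + n_perm)`. When
#' `exhaustive = TRUE` (or the number of distinct assignments is at most
#' `exhaustive_limit` with `exhaustive = NA`), all distinct label
#' assignments are enumerated and the exact proportion with
#' `delta <= delta_obs` is returned instead.
#'
#' @param delta_obs observed statistic (e.g. from [mrpp_statistic()]).
#' @param mat genes x samples matrix (pathway subspace).
#' @param labels group labels.
#' @param n_perm number of Monte-Carlo permutations (default 10000).
#' @param seed seed for the Monte-Carlo draw.
#' @param exhaustive TRUE/FALSE, or NA to choose automatically.
#' @param exhaustive_limit assignment-count threshold for the automatic
#'   choice (default 20000).
#' @return The p-value, with attribute `method` (`"exhaustive"` or
#'   `"monte-carlo"`) and `n_assignments` or `n_perm`.
#' @export
permutation_pvalue <- function(delta_obs, mat, labels, n_perm = 10000,
                               seed = 1, exhaustive = NA,
                               exhaustive_limit = 20000) {
  mat <- if (is.null(dim(mat))) rbind(mat) else as.matrix(mat)
  labels <- as.character(labels)
  N <- length(labels)
  D <- as.matrix(dist(t(mat)))
  groups <- unique(labels)
  n_assign <- exp(lgamma(N + 1) - sum(vapply(
    split(seq_len(N), labels), function(i) lgamma(length(i) + 1), 0)))
  if (is.na(exhaustive)) exhaustive <- n_assign <= exhaustive_limit

  if (exhaustive && length(groups) == 2L) {
    n1 <- sum(labels == groups[1])
    combs <- utils::combn(N, n1)
    deltas <- apply(combs, 2, function(idx) {
      .delta_from_dist(D, list(idx, setdiff(seq_len(N), idx)), N)
    })
    p <- mean(deltas <= delta_obs + 1e-12)
    return(structure(p, method = "exhaustive", n_assignments = ncol(combs)))
  }

  set.seed(seed)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    perm <- sample(labels)
    d <- .delta_from_dist(D, split(seq_len(N), perm), N)
    if (d <= delta_obs + 1e-12) hits <- hits + 1L
  }
  structure((1 + hits) / (1 + n_perm), method = "monte-carlo",
            n_perm = n_perm)
}

#' Benjamini-Hochberg selection
#'
#' Step-up FDR control at level `q`: returns BH-adjusted p-values and the
#' significance flags `p_adj <= q`.
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @param q FDR level (default 0.05).
#' @return Data frame `p`, `p_adj`, `significant` (empty input gives an
#'   empty frame).
#' @export
fdr_select <- function(pvalues, q = 0.05) {
  if (!length(pvalues)) {
    return(data.frame(p = numeric(0), p_adj = numeric(0),
                      significant = logical(0)))
  }
  p_adj <- p.adjust(pvalues, method = "BH")
  data.frame(p = pvalues, p_adj = p_adj, significant = p_adj <= q)
}

#' Read pathway gene sets from a GMT file
#'
#' @param path GMT file (tab-separated: set name, description, gene ids).
#' @return Named list of gene-id character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Pathway-level MRPP testing of a count matrix
#'
#' The full nonparametric pathway procedure: upper-quartile normalization,
#' logCPM conversion, gene standardization to unit variance, then for every
#' pathway the MRPP statistic over its genes, a permutation p-value, and
#' Benjamini-Hochberg selection at FDR `q` across pathways.
#'
#' @param counts genes x samples count matrix with gene-id rownames.
#' @param labels two-group sample labels.
#' @param pathways named list of gene-id vectors (e.g. from [read_gmt()]).
#' @param q FDR level (default 0.05).
#' @param n_perm Monte-Carlo permutations per pathway (default 10000;
#'   exhaustive enumeration is used automatically when feasible).
#' @param seed seed for the permutation draws.
#' @param min_genes pathways with fewer present genes are flagged (they are
#'   still tested down to 1 gene).
#' @return Data frame `pathway`, `n_genes`, `delta`, `p`, `p_adj`,
#'   `significant`, `flagged`; pathways with no present genes are dropped.
#' @export
mrpp_pathways <- function(counts, labels, pathways, q = 0.05,
                          n_perm = 10000, seed = 1, min_genes = 2L) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    stop("counts needs gene-id rownames", call. = FALSE)
  }
  factors <- upper_quartile_normalize(counts)
  lc <- log_cpm(counts, factors)
  lc <- suppressWarnings(standardize_genes(lc))
  res <- lapply(names(pathways), function(pw) {
    genes <- intersect(pathways[[pw]], rownames(lc))
    if (!length(genes)) return(NULL)
    sub <- lc[genes, , drop = FALSE]
    delta <- mrpp_statistic(sub, labels)
    p <- permutation_pvalue(delta, sub, labels, n_perm = n_perm, seed = seed)
    data.frame(pathway = pw, n_genes = length(genes), delta = delta,
               p = as.numeric(p), flagged = length(genes) < min_genes)
  })
  res <- do.call(rbind, res)
  if (is.null(res)) {
    stop("no pathway has any gene present in the matrix", call. = FALSE)
  }
  sel <- fdr_select(res$p, q = q)
  res$p_adj <- sel$p_adj
  res$significant <- sel$significant
  res[c("pathway", "n_genes", "delta", "p", "p_adj", "significant",
        "flagged")]
}
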