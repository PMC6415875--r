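#' Synthetic RNA-seq count scenario
#'
#' Negative-binomial count generator with pathway-level group shifts,
#' emulating a two-treatment shoot mRNA-seq design (default 4 replicates per
#' treatment, matching common in vitro experiments). Genes in the affected
#' pathways receive the stated log2 fold change in group 2.
#'
#' @param n_genes number of genes.
#' @param n_per_group samples per group (length-2 vector or scalar).
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2);
#'   0 gives Poisson counts.
#' @param lib_size_mu mean library-size scale (expected total counts scale).
#' @param lib_size_cv lognormal coefficient of variation of library sizes.
#' @param pathways named list of gene-id vectors; default: `n_pathways`
#'   disjoint sets of `pathway_size` genes.
#' @param n_pathways,pathway_size used only when `pathways` is NULL.
#' @param shifts named numeric vector: per-pathway log2 fold change applied
#'   to group 2 (names must be pathways; empty = global null).
#' @param baseline_log_mu,baseline_log_sd lognormal parameters of per-gene
#'   baseline mean expression.
#' @param seed mandatory seed.
#' @return A `count_scenario` list.
#' @export
count_scenario <- function(n_genes = 1000, n_per_group = c(4, 4),
                           dispersion = 0.1, lib_size_mu = 1,
                           lib_size_cv = 0.2, pathways = NULL,
                           n_pathways = 20, pathway_size = 10,
                           shifts = numeric(0),
                           baseline_log_mu = log(50), baseline_log_sd = 1,
                           seed) {
  if (missing(seed) || is.null(seed)) {
    stop("a seed is mandatory in a count_scenario", call. = FALSE)
  }
  if (length(n_per_group) == 1L) n_per_group <- rep(n_per_group, 2L)
  if (dispersion < 0) stop("dispersion must be >= 0", call. = FALSE)
  if (is.null(pathways)) {
    if (n_pathways * pathway_size > n_genes) {
      stop("n_pathways * pathway_size exceeds n_genes", call. = FALSE)
    }
    ids <- sprintf("g%04d", seq_len(n_genes))
    pathways <- split(ids[seq_len(n_pathways * pathway_size)],
                      rep(seq_len(n_pathways), each = pathway_size))
    names(pathways) <- sprintf("pw%03d", seq_len(n_pathways))
  }
  if (length(shifts) && !all(names(shifts) %in% names(pathways))) {
    stop("shift specified for unknown pathway: ",
         paste(setdiff(names(shifts), names(pathways)), collapse = ", "),
         call. = FALSE)
  }
  structure(list(n_genes = n_genes, n_per_group = n_per_group,
                 dispersion = dispersion, lib_size_mu = lib_size_mu,
                 lib_size_cv = lib_size_cv, pathways = pathways,
                 shifts = shifts, baseline_log_mu = baseline_log_mu,
                 baseline_log_sd = baseline_log_sd,
                 seed = as.integer(seed)),
            class = "count_scenario")
}

#' Simulate a count matrix with pathway effects
#'
#' @param scenario a [count_scenario()].
#' @return List: `counts` (genes x samples integer matrix), `labels`
#'   (`"group1"`/`"group2"`), `pathways`, and `truth` (data frame `pathway`,
#'   `log2fc`, `affected`).
#' @export
simulate_counts <- function(scenario) {
  stopifnot(inherits(scenario, "count_scenario"))
  sc <- scenario
  set.seed(sc$seed)
  n1 <- sc$n_per_group[1]; n2 <- sc$n_per_group[2]
  n_samples <- n1 + n2
  labels <- rep(c("group1", "group2"), c(n1, n2))
  ids <- sprintf("g%04d", seq_len(sc$n_genes))

  base_mu <- exp(rnorm(sc$n_genes, sc$baseline_log_mu, sc$baseline_log_sd))
  sdlog <- sqrt(log(1 + sc$lib_size_cv^2))
  libfac <- sc$lib_size_mu * exp(rnorm(n_samples, -sdlog^2 / 2, sdlog))

  lfc <- setNames(numeric(sc$n_genes), ids)
  for (pw in names(sc$shifts)) {
    genes <- intersect(sc$pathways[[pw]], ids)
    lfc[genes] <- lfc[genes] + sc$shifts[[pw]]
  }
  mu <- outer(base_mu, libfac)
  mu[, labels == "group2"] <- mu[, labels == "group2"] *
    2^lfc  # recycles per column
  counts <- if (sc$dispersion > 0) {
    matrix(rnbinom(length(mu), mu = mu, size = 1 / sc$dispersion),
           nrow = sc$n_genes)
  } else {
    matrix(stats::rpois(length(mu), lambda = mu), nrow = sc$n_genes)
  }
  rownames(counts) <- ids
  colnames(counts) <- sprintf("s%02d", seq_len(n_samples))
  truth <- data.frame(
    pathway = names(sc$pathways),
    log2fc = vapply(names(sc$pathways),
                    function(p) if (p %in% names(sc$shifts))
                      sc$shifts[[p]] else 0, 0),
    row.names = NULL)
  truth$affected <- truth$log2fc != 0
  list(counts = counts, labels = labels, pathways = sc$pathways,
       truth = truth)
}

#' Write pathways to a GMT file
#'
#' @param pathways named list of gene-id vectors.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(pathways, path) {
  lines <- vapply(names(pathways), function(nm) {
    paste(c(nm, "na", pathways[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
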