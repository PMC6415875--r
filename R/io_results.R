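#' Write a stage result table with provenance header
#'
#' Writes a TSV preceded by `#`-prefixed provenance lines: package version,
#' the hash of the configuration used, the seed, and any extra parameters.
#' Output is byte-identical across reruns with the same inputs and
#' configuration.
#'
#' @param table a data frame (may have zero rows: a header-only file is
#'   written).
#' @param path output path; the parent directory must exist.
#' @param config list of configuration values hashed into the header.
#' @param seed seed recorded in the header.
#' @param extra named character vector of additional header fields.
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path, config = list(), seed = NA,
                          extra = c()) {
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    stop("parent directory does not exist: ", dir, call. = FALSE)
  }
  hdr <- c(
    sprintf("# chamberflux_version: %s", as.character(packageVersion("chamberflux"))),
    sprintf("# config_hash: %s", rlang::hash(config)),
    sprintf("# seed: %s", as.character(seed)),
    if (length(extra)) sprintf("# %s: %s", names(extra), extra)
  )
  con <- file(path, open = "wb")  # binary: identical bytes on all platforms
  on.exit(close(con))
  writeLines(hdr, con)
  tbl <- as.data.frame(table)
  num <- vapply(tbl, is.numeric, TRUE)
  tbl[num] <- lapply(tbl[num], function(x) format(x, digits = 15, trim = TRUE))
  writeLines(paste(names(tbl), collapse = "\t"), con)
  if (nrow(tbl)) {
    writeLines(do.call(paste, c(unname(tbl), sep = "\t")), con)
  }
  invisible(path)
}

#' Read a stage result table written by [write_results()]
#'
#' @param path path to the TSV.
#' @return Data frame with attribute `header` (named character vector of the
#'   provenance fields).
#' @export
read_results <- function(path) {
  lines <- readLines(path)
  hdr_lines <- grep("^#", lines, value = TRUE)
  kv <- regmatches(hdr_lines, regexec("^# ([^:]+): (.*)$", hdr_lines))
  hdr <- setNames(vapply(kv, `[`, "", 3), vapply(kv, `[`, "", 2))
  body <- lines[!grepl("^#", lines)]
  tf <- textConnection(body)
  on.exit(close(tf))
  df <- read.csv(tf, sep = "\t")
  structure(df, header = hdr)
}
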