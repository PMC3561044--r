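## Readers and writers. Codon positions are 1-based and inclusive in every
## file; TSVs carry a header line and optional '#'-prefixed metadata.

#' Read in-frame ORF sequences from a FASTA file
#'
#' Records must be coding-strand, in-frame ORFs starting with AUG/ATG;
#' a terminal stop codon is allowed and stripped, internal stops are
#' rejected. T is normalised to U and case is folded.
#'
#' @param path FASTA file.
#' @return Named list mapping gene id (first whitespace-delimited token of
#'   the header) to a sense-codon vector.
#' @export
read_orf_fasta <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[[`, "", 1)
  if (anyDuplicated(ids))
    stop("duplicate record id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  out <- vector("list", length(seqs))
  names(out) <- ids
  stops <- c("UAA", "UAG", "UGA")
  for (i in seq_along(seqs)) {
    s <- as.character(seqs[[i]])
    codons <- tryCatch(as_codons(s), error = function(e)
      stop("record '", ids[i], "': ", conditionMessage(e), call. = FALSE))
    if (codons[1] != "AUG")
      stop("record '", ids[i], "' does not start with AUG")
    if (codons[length(codons)] %in% stops) codons <- codons[-length(codons)]
    if (any(codons %in% stops))
      stop("record '", ids[i], "' contains an internal stop codon")
    out[[i]] <- codons
  }
  out
}

#' Read an experimental ribosome-density table
#'
#' TSV with header columns `gene_id`, `rho_exp` (ribosomes per codon) and
#' optionally `F` (polysome-loaded fraction in `[0, 1]`).
#'
#' @param path TSV file; `#` lines are ignored.
#' @return Data frame of density records.
#' @export
read_density_tsv <- function(path) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("gene_id", "rho_exp") %in% names(df)))
    stop("density table must have columns gene_id, rho_exp")
  if ("F" %in% names(df) && any(df$F < 0 | df$F > 1, na.rm = TRUE))
    stop("polysome fractions F must lie in [0, 1]")
  df
}

#' Write a density table
#' @param density data frame with at least `gene_id`, `rho_exp`.
#' @param path output TSV path.
#' @export
write_density_tsv <- function(density, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# ribosome density, ribosomes per codon; positions 1-based",
             con)
  write.table(density, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an mRNA-abundance table
#'
#' TSV with header columns `gene_id` and `m` (transcript copies per cell).
#'
#' @param path TSV file.
#' @return Data frame.
#' @export
read_abundance_tsv <- function(path) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("gene_id", "m") %in% names(df)))
    stop("abundance table must have columns gene_id, m")
  if (any(df$m < 0)) stop("mRNA abundances must be >= 0")
  df
}

#' Write one response curve as TSV
#'
#' Columns: `alpha`, `J_raw`, `J_stderr`, `rho_raw`, `rho_stderr`,
#' `J_smooth`, `rho_smooth`.
#'
#' @param curve a `response_curve`.
#' @param path output path.
#' @export
write_curve_tsv <- function(curve, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# gene_id: ", curve$gene_id), con)
  writeLines(paste0("# smooth_window: ", curve$smooth_window), con)
  write.table(as.data.frame(curve), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a response curve written by [write_curve_tsv()]
#' @param path TSV path.
#' @return A `response_curve`.
#' @export
read_curve_tsv <- function(path) {
  hdr <- readLines(path, n = 10)
  gid <- sub("^# gene_id: ", "", grep("^# gene_id: ", hdr, value = TRUE)[1])
  win <- as.numeric(sub("^# smooth_window: ", "",
                        grep("^# smooth_window: ", hdr, value = TRUE)[1]))
  if (is.na(win)) win <- 10
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  cv <- response_curve(gene_id = gid, alpha = df$alpha, J_raw = df$J_raw,
                       rho_raw = df$rho_raw, J_stderr = df$J_stderr,
                       rho_stderr = df$rho_stderr, smooth_window = win)
  # preserve the stored smoothed series verbatim
  cv$J_smooth <- df$J_smooth
  cv$rho_smooth <- df$rho_smooth
  cv
}

#' Write a transcript summary table
#' @param summary data frame from [infer_genomewide()].
#' @param path output TSV path.
#' @export
write_summary_tsv <- function(summary, path) {
  write.table(summary, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records the package version, master seed and full configuration so
#' that any stochastic output is reproducible from the manifest alone.
#'
#' @param path output YAML path.
#' @param config a `sim_config` (or any list) to echo.
#' @param ... further named fields to record.
#' @export
write_manifest <- function(path, config, ...) {
  yaml::write_yaml(c(list(package = "ribotraffic",
                          version = as.character(packageVersion("ribotraffic")),
                          config = unclass(config)), list(...)), path)
  invisible(path)
}

#' Read a run configuration
#' @param path YAML file.
#' @return Named list.
#' @export
read_run_config <- function(path) yaml::read_yaml(path)
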