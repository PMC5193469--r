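#' Read a per-nucleus spot-count table
#'
#' Reads the tab-delimited per-nucleus format: header row with columns
#' `case_id`, `chromosome` (chr1|chr9|chr10|chr19), `nucleus_id`, `n_red`,
#' `n_green`. Malformed rows (unknown chromosome, negative or non-integer
#' counts) are reported with their line numbers.
#'
#' @param path path to a TSV file.
#' @return data frame with the five typed columns.
#' @examples
#' tsv <- system.file("extdata", "example_nucleus_counts.tsv",
#'                    package = "FISHcall")
#' head(readNucleusCounts(tsv))
#' @export
readNucleusCounts <- function(path) {
  if (!file.exists(path)) abort("readNucleusCounts: no such file: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("case_id", "chromosome", "nucleus_id", "n_red", "n_green")
  if (!all(need %in% names(df)))
    abort("readNucleusCounts: missing column(s): %s",
          paste(setdiff(need, names(df)), collapse = ", "))
  line <- seq_len(nrow(df)) + 1L   # header is line 1
  bad <- function(cond, what) {
    if (any(cond))
      abort("readNucleusCounts: %s at line(s) %s", what,
            paste(utils::head(line[cond], 10), collapse = ", "))
  }
  bad(!df$chromosome %in% CHROM_IDS, "unknown chromosome")
  red <- suppressWarnings(as.numeric(df$n_red))
  green <- suppressWarnings(as.numeric(df$n_green))
  bad(is.na(red) | is.na(green), "non-numeric count")
  bad(red < 0 | green < 0, "negative count")
  bad(red != floor(red) | green != floor(green), "non-integer count")
  data.frame(case_id = df$case_id, chromosome = df$chromosome,
             nucleus_id = df$nucleus_id, n_red = as.integer(red),
             n_green = as.integer(green), stringsAsFactors = FALSE)
}

#' Write a per-nucleus spot-count table
#'
#' @param counts data frame in the format of [readNucleusCounts()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeNucleusCounts <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write a cutoff configuration file
#'
#' Cutoffs travel as a small YAML file:
#' ```yaml
#' source: calibrated
#' chromosomes:
#'   chr9: {deletion_cutoff: 30, imbalance_cutoff: 40}
#' ```
#' Chromosomes absent from the file keep their published defaults.
#'
#' @param path YAML file path.
#' @param cutoffs a [CutoffSet-class] (for writing).
#' @return `readCutoffConfig()`: a [CutoffSet-class];
#'   `writeCutoffConfig()`: `path`, invisibly.
#' @export
readCutoffConfig <- function(path) {
  if (!file.exists(path)) abort("readCutoffConfig: no such file: %s", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$chromosomes))
    abort("readCutoffConfig: 'chromosomes' block missing in %s", path)
  base <- defaultCutoffs()
  df <- base@cutoffs
  for (id in names(cfg$chromosomes)) {
    if (!id %in% CHROM_IDS)
      abort("readCutoffConfig: unknown chromosome '%s'", id)
    entry <- cfg$chromosomes[[id]]
    i <- which(df$chrom == id)
    if (!is.null(entry$deletion_cutoff)) {
      df$deletion[i] <- entry$deletion_cutoff
      if (chromPair(id)@monosomyRule) df$monosomy[i] <- entry$deletion_cutoff
    }
    if (!is.null(entry$imbalance_cutoff))
      df$imbalance[i] <- entry$imbalance_cutoff
  }
  src <- if (is.null(cfg$source)) "defaults" else cfg$source
  new("CutoffSet", cutoffs = df, source = src,
      provenance = sprintf("loaded from %s", path))
}

#' @rdname readCutoffConfig
#' @export
writeCutoffConfig <- function(cutoffs, path) {
  stopifnot(is(cutoffs, "CutoffSet"))
  df <- cutoffs@cutoffs
  chroms <- lapply(seq_len(nrow(df)), function(i)
    list(deletion_cutoff = df$deletion[i], imbalance_cutoff = df$imbalance[i]))
  names(chroms) <- df$chrom
  yaml::write_yaml(list(source = cutoffs@source,
                        provenance = cutoffs@provenance,
                        chromosomes = chroms), path)
  invisible(path)
}

#' Write a per-case call table
#'
#' @param calls data frame from [callCohort()].
#' @param path output path (tab-delimited).
#' @return `path`, invisibly.
#' @export
writeCallTable <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
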