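#' Read a wild-type sequence from a FASTA file or a literal string
#'
#' If `source` names an existing file it is parsed as FASTA and must contain
#' exactly one record; otherwise it is taken as a literal sequence. Either
#' way the result is validated and uppercased.
#'
#' @param source path to a single-record FASTA file, or a bare sequence
#'   string.
#' @return a validated DNA sequence string.
#' @export
read_sequence <- function(source) {
  if (!is.character(source) || length(source) != 1L)
    stop("sequence source must be a single string", call. = FALSE)
  if (file.exists(source) && !dir.exists(source)) {
    set <- Biostrings::readDNAStringSet(source)
    if (length(set) != 1L)
      stop("ambiguous input: FASTA file ", source, " contains ",
           length(set), " records; exactly one is required", call. = FALSE)
    as_dna(as.character(set[[1]]), "FASTA sequence")
  } else {
    as_dna(source)
  }
}

.numeric_cols <- function(results) {
  names(results)[vapply(results, is.numeric, logical(1L)) &
                   names(results) != "rank"]
}

.config_header <- function(results, seed = NULL) {
  cfg <- attr(results, "cfg")
  c(paste0("# shapedesign version=", as.character(packageVersion("shapedesign"))),
    paste0("# wt=", attr(results, "wt")),
    paste0("# positions=", paste(attr(results, "positions"), collapse = ",")),
    paste0("# focal=", if (is.null(cfg$focal)) "all"
           else paste(cfg$focal, collapse = ",")),
    paste0("# features=", paste(cfg$features, collapse = ",")),
    paste0("# shape_metric=", cfg$shape_metric),
    paste0("# base_metric=", cfg$base_metric),
    paste0("# normalize=", .resolve_normalize(cfg)),
    paste0("# objective=", attr(results, "objective")),
    if (!is.null(seed)) paste0("# seed=", seed))
}

#' Write a design-result panel to TSV or JSON
#'
#' TSV output starts with `#`-prefixed provenance lines (configuration echo,
#' tool version, seed), then one row per candidate; numeric distance columns
#' use fixed 6-decimal formatting, so identical runs serialise
#' byte-identically. JSON output carries the same content as an object with
#' `config` and `candidates` keys.
#'
#' @param results a `design_result` from [run_design()].
#' @param path output file path.
#' @param format `"tsv"` (default) or `"json"`.
#' @param seed optional seed recorded in the provenance header.
#' @return `path`, invisibly.
#' @seealso [read_results()]
#' @export
write_results <- function(results, path, format = c("tsv", "json"),
                          seed = NULL) {
  format <- match.arg(format)
  stopifnot(inherits(results, "design_result"), nrow(results) >= 1L)
  if (format == "tsv") {
    df <- as.data.frame(results)
    for (col in .numeric_cols(results))
      df[[col]] <- sprintf("%.6f", df[[col]])
    df$is_wildtype <- ifelse(df$is_wildtype, "true", "false")
    con <- file(path, open = "wb")  # binary mode: LF on every platform
    on.exit(close(con))
    writeLines(.config_header(results, seed), con)
    writeLines(paste(names(df), collapse = "\t"), con)
    writeLines(do.call(paste, c(df, sep = "\t")), con)
  } else {
    cfg <- attr(results, "cfg")
    payload <- list(
      config = list(
        version = as.character(packageVersion("shapedesign")),
        wt = attr(results, "wt"),
        positions = attr(results, "positions"),
        focal = if (is.null(cfg$focal)) "all" else cfg$focal,
        features = cfg$features,
        shape_metric = cfg$shape_metric,
        base_metric = cfg$base_metric,
        normalize = .resolve_normalize(cfg),
        objective = attr(results, "objective"),
        seed = seed),
      candidates = as.data.frame(results))
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = 6,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Read back a TSV design-result file
#'
#' Round-trip reader for files written by [write_results()] (TSV dialect).
#' Provenance header lines are returned in the `"header"` attribute.
#'
#' @param path TSV file written by [write_results()].
#' @return a data.frame with the candidate table.
#' @export
read_results <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  df <- read.delim(text = lines[!startsWith(lines, "#")], sep = "\t",
                   stringsAsFactors = FALSE,
                   colClasses = c(sequence = "character",
                                  substitutions = "character"))
  df$is_wildtype <- df$is_wildtype == "true"
  attr(df, "header") <- hdr
  df
}
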