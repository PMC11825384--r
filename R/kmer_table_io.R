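# Plain-text k-mer table dialect: UTF-8, tab-separated, first non-comment
# line "kmer\t<feature>..."; one row per k-mer; '#' lines ignored; row order
# irrelevant. The writer emits lexicographic k-mer order with fixed
# 6-decimal values so identical tables serialise byte-identically.

#' Read a k-mer shape table from a text file
#'
#' Validates the file structurally (ragged rows, non-numeric values,
#' duplicate k-mers, mixed word lengths — all reported with the offending
#' line number), checks completeness (all `4^k` k-mers present for every
#' feature) and reverse-complement parity consistency.
#'
#' @param path file path.
#' @param on_parity_violation `"warn"` (default), `"error"` or `"ignore"`:
#'   what to do when a feature's values break its reverse-complement parity.
#' @return a `kmer_shape_table`.
#' @seealso [write_kmer_table()], [synth_table()]
#' @export
read_kmer_table <- function(path,
                            on_parity_violation = c("warn", "error", "ignore")) {
  on_parity_violation <- match.arg(on_parity_violation)
  if (!file.exists(path))
    stop("k-mer table file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines))
    stop("format error: empty k-mer table file ", path, call. = FALSE)

  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  if (length(header) < 2L || header[1] != "kmer")
    stop("format error (line ", lineno[1],
         "): header must be 'kmer<TAB><feature>...'", call. = FALSE)
  features <- header[-1]
  .feature_info(features)  # validates names, suggests on typo
  if (anyDuplicated(features))
    stop("format error (line ", lineno[1], "): duplicated feature column",
         call. = FALSE)

  rows <- fields[-1]
  rowno <- lineno[-1]
  if (!length(rows))
    stop("format error: table has no data rows", call. = FALSE)
  nf <- lengths(rows)
  if (any(nf != length(header))) {
    i <- which(nf != length(header))[1]
    stop("format error (line ", rowno[i], "): expected ", length(header),
         " fields, found ", nf[i], call. = FALSE)
  }
  kmers <- toupper(vapply(rows, `[[`, character(1L), 1L))
  k <- nchar(kmers[1])
  if (any(nchar(kmers) != k)) {
    i <- which(nchar(kmers) != k)[1]
    stop("format error (line ", rowno[i], "): mixed k-mer lengths (",
         nchar(kmers[i]), " vs ", k, ")", call. = FALSE)
  }
  bad_sym <- grepl("[^ACGT]", kmers)
  if (any(bad_sym)) {
    i <- which(bad_sym)[1]
    stop("format error (line ", rowno[i], "): invalid k-mer ",
         sQuote(kmers[i]), call. = FALSE)
  }
  if (anyDuplicated(kmers)) {
    i <- which(duplicated(kmers))[1]
    stop("format error (line ", rowno[i], "): duplicate k-mer ",
         sQuote(kmers[i]), call. = FALSE)
  }

  vals <- matrix(NA_real_, nrow = length(kmers), ncol = length(features),
                 dimnames = list(kmers, features))
  for (j in seq_along(features)) {
    raw <- vapply(rows, `[[`, character(1L), j + 1L)
    num <- suppressWarnings(as.numeric(raw))
    if (anyNA(num)) {
      i <- which(is.na(num))[1]
      stop("format error (line ", rowno[i], "): non-numeric value ",
           sQuote(raw[i]), " for feature ", features[j], call. = FALSE)
    }
    vals[, j] <- num
  }

  expected <- all_kmers(k)
  missing <- setdiff(expected, kmers)
  if (length(missing))
    stop("missing k-mer(s): table lacks ", length(missing), " of 4^", k,
         " words, e.g. ", paste(utils::head(missing, 3L), collapse = ", "),
         call. = FALSE)
  vals <- vals[expected, , drop = FALSE]

  table <- .new_kmer_table(k, vals)
  if (on_parity_violation != "ignore") {
    viol <- check_parity(table)
    if (nrow(viol)) {
      msg <- paste0("reverse-complement parity violated for ",
                    nrow(viol), " k-mer pair(s) in feature(s) ",
                    paste(unique(viol$feature), collapse = ", "),
                    " (e.g. ", viol$kmer[1], " vs revcomp)")
      if (on_parity_violation == "error") stop(msg, call. = FALSE)
      warning(msg, call. = FALSE)
    }
  }
  table
}

#' Write a k-mer shape table to a text file
#'
#' Emits the documented tab-separated dialect: lexicographic k-mer order,
#' fixed 6-decimal values. Two equal tables serialise byte-identically.
#'
#' @param table a `kmer_shape_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_kmer_table <- function(table, path) {
  stopifnot(inherits(table, "kmer_shape_table"))
  kmers <- all_kmers(table$k)
  vals <- table$values[kmers, , drop = FALSE]
  body <- vapply(seq_along(kmers), function(i) {
    paste(c(kmers[i], sprintf("%.6f", vals[i, ])), collapse = "\t")
  }, character(1L))
  writeLines(c(paste(c("kmer", table$features), collapse = "\t"), body),
             path)
  invisible(path)
}
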