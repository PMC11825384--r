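# The 14-feature shape catalogue. Step (inter-base pair) and intra-base pair
# parameter names and reverse-complement sign conventions follow the standard
# 3DNA rigid-body nomenclature; MGW and EP are groove-class features with one
# value per base pair. rc_parity records whether reading the molecule on the
# opposite strand preserves (SYMMETRIC) or negates (ANTISYMMETRIC) the value.
.SHAPE_CATALOGUE <- data.frame(
  name = c("Shift", "Slide", "Rise", "Tilt", "Roll", "HelT",
           "Shear", "Stretch", "Stagger", "Buckle", "ProT", "Opening",
           "MGW", "EP"),
  klass = c(rep("INTER_BP", 6L), rep("INTRA_BP", 6L), rep("GROOVE", 2L)),
  rc_parity = c("ANTISYMMETRIC", "SYMMETRIC", "SYMMETRIC",
                "ANTISYMMETRIC", "SYMMETRIC", "SYMMETRIC",
                "ANTISYMMETRIC", "SYMMETRIC", "SYMMETRIC",
                "ANTISYMMETRIC", "SYMMETRIC", "SYMMETRIC",
                "SYMMETRIC", "SYMMETRIC"),
  stringsAsFactors = FALSE
)

# Typical magnitudes used by the synthetic-table generator: per-feature centre
# and spread on the scales the features are conventionally reported in
# (angstroms for translations and MGW, degrees for rotations, kT/e for EP).
# Antisymmetric features are centred at 0 by necessity: their value must
# negate under reverse complement.
.SHAPE_SCALES <- data.frame(
  name = .SHAPE_CATALOGUE$name,
  mu = c(0, -0.5, 3.32, 0, 2.0, 34.3,
         0, -0.1, 0.05, 0, -8.0, 1.5,
         5.1, -4.5),
  sigma = c(0.25, 0.35, 0.12, 1.5, 3.0, 1.5,
            0.2, 0.05, 0.2, 5.0, 3.0, 2.5,
            0.45, 1.0),
  stringsAsFactors = FALSE
)

#' The DNA shape feature catalogue
#'
#' Fourteen features: six inter-base pair (step) parameters (Shift, Slide,
#' Rise, Tilt, Roll, HelT), six intra-base pair parameters (Shear, Stretch,
#' Stagger, Buckle, ProT, Opening) and two minor-groove features (MGW, EP).
#' For a length-n sequence a step feature has n-1 values; intra-base pair and
#' groove features have n values. `rc_parity` gives each feature's sign
#' behaviour under reverse complement.
#'
#' @return a data.frame with columns `name`, `klass` (one of `"INTER_BP"`,
#'   `"INTRA_BP"`, `"GROOVE"`) and `rc_parity` (`"SYMMETRIC"` or
#'   `"ANTISYMMETRIC"`).
#' @export
#' @examples
#' table(feature_catalogue()$klass)
feature_catalogue <- function() .SHAPE_CATALOGUE

.feature_info <- function(features) {
  cat <- .SHAPE_CATALOGUE
  bad <- setdiff(features, cat$name)
  if (length(bad)) {
    sugg <- vapply(bad, function(b) {
      d <- adist(toupper(b), toupper(cat$name))
      cat$name[which.min(d)]
    }, character(1L))
    stop("unknown shape feature(s): ", paste(sQuote(bad), collapse = ", "),
         "; did you mean ", paste(sQuote(unique(sugg)), collapse = ", "),
         "? Valid names: ", paste(cat$name, collapse = ", "), call. = FALSE)
  }
  cat[match(features, cat$name), , drop = FALSE]
}

#' All k-mers over the DNA alphabet, in lexicographic order
#'
#' @param k word length.
#' @return character vector of length `4^k`.
#' @export
all_kmers <- function(k) {
  stopifnot(is.numeric(k), length(k) == 1L, k >= 1L)
  out <- ""
  for (i in seq_len(k)) out <- paste0(rep(out, each = 4L), DNA_BASES)
  out
}

.revcomp_vec <- function(kmers) {
  vapply(strsplit(chartr("ACGT", "TGCA", kmers), "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1L))
}

.new_kmer_table <- function(k, values, edge_policy = "mean") {
  structure(
    list(k = as.integer(k),
         features = colnames(values),
         values = values,
         edge_policy = edge_policy,
         cache = new.env(parent = emptyenv())),
    class = "kmer_shape_table")
}

#' @export
print.kmer_shape_table <- function(x, ...) {
  cat("k-mer shape table: k =", x$k, "(", nrow(x$values), "k-mers ),",
      length(x$features), "feature(s):",
      paste(x$features, collapse = ", "), "\n")
  cat("edge policy:", x$edge_policy, "\n")
  invisible(x)
}

#' Generate a deterministic synthetic k-mer shape table
#'
#' Builds a complete lookup table assigning every k-mer one value per
#' requested feature, reverse-complement consistent by construction: a raw
#' draw `g(w)` per k-mer is symmetrised as
#' `value(w) = (g(w) + parity * g(revcomp(w))) / 2` with `parity = +1` for
#' SYMMETRIC and `-1` for ANTISYMMETRIC features, then placed on each
#' feature's conventional scale. Identical `(k, features, seed)` yield
#' byte-identical tables; the caller's RNG state is untouched.
#'
#' The table emulates the smooth sequence dependence of real shape features
#' (a fixed value per local sequence context) but its values are random: it
#' is a structurally valid stand-in for a trained predictor, not a source of
#' physical shape values.
#'
#' @param k odd window width, one of 3, 5, 7. Default 5.
#' @param features character vector of catalogue feature names; default the
#'   full 14-feature catalogue.
#' @param seed integer seed.
#' @param edge_policy default edge policy stored with the table; see
#'   [predict_shape()].
#' @return a `kmer_shape_table`.
#' @export
#' @examples
#' tab <- synth_table(3, c("MGW", "Roll"), seed = 1)
#' nrow(tab$values)  # 64
synth_table <- function(k = 5L, features = feature_catalogue()$name,
                        seed = 1L, edge_policy = "mean") {
  if (length(k) != 1L || !is.numeric(k) || k %% 2L == 0L || !k %in% c(3L, 5L, 7L))
    stop("invalid window: k must be an odd integer in {3, 5, 7}", call. = FALSE)
  info <- .feature_info(features)
  kmers <- all_kmers(k)
  rc_idx <- match(.revcomp_vec(kmers), kmers)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))

  vals <- matrix(NA_real_, nrow = length(kmers), ncol = nrow(info),
                 dimnames = list(kmers, info$name))
  for (j in seq_len(nrow(info))) {
    g <- rnorm(length(kmers))
    parity <- if (info$rc_parity[j] == "SYMMETRIC") 1 else -1
    sym <- (g + parity * g[rc_idx]) / 2
    sc <- .SHAPE_SCALES[match(info$name[j], .SHAPE_SCALES$name), ]
    vals[, j] <- if (parity == 1) sc$mu + sc$sigma * sym else sc$sigma * sym
  }
  .new_kmer_table(k, vals, edge_policy = edge_policy)
}

#' Check reverse-complement parity consistency of a k-mer table
#'
#' @param table a `kmer_shape_table`.
#' @param tol numeric tolerance.
#' @return a data.frame of violations (feature, kmer, value, rc_value);
#'   zero rows when the table is parity-consistent.
#' @export
check_parity <- function(table, tol = 1e-6) {
  stopifnot(inherits(table, "kmer_shape_table"))
  kmers <- rownames(table$values)
  rc_idx <- match(.revcomp_vec(kmers), kmers)
  info <- .feature_info(table$features)
  out <- list()
  for (j in seq_along(table$features)) {
    parity <- if (info$rc_parity[j] == "SYMMETRIC") 1 else -1
    v <- table$values[, j]
    bad <- which(abs(v[rc_idx] - parity * v) > tol)
    bad <- bad[kmers[bad] <= kmers[rc_idx[bad]]]  # report each pair once
    if (length(bad))
      out[[info$name[j]]] <- data.frame(
        feature = info$name[j], kmer = kmers[bad],
        value = unname(v[bad]), rc_value = unname(v[rc_idx[bad]]),
        stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(feature = character(), kmer = character(),
                      value = numeric(), rc_value = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# Look up table values for a vector of width-k windows that may contain "N"
# placeholders for off-sequence flank positions. Windows without N are direct
# row lookups; windows with N are resolved under the "mean" edge policy by
# averaging over all k-mers matching the known context (marginalising the
# missing flanks), with results memoised per table.
.lookup_windows <- function(table, windows, feature) {
  vals <- table$values[, feature]
  out <- rep(NA_real_, length(windows))
  has_n <- grepl("N", windows, fixed = TRUE)
  out[!has_n] <- vals[windows[!has_n]]
  if (any(has_n)) {
    for (w in unique(windows[has_n])) {
      key <- paste0(feature, "|", w)
      m <- table$cache[[key]]
      if (is.null(m)) {
        ch <- .seq_chars(w)
        opts <- lapply(ch, function(c) if (c == "N") DNA_BASES else c)
        grid <- do.call(expand.grid,
                        c(opts, list(stringsAsFactors = FALSE)))
        matches <- do.call(paste0, grid)
        m <- mean(vals[matches])
        assign(key, m, envir = table$cache)
      }
      out[windows == w] <- m
    }
  }
  out
}

#' Predict a DNA shape profile from a k-mer lookup table
#'
#' Slides the table's width-k window along the sequence. Intra-base pair and
#' groove features take, at each position, the table value of the window
#' centred there (n values). A step feature value at step t (between
#' positions t and t+1) is the average of the table values of the two
#' windows centred on its flanking positions t and t+1 (n-1 values) — the
#' symmetrised convention that makes profiles exactly reverse-complement
#' equivariant under a parity-consistent table.
#'
#' Near the sequence ends the window extends past the molecule; the
#' `edge_policy` decides what happens there:
#' \describe{
#'   \item{`"mean"`}{(default) the table is marginalised over the missing
#'     flank bases: the value is the mean over all k-mers matching the
#'     in-sequence context. Preserves the n / n-1 length contract.}
#'   \item{`"nan"`}{edge entries are `NA`.}
#'   \item{`"trim"`}{edge entries are dropped; vectors shorten, and the
#'     retained entries keep their position/step names.}
#' }
#'
#' @param s a DNA sequence string.
#' @param table a `kmer_shape_table` complete for the requested features.
#' @param features features to predict; default all features in the table.
#' @param edge_policy one of `"mean"`, `"nan"`, `"trim"`; default the
#'   table's stored policy.
#' @return a `shape_profile`: a named list of numeric vectors (one per
#'   feature, entries named by 1-based position or step index) with
#'   attributes `n` (sequence length) and `edge_policy`.
#' @export
#' @examples
#' tab <- synth_table(3, c("MGW", "Roll"), seed = 7)
#' prof <- predict_shape("ACGTACGTAC", tab)
#' lengths(prof)  # MGW: 10, Roll: 9
predict_shape <- function(s, table, features = table$features,
                          edge_policy = table$edge_policy) {
  stopifnot(inherits(table, "kmer_shape_table"))
  s <- as_dna(s)
  edge_policy <- match.arg(edge_policy, c("mean", "nan", "trim"))
  missing_feat <- setdiff(features, table$features)
  if (length(missing_feat))
    stop("table does not provide feature(s): ",
         paste(missing_feat, collapse = ", "), call. = FALSE)
  n <- nchar(s)
  k <- table$k
  h <- (k - 1L) %/% 2L
  padded <- paste0(strrep("N", h), s, strrep("N", h))
  windows <- substring(padded, seq_len(n), seq_len(n) + k - 1L)
  is_edge <- grepl("N", windows, fixed = TRUE)

  info <- .feature_info(features)
  prof <- vector("list", length(features))
  names(prof) <- features
  for (j in seq_along(features)) {
    feat <- features[j]
    pos_vals <- switch(edge_policy,
      mean = .lookup_windows(table, windows, feat),
      {
        v <- rep(NA_real_, n)
        v[!is_edge] <- table$values[windows[!is_edge], feat]
        v
      })
    if (info$klass[j] == "INTER_BP") {
      v <- if (n >= 2L) (pos_vals[-n] + pos_vals[-1L]) / 2 else numeric(0)
      names(v) <- as.character(seq_len(max(n - 1L, 0L)))
    } else {
      v <- pos_vals
      names(v) <- as.character(seq_len(n))
    }
    if (edge_policy == "trim") v <- v[!is.na(v)]
    prof[[j]] <- v
  }
  structure(prof, n = n, edge_policy = edge_policy, class = "shape_profile")
}

#' @export
print.shape_profile <- function(x, ...) {
  cat("shape profile for a length-", attr(x, "n"), " sequence (edge policy: ",
      attr(x, "edge_policy"), ")\n", sep = "")
  for (f in names(x))
    cat(sprintf("  %-8s [%d] %s\n", f, length(x[[f]]),
                paste(sprintf("%.3f", utils::head(x[[f]], 6L)),
                      collapse = " ")))
  invisible(x)
}
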