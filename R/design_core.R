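#' @keywords internal
MAX_MUTATION_POSITIONS <- 7L

.check_positions <- function(positions, n, what = "mutation positions") {
  if (!length(positions))
    stop(what, " must be non-empty", call. = FALSE)
  positions <- as.integer(positions)
  if (anyNA(positions))
    stop(what, " must be integers", call. = FALSE)
  if (anyDuplicated(positions))
    stop(what, " must be distinct", call. = FALSE)
  if (any(positions < 1L | positions > n))
    stop("coordinate error: ", what, " must lie in 1..", n,
         " (got ", paste(positions[positions < 1L | positions > n],
                         collapse = ", "), ")", call. = FALSE)
  sort(positions)
}

#' Enumerate all substitution candidates at a set of positions
#'
#' Returns the full Cartesian product of \{A,C,G,T\} at the selected
#' positions — `4^m` candidates for `m` positions, including the unmutated
#' wild type itself — with all other positions fixed. At most seven
#' positions may be selected (the candidate panel is capped at `4^7 =
#' 16384`). Candidates are generated in lexicographic sequence order.
#'
#' @param wt wild-type DNA sequence string.
#' @param positions 1-based positions to mutate (at most 7, distinct,
#'   within the sequence).
#' @return character vector of `4^length(positions)` candidate sequences.
#' @export
#' @examples
#' enumerate_candidates("ACGT", 2)  # AAGT ACGT AGGT ATGT
enumerate_candidates <- function(wt, positions) {
  wt <- as_dna(wt, "wild-type sequence")
  n <- nchar(wt)
  positions <- .check_positions(positions, n)
  m <- length(positions)
  if (m > MAX_MUTATION_POSITIONS)
    stop("position limit: mutations in more than ", MAX_MUTATION_POSITIONS,
         " nucleotide positions are not supported (got ", m, ")",
         call. = FALSE)
  total <- 4L^m
  # base at the j-th (leftmost-first) selected position varies slowest, so
  # the emitted candidates are already in lexicographic sequence order
  cols <- as.list(.seq_chars(wt))
  for (j in seq_len(m)) {
    cols[[positions[j]]] <- rep(rep(DNA_BASES, each = 4L^(m - j)),
                                times = 4L^(j - 1L))
  }
  do.call(paste0, cols)
}

#' Map focal positions to per-feature-class profile indices
#'
#' Intra-base pair and groove features are indexed by position, so the focal
#' positions map to themselves. Step (inter-base pair) features are indexed
#' by step; a focal nucleotide participates in both adjacent steps, so every
#' step with at least one endpoint in the focal set is included.
#'
#' @param focal 1-based focal positions.
#' @param klass `"INTER_BP"`, `"INTRA_BP"` or `"GROOVE"`.
#' @param n sequence length.
#' @return sorted integer vector of profile indices (positions or steps).
#' @export
#' @examples
#' focal_indices(c(3, 4, 5), "INTER_BP", 10)  # steps 2 3 4 5
focal_indices <- function(focal, klass, n) {
  focal <- .check_positions(focal, n, "focal positions")
  klass <- match.arg(klass, c("INTER_BP", "INTRA_BP", "GROOVE"))
  if (klass == "INTER_BP") {
    steps <- sort(unique(c(focal - 1L, focal)))
    steps[steps >= 1L & steps <= n - 1L]
  } else focal
}

#' Build a distance configuration
#'
#' @param shape_metric `"EUCLIDEAN"` (default) or `"PEARSON"`. Euclidean
#'   compares absolute shape values; Pearson (distance `1 - r` per feature,
#'   averaged over features) compares the pattern of a profile along the
#'   sequence regardless of its absolute level.
#' @param base_metric `"PHYSCHEM"` (default), `"ONEHOT"` or `"LEVENSHTEIN"`.
#' @param features non-empty subset of [feature_catalogue()] names; default
#'   `"MGW"`.
#' @param focal 1-based focal positions restricting the shape distance, or
#'   `NULL` (default) for the whole sequence.
#' @param normalize `TRUE`/`FALSE`, or `NULL` (default) for automatic:
#'   z-score per feature (pooled over the candidate ensemble) when two or
#'   more features with incommensurate units are combined, raw values for a
#'   single feature.
#' @return a `distance_config` list.
#' @export
distance_config <- function(shape_metric = c("EUCLIDEAN", "PEARSON"),
                            base_metric = c("PHYSCHEM", "ONEHOT", "LEVENSHTEIN"),
                            features = "MGW",
                            focal = NULL,
                            normalize = NULL) {
  shape_metric <- match.arg(toupper(shape_metric[1]),
                            c("EUCLIDEAN", "PEARSON"))
  base_metric <- match.arg(toupper(base_metric[1]),
                           c("PHYSCHEM", "ONEHOT", "LEVENSHTEIN"))
  if (!length(features))
    stop("at least one shape feature must be selected", call. = FALSE)
  .feature_info(features)
  if (!is.null(normalize)) stopifnot(is.logical(normalize), length(normalize) == 1L)
  structure(list(shape_metric = shape_metric, base_metric = base_metric,
                 features = features, focal = focal, normalize = normalize),
            class = "distance_config")
}

.resolve_normalize <- function(cfg) {
  if (!is.null(cfg$normalize)) cfg$normalize else length(cfg$features) >= 2L
}

.profile_values <- function(profile, feature, idx) {
  v <- profile[[feature]]
  if (is.null(v))
    stop("profile lacks feature ", feature, call. = FALSE)
  out <- v[as.character(idx)]
  if (anyNA(out))
    stop("profile has no usable value at index ",
         paste(idx[is.na(out)], collapse = ", "), " for feature ", feature,
         " (edge policy ", attr(profile, "edge_policy"), ")", call. = FALSE)
  out
}

.focal_or_all <- function(cfg, klass, n) {
  focal <- if (is.null(cfg$focal)) seq_len(n) else cfg$focal
  idx <- focal_indices(focal, klass, n)
  if (!length(idx))
    stop("empty focal index set for feature class ", klass, call. = FALSE)
  idx
}

# Shared driver: returns list(total, per_feature) for either metric.
# norm_stats: named list feature -> c(mean, sd), pooled over the candidate
# ensemble (computed by run_design); when NULL and normalization is on, the
# stats are pooled over the two profiles being compared.
.shape_distance <- function(p1, p2, cfg, norm_stats = NULL) {
  n <- attr(p1, "n")
  if (!identical(n, attr(p2, "n")))
    stop("shape mismatch: profiles come from sequences of different lengths",
         call. = FALSE)
  info <- .feature_info(cfg$features)
  normalize <- .resolve_normalize(cfg) && cfg$shape_metric == "EUCLIDEAN"
  per_feature <- setNames(numeric(nrow(info)), info$name)
  ss_total <- 0
  for (j in seq_len(nrow(info))) {
    feat <- info$name[j]
    idx <- .focal_or_all(cfg, info$klass[j], n)
    v1 <- .profile_values(p1, feat, idx)
    v2 <- .profile_values(p2, feat, idx)
    if (cfg$shape_metric == "EUCLIDEAN") {
      if (normalize) {
        st <- if (!is.null(norm_stats)) norm_stats[[feat]] else {
          pooled <- c(v1, v2)
          c(mean(pooled), max(sd(pooled), 1e-12))
        }
        v1 <- (v1 - st[1]) / st[2]
        v2 <- (v2 - st[1]) / st[2]
      }
      ss <- sum((v1 - v2)^2)
      per_feature[j] <- sqrt(ss)
      ss_total <- ss_total + ss
    } else {
      if (length(idx) < 3L)
        stop("insufficient focal points: Pearson shape distance needs at ",
             "least 3 usable values per feature (", feat, " has ",
             length(idx), ")", call. = FALSE)
      if (sd(v1) < 1e-12 || sd(v2) < 1e-12)
        stop("degenerate correlation: zero variance in the restricted ",
             feat, " profile; Pearson shape distance is undefined",
             call. = FALSE)
      per_feature[j] <- 1 - cor(v1, v2)
    }
  }
  total <- if (cfg$shape_metric == "EUCLIDEAN") sqrt(ss_total)
           else mean(per_feature)
  list(total = total, per_feature = per_feature)
}

#' Euclidean shape distance between two profiles
#'
#' Square root of the sum, over the selected features and focal indices, of
#' squared differences. With normalization on, values are first z-scored per
#' feature; the pooling statistics should come from the full candidate
#' ensemble (as [run_design()] does) — when called standalone they are
#' pooled over the two profiles being compared.
#'
#' @param p1,p2 `shape_profile` objects from equal-length sequences.
#' @param cfg a [distance_config()] with `shape_metric = "EUCLIDEAN"`.
#' @param norm_stats optional named list `feature -> c(mean, sd)` of pooling
#'   statistics for normalization.
#' @return nonnegative number, with attribute `per_feature` (per-feature
#'   distances).
#' @export
shape_distance_euclidean <- function(p1, p2, cfg = distance_config(),
                                     norm_stats = NULL) {
  cfg$shape_metric <- "EUCLIDEAN"
  d <- .shape_distance(p1, p2, cfg, norm_stats)
  structure(d$total, per_feature = d$per_feature)
}

#' Pearson shape distance between two profiles
#'
#' Per feature, `1 - r` where `r` is the Pearson correlation of the two
#' restricted profiles over the focal indices; the overall distance is the
#' unweighted mean over the selected features, in `[0, 2]`. Shift-invariant:
#' adding a constant to a profile leaves the distance at 0 — this metric
#' preserves the pattern of a shape parameter along the sequence rather than
#' its absolute values. Constant (zero-variance) restricted profiles and
#' focal sets of fewer than 3 values are errors, not silent zeros.
#'
#' @inheritParams shape_distance_euclidean
#' @param cfg a [distance_config()]; the shape metric is forced to PEARSON.
#' @return number in `[0, 2]`, with attribute `per_feature`.
#' @export
shape_distance_pearson <- function(p1, p2, cfg = distance_config()) {
  cfg$shape_metric <- "PEARSON"
  d <- .shape_distance(p1, p2, cfg)
  structure(d$total, per_feature = d$per_feature)
}

.base_distance_vec <- function(wt, candidates, base_metric) {
  wt_chars <- .seq_chars(wt)
  switch(base_metric,
    PHYSCHEM = vapply(candidates, function(s) {
      ch <- .seq_chars(s)
      as.numeric(sum(.PHYSCHEM_COST[cbind(wt_chars, ch)]))
    }, numeric(1L), USE.NAMES = FALSE),
    ONEHOT = vapply(candidates, function(s) {
      2 * sum(.seq_chars(s) != wt_chars)
    }, numeric(1L), USE.NAMES = FALSE),
    LEVENSHTEIN = as.numeric(adist(candidates, wt)))
}

.substitution_labels <- function(wt, candidates, positions) {
  wt_chars <- .seq_chars(wt)
  vapply(candidates, function(s) {
    ch <- .seq_chars(s)
    diff <- positions[ch[positions] != wt_chars[positions]]
    if (!length(diff)) return("")
    paste(sprintf("%d:%s>%s", diff, wt_chars[diff], ch[diff]),
          collapse = ";")
  }, character(1L), USE.NAMES = FALSE)
}

#' Run the full mutation-design computation
#'
#' The design pipeline: enumerate all `4^m` substitution candidates at the
#' selected positions, predict the shape profile of the wild type and of
#' every candidate with the k-mer table backend, compute each candidate's
#' base distance and (focal-restricted) shape distance from the wild type,
#' and rank the panel. The wild type itself appears as one candidate,
#' flagged, with both distances 0.
#'
#' Ranking is deterministic: by shape distance in the objective direction,
#' ties broken by ascending base distance, then by lexicographic sequence.
#'
#' @param wt wild-type DNA sequence string.
#' @param positions 1-based mutable positions (at most 7).
#' @param cfg a [distance_config()].
#' @param table a `kmer_shape_table` predictor backend.
#' @param objective `"maximize"` (default) to rank the largest shape changes
#'   first, `"minimize"` for the smallest.
#' @return a data.frame of class `design_result` with columns `sequence`,
#'   `substitutions` (semicolon-joined `pos:wt>mut`), `base_distance`,
#'   `shape_distance`, one `d_<feature>` column per selected feature,
#'   `is_wildtype` and `rank`, ordered by rank. Attributes record the
#'   wild type, positions, configuration and normalization statistics.
#' @export
#' @examples
#' tab <- synth_table(3, "MGW", seed = 11)
#' res <- run_design("ACGTACGTAC", positions = 5, table = tab)
#' res[, c("sequence", "base_distance", "shape_distance", "rank")]
run_design <- function(wt, positions, cfg = distance_config(), table,
                       objective = c("maximize", "minimize")) {
  objective <- match.arg(objective)
  stopifnot(inherits(cfg, "distance_config"),
            inherits(table, "kmer_shape_table"))
  wt <- as_dna(wt, "wild-type sequence")
  n <- nchar(wt)
  positions <- .check_positions(positions, n)
  candidates <- enumerate_candidates(wt, positions)
  if (!is.null(cfg$focal)) .check_positions(cfg$focal, n, "focal positions")

  profiles <- lapply(candidates, predict_shape, table = table,
                     features = cfg$features)
  wt_profile <- profiles[[match(wt, candidates)]]

  # pooled per-feature normalization statistics over the whole ensemble
  norm_stats <- NULL
  if (.resolve_normalize(cfg) && cfg$shape_metric == "EUCLIDEAN") {
    info <- .feature_info(cfg$features)
    norm_stats <- setNames(vector("list", nrow(info)), info$name)
    for (j in seq_len(nrow(info))) {
      idx <- .focal_or_all(cfg, info$klass[j], n)
      pooled <- unlist(lapply(profiles, .profile_values,
                              feature = info$name[j], idx = idx),
                       use.names = FALSE)
      norm_stats[[j]] <- c(mean(pooled), max(sd(pooled), 1e-12))
    }
  }

  dists <- lapply(profiles, function(p)
    .shape_distance(wt_profile, p, cfg, norm_stats))
  shape_distance <- vapply(dists, `[[`, numeric(1L), "total")
  pf <- vapply(dists, `[[`, numeric(length(cfg$features)), "per_feature")
  per_feature <- if (is.matrix(pf)) t(pf) else matrix(pf, ncol = 1L)
  colnames(per_feature) <- paste0("d_", cfg$features)

  res <- data.frame(
    sequence = candidates,
    substitutions = .substitution_labels(wt, candidates, positions),
    base_distance = .base_distance_vec(wt, candidates, cfg$base_metric),
    shape_distance = shape_distance,
    stringsAsFactors = FALSE)
  res <- cbind(res, as.data.frame(per_feature))
  res$is_wildtype <- candidates == wt

  shape_key <- if (objective == "maximize") -res$shape_distance
               else res$shape_distance
  ord <- order(shape_key, res$base_distance, res$sequence, method = "radix")
  res <- res[ord, , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL

  structure(res,
            wt = wt, positions = positions, cfg = cfg,
            objective = objective, norm_stats = norm_stats,
            class = c("design_result", "data.frame"))
}

#' Pareto front of a design-result panel
#'
#' Extracts the candidates not dominated in the (base distance, shape
#' distance) plane: base distance is always minimized (fewer / chemically
#' smaller edits are better), shape distance is maximized or minimized per
#' the objective. A candidate is dominated when another is at least as good
#' in both coordinates and strictly better in one. The wild type is excluded
#' when maximizing (its zero shape change is the anti-goal).
#'
#' @param results a `design_result` data.frame from [run_design()].
#' @param objective `"maximize"` (default) or `"minimize"` shape distance.
#' @return the non-dominated subset of `results`, ordered by ascending base
#'   distance.
#' @export
pareto_front <- function(results, objective = c("maximize", "minimize")) {
  objective <- match.arg(objective)
  stopifnot(is.data.frame(results), nrow(results) >= 1L)
  res <- results
  if (objective == "maximize" && "is_wildtype" %in% names(res))
    res <- res[!res$is_wildtype, , drop = FALSE]
  if (!nrow(res)) return(res)
  shape <- if (objective == "maximize") res$shape_distance
           else -res$shape_distance
  ord <- order(res$base_distance, -shape, method = "radix")
  res <- res[ord, , drop = FALSE]
  shape <- shape[ord]
  keep <- logical(nrow(res))
  best_shape <- -Inf
  best_base <- Inf
  for (i in seq_len(nrow(res))) {
    if (shape[i] > best_shape) {
      keep[i] <- TRUE
      best_shape <- shape[i]
      best_base <- res$base_distance[i]
    } else if (shape[i] == best_shape && res$base_distance[i] == best_base) {
      keep[i] <- TRUE  # exact tie with the current front point
    }
  }
  out <- res[keep, , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("wt", "positions", "cfg", "objective", "norm_stats"))
    attr(out, a) <- attr(results, a)
  class(out) <- class(results)
  out
}
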