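#' Define a rectangular region of interest
#'
#' ROIs are manually chosen rectangles on an RGB composite containing a
#' visually coherent acoustic structure. Ping indices are 0-based half-open
#' `[ping_start, ping_end)`; depths are half-open `[depth_top, depth_bottom)`
#' in metres, constrained to the upper 250 m (the 120 kHz range limit).
#'
#' @param id ROI identifier.
#' @param ping_start,ping_end 0-based half-open ping index range.
#' @param depth_top,depth_bottom depth range in m, `depth_bottom <= 250`.
#' @param triple composite the ROI was drawn on, e.g. `"18/38/70"`.
#' @param retain optional K-means cluster index to retain instead of the
#'   largest cluster (the semi-supervised override).
#' @export
roi <- function(id, ping_start, ping_end, depth_top, depth_bottom,
                triple = "18/38/70", retain = NA_integer_) {
  if (ping_end <= ping_start || depth_bottom <= depth_top) {
    stop_escore("ROI ranges must be non-empty")
  }
  if (depth_bottom > 250 + 1e-9) {
    stop_escore("ROI must lie within the first 250 m")
  }
  structure(list(id = id, ping_start = as.integer(ping_start),
                 ping_end = as.integer(ping_end),
                 depth_top = depth_top, depth_bottom = depth_bottom,
                 triple = triple, retain = as.integer(retain)),
            class = "roi")
}

#' Read ROI definitions from CSV
#'
#' Columns: `roi_id,ping_start,ping_end,depth_top,depth_bottom,triple,retain`
#' (indices 0-based half-open, depths in m, `retain` may be empty).
#' @param path CSV path.
#' @return list of [roi] objects.
#' @export
read_roi_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("roi_id", "ping_start", "ping_end", "depth_top", "depth_bottom")
  if (!all(need %in% names(df))) {
    stop_escore("ROI CSV must have columns ", paste(need, collapse = ","),
                class = "escore_format_error")
  }
  lapply(seq_len(nrow(df)), function(i) {
    roi(df$roi_id[i], df$ping_start[i], df$ping_end[i],
        df$depth_top[i], df$depth_bottom[i],
        triple = if ("triple" %in% names(df)) df$triple[i] else "18/38/70",
        retain = if ("retain" %in% names(df) && !is.na(df$retain[i]))
          df$retain[i] else NA_integer_)
  })
}

#' Extract non-missing delta-Sv triplets inside an ROI
#'
#' @param grid a `delta_sv_grid`.
#' @param roi an [roi]. Ping indices are 0-based against the grid rows;
#'   depth bounds select bins whose top edge lies in `[top, bottom)`.
#' @return list with `triplets` (n x 3 matrix), `ping`, `bin` coordinates.
#' @export
extract_roi_cells <- function(grid, roi) {
  stopifnot(inherits(grid, "delta_sv_grid"), inherits(roi, "roi"))
  np <- nrow(grid$d18_38)
  rows <- seq.int(roi$ping_start + 1L, min(roi$ping_end, np))
  if (roi$ping_start + 1L > np) stop_escore("ROI outside ping range")
  tops <- grid$depth_edges[-length(grid$depth_edges)]
  cols <- which(tops >= roi$depth_top - 1e-9 & tops < roi$depth_bottom - 1e-9)
  if (length(cols) == 0L) stop_escore("ROI selects no depth bins")
  cells <- delta_cells(grid, rows, cols)
  if (nrow(cells$triplets) == 0L) {
    stop_escore("ROI ", roi$id, " contains only MISSING cells")
  }
  cells
}

#' Refine an ROI into one echo-type by K-means
#'
#' Pixels inside an ROI are clustered on their delta-Sv triplets and a
#' single cluster -- the coherent acoustic structure -- is retained as the
#' echo-type: the largest cluster by membership, unless `retain` names a
#' specific cluster (clusters are reported sorted by decreasing size, so
#' `retain = 1` is the largest, `retain = 2` the runner-up, ...).
#'
#' @param cells output of [extract_roi_cells()].
#' @param k_roi number of K-means clusters within the ROI (default 3).
#' @param seed RNG seed; the refinement is bit-reproducible given the seed.
#' @param retain optional 1-based rank (by size) of the cluster to retain.
#' @param roi_id identifier recorded on the echo-type.
#' @return An `echo_type`: member coordinates, member triplets, and the mean
#'   triplet of the retained cluster.
#' @export
kmeans_refine <- function(cells, k_roi = 3L, seed = 1L, retain = NA_integer_,
                          roi_id = NA) {
  x <- cells$triplets
  n <- nrow(x)
  if (k_roi < 1L) stop_escore("k_roi must be >= 1")
  if (k_roi > n) stop_escore("k_roi (", k_roi, ") exceeds cell count (", n, ")")
  if (k_roi == 1L || n == 1L) {
    member <- seq_len(n)
  } else {
    set.seed(seed)
    km <- stats::kmeans(x, centers = k_roi, nstart = 10L, iter.max = 100L)
    ord <- order(tabulate(km$cluster, k_roi), decreasing = TRUE)
    pick <- if (is.na(retain)) 1L else as.integer(retain)
    if (pick < 1L || pick > k_roi) stop_escore("retain out of range")
    member <- which(km$cluster == ord[pick])
  }
  structure(list(id = roi_id, roi_id = roi_id,
                 ping = cells$ping[member], bin = cells$bin[member],
                 triplets = x[member, , drop = FALSE],
                 mean_triplet = colMeans(x[member, , drop = FALSE])),
            class = "echo_type")
}

#' Assemble an echo-type library
#'
#' @param echo_types list of `echo_type` objects.
#' @return An `echo_library`: data frame with one row per echo-type (id,
#'   mean triplet, member count, source ROI) plus a `class` column (NA until
#'   [hierarchical_classify()] labels it). Duplicated means are preserved.
#' @export
build_library <- function(echo_types) {
  if (length(echo_types) < 1L) stop_escore("need at least one echo-type")
  df <- data.frame(
    id = vapply(echo_types, function(e) as.character(e$id %||% NA), ""),
    d18_38 = vapply(echo_types, function(e) e$mean_triplet[[1L]], 1.0),
    d70_38 = vapply(echo_types, function(e) e$mean_triplet[[2L]], 1.0),
    d120_38 = vapply(echo_types, function(e) e$mean_triplet[[3L]], 1.0),
    n_cells = vapply(echo_types, function(e) nrow(e$triplets), 1L),
    class = NA_integer_,
    stringsAsFactors = FALSE)
  if (any(!is.finite(as.matrix(df[, 2:4])))) {
    stop_escore("non-finite echo-type mean triplet")
  }
  structure(list(table = df, echo_types = echo_types),
            class = "echo_library")
}

#' @export
print.echo_library <- function(x, ...) {
  k <- length(unique(stats::na.omit(x$table$class)))
  cat(sprintf("<echo_library> %d echo-types%s\n", nrow(x$table),
              if (k > 0) sprintf(", %d echo-classes", k) else " (unlabeled)"))
  invisible(x)
}

library_matrix <- function(lib) {
  as.matrix(lib$table[, c("d18_38", "d70_38", "d120_38")])
}

#' Cluster echo-types into echo-classes
#'
#' Agglomerative hierarchical clustering (Ward linkage on Euclidean
#' distances between echo-type mean triplets), cut at `k` classes. Class
#' indices 1..k are assigned by ascending class-centroid d18_38 so numbering
#' is deterministic.
#'
#' @param lib an `echo_library`.
#' @param k number of echo-classes (1 <= k <= n echo-types).
#' @return The library with the `class` column filled.
#' @export
hierarchical_classify <- function(lib, k) {
  stopifnot(inherits(lib, "echo_library"))
  x <- library_matrix(lib)
  n <- nrow(x)
  if (k < 1L || k > n) stop_escore("k must be in [1, ", n, "]")
  cl <- if (k == n) seq_len(n) else if (k == 1L) rep(1L, n) else
    stats::cutree(stats::hclust(stats::dist(x), method = "ward.D2"), k)
  cent <- vapply(seq_len(k), function(g) mean(x[cl == g, 1L]), 1.0)
  relab <- match(cl, order(cent))
  lib$table$class <- relab
  lib
}

## internal validity indices on a labelled 3-D point set ------------------

index_ch <- function(x, cl) {
  n <- nrow(x); k <- length(unique(cl))
  gm <- colMeans(x)
  bss <- sum(vapply(unique(cl), function(g) {
    m <- colMeans(x[cl == g, , drop = FALSE])
    sum(cl == g) * sum((m - gm)^2)
  }, 1.0))
  wss <- sum(vapply(unique(cl), function(g) {
    xs <- x[cl == g, , drop = FALSE]
    sum(sweep(xs, 2, colMeans(xs))^2)
  }, 1.0))
  (bss / (k - 1)) / (wss / (n - k))
}

index_db <- function(x, cl) {
  gs <- sort(unique(cl)); k <- length(gs)
  cent <- t(vapply(gs, function(g) colMeans(x[cl == g, , drop = FALSE]),
                   numeric(ncol(x))))
  s <- vapply(seq_len(k), function(i) {
    xs <- x[cl == gs[i], , drop = FALSE]
    mean(sqrt(rowSums(sweep(xs, 2, cent[i, ])^2)))
  }, 1.0)
  r <- vapply(seq_len(k), function(i) {
    max(vapply(setdiff(seq_len(k), i), function(j) {
      (s[i] + s[j]) / sqrt(sum((cent[i, ] - cent[j, ])^2))
    }, 1.0))
  }, 1.0)
  mean(r)
}

index_dunn <- function(x, cl) {
  d <- as.matrix(stats::dist(x))
  gs <- sort(unique(cl))
  sep <- Inf; diam <- 0
  for (i in seq_along(gs)) {
    ii <- cl == gs[i]
    diam <- max(diam, max(d[ii, ii]))
    for (j in seq_along(gs)) {
      if (j <= i) next
      sep <- min(sep, min(d[ii, cl == gs[j]]))
    }
  }
  sep / diam
}

#' Select the number of echo-classes by validity-index vote
#'
#' Each candidate `k` is scored on the Ward dendrogram cut by five cluster
#' validity indices -- average silhouette width, Calinski-Harabasz,
#' Davies-Bouldin, Dunn, and the gap statistic -- and each index votes for
#' its best `k`. The winner is the majority vote, ties broken toward the
#' smaller `k`.
#'
#' @param lib an `echo_library`.
#' @param k_candidates candidate class counts, within `[2, n-1]`.
#' @param seed seed for the gap statistic's reference bootstraps.
#' @param gap_b number of gap-statistic reference sets.
#' @return A `cluster_selection_report`: per-index best `k`, vote table, and
#'   the winning `k`.
#' @export
select_k <- function(lib, k_candidates = 2:8, seed = 1L, gap_b = 25L) {
  stopifnot(inherits(lib, "echo_library"))
  x <- library_matrix(lib)
  n <- nrow(x)
  k_candidates <- sort(unique(as.integer(k_candidates)))
  if (length(k_candidates) < 2L) stop_escore("need >= 2 candidate k values")
  if (min(k_candidates) < 2L || max(k_candidates) > n - 1L) {
    stop_escore("candidates must lie within [2, n-1]")
  }
  if (all(apply(x, 2, stats::sd) < 1e-12)) {
    stop_escore("degenerate library: all echo-types identical")
  }
  hc <- stats::hclust(stats::dist(x), method = "ward.D2")
  cuts <- lapply(k_candidates, function(k) stats::cutree(hc, k))
  d <- stats::dist(x)
  sil <- vapply(cuts, function(cl)
    mean(cluster::silhouette(cl, d)[, "sil_width"]), 1.0)
  ch <- vapply(cuts, function(cl) index_ch(x, cl), 1.0)
  db <- vapply(cuts, function(cl) index_db(x, cl), 1.0)
  dunn <- vapply(cuts, function(cl) index_dunn(x, cl), 1.0)
  set.seed(seed)
  gap <- cluster::clusGap(
    x, FUN = function(xx, k) list(cluster = stats::cutree(
      stats::hclust(stats::dist(xx), method = "ward.D2"), k)),
    K.max = max(k_candidates), B = gap_b, verbose = FALSE)
  gtab <- gap$Tab[k_candidates, , drop = FALSE]
  gap_k <- k_candidates[cluster::maxSE(gtab[, "gap"], gtab[, "SE.sim"],
                                       method = "firstSEmax")]
  best <- c(silhouette = k_candidates[which.max(sil)],
            calinski_harabasz = k_candidates[which.max(ch)],
            davies_bouldin = k_candidates[which.min(db)],
            dunn = k_candidates[which.max(dunn)],
            gap = gap_k)
  votes <- table(factor(best, levels = k_candidates))
  win <- k_candidates[which(votes == max(votes))]
  structure(list(k_candidates = k_candidates, index_choice = best,
                 votes = votes, winning_k = min(win),
                 scores = list(silhouette = sil, calinski_harabasz = ch,
                               davies_bouldin = db, dunn = dunn,
                               gap = gtab[, "gap"])),
            class = "cluster_selection_report")
}

#' @export
print.cluster_selection_report <- function(x, ...) {
  cat("<cluster_selection_report>\n  index choices:\n")
  for (nm in names(x$index_choice)) {
    cat(sprintf("    %-18s k = %d\n", nm, x$index_choice[[nm]]))
  }
  cat(sprintf("  winning k = %d\n", x$winning_k))
  invisible(x)
}

#' Validate echo-class labels with a random forest
#'
#' Fits a random forest on the three delta-Sv features with the echo-class
#' labels as response and reports the out-of-bag correct-classification
#' rate plus per-class OOB error rates.
#'
#' @param lib a labelled `echo_library`.
#' @param n_trees forest size (default 500).
#' @param seed RNG seed (bit-reproducible given the seed).
#' @param mtry features tried per split; default 1 (sqrt of 3, rounded).
#' @return An `rf_validation_report`.
#' @export
rf_validate <- function(lib, n_trees = 500L, seed = 1L, mtry = 1L) {
  stopifnot(inherits(lib, "echo_library"))
  cl <- lib$table$class
  if (anyNA(cl)) stop_escore("library must be labelled before validation")
  if (length(unique(cl)) < 2L) stop_escore("need >= 2 echo-classes")
  if (any(table(cl) < 2L)) {
    warning("echo-class with a single member: OOB rates will be unstable")
  }
  x <- library_matrix(lib)
  y <- factor(cl)
  set.seed(seed)
  rf <- randomForest::randomForest(x, y, ntree = n_trees, mtry = mtry)
  conf <- rf$confusion
  per_class <- 100 * conf[, "class.error"]
  oob_correct <- 100 * mean(rf$predicted == y)
  structure(list(oob_correct_pct = oob_correct,
                 per_class_error_pct = per_class,
                 n_trees = n_trees, seed = seed, confusion = conf),
            class = "rf_validation_report")
}

#' @export
print.rf_validation_report <- function(x, ...) {
  cat(sprintf("<rf_validation_report> OOB correct %.1f%% (%d trees)\n",
              x$oob_correct_pct, x$n_trees))
  for (i in seq_along(x$per_class_error_pct)) {
    cat(sprintf("  class %s error %.1f%%\n",
                names(x$per_class_error_pct)[i] %||% i,
                x$per_class_error_pct[[i]]))
  }
  invisible(x)
}

#' Assign a dominant frequency to each echo-class
#'
#' For each class, the mean Sv by frequency over the member cells of all
#' its echo-types; the dominant frequency is the argmax, ties broken toward
#' the lower frequency.
#'
#' @param lib a labelled `echo_library` whose echo-types carry member cell
#'   coordinates.
#' @param set the `echogram_set` the library was trained on.
#' @return Named numeric vector: dominant frequency (kHz) per class, with a
#'   `"response"` attribute holding the class x frequency mean-Sv matrix.
#' @export
dominant_frequency <- function(lib, set) {
  stopifnot(inherits(lib, "echo_library"), inherits(set, "echogram_set"))
  cl <- lib$table$class
  if (anyNA(cl)) stop_escore("library must be labelled")
  freqs <- sort(set$frequencies)
  ks <- sort(unique(cl))
  resp <- matrix(NA_real_, length(ks), length(freqs),
                 dimnames = list(paste0("class", ks), paste0(freqs, "kHz")))
  for (gi in seq_along(ks)) {
    ets <- lib$echo_types[cl == ks[gi]]
    ping <- unlist(lapply(ets, `[[`, "ping"))
    bin <- unlist(lapply(ets, `[[`, "bin"))
    idx <- cbind(ping, bin)
    for (fi in seq_along(freqs)) {
      v <- set$sv[[as.character(round(freqs[fi]))]][idx]
      resp[gi, fi] <- mean(v, na.rm = TRUE)
    }
  }
  dom <- freqs[apply(resp, 1L, which.max)]   # which.max: first (lowest) on tie
  names(dom) <- paste0("class", ks)
  attr(dom, "response") <- resp
  dom
}

#' Serialize an echo-type library to JSON
#' @param lib an `echo_library`.
#' @param path output path.
#' @export
write_library_json <- function(lib, path) {
  jsonlite::write_json(lib$table, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
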