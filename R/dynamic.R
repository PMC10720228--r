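# Sliding-window time-resolved FC: window construction, per-window edge
# vectors, k-means state estimation with cluster-count selection
# (Calinski-Harabasz / Davies-Bouldin) and silhouette diagnostics,
# per-subject state-dynamics metrics (NT, MDT, FRC), and group comparisons.

#' Sliding-window specification
#'
#' @param length_volumes Window length in volumes (default 18; 45 s at
#'   TR 2.5 s).
#' @param overlap_fraction Fractional overlap of consecutive windows
#'   (default 0.6).
#' @param tr_seconds Repetition time, seconds.
#' @param step_volumes Step between window starts; derived as
#'   `round(length * (1 - overlap))` when not given (18 and 0.6 give 7).
#' @return Object of class `window_spec`.
#' @export
window_spec <- function(length_volumes = 18, overlap_fraction = 0.6,
                        tr_seconds = 2.5, step_volumes = NULL) {
  if (is.null(step_volumes))
    step_volumes <- max(1L, as.integer(round(length_volumes *
                                               (1 - overlap_fraction))))
  stopifnot(length_volumes >= 2, overlap_fraction >= 0, overlap_fraction < 1,
            step_volumes >= 1)
  structure(list(length_volumes = as.integer(length_volumes),
                 overlap_fraction = overlap_fraction,
                 step_volumes = as.integer(step_volumes),
                 tr_seconds = tr_seconds,
                 duration_seconds = length_volumes * tr_seconds),
            class = "window_spec")
}

#' Window index ranges over a time series
#'
#' Windows start at volume 1, advance by the spec's step, and must lie fully
#' inside the series; a trailing partial window is discarded.
#'
#' @param n_timepoints Series length in volumes.
#' @param spec A [window_spec()].
#' @return Data frame `start`, `end` (inclusive volume indices).
#' @export
make_windows <- function(n_timepoints, spec = window_spec()) {
  stopifnot(inherits(spec, "window_spec"))
  if (n_timepoints < spec$length_volumes)
    stop("series shorter than one window (", n_timepoints, " < ",
         spec$length_volumes, " volumes)")
  starts <- seq(1L, n_timepoints - spec$length_volumes + 1L,
                by = spec$step_volumes)
  data.frame(start = starts, end = starts + spec$length_volumes - 1L)
}

#' Windowed functional connectivity
#'
#' Pearson correlation of all parcel pairs within each window, vectorized in
#' the canonical edge order. Raw r is used by default (the scale on which
#' the states are clustered); Fisher z is available via `fisher_z = TRUE`.
#' Windows containing a zero-variance parcel are flagged and their row set
#' to `NA`.
#'
#' @param timeseries T x P matrix.
#' @param windows Data frame from [make_windows()].
#' @param fisher_z Apply the Fisher transform to each window's correlations?
#' @return W x E matrix with attribute `flagged` (logical per window).
#' @export
windowed_fc <- function(timeseries, windows, fisher_z = FALSE) {
  x <- as.matrix(timeseries)
  idx <- edge_index_table(ncol(x))
  out <- matrix(NA_real_, nrow(windows), nrow(idx))
  flagged <- logical(nrow(windows))
  for (w in seq_len(nrow(windows))) {
    seg <- x[windows$start[w]:windows$end[w], , drop = FALSE]
    if (any(apply(seg, 2, stats::sd) == 0)) { flagged[w] <- TRUE; next }
    r <- vectorize_edges(stats::cor(seg), idx)
    out[w, ] <- if (fisher_z) atanh(clip_correlation(r)) else r
  }
  attr(out, "flagged") <- flagged
  out
}

# Internal cluster-quality indices on a points matrix (rows = observations)
# with Euclidean geometry; used on row-standardized FC vectors so that
# Euclidean distance is monotone in correlation distance.
calinski_harabasz <- function(x, cluster, centers) {
  n <- nrow(x); k <- nrow(centers)
  grand <- colMeans(x)
  wss <- sum((x - centers[cluster, , drop = FALSE])^2)
  bss <- sum(tabulate(cluster, k) * rowSums(sweep(centers, 2, grand)^2))
  (bss / (k - 1)) / (wss / (n - k))
}

davies_bouldin <- function(x, cluster, centers) {
  k <- nrow(centers)
  s <- vapply(seq_len(k), function(c) {
    rows <- cluster == c
    mean(sqrt(rowSums(sweep(x[rows, , drop = FALSE], 2, centers[c, ])^2)))
  }, numeric(1))
  m <- as.matrix(stats::dist(centers))
  r <- outer(s, s, "+") / m
  diag(r) <- -Inf
  mean(apply(r, 1, max))
}

silhouette_values <- function(x, cluster, max_points = 2000, seed = 1L) {
  n <- nrow(x)
  rows <- if (n > max_points)
    with_seed(seed, sort(sample.int(n, max_points))) else seq_len(n)
  d <- as.matrix(stats::dist(x[rows, , drop = FALSE]))
  cl <- cluster[rows]
  k <- max(cluster)
  vapply(seq_along(rows), function(i) {
    own <- cl == cl[i]
    a <- if (sum(own) > 1) sum(d[i, own]) / (sum(own) - 1) else 0
    b <- min(vapply(setdiff(seq_len(k), cl[i]), function(c) {
      other <- cl == c
      if (any(other)) mean(d[i, other]) else Inf
    }, numeric(1)))
    if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }, numeric(1))
}

# Row standardization that makes Euclidean k-means equivalent to clustering
# under correlation distance: squared distance between standardized rows is
# proportional to 1 - cor of the raw rows.
standardize_rows <- function(x) {
  mu <- rowMeans(x)
  s <- sqrt(rowSums((x - mu)^2))
  if (any(s == 0)) stop("constant FC window cannot be standardized")
  (x - mu) / s
}

#' Estimate recurring FC states by k-means over pooled windows
#'
#' Clusters all subjects' windowed FC vectors jointly (states are estimated
#' on the entire sample) with k-means under correlation distance, realized
#' by standardizing each window's edge vector so that Euclidean k-means on
#' the standardized rows orders solutions identically to correlation
#' distance. The number of states is searched over `k_range`, selected by
#' the Calinski-Harabasz index and cross-checked against Davies-Bouldin;
#' disagreement is recorded. Silhouette values of the selected solution
#' measure cluster separability.
#'
#' @param window_fc W_total x E matrix of pooled window FC vectors (rows
#'   from [windowed_fc()], stacked over subjects); flagged/NA rows are
#'   dropped.
#' @param subject Vector (length W_total) mapping each row to its subject.
#' @param k_range Candidate state counts (default 2:10).
#' @param nstart,iter_max K-means restarts and iteration cap (20, 300).
#' @param seed Integer seed controlling restarts and silhouette subsampling.
#' @return Object of class `state_model`: `k` (selected), `centroids`
#'   (k x E, on the original FC scale), `assignments` (data frame `subject`,
#'   `window`, `state`), `ch_index`/`db_index` per candidate k, `db_choice`,
#'   `selection_agrees`, `silhouette` values and their mean.
#' @export
cluster_states <- function(window_fc, subject, k_range = 2:10, nstart = 20,
                           iter_max = 300, seed = 1L) {
  stopifnot(nrow(window_fc) == length(subject))
  keep <- stats::complete.cases(window_fc)
  x_raw <- window_fc[keep, , drop = FALSE]
  subject <- subject[keep]
  if (nrow(x_raw) < max(k_range)) stop("fewer windows than clusters")
  x <- standardize_rows(x_raw)
  fits <- with_seed(substream_seed(seed, "kmeans"), {
    lapply(k_range, function(k)
      stats::kmeans(x, centers = k, nstart = nstart, iter.max = iter_max))
  })
  ch <- vapply(seq_along(k_range), function(i)
    calinski_harabasz(x, fits[[i]]$cluster, fits[[i]]$centers), numeric(1))
  db <- vapply(seq_along(k_range), function(i)
    davies_bouldin(x, fits[[i]]$cluster, fits[[i]]$centers), numeric(1))
  pick <- which.max(ch)
  db_pick <- which.min(db)
  fit <- fits[[pick]]
  sil <- silhouette_values(x, fit$cluster, seed = seed)
  # centroids reported on the raw FC scale for interpretability
  centroids <- t(vapply(seq_len(k_range[pick]), function(c)
    colMeans(x_raw[fit$cluster == c, , drop = FALSE]),
    numeric(ncol(x_raw))))
  win_index <- stats::ave(seq_along(subject), subject, FUN = seq_along)
  structure(list(k = k_range[pick], k_range = k_range,
                 centroids = centroids,
                 assignments = data.frame(subject = subject,
                                          window = win_index,
                                          state = fit$cluster),
                 ch_index = stats::setNames(ch, k_range),
                 db_index = stats::setNames(db, k_range),
                 db_choice = k_range[db_pick],
                 selection_agrees = pick == db_pick,
                 silhouette = sil, mean_silhouette = mean(sil)),
            class = "state_model")
}

#' @export
print.state_model <- function(x, ...) {
  cat(sprintf("FC state model: k = %d selected by Calinski-Harabasz%s\n",
              x$k, if (x$selection_agrees) " (Davies-Bouldin agrees)"
              else sprintf(" (Davies-Bouldin prefers k = %d)", x$db_choice)))
  cat(sprintf("  %d windows, mean silhouette %.3f\n",
              nrow(x$assignments), x$mean_silhouette))
  invisible(x)
}

#' State-dynamics metrics of one assignment sequence
#'
#' NT: number of transitions (consecutive unequal states). MDT: mean dwell
#' time per state, the mean length of maximal runs, in windows; `NA`
#' (flagged) for unvisited states. FRC: fraction of windows per state.
#'
#' @param states Integer state sequence of one subject's windows.
#' @param n_states Total number of states in the model.
#' @return List `nt`, `mdt` (length `n_states`), `frc` (length `n_states`,
#'   summing to 1).
#' @export
state_metrics <- function(states, n_states = max(states)) {
  stopifnot(length(states) >= 1, all(states >= 1), all(states <= n_states))
  runs <- rle(states)
  mdt <- vapply(seq_len(n_states), function(s) {
    if (any(runs$values == s)) mean(runs$lengths[runs$values == s])
    else NA_real_
  }, numeric(1))
  list(nt = sum(diff(states) != 0),
       mdt = mdt,
       frc = tabulate(states, n_states) / length(states))
}

#' Per-subject state-dynamics table
#'
#' @param model A [cluster_states()] result.
#' @return Data frame: `subject_id`, `nt`, then `mdt_state<k>` and
#'   `frc_state<k>` columns.
#' @export
subject_state_metrics <- function(model) {
  stopifnot(inherits(model, "state_model"))
  k <- model$k
  by_subject <- split(model$assignments$state, model$assignments$subject)
  rows <- lapply(names(by_subject), function(id) {
    m <- state_metrics(by_subject[[id]], n_states = k)
    stats::setNames(
      data.frame(id, m$nt, t(m$mdt), t(m$frc), stringsAsFactors = FALSE),
      c("subject_id", "nt", paste0("mdt_state", seq_len(k)),
        paste0("frc_state", seq_len(k))))
  })
  do.call(rbind, rows)
}

#' Compare state dynamics between groups
#'
#' NT is compared with a two-sided t-test and summarized as mean +/- sd;
#' each state's MDT and FRC with a Mann-Whitney U test, summarized as
#' median (range). A metric is flagged when a state is unvisited by every
#' subject of one group (its test is then computed on the visiting subjects
#' only).
#'
#' @param metrics Table from [subject_state_metrics()].
#' @param group Factor of length `nrow(metrics)` (2 levels; second level =
#'   case).
#' @return Data frame: `metric`, `state`, group summaries, `statistic`,
#'   `p`, `test`, `flagged`.
#' @export
compare_state_dynamics <- function(metrics, group) {
  group <- factor(group)
  stopifnot(nlevels(group) == 2, nrow(metrics) == length(group))
  g1 <- group == levels(group)[1]; g2 <- !g1
  summarize <- function(x, type) {
    x <- x[!is.na(x)]
    if (!length(x)) return("-")
    if (type == "mean_sd") sprintf("%.2f ± %.2f", mean(x), stats::sd(x))
    else sprintf("%.2f (%.2f-%.2f)", stats::median(x), min(x), max(x))
  }
  one <- function(x, metric, state, test) {
    flagged <- all(is.na(x[g1])) || all(is.na(x[g2]))
    res <- if (flagged) list(statistic = NA_real_, p.value = NA_real_)
    else tryCatch(
      if (test == "t") stats::t.test(x[g1], x[g2])
      else stats::wilcox.test(x[g1], x[g2], exact = FALSE),
      error = function(e) {         # e.g. zero variance in both groups
        flagged <<- TRUE
        list(statistic = NA_real_, p.value = NA_real_)
      })
    data.frame(metric = metric, state = state,
               group1 = summarize(x[g1], if (test == "t") "mean_sd" else "med"),
               group2 = summarize(x[g2], if (test == "t") "mean_sd" else "med"),
               statistic = unname(res$statistic), p = res$p.value,
               test = if (test == "t") "t-test" else "Mann-Whitney U",
               flagged = flagged)
  }
  k <- sum(startsWith(names(metrics), "mdt_state"))
  out <- list(one(metrics$nt, "NT", NA_integer_, "t"))
  for (s in seq_len(k)) {
    out <- c(out,
             list(one(metrics[[paste0("mdt_state", s)]], "MDT", s, "u")),
             list(one(metrics[[paste0("frc_state", s)]], "FRC", s, "u")))
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
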