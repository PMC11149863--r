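# Pipeline orchestration (generalized / targeted-hard / targeted-moderate)
# and bin-level evaluation with the multi-label confusion counting rules.

#' Run a classification pipeline over audio or detections
#'
#' The three pipeline modes share detection, 5-min-bin clustering and
#' cluster classification; the targeted modes insert a taxonomic family
#' delimitation step before (final) clustering:
#' \describe{
#'   \item{generalized}{detect, cluster, classify.}
#'   \item{targeted_hard}{detect, hard negative filter, cluster, classify.}
#'   \item{targeted_moderate}{detect, moderate negative filter (first
#'     clustering/classification pass removing dominant non-beaked-whale
#'     clusters), re-cluster the survivors with standard settings,
#'     classify.}
#' }
#'
#' @param x A `click_detections` object, or a list with `waveform` and
#'   `sample_rate` (audio is band-passed and detected first).
#' @param mode Pipeline mode.
#' @param model A `trained_network`.
#' @param detector_cfg A [detector_config()] (used when `x` is audio).
#' @param cluster_cfg A [cluster_config()] for the (final) clustering.
#' @param hard_cfg A [hard_filter_config()].
#' @param moderate_cfg A [moderate_filter_config()].
#' @param seed Integer master seed.
#' @return List with `clusters` (classified `click_cluster`s), `labels`
#'   (per-cluster prediction table with bin ids), `bin_table` (per-bin
#'   label sets from [bin_label_table()]), `detections` (the detections
#'   that reached final clustering) and `click_labels` (per-click label
#'   propagation of cluster labels).
#' @export
run_pipeline <- function(x, mode = c("generalized", "targeted_hard",
                                     "targeted_moderate"),
                         model, detector_cfg = detector_config(),
                         cluster_cfg = cluster_config(),
                         hard_cfg = hard_filter_config(),
                         moderate_cfg = moderate_filter_config(),
                         seed = 1L) {
  mode <- match.arg(mode)
  if (missing(model) || !inherits(model, "trained_network"))
    stop("a trained model is required")
  det <- if (inherits(x, "click_detections")) x
  else detect_clicks(x$waveform, x$sample_rate, detector_cfg)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, 2L))
  if (mode == "targeted_hard") {
    det <- hard_negative_filter(det, hard_cfg)$detections
  } else if (mode == "targeted_moderate") {
    det <- moderate_negative_filter(det, model, cluster_cfg, moderate_cfg,
                                    seed = seeds[1L])$detections
  }
  clusters <- cluster_bins(det, cluster_cfg, seed = seeds[2L])
  labels <- data.frame(bin_id = numeric(0), label = character(0),
                       score = numeric(0), n_clicks = integer(0))
  click_labels <- data.frame(click_id = integer(0), label = character(0))
  if (length(clusters)) {
    pred <- predict(model, clusters)
    for (i in seq_along(clusters)) {
      clusters[[i]]$label <- pred$label[i]
      clusters[[i]]$score <- pred$score[i]
    }
    labels <- data.frame(
      bin_id = vapply(clusters, `[[`, 0, "bin_id"),
      label = pred$label, score = pred$score,
      n_clicks = vapply(clusters, `[[`, 0L, "n_clicks"))
    click_labels <- data.frame(
      click_id = unlist(lapply(clusters, `[[`, "member_ids")),
      label = rep(pred$label, vapply(clusters, function(cl)
        length(cl$member_ids), 0L)))
  }
  list(clusters = clusters, labels = labels,
       bin_table = bin_label_table(labels), detections = det,
       click_labels = click_labels, mode = mode)
}

#' Per-bin label sets
#'
#' Aggregates per-cluster predictions into one row per (bin, label):
#' total clicks and mean probability score.
#'
#' @param labels Per-cluster label table (`bin_id`, `label`, `score`,
#'   `n_clicks`), as produced by [run_pipeline()].
#' @return Data frame with `bin_id`, `label`, `n_clicks`, `score`.
#' @export
bin_label_table <- function(labels) {
  if (!nrow(labels))
    return(data.frame(bin_id = numeric(0), label = character(0),
                      n_clicks = integer(0), score = numeric(0)))
  agg <- stats::aggregate(cbind(n_clicks, score) ~ bin_id + label,
                          data = labels, FUN = mean)
  cnt <- stats::aggregate(n_clicks ~ bin_id + label, data = labels, FUN = sum)
  agg$n_clicks <- cnt$n_clicks
  agg[order(agg$bin_id, agg$label), c("bin_id", "label", "n_clicks", "score")]
}

#' Reduce click-level ground truth to per-bin true label sets
#'
#' @param truth Data frame with `class_id` and `start_s` per click (e.g.
#'   the `truth` element of [render_scene()]).
#' @param bin_length Bin length, seconds.
#' @return Data frame with `bin_id` and `label`.
#' @export
truth_bin_table <- function(truth, bin_length = 300) {
  if (!nrow(truth))
    return(data.frame(bin_id = numeric(0), label = character(0)))
  out <- unique(data.frame(bin_id = floor(truth$start_s / bin_length),
                           label = truth$class_id))
  out[order(out$bin_id, out$label), ]
}

#' Bin-level confusion matrix with multi-label counting
#'
#' Within each bin every pairing of a true label with a predicted label
#' contributes one bin count: if one species is true but the classifier
#' assigned several labels, the bin is counted once per predicted label;
#' if several species are true but only one label was assigned, the label
#' is counted once per true class. Bins absent from either table count
#' under the explicit class `"No label"`. A lenient full-bin variant is
#' also computed in which a bin with the correct label among its
#' predictions counts only as correct (only fully misclassified bins are
#' penalized).
#'
#' @param truth Data frame `bin_id`, `label` of true per-bin label sets.
#' @param predicted Data frame `bin_id`, `label` of predicted label sets.
#' @param classes Class universe (default: the built-in 11 classes).
#' @param bins Optional bin universe; an error is raised if either table
#'   contains bins outside it. Default: all bins in either table.
#' @return Object of class `bin_confusion`: `counts` and `full_counts`
#'   matrices (true classes in rows, predicted in columns, both including
#'   `"No label"`), plus the bin universe.
#' @export
bin_confusion <- function(truth, predicted, classes = template_classes(),
                          bins = NULL) {
  if (is.null(bins)) {
    bins <- sort(unique(c(truth$bin_id, predicted$bin_id)))
  } else if (!all(c(truth$bin_id, predicted$bin_id) %in% bins)) {
    stop("bin ids outside the supplied bin universe")
  }
  lv <- c(classes, "No label")
  bad_t <- setdiff(truth$label, lv)
  bad_p <- setdiff(predicted$label, lv)
  if (length(bad_t) || length(bad_p))
    stop("labels outside the class universe: ",
         paste(c(bad_t, bad_p), collapse = ", "))
  counts <- matrix(0L, length(lv), length(lv), dimnames = list(lv, lv))
  full <- counts
  for (b in bins) {
    ts <- truth$label[truth$bin_id == b]
    ps <- predicted$label[predicted$bin_id == b]
    if (!length(ts)) ts <- "No label"
    if (!length(ps)) ps <- "No label"
    for (t in ts) {
      for (p in ps) counts[t, p] <- counts[t, p] + 1L
      if (t %in% ps) full[t, t] <- full[t, t] + 1L
      else for (p in ps) full[t, p] <- full[t, p] + 1L
    }
  }
  structure(list(counts = counts, full_counts = full, bins = bins),
            class = "bin_confusion")
}

#' Per-class precision and recall from a confusion matrix
#'
#' For each class `c` appearing among both row and column names (with
#' true classes in rows): `TP = M[c, c]`, `FN` is the rest of the row,
#' `FP` the rest of the column (including ambiguous and unlabeled rows),
#' precision `TP / (TP + FP)` and recall `TP / (TP + FN)` in percent.
#' Zero denominators give `NaN`, never 0.
#'
#' @param cm A `bin_confusion` object or a counts matrix with row/column
#'   names (rows: true classes, possibly with extra annotation rows).
#' @param full_bin Use the lenient full-bin counts (for `bin_confusion`
#'   inputs).
#' @param classes Classes to report; default: all classes present among
#'   both rows and columns, excluding `"No label"`.
#' @return Data frame with `class`, `tp`, `fn`, `fp`, `recall`,
#'   `precision` (percent).
#' @export
precision_recall <- function(cm, full_bin = FALSE, classes = NULL) {
  M <- if (inherits(cm, "bin_confusion")) {
    if (full_bin) cm$full_counts else cm$counts
  } else as.matrix(cm)
  if (any(M < 0)) stop("confusion counts must be non-negative")
  if (is.null(classes))
    classes <- setdiff(intersect(rownames(M), colnames(M)), "No label")
  out <- data.frame(class = classes, tp = NA_real_, fn = NA_real_,
                    fp = NA_real_, recall = NA_real_, precision = NA_real_)
  for (i in seq_along(classes)) {
    cl <- classes[i]
    tp <- M[cl, cl]
    fn <- sum(M[cl, ]) - tp
    fp <- sum(M[, cl]) - tp
    out$tp[i] <- tp; out$fn[i] <- fn; out$fp[i] <- fp
    out$recall[i] <- if (tp + fn > 0) 100 * tp / (tp + fn) else NaN
    out$precision[i] <- if (tp + fp > 0) 100 * tp / (tp + fp) else NaN
  }
  out
}

#' Summarize per-class metrics into the reported averages
#'
#' Unweighted arithmetic means of per-class recall and precision over the
#' requested classes (those with defined values), rounded to the nearest
#' whole percent, alongside the per-class table rounded to one decimal.
#'
#' @param pr Output of [precision_recall()].
#' @param classes Classes to average over (default: all rows of `pr`).
#' @return List with `per_class` (rounded table), `avg_recall` and
#'   `avg_precision` (whole percent).
#' @export
summarize_performance <- function(pr, classes = pr$class) {
  sub <- pr[pr$class %in% classes, , drop = FALSE]
  per_class <- sub
  per_class$recall <- round(per_class$recall, 1L)
  per_class$precision <- round(per_class$precision, 1L)
  list(per_class = per_class,
       avg_recall = round(mean(sub$recall[is.finite(sub$recall)])),
       avg_precision = round(mean(sub$precision[is.finite(sub$precision)])))
}

#' Write an evaluation report
#'
#' Writes the confusion matrix as CSV and the per-class metrics plus
#' averages as JSON.
#'
#' @param cm A `bin_confusion` object or counts matrix.
#' @param dir Output directory.
#' @param classes Classes averaged in the summary.
#' @return Invisible list of paths written.
#' @export
write_evaluation <- function(cm, dir, classes = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  M <- if (inherits(cm, "bin_confusion")) cm$counts else as.matrix(cm)
  pr <- precision_recall(cm, classes = classes)
  summ <- summarize_performance(pr)
  cm_path <- file.path(dir, "confusion_matrix.csv")
  js_path <- file.path(dir, "metrics.json")
  utils::write.csv(M, cm_path)
  jsonlite::write_json(list(per_class = summ$per_class,
                            avg_recall = summ$avg_recall,
                            avg_precision = summ$avg_precision),
                       js_path, auto_unbox = TRUE, digits = NA)
  invisible(list(confusion = cm_path, metrics = js_path))
}
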