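#' Case-study bin count tables
#'
#' Bin-level confusion counts from the manually annotated two-month case
#' study in the western North Atlantic, shipped with the package so the
#' reported precision/recall figures can be recomputed. Rows are true
#' classes (including ambiguous annotations such as `"Mm | Me"` and the
#' explicit `"No label"` row); columns are predicted classes. Four tables
#' are available: the targeted pipeline with a hard negative filter over
#' all case-study sites (`"hard_filter"`), and the site-WC comparison of
#' the targeted pipeline with a hard (`"wc_th"`) or moderate (`"wc_tm"`)
#' negative filter against the generalized pipeline (`"wc_g"`).
#'
#' @param table Which table to load.
#' @return Numeric matrix of 5-min-bin counts with true classes in rows
#'   and predicted classes in columns.
#' @seealso [precision_recall()], [summarize_performance()]
#' @export
case_study_bin_counts <- function(table = c("hard_filter", "wc_th", "wc_tm",
                                            "wc_g")) {
  table <- match.arg(table)
  path <- system.file("extdata", paste0("case_study_bins_", table, ".csv"),
                      package = "bwclassify", mustWork = TRUE)
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1L])
  rownames(m) <- df$true_class
  m
}
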