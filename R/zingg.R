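#' Zingg shape classification
#'
#' Classifies a particle as block, needle, lath or plate from its two
#' orthogonal-axis aspect ratios, `s_m = S/M` and `m_l = M/L`, against a
#' threshold `t` (default 0.66):
#' * block:  `s_m > t` and `m_l > t`
#' * needle: `s_m > t` and `m_l <= t`
#' * plate:  `s_m <= t` and `m_l > t`
#' * lath:   `s_m <= t` and `m_l <= t`
#'
#' A ratio exactly equal to the threshold falls on the `<=` side: a block
#' requires both ratios strictly greater than the threshold.
#'
#' @param s_m,m_l numeric vectors of ratios in \[0, 1\] (recycled together).
#' @param threshold classification threshold, default 0.66.
#' @return Character vector of labels among
#'   `c("block", "needle", "lath", "plate")`.
#' @export
zingg_classify <- function(s_m, m_l, threshold = 0.66) {
  n <- max(length(s_m), length(m_l))
  s_m <- rep_len(as.numeric(s_m), n)
  m_l <- rep_len(as.numeric(m_l), n)
  if (any(!is.finite(s_m)) || any(!is.finite(m_l)))
    stop("zingg_classify: non-finite ratio")
  if (any(s_m < 0 | s_m > 1 | m_l < 0 | m_l > 1))
    stop("zingg_classify: ratios must lie in [0, 1]")
  ifelse(s_m > threshold,
         ifelse(m_l > threshold, "block", "needle"),
         ifelse(m_l > threshold, "plate", "lath"))
}

#' Levels of the Zingg classification
#' @return `c("block", "needle", "lath", "plate")`
#' @export
zingg_levels <- function() c("block", "needle", "lath", "plate")

#' Classify a batch of aspect-ratio records
#'
#' @param records `data.frame` with columns `s_m` and `m_l`.
#' @param threshold Zingg threshold.
#' @return A list with `labels` (character vector, one per row) and
#'   `counts` (named integer vector over all four classes; sums to
#'   `nrow(records)`).
#' @export
zingg_classify_batch <- function(records, threshold = 0.66) {
  stopifnot(all(c("s_m", "m_l") %in% names(records)))
  labels <- if (nrow(records) == 0L) character(0)
            else zingg_classify(records$s_m, records$m_l, threshold = threshold)
  counts <- table(factor(labels, levels = zingg_levels()))
  list(labels = labels, counts = stats::setNames(as.integer(counts),
                                                 names(counts)))
}
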