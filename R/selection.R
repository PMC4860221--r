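# Gain-ratio attribute evaluation with a ranker:
# GainR(Class, Attribute) = (H(Class) - H(Class | Attribute)) / H(Attribute)
# with attributes discretized by equal-frequency binning.

#' Shannon entropy of class counts
#'
#' @param counts Non-negative counts, not all zero.
#' @return Entropy in bits, `-sum(p * log2(p))` over the non-zero classes.
#' @export
shannon_entropy <- function(counts) {
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  tot <- sum(counts)
  if (tot == 0) stop("all counts are zero", call. = FALSE)
  p <- counts[counts > 0] / tot
  -sum(p * log2(p))
}

#' Equal-frequency discretization
#'
#' Assigns values to `n_bins` bins of (as nearly as possible) equal
#' occupancy. Tied values always share a bin (the lower one), so a
#' constant vector occupies a single bin and the assignment is invariant
#' under strictly monotone transforms of the values.
#'
#' @param values Numeric vector.
#' @param n_bins Number of bins (>= 2).
#' @return Integer bin ids in `0:(n_bins - 1)`.
#' @export
discretize <- function(values, n_bins = 10) {
  if (n_bins < 2) stop("n_bins must be >= 2", call. = FALSE)
  n <- length(values)
  if (n == 0L) return(integer(0))
  r <- rank(values, ties.method = "min")
  as.integer(floor((r - 1) * n_bins / n))
}

#' Gain ratio of an attribute with respect to a class
#'
#' The attribute is discretized with [discretize()] (categorical input is
#' used as-is), then the information gain `H(Class) - H(Class | Attribute)`
#' is divided by the attribute entropy `H(Attribute)`. A constant
#' attribute (`H(Attribute) = 0`) scores 0 by convention.
#'
#' @param values Numeric attribute values (or a factor/character vector of
#'   categories, used without binning).
#' @param labels Class labels, same length, with >= 2 classes present.
#' @param n_bins Bins for discretization (default 10).
#' @return Non-negative gain-ratio score.
#' @export
gain_ratio <- function(values, labels, n_bins = 10) {
  if (length(values) != length(labels))
    stop("values and labels differ in length (", length(values), " vs ",
         length(labels), ")", call. = FALSE)
  if (length(unique(labels)) < 2L)
    stop("need >= 2 classes in labels", call. = FALSE)
  bins <- if (is.numeric(values)) discretize(values, n_bins) else as.character(values)
  tab <- table(bins, labels)
  bin_n <- rowSums(tab)
  h_attr <- shannon_entropy(bin_n)
  if (h_attr == 0) return(0)
  h_class <- shannon_entropy(colSums(tab))
  h_cond <- sum(vapply(seq_len(nrow(tab)), function(i) {
    if (bin_n[i] == 0) return(0)
    (bin_n[i] / sum(bin_n)) * shannon_entropy(tab[i, ])
  }, numeric(1)))
  (h_class - h_cond) / h_attr
}

#' Rank all attributes of a feature table by gain ratio
#'
#' @param feature_table A labelled [extract_feature_table()] result (or
#'   any data frame with a `label` column and numeric attribute columns).
#' @param n_bins Bins for discretization (default 10).
#' @return Data frame of class `attribute_ranking` with columns `rank`,
#'   `channel`, `feature`, `name`, `score`, sorted non-increasing by
#'   score with ties broken by registry order.
#' @export
rank_attributes <- function(feature_table, n_bins = 10) {
  if (is.null(feature_table$label) || anyNA(feature_table$label))
    stop("feature table must be fully labelled", call. = FALSE)
  reg <- attr(feature_table, "registry")
  id <- c("patient_id", "epoch_index", "label")
  cols <- setdiff(names(feature_table), id)
  scores <- vapply(cols, function(nm) {
    v <- feature_table[[nm]]
    if (anyNA(v)) v[is.na(v)] <- stats::median(v, na.rm = TRUE)
    gain_ratio(v, feature_table$label, n_bins)
  }, numeric(1))
  ord <- order(-scores, seq_along(scores))
  out <- data.frame(rank = seq_along(cols),
                    name = cols[ord],
                    score = unname(scores[ord]),
                    stringsAsFactors = FALSE)
  if (!is.null(reg)) {
    m <- match(out$name, reg$name)
    out$channel <- reg$channel[m]
    out$feature <- reg$feature[m]
    out <- out[, c("rank", "channel", "feature", "name", "score")]
  }
  class(out) <- c("attribute_ranking", "data.frame")
  out
}

#' @export
print.attribute_ranking <- function(x, n = 10, ...) {
  cat("<attribute_ranking>", nrow(x), "attributes\n")
  top <- utils::head(x, n)
  for (i in seq_len(nrow(top)))
    cat(sprintf("  %2d. %-28s (ranked: %.5f)\n", top$rank[i], top$name[i],
                top$score[i]))
  invisible(x)
}
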