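# Profiling reports: per-group detection and high-abundance sets, ranked
# composition tables with percent of total miR content, and multi-set
# Venn overlap counts.

#' Round half up to a number of decimals
#'
#' Display rounding for composition tables (base `round()` is half-to-even;
#' printed tables in this field round half up). All set operations and
#' cumulative sums use unrounded values.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 1).
#' @export
round_half_up <- function(x, digits = 1L) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

.group_cols <- function(cpm_mat, groups, group) {
  if (!group %in% groups) .stopf("unknown group '%s'", group)
  which(groups == group)
}

#' Features detected in a group
#'
#' A feature is detected when its mean CPM across the group's replicates
#' is at least `min_cpm` (inclusive bound; default 1).
#'
#' @param cpm_mat CPM matrix (features x samples).
#' @param groups group label per sample column.
#' @param group group to evaluate.
#' @param min_cpm detection threshold on the group-mean CPM (default 1).
#' @return character vector of feature names.
#' @export
detect_features <- function(cpm_mat, groups, group, min_cpm = 1) {
  cols <- .group_cols(cpm_mat, groups, group)
  m <- rowMeans(cpm_mat[, cols, drop = FALSE])
  rownames(cpm_mat)[m >= min_cpm]
}

#' @rdname detect_features
#' @export
abundant_features <- function(cpm_mat, groups, group, min_cpm = 1000) {
  detect_features(cpm_mat, groups, group, min_cpm = min_cpm)
}

#' Ranked composition of a group's miR content
#'
#' Features sorted by group-mean CPM descending (ties broken
#' lexicographically by feature name). Percent of total miR content is
#' mean CPM / 1e4 (unrounded; use [round_half_up()] for display);
#' cumulative percentages use the unrounded values. The share beyond
#' `top_n` is reported as the "Other miRNAs" remainder.
#'
#' @param cpm_mat CPM matrix (features x samples).
#' @param groups group label per sample column.
#' @param group group to profile.
#' @param top_n rows to keep in the display table (default 10).
#' @return data.frame with rank, feature, mean_cpm, percent,
#'   cumulative_percent for the top `top_n` features; attributes
#'   `other_percent` (remainder) and `full` (all features ranked).
#' @export
mir_composition <- function(cpm_mat, groups, group, top_n = 10L) {
  cols <- .group_cols(cpm_mat, groups, group)
  m <- rowMeans(cpm_mat[, cols, drop = FALSE])
  o <- order(-m, rownames(cpm_mat))
  full <- data.frame(
    rank = seq_along(o),
    feature = rownames(cpm_mat)[o],
    mean_cpm = m[o],
    percent = m[o] / 1e4,
    cumulative_percent = cumsum(m[o] / 1e4),
    row.names = NULL, stringsAsFactors = FALSE)
  top_n <- min(top_n, nrow(full))
  out <- full[seq_len(top_n), , drop = FALSE]
  attr(out, "other_percent") <- sum(full$percent) - sum(out$percent)
  attr(out, "full") <- full
  attr(out, "group") <- group
  out
}

#' Per-group profile summary
#'
#' Detected set (mean CPM >= `detect_cpm`), high-abundance set (mean CPM
#' >= `abundant_cpm`) and ranked composition for one group.
#'
#' @inheritParams mir_composition
#' @param detect_cpm detection threshold (default 1).
#' @param abundant_cpm high-abundance threshold (default 1000).
#' @return list of class `profile_summary`: `group`, `detected`,
#'   `abundant`, `composition`.
#' @export
profile_summary <- function(cpm_mat, groups, group, detect_cpm = 1,
                            abundant_cpm = 1000, top_n = 10L) {
  structure(list(
    group = group,
    detected = detect_features(cpm_mat, groups, group, detect_cpm),
    abundant = detect_features(cpm_mat, groups, group, abundant_cpm),
    composition = mir_composition(cpm_mat, groups, group, top_n)),
    class = "profile_summary")
}

#' @export
print.profile_summary <- function(x, ...) {
  cat(sprintf("Profile of group %s: %d detected, %d highly abundant\n",
              x$group, length(x$detected), length(x$abundant)))
  comp <- x$composition
  comp$percent <- round_half_up(comp$percent, 1)
  comp$cumulative_percent <- round_half_up(comp$cumulative_percent, 1)
  print.data.frame(comp, row.names = FALSE)
  cat(sprintf("  Other miRNAs: %.1f%%\n",
              round_half_up(attr(x$composition, "other_percent"), 1)))
  invisible(x)
}

#' Venn overlap counts of detected feature sets
#'
#' Exact region counts for all 2^k - 1 non-empty membership patterns over
#' 2 to 4 named sets, plus pairwise shared counts. Region counts sum to
#' the size of the union and are invariant to set input order.
#'
#' @param sets named list of 2-4 character vectors.
#' @return list of class `venn_counts`: `regions` (named integer vector;
#'   names are "&"-joined set names), `pairwise` (matrix of intersection
#'   sizes), `sets` (set sizes), `union_size`.
#' @export
venn_counts <- function(sets) {
  k <- length(sets)
  if (k < 2L || k > 4L) .stopf("venn_counts supports 2 to 4 sets, got %d", k)
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    .stopf("sets must be named")
  }
  sets <- lapply(sets, unique)
  nm <- names(sets)
  univ <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) univ %in% s, logical(length(univ)))
  if (length(univ) == 1L) member <- matrix(member, nrow = 1L)

  patterns <- unlist(lapply(seq_len(k), function(m) {
    combn(nm, m, paste, collapse = "&", simplify = FALSE)
  }))
  regions <- setNames(integer(length(patterns)), patterns)
  if (length(univ)) {
    key <- apply(member, 1L, function(r) paste(nm[r], collapse = "&"))
    tab <- table(key)
    regions[names(tab)] <- as.integer(tab)
  }
  pairwise <- matrix(0L, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    pairwise[i, j] <- length(intersect(sets[[i]], sets[[j]]))
  }
  structure(list(regions = regions, pairwise = pairwise,
                 sets = vapply(sets, length, integer(1)),
                 union_size = length(univ)),
            class = "venn_counts")
}

#' @export
print.venn_counts <- function(x, ...) {
  cat("Venn overlap of", length(x$sets), "sets; union =", x$union_size, "\n")
  for (r in names(x$regions)) {
    cat(sprintf("  %-30s %d\n", r, x$regions[[r]]))
  }
  invisible(x)
}
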