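# Identical-sequence clustering, assignment to a collapsed mature miR
# reference, and count/CPM matrices.

#' Collapse a mature miR reference by identical sequence
#'
#' Distinct genomic loci frequently yield byte-identical mature sequences;
#' such entries are merged into one feature. The merged name joins the
#' member names (lexicographic order) with "//" after stripping a shared
#' arm suffix, which is re-appended once with the "_" spelling, e.g.
#' mir-19b-1-3p + mir-19b-2-3p -> "mir-19b-1//mir-19b-2_3p". Gene ids of
#' members are joined with "/".
#'
#' @param mirs a `mature_mirs` data.frame from [read_mature_fasta()].
#' @return data.frame of class `collapsed_reference` with columns
#'   `feature`, `sequence`, `members` ("//"-joined), `n_members`,
#'   `gene_id`; one row per distinct sequence, ordered by feature name.
#' @export
collapse_reference <- function(mirs) {
  stopifnot(all(c("name", "sequence") %in% names(mirs)))
  groups <- split(seq_len(nrow(mirs)), mirs$sequence)
  rows <- lapply(groups, function(idx) {
    members <- sort(mirs$name[idx])
    gid <- mirs$gene_id[idx][order(mirs$name[idx])]
    gid <- gid[!is.na(gid)]
    data.frame(
      feature = merged_feature_name(members),
      sequence = mirs$sequence[idx[1]],
      members = paste(members, collapse = "//"),
      n_members = length(members),
      gene_id = if (length(gid)) paste(gid, collapse = "/") else NA_character_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$feature), , drop = FALSE]
  rownames(out) <- NULL
  if (anyDuplicated(out$feature)) {
    .stopf("collapse produced duplicate feature names")
  }
  structure(out, class = c("collapsed_reference", "data.frame"))
}

#' @rdname collapse_reference
#' @param members character vector of member miR names.
#' @export
merged_feature_name <- function(members) {
  members <- sort(members)
  if (length(members) == 1L) return(members)
  arm <- sub("^.*[-_](3p|5p)$", "\\1", members)
  has_arm <- grepl("[-_](3p|5p)$", members)
  if (all(has_arm) && length(unique(arm)) == 1L) {
    base <- sub("[-_](3p|5p)$", "", members)
    paste0(paste(base, collapse = "//"), "_", arm[1])
  } else {
    paste(members, collapse = "//")
  }
}

#' Cluster identical inserts
#'
#' Exact multiset tally of insert sequences: one cluster per distinct
#' sequence; cluster counts sum to the number of inserts.
#'
#' @param inserts character vector of (already size-filtered) insert
#'   sequences.
#' @return data.frame `sequence`, `count`, ordered by sequence.
#' @export
cluster_reads <- function(inserts) {
  if (!length(inserts)) {
    return(data.frame(sequence = character(0), count = integer(0),
                      stringsAsFactors = FALSE))
  }
  tab <- table(inserts)
  data.frame(sequence = names(tab), count = as.integer(tab),
             stringsAsFactors = FALSE)
}

#' Matching policy for cluster-to-reference assignment
#'
#' `exact` (the default, the strictest reading of alignment against the
#' mature reference) assigns a cluster only when its sequence equals a
#' reference sequence byte-for-byte. `tol3p` additionally matches 3'
#' isomiR length variants: a read that is a prefix of a mature missing at
#' most `tol` 3' bases, or a mature that is a prefix of the read with at
#' most `tol` extra 3' bases; no internal mismatches. Ties prefer an
#' exact-length match, then the longest matched mature, then the
#' lexicographically smallest feature name.
#'
#' @param type "exact" or "tol3p".
#' @param tol 3' length tolerance in nt for `tol3p` (default 2).
#' @return a `match_policy` list.
#' @export
match_policy <- function(type = c("exact", "tol3p"), tol = 2L) {
  type <- match.arg(type)
  tol <- as.integer(tol)
  if (type == "tol3p" && tol < 0L) .stopf("tol must be >= 0")
  structure(list(type = type, tol = if (type == "exact") 0L else tol),
            class = "match_policy")
}

#' Assign cluster sequences to reference features
#'
#' @param sequences character vector of cluster sequences.
#' @param ref a [collapse_reference()] object.
#' @param policy a [match_policy()] object.
#' @return character vector of feature names, NA where unassigned.
#'   Deterministic: independent of reference row order.
#' @export
assign_clusters <- function(sequences, ref, policy = match_policy()) {
  ord <- order(ref$feature)
  rseq <- ref$sequence[ord]
  rfeat <- ref$feature[ord]
  feat <- rfeat[match(sequences, rseq)]
  if (policy$type == "exact" || policy$tol == 0L || !anyNA(feat)) return(feat)

  rlen <- nchar(rseq)
  # maps for "read is a prefix of the mature, missing d 3' bases"
  pref_maps <- lapply(seq_len(policy$tol), function(d) {
    keep <- rlen > d
    split(which(keep)[order(rfeat[keep])],
          substr(rseq[keep], 1L, rlen[keep] - d)[order(rfeat[keep])])
  })
  exact_map <- split(seq_along(rseq), rseq)

  todo <- which(is.na(feat))
  for (i in todo) {
    s <- sequences[i]
    ls <- nchar(s)
    cand <- integer(0)
    for (d in seq_len(policy$tol)) {
      cand <- c(cand, pref_maps[[d]][[s]])              # mature longer by d
      if (ls - d >= 1L) {                               # read longer by d
        cand <- c(cand, exact_map[[substr(s, 1L, ls - d)]])
      }
    }
    cand <- unique(cand)
    if (!length(cand)) next
    # tie-break: exact length (none here, by construction), longest
    # matched mature, then lexicographically smallest feature name
    o <- order(-rlen[cand], rfeat[cand])
    feat[i] <- rfeat[cand[o[1]]]
  }
  feat
}

#' Quantify one library against the collapsed reference
#'
#' Clusters the inserts, assigns clusters to features, and tallies counts
#' per feature (zero-count features retained). Unassigned reads are
#' tallied separately and never become a matrix row.
#'
#' @param inserts character vector of insert sequences (miR/piRNA size
#'   fraction of one library).
#' @param ref a [collapse_reference()] object.
#' @param policy a [match_policy()] object.
#' @return list with `counts` (named integer vector over all reference
#'   features) and `unassigned` (integer).
#' @export
quantify_library <- function(inserts, ref, policy = match_policy()) {
  cl <- cluster_reads(inserts)
  feat <- assign_clusters(cl$sequence, ref, policy)
  counts <- setNames(integer(nrow(ref)), ref$feature)
  hit <- !is.na(feat)
  if (any(hit)) {
    agg <- tapply(cl$count[hit], feat[hit], sum)
    counts[names(agg)] <- as.integer(agg)
  }
  list(counts = counts, unassigned = sum(cl$count[!hit]))
}

#' Build the feature x sample count matrix
#'
#' @param sample_counts named list of [quantify_library()] results (one
#'   per sample; all produced with the same reference and policy).
#' @param manifest data.frame with `sample_id` and `group` columns; every
#'   quantified sample must appear in it.
#' @return object of class `mir_counts`: list with `counts` (integer
#'   matrix), `samples` (manifest rows in matrix column order),
#'   `unassigned` (named integer vector).
#' @export
build_count_matrix <- function(sample_counts, manifest) {
  sids <- names(sample_counts)
  missing <- setdiff(sids, manifest$sample_id)
  if (length(missing)) {
    .stopf("sample '%s' not present in the manifest", missing[1])
  }
  sids <- manifest$sample_id[manifest$sample_id %in% sids]
  feats <- names(sample_counts[[1]]$counts)
  counts <- vapply(sids, function(s) {
    v <- sample_counts[[s]]$counts
    if (!identical(names(v), feats)) {
      .stopf("sample '%s' was quantified against a different reference", s)
    }
    v
  }, integer(length(feats)))
  counts <- matrix(counts, nrow = length(feats),
                   dimnames = list(feats, sids))
  groups <- setNames(manifest$group[match(sids, manifest$sample_id)], sids)
  structure(list(
    counts = counts,
    samples = data.frame(sample_id = sids, group = unname(groups),
                         stringsAsFactors = FALSE),
    unassigned = vapply(sample_counts[sids], `[[`, integer(1), "unassigned")),
    class = "mir_counts")
}

#' @export
print.mir_counts <- function(x, ...) {
  cat(sprintf("mir_counts: %d features x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat("groups:", paste(sprintf("%s(%d)", names(table(x$samples$group)),
                               table(x$samples$group)), collapse = " "), "\n")
  invisible(x)
}

#' Counts-per-million normalisation
#'
#' `cpm[f, s] = counts[f, s] / sum_f(counts[f, s]) * 1e6`. The denominator
#' is the miR-assigned reads of the sample (total miR content), so
#' `cpm / 1e4` is the percent of total miR content. Samples with zero
#' assigned reads are left as zero columns with a warning.
#'
#' @param x a `mir_counts` object or a counts matrix.
#' @param ... unused.
#' @return numeric matrix of the same shape; every column with at least
#'   one assigned read sums to 1e6.
#' @export
cpm <- function(x, ...) UseMethod("cpm")

#' @rdname cpm
#' @export
cpm.mir_counts <- function(x, ...) cpm(x$counts)

#' @rdname cpm
#' @export
cpm.default <- function(x, ...) {
  x <- as.matrix(x)
  tot <- colSums(x)
  zero <- tot == 0
  if (any(zero)) {
    warning("sample(s) with zero assigned reads left as zero CPM columns: ",
            paste(colnames(x)[zero], collapse = ", "))
    tot[zero] <- 1
  }
  sweep(x, 2L, tot, "/") * 1e6
}

#' Group-mean CPM
#'
#' @param cpm_mat CPM matrix (features x samples).
#' @param groups character vector of group labels, one per sample column.
#' @return matrix features x groups of mean CPM.
#' @export
group_mean_cpm <- function(cpm_mat, groups) {
  stopifnot(ncol(cpm_mat) == length(groups))
  gs <- unique(groups)
  out <- vapply(gs, function(g) {
    rowMeans(cpm_mat[, groups == g, drop = FALSE])
  }, numeric(nrow(cpm_mat)))
  matrix(out, nrow = nrow(cpm_mat), dimnames = list(rownames(cpm_mat), gs))
}
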