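# Two-group negative-binomial exact-test differential enrichment with
# common dispersion (qCML-style), BH-FDR, and enriched/depleted
# classification. Variance model: var = mu + phi * mu^2; phi = 0
# degenerates to Poisson/binomial.

#' Differential-enrichment configuration
#'
#' @param fdr_threshold significance threshold on the adjusted p value
#'   (default 0.01).
#' @param fc_up minimum fold change (group B over group A) to call
#'   ENRICHED (default 2).
#' @param fc_down maximum fold change to call DEPLETED (default 0.5,
#'   i.e. 1/fc_up).
#' @param pseudo_cpm pseudo-count (CPM units) added to both group-mean
#'   CPMs before forming the fold change, so zero-count features have a
#'   finite fold change (default 0.5).
#' @param use_raw_p classify on the raw p value instead of the FDR
#'   (default FALSE).
#' @return a `de_config` list.
#' @export
de_config <- function(fdr_threshold = 0.01, fc_up = 2, fc_down = 0.5,
                      pseudo_cpm = 0.5, use_raw_p = FALSE) {
  stopifnot(fdr_threshold > 0, fdr_threshold <= 1, fc_up > 1,
            fc_down < 1, fc_down > 0, pseudo_cpm >= 0)
  structure(list(fdr_threshold = fdr_threshold, fc_up = fc_up,
                 fc_down = fc_down, pseudo_cpm = pseudo_cpm,
                 use_raw_p = use_raw_p),
            class = "de_config")
}

#' Equalize library sizes by pseudo-counts
#'
#' The conditional exact test requires equal library sizes. Counts are
#' scaled to the geometric mean of the per-sample totals and rounded
#' half-to-even to integers.
#'
#' @param counts integer matrix (features x samples).
#' @return list with `pseudo` (integer matrix), `common_size`, `factors`
#'   (per-sample scaling factors applied).
#' @export
equalize_libraries <- function(counts) {
  counts <- as.matrix(counts)
  libsize <- colSums(counts)
  if (any(libsize == 0)) {
    .stopf("sample '%s' has zero total counts; cannot equalize",
           colnames(counts)[which(libsize == 0)[1]])
  }
  common <- exp(mean(log(libsize)))
  f <- common / libsize
  pseudo <- round(sweep(counts, 2L, f, "*"))
  storage.mode(pseudo) <- "integer"
  list(pseudo = pseudo, common_size = common, factors = f)
}

# Negative-binomial conditional log-likelihood of one dispersion value,
# summed over features and groups; each feature is conditioned on its
# within-group total (multinomial-coefficient constants included so the
# value is a true log probability).
.cond_loglik <- function(phi, counts, groups) {
  r <- 1 / phi
  ll <- 0
  for (g in unique(groups)) {
    Y <- counts[, groups == g, drop = FALSE]
    n <- ncol(Y)
    z <- rowSums(Y)
    ll <- ll + sum(rowSums(lgamma(Y + r)) - n * lgamma(r) -
                     rowSums(lgamma(Y + 1)) -
                     lgamma(z + n * r) + lgamma(n * r) + lgamma(z + 1))
  }
  ll
}

#' Estimate the common negative-binomial dispersion
#'
#' Maximizes the summed per-feature conditional log-likelihood (each
#' feature conditioned on its within-group total) over a log-spaced grid
#' phi in [1e-4, 4], refined by golden-section search to relative
#' tolerance 1e-4. All-zero features are excluded.
#'
#' @param pseudo equalized count matrix from [equalize_libraries()].
#' @param groups character vector of group labels per sample column; at
#'   least one group needs >= 2 samples.
#' @param phi_range search interval for phi (default c(1e-4, 4)).
#' @param rel_tol golden-section relative tolerance on phi (default 1e-4).
#' @return list of class `dispersion_estimate`: `phi`, `method`, `loglik`.
#' @export
estimate_common_dispersion <- function(pseudo, groups,
                                       phi_range = c(1e-4, 4),
                                       rel_tol = 1e-4) {
  pseudo <- as.matrix(pseudo)
  stopifnot(ncol(pseudo) == length(groups))
  keep <- rowSums(pseudo) > 0
  if (!any(keep)) .stopf("no feature with positive counts")
  if (max(table(groups)) < 2L) {
    .stopf("dispersion estimation needs >= 2 samples in at least one group")
  }
  Y <- pseudo[keep, , drop = FALSE]
  obj <- function(phi) .cond_loglik(phi, Y, groups)

  grid <- exp(seq(log(phi_range[1]), log(phi_range[2]), length.out = 25))
  vals <- vapply(grid, obj, numeric(1))
  k <- which.max(vals)
  lo <- log(grid[max(1L, k - 1L)])
  hi <- log(grid[min(length(grid), k + 1L)])

  gr <- (sqrt(5) - 1) / 2  # golden-section on log(phi)
  a <- lo; b <- hi
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- obj(exp(x1)); f2 <- obj(exp(x2))
  while ((b - a) > rel_tol) {
    if (f1 < f2) {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- obj(exp(x2))
    } else {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- obj(exp(x1))
    }
  }
  phi <- exp((a + b) / 2)
  structure(list(phi = phi, method = "conditional-likelihood grid + golden section",
                 loglik = obj(phi)),
            class = "dispersion_estimate")
}

#' Two-group negative-binomial exact test
#'
#' Conditional on the total s of both group sums (counts from equalized
#' libraries), the split follows a beta-binomial law with shape parameters
#' n_a/phi and n_b/phi (each group sum is NB with size n_g/phi and equal
#' per-library mean; the mean cancels in the conditional). The two-sided
#' p value doubles the smaller tail, with the observed point mass included
#' in both tails, capped at 1. For s greater than `exact_limit` the tails
#' use a normal approximation with continuity correction (mean and
#' variance of the beta-binomial); below it, exact log-space summation
#' over all s+1 splits.
#'
#' @param counts_a,counts_b non-negative integer pseudo-counts of the two
#'   groups for one feature.
#' @param phi common NB dispersion (>= 0; 0 is the Poisson/binomial limit).
#' @param exact_limit maximum total for exact enumeration (default 5000).
#' @return two-sided p value in [0, 1].
#' @export
nb_exact_test <- function(counts_a, counts_b, phi, exact_limit = 5000L) {
  if (any(counts_a < 0) || any(counts_b < 0)) .stopf("negative counts")
  if (phi < 0) .stopf("phi must be >= 0")
  n_a <- length(counts_a); n_b <- length(counts_b)
  s <- sum(counts_a) + sum(counts_b)
  if (s == 0) return(1)
  obs <- sum(counts_a)

  if (phi == 0) {                      # Poisson limit: binomial split
    pr <- n_a / (n_a + n_b)
    lower <- pbinom(obs, s, pr)
    upper <- pbinom(obs - 1L, s, pr, lower.tail = FALSE)
    return(min(1, 2 * min(lower, upper)))
  }

  alpha_a <- n_a / phi
  alpha_b <- n_b / phi
  if (s <= exact_limit) {
    x <- 0:s
    lw <- lchoose(x + alpha_a - 1, x) + lchoose(s - x + alpha_b - 1, s - x)
    lw <- lw - max(lw)
    w <- exp(lw)
    w <- w / sum(w)
    lower <- sum(w[x <= obs])
    upper <- sum(w[x >= obs])
  } else {
    ab <- alpha_a + alpha_b
    mu <- s * alpha_a / ab
    v <- s * alpha_a * alpha_b * (ab + s) / (ab^2 * (ab + 1))
    lower <- pnorm(obs + 0.5, mu, sqrt(v))
    upper <- pnorm(obs - 0.5, mu, sqrt(v), lower.tail = FALSE)
  }
  min(1, 2 * min(lower, upper))
}

#' Benjamini-Hochberg step-up FDR
#'
#' Step-up adjustment with monotone enforcement; stable under ties and
#' invariant to input permutation (after restoring order).
#'
#' @param p_values numeric vector of p values in [0, 1].
#' @return adjusted q values, same order as the input.
#' @export
bh_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    .stopf("p values must lie in [0, 1]")
  }
  n <- length(p_values)
  if (!n) return(numeric(0))
  o <- order(p_values)
  q <- p_values[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

#' Classify features as enriched, depleted or not significant
#'
#' ENRICHED iff fold change >= `fc_up` and the significance value (FDR by
#' default) < `fdr_threshold`; DEPLETED iff fold change <= `fc_down` and
#' significant; otherwise NS.
#'
#' @param fold_change fold change of group B over group A.
#' @param fdr adjusted p values.
#' @param p_value raw p values (used when `cfg$use_raw_p`).
#' @param cfg a [de_config()] object.
#' @return factor with levels ENRICHED, DEPLETED, NS.
#' @export
classify_enrichment <- function(fold_change, fdr, p_value = fdr,
                                cfg = de_config()) {
  crit <- if (isTRUE(cfg$use_raw_p)) p_value else fdr
  cls <- rep("NS", length(fold_change))
  cls[fold_change >= cfg$fc_up & crit < cfg$fdr_threshold] <- "ENRICHED"
  cls[fold_change <= cfg$fc_down & crit < cfg$fdr_threshold] <- "DEPLETED"
  factor(cls, levels = c("ENRICHED", "DEPLETED", "NS"))
}

#' Two-group differential enrichment of miR counts
#'
#' Full classic workflow: library equalization, common-dispersion
#' estimation, per-feature NB exact test, BH-FDR, fold change from
#' pseudo-counted group-mean CPMs, and classification. Fold changes are
#' reported as group B over group A ("enrichment in B").
#'
#' @param x a `mir_counts` object from [build_count_matrix()].
#' @param group_a,group_b the two group labels to compare.
#' @param phi optional fixed dispersion; estimated from the data when NULL.
#' @param cfg a [de_config()] object.
#' @return data.frame of class `enrichment_result`: feature, mean_cpm_a,
#'   mean_cpm_b, fold_change, log2fc, p_value, fdr, class; one row per
#'   feature, in reference feature order. The dispersion used is attached
#'   as attribute `phi`.
#' @export
test_enrichment <- function(x, group_a, group_b, phi = NULL,
                            cfg = de_config()) {
  stopifnot(inherits(x, "mir_counts"))
  groups <- x$samples$group
  if (!group_a %in% groups) .stopf("unknown group '%s'", group_a)
  if (!group_b %in% groups) .stopf("unknown group '%s'", group_b)
  sel <- groups %in% c(group_a, group_b)
  counts <- x$counts[, sel, drop = FALSE]
  g <- groups[sel]

  eq <- equalize_libraries(counts)
  if (is.null(phi)) {
    phi <- estimate_common_dispersion(eq$pseudo, g)$phi
  }
  p <- vapply(seq_len(nrow(counts)), function(i) {
    nb_exact_test(eq$pseudo[i, g == group_a], eq$pseudo[i, g == group_b], phi)
  }, numeric(1))
  fdr <- bh_fdr(p)

  cpm_mat <- cpm(counts)
  mean_a <- rowMeans(cpm_mat[, g == group_a, drop = FALSE])
  mean_b <- rowMeans(cpm_mat[, g == group_b, drop = FALSE])
  fc <- (mean_b + cfg$pseudo_cpm) / (mean_a + cfg$pseudo_cpm)

  res <- data.frame(
    feature = rownames(counts),
    mean_cpm_a = mean_a, mean_cpm_b = mean_b,
    fold_change = fc, log2fc = log2(fc),
    p_value = p, fdr = fdr,
    class = classify_enrichment(fc, fdr, p, cfg),
    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "phi") <- phi
  attr(res, "groups") <- c(a = group_a, b = group_b)
  class(res) <- c("enrichment_result", "data.frame")
  res
}
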