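# Independent oracles (brute force / enumeration / closed form) and tiny
# fixture builders shared across the suite. Oracles deliberately avoid the
# package's own code paths.

# brute-force adapter scan: every (position, overlap) pair, leftmost wins
oracle_adapter_scan <- function(seq, adapter, min_overlap = 8, rate = 0.1) {
  L <- nchar(seq)
  A <- nchar(adapter)
  sc <- strsplit(seq, "")[[1]]
  ac <- strsplit(adapter, "")[[1]]
  for (i in seq_len(L)) {
    ov <- min(A, L - i + 1)
    if (ov < min_overlap) next
    mm <- sum(sc[i:(i + ov - 1)] != ac[seq_len(ov)])
    if (mm <= floor(rate * ov)) return(i - 1L)
  }
  NA_integer_
}

# brute-force longest prefix whose mean quality exceeds the threshold
oracle_qtrim_len <- function(q, threshold) {
  best <- 0L
  for (k in seq_along(q)) {
    if (mean(q[seq_len(k)]) > threshold) best <- k
  }
  best
}

# enumeration oracle for the conditional NB exact test: products of NB
# pmfs for the two group sums, normalized over all splits of the total
oracle_nb_p <- function(a, b, phi) {
  s <- sum(a) + sum(b)
  if (s == 0) return(1)
  obs <- sum(a)
  n_a <- length(a)
  n_b <- length(b)
  x <- 0:s
  if (phi == 0) {
    w <- dbinom(x, s, n_a / (n_a + n_b))
  } else {
    mu <- 7.3  # arbitrary per-library mean; cancels in the conditional
    w <- dnbinom(x, size = n_a / phi, mu = n_a * mu) *
      dnbinom(s - x, size = n_b / phi, mu = n_b * mu)
  }
  w <- w / sum(w)
  min(1, 2 * min(sum(w[x <= obs]), sum(w[x >= obs])))
}

# per-element membership enumeration for Venn regions
oracle_venn_regions <- function(sets) {
  univ <- unique(unlist(sets, use.names = FALSE))
  pat <- vapply(univ, function(e) {
    paste(names(sets)[vapply(sets, function(s) e %in% s, logical(1))],
          collapse = "&")
  }, character(1))
  table(pat)
}

# hash-free O(n^2) grouping of reference entries by identical sequence
oracle_group_by_sequence <- function(seqs) {
  groups <- list()
  for (i in seq_along(seqs)) {
    placed <- FALSE
    for (k in seq_along(groups)) {
      if (seqs[groups[[k]][1]] == seqs[i]) {
        groups[[k]] <- c(groups[[k]], i)
        placed <- TRUE
        break
      }
    }
    if (!placed) groups[[length(groups) + 1L]] <- i
  }
  groups
}

rand_dna <- function(n, len) {
  len <- rep_len(len, n)
  vapply(len, function(l) {
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
  }, character(1))
}

make_reads <- function(sequence, phred) {
  data.frame(read_id = paste0("r", seq_along(sequence)),
             sequence = sequence,
             quality = mirpipe::phred_encode(phred),
             stringsAsFactors = FALSE)
}

make_mirs <- function(name, sequence, gene_id = NA_character_) {
  structure(
    data.frame(name = name, description = "",
               gene_id = rep_len(gene_id, length(name)),
               sequence = sequence,
               arm = ifelse(grepl("[-_]5p$", name), "5p",
                            ifelse(grepl("[-_]3p$", name), "3p", NA_character_)),
               stringsAsFactors = FALSE),
    class = c("mature_mirs", "data.frame"))
}

make_mir_counts <- function(counts, groups) {
  structure(list(
    counts = counts,
    samples = data.frame(sample_id = colnames(counts), group = groups,
                         stringsAsFactors = FALSE),
    unassigned = setNames(integer(ncol(counts)), colnames(counts))),
    class = "mir_counts")
}

TEST_ADAPTER <- "TGGAATTCTCGGGTGCCAAGG"
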