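# Synthetic small RNA libraries with full ground truth: reference FASTA,
# group compositions, NB counts, and adapter-ligated FASTQ reads with a
# plateau-then-decay quality model and controlled contaminants. Every
# output is a pure function of (spec, seed); each library draws from its
# own RNG stream so adding a library never perturbs the others.

# Deterministic per-label RNG stream: Horner hash of the label mixed with
# the user seed, kept below 2^31.
.derive_seed <- function(seed, label) {
  p <- 2147483647
  h <- 0
  for (c in utf8ToInt(label)) h <- (h * 31 + c) %% p
  as.integer((h + (as.numeric(seed) %% p) * 48271) %% p)
}

.random_dna <- function(n, len) {
  if (n == 0L) return(character(0))
  chars <- sample(c("A", "C", "G", "T"), sum(len), replace = TRUE)
  ends <- cumsum(len)
  starts <- ends - len + 1L
  full <- paste(chars, collapse = "")
  substring(full, starts, ends)
}

#' Specification of a synthetic small RNA study
#'
#' Defaults mirror the profiled study design: 4 populations (Mk, MkMP,
#' PLP, PLT) with 3/3/3/2 replicate libraries, 51-cycle single-end reads,
#' and a heavy-tailed (log-normal, sigma = 2) miR composition in which a
#' handful of features dominate the content.
#'
#' @param n_mirs number of mature miR entries in the reference (300).
#' @param mature_length_range mature length range in nt (c(18, 25)).
#' @param groups named integer vector: replicates per group.
#' @param composition_model "lognormal" (exp(N(0, sigma)) shares) or
#'   "dirichlet" (unit-rate gamma shares).
#' @param sigma log-normal composition spread (default 2).
#' @param spike_design optional data.frame `feature` (collapsed feature
#'   name), `group`, `fold`: per-group abundance multipliers, renormalized
#'   within the group.
#' @param dispersion NB dispersion phi; variance = mu + phi mu^2 (0.1).
#' @param depth target reads per library (1e5).
#' @param adapter 3' adapter ligated to every insert (TruSeq small RNA 3'
#'   adapter by default).
#' @param read_length sequencing cycles (51).
#' @param qual_plateau,qual_decay_start,qual_decay_rate,qual_noise_sd
#'   quality model: Phred plateau, position where the 3' decay starts,
#'   decay per cycle, and the sd of per-base noise (clipped at +/- 3 sd).
#' @param contaminant_rates named rates in [0, 1), summing below 1:
#'   `no_adapter` (random reads without the adapter), `long_insert`
#'   (41 nt up to read_length - min_overlap inserts; the long fraction),
#'   `low_quality` (inserts whose qualities force EMPTY_AFTER_QTRIM).
#' @param n_duplicate_matures pairs of reference entries sharing one
#'   sequence under distinct locus names, exercising reference collapse (1).
#' @param adapter_min_overlap detection overlap assumed for the generator's
#'   by-construction guarantees (8, the pipeline default).
#' @param seed integer master seed.
#' @return a `simulation_spec` list.
#' @export
simulation_spec <- function(n_mirs = 300L,
                            mature_length_range = c(18L, 25L),
                            groups = c(Mk = 3L, MkMP = 3L, PLP = 3L, PLT = 2L),
                            composition_model = c("lognormal", "dirichlet"),
                            sigma = 2.0,
                            spike_design = NULL,
                            dispersion = 0.1,
                            depth = 1e5,
                            adapter = "TGGAATTCTCGGGTGCCAAGG",
                            read_length = 51L,
                            qual_plateau = 37L,
                            qual_decay_start = 40L,
                            qual_decay_rate = 0.5,
                            qual_noise_sd = 1,
                            contaminant_rates = c(no_adapter = 0, long_insert = 0,
                                                  low_quality = 0),
                            n_duplicate_matures = 1L,
                            adapter_min_overlap = 8L,
                            seed = 1L) {
  composition_model <- match.arg(composition_model)
  stopifnot(n_mirs >= 1L, length(mature_length_range) == 2L,
            mature_length_range[1] <= mature_length_range[2],
            !is.null(names(groups)), all(groups >= 1L),
            dispersion >= 0, depth >= 0)
  rates <- c(no_adapter = 0, long_insert = 0, low_quality = 0)
  rates[names(contaminant_rates)] <- contaminant_rates
  if (any(rates < 0) || any(rates >= 1) || sum(rates) >= 1) {
    .stopf("contaminant rates must lie in [0, 1) and sum below 1")
  }
  if (mature_length_range[2] + adapter_min_overlap > read_length) {
    .stopf("mature length %d + min overlap %d exceeds read length %d: adapter undetectable by construction",
           mature_length_range[2], adapter_min_overlap, read_length)
  }
  if (n_duplicate_matures * 2L > n_mirs) {
    .stopf("n_duplicate_matures too large for n_mirs")
  }
  structure(list(
    n_mirs = as.integer(n_mirs),
    mature_length_range = as.integer(mature_length_range),
    groups = groups, composition_model = composition_model, sigma = sigma,
    spike_design = spike_design, dispersion = dispersion, depth = depth,
    adapter = toupper(adapter), read_length = as.integer(read_length),
    qual_plateau = qual_plateau, qual_decay_start = qual_decay_start,
    qual_decay_rate = qual_decay_rate, qual_noise_sd = qual_noise_sd,
    contaminant_rates = rates,
    n_duplicate_matures = as.integer(n_duplicate_matures),
    adapter_min_overlap = as.integer(adapter_min_overlap),
    seed = as.integer(seed)),
    class = "simulation_spec")
}

.sim_params <- function(spec) {
  trim_params(spec$adapter, min_overlap = spec$adapter_min_overlap)
}

#' Generate the synthetic mature miR reference
#'
#' Draws unique random mature sequences (plus `n_duplicate_matures` pairs
#' sharing a sequence under distinct locus names). Sequences are rejected
#' when the 3' adapter would be falsely detected before the true insert
#' boundary of the read `mature + adapter`, so downstream adapter
#' detection is exact by construction. Deterministic under the spec seed.
#'
#' @param spec a [simulation_spec()] object.
#' @return a `mature_mirs` data.frame (name, gene_id, sequence, arm).
#' @export
generate_reference <- function(spec) {
  set.seed(.derive_seed(spec$seed, "reference"))
  lo <- spec$mature_length_range[1]; hi <- spec$mature_length_range[2]
  n_unique <- spec$n_mirs - spec$n_duplicate_matures
  if (lo == hi && 4^min(lo, 25) < n_unique) {
    .stopf("length range too narrow to generate %d unique sequences", n_unique)
  }
  params <- .sim_params(spec)
  seqs <- character(0)
  guard <- 0L
  while (length(seqs) < n_unique) {
    need <- n_unique - length(seqs)
    cand <- .random_dna(need, sample(lo:hi, need, replace = TRUE))
    # true boundary check: adapter must be detected exactly at the insert end
    pos <- adapter_positions(paste0(cand, spec$adapter), params)
    ok <- !is.na(pos) & pos == nchar(cand)
    seqs <- unique(c(seqs, cand[ok]))
    guard <- guard + 1L
    if (guard > 1000L) .stopf("could not generate %d unique clean sequences", n_unique)
  }
  # the first n_duplicate_matures sequences each belong to a locus pair
  # (distinct a/b names, identical sequence); the rest are singletons
  nd <- spec$n_duplicate_matures
  arm_all <- rep(c("5p", "3p"), length.out = n_unique)
  rows <- list()
  for (j in seq_len(nd)) {
    rows[[length(rows) + 1L]] <- data.frame(
      name = sprintf("sim-miR-%03d%s-%s", j, c("a", "b"), arm_all[j]),
      description = "",
      gene_id = sprintf("%d", 200000L + 2L * j - c(1L, 0L)),
      sequence = seqs[j], arm = arm_all[j], stringsAsFactors = FALSE)
  }
  if (n_unique > nd) {
    idx <- seq(nd + 1L, n_unique)
    rows[[length(rows) + 1L]] <- data.frame(
      name = sprintf("sim-miR-%03d-%s", idx, arm_all[idx]),
      description = "",
      gene_id = sprintf("%d", 100000L + idx),
      sequence = seqs[idx], arm = arm_all[idx], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("mature_mirs", "data.frame")
  out
}

#' Generate the true count matrix
#'
#' Per-group compositions come from the composition model (heavy-tailed
#' log-normal by default) with spike multipliers applied and renormalized;
#' counts are independent NB draws, `counts[f, s] ~ NB(mean = depth_assigned
#' * p_g(f), dispersion = phi)` where `depth_assigned` is the target depth
#' times the non-contaminant fraction.
#'
#' @param spec a [simulation_spec()] object.
#' @param ref collapsed reference ([collapse_reference()]); truth is keyed
#'   by collapsed feature so it compares directly with pipeline output.
#' @return list: `counts` (features x samples integer matrix), `samples`
#'   (data.frame sample_id, group), `composition` (features x groups),
#'   `depth_assigned`.
#' @export
generate_counts <- function(spec, ref) {
  feats <- ref$feature
  nf <- length(feats)
  set.seed(.derive_seed(spec$seed, "composition"))
  base <- switch(spec$composition_model,
                 lognormal = exp(rnorm(nf, 0, spec$sigma)),
                 dirichlet = rgamma(nf, shape = 1))
  base <- base / sum(base)

  comp <- vapply(names(spec$groups), function(g) {
    p <- base
    sd <- spec$spike_design
    if (!is.null(sd)) {
      sel <- sd$group == g
      if (any(sel)) {
        i <- match(sd$feature[sel], feats)
        if (anyNA(i)) .stopf("spike feature not in reference: %s",
                             sd$feature[sel][which(is.na(i))[1]])
        p[i] <- p[i] * sd$fold[sel]
      }
    }
    p / sum(p)
  }, numeric(nf))
  dimnames(comp) <- list(feats, names(spec$groups))

  depth_assigned <- spec$depth * (1 - sum(spec$contaminant_rates))
  samples <- data.frame(
    sample_id = unlist(lapply(names(spec$groups), function(g) {
      paste0(g, "_", seq_len(spec$groups[[g]]))
    })),
    group = rep(names(spec$groups), times = spec$groups),
    stringsAsFactors = FALSE)

  counts <- vapply(seq_len(nrow(samples)), function(i) {
    set.seed(.derive_seed(spec$seed, paste0("counts:", samples$sample_id[i])))
    mu <- depth_assigned * comp[, samples$group[i]]
    if (spec$dispersion == 0) {
      as.numeric(rpois(nf, mu))
    } else {
      as.numeric(rnbinom(nf, mu = mu, size = 1 / spec$dispersion))
    }
  }, numeric(nf))
  counts <- matrix(as.integer(counts), nrow = nf,
                   dimnames = list(feats, samples$sample_id))
  list(counts = counts, samples = samples, composition = comp,
       depth_assigned = depth_assigned)
}

# quality matrix for n reads: plateau, linear 3' decay, clipped noise;
# returns integer matrix read_length x n
.qual_matrix <- function(n, spec) {
  L <- spec$read_length
  base <- spec$qual_plateau -
    spec$qual_decay_rate * pmax(0, seq_len(L) - spec$qual_decay_start)
  noise <- matrix(rnorm(L * n, 0, spec$qual_noise_sd), nrow = L)
  noise <- pmin(pmax(noise, -3 * spec$qual_noise_sd), 3 * spec$qual_noise_sd)
  q <- round(base + noise)
  matrix(as.integer(pmin(pmax(q, 2L), 40L)), nrow = L)
}

.encode_qual_matrix <- function(Q) {
  L <- nrow(Q); n <- ncol(Q)
  if (n == 0L) return(character(0))
  full <- rawToChar(as.raw(as.vector(Q) + 33L))
  substring(full, (seq_len(n) - 1L) * L + 1L, seq_len(n) * L)
}

# assemble insert+adapter reads padded with random bases to read_length,
# rejection-sampling so the adapter is detected exactly at the true insert
# boundary (keeps the contaminant ledger exact by construction). When
# regen_inserts is TRUE, failed reads get a fresh random insert of the
# same length (contaminants); fixed inserts (matures) are only re-padded —
# they are pre-validated at reference generation.
.assemble_reads <- function(inserts, spec, params, regen_inserts = FALSE) {
  n <- length(inserts)
  if (!n) return(list(reads = character(0), inserts = inserts))
  L <- spec$read_length
  reads <- character(n)
  todo <- seq_len(n)
  guard <- 0L
  while (length(todo)) {
    body <- paste0(inserts[todo], spec$adapter)
    pad_len <- pmax(0L, L - nchar(body))
    reads[todo] <- substr(paste0(body, .random_dna(length(todo), pad_len)), 1L, L)
    pos <- adapter_positions(reads[todo], params)
    ok <- !is.na(pos) & pos == nchar(inserts[todo])
    todo <- todo[!ok]
    if (length(todo) && regen_inserts) {
      inserts[todo] <- .random_dna(length(todo), nchar(inserts[todo]))
    }
    guard <- guard + 1L
    if (guard > 1000L) .stopf("failed to assemble clean reads")
  }
  list(reads = reads, inserts = inserts)
}

#' Generate the per-library FASTQ files
#'
#' Every assigned read is its feature's mature sequence plus the adapter,
#' padded with random bases and truncated to `read_length`, under the
#' plateau/decay quality model. Contaminants are injected at the spec
#' rates, with counts drawn Binomial(depth, rate): adapter-less random
#' reads, long (above `insert_max`) inserts, and reads whose insert
#' qualities force EMPTY_AFTER_QTRIM. Read order is shuffled
#' deterministically per library.
#'
#' @param truth result of [generate_counts()].
#' @param ref collapsed reference.
#' @param spec a [simulation_spec()] object.
#' @param dir output directory for the FASTQ files.
#' @return the ground-truth ledger: data.frame per library with
#'   `assigned`, `no_adapter`, `long_insert`, `low_quality`, `depth`
#'   (realized reads written).
#' @export
generate_fastq <- function(truth, ref, spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  params <- .sim_params(spec)
  rates <- spec$contaminant_rates
  seq_of <- setNames(ref$sequence, ref$feature)
  ledger <- list()
  for (i in seq_len(nrow(truth$samples))) {
    sid <- truth$samples$sample_id[i]
    set.seed(.derive_seed(spec$seed, paste0("fastq:", sid)))

    counts <- truth$counts[, sid]
    assigned_ins <- rep(unname(seq_of[names(counts)]), counts)
    n_na <- rbinom(1L, spec$depth, rates[["no_adapter"]])
    n_li <- rbinom(1L, spec$depth, rates[["long_insert"]])
    n_lq <- rbinom(1L, spec$depth, rates[["low_quality"]])

    long_max_detect <- spec$read_length - spec$adapter_min_overlap
    li_ins <- .random_dna(n_li, sample(seq(params$insert_max + 1L, long_max_detect),
                                       n_li, replace = TRUE))
    lq_ins <- .random_dna(n_lq, sample(seq(params$insert_min, params$insert_max),
                                       n_lq, replace = TRUE))
    asm_a <- .assemble_reads(assigned_ins, spec, params, regen_inserts = FALSE)
    asm_c <- .assemble_reads(c(li_ins, lq_ins), spec, params, regen_inserts = TRUE)
    with_adapter <- c(assigned_ins, asm_c$inserts)
    reads <- c(asm_a$reads, asm_c$reads)

    # adapter-less contaminants: random reads, re-drawn until no adapter
    # is detectable anywhere
    na_reads <- character(0)
    todo <- n_na
    while (todo > 0L) {
      cand <- .random_dna(todo, rep(spec$read_length, todo))
      ok <- is.na(adapter_positions(cand, params))
      na_reads <- c(na_reads, cand[ok])
      todo <- n_na - length(na_reads)
    }
    reads <- c(reads, na_reads)
    n_tot <- length(reads)

    Q <- .qual_matrix(n_tot, spec)
    # low-quality contaminants: insert bases at Phred 2, so the mean of
    # every prefix is at most 2 and the quality trim empties the insert
    lq_idx <- length(assigned_ins) + n_li + seq_len(n_lq)
    for (k in lq_idx) Q[seq_len(nchar(with_adapter[k])), k] <- 2L
    quals <- .encode_qual_matrix(Q)

    perm <- sample.int(n_tot)
    rd <- new_srna_reads(sprintf("%s_read%07d", sid, seq_len(n_tot)),
                         reads[perm], quals[perm])
    write_fastq(rd, file.path(dir, paste0(sid, ".fastq")))
    ledger[[sid]] <- data.frame(
      sample_id = sid, assigned = length(assigned_ins),
      no_adapter = n_na, long_insert = n_li, low_quality = n_lq,
      depth = n_tot, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, ledger)
  rownames(out) <- NULL
  out
}

#' Simulate a complete ground-truth study
#'
#' Writes the reference FASTA, manifest TSV, per-library FASTQ files and
#' truth tables to `dir`; returns everything in memory as well.
#'
#' @param spec a [simulation_spec()] object.
#' @param dir output directory.
#' @return list of class `sim_study`: `reference` (mature_mirs),
#'   `collapsed` (collapsed_reference), `truth` ([generate_counts()]
#'   output), `ledger` (per-library read ledger), and the `reference_fasta`,
#'   `manifest` file paths.
#' @export
simulate_study <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  reference <- generate_reference(spec)
  collapsed <- collapse_reference(reference)
  truth <- generate_counts(spec, collapsed)
  ledger <- generate_fastq(truth, collapsed, spec, dir)

  fasta <- file.path(dir, "reference.fa")
  write_mature_fasta(reference, fasta)
  manifest <- data.frame(
    sample_id = truth$samples$sample_id,
    fastq = file.path(dir, paste0(truth$samples$sample_id, ".fastq")),
    group = truth$samples$group, stringsAsFactors = FALSE)
  mpath <- file.path(dir, "manifest.tsv")
  write_manifest(manifest, mpath)
  write_counts(truth$counts, file.path(dir, "true_counts.tsv"))
  write_json_atomic(list(ledger = ledger, depth = spec$depth,
                         contaminant_rates = as.list(spec$contaminant_rates)),
                    file.path(dir, "truth_ledger.json"))
  structure(list(reference = reference, collapsed = collapsed, truth = truth,
                 ledger = ledger, reference_fasta = fasta, manifest = mpath),
            class = "sim_study")
}
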