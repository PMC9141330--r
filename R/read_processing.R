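# Read cleanup: 3' adapter detection with mandatory retention, quality
# end-trimming to a mean Phred threshold, and size-fraction partitioning.
#
# Retention rule: only reads in which the 3' flanking adapter is detected
# are kept, because they represent full-length sequencing of the insert.

STATUS_LEVELS <- c("KEPT", "NO_ADAPTER", "EMPTY_AFTER_QTRIM", "OUT_OF_SIZE")
FRACTION_LEVELS <- c("MIR_PIRNA_18_40", "LONG_40_150", "NONE")

#' Trimming parameters
#'
#' @param adapter 3' adapter DNA sequence. The library kit's 3' adapter;
#'   the TruSeq small RNA 3' adapter is a common choice but the value is
#'   never hard-coded as correct.
#' @param min_overlap minimum adapter/read overlap (nt) for a detection
#'   (default 8).
#' @param max_mismatch_rate maximum fraction of mismatches allowed in the
#'   overlap; the allowance is `floor(rate * overlap)` (default 0.1). N
#'   bases count as mismatches.
#' @param qual_threshold mean Phred threshold Q: the retained prefix must
#'   have mean quality strictly greater than this (default 30).
#' @param insert_min,insert_max bounds (nt) of the miR/piRNA size fraction
#'   (defaults 18 and 40).
#' @param long_max upper bound (nt) of the long (snoRNA-range) fraction,
#'   which is counted but not quantified (default 150).
#' @return a `trim_params` list.
#' @export
trim_params <- function(adapter, min_overlap = 8L, max_mismatch_rate = 0.1,
                        qual_threshold = 30, insert_min = 18L,
                        insert_max = 40L, long_max = 150L) {
  adapter <- toupper(adapter)
  if (!nzchar(adapter) || grepl("[^ACGTN]", adapter)) {
    .stopf("adapter must be a non-empty DNA string over {A,C,G,T,N}")
  }
  min_overlap <- as.integer(min_overlap)
  if (min_overlap < 1L) .stopf("min_overlap must be >= 1")
  if (nchar(adapter) < min_overlap) .stopf("adapter shorter than min_overlap")
  if (max_mismatch_rate < 0 || max_mismatch_rate >= 1) {
    .stopf("max_mismatch_rate must be in [0, 1)")
  }
  if (insert_min > insert_max) .stopf("insert_min must be <= insert_max")
  structure(list(adapter = adapter, min_overlap = min_overlap,
                 max_mismatch_rate = max_mismatch_rate,
                 qual_threshold = qual_threshold,
                 insert_min = as.integer(insert_min),
                 insert_max = as.integer(insert_max),
                 long_max = as.integer(long_max)),
            class = "trim_params")
}

# Column-per-read raw byte matrix; reads padded with 0x01 (mismatches
# every base, and is never indexed beyond a read's own length).
.seq_raw_matrix <- function(seqs, width) {
  pad <- strrep("\x01", pmax(0L, width - nchar(seqs)))
  matrix(charToRaw(paste0(substr(paste0(seqs, pad), 1L, width), collapse = "")),
         nrow = width)
}

#' Locate the 3' adapter in reads
#'
#' Scans all start positions left to right. The adapter is detected at
#' position i when the overlap between the adapter prefix and the read
#' suffix starting at i (which either covers the whole adapter or runs to
#' the read end) has length >= `min_overlap` and at most
#' `floor(max_mismatch_rate * overlap)` mismatches; the leftmost detected
#' position wins and the insert is the read prefix before it.
#'
#' @param sequences character vector of read sequences.
#' @param params a [trim_params()] object.
#' @return integer vector of insert lengths (0 when the adapter starts at
#'   the first base); NA where no adapter was detected.
#' @export
adapter_positions <- function(sequences, params) {
  n <- length(sequences)
  res <- rep(NA_integer_, n)
  if (n == 0L) return(res)
  sequences <- toupper(sequences)
  L <- nchar(sequences)
  Lmax <- max(L)
  if (Lmax < params$min_overlap) return(res)
  M <- .seq_raw_matrix(sequences, Lmax)
  adp <- charToRaw(params$adapter)
  A <- length(adp)
  det <- logical(n)
  imax <- Lmax - params$min_overlap + 1L
  for (i in seq_len(imax)) {
    act <- which(!det & (L - i + 1L >= params$min_overlap))
    if (!length(act)) break
    ov <- pmin(A, L[act] - i + 1L)
    mm <- integer(length(act))
    mm_at_ov <- integer(length(act))
    for (j in seq_len(max(ov))) {
      mm <- mm + (M[i + j - 1L, act] != adp[j])
      hit <- ov == j
      if (any(hit)) mm_at_ov[hit] <- mm[hit]
    }
    ok <- mm_at_ov <= floor(params$max_mismatch_rate * ov)
    if (any(ok)) {
      res[act[ok]] <- i - 1L
      det[act[ok]] <- TRUE
    }
  }
  res
}

#' Detect and remove the 3' adapter from one read
#'
#' Adapter stage only: reads without a detected adapter get status
#' `NO_ADAPTER` (they are discarded downstream); detected reads return the
#' insert (possibly empty when the adapter starts at base 1).
#'
#' @param sequence read sequence (single string).
#' @param qualities integer Phred vector, same length as the sequence.
#' @param params a [trim_params()] object.
#' @return list with `status` ("KEPT" or "NO_ADAPTER"), `insert`,
#'   `insert_qualities`.
#' @export
detect_and_trim_adapter <- function(sequence, qualities, params) {
  stopifnot(length(sequence) == 1L, nchar(sequence) == length(qualities))
  pos <- adapter_positions(sequence, params)
  if (is.na(pos)) {
    return(list(status = "NO_ADAPTER", insert = NULL, insert_qualities = NULL))
  }
  list(status = "KEPT",
       insert = substr(sequence, 1L, pos),
       insert_qualities = qualities[seq_len(pos)])
}

#' Quality end-trim to a mean Phred threshold
#'
#' Returns the longest prefix whose mean Phred score is strictly greater
#' than `threshold` (equivalently, iteratively drop the last base until
#' the mean qualifies). May be empty. Trimming is from the 3' end only.
#'
#' @param sequence single DNA string.
#' @param qualities integer Phred vector of the same length.
#' @param threshold mean-quality threshold Q (default 30).
#' @return list with trimmed `sequence` and `qualities`.
#' @export
quality_end_trim <- function(sequence, qualities, threshold = 30) {
  stopifnot(nchar(sequence) == length(qualities))
  k <- 0L
  if (length(qualities)) {
    ok <- cumsum(qualities) > threshold * seq_along(qualities)
    if (any(ok)) k <- max(which(ok))
  }
  list(sequence = substr(sequence, 1L, k), qualities = qualities[seq_len(k)])
}

# Vectorised prefix lengths after quality end-trimming. quality: Phred+33
# strings; len: number of leading bases to consider per read.
.qtrim_lengths <- function(quality, len, threshold) {
  n <- length(quality)
  if (!n) return(integer(0))
  best <- integer(n)
  wmax <- max(len, 1L)
  Q <- matrix(as.integer(.seq_raw_matrix(quality, wmax)), nrow = wmax) - 33L
  cum <- numeric(n)
  for (j in seq_len(wmax)) {
    cum <- cum + Q[j, ]
    ok <- (j <= len) & (cum > threshold * j)
    best[ok] <- j
  }
  best
}

#' Partition inserts into size fractions
#'
#' Inserts of `insert_min`-`insert_max` nt (default 18-40) form the
#' miR/piRNA fraction that goes on to quantification; inserts of
#' `insert_max+1`-`long_max` nt (default 41-150) are the long
#' (snoRNA-range) fraction, which is counted but not quantified; anything
#' else is out of size.
#'
#' @param insert_length integer vector of insert lengths (nt).
#' @param params a [trim_params()] object.
#' @return factor with levels `MIR_PIRNA_18_40`, `LONG_40_150`, `NONE`.
#' @export
partition_by_size <- function(insert_length, params) {
  out <- rep("NONE", length(insert_length))
  out[insert_length >= params$insert_min & insert_length <= params$insert_max] <-
    "MIR_PIRNA_18_40"
  out[insert_length > params$insert_max & insert_length <= params$long_max] <-
    "LONG_40_150"
  factor(out, levels = FRACTION_LEVELS)
}

#' Run the full read-cleanup stage on a library
#'
#' Applies adapter detection, quality end-trimming and size partitioning.
#' The default order is adapter-first: the adapter defines the biological
#' insert boundary, and trimming quality first could destroy the adapter
#' and discard otherwise valid reads; `order = "qtrim-first"` reproduces
#' the literal listed order instead.
#'
#' A read whose adapter is detected at position 1 (empty insert) is
#' classed `OUT_OF_SIZE` (its adapter WAS detected; the size rule rejects
#' it); a read whose insert quality-trims to nothing is
#' `EMPTY_AFTER_QTRIM`.
#'
#' @param reads an `srna_reads` data.frame from [read_fastq()].
#' @param params a [trim_params()] object.
#' @param order "adapter-first" (default) or "qtrim-first".
#' @param keep_per_read also return the per-read status/fraction table.
#' @return list of class `trim_result`: `inserts` (data.frame `sequence`,
#'   `quality` for the miR/piRNA fraction), `attrition` (per-status and
#'   per-fraction counts summing to the input read count), and optionally
#'   `per_read`.
#' @export
process_library <- function(reads, params,
                            order = c("adapter-first", "qtrim-first"),
                            keep_per_read = FALSE) {
  order <- match.arg(order)
  n <- nrow(reads)
  status <- rep(NA_character_, n)
  ins_len <- integer(n)
  seqs <- reads$sequence
  quals <- reads$quality

  if (order == "qtrim-first") {
    qlen <- .qtrim_lengths(quals, nchar(seqs), params$qual_threshold)
    status[qlen == 0L] <- "EMPTY_AFTER_QTRIM"
    seqs <- substr(seqs, 1L, qlen)
    quals <- substr(quals, 1L, qlen)
  }

  todo <- is.na(status)
  pos <- rep(NA_integer_, n)
  pos[todo] <- adapter_positions(seqs[todo], params)
  status[todo & is.na(pos)] <- "NO_ADAPTER"

  det <- which(is.na(status))
  # adapter detected at base 1: empty insert, rejected by the size rule
  zero <- det[pos[det] == 0L]
  status[zero] <- "OUT_OF_SIZE"
  det <- setdiff(det, zero)
  ins_len[det] <- pos[det]

  if (order == "adapter-first" && length(det)) {
    qlen <- .qtrim_lengths(quals[det], ins_len[det], params$qual_threshold)
    status[det[qlen == 0L]] <- "EMPTY_AFTER_QTRIM"
    ins_len[det] <- qlen
    det <- det[qlen > 0L]
  }

  fraction <- rep(factor("NONE", levels = FRACTION_LEVELS), n)
  if (length(det)) {
    fr <- partition_by_size(ins_len[det], params)
    fraction[det] <- fr
    status[det[fr == "NONE"]] <- "OUT_OF_SIZE"
    status[det[fr != "NONE"]] <- "KEPT"
    fraction[det[fr == "NONE"]] <- "NONE"
  }
  status <- factor(status, levels = STATUS_LEVELS)

  mir <- which(status == "KEPT" & fraction == "MIR_PIRNA_18_40")
  inserts <- data.frame(
    sequence = substr(seqs[mir], 1L, ins_len[mir]),
    quality = substr(quals[mir], 1L, ins_len[mir]),
    stringsAsFactors = FALSE)

  attrition <- list(
    total = n,
    status = as.list(table(status)),
    fraction = as.list(table(fraction[status == "KEPT"])))
  out <- list(inserts = inserts, attrition = attrition, params = params,
              order = order)
  if (keep_per_read) {
    out$per_read <- data.frame(read_id = reads$read_id, status = status,
                               fraction = fraction,
                               insert_length = ifelse(status == "KEPT", ins_len, NA),
                               stringsAsFactors = FALSE)
  }
  structure(out, class = "trim_result")
}

#' @export
print.trim_result <- function(x, ...) {
  cat("Read-cleanup result:", x$attrition$total, "reads\n")
  st <- unlist(x$attrition$status)
  for (s in names(st)) cat(sprintf("  %-18s %d\n", s, st[s]))
  fr <- unlist(x$attrition$fraction)
  for (s in names(fr)) cat(sprintf("  kept %-13s %d\n", s, fr[s]))
  invisible(x)
}
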