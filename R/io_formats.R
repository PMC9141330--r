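# IO for the standard formats the pipeline touches: FASTQ (Phred+33,
# optionally gzipped), mature-miR FASTA (miRBase dialect, RNA alphabet),
# TSV manifests and count matrices, JSON summaries.

.is_gz <- function(path) grepl("\\.gz$", path, ignore.case = TRUE)

.read_lines <- function(path) {
  con <- if (.is_gz(path)) gzfile(path, open = "rt") else file(path, open = "rt")
  on.exit(close(con))
  readLines(con)
}

.write_lines <- function(lines, path) {
  con <- if (.is_gz(path)) gzfile(path, open = "wt") else file(path, open = "wt")
  on.exit(close(con))
  writeLines(lines, con)
}

#' Decode and encode Phred+33 quality strings
#'
#' @param quality character vector of Phred+33 encoded quality strings.
#' @param offset integer ASCII offset, 33 by default (no Phred+64
#'   autodetection; pass 64 explicitly for legacy data).
#' @return `phred_decode` returns a list of integer vectors; `phred_encode`
#'   the inverse character vector.
#' @export
phred_decode <- function(quality, offset = 33L) {
  lapply(quality, function(q) {
    if (!nzchar(q)) integer(0) else utf8ToInt(q) - as.integer(offset)
  })
}

#' @rdname phred_decode
#' @param scores list of integer Phred score vectors.
#' @export
phred_encode <- function(scores, offset = 33L) {
  vapply(scores, function(s) {
    if (!length(s)) "" else intToUtf8(as.integer(s) + as.integer(offset))
  }, character(1))
}

#' Read a single-end small RNA FASTQ file
#'
#' Strict 4-line-record FASTQ reader. Phred+33 is assumed (HiSeq-era
#' chemistry); gzip input is sniffed from the `.gz` extension. Malformed
#' records are hard errors naming the offending record index.
#'
#' @param path FASTQ file, optionally gzip-compressed.
#' @param offset quality ASCII offset (default 33).
#' @param max_phred upper bound for decoded Phred scores (default 60).
#' @return data.frame with columns `read_id`, `sequence`, `quality`
#'   (Phred+33 string), of class `srna_reads`. Decoding is lossless:
#'   `write_fastq()` then `read_fastq()` is the identity.
#' @export
read_fastq <- function(path, offset = 33L, max_phred = 60L) {
  if (!file.exists(path)) .stopf("FASTQ file not found: %s", path)
  lines <- .read_lines(path)
  if (length(lines) == 0L) {
    return(new_srna_reads(character(0), character(0), character(0)))
  }
  if (length(lines) %% 4L != 0L) {
    .stopf("malformed FASTQ %s: %d lines is not a multiple of 4",
           path, length(lines))
  }
  idx <- seq(1L, length(lines), by = 4L)
  hdr <- lines[idx]
  seqs <- toupper(lines[idx + 1L])
  plus <- lines[idx + 2L]
  qual <- lines[idx + 3L]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad)) .stopf("FASTQ record %d: header does not start with '@'", bad[1])
  bad <- which(!startsWith(plus, "+"))
  if (length(bad)) .stopf("FASTQ record %d: separator line does not start with '+'", bad[1])
  bad <- which(nchar(seqs) != nchar(qual))
  if (length(bad)) {
    .stopf("FASTQ record %d: sequence length %d != quality length %d",
           bad[1], nchar(seqs[bad[1]]), nchar(qual[bad[1]]))
  }
  bad <- which(grepl("[^ACGTN]", seqs))
  if (length(bad)) .stopf("FASTQ record %d: sequence has characters outside {A,C,G,T,N}", bad[1])
  qcat <- paste(qual, collapse = "")
  if (nzchar(qcat)) {
    sc <- utf8ToInt(qcat) - as.integer(offset)
    if (min(sc) < 0L || max(sc) > max_phred) {
      bad <- which(vapply(qual, function(q) {
        nzchar(q) && {
          s <- utf8ToInt(q) - as.integer(offset)
          min(s) < 0L || max(s) > max_phred
        }
      }, logical(1)))[1]
      .stopf("FASTQ record %d: decoded Phred scores outside [0, %d]; wrong offset?",
             bad, max_phred)
    }
  }
  new_srna_reads(sub("^@", "", hdr), seqs, qual)
}

new_srna_reads <- function(read_id, sequence, quality) {
  structure(
    data.frame(read_id = read_id, sequence = sequence, quality = quality,
               stringsAsFactors = FALSE),
    class = c("srna_reads", "data.frame"))
}

#' @rdname read_fastq
#' @param reads data.frame with `read_id`, `sequence`, `quality` columns.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("read_id", "sequence", "quality") %in% names(reads)))
  if (any(nchar(reads$sequence) != nchar(reads$quality))) {
    .stopf("write_fastq: sequence/quality length mismatch")
  }
  n <- nrow(reads)
  lines <- character(4L * n)
  if (n) {
    lines[seq(1L, 4L * n, by = 4L)] <- paste0("@", reads$read_id)
    lines[seq(2L, 4L * n, by = 4L)] <- reads$sequence
    lines[seq(3L, 4L * n, by = 4L)] <- "+"
    lines[seq(4L, 4L * n, by = 4L)] <- reads$quality
  }
  .write_lines(lines, path)
  invisible(path)
}

#' Read a mature miR reference FASTA (miRBase dialect)
#'
#' Sequences are uppercased with U converted to T. The miR name is the
#' first whitespace-delimited header token; the remainder is kept as the
#' description. Duplicate names are rejected; duplicate sequences are
#' allowed (they are merged later by [collapse_reference()]).
#'
#' @param path FASTA file.
#' @param length_range allowed mature length range (default c(15, 30)).
#' @return data.frame of class `mature_mirs` with columns `name`,
#'   `description`, `gene_id` (NA unless encoded as `gene_id=<id>` in the
#'   description), `sequence`, `arm` ("5p"/"3p"/NA).
#' @export
read_mature_fasta <- function(path, length_range = c(15L, 30L)) {
  if (!file.exists(path)) .stopf("FASTA file not found: %s", path)
  set <- Biostrings::readBStringSet(path)
  hdr <- names(set)
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs))) {
    .stopf("FASTA entry '%s' has an empty sequence",
           hdr[which(!nzchar(seqs))[1]])
  }
  bad <- which(grepl("[^ACGUTN]", seqs))
  if (length(bad)) {
    .stopf("FASTA entry '%s': characters outside {A,C,G,U,T,N}", hdr[bad[1]])
  }
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  name <- sub("\\s.*$", "", hdr)
  desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  if (anyDuplicated(name)) {
    .stopf("duplicate miR name in FASTA: %s", name[duplicated(name)][1])
  }
  len <- nchar(seqs)
  if (any(len < length_range[1] | len > length_range[2])) {
    i <- which(len < length_range[1] | len > length_range[2])[1]
    .stopf("mature sequence '%s' has length %d outside [%d, %d]",
           name[i], len[i], length_range[1], length_range[2])
  }
  gene_id <- ifelse(grepl("gene_id=", desc),
                    sub(".*gene_id=(\\S+).*", "\\1", desc), NA_character_)
  arm <- ifelse(grepl("[-_]5p$", name), "5p",
                ifelse(grepl("[-_]3p$", name), "3p", NA_character_))
  structure(
    data.frame(name = name, description = desc, gene_id = gene_id,
               sequence = seqs, arm = arm, stringsAsFactors = FALSE),
    class = c("mature_mirs", "data.frame"))
}

#' @rdname read_mature_fasta
#' @param mirs data.frame with `name` and `sequence` columns (DNA); an
#'   optional `gene_id` column is encoded into the description.
#' @param rna write the sequence in the RNA alphabet (T as U), matching the
#'   miRBase mature file convention. Default TRUE.
#' @export
write_mature_fasta <- function(mirs, path, rna = TRUE) {
  seqs <- toupper(mirs$sequence)
  if (rna) seqs <- gsub("T", "U", seqs, fixed = TRUE)
  hdr <- mirs$name
  if (!is.null(mirs$gene_id)) {
    has <- !is.na(mirs$gene_id)
    hdr[has] <- paste0(hdr[has], " gene_id=", mirs$gene_id[has])
  }
  .write_lines(as.vector(rbind(paste0(">", hdr), seqs)), path)
  invisible(path)
}

#' Read and write the sample manifest (TSV)
#'
#' The manifest maps `sample_id` to a FASTQ path and a group label
#' (e.g. Mk, MkMP, PLP, PLT). Sample ids must be unique.
#'
#' @param path TSV file with header `sample_id`, `fastq`, `group`.
#' @return data.frame with those columns.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) .stopf("manifest not found: %s", path)
  m <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                  colClasses = "character")
  need <- c("sample_id", "fastq", "group")
  if (!all(need %in% names(m))) {
    .stopf("manifest must have columns: %s", paste(need, collapse = ", "))
  }
  if (anyDuplicated(m$sample_id)) {
    .stopf("duplicate sample_id in manifest: %s",
           m$sample_id[duplicated(m$sample_id)][1])
  }
  if (any(!nzchar(m$group))) .stopf("manifest has an empty group label")
  m[, need]
}

#' @rdname read_manifest
#' @param manifest data.frame with `sample_id`, `fastq`, `group`.
#' @export
write_manifest <- function(manifest, path) {
  write.table(manifest, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write a feature x sample count matrix (TSV)
#'
#' Feature ids are in the first column (`feature`); remaining columns are
#' samples. Counts must be non-negative integers; `write_counts()` then
#' `read_counts()` round-trips exactly, preserving column order.
#'
#' @param path TSV file.
#' @return integer matrix with feature rownames and sample colnames.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) .stopf("counts file not found: %s", path)
  d <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                  colClasses = "character", check.names = FALSE)
  if (names(d)[1] != "feature") .stopf("first column of a counts TSV must be 'feature'")
  vals <- as.matrix(d[, -1, drop = FALSE])
  bad <- which(!grepl("^[0-9]+$", vals))
  if (length(bad)) {
    .stopf("counts TSV %s: value '%s' is not a non-negative integer",
           path, vals[bad[1]])
  }
  m <- matrix(as.integer(vals), nrow = nrow(vals),
              dimnames = list(d$feature, colnames(vals)))
  m
}

#' @rdname read_counts
#' @param counts integer matrix (features x samples), with dimnames.
#' @export
write_counts <- function(counts, path) {
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    .stopf("count matrix must have feature rownames and sample colnames")
  }
  storage <- counts
  if (any(storage < 0) || any(storage != round(storage))) {
    .stopf("count matrix has negative or non-integer values")
  }
  d <- data.frame(feature = rownames(counts), counts, check.names = FALSE,
                  stringsAsFactors = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Atomic JSON write (write-then-rename): partial failures never leave a
# truncated file behind.
write_json_atomic <- function(x, path, ...) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, pretty = TRUE, ...)
  file.rename(tmp, path)
  invisible(path)
}
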