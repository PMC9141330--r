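# End-to-end orchestration: trim -> quantify -> normalize -> differential
# enrichment -> profile reports, from a single config.

.config_defaults <- list(
  adapter = NULL, min_overlap = 8L, mismatch_rate = 0.1,
  qual_threshold = 30, insert_min = 18L, insert_max = 40L, long_max = 150L,
  order = "adapter-first",
  match_policy = "exact", tol = 2L,
  group_a = NULL, group_b = NULL,
  fdr_threshold = 0.01, fc_up = 2, fc_down = 0.5, use_raw_p = FALSE,
  detect_cpm = 1, abundant_cpm = 1000, top_n = 10L)

#' Pipeline configuration
#'
#' @param manifest path to the sample manifest TSV (see [read_manifest()]).
#' @param reference path to the mature miR FASTA.
#' @param ... overrides of the trimming, matching, DE and report defaults:
#'   `adapter` (required), `min_overlap`, `mismatch_rate`,
#'   `qual_threshold`, `insert_min`, `insert_max`, `long_max`, `order`,
#'   `match_policy` ("exact"/"tol3p"), `tol`, `group_a`, `group_b`,
#'   `fdr_threshold`, `fc_up`, `fc_down`, `use_raw_p`, `detect_cpm`,
#'   `abundant_cpm`, `top_n`.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(manifest, reference, ...) {
  over <- list(...)
  unknown <- setdiff(names(over), names(.config_defaults))
  if (length(unknown)) .stopf("unknown config key: %s", unknown[1])
  cfg <- utils::modifyList(.config_defaults, over)
  cfg$manifest <- manifest
  cfg$reference <- reference
  if (is.null(cfg$adapter)) .stopf("config must provide the 3' adapter sequence")
  structure(cfg, class = "pipeline_config")
}

#' Read a key:value pipeline config file
#'
#' Minimal YAML-style flat key/value file: one `key: value` pair per line;
#' blank lines and `#` comments ignored. Values that parse as numbers are
#' converted.
#'
#' @param path config file path.
#' @return a `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) .stopf("config file not found: %s", path)
  lines <- .read_lines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z_0-9]+)\\s*:\\s*(.*)$", lines))
  bad <- which(vapply(kv, length, integer(1)) != 3L)
  if (length(bad)) .stopf("config line not 'key: value': %s", lines[bad[1]])
  keys <- vapply(kv, `[`, character(1), 2L)
  vals <- lapply(kv, function(m) {
    v <- trimws(m[3])
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num
    else if (v %in% c("TRUE", "true")) TRUE
    else if (v %in% c("FALSE", "false")) FALSE
    else v
  })
  cfg <- setNames(vals, keys)
  if (is.null(cfg$manifest) || is.null(cfg$reference)) {
    .stopf("config must provide 'manifest' and 'reference' paths")
  }
  do.call(pipeline_config,
          c(list(manifest = cfg$manifest, reference = cfg$reference),
            cfg[setdiff(names(cfg), c("manifest", "reference"))]))
}

.config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(cfg[order(names(cfg))]), tmp)
  unname(tools::md5sum(tmp))
}

# write-then-rename so partial failures never leave truncated outputs
.atomic <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  writer(tmp)
  file.rename(tmp, path)
  path
}

#' Run the full profiling pipeline
#'
#' Reads the manifest and reference, trims and quantifies every library,
#' builds count and CPM matrices, computes per-group profiles and Venn
#' overlaps of the detected sets, runs the two-group enrichment test when
#' `group_a`/`group_b` are configured, and writes all outputs to
#' `out_dir`. Fully deterministic given config and inputs; every output
#' set is stamped with the config hash in `run_summary.json`. Files are
#' written via write-then-rename.
#'
#' @param config a [pipeline_config()] object or path to a config file.
#' @param out_dir output directory (created if needed).
#' @return (invisibly) a list with the in-memory results: `counts`
#'   (mir_counts), `cpm`, `attrition`, `profiles`, `venn`, `enrichment`,
#'   `summary`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  if (!file.exists(config$reference)) {
    .stopf("reference FASTA not found: %s", config$reference)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  manifest <- read_manifest(config$manifest)
  ref <- collapse_reference(read_mature_fasta(config$reference))
  params <- trim_params(config$adapter, config$min_overlap,
                        config$mismatch_rate, config$qual_threshold,
                        config$insert_min, config$insert_max, config$long_max)
  policy <- match_policy(config$match_policy, config$tol)

  attrition <- list()
  sample_counts <- list()
  for (i in seq_len(nrow(manifest))) {
    sid <- manifest$sample_id[i]
    reads <- read_fastq(manifest$fastq[i])
    trim <- process_library(reads, params, order = config$order)
    attrition[[sid]] <- trim$attrition
    sample_counts[[sid]] <- quantify_library(trim$inserts$sequence, ref, policy)
  }

  x <- build_count_matrix(sample_counts, manifest)
  cpm_mat <- cpm(x)
  groups <- x$samples$group

  profiles <- lapply(unique(groups), function(g) {
    profile_summary(cpm_mat, groups, g, config$detect_cpm,
                    config$abundant_cpm, config$top_n)
  })
  names(profiles) <- unique(groups)

  venn <- NULL
  if (length(unique(groups)) >= 2L && length(unique(groups)) <= 4L) {
    venn <- venn_counts(lapply(profiles, `[[`, "detected"))
  }

  enrichment <- NULL
  if (!is.null(config$group_a) && !is.null(config$group_b)) {
    enrichment <- test_enrichment(
      x, config$group_a, config$group_b,
      cfg = de_config(config$fdr_threshold, config$fc_up, config$fc_down,
                      use_raw_p = isTRUE(config$use_raw_p)))
  }

  hash <- .config_hash(unclass(config))
  .atomic(file.path(out_dir, "counts.tsv"),
          function(p) write_counts(x$counts, p))
  .atomic(file.path(out_dir, "cpm.tsv"), function(p) {
    d <- data.frame(feature = rownames(cpm_mat), cpm_mat, check.names = FALSE)
    write.table(d, p, sep = "\t", quote = FALSE, row.names = FALSE)
  })
  write_json_atomic(list(config_hash = hash, policy = unclass(policy),
                         unassigned = as.list(x$unassigned),
                         attrition = attrition),
                    file.path(out_dir, "attrition.json"))
  write_json_atomic(
    list(config_hash = hash,
         profiles = lapply(profiles, function(p) list(
           group = p$group,
           n_detected = length(p$detected),
           n_abundant = length(p$abundant),
           detected = p$detected, abundant = p$abundant,
           composition = p$composition,
           other_percent = attr(p$composition, "other_percent")))),
    file.path(out_dir, "profiles.json"))
  if (!is.null(venn)) {
    write_json_atomic(list(config_hash = hash,
                           regions = as.list(venn$regions),
                           pairwise = venn$pairwise,
                           union_size = venn$union_size),
                      file.path(out_dir, "venn.json"))
  }
  if (!is.null(enrichment)) {
    .atomic(file.path(out_dir,
                      sprintf("de_%s_vs_%s.tsv", config$group_b, config$group_a)),
            function(p) write.table(enrichment, p, sep = "\t", quote = FALSE,
                                    row.names = FALSE))
  }
  summary <- list(
    config_hash = hash,
    n_samples = nrow(manifest),
    n_features = nrow(ref),
    groups = as.list(table(groups)),
    phi = if (!is.null(enrichment)) attr(enrichment, "phi") else NULL,
    de_classes = if (!is.null(enrichment)) as.list(table(enrichment$class)) else NULL)
  write_json_atomic(summary, file.path(out_dir, "run_summary.json"))

  invisible(list(counts = x, cpm = cpm_mat, attrition = attrition,
                 profiles = profiles, venn = venn, enrichment = enrichment,
                 summary = summary))
}
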