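# Reference collapse, clustering, assignment, count/CPM matrices

test_that("collapse_reference merges identical matures with the //-name convention", {
  S <- "TGTGCAAATCCATGCAAAACTGA"
  mirs <- make_mirs(c("mir-19b-1-3p", "mir-19b-2-3p"), c(S, S))
  ref <- collapse_reference(mirs)
  expect_equal(nrow(ref), 1L)
  expect_equal(ref$feature, "mir-19b-1//mir-19b-2_3p")
  expect_equal(ref$n_members, 2L)

  # all sequences distinct: identity mapping
  mirs2 <- make_mirs(paste0("mir-", 1:4, "-5p"), rand_dna(4, 22))
  ref2 <- collapse_reference(mirs2)
  expect_equal(nrow(ref2), 4L)
  expect_setequal(ref2$feature, mirs2$name)

  # three loci sharing one sequence become one 3-member feature
  mirs3 <- make_mirs(c("mir-x-1-3p", "mir-x-2-3p", "mir-x-3-3p"),
                     rep("ACGTACGTACGTACGTACGTAC", 3))
  ref3 <- collapse_reference(mirs3)
  expect_equal(ref3$n_members, 3L)
  expect_equal(ref3$feature, "mir-x-1//mir-x-2//mir-x-3_3p")

  # gene ids of members are joined with "/" (multi-locus display style)
  mirs4 <- make_mirs(c("mir-d-1-5p", "mir-d-2-5p"),
                     rep("TTGTACGTACGTACGTACGTAC", 2),
                     gene_id = c("406995", "406996"))
  expect_equal(collapse_reference(mirs4)$gene_id, "406995/406996")

  # mixed arms: no arm factoring, plain join
  mirs5 <- make_mirs(c("mir-a-5p", "mir-b-3p"), rep("CCGTACGTACGTACGTACGTAC", 2))
  expect_equal(collapse_reference(mirs5)$feature, "mir-a-5p//mir-b-3p")
})

test_that("collapse_reference matches the O(n^2) grouping oracle on random input", {
  set.seed(301)
  for (k in 1:20) {
    n <- sample(5:40, 1)
    pool <- rand_dna(max(2, n %/% 2), 20)
    seqs <- sample(pool, n, replace = TRUE)
    mirs <- make_mirs(sprintf("mir-%03d-5p", seq_len(n)), seqs)
    ref <- collapse_reference(mirs)
    oracle <- oracle_group_by_sequence(seqs)
    expect_equal(nrow(ref), length(oracle))
    expect_equal(sort(ref$n_members),
                 sort(vapply(oracle, length, integer(1))))
    expect_equal(sum(ref$n_members), n)
  }
})

test_that("cluster_reads is an exact multiset tally", {
  cl <- cluster_reads(c("ACGT", "ACGT", "TTTT"))
  expect_equal(cl$count[cl$sequence == "ACGT"], 2L)
  expect_equal(cl$count[cl$sequence == "TTTT"], 1L)
  expect_equal(nrow(cluster_reads(character(0))), 0L)

  set.seed(302)
  ins <- sample(rand_dna(50, 22), 1e4, replace = TRUE)
  cl2 <- cluster_reads(ins)
  r <- rle(sort(ins))                      # sort-and-scan oracle
  expect_equal(cl2$sequence, r$values)
  expect_equal(cl2$count, r$lengths)
  expect_equal(sum(cl2$count), length(ins))
})

test_that("assignment policies: exact and 3' tolerance with deterministic tie-break", {
  seqs <- c("AAGCTGCCAGTTGAAGAACTGT", "TGTCAGTTTGTCAAATACCCCA")
  ref <- collapse_reference(make_mirs(c("hsa-miR-22-3p", "hsa-miR-337-5p"), seqs))
  exact <- match_policy("exact")
  tol <- match_policy("tol3p", 2)

  expect_equal(assign_clusters(seqs[1], ref, exact), "hsa-miR-22-3p")
  short <- substr(seqs[1], 1, nchar(seqs[1]) - 2)      # read misses 2 3' nt
  expect_true(is.na(assign_clusters(short, ref, exact)))
  expect_equal(assign_clusters(short, ref, tol), "hsa-miR-22-3p")
  long <- paste0(seqs[1], "TG")                         # 2 extra 3' nt
  expect_equal(assign_clusters(long, ref, tol), "hsa-miR-22-3p")
  expect_true(is.na(assign_clusters(paste0(seqs[1], "TGA"), ref, tol)))

  # tie-break: prefer the longest matched mature, then smallest name
  base <- "ACGTACGTACGTACGTACGT"
  ref2 <- collapse_reference(make_mirs(c("mir-bb", "mir-aa"),
                                       c(paste0(base, "TG"), paste0(base, "T"))))
  expect_equal(assign_clusters(base, ref2, tol), "mir-bb")   # longer mature wins
  ref3 <- collapse_reference(make_mirs(c("mir-bb", "mir-aa"),
                                       c(paste0(base, "T"), paste0(base, "G"))))
  expect_equal(assign_clusters(base, ref3, tol), "mir-aa")   # lexicographic
})

test_that("tolerance assignment agrees with the brute-force (feature, trim) oracle", {
  set.seed(303)
  oracle_assign <- function(s, ref, t) {
    cand <- data.frame(feature = character(0), len = integer(0))
    for (j in seq_len(nrow(ref))) {
      r <- ref$sequence[j]
      dl <- nchar(r) - nchar(s)
      hit <- (dl == 0 && s == r) ||
        (dl > 0 && dl <= t && startsWith(r, s)) ||
        (dl < 0 && -dl <= t && startsWith(s, r))
      if (hit) cand <- rbind(cand, data.frame(feature = ref$feature[j],
                                              len = nchar(r),
                                              exact = dl == 0))
    }
    if (!nrow(cand)) return(NA_character_)
    cand <- cand[order(-cand$exact, -cand$len, cand$feature), ]
    cand$feature[1]
  }
  ref <- collapse_reference(make_mirs(sprintf("mir-%02d-3p", 1:30),
                                      rand_dna(30, sample(18:25, 30, replace = TRUE))))
  pol <- match_policy("tol3p", 2)
  # reads derived from the reference with 3' jitter plus random background
  reads <- c(
    vapply(sample(ref$sequence, 200, replace = TRUE), function(r) {
      d <- sample(-2:2, 1)
      if (d >= 0) substr(r, 1, nchar(r) - d) else paste0(r, rand_dna(1, -d))
    }, character(1)),
    rand_dna(50, sample(18:25, 50, replace = TRUE)))
  got <- assign_clusters(reads, ref, pol)
  want <- vapply(reads, oracle_assign, character(1), ref = ref, t = 2L)
  expect_equal(unname(got), unname(want))
})

test_that("assignment is invariant to reference entry order", {
  set.seed(304)
  mirs <- make_mirs(sprintf("mir-%02d-5p", 1:20), rand_dna(20, 22))
  reads <- c(sample(mirs$sequence, 100, replace = TRUE), rand_dna(20, 22))
  ref1 <- collapse_reference(mirs)
  ref2 <- collapse_reference(mirs[sample(nrow(mirs)), ])
  for (pol in list(match_policy("exact"), match_policy("tol3p", 2))) {
    expect_identical(assign_clusters(reads, ref1, pol),
                     assign_clusters(reads, ref2, pol))
  }
})

test_that("build_count_matrix keeps zero rows and validates the manifest", {
  ref <- collapse_reference(make_mirs(c("mirA-5p", "mirB-3p"),
                                      c("ACGTACGTACGTACGTAC", "TGCATGCATGCATGCATG")))
  q <- quantify_library(rep("ACGTACGTACGTACGTAC", 5), ref)
  expect_equal(unname(q$counts["mirA-5p"]), 5L)
  expect_equal(unname(q$counts["mirB-3p"]), 0L)       # all-zero row retained
  expect_equal(q$unassigned, 0L)

  man <- data.frame(sample_id = "s1", fastq = "x", group = "Mk",
                    stringsAsFactors = FALSE)
  x <- build_count_matrix(list(s1 = q), man)
  expect_equal(dim(x$counts), c(2L, 1L))
  expect_equal(x$counts["mirA-5p", "s1"], 5L)
  expect_error(build_count_matrix(list(s2 = q), man), "not present in the manifest")

  # unassigned reads tallied separately, never a row
  q2 <- quantify_library(c("ACGTACGTACGTACGTAC", "GGGGGGGGGGGGGGGGGG"), ref)
  expect_equal(q2$unassigned, 1L)
  expect_equal(nrow(build_count_matrix(list(s1 = q2), man)$counts), 2L)
})

test_that("cpm normalizes columns to one million over assigned reads", {
  m <- matrix(c(50L, 30L, 20L), 3, dimnames = list(c("A", "B", "C"), "s1"))
  expect_equal(unname(cpm(m)[, 1]), c(5e5, 3e5, 2e5))

  set.seed(305)
  r <- matrix(rpois(60, 40), 6,
              dimnames = list(paste0("f", 1:6), paste0("s", 1:10)))
  expect_true(all(abs(colSums(cpm(r)) - 1e6) <= 1e-6 * 1e6))

  z <- cbind(r[, 1, drop = FALSE], s0 = 0L)
  expect_warning(cz <- cpm(z), "zero assigned reads")
  expect_equal(unname(cz[, "s0"]), rep(0, 6))

  # Table-1 semantics: CPM / 1e4 is percent of total miR content
  expect_equal(round_half_up(164087 / 1e4, 1), 16.4)

  g <- group_mean_cpm(cpm(r), rep(c("A", "B"), each = 5))
  expect_equal(g[, "A"], rowMeans(cpm(r)[, 1:5]))
})
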