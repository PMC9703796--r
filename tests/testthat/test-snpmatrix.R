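toy_records <- function() {
  # 2 samples x 4 sites exercising every filter rule
  a1 <- matrix(c("A", "A",  "A", "G",  "A", "G",  "C", "C"), nrow = 2)
  a2 <- matrix(c("A", "A",  "A", "G",  "G", "G",  "C", "C"), nrow = 2)
  depth <- matrix(c(3L, 10L,  10L, 4L,  10L, 10L,  8L, 8L), nrow = 2)
  site_records(chrom = rep("c1", 4), pos = 1:4, ref = c("A", "A", "A", "C"),
               qual = c(50, 19, 50, 20), a1 = a1, a2 = a2, depth = depth,
               samples = c("s1", "s2"))
}

test_that("site filters mask by depth, quality and heterozygosity with inclusive boundaries", {
  calls <- filter_sites(toy_records())
  # site 1: s1 depth 3 -> N; s2 passes
  expect_equal(unname(calls[, 1]), c("N", "A"))
  # site 2: qual 19 < 20 masks both despite depths 10 and 4
  expect_equal(unname(calls[, 2]), c("N", "N"))
  # site 3: s1 heterozygous A/G -> N; s2 homozygous G passes
  expect_equal(unname(calls[, 3]), c("N", "G"))
  # site 4: boundary depth 4 was site 2; here qual 20 and depth 8 pass
  expect_equal(unname(calls[, 4]), c("C", "C"))
  reason <- attr(calls, "mask_reason")
  expect_equal(unname(reason[, 1]), c("depth", "ok"))
  expect_equal(unname(reason[, 2]), c("quality", "quality"))
  expect_equal(unname(reason[, 3]), c("het", "ok"))
  # depth-4 boundary passes explicitly
  rec <- toy_records()
  expect_equal(unname(filter_sites(rec)[2, 2]), "N")   # masked by quality only
  rec$qual[2] <- 20
  expect_equal(unname(filter_sites(rec)[2, 2]), "G")   # depth 4, qual 20 pass
})

test_that("drop_site heterozygosity policy masks whole columns", {
  calls <- filter_sites(toy_records(), het_policy = "drop_site")
  expect_equal(unname(calls[, 3]), c("N", "N"))
})

test_that("negative depth is rejected at construction", {
  expect_error(site_records(chrom = "c1", pos = 1, ref = "A", qual = 30,
                            a1 = matrix("A"), a2 = matrix("A"),
                            depth = matrix(-1L), samples = "s1"),
               "negative")
})

test_that("sites_to_alignment maps records to columns and demands sorted input", {
  m <- sites_to_alignment(toy_records())
  expect_equal(dim(m), c(2L, 4L))
  expect_equal(colnames(m), paste0("c1:", 1:4))
  rec <- toy_records()
  rec$pos <- c(2L, 1L, 3L, 4L)
  expect_error(sites_to_alignment(rec), "sorted")
  # planted pass/fail pattern reproduces exactly
  set.seed(1)
  truth <- matrix(sample(c("A", "C", "G", "T"), 200, replace = TRUE), nrow = 4,
                  dimnames = list(paste0("s", 1:4), NULL))
  sd <- generate_site_records(truth, fixture_config(seed = 3))
  m2 <- sites_to_alignment(sd$records)
  expect_identical(unname(m2 == "N"), unname(sd$ledger != "ok"))
  expect_identical(unname(m2[sd$ledger == "ok"]),
                   unname(truth[sd$ledger == "ok"]))
})

test_that("consensus calls plurality bases, IUPAC ties and N for no data", {
  expect_equal(consensus_sequence(list(c(A = 5, G = 2))), "A")
  expect_equal(consensus_sequence(list(c(A = 3, G = 3))), "R")
  expect_equal(consensus_sequence(list(c(C = 2, T = 2))), "Y")
  expect_equal(consensus_sequence(list(stats::setNames(numeric(0), character(0)))), "N")
  expect_equal(consensus_sequence(list(c(A = 1), c(A = 2, C = 2, G = 2, T = 2),
                                       c(T = 9))), "ANT")
})

test_that("column missing fractions count N, gap and ?", {
  m <- rbind(s1 = c("A", "N", "-"), s2 = c("N", "A", "A"),
             s3 = c("N", "A", "A"), s4 = c("A", "A", "A"))
  expect_equal(column_missing_fraction(m, 1), 0.5)
  expect_equal(column_missing_fraction(m), c(0.5, 0.25, 0.25))
  expect_error(column_missing_fraction(m, 9), "out of range")
})

test_that("missing threshold is inclusive and monotone", {
  m <- rbind(s1 = c("A", "N", "A"), s2 = c("N", "N", "A"),
             s3 = c("A", "A", "A"), s4 = c("A", "A", "A"))
  # col1 has 1/4, col2 has 2/4 missing
  expect_equal(ncol(apply_missing_threshold(m, 0.5)), 3L)   # inclusive at 0.5
  expect_equal(ncol(apply_missing_threshold(m, 0.4)), 2L)
  expect_equal(ncol(apply_missing_threshold(m, 0)), 1L)
  # monotonicity on a random matrix
  set.seed(8)
  big <- matrix(sample(c("A", "C", "N"), 600, replace = TRUE,
                       prob = c(0.4, 0.3, 0.3)), nrow = 6)
  widths <- vapply(c(0, 0.2, 0.4, 0.5, 0.6, 1),
                   function(x) ncol(apply_missing_threshold(big, x)), 0L)
  expect_true(all(diff(widths) >= 0))
})

test_that("invariant-site removal needs two real states and is idempotent", {
  m <- rbind(s1 = c("A", "A", "A", "A"), s2 = c("A", "A", "N", "C"),
             s3 = c("A", "G", "N", "-"))
  out <- remove_invariant_sites(m)
  expect_equal(ncol(out), 2L)                     # cols 2 (A/G) and 4 (A/C)
  expect_equal(attr(out, "n_removed"), 2L)        # col 1 invariant, col 3 single state
  out2 <- remove_invariant_sites(out)
  expect_equal(dim(out2), dim(out))
  expect_equal(as.vector(out2), as.vector(out))
})

test_that("concatenation pads absent taxa and partition split round-trips", {
  m1 <- matrix("A", 2, 100, dimnames = list(c("x", "y"), NULL))
  m2 <- matrix("C", 2, 250, dimnames = list(c("x", "z"), NULL))
  sm <- concatenate_alignments(list(g1 = m1, g2 = m2))
  expect_equal(dim(sm), c(3L, 350L))
  parts <- attr(sm, "partitions")
  expect_equal(parts$start, c(1L, 101L))
  expect_equal(parts$end, c(100L, 350L))
  expect_true(all(sm["z", 1:100] == "N"))
  expect_true(all(sm["y", 101:350] == "N"))
  back <- split_by_partition(sm)
  expect_identical(back$g1[c("x", "y"), ], m1)
  expect_identical(back$g2[c("x", "z"), ], m2)
  # single matrix concatenation is the identity on content
  one <- concatenate_alignments(list(solo = m1))
  expect_identical(unname(one[, ]), unname(m1))
  dup <- matrix("A", 2, 3, dimnames = list(c("x", "x"), NULL))
  expect_error(concatenate_alignments(list(bad = dup)), "duplicate")
})

test_that("mask_uncovered unions coverage and complements correctly", {
  mk <- mask_uncovered(200, list(data.frame(start = 0, end = 100)))
  expect_equal(mk$kept, data.frame(start = 0, end = 100))
  expect_equal(mk$masked, data.frame(start = 100, end = 200))
  # five samples covering disjoint fifths -> everything kept
  fifths <- lapply(0:4, function(i)
    data.frame(start = i * 40, end = (i + 1) * 40))
  mk2 <- mask_uncovered(200, fifths)
  expect_equal(mk2$kept, data.frame(start = 0, end = 200))
  expect_equal(nrow(mk2$masked), 0L)
  expect_error(mask_uncovered(50, list(data.frame(start = 10, end = 60))),
               "bounds")
  # random fixture vs positionwise membership scan
  set.seed(21)
  maps <- lapply(1:4, function(i) {
    s <- sort(sample(0:90, 5))
    data.frame(start = s, end = s + sample(1:10, 5, replace = TRUE))
  })
  mk3 <- mask_uncovered(100, maps)
  covered <- rep(FALSE, 100)
  for (m in maps) for (r in seq_len(nrow(m)))
    covered[(m$start[r] + 1):m$end[r]] <- TRUE
  got <- rep(FALSE, 100)
  for (r in seq_len(nrow(mk3$kept)))
    got[(mk3$kept$start[r] + 1):mk3$kept$end[r]] <- TRUE
  expect_identical(got, covered)
})

test_that("gene length filter is inclusive at the cutoff", {
  alns <- list(a = matrix("A", 2, 999), b = matrix("A", 2, 1000),
               c = matrix("A", 2, 3000))
  expect_equal(names(filter_genes_by_length(alns, 1000)), c("b", "c"))
  expect_equal(names(filter_genes_by_length(alns, 3000)), "c")
  expect_length(filter_genes_by_length(list(), 1000), 0L)
})

test_that("FASTA and VCF round-trip through files", {
  set.seed(2)
  truth <- matrix(sample(c("A", "C", "G", "T"), 120, replace = TRUE), nrow = 3,
                  dimnames = list(paste0("s", 1:3), NULL))
  fa <- file.path(tempdir(), "aln.fasta")
  write_fasta_alignment(truth, fa)
  expect_identical(read_fasta_alignment(fa), truth)

  sd <- generate_site_records(truth, fixture_config(seed = 5))
  vcf <- file.path(tempdir(), "sites.vcf")
  write_vcf_records(sd$records, vcf)
  back <- read_vcf_records(vcf)
  expect_identical(unname(back$a1), unname(sd$records$a1))
  expect_identical(unname(back$a2), unname(sd$records$a2))
  expect_identical(unname(back$depth), unname(sd$records$depth))
  expect_equal(back$qual, sd$records$qual, tolerance = 1e-4)
  expect_equal(back$pos, sd$records$pos)
  # filtering the re-read records gives the same alignment
  expect_identical(unname(sites_to_alignment(back)),
                   unname(sites_to_alignment(sd$records)))
})

test_that("partition file writer emits RAxML-style lines", {
  m1 <- matrix("A", 2, 10, dimnames = list(c("x", "y"), NULL))
  sm <- concatenate_alignments(list(gA = m1, gB = m1))
  p <- file.path(tempdir(), "parts.txt")
  write_partition_file(sm, p)
  expect_equal(readLines(p), c("DNA, gA = 1-10", "DNA, gB = 11-20"))
})
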