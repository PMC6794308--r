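mk_reads <- function(n, branch_length = 0.5, read_len = 125, gene = "ITS",
                     clade = "A", sample_id = "s1") {
  data.frame(read_id = sprintf("r%05d", seq_len(n)), gene = gene,
             clade = clade, branch_length = branch_length,
             read_len_nt = read_len, sample_id = sample_id)
}

test_that("read filtering removes long branches and short reads, partitioning the input", {
  ok <- mk_reads(988)
  bad <- mk_reads(12, branch_length = 3.0)
  bad$read_id <- sprintf("x%05d", 1:12)
  res <- filter_reads(rbind(ok, bad))
  expect_equal(res$removed_fraction, 0.012)
  expect_equal(nrow(res$kept), 988)
  expect_setequal(c(res$kept$read_id, res$removed$read_id),
                  c(ok$read_id, bad$read_id))
  # clean input: nothing removed
  expect_equal(filter_reads(ok)$removed_fraction, 0)
  # short reads are removed regardless of branch length
  short <- mk_reads(1, branch_length = 0.1, read_len = 90)
  short$read_id <- "short1"
  expect_equal(nrow(filter_reads(rbind(ok, short))$removed), 1)
})

test_that("paired reads placed as one are counted once", {
  r <- mk_reads(4)
  r$read_id <- c("a", "a", "b", "c")  # mates of read a collapse
  res <- filter_reads(r)
  expect_equal(nrow(res$kept) + nrow(res$removed), 3)
})

test_that("abundance normalization divides by library size, gene length and copy number", {
  reads <- mk_reads(50)
  samples <- data.frame(sample_id = "s1", library_size = 1e6)
  genes <- data.frame(gene = "ITS", ref_length = 500, length_unit = "nt")
  tab <- normalize_abundance(reads, samples, genes)
  expect_equal(tab$abundance, 50 / (1e6 * 500) * 100)
  expect_equal(tab$count, 50L)
  # two-copy clade gets half the abundance of an identical one-copy clade
  reads2 <- rbind(mk_reads(50, clade = "one_copy"),
                  within(mk_reads(50, clade = "two_copy"),
                         read_id <- sprintf("t%05d", 1:50)))
  cn <- data.frame(gene = "ITS", clade = "two_copy", copy_number = 2)
  tab2 <- normalize_abundance(reads2, samples, genes, cn)
  expect_equal(tab2$abundance[tab2$clade == "two_copy"],
               tab2$abundance[tab2$clade == "one_copy"] / 2)
  # multiplying the corrected abundance back by copy number restores it
  expect_equal(tab2$abundance[tab2$clade == "two_copy"] * 2,
               tab2$abundance[tab2$clade == "one_copy"])
  # doubling library size halves abundance
  tab3 <- normalize_abundance(reads, data.frame(sample_id = "s1",
                                                library_size = 2e6), genes)
  expect_equal(tab3$abundance, tab$abundance / 2)
})

test_that("normalization is order-invariant and additive over read batches", {
  samples <- data.frame(sample_id = "s1", library_size = 1e5)
  genes <- data.frame(gene = "ITS", ref_length = 600, length_unit = "nt")
  a <- mk_reads(30, clade = "A")
  b <- within(mk_reads(20, clade = "B"), read_id <- sprintf("b%05d", 1:20))
  tab_fwd <- normalize_abundance(rbind(a, b), samples, genes)
  tab_rev <- normalize_abundance(rbind(b, a)[sample(50), ], samples, genes)
  expect_equal(tab_fwd, tab_rev)
  tab_a <- normalize_abundance(a, samples, genes)
  expect_equal(tab_fwd$abundance[tab_fwd$clade == "A"], tab_a$abundance)
})

test_that("missing sample or gene metadata is a hard error naming the offenders", {
  reads <- mk_reads(5)
  genes <- data.frame(gene = "ITS", ref_length = 500, length_unit = "nt")
  expect_error(normalize_abundance(reads,
                                   data.frame(sample_id = "other",
                                              library_size = 1e6), genes),
               "s1")
  expect_error(normalize_abundance(reads,
                                   data.frame(sample_id = "s1",
                                              library_size = 1e6),
                                   data.frame(gene = "rpoB", ref_length = 1,
                                              length_unit = "aa")),
               "ITS")
})

test_that("virus:host ratio compares length-normalized marker abundances", {
  samples <- data.frame(sample_id = "s1", library_size = 1e6)
  genes <- data.frame(gene = c("polA", "rpoB"), ref_length = c(700, 1200),
                      length_unit = "aa")
  # equal length-normalized abundances -> ratio 1
  reads <- rbind(mk_reads(70, gene = "polA", clade = "virus"),
                 within(mk_reads(120, gene = "rpoB", clade = "host"),
                        read_id <- sprintf("h%05d", 1:120)))
  tab <- normalize_abundance(reads, samples, genes)
  expect_equal(virus_host_ratio(tab, "polA", "rpoB", "s1"), 1)
  # zero host abundance: undefined, not infinite
  tabv <- normalize_abundance(mk_reads(70, gene = "polA", clade = "virus"),
                              samples, genes)
  r <- virus_host_ratio(tabv, "polA", "rpoB", "s1")
  expect_true(is.na(r))
  expect_true(attr(r, "undefined"))
})

test_that("composition fractions sum to one and match simple cases", {
  samples <- data.frame(sample_id = "s1", library_size = 1e6)
  genes <- data.frame(gene = "ITS", ref_length = 500, length_unit = "nt")
  tab1 <- normalize_abundance(mk_reads(10), samples, genes)
  expect_equal(composition_fractions(tab1, "ITS", "s1"), c(A = 1))
  two <- rbind(mk_reads(40, clade = "A"),
               within(mk_reads(40, clade = "B"), read_id <- sprintf("b%d", 1:40)))
  tab2 <- normalize_abundance(two, samples, genes)
  expect_equal(unname(composition_fractions(tab2, "ITS", "s1")), c(0.5, 0.5))
  expect_error(composition_fractions(tab2, "psbD", "s1"), "no abundance")
})

test_that("proportion comparison measures departure from the 1:1 line", {
  samples <- data.frame(sample_id = c("s1", "s2"), library_size = c(1e6, 2e6))
  genes <- data.frame(gene = "ITS", ref_length = 500, length_unit = "nt")
  reads <- rbind(mk_reads(30, clade = "A", sample_id = "s1"),
                 within(mk_reads(10, clade = "B", sample_id = "s1"),
                        read_id <- sprintf("b%d", 1:10)),
                 within(mk_reads(60, clade = "A", sample_id = "s2"),
                        read_id <- sprintf("c%d", 1:60)),
                 within(mk_reads(20, clade = "B", sample_id = "s2"),
                        read_id <- sprintf("d%d", 1:20)))
  tab <- normalize_abundance(reads, samples, genes)
  cmp <- compare_proportions(tab, "ITS", "s1", "s2")
  expect_equal(cmp$max_abs_deviation, 0)
  expect_equal(cmp$rms_deviation, 0)
  # disjoint clade sets: the largest single proportion bounds the deviation
  reads2 <- rbind(mk_reads(30, clade = "A", sample_id = "s1"),
                  within(mk_reads(30, clade = "B", sample_id = "s2"),
                         read_id <- sprintf("e%d", 1:30)))
  tab2 <- normalize_abundance(reads2, samples, genes)
  cmp2 <- compare_proportions(tab2, "ITS", "s1", "s2")
  expect_equal(cmp2$max_abs_deviation, 1)
})

test_that("RMS deviation between replicate draws shrinks with sequencing depth", {
  sds <- vapply(c(500, 50000), function(depth) {
    cfg <- quiet_scenario(seed = 5, library_sizes = c(a = 1e6, b = 1e6),
                          marker_reads = depth)
    plc <- make_placement_table(cfg)
    tab <- normalize_abundance(filter_reads(plc$reads)$kept, plc$samples,
                               plc$genes, plc$copy_numbers)
    compare_proportions(tab, "ITS", "a", "b")$rms_deviation
  }, numeric(1))
  expect_lt(sds[2], sds[1])
})

test_that("peptide sharing handles subset, disjoint and partition cases", {
  obs <- data.frame(
    sample_id = c(rep("f", 4), rep("x", 6), rep("y", 2)),
    peptide = c("p1", "p2", "p3", "p4",
                "p1", "p2", "p3", "p4", "p5", "p6",
                "q1", "q2"),
    taxon = "cyanobacteria")
  res <- peptide_overlap(obs, "f", c("x", "y"))
  expect_equal(unname(res$shared), c(1, 0))
  expect_equal(sum(res$partition$fraction), 1)
  expect_equal(res$partition$fraction[res$partition$subset == "x"], 1)
  expect_error(peptide_overlap(obs, "f", "x", taxon_filter = "diatom"),
               "no peptides")
})
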