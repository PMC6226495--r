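test_that("reading a count table yields index-aligned objects with row-sum depths", {
  tab_path <- write_tsv_fixture(c(
    "sample_id\totu_1\totu_2",
    "s1\t5\t0",
    "s2\t1\t2",
    "s3\t0\t7"))
  tax_path <- write_tsv_fixture(c(
    "otu_id\tlineage",
    "otu_1\tp__Firmicutes;f__Lactobacillaceae;g__Lactobacillus",
    "otu_2\tp__Firmicutes;o__Clostridiales;f__Ruminococcaceae"))
  meta_path <- write_tsv_fixture(c(
    "sample_id\tstudy\tplatform\tregion\tbreed\ttreatment",
    "s1\tA\tMiSeq\tV4\tCobb\tcontrol",
    "s2\tA\tMiSeq\tV4\tCobb\tAGP",
    "s3\tB\t454\tV1-V3\tRoss\tcontrol"))
  x <- read_otu_table(tab_path, tax_path, meta_path)
  expect_s3_class(x$table, "otu_table")
  expect_equal(unname(x$table$depths), c(5, 3, 7))
  expect_equal(x$table$counts["s2", "otu_2"], 2)
  expect_equal(x$taxonomy$display_label, c("Lactobacillus",
                                           "family Ruminococcaceae"))
  expect_equal(x$metadata$breed, c("Cobb", "Cobb", "Ross"))
})

test_that("malformed tables are rejected, never silently zeroed", {
  tax <- write_tsv_fixture(c("otu_id\tlineage", "otu_1\tg__G1",
                             "otu_2\tg__G2"))
  meta <- write_tsv_fixture(c(
    "sample_id\tstudy\tplatform\tregion\tbreed\ttreatment",
    "s1\tA\tM\tV4\tB\tc", "s2\tA\tM\tV4\tB\tc"))
  neg <- write_tsv_fixture(c("id\totu_1\totu_2", "s1\t-1\t2", "s2\t1\t2"))
  expect_error(read_otu_table(neg, tax, meta), "negative count")
  junk <- write_tsv_fixture(c("id\totu_1\totu_2", "s1\tx\t2", "s2\t1\t2"))
  expect_error(read_otu_table(junk, tax, meta), "unparseable")
  ok <- write_tsv_fixture(c("id\totu_1\totu_2\totu_3",
                            "s1\t1\t2\t3", "s2\t1\t2\t3"))
  expect_error(read_otu_table(ok, tax, meta), "otu_3")
  expect_error(read_otu_table("/nonexistent/file.tsv", tax, meta),
               "not found")
  expect_error(otu_table(matrix(c(1, 1.5, 2, 3), 2, 2,
                                dimnames = list(c("a", "b"), c("x", "y")))),
               "non-integer")
  expect_error(make_table(matrix(1:4, 2, 2), sample_ids = c("s", "s")),
               "duplicate")
})

test_that("total-read filter uses strict 'more than' semantics and is idempotent", {
  counts <- rbind(c(75, 45, 50, 100, 40), c(75, 45, 51, 0, 40))
  tab <- make_table(counts, otu_ids = c("A", "B", "C", "Dd", "E"))
  # totals: A=150, B=90, C=101, Dd=100, E=80
  f <- filter_by_total_reads(tab, 79)
  expect_setequal(f$otu_ids, c("A", "B", "C", "Dd", "E"))
  expect_error(filter_by_total_reads(tab, 100), "fewer than 4")
  tab2 <- make_table(cbind(counts, c(300, 5), c(200, 200)),
                     otu_ids = c("A", "B", "C", "Dd", "E", "F", "G"))
  f100 <- filter_by_total_reads(tab2, 100)
  expect_setequal(f100$otu_ids, c("A", "C", "F", "G"))  # 100 is not > 100
  expect_identical(filter_by_total_reads(f100, 100)$counts, f100$counts)
  expect_error(filter_by_total_reads(tab, 0), "positive")
  expect_identical(f100$sample_ids, tab2$sample_ids)
})

test_that("rare genera are regrouped under family, else order, at the OTU-count threshold", {
  ids <- sprintf("o%02d", 1:32)
  tax <- make_taxonomy(ids,
                       genus = c(rep("Common", 15), rep("Rare", 14),
                                 "Orphan", "Orphan2", NA),
                       family = c(rep("FamA", 29), NA, NA, "FamB"),
                       order = c(rep("OrdA", 30), NA, "OrdB"))
  out <- relabel_rare_genera(tax, min_otus = 15)
  expect_equal(nrow(out), nrow(tax))                    # labels only
  expect_true(all(out$display_label[1:15] == "Common")) # 15 OTUs: kept
  expect_true(all(out$display_label[16:29] == "family FamA"))
  expect_equal(out$display_label[30], "order OrdA")     # family unresolved
  expect_equal(out$display_label[31], "Orphan2")        # nothing higher
  expect_equal(out$display_label[32], "family FamB")    # genus unresolved
})

test_that("count tables and networks round-trip bit-exactly through disk", {
  sim <- simulate_community_files(D = 8, n_samples = 6, n_clusters = 0,
                                  seed = 5)
  d <- tempfile(); dir.create(d)
  write_otu_table(sim, file.path(d, "t.tsv"), file.path(d, "x.tsv"),
                  file.path(d, "m.tsv"))
  back <- read_otu_table(file.path(d, "t.tsv"), file.path(d, "x.tsv"),
                         file.path(d, "m.tsv"))
  expect_identical(back$table$counts, sim$table$counts)

  rho <- diag(4); rho[1, 2] <- rho[2, 1] <- 0.4
  rho[3, 4] <- rho[4, 3] <- -0.6
  pv <- matrix(1, 4, 4); pv[1, 2] <- pv[2, 1] <- 0.01
  pv[3, 4] <- pv[4, 3] <- 0.001
  net <- build_network(fake_corr(rho, pv))
  for (fmt in c("edge-tsv", "graphml")) {
    f <- tempfile()
    export_network(net, f, fmt)
    back <- read_network(f, fmt)
    expect_equal(back$edges[, c("source", "target", "rho", "pvalue", "sign")],
                 net$edges[, c("source", "target", "rho", "pvalue", "sign")],
                 tolerance = 1e-12)
  }
  expect_equal(net$edges$sign, c("+", "-"))
  # empty network: header-only TSV
  empty <- build_network(fake_corr(diag(4), matrix(1, 4, 4)))
  f <- tempfile()
  export_network(empty, f, "edge-tsv")
  expect_length(readLines(f), 1)
  expect_error(export_network(net, tempfile(), "xml"))
})
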