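test_that("cross-tab marginals are sums of their cells", {
  rb <- matrix(1:30, 5, 6,
               dimnames = list(c("neural", "ubiq_high", "ubiq_low",
                                 "ubiq_med", "other"), NULL))
  nr <- matrix(0L, 5, 6, dimnames = dimnames(rb))
  tot <- crosstab_totals(rb, nr)
  expect_equal(unname(tot$robust_row_totals), unname(rowSums(rb)))
  expect_equal(tot$robust_total, sum(1:30))
  expect_equal(tot$nonrobust_total, 0)
  expect_equal(tot$grand_total, sum(1:30))
  expect_error(crosstab_totals(rb - 5, nr), "non-negative")
})

test_that("tabulation partitions classified genic sites, empty input included", {
  empty <- data.frame(class = character(0), robust = logical(0),
                      feature = character(0))
  ct0 <- tabulate_sites(empty)
  expect_equal(ct0$totals$grand_total, 0)
  expect_true(all(ct0$robust == 0))

  land <- default_small_landscape()
  ct <- tabulate_sites(land$records)
  rec <- land$records
  genic <- rec$class != "unclassified" &
    rec$feature %in% c("five_utr", "recoding", "synonymous",
                       "splice_junction", "intron", "three_utr")
  expect_equal(ct$totals$grand_total, sum(genic))
  expect_equal(sum(ct$totals$robust_row_totals), ct$totals$robust_total)
  expect_equal(sum(ct$totals$nonrobust_row_totals), ct$totals$nonrobust_total)
  expect_equal(ct$totals$robust_total + ct$totals$nonrobust_total,
               ct$totals$grand_total)
  expect_equal(ct$n_unclassified, sum(rec$class == "unclassified"))
  # writing is deterministic
  p1 <- tempfile(); p2 <- tempfile()
  write_crosstab(ct, p1); write_crosstab(ct, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("frequency histograms report the sub-1% mass explicitly", {
  rec <- data.frame(wn = c(0.005, 0.5), wnn = c(0, 0))
  h <- frequency_histogram(rec, "neural")
  expect_equal(h$frac_below_1pct, 0.5)
  expect_equal(sum(h$fractions), 1)
  all_zero <- data.frame(wn = rep(0, 7), wnn = 0)
  expect_equal(frequency_histogram(all_zero, "neural")$frac_below_1pct, 1)
  expect_error(frequency_histogram(data.frame(wn = NA_real_, wnn = NA_real_),
                                   "neural"), "no sites")
})

test_that("ubiquitous-low sites mass below 5% as their Beta model implies", {
  sim <- default_sim()
  land <- default_landscape()
  ul <- land$records[land$records$site_id %in%
    sim$truth$sites$site_id[sim$truth$sites$true_class == "ubiq_low"], ]
  obs <- mean(ul$wn < 0.05, na.rm = TRUE)
  # oracle: expected WN per site from the planted per-tissue frequencies
  neural_cols <- sim$tissues$sample_id[sim$tissues$group == "neural"]
  tw <- rowMeans(sim$truth$freq[ul$site_id, neural_cols])
  want <- mean(tw < 0.05)
  se <- sqrt(want * (1 - want) / nrow(ul))
  expect_lt(abs(obs - want), 4 * se + 0.02)
})

test_that("tissue clustering separates neural from non-neural samples", {
  f <- matrix(c(0.9, 0.1, 0.8, 0.2), 2, 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  tc <- tissue_clustering(cbind(f, s3 = f[, 1]))
  expect_equal(unname(diag(tc$correlation)), rep(1, 3))
  expect_equal(tc$correlation["s1", "s3"], 1)
  expect_true(isSymmetric(tc$correlation))
  expect_error(tissue_clustering(f[, 1, drop = FALSE]), "two samples")

  land <- default_landscape()
  sim <- default_sim()
  keep <- sim$tissues$sample_id[sim$tissues$group %in%
                                  c("neural", "non_neural")]
  tc2 <- tissue_clustering(land$freqs$f[land$constitutive, keep])
  k <- stats::cutree(tc2$hclust, 2)
  grp <- sim$tissues$group[match(names(k), sim$tissues$sample_id)]
  expect_equal(length(unique(k[grp == "neural"])), 1L)
  expect_equal(length(unique(k[grp == "non_neural"])), 1L)
  expect_false(unique(k[grp == "neural"]) ==
                 unique(k[grp == "non_neural"]))
  # newick export parses back with the same tips
  nw <- tempfile(fileext = ".nwk")
  write_clustering(tc2, tempfile(), nw)
  tree <- ape::read.tree(nw)
  expect_setequal(tree$tip.label, keep)
})

test_that("gene profiles keep positions ordered and missing cells missing", {
  land <- default_small_landscape()
  rec <- land$records[!is.na(land$records$gene_id), ]
  gene <- names(sort(table(rec$gene_id), decreasing = TRUE))[1]
  gp <- gene_profile(gene, land$records, land$freqs)
  pos <- land$records$pos[match(rownames(gp), land$records$site_id)]
  expect_true(all(diff(pos) > 0))
  depth <- land$freqs$depth[rownames(gp), ]
  expect_true(all(is.na(gp[depth == 0])))
  expect_error(gene_profile("no_such_gene", land$records, land$freqs),
               "no edited sites")
  # a single-site gene yields that site's frequency vector
  singles <- names(table(rec$gene_id))[table(rec$gene_id) == 1]
  if (length(singles)) {
    gp1 <- gene_profile(singles[1], land$records, land$freqs)
    sid <- rec$site_id[rec$gene_id == singles[1]]
    expect_equal(gp1[1, ], land$freqs$f[sid, ])
  }
})

test_that("neural-type sites show higher neural than non-neural frequencies", {
  sim <- default_sim()
  land <- default_landscape()
  rec <- land$records
  neural_sites <- rec$site_id[rec$class == "neural"]
  neural_cols <- sim$tissues$sample_id[sim$tissues$group == "neural"]
  nn_cols <- sim$tissues$sample_id[sim$tissues$group == "non_neural"]
  f <- land$freqs$f[neural_sites, ]
  expect_gt(mean(f[, neural_cols], na.rm = TRUE),
            mean(f[, nn_cols], na.rm = TRUE) + 0.2)
})
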