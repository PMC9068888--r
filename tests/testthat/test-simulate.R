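test_that("configuration errors are caught up front", {
  expect_error(simulation_config(tissue_panel = data.frame(
    sample_id = c("a", "b"), group = c("neural", "mixed"))),
    "non-neural")
  expect_error(simulation_config(site_counts = c(neural = -5L)),
               "non-negative")
  expect_error(simulation_config(site_counts = c(bogus = 5L)), "classes")
  expect_error(simulation_config(depth_mean = 0), "positive")
})

test_that("the generator is byte-identical under a fixed seed", {
  cfg <- small_config(seed = 41)
  d1 <- tempfile(); d2 <- tempfile()
  write_dataset(simulate_dataset(cfg), d1)
  write_dataset(simulate_dataset(cfg), d2)
  files <- list.files(d1)
  expect_setequal(files, list.files(d2))
  for (f in files) {
    expect_identical(readBin(file.path(d1, f), "raw", n = 5e6),
                     readBin(file.path(d2, f), "raw", n = 5e6),
                     info = f)
  }
  # and a different seed changes the data
  d3 <- tempfile()
  write_dataset(simulate_dataset(small_config(seed = 42)), d3)
  expect_false(identical(
    readBin(file.path(d1, "counts.tsv"), "raw", n = 5e6),
    readBin(file.path(d3, "counts.tsv"), "raw", n = 5e6)))
})

test_that("planted class counts equal the configured counts", {
  sim <- small_sim()
  got <- table(sim$truth$sites$true_class)
  want <- sim$config$site_counts
  expect_equal(as.integer(got[names(want)]), unname(as.integer(want)))
  # a class configured to zero leaves no truth rows
  cfg0 <- small_config(seed = 5,
                       site_counts = c(neural = 0L, ubiq_low = 20L,
                                       ubiq_med = 20L, ubiq_high = 20L,
                                       het_artifact = 20L, unedited = 20L))
  sim0 <- simulate_dataset(cfg0)
  expect_false("neural" %in% sim0$truth$sites$true_class)
  expect_equal(nrow(sim0$truth$sites), 100L)
})

test_that("every planted site is an adenosine on the transcribed strand", {
  sim <- small_sim()
  ts <- sim$truth$sites
  base <- mapply(function(ch, p)
    as.character(Biostrings::subseq(sim$genome[[ch]], p, p)),
    ts$chrom, ts$pos)
  on_tx <- ifelse(ts$strand == "-",
                  c(A = "T", C = "G", G = "C", T = "A")[base], base)
  expect_true(all(on_tx == "A"))
  # and every site lies on a generated chromosome, inside it
  expect_true(all(ts$chrom %in% names(sim$genome)))
  expect_true(all(ts$pos >= 1 &
                    ts$pos <= Biostrings::width(sim$genome)[
                      match(ts$chrom, names(sim$genome))]))
})

test_that("planted frequencies track the configured Beta means", {
  sim <- default_sim()   # >= 500 sites per class at depth mean 50
  ts <- sim$truth$sites
  fr <- sim$truth$freq
  pars <- sim$config$class_frequency_params
  neural_cols <- sim$tissues$sample_id[sim$tissues$group == "neural"]
  nn_cols <- sim$tissues$sample_id[sim$tissues$group == "non_neural"]
  for (cl in c("neural", "ubiq_low", "ubiq_med", "ubiq_high")) {
    rows <- ts$true_class == cl
    p <- pars[pars$class == cl, ]
    for (side in list(list(cols = neural_cols, mu = p$mean_neural),
                      list(cols = nn_cols, mu = p$mean_non_neural))) {
      x <- as.vector(fr[rows, side$cols])
      se <- stats::sd(x) / sqrt(length(x))
      expect_lt(abs(mean(x) - side$mu), 3 * se + 1e-12)
    }
  }
  # unedited sites emit no edited reads at all
  un <- ts$true_class == "unedited"
  expect_true(all(sim$counts$G[un, ] == 0L))
  # heterozygous artifacts sit near 0.5 everywhere and are genotyped AG
  het <- ts$true_class == "het_artifact"
  expect_lt(abs(mean(fr[het, ]) - 0.5), 0.01)
  expect_true(all(sim$genotypes$genotype[het] == "AG"))
  expect_true(all(sim$genotypes$genotype[!het] == "AA"))
})

test_that("read depths are overdispersed with the configured mean", {
  sim <- default_sim()
  depth <- sim$counts$A + sim$counts$G
  m <- mean(depth)
  expect_lt(abs(m - sim$config$depth_mean), 1)
  # variance far above Poisson
  expect_gt(stats::var(as.vector(depth)), 5 * m)
})

test_that("recovery evaluation satisfies its accounting identities", {
  sim <- small_sim()
  truth <- sim$truth$sites
  # calls identical to truth -> diagonal confusion, recall 1 everywhere
  fake <- data.frame(site_id = truth$site_id, class = truth$true_class)
  fake$class[fake$class == "het_artifact"] <- "excluded"
  fake$class[fake$class == "unedited"] <- "not_called"
  ev <- evaluate_recovery(truth, fake)
  expect_true(all(ev$recall == 1))
  expect_equal(sum(ev$confusion), nrow(truth))
  # empty call set: everything lands in not_called
  ev0 <- evaluate_recovery(truth,
                           data.frame(site_id = character(0),
                                      class = character(0)))
  expect_equal(sum(ev0$confusion[, "not_called"]), nrow(truth))
})

test_that("a dataset round-trips through its files", {
  sim <- small_sim()
  dir <- tempfile()
  write_dataset(sim, dir)
  rt <- read_dataset(dir)
  expect_identical(rt$counts$A, sim$counts$A)
  expect_identical(rt$genotypes$genotype, sim$genotypes$genotype)
  expect_equal(rt$truth$sites$true_class, sim$truth$sites$true_class)
  expect_equal(dim(rt$truth$freq), dim(sim$truth$freq))
  ord <- order(sim$outgroups$tracks[[1]]$chrom, sim$outgroups$tracks[[1]]$pos)
  expect_equal(rt$outgroups$tracks[[1]]$allele1,
               sim$outgroups$tracks[[1]]$allele1[ord])
  models <- read_gene_models(file.path(dir, "genes.gff3"))
  expect_true(all(unique(sim$truth$sites$gene_id) %in%
                    names(models$primary)))
})
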