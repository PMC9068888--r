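test_that("longest isoform is primary, ties broken lexicographically", {
  gff <- c(
    "##gff-version 3",
    "chr1\tt\tgene\t1\t1000\t.\t+\t.\tID=g1",
    "chr1\tt\tmRNA\t1\t500\t.\t+\t.\tID=g1.b;Parent=g1",
    "chr1\tt\texon\t1\t300\t.\t+\t.\tParent=g1.b",
    "chr1\tt\tmRNA\t1\t1000\t.\t+\t.\tID=g1.a;Parent=g1",
    "chr1\tt\texon\t1\t200\t.\t+\t.\tParent=g1.a",
    "chr1\tt\texon\t500\t599\t.\t+\t.\tParent=g1.a",
    "chr1\tt\tmRNA\t1\t1000\t.\t+\t.\tID=g1.c;Parent=g1",
    "chr1\tt\texon\t1\t150\t.\t+\t.\tParent=g1.c",
    "chr1\tt\texon\t500\t649\t.\t+\t.\tParent=g1.c")
  path <- tempfile(fileext = ".gff3")
  writeLines(gff, path)
  models <- read_gene_models(path)
  # g1.a and g1.c are both 300 bp (beating g1.b at 300? no: g1.b is 300 too)
  # all three are 300 bp long: lexicographic tie-break picks g1.a
  expect_equal(unname(models$primary["g1"]), "g1.a")
})

test_that("codon consequences follow the genetic code on both strands", {
  # plus strand: codon TAT with the edit at codon position 2 -> TGT, Tyr>Cys
  toy <- toy_cds_gene("ATGTATAAACCCTGA")
  s <- toy$cds_start
  sites <- data.frame(chrom = "chrT",
                      pos = c(s + 4, s + 8, s + 2),
                      strand = "+")
  ann <- annotate_sites(sites, toy$models, toy$genome)
  expect_equal(ann$feature, c("recoding", "synonymous", "synonymous"))
  expect_equal(ann$ref_codon[1], "TAT")
  expect_equal(ann$alt_codon[1], "TGT")
  expect_equal(ann$ref_aa[1], "Y")
  expect_equal(ann$alt_aa[1], "C")
  # AAA -> AAG at codon position 3 is synonymous Lys
  expect_equal(ann$ref_codon[2], "AAA")
  expect_equal(ann$alt_codon[2], "AAG")
  expect_equal(ann$ref_aa[2], "K")
  # AAA -> GAA at codon position 1 recodes Lys>Glu with BLOSUM62 score 1
  sites2 <- data.frame(chrom = "chrT", pos = s + 6, strand = "+")
  ann2 <- annotate_sites(sites2, toy$models, toy$genome)
  expect_equal(ann2$feature, "recoding")
  expect_equal(paste0(ann2$ref_aa, ann2$alt_aa), "KE")
  expect_equal(ann2$blosum62, 1L)
})

test_that("UTR, intron and splice-junction assignment is position-exact", {
  toy <- toy_gene_set()
  sites <- data.frame(
    chrom = "chr1",
    pos = c(120,   # exon 1 before CDS -> 5' UTR
            360,   # past the stop codon inside the last exon -> 3' UTR
            250,   # middle of the intron
            221,   # first intronic base after exon 1 -> splice window
            220,   # terminal exonic base -> splice window
            223,   # third intronic base -> plain intron
            50),   # outside the gene
    strand = "+")
  ann <- annotate_sites(sites, toy$models, toy$genome)
  expect_equal(ann$feature,
               c("five_utr", "three_utr", "intron", "splice_junction",
                 "splice_junction", "intron", "intergenic"))
  # minus-strand gene: 5' UTR is at the genomic right end
  msites <- data.frame(chrom = "chr2", pos = c(380, 120), strand = "-")
  mann <- annotate_sites(msites, toy$models, toy$genome)
  expect_equal(mann$feature, c("five_utr", "three_utr"))
})

test_that("feature assignment matches the per-base oracle everywhere", {
  toy <- toy_gene_set()
  map <- oracle_feature_map(toy$models, toy$genome)
  for (tx in toy$models$transcripts) {
    span <- (min(tx$exons[, 1]) - 5):(max(tx$exons[, 2]) + 5)
    sites <- data.frame(chrom = tx$chrom, pos = span, strand = tx$strand)
    ann <- annotate_sites(sites, toy$models, toy$genome)
    expect_identical(ann$feature, map[[tx$chrom]][span])
  }
})

test_that("synonymous annotations re-translate to the same protein", {
  sim <- small_sim()
  land <- default_small_landscape()
  rec <- land$records
  syn <- rec[!is.na(rec$feature) & rec$feature == "synonymous", ]
  expect_gt(nrow(syn), 0)
  expect_true(all(syn$ref_aa == syn$alt_aa))
  rc <- rec[!is.na(rec$feature) & rec$feature == "recoding", ]
  expect_true(all(rc$ref_aa != rc$alt_aa))
})

test_that("interval overlap uses half-open BED semantics", {
  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t100\t200\trep1", bed)
  repeats <- read_repeats(bed)
  sites <- data.frame(chrom = "chr1", pos = c(100, 101, 200, 201),
                      strand = "+")
  flags <- overlap_flags(sites, repeats = repeats)
  # BED [100, 200) covers 1-based positions 101..200
  expect_equal(flags$in_repeat, c(FALSE, TRUE, TRUE, FALSE))
})

test_that("protein-domain overlap maps through codon coordinates", {
  toy <- toy_cds_gene(paste(rep("ATGAAACCC", 20), collapse = ""))
  s <- toy$cds_start
  # residue 12 occupies CDS positions 34..36
  sites <- data.frame(chrom = "chrT", pos = s + c(34, 26, 88) - 1,
                      strand = "+")
  ann <- annotate_sites(sites, toy$models, toy$genome)
  expect_equal(ann$aa_pos, c(12, 9, 30))
  domains <- data.frame(transcript_id = "g1.t1", start_aa = 10, end_aa = 30,
                        label = "DOM")
  flags <- overlap_flags(sites, ann, domains = domains, models = toy$models)
  expect_equal(flags$in_domain, c(TRUE, FALSE, FALSE))  # [10, 30) half-open
  bad <- data.frame(transcript_id = "missing.t1", start_aa = 1, end_aa = 5,
                    label = "X")
  expect_error(overlap_flags(sites, ann, domains = bad, models = toy$models),
               "missing.t1")
})

test_that("editable-adenosine background counts depth>10 A's with no G reads", {
  toy <- toy_cds_gene("ATGAAAAAAAAATGA")  # CDS rich in adenosines
  s <- toy$cds_start
  pos <- s + 0:14
  sites <- data.frame(chrom = "chrT", pos = pos, strand = "+")
  n <- length(pos)
  a <- matrix(11L, n, 2, dimnames = list(NULL, c("s1", "s2")))
  g <- matrix(0L, n, 2, dimnames = list(NULL, c("s1", "s2")))
  a[1:3, ] <- 5L                       # depth 10, not > 10
  g[4, 1] <- 1L                        # has an alternate read
  counts <- allele_counts(sites, a, g)
  bg <- editable_background(counts, toy$models, toy$genome)
  # A positions: 1, 4:12, 14 (15 bases ATG AAA AAA AAA TGA)
  # minus 3 shallow (positions 1..3 include A at 1) minus the g-carrying 4
  a_pos <- which(strsplit("ATGAAAAAAAAATGA", "")[[1]] == "A")
  deep <- setdiff(a_pos, c(1:3, 4))
  expect_equal(sum(bg$editable_a), length(deep))
  # enrichment: all edited sites in one feature
  edited <- data.frame(feature = c("synonymous", "synonymous"))
  bg2 <- editable_background(counts, toy$models, toy$genome, edited = edited)
  syn_row <- bg2[bg2$feature == "synonymous", ]
  expect_gt(syn_row$enrichment, 1)
  expect_equal(bg2$enrichment[bg2$feature == "recoding"], 0)
})
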