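test_that("packaged instrument fixture matches the printed table", {
  tab <- load_table1_fixture()
  expect_s3_class(tab, "summary_stats")
  expect_identical(nrow(tab), 162L)

  first <- tab[1, ]
  expect_identical(first$snp_id, "rs11130222")
  expect_identical(first$effect_allele, "A")
  expect_identical(first$other_allele, "T")
  expect_equal(first$eaf, 0.59)
  expect_equal(first$beta, 0.025)
  expect_equal(first$se, 0.0023)

  row <- tab[tab$snp_id == "rs140711597", ]
  expect_equal(row$beta, 0.052)
  expect_equal(row$se, 0.0091)
  expect_identical(row$effect_allele, "C")
  expect_identical(row$other_allele, "G")

  # frozen from an independent hand tally of the printed effect-size column
  expect_identical(sum(tab$beta < 0), 71L)
  # every candidate instrument is genome-wide significant
  expect_true(all(tab$pval <= 4.86e-8))
})

test_that("read_summary_stats validates structure and rows", {
  # empty file with header only: empty table, no error
  path <- write_raw_tsv(toy_table(0L))
  empty <- read_summary_stats(path)
  expect_identical(nrow(empty), 0L)

  # missing mandatory column is a configuration error
  bad <- toy_table(); bad$se <- NULL
  expect_error(read_summary_stats(write_raw_tsv(bad)),
               "configuration error.*se")

  # se = 0 rejected with the field and the file line named
  bad <- toy_table(); bad$se[2] <- 0
  expect_error(read_summary_stats(write_raw_tsv(bad)), "line 3.*'se'")

  # unparseable numeric names the offending field
  bad <- toy_table(); bad$beta <- as.character(bad$beta); bad$beta[1] <- "x"
  expect_error(read_summary_stats(write_raw_tsv(bad)), "'beta' is not numeric")

  # eaf on the boundary violates the open-interval invariant
  bad <- toy_table(); bad$eaf[1] <- 1
  expect_error(read_summary_stats(write_raw_tsv(bad)), "'eaf'")

  # identical alleles rejected
  bad <- toy_table(); bad$other_allele[1] <- bad$effect_allele[1]
  expect_error(read_summary_stats(write_raw_tsv(bad)), "effect_allele")

  # on_invalid = "drop" keeps the good rows and reports the bad ones
  bad <- toy_table(); bad$se[2] <- 0
  expect_warning(kept <- read_summary_stats(write_raw_tsv(bad),
                                            on_invalid = "drop"),
                 "dropping 1 invalid")
  expect_identical(nrow(kept), 2L)
  expect_identical(attr(kept, "invalid_rows")$field, "se")
})

test_that("column_map adapts foreign headers", {
  df <- toy_table()
  names(df) <- c("SNP", "A1", "A2", "freq", "b", "stderr", "p")
  path <- write_raw_tsv(df)
  expect_error(read_summary_stats(path), "configuration error")
  got <- read_summary_stats(path, column_map = c(
    snp_id = "SNP", effect_allele = "A1", other_allele = "A2",
    eaf = "freq", beta = "b", se = "stderr", pval = "p"))
  expect_equal(got$beta, toy_table()$beta)
})

test_that("read/write/read round trip preserves numerics exactly", {
  tab <- load_table1_fixture()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_summary_stats(tab, path)
  back <- read_summary_stats(path)
  for (col in c("eaf", "beta", "se", "pval")) {
    expect_identical(back[[col]], tab[[col]])
  }
})

test_that("harmonize aligns, flips, and drops per the documented policy", {
  expo <- data.frame(snp_id = "rs1", effect_allele = "A", other_allele = "G",
                     eaf = 0.3, beta = 0.02, se = 0.003, pval = 1e-10,
                     stringsAsFactors = FALSE)
  out_same <- expo; out_same$beta <- -0.05; out_same$se <- 0.02
  set <- harmonize(expo, out_same)
  expect_equal(set$beta_outcome, -0.05)
  expect_identical(set$action, "kept_as_is")

  # swapped alleles: outcome beta negated, action recorded
  out_swap <- out_same
  out_swap$effect_allele <- "G"; out_swap$other_allele <- "A"
  out_swap$eaf <- 0.7
  set <- harmonize(expo, out_swap)
  expect_equal(set$beta_outcome, 0.05)
  expect_identical(set$action, "allele_flip")
  expect_equal(set$eaf_outcome, 0.3)   # reflected for the report
  expect_equal(set$eaf, 0.3)           # exposure EAF governs

  # strand complement (T/C is the complement of A/G) still aligns
  out_strand <- out_same
  out_strand$effect_allele <- "T"; out_strand$other_allele <- "C"
  set <- harmonize(expo, out_strand)
  expect_equal(set$beta_outcome, -0.05)
  expect_identical(set$action, "kept_as_is")

  # ambiguous palindrome near EAF 0.5 dropped
  pal <- expo; pal$effect_allele <- "A"; pal$other_allele <- "T"
  pal$eaf <- 0.50
  set <- harmonize(pal, pal)
  expect_identical(nrow(set), 0L)
  expect_identical(provenance(set)$step, "harmonize_palindromic")

  # ...but kept when the frequency is informative
  pal$eaf <- 0.20
  expect_identical(harmonize(pal, pal)$action, "kept_as_is")

  # no shared alleles: explicit mismatch drop, never silently kept
  out_bad <- out_same
  out_bad$effect_allele <- "C"; out_bad$other_allele <- "A"
  set <- harmonize(expo, out_bad)
  expect_identical(nrow(set), 0L)
  expect_match(provenance(set)$step, "allele_mismatch")

  # absent from outcome
  set <- harmonize(expo, out_same[0, ])
  expect_identical(attr(set, "actions")$action, "dropped_missing")
})

test_that("harmonization is involutive on sign", {
  tab <- load_table1_fixture()
  pal <- tab$effect_allele == chartr("ACGT", "TGCA", tab$other_allele)
  tab <- tab[!pal, ]   # palindromes aside, by design they drop
  swapped <- tab
  swapped$effect_allele <- tab$other_allele
  swapped$other_allele <- tab$effect_allele
  swapped$beta <- -tab$beta
  swapped$eaf <- 1 - tab$eaf
  set <- harmonize(tab, swapped)
  expect_identical(nrow(set), nrow(tab))
  expect_true(all(set$action == "allele_flip"))
  # negated twice: net identity
  expect_equal(set$beta_outcome, tab$beta)
})

test_that("no record is both retained and listed as removed", {
  tab <- load_table1_fixture()
  out <- tab[seq(1, 162, by = 2), ]   # half missing from outcome
  set <- harmonize(tab, out)
  removed <- unlist(strsplit(provenance(set)$snps, ","))
  expect_length(intersect(set$snp_id, removed), 0)
  expect_identical(nrow(set) + length(removed), attr(set, "n_initial"))
})
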