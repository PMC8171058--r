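test_that("odds ratios are log-transformed at ingestion", {
  df <- data.frame(rsid = c("rs1", "rs2", "rs3"),
                   A1 = c("A", "C", "G"), A2 = c("G", "T", "A"),
                   OR = c(1.0, 2.0, 0.5), SE = c(0.1, 0.1, 0.1),
                   P = c(0.5, 1e-9, 1e-9))
  path <- make_tmp_tsv(df)
  tab <- read_gwas_table(path,
                         column_map = list(snp_id = "rsid",
                                           effect_allele = "A1",
                                           other_allele = "A2",
                                           effect = "OR", se = "SE",
                                           pvalue = "P"),
                         trait_type = "binary", effect_is_or = TRUE)
  expect_equal(tab$records$beta, c(0, log(2), -log(2)))
  expect_identical(tab$trait_type, "binary")
})

test_that("invalid rows are dropped and counted", {
  df <- data.frame(snp_id = c("rs1", "rs2", "rs3", "rs4"),
                   effect_allele = c("A", "C", "G", "A"),
                   other_allele = c("G", "T", "G", "T"),
                   beta = c(0.1, 0.2, 0.3, 0.4),
                   se = c(0.1, 0, 0.1, 0.1),
                   pvalue = c(0.5, 0.5, 0.5, 0.5))
  ## rs2: se = 0; rs3: identical alleles
  tab <- gwas_table(df, "t", "continuous")
  expect_identical(tab$records$snp_id, c("rs1", "rs4"))
  expect_identical(tab$n_dropped, 2L)
})

test_that("duplicate snp ids keep the smallest p-value", {
  df <- data.frame(snp_id = c("rs1", "rs1", "rs2"),
                   effect_allele = "A", other_allele = "G",
                   beta = c(0.1, 0.9, 0.2), se = 0.1,
                   pvalue = c(0.5, 1e-4, 0.1))
  tab <- gwas_table(df, "t", "continuous")
  expect_identical(nrow(tab$records), 2L)
  expect_equal(tab$records$beta[tab$records$snp_id == "rs1"], 0.9)
  expect_identical(tab$n_dropped, 1L)
})

test_that("p-values of exactly zero are floored to a positive constant", {
  df <- data.frame(snp_id = "rs1", effect_allele = "A", other_allele = "G",
                   beta = 1, se = 0.01, pvalue = 0)
  tab <- gwas_table(df, "t", "continuous")
  expect_gt(tab$records$pvalue, 0)
  expect_identical(tab$records$pvalue, mrflow:::P_FLOOR)
})

test_that("a 1000-row table round-trips losslessly", {
  sim <- simulate_pair(sim_config(n_snps = 1000, n_instruments = 20,
                                  seed = 404))
  path <- tempfile(fileext = ".tsv")
  write_gwas_table(sim$exposure, path)
  back <- read_gwas_table(path, canonical_column_map(),
                          trait_id = "exposure", trait_type = "continuous")
  expect_equal(back$records$beta, sim$exposure$records$beta)
  expect_equal(back$records$se, sim$exposure$records$se)
  expect_equal(back$records$pvalue, sim$exposure$records$pvalue)
  expect_identical(back$records$snp_id, sim$exposure$records$snp_id)
  expect_identical(back$records$effect_allele,
                   sim$exposure$records$effect_allele)
})

test_that("configuration and empty-table errors are raised", {
  df <- data.frame(rsid = "rs1", A1 = "A", A2 = "G", b = 0.1, s = 0.1,
                   p = 0.5)
  path <- make_tmp_tsv(df)
  expect_error(
    read_gwas_table(path, column_map = list(snp_id = "rsid",
                                            effect_allele = "A1",
                                            other_allele = "A2",
                                            effect = "b", se = "s")),
    "mandatory")
  expect_error(
    read_gwas_table(path, column_map = list(snp_id = "rsid",
                                            effect_allele = "A1",
                                            other_allele = "A2",
                                            effect = "beta_missing",
                                            se = "s", pvalue = "p")),
    "not found")
  df_bad <- data.frame(rsid = "rs1", A1 = "A", A2 = "G", b = 0.1, s = -1,
                       p = 0.5)
  expect_error(
    read_gwas_table(make_tmp_tsv(df_bad),
                    column_map = list(snp_id = "rsid", effect_allele = "A1",
                                      other_allele = "A2", effect = "b",
                                      se = "s", pvalue = "p")),
    "no valid rows")
})
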