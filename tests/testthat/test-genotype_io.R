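# Genotype ingestion, region extraction, QC and imputation.

test_that("read_vcf maps diploid GT fields to additive dosages", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_fixture(
    path, chrom = c("chr19", "chr19"), pos = c(100, 200),
    id = c("rs1", "."), ref = c("A", "C"), alt = c("G", "T"),
    gts = rbind(c("0/0", "0/1", "1/1"), c("0|1", "./.", "1/1"))
  )
  gm <- read_vcf(path)
  expect_equal(unname(gm$calls[, "rs1"]), c(0, 1, 2))
  # missing-call convention and phased separator
  expect_equal(unname(gm$calls[, 2]), c(1, NA, 2))
  # absent ID synthesized positionally
  expect_equal(gm$variants$id[2], "chr19:200:C:T")
})

test_that("read_vcf flags multiallelic records and rejects non-diploid GT", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_fixture(
    path, chrom = rep("chr1", 2), pos = c(5, 9),
    id = c("rs1", "rs2"), ref = c("A", "C"), alt = c("G,T", "T"),
    gts = rbind(c("1/2", "0/0"), c("0/1", "0/0"))
  )
  gm <- read_vcf(path)
  expect_true(gm$variants$multiallelic[gm$variants$id == "rs1"])
  expect_false(gm$variants$multiallelic[gm$variants$id == "rs2"])
  # dosage of a multiallelic call counts non-reference alleles
  expect_equal(unname(gm$calls[1, "rs1"]), 2)

  bad <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_fixture(bad, chrom = "chr1", pos = 5, id = "rs1", ref = "A",
                    alt = "G", gts = rbind(c("0/1/1", "0/0")))
  expect_error(read_vcf(bad), "non-diploid.*chr1:5")
})

test_that("read_vcf captures GQ and DP and region filter restricts variants", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_fixture(
    path, chrom = rep("chr2", 3), pos = c(10, 50, 90),
    id = paste0("rs", 1:3), ref = rep("A", 3), alt = rep("G", 3),
    gts = rbind(c("0/0:35:20", "0/1:12:30"), c("0/1:50:9", "1/1:60:40"),
                c("0/0:25:25", "0/1:30:30")),
    format = "GT:GQ:DP"
  )
  gm <- read_vcf(path, region = list(chrom = "chr2", start = 40, end = 95))
  expect_equal(gm$variants$pos, c(50, 90))
  expect_equal(unname(gm$gq[2, "rs2"]), 60)
  expect_equal(unname(gm$dp[1, "rs2"]), 9)
})

test_that("extract_region keeps the closed interval and composes", {
  gm <- make_gm(matrix(0:2, 3, 5))  # positions 10..50
  r <- extract_region(gm, "chr1", 15, 42)
  expect_equal(r$variants$pos, c(20, 30, 40))
  expect_equal(n_samples(r), 3)
  # whole-range extraction is the identity
  expect_equal(extract_region(gm, "chr1", 1, 100)$variants, gm$variants)
  # chromosome mismatch yields an empty matrix with a warning
  expect_warning(e <- extract_region(gm, "chrX", 1, 100), "no variants")
  expect_equal(n_snps(e), 0)
  # nested extraction equals one extraction with the inner interval
  outer <- extract_region(gm, "chr1", 15, 45)
  expect_equal(extract_region(outer, "chr1", 20, 40)$calls,
               extract_region(gm, "chr1", 20, 40)$calls)
})

test_that("mask_low_quality masks strictly below the GQ/DP thresholds", {
  calls <- matrix(1, 2, 2)
  gq <- rbind(c(19, 20), c(45, 33))
  dp <- rbind(c(30, 10), c(9, 40))
  gm <- make_gm(calls, gq = gq, dp = dp)
  out <- mask_low_quality(gm, qc_thresholds())
  expect_true(is.na(out$calls[1, 1]))   # GQ 19 < 20
  expect_equal(out$calls[1, 2], 1)      # boundary GQ 20 / DP 10 kept
  expect_true(is.na(out$calls[2, 1]))   # DP 9 < 10
  expect_equal(out$calls[2, 2], 1)

  plain <- make_gm(calls)
  expect_warning(same <- mask_low_quality(plain), "no GQ/DP")
  expect_identical(same$calls, plain$calls)
})

test_that("hwe_exact_pvalue matches the enumeration oracle", {
  expect_equal(hwe_exact_pvalue(12, 0, 0), 1.0)  # monomorphic
  cases <- list(c(25, 50, 25), c(5, 0, 5), c(3, 4, 3), c(10, 30, 60),
                c(1, 1, 1), c(0, 5, 0), c(57, 14, 1), c(80, 15, 105))
  for (cs in cases) {
    expect_equal(hwe_exact_pvalue(cs[1], cs[2], cs[3]),
                 hwe_oracle(cs[1], cs[2], cs[3]), tolerance = 1e-12,
                 info = paste(cs, collapse = ","))
  }
  # stronger heterozygote deficit gives a smaller p at fixed allele counts
  expect_lt(hwe_exact_pvalue(5, 0, 5), hwe_exact_pvalue(3, 4, 3))
  expect_error(hwe_exact_pvalue(0, 0, 0), "at least one")
})

test_that("maf counts alleles over non-missing calls and is flip-symmetric", {
  expect_equal(maf(c(1, 1, 1, 1)), 0.5)
  expect_equal(maf(c(0, 0, 0, 0)), 0)
  expect_equal(maf(c(0, 1, 2, NA)), 0.5)  # 3 alt of 6 alleles
  withr::with_seed(4, {
    for (i in 1:20) {
      g <- sample(c(0:2, NA), 30, replace = TRUE)
      if (all(is.na(g))) next
      expect_equal(maf(g), maf(2 - g))
    }
  })
  expect_error(maf(c(NA, NA)), "all calls missing")
})

test_that("variant_qc removes violators under the documented precedence", {
  withr::with_seed(11, {
    n <- 60
    calls <- matrix(rbinom(n * 10, 2, 0.3), n, 10)
    calls[seq(1, n, by = 2), 3] <- NA     # call rate 0.5 -> low_call_rate
    calls[, 5] <- 0                        # monomorphic (maf 0 -> maf reason)
    calls[, 7] <- rep(c(0, 2), n / 2)      # no hets at 50% freq -> HWE extreme
    gm <- make_gm(calls)
  })
  res <- variant_qc(gm, qc_thresholds())
  expect_equal(res$report$n_survivors, 7)
  reasons <- res$report$variants$removal_reason
  expect_equal(reasons[3], "low_call_rate")
  expect_equal(reasons[5], "maf")
  expect_equal(reasons[7], "hwe")
  expect_equal(sum(reasons == "none"), 7)

  # disabled thresholds leave the matrix untouched
  off <- qc_thresholds(min_variant_call_rate = 0, hwe_p_min = 0, maf_min = 0,
                       max_missing_rate = 1, remove_monomorphic = FALSE)
  expect_equal(n_snps(variant_qc(gm, off)$matrix), 10)

  # a variant failing call-rate and MAF reports the first rule in order
  calls2 <- matrix(rbinom(40 * 4, 2, 0.4), 40, 4)
  calls2[1:30, 2] <- NA
  calls2[31:40, 2] <- 0
  res2 <- variant_qc(make_gm(calls2), qc_thresholds())
  expect_equal(res2$report$variants$removal_reason[2], "low_call_rate")
})

test_that("variant_qc is idempotent and errors when nothing survives", {
  gm <- null_gm(80, 20, seed = 5)
  once <- variant_qc(gm)
  twice <- variant_qc(once$matrix)
  expect_equal(variant_ids(twice$matrix), variant_ids(once$matrix))
  expect_equal(twice$report$n_survivors, once$report$n_survivors)

  mono <- make_gm(matrix(0, 10, 3))
  expect_error(variant_qc(mono), "review the thresholds")
})

test_that("impute_knn matches the brute-force neighbour oracle", {
  withr::with_seed(21, {
    for (rep in 1:10) {
      M <- matrix(sample(0:2, 18, replace = TRUE), 6, 3)
      i <- sample(6, 1); j <- sample(3, 1)
      M[i, j] <- NA
      gm <- make_gm(M)
      out <- impute_knn(gm, k = 2)
      expect_equal(out$calls[i, j], knn_oracle_cell(M, i, j, k = 2))
    }
  })
})

test_that("impute_knn preserves observed calls and leaves no missingness", {
  gm <- null_gm(40, 15, seed = 9)
  expect_identical(impute_knn(gm)$calls, gm$calls)  # nothing to do

  withr::with_seed(10, {
    gm$calls[sample(length(gm$calls), 60)] <- NA
  })
  obs <- !is.na(gm$calls)
  out <- impute_knn(gm, k = 5)
  expect_false(anyNA(out$calls))
  expect_identical(out$calls[obs], gm$calls[obs])
  expect_true(all(out$calls %in% 0:2))

  # a duplicated sample is its own zero-distance neighbour
  M <- matrix(c(0, 1, 2, 2, 1, 0), 3, 2)
  M <- rbind(M, M, M)  # need >= k donors
  M2 <- rbind(M, M[1, ])
  M2[10, 1] <- NA
  expect_equal(impute_knn(make_gm(M2), k = 1)$calls[10, 1], M[1, 1])

  allmiss <- make_gm(cbind(c(0, 1, 1), NA))
  expect_error(impute_knn(allmiss), "rs2")
})
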