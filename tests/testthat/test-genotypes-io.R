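test_that("GENEPOP and table writers round-trip calls, metadata and missing pattern", {
  gm0 <- random_gm(n = 10, L = 5, missing_rate = 0.15, n_pops = 3, seed = 11)
  ## GENEPOP groups individuals into POP blocks, so compare in block order
  gm <- subset_genotypes(gm0, order(match(gm0$ind$locality,
                                          unique(gm0$ind$locality))))
  for (fmt in c("genepop", "table")) {
    f <- withr::local_tempfile(fileext = ".txt")
    write_genotypes(gm, f, fmt)
    back <- load_genotypes(f, fmt)
    expect_identical(back$a1, gm$a1, info = fmt)
    expect_identical(back$a2, gm$a2, info = fmt)
    expect_identical(back$ind$id, gm$ind$id, info = fmt)
    if (fmt == "table") {
      expect_identical(back$ind, gm$ind)
    } else {
      ## GENEPOP keeps POP block structure, not labels
      expect_identical(as.integer(factor(back$ind$locality,
                                         unique(back$ind$locality))),
                       as.integer(factor(gm$ind$locality,
                                         unique(gm$ind$locality))))
    }
  }
})

test_that("GENEPOP reader handles 3-digit coding and sidecar metadata", {
  f <- withr::local_tempfile()
  writeLines(c(
    "title line", "locA", "locB", "POP",
    "s1 , 153155 101101",
    "s2 , 153153 000000",
    "POP",
    "s3 , 155161 101103"
  ), f)
  md <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(id = c("s1", "s2", "s3"), sex = c("F", "M", "F"),
                       locality = c("Dornoch", "Dornoch", "Cromarty")),
            md, row.names = FALSE)
  gm <- load_genotypes(f, "genepop", metadata = md)
  expect_equal(n_individuals(gm), 3)
  expect_equal(gm$loci, c("locA", "locB"))
  expect_equal(gm$a1[1, ], c(locA = 153L, locB = 101L))
  expect_true(is.na(gm$a1[2, "locB"]) && is.na(gm$a2[2, "locB"]))
  expect_equal(gm$ind$locality, c("Dornoch", "Dornoch", "Cromarty"))
  expect_equal(gm$ind$sex, c("F", "M", "F"))
})

test_that("malformed files raise named parse errors", {
  f <- withr::local_tempfile()
  writeLines(character(0), f)
  expect_error(load_genotypes(f, "genepop"), "empty|truncated")
  writeLines(c("t", "locA", "POP", "s1 , 0101 0202"), f)
  expect_error(load_genotypes(f, "genepop"), "ragged")
  writeLines(c("t", "locA", "POP", "s1 , 0101", "POP", "s1 , 0202"), f)
  expect_error(load_genotypes(f, "genepop"), "duplicate")
  expect_error(load_genotypes(tempfile(), "genepop"), "not found")
})

test_that("size-to-repeat conversion rounds within tolerance and errors beyond", {
  gm <- gm_from_calls(list(SGPV17 = c(153L, 153L, 155L)),
                      list(SGPV17 = c(155L, 161L, 161L)))
  defs <- list(locus_def("SGPV17", motif_length = 2, size_offset = 103))
  ru <- to_repeat_units(gm, defs)
  expect_equal(sort(unique(c(ru$a1, ru$a2))), c(25L, 26L, 29L))
  ## off-ladder call: size 154 is half a repeat off
  gm2 <- gm_from_calls(list(SGPV17 = c(153L, 154L)),
                       list(SGPV17 = c(153L, 154L)))
  expect_error(to_repeat_units(gm2, defs, tolerance = 0),
               "off-ladder.*SGPV17.*i02")
  ## idempotent when already repeat units
  defs0 <- list(locus_def("SGPV17", 1, 0))
  expect_identical(to_repeat_units(ru, defs0), ru)
})

test_that("allele frequencies count gene copies and skip missing calls", {
  gm <- gm_from_calls(list(L1 = c(10L, 10L, 12L, NA)),
                      list(L1 = c(10L, 12L, 12L, NA)))
  ft <- allele_frequencies(gm, "pooled")
  expect_equal(ft$freq$L1$all, c("10" = 0.5, "12" = 0.5))
  expect_equal(ft$n_genes$L1$all, 6)
  ## per-group sums to 1 within 1e-12 on random data
  gm2 <- random_gm(n = 30, L = 6, seed = 3)
  ft2 <- allele_frequencies(gm2, "by_locality")
  for (l in names(ft2$freq)) for (g in names(ft2$freq[[l]])) {
    f <- ft2$freq[[l]][[g]]
    if (!is.null(f)) expect_lt(abs(sum(f) - 1), 1e-12)
  }
})

test_that("polymorphism profile counts alleles, sex-specific flags and missing fraction", {
  gm <- gm_from_calls(
    list(mono = rep(8L, 5), di = c(10L, 10L, 12L, 12L, NA)),
    list(mono = rep(8L, 5), di = c(10L, 12L, 12L, 12L, NA)),
    sex = c("F", "F", "M", "M", "F")
  )
  pr <- polymorphism_profile(gm)
  expect_equal(pr$loci$A, c(1L, 2L))
  expect_equal(pr$loci$polymorphic, c(FALSE, TRUE))
  expect_equal(pr$loci$S, c(5L, 4L))
  expect_equal(pr$missing_fraction, 1 / 10)
  ## locus polymorphic in females only
  gm2 <- gm_from_calls(list(L = c(10L, 12L, 10L, 10L)),
                       list(L = c(10L, 12L, 10L, 10L)),
                       sex = c("F", "F", "M", "M"))
  pr2 <- polymorphism_profile(gm2)
  expect_true(pr2$loci$polymorphic_F)
  expect_false(pr2$loci$polymorphic_M)
})
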