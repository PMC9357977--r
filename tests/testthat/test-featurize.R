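# Frozen reference values (computed once from the reference
# fingerprint/descriptor toolkit and fixed here as the contract).
CCO_ECFP6_BITS <- c(80L, 222L, 294L, 807L, 1057L, 1410L)        # 0-based
BENZENE_MACCS_BITS <- c(162L, 163L, 165L)                       # 0-based
CCO_MACCS_BITS <- c(82L, 109L, 114L, 139L, 153L, 155L, 157L, 160L, 164L)

test_that("ECFP6 reproduces the frozen bit set and is deterministic", {
  v <- compute_ecfp6("CCO")
  expect_length(v, 2048L)
  expect_identical(which(v == 1L) - 1L, CCO_ECFP6_BITS)
  expect_identical(compute_ecfp6("CCO"), v)
})

test_that("MACCS keys match the frozen fixtures and have 167 bits", {
  vb <- compute_maccs("c1ccccc1")
  expect_length(vb, 167L)
  expect_identical(which(vb == 1L) - 1L, BENZENE_MACCS_BITS)
  vc <- compute_maccs("CCO")
  expect_identical(which(vc == 1L) - 1L, CCO_MACCS_BITS)
  expect_gt(sum(vc), 0)
})

test_that("descriptor block has 208 entries with sane chemistry", {
  v <- compute_rdkit_block("CCO")
  expect_length(v, 208L)
  expect_named(v)
  expect_equal(unname(v["MolWt"]), 46.07, tolerance = 1e-3)
  # heavy-atom count grows monotonically with chain length
  expect_lt(compute_rdkit_block("C")[["HeavyAtomCount"]],
            compute_rdkit_block("CC")[["HeavyAtomCount"]])
})

test_that("unparsable and empty SMILES raise featurization errors", {
  expect_error(compute_ecfp6("not_a_smiles"), class = "forgenet_featurize_error")
  expect_error(compute_maccs(""), class = "forgenet_featurize_error")
  bad <- data.frame(id = c("ok", "bad"), smiles = c("CCO", "xyz["),
                    label = c(1L, -1L))
  err <- expect_error(featurize_compounds(bad),
                      class = "forgenet_featurize_error")
  expect_match(conditionMessage(err), "bad")
})

test_that("fused matrix is 2423 wide with loss-free column provenance", {
  fx <- fixture_compounds()
  ff <- featurize_compounds(fx[c(2, 8, 12), ])
  expect_s3_class(ff, "fused_features")
  expect_identical(ncol(ff$matrix), 2423L)
  expect_identical(ff$blocks$end - ff$blocks$start + 1L, c(2048L, 167L, 208L))
  expect_identical(column_provenance(ff, 1)$block, "ECFP6")
  expect_identical(column_provenance(ff, 2049)$block, "MACCS")
  expect_identical(column_provenance(ff, 2216), list(block = "RDKIT", index = 1L))
  expect_identical(column_provenance(ff, 2423)$index, 208L)
  # every fused column maps back to exactly one block/index pair
  prov <- vapply(c(1, 500, 2048, 2049, 2215, 2216, 2423), function(j) {
    p <- column_provenance(ff, j)
    paste(p$block, p$index)
  }, character(1))
  expect_false(anyDuplicated(prov) > 0)
})

test_that("fusion validates block order, row counts and binary content", {
  e <- feature_block("ECFP6", matrix(0, 2, 8))
  m <- feature_block("MACCS", matrix(0, 2, 167))
  r <- feature_block("RDKIT", matrix(rnorm(6), 2, 3))
  fused <- fuse_blocks(list(e, m, r), standardize = FALSE)
  expect_identical(dim(fused$matrix), c(2L, 178L))
  expect_error(fuse_blocks(list(m, e, r)), class = "forgenet_fusion_error")
  r1 <- feature_block("RDKIT", matrix(0, 3, 3))
  expect_error(fuse_blocks(list(e, m, r1)), class = "forgenet_fusion_error")
  expect_error(feature_block("ECFP6", matrix(2, 1, 4)),
               class = "forgenet_featurize_error")
})

test_that("row permutation of all blocks permutes the fused matrix identically", {
  set.seed(7)
  mk <- function(perm) {
    e <- matrix(rbinom(5 * 8, 1, 0.3), 5, 8)[perm, ]
    m <- matrix(rbinom(5 * 167, 1, 0.1), 5, 167)[perm, ]
    r <- matrix(rnorm(5 * 3), 5, 3)[perm, ]
    list(e = e, m = m, r = r)
  }
  base <- mk(1:5)
  fuse_of <- function(b) {
    fuse_blocks(list(feature_block("ECFP6", b$e), feature_block("MACCS", b$m),
                     feature_block("RDKIT", b$r)), standardize = FALSE)$matrix
  }
  perm <- c(3, 1, 5, 2, 4)
  permuted <- list(e = base$e[perm, ], m = base$m[perm, ], r = base$r[perm, ])
  expect_identical(fuse_of(base)[perm, ], fuse_of(permuted))
})

test_that("RDKIT standardization uses training statistics only", {
  e <- feature_block("ECFP6", matrix(0, 4, 4))
  m <- feature_block("MACCS", matrix(0, 4, 167))
  r <- feature_block("RDKIT", matrix(c(1, 2, 3, 4, 10, 20, 30, 40), 4, 2))
  tr <- fuse_blocks(list(e, m, r), standardize = TRUE)
  idx <- tr$blocks$start[3]:tr$blocks$end[3]
  expect_equal(colMeans(tr$matrix[, idx]), c(0, 0), ignore_attr = TRUE)
  # refusing with the training stats leaves test columns off-center
  r_te <- feature_block("RDKIT", matrix(c(5, 6, 50, 60), 2, 2))
  e2 <- feature_block("ECFP6", matrix(0, 2, 4))
  m2 <- feature_block("MACCS", matrix(0, 2, 167))
  te <- fuse_blocks(list(e2, m2, r_te), standardize = TRUE,
                    stats = tr$rdkit_stats)
  expect_equal(te$matrix[1, idx[1]], (5 - 2.5) / sd(1:4))
})

test_that("feature TSV + manifest round-trips the fused object", {
  fx <- head(fixture_compounds(), 3)
  ff <- featurize_compounds(fx)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_features(ff, tsv)
  back <- read_features(tsv)
  expect_equal(back$matrix, ff$matrix, tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(back$labels, ff$labels)
  expect_identical(back$blocks$end, ff$blocks$end)
})

test_that("compound CSV reader maps label tokens and rejects junk", {
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,smiles,label", "a,CCO,active", "b,CCC,0", "c,CCN,1"), csv)
  df <- read_compounds(csv)
  expect_identical(df$label, c(1L, -1L, 1L))
  writeLines(c("id,smiles,label", "a,CCO,maybe"), csv)
  expect_error(read_compounds(csv), class = "forgenet_input_error")
})
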