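test_that("generated directions are unit, separated and near-uniform", {
  d6 <- generate_directions(6, seed = 0)
  expect_equal(sqrt(rowSums(d6^2)), rep(1, 6), tolerance = 1e-9)
  ## pairwise minimum angle (mod antipodal symmetry) above 10 degrees
  cosang <- abs(tcrossprod(d6))
  diag(cosang) <- 0
  expect_lt(max(cosang), cos(10 * pi / 180))

  d90 <- generate_directions(90, seed = 1)
  M <- crossprod(d90) / 90
  expect_lt(max(abs(M - diag(3) / 3)), 0.02)

  expect_error(generate_directions(4), "at least 6")
  expect_identical(generate_directions(20, seed = 5),
                   generate_directions(20, seed = 5))
})

test_that("HCP-like scheme has the protocol's volume bookkeeping", {
  sch <- hcp_scheme()
  expect_equal(length(sch$bvals), 288L)
  expect_equal(sum(sch$bvals > 0), 270L)
  expect_equal(sum(sch$bvals == 0), 18L)
  expect_setequal(sch$shells, c(1000, 2000, 3000))
  ## every direction unit, b0 placeholders zero
  dw <- sch$bvals > 0
  expect_equal(sqrt(rowSums(sch$bvecs[dw, ]^2)), rep(1, 270),
               tolerance = 1e-9)
  expect_true(all(sch$bvecs[!dw, ] == 0))
  ## shell_index partitions the DW volumes
  idx <- sort(unname(unlist(sch$shell_index)))
  expect_identical(idx, which(dw))

  small <- build_hcp_like_scheme(n_per_shell = 10, shells = 1000)
  expect_equal(length(small$bvals), 28L)
})

test_that("subset_scheme returns the named shells, order-preserved", {
  sch <- hcp_scheme()
  s1 <- subset_scheme(sch, "b_1000")
  expect_equal(length(s1$bvals), 108L)
  s23 <- subset_scheme(sch, "b_2000-3000")
  expect_equal(length(s23$bvals), 198L)
  expect_setequal(unique(s23$bvals), c(0, 2000, 3000))
  ## identity and idempotence
  expect_equal(subset_scheme(sch, "b_All")$bvals, sch$bvals)
  s1b <- subset_scheme(s1, "b_1000")
  expect_equal(s1b$bvals, s1$bvals)
  expect_equal(s1b$bvecs, s1$bvecs)
  ## order preserved
  expect_true(all(diff(attr(s23, "volume_index")) > 0))
  ## union of one-shell DW volumes reconstructs b_All's DW volumes
  dw_idx <- c(attr(subset_scheme(sch, "b_1000"), "volume_index"),
              attr(subset_scheme(sch, "b_2000"), "volume_index"),
              attr(subset_scheme(sch, "b_3000"), "volume_index"))
  dw_idx <- sort(unique(dw_idx[sch$bvals[dw_idx] > 0]))
  expect_identical(dw_idx, which(sch$bvals > 0))
  ## all seven labels constructible
  for (lab in scheme_labels())
    expect_s3_class(subset_scheme(sch, lab), "gradient_scheme")
  expect_error(subset_scheme(sch, "b_9000"), "lacks shell")
  expect_error(subset_scheme(sch, "nonsense"), "unknown")
})

test_that("bval/bvec files round-trip and validate", {
  sch <- hcp_scheme()
  bval <- tempfile(fileext = ".bval"); bvec <- tempfile(fileext = ".bvec")
  write_bval_bvec(sch, bval, bvec)
  back <- read_bval_bvec(bval, bvec, name = "b_All")
  expect_identical(back$bvals, sch$bvals)
  expect_identical(back$bvecs, sch$bvecs)
  ## re-write is bit-identical
  bval2 <- tempfile(); bvec2 <- tempfile()
  write_bval_bvec(back, bval2, bvec2)
  expect_identical(readLines(bval), readLines(bval2))
  expect_identical(readLines(bvec), readLines(bvec2))

  ## non-unit column triggers renormalisation warning
  writeLines("0 1000", bval)
  writeLines(c("0 0.999", "0 0", "0 0"), bvec)
  expect_warning(s <- read_bval_bvec(bval, bvec), "renormalising")
  expect_equal(sqrt(sum(s$bvecs[2, ]^2)), 1)

  ## column mismatch errors
  writeLines("0 1000 2000", bval)
  expect_error(read_bval_bvec(bval, bvec), "column counts")

  ## shell snapping within 50 s/mm2
  writeLines("5 995 1005", bval)
  writeLines(c("0 1 0", "0 0 1", "0 0 0"), bvec)
  s <- read_bval_bvec(bval, bvec)
  expect_equal(sort(unique(s$bvals)), c(0, 1000))
})
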