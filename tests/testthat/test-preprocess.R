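mkStudy <- function(id = "s1", dims = c(5, 12, 12), seed = 1, views = NULL) {
  set.seed(seed)
  if (is.null(views)) {
    views <- lapply(1:3, function(i) array(rnorm(prod(dims)), dims))
    names(views) <- c("sagittal", "coronal", "axial")
  }
  structure(list(examId = id, views = views,
                 labels = c(abnormal = 1L, acl = 0L, meniscus = 1L)),
            class = "RawStudy")
}

test_that("deduplication keeps the first occurrence and is idempotent", {
  a <- mkStudy("a", seed = 1)
  aCopy <- mkStudy("a", seed = 1)
  b <- mkStudy("b", seed = 2)
  expect_identical(dedupeStudies(list(a, aCopy, b)), list(a, b))
  expect_identical(dedupeStudies(list(a, b)), list(a, b))
  once <- dedupeStudies(list(a, aCopy, b, b))
  expect_identical(dedupeStudies(once), once)
  # same id, different content: both survive
  a2 <- mkStudy("a", seed = 3)
  expect_length(dedupeStudies(list(a, a2)), 2L)
  expect_identical(dedupeStudies(list()), list())
})

test_that("validation enumerates every failed check", {
  good <- mkStudy()
  chk <- validateStudy(good)
  expect_true(chk$accepted)
  expect_length(chk$reasons, 0L)

  noAxial <- good
  noAxial$views$axial <- NULL
  chk <- validateStudy(noAxial)
  expect_false(chk$accepted)
  expect_identical(chk$reasons, "missing view: axial")

  bad <- good
  bad$views$coronal[2, 3, 4] <- NaN
  bad$views$sagittal <- NULL
  chk <- validateStudy(bad)
  expect_false(chk$accepted)
  expect_setequal(chk$reasons, c("missing view: sagittal",
                                 "view coronal: non-finite values"))
})

test_that("slice sampling follows the uniform index rule exactly", {
  stamp <- function(n) array(as.numeric(0:(n - 1)), c(n, 1, 1))
  sampled <- function(n, S) as.vector(sampleSlices(stamp(n), S))
  expect_identical(sampled(32, 32), as.numeric(0:31))
  expect_identical(sampled(64, 32), as.numeric(seq(0, 62, by = 2)))
  expect_identical(sampled(3, 8), c(0, 0, 0, 1, 1, 1, 2, 2))
  # property over a small exhaustive grid: formula, monotonicity, coverage
  for (n in c(1, 2, 3, 5, 8, 12))
    for (S in c(1, 2, 3, 5, 8, 12)) {
      got <- sampled(n, S)
      expect_identical(got, floor((0:(S - 1)) * n / S))
      expect_true(all(diff(got) >= 0))
      expect_identical(got[1], 0)
    }
  expect_error(sampleSlices(array(0, c(0, 2, 2)), 4), "nonempty")
})

test_that("resize and crop preserve identities and means", {
  set.seed(8)
  v <- array(rnorm(4 * 16 * 16), c(4, 16, 16))
  expect_equal(resizeAndCrop(v, 16, 1), v, tolerance = 1e-6)
  const <- array(3.7, c(2, 10, 14))
  out <- resizeAndCrop(const, 8, 1)
  expect_equal(dim(out), c(2, 8, 8))
  expect_equal(as.vector(out), rep(3.7, 2 * 64), tolerance = 1e-12)
  # 2R x 2R checkerboard down to R: each output pixel averages a 2x2 block
  R <- 6L
  cb <- outer(1:(2 * R), 1:(2 * R), function(i, j) (i + j) %% 2)
  vol <- array(cb, c(1, 2 * R, 2 * R))
  small <- resizeAndCrop(vol, R, 1)
  expect_equal(mean(small), mean(cb), tolerance = 1e-6)
  expect_equal(as.vector(small), rep(0.5, R * R), tolerance = 1e-12)
})

test_that("per-study normalization matches the z-score closed form", {
  cons <- lapply(1:3, function(i) array(5, c(2, 3, 3)))
  names(cons) <- c("sagittal", "coronal", "axial")
  nm <- normalizeStudy(cons)
  expect_true(nm$degenerate)
  expect_true(all(vapply(nm$views, function(v) all(v == 0), TRUE)))

  # pixels {1,2,3}: population z-scores +/-1.2247, 0 (invariant to the
  # preliminary min-max scaling)
  tri <- list(sagittal = array(1, c(1, 1, 1)), coronal = array(2, c(1, 1, 1)),
              axial = array(3, c(1, 1, 1)))
  nm <- normalizeStudy(tri)
  expect_equal(unlist(nm$views, use.names = FALSE),
               c(-1.2247, 0, 1.2247), tolerance = 1e-4)

  set.seed(2)
  rnd <- lapply(1:3, function(i) array(runif(4 * 5 * 5, 10, 50), c(4, 5, 5)))
  names(rnd) <- c("sagittal", "coronal", "axial")
  nm <- normalizeStudy(rnd)
  allv <- unlist(nm$views, use.names = FALSE)
  expect_lt(abs(mean(allv)), 1e-6)
  expect_lt(abs(sqrt(mean((allv - mean(allv))^2)) - 1), 1e-6)
  expect_false(nm$degenerate)
})

test_that("augmentation is consistent per view, seeded, and label-preserving", {
  ex <- tinyExams(1L, seed = 40L)[[1]]
  set.seed(1)
  ident <- augmentExam(ex, rotate_degrees = 0, flip_prob = 0)
  expect_identical(ident@views, ex@views)
  expect_identical(ident@labels, ex@labels)
  # flip is an involution
  m <- matrix(1:12, 3, 4)
  expect_identical(TriViewMIL:::flipSliceH(TriViewMIL:::flipSliceH(m)), m)
  # same seed, same draw
  set.seed(99); a <- augmentExam(ex)
  set.seed(99); b <- augmentExam(ex)
  expect_identical(a@views, b@views)
  # all slices of a view share one transform: a flipped-only view matches
  # slice-wise flipping of the original
  set.seed(5)
  fl <- augmentExam(ex, rotate_degrees = 0, flip_prob = 1)
  v1 <- ex@views$sagittal
  got <- fl@views$sagittal
  for (s in seq_len(dim(v1)[1]))
    expect_identical(got[s, , ], TriViewMIL:::flipSliceH(v1[s, , ]))
})

test_that("the pipeline always emits (3, S, R, R) with a faithful manifest", {
  cfg <- preprocessConfig(S = 6L, R = 16L)
  studies <- list(mkStudy("a", dims = c(3, 20, 24), seed = 1),
                  mkStudy("b", dims = c(11, 16, 16), seed = 2),
                  mkStudy("c", dims = c(7, 30, 18), seed = 3))
  studies[[3]]$views$axial <- NULL           # one rejected study
  res <- preprocessDataset(studies, cfg,
                           manifestPath = f <- tempfile(fileext = ".jsonl"))
  expect_length(res$exams, 2L)
  for (e in res$exams) {
    expect_s4_class(e, "ExamTensor")
    for (v in e@views) expect_equal(dim(v), c(6, 16, 16))
  }
  expect_identical(res$manifest$accepted, c(TRUE, TRUE, FALSE))
  expect_match(res$manifest$reasons[3], "missing view: axial")
  lines <- readLines(f)
  expect_length(lines, 3L)
  rec <- jsonlite::fromJSON(lines[3])
  expect_false(rec$accepted)
  # determinism of the full pipeline
  res2 <- preprocessDataset(studies, cfg)
  expect_identical(lapply(res$exams, function(e) e@views),
                   lapply(res2$exams, function(e) e@views))
})
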