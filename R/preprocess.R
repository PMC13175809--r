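## Deterministic study-level cleaning, validation, standardization, slice
## sampling and augmentation, producing fixed-shape exam tensors.

#' Preprocessing configuration
#'
#' @param S slices kept per view after uniform sampling (benchmark value 32).
#' @param R output resolution in pixels (benchmark value 224).
#' @param crop_fraction center-crop field of view as a fraction of the resized
#'   extent, in (0, 1]; slices are resized to `round(R / crop_fraction)` per
#'   side and then center-cropped to `R x R`.
#' @param rotate_degrees maximum in-plane augmentation rotation (degrees,
#'   sampled uniformly in +/- this range, one angle per view).
#' @param flip_prob horizontal flip probability (one decision per view).
#' @param seed integer RNG seed for augmentation.
#' @return validated config list of class `PreprocessConfig`.
#' @export
preprocessConfig <- function(S = 32L, R = 224L, crop_fraction = 1,
                             rotate_degrees = 10, flip_prob = 0.5, seed = 1L) {
  cfg <- list(S = as.integer(S), R = as.integer(R),
              crop_fraction = crop_fraction, rotate_degrees = rotate_degrees,
              flip_prob = flip_prob, seed = as.integer(seed))
  if (is.na(cfg$S) || cfg$S < 1L) stop("preprocessConfig: S must be >= 1")
  if (is.na(cfg$R) || cfg$R < 8L) stop("preprocessConfig: R must be >= 8")
  if (!is.numeric(crop_fraction) || crop_fraction <= 0 || crop_fraction > 1)
    stop("preprocessConfig: crop_fraction must be in (0, 1]")
  if (rotate_degrees < 0) stop("preprocessConfig: rotate_degrees must be >= 0")
  if (flip_prob < 0 || flip_prob > 1)
    stop("preprocessConfig: flip_prob must be in [0, 1]")
  class(cfg) <- "PreprocessConfig"
  cfg
}

studyContentHash <- function(study) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(list(study$examId, study$views), con)
  close(con)
  unname(tools::md5sum(f))
}

#' Remove duplicate studies
#'
#' Hashes each study's identifier together with its ordered view contents and
#' keeps the first occurrence of each hash, preserving the order of survivors.
#' Idempotent.
#'
#' @param studies list of `RawStudy`.
#' @return list of `RawStudy` with exact duplicates removed.
#' @export
dedupeStudies <- function(studies) {
  if (length(studies) == 0L) return(studies)
  hashes <- vapply(studies, studyContentHash, "")
  studies[!duplicated(hashes)]
}

#' Validate a raw study
#'
#' A study is accepted iff all three views are present and every view is a
#' rank-3 array with positive spatial dimensions and only finite values.
#' Rejection is a value, not an error: every failed check is enumerated.
#'
#' @param study a `RawStudy`.
#' @return list with `accepted` (logical) and `reasons` (character vector,
#'   empty when accepted).
#' @export
validateStudy <- function(study) {
  reasons <- character()
  for (v in VIEW_NAMES) {
    a <- study$views[[v]]
    if (is.null(a)) {
      reasons <- c(reasons, paste0("missing view: ", v))
      next
    }
    if (!is.array(a) || length(dim(a)) != 3L) {
      reasons <- c(reasons, paste0("view ", v, ": not a rank-3 array"))
      next
    }
    if (any(dim(a) < 1L))
      reasons <- c(reasons, paste0("view ", v, ": non-positive dimensions"))
    else if (!all(is.finite(a)))
      reasons <- c(reasons, paste0("view ", v, ": non-finite values"))
  }
  list(accepted = length(reasons) == 0L, reasons = reasons)
}

#' Uniformly sample a fixed number of slices
#'
#' Output slice k (0-based) is input slice `floor(k * n / S)`, which strides
#' through the stack when `n >= S` and repeats slices when `n < S`; the
#' identity when `n == S`. Monotone and order-preserving.
#'
#' @param volume rank-3 array, slices first.
#' @param S number of output slices.
#' @return rank-3 array with `S` slices.
#' @export
sampleSlices <- function(volume, S) {
  if (!is.array(volume) || length(dim(volume)) != 3L || dim(volume)[1] < 1L)
    stop("sampleSlices: volume must be a nonempty rank-3 array")
  S <- as.integer(S)
  if (is.na(S) || S < 1L) stop("sampleSlices: S must be >= 1")
  n <- dim(volume)[1]
  idx <- floor(seq.int(0L, S - 1L) * n / S) + 1L
  volume[idx, , , drop = FALSE]
}

sliceSampleIndices <- function(n, S) floor(seq.int(0L, S - 1L) * n / S) + 1L

## 1-D bilinear interpolation weights (half-pixel-center convention) as an
## n_out x n_in matrix, so resizing is two matrix products
resizeMatrix <- function(nIn, nOut) {
  W <- matrix(0, nOut, nIn)
  x <- (seq_len(nOut) - 0.5) * nIn / nOut - 0.5
  x0 <- floor(x)
  tfrac <- x - x0
  lo <- pmin(pmax(x0, 0), nIn - 1)
  hi <- pmin(x0 + 1, nIn - 1)
  for (i in seq_len(nOut)) {
    W[i, lo[i] + 1] <- W[i, lo[i] + 1] + (1 - tfrac[i])
    W[i, hi[i] + 1] <- W[i, hi[i] + 1] + tfrac[i]
  }
  W
}

#' Resize and center-crop every slice of a volume
#'
#' Each slice is bilinearly resized (half-pixel-center convention, applied as
#' interpolation-weight matrix products) to `round(R / crop_fraction)` pixels
#' per side, then center-cropped to `R x R`. The same transform is applied to
#' all slices.
#'
#' @param volume rank-3 array (slices x rows x cols).
#' @param R output side length.
#' @param crop_fraction center-crop fraction in (0, 1].
#' @return rank-3 array (slices x R x R).
#' @export
resizeAndCrop <- function(volume, R, crop_fraction = 1) {
  if (!is.array(volume) || length(dim(volume)) != 3L)
    stop("resizeAndCrop: volume must be a rank-3 array")
  R <- as.integer(R)
  target <- as.integer(round(R / crop_fraction))
  if (target < R)
    stop("resizeAndCrop: crop size R exceeds the post-resize extent")
  d <- dim(volume)
  Wr <- resizeMatrix(d[2], target)
  Wc <- resizeMatrix(d[3], target)
  start <- (target - R) %/% 2L
  keep <- start + seq_len(R)
  out <- array(0, c(d[1], R, R))
  for (s in seq_len(d[1])) {
    rs <- Wr %*% volume[s, , ] %*% t(Wc)
    out[s, , ] <- rs[keep, keep]
  }
  out
}

#' Per-study z-score normalization
#'
#' Intensities are first min-max scaled to [0, 1] over the whole study, then
#' z-scored with one mean and one population standard deviation computed over
#' all pixels of all three views. Constant (degenerate) studies map to all
#' zeros via the sd floor.
#'
#' @param views named list of three rank-3 arrays.
#' @param sdFloor lower bound on the standard deviation (default 1e-8).
#' @return list with `views` (normalized), `mean`, `sd` (of the scaled
#'   intensities), and `degenerate` flag.
#' @export
normalizeStudy <- function(views, sdFloor = 1e-8) {
  allv <- unlist(lapply(views, as.vector), use.names = FALSE)
  if (length(allv) == 0L) stop("normalizeStudy: study has no pixels")
  rng <- range(allv)
  scale <- max(rng[2] - rng[1], sdFloor)
  degenerate <- (rng[2] - rng[1]) < sdFloor
  views <- lapply(views, function(v) (v - rng[1]) / scale)
  allv <- (allv - rng[1]) / scale
  mu <- mean(allv)
  sdv <- sqrt(mean((allv - mu)^2))          # population convention
  degenerate <- degenerate || sdv < sdFloor
  denom <- max(sdv, sdFloor)
  views <- lapply(views, function(v)
    if (degenerate) array(0, dim(v)) else (v - mu) / denom)
  list(views = views, mean = mu, sd = sdv, degenerate = degenerate)
}

flipSliceH <- function(mat) mat[, rev(seq_len(ncol(mat))), drop = FALSE]

## in-plane rotation about the slice center, bilinear resampling, zero fill
rotateSlice <- function(mat, degrees) {
  if (degrees == 0) return(mat)
  nr <- nrow(mat); nc <- ncol(mat)
  th <- degrees * pi / 180
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  gr <- matrix(seq_len(nr), nr, nc) - cy
  gc <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - cx
  sy <- cos(th) * gr + sin(th) * gc + cy     # inverse mapping
  sx <- -sin(th) * gr + cos(th) * gc + cx
  y0 <- floor(sy); x0 <- floor(sx)
  ty <- sy - y0; tx <- sx - x0
  at <- function(yy, xx) {
    ok <- yy >= 1 & yy <= nr & xx >= 1 & xx <= nc
    v <- numeric(length(yy))
    v[ok] <- mat[cbind(yy[ok], xx[ok])]
    v
  }
  v <- (1 - ty) * (1 - tx) * at(y0, x0) + (1 - ty) * tx * at(y0, x0 + 1) +
    ty * (1 - tx) * at(y0 + 1, x0) + ty * tx * at(y0 + 1, x0 + 1)
  matrix(v, nr, nc)
}

#' Consistent geometric augmentation of an exam
#'
#' Samples one rotation angle (uniform in +/- `rotate_degrees`) and one
#' horizontal-flip decision per view from the current RNG stream and applies
#' them identically to every slice of that view. Labels are untouched.
#' Intended for training mode only.
#'
#' @param exam an [ExamTensor-class].
#' @param rotate_degrees maximum rotation angle (degrees).
#' @param flip_prob horizontal flip probability.
#' @return augmented `ExamTensor`.
#' @export
augmentExam <- function(exam, rotate_degrees = 10, flip_prob = 0.5) {
  views <- exam@views
  for (v in VIEW_NAMES) {
    ang <- if (rotate_degrees > 0) stats::runif(1, -rotate_degrees, rotate_degrees) else 0
    flip <- stats::runif(1) < flip_prob
    a <- views[[v]]
    for (s in seq_len(dim(a)[1])) {
      sl <- a[s, , ]
      if (ang != 0) sl <- rotateSlice(sl, ang)
      if (flip) sl <- flipSliceH(sl)
      a[s, , ] <- sl
    }
    views[[v]] <- a
  }
  methods::initialize(exam, views = views)
}

#' Preprocess one validated study into a fixed-shape exam tensor
#'
#' Applies uniform slice sampling, bilinear resize + center crop, and
#' per-study z-score normalization. Rejected studies return `NULL` with the
#' rejection reasons attached via the manifest of [preprocessDataset()].
#'
#' @param study a `RawStudy` (or `SynthExam`).
#' @param config a [preprocessConfig()].
#' @return an [ExamTensor-class], or `NULL` when the study fails validation.
#' @export
preprocessStudy <- function(study, config) {
  chk <- validateStudy(study)
  if (!chk$accepted) return(NULL)
  views <- lapply(study$views[VIEW_NAMES], function(v)
    resizeAndCrop(sampleSlices(v, config$S), config$R, config$crop_fraction))
  nm <- normalizeStudy(views)
  lbl <- stats::setNames(rep(NA_integer_, 3L), LABEL_NAMES)
  if (!is.null(study$labels))
    lbl[names(study$labels)] <- as.integer(study$labels)
  methods::new("ExamTensor", examId = study$examId, views = nm$views,
               normMean = nm$mean, normSd = nm$sd, degenerate = nm$degenerate,
               labels = lbl)
}

#' Preprocess a collection of studies
#'
#' Deduplicates, validates and standardizes every study; returns the accepted
#' exam tensors plus a manifest row per input study.
#'
#' @param studies list of `RawStudy`.
#' @param config a [preprocessConfig()].
#' @param manifestPath optional path; when given, the manifest is written as
#'   JSON lines (exam_id, accepted, reasons, normalization record).
#' @return list with `exams` (list of [ExamTensor-class]) and `manifest`
#'   (data.frame).
#' @export
preprocessDataset <- function(studies, config, manifestPath = NULL) {
  studies <- dedupeStudies(studies)
  exams <- list()
  rows <- vector("list", length(studies))
  for (i in seq_along(studies)) {
    st <- studies[[i]]
    chk <- validateStudy(st)
    et <- if (chk$accepted) preprocessStudy(st, config) else NULL
    if (!is.null(et)) exams[[length(exams) + 1L]] <- et
    rows[[i]] <- list(exam_id = st$examId, accepted = chk$accepted,
                      reasons = chk$reasons,
                      norm_mean = if (is.null(et)) NA_real_ else et@normMean,
                      norm_sd = if (is.null(et)) NA_real_ else et@normSd)
  }
  manifest <- data.frame(
    exam_id = vapply(rows, `[[`, "", "exam_id"),
    accepted = vapply(rows, `[[`, TRUE, "accepted"),
    reasons = vapply(rows, function(r) paste(r$reasons, collapse = "; "), ""),
    norm_mean = vapply(rows, `[[`, 1, "norm_mean"),
    norm_sd = vapply(rows, `[[`, 1, "norm_sd"),
    stringsAsFactors = FALSE)
  if (!is.null(manifestPath)) {
    con <- file(manifestPath, "w")
    for (r in rows)
      writeLines(jsonlite::toJSON(r, auto_unbox = TRUE, null = "null"), con)
    close(con)
  }
  list(exams = exams, manifest = manifest)
}
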