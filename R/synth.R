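## Synthetic three-view exam generator in the MRNet directory layout.
##
## Emulates the public benchmark's structure only: per exam, three stacked
## grayscale slice arrays (sagittal/coronal/axial) with variable slice counts,
## three exam-level binary labels obeying the tear-implies-abnormal hierarchy,
## and a planted, label-dependent bright ellipsoidal lesion so that learned
## aggregation/fusion has a recoverable signal. No MRI physics is simulated.

#' Configuration for the synthetic exam generator
#'
#' @param n_exams number of exams to generate.
#' @param prevalence_acl,prevalence_meniscus marginal probabilities of the two
#'   tear labels (drawn independently).
#' @param p_abnormal_extra probability that an exam with no tear is still
#'   abnormal (lesion planted in one random view).
#' @param slice_count_range integer interval for per-view slice counts.
#' @param base_resolution raw pixels per side.
#' @param signal_delta lesion intensity offset in units of `noise_sd`.
#' @param noise_sd standard deviation of the Gaussian background around the
#'   mid-gray level 0.5.
#' @param seed integer RNG seed; per-exam substreams are derived from it by
#'   counter, so exam i is identical regardless of generation order.
#' @return validated config list of class `SynthConfig`.
#' @export
synthConfig <- function(n_exams = 100L, prevalence_acl = 0.20,
                        prevalence_meniscus = 0.35, p_abnormal_extra = 0.50,
                        slice_count_range = c(20L, 48L),
                        base_resolution = 64L, signal_delta = 3.0,
                        noise_sd = 0.1, seed = 1L) {
  cfg <- list(n_exams = as.integer(n_exams), prevalence_acl = prevalence_acl,
              prevalence_meniscus = prevalence_meniscus,
              p_abnormal_extra = p_abnormal_extra,
              slice_count_range = as.integer(slice_count_range),
              base_resolution = as.integer(base_resolution),
              signal_delta = signal_delta, noise_sd = noise_sd,
              seed = as.integer(seed))
  chkProb <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop("synthConfig: field '", field, "' must be a probability in [0,1]")
  }
  chkProb("prevalence_acl"); chkProb("prevalence_meniscus")
  chkProb("p_abnormal_extra")
  if (is.na(cfg$n_exams) || cfg$n_exams < 0L)
    stop("synthConfig: field 'n_exams' must be a nonnegative count")
  if (length(cfg$slice_count_range) != 2L || any(is.na(cfg$slice_count_range)) ||
      cfg$slice_count_range[1] < 1L ||
      cfg$slice_count_range[1] > cfg$slice_count_range[2])
    stop("synthConfig: field 'slice_count_range' must be an integer interval with min >= 1")
  if (is.na(cfg$base_resolution) || cfg$base_resolution < 8L)
    stop("synthConfig: field 'base_resolution' must be >= 8")
  if (!is.numeric(cfg$signal_delta) || is.na(cfg$signal_delta) || cfg$signal_delta < 0)
    stop("synthConfig: field 'signal_delta' must be >= 0")
  if (!is.numeric(cfg$noise_sd) || is.na(cfg$noise_sd) || cfg$noise_sd <= 0)
    stop("synthConfig: field 'noise_sd' must be > 0")
  if (is.na(cfg$seed)) stop("synthConfig: field 'seed' must be an integer")
  class(cfg) <- "SynthConfig"
  cfg
}

## round a numeric vector/array to exact float32 values so that the float32
## NPY files on disk round-trip bit-for-bit with the in-memory arrays
quantizeF32 <- function(x) {
  v <- readBin(writeBin(as.vector(x), raw(), size = 4L), "numeric",
               n = length(x), size = 4L)
  if (!is.null(dim(x))) dim(v) <- dim(x)
  v
}

derivedSeed <- function(seed, counter) {
  as.integer((as.double(seed) * 1000003 + counter) %% 2147483647)
}

## add delta inside a random ellipsoid spanning a contiguous slice band,
## centered within the central half of the volume
plantLesion <- function(vol, delta) {
  d <- dim(vol)
  ctr <- c(stats::runif(1, 0.3, 0.7) * d[1],
           stats::runif(1, 0.3, 0.7) * d[2],
           stats::runif(1, 0.3, 0.7) * d[3])
  semi <- c(max(1.5, stats::runif(1, 0.15, 0.30) * d[1]),
            stats::runif(1, 0.12, 0.22) * d[2],
            stats::runif(1, 0.12, 0.22) * d[3])
  ds <- ((seq_len(d[1]) - ctr[1]) / semi[1])^2
  dr <- ((seq_len(d[2]) - ctr[2]) / semi[2])^2
  dc <- ((seq_len(d[3]) - ctr[3]) / semi[3])^2
  mask <- outer(outer(ds, dr, "+"), dc, "+") <= 1
  prev <- attr(vol, "lesions")
  vol[mask] <- vol[mask] + delta
  attr(vol, "lesions") <- c(prev, list(list(center = ctr, semi = semi,
                                            voxels = sum(mask))))
  vol
}

#' Ellipsoid lesion mask from recorded lesion geometry
#'
#' Reconstructs the logical voxel mask of one planted lesion from the
#' metadata attached to a generated view (attribute `"lesions"`).
#'
#' @param dims view dimensions (slices, rows, cols).
#' @param lesion one element of `attr(view, "lesions")`.
#' @return logical array of shape `dims`.
#' @export
lesionMask <- function(dims, lesion) {
  ds <- ((seq_len(dims[1]) - lesion$center[1]) / lesion$semi[1])^2
  dr <- ((seq_len(dims[2]) - lesion$center[2]) / lesion$semi[2])^2
  dc <- ((seq_len(dims[3]) - lesion$center[3]) / lesion$semi[3])^2
  outer(outer(ds, dr, "+"), dc, "+") <= 1
}

#' Generate a synthetic exam dataset
#'
#' Draws labels per exam (tears independently at the configured prevalences;
#' a no-tear exam is abnormal with probability `p_abnormal_extra`), generates
#' Gaussian-background volumes for the three views with per-view slice counts
#' in `slice_count_range`, and plants a bright ellipsoid
#' (`signal_delta * noise_sd` above background) in a label-specific view
#' subset: ACL in sagittal+coronal, meniscus in coronal+axial, extra-abnormal
#' in one random view. The label hierarchy (tear implies abnormal) holds by
#' construction.
#'
#' @param config a [synthConfig()].
#' @param idOffset integer added to exam numbering (to keep ids disjoint
#'   across splits generated from separate configs).
#' @return list with `exams` (list of `SynthExam`: examId, views, labels) and
#'   `labels` (data.frame exam_id/abnormal/acl/meniscus).
#' @export
generateDataset <- function(config, idOffset = 0L) {
  if (!inherits(config, "SynthConfig")) config <- do.call(synthConfig, config)
  res <- config$base_resolution
  delta <- config$signal_delta * config$noise_sd
  exams <- vector("list", config$n_exams)
  for (i in seq_len(config$n_exams)) {
    set.seed(derivedSeed(config$seed, i + idOffset))
    acl <- stats::rbinom(1, 1, config$prevalence_acl)
    men <- stats::rbinom(1, 1, config$prevalence_meniscus)
    extra <- if (acl == 0 && men == 0)
      stats::rbinom(1, 1, config$p_abnormal_extra) else 0L
    abnormal <- as.integer(acl == 1L || men == 1L || extra == 1L)
    nsl <- sample(seq.int(config$slice_count_range[1], config$slice_count_range[2]),
                  3L, replace = TRUE)
    views <- lapply(nsl, function(s)
      array(stats::rnorm(s * res * res, 0.5, config$noise_sd), c(s, res, res)))
    names(views) <- VIEW_NAMES
    target <- list()
    if (acl == 1L) target <- c(target, list("sagittal", "coronal"))
    if (men == 1L) target <- c(target, list("coronal", "axial"))
    if (extra == 1L) target <- c(target, list(VIEW_NAMES[sample.int(3L, 1L)]))
    for (v in unique(unlist(target)))
      views[[v]] <- plantLesion(views[[v]], delta)
    views <- lapply(views, function(v) {
      q <- quantizeF32(v)
      attr(q, "lesions") <- attr(v, "lesions")
      q
    })
    exams[[i]] <- structure(
      list(examId = sprintf("%04d", i + idOffset - 1L), views = views,
           labels = c(abnormal = abnormal, acl = acl, meniscus = men)),
      class = "SynthExam")
  }
  labels <- data.frame(
    exam_id = vapply(exams, function(e) e$examId, ""),
    abnormal = vapply(exams, function(e) e$labels[["abnormal"]], 1L),
    acl = vapply(exams, function(e) e$labels[["acl"]], 1L),
    meniscus = vapply(exams, function(e) e$labels[["meniscus"]], 1L),
    stringsAsFactors = FALSE)
  list(exams = exams, labels = labels)
}

#' Write a dataset in the MRNet-style directory layout
#'
#' Produces `<root>/<split>/<view>/<exam_id>.npy` (rank-3 float32 arrays,
#' slices first) and `<root>/<split>-<label>.csv` (two headerless columns:
#' exam_id, value).
#'
#' @param dataset result of [generateDataset()].
#' @param root output directory (created if needed).
#' @param split split name, conventionally train/valid/test.
#' @return `root`, invisibly.
#' @export
writeMRNetLayout <- function(dataset, root, split = "train") {
  if (length(dataset$exams) == 0L)
    stop("writeMRNetLayout: dataset is empty, nothing written")
  if (!dir.exists(root) && !dir.create(root, recursive = TRUE))
    stop("writeMRNetLayout: cannot create output directory: ", root)
  for (v in VIEW_NAMES) {
    d <- file.path(root, split, v)
    if (!dir.exists(d) && !dir.create(d, recursive = TRUE))
      stop("writeMRNetLayout: cannot create output directory: ", d)
  }
  for (e in dataset$exams)
    for (v in VIEW_NAMES)
      writeNpy(e$views[[v]], file.path(root, split, v, paste0(e$examId, ".npy")),
               dtype = "float32")
  for (lb in LABEL_NAMES)
    utils::write.table(dataset$labels[, c("exam_id", lb)],
                       file.path(root, paste0(split, "-", lb, ".csv")),
                       sep = ",", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  invisible(root)
}

#' Read an MRNet-style directory layout
#'
#' Inverse of [writeMRNetLayout()]: collects all exam ids present under any
#' view directory, loads whichever view files exist for each (missing views
#' are left absent so [validateStudy()] can reject the study), and attaches
#' labels from the split's CSV files when present.
#'
#' @param root dataset root directory.
#' @param split split name.
#' @return list of `RawStudy` (examId, views, labels).
#' @export
readMRNetLayout <- function(root, split = "train") {
  base <- file.path(root, split)
  if (!dir.exists(base)) stop("readMRNetLayout: no such split directory: ", base)
  ids <- sort(unique(unlist(lapply(VIEW_NAMES, function(v)
    sub("\\.npy$", "", list.files(file.path(base, v), pattern = "\\.npy$"))))))
  labels <- NULL
  for (lb in LABEL_NAMES) {
    f <- file.path(root, paste0(split, "-", lb, ".csv"))
    if (file.exists(f)) {
      tb <- utils::read.table(f, sep = ",", header = FALSE,
                              colClasses = c("character", "integer"))
      lbv <- stats::setNames(tb[[2]], tb[[1]])
      labels <- if (is.null(labels)) data.frame(exam_id = names(lbv), row.names = names(lbv)) else labels
      labels[[lb]] <- lbv[rownames(labels)]
    }
  }
  lapply(ids, function(id) {
    views <- list()
    for (v in VIEW_NAMES) {
      f <- file.path(base, v, paste0(id, ".npy"))
      if (file.exists(f)) views[[v]] <- readNpy(f)
    }
    lbl <- stats::setNames(rep(NA_integer_, 3L), LABEL_NAMES)
    if (!is.null(labels) && id %in% rownames(labels))
      for (lb in intersect(LABEL_NAMES, colnames(labels)))
        lbl[[lb]] <- as.integer(labels[id, lb])
    structure(list(examId = id, views = views, labels = lbl),
              class = "RawStudy")
  })
}
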