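## Anterior-commissure-normalized intensity statistics over nucleus masks:
## normalization, per-region summaries, age correlation, two-group
## comparison and Cook's-distance outlier screening.

#' Normalize a volume to the anterior commissure intensity
#'
#' Divides every voxel by the mean intensity over the supplied AC mask (in
#' practice the widest coronal strip of the anterior commissure, a
#' structure whose intensity does not drift with age), so the normalized AC
#' region has mean 1 and all downstream statistics are invariant to global
#' intensity rescaling of the raw volume.
#'
#' @param volume an \code{\link{MRVolume}} (typically an
#'   \code{\link{SWIVolume}})
#' @param acMask logical array matching the volume, marking AC voxels
#' @return list with \code{volume} (normalized, same class) and
#'   \code{acMean}
#' @export
acNormalize <- function(volume, acMask) {
  stopifnot(is(volume, "MRVolume"))
  if (!identical(dim(acMask), dim(volume@data)))
    stop("acMask must match the volume dimensions")
  if (!any(acMask)) stop("acMask is empty")
  acMean <- mean(volume@data[acMask], na.rm = TRUE)
  if (!is.finite(acMean) || acMean <= 0)
    stop(sprintf("AC mean intensity must be positive, got %.4g", acMean))
  out <- volume
  out@data <- volume@data / acMean
  list(volume = out, acMean = acMean)
}

#' Per-nucleus intensity summaries
#'
#' Mean, SD and voxel count of a (normalized) volume over each labeled
#' region. The SD convention defaults to the population SD (divide by N);
#' the sample convention (N - 1) is available via \code{sd}.
#'
#' @param volume an \code{\link{MRVolume}}
#' @param labels a \code{\link{LabelVolume}} on the same grid, or a named
#'   list of logical masks
#' @param sd \code{"population"} or \code{"sample"}
#' @return data.frame with columns nucleus, mean, sd, voxels
#' @export
regionStats <- function(volume, labels, sd = c("population", "sample")) {
  sd <- match.arg(sd)
  stopifnot(is(volume, "MRVolume"))
  masks <- if (is(labels, "LabelVolume")) {
    if (!identical(dim(labels@data), dim(volume@data)))
      stop("label volume must match the intensity volume dimensions")
    stats::setNames(
      lapply(labels@labelTable$code, function(cd) labels@data == cd),
      labels@labelTable$name)
  } else labels
  rows <- lapply(names(masks), function(nm) {
    v <- volume@data[masks[[nm]]]
    v <- v[!is.na(v)]
    if (length(v) == 0) {
      warning(sprintf("region '%s' is empty; excluded", nm))
      return(NULL)
    }
    m <- mean(v)
    s <- if (sd == "population") sqrt(mean((v - m)^2)) else stats::sd(v)
    if (length(v) == 1 && sd == "sample") s <- 0
    data.frame(nucleus = nm, mean = m, sd = s, voxels = length(v))
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' Age correlation of nucleus intensity
#'
#' Pearson correlation between subject age and per-subject mean normalized
#' intensity for one nucleus, with the two-sided p-value from the exact t
#' reference distribution, \eqn{t = r \sqrt{df} / \sqrt{1 - r^2}},
#' df = n - 2.
#'
#' @param cohort a \code{\link{CohortTable}}
#' @param nucleus nucleus label present in the cohort
#' @return data.frame with columns nucleus, r, df, p, n
#' @examples
#' co <- referenceCohort()
#' ageCorrelation(co, "MGN")   # r about -0.91, p < 0.01
#' @export
ageCorrelation <- function(cohort, nucleus) {
  stopifnot(is(cohort, "CohortTable"))
  x <- ages(cohort)
  y <- nucleusMeans(cohort, nucleus)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 subjects with age and intensity")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop(sprintf("undefined correlation for '%s': zero variance", nucleus))
  ct <- stats::cor.test(x, y, method = "pearson")
  data.frame(nucleus = nucleus, r = unname(ct$estimate),
             df = unname(ct$parameter), p = ct$p.value, n = length(x))
}

#' @describeIn ageCorrelation correlation for every nucleus in the cohort
#' @export
ageCorrelationAll <- function(cohort) {
  do.call(rbind, lapply(nucleusNames(cohort),
                        function(nm) ageCorrelation(cohort, nm)))
}

#' Exact permutation p-value for an age correlation
#'
#' Enumerates all n! permutations of the intensity values (n <= 8) and
#' reports the fraction with |r| at least the observed |r|. Used as an
#' assumption-free cross-check of the t-based p-value.
#'
#' @param x ages
#' @param y nucleus means
#' @return two-sided permutation p-value
#' @export
permutationPValue <- function(x, y) {
  n <- length(x)
  if (n > 8) stop("exact enumeration is limited to n <= 8")
  perms <- permuteAll(n)
  rObs <- abs(stats::cor(x, y))
  rPerm <- abs(apply(perms, 1, function(ix) stats::cor(x, y[ix])))
  mean(rPerm >= rObs - 1e-12)
}

permuteAll <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permuteAll(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

#' Two-sample t-test between intensity groups
#'
#' Compares pooled values of an anterior group (e.g. VA + VLo) against a
#' posterior group (e.g. pulvinar + MGN). Welch's unequal-variance test by
#' default; a pooled-variance test via \code{pooled = TRUE}.
#'
#' @param groupA,groupB numeric value vectors (each length >= 2)
#' @param pooled use the pooled-variance (classical) test
#' @return list with \code{t}, \code{df}, \code{p}
#' @export
groupTTest <- function(groupA, groupB, pooled = FALSE) {
  if (length(groupA) < 2 || length(groupB) < 2)
    stop("each group needs at least 2 values")
  tt <- stats::t.test(groupA, groupB, var.equal = pooled)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' Cook's-distance outlier screening
#'
#' Fits the simple linear regression of nucleus mean intensity on age and
#' computes Cook's distance for every subject,
#' \eqn{D_i = (e_i^2 / (2 \cdot MSE)) \cdot h_i / (1 - h_i)^2}. A subject
#' is flagged as an outlier when its distance exceeds
#' \code{threshFactor} times the mean distance across subjects. A perfect
#' fit (MSE = 0) yields all-zero distances and no flags.
#'
#' @param age independent variable (years), length >= 4
#' @param y per-subject nucleus means
#' @param threshFactor multiple of the mean distance, default 3
#' @return list with \code{distances}, \code{threshold}, \code{flags}
#'   (logical) and \code{flagged} (indices)
#' @export
cooksOutliers <- function(age, y, threshFactor = 3) {
  n <- length(age)
  if (n < 4 || length(y) != n)
    stop("need >= 4 paired observations for the influence screen")
  fit <- stats::lm(y ~ age)
  mse <- mean(stats::residuals(fit)^2) * n / (n - 2)
  if (mse < 1e-24 * max(mean(y^2), 1)) {
    d <- rep(0, n)
  } else {
    d <- unname(stats::cooks.distance(fit))
  }
  thr <- threshFactor * mean(d)
  flags <- d > thr & thr > 0
  list(distances = d, threshold = thr, flags = flags,
       flagged = which(flags))
}

#' @describeIn cooksOutliers screen every nucleus of a cohort; returns a
#'   data.frame (nucleus, subject, distance, flag)
#' @param cohort a \code{\link{CohortTable}}
#' @param nuclei labels to screen (default: all in the cohort)
#' @export
cooksOutliersCohort <- function(cohort, nuclei = NULL, threshFactor = 3) {
  stopifnot(is(cohort, "CohortTable"))
  if (is.null(nuclei)) nuclei <- nucleusNames(cohort)
  a <- ages(cohort)
  do.call(rbind, lapply(nuclei, function(nm) {
    res <- cooksOutliers(a, nucleusMeans(cohort, nm), threshFactor)
    data.frame(nucleus = nm, subject = cohort@subjects$subject,
               distance = res$distances, flag = res$flags)
  }))
}

#' Bundled reference cohort
#'
#' A seven-subject rhesus macaque cohort (ages 4-22 years, six female and
#' one male) scanned with 7T susceptibility-weighted imaging: per-nucleus
#' mean and SD of AC-normalized SWI intensity for seven thalamic nuclei
#' (pulvinar, MGN, VPLc, VPLo, MD, VLo, VA). Intensities are two-decimal
#' published summaries; they serve as the package's worked reference
#' dataset for the age-correlation and outlier-screening pipeline.
#'
#' @return a \code{\link{CohortTable}}
#' @examples
#' co <- referenceCohort()
#' ageCorrelationAll(co)
#' @export
referenceCohort <- function() {
  subjects <- data.frame(
    subject = 1:7,
    sex = c("F", "F", "F", "F", "F", "F", "M"),
    age = c(22, 22, 14, 13, 10, 9, 4))
  vals <- list(
    Pulvinar = list(mean = c(0.78, 0.52, 1.55, 0.81, 1.05, 1.31, 1.42),
                    sd   = c(0.35, 0.23, 0.26, 0.34, 0.19, 0.23, 0.24)),
    MGN      = list(mean = c(0.65, 0.57, 1.11, 0.76, 1.09, 1.14, 1.28),
                    sd   = c(0.23, 0.19, 0.17, 0.24, 0.17, 0.28, 0.28)),
    VPLc     = list(mean = c(1.08, 0.82, 1.30, 1.07, 1.14, 1.22, 1.38),
                    sd   = c(0.22, 0.14, 0.19, 0.14, 0.09, 0.22, 0.18)),
    VPLo     = list(mean = c(1.29, 0.98, 1.70, 1.32, 1.21, 1.21, 1.45),
                    sd   = c(0.16, 0.11, 0.16, 0.15, 0.11, 0.28, 0.19)),
    MD       = list(mean = c(1.26, 0.74, 1.68, 1.12, 1.22, 1.31, 1.54),
                    sd   = c(0.32, 0.23, 0.24, 0.29, 0.15, 0.29, 0.21)),
    VLo      = list(mean = c(1.37, 0.92, 1.67, 1.36, 1.14, 1.40, 1.34),
                    sd   = c(0.11, 0.11, 0.24, 0.19, 0.11, 0.30, 0.24)),
    VA       = list(mean = c(1.34, 0.90, 1.65, 1.36, 1.10, 1.44, 1.35),
                    sd   = c(0.14, 0.12, 0.20, 0.15, 0.13, 0.25, 0.26)))
  intensity <- do.call(rbind, lapply(names(vals), function(nm)
    data.frame(subject = 1:7, nucleus = nm,
               mean = vals[[nm]]$mean, sd = vals[[nm]]$sd)))
  CohortTable(subjects, intensity)
}
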