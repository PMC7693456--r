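#' Clean ROI time series
#'
#' Applies, in order: zero-phase 4th-order Butterworth low-pass filtering
#' (forward-backward, so no phase distortion), then a single joint
#' least-squares projection removing the intercept, a linear trend and any
#' supplied nuisance regressors. Because the projection is the final step,
#' every output column has an exactly zero fitted linear trend and is exactly
#' orthogonal to each nuisance regressor.
#'
#' @param ts numeric matrix, timepoints x nodes.
#' @param tr_seconds repetition time in seconds (sampling interval).
#' @param nuisance optional numeric matrix of nuisance regressors
#'   (rows match timepoints). Rank-deficient columns are dropped with a
#'   warning.
#' @param cutoff_hz low-pass cutoff in Hz; must be below the Nyquist
#'   frequency \code{1/(2 tr_seconds)}. \code{NULL} skips filtering.
#' @return cleaned matrix of the same dimension, with \code{tr_seconds}
#'   attached as an attribute.
#' @examples
#' ts <- matrix(rnorm(230 * 3), 230, 3)
#' out <- clean_timeseries(ts, tr_seconds = 2, cutoff_hz = 0.1)
#' @export
clean_timeseries <- function(ts, tr_seconds, nuisance = NULL,
                             cutoff_hz = 0.1) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 2L) stopf("need at least 2 timepoints")
  check_finite(ts, "time series")
  nt <- nrow(ts)

  if (!is.null(cutoff_hz)) {
    nyquist <- 1 / (2 * tr_seconds)
    if (cutoff_hz >= nyquist)
      stopf("cutoff_hz (%g) must be below the Nyquist frequency (%g Hz)",
            cutoff_hz, nyquist)
    bf <- signal::butter(4, cutoff_hz / nyquist, type = "low")
    ts <- apply(ts, 2L, function(col) signal::filtfilt(bf, col))
  }

  design <- cbind(intercept = 1, trend = seq_len(nt) - (nt + 1) / 2)
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != nt)
      stopf("nuisance has %d rows but time series has %d timepoints",
            nrow(nuisance), nt)
    check_finite(nuisance, "nuisance regressors")
    full <- cbind(design, nuisance)
    q <- qr(full)
    if (q$rank < ncol(full)) {
      drop <- q$pivot[(q$rank + 1L):ncol(full)]
      warning(sprintf("dropping %d rank-deficient nuisance column(s)",
                      length(drop)))
      full <- full[, -drop, drop = FALSE]
    }
    design <- full
  }
  out <- stats::lm.fit(design, ts)$residuals
  out <- matrix(out, nt, ncol(ts), dimnames = dimnames(ts))
  attr(out, "tr_seconds") <- tr_seconds
  out
}

#' Framewise displacement from six rigid-body motion parameters
#'
#' Power-style framewise displacement: at each frame t >= 2,
#' \code{FD_t = sum(|d translations|) + r * sum(|d rotations|)}, where the
#' three rotation increments (radians) are converted to an arc length on a
#' sphere of radius \code{head_radius_mm}.
#'
#' @param motion numeric matrix, volumes x 6: translations (mm) in columns
#'   1-3, rotations (radians) in columns 4-6.
#' @param head_radius_mm sphere radius for the rotation-to-displacement
#'   conversion; 50 mm by default.
#' @return list with \code{fd} (length \code{nrow(motion) - 1}) and
#'   \code{mean_fd}.
#' @examples
#' m <- matrix(0, 10, 6); m[6:10, 1] <- 1
#' framewise_displacement(m)$fd   # single 1 mm spike
#' @export
framewise_displacement <- function(motion, head_radius_mm = 50) {
  motion <- as.matrix(motion)
  if (nrow(motion) < 2L) stopf("need at least 2 volumes")
  if (ncol(motion) != 6L) stopf("motion must have 6 columns")
  check_finite(motion, "motion parameters")
  d <- abs(diff(motion))
  fd <- rowSums(d[, 1:3, drop = FALSE]) +
    head_radius_mm * rowSums(d[, 4:6, drop = FALSE])
  list(fd = as.numeric(fd), mean_fd = mean(fd))
}

#' Build a connectivity matrix from ROI time series
#'
#' Pearson correlation of every column pair, optionally Fisher-z transformed
#' (\code{atanh}) after clipping r to +/-(1 - 1e-7) so the transform stays
#' finite. The diagonal is stored as 0 on both scales so that mask algebra
#' downstream is well defined.
#'
#' @param ts numeric matrix, timepoints x nodes; column names are taken as
#'   node labels.
#' @param to_fisher_z logical; transform correlations to Fisher z.
#' @param subject_id optional subject identifier carried on the result.
#' @return a \code{conn_matrix}: list with \code{values} (symmetric
#'   nodes x nodes matrix, zero diagonal), \code{scale} (\code{"pearson_r"}
#'   or \code{"fisher_z"}) and \code{subject_id}.
#' @export
fc_matrix <- function(ts, to_fisher_z = TRUE, subject_id = NA_character_) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 2L) stopf("need at least 2 timepoints")
  check_finite(ts, "time series")
  v <- apply(ts, 2L, stats::var)
  if (any(v == 0)) {
    bad <- colnames(ts)[v == 0]
    if (is.null(bad)) bad <- which(v == 0)
    stopf("zero-variance column(s): %s", paste(bad, collapse = ", "))
  }
  r <- stats::cor(ts)
  r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
  vals <- if (to_fisher_z) atanh(r) else r
  diag(vals) <- 0
  vals <- (vals + t(vals)) / 2    # enforce exact symmetry
  conn_matrix(vals, scale = if (to_fisher_z) "fisher_z" else "pearson_r",
              subject_id = subject_id)
}

#' Connectivity-matrix constructor
#'
#' @param values symmetric numeric matrix with zero diagonal.
#' @param scale \code{"pearson_r"} or \code{"fisher_z"}.
#' @param subject_id optional identifier.
#' @return a \code{conn_matrix} object.
#' @export
conn_matrix <- function(values, scale = c("fisher_z", "pearson_r"),
                        subject_id = NA_character_) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stopf("connectivity matrix must be square")
  if (max(abs(values - t(values))) > 1e-12)
    stopf("connectivity matrix must be symmetric (tolerance 1e-12)")
  if (any(diag(values) != 0)) stopf("diagonal must be stored as 0")
  structure(list(values = values, scale = scale, subject_id = subject_id),
            class = "conn_matrix")
}

#' @export
print.conn_matrix <- function(x, ...) {
  cat(sprintf("Connectivity matrix (%d x %d, scale = %s, subject = %s)\n",
              nrow(x$values), ncol(x$values), x$scale, x$subject_id))
  invisible(x)
}
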