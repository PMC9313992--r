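# Missing-cell detection: quantitative cells use NA, qualitative cells use the
# 0.5 data-loss code (binary features are otherwise exactly 0 or 1).
is_missing_cell <- function(values, kind) {
  if (kind == "qualitative") is.na(values) | values == 0.5 else is.na(values)
}

#' Deduplicate a cohort to one record per patient
#'
#' Rows without a patient identifier (NA or empty) are dropped first; then,
#' for every remaining identifier, only the record with the latest timestamp
#' is kept (ties broken by last occurrence). Row order of the survivors
#' follows their original order, so an already-deduplicated table passes
#' through unchanged.
#'
#' @param cohort a cohort data.frame with \code{patient_id} and
#'   \code{timestamp} columns.
#' @return the deduplicated cohort.
#' @export
deduplicate <- function(cohort) {
  stopifnot(all(c("patient_id", "timestamp") %in% names(cohort)))
  keep <- !is.na(cohort$patient_id) & cohort$patient_id != "" &
    cohort$patient_id != "-"
  cohort <- cohort[keep, , drop = FALSE]
  if (nrow(cohort) == 0L) return(cohort)
  best <- tapply(seq_len(nrow(cohort)), cohort$patient_id, function(idx) {
    ts <- cohort$timestamp[idx]
    idx[max(which(ts == max(ts)))]
  })
  out <- cohort[sort(as.integer(best)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Drop records whose information-loss rate exceeds a threshold
#'
#' A record is removed when the fraction of its feature cells that are
#' missing is strictly greater than \code{threshold} (default 0.80: a record
#' with exactly 80\% of cells missing is retained).
#'
#' @param cohort deduplicated cohort.
#' @param schema feature schema (name, kind).
#' @param threshold maximal tolerated missing fraction, in [0, 1].
#' @return the filtered cohort.
#' @export
filter_missingness <- function(cohort, schema, threshold = 0.80) {
  if (!is.numeric(threshold) || threshold < 0 || threshold > 1) {
    stop("`threshold` must lie in [0, 1]", call. = FALSE)
  }
  miss <- sapply(seq_len(nrow(schema)), function(j) {
    is_missing_cell(cohort[[schema$name[j]]], schema$kind[j])
  })
  miss <- matrix(miss, nrow = nrow(cohort))
  frac <- rowMeans(miss)
  out <- cohort[frac <= threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Clamp quantitative outliers with Tukey fences and schema bounds
#'
#' Per quantitative column, quartiles are computed over non-missing entries
#' with linear interpolation between order statistics (quantile type 7);
#' values strictly below \eqn{Q_1 - 1.5\,\mathrm{IQR}} or strictly above
#' \eqn{Q_3 + 1.5\,\mathrm{IQR}} are set to the fence (a value exactly on a
#' fence is untouched). The schema's physiologic lower/upper bounds are then
#' applied as hard clamps. Columns with fewer than 4 non-missing values are
#' left unclamped with a warning. Qualitative columns pass through.
#'
#' @param cohort cohort with possibly missing cells.
#' @param schema feature schema with bounds.
#' @return the cohort with clamped quantitative columns.
#' @export
clamp_outliers_iqr <- function(cohort, schema) {
  for (j in which(schema$kind == "quantitative")) {
    nm <- schema$name[j]
    v <- cohort[[nm]]
    obs <- !is.na(v)
    if (sum(obs) < 4L) {
      warning(sprintf("column '%s' has < 4 observed values; left unclamped", nm))
      next
    }
    q <- stats::quantile(v[obs], c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- q[2] - q[1]
    lo <- q[1] - 1.5 * iqr
    hi <- q[2] + 1.5 * iqr
    v[obs & v < lo] <- lo
    v[obs & v > hi] <- hi
    if (!is.na(schema$lower[j])) v[obs & v < schema$lower[j]] <- schema$lower[j]
    if (!is.na(schema$upper[j])) v[obs & v > schema$upper[j]] <- schema$upper[j]
    cohort[[nm]] <- v
  }
  cohort
}

#' Impute missing feature cells
#'
#' Missing quantitative cells receive the column median of the observed
#' values; missing qualitative cells keep the 0.5 data-loss code (NA cells
#' are set to 0.5), which places an unknown binary status half-way between
#' absent and present. Idempotent.
#'
#' @param cohort missingness-filtered cohort.
#' @param schema feature schema.
#' @return the cohort with no missing markers left.
#' @export
impute_missing <- function(cohort, schema) {
  for (j in seq_len(nrow(schema))) {
    nm <- schema$name[j]
    v <- cohort[[nm]]
    if (schema$kind[j] == "quantitative") {
      if (all(is.na(v))) {
        stop(sprintf("column '%s' is entirely missing", nm), call. = FALSE)
      }
      v[is.na(v)] <- stats::median(v, na.rm = TRUE)
    } else {
      v[is.na(v)] <- 0.5
    }
    cohort[[nm]] <- v
  }
  cohort
}

#' Z-score normalize a feature matrix
#'
#' Per column: subtract the mean and divide by the sample standard deviation
#' (denominator n - 1). Constant columns map to all zeros.
#'
#' @param X numeric matrix (rows = patients).
#' @return the standardized matrix.
#' @export
zscore <- function(X) {
  X <- as.matrix(X)
  mu <- colMeans(X)
  sd <- apply(X, 2L, stats::sd)
  Xc <- sweep(X, 2L, mu)
  nz <- sd > 0
  Xc[, nz] <- sweep(Xc[, nz, drop = FALSE], 2L, sd[nz], "/")
  Xc[, !nz] <- 0
  Xc
}

#' Train/test split with an internal validation subset
#'
#' Draws a uniformly random permutation under \code{seed}; the first
#' \eqn{\lfloor \mathrm{frac} \cdot n \rfloor} indices form the training set
#' and the rest the test set. The last 20\% of the training indices (same
#' seed stream) are additionally exposed as an internal validation subset
#' used for early stopping.
#'
#' @param n number of patients.
#' @param train_frac training fraction, in (0, 1); default 0.60.
#' @param seed integer seed.
#' @return list with integer index vectors \code{train} (all training
#'   indices), \code{train_fit} (training minus validation), \code{val},
#'   \code{test}.
#' @export
split_masks <- function(n, train_frac = 0.60, seed = 21) {
  stopifnot(n >= 2)
  if (train_frac <= 0 || train_frac >= 1) {
    stop("`train_frac` must lie strictly inside (0, 1)", call. = FALSE)
  }
  set.seed(as.integer(seed))
  perm <- sample.int(n)
  ntrain <- floor(train_frac * n)
  train <- perm[seq_len(ntrain)]
  test <- perm[(ntrain + 1L):n]
  nval <- floor(0.2 * ntrain)
  val <- if (nval > 0) train[(ntrain - nval + 1L):ntrain] else integer(0)
  train_fit <- if (nval > 0) train[seq_len(ntrain - nval)] else train
  list(train = train, train_fit = train_fit, val = val, test = test)
}

#' Run the full preprocessing pipeline
#'
#' Fixed stage order: deduplicate, missingness filter, IQR outlier clamping,
#' imputation, z-score normalization. Returns both the normalized feature
#' matrix (for graph kernels and the GCN) and the raw post-imputation feature
#' table (for phenotype measures, whose thresholds live in clinical units).
#'
#' @param cohort raw cohort table.
#' @param schema feature schema.
#' @param miss_threshold missingness filter threshold.
#' @return list with \code{X} (N x D normalized matrix), \code{raw}
#'   (post-clamp/impute feature data.frame in clinical units),
#'   \code{patient_ids}, \code{labels} (0/1 integer vector), \code{schema}.
#' @export
preprocess_cohort <- function(cohort, schema, miss_threshold = 0.80) {
  dd <- deduplicate(cohort)
  dd <- filter_missingness(dd, schema, miss_threshold)
  dd <- clamp_outliers_iqr(dd, schema)
  dd <- impute_missing(dd, schema)
  raw <- dd[, schema$name, drop = FALSE]
  X <- zscore(as.matrix(raw))
  rownames(X) <- dd$patient_id
  list(X = X, raw = raw, patient_ids = dd$patient_id,
       labels = as.integer(dd$label), schema = schema)
}
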