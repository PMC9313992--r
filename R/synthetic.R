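#' Specification for a synthetic CHD cohort
#'
#' Describes the marginal structure of a synthetic postoperative coronary
#' heart disease cohort: quantitative features given as median and
#' interquartile range, qualitative (binary-coded) features given as a
#' positive-prevalence fraction, an outcome prevalence, messiness rates
#' (duplicate records, missing cells, gross outliers) and a planted
#' community-structured risk signal.
#'
#' Quantitative features are drawn from a two-piece (split) normal matched to
#' the requested quartiles: with \eqn{z_{0.75} = \Phi^{-1}(0.75)}, a standard
#' normal deviate \eqn{z} maps to \eqn{m + z (q_3 - m)/z_{0.75}} when
#' \eqn{z \ge 0} and \eqn{m + z (m - q_1)/z_{0.75}} otherwise, which
#' reproduces the asymmetric IQRs of skewed laboratory markers in closed form
#' while keeping the median exact.
#'
#' The label is Bernoulli under a logistic model on a weighted sum of risk
#' features (by default age and smoking) plus a community effect: patients are
#' partitioned into \code{n_communities} groups, each group both shifts a
#' direction in quantitative feature space, the directions mutually
#' orthogonal across communities (so the communities are
#' visible to feature-similarity graphs) and carries its own risk offset.
#' \code{signal_strength} scales the whole planted signal; 0 makes the label
#' independent of every feature. The intercept is calibrated by bisection so
#' the expected prevalence matches \code{prevalence}.
#'
#' @param n_patients number of distinct patients.
#' @param prevalence target fraction of death outcomes, in (0, 1).
#' @param quant_features data.frame with columns \code{name}, \code{median},
#'   \code{q1}, \code{q3} (and optionally \code{lower}, \code{upper} schema
#'   bounds). Defaults to the bundled CHD registry profile.
#' @param qual_features data.frame with columns \code{name}, \code{prevalence}.
#' @param duplicate_rate fraction of patients carrying more than one record.
#' @param missing_rate per-cell missingness fraction (missing completely at
#'   random).
#' @param outlier_rate per-cell gross-outlier fraction.
#' @param n_communities number of latent patient communities.
#' @param signal_strength nonnegative scale of the planted risk signal.
#' @param risk_features character vector of feature names carrying direct
#'   risk weight (must exist in the schema).
#' @param community_shift size of the community shift applied to quantitative
#'   features, in units of each feature's own scale.
#' @param seed integer seed controlling every random draw.
#'
#' @return An object of class \code{synthetic_spec}.
#' @seealso [generate_cohort()], [ground_truth()], [chd_schema()]
#' @export
synthetic_spec <- function(n_patients = 2702,
                           prevalence = 0.044,
                           quant_features = chd_quant_features(),
                           qual_features = chd_qual_features(),
                           duplicate_rate = 0.15,
                           missing_rate = 0.03,
                           outlier_rate = 0.005,
                           n_communities = 4,
                           signal_strength = 2.5,
                           risk_features = c("age", "smoking"),
                           community_shift = 0.8,
                           seed = 21) {
  stopifnot(n_patients >= 1)
  stopifnot_prob(prevalence, "prevalence")
  if (prevalence <= 0 || prevalence >= 1) {
    stop("`prevalence` must lie strictly inside (0, 1)", call. = FALSE)
  }
  stopifnot_prob(duplicate_rate, "duplicate_rate")
  stopifnot_prob(missing_rate, "missing_rate")
  stopifnot_prob(outlier_rate, "outlier_rate")
  stopifnot(n_communities >= 1, signal_strength >= 0)
  qf <- as.data.frame(quant_features)
  if (!all(qf$q1 < qf$median & qf$median < qf$q3)) {
    stop("every quantitative feature needs q1 < median < q3", call. = FALSE)
  }
  cf <- as.data.frame(qual_features)
  stopifnot(all(cf$prevalence >= 0 & cf$prevalence <= 1))
  all_names <- c(qf$name, cf$name)
  if (anyDuplicated(all_names)) stop("feature names must be unique", call. = FALSE)
  if (!all(risk_features %in% all_names)) {
    stop("risk_features must name features in the schema", call. = FALSE)
  }
  structure(list(
    n_patients = as.integer(n_patients), prevalence = prevalence,
    quant_features = qf, qual_features = cf,
    duplicate_rate = duplicate_rate, missing_rate = missing_rate,
    outlier_rate = outlier_rate, n_communities = as.integer(n_communities),
    signal_strength = signal_strength, risk_features = risk_features,
    community_shift = community_shift, seed = as.integer(seed)
  ), class = "synthetic_spec")
}

#' Default quantitative feature profile of the synthetic CHD cohort
#'
#' Medians and interquartile ranges typical of a postoperative CHD registry
#' (age in years, BMI in kg/m^2, heart rate in bpm, echocardiographic and
#' blood-test markers in clinical units), together with plausible physiologic
#' bounds used as hard clamps during preprocessing.
#'
#' @return data.frame with columns name, median, q1, q3, lower, upper.
#' @export
chd_quant_features <- function() {
  data.frame(
    name = c("age", "bmi", "heart_rate", "e_wave_velocity", "lvef",
             "lv_mass_index", "total_cholesterol", "ldl", "triglycerides",
             "nt_probnp", "apolipoprotein_a"),
    median = c(65, 24.0, 68, 0.06, 63.3, 103.4, 3.95, 2.48, 1.43, 129, 1.19),
    q1     = c(57, 22.7, 61, 0.04, 55.1,  86.5, 3.24, 1.85, 1.03,  37, 1.04),
    q3     = c(72, 26.0, 76, 0.07, 68.6, 121.0, 4.85, 3.28, 2.00, 538, 1.33),
    lower  = c(18, 10, 30, 0.005, 10, 30, 0.5, 0.2, 0.1, 1, 0.3),
    upper  = c(110, 60, 220, 0.5, 90, 300, 15, 10, 20, 35000, 3),
    stringsAsFactors = FALSE
  )
}

#' Default qualitative feature profile of the synthetic CHD cohort
#'
#' Binary-coded clinical variables (1 = present, 0 = absent) with their
#' positive prevalence: demographics and habits, medical history, medication
#' status and coronary lesion descriptors.
#'
#' @return data.frame with columns name, prevalence.
#' @export
chd_qual_features <- function() {
  data.frame(
    name = c("sex_male", "smoking", "diabetes", "hypertension",
             "renal_insufficiency", "statin", "spironolactone", "aspirin",
             "bifurcation_lesion", "cto", "angulation", "calcification",
             "lesion_type_b2c", "target_vessel_lad"),
    prevalence = c(0.817, 0.433, 0.300, 0.425, 0.010, 0.786, 0.096, 0.982,
                   0.25, 0.12, 0.18, 0.30, 0.45, 0.55),
    stringsAsFactors = FALSE
  )
}

#' Feature schema of a synthetic specification
#'
#' @param spec a \code{synthetic_spec}.
#' @return data.frame with columns name, kind ("quantitative"/"qualitative"),
#'   lower, upper (NA for qualitative features).
#' @export
chd_schema <- function(spec = synthetic_spec()) {
  qf <- spec$quant_features
  lower <- if ("lower" %in% names(qf)) qf$lower else rep(NA_real_, nrow(qf))
  upper <- if ("upper" %in% names(qf)) qf$upper else rep(NA_real_, nrow(qf))
  rbind(
    data.frame(name = qf$name, kind = "quantitative",
               lower = lower, upper = upper, stringsAsFactors = FALSE),
    data.frame(name = spec$qual_features$name, kind = "qualitative",
               lower = NA_real_, upper = NA_real_, stringsAsFactors = FALSE)
  )
}

# Split-normal draw matched to (q1, median, q3) with equal tail masses.
rsplitnorm <- function(n, m, q1, q3) {
  z75 <- stats::qnorm(0.75)
  z <- stats::rnorm(n)
  sR <- (q3 - m) / z75
  sL <- (m - q1) / z75
  m + ifelse(z >= 0, z * sR, z * sL)
}

#' Generate a synthetic CHD cohort table
#'
#' Draws one record per patient from the spec's marginal distributions, plants
#' the community/risk signal described in [synthetic_spec()], calibrates the
#' logistic intercept so realized prevalence matches the spec, then injects
#' duplicate records (earlier timestamps, perturbed features), missing cells
#' and gross outliers at the stated rates. Deterministic for a fixed seed.
#'
#' @param spec a \code{synthetic_spec}.
#' @return A data.frame of class \code{cohort_table}: columns
#'   \code{patient_id}, \code{timestamp}, \code{label}, then the features in
#'   schema order. Missing quantitative cells are \code{NA}; missing
#'   qualitative cells carry the 0.5 data-loss code. Latent ground truth is
#'   attached as attributes (see [ground_truth()]).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_patients
  qf <- spec$quant_features
  cf <- spec$qual_features
  nq <- nrow(qf)

  # communities and their shift directions in quantitative-feature space
  # each community offsets the quantitative features along its own direction
  # with per-feature RMS shift = community_shift feature-scale units; the
  # directions are mutually orthogonal so every pair of communities is
  # equally separated and recoverable from feature similarity (the signal is
  # graph-aligned, not only label-aligned) — random directions can nearly
  # collide, which would silently merge two communities
  comm <- sample.int(spec$n_communities, n, replace = TRUE)
  dirs <- matrix(stats::rnorm(spec$n_communities * nq), spec$n_communities, nq)
  if (spec$n_communities <= nq) {
    dirs <- t(qr.Q(qr(t(dirs)))[, seq_len(spec$n_communities), drop = FALSE]) *
      sqrt(nq)
  }

  Q <- matrix(NA_real_, n, nq, dimnames = list(NULL, qf$name))
  for (j in seq_len(nq)) {
    scale_j <- (qf$q3[j] - qf$q1[j]) / (2 * stats::qnorm(0.75))
    Q[, j] <- rsplitnorm(n, qf$median[j], qf$q1[j], qf$q3[j]) +
      spec$community_shift * scale_j * dirs[comm, j]
  }
  C <- matrix(NA_real_, n, nrow(cf), dimnames = list(NULL, cf$name))
  for (j in seq_len(nrow(cf))) {
    C[, j] <- as.numeric(stats::runif(n) < cf$prevalence[j])
  }

  # linear risk score: standardized risk features + community offsets
  feats <- cbind(Q, C)
  risk <- rep(0, n)
  for (f in spec$risk_features) {
    v <- feats[, f]
    s <- stats::sd(v)
    risk <- risk + if (s > 0) (v - mean(v)) / s else 0
  }
  risk <- risk / max(1, length(spec$risk_features))
  comm_eff <- seq(-1, 1, length.out = spec$n_communities)
  eta_raw <- spec$signal_strength * (risk + comm_eff[comm])

  # calibrate intercept by bisection so E[plogis(b0 + eta)] = prevalence
  target <- spec$prevalence
  f <- function(b0) mean(stats::plogis(b0 + eta_raw)) - target
  lo <- -30; hi <- 30
  if (f(lo) > 0 || f(hi) < 0) {
    stop(sprintf("prevalence calibration failed: achievable range (%.4f, %.4f)",
                 mean(stats::plogis(lo + eta_raw)),
                 mean(stats::plogis(hi + eta_raw))), call. = FALSE)
  }
  for (it in seq_len(50)) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  b0 <- (lo + hi) / 2
  p_latent <- stats::plogis(b0 + eta_raw)
  label <- as.integer(stats::runif(n) < p_latent)

  achieved <- mean(p_latent)
  if (abs(achieved - target) / target > 0.2) {
    stop(sprintf("prevalence calibration failed: achieved %.4f vs target %.4f",
                 achieved, target), call. = FALSE)
  }

  ids <- sprintf("P%05d", seq_len(n))
  base <- data.frame(patient_id = ids, timestamp = 1000 + seq_len(n),
                     label = label, stringsAsFactors = FALSE)
  base <- cbind(base, as.data.frame(feats))

  # duplicates: earlier, perturbed copies of the canonical (latest) record
  ndup <- round(spec$duplicate_rate * n)
  if (ndup > 0) {
    dup_idx <- sample.int(n, ndup)
    dup <- base[dup_idx, , drop = FALSE]
    dup$timestamp <- dup$timestamp - sample.int(500, ndup, replace = TRUE)
    for (j in seq_len(nq)) {
      scale_j <- (qf$q3[j] - qf$q1[j]) / (2 * stats::qnorm(0.75))
      dup[[qf$name[j]]] <- dup[[qf$name[j]]] + stats::rnorm(ndup, 0, 0.2 * scale_j)
    }
    base <- rbind(base, dup)
    base <- base[order(base$patient_id, base$timestamp), , drop = FALSE]
    rownames(base) <- NULL
  }

  fcols <- c(qf$name, cf$name)
  ncells <- nrow(base) * length(fcols)
  # gross outliers: quantitative cells pushed far outside the Tukey fences
  if (spec$outlier_rate > 0) {
    for (j in seq_len(nq)) {
      hit <- stats::runif(nrow(base)) < spec$outlier_rate
      if (any(hit)) {
        iqr <- qf$q3[j] - qf$q1[j]
        sgn <- sample(c(-1, 1), sum(hit), replace = TRUE)
        base[[qf$name[j]]][hit] <- qf$median[j] + sgn * (6 * iqr + abs(stats::rnorm(sum(hit), 0, iqr)))
      }
    }
  }
  # MCAR missingness: NA for quantitative, 0.5 data-loss code for qualitative
  if (spec$missing_rate > 0) {
    for (nm in qf$name) {
      base[[nm]][stats::runif(nrow(base)) < spec$missing_rate] <- NA_real_
    }
    for (nm in cf$name) {
      base[[nm]][stats::runif(nrow(base)) < spec$missing_rate] <- 0.5
    }
  }

  structure(base,
            class = c("cohort_table", "data.frame"),
            spec_digest = spec_digest(spec),
            latent_prob = stats::setNames(p_latent, ids),
            community = stats::setNames(comm, ids),
            risk_score = stats::setNames(eta_raw, ids))
}

spec_digest <- function(spec) {
  paste(spec$n_patients, spec$prevalence, spec$seed, spec$signal_strength,
        spec$n_communities, nrow(spec$quant_features),
        nrow(spec$qual_features), sep = "|")
}

#' Latent ground truth of a generated cohort
#'
#' Returns the exact per-patient latent death probabilities, community
#' assignments and linear risk scores used when the cohort was generated,
#' enabling oracle discrimination (AUC) computations against the planted
#' signal.
#'
#' @param spec the \code{synthetic_spec} the cohort was generated from.
#' @param cohort the corresponding \code{cohort_table}.
#' @return list with \code{latent_prob}, \code{community}, \code{risk_score},
#'   each named by patient id.
#' @export
ground_truth <- function(spec, cohort) {
  stopifnot(inherits(spec, "synthetic_spec"), inherits(cohort, "cohort_table"))
  if (!identical(attr(cohort, "spec_digest"), spec_digest(spec))) {
    stop("cohort was not generated from this spec", call. = FALSE)
  }
  list(latent_prob = attr(cohort, "latent_prob"),
       community = attr(cohort, "community"),
       risk_score = attr(cohort, "risk_score"))
}

#' Write / read a cohort CSV with its schema sidecar
#'
#' The CSV has a header row and one record per line: \code{patient_id},
#' \code{timestamp}, \code{label}, then features in schema order. Missing
#' quantitative cells are empty fields; missing qualitative cells carry the
#' 0.5 code. The sidecar is a plain-text \code{name,kind,lower,upper} table
#' declaring each feature's kind and valid bounds. Numeric fields use a fixed
#' 9-significant-digit format so repeated writes are byte-identical.
#'
#' @param cohort a \code{cohort_table} (or conforming data.frame).
#' @param schema feature schema as from [chd_schema()].
#' @param path CSV path; the sidecar is written to \code{paste0(path, ".schema")}.
#' @return \code{path}, invisibly.
#' @export
write_cohort_csv <- function(cohort, schema, path) {
  fcols <- schema$name
  stopifnot(all(fcols %in% names(cohort)))
  out <- data.frame(patient_id = cohort$patient_id,
                    timestamp = format_num(cohort$timestamp),
                    label = cohort$label, stringsAsFactors = FALSE)
  for (nm in fcols) out[[nm]] <- format_num(cohort[[nm]])
  utils::write.table(out, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  sidecar <- data.frame(name = schema$name, kind = schema$kind,
                        lower = format_num(schema$lower),
                        upper = format_num(schema$upper))
  utils::write.table(sidecar, paste0(path, ".schema"), sep = ",",
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  schema <- utils::read.csv(paste0(path, ".schema"), stringsAsFactors = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(patient_id = "character"))
  for (nm in schema$name) df[[nm]] <- as.numeric(df[[nm]])
  structure(df, class = c("cohort_table", "data.frame"), schema = schema)
}
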