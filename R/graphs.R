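#' Patient-to-patient correlation distance matrix
#'
#' \eqn{\rho(i,j) = 1 - r(x_i, x_j)} where \eqn{r} is the Pearson correlation
#' between the two patients' full normalized feature vectors. The kernel
#' width \eqn{\sigma} is the mean of the off-diagonal \eqn{\rho} entries
#' (self-distances excluded so they do not bias \eqn{\sigma} toward 0).
#' Patients with zero feature variance get correlation 0 (\eqn{\rho = 1})
#' against everyone, with a warning.
#'
#' @param X N x D normalized feature matrix, N >= 2, D >= 2.
#' @return list with \code{rho} (N x N, symmetric, zero diagonal) and scalar
#'   \code{sigma}.
#' @export
correlation_distance_matrix <- function(X) {
  X <- as.matrix(X)
  stopifnot(nrow(X) >= 2, ncol(X) >= 2)
  rowsd <- apply(X, 1L, stats::sd)
  degen <- rowsd == 0 | is.na(rowsd)
  if (any(degen)) {
    warning(sprintf("%d zero-variance patient row(s); their correlations set to 0",
                    sum(degen)))
  }
  r <- suppressWarnings(stats::cor(t(X)))
  r[degen, ] <- 0
  r[, degen] <- 0
  rho <- 1 - r
  diag(rho) <- 0
  sigma <- mean(rho[upper.tri(rho)])
  list(rho = rho, sigma = sigma)
}

#' Phenotype-measure definitions
#'
#' A phenotypic measure is a designated clinical variable used for population
#' graph edge weighting: qualitative measures contribute via a delta rule
#' (values equal), quantitative measures via a unit step rule
#' (\eqn{|\mu_i - \mu_j| < \beta}). Thresholds are in clinical units, so
#' measures are evaluated on pre-normalization values. The defaults — age
#' (\eqn{\beta} = 5 years) and smoking — are the combination that carries the
#' planted risk signal of the synthetic cohort; BMI uses \eqn{\beta} = 2.
#'
#' @param names character vector of measure names.
#' @param schema feature schema declaring each feature's kind.
#' @param beta named numeric vector of thresholds for quantitative measures.
#' @return data.frame with columns name, kind, beta.
#' @export
phenotype_measures <- function(names = c("age", "smoking"),
                               schema = chd_schema(),
                               beta = c(age = 5, bmi = 2)) {
  stopifnot(length(names) >= 1)
  kind <- schema$kind[match(names, schema$name)]
  if (anyNA(kind)) {
    stop("unknown measure(s): ", paste(names[is.na(kind)], collapse = ", "),
         call. = FALSE)
  }
  b <- ifelse(kind == "quantitative", beta[names], NA_real_)
  if (any(kind == "quantitative" & (is.na(b) | b <= 0))) {
    stop("every quantitative measure needs a positive beta", call. = FALSE)
  }
  data.frame(name = names, kind = kind, beta = as.numeric(b),
             stringsAsFactors = FALSE)
}

#' Pairwise phenotype similarity matrix
#'
#' Entry (i, j) is the number of measures on which patients i and j agree:
#' exact equality for qualitative measures, \eqn{|\mu_i - \mu_j| < \beta} for
#' quantitative ones. Values in \eqn{[0, H]}. A missing raw value contributes
#' 0 to every pair involving it.
#'
#' @param raw data.frame of pre-normalization feature values.
#' @param measures as from [phenotype_measures()].
#' @return N x N integer-valued matrix.
#' @export
phenotype_similarity <- function(raw, measures) {
  n <- nrow(raw)
  P <- matrix(0, n, n)
  for (j in seq_len(nrow(measures))) {
    v <- raw[[measures$name[j]]]
    if (measures$kind[j] == "qualitative") {
      ok <- !is.na(v) & v != 0.5     # 0.5 = data-loss code, never matches
      term <- outer(v, v, "==") & outer(ok, ok, "&")
    } else {
      ok <- !is.na(v)
      term <- (abs(outer(v, v, "-")) < measures$beta[j]) & outer(ok, ok, "&")
    }
    P <- P + term
  }
  diag(P) <- 0
  P
}

#' Population graph adjacency
#'
#' Edge weight between patients i and j is
#' \deqn{A(i,j) = \exp(-\rho(i,j)^2 / 2\sigma^2) \cdot \sum_h E(M_h(i), M_h(j)),}
#' a Gaussian kernel on the correlation distance of their normalized feature
#' vectors multiplied by the number of matching phenotypic measures.
#' Symmetric, zero diagonal, entries in \eqn{[0, H]}.
#'
#' @param X normalized feature matrix (kernel part).
#' @param raw pre-normalization feature table (phenotype part).
#' @param measures as from [phenotype_measures()].
#' @return list of class \code{patient_graph}: \code{A}, \code{kind} =
#'   "population", \code{provenance}.
#' @export
population_adjacency <- function(X, raw, measures) {
  cd <- correlation_distance_matrix(X)
  if (cd$sigma <= 0) stop("degenerate cohort: sigma = 0", call. = FALSE)
  K <- exp(-cd$rho^2 / (2 * cd$sigma^2))
  A <- K * phenotype_similarity(raw, measures)
  diag(A) <- 0
  structure(list(A = A, kind = "population",
                 provenance = list(measures = measures, sigma = cd$sigma)),
            class = "patient_graph")
}

#' Cosine similarity matrix between patient feature vectors
#'
#' \eqn{S(i,j) = x_i \cdot x_j / (\|x_i\| \|x_j\|)}; symmetric, unit
#' diagonal, entries in [-1, 1]. All-zero rows get similarity 0 against
#' everyone (diagonal stays 1), with a warning.
#'
#' @param X N x D feature matrix.
#' @return N x N similarity matrix.
#' @export
cosine_similarity_matrix <- function(X) {
  X <- as.matrix(X)
  nrm <- sqrt(rowSums(X^2))
  zero <- nrm == 0
  if (any(zero)) {
    warning(sprintf("%d all-zero row(s); their similarities set to 0", sum(zero)))
    nrm[zero] <- 1
  }
  S <- tcrossprod(X / nrm)
  S[zero, ] <- 0
  S[, zero] <- 0
  S <- (S + t(S)) / 2
  diag(S) <- 1
  S
}

#' K-nearest-neighbor graph adjacency
#'
#' Each node selects its k most cosine-similar other nodes (ties broken by
#' lower index, self excluded); the directed selections are symmetrized by
#' union, so an edge exists when either endpoint selected the other. Binary,
#' zero diagonal; every node's degree is at least k.
#'
#' @param S N x N similarity matrix.
#' @param k number of neighbors, 1 <= k <= N-1.
#' @return list of class \code{patient_graph}: \code{A} (0/1), \code{kind} =
#'   "knn", \code{provenance}.
#' @export
knn_adjacency <- function(S, k) {
  n <- nrow(S)
  if (k < 1 || k > n - 1) stop("`k` must lie in [1, N-1]", call. = FALSE)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- S[i, ]
    s[i] <- -Inf
    nb <- order(-s, seq_len(n))[seq_len(k)]
    A[i, nb] <- 1
  }
  A <- pmax(A, t(A))    # undirected: union of directed selections
  diag(A) <- 0
  structure(list(A = A, kind = "knn", provenance = list(k = k)),
            class = "patient_graph")
}

#' Write / read a patient graph as a weighted edge list
#'
#' Plain-text lines \code{i,j,w} with \code{i < j} (1-based indices), one per
#' undirected edge with nonzero weight, preceded by a header. Weights use the
#' canonical 9-significant-digit format.
#'
#' @param graph a \code{patient_graph}.
#' @param path output path.
#' @param n number of nodes (needed on read to restore isolated nodes).
#' @return \code{path} / the reconstructed \code{patient_graph}.
#' @export
write_edge_list <- function(graph, path) {
  A <- graph$A
  idx <- which(upper.tri(A) & A != 0, arr.ind = TRUE)
  df <- data.frame(i = idx[, 1], j = idx[, 2],
                   w = format_num(A[idx]))
  df <- df[order(df$i, df$j), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# kind=%s n=%d", graph$kind, nrow(A)), con)
  writeLines("i,j,w", con)
  writeLines(sprintf("%d,%d,%s", df$i, df$j, df$w), con)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path, n = NULL) {
  lines <- readLines(path)
  hdr <- lines[1]
  kind <- sub(".*kind=(\\S+).*", "\\1", hdr)
  n_hdr <- as.integer(sub(".*n=(\\d+).*", "\\1", hdr))
  n <- n %||% n_hdr
  df <- utils::read.csv(text = lines[-1], stringsAsFactors = FALSE)
  A <- matrix(0, n, n)
  if (nrow(df) > 0) {
    A[cbind(df$i, df$j)] <- df$w
    A[cbind(df$j, df$i)] <- df$w
  }
  structure(list(A = A, kind = kind, provenance = list(file = path)),
            class = "patient_graph")
}
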