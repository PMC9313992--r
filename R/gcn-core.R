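#' Self-loop symmetric normalization of an adjacency matrix
#'
#' \eqn{\hat{A} = \tilde{D}^{-1/2} \tilde{A} \tilde{D}^{-1/2}} with
#' \eqn{\tilde{A} = A + I} and \eqn{\tilde{D}} the diagonal degree matrix of
#' \eqn{\tilde{A}}. The self-loop guarantees positive degrees, and the
#' spectral radius of the result is at most 1.
#'
#' @param A symmetric nonnegative adjacency matrix, or a \code{patient_graph}.
#' @return the normalized N x N matrix.
#' @export
normalize_adjacency <- function(A) {
  if (inherits(A, "patient_graph")) A <- A$A
  A <- as.matrix(A)
  if (any(A < 0)) stop("adjacency must be nonnegative", call. = FALSE)
  if (max(abs(A - t(A))) > 1e-8) stop("adjacency must be symmetric", call. = FALSE)
  At <- A + diag(nrow(A))
  dinv <- 1 / sqrt(rowSums(At))
  At * tcrossprod(dinv)
}

#' Single graph-convolution layer
#'
#' \eqn{H' = \mathrm{act}(\hat{A} H W)}. During training, dropout is applied
#' to the layer input (inverted dropout, so expected activations are
#' unchanged); at evaluation the input passes through untouched.
#'
#' @param Ahat normalized adjacency.
#' @param H input node representations (N x d_in).
#' @param W weight matrix (d_in x d_out).
#' @param activation "relu" or "none".
#' @param dropout dropout rate in [0, 1).
#' @param training logical; dropout is active only when TRUE.
#' @return N x d_out output representations.
#' @export
gcn_layer <- function(Ahat, H, W, activation = c("relu", "none"),
                      dropout = 0, training = FALSE) {
  activation <- match.arg(activation)
  if (ncol(Ahat) != nrow(H) || ncol(H) != nrow(W)) {
    stop("shape mismatch in gcn_layer", call. = FALSE)
  }
  if (training && dropout > 0) {
    mask <- matrix(stats::runif(length(H)) >= dropout, nrow(H), ncol(H))
    H <- H * mask / (1 - dropout)
  }
  out <- Ahat %*% H %*% W
  if (activation == "relu") out <- relu(out)
  out
}

#' Two-layer GCN forward pass to class probabilities
#'
#' \eqn{Z = \mathrm{softmax}(\hat{A}\,\mathrm{ReLU}(\hat{A} X W_0)\, W_1)}
#' with a per-node (row-wise) softmax over the classes.
#'
#' @param Ahat normalized adjacency.
#' @param X node features.
#' @param W0 input-to-hidden weights.
#' @param W1 hidden-to-class weights.
#' @return N x C matrix of class probabilities (rows sum to 1).
#' @export
two_layer_forward <- function(Ahat, X, W0, W1) {
  H1 <- gcn_layer(Ahat, X, W0, activation = "relu")
  logits <- Ahat %*% H1 %*% W1
  if (any(!is.finite(logits))) stop("non-finite intermediate", call. = FALSE)
  softmax_rows(logits)
}

# Fan-in scaled symmetric-uniform init (Glorot-style), seeded by the caller.
init_weight <- function(d_in, d_out) {
  b <- sqrt(6 / (d_in + d_out))
  matrix(stats::runif(d_in * d_out, -b, b), d_in, d_out)
}
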