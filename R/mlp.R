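# Multi-layer perceptron current maps.
#
# Inputs are stored column-wise (d x K, columns = samples) so layer forward
# passes are single matrix products.  Backpropagation is written by hand and
# verified against central finite differences in the tests; there is no
# autodiff anywhere in the package.

#' Fit an affine input normalizer
#'
#' Maps the per-channel minimum and maximum of the training inputs to -1 and
#' +1.  The perceptron current maps apply this normalization before their
#' first layer so tanh units operate in a well-scaled regime.
#'
#' @param X training inputs, one column per sample (d x K) or a numeric
#'   vector for d = 1.
#' @return a list with fields `lo`, `hi` (class `rmm_normalizer`).
#' @export
fit_normalizer <- function(X) {
  if (is.vector(X)) X <- matrix(X, nrow = 1L)
  if (ncol(X) < 2L) stop_invalid("need at least two samples to fit a normalizer")
  lo <- apply(X, 1L, min)
  hi <- apply(X, 1L, max)
  bad <- which(!(hi > lo))
  if (length(bad))
    stop_invalid("degenerate (constant) input channel(s): ",
                 paste(bad, collapse = ", "))
  structure(list(lo = lo, hi = hi), class = "rmm_normalizer")
}

#' Apply a normalizer
#' @param norm an `rmm_normalizer`.
#' @param X inputs, d x K.
#' @return normalized inputs in \[-1, 1\] on the training range.
#' @export
apply_normalizer <- function(norm, X) {
  (2 * (X - norm$lo)) / (norm$hi - norm$lo) - 1
}

# identity normalizer (used by toy fixtures)
identity_normalizer <- function(d) {
  structure(list(lo = rep(-1, d), hi = rep(1, d)), class = "rmm_normalizer")
}

#' Initialize a perceptron with the Nguyen-Widrow heuristic
#'
#' Hidden-layer weight rows get random directions rescaled to magnitude
#' `0.7 * H^(1/fan_in)`; biases are drawn uniformly on \[-1, 1\] so the tanh
#' units are spread over the normalized input range.  The linear output
#' layer is drawn uniformly and scaled by `1/sqrt(H)`; it has no bias.
#' Uses the current RNG state (seed it at the circuit level).
#'
#' @param d_in input dimension (after normalization).
#' @param hidden integer vector of hidden-layer widths (length L >= 1).
#' @param norm an `rmm_normalizer` for the raw inputs.
#' @return a list with `W` (L+1 matrices), `b` (L vectors), `norm`
#'   (class `rmm_mlp`).
#' @export
mlp_init <- function(d_in, hidden, norm = identity_normalizer(d_in)) {
  stopifnot(length(hidden) >= 1L, all(hidden >= 1L))
  L <- length(hidden)
  W <- vector("list", L + 1L)
  b <- vector("list", L)
  din <- d_in
  for (l in seq_len(L)) {
    H <- hidden[l]
    Wl <- matrix(stats::runif(H * din, -0.5, 0.5), H, din)
    rn <- sqrt(rowSums(Wl^2))
    scale <- 0.7 * H^(1 / din)
    W[[l]] <- Wl * (scale / pmax(rn, 1e-12))
    b[[l]] <- stats::runif(H, -1, 1)
    din <- H
  }
  W[[L + 1L]] <- matrix(stats::runif(hidden[L], -1, 1) / sqrt(hidden[L]),
                        1L, hidden[L])
  structure(list(W = W, b = b, norm = norm), class = "rmm_mlp")
}

#' Perceptron forward pass
#'
#' Computes `W[L+1] tanh(W[L] ... tanh(W[1] q(X) + b[1]) ... + b[L])` where
#' `q` is the stored affine normalizer.
#'
#' @param p an `rmm_mlp`.
#' @param X raw inputs, d x K (or a vector for one sample).
#' @param cache if TRUE also return layer activations for backprop.
#' @return numeric row (1 x K) of outputs, or a list `(y, acts)` if
#'   `cache = TRUE`.
#' @export
mlp_forward <- function(p, X, cache = FALSE) {
  if (is.vector(X)) X <- matrix(X, ncol = 1L)
  if (nrow(X) != length(p$norm$lo))
    stop_invalid("perceptron input has ", nrow(X), " channels; expected ",
                 length(p$norm$lo))
  L <- length(p$b)
  acts <- vector("list", L + 1L)
  A <- apply_normalizer(p$norm, X)
  acts[[1L]] <- A
  for (l in seq_len(L)) {
    A <- tanh(p$W[[l]] %*% A + p$b[[l]])
    acts[[l + 1L]] <- A
  }
  y <- p$W[[L + 1L]] %*% A
  if (cache) list(y = y, acts = acts) else y
}

# Backward pass.  `dy` is the 1 x K adjoint of the output.  Returns per-layer
# weight/bias gradients and the gradient with respect to the *raw* inputs
# (chain rule through the normalizer scaling 2/(hi - lo)).
mlp_backprop <- function(p, acts, dy) {
  L <- length(p$b)
  gW <- vector("list", L + 1L)
  gb <- vector("list", L)
  delta <- dy                                  # adjoint at current layer output
  gW[[L + 1L]] <- delta %*% t(acts[[L + 1L]])
  back <- t(p$W[[L + 1L]]) %*% delta           # adjoint at tanh output of layer L
  for (l in L:1) {
    dz <- back * (1 - acts[[l + 1L]]^2)        # through tanh
    gW[[l]] <- dz %*% t(acts[[l]])
    gb[[l]] <- rowSums(dz)
    back <- t(p$W[[l]]) %*% dz
  }
  gX <- back * (2 / (p$norm$hi - p$norm$lo))
  list(gW = gW, gb = gb, gX = gX)
}

# Gradient of the scalar output with respect to the raw inputs at each
# column of X; returns d x K.  Used for exact Jacobians in the admittance
# layer and for BPTT input adjoints.
mlp_input_grad <- function(p, X) {
  fw <- mlp_forward(p, X, cache = TRUE)
  K <- ncol(fw$y)
  mlp_backprop(p, fw$acts, matrix(1, 1L, K))$gX
}

# flatten / unflatten MLP parameters (traversal order W1,b1,...,WL,bL,WL+1)
mlp_param_vec <- function(p) {
  L <- length(p$b)
  out <- list()
  for (l in seq_len(L)) out <- c(out, list(as.numeric(p$W[[l]]), p$b[[l]]))
  c(unlist(out), as.numeric(p$W[[L + 1L]]))
}

mlp_set_params <- function(p, v) {
  L <- length(p$b)
  pos <- 0L
  for (l in seq_len(L)) {
    nw <- length(p$W[[l]])
    p$W[[l]][] <- v[pos + seq_len(nw)]; pos <- pos + nw
    nb <- length(p$b[[l]])
    p$b[[l]][] <- v[pos + seq_len(nb)]; pos <- pos + nb
  }
  nw <- length(p$W[[L + 1L]])
  p$W[[L + 1L]][] <- v[pos + seq_len(nw)]; pos <- pos + nw
  stopifnot(pos == length(v))
  p
}

mlp_n_params <- function(p) {
  sum(lengths(p$W)) + sum(lengths(p$b))
}

# gradient list -> vector in the same traversal order
mlp_grad_vec <- function(g, L) {
  out <- list()
  for (l in seq_len(L)) out <- c(out, list(as.numeric(g$gW[[l]]), g$gb[[l]]))
  c(unlist(out), as.numeric(g$gW[[L + 1L]]))
}
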