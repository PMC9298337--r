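# --- small dense networks in base R -------------------------------------
# two ReLU hidden layers; the policy head ends in a K-way softmax, the
# critic in a single linear unit

mlp_init <- function(input_dim, hidden, output_dim, out_scale = 0.01) {
  he <- function(fan_in, fan_out, scale = sqrt(2 / fan_in))
    matrix(stats::rnorm(fan_in * fan_out, 0, scale), fan_in, fan_out)
  list(W1 = he(input_dim, hidden), b1 = numeric(hidden),
       W2 = he(hidden, hidden),    b2 = numeric(hidden),
       W3 = he(hidden, output_dim, out_scale), b3 = numeric(output_dim))
}

# X: n x input_dim; returns pre-activations for backprop
mlp_forward <- function(net, X) {
  Z1 <- sweep(X %*% net$W1, 2, net$b1, `+`); A1 <- pmax(Z1, 0)
  Z2 <- sweep(A1 %*% net$W2, 2, net$b2, `+`); A2 <- pmax(Z2, 0)
  U <- sweep(A2 %*% net$W3, 2, net$b3, `+`)
  list(X = X, Z1 = Z1, A1 = A1, Z2 = Z2, A2 = A2, U = U)
}

mlp_backward <- function(net, fw, dU) {
  dW3 <- crossprod(fw$A2, dU); db3 <- colSums(dU)
  dA2 <- dU %*% t(net$W3); dZ2 <- dA2 * (fw$Z2 > 0)
  dW2 <- crossprod(fw$A1, dZ2); db2 <- colSums(dZ2)
  dA1 <- dZ2 %*% t(net$W2); dZ1 <- dA1 * (fw$Z1 > 0)
  dW1 <- crossprod(fw$X, dZ1); db1 <- colSums(dZ1)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2, W3 = dW3, b3 = db3)
}

softmax_rows <- function(U) {
  E <- exp(U - apply(U, 1, max))
  E / rowSums(E)
}

#' Policy network
#'
#' A dense network with two ReLU hidden layers and a K-way softmax head
#' mapping the trial state vector to allocation probabilities pi(k | s).
#'
#' @param input_dim state dimension (3K - 1; 14 for the default grid).
#' @param K number of doses.
#' @param hidden units per hidden layer.
#' @param seed seed for the weight initialization.
#' @return object of class `policy_net`.
#' @export
policy_network <- function(input_dim = 14, K = 5, hidden = 256,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  structure(c(mlp_init(input_dim, hidden, K),
              list(input_dim = input_dim, K = K, hidden = hidden)),
            class = "policy_net")
}

#' Forward pass of a policy network
#'
#' @param net a [policy_network()].
#' @param s a state vector, or a matrix of states (one per row).
#' @return probability vector over the K doses (or a matrix, one row per
#'   state); rows sum to 1.
#' @export
policy_forward <- function(net, s) {
  S <- if (is.matrix(s)) s else matrix(s, nrow = 1)
  if (ncol(S) != net$input_dim) stop("state dimension mismatch")
  P <- softmax_rows(mlp_forward(net, S)$U)
  if (is.matrix(s)) P else drop(P)
}

#' Deploy a policy for one block
#'
#' Draws the block's subjects i.i.d. from pi(. | s) and tallies them
#' (`mode = "sample"`, the default), or apportions the block
#' deterministically by efficient rounding of pi (`mode = "round"`).
#'
#' @param net a [policy_network()] (or the `net` of a trained policy).
#' @param s state vector.
#' @param N_block block size.
#' @param rng optional trial RNG stream set (used by [run_trial()]); when
#'   `NULL` the current R stream is used.
#' @param mode `"sample"` or `"round"`.
#' @return integer per-dose counts summing to `N_block`.
#' @export
deploy_policy <- function(net, s, N_block, rng = NULL,
                          mode = c("sample", "round")) {
  mode <- match.arg(mode)
  p <- policy_forward(net, s)
  if (mode == "round") return(efficient_round(p / sum(p), N_block))
  draw <- function() sample.int(net$K, N_block, replace = TRUE, prob = p)
  ks <- if (is.null(rng)) draw() else with_stream(rng, "alloc", draw())
  tabulate(ks, nbins = net$K)
}

#' Save / load a policy
#'
#' Checkpoints are plain RDS files holding the network parameters and the
#' training log.
#'
#' @param policy an `rl_policy` (from [train_policy()]) or `policy_net`.
#' @param path file path.
#' @export
save_policy <- function(policy, path) {
  saveRDS(policy, path)
  invisible(path)
}

#' @rdname save_policy
#' @export
load_policy <- function(path) readRDS(path)
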