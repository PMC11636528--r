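# epsilon-stabilized proportional redistribution of one layer's relevance:
# contributions z_j share R_up in proportion to z_j / (sum(z) + eps*sign).
# The bias is deliberately left out of the denominator so that relevance is
# (approximately) conserved down to the inputs.
lrp_redistribute <- function(z, r_up, eps) {
  denom <- sum(z)
  denom <- denom + eps * sign(denom)
  if (denom == 0) return(numeric(length(z)))
  z / denom * r_up
}

#' Layer-wise relevance propagation for the sparse network
#'
#' Redistributes the classifier output back through the network with the
#' epsilon rule: at each layer, an upstream node's relevance is shared
#' among its inputs in proportion to their contributions
#' `z_j = a_j * w_j`, stabilized by `eps * sign(sum z)`. The starting
#' relevance is the output activation for the positive class, or
#' `1 - activation` (with the output weights sign-flipped) for the negative
#' class, so relevance always measures contribution *toward* the requested
#' class. Inputs whose outgoing weights are all structurally absent or zero
#' receive relevance exactly 0, and the total input relevance matches the
#' output relevance up to the stabilizer.
#'
#' @param weights `network_weights` from [train_network()].
#' @param x one feature vector.
#' @param target_class 0 or 1.
#' @param eps stabilizer (default 1e-6).
#' @return numeric vector of per-input relevance values.
#' @export
lrp_relevance <- function(weights, x, target_class = 1L, eps = 1e-6) {
  spec <- weights$spec
  x <- as.numeric(x)
  if (length(x) != spec$n_inputs) stop("feature width does not match network")
  if (!target_class %in% c(0, 1)) stop("target_class must be 0 or 1")
  fw <- nn_forward(weights, x)
  a1 <- as.numeric(fw$a1)
  a2 <- as.numeric(fw$a2)
  a3 <- as.numeric(fw$a3)

  if (target_class == 1) {
    w3 <- weights$w3
    r_out <- a3
  } else {
    w3 <- -weights$w3  # class-0 logit is the negated class-1 logit
    r_out <- 1 - a3
  }

  # output <- second hidden layer
  r2 <- lrp_redistribute(a2 * w3, r_out, eps)

  # second <- first hidden layer (blockwise: each h2 node has its own pool)
  z1 <- a1 * weights$w2
  r1 <- numeric(spec$n_h1)
  for (b in seq_len(spec$n_h2)) {
    hh <- which(spec$block_of_h1 == b)
    r1[hh] <- lrp_redistribute(z1[hh], r2[b], eps)
  }

  # first hidden layer <- inputs: each h1 node has a single input edge, so
  # proportional redistribution hands its whole relevance to that input --
  # except a zero contribution (structurally absent or silent edge), which
  # gets nothing
  z0 <- x[spec$input_of_h1] * weights$w1
  share <- ifelse(z0 == 0, 0, r1)
  as.numeric(rowsum(share, spec$input_of_h1))
}
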