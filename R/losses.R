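# Pretraining objectives: ZIP count downsampling, ZINB/NB/MSE reconstruction
# likelihoods, hierarchical classification loss, contrastive disentanglement.
# Each loss has an internal *_grad companion returning analytic derivatives.

#' Downsample a count profile with a zero-inflated Poisson
#'
#' Per element: draw `p ~ Poisson(x * r * s)` and `u ~ Uniform(0,1)`, keep the
#' gene iff `u >= r * s`, and return `max((x - p) * keep, 0)`. Roughly half of
#' the removed counts come from Poisson thinning and half from complete
#' dropout of genes; the realized removed fraction depends (slightly) on `r`.
#'
#' @param x nonnegative integer counts (vector or matrix).
#' @param r dropout fraction in \[0, 1\] (default 0.6).
#' @param s scale hyperparameter (default 0.55); `r * s` must be < 1.
#' @return downsampled counts, same shape, `0 <= out <= x`.
#' @export
downsample <- function(x, r = 0.6, s = 0.55) {
  if (any(x < 0) || any(x != floor(x))) stop("x must be nonnegative integers")
  if (r < 0 || r > 1) stop("r must be in [0, 1]")
  if (r * s >= 1) stop("r * s must be < 1")
  if (r == 0) return(x)
  p <- stats::rpois(length(x), as.numeric(x) * r * s)
  keep <- stats::runif(length(x)) >= r * s
  out <- pmax((as.numeric(x) - p) * keep, 0)
  if (is.matrix(x)) out <- matrix(out, nrow(x), ncol(x), dimnames = dimnames(x))
  out
}

# log NB(x | mu, theta) in log space (valid for x >= 0)
log_nb <- function(x, mu, theta) {
  lgamma(x + theta) - lgamma(theta) - lgamma(x + 1) +
    theta * (log(theta) - log(theta + mu)) +
    x * (log(mu) - log(theta + mu))
}

# per-entry ZINB log-likelihood; pi = sigmoid(rho)
zinb_loglik <- function(x, mu, theta, rho) {
  lp <- -softplus(-rho)                 # log pi
  lq <- -softplus(rho)                  # log (1 - pi)
  ll <- lq + log_nb(x, mu, theta)
  z <- x == 0
  if (any(z)) {
    g <- theta * (log(theta) - log(theta + mu))
    a <- lp[z]; b <- lq[z] + g[z]
    m <- pmax(a, b)
    ll[z] <- m + log(exp(a - m) + exp(b - m))
  }
  ll
}

#' Mean ZINB negative log-likelihood
#'
#' The reconstruction loss: `-mean(log L(x | mu, theta, pi))` with
#' `L = pi * I(x = 0) + (1 - pi) * NB(x | mu, theta)` and `pi = sigmoid(rho)`,
#' computed in log space via log-gamma.
#'
#' @param x observed counts.
#' @param mu,theta,rho ZINB parameters per entry (theta is the NB
#'   inverse-dispersion; rho the zero-inflation logit).
#' @return scalar mean negative log-likelihood.
#' @export
zinb_nll <- function(x, mu, theta, rho) {
  stopifnot(length(mu) == length(x), length(theta) == length(x),
            length(rho) == length(x))
  if (any(mu <= 0) || any(theta <= 0)) stop("mu and theta must be > 0")
  ll <- zinb_loglik(as.numeric(x), as.numeric(mu), as.numeric(theta),
                    as.numeric(rho))
  if (any(!is.finite(ll)))
    stop("non-finite ZINB log-likelihood at entries: ",
         paste(utils::head(which(!is.finite(ll)), 5L), collapse = ", "))
  -mean(ll)
}

#' Mean NB negative log-likelihood (no zero inflation)
#' @inheritParams zinb_nll
#' @return scalar mean negative log-likelihood.
#' @export
nb_nll <- function(x, mu, theta) {
  ll <- log_nb(as.numeric(x), as.numeric(mu), as.numeric(theta))
  if (any(!is.finite(ll))) stop("non-finite NB log-likelihood")
  -mean(ll)
}

#' Mean squared error on log-transformed counts
#' @param pred decoded log2 count values.
#' @param x observed counts.
#' @return scalar MSE between `pred` and `log2(x + 1)`.
#' @export
mse_loss <- function(pred, x) mean((as.numeric(pred) - log2(as.numeric(x) + 1))^2)

# gradients of the per-entry NLL wrt (mu, theta, rho); `zero_inflated = FALSE`
# gives the NB loss (rho ignored). Returns per-entry derivative vectors.
zinb_nll_grad <- function(x, mu, theta, rho, zero_inflated = TRUE) {
  x <- as.numeric(x)
  tm <- theta + mu
  dll_mu <- x / mu - (x + theta) / tm
  dll_th <- digamma(x + theta) - digamma(theta) + log(theta / tm) +
    (mu - x) / tm
  if (!zero_inflated)
    return(list(dmu = -dll_mu, dtheta = -dll_th, drho = rep(0, length(x))))
  pi_ <- sigmoid(rho)
  dll_rho <- rep(-1, length(x)) * pi_
  z <- x == 0
  if (any(z)) {
    lp <- -softplus(-rho[z]); lq <- -softplus(rho[z])
    g <- theta[z] * (log(theta[z]) - log(tm[z]))
    a <- lp; b <- lq + g
    m <- pmax(a, b)
    ll0 <- m + log(exp(a - m) + exp(b - m))
    wp <- exp(a - ll0); wq <- exp(b - ll0)
    dll_mu[z] <- wq * (-theta[z] / tm[z])
    dll_th[z] <- wq * (log(theta[z] / tm[z]) + mu[z] / tm[z])
    dll_rho[z] <- wp * (1 - pi_[z]) - wq * pi_[z]
  }
  list(dmu = -dll_mu, dtheta = -dll_th, drho = -dll_rho)
}

#' Hierarchical classification loss
#'
#' Softmax cross-entropy over leaf logits; when the label is an internal
#' ontology node, the descendant-leaf logit block is collapsed to a single
#' logit by log-sum-exp, and the cross-entropy is taken against that collapsed
#' position (equivalently: `LSE(all logits) - LSE(descendant logits)`). A leaf
#' label reduces to standard softmax cross-entropy.
#'
#' @param logits numeric vector of leaf logits named by leaf label (length
#'   `|T|`).
#' @param label a node of `onto` (leaf or internal).
#' @param onto the class [ontology()].
#' @return scalar loss.
#' @export
hierarchical_ce <- function(logits, label, onto) {
  if (!label %in% onto$nodes) stop("label not in the ontology: ", label)
  if (is.null(names(logits))) names(logits) <- onto$leaves
  if (length(logits) != length(onto$leaves))
    stop("logits length must equal the number of leaves")
  D <- leaf_descendants(onto, label)
  logsumexp(logits) - logsumexp(logits[D])
}

# batched loss + gradient; labels may contain NA (unknown -> contributes 0).
# Z: b x |T| logits (columns in onto$leaves order). Mean over labeled cells.
hierarchical_ce_grad <- function(Z, labels, onto) {
  leaves <- onto$leaves
  dZ <- matrix(0, nrow(Z), ncol(Z))
  known <- which(!is.na(labels))
  if (!length(known)) return(list(loss = 0, dZ = dZ, n = 0L))
  total <- 0
  for (i in known) {
    z <- Z[i, ]
    D <- match(leaf_descendants(onto, labels[i]), leaves)
    p <- softmax_vec(z)
    pd <- softmax_vec(z[D])
    total <- total + (logsumexp(z) - logsumexp(z[D]))
    g <- p
    g[D] <- g[D] - pd
    dZ[i, ] <- g
  }
  list(loss = total / length(known), dZ = dZ / length(known),
       n = length(known))
}

#' Contrastive disentanglement loss
#'
#' Mean over all ordered pairs (including self-pairs) of `1 - cos(e_i, e_j)`
#' (`sign = "as_printed"`) or `1 + cos(e_i, e_j)` (`sign = "repel"`, which
#' actively pushes the embeddings apart).
#'
#' @param E numeric matrix, one embedding per row (all rows nonzero).
#' @param sign `"as_printed"` or `"repel"`.
#' @return scalar in \[0, 2\].
#' @export
contrastive_loss <- function(E, sign = c("as_printed", "repel")) {
  contrastive_grad(E, match.arg(sign))$loss
}

contrastive_grad <- function(E, sign = "as_printed") {
  m <- nrow(E)
  nrm <- sqrt(rowSums(E^2))
  if (any(nrm == 0)) stop("zero-norm embedding in contrastive loss")
  U <- E / nrm                            # unit rows
  C <- tcrossprod(U)                      # cosine matrix
  sgn <- if (sign == "as_printed") -1 else 1   # d loss / d cos
  loss <- mean(1 + sgn * C)
  # dL/dU_i = (sgn/m^2) * 2 * sum_j U_j (ordered pairs; self-pair grad is 0
  # since cos(e,e) = 1 identically)
  S <- colSums(U)
  dU <- (2 * sgn / m^2) * (matrix(S, m, ncol(E), byrow = TRUE) - U)
  # chain through normalization: dE_i = (I - U_i U_i^T) dU_i / |E_i|
  dE <- (dU - U * rowSums(dU * U)) / nrm
  list(loss = loss, dE = dE)
}
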