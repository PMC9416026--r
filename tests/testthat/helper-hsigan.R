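# Shared fixtures: everything is generated in code at test time.

tiny_params <- function(bands = 8L, seed = 1L, height = 16L, width = 16L, ...)
  phantom_params(height = height, width = width, bands = bands, seed = seed,
                 ...)

# central finite-difference gradient of `fn()` w.r.t. one entry of the
# array `layer[[pname]]`
numgrad_param <- function(layer, pname, idx, fn, eps = 1e-6) {
  orig <- layer[[pname]]
  pert <- orig
  pert[idx] <- orig[idx] + eps
  layer[[pname]] <- pert
  up <- fn()
  pert[idx] <- orig[idx] - eps
  layer[[pname]] <- pert
  dn <- fn()
  layer[[pname]] <- orig
  (up - dn) / (2 * eps)
}

# brute-force principal matrix square root through the (generally
# non-symmetric) eigendecomposition -- the independent oracle for the
# Frechet-distance trace term
sqrtm_oracle <- function(A) {
  e <- eigen(A)
  Re(e$vectors %*% diag(sqrt(as.complex(e$values)), nrow(A)) %*%
       solve(e$vectors))
}

fid_oracle <- function(mu1, S1, mu2, S2) {
  sum((mu1 - mu2)^2) + sum(diag(S1 + S2 - 2 * sqrtm_oracle(S1 %*% S2)))
}

moments <- function(mu, sigma, n = 10L)
  structure(list(mu = mu, sigma = as.matrix(sigma), n = n),
            class = "feature_moments")

random_psd <- function(p) {
  A <- matrix(rnorm(p * p), p)
  crossprod(A) / p + diag(0.1, p)
}
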