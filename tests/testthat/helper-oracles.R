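# Independent oracles used across the suite.

# Exact batch posterior of the random-walk + noise model by direct joint
# complex-Gaussian conditioning. States 0..I with prior covariance
# K[i,u] = sigma02 + min(i,u) * sigma_v2 and mean z0; observations on 1..I.
batch_posterior <- function(y, sigma_eps2, sigma_v2, z0, sigma02) {
  I <- length(y)
  K <- outer(0:I, 0:I, function(a, b) sigma02 + pmin(a, b) * sigma_v2)
  H <- cbind(0, diag(I))
  Syy <- H %*% K %*% t(H) + sigma_eps2 * diag(I)
  Kxy <- K %*% t(H)
  mu <- rep(z0, I + 1) + Kxy %*% solve(Syy, y - rep(z0, I))
  P <- K - Kxy %*% solve(Syy, t(Kxy))
  # filtered mean/var of state i given y[1:i]
  filt <- lapply(seq_len(I), function(i) {
    Hi <- H[seq_len(i), , drop = FALSE]
    Si <- Hi %*% K %*% t(Hi) + sigma_eps2 * diag(i)
    Kxi <- K %*% t(Hi)
    m <- rep(z0, I + 1) + Kxi %*% solve(Si, y[seq_len(i)] - rep(z0, i))
    V <- K - Kxi %*% solve(Si, t(Kxi))
    list(mean = m[i + 1], var = Re(V[i + 1, i + 1]))
  })
  list(sm_mean = mu[-1], sm_mean0 = mu[1],
       sm_var = Re(diag(P))[-1], sm_var0 = Re(P[1, 1]),
       lag1 = Re(P[cbind(1:I, 2:(I + 1))]),    # cov(state i-1, state i)
       cov = Re(P),
       filt_mean = sapply(filt, `[[`, "mean"),
       filt_var = sapply(filt, `[[`, "var"))
}

rand_cplx <- function(n, sd = 1) {
  complex(real = stats::rnorm(n, sd = sd),
          imaginary = stats::rnorm(n, sd = sd))
}

# Exhaustive best ridge path for tiny TFRs (the DP oracle).
ridge_enumerate <- function(A, lam) {
  S <- nrow(A); I <- ncol(A)
  paths <- as.matrix(do.call(expand.grid, rep(list(seq_len(S)), I)))
  score <- apply(paths, 1L, function(p) {
    sum(A[cbind(p, seq_len(I))]) -
      (if (I > 1) lam * sum(abs(diff(p))) else 0)
  })
  list(best = max(score), path = paths[which.max(score), ])
}

# 1-D transportation LP solved independently with scipy.optimize.linprog
# (exact transport optimum on a tiny instance).
emd_lp_oracle <- function(pos, p, q) {
  spec <- jsonlite::toJSON(list(pos = pos, p = p, q = q), digits = NA)
  script <- '
import sys, json
import numpy as np
from scipy.optimize import linprog
d = json.load(sys.stdin)
pos, p, q = map(np.asarray, (d["pos"], d["p"], d["q"]))
n = len(pos)
cost = np.abs(pos[:, None] - pos[None, :]).ravel()
A_eq, b_eq = [], []
for i in range(n):
    r = np.zeros((n, n)); r[i, :] = 1
    A_eq.append(r.ravel()); b_eq.append(p[i])
for j in range(n):
    c = np.zeros((n, n)); c[:, j] = 1
    A_eq.append(c.ravel()); b_eq.append(q[j])
res = linprog(cost, A_eq=np.array(A_eq), b_eq=np.array(b_eq),
              bounds=(0, None), method="highs")
print(repr(res.fun))
'
  py <- tempfile(fileext = ".py")
  writeLines(script, py)
  out <- system2("python", py, input = as.character(spec), stdout = TRUE)
  unlink(py)
  as.numeric(out[length(out)])
}

# small noisy benchmark records used by several files
noisy_example1 <- function(seed = 7) add_noise(gen_example("example1"), 0.1, seed = seed)

# quick random spectral observations
rand_obs <- function(S, I, sd = 1) matrix(rand_cplx(S * I, sd), S, I)
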