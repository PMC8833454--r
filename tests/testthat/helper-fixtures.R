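# shared fixtures, built in code and memoized per test session

.fixture_env <- new.env(parent = emptyenv())

fixture_anatomy <- function() {
  if (is.null(.fixture_env$anatomy))
    .fixture_env$anatomy <- make_phantom_anatomy(c(16L, 16L, 16L), 4L, 0.1,
                                                 seed = 1L)
  .fixture_env$anatomy
}

rand_volume <- function(shape = c(5L, 5L, 5L), seed = 1L, affine = diag(4)) {
  set.seed(seed)
  volume(array(runif(prod(shape)), dim = shape), affine)
}

# literal Benjamini-Hochberg step-up, written directly from the definition
bh_oracle <- function(p, q) {
  m <- length(p)
  ps <- sort(p)
  k_ok <- 0
  for (k in seq_len(m)) if (ps[k] <= k * q / m) k_ok <- k
  if (k_ok == 0) return(rep(FALSE, m))
  p <= ps[k_ok]
}

# independent SVR weight route (e1071, also libsvm but a separate code path)
e1071_weights <- function(X, y, c, epsilon = 0.1) {
  m <- e1071::svm(X, y, type = "eps-regression", kernel = "linear",
                  cost = c, epsilon = epsilon, scale = FALSE)
  drop(t(m$SV) %*% m$coefs)
}
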