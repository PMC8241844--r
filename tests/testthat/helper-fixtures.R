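# Shared fixtures and independent oracles for the test suite.

test_geom <- function(shape = c(8L, 8L, 8L), vox = 2) {
  aff <- diag(c(rep(vox, 3), 1))
  aff[1:3, 4] <- -vox * shape / 2
  grid_geometry(shape, aff)
}

lesion_from_idx <- function(shape, idx) {
  arr <- array(0, dim = shape)
  arr[idx] <- 1
  arr
}

# n random blob-free Bernoulli lesions (not connected; fine for masking and
# flattening tests, which do not care about lesion shape)
random_cohort <- function(n = 20, shape = c(10L, 10L, 10L), seed = 1,
                          p = 0.15) {
  set.seed(seed)
  lesions <- lapply(seq_len(n), function(i) {
    arr <- array(stats::rbinom(prod(shape), 1, p), dim = shape)
    if (sum(arr) == 0) arr[1L] <- 1
    arr
  })
  lesion_cohort(lesions, stats::rnorm(n), test_geom(shape))
}

# small, fast simulation config: 16^3 grid, modest lesion sizes
fast_config <- function(n_subjects = 60, seed = 1, ...) {
  simulation_config(n_subjects = n_subjects, grid_shape = c(16L, 16L, 16L),
                    volume_lognormal_params = c(log(60), 0.9),
                    placement_bias_sd = c(2.5, 3, 3), seed = seed, ...)
}

# Independent connected-component oracle: plain R flood fill with an explicit
# stack, scanning neighbor offsets per voxel.
flood_fill_oracle <- function(arr, connectivity = 26) {
  shp <- dim(arr)
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  m <- rowSums(abs(off))
  off <- off[m > 0 & m <= switch(as.character(connectivity),
                                 "6" = 1, "18" = 2, "26" = 3), , drop = FALSE]
  lab <- array(0L, dim = shp)
  nxt <- 0L
  todo <- which(arr != 0)
  for (s in todo) {
    if (lab[s] != 0L) next
    nxt <- nxt + 1L
    stack <- s
    lab[s] <- nxt
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      vi <- arrayInd(v, shp)
      for (r in seq_len(nrow(off))) {
        w <- vi + off[r, ]
        if (any(w < 1) || any(w > shp)) next
        wl <- w[1] + (w[2] - 1) * shp[1] + (w[3] - 1) * shp[1] * shp[2]
        if (arr[wl] != 0 && lab[wl] == 0L) {
          lab[wl] <- nxt
          stack <- c(stack, wl)
        }
      }
    }
  }
  lab
}

# Two labelings define the same partition of the foreground?
same_partition <- function(a, b) {
  fa <- which(a != 0)
  fb <- which(b != 0)
  if (!identical(fa, fb)) return(FALSE)
  key <- paste(a[fa], b[fa])
  length(unique(key)) == length(unique(a[fa])) &&
    length(unique(key)) == length(unique(b[fb]))
}

# Brute-force epsilon-SVR dual by exhaustive KKT active-set enumeration:
# each sample is in one of 5 states (inactive; alpha free; alpha = C;
# alpha* free; alpha* = C); every combination is solved as a linear KKT
# system and feasibility-checked; the feasible solution maximizing the dual
# objective is returned. Exponential in n -- intended for n <= 7.
svr_dual_enum <- function(K, y, C, eps, tol = 1e-9) {
  n <- length(y)
  states <- as.matrix(expand.grid(rep(list(1:5), n)))
  best <- NULL
  best_obj <- -Inf
  obj <- function(dc) -0.5 * drop(t(dc) %*% K %*% dc) -
    eps * sum(abs(dc)) + sum(y * dc)
  for (s in seq_len(nrow(states))) {
    st <- states[s, ]
    free <- which(st == 2 | st == 4)
    dc <- numeric(n)
    dc[st == 3] <- C
    dc[st == 5] <- -C
    nf <- length(free)
    if (nf == 0) next  # intercept undetermined; generic fixtures have free SVs
    A <- matrix(0, nf + 1, nf + 1)
    rhs <- numeric(nf + 1)
    for (r in seq_len(nf)) {
      i <- free[r]
      A[r, seq_len(nf)] <- K[i, free]
      A[r, nf + 1] <- 1
      tgt <- if (st[i] == 2) y[i] - eps else y[i] + eps
      rhs[r] <- tgt - sum(K[i, -free, drop = FALSE] %*% dc[-free])
    }
    A[nf + 1, seq_len(nf)] <- 1
    rhs[nf + 1] <- -sum(dc[-free])
    sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
    if (is.null(sol)) next
    dc[free] <- sol[seq_len(nf)]
    b <- sol[nf + 1]
    if (any(st == 2 & (dc < -tol | dc > C + tol)) ||
        any(st == 4 & (dc > tol | dc < -C - tol))) next
    g <- drop(K %*% dc) + b - y
    ok <- all(
      (st != 1 | (g >= -eps - tol & g <= eps + tol)) &
      (st != 3 | g <= -eps + tol) &
      (st != 5 | g >= eps - tol))
    if (!ok) next
    o <- obj(dc)
    if (o > best_obj) {
      best_obj <- o
      best <- list(dual_coef = dc, intercept = b, obj = o)
    }
  }
  best
}

# assemble an svr_model by hand (for back-projection unit tests)
manual_svr_model <- function(X, dual_coef, intercept = 0, gamma = 0.1) {
  structure(list(dual_coef = dual_coef, support = which(dual_coef != 0),
                 intercept = intercept,
                 params = svr_hyperparams(C = 1, gamma = gamma),
                 X = X,
                 fingerprint = lesionmap:::data_fingerprint(X, 0)),
            class = "svr_model")
}
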