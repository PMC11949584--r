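# Evaluate `code` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is untouched. seed = NULL runs on the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

#' Hemodynamic (Balloon-Windkessel) parameters
#'
#' Biophysical constants of the forward model mapping neural activity to
#' BOLD. Defaults follow the standard values of the DCM lineage this class
#' of simulators descends from.
#'
#' @param kappa Vasodilatory signal decay rate, 1/s.
#' @param gamma Flow-dependent elimination rate, 1/s.
#' @param tau Hemodynamic transit time, s.
#' @param alpha_grubb Vessel stiffness exponent (Grubb's exponent),
#'   unitless, in (0, 1).
#' @param rho_oxy Resting oxygen extraction fraction, unitless, in (0, 1).
#' @param v0 Resting blood volume fraction, unitless, in (0, 1).
#' @return A `hemodynamic_params` object; the BOLD readout coefficients are
#'   derived as k1 = 7 rho, k2 = 2, k3 = 2 rho - 0.2.
#' @export
hemodynamic_params <- function(kappa = 0.65, gamma = 0.41, tau = 0.98,
                               alpha_grubb = 0.32, rho_oxy = 0.34,
                               v0 = 0.02) {
  vals <- c(kappa = kappa, gamma = gamma, tau = tau,
            alpha_grubb = alpha_grubb, rho_oxy = rho_oxy, v0 = v0)
  if (any(vals <= 0)) stop("all hemodynamic parameters must be positive")
  if (any(vals[c("alpha_grubb", "rho_oxy", "v0")] >= 1)) {
    stop("alpha_grubb, rho_oxy and v0 must lie in (0, 1)")
  }
  structure(list(kappa = kappa, gamma = gamma, tau = tau,
                 alpha_grubb = alpha_grubb, rho_oxy = rho_oxy, v0 = v0,
                 k1 = 7 * rho_oxy, k2 = 2, k3 = 2 * rho_oxy - 0.2),
            class = "hemodynamic_params")
}

#' Ground-truth generative model
#'
#' The signed directed graph and dynamics parameters of the synthetic
#' benchmark: linear neural dynamics dz/dt = sigma * A z + C u with
#' unit-amplitude Poisson impulse inputs (C = I), later passed through
#' Balloon-Windkessel hemodynamics and sampled at the TR. `A[i, j] != 0`
#' means a ground-truth causal edge i -> j; the diagonal holds the
#' (negative) self-decay. Stability (all eigenvalues of sigma * A with
#' negative real part) is checked at construction.
#'
#' @param adjacency_signed Signed N x N coupling matrix A.
#' @param sigma Positive global coupling gain.
#' @param poisson_rate Poisson input rate, events per second per node.
#' @param impulse_amplitude Amplitude added to z per input event.
#' @param dt_seconds Euler integration step, s; must divide `tr_seconds`.
#' @param duration_seconds Total simulated time, s.
#' @param tr_seconds Sampling interval of the synthetic scan, s.
#' @param seed Integer seed for reproducibility.
#' @param node_labels Optional node names; default `n1..nN`.
#' @return A `ground_truth_model` object.
#' @export
ground_truth_model <- function(adjacency_signed, sigma = 1,
                               poisson_rate = 0.5, impulse_amplitude = 1,
                               dt_seconds = 0.01, duration_seconds = 600,
                               tr_seconds = 1.2, seed = 1L,
                               node_labels = NULL) {
  A <- as.matrix(adjacency_signed)
  if (nrow(A) != ncol(A)) stop("adjacency_signed must be square")
  if (sigma <= 0) stop("sigma must be positive")
  ev <- eigen(sigma * A, only.values = TRUE)$values
  if (any(Re(ev) >= 0)) {
    stop("unstable dynamics: eigenvalues of sigma * A must all have ",
         "negative real part (max Re = ", signif(max(Re(ev)), 4), ")")
  }
  ratio <- tr_seconds / dt_seconds
  if (abs(ratio - round(ratio)) > 1e-8) {
    stop("dt_seconds must divide tr_seconds (ratio ", ratio, ")")
  }
  if (is.null(node_labels)) node_labels <- paste0("n", seq_len(nrow(A)))
  structure(
    list(adjacency_signed = A, sigma = sigma, poisson_rate = poisson_rate,
         impulse_amplitude = impulse_amplitude, dt_seconds = dt_seconds,
         duration_seconds = duration_seconds, tr_seconds = tr_seconds,
         seed = as.integer(seed), node_labels = node_labels),
    class = "ground_truth_model"
  )
}

#' Random stable cyclic ground-truth graph
#'
#' Draws a signed adjacency with the requested off-diagonal density
#' (expected fraction of the n(n-1) ordered pairs carrying an edge), a
#' requested fraction of connected node pairs made reciprocal (2-cycles,
#' which dominate real cortical connectivity), coupling weights uniform in
#' `weight_range` (a fraction `negative_fraction` flipped negative), and a
#' common negative self-decay on the diagonal. Draws are rejected and
#' resampled until the sigma-scaled continuous dynamics are stable.
#'
#' @param n_nodes Number of nodes.
#' @param density Expected off-diagonal edge density in (0, 1), counted
#'   over ordered pairs.
#' @param bidirectional_fraction Fraction of connected pairs that are
#'   reciprocal, in \[0, 1\].
#' @param weight_range Length-2 positive interval for coupling magnitudes.
#' @param self_decay Negative diagonal value.
#' @param seed Integer seed.
#' @param sigma Gain used for the stability check.
#' @param negative_fraction Fraction of couplings given negative sign.
#' @param max_tries Resampling budget before giving up.
#' @return The signed adjacency matrix.
#' @export
make_random_cyclic_graph <- function(n_nodes, density,
                                     bidirectional_fraction = 0.5,
                                     weight_range = c(0.2, 0.6),
                                     self_decay = -1, seed = 1L,
                                     sigma = 1, negative_fraction = 0,
                                     max_tries = 200L) {
  stopifnot(n_nodes >= 1, density >= 0, density < 1,
            bidirectional_fraction >= 0, bidirectional_fraction <= 1,
            length(weight_range) == 2L, all(weight_range > 0),
            self_decay < 0)
  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      A <- matrix(0, n_nodes, n_nodes)
      diag(A) <- self_decay
      pairs <- which(upper.tri(matrix(0, n_nodes, n_nodes)), arr.ind = TRUE)
      # density is over ordered pairs; a connected pair carries on average
      # (1 + b) ordered edges, so connect density*n(n-1)/(1+b) pairs.
      n_connect <- round(density * n_nodes * (n_nodes - 1) /
                           (1 + bidirectional_fraction))
      n_connect <- min(n_connect, nrow(pairs))
      if (n_connect > 0) {
        sel <- pairs[sample.int(nrow(pairs), n_connect), , drop = FALSE]
        n_bi <- round(bidirectional_fraction * n_connect)
        bi <- rep(c(TRUE, FALSE), c(n_bi, n_connect - n_bi))[
          sample.int(n_connect)]
        for (r in seq_len(n_connect)) {
          u <- sel[r, 1L]; v <- sel[r, 2L]
          draw <- function() {
            w <- stats::runif(1, weight_range[1L], weight_range[2L])
            if (stats::runif(1) < negative_fraction) -w else w
          }
          if (bi[r]) {
            A[u, v] <- draw(); A[v, u] <- draw()
          } else if (stats::runif(1) < 0.5) {
            A[u, v] <- draw()
          } else {
            A[v, u] <- draw()
          }
        }
      }
      ev <- eigen(sigma * A, only.values = TRUE)$values
      if (all(Re(ev) < 0)) return(A)
    }
    stop("no stable graph found after ", max_tries,
         " draws; reduce weight_range or density, or increase |self_decay|")
  })
}

#' Simulate the latent neural dynamics
#'
#' Euler integration of dz/dt = sigma * A z + C u from z(0) = z0, where u
#' is an independent Poisson impulse train per node (C = I): each event
#' adds `impulse_amplitude` to that node's state. Reproducible under the
#' model's seed.
#'
#' @param model A [ground_truth_model()].
#' @param z0 Initial state; default zero.
#' @return Matrix of neural states, (duration / dt) rows x N columns.
#' @export
simulate_neural <- function(model, z0 = NULL) {
  stopifnot(inherits(model, "ground_truth_model"))
  N <- nrow(model$adjacency_signed)
  dt <- model$dt_seconds
  n_steps <- round(model$duration_seconds / dt)
  if (is.null(z0)) z0 <- numeric(N)
  events <- with_seed(model$seed, {
    matrix(stats::rpois(n_steps * N, model$poisson_rate * dt), n_steps, N)
  })
  # Edge convention is A[i, j] != 0 <=> i -> j, so the drift matrix acting
  # on the state vector is the transpose (targets receive from sources):
  # z_{k+1} = (I + dt sigma A') z_k + amplitude * events_k
  M <- diag(N) + dt * model$sigma * t(model$adjacency_signed)
  z <- matrix(0, n_steps, N, dimnames = list(NULL, model$node_labels))
  state <- z0
  amp <- model$impulse_amplitude
  for (k in seq_len(n_steps)) {
    state <- drop(M %*% state) + amp * events[k, ]
    z[k, ] <- state
  }
  if (any(!is.finite(z)) || max(abs(z)) > 1e6) {
    stop("neural simulation diverged (|z| exceeded 1e6): the model is ",
         "numerically unstable at dt = ", dt)
  }
  z
}

# One Euler pass of the Balloon-Windkessel states at step `dt`, with the
# neural drive linearly interpolated onto the sub-step grid when substep>1.
bw_integrate <- function(z, params, dt, substep = 1L) {
  n_steps <- nrow(z); N <- ncol(z)
  h <- dt / substep
  s <- numeric(N); f <- rep(1, N); v <- rep(1, N); q <- rep(1, N)
  bold <- matrix(0, n_steps, N, dimnames = dimnames(z))
  ia <- 1 / params$alpha_grubb
  rho <- params$rho_oxy
  for (k in seq_len(n_steps)) {
    zk <- z[k, ]
    for (sub in seq_len(substep)) {
      fv <- v^(ia - 1)
      E <- 1 - (1 - rho)^(1 / f)
      s_new <- s + h * (zk - params$kappa * s - params$gamma * (f - 1))
      f_new <- f + h * s
      v_new <- v + h * (f - v^ia) / params$tau
      q_new <- q + h * (f * E / rho - q * fv) / params$tau
      s <- s_new; f <- f_new; v <- v_new; q <- q_new
    }
    if (any(f <= 0) || any(v <= 0) || any(q <= 0)) return(NULL)
    bold[k, ] <- params$v0 * (params$k1 * (1 - q) +
                                params$k2 * (1 - q / v) +
                                params$k3 * (1 - v))
  }
  bold
}

#' Balloon-Windkessel hemodynamic forward model
#'
#' Maps neural activity to BOLD through, per node, the vasodilatory signal
#' s, blood inflow f, blood volume v and deoxyhemoglobin content q:
#'
#'   ds/dt = z - kappa s - gamma (f - 1)
#'   df/dt = s
#'   tau dv/dt = f - v^(1/alpha)
#'   tau dq/dt = f (1 - (1 - rho)^(1/f)) / rho - q v^(1/alpha - 1)
#'
#' with readout BOLD = v0 (k1 (1 - q) + k2 (1 - q/v) + k3 (1 - v)). The
#' resting fixed point s = 0, f = v = q = 1 yields BOLD identically 0, so
#' traces are fluctuations around a zero baseline. If state positivity is
#' violated the integration is retried once at half the step before
#' erroring.
#'
#' @param z Neural state matrix (time steps x nodes) on a `dt` grid.
#' @param params A [hemodynamic_params()].
#' @param dt Integration step in seconds (the grid of `z`).
#' @return BOLD matrix of the same shape as `z`.
#' @export
balloon_windkessel <- function(z, params = hemodynamic_params(), dt) {
  stopifnot(inherits(params, "hemodynamic_params"), all(is.finite(z)))
  z <- as.matrix(z)
  bold <- bw_integrate(z, params, dt, substep = 1L)
  if (is.null(bold)) {
    bold <- bw_integrate(z, params, dt, substep = 2L)
  }
  if (is.null(bold)) {
    stop("hemodynamic state positivity violated even at half step; ",
         "neural input too large or dt too coarse")
  }
  bold
}

#' Sample a BOLD trace at the scanner TR
#'
#' Decimates a dense BOLD matrix (on the integration `dt` grid) to the TR
#' grid (taking the sample at t = TR, 2 TR, ...), adds white Gaussian
#' measurement noise, and packages the result as a [ts_panel()].
#'
#' @param bold BOLD matrix at resolution `dt`.
#' @param dt Integration step of `bold`, s.
#' @param tr_seconds Sampling interval, s; must be a multiple of `dt`.
#' @param noise_sd Standard deviation of additive measurement noise.
#' @param seed Seed for the noise draw.
#' @param node_labels Optional node names.
#' @return A `ts_panel` with `floor(n_steps * dt / tr)` rows.
#' @export
sample_bold <- function(bold, dt, tr_seconds, noise_sd = 0, seed = 1L,
                        node_labels = colnames(bold)) {
  ratio <- tr_seconds / dt
  if (abs(ratio - round(ratio)) > 1e-8) {
    stop("tr_seconds must be a multiple of dt")
  }
  ratio <- round(ratio)
  idx <- seq.int(ratio, nrow(bold), by = ratio)
  out <- bold[idx, , drop = FALSE]
  if (noise_sd > 0) {
    out <- out + with_seed(seed, {
      matrix(stats::rnorm(length(out), sd = noise_sd), nrow(out), ncol(out))
    })
  }
  ts_panel(out, node_labels = node_labels, tr_seconds = tr_seconds)
}

#' Simulate a full synthetic scan
#'
#' Convenience wrapper composing [simulate_neural()],
#' [balloon_windkessel()] and [sample_bold()] for a ground-truth model.
#'
#' @param model A [ground_truth_model()].
#' @param hemo A [hemodynamic_params()].
#' @param noise_sd Measurement noise SD added at sampling time.
#' @return A `ts_panel` of synthetic BOLD.
#' @export
simulate_bold_panel <- function(model, hemo = hemodynamic_params(),
                                noise_sd = 0) {
  z <- simulate_neural(model)
  bold <- balloon_windkessel(z, hemo, model$dt_seconds)
  sample_bold(bold, model$dt_seconds, model$tr_seconds,
              noise_sd = noise_sd, seed = model$seed + 1L,
              node_labels = model$node_labels)
}

#' Simulate a stationary VAR panel
#'
#' Draws a vector-autoregressive path x(t) = sum_s B_s x(t - s) + e(t)
#' with Gaussian innovations of the given covariance, after a burn-in.
#' Used as a test oracle generator: the ground truth is the nonzero
#' coefficient pattern plus the lag-0 dependence pattern implied by
#' off-diagonal innovation covariance.
#'
#' @param coefficients List of N x N coefficient matrices `B_s`, entry
#'   `B_s[i, j]` the effect of x_i(t - s) on x_j(t), one per lag s >= 1.
#' @param innovation_cov N x N symmetric positive-definite innovation
#'   covariance.
#' @param t_points Number of retained time points.
#' @param seed Integer seed.
#' @param burn_in Discarded initial steps; default 200.
#' @param tr_seconds TR recorded on the output panel.
#' @param node_labels Optional node names.
#' @return A `ts_panel`.
#' @export
simulate_var <- function(coefficients, innovation_cov, t_points, seed = 1L,
                         burn_in = 200L, tr_seconds = 1,
                         node_labels = NULL) {
  if (is.matrix(coefficients)) coefficients <- list(coefficients)
  p <- length(coefficients)
  N <- nrow(innovation_cov)
  stopifnot(all(vapply(coefficients, function(B)
    all(dim(B) == c(N, N)), logical(1))))
  # companion-form stationarity check; note transpose: rows act as sources
  comp <- matrix(0, N * p, N * p)
  for (s in seq_len(p)) {
    comp[seq_len(N), (s - 1L) * N + seq_len(N)] <- t(coefficients[[s]])
  }
  if (p > 1L) {
    comp[N + seq_len(N * (p - 1L)), seq_len(N * (p - 1L))] <-
      diag(N * (p - 1L))
  }
  if (max(Mod(eigen(comp, only.values = TRUE)$values)) >= 1) {
    stop("nonstationary VAR: companion-form spectral radius >= 1")
  }
  ch <- chol(innovation_cov)
  total <- t_points + burn_in
  x <- with_seed(seed, {
    e <- matrix(stats::rnorm(total * N), total, N) %*% ch
    out <- matrix(0, total, N)
    for (t in seq_len(total)) {
      acc <- e[t, ]
      for (s in seq_len(min(p, t - 1L))) {
        acc <- acc + drop(crossprod(coefficients[[s]], out[t - s, ]))
      }
      out[t, ] <- acc
    }
    out
  })
  if (is.null(node_labels)) node_labels <- paste0("n", seq_len(N))
  ts_panel(x[burn_in + seq_len(t_points), , drop = FALSE],
           node_labels = node_labels, tr_seconds = tr_seconds)
}
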