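dcm_nodes <- function() c("temporal_L", "prefrontal_L",
                          "temporal_R", "prefrontal_R")
dcm_inputs_names <- function() {
  as.vector(outer(c("good", "bad", "novel", "familiar"), c("L", "R"),
                  paste, sep = "_"))
}

# hemisphere contralateral to a stimulated hemifield
contra_nodes <- function(hemifield) {
  if (hemifield == "L") c(3L, 4L) else c(1L, 2L)  # temporal, prefrontal
}

#' Specify one bilinear model of the temporal-prefrontal network
#'
#' Four nodes (temporal and prefrontal, left and right hemisphere) and
#' eight inputs (`{good,bad,novel,familiar} x {L,R}` hemifield). The fixed
#' connectivity `A` is identical in every model: negative self-decay on the
#' diagonal (parameterized `-exp(theta)`) and reciprocal
#' temporal-prefrontal connections within each hemisphere. Good and Novel
#' inputs modulate the forward and backward connections of the hemisphere
#' contralateral to the stimulated hemifield. The input scheme sets which
#' nodes receive direct (contralateral) visual drive; the self-modulation
#' scheme sets which inputs get free diagonal entries in their `B` matrix
#' (on all four nodes).
#'
#' @param input_scheme `"temporal"`, `"prefrontal"`, or `"double"`.
#' @param self_mod_scheme `"simple"` (no self-modulation), `"GN"`
#'   (good/novel inputs), or `"GBNF"` (all eight inputs).
#' @return Object of class `dcm_model` with mask matrices and a free-
#'   parameter table.
#' @export
dcm_model <- function(input_scheme = c("temporal", "prefrontal", "double"),
                      self_mod_scheme = c("simple", "GN", "GBNF")) {
  input_scheme <- match.arg(input_scheme)
  self_mod_scheme <- match.arg(self_mod_scheme)
  k <- 4L; m <- 8L
  nodes <- dcm_nodes(); inputs <- dcm_inputs_names()

  A_mask <- matrix(FALSE, k, k, dimnames = list(nodes, nodes))
  # row = target: forward temporal -> prefrontal, backward prefrontal -> temporal
  A_mask[2, 1] <- A_mask[1, 2] <- TRUE
  A_mask[4, 3] <- A_mask[3, 4] <- TRUE

  B_masks <- lapply(inputs, function(nm) {
    Bm <- matrix(FALSE, k, k, dimnames = list(nodes, nodes))
    parts <- strsplit(nm, "_")[[1]]
    if (parts[1] %in% c("good", "novel")) {
      nd <- contra_nodes(parts[2])
      Bm[nd[2], nd[1]] <- TRUE  # forward
      Bm[nd[1], nd[2]] <- TRUE  # backward
    }
    self_on <- switch(self_mod_scheme,
                      simple = FALSE,
                      GN = parts[1] %in% c("good", "novel"),
                      GBNF = TRUE)
    if (self_on) diag(Bm) <- TRUE
    Bm
  })
  names(B_masks) <- inputs

  C_mask <- matrix(FALSE, k, m, dimnames = list(nodes, inputs))
  for (j in seq_len(m)) {
    hemi <- sub("^.*_", "", inputs[j])
    nd <- contra_nodes(hemi)
    if (input_scheme %in% c("temporal", "double")) C_mask[nd[1], j] <- TRUE
    if (input_scheme %in% c("prefrontal", "double")) C_mask[nd[2], j] <- TRUE
  }

  par_table <- rbind(
    data.frame(block = "A_self", i = 1:4, j = 1:4,
               name = paste0("A_self_", nodes)),
    {
      w <- which(A_mask, arr.ind = TRUE)
      data.frame(block = "A", i = w[, 1], j = w[, 2],
                 name = paste0("A_", nodes[w[, 1]], "<-", nodes[w[, 2]]))
    },
    do.call(rbind, lapply(seq_len(m), function(jj) {
      w <- which(B_masks[[jj]], arr.ind = TRUE)
      if (nrow(w) == 0) return(NULL)
      data.frame(block = paste0("B", jj), i = w[, 1], j = w[, 2],
                 name = paste0("B_", inputs[jj], "_", nodes[w[, 1]],
                               "<-", nodes[w[, 2]]))
    })),
    {
      w <- which(C_mask, arr.ind = TRUE)
      data.frame(block = "C", i = w[, 1], j = w[, 2],
                 name = paste0("C_", nodes[w[, 1]], "<-", inputs[w[, 2]]))
    },
    data.frame(block = "eps", i = NA, j = NA, name = "log_eps")
  )
  structure(list(k = k, m = m, nodes = nodes, inputs = inputs,
                 input_scheme = input_scheme,
                 self_mod_scheme = self_mod_scheme,
                 A_mask = A_mask, B_masks = B_masks, C_mask = C_mask,
                 par_table = par_table, n_free = nrow(par_table)),
            class = "dcm_model")
}

#' @export
print.dcm_model <- function(x, ...) {
  cat(sprintf("<dcm_model> input=%s, self_mod=%s, %d free parameters\n",
              x$input_scheme, x$self_mod_scheme, x$n_free))
  invisible(x)
}

#' Enumerate the 3 x 3 model grid
#'
#' Full cross of the three input schemes (temporal, prefrontal, double) and
#' the three self-modulation schemes (simple, G/N, G/B/N/F); all nine share
#' the same `A` structure and the Good/Novel modulation of forward and
#' backward connections.
#'
#' @return Named list of nine [dcm_model()] objects.
#' @export
dcm_model_grid <- function() {
  grid <- expand.grid(input = c("temporal", "prefrontal", "double"),
                      self = c("simple", "GN", "GBNF"),
                      stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(grid)),
                function(i) dcm_model(grid$input[i], grid$self[i]))
  names(out) <- paste(grid$input, grid$self, sep = "_")
  out
}

# Precompute flat index maps from the parameter table so that repeated
# unpacking (once per objective evaluation during fitting) is cheap.
dcm_make_unpack <- function(model) {
  k <- model$k; m <- model$m
  pt <- model$par_table
  self_pos <- which(pt$block == "A_self")
  diag_flat <- (seq_len(k) - 1L) * k + seq_len(k)
  Aoff_pos <- which(pt$block == "A")
  Aoff_flat <- pt$i[Aoff_pos] + (pt$j[Aoff_pos] - 1L) * k
  B_pos <- lapply(seq_len(m), function(jj) which(pt$block == paste0("B", jj)))
  B_flat <- lapply(seq_len(m), function(jj) {
    sel <- B_pos[[jj]]
    pt$i[sel] + (pt$j[sel] - 1L) * k
  })
  C_pos <- which(pt$block == "C")
  C_flat <- pt$i[C_pos] + (pt$j[C_pos] - 1L) * k
  eps_pos <- which(pt$block == "eps")
  A0 <- matrix(0, k, k); C0 <- matrix(0, k, m); B0 <- matrix(0, k, k)
  function(theta) {
    A <- A0
    A[diag_flat] <- -exp(theta[self_pos])
    A[Aoff_flat] <- theta[Aoff_pos]
    B <- lapply(seq_len(m), function(jj) {
      Bm <- B0
      if (length(B_pos[[jj]])) Bm[B_flat[[jj]]] <- theta[B_pos[[jj]]]
      Bm
    })
    C <- C0
    C[C_flat] <- theta[C_pos]
    list(A = A, B = B, C = C, eps = exp(theta[eps_pos]))
  }
}

#' Expand a free-parameter vector into model matrices
#'
#' Maps `theta` (ordered as `model$par_table`) onto the constrained
#' matrices: diagonal of `A` is `-exp(theta)`, masked off-diagonal `A`,
#' `B`, and `C` entries are filled directly, and the readout gain is
#' `exp(log_eps)`.
#'
#' @param model A [dcm_model()].
#' @param theta Numeric free-parameter vector.
#' @return List with `A` (k x k), `B` (list of m k x k matrices), `C`
#'   (k x m), `eps`.
#' @export
dcm_unpack <- function(model, theta) {
  stopifnot(length(theta) == model$n_free)
  out <- dcm_make_unpack(model)(theta)
  dimnames(out$A) <- dimnames(model$A_mask)
  out
}

#' Default hemodynamic constants for the balloon stage
#'
#' Canonical prior means: signal decay `kappa` (1/s), flow autoregulation
#' `gamma` (1/s), transit time `tau` (s), vessel stiffness `alpha`, resting
#' oxygen extraction `E0`. All are held fixed during fitting; only the
#' readout gain `eps` is free.
#'
#' @return Named numeric vector.
#' @export
dcm_hemo_defaults <- function() {
  c(kappa = 0.64, gamma = 0.32, tau = 2.0, alpha = 0.32, E0 = 0.34)
}

#' Condition input matrix for a scan design
#'
#' Maps the design's condition boxcars onto the eight DCM input rows
#' (`{good,bad,novel,familiar} x {L,R}`); rows of the other scan dimension
#' are zero. Concatenate a GB and an NF design (`cbind`) to drive all eight
#' inputs, as when one `A` must serve both tasks.
#'
#' @param design A [make_design()] scan design.
#' @return m x volumes matrix.
#' @export
dcm_input_matrix <- function(design) {
  box <- condition_boxcars(design)
  U <- matrix(0, 8, n_volumes(design),
              dimnames = list(dcm_inputs_names(), NULL))
  map <- c(left = "L", right = "R")
  for (cn in colnames(box)) {
    parts <- strsplit(cn, "_")[[1]]
    U[paste(parts[1], map[[parts[2]]], sep = "_"), ] <- box[, cn]
  }
  U
}

#' Simulate node time series from a bilinear model
#'
#' Integrates the neural state equation with fixed-step 4th-order
#' Runge-Kutta at `tr_s / substeps`, passes each node through the balloon
#' hemodynamic model, and emits the blood-volume contrast-agent readout
#' `y = -eps (v - 1)` sampled at the TR. Optionally adds Gaussian
#' observation noise at a given SNR.
#'
#' @param model A [dcm_model()].
#' @param theta Free-parameter vector (see `model$par_table`) or a list
#'   with `A`, `B`, `C`, `eps`.
#' @param U Input matrix (m x volumes), e.g. [dcm_input_matrix()].
#' @param tr_s Seconds per volume.
#' @param substeps Integration steps per TR (default 16).
#' @param snr Signal-to-noise ratio of added observation noise (per-node
#'   signal SD over noise SD); `NULL` for noise-free output.
#' @param seed Seed for the observation noise.
#' @param hemo Hemodynamic constants ([dcm_hemo_defaults()]).
#' @return k x volumes matrix of node signals (rownames = node names).
#' @export
simulate_dcm <- function(model, theta, U, tr_s = 2.5, substeps = 16,
                         snr = NULL, seed = NULL,
                         hemo = dcm_hemo_defaults()) {
  stopifnot(inherits(model, "dcm_model"), nrow(U) == model$m)
  pars <- if (is.list(theta)) theta else dcm_unpack(model, theta)
  # stability: every input configuration occurring in U must give a
  # neural system with eigenvalues strictly in the left half plane
  configs <- unique(t(U))
  for (r in seq_len(nrow(configs))) {
    M <- pars$A
    for (j in seq_len(model$m)) M <- M + configs[r, j] * pars$B[[j]]
    ev <- eigen(M, only.values = TRUE)$values
    if (any(Re(ev) >= 0)) {
      stop(sprintf(
        "unstable neural system: eigenvalue %.4g%+.4gi has nonnegative real part",
        Re(ev[which.max(Re(ev))]), Im(ev[which.max(Re(ev))])))
    }
  }
  Y <- dcm_simulate_cpp(pars$A, pars$B, pars$C, U, tr_s, as.integer(substeps),
                        pars$eps, dcm_hemo_vec(hemo), TRUE)
  rownames(Y) <- model$nodes
  if (!is.null(snr)) {
    Y <- with_seed(seed, {
      sds <- apply(Y, 1, stats::sd) / snr
      Y + matrix(stats::rnorm(length(Y)), nrow(Y)) * sds
    })
  }
  Y
}

dcm_hemo_vec <- function(hemo) {
  as.numeric(hemo[c("kappa", "gamma", "tau", "alpha", "E0")])
}

#' Default shrinkage priors for DCM fitting
#'
#' Zero-mean Gaussians: variance 0.25 (`sd = 0.5`) on every free entry of
#' `A` (off-diagonal), `B`, and `C`, and on the self-decay log-rates
#' (centering the decay at -1/s). The log readout gain gets a much tighter
#' prior (`sd_log_eps = 0.1`): the gain and the input matrix `C` scale the
#' output jointly, so the gain is pinned near 1 to resolve that degeneracy
#' (the same reason hemodynamic parameters conventionally carry tight
#' priors).
#'
#' @param sd Prior standard deviation for connectivity parameters.
#' @param sd_log_eps Prior standard deviation for the log readout gain.
#' @return List with `sd` and `sd_log_eps`.
#' @export
dcm_priors <- function(sd = 0.5, sd_log_eps = 0.1) {
  stopifnot(sd > 0, sd_log_eps > 0)
  list(sd = sd, sd_log_eps = sd_log_eps)
}

# per-parameter prior SD vector in par_table order
dcm_prior_sd <- function(model, priors) {
  ifelse(model$par_table$block == "eps", priors$sd_log_eps, priors$sd)
}

#' Fit a bilinear model by MAP with Laplace evidence
#'
#' Maximum a posteriori estimation of the free parameters: Gaussian
#' log-likelihood (observation noise variance profiled as `RSS/N`) plus the
#' Gaussian shrinkage prior, maximized by multi-start Levenberg-Marquardt
#' on the prior-augmented residual vector. The log model evidence is the
#' Laplace approximation `log joint at MAP - 0.5 log det(H) +
#' (d/2) log 2 pi`, with `H` the Gauss-Newton curvature `J'J` of the
#' standardized residuals at the MAP.
#'
#' @param data k x T node signal matrix.
#' @param model A [dcm_model()].
#' @param U Input matrix matching `data` columns.
#' @param tr_s,substeps,hemo Forward-model settings (see [simulate_dcm()]).
#' @param priors [dcm_priors()].
#' @param seed Seed for the restart jitter.
#' @param n_starts Number of restarts (first start is the prior mean).
#' @param maxiter Levenberg-Marquardt iterations per start.
#' @return Object of class `dcm_fit`: `theta` (named MAP estimates),
#'   `params` (`A`, `B`, `C`, `eps`), `log_evidence`, `log_joint`, `sigma`,
#'   `fitted`, `flagged`, `model`.
#' @export
fit_dcm <- function(data, model, U, tr_s = 2.5, substeps = 16,
                    priors = dcm_priors(), seed = 1, n_starts = 8,
                    maxiter = 30, hemo = dcm_hemo_defaults()) {
  stopifnot(inherits(model, "dcm_model"), nrow(data) == model$k,
            ncol(data) == ncol(U))
  d <- model$n_free
  N <- length(data)
  if (N < 10 * d) {
    stop(sprintf("need at least %d data points for %d free parameters",
                 10 * d, d))
  }
  hv <- dcm_hemo_vec(hemo)
  yvec <- as.vector(data)
  unpack <- dcm_make_unpack(model)
  substeps <- as.integer(substeps)
  prior_sd <- dcm_prior_sd(model, priors)
  sim <- function(theta) {
    pars <- unpack(theta)
    # deoxyhemoglobin does not feed the blood-volume readout; skip it here
    as.vector(dcm_simulate_cpp(pars$A, pars$B, pars$C, U, tr_s,
                               substeps, pars$eps, hv, FALSE))
  }
  resid_fun <- function(theta, sigma) {
    yh <- sim(theta)
    if (!all(is.finite(yh))) yh <- rep(1e6, N)
    c((yvec - yh) / sigma, theta / prior_sd)
  }
  log_joint <- function(theta) {
    yh <- sim(theta)
    if (!all(is.finite(yh))) return(-Inf)
    rss <- sum((yvec - yh)^2)
    sigma2 <- rss / N
    ll <- -N / 2 * log(2 * pi * sigma2) - N / 2
    lp <- sum(stats::dnorm(theta, 0, prior_sd, log = TRUE))
    ll + lp
  }

  starts <- with_seed(seed, {
    c(list(rep(0, d)),
      lapply(seq_len(max(n_starts - 1, 0)),
             function(i) stats::rnorm(d, 0, 0.15)))
  })[seq_len(n_starts)]

  best <- NULL
  for (st in starts) {
    theta <- st
    sigma <- stats::sd(yvec)
    if (!is.finite(sigma) || sigma <= 0) sigma <- 1
    ok <- TRUE
    for (outer in 1:4) {
      fit <- tryCatch(
        minpack.lm::nls.lm(par = theta, fn = resid_fun, sigma = sigma,
                           control = minpack.lm::nls.lm.control(
                             maxiter = maxiter, ptol = 1e-8, ftol = 1e-8)),
        error = function(e) NULL)
      if (is.null(fit)) { ok <- FALSE; break }
      theta <- fit$par
      rss <- sum((yvec - sim(theta))^2)
      sigma_new <- max(sqrt(rss / N), 1e-8)
      if (!is.finite(sigma_new)) { ok <- FALSE; break }
      converged_sigma <- abs(sigma_new - sigma) < 0.02 * sigma
      sigma <- sigma_new
      if (converged_sigma) break
    }
    if (!ok) next
    lj <- log_joint(theta)
    if (is.null(best) || lj > best$lj) {
      best <- list(theta = theta, lj = lj, sigma = sigma, info = fit$info)
    }
  }
  if (is.null(best)) {
    return(structure(list(theta = rep(NA_real_, d), model = model,
                          log_evidence = -Inf, flagged = TRUE,
                          message = "all restarts failed"),
                     class = "dcm_fit"))
  }

  theta <- best$theta
  sigma <- best$sigma
  # Gauss-Newton curvature of the standardized residuals (forward diff)
  r0 <- resid_fun(theta, sigma)
  J <- matrix(0, length(r0), d)
  h <- 1e-5
  for (ii in seq_len(d)) {
    tp <- theta; tp[ii] <- tp[ii] + h
    J[, ii] <- (resid_fun(tp, sigma) - r0) / h
  }
  H <- crossprod(J)
  ch <- tryCatch(chol(H + diag(1e-10, d)), error = function(e) NULL)
  flagged <- is.null(ch) || !(best$info %in% 1:4)
  logdetH <- if (is.null(ch)) NA_real_ else 2 * sum(log(diag(ch)))
  log_ev <- if (is.null(ch)) -Inf else
    best$lj + d / 2 * log(2 * pi) - logdetH / 2

  pars <- dcm_unpack(model, theta)
  names(theta) <- model$par_table$name
  fitted <- matrix(sim(theta), model$k, dimnames = list(model$nodes, NULL))
  structure(list(theta = theta, params = pars, log_evidence = log_ev,
                 log_joint = best$lj, sigma = sigma, fitted = fitted,
                 posterior_cov = if (!is.null(ch)) chol2inv(ch) else NULL,
                 info = best$info, flagged = flagged, model = model),
            class = "dcm_fit")
}

#' @export
print.dcm_fit <- function(x, ...) {
  cat(sprintf("<dcm_fit> %s/%s: log evidence %.2f, sigma %.4g%s\n",
              x$model$input_scheme, x$model$self_mod_scheme,
              x$log_evidence, x$sigma,
              if (isTRUE(x$flagged)) " [flagged]" else ""))
  invisible(x)
}

#' Fixed-effects Bayesian model selection
#'
#' Compares fitted models by Laplace log evidence: returns the winner and
#' posterior model probabilities (softmax of the log evidences under a
#' uniform model prior). Flagged (non-converged) fits are excluded with a
#' warning; evidence ties are broken toward the model with fewer free
#' parameters.
#'
#' @param fits Named list of [fit_dcm()] results.
#' @return List: `best` (name), `table` (data frame with `model`, `n_free`,
#'   `log_evidence`, `posterior`).
#' @export
model_select <- function(fits) {
  stopifnot(length(fits) >= 1)
  if (is.null(names(fits))) names(fits) <- paste0("model", seq_along(fits))
  flagged <- vapply(fits, function(f) isTRUE(f$flagged), logical(1))
  if (any(flagged)) {
    warning("excluding flagged fit(s): ",
            paste(names(fits)[flagged], collapse = ", "))
    fits <- fits[!flagged]
  }
  if (length(fits) == 0) stop("no valid fits to compare")
  lev <- vapply(fits, function(f) f$log_evidence, numeric(1))
  nf <- vapply(fits, function(f) f$model$n_free, numeric(1))
  post <- exp(lev - max(lev))
  post <- post / sum(post)
  top <- which(lev >= max(lev) - 1e-8)
  best <- names(fits)[top[which.min(nf[top])]]
  list(best = best,
       table = data.frame(model = names(fits), n_free = nf,
                          log_evidence = lev, posterior = post,
                          row.names = NULL))
}

#' Contra/ipsi-averaged effective connection weights
#'
#' For each condition, the effective weight of a directed connection during
#' a presentation is the `A` entry plus that presentation's `B` entry.
#' Left- and right-hemifield presentations are combined by relabeling
#' hemispheres as contralateral or ipsilateral to the stimulus and
#' averaging, giving forward (temporal to prefrontal) and backward
#' (prefrontal to temporal) weights per side, with their signs.
#'
#' @param fit A [fit_dcm()] result.
#' @param conditions Conditions to report (default good and novel, the
#'   modulated ones).
#' @return Data frame: `condition`, `edge` (forward/backward), `side`
#'   (contra/ipsi), `weight`, `sign`.
#' @export
summarize_edges <- function(fit, conditions = c("good", "novel")) {
  stopifnot(inherits(fit, "dcm_fit"))
  A <- fit$params$A
  B <- fit$params$B
  inputs <- fit$model$inputs
  rows <- list()
  for (cond in conditions) {
    for (edge in c("forward", "backward")) {
      for (side in c("contra", "ipsi")) {
        vals <- vapply(c("L", "R"), function(hemi) {
          jj <- match(paste(cond, hemi, sep = "_"), inputs)
          hemi_nodes <- if ((side == "contra") == (hemi == "L")) {
            c(3L, 4L)  # right hemisphere
          } else {
            c(1L, 2L)  # left hemisphere
          }
          idx <- if (edge == "forward") c(hemi_nodes[2], hemi_nodes[1])
                 else c(hemi_nodes[1], hemi_nodes[2])
          A[idx[1], idx[2]] +
            (if (!is.na(jj)) B[[jj]][idx[1], idx[2]] else 0)
        }, numeric(1))
        rows[[length(rows) + 1]] <- data.frame(
          condition = cond, edge = edge, side = side,
          weight = mean(vals), sign = sign(mean(vals)))
      }
    }
  }
  do.call(rbind, rows)
}
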