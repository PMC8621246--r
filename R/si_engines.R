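# Nine binary animal-inspired swarm optimizers over feature masks.
#
# All engines share a continuous-relaxation representation: position-based
# engines (GWO, WOA, MFO, CS, FA, MRFO) keep positions in [0,1]^d, clipped
# after every update, and binarize by thresholding at 0.5; velocity/step-based
# engines (PSO, BA, DF) work directly on binary masks and binarize their
# velocity (or step) through the S-shaped sigmoid transfer function: a bit is
# set iff U(0,1) < 1/(1+exp(-v)). Every mask is repaired to be non-empty
# before evaluation, and a central tracker records the best mask ever
# evaluated, which makes the best-so-far fitness history non-increasing for
# every engine (elitism).

SI_ALGORITHMS <- c("GWO", "WOA", "BA", "CS", "FA", "MFO", "PSO", "MRFO", "DF")

# Tuned population sizes and algorithm constants. N and the four tuned
# parameters (BA R=A=0.2, PSO MinW=0.1, CS ProbF=0.3, DF MinW=0.5) are the
# study defaults; the remaining constants are the canonical values from the
# original algorithm publications.
si_defaults <- function(algorithm) {
  switch(algorithm,
    GWO = list(N = 10),
    WOA = list(N = 10, b = 1),
    BA = list(N = 30, A = 0.2, R = 0.2, fmin = 0, fmax = 2, flip_p = 0.1),
    CS = list(N = 80, ProbF = 0.3, levy_beta = 1.5, step_scale = 0.01),
    FA = list(N = 30, beta0 = 1, gamma = 1, alpha0 = 0.5, alpha_decay = 0.97),
    MFO = list(N = 90, b = 1),
    PSO = list(N = 80, MinW = 0.1, MaxW = 0.9, c1 = 2, c2 = 2, vmax = 6),
    MRFO = list(N = 10, S = 2),
    DF = list(N = 30, MinW = 0.5, MaxW = 0.9, vmax = 6))
}

#' Configure a swarm-intelligence engine
#'
#' @param algorithm One of `"GWO"`, `"WOA"`, `"BA"`, `"CS"`, `"FA"`, `"MFO"`,
#'   `"PSO"`, `"MRFO"`, `"DF"`.
#' @param N Population size; defaults to the per-engine tuned value
#'   (GWO/WOA/MRFO 10, FA/BA/DF 30, MFO 90, PSO/CS 80).
#' @param T Maximum number of iterations (default 150).
#' @param seed Integer seed; one RNG stream drives the whole run.
#' @param params Named list of overrides for the algorithm constants (e.g.
#'   `list(A = 0.2, R = 0.2)` for BA).
#' @return A list of class `SwarmConfig`.
#' @export
swarm_config <- function(algorithm, N = NULL, T = 150, seed = 0, params = list()) {
  algorithm <- match.arg(toupper(algorithm), SI_ALGORITHMS)
  p <- si_defaults(algorithm)
  p[names(params)] <- params
  if (!is.null(N)) p$N <- N
  if (p$N < 2) zs_stop("population size N must be >= 2", "zooselect_error_invalid_spec")
  if (T < 1) zs_stop("T must be >= 1", "zooselect_error_invalid_spec")
  structure(list(algorithm = algorithm, N = as.integer(p$N), T = as.integer(T),
                 seed = as.integer(seed), params = p),
            class = "SwarmConfig")
}

#' Binarize a continuous position or velocity vector
#'
#' Threshold mode sets a bit iff the position exceeds 0.5 (strictly); sigmoid
#' mode sets a bit iff a uniform draw falls below the logistic transform of
#' the velocity, consuming one draw per entry from the current RNG stream.
#'
#' @param x Numeric vector.
#' @param mode `"threshold"` or `"sigmoid"`.
#' @return Integer 0/1 vector.
#' @export
binarize <- function(x, mode = c("threshold", "sigmoid")) {
  mode <- match.arg(mode)
  if (mode == "threshold") as.integer(x > 0.5)
  else as.integer(stats::runif(length(x)) < stats::plogis(x))
}

#' Repair an empty feature mask
#'
#' All-zero masks get exactly one uniformly chosen bit set; non-empty masks
#' are returned unchanged.
#'
#' @param mask Integer/logical 0-1 vector.
#' @return Integer 0/1 vector with at least one bit set.
#' @export
repair_mask <- function(mask) {
  mask <- as.integer(mask)
  if (!any(mask == 1L)) mask[sample.int(length(mask), 1L)] <- 1L
  mask
}

# row-wise repair for a population mask matrix
repair_rows <- function(m) {
  z <- which(rowSums(m) == 0)
  for (i in z) m[i, sample.int(ncol(m), 1L)] <- 1
  m
}

threshold_rows <- function(pos) (pos > 0.5) * 1

sigmoid_rows <- function(v) {
  (matrix(stats::runif(length(v)), nrow(v), ncol(v)) < stats::plogis(v)) * 1
}

#' Initialize a swarm population
#'
#' Positions are uniform on `[0,1]^d`; masks are the thresholded, repaired
#' positions; velocities (where the engine uses them) start at zero.
#'
#' @param d Problem dimension (number of features).
#' @param cfg A [swarm_config()].
#' @return List with `positions` (`N x d`), `masks` (`N x d`, 0/1) and
#'   `velocities` (`N x d`, zero).
#' @export
init_population <- function(d, cfg) {
  stopifnot(inherits(cfg, "SwarmConfig"), d >= 1)
  with_seed(cfg$seed, {
    pos <- matrix(stats::runif(cfg$N * d), cfg$N, d)
    list(positions = pos,
         masks = repair_rows(threshold_rows(pos)),
         velocities = matrix(0, cfg$N, d))
  })
}

# Mantegna's method for Levy-stable step lengths (used by cuckoo search).
levy_sigma <- function(beta) {
  (gamma(1 + beta) * sin(pi * beta / 2) /
     (gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)))^(1 / beta)
}

levy_step <- function(n, beta, sigma) {
  u <- stats::rnorm(n, 0, sigma)
  v <- stats::rnorm(n)
  u / abs(v)^(1 / beta)
}

# Deterministic preference used for best-so-far tracking: lower fitness, then
# fewer selected features, then the lexicographically smaller mask.
mask_better <- function(v1, s1, m1, v2, s2, m2) {
  if (v1 != v2) return(v1 < v2)
  if (s1 != s2) return(s1 < s2)
  dif <- which(m1 != m2)
  length(dif) > 0 && m1[dif[1]] < m2[dif[1]]
}

#' Run one binary swarm-intelligence feature-selection engine
#'
#' Initializes a population, performs `cfg$T` iterations of the configured
#' update rule, evaluates every proposed mask with the wrapper fitness and
#' returns the best mask ever evaluated together with the best-so-far history.
#' Fully deterministic given `(algorithm, seed, dataset)`.
#'
#' @param ds_train Training dataset (typically prefiltered to <= 1000
#'   features).
#' @param cfg A [swarm_config()].
#' @param fit_cfg A [fitness_config()]; its seed fixes the inner 2:1 split
#'   for the whole run.
#' @return Object of class `EngineResult`: `best_mask` (0/1 vector),
#'   `best_fitness` (`FitnessValue`), `fitness_history` (length `T`,
#'   non-increasing), `n_evaluations`, `algorithm`.
#' @export
run_si <- function(ds_train, cfg, fit_cfg = fitness_config()) {
  stopifnot(inherits(ds_train, "OmicsDataset"), inherits(cfg, "SwarmConfig"))
  d <- n_features(ds_train)
  N <- cfg$N
  T <- cfg$T
  p <- cfg$params
  evaluator <- make_fitness_evaluator(ds_train, fit_cfg)

  env <- new.env(parent = emptyenv())
  env$value <- Inf; env$selected <- Inf; env$mask <- NULL; env$best <- NULL
  env$n <- 0L
  track <- function(value, error_rate, ns, mask) {
    env$n <- env$n + 1L
    if (is.null(env$mask) ||
        mask_better(value, ns, mask, env$value, env$selected, env$mask)) {
      env$value <- value
      env$selected <- ns
      env$mask <- mask
      env$best <- structure(list(value = value, error_rate = error_rate,
                                 n_selected = ns, dimension = d),
                            class = "FitnessValue")
    }
  }
  eval_mask <- function(mask) {
    res <- evaluator(mask)
    track(res$value, res$error_rate, res$n_selected, mask)
    res$value
  }
  batch <- attr(evaluator, "batch")
  eval_rows <- if (is.null(batch)) {
    function(m) vapply(seq_len(nrow(m)), function(i) eval_mask(m[i, ]), numeric(1))
  } else {
    function(m) {
      res <- batch(m)
      for (i in seq_len(nrow(m))) {
        track(res$values[i], res$errors[i], res$n_selected[i], m[i, ])
      }
      res$values
    }
  }

  step <- switch(cfg$algorithm,
                 GWO = step_gwo, WOA = step_woa, BA = step_ba, CS = step_cs,
                 FA = step_fa, MFO = step_mfo, PSO = step_pso,
                 MRFO = step_mrfo, DF = step_df)

  with_seed(cfg$seed, {
    pos <- matrix(stats::runif(N * d), N, d)
    mask <- repair_rows(threshold_rows(pos))
    fit <- eval_rows(mask)
    st <- list(pos = pos, mask = mask, fit = fit)
    st <- switch(cfg$algorithm,
      GWO = { ord <- order(fit); lead <- ord[pmin(1:3, N)]
              c(st, list(lead_pos = pos[lead, , drop = FALSE], lead_fit = fit[lead])) },
      WOA = , MRFO = { b <- which.min(fit)
              c(st, list(best_pos = pos[b, ], best_fit = fit[b])) },
      MFO = { ord <- order(fit)
              c(st, list(flame_pos = pos[ord, , drop = FALSE], flame_fit = fit[ord])) },
      PSO = { g <- which.min(fit)
              c(st, list(vel = matrix(0, N, d), pbest_mask = mask, pbest_fit = fit,
                         gbest_mask = mask[g, ], gbest_fit = fit[g])) },
      BA = c(st, list(vel = matrix(0, N, d))),
      DF = c(st, list(dx = matrix(0, N, d))),
      CS = , FA = st)
    if (cfg$algorithm == "CS") {
      st$levy_sigma <- levy_sigma(p$levy_beta)
    }

    history <- numeric(T)
    for (t in 0:(T - 1)) {
      st <- step(st, t, T, N, d, p, eval_mask, eval_rows, env)
      history[t + 1] <- env$value
    }
    structure(list(best_mask = env$mask,
                   best_fitness = env$best,
                   fitness_history = history,
                   n_evaluations = env$n,
                   algorithm = cfg$algorithm),
              class = "EngineResult")
  })
}

#' @export
print.EngineResult <- function(x, ...) {
  cat(sprintf("<EngineResult:%s> best fitness %.6f, %d features, %d evaluations\n",
              x$algorithm, x$best_fitness$value, x$best_fitness$n_selected,
              x$n_evaluations))
  invisible(x)
}

# ---- engine steps -----------------------------------------------------------
# Each step takes/returns the engine state; t runs 0..T-1.

# Grey wolf: positions move toward the alpha/beta/delta leaders, with the
# encircling coefficient a(t) = 2 - 2t/T shrinking linearly to zero.
step_gwo <- function(st, t, T, N, d, p, eval_mask, eval_rows, env) {
  a <- 2 - 2 * t / T
  newpos <- matrix(0, N, d)
  for (L in 1:3) {
    r1 <- matrix(stats::runif(N * d), N, d)
    r2 <- matrix(stats::runif(N * d), N, d)
    A <- 2 * a * r1 - a
    C <- 2 * r2
    XL <- matrix(st$lead_pos[L, ], N, d, byrow = TRUE)
    newpos <- newpos + XL - A * abs(C * XL - st$pos)
  }
  st$pos <- clip01(newpos / 3)
  st$mask <- repair_rows(threshold_rows(st$pos))
  st$fit <- eval_rows(st$mask)
  allp <- rbind(st$lead_pos, st$pos)
  allf <- c(st$lead_fit, st$fit)
  keep <- order(allf)[1:3]
  st$lead_pos <- allp[keep, , drop = FALSE]
  st$lead_fit <- allf[keep]
  st
}

# Whale: shrinking encirclement of the best solution, exploration toward a
# random agent while |A| >= 1, and the logarithmic spiral bubble-net move.
step_woa <- function(st, t, T, N, d, p, eval_mask, eval_rows, env) {
  a <- 2 - 2 * t / T
  newpos <- st$pos
  for (i in 1:N) {
    if (stats::runif(1) < 0.5) {
      A <- 2 * a * stats::runif(1) - a
      C <- 2 * stats::runif(1)
      ref <- if (abs(A) < 1) st$best_pos else st$pos[sample.int(N, 1), ]
      newpos[i, ] <- ref - A * abs(C * ref - st$pos[i, ])
    } else {
      l <- stats::runif(1, -1, 1)
      newpos[i, ] <- abs(st$best_pos - st$pos[i, ]) * exp(p$b * l) * cos(2 * pi * l) +
        st$best_pos
    }
  }
  st$pos <- clip01(newpos)
  st$mask <- repair_rows(threshold_rows(st$pos))
  st$fit <- eval_rows(st$mask)
  m <- which.min(st$fit)
  if (st$fit[m] < st$best_fit) {
    st$best_pos <- st$pos[m, ]
    st$best_fit <- st$fit[m]
  }
  st
}

# Bat: frequency-tuned velocities over the binary mask space, a pulse-rate
# gated local walk around the best mask (bit flips at rate flip_p), and
# loudness-gated greedy acceptance. A and R stay fixed at their tuned values.
step_ba <- function(st, t, T, N, d, p, eval_mask, eval_rows, env) {
  gbest <- env$mask
  for (i in 1:N) {
    f <- p$fmin + (p$fmax - p$fmin) * stats::runif(1)
    st$vel[i, ] <- st$vel[i, ] + (st$mask[i, ] - gbest) * f
    cand <- as.integer(stats::runif(d) < stats::plogis(st$vel[i, ]))
    if (stats::runif(1) > p$R) {
      cand <- gbest
      fl <- stats::runif(d) < p$flip_p
      cand[fl] <- 1L - cand[fl]
    }
    cand <- repair_mask(cand)
    cf <- eval_mask(cand)
    if (stats::runif(1) < p$A && cf < st$fit[i]) {
      st$mask[i, ] <- cand
      st$fit[i] <- cf
    }
  }
  st
}

# Cuckoo: Levy-flight proposals replace a random nest when better; a ProbF
# fraction of nests (never the best) is abandoned and rebuilt from the
# difference of two random nests.
step_cs <- function(st, t, T, N, d, p, eval_mask, eval_rows, env) {
  best_i <- which.min(st$fit)
  bestp <- st$pos[best_i, ]
  for (i in 1:N) {
    s <- levy_step(d, p$levy_beta, st$levy_sigma)
    xn <- clip01(st$pos[i, ] + p$step_scale * s * (st$pos[i, ] - bestp))
    mn <- repair_mask(as.integer(xn > 0.5))
    fn <- eval_mask(mn)
    j <- sample.int(N, 1)
    if (fn < st$fit[j]) {
      st$pos[j, ] <- xn
      st$mask[j, ] <- mn
      st$fit[j] <- fn
    }
  }
  best_i <- which.min(st$fit)
  abandon <- stats::runif(N) < p$ProbF
  abandon[best_i] <- FALSE
  for (i in which(abandon)) {
    pq <- sample.int(N, 2)
    xn <- clip01(st$pos[i, ] + stats::runif(1) * (st$pos[pq[1], ] - st$pos[pq[2], ]))
    mn <- repair_mask(as.integer(xn > 0.5))
    st$pos[i, ] <- xn
    st$mask[i, ] <- mn
    st$fit[i] <- eval_mask(mn)
  }
  st
}

# Firefly: every firefly moves toward each brighter one with attraction
# beta0 * exp(-gamma r^2) plus a decaying random walk; the brightest (and any
# firefly with no brighter neighbour) takes only the random term.
step_fa <- function(st, t, T, N, d, p, eval_mask, eval_rows, env) {
  alpha_t <- p$alpha0 * p$alpha_decay^t
  newpos <- st$pos
  best_i <- which.min(st$fit)
  for (i in 1:N) {
    moved <- FALSE
    if (i != best_i) {
      for (j in 1:N) {
        if (st$fit[j] < st$fit[i]) {
          r2 <- sum((newpos[i, ] - st$pos[j, ])^2)
          beta <- p$beta0 * exp(-p$gamma * r2)
          newpos[i, ] <- newpos[i, ] + beta * (st$pos[j, ] - newpos[i, ]) +
            alpha_t * (stats::runif(d) - 0.5)
          moved <- TRUE
        }
      }
    }
    if (!moved) newpos[i, ] <- newpos[i, ] + alpha_t * (stats::runif(d) - 0.5)
  }
  st$pos <- clip01(newpos)
  st$mask <- repair_rows(threshold_rows(st$pos))
  st$fit <- eval_rows(st$mask)
  st
}

# Moth-flame: moths spiral around a sorted flame archive whose length shrinks
# from N to 1 over the run; the archive keeps the N best positions ever seen.
step_mfo <- function(st, t, T, N, d, p, eval_mask, eval_rows, env) {
  n_fl <- max(1, round(N - t * (N - 1) / T))
  r_t <- -1 - t / T
  newpos <- st$pos
  for (i in 1:N) {
    Fi <- st$flame_pos[min(i, n_fl), ]
    tau <- stats::runif(d, r_t, 1)
    newpos[i, ] <- abs(Fi - st$pos[i, ]) * exp(p$b * tau) * cos(2 * pi * tau) + Fi
  }
  st$pos <- clip01(newpos)
  st$mask <- repair_rows(threshold_rows(st$pos))
  st$fit <- eval_rows(st$mask)
  allp <- rbind(st$flame_pos, st$pos)
  allf <- c(st$flame_fit, st$fit)
  keep <- order(allf)[seq_len(N)]
  st$flame_pos <- allp[keep, , drop = FALSE]
  st$flame_fit <- allf[keep]
  st
}

# Particle swarm: inertia-weighted velocities over the binary mask space with
# cognitive/social pulls toward personal and global bests; velocities clamped
# to [-vmax, vmax] before the sigmoid transfer.
step_pso <- function(st, t, T, N, d, p, eval_mask, eval_rows, env) {
  w <- p$MaxW - (p$MaxW - p$MinW) * t / T
  r1 <- matrix(stats::runif(N * d), N, d)
  r2 <- matrix(stats::runif(N * d), N, d)
  G <- matrix(st$gbest_mask, N, d, byrow = TRUE)
  st$vel <- w * st$vel + p$c1 * r1 * (st$pbest_mask - st$mask) +
    p$c2 * r2 * (G - st$mask)
  st$vel <- pmin(pmax(st$vel, -p$vmax), p$vmax)
  st$mask <- repair_rows(sigmoid_rows(st$vel))
  st$fit <- eval_rows(st$mask)
  imp <- st$fit < st$pbest_fit
  if (any(imp)) {
    st$pbest_mask[imp, ] <- st$mask[imp, ]
    st$pbest_fit[imp] <- st$fit[imp]
  }
  g <- which.min(st$pbest_fit)
  if (st$pbest_fit[g] < st$gbest_fit) {
    st$gbest_mask <- st$pbest_mask[g, ]
    st$gbest_fit <- st$pbest_fit[g]
  }
  st
}

# Manta ray: chain or cyclone foraging (cyclone around a random point early,
# around the best later) followed by a somersault around the best position.
step_mrfo <- function(st, t, T, N, d, p, eval_mask, eval_rows, env) {
  t1 <- t + 1
  bp <- st$best_pos
  newpos <- st$pos
  for (i in 1:N) {
    if (stats::runif(1) < 0.5) {
      r1 <- stats::runif(1)
      beta <- 2 * exp(r1 * (T - t1 + 1) / T) * sin(2 * pi * r1)
      ref <- if (t1 / T < stats::runif(1)) stats::runif(d) else bp
      prev <- if (i == 1) ref else newpos[i - 1, ]
      newpos[i, ] <- ref + stats::runif(d) * (prev - st$pos[i, ]) +
        beta * (ref - st$pos[i, ])
    } else {
      r <- stats::runif(d)
      alpha <- 2 * r * sqrt(abs(log(r)))
      prev <- if (i == 1) bp else newpos[i - 1, ]
      newpos[i, ] <- st$pos[i, ] + r * (prev - st$pos[i, ]) +
        alpha * (bp - st$pos[i, ])
    }
  }
  r2 <- matrix(stats::runif(N * d), N, d)
  r3 <- matrix(stats::runif(N * d), N, d)
  BP <- matrix(bp, N, d, byrow = TRUE)
  newpos <- newpos + p$S * (r2 * BP - r3 * newpos)
  st$pos <- clip01(newpos)
  st$mask <- repair_rows(threshold_rows(st$pos))
  st$fit <- eval_rows(st$mask)
  m <- which.min(st$fit)
  if (st$fit[m] < st$best_fit) {
    st$best_pos <- st$pos[m, ]
    st$best_fit <- st$fit[m]
  }
  st
}

# Dragonfly: separation/alignment/cohesion over the whole swarm plus food
# attraction (best-so-far mask) and enemy distraction (current worst mask),
# with inertia 0.9 -> MinW and the canonical decaying behaviour weights.
step_df <- function(st, t, T, N, d, p, eval_mask, eval_rows, env) {
  w <- p$MaxW - (p$MaxW - p$MinW) * t / T
  my_c <- 0.1 - t * (0.1 / (T / 2))
  if (my_c < 0) my_c <- 0
  sw <- 2 * stats::runif(1) * my_c
  aw <- 2 * stats::runif(1) * my_c
  cw <- 2 * stats::runif(1) * my_c
  fw <- 2 * stats::runif(1)
  ew <- my_c
  food <- env$mask
  enemy <- st$mask[which.max(st$fit), ]
  csum <- colSums(st$mask)
  dsum <- colSums(st$dx)
  newdx <- st$dx
  for (i in 1:N) {
    xi <- st$mask[i, ]
    S <- -((csum - xi) - (N - 1) * xi)
    A <- (dsum - st$dx[i, ]) / (N - 1)
    C <- (csum - xi) / (N - 1) - xi
    Fv <- food - xi
    Ev <- enemy + xi
    newdx[i, ] <- w * st$dx[i, ] + sw * S + aw * A + cw * C + fw * Fv + ew * Ev
  }
  st$dx <- pmin(pmax(newdx, -p$vmax), p$vmax)
  st$mask <- repair_rows(sigmoid_rows(st$dx))
  st$fit <- eval_rows(st$mask)
  st
}
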