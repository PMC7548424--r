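# Shared fixtures and independent oracles, built in code.

MONTAGE <- standard_montage()

# a flat VERP whose traces can be set per electrode
make_verp <- function(times = seq(-200, 400, by = 4), condition = "upper",
                      fill = 0, meta = NULL) {
  d <- matrix(fill, 32, length(times),
              dimnames = list(MONTAGE$labels, NULL))
  verp(d, times, condition, n_trials = 10, MONTAGE, meta = meta)
}

gauss_bump <- function(times, center, width = 20, amp = 1) {
  amp * exp(-0.5 * ((times - center) / width)^2)
}

# small epoch set with hand-built signal
make_epochs <- function(signal, times, srate, events = NULL, meta = NULL,
                        keep = NULL) {
  n <- dim(signal)[1]
  if (is.null(events))
    events <- data.frame(field = rep(c("upper", "lower"), length.out = n),
                         side = rep(c("left", "right"), length.out = n),
                         target = FALSE, rt = NA_real_)
  epoch_set(signal, times, srate, MONTAGE, events, keep = keep, meta = meta)
}

# --- independent oracles -----------------------------------------------

# AUC by exhaustive concordant-pair counting (case = CC; low scores more
# CC-like when direction == "le")
auc_pairs <- function(score, is_cc, direction = "le") {
  s <- if (direction == "le") -score else score
  x <- s[is_cc]; y <- s[!is_cc]
  tot <- 0
  for (xi in x) for (yj in y)
    tot <- tot + (xi > yj) + 0.5 * (xi == yj)
  tot / (length(x) * length(y))
}

# Youden threshold by brute-force scan over every rule "score <= t -> CC"
youden_bruteforce <- function(score, is_cc) {
  best_j <- -Inf; best_t <- NA; best_spec <- -Inf
  for (t in sort(unique(score))) {
    sens <- mean(score[is_cc] <= t)
    spec <- mean(score[!is_cc] > t)
    j <- sens + spec - 1
    if (j > best_j + 1e-12 ||
        (abs(j - best_j) <= 1e-12 && spec > best_spec)) {
      best_j <- j; best_t <- t; best_spec <- spec
    }
  }
  list(threshold = best_t, j = best_j)
}

# linear SVM weights from an independent solver: L-BFGS-B on the same
# box-constrained dual (bias as augmented feature)
svm_qp_oracle <- function(X, y, cost) {
  Xa <- cbind(X, 1)
  Q <- (Xa %*% t(Xa)) * outer(y, y)
  obj <- function(a) 0.5 * drop(a %*% Q %*% a) - sum(a)
  gr <- function(a) drop(Q %*% a) - 1
  o <- stats::optim(rep(cost / 2, length(y)), obj, gr, method = "L-BFGS-B",
                    lower = 0, upper = cost,
                    control = list(maxit = 5000, factr = 10))
  w <- drop(t(Xa) %*% (o$par * y))
  list(w = w[-length(w)], b = w[length(w)])
}

# quick simulated participant at small scale
sim_small <- function(group = "Control", seed = 1, atten = NULL,
                      artifacts = artifact_spec(), tpq = 11, srate = 100,
                      age = 20, components = default_components()) {
  meta <- participant_meta(paste0("t_", group, seed), group, age,
                           age_at_surgery = if (group == "Control") NA else 24,
                           time_since_surgery = if (group == "Control") NA
                                                else 120)
  simulate_participant(meta, components, artifacts, tpq, srate, seed,
                       p1_attenuation = atten)
}

quiet_artifacts <- artifact_spec(blink_rate = 0, saccade_rate = 0,
                                 alpha_amp = 0, noise_scale = 0)
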