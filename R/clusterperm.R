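# Cluster-based permutation test for the upper- vs lower-field P1 effect:
# paired t-values over posterior electrode x time cells, cluster formation
# by scalp adjacency and temporal contiguity, cluster mass = sum of t, and
# a max-cluster-mass null distribution from within-participant condition
# sign-flips (two-tailed, family-wise error controlled).

# connected components of supra-threshold cells on an electrode x time grid.
# mask: logical E x T; nb: list of spatially adjacent electrode indices.
# returns list of integer index vectors (linear indices into the grid).
grid_clusters <- function(mask, nb) {
  n_e <- nrow(mask); n_t <- ncol(mask)
  lab <- array(0L, dim(mask))
  out <- list()
  k <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    k <- k + 1L
    queue <- start
    lab[start] <- k
    members <- start
    while (length(queue)) {
      cell <- queue[[1]]; queue <- queue[-1]
      e <- (cell - 1L) %% n_e + 1L
      t <- (cell - 1L) %/% n_e + 1L
      cand <- c(if (t > 1L) cell - n_e, if (t < n_t) cell + n_e,
                (t - 1L) * n_e + nb[[e]])
      cand <- cand[mask[cand] & lab[cand] == 0L]
      if (length(cand)) {
        lab[cand] <- k
        queue <- c(queue, cand)
        members <- c(members, cand)
      }
    }
    out[[k]] <- members
  }
  out
}

# largest |cluster mass| for one t-map (both tails)
max_cluster_mass <- function(tv, thr, nb) {
  m <- 0
  for (sgn in c(1, -1)) {
    cl <- grid_clusters(sgn * tv > thr, nb)
    if (length(cl))
      m <- max(m, max(vapply(cl, function(ix) abs(sum(tv[ix])), numeric(1))))
  }
  m
}

#' Cluster-based permutation test for a paired condition difference
#'
#' Tests whether the upper-field VERP amplitude differs from the
#' lower-field amplitude over a set of electrodes and a time window.
#' Per electrode-time cell a paired t-value is computed; cells exceeding
#' the two-tailed cluster-forming threshold (`alpha` on the t distribution
#' with n-1 df) are grouped into clusters by scalp adjacency (electrodes
#' within `adjacency_radius` chord units) and temporal contiguity; the
#' cluster statistic is the summed t (mass). The null distribution of the
#' maximal |mass| is built from random within-participant condition
#' sign-flips, giving family-wise-error-controlled Monte-Carlo p-values.
#'
#' @param verps_upper,verps_lower paired lists of [verp()]s (same
#'   participant order), or `NULL` if `diff_array` is given.
#' @param montage montage; defaults to the first VERP's montage.
#' @param electrodes electrode subset (default the 13 posterior).
#' @param window_ms analysis window, default `c(120, 170)` (50 ms around
#'   the group P1 latency).
#' @param n_perm number of sign-flip permutations (default 10000).
#' @param seed RNG seed.
#' @param cluster_alpha two-tailed cluster-forming alpha (default .05).
#' @param adjacency_radius scalp neighbourhood radius (default 0.65).
#' @param diff_array optional participant x electrode x time array of
#'   paired differences, bypassing the VERP lists (electrode dim must match
#'   `electrodes`).
#' @return a `cluster_test_result`: list with `clusters` (data.frame:
#'   mass, sign, n_cells, p), `members` (list of electrode/time member
#'   tables), `t_map`, `t_threshold`, `n_perm`, `max_null`.
#' @export
cluster_permutation_test <- function(verps_upper = NULL, verps_lower = NULL,
                                     montage = NULL,
                                     electrodes = NULL,
                                     window_ms = c(120, 170),
                                     n_perm = 10000, seed = 1,
                                     cluster_alpha = 0.05,
                                     adjacency_radius = 0.65,
                                     diff_array = NULL) {
  if (is.null(diff_array)) {
    stopifnot(length(verps_upper) == length(verps_lower),
              length(verps_upper) >= 2)
    if (is.null(montage)) montage <- verps_upper[[1]]$montage
    if (is.null(electrodes)) electrodes <- montage$posterior
    times <- verps_upper[[1]]$times
    tix <- time_index(times, window_ms[1], window_ms[2])
    n <- length(verps_upper)
    diff_array <- array(0, c(n, length(electrodes), length(tix)))
    for (i in seq_len(n))
      diff_array[i, , ] <- verps_upper[[i]]$data[electrodes, tix] -
        verps_lower[[i]]$data[electrodes, tix]
    sel_times <- times[tix]
  } else {
    if (is.null(montage)) montage <- standard_montage()
    if (is.null(electrodes)) electrodes <- montage$posterior
    stopifnot(dim(diff_array)[2] == length(electrodes))
    sel_times <- seq_len(dim(diff_array)[3])
  }
  n <- dim(diff_array)[1]
  if (n < 2) stop("need >= 2 participants")
  n_e <- dim(diff_array)[2]; n_t <- dim(diff_array)[3]

  adj <- electrode_adjacency(montage, electrodes, adjacency_radius)
  nb <- lapply(seq_len(n_e), function(e) which(adj[e, ]))

  d <- matrix(diff_array, n)                 # n x (E*T), electrode fastest
  ssq <- colSums(d^2)
  t_of <- function(s) {                      # s: vector/matrix of sign flips
    m <- (s %*% d) / n
    v <- (rep(1, nrow(m)) %o% ssq - n * m^2) / (n - 1)
    v[v < .Machine$double.eps] <- .Machine$double.eps
    m / sqrt(v / n)
  }
  t_obs <- matrix(t_of(matrix(1, 1, n)), n_e, n_t)
  thr <- stats::qt(1 - cluster_alpha / 2, df = n - 1)

  clusters <- list(); masses <- numeric(0); signs <- integer(0)
  for (sgn in c(1L, -1L)) {
    cl <- grid_clusters(sgn * t_obs > thr, nb)
    for (ix in cl) {
      clusters[[length(clusters) + 1L]] <- ix
      masses <- c(masses, sum(t_obs[ix]))
      signs <- c(signs, sgn)
    }
  }

  set.seed(seed)
  smat <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
  t_perm <- t_of(smat)                       # n_perm x (E*T)
  max_null <- vapply(seq_len(n_perm), function(k)
    max_cluster_mass(matrix(t_perm[k, ], n_e, n_t), thr, nb), numeric(1))

  p <- vapply(masses, function(m)
    (1 + sum(max_null >= abs(m))) / (n_perm + 1), numeric(1))

  members <- lapply(clusters, function(ix) {
    data.frame(electrode = electrodes[(ix - 1L) %% n_e + 1L],
               time = sel_times[(ix - 1L) %/% n_e + 1L])
  })
  ord <- order(-abs(masses))
  structure(list(
    clusters = if (length(masses))
      data.frame(mass = masses, sign = signs,
                 n_cells = vapply(clusters, length, integer(1)),
                 p = p)[ord, , drop = FALSE]
      else data.frame(mass = numeric(0), sign = integer(0),
                      n_cells = integer(0), p = numeric(0)),
    members = members[ord],
    t_map = t_obs, t_threshold = thr, n_perm = n_perm,
    max_null = max_null, electrodes = electrodes, times = sel_times,
    seed = seed
  ), class = "cluster_test_result")
}

#' @export
print.cluster_test_result <- function(x, ...) {
  cat("<cluster_test_result>", nrow(x$clusters), "cluster(s),",
      x$n_perm, "permutations\n")
  if (nrow(x$clusters)) print(utils::head(x$clusters, 5))
  invisible(x)
}
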