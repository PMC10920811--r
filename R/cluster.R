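#' Channel adjacency from sensor geometry
#'
#' Two channels are adjacent when their 3-D distance is at most `scale` times
#' the median nearest-neighbor distance of the montage. This recovers the
#' natural neighborhood structure (e.g. the 4-neighborhood of a regular grid
#' at the default scale) without a hand-drawn neighbor list.
#'
#' @param montage A `bandcov_montage`, or a list with `ch_names` and
#'   `positions`.
#' @param scale Distance multiplier (default 1.3).
#' @return An object of class `adjacency_graph`: list with `ch_names` and the
#'   symmetric logical `adjacency` matrix (no self-loops).
#' @export
channel_adjacency <- function(montage, scale = 1.3) {
  pos <- as.matrix(montage$positions)
  nms <- montage$ch_names %||% rownames(pos)
  if (nrow(pos) < 2) stop_invalid("need at least 2 channels")
  d <- as.matrix(stats::dist(pos))
  diag(d) <- Inf
  if (any(d == 0)) stop_invalid("duplicate channel positions")
  nn <- apply(d, 1, min)
  adj <- d <= scale * median(nn)
  diag(adj) <- FALSE
  dimnames(adj) <- list(nms, nms)
  comp <- graph_components(adj)
  if (max(comp) > 1)
    message("adjacency graph has ", max(comp), " connected components")
  structure(list(ch_names = nms, adjacency = adj, scale = scale),
            class = "adjacency_graph")
}

# Connected components of a logical adjacency matrix (iterative BFS).
graph_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0) next
    cur <- cur + 1L
    stack <- s
    comp[s] <- cur
    while (length(stack) > 0) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      stack <- c(stack, nb)
    }
  }
  comp
}

#' @export
print.adjacency_graph <- function(x, ...) {
  cat(sprintf("<adjacency_graph> %d channels, %d edges (scale %.2f)\n",
              length(x$ch_names), sum(x$adjacency) / 2, x$scale))
  invisible(x)
}

#' Subject-level mean band power
#'
#' Averages a `psd_set` over each subject's epochs, the exchangeable unit for
#' group-level inference.
#'
#' @param psd A `psd_set` carrying subject and group labels.
#' @param task Optional task restriction.
#' @return A list with `power` (subjects x channels x bands), `subjects`,
#'   `groups`.
#' @export
summarize_psd_by_subject <- function(psd, task = NULL) {
  keep <- seq_len(dim(psd$power)[1])
  if (!is.null(task)) keep <- keep[psd$task[keep] %in% task]
  subj <- psd$subject[keep]
  us <- unique(subj)
  d <- dim(psd$power)
  out <- array(0, dim = c(length(us), d[2], d[3]),
               dimnames = list(us, psd$ch_names, psd$bands$name))
  grp <- character(length(us))
  for (i in seq_along(us)) {
    idx <- keep[subj == us[i]]
    sl <- psd$power[idx, , , drop = FALSE]
    out[i, , ] <- apply(sl, c(2, 3), mean)
    grp[i] <- psd$group[idx[1]]
  }
  list(power = out, subjects = us, groups = grp)
}

# Supra-threshold clusters of a channels-vector of T values within one band.
find_clusters_1band <- function(tvec, adj, thr) {
  out <- list()
  for (sgn in c(1, -1)) {
    sup <- if (sgn > 0) tvec > thr else tvec < -thr
    comp <- rep(NA_integer_, length(tvec))
    adj_sup <- adj & outer(sup, sup)
    if (any(sup)) {
      cc <- graph_components(adj_sup | diag(length(tvec)))
      for (cid in unique(cc[sup])) {
        ch <- which(cc == cid & sup)
        out[[length(out) + 1]] <- list(channels = ch, sign = sgn,
                                       mass = sum(tvec[ch]))
      }
    }
  }
  out
}

# Pooled-variance two-sample T statistics for all cells, vectorized over a
# permutation indicator matrix P1 (perms x subjects, 1 = group 1).
t_stats_perms <- function(X, P1) {
  n <- nrow(X)
  n1 <- rowSums(P1)
  n2 <- n - n1
  X2 <- X^2
  s1 <- P1 %*% X
  s2 <- matrix(colSums(X), nrow(P1), ncol(X), byrow = TRUE) - s1
  q1 <- P1 %*% X2
  q2 <- matrix(colSums(X2), nrow(P1), ncol(X), byrow = TRUE) - q1
  m1 <- s1 / n1
  m2 <- s2 / n2
  v1 <- (q1 - n1 * m1^2) / (n1 - 1)
  v2 <- (q2 - n2 * m2^2) / (n2 - 1)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

#' Cluster-based permutation test of group differences in band power
#'
#' Compares two groups of subjects on per-(channel, band) mean power with a
#' two-sample T statistic, clusters supra-threshold channels (|T| >
#' `t_threshold`) by spatial adjacency within each band (positive and
#' negative excursions separately), and tests each cluster's mass (sum of T)
#' against the permutation null of the maximum |cluster mass| under random
#' reassignment of subjects to groups. Subjects - not epochs - are permuted:
#' the subject is the exchangeable unit for group inference.
#'
#' When the group sizes admit fewer distinct label assignments than `n_perm`,
#' all of them are enumerated instead (with a warning).
#'
#' @param psd_subj Subjects x channels x bands array of mean power (e.g. from
#'   [summarize_psd_by_subject()]).
#' @param groups Group label per subject (2 groups, >= 2 subjects each).
#' @param adjacency An `adjacency_graph` over the channels.
#' @param t_threshold Cluster-forming threshold on T (> 0; default 6, a
#'   deliberately strict value - see the package vignette for calibration at
#'   conventional thresholds).
#' @param n_perm Number of permutations (default 1024).
#' @param seed Permutation RNG seed.
#' @param positive_group The group whose excess power gives positive T
#'   (default: the lexicographically larger label, "M" for M/H cohorts).
#' @return An object of class `cluster_result`: `clusters` (data frame: band,
#'   channels, sign, mass, p_value), `tmap` (channels x bands), `null_max`
#'   (permutation distribution), `t_threshold`, `n_perm`.
#' @export
cluster_permutation_test <- function(psd_subj, groups, adjacency,
                                     t_threshold = 6, n_perm = 1024,
                                     seed = 1L, positive_group = NULL) {
  if (t_threshold <= 0) stop_invalid("t_threshold must be > 0")
  stopifnot(inherits(adjacency, "adjacency_graph"))
  d <- dim(psd_subj)
  nS <- d[1]; N <- d[2]; K <- d[3]
  groups <- as.character(groups)
  gl <- sort(unique(groups))
  if (length(gl) != 2 || min(table(groups)) < 2)
    stop_invalid("need two groups with at least 2 subjects each")
  if (N != length(adjacency$ch_names))
    stop_invalid("adjacency does not match the channel dimension")
  band_names <- dimnames(psd_subj)[[3]] %||% paste0("band", seq_len(K))
  ch_names <- adjacency$ch_names

  positive_group <- positive_group %||% gl[2]
  if (!positive_group %in% gl)
    stop_invalid("positive_group is not one of the group labels")
  X <- matrix(psd_subj, nS, N * K)
  obs_ind <- matrix(as.numeric(groups == positive_group), 1, nS)
  tobs <- matrix(t_stats_perms(X, obs_ind), N, K,
                 dimnames = list(ch_names, band_names))

  n1 <- sum(groups == positive_group)
  n_distinct <- choose(nS, n1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  if (n_distinct <= n_perm) {
    warning("only ", n_distinct, " distinct label assignments; ",
            "using exhaustive enumeration instead of ", n_perm,
            " random permutations")
    combs <- combn(nS, n1)
    P1 <- matrix(0, ncol(combs), nS)
    for (i in seq_len(ncol(combs))) P1[i, combs[, i]] <- 1
  } else {
    P1 <- t(replicate(n_perm, {
      v <- numeric(nS); v[sample.int(nS, n1)] <- 1; v
    }))
  }
  n_used <- nrow(P1)
  Tp <- t_stats_perms(X, P1)
  nbr <- lapply(seq_len(N), function(i) which(adjacency$adjacency[i, ]))
  null_max <- vapply(seq_len(n_used), function(i)
    .max_cluster_mass(matrix(Tp[i, ], N, K), nbr, t_threshold), 0)

  rows <- list()
  for (k in seq_len(K)) {
    cl <- find_clusters_1band(tobs[, k], adjacency$adjacency, t_threshold)
    for (ci in cl) {
      pval <- (1 + sum(null_max >= abs(ci$mass))) / (n_used + 1)
      rows[[length(rows) + 1]] <- data.frame(
        band = band_names[k],
        channels = paste(ch_names[ci$channels], collapse = ","),
        n_channels = length(ci$channels),
        sign = ci$sign, mass = ci$mass, p_value = pval,
        stringsAsFactors = FALSE)
    }
  }
  clusters <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(band = character(0), channels = character(0),
               n_channels = integer(0), sign = numeric(0), mass = numeric(0),
               p_value = numeric(0))
  structure(list(clusters = clusters, tmap = tobs, null_max = null_max,
                 t_threshold = t_threshold, n_perm = n_used,
                 groups = gl),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> threshold |T| > %g, %d permutations\n",
              x$t_threshold, x$n_perm))
  if (nrow(x$clusters) == 0) cat("  no supra-threshold clusters\n")
  else print(x$clusters[, c("band", "n_channels", "sign", "mass", "p_value")])
  invisible(x)
}

#' Spearman correlation between band power and behavior, permutation-tested
#'
#' Per band, the Spearman rank correlation between subjects' channel-mean
#' band power and a behavioral score, with a permutation p-value obtained by
#' shuffling the behavior vector across subjects. The Bonferroni-corrected
#' per-band significance threshold `alpha / K` is reported alongside (for the
#' default seven bands and alpha = 0.05 this is 0.05/7 ~ 0.00714).
#'
#' @param band_power Subjects x bands matrix of channel-mean power.
#' @param behavior Behavioral score per subject (finite, non-constant).
#' @param n_perm Number of permutations (default 1024).
#' @param alpha Family-wise level used for the corrected threshold.
#' @param seed Permutation RNG seed.
#' @return A list with `table` (band, rho, p_value), `corrected_alpha`,
#'   `n_perm`.
#' @export
spearman_cluster_correlation <- function(band_power, behavior, n_perm = 1024,
                                         alpha = 0.05, seed = 1L) {
  band_power <- as.matrix(band_power)
  nS <- nrow(band_power)
  if (nS < 5) stop_invalid("need at least 5 subjects")
  if (length(behavior) != nS) stop_invalid("one behavior value per subject")
  if (!all(is.finite(behavior))) stop_invalid("behavior must be finite")
  if (sd(behavior) == 0) stop("behavior vector is constant", call. = FALSE)
  K <- ncol(band_power)
  band_names <- colnames(band_power) %||% paste0("band", seq_len(K))

  br <- rank(behavior)
  Xr <- apply(band_power, 2, rank)
  rho_obs <- as.numeric(cor(br, Xr))

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  null_rho <- matrix(0, n_perm, K)
  for (i in seq_len(n_perm))
    null_rho[i, ] <- cor(br[sample.int(nS)], Xr)
  p <- vapply(seq_len(K), function(k)
    (1 + sum(abs(null_rho[, k]) >= abs(rho_obs[k]))) / (n_perm + 1), 0)
  list(table = data.frame(band = band_names, rho = rho_obs, p_value = p,
                          stringsAsFactors = FALSE),
       corrected_alpha = alpha / K, n_perm = n_perm)
}
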