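# Automatic MTV delineation algorithms. Each method operates on the SUVs
# inside a user-supplied bounding box, returns a single 26-connected mask on
# the full grid, and flags hard failures. All methods are deterministic
# given (volume, box, config).

#' The supported PET auto-segmentation method names
#' @export
PETAS_METHODS <- c("AT", "KM2", "KM3", "KM4", "FCM2", "GCM3", "GCM4",
                   "RG", "WT")

as_segmentation_result <- function(method, grid_shape, mask_sub = NULL,
                                   box = NULL, failed = FALSE,
                                   iterations = 0L, converged = TRUE,
                                   diagnostics = NULL) {
  mask <- if (is.null(mask_sub)) array(FALSE, grid_shape)
          else embed_box(mask_sub, box, grid_shape)
  if (!failed && !any(mask)) failed <- TRUE
  structure(list(method_name = method, mask = mask, failed = failed,
                 iterations_used = as.integer(iterations),
                 converged = converged, diagnostics = diagnostics),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<%s> %s, %d voxels, %d iterations%s\n", x$method_name,
              if (x$failed) "FAILED" else "ok", sum(x$mask),
              x$iterations_used,
              if (isTRUE(x$converged)) "" else " (not converged)"))
  invisible(x)
}

# Initial cluster centres evenly spaced over the observed SUV range.
# Quantile-based placement degenerates on lesion-on-background boxes where
# most voxels share the background value, so value-range spacing is used.
range_centres <- function(x, k) {
  lo <- min(x); hi <- max(x)
  lo + (2 * seq_len(k) - 1) / (2 * k) * (hi - lo)
}

#' Adaptive iterative thresholding (AT) with background subtraction
#'
#' The background level B is the mean SUV of the one-voxel-thick shell just
#' inside the box boundary. Starting from `T0 = B + w (SUVmax - B)`, the
#' threshold is iterated as `T' = B + w (mean{SUV > T} - B)` until it moves
#' by less than `tol`. The MTV is the largest 26-connected component above
#' the converged threshold.
#'
#' @param vol An [suv_volume()].
#' @param box A [bounding_box()].
#' @param tol Convergence tolerance on the threshold (SUV).
#' @param max_iter Maximum threshold iterations.
#' @param w Foreground weight in the threshold update (default 0.5).
#' @return A `segmentation_result`.
#' @export
segment_at <- function(vol, box, tol = 1e-3, max_iter = 100L, w = 0.5) {
  sub <- crop_box(vol$values, box)
  dm <- dim(vol$values)
  if (length(sub) < 8L) stop("box must contain at least 8 voxels")
  B <- mean(sub[shell_mask(dim(sub))])
  Tk <- B + w * (max(sub) - B)
  if (!any(sub > Tk))
    return(as_segmentation_result("AT", dm, failed = TRUE))
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    fg <- sub > Tk
    if (!any(fg))
      return(as_segmentation_result("AT", dm, failed = TRUE, iterations = it))
    Tn <- B + w * (mean(sub[fg]) - B)
    if (abs(Tn - Tk) < tol) { Tk <- Tn; converged <- TRUE; break }
    Tk <- Tn
  }
  if (!converged) warning("AT threshold did not converge in ", max_iter,
                          " iterations")
  msub <- largest_component(sub > Tk)
  as_segmentation_result("AT", dm, msub, box, iterations = it,
                         converged = converged,
                         diagnostics = list(threshold = Tk, background = B))
}

# 1-D Lloyd k-means with deterministic range-spaced initialisation.
km_cluster <- function(x, k, tol = 1e-6, max_iter = 100L) {
  ctr <- range_centres(x, k)
  assign_prev <- rep(0L, length(x))
  it <- 0L
  repeat {
    it <- it + 1L
    d <- abs(outer(x, ctr, `-`))
    asg <- max.col(-d, ties.method = "first")
    newc <- ctr
    for (c in seq_len(k)) if (any(asg == c)) newc[c] <- mean(x[asg == c])
    shift <- max(abs(newc - ctr))
    ctr <- newc
    if (identical(asg, assign_prev) || shift < tol || it >= max_iter) break
    assign_prev <- asg
  }
  list(assignment = asg, centres = ctr, iterations = it)
}

#' K-means clustering segmentation (KM2/KM3/KM4)
#'
#' 1-D k-means on the SUVs inside the box, deterministically initialised at
#' k centres evenly spaced over the SUV range; the MTV is the largest
#' 26-connected component of the highest-mean cluster.
#'
#' @inheritParams segment_at
#' @param k Number of clusters (2, 3 or 4).
#' @param seed Accepted for interface uniformity; the method is
#'   deterministic and does not consume randomness.
#' @export
segment_km <- function(vol, box, k = 2L, seed = NULL) {
  stopifnot(k %in% 2:4)
  sub <- crop_box(vol$values, box)
  dm <- dim(vol$values)
  method <- paste0("KM", k)
  if (length(sub) < k || diff(range(sub)) == 0)
    return(as_segmentation_result(method, dm, failed = TRUE))
  cl <- km_cluster(as.vector(sub), k)
  top <- which.max(cl$centres)
  msub <- array(cl$assignment == top, dim(sub))
  if (!any(msub))
    return(as_segmentation_result(method, dm, failed = TRUE,
                                  iterations = cl$iterations))
  as_segmentation_result(method, dm, largest_component(msub), box,
                         iterations = cl$iterations,
                         diagnostics = list(centres = cl$centres))
}

# Fuzzy c-means in 1-D: memberships u_ij propto d_ij^(-2/(m-1)), centres are
# u^m-weighted means; stops when the largest membership change is < tol.
fcm_cluster <- function(x, k, m = 2, tol = 1e-4, max_iter = 100L) {
  ctr <- range_centres(x, k)
  U <- matrix(1 / k, length(x), k)
  it <- 0L
  repeat {
    it <- it + 1L
    d <- abs(outer(x, ctr, `-`))
    d[d < 1e-12] <- 1e-12
    tmp <- d^(-2 / (m - 1))
    Un <- tmp / rowSums(tmp)
    um <- Un^m
    ctr <- colSums(um * x) / colSums(um)
    delta <- max(abs(Un - U))
    U <- Un
    if (delta < tol || it >= max_iter) break
  }
  list(memberships = U, centres = ctr, iterations = it,
       converged = it < max_iter)
}

#' Fuzzy c-means segmentation (FCM2)
#'
#' Standard fuzzy c-means with fuzziness `m` on the SUVs inside the box;
#' the MTV is the largest 26-connected component of voxels whose membership
#' in the highest-mean cluster exceeds 0.5.
#'
#' @inheritParams segment_km
#' @param m Fuzziness exponent (> 1).
#' @param tol Stop when the largest membership change falls below this.
#' @param max_iter Iteration cap.
#' @export
segment_fcm <- function(vol, box, k = 2L, m = 2, tol = 1e-4,
                        max_iter = 100L) {
  sub <- crop_box(vol$values, box)
  dm <- dim(vol$values)
  if (length(sub) < k || diff(range(sub)) == 0)
    return(as_segmentation_result("FCM2", dm, failed = TRUE))
  cl <- fcm_cluster(as.vector(sub), k, m, tol, max_iter)
  top <- which.max(cl$centres)
  msub <- array(cl$memberships[, top] > 0.5, dim(sub))
  if (!any(msub))
    return(as_segmentation_result("FCM2", dm, failed = TRUE,
                                  iterations = cl$iterations))
  as_segmentation_result("FCM2", dm, largest_component(msub), box,
                         iterations = cl$iterations,
                         converged = cl$converged,
                         diagnostics = list(centres = cl$centres))
}

# 1-D Gaussian mixture EM with range-spaced initial means, shared variance
# floor, log-space responsibilities, stopping on log-likelihood gain < tol.
gmm_em <- function(x, k, tol = 1e-6, max_iter = 200L, var_floor = 1e-6) {
  n <- length(x)
  mu <- range_centres(x, k)
  v <- rep(max(stats::var(x), var_floor), k)
  w <- rep(1 / k, k)
  ll_trace <- numeric(0)
  ll_prev <- -Inf
  it <- 0L
  collapsed <- FALSE
  repeat {
    it <- it + 1L
    logd <- vapply(seq_len(k), function(c)
      stats::dnorm(x, mu[c], sqrt(v[c]), log = TRUE) + log(w[c]),
      numeric(n))
    mx <- logd[, 1]
    for (c in seq_len(k)[-1]) mx <- pmax(mx, logd[, c])
    lse <- mx + log(rowSums(exp(logd - mx)))
    ll <- sum(lse)
    ll_trace <- c(ll_trace, ll)
    R <- exp(logd - lse)
    nk <- colSums(R)
    if (any(nk / n < 1e-8)) { collapsed <- TRUE; break }
    w <- nk / n
    mu <- colSums(R * x) / nk
    v <- pmax(colSums(R * (outer(x, mu, `-`)^2)) / nk, var_floor)
    if (ll - ll_prev < tol && it > 1L) break
    ll_prev <- ll
    if (it >= max_iter) break
  }
  list(means = mu, vars = v, weights = w, resp = R, iterations = it,
       loglik_trace = ll_trace, collapsed = collapsed)
}

#' Gaussian-mixture clustering segmentation (GCM3/GCM4)
#'
#' EM for a 1-D k-component Gaussian mixture on the box SUVs (deterministic
#' range-spaced initial means, equal weights, variance floor); the MTV is
#' the largest 26-connected component of voxels whose maximum-posterior
#' component is the highest-mean component. A component whose weight
#' collapses marks the fit as failed.
#'
#' @inheritParams segment_km
#' @param tol Stop when the log-likelihood gain falls below this.
#' @param max_iter EM iteration cap.
#' @param var_floor Lower bound on component variances (SUV^2).
#' @export
segment_gcm <- function(vol, box, k = 3L, seed = NULL, tol = 1e-4,
                        max_iter = 200L, var_floor = 1e-6) {
  stopifnot(k %in% 3:4)
  sub <- crop_box(vol$values, box)
  dm <- dim(vol$values)
  method <- paste0("GCM", k)
  if (length(sub) < 10L * k)
    stop("box must contain at least 10k voxels for a k-component mixture")
  if (diff(range(sub)) == 0)
    return(as_segmentation_result(method, dm, failed = TRUE))
  fit <- gmm_em(as.vector(sub), k, tol, max_iter, var_floor)
  if (fit$collapsed)
    return(as_segmentation_result(method, dm, failed = TRUE,
                                  iterations = fit$iterations,
                                  diagnostics = fit["loglik_trace"]))
  top <- which.max(fit$means)
  asg <- max.col(fit$resp, ties.method = "first")
  msub <- array(asg == top, dim(sub))
  if (!any(msub))
    return(as_segmentation_result(method, dm, failed = TRUE,
                                  iterations = fit$iterations))
  as_segmentation_result(method, dm, largest_component(msub), box,
                         iterations = fit$iterations,
                         diagnostics = list(means = fit$means,
                                            loglik_trace = fit$loglik_trace))
}

#' Region growing segmentation (RG)
#'
#' Seeds at the maximum-SUV voxel of the box (ties broken by lexicographic
#' voxel order). Each pass admits 26-neighbours of the current region whose
#' SUV is at least a fraction `f` of the current region mean, and growth
#' stops when a pass adds no more than 5% of the voxels already in the
#' region. A region reaching the box boundary is a failure.
#'
#' @inheritParams segment_at
#' @param f Similarity fraction of the region mean (default 0.6).
#' @param stop_frac Growth-termination fraction (default 0.05).
#' @param max_iter Pass cap.
#' @export
segment_rg <- function(vol, box, f = 0.6, stop_frac = 0.05,
                       max_iter = 1000L) {
  sub <- crop_box(vol$values, box)
  dm <- dim(vol$values)
  sdm <- dim(sub)
  shell <- shell_mask(sdm)
  region <- array(FALSE, sdm)
  region[which.max(sub)] <- TRUE
  if (any(region & shell))
    return(as_segmentation_result("RG", dm, failed = TRUE))
  offs <- neighbour_offsets()
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    n_before <- sum(region)
    nb <- array(FALSE, sdm)
    for (r in seq_len(nrow(offs)))
      nb <- nb | shift_padded(region, offs[r, ], FALSE)
    cand <- nb & !region
    adm <- cand & (sub >= f * mean(sub[region]))
    region <- region | adm
    if (any(region & shell))
      return(as_segmentation_result("RG", dm, failed = TRUE,
                                    iterations = it))
    if (sum(adm) <= stop_frac * n_before) break
  }
  as_segmentation_result("RG", dm, region, box, iterations = it)
}

#' Watershed transform segmentation (WT)
#'
#' Computes the 3D Sobel gradient magnitude inside the box and performs a
#' marker-based watershed cut: the foreground marker is the maximum-SUV
#' voxel, the background marker is the box boundary shell, and the
#' catchment split is the minimax cut on the minimum spanning tree of the
#' 6-neighbour voxel graph weighted by mean endpoint gradient. The MTV is
#' the foreground-marker side of the cut.
#'
#' @inheritParams segment_at
#' @export
segment_wt <- function(vol, box) {
  sub <- crop_box(vol$values, box)
  dm <- dim(vol$values)
  sdm <- dim(sub)
  grad <- sobel_gradient(sub)
  shell <- shell_mask(sdm)
  fg <- which.max(sub)
  if (shell[fg])
    return(as_segmentation_result("WT", dm, failed = TRUE))
  n <- length(sub)
  lin <- array(seq_len(n), sdm)
  e1 <- integer(0); e2 <- integer(0); wts <- numeric(0)
  for (ax in 1:3) {
    d <- c(0L, 0L, 0L); d[ax] <- 1L
    src <- lin
    tgt <- shift_padded(lin, d, 0L)
    keep <- tgt > 0L
    e1 <- c(e1, src[keep]); e2 <- c(e2, tgt[keep])
    wts <- c(wts, (grad[src[keep]] + grad[tgt[keep]]) / 2)
  }
  # merge the background shell into one marker with zero-weight chain edges
  sv <- which(shell)
  if (length(sv) > 1L) {
    e1 <- c(e1, sv[-length(sv)]); e2 <- c(e2, sv[-1L])
    wts <- c(wts, rep(0, length(sv) - 1L))
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::add_edges(g, rbind(e1, e2))
  igraph::E(g)$weight <- wts
  tree <- igraph::mst(g)
  path <- igraph::shortest_paths(tree, from = fg, to = sv[1L],
                                 output = "epath")$epath[[1L]]
  pw <- igraph::E(tree)$weight[as.integer(path)]
  if (length(pw) == 0L || max(pw) <= 1e-9)
    return(as_segmentation_result("WT", dm, failed = TRUE))
  cut_edge <- path[which.max(pw)]
  tree2 <- igraph::delete_edges(tree, cut_edge)
  memb <- igraph::components(tree2)$membership
  msub <- array(memb == memb[fg], sdm)
  as_segmentation_result("WT", dm, largest_component(msub), box,
                         diagnostics = list(cut_weight = max(pw)))
}

#' Dispatch a segmentation method by name
#'
#' @inheritParams segment_at
#' @param method One of `AT`, `KM2`, `KM3`, `KM4`, `FCM2`, `GCM3`, `GCM4`,
#'   `RG`, `WT`.
#' @param ... Passed to the underlying method.
#' @export
segment_mtv <- function(vol, box, method, ...) {
  method <- match.arg(method, PETAS_METHODS)
  switch(method,
         AT = segment_at(vol, box, ...),
         KM2 = segment_km(vol, box, k = 2L, ...),
         KM3 = segment_km(vol, box, k = 3L, ...),
         KM4 = segment_km(vol, box, k = 4L, ...),
         FCM2 = segment_fcm(vol, box, k = 2L, ...),
         GCM3 = segment_gcm(vol, box, k = 3L, ...),
         GCM4 = segment_gcm(vol, box, k = 4L, ...),
         RG = segment_rg(vol, box, ...),
         WT = segment_wt(vol, box, ...))
}

#' Automated contour-failure screen
#'
#' Replaces subjective radiologist review with explicit rules: a contour is
#' not representative if (a) the mask is empty or the method flagged a hard
#' failure, (b) it conforms to the bounding box (at least `boundary_frac` of
#' the box boundary voxels are in the mask), or (c), when ground truth is
#' available, its Dice overlap with the truth falls below `dice_min`.
#'
#' @param result A `segmentation_result`.
#' @param box The [bounding_box()] the method ran in.
#' @param truth Optional ground truth (list with a `mask` element).
#' @param boundary_frac Box-boundary occupancy threshold (default 0.20).
#' @param dice_min Dice threshold for "greatly different" (default 0.30).
#' @return TRUE when the contour fails the screen.
#' @export
flag_failed_contour <- function(result, box, truth = NULL,
                                boundary_frac = 0.20, dice_min = 0.30) {
  if (isTRUE(result$failed) || !any(result$mask)) return(TRUE)
  sub <- crop_box(result$mask, box)
  shell <- shell_mask(dim(sub))
  if (sum(sub[shell]) >= boundary_frac * sum(shell)) return(TRUE)
  if (!is.null(truth) && dice(result$mask, truth$mask) < dice_min)
    return(TRUE)
  FALSE
}
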