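#' Scale a contact matrix to a target cis depth
#'
#' Multiplies all counts by a single factor so that the total cis contact
#' count (each unordered bin pair counted once) equals `target`; relative
#' structure is unchanged.
#'
#' @param mat A [contact_matrix()].
#' @param target Target total cis contacts (default 1e8, i.e. 100 million).
#' @return The scaled `contact_matrix`.
#' @export
normalize_depth <- function(mat, target = 1e8) {
  stopifnot(inherits(mat, "contact_matrix"))
  total <- cis_total(mat)
  if (total <= 0) stop("empty contact matrix cannot be depth-normalized")
  mat$counts <- mat$counts * (target / total)
  mat
}

#' Knight-Ruiz matrix balancing
#'
#' Finds positive weights `w` such that the balanced matrix
#' `B[i,j] = w[i] * M[i,j] * w[j]` has all (unmasked) row sums equal to 1.
#' Rows/columns with zero marginal are masked out before balancing and get
#' `NA` weights. The solver is a damped Newton iteration on the balancing
#' equations `x * (M x) = 1`, with a symmetric
#' Sinkhorn-style fixed-point fallback if Newton stalls; both reach the
#' same fixed point.
#'
#' @param mat A [contact_matrix()] (symmetric, non-negative).
#' @param tol Convergence tolerance on `max |rowsum - 1|` of the balanced
#'   matrix.
#' @param max_iter Iteration budget (shared across Newton + fallback).
#' @return A `contact_matrix` whose `counts` are the balanced matrix and
#'   whose `weights` hold the per-bin balancing weights (`NA` at masked
#'   bins); attribute `masked` lists masked bin indices.
#' @export
kr_balance <- function(mat, tol = 1e-8, max_iter = 3000) {
  stopifnot(inherits(mat, "contact_matrix"))
  m <- mat$counts
  n <- nrow(m)
  masked <- which(rowSums(m) == 0)
  keep <- setdiff(seq_len(n), masked)
  if (length(keep) == 0) stop("all rows are empty")
  a <- m[keep, keep, drop = FALSE]

  x <- 1 / sqrt(rowSums(a))
  iter <- 0
  newton_ok <- TRUE
  residual <- function(x) x * as.vector(a %*% x) - 1
  while (iter < max_iter) {
    r <- residual(x)
    if (max(abs(r)) < tol) break
    iter <- iter + 1
    if (newton_ok) {
      ax <- as.vector(a %*% x)
      jac <- a * x            # diag(x) %*% a
      diag(jac) <- diag(jac) + ax
      delta <- tryCatch(solve(jac, -r), error = function(e) NULL)
      if (is.null(delta) || any(!is.finite(delta))) {
        newton_ok <- FALSE
        next
      }
      step <- 1
      while (any(x + step * delta <= 0)) step <- step / 2
      x_new <- x + step * delta
      if (max(abs(residual(x_new))) > 0.9 * max(abs(r)) && step < 1) {
        # Newton stalls against the positivity constraint: switch over
        newton_ok <- FALSE
        next
      }
      x <- x_new
    } else {
      rs <- x * as.vector(a %*% x)
      x <- x / sqrt(rs)
    }
  }
  if (max(abs(residual(x))) >= tol)
    stop(sprintf(
      "KR balancing did not converge in %d iterations (residual %.3g)",
      max_iter, max(abs(residual(x)))))

  w <- rep(NA_real_, n)
  w[keep] <- x
  b <- matrix(0, n, n)
  b[keep, keep] <- a * tcrossprod(x)
  out <- mat
  out$counts <- b
  out$weights <- w
  attr(out, "masked") <- masked
  out
}

#' Directionality index profile
#'
#' For each bin `i`, sums contacts to the `window` bins upstream (`A`) and
#' downstream (`B`) and computes
#' `DI = sign(B - A) * ((A - E)^2 / E + (B - E)^2 / E)` with
#' `E = (A + B) / 2`. Positive DI marks downstream-biased bins (domain
#' starts), negative DI upstream-biased bins (domain ends). Bins with
#' truncated windows (near the matrix edge) are flagged; bins with no
#' coverage (`A + B == 0`) get `NA` (missing, not zero).
#'
#' @param mat A [contact_matrix()].
#' @param window Window size in bins; default `round(2e6 / bin_size)`
#'   (2 Mb worth of bins).
#' @return data.frame of class `di_profile`: `bin`, `start`, `end`, `A`,
#'   `B`, `di`, `truncated`; window and bin size kept as attributes.
#' @export
directionality_index <- function(mat, window = NULL) {
  stopifnot(inherits(mat, "contact_matrix"))
  if (is.null(window)) window <- max(1L, round(2e6 / mat$bin_size))
  if (window < 1) stop("window must be at least 1 bin")
  m <- mat$counts
  n <- nrow(m)
  A <- B <- numeric(n)
  for (i in seq_len(n)) {
    up <- seq(max(1L, i - window), i - 1L)
    dn <- seq(i + 1L, min(n, i + window))
    A[i] <- if (i > 1) sum(m[i, up]) else 0
    B[i] <- if (i < n) sum(m[i, dn]) else 0
  }
  E <- (A + B) / 2
  di <- ifelse(A + B == 0, NA_real_,
               ifelse(A == B, 0,
                      sign(B - A) * ((A - E)^2 / E + (B - E)^2 / E)))
  out <- data.frame(bin = seq_len(n),
                    start = mat$start + (seq_len(n) - 1) * mat$bin_size,
                    end = mat$start + seq_len(n) * mat$bin_size,
                    A = A, B = B, di = di,
                    truncated = seq_len(n) <= window |
                      seq_len(n) > n - window)
  attr(out, "window") <- window
  attr(out, "bin_size") <- mat$bin_size
  attr(out, "chrom") <- mat$chrom
  class(out) <- c("di_profile", "data.frame")
  out
}

#' Decode DI states with a Gaussian hidden Markov model
#'
#' Fits an HMM with Gaussian emissions to the DI sequence by Baum-Welch EM
#' (quantile-based initialization, forward-backward posteriors) and decodes
#' per-bin states. States are relabelled by increasing emission mean as
#' `upstream` (negative DI, domain end), `none`, `downstream` (positive DI,
#' domain start). Missing DI bins are treated as unobserved (posteriors
#' driven by the transition structure). MAP ties are broken toward the
#' unbiased state.
#'
#' @param di A `di_profile` from [directionality_index()] (or a bare
#'   numeric DI vector).
#' @param n_states Number of hidden states (default 3).
#' @param max_iter,tol EM iteration budget and log-likelihood tolerance.
#' @param seed Optional seed (the default initialization is deterministic;
#'   the seed only matters if random restarts are added).
#' @return Object of class `di_hmm`: list with `posterior` (bins x states,
#'   rows sum to 1), `state` (MAP label per bin), `state_levels`, `means`,
#'   `sds`, `transition`, `loglik` (trace), `converged`.
#' @export
fit_hmm <- function(di, n_states = 3, max_iter = 200, tol = 1e-6,
                    seed = NULL) {
  x <- if (inherits(di, "di_profile") || is.data.frame(di)) di$di
       else as.numeric(di)
  anchor <- if (n_states == 3) 2L else NULL
  fit <- .with_seed(seed, .gaussian_hmm_em(x, n_states, max_iter, tol,
                                           anchor_state = anchor))
  ord <- order(fit$means)
  post <- fit$posterior[, ord, drop = FALSE]
  levels <- if (n_states == 3) c("upstream", "none", "downstream")
            else paste0("state", seq_len(n_states))
  colnames(post) <- levels
  # MAP with ties toward the middle (unbiased) state
  mid <- ceiling(n_states / 2)
  map <- apply(post, 1, function(p) {
    top <- which(p == max(p))
    if (length(top) > 1 && mid %in% top) mid else top[1]
  })
  structure(list(posterior = post, state = levels[map],
                 state_levels = levels,
                 means = fit$means[ord], sds = fit$sds[ord],
                 transition = fit$transition[ord, ord, drop = FALSE],
                 loglik = fit$loglik, converged = fit$converged),
            class = "di_hmm")
}

#' @export
print.di_hmm <- function(x, ...) {
  cat("Gaussian-emission HMM over", nrow(x$posterior), "bins\n")
  cat("  state means:", paste(sprintf("%s=%.3g", x$state_levels, x$means),
                              collapse = ", "), "\n")
  cat("  log-likelihood:", utils::tail(x$loglik, 1),
      if (x$converged) "(converged)" else "(not converged)", "\n")
  invisible(x)
}

#' Call topological domains from decoded DI states
#'
#' Merges consecutive bins with identical MAP states into regions, excludes
#' regions spanning fewer than `min_bins` bins or with a median posterior
#' (of their own state) below `min_median_posterior`, and defines each
#' domain as extending from a retained downstream-biased region (the
#' upstream boundary) to the end of the next retained upstream-biased
#' region (the downstream boundary).
#'
#' @param hmm A `di_hmm` from [fit_hmm()].
#' @param di The matching `di_profile` (used for coordinates; optional).
#' @param min_bins Minimum region length in bins (regions with fewer are
#'   excluded).
#' @param min_median_posterior Minimum median posterior probability of the
#'   region's state (regions below are excluded).
#' @return Object of class `tad_set`: list with `domains` (data.frame of
#'   half-open bin-index intervals `start_bin`/`end_bin`, plus bp
#'   coordinates when `di` is supplied), `boundaries` (bin indices),
#'   `regions` (all candidate regions with retention flags) and the filter
#'   settings. No retained regions yields an empty (not an error) set.
#' @export
call_tads <- function(hmm, di = NULL, min_bins = 3,
                      min_median_posterior = 0.99) {
  stopifnot(inherits(hmm, "di_hmm"))
  st <- hmm$state
  r <- rle(st)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  med <- vapply(seq_along(starts), function(i)
    stats::median(hmm$posterior[starts[i]:ends[i], r$values[i]]),
    numeric(1))
  regions <- data.frame(start_bin = starts, end_bin = ends + 1L,
                        n_bins = r$lengths, state = r$values,
                        median_posterior = med,
                        retained = r$lengths >= min_bins &
                          med >= min_median_posterior,
                        stringsAsFactors = FALSE)
  kept <- regions[regions$retained, , drop = FALSE]
  dom_start <- dom_end <- integer(0)
  open <- NA_integer_
  for (i in seq_len(nrow(kept))) {
    if (kept$state[i] == "downstream" && is.na(open))
      open <- kept$start_bin[i]
    else if (kept$state[i] == "upstream" && !is.na(open)) {
      dom_start <- c(dom_start, open)
      dom_end <- c(dom_end, kept$end_bin[i])   # half-open
      open <- NA_integer_
    }
  }
  domains <- data.frame(start_bin = dom_start, end_bin = dom_end,
                        n_bins = dom_end - dom_start)
  if (!is.null(di)) {
    bs <- attr(di, "bin_size")
    origin <- if (nrow(di)) di$start[1] else 0
    domains$start_bp <- origin + (domains$start_bin - 1) * bs
    domains$end_bp <- origin + (domains$end_bin - 1) * bs
  }
  structure(list(domains = domains,
                 boundaries = sort(unique(c(dom_start, dom_end))),
                 regions = regions,
                 min_bins = min_bins,
                 min_median_posterior = min_median_posterior),
            class = "tad_set")
}

#' @export
print.tad_set <- function(x, ...) {
  cat("TAD set:", nrow(x$domains), "domains from",
      sum(x$regions$retained), "retained of", nrow(x$regions),
      "candidate regions\n")
  cat(sprintf("  filters: >= %d bins, median posterior >= %.2f\n",
              x$min_bins, x$min_median_posterior))
  invisible(x)
}

#' Differential contact map
#'
#' Elementwise difference of two identically binned, identically
#' depth-normalized contact matrices (conventionally mutant minus
#' wild type). Swapping the arguments negates the result.
#'
#' @param mat_a Minuend `contact_matrix` (e.g. mutant).
#' @param mat_b Subtrahend `contact_matrix` (e.g. wild type).
#' @return A `contact_matrix`-shaped object of class `diff_contact_matrix`
#'   whose `counts` are the signed differences.
#' @export
differential_contact_map <- function(mat_a, mat_b) {
  stopifnot(inherits(mat_a, "contact_matrix"),
            inherits(mat_b, "contact_matrix"))
  if (!identical(dim(mat_a$counts), dim(mat_b$counts)))
    stop("contact matrices have different shapes")
  if (mat_a$bin_size != mat_b$bin_size)
    stop("contact matrices have different bin sizes")
  out <- mat_a
  out$counts <- mat_a$counts - mat_b$counts
  class(out) <- c("diff_contact_matrix", "contact_matrix")
  out
}
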