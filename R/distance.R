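#' Enhancer element set assigned to a gene cluster
#'
#' Cluster-to-enhancer assignment: alpha -> HS5-1, beta -> HS18-22 (the
#' elements HS18-20, HS21, HS22), gamma -> HS5-1bL. Background genes have
#' no assigned element set.
#'
#' @param cluster Character vector of cluster labels
#'   (`"alpha"`, `"beta"`, `"gamma"`, `"background"`).
#' @return A list (one entry per input) of element-name character vectors;
#'   `NULL` for background genes.
#' @export
assign_enhancer <- function(cluster) {
  map <- list(alpha = "HS5-1",
              beta = c("HS18-20", "HS21", "HS22"),
              gamma = "HS5-1bL",
              background = NULL)
  bad <- setdiff(unique(cluster), names(map))
  if (length(bad)) stop("unknown cluster label(s): ", paste(bad, collapse = ", "))
  out <- map[cluster]
  names(out) <- NULL
  out
}

#' Reference coordinate of an enhancer element set
#'
#' The reference point used on the enhancer side of every distance
#' computation: by default the midpoint of the spanning interval of the set
#' (from the smallest element start to the largest element end); the
#' `"edge"` rule instead uses the edge of the spanning interval nearest to
#' the query anchor.
#'
#' @param elements Character vector of element names.
#' @param annotation A `locus_annotation`.
#' @param rule `"midpoint"` (default) or `"edge"`.
#' @param anchor Query anchor (bp), required for the `"edge"` rule.
#' @return Reference coordinate in bp.
#' @export
enhancer_reference_point <- function(elements, annotation,
                                     rule = c("midpoint", "edge"),
                                     anchor = NULL) {
  rule <- match.arg(rule)
  enh <- annotation$enhancers
  miss <- setdiff(elements, enh$name)
  if (length(miss)) stop("unknown enhancer element(s): ",
                         paste(miss, collapse = ", "))
  sel <- enh[enh$name %in% elements, , drop = FALSE]
  span <- c(min(sel$start), max(sel$end))
  if (rule == "midpoint") return((span[1] + span[2]) / 2)
  if (is.null(anchor)) stop("edge rule requires an anchor")
  if (anchor < span[1]) span[1] else if (anchor >= span[2]) span[2] else anchor
}

#' Promoter-enhancer linear distance
#'
#' Distance in bp between each gene's anchor (5'-UTR position) and the
#' reference point of its assigned enhancer element set. Background genes
#' get `NA`.
#'
#' @param annotation A `locus_annotation`.
#' @param rule Enhancer-side reference rule, see
#'   [enhancer_reference_point()].
#' @return Named numeric vector (names = gene ids) of distances in bp.
#' @export
promoter_enhancer_distance <- function(annotation,
                                       rule = c("midpoint", "edge")) {
  rule <- match.arg(rule)
  genes <- annotation$genes
  if (any(is.na(genes$anchor))) stop("missing gene anchor(s)")
  sets <- assign_enhancer(genes$cluster)
  d <- vapply(seq_len(nrow(genes)), function(i) {
    if (is.null(sets[[i]])) return(NA_real_)
    ref <- enhancer_reference_point(sets[[i]], annotation, rule,
                                    anchor = genes$anchor[i])
    abs(genes$anchor[i] - ref)
  }, numeric(1))
  names(d) <- genes$id
  d
}

#' Pair fold changes with promoter-enhancer distances
#'
#' Inner join of a fold-change table with the clustered genes of the
#' annotation, by gene id. Clustered genes absent from the fold-change
#' table are dropped with a warning; duplicate ids are an error.
#'
#' @param fc A fold-change table from [fold_change()] (columns `id`,
#'   `log2fc`, optionally `modality`).
#' @param annotation A `locus_annotation`.
#' @param rule Distance rule, see [enhancer_reference_point()].
#' @return data.frame with columns `id`, `cluster`, `distance`, `log2fc`
#'   and `modality`.
#' @export
make_pairs <- function(fc, annotation, rule = c("midpoint", "edge")) {
  rule <- match.arg(rule)
  if (anyDuplicated(fc$id)) stop("duplicate gene ids in fold-change table")
  genes <- annotation$genes
  if (anyDuplicated(genes$id)) stop("duplicate gene ids in annotation")
  cl <- genes[genes$cluster != "background", , drop = FALSE]
  d <- promoter_enhancer_distance(annotation, rule)
  keep <- cl$id %in% fc$id
  if (any(!keep))
    warning(sum(!keep), " clustered gene(s) missing from fold-change table; dropped")
  cl <- cl[keep, , drop = FALSE]
  if (nrow(cl) == 0)
    return(data.frame(id = character(), cluster = character(),
                      distance = numeric(), log2fc = numeric(),
                      modality = character(), stringsAsFactors = FALSE))
  i <- match(cl$id, fc$id)
  data.frame(id = cl$id, cluster = cl$cluster,
             distance = unname(d[cl$id]),
             log2fc = fc$log2fc[i],
             modality = if ("modality" %in% names(fc))
               fc$modality[i] else NA_character_,
             stringsAsFactors = FALSE)
}

#' Fit the distance trend of fold changes
#'
#' Ordinary least squares of per-gene log2 fold change on promoter-enhancer
#' distance. Under the generator's exponential contact model (background
#' disabled) the expected slope is `-eta * (1/lambda_mut - 1/lambda_wt) /
#' ln 2` per bp, so the linear fit is the natural estimator of the
#' processivity change (see [recover_processivity_delta()]).
#'
#' @param pairs data.frame from [make_pairs()] (columns `distance`,
#'   `log2fc`).
#' @param conf_level Confidence level for the slope interval.
#' @return An object of class `distance_trend` with methods `print`,
#'   `summary`, `coef`, `predict`, `confint` and `plot`.
#' @export
fit_distance_trend <- function(pairs, conf_level = 0.95) {
  stopifnot(all(c("distance", "log2fc") %in% names(pairs)))
  ok <- is.finite(pairs$distance) & is.finite(pairs$log2fc)
  pairs <- pairs[ok, , drop = FALSE]
  if (nrow(pairs) < 3) stop("need at least 3 finite points to fit a trend")
  fit <- stats::lm(log2fc ~ distance, data = pairs)
  ci <- stats::confint(fit, "distance", level = conf_level)
  structure(list(lm = fit,
                 slope = unname(stats::coef(fit)["distance"]),
                 intercept = unname(stats::coef(fit)["(Intercept)"]),
                 slope_ci = as.numeric(ci),
                 conf_level = conf_level,
                 n = nrow(pairs),
                 modality = if ("modality" %in% names(pairs))
                   pairs$modality[1] else NA_character_,
                 pairs = pairs),
            class = "distance_trend")
}

#' @export
print.distance_trend <- function(x, ...) {
  cat("Distance trend of log2 fold change",
      if (!is.na(x$modality)) sprintf("(%s)", x$modality) else "", "\n")
  cat(sprintf("  slope: %.4g per bp (%g%% CI %.4g .. %.4g), n = %d\n",
              x$slope, 100 * x$conf_level, x$slope_ci[1], x$slope_ci[2], x$n))
  invisible(x)
}

#' @export
summary.distance_trend <- function(object, ...) summary(object$lm, ...)

#' @export
coef.distance_trend <- function(object, ...) stats::coef(object$lm)

#' @export
predict.distance_trend <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::predict(object$lm, ...))
  if (is.numeric(newdata)) newdata <- data.frame(distance = newdata)
  stats::predict(object$lm, newdata = newdata, ...)
}

#' @export
confint.distance_trend <- function(object, parm = "distance",
                                   level = object$conf_level, ...) {
  stats::confint(object$lm, parm = parm, level = level, ...)
}

#' @export
plot.distance_trend <- function(x, ...) {
  plot(x$pairs$distance, x$pairs$log2fc, xlab = "promoter-enhancer distance (bp)",
       ylab = "log2 fold change", ...)
  graphics::abline(x$lm, col = "red3")
  smoother <- try(stats::lowess(x$pairs$distance, x$pairs$log2fc), silent = TRUE)
  if (!inherits(smoother, "try-error"))
    graphics::lines(smoother, col = "grey40", lty = 2)
  invisible(x)
}

#' Invert a distance trend to a processivity change
#'
#' Under the generator model the fitted slope equals
#' `-eta * Delta(1/lambda) / ln 2`, so
#' `Delta(1/lambda) = -slope * ln 2 / eta`, and given the wild-type mean
#' extruded length the implied mutant value is
#' `lambda_mut = 1 / (1/lambda_wt + Delta(1/lambda))`. A positive
#' `Delta(1/lambda)` means reduced processivity.
#'
#' @param fit A `distance_trend` (or a bare numeric slope, per bp).
#' @param lambda_wt Assumed wild-type mean extruded length (bp).
#' @param eta Expression-coupling exponent used by the generator.
#' @return Object of class `processivity_delta`: list with
#'   `delta_inv_lambda` (per bp), `lambda_mut` (bp), `lambda_wt`,
#'   `consistent` (FALSE when the implied `lambda_mut` is non-positive).
#' @export
recover_processivity_delta <- function(fit, lambda_wt = 400000, eta = 1) {
  slope <- if (inherits(fit, "distance_trend")) fit$slope else as.numeric(fit)
  if (!is.finite(slope)) stop("slope is not finite")
  if (eta == 0) stop("eta = 0 carries no distance information")
  delta <- -slope * log(2) / eta
  inv_mut <- 1 / lambda_wt + delta
  lambda_mut <- if (inv_mut > 0) 1 / inv_mut else NA_real_
  structure(list(delta_inv_lambda = delta, lambda_mut = lambda_mut,
                 lambda_wt = lambda_wt, eta = eta, slope = slope,
                 consistent = inv_mut > 0),
            class = "processivity_delta")
}

#' @export
print.processivity_delta <- function(x, ...) {
  cat("Processivity change implied by distance trend\n")
  cat(sprintf("  Delta(1/lambda): %.4g per bp (%s processivity)\n",
              x$delta_inv_lambda,
              if (x$delta_inv_lambda > 0) "reduced" else "increased"))
  if (x$consistent)
    cat(sprintf("  implied lambda_mut: %.0f bp (given lambda_wt = %.0f bp)\n",
                x$lambda_mut, x$lambda_wt))
  else cat("  inconsistent: implied 1/lambda_mut <= 0\n")
  invisible(x)
}

#' Per-cluster fold-change contrast
#'
#' Summarizes log2 fold changes per cluster (mean, median) with bootstrap
#' confidence intervals for the mean, and reports the cluster ordering.
#'
#' @param fc Fold-change table (columns `id`, `log2fc`).
#' @param annotation A `locus_annotation`.
#' @param n_boot Number of bootstrap resamples (must be >= 1).
#' @param conf_level Confidence level.
#' @return data.frame with one row per cluster: `cluster`, `n`, `mean`,
#'   `median`, `ci_lo`, `ci_hi`; attribute `ordering` gives cluster names
#'   sorted by increasing mean log2FC. Empty clusters are flagged with
#'   `n = 0` and `NA` summaries.
#' @export
cluster_contrast <- function(fc, annotation, n_boot = 1000,
                             conf_level = 0.95) {
  if (n_boot < 1) stop("n_boot must be at least 1")
  genes <- annotation$genes
  cl <- genes[genes$cluster != "background", , drop = FALSE]
  x <- fc$log2fc[match(cl$id, fc$id)]
  alpha2 <- (1 - conf_level) / 2
  out <- do.call(rbind, lapply(c("alpha", "beta", "gamma"), function(k) {
    v <- x[cl$cluster == k & !is.na(x)]
    if (length(v) == 0) {
      warning("empty cluster: ", k)
      return(data.frame(cluster = k, n = 0L, mean = NA_real_,
                        median = NA_real_, ci_lo = NA_real_,
                        ci_hi = NA_real_, stringsAsFactors = FALSE))
    }
    boots <- vapply(seq_len(n_boot), function(b)
      mean(sample(v, length(v), replace = TRUE)), numeric(1))
    data.frame(cluster = k, n = length(v), mean = mean(v),
               median = stats::median(v),
               ci_lo = unname(stats::quantile(boots, alpha2)),
               ci_hi = unname(stats::quantile(boots, 1 - alpha2)),
               stringsAsFactors = FALSE)
  }))
  attr(out, "ordering") <- out$cluster[order(out$mean)]
  out
}
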